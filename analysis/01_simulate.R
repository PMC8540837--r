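#!/usr/bin/env Rscript
# Stage 0: generate every synthetic input the downstream analyses consume,
# with ground-truth sidecars. All seeds are fixed so the whole workflow is
# reproducible end to end.

suppressMessages(library(peatmox))
suppressMessages(library(jsonlite))

outdir <- "results/simdata"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
message("writing synthetic inputs to ", outdir)

## 1. Closed-bottle CH4 decay series: 24 soil microcosms, 2 temperatures x
##    2 CH4 levels, four measurements over 24 h, 5% multiplicative GC noise.
set.seed(101)
design <- expand.grid(temp_C = c(8, 15), ch4 = c("0.1%", "1%"), rep = 1:6)
design$bottle_id <- paste0("b", seq_len(nrow(design)))
design$k_true <- runif(nrow(design), 0.01, 0.12)
meas <- do.call(rbind, lapply(seq_len(nrow(design)), function(i) {
  c0 <- if (design$ch4[i] == "0.1%") 1000 else 10000
  s <- gen_gas_series(design$k_true[i], c0, times_h = c(0, 8, 16, 24),
                      noise_sd = 0.05)
  data.frame(bottle_id = design$bottle_id[i], time_h = s$times_h,
             ch4_ppm = s$ch4_ppm)
}))
bottles <- data.frame(bottle_id = design$bottle_id, total_mL = 50,
                      liquid_mL = 0, temp_C = design$temp_C,
                      ch4_level = design$ch4, fresh_g = 4,
                      water_fraction = 0.8)
write_tsv_table(meas, file.path(outdir, "measurements.tsv"))
write_tsv_table(bottles, file.path(outdir, "bottles.tsv"))
write_json(design, file.path(outdir, "gas_truth.json"), digits = NA)

## 2. qPCR dilution standard (7 decades, triplicate, 0.15-cycle noise) and
##    four unknown samples with known transcript loads.
std <- gen_dilution_cq(slope = -3.4, intercept = 38, noise_sd_cq = 0.15,
                       seed = 102)
write_tsv_table(data.frame(copies = std$copies, cq = std$cq),
                file.path(outdir, "qpcr_standard.tsv"))
set.seed(103)
true_copies <- 10^runif(4, 2.5, 5.5)
samples <- do.call(rbind, lapply(1:4, function(i)
  data.frame(sample_id = paste0("q", i), replicate = 1:3,
             cq = 38 - 3.4 * log10(true_copies[i]) + rnorm(3, 0, 0.15))))
write_tsv_table(samples, file.path(outdir, "qpcr_samples.tsv"))
write_json(list(true_copies_per_reaction = true_copies),
           file.path(outdir, "qpcr_truth.json"), digits = NA)

## 3. pmoA-like amplicons: 5 reference ORFs, 800 reads, planted defects.
refs <- gen_reference_orfs(5, 465, seed = 104, prefix = "pmoA_ref")
write_fasta(refs, file.path(outdir, "reference_orfs.fasta"))
amp <- gen_amplicons(refs, 800,
                     list(stop_codon = 0.05, frameshift = 0.05,
                          low_quality_window = 0.10), seed = 105)
write_fastq(amp$reads, file.path(outdir, "amplicons.fastq"))
write_tsv_table(amp$truth, file.path(outdir, "amplicon_truth.tsv"))

## 4. Two-treatment OTU tables with the planted 7-vs-1 (grazed) and 4-vs-1
##    (exclosed) indicator structure, mid-rank taxa, 8-fold effect.
cfg <- pipeline_config()
for (tr in c("grazed", "exclosed")) {
  planted <- cfg[[paste0("indicators_", tr)]]
  cm <- gen_community(n_per_group = 8, n_otus = 50, indicators = planted,
                      depth = 5000, seed = if (tr == "grazed") 106 else 107)
  tab <- data.frame(sample = rownames(cm$counts), group = cm$metadata$group,
                    cm$counts, check.names = FALSE)
  write_tsv_table(tab, file.path(outdir, paste0("otu_", tr, ".tsv")))
  write_tsv_table(planted, file.path(outdir, paste0("otu_", tr, "_truth.tsv")))
}

## 5. Alignment for the phylogeny stage: JC evolution along a known 8-taxon
##    tree, 452 columns (the analysed section length).
set.seed(108)
true_tree <- ape::rtree(8, tip.label = paste0("otu", 21:28))
true_tree$edge.length <- true_tree$edge.length * 0.1
aln <- evolve_sequences(true_tree, 452, seed = 109)
write_fasta(apply(unclass(aln), 1, paste0, collapse = ""),
            file.path(outdir, "bioindicator_alignment.fasta"))
write_newick(true_tree, file.path(outdir, "true_tree.nwk"))

message("done: ", length(list.files(outdir)), " files")
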