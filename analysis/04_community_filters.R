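#!/usr/bin/env Rscript
# Stage 3: amplicon post-processing: sliding-window quality filter, reading
# frame / stop-codon screen, length windows, taxonomy by best alignment, and
# community normalisation (relative abundance, 1/1000 denoising, log
# transform) for both treatments.

suppressMessages(library(peatmox))
suppressMessages(library(jsonlite))

simdir <- "results/simdata"
if (!file.exists(file.path(simdir, "amplicons.fastq")))
  stop("run analysis/01_simulate.R first")

reads <- read_fastq(file.path(simdir, "amplicons.fastq"))
message(length(reads$ids), " input reads")

qf <- quality_window_filter(reads)
message(nrow(qf$rejected), " reads failed the 50-nt / Q20 window filter")

verdicts <- lapply(qf$kept$sequences, frame_stop_filter)
pass_frame <- vapply(verdicts, `[[`, logical(1), "pass")
message(sum(!pass_frame), " reads failed the frame/stop screen (",
        sum(vapply(verdicts, `[[`, character(1), "reason") == "framing"),
        " framing, ",
        sum(vapply(verdicts, `[[`, character(1), "reason") == "stop_codon"),
        " stop codons)")

kept <- qf$kept$sequences[pass_frame]
in_window <- length_window_filter(nchar(kept), "mb661R")
message(sum(!in_window), " representatives outside the mb661R length window")
kept <- kept[in_window]

# the planted truth says which reads should have survived
truth <- read_tsv_table(file.path(simdir, "amplicon_truth.tsv"))
expected <- sum(truth$defect == "none")
message(sprintf("surviving reads: %d (expected from truth: %d)",
                length(kept), expected))

db <- reference_db(paste0("Methylococcaceae;", names(
  read_fasta(file.path(simdir, "reference_orfs.fasta")))),
  read_fasta(file.path(simdir, "reference_orfs.fasta")), "mb661R")
tax <- lapply(unique(kept), assign_taxonomy, db = db)
message(sprintf("taxonomy assigned to %d unique sequences; all >= %.1f%% identity",
                length(tax), min(vapply(tax, `[[`, numeric(1),
                                        "percent_identity"))))

report <- list(input = length(reads$ids),
               low_quality = nrow(qf$rejected),
               frame_or_stop = sum(!pass_frame),
               out_of_window = sum(!in_window),
               surviving = length(kept))

# community normalisation for both treatments
dir.create("results/normalized", showWarnings = FALSE, recursive = TRUE)
for (tr in c("grazed", "exclosed")) {
  tab <- read_tsv_table(file.path(simdir, paste0("otu_", tr, ".tsv")))
  counts <- as.matrix(tab[, -(1:2)])
  rownames(counts) <- tab$sample
  rel <- to_relative_abundance(counts)
  dn <- denoise(rel, counts, threshold = 1e-3)
  message(sprintf("%s: denoising removed %.2f%% of reads (%d entries)",
                  tr, 100 * dn$removed_fraction, dn$n_zeroed))
  report[[paste0("denoise_removed_", tr)]] <- dn$removed_fraction
  out <- data.frame(sample = rownames(dn$rel), group = tab$group,
                    dn$rel, check.names = FALSE)
  write_tsv_table(out, file.path("results/normalized",
                                 paste0("otu_", tr, "_relative.tsv")))
}

write_json(report, "results/filter_report.json", auto_unbox = TRUE,
           digits = NA)
message("wrote results/filter_report.json and results/normalized/")
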