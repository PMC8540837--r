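# Readers/writers for the plain-text formats the pipeline exchanges.
# Sequence formats go through Biostrings; tables are plain TSV.

#' Read and write tab-separated tables
#'
#' @param path File path.
#' @return `read_tsv_table`: a data.frame.
#' @export
read_tsv_table <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname read_tsv_table
#' @param x A data.frame.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' FASTQ input/output for amplicon reads
#'
#' @param path FASTQ file path.
#' @return `read_fastq`: an [amplicon_reads()] object.
#' @export
read_fastq <- function(path) {
  # Biostrings warns about dropping its own FASTQ metadata columns; harmless
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  quals <- as(Biostrings::quality(x), "IntegerList")
  amplicon_reads(names(x), as.character(x), as.list(quals))
}

#' @rdname read_fastq
#' @param reads An [amplicon_reads()] object.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(inherits(reads, "amplicon_reads"))
  seqs <- Biostrings::DNAStringSet(reads$sequences)
  names(seqs) <- reads$ids
  qual <- Biostrings::PhredQuality(
    vapply(reads$qualities,
           function(q) paste(rawToChar(as.raw(q + 33L), multiple = TRUE),
                             collapse = ""),
           character(1)))
  x <- Biostrings::QualityScaledDNAStringSet(seqs, qual)
  Biostrings::writeQualityScaledXStringSet(x, path)
  invisible(path)
}

#' FASTA input/output
#'
#' @param path FASTA file path.
#' @return `read_fasta`: a named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param sequences Named character vector of DNA strings.
#' @export
write_fasta <- function(sequences, path) {
  x <- Biostrings::DNAStringSet(sequences)
  names(x) <- names(sequences)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Fit per-bottle oxidation rates from long-format measurement tables
#'
#' Joins a long measurement table (`bottle_id`, `time_h`, `ch4_ppm`) with a
#' bottle-metadata table (`bottle_id`, `total_mL`, `liquid_mL`, `temp_C`,
#' optional `gas_sample_mL`, `liquid_sample_uL`, `fresh_g`, `water_fraction`)
#' and fits the first-order rate constant for every bottle. When soil masses
#' are present, the dry-weight-normalised oxidation rate is added, computed
#' from the fitted initial headspace mass over the first day
#' (k x mass(c0), converted to ug/g dry weight/day).
#'
#' @param measurements data.frame of measurements.
#' @param bottles data.frame of bottle metadata.
#' @param henry [henry_params()] for dissolved-phase terms.
#' @return data.frame, one row per bottle: `bottle_id`, `k_per_h`, `r2`,
#'   `n`, `degenerate`, and where soil data allow, `rate_ug_per_gdw_d`.
#' @export
bottle_rates <- function(measurements, bottles, henry = henry_params()) {
  need <- c("bottle_id", "time_h", "ch4_ppm")
  if (!all(need %in% names(measurements)))
    stop("measurements need columns: ", paste(need, collapse = ", "))
  if (!all(c("bottle_id", "total_mL", "temp_C") %in% names(bottles)))
    stop("bottles need at least bottle_id, total_mL, temp_C")
  rows <- lapply(seq_len(nrow(bottles)), function(i) {
    b <- bottles[i, ]
    m <- measurements[measurements$bottle_id == b$bottle_id, , drop = FALSE]
    if (nrow(m) < 2) stop("bottle ", b$bottle_id, ": fewer than 2 measurements")
    m <- m[order(m$time_h), ]
    spec <- bottle_spec(b$total_mL,
                        if ("liquid_mL" %in% names(b) && !is.na(b$liquid_mL))
                          b$liquid_mL else 0,
                        b$temp_C)
    s <- gas_timeseries(m$time_h, m$ch4_ppm, spec,
                        gas_sample_mL = if ("gas_sample_mL" %in% names(b) &&
                                            !is.na(b$gas_sample_mL))
                          b$gas_sample_mL else 0,
                        liquid_sample_mL = if ("liquid_sample_uL" %in% names(b) &&
                                               !is.na(b$liquid_sample_uL))
                          b$liquid_sample_uL / 1000 else 0)
    fit <- fit_first_order(s)
    out <- data.frame(bottle_id = b$bottle_id, k_per_h = fit$k,
                      r2 = fit$r_squared, n = fit$n_points,
                      degenerate = fit$degenerate)
    if (all(c("fresh_g", "water_fraction") %in% names(b)) &&
        !is.na(b$fresh_g) && !is.na(b$water_fraction)) {
      soil <- soil_context(b$fresh_g, b$water_fraction)
      c0 <- exp(fit$intercept)
      mass0 <- total_ch4_mass(spec, c0, henry)
      out$rate_ug_per_gdw_d <- rate_per_dry_weight(fit$k * mass0, soil)
    }
    out
  })
  do.call(rbind, rows)
}
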