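#' Amplicon read set
#'
#' Container for primer-trimmed amplicon reads with per-base Phred scores.
#'
#' @param ids Character read identifiers (unique).
#' @param sequences Character DNA strings (alphabet ACGTN).
#' @param qualities List of integer Phred vectors, one per read, each the
#'   same length as its sequence.
#' @return Object of class `amplicon_reads`.
#' @export
amplicon_reads <- function(ids, sequences, qualities) {
  if (length(ids) != length(sequences) || length(ids) != length(qualities))
    stop("ids, sequences and qualities must have equal length")
  if (anyDuplicated(ids)) stop("read ids must be unique")
  bad <- which(nchar(sequences) != lengths(qualities))
  structure(list(ids = as.character(ids),
                 sequences = toupper(as.character(sequences)),
                 qualities = qualities,
                 length_mismatch = ids[bad]),
            class = "amplicon_reads")
}

#' @export
print.amplicon_reads <- function(x, ...) {
  cat(sprintf("<amplicon_reads> %d reads, lengths %d-%d nt\n",
              length(x$ids), min(nchar(x$sequences)), max(nchar(x$sequences))))
  invisible(x)
}

#' Sliding-window quality filter
#'
#' Discards a read iff any 50-nt sliding window (step 1) has a mean Phred
#' score below 20; reads shorter than the window are judged on their full
#' length. Reads whose quality vector does not match the sequence length are
#' rejected with reason `length_mismatch`.
#'
#' @param reads An [amplicon_reads()] object.
#' @param window Window length in nucleotides.
#' @param min_mean_q Minimum acceptable mean Phred score within any window.
#' @return List with `kept` (an `amplicon_reads` subset) and `rejected`
#'   (data.frame `id`, `reason`).
#' @export
quality_window_filter <- function(reads, window = 50, min_mean_q = 20) {
  stopifnot(inherits(reads, "amplicon_reads"))
  n <- length(reads$ids)
  keep <- logical(n)
  reason <- character(n)
  for (i in seq_len(n)) {
    q <- reads$qualities[[i]]
    if (length(q) != nchar(reads$sequences[i])) {
      reason[i] <- "length_mismatch"
      next
    }
    if (length(q) <= window) {
      ok <- mean(q) >= min_mean_q
    } else {
      # rolling mean via cumulative sums: all windows of length `window`
      cs <- cumsum(c(0, q))
      win_means <- (cs[(window + 1):(length(q) + 1)] -
                    cs[1:(length(q) - window + 1)]) / window
      ok <- all(win_means >= min_mean_q)
    }
    keep[i] <- ok
    if (!ok) reason[i] <- "low_quality_window"
  }
  kept <- amplicon_reads(reads$ids[keep], reads$sequences[keep],
                         reads$qualities[keep])
  list(kept = kept,
       rejected = data.frame(id = reads$ids[!keep],
                             reason = reason[!keep]))
}

.IUPAC_DNA <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                "B", "D", "H", "V", "N", "-")

#' Reading-frame and stop-codon screen
#'
#' A protein-coding amplicon must translate cleanly: the screen fails a
#' sequence whose length is not divisible by three (a frameshift indel) or
#' that contains an in-frame stop codon (TAA/TAG/TGA, bacterial code).
#'
#' @param sequence A DNA string (IUPAC alphabet).
#' @param frame_offset Codon phase of the first base (0, 1 or 2); 0 for
#'   primer-trimmed in-frame amplicons.
#' @return List: `pass` (logical) and `reason` (`""`, `"framing"` or
#'   `"stop_codon"`).
#' @export
frame_stop_filter <- function(sequence, frame_offset = 0) {
  sequence <- toupper(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  if (!all(chars %in% .IUPAC_DNA))
    stop("non-IUPAC characters in sequence: ",
         paste(unique(chars[!chars %in% .IUPAC_DNA]), collapse = ", "))
  if (!frame_offset %in% 0:2) stop("frame_offset must be 0, 1 or 2")
  n <- nchar(sequence)
  if (n %% 3L != 0L) return(list(pass = FALSE, reason = "framing"))
  n_codons <- (n - frame_offset) %/% 3L
  if (n_codons > 0) {
    starts <- frame_offset + 3L * (seq_len(n_codons) - 1L) + 1L
    codons <- substring(sequence, starts, starts + 2L)
    if (any(codons %in% c("TAA", "TAG", "TGA")))
      return(list(pass = FALSE, reason = "stop_codon"))
  }
  list(pass = TRUE, reason = "")
}

# Inclusive OTU representative-length windows per pmoA primer set
.LENGTH_WINDOWS <- list(mb661R = c(465L, 474L), A682R = c(492L, 495L))

#' OTU length-window filter
#'
#' Keeps an OTU whose representative sequence length falls inside the
#' primer-set-specific window (inclusive): 465-474 nt for mb661R, 492-495 nt
#' for A682R. Lengths outside the window flag obvious sequencing errors.
#'
#' @param sequence Representative DNA string (or an integer length).
#' @param primer_set `"mb661R"` or `"A682R"`.
#' @return Logical pass/fail.
#' @export
length_window_filter <- function(sequence, primer_set = c("mb661R", "A682R")) {
  primer_set <- match.arg(primer_set)
  len <- if (is.character(sequence)) nchar(sequence) else as.integer(sequence)
  w <- .LENGTH_WINDOWS[[primer_set]]
  len >= w[1] & len <= w[2]
}

#' Convert an OTU count table to relative abundances
#'
#' @param counts Samples x OTUs non-negative matrix.
#' @return Matrix of the same shape with rows summing to 1 (empty samples
#'   stay zero and are listed in the `empty_samples` attribute).
#' @export
to_relative_abundance <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  rs <- rowSums(counts)
  rel <- counts
  nz <- rs > 0
  rel[nz, ] <- counts[nz, , drop = FALSE] / rs[nz]
  empty <- rownames(counts)[!nz]
  if (is.null(empty)) empty <- which(!nz)
  if (any(!nz)) warning("empty sample(s) left as all-zero rows")
  attr(rel, "empty_samples") <- empty
  rel
}

#' Denoise low-abundance OTU entries
#'
#' Sets to zero, per sample, every entry whose relative abundance is
#' strictly below `threshold` (default one thousandth of the community),
#' then renormalises the surviving entries. Reports the fraction of the
#' original reads removed (computed from `counts` when supplied, else from
#' the relative matrix assuming equal depths).
#'
#' @param rel Samples x OTUs relative-abundance matrix (rows sum to 1 or 0).
#' @param counts Optional matching count matrix for the read-fraction report.
#' @param threshold Relative-abundance cutoff in (0, 1).
#' @return List: `rel` (denoised, renormalised), `removed_fraction`,
#'   `n_zeroed` (entries zeroed).
#' @export
denoise <- function(rel, counts = NULL, threshold = 1e-3) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  rel <- as.matrix(rel)
  drop_mask <- rel < threshold & rel > 0
  if (!is.null(counts)) {
    counts <- as.matrix(counts)
    if (!all(dim(counts) == dim(rel))) stop("counts and rel dimensions differ")
    removed <- sum(counts[drop_mask]) / sum(counts)
  } else {
    removed <- mean(rowSums(rel * drop_mask))
  }
  rel[drop_mask] <- 0
  rs <- rowSums(rel)
  nz <- rs > 0
  rel[nz, ] <- rel[nz, , drop = FALSE] / rs[nz]
  list(rel = rel, removed_fraction = removed, n_zeroed = sum(drop_mask))
}

#' Logarithmic community normalisation
#'
#' Maps positive entries x to log_b(x) + 1 and keeps zeros at zero, the
#' standard decostand-style "log" transform used before ordination. Applied
#' to whatever matrix is supplied (counts or relative abundances); values in
#' (0, 1) produce negatives, which triggers a warning.
#'
#' @param x Non-negative matrix.
#' @param base Logarithm base (default 2).
#' @return Transformed matrix.
#' @export
log_normalize <- function(x, base = 2) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("log normalisation requires non-negative entries")
  if (base <= 0 || base == 1) stop("invalid logarithm base")
  pos <- x > 0
  if (any(x[pos] < 1))
    warning("entries in (0, 1) map to negative values under log_b(x) + 1")
  out <- x
  out[pos] <- log(x[pos], base = base) + 1
  out
}
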