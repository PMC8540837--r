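#' Reference database of trimmed pmoA sequences
#'
#' @param taxonomy Character taxonomy paths, one per entry.
#' @param sequences Character DNA strings trimmed to the primer window.
#' @param primer_set Primer-set tag, `"mb661R"` or `"A682R"`.
#' @return Object of class `reference_db`.
#' @export
reference_db <- function(taxonomy, sequences,
                         primer_set = c("mb661R", "A682R")) {
  primer_set <- match.arg(primer_set)
  if (length(taxonomy) != length(sequences))
    stop("taxonomy and sequences must have equal length")
  if (length(sequences) == 0) stop("reference database is empty")
  structure(list(taxonomy = as.character(taxonomy),
                 sequences = toupper(as.character(sequences)),
                 primer_set = primer_set),
            class = "reference_db")
}

#' Assign taxonomy by best global alignment
#'
#' Aligns the OTU's dominant (representative) sequence globally against every
#' database entry (Needleman-Wunsch via Biostrings) and returns the taxonomy
#' of the best-scoring entry. Percent identity is matches divided by
#' alignment columns. Score ties are broken by database order and flagged.
#'
#' @param sequence Representative DNA string.
#' @param db A [reference_db()].
#' @param match,mismatch,gap_opening,gap_extension Alignment scoring.
#' @return List: `taxonomy`, `percent_identity`, `best_index`, `tie`
#'   (logical).
#' @export
assign_taxonomy <- function(sequence, db, match = 1, mismatch = -1,
                            gap_opening = 2, gap_extension = 1) {
  stopifnot(inherits(db, "reference_db"))
  sub_mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = FALSE)
  alns <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(db$sequences),
    subject = Biostrings::DNAString(toupper(sequence)),
    type = "global", substitutionMatrix = sub_mat,
    gapOpening = gap_opening, gapExtension = gap_extension)
  scores <- Biostrings::score(alns)
  best <- which.max(scores)
  tie <- sum(scores == scores[best]) > 1
  if (tie) best <- which(scores == scores[best])[1]
  aln <- alns[best]
  pid <- Biostrings::nmatch(aln) / Biostrings::nchar(aln) * 100
  list(taxonomy = db$taxonomy[best], percent_identity = as.numeric(pid),
       best_index = best, tie = tie)
}
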