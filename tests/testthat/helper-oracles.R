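# Independent brute-force oracles the implementation is checked against.

# IndVal by direct evaluation of the definition, one OTU and group at a time.
oracle_indval <- function(x, groups) {
  groups <- factor(groups)
  lev <- levels(groups)
  iv <- matrix(0, ncol(x), length(lev),
               dimnames = list(colnames(x), lev))
  for (i in seq_len(ncol(x))) {
    mns <- sapply(lev, function(g) mean(x[groups == g, i]))
    for (j in seq_along(lev)) {
      A <- if (sum(mns) > 0) mns[j] / sum(mns) else 0
      B <- mean(x[groups == lev[j], i] > 0)
      iv[i, j] <- A * B
    }
  }
  iv
}

# Quality-window decision by explicit enumeration of every window.
oracle_window_fails <- function(q, window = 50, min_q = 20) {
  n <- length(q)
  if (n <= window) return(mean(q) < min_q)
  any(sapply(seq_len(n - window + 1),
             function(s) mean(q[s:(s + window - 1)]) < min_q))
}

# Random reads with uniform random qualities for property tests.
random_reads <- function(n, len_range = c(40, 300), q_range = c(5, 40),
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lens <- sample(len_range[1]:len_range[2], n, replace = TRUE)
  amplicon_reads(
    ids = paste0("r", seq_len(n)),
    sequences = vapply(lens, function(L)
      paste0(sample(c("A", "C", "G", "T"), L, replace = TRUE),
             collapse = ""), character(1)),
    qualities = lapply(lens, function(L)
      sample(q_range[1]:q_range[2], L, replace = TRUE)))
}

# Alignment as ape DNAbin, for cross-checks against ape's estimators.
aln_to_dnabin <- function(aln) {
  m <- unclass(aln)
  ape::as.DNAbin(tolower(m))
}
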