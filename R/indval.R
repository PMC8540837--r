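#' Dufrene-Legendre indicator value analysis
#'
#' For OTU i and group j, specificity A_ij is the mean abundance of i in j
#' divided by the sum of its group mean abundances, fidelity B_ij is the
#' fraction of samples in j where i occurs, and IndVal_ij = A_ij x B_ij.
#' The indicator value of an OTU is its maximum over groups, attained in its
#' best group.
#'
#' @param x Samples x OTUs abundance matrix (relative or raw).
#' @param groups Factor (or vector) of group labels, one per sample; every
#'   group must contain at least two samples.
#' @return Object of class `indval_result`: matrices `A`, `B`, `indval`
#'   (OTUs x groups), `best_group`, `indval_max`, `groups`.
#' @examples
#' x <- rbind(matrix(c(5, 0), 4, 2, byrow = TRUE),
#'            matrix(c(0, 5), 4, 2, byrow = TRUE))
#' indval(x, rep(c("low", "high"), each = 4))$indval_max  # 1, 1
#' @export
indval <- function(x, groups) {
  x <- as.matrix(x)
  groups <- factor(groups)
  if (length(groups) != nrow(x))
    stop("one group label per sample (matrix row) required")
  sizes <- table(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(sizes < 2)) stop("every group needs at least 2 samples")
  lev <- levels(groups)
  n_otu <- ncol(x)
  means <- matrix(0, length(lev), n_otu)      # groups x otus
  occ <- matrix(0, length(lev), n_otu)
  for (j in seq_along(lev)) {
    xg <- x[groups == lev[j], , drop = FALSE]
    means[j, ] <- colMeans(xg)
    occ[j, ] <- colMeans(xg > 0)
  }
  tot <- colSums(means)
  A <- t(means) / ifelse(tot > 0, tot, NA_real_)   # otus x groups
  A[is.na(A)] <- 0                                  # absent OTUs: IndVal 0
  B <- t(occ)
  iv <- A * B
  colnames(A) <- colnames(B) <- colnames(iv) <- lev
  if (!is.null(colnames(x)))
    rownames(A) <- rownames(B) <- rownames(iv) <- colnames(x)
  best <- lev[max.col(iv, ties.method = "first")]
  structure(list(A = A, B = B, indval = iv,
                 best_group = best,
                 indval_max = apply(iv, 1, max),
                 groups = groups),
            class = "indval_result")
}

# max-over-groups IndVal for a batch of label permutations.
# perm_idx: n_perm x n_samples matrix of permuted sample indices.
.indval_max_batch <- function(x, groups, perm_idx) {
  lev <- levels(groups)
  n <- nrow(x)
  pres <- (x > 0) * 1
  # P_j[p, s] = 1 if sample s gets a group-j label in permutation p
  lab <- matrix(as.integer(groups)[t(perm_idx)], ncol = n, byrow = TRUE)
  means <- vector("list", length(lev))
  occs <- vector("list", length(lev))
  for (j in seq_along(lev)) {
    P <- (lab == j) * 1
    nj <- sum(groups == lev[j])
    means[[j]] <- (P %*% x) / nj       # n_perm x n_otu
    occs[[j]] <- (P %*% pres) / nj
  }
  tot <- Reduce(`+`, means)
  iv_max <- matrix(0, nrow(perm_idx), ncol(x))
  for (j in seq_along(lev)) {
    A <- means[[j]] / ifelse(tot > 0, tot, NA_real_)
    A[is.na(A)] <- 0
    iv_max <- pmax(iv_max, A * occs[[j]])
  }
  iv_max
}

#' Permutation p-values for indicator values
#'
#' Tests each OTU's maximum indicator value against a null obtained by
#' shuffling the group labels. By default, p = (number of permutations with
#' a null IndVal >= the observed + 1) / (n_permutations + 1), the
#' add-one-corrected Monte Carlo estimate; `strict = TRUE` counts only
#' strictly larger null values. `exhaustive = TRUE` (two groups only)
#' enumerates every distinct label arrangement instead and reports the plain
#' fraction.
#'
#' @param x Samples x OTUs abundance matrix.
#' @param groups Group labels (see [indval()]).
#' @param n_permutations Number of random label shuffles.
#' @param seed Optional integer seed for reproducibility.
#' @param exhaustive Enumerate all distinct label arrangements (2 groups).
#' @param strict Compare with `>` instead of `>=`.
#' @return Numeric vector of p-values, one per OTU (named when `x` has
#'   column names).
#' @export
permutation_pvalue <- function(x, groups, n_permutations = 10000,
                               seed = NULL, exhaustive = FALSE,
                               strict = FALSE) {
  x <- as.matrix(x)
  groups <- factor(groups)
  obs <- indval(x, groups)$indval_max
  n <- nrow(x)
  if (exhaustive) {
    if (nlevels(groups) != 2)
      stop("exhaustive enumeration implemented for two groups only")
    n1 <- sum(groups == levels(groups)[1])
    sets <- utils::combn(n, n1)
    perm_idx <- t(apply(sets, 2, function(s) c(s, setdiff(seq_len(n), s))))
    null_max <- .indval_max_batch(x, groups, perm_idx)
    cmp <- if (strict) sweep(null_max, 2, obs, `>`)
           else sweep(null_max, 2, obs, `>=`)
    p <- colSums(cmp) / nrow(perm_idx)
  } else {
    if (n_permutations < 1) stop("need at least one permutation")
    if (!is.null(seed)) set.seed(seed)
    perm_idx <- t(vapply(seq_len(n_permutations),
                         function(i) sample.int(n), integer(n)))
    null_max <- .indval_max_batch(x, groups, perm_idx)
    cmp <- if (strict) sweep(null_max, 2, obs, `>`)
           else sweep(null_max, 2, obs, `>=`)
    p <- (colSums(cmp) + 1) / (n_permutations + 1)
  }
  names(p) <- colnames(x)
  p
}

#' Select responding bioindicator OTUs
#'
#' An OTU responds to a CH4 level when its permutation p-value is below
#' `alpha`; it is reported for its best (maximum-IndVal) group.
#'
#' @param result An [indval()] result.
#' @param p Permutation p-values from [permutation_pvalue()] on the same
#'   table.
#' @param alpha Significance cutoff (the analysis uses 0.01, uncorrected).
#' @return data.frame `otu`, `group`, `indval`, `A`, `B`, `p`, sorted by
#'   group then decreasing IndVal.
#' @export
responding_bioindicators <- function(result, p, alpha = 0.01) {
  stopifnot(inherits(result, "indval_result"))
  if (length(p) != nrow(result$indval))
    stop("p-value vector length must match the number of OTUs")
  otus <- rownames(result$indval)
  if (is.null(otus)) otus <- paste0("otu", seq_len(nrow(result$indval)))
  sel <- which(p < alpha)
  out <- data.frame(otu = otus[sel],
                    group = result$best_group[sel],
                    indval = result$indval_max[sel],
                    A = result$A[cbind(sel, match(result$best_group[sel],
                                                  colnames(result$A)))],
                    B = result$B[cbind(sel, match(result$best_group[sel],
                                                  colnames(result$B)))],
                    p = p[sel], row.names = NULL)
  out[order(out$group, -out$indval), , drop = FALSE]
}

#' Select unconditional bioindicator OTUs across grazing treatments
#'
#' Combines the responding-bioindicator selections of the grazed and
#' exclosed analyses (run on a shared OTU space) into the unconditional set:
#' (1) OTUs responding to the same CH4 level in both treatments, labeled
#' "peat soil independent"; (2) OTUs responding in one treatment and absent
#' (zero abundance in every sample, after denoising) from the other, labeled
#' by the treatment where they respond.
#'
#' @param grazed,exclosed data.frames from [responding_bioindicators()] for
#'   the two treatments.
#' @param presence List with logical vectors `grazed` and `exclosed`, named
#'   by OTU over the shared OTU space: TRUE when the OTU occurs in that
#'   treatment.
#' @return data.frame `otu`, `ch4_level`, `criterion` (1 or 2), `label`.
#' @export
unconditional_bioindicators <- function(grazed, exclosed, presence) {
  if (!all(c("grazed", "exclosed") %in% names(presence)))
    stop("presence must have 'grazed' and 'exclosed' components")
  pg <- presence$grazed
  pe <- presence$exclosed
  if (is.null(names(pg)) || is.null(names(pe)) ||
      !setequal(names(pg), names(pe)))
    stop("mismatched OTU spaces between treatments")
  rows <- list()
  # criterion 1: same-level responders in both treatments
  both <- merge(grazed[, c("otu", "group")], exclosed[, c("otu", "group")],
                by = c("otu", "group"))
  if (nrow(both) > 0)
    rows[[1]] <- data.frame(otu = both$otu, ch4_level = both$group,
                            criterion = 1L, label = "peat soil independent")
  # criterion 2: responder in one treatment, absent from the other
  g2 <- grazed[!pe[grazed$otu], , drop = FALSE]
  if (nrow(g2) > 0)
    rows[[length(rows) + 1]] <- data.frame(otu = g2$otu, ch4_level = g2$group,
                                           criterion = 2L, label = "grazed")
  e2 <- exclosed[!pg[exclosed$otu], , drop = FALSE]
  if (nrow(e2) > 0)
    rows[[length(rows) + 1]] <- data.frame(otu = e2$otu, ch4_level = e2$group,
                                           criterion = 2L, label = "exclosed")
  if (length(rows) == 0)
    return(data.frame(otu = character(), ch4_level = character(),
                      criterion = integer(), label = character()))
  out <- do.call(rbind, rows)
  out[!duplicated(out$otu), , drop = FALSE]
}
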