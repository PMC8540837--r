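#' Multiple sequence alignment container
#'
#' @param ids Unique taxon labels.
#' @param sequences Equal-length aligned DNA strings over A, C, G, T, -, N.
#' @return Object of class `seq_alignment` (a character matrix, taxa x
#'   columns, with row names).
#' @export
sequence_alignment <- function(ids, sequences) {
  if (length(ids) != length(sequences)) stop("ids and sequences lengths differ")
  if (length(ids) < 2) stop("an alignment needs at least 2 sequences")
  if (anyDuplicated(ids)) stop("taxon labels must be unique")
  L <- unique(nchar(sequences))
  if (length(L) != 1) stop("aligned sequences must have equal length")
  if (L == 0) stop("zero-length alignment")
  m <- do.call(rbind, strsplit(toupper(sequences), "", fixed = TRUE))
  rownames(m) <- ids
  class(m) <- c("seq_alignment", class(m))
  m
}

.aln_matrix <- function(x) {
  if (inherits(x, "seq_alignment")) return(unclass(x))
  if (is.matrix(x) && is.character(x)) return(x)
  if (is.character(x) && !is.null(names(x)))
    return(unclass(sequence_alignment(names(x), x)))
  stop("expected a seq_alignment, character matrix, or named character vector")
}

#' Jukes-Cantor distance matrix
#'
#' Pairwise mismatch proportions p over the columns where both sequences
#' carry an unambiguous base (gap and N columns dropped pairwise; set
#' `pairwise_deletion = FALSE` to drop such columns for all pairs at once),
#' corrected to expected substitutions per site by
#' \eqn{d = -\frac{3}{4}\ln(1 - \frac{4p}{3})}. Pairs at or beyond the
#' saturation bound p >= 3/4 have no finite JC distance.
#'
#' @param aln A [sequence_alignment()] (or character matrix / named vector).
#' @param pairwise_deletion Drop gap/N columns per pair (default) or globally.
#' @param on_saturation `"error"` to stop, `"cap"` to substitute `cap` and
#'   record the pair, `"na"` to leave NA.
#' @param cap Distance substituted for saturated pairs when capping.
#' @return Symmetric distance matrix (substitutions/site) with a
#'   `saturated_pairs` attribute (two-column matrix of labels).
#' @export
jc_distance <- function(aln, pairwise_deletion = TRUE,
                        on_saturation = c("error", "cap", "na"), cap = 5) {
  on_saturation <- match.arg(on_saturation)
  m <- .aln_matrix(aln)
  good <- m %in% c("A", "C", "G", "T")
  dim(good) <- dim(m)
  if (!pairwise_deletion) {
    keep <- colSums(good) == nrow(m)
    m <- m[, keep, drop = FALSE]
    good <- good[, keep, drop = FALSE]
  }
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  sat <- NULL
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- good[i, ] & good[j, ]
      n_cmp <- sum(ok)
      if (n_cmp == 0)
        stop(sprintf("no comparable columns between '%s' and '%s'",
                     rownames(m)[i], rownames(m)[j]))
      p <- sum(m[i, ok] != m[j, ok]) / n_cmp
      if (p >= 0.75) {
        sat <- rbind(sat, c(rownames(m)[i], rownames(m)[j]))
        d <- switch(on_saturation,
                    error = stop(sprintf(
                      "saturated pair '%s'/'%s' (p = %.3f >= 0.75): JC distance undefined",
                      rownames(m)[i], rownames(m)[j], p)),
                    cap = cap,
                    na = NA_real_)
      } else {
        d <- -0.75 * log(1 - 4 * p / 3)
      }
      D[i, j] <- D[j, i] <- d
    }
  }
  attr(D, "saturated_pairs") <- sat
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classic Saitou-Nei neighbor joining with the Studier-Keppler Q criterion.
#' On an additive distance matrix it reconstructs the generating topology
#' and branch lengths exactly. Q ties are broken by the lowest index pair
#' (row-major) for reproducibility; negative branch-length estimates are
#' clamped to zero and counted in the `clamped` attribute.
#'
#' @param D Square symmetric distance matrix with zero diagonal (row names
#'   become tip labels).
#' @return An unrooted `phylo` tree (ape).
#' @export
neighbor_joining <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D)) stop("distance matrix must be square")
  if (any(abs(D - t(D)) > 1e-8)) stop("distance matrix must be symmetric")
  if (any(!is.finite(D))) stop("distance matrix must be finite")
  n <- nrow(D)
  if (n < 2) stop("need at least 2 taxa")
  labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  clamped <- 0L
  clamp <- function(b) {
    if (b < 0) { clamped <<- clamped + 1L; 0 } else b
  }
  fmt <- function(b) sprintf("%.17g", b)
  sub <- labels
  if (n == 2) {
    half <- D[1, 2] / 2
    nwk <- sprintf("(%s:%s,%s:%s);", sub[1], fmt(half), sub[2], fmt(half))
  } else {
    while (n > 3) {
      r <- rowSums(D)
      Q <- (n - 2) * D - outer(r, r, `+`)
      diag(Q) <- Inf
      hits <- which(Q == min(Q), arr.ind = TRUE)
      hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
      hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
      i <- hits[1, 1]; j <- hits[1, 2]
      bi <- clamp(D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2)))
      bj <- clamp(D[i, j] - (D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))))
      newsub <- sprintf("(%s:%s,%s:%s)", sub[i], fmt(bi), sub[j], fmt(bj))
      k <- setdiff(seq_len(n), c(i, j))
      dnew <- (D[i, k] + D[j, k] - D[i, j]) / 2
      D <- rbind(cbind(D[k, k, drop = FALSE], dnew), c(dnew, 0))
      sub <- c(sub[k], newsub)
      n <- n - 1
    }
    b1 <- clamp((D[1, 2] + D[1, 3] - D[2, 3]) / 2)
    b2 <- clamp((D[1, 2] + D[2, 3] - D[1, 3]) / 2)
    b3 <- clamp((D[1, 3] + D[2, 3] - D[1, 2]) / 2)
    nwk <- sprintf("(%s:%s,%s:%s,%s:%s);",
                   sub[1], fmt(b1), sub[2], fmt(b2), sub[3], fmt(b3))
  }
  tree <- ape::read.tree(text = nwk)
  attr(tree, "clamped") <- clamped
  tree
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the JC + NJ tree
#' for each replicate, and annotates each internal edge of the full-data
#' tree with the percentage of replicates containing the same bipartition.
#' Saturated pairs arising in a replicate are capped per [jc_distance()]
#' (the count is reported).
#'
#' @param aln A [sequence_alignment()] with >= 4 taxa.
#' @param n_replicates Number of bootstrap replicates.
#' @param seed Optional integer seed.
#' @param pairwise_deletion Passed to [jc_distance()].
#' @return The point-estimate `phylo` tree with `node.label` set to the
#'   support percentages; also carries `support` and `n_saturated_replicates`
#'   attributes.
#' @export
bootstrap_support <- function(aln, n_replicates = 500, seed = NULL,
                              pairwise_deletion = TRUE) {
  m <- .aln_matrix(aln)
  if (nrow(m) < 4)
    stop("bootstrap bipartition support needs at least 4 taxa")
  if (n_replicates < 1) stop("need at least one replicate")
  if (!is.null(seed)) set.seed(seed)
  point <- neighbor_joining(jc_distance(m, pairwise_deletion))
  n_sat <- 0L
  boots <- vector("list", n_replicates)
  for (b in seq_len(n_replicates)) {
    cols <- sample.int(ncol(m), replace = TRUE)
    Db <- jc_distance(m[, cols, drop = FALSE], pairwise_deletion,
                      on_saturation = "cap")
    if (!is.null(attr(Db, "saturated_pairs"))) n_sat <- n_sat + 1L
    boots[[b]] <- neighbor_joining(Db)
  }
  class(boots) <- "multiPhylo"
  counts <- ape::prop.clades(point, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- counts / n_replicates * 100
  point$node.label <- as.character(round(support, 1))
  attr(point, "support") <- support
  attr(point, "n_saturated_replicates") <- n_sat
  point
}

#' Flag well-supported edges
#'
#' Presentation helper marking internal edges whose bootstrap support
#' exceeds a threshold (trees are conventionally annotated at >80).
#'
#' @param tree A tree from [bootstrap_support()].
#' @param threshold Support percentage above which an edge is marked.
#' @return Logical vector over internal nodes.
#' @export
high_support_edges <- function(tree, threshold = 80) {
  s <- attr(tree, "support")
  if (is.null(s)) stop("tree carries no bootstrap supports")
  s > threshold
}

#' Write and read Newick tree text
#'
#' Thin wrappers around ape's Newick serialisation, with an explicit
#' balanced-parenthesis check that reports the byte offset of the first
#' imbalance on malformed input. The round trip preserves topology, branch
#' lengths (to printed precision), tip labels and node (support) labels.
#'
#' @param tree A `phylo` object.
#' @param path Optional output file; when NULL the Newick string is returned.
#' @return `write_newick`: the Newick string (invisibly when writing to a
#'   file); `read_newick`: a `phylo`.
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  txt <- ape::write.tree(tree)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' @rdname write_newick
#' @param text Newick string (or a path to a file containing one).
#' @export
read_newick <- function(text) {
  if (length(text) == 1 && file.exists(text)) text <- readLines(text)
  text <- paste(text, collapse = "")
  depth <- 0L
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L)
      stop(sprintf("unbalanced ')' at offset %d", i))
  }
  if (depth != 0L)
    stop(sprintf("unbalanced '(': %d unclosed at end of text", depth))
  tree <- tryCatch(ape::read.tree(text = text), error = function(e) NULL,
                   warning = function(w) NULL)
  if (is.null(tree)) stop("Newick parse error")
  tree
}
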