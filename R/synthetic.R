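# Seeded generators producing every input the pipeline consumes, each with a
# ground-truth record so downstream stages can be scored without re-deriving
# the truth. Identical seed and parameters give bit-identical output.

#' Simulate a closed-bottle headspace CH4 decay series
#'
#' First-order decay C(t) = c0 exp(-k t) with multiplicative Gaussian
#' measurement noise (GC error scales with concentration).
#'
#' @param k True first-order rate constant (per h), >= 0.
#' @param c0 Initial mixing ratio (ppm), > 0.
#' @param times_h Measurement times (h).
#' @param noise_sd Multiplicative noise standard deviation (fraction).
#' @param bottle A [bottle_spec()].
#' @param seed Optional integer seed.
#' @param gas_sample_mL,liquid_sample_mL Per-measurement sampling volumes.
#' @return A [gas_timeseries()] with a `truth` attribute (list `k`, `c0`).
#' @export
gen_gas_series <- function(k, c0, times_h = c(0, 8, 16, 24), noise_sd = 0,
                           bottle = bottle_spec(50, 0, temp_C = 8),
                           seed = NULL, gas_sample_mL = 0,
                           liquid_sample_mL = 0) {
  if (k < 0) stop("k must be non-negative")
  if (c0 <= 0) stop("c0 must be positive")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  mu <- c0 * exp(-k * times_h)
  eps <- if (noise_sd > 0) stats::rnorm(length(times_h), 0, noise_sd) else 0
  ppm <- mu * (1 + eps)
  if (any(ppm <= 0)) stop("noise drove a mixing ratio non-positive; lower noise_sd")
  s <- gas_timeseries(times_h, ppm, bottle, gas_sample_mL, liquid_sample_mL)
  attr(s, "truth") <- list(k = k, c0 = c0)
  s
}

#' Simulate a two-group OTU table with planted indicator taxa
#'
#' Dirichlet-multinomial counts: per-sample proportions are drawn from a
#' Dirichlet whose parameters follow a power-law base composition; planted
#' indicator OTUs have their Dirichlet parameter multiplied by `fold_effect`
#' in their target group and occur in that group's samples with probability
#' `occupancy`. Sequencing depth is exact (multinomial).
#'
#' @param n_per_group Samples per group.
#' @param n_otus Number of OTUs.
#' @param base_concentration Dirichlet parameter vector (length `n_otus`);
#'   default: total concentration 200 spread as 1/rank, i.e. a power-law
#'   community with moderate between-replicate overdispersion.
#' @param indicators data.frame with columns `otu` (index), `group` (a value
#'   of `group_labels`), `fold_effect` (> 0), `occupancy` (in [0, 1]).
#' @param depth Reads per sample (> 0).
#' @param group_labels Two group names (CH4 levels).
#' @param seed Optional integer seed.
#' @return List: `counts` (samples x OTUs integer matrix), `metadata`
#'   (data.frame `sample`, `group`), `truth` (the indicators table).
#' @export
gen_community <- function(n_per_group = 8, n_otus = 50,
                          base_concentration = NULL, indicators = NULL,
                          depth = 5000, group_labels = c("0.1%", "1%"),
                          seed = NULL) {
  if (depth <= 0) stop("depth must be positive")
  if (length(group_labels) != 2) stop("two group labels required")
  if (is.null(base_concentration)) {
    w <- 1 / seq_len(n_otus)
    base_concentration <- 200 * w / sum(w)
  }
  if (length(base_concentration) != n_otus)
    stop("base_concentration must have length n_otus")
  if (!is.null(indicators)) {
    stopifnot(all(c("otu", "group", "fold_effect", "occupancy") %in%
                    names(indicators)))
    if (any(indicators$fold_effect <= 0)) stop("fold_effect must be > 0")
    if (any(indicators$occupancy < 0 | indicators$occupancy > 1))
      stop("occupancy must be in [0, 1]")
    if (!all(indicators$group %in% group_labels))
      stop("indicator groups must be among group_labels")
  }
  if (!is.null(seed)) set.seed(seed)
  groups <- rep(group_labels, each = n_per_group)
  n <- length(groups)
  counts <- matrix(0L, n, n_otus,
                   dimnames = list(paste0("s", seq_len(n)),
                                   paste0("otu", seq_len(n_otus))))
  for (s in seq_len(n)) {
    alpha <- base_concentration
    mask <- rep(TRUE, n_otus)
    if (!is.null(indicators)) {
      for (r in seq_len(nrow(indicators))) {
        o <- indicators$otu[r]
        if (indicators$group[r] == groups[s]) {
          alpha[o] <- alpha[o] * indicators$fold_effect[r]
          if (stats::runif(1) > indicators$occupancy[r]) mask[o] <- FALSE
        }
      }
    }
    g <- stats::rgamma(n_otus, shape = alpha, rate = 1)
    g[!mask] <- 0
    counts[s, ] <- as.integer(stats::rmultinom(1, depth, g / sum(g)))
  }
  list(counts = counts,
       metadata = data.frame(sample = rownames(counts), group = groups),
       truth = indicators)
}

.SENSE_CODONS <- setdiff(
  apply(expand.grid(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                    c("T", "C", "A", "G")), 1, paste0, collapse = ""),
  c("TAA", "TAG", "TGA"))

#' Generate stop-free pmoA-like open reading frames
#'
#' Random in-frame coding sequences built from sense codons only, usable as
#' reference entries and as templates for read simulation.
#'
#' @param n Number of sequences.
#' @param length_nt Sequence length (multiple of 3).
#' @param seed Optional integer seed.
#' @param prefix Name prefix for the reference labels.
#' @return Named character vector of DNA strings.
#' @export
gen_reference_orfs <- function(n = 5, length_nt = 465, seed = NULL,
                               prefix = "ref") {
  if (length_nt %% 3 != 0) stop("length_nt must be a multiple of 3")
  if (!is.null(seed)) set.seed(seed)
  out <- vapply(seq_len(n), function(i)
    paste0(sample(.SENSE_CODONS, length_nt / 3, replace = TRUE),
           collapse = ""), character(1))
  names(out) <- paste0(prefix, seq_len(n))
  out
}

#' Simulate amplicon reads with planted filterable defects
#'
#' Copies reads from stop-free reference ORFs and plants, at the stated
#' rates, exactly the defect classes the filters remove: an in-frame stop
#' codon, a single-nucleotide deletion (frameshift), or a 50-nt low-quality
#' window (Phred 10 against a clean baseline of `base_q`). The truth table
#' labels each read's defect class, so the filter stages can be scored
#' exactly.
#'
#' @param references Named character vector of in-frame reference sequences
#'   (e.g. from [gen_reference_orfs()]).
#' @param n_reads Number of reads.
#' @param defect_rates List with rates `stop_codon`, `frameshift`,
#'   `low_quality_window`, each in [0, 1], summing to <= 1.
#' @param seed Optional integer seed.
#' @param base_q Baseline Phred score of clean bases.
#' @return List: `reads` (an [amplicon_reads()]), `truth` (data.frame `id`,
#'   `defect`, `reference`).
#' @export
gen_amplicons <- function(references, n_reads,
                          defect_rates = list(stop_codon = 0, frameshift = 0,
                                              low_quality_window = 0),
                          seed = NULL, base_q = 35) {
  if (length(references) == 0) stop("empty reference set")
  rates <- c(stop_codon = defect_rates$stop_codon %||% 0,
             frameshift = defect_rates$frameshift %||% 0,
             low_quality_window = defect_rates$low_quality_window %||% 0)
  if (any(rates < 0 | rates > 1) || sum(rates) > 1)
    stop("defect rates must lie in [0, 1] and sum to <= 1")
  if (!is.null(seed)) set.seed(seed)
  classes <- sample(c(names(rates), "none"), n_reads, replace = TRUE,
                    prob = c(rates, 1 - sum(rates)))
  ids <- sprintf("read%04d", seq_len(n_reads))
  seqs <- character(n_reads)
  quals <- vector("list", n_reads)
  refs <- sample(names(references), n_reads, replace = TRUE)
  for (i in seq_len(n_reads)) {
    s <- references[[refs[i]]]
    q <- rep(as.integer(base_q), nchar(s))
    if (classes[i] == "stop_codon") {
      cod <- sample(nchar(s) %/% 3, 1)
      substr(s, 3 * cod - 2, 3 * cod) <- sample(c("TAA", "TAG", "TGA"), 1)
    } else if (classes[i] == "frameshift") {
      pos <- sample(nchar(s), 1)
      s <- paste0(substr(s, 1, pos - 1), substr(s, pos + 1, nchar(s)))
      q <- q[-1]
    } else if (classes[i] == "low_quality_window") {
      start <- sample(nchar(s) - 49, 1)
      q[start:(start + 49)] <- 10L
    }
    seqs[i] <- s
    quals[[i]] <- q
  }
  list(reads = amplicon_reads(ids, seqs, quals),
       truth = data.frame(id = ids, defect = classes, reference = refs))
}

#' Simulate a qPCR dilution-series standard
#'
#' Log-linear Cq response over a decadal dilution series (default: seven
#' decades from 7.15e6 down to 7.15 copies per reaction) with optional
#' Gaussian cycle noise.
#'
#' @param slope True slope (Cq per log10 copies), negative.
#' @param intercept True intercept (Cq at one copy).
#' @param levels Copy numbers of the series.
#' @param replicates Technical replicates per level.
#' @param noise_sd_cq Cycle noise standard deviation.
#' @param seed Optional integer seed.
#' @return A [dilution_standard()] with a `truth` attribute.
#' @export
gen_dilution_cq <- function(slope = -3.4, intercept = 38,
                            levels = 7.15e6 / 10^(0:6), replicates = 3,
                            noise_sd_cq = 0, seed = NULL) {
  if (any(levels <= 0)) stop("copy levels must be positive")
  if (!is.null(seed)) set.seed(seed)
  copies <- rep(levels, each = replicates)
  cq <- intercept + slope * log10(copies) +
    stats::rnorm(length(copies), 0, noise_sd_cq)
  std <- dilution_standard(copies, cq)
  attr(std, "truth") <- list(slope = slope, intercept = intercept)
  std
}

#' Evolve sequences along a tree under the Jukes-Cantor model
#'
#' Draws a uniform-random root sequence and mutates it along each branch
#' with the exact JC transition probabilities (probability of staying at a
#' base is 1/4 + 3/4 exp(-4d/3) for branch length d in substitutions/site).
#'
#' @param tree A `phylo` with branch lengths in substitutions/site.
#' @param length Alignment length (columns), > 0.
#' @param seed Optional integer seed.
#' @return A [sequence_alignment()] of the tip sequences with the generating
#'   tree in the `truth_tree` attribute.
#' @export
evolve_sequences <- function(tree, length, seed = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (length <= 0) stop("alignment length must be positive")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (!is.null(seed)) set.seed(seed)
  bases <- c("A", "C", "G", "T")
  tree2 <- stats::reorder(tree, "cladewise")  # parents precede children
  n_tip <- length(tree2$tip.label)
  n_node <- tree2$Nnode
  seqs <- vector("list", n_tip + n_node)
  root <- n_tip + 1L
  seqs[[root]] <- sample.int(4, length, replace = TRUE)
  for (e in seq_len(nrow(tree2$edge))) {
    parent <- tree2$edge[e, 1]
    child <- tree2$edge[e, 2]
    d <- tree2$edge.length[e]
    p_stay <- 0.25 + 0.75 * exp(-4 * d / 3)
    s <- seqs[[parent]]
    change <- stats::runif(length) > p_stay
    if (any(change)) {
      shift <- sample.int(3, sum(change), replace = TRUE)
      s[change] <- (s[change] + shift - 1L) %% 4L + 1L
    }
    seqs[[child]] <- s
  }
  tips <- vapply(seq_len(n_tip),
                 function(i) paste0(bases[seqs[[i]]], collapse = ""),
                 character(1))
  aln <- sequence_alignment(tree2$tip.label, tips)
  attr(aln, "truth_tree") <- tree
  aln
}

`%||%` <- function(a, b) if (is.null(a)) b else a
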