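#' Mutant-allele tumor heterogeneity (MATH) score
#'
#' `100 * 1.4826 * median(|vaf - median(vaf)|) / median(vaf)`: the
#' MAD-based dispersion of the variant allele fractions relative to their
#' median, on the percentage scale. Scale-invariant and non-negative.
#'
#' @param vafs numeric vector of variant allele fractions (>= 2 values,
#'   median > 0).
#' @return The MATH score.
#' @examples
#' math_score(c(0.2, 0.25, 0.3))
#' @export
math_score <- function(vafs) {
  if (length(vafs) < 2L) stop("need at least 2 VAFs")
  m <- stats::median(vafs)
  if (m <= 0) stop("median VAF must be > 0")
  100 * (1.4826 * stats::median(abs(vafs - m))) / m
}

#' Filter somatic SNVs for VAF clustering
#'
#' Keeps records with VAF at most `max_vaf` (higher VAFs are likely
#' inflated by copy-number loss) and total depth at least `min_depth`.
#'
#' @param records data.frame with `ref_count`, `alt_count` (a `vaf`
#'   column is recomputed if absent).
#' @param max_vaf maximum VAF retained (default 0.6; strictly above is
#'   removed).
#' @param min_depth minimum `ref_count + alt_count` (default 14).
#' @return The filtered data.frame.
#' @export
filter_for_clustering <- function(records, max_vaf = 0.6, min_depth = 14L) {
  depth <- records$ref_count + records$alt_count
  vaf <- ifelse(depth > 0, records$alt_count / depth, NA_real_)
  records[!is.na(vaf) & vaf <= max_vaf & depth >= min_depth, , drop = FALSE]
}

#' Filter somatic SNVs for tree building
#'
#' Removes records lying in a copy-number segment with `|lr| > max_abs_lr`
#' AND segment p-value `< max_p` (both conditions must hold); records
#' without an overlapping segment are kept.
#'
#' @param records data.frame; optional columns `lr` and `cnv_p` (`NA`
#'   where no segment overlaps).
#' @param max_abs_lr log-ratio magnitude threshold, default 0.2.
#' @param max_p segment p-value threshold, default 0.01.
#' @return The filtered data.frame.
#' @export
filter_for_trees <- function(records, max_abs_lr = 0.2, max_p = 0.01) {
  if (!all(c("lr", "cnv_p") %in% names(records))) return(records)
  drop <- !is.na(records$lr) & !is.na(records$cnv_p) &
    abs(records$lr) > max_abs_lr & records$cnv_p < max_p
  records[!drop, , drop = FALSE]
}

#' Fit a binomial mixture to alt/depth counts
#'
#' Expectation-maximization for a k-component binomial mixture on
#' per-site (alt_count, depth) pairs, with multiple seeded restarts from
#' quantile-spread initial success probabilities.
#'
#' @param alt,depth integer vectors (alt <= depth).
#' @param k number of components (>= 1).
#' @param n_restarts EM restarts (default 10).
#' @param seed integer seed.
#' @param max_iter,tol EM iteration cap and log-likelihood tolerance.
#' @return list `k`, `prop` (mixing weights), `p` (success
#'   probabilities), `loglik`, `bic`.
#' @export
fit_binomial_mixture <- function(alt, depth, k, n_restarts = 10L, seed = 1L,
                                 max_iter = 300L, tol = 1e-8) {
  stopifnot(length(alt) == length(depth), all(alt <= depth), k >= 1)
  n <- length(alt)
  vaf <- alt / depth
  set.seed(derive_seed(seed, paste0("binmix_k", k)))

  run_em <- function(p0) {
    prop <- rep(1 / k, k)
    p <- pmin(pmax(p0, 1e-4), 1 - 1e-4)
    ll_old <- -Inf
    for (it in seq_len(max_iter)) {
      logd <- vapply(seq_len(k), function(j)
        stats::dbinom(alt, depth, p[j], log = TRUE) + log(prop[j]),
        numeric(n))
      mx <- apply(logd, 1L, max)
      lse <- mx + log(rowSums(exp(logd - mx)))
      resp <- exp(logd - lse)
      ll <- sum(lse)
      prop <- colMeans(resp)
      p <- pmin(pmax(colSums(resp * alt) / colSums(resp * depth),
                     1e-4), 1 - 1e-4)
      if (ll - ll_old < tol && it > 1L) break
      ll_old <- ll
    }
    list(prop = prop, p = p, loglik = ll)
  }

  base_q <- stats::quantile(vaf, probs = seq(0.5 / k, 1 - 0.5 / k,
                                             length.out = k))
  best <- NULL
  for (r in seq_len(n_restarts)) {
    p0 <- if (r == 1L) base_q else
      base_q + stats::rnorm(k, 0, 0.05)
    fit <- run_em(sort(p0))
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  n_par <- 2 * k - 1  # k success probs + (k-1) free mixing weights
  best$k <- as.integer(k)
  best$bic <- -2 * best$loglik + n_par * log(n)
  best
}

#' Estimate the number of clones from somatic VAFs
#'
#' Fits binomial mixtures with 1 to `k_max` components to the (already
#' filtered) alt/depth counts and returns the component count minimizing
#' the Bayesian information criterion. A stand-in for full VAF-clustering
#' tools: same inputs and filters, simpler model.
#'
#' @param records data.frame with `ref_count`, `alt_count` (>= 10 rows).
#' @param k_max maximum number of clones considered (default 5).
#' @param n_restarts EM restarts per k (default 10).
#' @param seed integer seed.
#' @return Estimated clone count (integer); the full fit table is
#'   attached as attribute `fits`.
#' @export
estimate_clone_count <- function(records, k_max = 5L, n_restarts = 10L,
                                 seed = 1L) {
  if (nrow(records) < 10L) stop("need at least 10 records")
  alt <- records$alt_count
  depth <- records$ref_count + records$alt_count
  fits <- lapply(seq_len(k_max), function(k)
    fit_binomial_mixture(alt, depth, k, n_restarts, seed))
  bic <- vapply(fits, `[[`, numeric(1), "bic")
  k <- which.min(bic)
  structure(as.integer(k),
            fits = data.frame(k = seq_len(k_max), bic = bic,
                              loglik = vapply(fits, `[[`, numeric(1),
                                              "loglik")))
}

#' Construct and validate a clone tree
#'
#' A clone tree is stored as a parent vector: `parents[i]` is the parent
#' of node i, with the root marked by `parents[root] == root` (or 0 /
#' `NA`). The tree must have exactly one root, be acyclic and connected.
#'
#' @param parents integer parent vector.
#' @param mutations optional per-node mutation counts (same length).
#' @return A `clone_tree` list with `parents`, `mutations`, `root`.
#' @export
clone_tree <- function(parents, mutations = NULL) {
  n <- length(parents)
  if (n < 1L) stop("tree must have at least one node")
  parents <- as.integer(parents)
  root <- which(is.na(parents) | parents == 0L | parents == seq_len(n))
  if (length(root) != 1L) {
    stop("tree must have exactly one root, found ", length(root))
  }
  if (any(parents[-root] < 1L | parents[-root] > n, na.rm = TRUE)) {
    stop("parent index out of range")
  }
  # every node must reach the root without revisiting a node
  for (v in seq_len(n)) {
    seen <- logical(n)
    while (v != root) {
      if (seen[v]) stop("cycle detected in parent vector")
      seen[v] <- TRUE
      v <- parents[v]
    }
  }
  if (!is.null(mutations) && length(mutations) != n) {
    stop("mutations must match the number of nodes")
  }
  structure(list(parents = parents, mutations = mutations, root = root),
            class = "clone_tree")
}

#' Classify a clone tree as linear or branching
#'
#' Linear when every node has at most one child (a single lineage,
#' including the one-node tree); branching otherwise.
#'
#' @param tree a `clone_tree` (or a parent vector, validated on the fly).
#' @return `"linear"` or `"branching"`.
#' @export
classify_tree <- function(tree) {
  if (!inherits(tree, "clone_tree")) tree <- clone_tree(tree)
  n <- length(tree$parents)
  kids <- tabulate(tree$parents[-tree$root], nbins = n)
  if (max(c(kids, 0L)) <= 1L) "linear" else "branching"
}

#' Compare a binary clonality property between two cohorts
#'
#' Builds the 2x2 table of samples with/without the property (single
#' clone, or linear tree topology) per cohort and applies
#' [fisher_exact_2x2()].
#'
#' @param cohort_a,cohort_b per-sample values: clone counts (integers)
#'   under `mode = "clone_count_is_1"`, or topology labels
#'   (`"linear"`/`"branching"`) under `mode = "tree_is_linear"`.
#' @param mode which binary summary to compare.
#' @return list with `table` (2x2 matrix) and `p`.
#' @export
compare_clonality <- function(cohort_a, cohort_b,
                              mode = c("clone_count_is_1",
                                       "tree_is_linear")) {
  mode <- match.arg(mode)
  if (length(cohort_a) == 0L || length(cohort_b) == 0L) {
    stop("cohorts must be non-empty")
  }
  as_flag <- function(v) {
    if (mode == "clone_count_is_1") as.integer(v) == 1L
    else v == "linear"
  }
  fa <- as_flag(cohort_a); fb <- as_flag(cohort_b)
  tab <- matrix(c(sum(fa), sum(!fa), sum(fb), sum(!fb)), 2L, byrow = TRUE,
                dimnames = list(c("A", "B"), c("yes", "no")))
  list(table = tab, p = fisher_exact_2x2(tab))
}
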