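#' Two-sided Fisher exact test on a 2x2 table
#'
#' Two-sided p-value under the probability-mass rule: the sum of
#' hypergeometric probabilities (margins fixed) of every table at most as
#' probable as the observed one.
#'
#' @param tab 2x2 matrix (or length-4 vector, filled by row: a, b, c, d)
#'   of non-negative counts; rows are cohorts, columns event/no-event.
#' @return The two-sided p-value in (0, 1].
#' @examples
#' fisher_exact_2x2(matrix(c(6, 14, 0, 23), 2, byrow = TRUE))
#' @export
fisher_exact_2x2 <- function(tab) {
  if (!is.matrix(tab)) tab <- matrix(as.numeric(tab), 2L, byrow = TRUE)
  stopifnot(identical(dim(tab), c(2L, 2L)))
  if (any(tab < 0)) stop("counts must be non-negative")
  if (sum(tab) == 0) stop("all-zero table")
  min(stats::fisher.test(tab)$p.value, 1)
}

#' Bonferroni correction
#'
#' Multiplies each p-value by the number of tests `m` and caps at 1.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @param m number of tests; defaults to `length(p)` and may exceed it
#'   when only a subset of a family's p-values is supplied.
#' @return Adjusted p-values.
#' @export
bonferroni <- function(p, m = length(p)) {
  if (m < 1) stop("m must be >= 1")
  stopifnot(all(p >= 0 & p <= 1))
  stats::p.adjust(p, method = "bonferroni", n = max(m, length(p)))
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact permutation p-value when the combined sample size is at most 12
#' and there are no ties; otherwise the normal approximation with tie
#' correction and continuity correction.
#'
#' @param x,y non-empty numeric samples.
#' @param exact_max combined-size cutoff for the exact mode (default 12).
#' @return The two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max = 12L) {
  if (length(x) == 0L || length(y) == 0L) stop("samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- (length(x) + length(y)) <= exact_max && !ties
  suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = TRUE)$p.value
  )
}

#' Two-proportion z-test with Yates' continuity correction
#'
#' Tests `k1/n1` against `k2/n2` using the pooled-variance z statistic
#' with Yates' correction `0.5 * (1/n1 + 1/n2)` subtracted from the
#' absolute difference (clamped at zero). When the pooled proportion is 0
#' or 1 there is no evidence of a difference and p = 1 by convention.
#'
#' @param k1,n1,k2,n2 successes and totals per group (`0 <= k <= n`,
#'   `n >= 1`).
#' @return The two-sided p-value.
#' @export
two_proportion_z_yates <- function(k1, n1, k2, n2) {
  stopifnot(n1 >= 1, n2 >= 1, k1 >= 0, k1 <= n1, k2 >= 0, k2 <= n2)
  p_hat <- (k1 + k2) / (n1 + n2)
  if (p_hat <= 0 || p_hat >= 1) return(1)
  d <- abs(k1 / n1 - k2 / n2) - 0.5 * (1 / n1 + 1 / n2)
  d <- max(d, 0)
  z <- d / sqrt(p_hat * (1 - p_hat) * (1 / n1 + 1 / n2))
  2 * stats::pnorm(-z)
}

#' Per-bin Fisher comparison of two cohort frequency maps
#'
#' For every genome bin and event type (gain, loss), builds the 2x2 table
#' of samples with/without the event in each cohort and applies the Fisher
#' exact test. Significance is assessed on raw p-values or after
#' Bonferroni adjustment across all (bin, type) tests.
#'
#' @param map_a,map_b frequency maps from [bin_frequency_map()], on an
#'   identical bin grid.
#' @param n_a,n_b cohort sizes; default to the maps' `n_samples`
#'   attribute.
#' @param alpha significance level (default 0.05).
#' @param adjust `"none"` (default) or `"bonferroni"`.
#' @param .cache optional environment memoizing p-values by count table;
#'   identical tables always yield identical p-values, so the memo cannot
#'   alter results.
#' @return data.frame `chrom`, `bin_start`, `bin_end`, `type`, `p_raw`,
#'   `p_adj`, `significant`.
#' @export
per_bin_fisher <- function(map_a, map_b, n_a = attr(map_a, "n_samples"),
                           n_b = attr(map_b, "n_samples"), alpha = 0.05,
                           adjust = c("none", "bonferroni"),
                           .cache = NULL) {
  adjust <- match.arg(adjust)
  if (!identical(map_a[, c("chrom", "bin_start", "bin_end")],
                 map_b[, c("chrom", "bin_start", "bin_end")])) {
    stop("frequency maps are on different bin grids")
  }
  stopifnot(!is.null(n_a), !is.null(n_b))
  res <- lapply(c("gain", "loss"), function(type) {
    col <- paste0(type, "_freq")
    k_a <- as.integer(round(map_a[[col]] * n_a))
    k_b <- as.integer(round(map_b[[col]] * n_b))
    p <- fisher_p_vec(k_a, n_a, k_b, n_b, .cache)
    data.frame(chrom = map_a$chrom, bin_start = map_a$bin_start,
               bin_end = map_a$bin_end, type = type, p_raw = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- bonferroni(out$p_raw)
  out$significant <- if (adjust == "none") out$p_raw < alpha
                     else out$p_adj < alpha
  out
}

# vectorized memoized Fisher p for (k_a of n_a) vs (k_b of n_b)
fisher_p_vec <- function(k_a, n_a, k_b, n_b, cache = NULL) {
  key <- paste(k_a, k_b, sep = ",")
  uk <- !duplicated(key)
  pu <- vapply(which(uk), function(i) {
    kk <- key[i]
    if (!is.null(cache) && !is.null(cache[[kk]])) return(cache[[kk]])
    p <- fisher_exact_2x2(matrix(c(k_a[i], n_a - k_a[i],
                                   k_b[i], n_b - k_b[i]), 2L, byrow = TRUE))
    if (!is.null(cache)) cache[[kk]] <- p
    p
  }, numeric(1))
  unname(pu[match(key, key[uk])])
}

#' Count significant peaks between two cohorts' CNV calls
#'
#' Runs the full map-then-test path: builds one frequency map per cohort
#' from the per-sample calls and counts significant (bin, type) peaks via
#' [per_bin_fisher()].
#'
#' @param calls named list of per-sample classified segment data.frames.
#' @param labels data.frame `sample_id`, `cohort` (exactly two cohorts).
#' @param spec [genome_spec()].
#' @param map_bin bin width in bp, default 1 Mb.
#' @inheritParams per_bin_fisher
#' @return Number of significant peaks (integer).
#' @export
count_significant_peaks <- function(calls, labels, spec, map_bin = 1e6,
                                    alpha = 0.05,
                                    adjust = c("none", "bonferroni"),
                                    .cache = NULL) {
  adjust <- match.arg(adjust)
  groups <- split(labels$sample_id, labels$cohort)
  if (length(groups) != 2L) stop("labels must define exactly two cohorts")
  map_a <- bin_frequency_map(calls, spec, groups[[1L]], map_bin)
  map_b <- bin_frequency_map(calls, spec, groups[[2L]], map_bin)
  peaks <- per_bin_fisher(map_a, map_b, alpha = alpha, adjust = adjust,
                          .cache = .cache)
  sum(peaks$significant)
}

#' Label-randomization null for significant-peak counts
#'
#' Shuffles cohort labels (group sizes preserved), re-runs the full
#' frequency-map + per-bin Fisher pipeline on the fixed per-sample calls,
#' and records the number of significant peaks per iteration.
#'
#' @inheritParams count_significant_peaks
#' @param n_iter number of label shuffles (>= 1), default 1000.
#' @param seed integer seed; the summary is deterministic given the seed.
#' @return A `randomization_summary`: list with `n_iter`, `alpha`,
#'   `adjust`, `counts` (length `n_iter`), `median`, `min`, `max`.
#' @export
randomization_null <- function(calls, labels, spec, map_bin = 1e6,
                               n_iter = 1000L, alpha = 0.05,
                               adjust = c("none", "bonferroni"),
                               seed = 1L) {
  adjust <- match.arg(adjust)
  if (n_iter < 1) stop("n_iter must be >= 1")
  set.seed(derive_seed(seed, "randomization_null"))
  cache <- new.env(parent = emptyenv())
  counts <- vapply(seq_len(n_iter), function(i) {
    shuffled <- labels
    shuffled$cohort <- sample(labels$cohort)
    count_significant_peaks(calls, shuffled, spec, map_bin, alpha, adjust,
                            .cache = cache)
  }, numeric(1))
  structure(list(n_iter = as.integer(n_iter), alpha = alpha,
                 adjust = adjust, counts = as.integer(counts),
                 median = stats::median(counts), min = min(counts),
                 max = max(counts)),
            class = "randomization_summary")
}

#' @export
print.randomization_summary <- function(x, ...) {
  cat(sprintf(
    "randomization null: %d iterations, alpha=%g (%s)\n  significant peaks: median %g, min %d, max %d\n",
    x$n_iter, x$alpha, x$adjust, x$median, x$min, x$max))
  invisible(x)
}
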