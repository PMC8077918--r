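# Independent brute-force oracles used across the suite. These never call
# into the code paths they check.

# O(n*w) truncated-window sliding median, NAs excluded
oracle_sliding_median <- function(v, hw) {
  n <- length(v)
  vapply(seq_len(n), function(b) {
    if (is.na(v[b])) return(NA_real_)
    w <- v[max(1, b - hw):min(n, b + hw)]
    median(w, na.rm = TRUE)
  }, numeric(1))
}

# two-sided Fisher p by full enumeration of all 2x2 tables with the
# observed margins, probability-mass rule
oracle_fisher_enum <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  support <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- vapply(support, function(x) {
    choose(r1, x) * choose(n - r1, c1 - x) / choose(n, c1)
  }, numeric(1))
  p_obs <- probs[match(a, support)]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exact two-sided Wilcoxon rank-sum p by enumerating every assignment of
# the pooled ranks to group x
oracle_wilcoxon_enum <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  nx <- length(x)
  w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- combn(length(pooled), nx)
  w_all <- apply(combos, 2, function(i) sum(r[i]) - nx * (nx + 1) / 2)
  mu <- nx * length(y) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
}

# LCA by explicit root-path construction and intersection
oracle_lca <- function(tax, nodes) {
  path_of <- function(id) {
    p <- id
    repeat {
      parent <- tax$parent_id[match(id, tax$node_id)]
      if (parent == id) break
      id <- parent
      p <- c(p, id)
    }
    p
  }
  paths <- lapply(nodes, path_of)
  common <- Reduce(intersect, paths)
  common[1]
}

# frequency map by IRanges overlap scan, one sample/type/bin at a time
oracle_freq_map <- function(calls, spec, samples, map_bin = 1e6) {
  grid <- wgscohort::map_bins(spec, map_bin)
  for (type in c("gain", "loss")) {
    cnt <- integer(nrow(grid))
    for (sid in samples) {
      seg <- calls[[sid]]
      seg <- seg[seg$call == type, , drop = FALSE]
      hit <- logical(nrow(grid))
      for (ch in unique(grid$chrom)) {
        gi <- which(grid$chrom == ch)
        s <- seg[seg$chrom == ch, , drop = FALSE]
        if (!nrow(s)) next
        ov <- IRanges::countOverlaps(
          IRanges::IRanges(grid$bin_start[gi] + 1, grid$bin_end[gi]),
          IRanges::IRanges(s$start + 1, s$end),
          minoverlap = 1L)
        hit[gi] <- ov > 0
      }
      cnt <- cnt + hit
    }
    grid[[paste0(type, "_freq")]] <- cnt / length(samples)
  }
  grid
}

# fixed small genome used by several CNV tests
test_genome <- function(bin_size = 3000) {
  genome_spec(c(chr1 = 30e6, chr2 = 20e6), bin_size = bin_size)
}

# bin-aligned planted events spanning small and large scales
test_events <- function(bin = 3000) {
  data.frame(
    chrom = c("chr1", "chr1", "chr1", "chr2", "chr2", "chr2"),
    start = c(1000, 3333, 6667, 667, 2666, 4666) * bin,
    end = c(1000 + 50, 3333 + 666, 6667 + 600, 667 + 100, 2666 + 666,
            4666 + 200) * bin,
    true_lr = c(0.3, 0.6, -1.0, -0.3, 1.0, 0.6)
  )
}
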