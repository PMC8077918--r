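#' Scale a normal read-depth profile to the tumor's total signal
#'
#' Multiplies every bin of the normal profile by the ratio of total tumor
#' signal to total normal signal, so that the two profiles carry the same
#' total read depth before log-ratio computation.
#'
#' @param tumor,normal `rd_profile` objects on the same genome partition.
#' @return The normalized normal `rd_profile` (total equals the tumor's).
#' @export
normalize_normal <- function(tumor, normal) {
  check_same_partition(tumor, normal)
  tot_t <- sum(vapply(tumor$bins, sum, numeric(1)))
  tot_n <- sum(vapply(normal$bins, sum, numeric(1)))
  if (tot_n <= 0) stop("normal profile has zero total signal")
  out <- normal
  out$bins <- lapply(normal$bins, function(v) v * (tot_t / tot_n))
  out
}

check_same_partition <- function(a, b) {
  if (!identical(names(a$bins), names(b$bins))) {
    stop("profiles disagree on chromosomes: ",
         paste(symdiff_chr(names(a$bins), names(b$bins)), collapse = ", "))
  }
  if (a$bin_size != b$bin_size) stop("profiles disagree on bin_size")
  for (ch in names(a$bins)) {
    if (length(a$bins[[ch]]) != length(b$bins[[ch]])) {
      stop("profiles disagree on bin count for chromosome ", ch)
    }
  }
  invisible(TRUE)
}

symdiff_chr <- function(x, y) union(setdiff(x, y), setdiff(y, x))

#' Compute the binned tumor/normal log-ratio track
#'
#' Aggregates both profiles into `bin_size`-bp bins (the input bin size
#' must divide `bin_size`; a trailing partial bin is allowed) and computes
#' `LR(b) = log2(sum tumor in b / sum normalized normal in b)`. Bins where
#' either total is zero have no defined log-ratio and are masked (`NA`);
#' masked bins are excluded from smoothing windows and split segments.
#'
#' @param tumor tumor `rd_profile`.
#' @param normal_hat normalized normal `rd_profile` (see
#'   [normalize_normal()]).
#' @param bin_size analysis bin width in bp, default 3000.
#' @return An `lr_track`: list with `bin_size`, `smoothed = FALSE`, and
#'   per-chromosome `values` (plus `tumor_bins`/`normal_bins` totals kept
#'   for per-segment log-ratio recomputation).
#' @export
bin_log_ratio <- function(tumor, normal_hat, bin_size = 3000L) {
  check_same_partition(tumor, normal_hat)
  if (bin_size %% tumor$bin_size != 0) {
    stop("bin_size must be a multiple of the profile bin size")
  }
  f <- as.integer(bin_size / tumor$bin_size)
  agg <- function(v) {
    if (f == 1L) return(v)
    idx <- (seq_along(v) - 1L) %/% f
    as.numeric(tapply(v, idx, sum))
  }
  tb <- lapply(tumor$bins, agg)
  nb <- lapply(normal_hat$bins, agg)
  values <- mapply(function(t, n) {
    lr <- ifelse(t > 0 & n > 0, log2(t / n), NA_real_)
    lr
  }, tb, nb, SIMPLIFY = FALSE)
  structure(list(bin_size = as.integer(bin_size), smoothed = FALSE,
                 values = values, tumor_bins = tb, normal_bins = nb),
            class = "lr_track")
}

#' @export
print.lr_track <- function(x, ...) {
  cat(sprintf("lr_track: %d chromosome(s), bin_size=%d, smoothed=%s\n",
              length(x$values), x$bin_size, x$smoothed))
  invisible(x)
}

#' Sliding-median smoothing of a log-ratio track
#'
#' Replaces the value at each bin with the median of the bins within
#' `half_window` on either side (a centered window of `2*half_window + 1`
#' bins, truncated at chromosome edges). Masked (`NA`) bins are excluded
#' from every window's median and remain masked in the output. A window
#' wider than the chromosome truncates to the whole chromosome with a
#' warning.
#'
#' @param lr unsmoothed `lr_track`.
#' @param half_window half-window in bins; the default 500 gives the
#'   conventional 1000-bin total window.
#' @return The smoothed `lr_track` (`smoothed = TRUE`).
#' @export
smooth_lr <- function(lr, half_window = 500L) {
  stopifnot(inherits(lr, "lr_track"), half_window >= 0)
  if (isTRUE(lr$smoothed)) stop("track is already smoothed")
  hw <- as.integer(half_window)
  out <- lr
  out$values <- lapply(lr$values, function(v) sliding_median(v, hw))
  out$smoothed <- TRUE
  out
}

# truncated-window sliding median; NA values excluded from windows and
# preserved in place. Uses stats::runmed for full interior windows when
# the track has no masked bins.
sliding_median <- function(v, hw) {
  n <- length(v)
  if (n == 0L) return(v)
  if (2L * hw + 1L > n) {
    warning("smoothing window wider than chromosome; truncating to ",
            n, " bins")
  }
  if (!anyNA(v)) {
    k <- min(2L * hw + 1L, if (n %% 2L == 0L) n - 1L else n)
    if (k >= 3L) {
      out <- stats::runmed(v, k, endrule = "keep")
      edge <- (k - 1L) %/% 2L
      for (b in seq_len(min(edge, n))) {
        out[b] <- stats::median(v[max(1L, b - hw):min(n, b + hw)])
      }
      for (b in seq.int(max(1L, n - edge + 1L), n)) {
        out[b] <- stats::median(v[max(1L, b - hw):min(n, b + hw)])
      }
      return(as.numeric(out))
    }
  }
  vapply(seq_len(n), function(b) {
    w <- v[max(1L, b - hw):min(n, b + hw)]
    if (is.na(v[b])) NA_real_ else stats::median(w, na.rm = TRUE)
  }, numeric(1))
}

#' Segment a smoothed track into constant-level regions
#'
#' Scans each chromosome for maximal runs of bins whose smoothed values
#' differ by at most `tol` from the run's first value; each run becomes
#' one segment. The segment log-ratio is recomputed from the raw binned
#' totals, `log2(sum tumor / sum normalized normal)` over the segment's
#' bins — not as the mean of smoothed values. Masked bins form their own
#' (log-ratio `NA`) segments so that segments tile every chromosome.
#'
#' @param smoothed smoothed `lr_track` (must carry the binned totals, i.e.
#'   come from [bin_log_ratio()] + [smooth_lr()]).
#' @param tol constancy tolerance on smoothed values; the default 1e-9
#'   only guards floating-point noise.
#' @param sample_id sample label stamped on segments.
#' @return data.frame of segments: `chrom`, `start`, `end` (0-based
#'   half-open bp), `n_bins`, `lr` (`NA` over masked gaps), `call`
#'   (`"unset"`), `sample_id`.
#' @export
segment_constant <- function(smoothed, tol = 1e-9, sample_id = "sample") {
  stopifnot(inherits(smoothed, "lr_track"), isTRUE(smoothed$smoothed))
  bs <- smoothed$bin_size
  res <- lapply(names(smoothed$values), function(ch) {
    v <- smoothed$values[[ch]]
    n <- length(v)
    if (n == 0L) return(NULL)
    run_id <- integer(n)
    cur <- 1L
    anchor <- v[1L]
    run_id[1L] <- cur
    for (b in seq_len(n)[-1L]) {
      same <- if (is.na(v[b]) || is.na(anchor)) {
        is.na(v[b]) && is.na(anchor)
      } else {
        abs(v[b] - anchor) <= tol
      }
      if (!same) {
        cur <- cur + 1L
        anchor <- v[b]
      }
      run_id[b] <- cur
    }
    first <- which(!duplicated(run_id))
    last <- c(first[-1L] - 1L, n)
    tb <- smoothed$tumor_bins[[ch]]
    nb <- smoothed$normal_bins[[ch]]
    lr <- mapply(function(a, b2) {
      ts <- sum(tb[a:b2]); ns <- sum(nb[a:b2])
      if (ts > 0 && ns > 0) log2(ts / ns) else NA_real_
    }, first, last)
    masked <- is.na(v[first])
    lr[masked] <- NA_real_
    data.frame(chrom = ch,
               start = (first - 1L) * as.numeric(bs),
               end = pmin(last * as.numeric(bs), Inf),
               n_bins = last - first + 1L,
               lr = lr, call = "unset", sample_id = sample_id,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Classify segments as gain, loss or neutral
#'
#' A segment is a gain when its log-ratio strictly exceeds `gain_thr` and
#' its length strictly exceeds `min_len`; a loss when the log-ratio is
#' strictly below `loss_thr` at the same length requirement; otherwise
#' neutral. A log-ratio exactly at a threshold is neutral. Masked
#' (log-ratio `NA`) segments are neutral.
#'
#' @param segments data.frame from [segment_constant()] (or any frame with
#'   `start`, `end`, `lr`).
#' @param gain_thr,loss_thr log2-ratio thresholds, defaults +0.2 / -0.2.
#' @param min_len minimum event length in bp (strict), default 100000.
#' @return The segment data.frame with `call` set.
#' @export
classify_segments <- function(segments, gain_thr = 0.2, loss_thr = -0.2,
                              min_len = 1e5) {
  stopifnot(all(c("start", "end", "lr") %in% names(segments)))
  len <- segments$end - segments$start
  lr <- segments$lr
  call <- rep("neutral", nrow(segments))
  call[!is.na(lr) & lr > gain_thr & len > min_len] <- "gain"
  call[!is.na(lr) & lr < loss_thr & len > min_len] <- "loss"
  segments$call <- call
  segments
}

#' Run the full read-depth CNV pipeline on one tumor/normal pair
#'
#' Convenience wrapper chaining [normalize_normal()], [bin_log_ratio()],
#' [smooth_lr()], [segment_constant()] and [classify_segments()].
#'
#' @inheritParams normalize_normal
#' @inheritParams bin_log_ratio
#' @inheritParams smooth_lr
#' @inheritParams segment_constant
#' @inheritParams classify_segments
#' @return Classified segment data.frame (see [classify_segments()]).
#' @examples
#' gs <- genome_spec(c(chr1 = 6e6), bin_size = 3000)
#' ev <- data.frame(chrom = "chr1", start = 2.4e6, end = 3.0e6, true_lr = 1)
#' rd <- gen_rd_profiles(gs, ev, base_depth = 100, noise_sd = 0, seed = 1)
#' seg <- call_cnv_segments(rd$tumor, rd$normal, half_window = 20)
#' seg[seg$call != "neutral", ]
#' @export
call_cnv_segments <- function(tumor, normal, bin_size = 3000L,
                              half_window = 500L, tol = 1e-9,
                              gain_thr = 0.2, loss_thr = -0.2,
                              min_len = 1e5, sample_id = tumor$sample_id) {
  nh <- normalize_normal(tumor, normal)
  lr <- bin_log_ratio(tumor, nh, bin_size)
  sm <- smooth_lr(lr, half_window)
  seg <- segment_constant(sm, tol, sample_id = sample_id)
  # clip trailing partial-bin coordinates to the track length implied by
  # the profile (last bin may be shorter than bin_size)
  for (ch in names(tumor$bins)) {
    chr_len <- length(tumor$bins[[ch]]) * as.numeric(tumor$bin_size)
    i <- seg$chrom == ch
    seg$end[i] <- pmin(seg$end[i], chr_len)
  }
  classify_segments(seg, gain_thr, loss_thr, min_len)
}

#' Intersect pipeline calls with an external caller's segments
#'
#' Keeps pipeline segments that overlap (by at least 1 bp) an external
#' segment of the same sign — the plumbing used to retain only the
#' strongest externally-called events that also survive the
#' signal-processing filter.
#'
#' @param calls classified segment data.frame (`call` in gain/loss).
#' @param external data.frame with `chrom`, `start`, `end`, `lr` (sign
#'   carries the event direction).
#' @return The subset of `calls` (gain/loss rows only) confirmed by an
#'   external segment of matching sign.
#' @export
intersect_calls <- function(calls, external) {
  ev <- calls[calls$call %in% c("gain", "loss"), , drop = FALSE]
  if (nrow(ev) == 0L || nrow(external) == 0L) return(ev[0L, ])
  keep <- vapply(seq_len(nrow(ev)), function(i) {
    same <- external$chrom == ev$chrom[i] &
      sign(external$lr) == sign(ev$lr[i])
    any(same & external$start < ev$end[i] & external$end > ev$start[i])
  }, logical(1))
  ev[keep, , drop = FALSE]
}

#' Score recovery of planted CNV events
#'
#' Compares classified calls against planted truth. In `exact` mode a
#' planted event counts as recovered only if a call of the right type has
#' identical bin-aligned boundaries; otherwise an overlap of at least
#' `min_overlap_frac` of the event's length suffices. Precision is scored
#' symmetrically over the called gain/loss segments.
#'
#' @param calls classified segment data.frame.
#' @param truth planted-event data.frame with `chrom`, `true_lr` and
#'   either `bin_start`/`bin_end` or `start`/`end`.
#' @param exact logical; require exact boundary recovery.
#' @param min_overlap_frac overlap fraction for non-exact matching.
#' @return list with `recall`, `precision`, `n_truth`, `n_called`.
#' @export
score_cnv_recovery <- function(calls, truth, exact = FALSE,
                               min_overlap_frac = 0.5) {
  ts <- if ("bin_start" %in% names(truth)) truth$bin_start else truth$start
  te <- if ("bin_end" %in% names(truth)) truth$bin_end else truth$end
  ttype <- ifelse(truth$true_lr > 0, "gain", "loss")
  ev <- calls[calls$call %in% c("gain", "loss"), , drop = FALSE]

  match_one <- function(ch, s, e, type) {
    cand <- ev$chrom == ch & ev$call == type
    if (!any(cand)) return(FALSE)
    if (exact) {
      return(any(cand & ev$start == s & ev$end == e))
    }
    ov <- pmin(ev$end, e) - pmax(ev$start, s)
    any(cand & ov >= min_overlap_frac * (e - s))
  }
  rec <- vapply(seq_len(nrow(truth)), function(i)
    match_one(truth$chrom[i], ts[i], te[i], ttype[i]), logical(1))
  prec <- vapply(seq_len(nrow(ev)), function(i) {
    cand <- truth$chrom == ev$chrom[i] & ttype == ev$call[i]
    if (!any(cand)) return(FALSE)
    if (exact) return(any(cand & ts == ev$start[i] & te == ev$end[i]))
    ov <- pmin(te, ev$end[i]) - pmax(ts, ev$start[i])
    any(cand & ov >= min_overlap_frac * (te - ts))
  }, logical(1))
  list(recall = if (nrow(truth)) mean(rec) else NA_real_,
       precision = if (nrow(ev)) mean(prec) else NA_real_,
       n_truth = nrow(truth), n_called = nrow(ev))
}
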