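#' Build the genome-wide 1-Mb bin grid for a genome
#'
#' @param spec [genome_spec()].
#' @param map_bin bin width in bp (default 1 Mb).
#' @return data.frame `chrom`, `bin_start`, `bin_end` tiling the genome.
#' @export
map_bins <- function(spec, map_bin = 1e6) {
  stopifnot(inherits(spec, "genome_spec"), map_bin > 0)
  res <- lapply(seq_len(nrow(spec$chromosomes)), function(i) {
    len <- spec$chromosomes$length[i]
    nb <- ceiling(len / map_bin)
    s <- (seq_len(nb) - 1) * map_bin
    data.frame(chrom = spec$chromosomes$chrom[i],
               bin_start = s, bin_end = pmin(s + map_bin, len),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Per-bin cohort frequency of gain and loss events
#'
#' Maps each sample's classified segments onto a fixed genome-wide bin
#' grid and reports, per bin and event type, the fraction of cohort
#' samples with at least one segment of that type overlapping the bin by
#' at least 1 bp. A segment straddling a bin boundary is counted in every
#' bin it touches.
#'
#' @param calls named list of per-sample classified segment data.frames
#'   (columns `chrom`, `start`, `end`, `call`).
#' @param spec [genome_spec()] shared by all samples.
#' @param samples sample names forming the cohort; defaults to
#'   `names(calls)`. The cohort must be non-empty.
#' @param map_bin bin width in bp, default 1 Mb.
#' @return data.frame `chrom`, `bin_start`, `bin_end`, `gain_freq`,
#'   `loss_freq` with attribute `n_samples`.
#' @export
bin_frequency_map <- function(calls, spec, samples = names(calls),
                              map_bin = 1e6) {
  if (length(samples) == 0L) stop("cohort is empty")
  missing <- setdiff(samples, names(calls))
  if (length(missing)) stop("no calls for sample: ", missing[1L])
  grid <- map_bins(spec, map_bin)
  # global bin index: offset per chromosome
  nb <- tapply(grid$bin_start, grid$chrom, length)
  offs <- stats::setNames(
    cumsum(c(0, as.numeric(nb[unique(grid$chrom)][-length(nb)]))),
    unique(grid$chrom))
  total <- nrow(grid)
  gain <- numeric(total)
  loss <- numeric(total)
  for (sid in samples) {
    seg <- calls[[sid]]
    for (type in c("gain", "loss")) {
      s <- seg[seg$call == type, , drop = FALSE]
      if (nrow(s) == 0L) next
      idx <- unlist(lapply(seq_len(nrow(s)), function(i) {
        first <- floor(s$start[i] / map_bin)
        last <- floor((s$end[i] - 1) / map_bin)
        offs[[s$chrom[i]]] + seq.int(first, last) + 1L
      }))
      idx <- unique(idx)
      if (type == "gain") gain[idx] <- gain[idx] + 1
      else loss[idx] <- loss[idx] + 1
    }
  }
  grid$gain_freq <- gain / length(samples)
  grid$loss_freq <- loss / length(samples)
  attr(grid, "n_samples") <- length(samples)
  grid
}
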