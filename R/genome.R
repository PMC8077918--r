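#' Define a genome partition
#'
#' A `genome_spec` records the chromosomes of a (possibly synthetic) genome
#' and the bin size at which read-depth tracks are stored. All pipeline
#' stages that need to agree on a coordinate system take one of these.
#'
#' @param chromosomes data.frame with columns `chrom` (character, unique)
#'   and `length` (integer bp, > 0), or a named numeric vector of lengths.
#' @param bin_size bin width in bp (> 0) for read-depth storage.
#' @return An object of class `genome_spec`: a list with `chromosomes`
#'   (data.frame) and `bin_size`.
#' @examples
#' genome_spec(c(chr1 = 30e6, chr2 = 20e6), bin_size = 3000)
#' @export
genome_spec <- function(chromosomes, bin_size = 3000L) {
  if (is.numeric(chromosomes) && !is.null(names(chromosomes))) {
    chromosomes <- data.frame(
      chrom = names(chromosomes),
      length = as.numeric(unname(chromosomes)),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(is.data.frame(chromosomes),
            all(c("chrom", "length") %in% names(chromosomes)))
  if (anyDuplicated(chromosomes$chrom)) {
    stop("chromosome names must be unique")
  }
  if (any(chromosomes$length <= 0)) stop("chromosome lengths must be > 0")
  if (length(bin_size) != 1L || bin_size <= 0) stop("bin_size must be > 0")
  structure(
    list(chromosomes = chromosomes[, c("chrom", "length")],
         bin_size = as.integer(bin_size)),
    class = "genome_spec"
  )
}

#' @export
print.genome_spec <- function(x, ...) {
  cat(sprintf("genome_spec: %d chromosome(s), %.3g bp total, bin_size=%d\n",
              nrow(x$chromosomes), sum(x$chromosomes$length), x$bin_size))
  invisible(x)
}

# number of bins per chromosome (trailing partial bin counts as one)
n_bins <- function(spec, bin_size = spec$bin_size) {
  stats::setNames(as.integer(ceiling(spec$chromosomes$length / bin_size)),
                  spec$chromosomes$chrom)
}

chrom_length <- function(spec, chrom) {
  i <- match(chrom, spec$chromosomes$chrom)
  if (any(is.na(i))) stop("unknown chromosome: ", chrom[is.na(i)][1L])
  spec$chromosomes$length[i]
}

#' Derive a submodule seed from a global seed
#'
#' All generators accept a single global seed; independent random streams
#' for submodules are derived deterministically by hashing a text label
#' into the seed. The result always fits in a 32-bit signed integer.
#'
#' @param seed integer global seed.
#' @param label character label naming the consumer stream.
#' @return A derived integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(length(seed) == 1L, length(label) == 1L)
  h <- 0
  for (code in utf8ToInt(label)) {
    h <- (h * 131 + code) %% 2147483647
  }
  as.integer((abs(as.numeric(seed)) * 48271 + h) %% 2147483646 + 1)
}
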