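#' Mutation-class labels
#'
#' Pyrimidine-centered substitution classes: the 6 single-nucleotide
#' classes `C>A ... T>G`, or the 96 trinucleotide classes written
#' `{5'}[ref>alt]{3'}` (e.g. `"A[C>T]G"`), ordered by substitution class,
#' then 5' flank, then 3' flank.
#'
#' @param mode 6 or 96.
#' @return Character vector of class labels.
#' @export
spectrum_classes <- function(mode = 96) {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  if (mode == 6) return(subs)
  if (mode != 96) stop("mode must be 6 or 96")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s) {
    as.vector(t(outer(bases, bases, function(f5, f3)
      paste0(f5, "[", s, "]", f3))))
  }))
}

rev_comp <- function(x) {
  vapply(strsplit(chartr("ACGT", "TGCA", x), ""), function(ch)
    paste(rev(ch), collapse = ""), character(1))
}

#' Build a mutation spectrum from somatic SNVs
#'
#' Counts mutations into pyrimidine-centered classes (purine-reference
#' mutations are reverse-complemented, together with their trinucleotide
#' context) and normalizes to proportions.
#'
#' @param snvs data.frame with columns `ref`, `alt` and (for `mode = 96`)
#'   `context`, the 3-base reference context whose middle base equals
#'   `ref`.
#' @param mode 6 (single-nucleotide) or 96 (trinucleotide) classes.
#' @return A `mutation_spectrum`: list with `mode`, `labels`, `counts`,
#'   `proportions` (non-negative, summing to 1).
#' @examples
#' build_spectrum(data.frame(ref = "G", alt = "A", context = "TGT"), 96)
#' @export
build_spectrum <- function(snvs, mode = 96) {
  stopifnot(all(c("ref", "alt") %in% names(snvs)), nrow(snvs) >= 1)
  ref <- toupper(snvs$ref); alt <- toupper(snvs$alt)
  ok <- ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  if (!all(ok)) stop("invalid base in ref/alt")
  if (any(ref == alt)) stop("ref must differ from alt")

  if (mode == 96) {
    if (!"context" %in% names(snvs)) stop("mode 96 requires a context column")
    ctx <- toupper(snvs$context)
    if (any(nchar(ctx) != 3L)) stop("context must be 3 bases")
    if (any(substr(ctx, 2, 2) != ref)) {
      stop("context middle base must equal ref")
    }
  }

  flip <- ref %in% c("A", "G")
  comp <- function(b) chartr("ACGT", "TGCA", b)
  ref2 <- ifelse(flip, comp(ref), ref)
  alt2 <- ifelse(flip, comp(alt), alt)
  labels <- spectrum_classes(mode)
  if (mode == 6) {
    cls <- paste0(ref2, ">", alt2)
  } else {
    ctx2 <- ctx
    if (any(flip)) {
      ctx2[flip] <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAStringSet(ctx[flip])))
    }
    cls <- paste0(substr(ctx2, 1, 1), "[", ref2, ">", alt2, "]",
                  substr(ctx2, 3, 3))
  }
  counts <- table(factor(cls, levels = labels))
  structure(list(mode = mode, labels = labels,
                 counts = as.integer(counts),
                 proportions = as.numeric(counts) / sum(counts)),
            class = "mutation_spectrum")
}

#' @export
print.mutation_spectrum <- function(x, ...) {
  cat(sprintf("mutation_spectrum: %d classes, %d mutations\n",
              x$mode, sum(x$counts)))
  invisible(x)
}

#' Fit non-negative signature weights to a 96-class spectrum
#'
#' Minimizes the squared error between the observed spectrum and a
#' non-negative combination of reference signatures with total weight at
#' most 1. Weights below `trim` are zeroed and the fit repeated on the
#' surviving signatures until stable. Deterministic.
#'
#' @param spectrum a 96-class `mutation_spectrum` or a numeric 96-vector
#'   of proportions.
#' @param reference 96 x S numeric matrix; each column a reference
#'   signature (proportions summing to 1). Column names name the
#'   signatures.
#' @param trim weight threshold below which a signature is dropped,
#'   default 0.06.
#' @return Named non-negative weight vector (sum <= 1) with attribute
#'   `residual` (final residual sum of squares).
#' @export
fit_signature_weights <- function(spectrum, reference, trim = 0.06) {
  b <- if (inherits(spectrum, "mutation_spectrum")) spectrum$proportions
       else as.numeric(spectrum)
  reference <- as.matrix(reference)
  if (ncol(reference) < 1L) stop("need at least one reference signature")
  stopifnot(length(b) == nrow(reference))
  if (is.null(colnames(reference))) {
    colnames(reference) <- paste0("sig", seq_len(ncol(reference)))
  }

  nnls_sum1 <- function(A, y) {
    w <- pracma::lsqnonneg(A, y)$x
    if (sum(w) > 1 + 1e-9) {
      # re-solve with the total-weight budget enforced via a heavily
      # weighted sum-to-one row
      M <- 1e6
      w <- pracma::lsqnonneg(rbind(A, M * rep(1, ncol(A))), c(y, M))$x
    }
    w
  }

  active <- seq_len(ncol(reference))
  repeat {
    w_act <- nnls_sum1(reference[, active, drop = FALSE], b)
    drop <- w_act < trim & w_act > 0
    small <- which(w_act < trim)
    if (length(small) == 0L || length(small) == length(active)) break
    active <- active[w_act >= trim]
  }
  w <- numeric(ncol(reference))
  w_act[w_act < trim] <- 0
  w[active] <- w_act
  names(w) <- colnames(reference)
  attr(w, "residual") <- sum((b - as.numeric(reference %*% w))^2)
  w
}
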