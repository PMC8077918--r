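#' Detect loss of heterozygosity from paired site calls
#'
#' A site is called LOH when (i) the normal genotype is heterozygous and
#' (ii) the tumor alternate-allele fraction is within `af_tol` of 0 or 1
#' at a tumor depth of at least `min_tumor_depth`. Observed allele
#' fractions are never exactly 0.5 in real data, so criterion (i) is
#' carried by the genotype call rather than the literal frequency.
#'
#' @param sites data.frame with columns `chrom`, `pos`, `normal_gt`
#'   (`hom_ref`/`het`/`hom_alt`), `t_ref`, `t_alt`.
#' @param min_tumor_depth minimum tumor depth (`t_ref + t_alt`),
#'   default 10.
#' @param af_tol tolerance around 0/1 for the tumor allele fraction,
#'   default 0.02.
#' @return The subset of `sites` called LOH, with added columns
#'   `tumor_af` and `direction` (`"to_ref"` or `"to_alt"`). Each input
#'   site appears at most once.
#' @export
detect_loh <- function(sites, min_tumor_depth = 10L, af_tol = 0.02) {
  stopifnot(all(c("chrom", "pos", "normal_gt", "t_ref", "t_alt") %in%
                  names(sites)))
  if (any(sites$t_ref < 0 | sites$t_alt < 0)) {
    stop("read counts must be non-negative")
  }
  depth <- sites$t_ref + sites$t_alt
  af <- ifelse(depth > 0, sites$t_alt / depth, NA_real_)
  hit <- sites$normal_gt == "het" & depth >= min_tumor_depth &
    !is.na(af) & (af <= af_tol | af >= 1 - af_tol)
  out <- sites[hit, , drop = FALSE]
  out$tumor_af <- af[hit]
  out$direction <- ifelse(out$tumor_af <= af_tol, "to_ref", "to_alt")
  out
}
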