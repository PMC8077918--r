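#' Simulate paired tumor/normal read-depth profiles with planted CNVs
#'
#' Generates binned read-depth tracks for a tumor and its matched normal on
#' a shared genome partition. The normal track fluctuates around
#' `base_depth` reads per bin; the tumor track is multiplied by
#' `2^true_lr` inside each planted event (partial boundary bins are scaled
#' in proportion to their overlap). Noise is Gaussian on bin totals with
#' standard deviation `noise_sd * sqrt(base_depth)`; a per-bin Poisson mode
#' is available for count-level realism.
#'
#' @param spec [genome_spec()].
#' @param events data.frame of planted CNVs: columns `chrom`, `start`,
#'   `end` (0-based half-open bp) and `true_lr` (log2 units, non-zero).
#'   May have zero rows.
#' @param base_depth expected reads per bin in the normal (> 0).
#' @param noise_sd noise scale (>= 0); 0 gives deterministic tracks.
#' @param seed integer seed; output is a pure function of arguments.
#' @param noise_model `"gaussian"` (default, noise on bin totals) or
#'   `"poisson"` (bin totals drawn Poisson around their expectation;
#'   `noise_sd` is ignored).
#' @return list with `tumor` and `normal` (each an `rd_profile`: fields
#'   `sample_id`, `tissue`, `bin_size`, `bins` = per-chromosome numeric
#'   vectors) and `truth` (the planted events, bin-aligned coordinates
#'   added as `bin_start`/`bin_end`).
#' @examples
#' gs <- genome_spec(c(chr1 = 3e6), bin_size = 3000)
#' ev <- data.frame(chrom = "chr1", start = 9e5, end = 1.2e6, true_lr = 1)
#' rd <- gen_rd_profiles(gs, ev, base_depth = 100, noise_sd = 0, seed = 1)
#' @export
gen_rd_profiles <- function(spec, events, base_depth, noise_sd, seed,
                            noise_model = c("gaussian", "poisson")) {
  noise_model <- match.arg(noise_model)
  stopifnot(inherits(spec, "genome_spec"), base_depth > 0, noise_sd >= 0)
  if (is.null(events) || nrow(as.data.frame(events)) == 0L) {
    events <- data.frame(chrom = character(), start = numeric(),
                         end = numeric(), true_lr = numeric())
  }
  events <- as.data.frame(events)
  stopifnot(all(c("chrom", "start", "end", "true_lr") %in% names(events)))
  if (nrow(events)) {
    if (any(events$start >= events$end)) stop("event start must be < end")
    if (any(events$true_lr == 0)) stop("planted events must have true_lr != 0")
    len <- chrom_length(spec, events$chrom)
    bad <- events$start < 0 | events$end > len
    if (any(bad)) {
      b <- which(bad)[1L]
      stop(sprintf("event outside chromosome bounds: %s:%d-%d (length %d)",
                   events$chrom[b], events$start[b], events$end[b], len[b]))
    }
  }

  bs <- spec$bin_size
  nb <- n_bins(spec)
  make_track <- function(mult_list, tissue, stream) {
    set.seed(derive_seed(seed, paste0("rd_", tissue, "_", stream)))
    bins <- lapply(spec$chromosomes$chrom, function(ch) {
      mu <- base_depth * mult_list[[ch]]
      v <- switch(noise_model,
        gaussian = mu + if (noise_sd > 0)
          stats::rnorm(length(mu), 0, noise_sd * sqrt(base_depth)) else 0,
        poisson = as.numeric(stats::rpois(length(mu), mu))
      )
      pmax(v, 0)
    })
    names(bins) <- spec$chromosomes$chrom
    structure(list(sample_id = "sim", tissue = tissue, bin_size = bs,
                   bins = bins),
              class = "rd_profile")
  }

  unit <- lapply(stats::setNames(nm = spec$chromosomes$chrom),
                 function(ch) rep(1, nb[[ch]]))
  mult <- unit
  for (i in seq_len(nrow(events))) {
    ch <- events$chrom[i]
    idx0 <- seq(floor(events$start[i] / bs), ceiling(events$end[i] / bs) - 1L)
    b_start <- idx0 * bs
    b_end <- pmin(b_start + bs, chrom_length(spec, ch))
    ov <- pmin(events$end[i], b_end) - pmax(events$start[i], b_start)
    frac <- ov / (b_end - b_start)
    j <- idx0 + 1L
    mult[[ch]][j] <- mult[[ch]][j] * (frac * 2^events$true_lr[i] + (1 - frac))
  }

  truth <- events
  if (nrow(truth)) {
    truth$bin_start <- floor(truth$start / bs) * bs
    truth$bin_end <- pmin(ceiling(truth$end / bs) * bs,
                          chrom_length(spec, truth$chrom))
  }
  list(tumor = make_track(mult, "tumor", "t"),
       normal = make_track(unit, "normal", "n"),
       truth = truth)
}

#' Simulate a paired-genotype site table with a planted LOH fraction
#'
#' Emits one row per germline site with the normal genotype and tumor
#' ref/alt read counts, plus a per-site truth label. Exactly
#' `round(n_sites * het_fraction)` sites are heterozygous in the normal;
#' of those, `round(. * loh_fraction)` are planted as loss of
#' heterozygosity (tumor allele fraction exactly 0 or 1). Remaining sites
#' are split between homozygous reference and homozygous alternate.
#'
#' @param n_sites number of sites (> 0).
#' @param het_fraction fraction of sites heterozygous in the normal, in
#'   \[0, 1\].
#' @param loh_fraction fraction of het sites planted as LOH, in \[0, 1\].
#' @param tumor_depth mean tumor depth (Poisson, truncated >= 1) under the
#'   `"binomial"` noise mode; exact depth under `"none"`.
#' @param seed integer seed.
#' @param noise `"binomial"` (counts resampled binomially around the true
#'   allele fraction) or `"none"` (counts are exact: `alt = round(depth *
#'   af)` at constant depth).
#' @return data.frame with `chrom`, `pos` (1-based), `normal_gt`
#'   (`hom_ref`/`het`/`hom_alt`), `t_ref`, `t_alt`, and truth columns
#'   `true_af` and `true_loh` (logical).
#' @export
gen_genotype_table <- function(n_sites, het_fraction, loh_fraction,
                               tumor_depth, seed,
                               noise = c("binomial", "none")) {
  noise <- match.arg(noise)
  if (length(n_sites) != 1L || n_sites <= 0) stop("n_sites must be > 0")
  stopifnot(het_fraction >= 0, het_fraction <= 1,
            loh_fraction >= 0, loh_fraction <= 1, tumor_depth >= 1)
  set.seed(derive_seed(seed, "genotype_table"))

  n_het <- round(n_sites * het_fraction)
  n_loh <- round(n_het * loh_fraction)
  n_hom <- n_sites - n_het

  gt <- c(rep("het", n_het),
          rep(c("hom_ref", "hom_alt"), length.out = n_hom))
  true_loh <- c(rep(TRUE, n_loh), rep(FALSE, n_sites - n_loh))
  true_af <- ifelse(gt == "het", 0.5, ifelse(gt == "hom_alt", 1, 0))
  # planted LOH: het site drifts to one homozygous state in the tumor
  true_af[true_loh] <- sample(c(0, 1), n_loh, replace = TRUE)

  ord <- sample.int(n_sites)
  gt <- gt[ord]; true_loh <- true_loh[ord]; true_af <- true_af[ord]

  if (noise == "binomial") {
    depth <- stats::rpois(n_sites, tumor_depth)
    depth[depth < 1L] <- 1L
    alt <- stats::rbinom(n_sites, depth, true_af)
  } else {
    depth <- rep(as.integer(tumor_depth), n_sites)
    alt <- as.integer(round(depth * true_af))
  }
  data.frame(
    chrom = "chr1",
    pos = sort(sample.int(n_sites * 100L, n_sites)),
    normal_gt = gt,
    t_ref = as.integer(depth - alt),
    t_alt = as.integer(alt),
    true_af = true_af,
    true_loh = true_loh,
    stringsAsFactors = FALSE
  )
}

#' Simulate a somatic VAF table from a planted clone structure
#'
#' Each clone contributes `mutations_per_clone` somatic SNVs; a mutation
#' of a clone with cellular fraction f has true variant allele fraction
#' f/2 (diploid heterozygous convention). Per-site depth is Poisson around
#' `mean_depth` (truncated >= 1) and alt counts are binomial.
#'
#' @param clone_fractions cellular fractions in (0, 1\], sorted descending.
#' @param mutations_per_clone integer vector, same length.
#' @param mean_depth mean sequencing depth (>= 1).
#' @param seed integer seed.
#' @return data.frame `chrom`, `pos`, `ref_count`, `alt_count`,
#'   `true_clone` (1-based clone index), `true_vaf`.
#' @export
gen_vaf_table <- function(clone_fractions, mutations_per_clone, mean_depth,
                          seed) {
  if (length(clone_fractions) == 0L) stop("clone list must be non-empty")
  stopifnot(length(clone_fractions) == length(mutations_per_clone),
            all(clone_fractions > 0), all(clone_fractions <= 1),
            mean_depth >= 1)
  if (is.unsorted(rev(clone_fractions), strictly = FALSE)) {
    stop("clone_fractions must be sorted descending")
  }
  set.seed(derive_seed(seed, "vaf_table"))
  clone <- rep(seq_along(clone_fractions), mutations_per_clone)
  n <- length(clone)
  if (n == 0L) {
    return(data.frame(chrom = character(), pos = integer(),
                      ref_count = integer(), alt_count = integer(),
                      true_clone = integer(), true_vaf = numeric()))
  }
  vaf <- clone_fractions[clone] / 2
  depth <- stats::rpois(n, mean_depth)
  depth[depth < 1L] <- 1L
  alt <- stats::rbinom(n, depth, vaf)
  data.frame(
    chrom = "chr1",
    pos = sort(sample.int(n * 1000L, n)),
    ref_count = as.integer(depth - alt),
    alt_count = as.integer(alt),
    true_clone = clone,
    true_vaf = vaf
  )
}

#' Simulate a rooted taxonomy and per-read hit patterns
#'
#' Builds a random rooted taxonomy with `n_leaves` leaves and at most
#' `depth` levels below the root, then attaches reads whose hits reference
#' leaves. The truth node for each read is computed by brute-force
#' root-path intersection (independent of the package's LCA assigner).
#'
#' @param n_leaves number of leaf taxa (>= 1).
#' @param depth number of internal levels below the root (>= 1).
#' @param reads either an integer number of random reads (each hitting
#'   1-4 distinct leaves) or a list of character vectors of leaf names.
#' @param seed integer seed.
#' @return list with `taxonomy` (data.frame `node_id`, `parent_id`,
#'   `rank`, `name`; root has `parent_id == node_id`), `hits` (data.frame
#'   `read_id`, `leaves` comma-separated) and `truth` (data.frame
#'   `read_id`, `true_node`).
#' @export
gen_taxonomy_and_hits <- function(n_leaves, depth, reads, seed) {
  stopifnot(n_leaves >= 1, depth >= 1)
  set.seed(derive_seed(seed, "taxonomy"))

  # level sizes grow geometrically from the root to the leaf layer
  sizes <- unique(pmax(1L, round(n_leaves^(seq_len(depth - 1) / depth))))
  sizes <- c(1L, sizes[sizes < n_leaves], n_leaves)
  ids <- list("root")
  rows <- data.frame(node_id = "root", parent_id = "root", rank = "root",
                     name = "root", stringsAsFactors = FALSE)
  for (lv in seq_along(sizes)[-1L]) {
    k <- sizes[lv]
    is_leaf <- lv == length(sizes)
    id <- if (is_leaf) paste0("leaf", seq_len(k)) else
      paste0("n", lv - 1L, "_", seq_len(k))
    parent <- ids[[lv - 1L]][c(seq_along(ids[[lv - 1L]]),
                               sample(length(ids[[lv - 1L]]),
                                      max(0L, k - length(ids[[lv - 1L]])),
                                      replace = TRUE))][seq_len(k)]
    rows <- rbind(rows, data.frame(
      node_id = id, parent_id = parent,
      rank = if (is_leaf) "species" else paste0("level", lv - 1L),
      name = id, stringsAsFactors = FALSE))
    ids[[lv]] <- id
  }
  leaves <- ids[[length(sizes)]]
  # drop childless internal nodes so every non-leaf is on a root-leaf path
  repeat {
    internal <- setdiff(rows$node_id, leaves)
    childless <- setdiff(internal, c(rows$parent_id, "root"))
    if (!length(childless)) break
    rows <- rows[!rows$node_id %in% childless, ]
  }

  if (is.numeric(reads)) {
    reads <- lapply(seq_len(reads), function(i) {
      sample(leaves, sample.int(min(4L, n_leaves), 1L))
    })
  }
  bad <- setdiff(unlist(reads), leaves)
  if (length(bad)) stop("hit references unknown leaf: ", bad[1L])

  root_path <- function(node) {
    p <- node
    while (node != rows$parent_id[match(node, rows$node_id)]) {
      node <- rows$parent_id[match(node, rows$node_id)]
      p <- c(p, node)
    }
    p
  }
  truth <- vapply(reads, function(hit) {
    paths <- lapply(hit, root_path)
    common <- Reduce(intersect, paths)
    common[1L]  # paths are leaf-to-root; first shared entry is deepest
  }, character(1))

  rid <- paste0("read", seq_along(reads))
  list(
    taxonomy = rows,
    hits = data.frame(read_id = rid,
                      leaves = vapply(reads, paste, "", collapse = ","),
                      stringsAsFactors = FALSE),
    truth = data.frame(read_id = rid, true_node = truth,
                       stringsAsFactors = FALSE)
  )
}

#' Simulate binary per-sample features for two cohorts
#'
#' Feature k is present (1) with probability `p_a` in cohort A and `p_b`
#' in cohort B, independently across samples and features.
#'
#' @param n_a,n_b cohort sizes (>= 1).
#' @param effect named list (or data.frame with columns `p_a`, `p_b`) of
#'   per-feature probability pairs in \[0, 1\].
#' @param seed integer seed.
#' @return list with `labels` (data.frame `sample_id`, `cohort`) and
#'   `features` (data.frame, one 0/1 column per feature).
#' @export
gen_cohort_features <- function(n_a, n_b, effect, seed) {
  if (n_a < 1 || n_b < 1) stop("cohort sizes must be >= 1")
  if (is.data.frame(effect)) {
    effect <- stats::setNames(
      lapply(seq_len(nrow(effect)), function(i) c(effect$p_a[i], effect$p_b[i])),
      rownames(effect))
  }
  probs <- do.call(rbind, effect)
  stopifnot(ncol(probs) == 2, all(probs >= 0), all(probs <= 1))
  set.seed(derive_seed(seed, "cohort_features"))
  n <- n_a + n_b
  cohort <- rep(c("A", "B"), c(n_a, n_b))
  feat <- vapply(seq_len(nrow(probs)), function(k) {
    p <- ifelse(cohort == "A", probs[k, 1L], probs[k, 2L])
    stats::rbinom(n, 1L, p)
  }, integer(n))
  colnames(feat) <- names(effect)
  list(
    labels = data.frame(sample_id = sprintf("S%02d", seq_len(n)),
                        cohort = cohort, stringsAsFactors = FALSE),
    features = as.data.frame(feat)
  )
}

#' Simulate somatic SNVs from a signature mixture
#'
#' Draws `n` mutations whose trinucleotide-class distribution is the
#' mixture `reference %*% weights`; used to test round-trip recovery of
#' signature weights from a built spectrum.
#'
#' @param weights non-negative vector summing to 1, one entry per
#'   reference column.
#' @param reference 96 x S matrix of reference signatures (columns sum
#'   to 1), rows in [spectrum_classes()] order.
#' @param n number of mutations to draw.
#' @param seed integer seed.
#' @return data.frame `ref`, `alt`, `context` suitable for
#'   [build_spectrum()].
#' @export
gen_signature_snvs <- function(weights, reference, n, seed) {
  stopifnot(length(weights) == ncol(reference), all(weights >= 0),
            abs(sum(weights) - 1) < 1e-8, nrow(reference) == 96)
  set.seed(derive_seed(seed, "signature_snvs"))
  p <- as.numeric(reference %*% weights)
  cls <- sample(spectrum_classes(96), n, replace = TRUE, prob = p)
  ref <- substr(cls, 3, 3)
  data.frame(
    ref = ref,
    alt = substr(cls, 5, 5),
    context = paste0(substr(cls, 1, 1), ref, substr(cls, 7, 7)),
    stringsAsFactors = FALSE
  )
}

#' Simulate per-sample CNV segment calls from one event distribution
#'
#' Draws classified gain/loss segment calls for many samples from a single
#' generative distribution (Poisson number of events per sample, uniform
#' lengths, log-ratios sampled from `lr_choices`). Used for cohort-level
#' calibration experiments where both cohorts must share identical CNV
#' parameters.
#'
#' @param sample_ids character vector of sample names.
#' @param spec [genome_spec()].
#' @param events_per_sample Poisson mean number of events per sample.
#' @param length_range numeric length-2, event length range in bp.
#' @param lr_choices log-ratio magnitudes to sample from (sign random).
#' @param seed integer seed.
#' @return named list (per sample) of segment data.frames (`chrom`,
#'   `start`, `end`, `lr`, `call`).
#' @export
gen_segment_calls <- function(sample_ids, spec, events_per_sample = 4,
                              length_range = c(2e5, 5e6),
                              lr_choices = c(0.3, 0.6, 1.0), seed = 1L) {
  stopifnot(inherits(spec, "genome_spec"))
  set.seed(derive_seed(seed, "segment_calls"))
  lens <- stats::setNames(spec$chromosomes$length, spec$chromosomes$chrom)
  out <- lapply(sample_ids, function(sid) {
    k <- stats::rpois(1L, events_per_sample)
    if (k == 0L) {
      return(data.frame(chrom = character(), start = numeric(),
                        end = numeric(), lr = numeric(), call = character()))
    }
    ch <- sample(names(lens), k, replace = TRUE,
                 prob = lens / sum(lens))
    L <- stats::runif(k, length_range[1L], length_range[2L])
    L <- pmin(L, lens[ch])
    s <- floor(stats::runif(k, 0, lens[ch] - L))
    lr <- sample(lr_choices, k, replace = TRUE) *
      sample(c(-1, 1), k, replace = TRUE)
    data.frame(chrom = ch, start = s, end = s + round(L), lr = lr,
               call = ifelse(lr > 0, "gain", "loss"),
               stringsAsFactors = FALSE)
  })
  stats::setNames(out, sample_ids)
}
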