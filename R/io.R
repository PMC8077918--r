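#' Write a read-depth profile as bedGraph
#'
#' One record per bin, 0-based half-open coordinates, bin value in the
#' score column.
#'
#' @param profile an `rd_profile`.
#' @param path output file path.
#' @param spec optional [genome_spec()]; clips the last bin of each
#'   chromosome to the chromosome length.
#' @return `path`, invisibly.
#' @export
write_rd_bedgraph <- function(profile, path, spec = NULL) {
  bs <- profile$bin_size
  parts <- lapply(names(profile$bins), function(ch) {
    v <- profile$bins[[ch]]
    start0 <- (seq_along(v) - 1) * bs
    end0 <- start0 + bs
    if (!is.null(spec)) end0 <- pmin(end0, chrom_length(spec, ch))
    data.frame(chrom = ch, start0 = start0, end0 = end0, score = v)
  })
  df <- do.call(rbind, parts)
  gr <- GenomicRanges::GRanges(
    df$chrom, IRanges::IRanges(start = df$start0 + 1, end = df$end0),
    score = df$score)
  rtracklayer::export.bedGraph(gr, path)
  invisible(path)
}

#' Read a read-depth profile from bedGraph
#'
#' Expects records on a uniform bin grid (the trailing bin of a
#' chromosome may be partial).
#'
#' @param path bedGraph file.
#' @param spec [genome_spec()] giving chromosomes and bin size.
#' @param sample_id,tissue metadata stamped on the profile.
#' @return An `rd_profile`.
#' @export
read_rd_bedgraph <- function(path, spec, sample_id = "sample",
                             tissue = "tumor") {
  gr <- rtracklayer::import(path, format = "bedGraph")
  bs <- spec$bin_size
  nb <- n_bins(spec)
  bins <- lapply(stats::setNames(nm = spec$chromosomes$chrom), function(ch) {
    g <- gr[GenomicRanges::seqnames(gr) == ch]
    v <- numeric(nb[[ch]])
    if (length(g)) {
      idx <- (GenomicRanges::start(g) - 1) %/% bs + 1
      v[idx] <- GenomicRanges::mcols(g)$score
    }
    v
  })
  structure(list(sample_id = sample_id, tissue = tissue,
                 bin_size = as.integer(bs), bins = bins),
            class = "rd_profile")
}

#' @export
print.rd_profile <- function(x, ...) {
  cat(sprintf("rd_profile %s (%s): %d chromosome(s), bin_size=%d\n",
              x$sample_id, x$tissue, length(x$bins), x$bin_size))
  invisible(x)
}

#' Write classified segments as BED6
#'
#' `name` carries the call, `score` is `round(1000 * |lr|)` capped at
#' 1000, coordinates are 0-based half-open.
#'
#' @param segments classified segment data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_segments_bed <- function(segments, path) {
  score <- pmin(round(1000 * abs(ifelse(is.na(segments$lr), 0,
                                        segments$lr))), 1000)
  gr <- GenomicRanges::GRanges(
    segments$chrom,
    IRanges::IRanges(start = segments$start + 1, end = segments$end),
    name = segments$call, score = score)
  rtracklayer::export.bed(gr, path)
  invisible(path)
}

#' Read a BED segment file
#'
#' @param path BED file written by [write_segments_bed()] (or any BED
#'   whose name column holds gain/loss/neutral calls).
#' @return data.frame `chrom`, `start`, `end`, `call`, `lr` (recovered
#'   from the score column as `score/1000`, sign unknown hence `NA` for
#'   neutral and signed by call otherwise).
#' @export
read_segments_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  call <- as.character(GenomicRanges::mcols(gr)$name)
  score <- GenomicRanges::mcols(gr)$score
  lr <- ifelse(call == "gain", score / 1000,
               ifelse(call == "loss", -score / 1000, NA_real_))
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             call = call, lr = lr, stringsAsFactors = FALSE)
}

#' Read/write tab-separated tables
#'
#' Thin wrappers fixing the dialect used throughout (header, tabs, no
#' quoting, no row names).
#'
#' @param x data.frame to write.
#' @param path file path.
#' @return `read_tsv_table` returns a data.frame; `write_tsv_table`
#'   returns `path` invisibly.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv_table
#' @export
read_tsv_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE)
}

#' Read a taxonomy table
#'
#' TSV with columns `node_id`, `parent_id`, `rank`, `name`; the root has
#' `parent_id == node_id`.
#'
#' @param path file path.
#' @return A validated [taxonomy_tree()].
#' @export
read_taxonomy <- function(path) {
  taxonomy_tree(read_tsv_table(path))
}

#' Read a clone tree from JSON
#'
#' Expects `{"parents": [...], "mutations": [...]}` with 1-based parent
#' indices and the root marked by its own index (or 0).
#'
#' @param path JSON file path.
#' @return A [clone_tree()].
#' @export
read_clone_tree <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  clone_tree(j$parents, j$mutations)
}

#' Write a randomization summary as JSON
#'
#' @param summary a `randomization_summary` from [randomization_null()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_randomization_json <- function(summary, path) {
  jsonlite::write_json(
    list(n_iter = summary$n_iter, alpha = summary$alpha,
         adjust = summary$adjust, median = summary$median,
         min = summary$min, max = summary$max, counts = summary$counts),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
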