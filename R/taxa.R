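#' Validate a taxonomy tree table
#'
#' @param nodes data.frame with columns `node_id`, `parent_id`, `rank`,
#'   `name`; the root is the unique node with `parent_id == node_id`.
#' @return The validated data.frame with class `taxonomy_tree` and
#'   attribute `root`.
#' @export
taxonomy_tree <- function(nodes) {
  stopifnot(all(c("node_id", "parent_id", "rank", "name") %in% names(nodes)))
  if (anyDuplicated(nodes$node_id)) stop("duplicate node_id")
  root <- nodes$node_id[nodes$parent_id == nodes$node_id]
  if (length(root) != 1L) {
    stop("taxonomy must have exactly one root, found ", length(root))
  }
  unknown <- setdiff(nodes$parent_id, nodes$node_id)
  if (length(unknown)) stop("parent not in table: ", unknown[1L])
  # acyclicity: every node must reach the root
  pidx <- match(nodes$parent_id, nodes$node_id)
  ridx <- match(root, nodes$node_id)
  for (v in seq_len(nrow(nodes))) {
    seen <- logical(nrow(nodes))
    while (v != ridx) {
      if (seen[v]) stop("cycle in taxonomy at node ", nodes$node_id[v])
      seen[v] <- TRUE
      v <- pidx[v]
    }
  }
  structure(nodes, class = c("taxonomy_tree", "data.frame"), root = root)
}

# per-node path to root (node first), as a named list of id vectors
tax_paths <- function(tax) {
  pidx <- match(tax$parent_id, tax$node_id)
  root <- attr(tax, "root")
  ridx <- match(root, tax$node_id)
  paths <- vector("list", nrow(tax))
  for (i in seq_len(nrow(tax))) {
    v <- i
    p <- v
    while (v != ridx) {
      v <- pidx[v]
      p <- c(p, v)
    }
    paths[[i]] <- tax$node_id[p]
  }
  stats::setNames(paths, tax$node_id)
}

#' Filter out host-derived reads
#'
#' Removes reads with evidence of host origin: any qualifying host hit
#' (mismatch rate at most `max_mm_per_100bp` per 100 bp), overlap with
#' host repeat sequence, or host multi-mapping. `host_hits` counts host
#' alignments at acceptable mismatch rate; reads whose only host evidence
#' is a high-mismatch alignment are retained.
#'
#' @param reads data.frame with columns `read_id`, `length`, `host_hits`,
#'   `host_min_mm` (`NA` when no host alignment), `repeat_flag`.
#' @param max_mm_per_100bp mismatch-rate threshold (default 5 per 100 bp).
#' @param multimap_cap host multi-mapping search cap (default 200).
#' @param above_cap `"remove"` (default, conservative) or `"retain"` for
#'   reads whose host hit count exceeds the cap.
#' @return The retained subset of `reads`.
#' @export
filter_host <- function(reads, max_mm_per_100bp = 5, multimap_cap = 200L,
                        above_cap = c("remove", "retain")) {
  above_cap <- match.arg(above_cap)
  stopifnot(all(c("read_id", "length", "host_hits", "host_min_mm",
                  "repeat_flag") %in% names(reads)))
  mm_rate <- reads$host_min_mm / reads$length * 100
  confident_host <- !is.na(mm_rate) & mm_rate <= max_mm_per_100bp
  multi <- reads$host_hits >= 1L & reads$host_hits <= multimap_cap
  over <- reads$host_hits > multimap_cap & above_cap == "remove"
  drop <- confident_host | reads$repeat_flag | multi | over
  reads[!drop, , drop = FALSE]
}

#' Assign reads to their most parsimonious taxonomy node
#'
#' Returns, for each read, the lowest common ancestor of the leaves its
#' zero-mismatch exogenous hits map to.
#'
#' @param hits per-read hit genomes: a character vector (single read,
#'   genome ids) or a list of such vectors.
#' @param taxonomy [taxonomy_tree()].
#' @param genome_map named character vector mapping genome ids to leaf
#'   `node_id`s; defaults to the identity (hits already name leaves).
#' @return Node id (single read) or character vector of node ids.
#' @export
assign_parsimonious <- function(hits, taxonomy, genome_map = NULL) {
  if (!inherits(taxonomy, "taxonomy_tree")) taxonomy <- taxonomy_tree(taxonomy)
  single <- !is.list(hits)
  if (single) hits <- list(hits)
  if (any(lengths(hits) == 0L)) stop("each read must have at least one hit")
  paths <- tax_paths(taxonomy)
  depth <- lengths(paths)

  to_node <- function(g) {
    node <- if (is.null(genome_map)) g else unname(genome_map[g])
    if (any(is.na(node)) || !all(node %in% names(paths))) {
      stop("unmapped genome id: ",
           g[is.na(node) | !(node %in% names(paths))][1L])
    }
    node
  }
  out <- vapply(hits, function(g) {
    nodes <- unique(to_node(g))
    anc <- Reduce(intersect, paths[nodes])  # node-to-root order
    anc[1L]
  }, character(1))
  if (single) out[[1L]] else out
}

#' Summarize taxonomic assignments across samples
#'
#' Rolls per-read node assignments up the taxonomy (a read assigned to a
#' node counts for that node and all its ancestors), ranks taxa by total
#' read count, and — when cohort labels are supplied — tests per-taxon
#' presence/absence between the two cohorts with the Fisher exact test.
#'
#' @param assignments data.frame with `sample_id`, `node_id` (one row per
#'   assigned read).
#' @param taxonomy [taxonomy_tree()].
#' @param labels optional data.frame `sample_id`, `cohort` (two cohorts).
#' @param top_n number of top taxa to keep (default 100).
#' @return data.frame ranked by `total_reads`: `node_id`, `rank`, `name`,
#'   `total_reads`, `n_samples`, and with labels also `n_a`, `n_b`,
#'   `fisher_p`.
#' @export
summarize_taxa <- function(assignments, taxonomy, labels = NULL,
                           top_n = 100L) {
  if (!inherits(taxonomy, "taxonomy_tree")) taxonomy <- taxonomy_tree(taxonomy)
  if (nrow(assignments) < 1L) stop("need at least one assignment")
  paths <- tax_paths(taxonomy)
  # expand each read to (sample, ancestor) pairs, dedup nothing: counts
  # roll up; per-sample presence dedups below
  anc <- paths[assignments$node_id]
  expand <- data.frame(
    sample_id = rep(assignments$sample_id, lengths(anc)),
    node_id = unlist(anc, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  total <- table(expand$node_id)
  pres <- unique(expand)
  nsamp <- table(pres$node_id)

  out <- data.frame(node_id = names(total),
                    total_reads = as.integer(total),
                    stringsAsFactors = FALSE)
  out$n_samples <- as.integer(nsamp[out$node_id])
  out$rank <- taxonomy$rank[match(out$node_id, taxonomy$node_id)]
  out$name <- taxonomy$name[match(out$node_id, taxonomy$node_id)]

  if (!is.null(labels)) {
    groups <- split(labels$sample_id, labels$cohort)
    if (length(groups) != 2L) stop("labels must define exactly two cohorts")
    out$n_a <- vapply(out$node_id, function(nd)
      length(intersect(groups[[1L]], pres$sample_id[pres$node_id == nd])),
      integer(1))
    out$n_b <- vapply(out$node_id, function(nd)
      length(intersect(groups[[2L]], pres$sample_id[pres$node_id == nd])),
      integer(1))
    out$fisher_p <- vapply(seq_len(nrow(out)), function(i)
      fisher_exact_2x2(matrix(c(out$n_a[i], length(groups[[1L]]) - out$n_a[i],
                                out$n_b[i], length(groups[[2L]]) - out$n_b[i]),
                              2L, byrow = TRUE)), numeric(1))
  }
  out <- out[order(-out$total_reads, out$node_id), ]
  rownames(out) <- NULL
  utils::head(out, top_n)
}
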