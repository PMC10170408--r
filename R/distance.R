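#' Levenshtein edit distance between two sequences
#'
#' Unit-cost dynamic-programming edit distance (substitution, insertion,
#' deletion), computed row by row with two vectors.
#'
#' @param a,b Nonempty character strings.
#' @return Nonnegative integer distance.
#' @examples
#' ld_distance("KITTEN", "SITTING") # 3
#' @export
ld_distance <- function(a, b) {
  if (!is.character(a) || !is.character(b) || length(a) != 1L || length(b) != 1L ||
      is.na(a) || is.na(b) || !nzchar(a) || !nzchar(b)) {
    stop("`a` and `b` must be nonempty strings.", call. = FALSE)
  }
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  prev <- 0:length(cb)
  for (i in seq_along(ca)) {
    cur <- numeric(length(cb) + 1L)
    cur[1] <- i
    sub_cost <- prev[-length(prev)] + (ca[i] != cb)
    for (j in seq_along(cb)) {
      cur[j + 1L] <- min(cur[j] + 1, prev[j + 1L] + 1, sub_cost[j])
    }
    prev <- cur
  }
  as.integer(prev[length(prev)])
}

# All unordered pairs at Levenshtein distance exactly 1, found without
# computing the full distance matrix:
#   * substitutions: within each length bucket, hash each sequence L times
#     with one position masked; distinct sequences sharing a masked key
#     differ at exactly that position.
#   * single indels: a pair (s, t) with |s| = |t| + 1 is at LD 1 iff t
#     equals one of the |s| deletion variants of s.
# Returns a two-column integer matrix of indices into `sequences`.
#' @keywords internal
#' @noRd
ld1_pairs_fast <- function(sequences) {
  n <- length(sequences)
  if (n < 2L) return(matrix(integer(0), ncol = 2L))
  lens <- nchar(sequences)
  pairs <- vector("list", 0L)

  # substitution pairs within each length bucket
  for (L in sort(unique(lens))) {
    idx <- which(lens == L)
    if (length(idx) < 2L || L < 1L) next
    seqs <- sequences[idx]
    for (p in seq_len(L)) {
      masked <- paste0(substr(seqs, 1L, p - 1L), "\r", substr(seqs, p + 1L, L))
      dt <- data.table::data.table(kk = masked, id = idx)
      dup <- dt[, .N, by = "kk"][N > 1L, kk]
      if (length(dup) == 0L) next
      grp <- dt[kk %in% dup]
      hits <- grp[grp, on = "kk", allow.cartesian = TRUE][id < i.id, list(id, i.id)]
      if (nrow(hits) > 0L) {
        pairs[[length(pairs) + 1L]] <- as.matrix(hits)
      }
    }
  }

  # indel pairs between adjacent length buckets
  for (L in sort(unique(lens))) {
    long_idx <- which(lens == L + 1L)
    short_idx <- which(lens == L)
    if (length(long_idx) == 0L || length(short_idx) == 0L) next
    short_seqs <- sequences[short_idx]
    long_seqs <- sequences[long_idx]
    del_list <- lapply(seq_len(L + 1L), function(p) {
      paste0(substr(long_seqs, 1L, p - 1L), substr(long_seqs, p + 1L, L + 1L))
    })
    variants <- unlist(del_list, use.names = FALSE)
    owner <- rep(long_idx, times = L + 1L)
    hit <- match(variants, short_seqs)
    found <- which(!is.na(hit))
    if (length(found) > 0L) {
      mm <- cbind(short_idx[hit[found]], owner[found])
      mm <- unique(mm)
      pairs[[length(pairs) + 1L]] <- mm
    }
  }

  if (length(pairs) == 0L) return(matrix(integer(0), ncol = 2L))
  out <- do.call(rbind, pairs)
  out <- cbind(pmin(out[, 1L], out[, 2L]), pmax(out[, 1L], out[, 2L]))
  unique(out)
}

#' Build the LD=1 sequence-convergence network of a repertoire
#'
#' Nodes are the unique CDR3 amino-acid sequences; undirected edges
#' connect pairs at Levenshtein distance exactly 1. Edges are found by
#' length-bucketed masked-position hashing (substitutions) plus
#' deletion-variant hashing (single indels), which is equivalent to the
#' all-pairs dynamic-programming distance but near-linear in practice.
#' The connectivity fraction is edges divided by nodes, a global
#' sequence-convergence measure; isolated nodes count toward the
#' denominator.
#'
#' @param sequences Character vector of unique CDR3 amino-acid sequences.
#' @return An object of class `tcr_network`: list with `graph` (an
#'   \pkg{igraph} graph whose vertex names are the sequences), `degree`
#'   (named integer vector), `n_nodes`, `n_edges`,
#'   `connectivity_fraction`.
#' @examples
#' net <- build_ld1_network(c("CASSF", "CASTF", "CASSFG", "CAKKF"))
#' net$n_edges # 2
#' @export
build_ld1_network <- function(sequences) {
  if (anyDuplicated(sequences) > 0L) {
    stop("`sequences` must be deduplicated.", call. = FALSE)
  }
  if (any(is.na(sequences) | !nzchar(sequences))) {
    stop("Sequences must be nonempty strings.", call. = FALSE)
  }
  pairs <- ld1_pairs_fast(sequences)
  g <- igraph::make_empty_graph(n = length(sequences), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = sequences)
  if (nrow(pairs) > 0L) {
    g <- igraph::add_edges(g, t(pairs))
  }
  deg <- igraph::degree(g)
  structure(
    list(
      graph = g,
      degree = deg,
      n_nodes = igraph::vcount(g),
      n_edges = igraph::ecount(g),
      connectivity_fraction = if (length(sequences) > 0L) {
        igraph::ecount(g) / igraph::vcount(g)
      } else {
        NA_real_
      }
    ),
    class = "tcr_network"
  )
}

#' @export
print.tcr_network <- function(x, ...) {
  cat(sprintf("LD=1 convergence network: %d nodes, %d edges (connectivity fraction %.4f)\n",
              x$n_nodes, x$n_edges, x$connectivity_fraction))
  invisible(x)
}

#' Export a network as an edge list and GraphML
#'
#' Writes a two-column TSV (`source`, `target`) and, optionally, a
#' GraphML file with node attributes for external viewers such as
#' Cytoscape.
#'
#' @param network A `tcr_network`.
#' @param edge_path Output TSV path.
#' @param graphml_path Optional GraphML output path.
#' @param node_attrs Optional data frame with a `cdr3_aa` column plus
#'   attribute columns (e.g. templates, sharing_level) to attach to
#'   vertices before the GraphML export.
#' @return `edge_path`, invisibly.
#' @export
write_network <- function(network, edge_path, graphml_path = NULL,
                          node_attrs = NULL) {
  el <- igraph::as_edgelist(network$graph, names = TRUE)
  readr::write_tsv(tibble::tibble(source = el[, 1], target = el[, 2]),
                   edge_path, progress = FALSE)
  if (!is.null(graphml_path)) {
    g <- network$graph
    if (!is.null(node_attrs)) {
      ord <- match(igraph::V(g)$name, node_attrs$cdr3_aa)
      for (col in setdiff(names(node_attrs), "cdr3_aa")) {
        g <- igraph::set_vertex_attr(g, col, value = node_attrs[[col]][ord])
      }
    }
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  invisible(edge_path)
}
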