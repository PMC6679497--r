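#' Load an undirected interaction network from a TSV edge list
#'
#' Reads a protein-protein interaction (PPI) edge list with two
#' whitespace/tab-separated columns (`node_a`, `node_b`). Lines starting with
#' `#` are comments. The result is a simple undirected [igraph][igraph::graph]:
#' duplicate edges (in either orientation) are collapsed and self-loops are
#' dropped with a logged count. A node that appears only in self-loops is
#' dropped with them. Node identifiers are taken verbatim (case-sensitive).
#'
#' @param path Path to the edge-list file.
#' @return An undirected `igraph` graph with a `name` vertex attribute.
#' @export
#' @examples
#' f <- tempfile()
#' writeLines(c("# demo", "A\tB", "B\tA", "B\tC"), f)
#' g <- load_edge_list(f)
#' igraph::vcount(g) # 3
load_edge_list <- function(path) {
  if (!file.exists(path)) {
    ss_stop("io", sprintf("cannot read edge list: '%s' does not exist", path))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    ss_stop("format", sprintf(
      "no edges parsed from '%s': expected lines with two whitespace-separated node IDs",
      path
    ))
  }
  fields <- strsplit(lines, "[ \t]+")
  bad <- which(vapply(fields, length, 1L) < 2L)
  if (length(bad) > 0L) {
    ss_stop("format", sprintf(
      "line %d of '%s' has fewer than two whitespace-separated columns (node_a<TAB>node_b expected)",
      bad[1L], path
    ))
  }
  a <- vapply(fields, `[[`, "", 1L)
  b <- vapply(fields, `[[`, "", 2L)
  edges_from_pairs(a, b, source = path)
}

# Shared constructor: dedups {a,b}=={b,a}, drops self-loops (and nodes that
# only ever appear in self-loops), reports counts.
edges_from_pairs <- function(a, b, source = "<edges>") {
  loops <- a == b
  n_loops <- sum(loops)
  a <- a[!loops]
  b <- b[!loops]
  if (length(a) == 0L) {
    ss_stop("format", sprintf(
      "no non-loop edges parsed from '%s': expected lines with two distinct node IDs",
      source
    ))
  }
  key <- ifelse(a < b, paste(a, b, sep = "\r"), paste(b, a, sep = "\r"))
  keep <- !duplicated(key)
  n_dup <- sum(!keep)
  pairs <- do.call(rbind, strsplit(key[keep], "\r", fixed = TRUE))
  g <- igraph::graph_from_edgelist(pairs, directed = FALSE)
  if (n_loops > 0L || n_dup > 0L) {
    ss_info("load_edge_list: dropped %d self-loop(s) and %d duplicate edge(s) from '%s'",
            n_loops, n_dup, source)
  }
  g
}

#' Induce a disease (or target) subnetwork on a gene set
#'
#' Maps a gene set onto a background network, takes the induced subgraph, and
#' removes nodes left without any edge (isolates), following the standard
#' disease-network construction in network pharmacology. Counts of unmapped
#' genes and removed isolates are logged.
#'
#' @param net Background network (`igraph`, from [load_edge_list()]).
#' @param genes Character vector of node identifiers (non-empty).
#' @param label Optional label used in log messages.
#' @return The induced `igraph` subnetwork with isolates removed.
#' @export
induce_subnetwork <- function(net, genes, label = "gene set") {
  genes <- unique(as.character(genes))
  if (length(genes) == 0L) {
    ss_stop("domain", "cannot induce a subnetwork on an empty gene set")
  }
  mapped <- intersect(genes, igraph::V(net)$name)
  n_unmapped <- length(genes) - length(mapped)
  if (length(mapped) == 0L) {
    ss_stop("degenerate_network", sprintf(
      "none of the %d genes in the %s map to the background network", length(genes), label
    ))
  }
  sub <- igraph::induced_subgraph(net, mapped)
  iso <- igraph::degree(sub) == 0
  n_iso <- sum(iso)
  sub <- igraph::delete_vertices(sub, which(iso))
  if (igraph::ecount(sub) == 0L) {
    ss_stop("degenerate_network", sprintf(
      "induced %s subnetwork has no edges after isolate removal", label
    ))
  }
  if (n_unmapped > 0L || n_iso > 0L) {
    ss_info("induce_subnetwork(%s): %d unmapped gene(s), %d isolate(s) removed; kept %d nodes / %d edges",
            label, n_unmapped, n_iso, igraph::vcount(sub), igraph::ecount(sub))
  }
  sub
}

#' Node centralities and the combined centrality score CS
#'
#' Computes, for every node of the scoring network, normalized betweenness
#' `Bn` (pair-normalized by \eqn{(n-1)(n-2)/2}), Wasserman-Faust
#' component-scaled closeness `Cn`, PageRank `Pr` (uniform teleport), and the
#' centrality score `CS = Bn + Cn + Pr`. CS measures how central ("hub-like")
#' a protein is in the disease signaling network; target sets concentrated on
#' high-CS nodes are preferred by the target-network synergy score.
#'
#' Closeness for node v uses the reachable set R(v) (excluding v):
#' \eqn{Cn(v) = (|R|/(n-1)) \cdot (|R| / \sum_{u \in R} d(v,u))}, which on a
#' connected graph reduces to the usual \eqn{(n-1)/\sum d} and stays
#' well-defined if components remain after isolate removal.
#'
#' @param net Scoring network (`igraph`), at least 2 nodes and 1 edge.
#' @param damping PageRank damping factor (default 0.85).
#' @return A `data.frame` with columns `node`, `betweenness`, `closeness`,
#'   `pagerank`, `cs`.
#' @export
compute_centralities <- function(net, damping = 0.85) {
  n <- igraph::vcount(net)
  if (n < 2L || igraph::ecount(net) < 1L) {
    ss_stop("degenerate_network", "centralities need a network with >= 2 nodes and >= 1 edge")
  }
  bn_raw <- igraph::betweenness(net, directed = FALSE, normalized = FALSE)
  denom <- (n - 1) * (n - 2) / 2
  bn <- if (denom > 0) bn_raw / denom else rep(0, n)

  d <- igraph::distances(net)
  cn <- vapply(seq_len(n), function(i) {
    di <- d[i, -i]
    reach <- di[is.finite(di)]
    r <- length(reach)
    if (r == 0L || sum(reach) == 0) return(0)
    (r / (n - 1)) * (r / sum(reach))
  }, numeric(1))

  pr <- igraph::page_rank(net, damping = damping, directed = FALSE)$vector

  data.frame(
    node = igraph::V(net)$name,
    betweenness = unname(bn),
    closeness = unname(cn),
    pagerank = unname(pr),
    cs = unname(bn + cn + pr),
    stringsAsFactors = FALSE
  )
}

#' @rdname compute_centralities
#' @param tab Centrality table from [compute_centralities()].
#' @param path Output TSV path.
#' @export
write_centrality_table <- function(tab, path) {
  out <- tab
  num <- vapply(out, is.numeric, TRUE)
  out[num] <- lapply(out[num], function(x) formatC(signif(x, 6), format = "g", digits = 6))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene set (one identifier per line, '#' comments)
#' @param path Path to the gene list file.
#' @return Character vector of unique identifiers.
#' @export
read_gene_set <- function(path) {
  if (!file.exists(path)) ss_stop("io", sprintf("cannot read gene set '%s'", path))
  x <- trimws(readLines(path, warn = FALSE))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  unique(x)
}

#' Write a network as a two-column TSV edge list
#' @param net An `igraph` network.
#' @param path Output path.
#' @export
write_edge_list <- function(net, path) {
  el <- igraph::as_edgelist(net)
  writeLines(c("# node_a\tnode_b", paste(el[, 1], el[, 2], sep = "\t")), path)
  invisible(path)
}
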