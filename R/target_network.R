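#' Minimum network distance from a target to a target set
#'
#' Unweighted shortest-path distance (hops) from node `t` to the nearest
#' member of target set `targets`, restricted to nodes present in `net`.
#' Returns 0 when `t` itself belongs to the set (and to the network), and
#' `Inf` (the UNREACHABLE sentinel) when `t` is absent from the network or no
#' set member is reachable.
#'
#' @param t A node identifier.
#' @param targets Character vector of node identifiers (non-empty).
#' @param net Scoring network (`igraph`).
#' @return A non-negative integer distance, or `Inf`.
#' @export
min_distance <- function(t, targets, net) {
  targets <- unique(as.character(targets))
  if (length(targets) == 0L) {
    ss_stop("domain", "min_distance: target set is empty")
  }
  nodes <- igraph::V(net)$name
  if (!(t %in% nodes)) return(Inf)
  mapped <- intersect(targets, nodes)
  if (length(mapped) == 0L) return(Inf)
  if (t %in% mapped) return(0)
  min(igraph::distances(net, v = t, to = mapped))
}

#' Target-network synergistic score between two drugs
#'
#' For drugs with mapped target sets \eqn{T_k} (size m) and \eqn{T_h}
#' (size n) on a scoring network with centrality scores CS, the score is the
#' sum of two CS-weighted means of proximity factors:
#' \deqn{S = \frac{\sum_i CS(t_{ki}) w(D(t_{ki},T_h)/n^2)}{\sum_i CS(t_{ki})}
#'         + \frac{\sum_j CS(t_{hj}) w(D(t_{hj},T_k)/m^2)}{\sum_j CS(t_{hj})}}
#' with \eqn{D} the minimum shortest-path distance ([min_distance()]) and
#' \eqn{w(x) = e^{-x}} under the default `"decay"` convention, so close,
#' hub-centered target sets score high and \eqn{S \in [0, 2]} with
#' \eqn{S = 2} iff the mapped sets coincide. `exponent_sign = "literal"`
#' uses \eqn{w(x) = e^{+x}} instead (growth with distance). An unreachable
#' target contributes factor 0 under either convention (the \eqn{D \to
#' \infty} decay limit). Note the crossed denominators: distances from
#' \eqn{T_k} are scaled by \eqn{n^2} (the size of the *other* mapped set)
#' and vice versa. Targets absent from the scoring network are excluded from
#' the sums.
#'
#' @param targets_a,targets_b Character vectors of target node IDs.
#' @param net Scoring network (`igraph`).
#' @param cs Centrality table from [compute_centralities()] on `net`.
#' @param exponent_sign `"decay"` (default) or `"literal"`.
#' @return A single numeric score.
#' @export
s_tnetwork <- function(targets_a, targets_b, net, cs,
                       exponent_sign = c("decay", "literal")) {
  exponent_sign <- match.arg(exponent_sign)
  targets_a <- unique(as.character(targets_a))
  targets_b <- unique(as.character(targets_b))
  if (length(targets_a) == 0L || length(targets_b) == 0L) {
    ss_stop("undefined_score", "s_tnetwork: a drug has an empty target set")
  }
  nodes <- igraph::V(net)$name
  ta <- intersect(targets_a, nodes)
  tb <- intersect(targets_b, nodes)
  m <- length(ta)
  n <- length(tb)
  if (m == 0L || n == 0L) {
    ss_stop("undefined_score",
            "s_tnetwork: a drug has no targets mapped to the scoring network")
  }
  n_drop <- (length(targets_a) - m) + (length(targets_b) - n)
  if (n_drop > 0L) {
    ss_info("s_tnetwork: %d target(s) absent from the scoring network were excluded", n_drop)
  }
  csv <- stats::setNames(cs$cs, cs$node)

  half <- function(from, to_set, scale2) {
    w <- csv[from]
    if (any(is.na(w))) {
      ss_stop("undefined_score", "s_tnetwork: target missing from the centrality table")
    }
    if (sum(w) <= 0) {
      ss_stop("undefined_score", "s_tnetwork: total centrality score of a target set is zero")
    }
    d <- vapply(from, min_distance, numeric(1), targets = to_set, net = net)
    fac <- ifelse(is.infinite(d), 0,
                  if (exponent_sign == "decay") exp(-d / scale2) else exp(d / scale2))
    sum(w * fac) / sum(w)
  }

  half(ta, tb, n^2) + half(tb, ta, m^2)
}

#' Read a long-format drug-target table
#'
#' TSV with columns `drug_id`, `target_id` (header line optional), `#`
#' comments allowed.
#'
#' @param path Path to the table.
#' @return A `data.frame` with columns `drug_id`, `target_id` (deduplicated).
#' @export
read_targets <- function(path) {
  if (!file.exists(path)) ss_stop("io", sprintf("cannot read target table '%s'", path))
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) > 0L && grepl("^drug_id[ \t]", lines[1L])) lines <- lines[-1L]
  if (length(lines) == 0L) {
    return(data.frame(drug_id = character(), target_id = character(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "[ \t]+")
  if (any(vapply(fields, length, 1L) < 2L)) {
    ss_stop("format", sprintf("target table '%s' needs two columns: drug_id, target_id", path))
  }
  out <- data.frame(
    drug_id = vapply(fields, `[[`, "", 1L),
    target_id = vapply(fields, `[[`, "", 2L),
    stringsAsFactors = FALSE
  )
  unique(out)
}

#' Extract one drug's target set from a long-format table
#' @param targets Table from [read_targets()].
#' @param drug_id Drug identifier.
#' @return Character vector of target IDs (possibly empty).
#' @export
targets_of <- function(targets, drug_id) {
  unique(targets$target_id[targets$drug_id == drug_id])
}
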