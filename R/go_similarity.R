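#' Parse a minimal OBO ontology (id / name / is_a / is_obsolete)
#'
#' Reads OBO 1.2-style `[Term]` stanzas. Only the tags `id`, `name`, `is_a`
#' and `is_obsolete` are honored; everything else is ignored. A dangling
#' `is_a` reference is dropped with a warning; a cycle among `is_a` edges is
#' an error (the ontology must be a DAG).
#'
#' @param path Path to the OBO file.
#' @return An object of class `synscreen_ontology`: list with `terms`
#'   (character), `parents` (named list of character), `obsolete` (character),
#'   `names` (named character).
#' @export
parse_obo <- function(path) {
  if (!file.exists(path)) ss_stop("io", sprintf("cannot read ontology '%s'", path))
  lines <- readLines(path, warn = FALSE)
  term_ids <- character()
  parents <- list()
  obsolete <- character()
  term_names <- character()

  cur_id <- NA_character_
  in_term <- FALSE
  flush_ok <- function() !is.na(cur_id)
  for (ln in lines) {
    ln <- trimws(sub("!.*$", "", ln)) # strip OBO comments
    if (ln == "[Term]") {
      in_term <- TRUE
      cur_id <- NA_character_
      next
    }
    if (grepl("^\\[", ln)) { # [Typedef] etc.
      in_term <- FALSE
      next
    }
    if (!in_term || !nzchar(ln)) next
    if (startsWith(ln, "id:")) {
      cur_id <- trimws(sub("^id:", "", ln))
      term_ids <- c(term_ids, cur_id)
      parents[[cur_id]] <- character()
    } else if (startsWith(ln, "is_a:") && flush_ok()) {
      parents[[cur_id]] <- c(parents[[cur_id]], trimws(sub("^is_a:", "", ln)))
    } else if (startsWith(ln, "name:") && flush_ok()) {
      term_names[cur_id] <- trimws(sub("^name:", "", ln))
    } else if (startsWith(ln, "is_obsolete:") && flush_ok()) {
      if (grepl("true", ln, fixed = TRUE)) obsolete <- c(obsolete, cur_id)
    }
  }
  if (length(term_ids) == 0L) {
    ss_stop("format", sprintf("no [Term] stanzas found in '%s'", path))
  }

  # drop dangling is_a references
  n_dangling <- 0L
  for (id in names(parents)) {
    known <- parents[[id]] %in% term_ids
    n_dangling <- n_dangling + sum(!known)
    parents[[id]] <- unique(parents[[id]][known])
  }
  if (n_dangling > 0L) {
    ss_warn("dangling_isa", sprintf(
      "parse_obo: dropped %d is_a reference(s) to unknown terms in '%s'", n_dangling, path))
  }

  # Kahn's algorithm: any leftover node sits on a cycle
  indeg <- stats::setNames(integer(length(term_ids)), term_ids)
  for (id in names(parents)) for (p in parents[[id]]) indeg[p] <- indeg[p] + 1L
  queue <- names(indeg)[indeg == 0L]
  seen <- 0L
  while (length(queue) > 0L) {
    v <- queue[1L]; queue <- queue[-1L]; seen <- seen + 1L
    for (p in parents[[v]]) {
      indeg[p] <- indeg[p] - 1L
      if (indeg[p] == 0L) queue <- c(queue, p)
    }
  }
  if (seen < length(term_ids)) {
    ss_stop("ontology", sprintf("is_a cycle detected in '%s'", path))
  }
  if (length(obsolete) > 0L) {
    ss_info("parse_obo: %d obsolete term(s) excluded from similarity", length(obsolete))
  }
  structure(
    list(terms = term_ids, parents = parents,
         obsolete = unique(obsolete), names = term_names),
    class = "synscreen_ontology"
  )
}

#' Ancestors of a term (reflexive-transitive is_a closure)
#' @param ontology A `synscreen_ontology`.
#' @param term Term identifier.
#' @return Character vector of ancestor term IDs, including `term` itself.
#' @export
term_ancestors <- function(ontology, term) {
  if (!(term %in% ontology$terms)) {
    ss_stop("missing_annotation", sprintf("unknown ontology term '%s'", term))
  }
  out <- character()
  stack <- term
  while (length(stack) > 0L) {
    v <- stack[1L]; stack <- stack[-1L]
    if (v %in% out) next
    out <- c(out, v)
    stack <- c(stack, ontology$parents[[v]])
  }
  out
}

#' Build an annotation corpus with cumulative term frequencies
#'
#' Counts every annotation row toward its term and all of that term's
#' ancestors (cumulative counting, as in information-content semantic
#' similarity), then converts counts to probabilities
#' \eqn{p(t) = Freq(t) / \max Freq}. Rows annotating obsolete or unknown
#' terms are dropped with a warning.
#'
#' @param ontology A `synscreen_ontology` from [parse_obo()].
#' @param annotations `data.frame` with columns `gene_id`, `term_id`.
#' @param genes Optional character vector restricting the corpus to
#'   annotations of these genes (the `target_union` corpus scope); `NULL`
#'   uses every annotation row.
#' @return Object of class `synscreen_go_corpus`: list with `ontology`,
#'   `gene2terms` (named list), `freq` and `p` (named numeric vectors).
#' @export
build_go_corpus <- function(ontology, annotations, genes = NULL) {
  stopifnot(inherits(ontology, "synscreen_ontology"))
  ann <- unique(annotations[, c("gene_id", "term_id")])
  if (!is.null(genes)) ann <- ann[ann$gene_id %in% genes, , drop = FALSE]
  known <- ann$term_id %in% ontology$terms & !(ann$term_id %in% ontology$obsolete)
  if (any(!known)) {
    ss_warn("unknown_term", sprintf(
      "build_go_corpus: dropped %d annotation(s) to unknown or obsolete terms", sum(!known)))
    ann <- ann[known, , drop = FALSE]
  }
  if (nrow(ann) == 0L) {
    ss_stop("domain", "build_go_corpus: no usable annotations")
  }

  anc_cache <- new.env(parent = emptyenv())
  anc <- function(t) {
    if (!is.null(anc_cache[[t]])) return(anc_cache[[t]])
    a <- term_ancestors(ontology, t)
    anc_cache[[t]] <- a
    a
  }

  freq <- stats::setNames(numeric(length(ontology$terms)), ontology$terms)
  direct <- table(ann$term_id)
  for (t in names(direct)) {
    freq[anc(t)] <- freq[anc(t)] + as.numeric(direct[[t]])
  }
  maxfreq <- max(freq)
  p <- freq / maxfreq

  gene2terms <- split(ann$term_id, ann$gene_id)
  structure(
    list(ontology = ontology, gene2terms = gene2terms, freq = freq, p = p),
    class = "synscreen_go_corpus"
  )
}

#' Annotation probability of a term
#'
#' \eqn{p(t) = Freq(t)/\max(Freq)} with cumulative frequencies; the most
#' frequently hit term (the root of an annotated rooted DAG) has p = 1.
#'
#' @param corpus A `synscreen_go_corpus`.
#' @param term Term identifier.
#' @return Probability in (0, 1].
#' @export
term_probability <- function(corpus, term) {
  p <- corpus$p[term]
  if (is.na(p) || p <= 0 || term %in% corpus$ontology$obsolete) {
    ss_stop("missing_annotation", sprintf(
      "term '%s' has no (cumulative) annotations in the corpus", term))
  }
  unname(p)
}

#' Information-content similarity of two ontology terms
#'
#' Lin-style similarity over the annotation corpus:
#' \deqn{sim(t_1, t_2) = \frac{2 \log_2 p(A^*)}{\log_2 p(t_1) + \log_2 p(t_2)}}
#' where \eqn{A^*} is selected among the common ancestors of the two terms.
#' Under the default `mica_rule = "mica"`, \eqn{A^*} is the Most Informative
#' Common Ancestor (minimum p); `"literal_max"` picks the maximum-p ancestor
#' instead (on a rooted DAG that is the root, making the similarity 0 for any
#' distinct pair). Identical terms score 1 by definition; if both terms have
#' p = 1 the denominator vanishes and distinct terms score 0. A pair with no
#' common ancestor scores 0 with a warning.
#'
#' @param corpus A `synscreen_go_corpus`.
#' @param t1,t2 Annotated term identifiers.
#' @param mica_rule `"mica"` (default) or `"literal_max"`.
#' @return Similarity in \[0, 1\].
#' @export
term_similarity <- function(corpus, t1, t2, mica_rule = c("mica", "literal_max")) {
  mica_rule <- match.arg(mica_rule)
  p1 <- term_probability(corpus, t1)
  p2 <- term_probability(corpus, t2)
  if (t1 == t2) return(1)
  common <- intersect(term_ancestors(corpus$ontology, t1),
                      term_ancestors(corpus$ontology, t2))
  common <- setdiff(common, corpus$ontology$obsolete)
  common <- common[corpus$p[common] > 0]
  if (length(common) == 0L) {
    ss_warn("no_common_ancestor", sprintf(
      "terms '%s' and '%s' share no annotated common ancestor; similarity 0", t1, t2))
    return(0)
  }
  pA <- if (mica_rule == "mica") min(corpus$p[common]) else max(corpus$p[common])
  denom <- log2(p1) + log2(p2)
  if (denom == 0) return(0)
  2 * log2(pA) / denom
}

#' Functional similarity of two genes
#'
#' Aggregates [term_similarity()] over all cross pairs of the two genes'
#' annotated terms: `"max"` (default), `"avg"`, or `"bma"` (best-match
#' average). An unannotated gene scores 0 against everything, with a warning.
#'
#' @param corpus A `synscreen_go_corpus`.
#' @param g1,g2 Gene identifiers.
#' @param aggregation `"max"`, `"bma"` or `"avg"`.
#' @param mica_rule Passed to [term_similarity()].
#' @return Similarity in \[0, 1\].
#' @export
gene_pair_similarity <- function(corpus, g1, g2,
                                 aggregation = c("max", "bma", "avg"),
                                 mica_rule = "mica") {
  aggregation <- match.arg(aggregation)
  usable <- function(g) {
    ts <- corpus$gene2terms[[g]]
    ts <- setdiff(unique(ts), corpus$ontology$obsolete)
    ts[!is.na(corpus$p[ts]) & corpus$p[ts] > 0]
  }
  ts1 <- usable(g1)
  ts2 <- usable(g2)
  if (length(ts1) == 0L || length(ts2) == 0L) {
    ss_warn("unannotated_gene", sprintf(
      "gene '%s' has no usable annotations; similarity 0",
      if (length(ts1) == 0L) g1 else g2))
    return(0)
  }
  simmat <- outer(ts1, ts2, Vectorize(function(a, b) {
    term_similarity(corpus, a, b, mica_rule = mica_rule)
  }))
  simmat <- matrix(simmat, nrow = length(ts1))
  switch(aggregation,
    max = max(simmat),
    avg = mean(simmat),
    bma = mean(c(apply(simmat, 1, max), apply(simmat, 2, max)))
  )
}

#' Functional synergistic score of two target sets
#'
#' Averages [gene_pair_similarity()] over all ordered cross pairs between the
#' target sets (each unordered cross pair counted twice), divided by the
#' number of ordered pairs among the pooled m + n targets:
#' \deqn{S_{function} = \frac{2 \sum_{i,j} sim(t_{ki}, t_{hj})}{(m+n)(m+n-1)}}
#' so \eqn{S \in [0, 1]}, reaching 1 only at m = n = 1 with identical
#' annotations.
#'
#' @param targets_a,targets_b Character vectors of gene IDs (non-empty).
#' @param corpus A `synscreen_go_corpus`.
#' @param aggregation,mica_rule Passed to [gene_pair_similarity()].
#' @return Score in \[0, 1\].
#' @export
s_function <- function(targets_a, targets_b, corpus,
                       aggregation = "max", mica_rule = "mica") {
  targets_a <- unique(as.character(targets_a))
  targets_b <- unique(as.character(targets_b))
  m <- length(targets_a)
  n <- length(targets_b)
  if (m == 0L || n == 0L) {
    ss_stop("undefined_score", "s_function: a drug has an empty target set")
  }
  total <- 0
  for (a in targets_a) {
    for (b in targets_b) {
      total <- total + gene_pair_similarity(corpus, a, b,
                                            aggregation = aggregation,
                                            mica_rule = mica_rule)
    }
  }
  2 * total / ((m + n) * (m + n - 1))
}

#' Read a GAF-lite annotation table (gene_id, term_id)
#' @param path TSV path; '#' comments; optional header.
#' @return `data.frame` with columns `gene_id`, `term_id`.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) ss_stop("io", sprintf("cannot read annotations '%s'", path))
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) > 0L && grepl("^gene_id[ \t]", lines[1L])) lines <- lines[-1L]
  if (length(lines) == 0L) ss_stop("format", sprintf("no annotation rows in '%s'", path))
  fields <- strsplit(lines, "[ \t]+")
  if (any(vapply(fields, length, 1L) < 2L)) {
    ss_stop("format", sprintf("annotation table '%s' needs two columns: gene_id, term_id", path))
  }
  data.frame(
    gene_id = vapply(fields, `[[`, "", 1L),
    term_id = vapply(fields, `[[`, "", 2L),
    stringsAsFactors = FALSE
  )
}
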