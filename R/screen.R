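#' Run the full combination screen
#'
#' End-to-end pipeline: build the scoring network, compute centralities,
#' build the annotation corpus, assemble the three synergy axes for every
#' candidate against the reference drug, normalize, and rank along the
#' diagonal of the score cube. Inputs may be given as in-memory objects or
#' as file paths (detected by type: a character scalar is treated as a
#' path).
#'
#' The scoring network depends on `config$scoring_graph`: `"disease"`
#' (default) induces the subnetwork on the disease genes; `"background"`
#' scores on the full network; `"disease_plus_targets"` induces on the union
#' of disease genes and all drugs' targets (useful when drug targets fall
#' outside the disease network).
#'
#' @param network Background PPI network: `igraph` or edge-list TSV path.
#' @param disease_genes Character vector of gene IDs, or a file path.
#' @param targets Drug-target table (`data.frame` with `drug_id`,
#'   `target_id`) or TSV path; must contain the reference drug.
#' @param reference Reference drug identifier (e.g. the anchor DMARD).
#' @param smiles Optional SMILES table (`drug_id`, `smiles`) or .smi path.
#' @param sites Optional pharmacophore site table or TSV path.
#' @param obo Optional ontology (`synscreen_ontology` or OBO path).
#' @param annotations Optional annotation table (`gene_id`, `term_id`) or
#'   TSV path; required together with `obo` for the function axis.
#' @param config Configuration list from [load_config()].
#' @return Ranked `data.frame` from [normalize_and_rank()].
#' @export
run_screen <- function(network, disease_genes, targets, reference,
                       smiles = NULL, sites = NULL,
                       obo = NULL, annotations = NULL,
                       config = default_config()) {
  config <- validate_config(config)
  net <- if (is.character(network)) load_edge_list(network) else network
  if (is.character(disease_genes) && length(disease_genes) == 1L &&
      file.exists(disease_genes)) {
    disease_genes <- read_gene_set(disease_genes)
  }
  if (is.character(targets)) targets <- read_targets(targets)
  if (is.character(smiles)) smiles <- read_smiles(smiles)
  if (is.character(sites)) sites <- read_sites(sites)
  if (is.character(obo)) obo <- parse_obo(obo)
  if (is.character(annotations)) annotations <- read_annotations(annotations)

  drug_ids <- union(unique(targets$drug_id),
                    if (is.null(smiles)) character() else unique(smiles$drug_id))
  if (!(reference %in% drug_ids)) {
    ss_stop("domain", sprintf("reference drug '%s' not found in the inputs", reference))
  }

  all_targets <- unique(targets$target_id)
  scoring_net <- switch(config$scoring_graph,
    background = net,
    disease = induce_subnetwork(net, disease_genes, label = "disease"),
    disease_plus_targets = induce_subnetwork(
      net, union(disease_genes, all_targets), label = "disease+targets")
  )
  cs <- compute_centralities(scoring_net, damping = config$damping)

  corpus <- NULL
  if (!is.null(obo) && !is.null(annotations)) {
    scope_genes <- if (config$corpus_scope == "target_union") all_targets else NULL
    corpus <- build_go_corpus(obo, annotations, genes = scope_genes)
  }

  record_of <- function(id) {
    smi <- if (!is.null(smiles) && id %in% smiles$drug_id) {
      smiles$smiles[match(id, smiles$drug_id)]
    } else NA_character_
    st <- if (!is.null(sites)) sites_of(sites, id) else NULL
    drug_record(id, smiles = smi, targets = targets_of(targets, id), sites = st)
  }

  ref <- record_of(reference)
  candidates <- lapply(setdiff(drug_ids, reference), record_of)
  raw <- assemble_scores(ref, candidates, scoring_net, cs, corpus, config)
  normalize_and_rank(raw, total_rule = config$total_rule)
}
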