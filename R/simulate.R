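# Seeded synthetic fixture generators. Everything here is a pure function of
# (parameters, seed): regenerating with the same seed is byte-identical, so
# tests and the acceptance script run fully offline.

# Run code under a temporary RNG state; the caller's stream is untouched.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Small built-in library of drug-like canonical SMILES (toys: they exercise
# the LINGO machinery, not chemistry). First two are the reference-drug and
# planted-synergist structures used by simulate_bundle().
toy_smiles_library <- c(
  "CC1=C(C=NO1)C(=O)NC1=CC=C(C=C1)C(F)(F)F",
  "CC1=NC(C)=C(C)N=C1C",
  "CC(=O)OC1=CC=CC=C1C(=O)O",
  "CN1C=NC2=C1C(=O)N(C)C(=O)N2C",
  "CC(C)CC1=CC=C(C=C1)C(C)C(=O)O",
  "CC(=O)NC1=CC=C(O)C=C1",
  "COC1=CC=C2C=C(C(C)C(=O)O)C=CC2=C1",
  "NC1=CC=C(C=C1)S(=O)(=O)NC1=NC=CC=N1",
  "OC(=O)C1=CC=CC=C1O",
  "CN(C)CCC1=CNC2=CC=CC=C12",
  "ClC1=CC=C(C=C1)C1=NC=CN1",
  "OCC1OC(O)C(O)C(O)C1O"
)

#' Generate a connected random interaction network
#'
#' `model = "random"` draws an Erdos-Renyi G(n, p) graph with
#' `p = edge_param`; `model = "scale_free"` draws a Barabasi-Albert
#' preferential-attachment graph adding `edge_param` edges per node (hubby,
#' like real PPI networks). If the draw is disconnected, the components are
#' chained together by single deterministic edges. Nodes are named
#' `G001, G002, ...`.
#'
#' @param n_nodes Number of nodes (>= 4).
#' @param model `"scale_free"` or `"random"`.
#' @param edge_param Attachment edges per node, or edge probability.
#' @param seed Integer seed (mandatory; generators have no wall-clock
#'   defaults).
#' @param path Optional TSV path to write the edge list to.
#' @return An `igraph` network.
#' @export
gen_ppi <- function(n_nodes, model = c("scale_free", "random"), edge_param = 2,
                    seed, path = NULL) {
  model <- match.arg(model)
  if (n_nodes < 4L) ss_stop("domain", "gen_ppi: need n_nodes >= 4")
  g <- with_seed(seed, {
    if (model == "random") {
      igraph::sample_gnp(n_nodes, p = edge_param)
    } else {
      igraph::sample_pa(n_nodes, m = edge_param, directed = FALSE)
    }
  })
  if (igraph::ecount(g) == 0L) {
    ss_stop("domain", "gen_ppi: parameters yielded a network with no edges")
  }
  igraph::V(g)$name <- sprintf("G%03d", seq_len(n_nodes))
  comp <- igraph::components(g)
  if (comp$no > 1L) {
    anchors <- vapply(seq_len(comp$no), function(k) which(comp$membership == k)[1L], 1L)
    for (k in 2:comp$no) g <- igraph::add_edges(g, c(anchors[1L], anchors[k]))
  }
  g <- igraph::simplify(g)
  if (!is.null(path)) write_edge_list(g, path)
  g
}

#' Generate a toy rooted ontology with annotations
#'
#' Builds a complete tree of the given depth and branching factor (depth
#' counts levels, so `depth = 2, branching = 2` gives a root plus two
#' children). Every term receives at least one direct annotation, which
#' makes cumulative frequencies strictly decrease with depth along every
#' path; additionally every gene is annotated to one random term, so no gene
#' is silent. Term IDs are `T:0001, ...` with the root first.
#'
#' @param depth Number of levels (>= 2).
#' @param branching Children per internal term (>= 1).
#' @param genes Character vector of gene identifiers to annotate.
#' @param seed Integer seed.
#' @param obo_path,ann_path Optional output paths (OBO / TSV).
#' @return List with `ontology` (`synscreen_ontology`), `annotations`
#'   (`data.frame`), and `obo_lines` (the OBO text).
#' @export
gen_go_corpus <- function(depth, branching, genes, seed,
                          obo_path = NULL, ann_path = NULL) {
  if (depth < 2L) ss_stop("domain", "gen_go_corpus: need depth >= 2")
  if (branching < 1L) ss_stop("domain", "gen_go_corpus: need branching >= 1")
  if (length(genes) == 0L) ss_stop("domain", "gen_go_corpus: no genes to annotate")

  ids <- character()
  parent_of <- character()
  level_of <- integer()
  nxt <- 1L
  new_term <- function() {
    id <- sprintf("T:%04d", nxt)
    nxt <<- nxt + 1L
    id
  }
  root <- new_term()
  ids <- root; parent_of[root] <- NA_character_; level_of[root] <- 1L
  frontier <- root
  for (lev in 2:depth) {
    nf <- character()
    for (par in frontier) {
      for (b in seq_len(branching)) {
        id <- new_term()
        ids <- c(ids, id)
        parent_of[id] <- par
        level_of[id] <- lev
        nf <- c(nf, id)
      }
    }
    frontier <- nf
  }

  obo_lines <- c("format-version: 1.2", "")
  for (id in ids) {
    obo_lines <- c(obo_lines, "[Term]", paste0("id: ", id),
                   paste0("name: synthetic term ", id))
    if (!is.na(parent_of[id])) {
      obo_lines <- c(obo_lines, paste0("is_a: ", parent_of[id]))
    }
    obo_lines <- c(obo_lines, "")
  }

  ann <- with_seed(seed, {
    rows <- data.frame(gene_id = character(), term_id = character(),
                       stringsAsFactors = FALSE)
    # deeper terms get fewer direct annotations (IC grows with depth)
    for (id in ids) {
      k <- max(depth - level_of[id] + 1L, 1L)
      rows <- rbind(rows, data.frame(
        gene_id = sample(genes, k, replace = TRUE),
        term_id = id, stringsAsFactors = FALSE))
    }
    # every gene annotated somewhere
    rows <- rbind(rows, data.frame(
      gene_id = genes,
      term_id = sample(ids, length(genes), replace = TRUE),
      stringsAsFactors = FALSE))
    unique(rows)
  })
  ann <- ann[order(ann$gene_id, ann$term_id), , drop = FALSE]
  rownames(ann) <- NULL

  if (!is.null(obo_path)) writeLines(obo_lines, obo_path)
  if (!is.null(ann_path)) {
    writeLines(c("gene_id\tterm_id", paste(ann$gene_id, ann$term_id, sep = "\t")),
               ann_path)
  }
  ontology <- structure(
    list(terms = ids,
         parents = stats::setNames(
           lapply(ids, function(i) if (is.na(parent_of[i])) character() else parent_of[i]),
           ids),
         obsolete = character(),
         names = stats::setNames(paste("synthetic term", ids), ids)),
    class = "synscreen_ontology"
  )
  list(ontology = ontology, annotations = ann, obo_lines = obo_lines)
}

#' Generate a panel of synthetic drugs
#'
#' Draws SMILES from the built-in toy library, samples `targets_per_drug`
#' target nodes per drug from the supplied node set, and places 2-4 random
#' pharmacophore sites per drug in a shared frame. Drug IDs are
#' `CAND01, ...`. `n_drugs = 0` yields empty tables (headers only when
#' written).
#'
#' @param n_drugs Number of drugs (>= 0).
#' @param nodes Character vector of network node IDs to sample targets from.
#' @param seed Integer seed.
#' @param targets_per_drug Targets per drug (default 3).
#' @return List of `data.frame`s: `smiles` (drug_id, smiles), `targets`
#'   (drug_id, target_id), `sites` (drug_id, site_type, x, y, z).
#' @export
gen_drug_panel <- function(n_drugs, nodes, seed, targets_per_drug = 3L) {
  if (n_drugs < 0L) ss_stop("domain", "gen_drug_panel: need n_drugs >= 0")
  empty <- list(
    smiles = data.frame(drug_id = character(), smiles = character(),
                        stringsAsFactors = FALSE),
    targets = data.frame(drug_id = character(), target_id = character(),
                         stringsAsFactors = FALSE),
    sites = data.frame(drug_id = character(), site_type = character(),
                       x = numeric(), y = numeric(), z = numeric(),
                       stringsAsFactors = FALSE)
  )
  if (n_drugs == 0L) return(empty)
  with_seed(seed, {
    ids <- sprintf("CAND%02d", seq_len(n_drugs))
    smiles <- data.frame(
      drug_id = ids,
      smiles = sample(toy_smiles_library, n_drugs, replace = TRUE),
      stringsAsFactors = FALSE
    )
    targets <- do.call(rbind, lapply(ids, function(id) data.frame(
      drug_id = id,
      target_id = sample(nodes, min(targets_per_drug, length(nodes))),
      stringsAsFactors = FALSE)))
    sites <- do.call(rbind, lapply(ids, function(id) {
      k <- sample(2:4, 1L)
      data.frame(drug_id = id,
                 site_type = sample(c("A", "D", "H", "N", "P", "R"), k, replace = TRUE),
                 x = round(stats::runif(k, -5, 5), 3),
                 y = round(stats::runif(k, -5, 5), 3),
                 z = round(stats::runif(k, -5, 5), 3),
                 stringsAsFactors = FALSE)
    }))
    list(smiles = smiles, targets = targets, sites = sites)
  })
}

#' The hand-computed gold instance
#'
#' A minimal fully worked screen whose every score is known in closed form:
#' the path network A-B-C-D-E as disease network, a reference drug (target
#' B, SMILES `CCCCC`, one acceptor site at the origin) and one candidate
#' (target D, SMILES `CCCC`, one acceptor site at (1, 0, 0)), and a 4-term
#' ontology whose cumulative annotation probabilities are exactly
#' 1, 1/2, 1/4, 1/8. The `manifest` entry records the expected raw scores:
#' s_tnetwork = 2e^-2, s_function = 0.4, s_2d = 2/3, s_3d = e^-1,
#' s_similarity = 2/3 + e^-1.
#'
#' @param dir Optional directory; when given, all input files (ppi.tsv,
#'   disease_genes.txt, targets.tsv, drugs.smi, sites.tsv, go.obo,
#'   annotations.tsv, config.json, manifest.json) are written there.
#' @return List with `net`, `disease_genes`, `targets`, `smiles`, `sites`,
#'   `ontology`, `annotations`, `reference`, `config`, `manifest`, and
#'   `files` (paths, when `dir` is given).
#' @export
gold_instance <- function(dir = NULL) {
  net <- igraph::graph_from_edgelist(
    cbind(c("A", "B", "C", "D"), c("B", "C", "D", "E")), directed = FALSE)
  disease_genes <- c("A", "B", "C", "D", "E")
  targets <- data.frame(
    drug_id = c("REF", "CAND"),
    target_id = c("B", "D"),
    stringsAsFactors = FALSE
  )
  smiles <- data.frame(
    drug_id = c("REF", "CAND"),
    smiles = c("CCCCC", "CCCC"),
    stringsAsFactors = FALSE
  )
  sites <- data.frame(
    drug_id = c("REF", "CAND"),
    site_type = c("A", "A"),
    x = c(0, 1), y = c(0, 0), z = c(0, 0),
    stringsAsFactors = FALSE
  )
  obo_lines <- c(
    "format-version: 1.2", "",
    "[Term]", "id: T:0001", "name: root", "",
    "[Term]", "id: T:0002", "name: mid", "is_a: T:0001", "",
    "[Term]", "id: T:0003", "name: leaf-x", "is_a: T:0002", "",
    "[Term]", "id: T:0004", "name: leaf-y", "is_a: T:0002", ""
  )
  # cumulative counts: T:0003 = 2, T:0004 = 1, T:0002 = 4, T:0001 = 8
  # -> p = 1/4, 1/8, 1/2, 1
  annotations <- data.frame(
    gene_id = c("B", "GX1", "D", "GX2", "GX3", "GX4", "GX5", "GX6"),
    term_id = c("T:0003", "T:0003", "T:0004", "T:0002",
                "T:0001", "T:0001", "T:0001", "T:0001"),
    stringsAsFactors = FALSE
  )
  config <- default_config()
  manifest <- list(
    seed = NA_integer_,
    reference = "REF",
    candidate = "CAND",
    expected = list(
      s_tnetwork = 2 * exp(-2),
      s_function = 0.4,
      s_2d = 2 / 3,
      s_3d = exp(-1),
      s_similarity = 2 / 3 + exp(-1)
    )
  )
  out <- list(net = net, disease_genes = disease_genes, targets = targets,
              smiles = smiles, sites = sites,
              ontology = NULL, annotations = annotations,
              obo_lines = obo_lines, reference = "REF",
              config = config, manifest = manifest)

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- list(
      network = file.path(dir, "ppi.tsv"),
      disease_genes = file.path(dir, "disease_genes.txt"),
      targets = file.path(dir, "targets.tsv"),
      smiles = file.path(dir, "drugs.smi"),
      sites = file.path(dir, "sites.tsv"),
      obo = file.path(dir, "go.obo"),
      annotations = file.path(dir, "annotations.tsv"),
      config = file.path(dir, "config.json"),
      manifest = file.path(dir, "manifest.json")
    )
    write_edge_list(net, files$network)
    writeLines(disease_genes, files$disease_genes)
    writeLines(c("drug_id\ttarget_id",
                 paste(targets$drug_id, targets$target_id, sep = "\t")),
               files$targets)
    writeLines(paste(smiles$smiles, smiles$drug_id, sep = "\t"), files$smiles)
    writeLines(c("drug_id\tsite_type\tx\ty\tz",
                 paste(sites$drug_id, sites$site_type, sites$x, sites$y, sites$z,
                       sep = "\t")),
               files$sites)
    writeLines(obo_lines, files$obo)
    writeLines(c("gene_id\tterm_id",
                 paste(annotations$gene_id, annotations$term_id, sep = "\t")),
               files$annotations)
    jsonlite::write_json(config[!vapply(config, is.null, TRUE)], files$config,
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(manifest, files$manifest, auto_unbox = TRUE, digits = NA)
    out$files <- files
  }
  out
}

#' Write a complete synthetic fixture bundle
#'
#' Generates a scale-free background network, a hub-centered disease gene
#' set, a reference drug targeting the disease network's highest-CS hubs,
#' a panel of decoy candidates, a toy ontology annotating every gene, and
#' (optionally) a planted synergist: a candidate that shares the reference
#' drug's structure, keeps two of its three targets and moves the third to
#' an adjacent hub, with pharmacophore sites jittered by 0.05 Angstrom. The
#' planted candidate is what an ideal screen should rank first.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed (mandatory).
#' @param n_nodes Background network size (default 60).
#' @param n_drugs Number of decoy candidates (default 8).
#' @param planted_synergist Add the planted candidate `PLANTED`
#'   (default `FALSE`).
#' @return Named list of file paths (network, disease_genes, targets,
#'   smiles, sites, obo, annotations, config, manifest).
#' @export
simulate_bundle <- function(out_dir, seed, n_nodes = 60L, n_drugs = 8L,
                            planted_synergist = FALSE) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  files <- list(
    network = file.path(out_dir, "ppi.tsv"),
    disease_genes = file.path(out_dir, "disease_genes.txt"),
    targets = file.path(out_dir, "targets.tsv"),
    smiles = file.path(out_dir, "drugs.smi"),
    sites = file.path(out_dir, "sites.tsv"),
    obo = file.path(out_dir, "go.obo"),
    annotations = file.path(out_dir, "annotations.tsv"),
    config = file.path(out_dir, "config.json"),
    manifest = file.path(out_dir, "manifest.json")
  )

  net <- gen_ppi(n_nodes, model = "scale_free", edge_param = 2, seed = seed,
                 path = files$network)

  # disease genes: the hub region (top third by degree, at least 12 nodes)
  deg <- igraph::degree(net)
  k <- max(12L, ceiling(n_nodes / 3))
  disease_genes <- names(sort(deg, decreasing = TRUE))[seq_len(min(k, n_nodes))]
  disease_genes <- sort(disease_genes)
  writeLines(disease_genes, files$disease_genes)

  dnet <- induce_subnetwork(net, disease_genes, label = "disease")
  cs <- compute_centralities(dnet)
  hubs <- cs$node[order(-cs$cs)]

  ref_targets <- hubs[seq_len(min(3L, length(hubs)))]
  ref_sites <- data.frame(
    drug_id = "REF",
    site_type = c("A", "D", "R"),
    x = c(0, 1.5, -1.2), y = c(0, 0.5, 2.0), z = c(0, -1.0, 0.3),
    stringsAsFactors = FALSE
  )

  panel <- gen_drug_panel(n_drugs, nodes = igraph::V(net)$name, seed = seed + 1L)

  smiles <- rbind(
    data.frame(drug_id = "REF", smiles = toy_smiles_library[1L],
               stringsAsFactors = FALSE),
    panel$smiles
  )
  targets <- rbind(
    data.frame(drug_id = "REF", target_id = ref_targets,
               stringsAsFactors = FALSE),
    panel$targets
  )
  sites <- rbind(ref_sites, panel$sites)

  planted_id <- NULL
  if (planted_synergist) {
    planted_id <- "PLANTED"
    moved <- ref_targets[3L]
    nbrs <- setdiff(names(igraph::neighbors(dnet, ref_targets[1L])), ref_targets)
    planted_targets <- c(ref_targets[1:2],
                         if (length(nbrs) > 0L) sort(nbrs)[1L] else moved)
    jit <- with_seed(seed + 2L,
                     round(stats::runif(nrow(ref_sites) * 3, -0.05, 0.05), 4))
    planted_sites <- ref_sites
    planted_sites$drug_id <- planted_id
    planted_sites[, c("x", "y", "z")] <- ref_sites[, c("x", "y", "z")] +
      matrix(jit, ncol = 3)
    smiles <- rbind(smiles, data.frame(drug_id = planted_id,
                                       smiles = toy_smiles_library[1L],
                                       stringsAsFactors = FALSE))
    targets <- rbind(targets, data.frame(drug_id = planted_id,
                                         target_id = planted_targets,
                                         stringsAsFactors = FALSE))
    sites <- rbind(sites, planted_sites)
  }

  writeLines(paste(smiles$smiles, smiles$drug_id, sep = "\t"), files$smiles)
  writeLines(c("drug_id\ttarget_id",
               paste(targets$drug_id, targets$target_id, sep = "\t")),
             files$targets)
  writeLines(c("drug_id\tsite_type\tx\ty\tz",
               paste(sites$drug_id, sites$site_type, sites$x, sites$y, sites$z,
                     sep = "\t")),
             files$sites)

  gen_go_corpus(depth = 4L, branching = 2L, genes = igraph::V(net)$name,
                seed = seed + 3L, obo_path = files$obo, ann_path = files$annotations)

  cfg <- default_config()
  cfg$seed <- as.integer(seed)
  jsonlite::write_json(cfg[!vapply(cfg, is.null, TRUE)], files$config,
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(seed = as.integer(seed), n_nodes = as.integer(n_nodes),
         n_drugs = as.integer(n_drugs), reference = "REF",
         planted = planted_id, reference_targets = ref_targets),
    files$manifest, auto_unbox = TRUE, digits = NA)

  files
}
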