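#' Construct a drug record
#'
#' Bundles the per-drug inputs of the screen: identifier, canonical SMILES,
#' target gene set, and (optionally) a pre-aligned pharmacophore site set.
#'
#' @param drug_id Drug identifier.
#' @param smiles SMILES string or `NA`.
#' @param targets Character vector of target node IDs (may be empty).
#' @param sites `data.frame` with `site_type`, `x`, `y`, `z`, or `NULL`.
#' @return Object of class `synscreen_drug`.
#' @export
drug_record <- function(drug_id, smiles = NA_character_,
                        targets = character(), sites = NULL) {
  structure(
    list(drug_id = drug_id, smiles = smiles,
         targets = unique(as.character(targets)), sites = sites),
    class = "synscreen_drug"
  )
}

#' Assemble raw synergy score axes for each candidate
#'
#' Computes, per candidate against the reference drug, the three raw axes:
#' target-network synergy [s_tnetwork()], functional synergy [s_function()],
#' and chemical similarity (LINGO 2D [lingosim()] + pharmacophore 3D
#' [s_3d()]). A candidate failing on an axis (no mapped targets, no
#' annotations, missing structure or site data) is downgraded to 0 on that
#' axis with a structured warning, never excluded — partial data must not
#' silently shrink the screen.
#'
#' @param reference A `synscreen_drug` (must have at least one mapped target).
#' @param candidates Non-empty list of `synscreen_drug` records.
#' @param net Scoring network (`igraph`).
#' @param cs Centrality table from [compute_centralities()] on `net`.
#' @param corpus A `synscreen_go_corpus`, or `NULL` to zero the function axis.
#' @param config Configuration list from [load_config()].
#' @return `data.frame` with columns `drug_id`, `s_tnetwork`, `s_function`,
#'   `s_2d`, `s_3d`, `s_similarity` (one row per candidate, input order).
#' @export
assemble_scores <- function(reference, candidates, net, cs, corpus,
                            config = default_config()) {
  if (length(candidates) == 0L) {
    ss_stop("domain", "assemble_scores: empty candidate list")
  }
  if (length(intersect(reference$targets, igraph::V(net)$name)) == 0L) {
    ss_stop("domain", sprintf(
      "reference drug '%s' has no targets mapped to the scoring network",
      reference$drug_id))
  }
  ref_profile <- if (!is.na(reference$smiles)) {
    lingo_profile(reference$smiles, q = config$q)
  } else NULL

  axis0 <- function(expr, cand_id, axis) {
    tryCatch(expr, synscreen_error = function(e) {
      ss_warn("axis_downgrade", sprintf(
        "candidate '%s': %s axis downgraded to 0 (%s)", cand_id, axis,
        conditionMessage(e)))
      0
    })
  }

  rows <- lapply(candidates, function(cand) {
    stn <- axis0(
      s_tnetwork(reference$targets, cand$targets, net, cs,
                 exponent_sign = config$exponent_sign),
      cand$drug_id, "target-network")
    sfn <- if (is.null(corpus)) 0 else axis0(
      suppressWarnings(
        s_function(reference$targets, cand$targets, corpus,
                   aggregation = config$aggregation,
                   mica_rule = config$mica_rule)),
      cand$drug_id, "function")
    s2 <- if (is.null(ref_profile) || is.na(cand$smiles)) {
      ss_warn("axis_downgrade", sprintf(
        "candidate '%s': 2D axis downgraded to 0 (missing SMILES)", cand$drug_id))
      0
    } else {
      lingosim(ref_profile, lingo_profile(cand$smiles, q = config$q))
    }
    have_sites <- !is.null(reference$sites) && nrow(reference$sites) > 0L &&
      !is.null(cand$sites) && nrow(cand$sites) > 0L
    s3 <- if (have_sites) {
      axis0(s_3d(reference$sites, cand$sites, sigma = config$sigma),
            cand$drug_id, "3D")
    } else if (config$missing_3d == "skip_axis") {
      ss_warn("missing_3d", sprintf(
        "candidate '%s': no 3D site data; similarity axis uses 2D only", cand$drug_id))
      NA_real_
    } else {
      ss_warn("missing_3d", sprintf(
        "candidate '%s': no 3D site data; 3D score set to 0", cand$drug_id))
      0
    }
    data.frame(
      drug_id = cand$drug_id,
      s_tnetwork = stn,
      s_function = sfn,
      s_2d = s2,
      s_3d = s3,
      s_similarity = s2 + if (is.na(s3)) 0 else s3,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Normalize score axes and rank candidates along the diagonal
#'
#' Min-max normalizes each raw axis (`s_tnetwork`, `s_function`,
#' `s_similarity`) to \[0, 1\] across candidates (a constant axis maps to 0.5
#' for everyone, keeping it neutral), then combines:
#' `"diagonal"` (default) projects the normalized triple (x, y, z) onto the
#' unit diagonal of the score cube, `total = (x + y + z) / sqrt(3)` — the
#' candidate farthest from the origin along the diagonal ranks first;
#' `"sum"` uses x + y + z (identical ordering); `"euclidean"` uses the
#' distance from the origin. Ties are broken lexicographically by `drug_id`.
#'
#' @param scores `data.frame` from [assemble_scores()] (>= 1 row).
#' @param total_rule `"diagonal"`, `"sum"` or `"euclidean"`.
#' @return The input with added columns `norm_x`, `norm_y`, `norm_z`,
#'   `total`, `rank`, sorted by rank.
#' @export
normalize_and_rank <- function(scores, total_rule = c("diagonal", "sum", "euclidean")) {
  total_rule <- match.arg(total_rule)
  if (nrow(scores) == 0L) ss_stop("domain", "normalize_and_rank: no candidates")
  minmax <- function(v) {
    rng <- range(v)
    if (diff(rng) == 0) rep(0.5, length(v)) else (v - rng[1L]) / diff(rng)
  }
  x <- minmax(scores$s_tnetwork)
  y <- minmax(scores$s_function)
  z <- minmax(scores$s_similarity)
  total <- switch(total_rule,
    diagonal = (x + y + z) / sqrt(3),
    sum = x + y + z,
    euclidean = sqrt(x^2 + y^2 + z^2)
  )
  out <- scores
  out$norm_x <- x
  out$norm_y <- y
  out$norm_z <- z
  out$total <- total
  ord <- order(-total, out$drug_id)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("rank", "drug_id", "s_tnetwork", "s_function", "s_2d", "s_3d",
          "s_similarity", "norm_x", "norm_y", "norm_z", "total")]
}

#' Write a ranked candidate table as TSV
#'
#' Fixed column order (rank, drug_id, s_tnetwork, s_function, s_2d, s_3d,
#' s_similarity, norm_x, norm_y, norm_z, total); floats at 6 significant
#' digits; deterministic ordering — re-writing the same table is
#' byte-identical.
#'
#' @param ranked Table from [normalize_and_rank()] (non-empty).
#' @param path Output TSV path.
#' @export
write_ranked_table <- function(ranked, path) {
  if (nrow(ranked) == 0L) ss_stop("domain", "write_ranked_table: empty table")
  out <- ranked
  num <- vapply(out, is.double, TRUE)
  out[num] <- lapply(out[num], function(x) {
    ifelse(is.na(x), "NA", formatC(signif(x, 6), format = "g", digits = 6))
  })
  con <- tryCatch(file(path, "w"), error = function(e) {
    ss_stop("io", sprintf("cannot write '%s': %s", path, conditionMessage(e)))
  })
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a ranked table written by [write_ranked_table()]
#' @param path TSV path.
#' @return `data.frame` with the fixed column set.
#' @export
read_ranked_table <- function(path) {
  if (!file.exists(path)) ss_stop("io", sprintf("cannot read ranked table '%s'", path))
  utils::read.delim(path, stringsAsFactors = FALSE)
}
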