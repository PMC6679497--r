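make_gold_ctx <- function() {
  gi <- gold_instance()
  dnet <- induce_subnetwork(gi$net, gi$disease_genes)
  cs <- compute_centralities(dnet)
  obo <- tempfile(fileext = ".obo")
  writeLines(gi$obo_lines, obo)
  corp <- build_go_corpus(parse_obo(obo), gi$annotations)
  list(gi = gi, net = dnet, cs = cs, corpus = corp)
}

test_that("a candidate identical to the reference hits the identity bounds", {
  ctx <- make_gold_ctx()
  ref <- drug_record("REF", smiles = "CCCCC", targets = "B",
                     sites = data.frame(site_type = "A", x = 0, y = 0, z = 0))
  twin <- drug_record("TWIN", smiles = ref$smiles, targets = ref$targets,
                      sites = ref$sites)
  raw <- assemble_scores(ref, list(twin), ctx$net, ctx$cs, ctx$corpus)
  expect_equal(raw$s_tnetwork, 2.0)
  expect_equal(raw$s_2d, 1.0)
  expect_equal(raw$s_3d, 1.0)
  expect_equal(raw$s_similarity, 2.0)
  expect_equal(raw$s_function, 1.0) # m = n = 1, same annotation (gene B)
})

test_that("per-axis failures downgrade to 0 with warnings, never exclude", {
  ctx <- make_gold_ctx()
  ref <- drug_record("REF", smiles = "CCCCC", targets = "B",
                     sites = data.frame(site_type = "A", x = 0, y = 0, z = 0))
  lame <- drug_record("LAME") # no targets, no structure, no sites
  raw <- suppressWarnings(assemble_scores(ref, list(lame), ctx$net, ctx$cs,
                                          ctx$corpus))
  expect_equal(nrow(raw), 1L)
  expect_equal(raw$s_tnetwork, 0)
  expect_equal(raw$s_similarity, 0)
  suppressWarnings(expect_ss_warning(
    assemble_scores(ref, list(lame), ctx$net, ctx$cs, ctx$corpus),
    "axis_downgrade"))

  # empty candidate list and unmapped reference are hard errors
  expect_ss_error(assemble_scores(ref, list(), ctx$net, ctx$cs, ctx$corpus),
                  "domain")
  bad_ref <- drug_record("BAD", targets = "NOT_IN_NET")
  expect_ss_error(assemble_scores(bad_ref, list(lame), ctx$net, ctx$cs,
                                  ctx$corpus), "domain")
})

test_that("min-max normalization and diagonal projection follow the stated rules", {
  raw <- data.frame(
    drug_id = c("d1", "d2", "d3"),
    s_tnetwork = c(0.2, 1.0, 2.0),
    s_function = c(0.1, 0.2, 0.3),
    s_2d = c(0.5, 0.5, 0.5),
    s_3d = c(0, 0, 0),
    s_similarity = c(0.5, 0.5, 0.5), # constant axis -> 0.5 for all
    stringsAsFactors = FALSE
  )
  ranked <- normalize_and_rank(raw)
  byid <- ranked[match(c("d1", "d2", "d3"), ranked$drug_id), ]
  expect_equal(byid$norm_x, c(0, 4 / 9, 1), tolerance = 1e-12)
  expect_equal(byid$norm_z, rep(0.5, 3))
  expect_equal(ranked$total, (ranked$norm_x + ranked$norm_y + ranked$norm_z) / sqrt(3),
               tolerance = 1e-12)
  expect_equal(ranked$rank, 1:3)
  expect_equal(ranked$drug_id[1], "d3")

  # a full-scoring triple projects to sqrt(3); an all-zero one to 0
  expect_equal(max(ranked$total), (1 + 0.3 / 0.3 * 0 + 1 + 0.5) / sqrt(3),
               tolerance = 1e-12) # d3: x=1, y=1, z=0.5
  expect_equal(min(ranked$norm_x), 0)
})

test_that("ranking is invariant under positive affine rescaling of a raw axis", {
  set.seed(31)
  raw <- data.frame(
    drug_id = sprintf("d%02d", 1:6),
    s_tnetwork = stats::runif(6, 0, 2),
    s_function = stats::runif(6),
    s_2d = stats::runif(6),
    s_3d = stats::runif(6),
    stringsAsFactors = FALSE
  )
  raw$s_similarity <- raw$s_2d + raw$s_3d
  r1 <- normalize_and_rank(raw)
  raw2 <- raw
  raw2$s_tnetwork <- 3.7 * raw2$s_tnetwork + 0.9
  r2 <- normalize_and_rank(raw2)
  expect_equal(r1$drug_id, r2$drug_id)
  expect_equal(r1$total, r2$total, tolerance = 1e-12)

  # ties break lexicographically by drug_id
  tie <- raw
  tie[, c("s_tnetwork", "s_function", "s_2d", "s_3d", "s_similarity")] <- 1
  rt <- normalize_and_rank(tie)
  expect_equal(rt$drug_id, sort(tie$drug_id))

  # total rules order identically for diagonal and sum
  r_sum <- normalize_and_rank(raw, total_rule = "sum")
  expect_equal(r1$drug_id, r_sum$drug_id)
  expect_equal(r_sum$total, r1$total * sqrt(3), tolerance = 1e-12)
})

test_that("the screen is deterministic for a fixed input and config", {
  ctx <- make_gold_ctx()
  gi <- ctx$gi
  run1 <- run_screen(gi$net, gi$disease_genes, gi$targets, "REF",
                     smiles = gi$smiles, sites = gi$sites)
  run2 <- run_screen(gi$net, gi$disease_genes, gi$targets, "REF",
                     smiles = gi$smiles, sites = gi$sites)
  expect_identical(run1, run2)
  expect_ss_error(
    run_screen(gi$net, gi$disease_genes, gi$targets, "NOSUCH",
               smiles = gi$smiles), "domain")
})
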