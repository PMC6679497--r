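test_that("OBO parsing resolves parents, obsoletes, dangling refs, and cycles", {
  f <- tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: A", "name: a", "",
               "[Term]", "id: B", "name: b", "is_a: A ! a"), f)
  ont <- parse_obo(f)
  expect_equal(ont$parents[["B"]], "A")
  expect_equal(ont$parents[["A"]], character())

  writeLines(c("[Term]", "id: A", "",
               "[Term]", "id: B", "is_a: A", "is_obsolete: true"), f)
  ont <- suppressMessages(parse_obo(f))
  expect_equal(ont$obsolete, "B")

  writeLines(c("[Term]", "id: A", "is_a: GHOST", "",
               "[Term]", "id: B", "is_a: A"), f)
  expect_ss_warning(parse_obo(f), "dangling_isa")

  writeLines(c("[Term]", "id: A", "is_a: B", "",
               "[Term]", "id: B", "is_a: A"), f)
  expect_ss_error(parse_obo(f), "ontology")

  writeLines("no stanzas here", f)
  expect_ss_error(parse_obo(f), "format")
})

test_that("term probabilities use cumulative frequencies over MaxFreq", {
  corp <- toy_corpus()
  expect_equal(term_probability(corp, "T:0001"), 1.0)
  expect_equal(term_probability(corp, "T:0002"), 0.5)
  expect_equal(term_probability(corp, "T:0003"), 0.25)
  expect_equal(term_probability(corp, "T:0004"), 0.125)
  expect_ss_error(term_probability(corp, "T:9999"), "missing_annotation")

  # cumulative counting: parent frequency dominates every child's
  for (id in names(corp$ontology$parents)) {
    for (par in corp$ontology$parents[[id]]) {
      expect_gte(corp$freq[[par]], corp$freq[[id]])
    }
  }
})

test_that("term similarity follows the information-content form with the MICA rule", {
  corp <- toy_corpus()
  # siblings X (p=1/4), Y (p=1/8), MICA mid (p=1/2): 2*(-1)/((-2)+(-3)) = 0.4
  expect_equal(term_similarity(corp, "T:0003", "T:0004"), 0.4)
  # identity
  expect_equal(term_similarity(corp, "T:0004", "T:0004"), 1.0)
  # symmetric
  expect_equal(term_similarity(corp, "T:0004", "T:0003"), 0.4)
  # literal printed rule picks the root (p = 1): numerator 0
  expect_equal(term_similarity(corp, "T:0003", "T:0004",
                               mica_rule = "literal_max"), 0)
})

test_that("root-only ancestry and degenerate probabilities give similarity 0", {
  f <- tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: R", "",
               "[Term]", "id: X", "is_a: R", "",
               "[Term]", "id: Y", "is_a: R"), f)
  ont <- parse_obo(f)
  ann <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                    term_id = c("X", "X", "Y", "Y"))
  corp <- build_go_corpus(ont, ann)
  # only common ancestor is the root with p = 1: 2*log2(1) = 0
  expect_equal(term_similarity(corp, "X", "Y"), 0)

  # both terms at p = 1: denominator vanishes, distinct terms score 0
  ann2 <- data.frame(gene_id = c("g1", "g2"), term_id = c("X", "X"))
  corp2 <- build_go_corpus(ont, ann2)
  expect_equal(term_probability(corp2, "X"), 1.0)
  expect_equal(term_similarity(corp2, "X", "R"), 0)
})

test_that("gene similarity aggregates cross term pairs and tolerates gaps", {
  corp <- toy_corpus()
  # identical single annotations
  expect_equal(gene_pair_similarity(corp, "B", "GX1"), 1.0) # both T:0003
  # single cross pair
  expect_equal(gene_pair_similarity(corp, "B", "D"), 0.4)
  # unannotated gene scores 0 with a structured warning
  expect_ss_warning(
    val <- gene_pair_similarity(corp, "B", "UNKNOWN_GENE"),
    "unannotated_gene")
  expect_equal(val, 0)

  # aggregation rules on a multi-annotated gene
  ann <- rbind(data.frame(gene_id = "multi", term_id = c("T:0003", "T:0004")),
               data.frame(gene_id = c("B", "GX1", "D", "GX2", "GX3", "GX4",
                                      "GX5", "GX6"),
                          term_id = c("T:0003", "T:0003", "T:0004", "T:0002",
                                      "T:0001", "T:0001", "T:0001", "T:0001")))
  corp2 <- build_go_corpus(corp$ontology, ann)
  s_max <- gene_pair_similarity(corp2, "multi", "B", aggregation = "max")
  s_avg <- gene_pair_similarity(corp2, "multi", "B", aggregation = "avg")
  expect_equal(s_max, 1.0)
  expect_lt(s_avg, s_max)
})

test_that("s_function follows the ordered-pair formula and its bounds", {
  corp <- toy_corpus()
  # m = n = 1, identical annotation: 2*1/(2*1) = 1
  expect_equal(s_function("B", "GX1", corp), 1.0)
  # m = n = 1, sim 0.4
  expect_equal(s_function("B", "D", corp), 0.4)
  # all cross similarities 0
  expect_equal(suppressWarnings(s_function("B", "UNKNOWN", corp)), 0)
  expect_ss_error(s_function(character(), "B", corp), "undefined_score")

  # m = 2, n = 1: denominator (m+n)(m+n-1) = 6, two ordered copies of each
  # cross pair
  s <- s_function(c("B", "GX2"), "D", corp)
  sim_bd <- gene_pair_similarity(corp, "B", "D")
  sim_gd <- gene_pair_similarity(corp, "GX2", "D")
  expect_equal(s, 2 * (sim_bd + sim_gd) / 6, tolerance = 1e-12)

  # symmetry and bounds on random draws from the corpus genes
  set.seed(5)
  genes <- names(corp$gene2terms)
  for (rep in 1:25) {
    ta <- sample(genes, sample(1:3, 1))
    tb <- sample(genes, sample(1:3, 1))
    s_ab <- s_function(ta, tb, corp)
    expect_equal(s_ab, s_function(tb, ta, corp), tolerance = 1e-12)
    expect_gte(s_ab, 0)
    expect_lte(s_ab, 1)
  }
})

test_that("moving the common ancestor rootward never increases MICA similarity", {
  # chain root - M1 - M2 with two leaves under M2; compare similarity when
  # the leaves' deepest shared ancestor is M2 (p small) vs only M1 (p larger)
  f <- tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: R", "",
               "[Term]", "id: M1", "is_a: R", "",
               "[Term]", "id: M2", "is_a: M1", "",
               "[Term]", "id: X", "is_a: M2", "",
               "[Term]", "id: Y", "is_a: M2", "",
               "[Term]", "id: Z", "is_a: M1"), f)
  ont <- parse_obo(f)
  ann <- data.frame(
    gene_id = paste0("g", 1:8),
    term_id = c("X", "Y", "Z", "M1", "R", "R", "R", "R"))
  corp <- build_go_corpus(ont, ann)
  deep <- term_similarity(corp, "X", "Y") # MICA = M2
  shallow <- term_similarity(corp, "X", "Z") # MICA = M1 (closer to root)
  expect_gt(corp$p[["M1"]], corp$p[["M2"]])
  expect_gt(deep, shallow)
})

test_that("annotation reader rejects malformed tables", {
  f <- tempfile()
  writeLines(c("gene_id\tterm_id", "g1\tT:0001"), f)
  ann <- read_annotations(f)
  expect_equal(ann$gene_id, "g1")
  writeLines("onlyonecolumn", f)
  expect_ss_error(read_annotations(f), "format")
})
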