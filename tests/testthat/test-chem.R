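test_that("ring-number substitution rewrites ring labels only", {
  expect_equal(preprocess_smiles("C1CCCCC1"), "C0CCCCC0")
  expect_equal(preprocess_smiles("C%12CC%12"), "C%00CC%00")
  expect_equal(preprocess_smiles("[13CH4]"), "[13CH4]") # bracket digits kept
  expect_equal(preprocess_smiles("C1C[13CH2]C1"), "C0C[13CH2]C0")
  expect_ss_error(preprocess_smiles("[13CH4"), "format")
  expect_ss_error(preprocess_smiles("13CH4]"), "format")
  expect_ss_error(preprocess_smiles(""), "domain")
})

test_that("LINGO profiles enumerate overlapping windows", {
  p <- lingo_profile("CCCCC", q = 4)
  expect_equal(as.integer(p["CCCC"]), 2L)
  expect_equal(length(p), 1L)

  # short-string rule: whole string is one LINGO
  p <- lingo_profile("CCO", q = 4)
  expect_equal(as.integer(p["CCO"]), 1L)

  p <- lingo_profile("CC(C)O", q = 4)
  expect_equal(sort(names(p)), sort(c("CC(C", "C(C)", "(C)O")))
  expect_true(all(p == 1L))

  # window-count conservation: sum(counts) = max(len - q + 1, 1)
  set.seed(3)
  for (s in c("C1CCCCC1", "CC(=O)OC1=CC=CC=C1C(=O)O", "CO", "C")) {
    prof <- lingo_profile(s, q = 4)
    expect_equal(sum(prof), max(nchar(preprocess_smiles(s)) - 3L, 1L))
  }
  expect_ss_error(lingo_profile("CC", q = 0), "domain")
})

test_that("lingosim follows the count-profile Tanimoto form", {
  p1 <- lingo_profile("CCCCC")
  p2 <- lingo_profile("CCCC")
  expect_equal(lingosim(p1, p2), 1 - 1 / 3, tolerance = 1e-12)
  expect_equal(lingosim(p1, p1), 1.0)
  # disjoint LINGO sets
  expect_equal(lingosim(lingo_profile("CCCC"), lingo_profile("NNNN")), 0)
  # mismatched q
  expect_ss_error(lingosim(lingo_profile("CCCC", q = 4),
                           lingo_profile("CCCC", q = 3)), "domain")
})

test_that("lingosim is symmetric, bounded, and 1 only for identical profiles", {
  smis <- c("CC1=NC(C)=C(C)N=C1C", "CC(=O)OC1=CC=CC=C1C(=O)O",
            "CN1C=NC2=C1C(=O)N(C)C(=O)N2C", "CCCCC", "CCO")
  for (a in smis) {
    for (b in smis) {
      s <- lingosim(lingo_profile(a), lingo_profile(b))
      expect_equal(s, lingosim(lingo_profile(b), lingo_profile(a)),
                   tolerance = 1e-12)
      expect_gte(s, 0)
      expect_lte(s, 1)
      if (identical(a, b)) expect_equal(s, 1.0)
    }
  }
})

test_that("site overlap sums same-type Gaussian pair terms", {
  a <- data.frame(site_type = "A", x = 0, y = 0, z = 0)
  b <- data.frame(site_type = "A", x = 1, y = 0, z = 0)
  expect_equal(site_overlap(a, a), 1.0) # exp(0)
  expect_equal(site_overlap(a, b), exp(-1), tolerance = 1e-12)
  expect_equal(site_overlap(a, b, sigma = 2), exp(-1 / 4), tolerance = 1e-12)

  # different types never overlap
  d <- data.frame(site_type = "D", x = 0, y = 0, z = 0)
  expect_equal(site_overlap(a, d), 0)

  # identical multi-type sets: cross overlap equals self overlap
  m <- data.frame(site_type = c("A", "D", "R"),
                  x = c(0, 1, 2), y = 0, z = 0)
  expect_equal(site_overlap(m, m), site_overlap(m, m))

  expect_ss_error(site_overlap(a[0, ], b), "undefined_overlap")
  bad <- data.frame(site_type = "Q", x = 0, y = 0, z = 0)
  expect_ss_error(site_overlap(a, bad), "format")
})

test_that("3D score is a clamped self-overlap ratio", {
  a <- data.frame(site_type = "A", x = 0, y = 0, z = 0)
  b <- data.frame(site_type = "A", x = 1, y = 0, z = 0)
  expect_equal(s_3d(a, a), 1.0)
  expect_equal(s_3d(a, b), exp(-1), tolerance = 1e-12)
  expect_equal(s_3d(a, b), s_3d(b, a), tolerance = 1e-12)
  # no shared types
  d <- data.frame(site_type = "D", x = 0, y = 0, z = 0)
  expect_equal(s_3d(a, d), 0)

  # bounded on random site sets
  set.seed(9)
  for (rep in 1:20) {
    mk <- function() data.frame(
      site_type = sample(c("A", "D", "H", "N", "P", "R"), sample(1:4, 1),
                         replace = TRUE),
      x = stats::runif(1), y = stats::runif(1), z = stats::runif(1))
    sa <- mk(); sb <- mk()
    v <- s_3d(sa, sb)
    expect_gte(v, 0)
    expect_lte(v, 1)
    expect_equal(v, s_3d(sb, sa), tolerance = 1e-12)
  }
})

test_that("total similarity is the sum of the 2D and 3D components", {
  expect_equal(s_similarity(1, 1), 2)
  expect_equal(s_similarity(0, 0), 0)
  expect_equal(s_similarity(1 - 1 / 3, exp(-1)), 2 / 3 + exp(-1),
               tolerance = 1e-12)
})

test_that("SMILES and site files round-trip through their readers", {
  f <- tempfile(fileext = ".smi")
  writeLines(c("# library", "CCCCC\tREF", "CCCC\tCAND"), f)
  smi <- read_smiles(f)
  expect_equal(smi$drug_id, c("REF", "CAND"))
  expect_equal(smi$smiles[1], "CCCCC")

  g <- tempfile(fileext = ".tsv")
  writeLines(c("drug_id\tsite_type\tx\ty\tz", "REF\tA\t0\t0\t0",
               "CAND\tA\t1\t0\t0"), g)
  st <- read_sites(g)
  expect_equal(nrow(sites_of(st, "REF")), 1L)
  writeLines(c("drug_id\tsite_type\tx\ty\tz", "REF\tQ\t0\t0\t0"), g)
  expect_ss_error(read_sites(g), "format")
  writeLines(c("bad\theader", "REF\tA"), g)
  expect_ss_error(read_sites(g), "format")
})
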