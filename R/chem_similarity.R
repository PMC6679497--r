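#' Ring-number substitution for LINGO profiling
#'
#' Replaces every ring-closure label in a SMILES string with `0`: single
#' digits outside square brackets become `0`, and two-digit `%nn` labels
#' become `%00`. Digits inside square brackets (isotopes, charges, H counts)
#' are untouched. Input is expected to be canonical SMILES; canonicalization
#' is the caller's responsibility.
#'
#' @param raw A non-empty SMILES string.
#' @return The processed SMILES string.
#' @export
#' @examples
#' preprocess_smiles("C1CCCCC1") # "C0CCCCC0"
preprocess_smiles <- function(raw) {
  if (!is.character(raw) || length(raw) != 1L || !nzchar(raw)) {
    ss_stop("domain", "preprocess_smiles: SMILES must be a single non-empty string")
  }
  chars <- strsplit(raw, "", fixed = TRUE)[[1L]]
  out <- character(length(chars))
  depth <- 0L
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") depth <- depth + 1L
    if (ch == "]") {
      depth <- depth - 1L
      if (depth < 0L) ss_stop("format", "preprocess_smiles: unbalanced ']' in SMILES")
    }
    if (depth == 0L && ch == "%" && i + 2L <= n &&
        grepl("^[0-9]$", chars[i + 1L]) && grepl("^[0-9]$", chars[i + 2L])) {
      out[i] <- "%"; out[i + 1L] <- "0"; out[i + 2L] <- "0"
      i <- i + 3L
      next
    }
    out[i] <- if (depth == 0L && grepl("^[0-9]$", ch)) "0" else ch
    i <- i + 1L
  }
  if (depth != 0L) ss_stop("format", "preprocess_smiles: unbalanced '[' in SMILES")
  paste(out, collapse = "")
}

#' LINGO profile of a SMILES string
#'
#' Counts all overlapping length-`q` substrings (LINGOs) of the ring-number
#' substituted SMILES; a string shorter than `q` yields itself as a single
#' LINGO. A string of length n yields n - q + 1 windows.
#'
#' @param smiles SMILES string (raw; ring substitution applied internally
#'   unless `preprocess = FALSE`).
#' @param q Substring length in characters (default 4, the standard LINGO
#'   length).
#' @param preprocess Apply [preprocess_smiles()] first (default `TRUE`).
#' @return Named integer vector of LINGO counts with attribute `q`.
#' @export
lingo_profile <- function(smiles, q = 4L, preprocess = TRUE) {
  if (q < 1L) ss_stop("domain", "lingo_profile: q must be >= 1")
  s <- if (preprocess) preprocess_smiles(smiles) else smiles
  len <- nchar(s)
  subs <- if (len < q) s else {
    starts <- seq_len(len - q + 1L)
    substring(s, starts, starts + q - 1L)
  }
  counts <- table(subs)
  out <- stats::setNames(as.integer(counts), names(counts))
  attr(out, "q") <- as.integer(q)
  out
}

#' LINGOsim 2D similarity of two LINGO profiles
#'
#' Count-profile Tanimoto-style similarity over the union of LINGOs:
#' \deqn{S_{2D} = \frac{1}{m} \sum_{k=1}^{m}
#'   \left[1 - \frac{|N_{i,k} - N_{j,k}|}{N_{i,k} + N_{j,k}}\right]}
#' where m is the number of unique LINGOs across both compounds and absent
#' LINGOs count 0. Equals 1 iff the profiles are identical; 0 for disjoint
#' LINGO sets.
#'
#' @param p1,p2 Profiles from [lingo_profile()] built with the same `q`.
#' @return Similarity in \[0, 1\].
#' @export
lingosim <- function(p1, p2) {
  if (!identical(attr(p1, "q"), attr(p2, "q"))) {
    ss_stop("domain", "lingosim: profiles were built with different q")
  }
  keys <- union(names(p1), names(p2))
  n1 <- ifelse(keys %in% names(p1), p1[keys], 0)
  n2 <- ifelse(keys %in% names(p2), p2[keys], 0)
  mean(1 - abs(n1 - n2) / (n1 + n2))
}

#' Gaussian overlap of two pharmacophore site sets
#'
#' Sites are typed 3D feature points (acceptor A, donor D, hydrophobe H,
#' negative N, positive P, aromatic ring R) assumed pre-aligned to a shared
#' coordinate frame. The overlap is the sum over all same-type site pairs
#' (one from each set; for a self-overlap, all ordered intra-set pairs
#' including each site with itself) of \eqn{e^{-d^2/\sigma^2}} with d the
#' Euclidean distance in Angstrom.
#'
#' @param a,b Site sets: `data.frame`s with columns `site_type`, `x`, `y`,
#'   `z` (non-empty).
#' @param sigma Gaussian width in Angstrom (default 1.0).
#' @return Non-negative overlap value.
#' @export
site_overlap <- function(a, b, sigma = 1.0) {
  check_sites <- function(s, who) {
    if (is.null(s) || nrow(s) == 0L) {
      ss_stop("undefined_overlap", sprintf("site_overlap: %s site set is empty", who))
    }
    bad <- !(s$site_type %in% c("A", "D", "H", "N", "P", "R"))
    if (any(bad)) {
      ss_stop("format", sprintf(
        "site_overlap: unknown site type '%s' (alphabet is A,D,H,N,P,R)",
        s$site_type[bad][1L]))
    }
    if (!all(is.finite(c(s$x, s$y, s$z)))) {
      ss_stop("format", "site_overlap: non-finite site coordinates")
    }
  }
  check_sites(a, "first")
  check_sites(b, "second")
  total <- 0
  for (ty in intersect(unique(a$site_type), unique(b$site_type))) {
    pa <- as.matrix(a[a$site_type == ty, c("x", "y", "z")])
    pb <- as.matrix(b[b$site_type == ty, c("x", "y", "z")])
    for (i in seq_len(nrow(pa))) {
      d2 <- colSums((t(pb) - pa[i, ])^2)
      total <- total + sum(exp(-d2 / sigma^2))
    }
  }
  total
}

#' 3D pharmacophore similarity score
#'
#' Ratio of the cross overlap to the larger self-overlap,
#' \eqn{S_{3D} = O(d_i, d_j) / \max(O(d_i, d_i), O(d_j, d_j))}, clamped to
#' \[0, 1\] (the Gaussian cross-sum is not guaranteed below the self-overlap
#' for asymmetric site counts). A surrogate for proprietary volume-overlap
#' shape scores; no conformer generation or alignment is performed, the
#' input coordinates must already share a frame.
#'
#' @inheritParams site_overlap
#' @return Score in \[0, 1\]; 1 for identical site sets.
#' @export
s_3d <- function(a, b, sigma = 1.0) {
  cross <- site_overlap(a, b, sigma)
  self_max <- max(site_overlap(a, a, sigma), site_overlap(b, b, sigma))
  min(max(cross / self_max, 0), 1)
}

#' Total chemical similarity score
#'
#' \eqn{S_{similarity} = S_{2D} + S_{3D}}, each component in \[0, 1\].
#'
#' @param s2d,s3d Component scores.
#' @return Sum in \[0, 2\].
#' @export
s_similarity <- function(s2d, s3d) {
  s2d + s3d
}

#' Read a .smi SMILES file ("SMILES<ws>drug_id" per line)
#' @param path Path to the .smi file; '#' comments allowed.
#' @return `data.frame` with columns `drug_id`, `smiles`.
#' @export
read_smiles <- function(path) {
  if (!file.exists(path)) ss_stop("io", sprintf("cannot read SMILES file '%s'", path))
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) ss_stop("format", sprintf("no SMILES records in '%s'", path))
  fields <- strsplit(lines, "[ \t]+")
  if (any(vapply(fields, length, 1L) < 2L)) {
    ss_stop("format", sprintf("'%s': each line must be 'SMILES<whitespace>drug_id'", path))
  }
  data.frame(
    drug_id = vapply(fields, `[[`, "", 2L),
    smiles = vapply(fields, `[[`, "", 1L),
    stringsAsFactors = FALSE
  )
}

#' Read a pharmacophore site table
#'
#' TSV with a required header `drug_id site_type x y z`; site types must be
#' from the six-letter alphabet A (acceptor), D (donor), H (hydrophobe),
#' N (negative), P (positive), R (aromatic ring). Coordinates in Angstrom,
#' pre-aligned to a shared frame.
#'
#' @param path Path to the TSV.
#' @return `data.frame` with columns `drug_id`, `site_type`, `x`, `y`, `z`.
#' @export
read_sites <- function(path) {
  if (!file.exists(path)) ss_stop("io", sprintf("cannot read site table '%s'", path))
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("drug_id", "site_type", "x", "y", "z")
  if (!all(need %in% names(df))) {
    ss_stop("format", sprintf("site table '%s' must have header: %s",
                              path, paste(need, collapse = ", ")))
  }
  bad <- !(df$site_type %in% c("A", "D", "H", "N", "P", "R"))
  if (any(bad)) {
    ss_stop("format", sprintf("site table '%s': unknown site type '%s'",
                              path, df$site_type[bad][1L]))
  }
  df[, need]
}

#' Extract one drug's sites from a site table
#' @param sites Table from [read_sites()].
#' @param drug_id Drug identifier.
#' @return `data.frame` of sites (possibly 0 rows).
#' @export
sites_of <- function(sites, drug_id) {
  sites[sites$drug_id == drug_id, c("site_type", "x", "y", "z"), drop = FALSE]
}
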