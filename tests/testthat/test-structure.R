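toy_complex <- function(n = 40, contact = c(10, 20), seed = 1,
                        margin = 8, ...) {
  path <- tempfile(fileext = ".pdb")
  simulate_complex(n, contact, path, margin = margin, seed = seed, ...)
  list(path = path, complex = read_structure(path))
}

test_that("simulated complexes round-trip through the PDB reader", {
  tc <- toy_complex()
  cx <- tc$complex
  expect_s3_class(cx, "structure_complex")
  expect_equal(cx$protein_chains, "A")
  expect_equal(cx$rna_chains, "B")
  expect_equal(sum(cx$atoms$type == "protein"), 40L)
  expect_equal(sum(cx$atoms$type == "rna"), 11L)
})

test_that("min distance matches brute force and the planted geometry", {
  tc <- toy_complex()
  cx <- tc$complex
  at <- cx$atoms
  rna <- as.matrix(at[at$type == "rna", c("x", "y", "z")])
  for (res in c(5L, 10L, 15L, 25L, 40L)) {
    p <- as.matrix(at[at$type == "protein" & at$resno == res,
                      c("x", "y", "z")])
    expect_equal(min_distance_to_rna(cx, "A", res), brute_min_dist(p, rna),
                 tolerance = 1e-9)
  }
  # contact residues sit 3 Angstrom from the RNA trace, the rest >= 8
  expect_equal(min_distance_to_rna(cx, "A", 15), 3, tolerance = 0.3)
  expect_gte(min_distance_to_rna(cx, "A", 25), 8)
  expect_error(min_distance_to_rna(cx, "A", 999), "not found")
})

test_that("distances are invariant under rigid transforms", {
  set.seed(33)
  tc <- toy_complex()
  for (rep in 1:5) {
    moved <- transform_pdb(tc$path, tempfile(fileext = ".pdb"))
    cx2 <- read_structure(moved)
    for (res in c(12L, 30L)) {
      expect_equal(min_distance_to_rna(cx2, "A", res),
                   min_distance_to_rna(tc$complex, "A", res),
                   tolerance = 1e-3)
    }
  }
})

test_that("proximity classification matches the planted contact exactly", {
  tc <- toy_complex(n = 60, contact = c(25, 35))
  cm <- data.frame(structure_id = tc$complex$structure_id, chain = "A",
                   struct_start = 1L, struct_end = 60L,
                   protein_id = "P1", offset = 0L)
  # tile the protein in 5-residue fragments
  frs <- data.frame(protein_id = "P1",
                    start = seq(1L, 56L, by = 5L))
  frs$end <- frs$start + 4L
  cls <- vapply(seq_len(nrow(frs)), function(i)
    classify_fragment_proximal(frs[i, ], tc$complex, cm), character(1))
  planted <- frs$start <= 35L & frs$end >= 25L
  expect_identical(cls == "proximal", planted)

  # boundary inclusivity: a residue at exactly the cutoff is proximal
  exact <- toy_complex(n = 10, contact = c(3, 5), contact_distance = 4.3)
  cme <- data.frame(structure_id = exact$complex$structure_id, chain = "A",
                    struct_start = 1L, struct_end = 10L,
                    protein_id = "P1", offset = 0L)
  expect_equal(classify_fragment_proximal(
    data.frame(protein_id = "P1", start = 3L, end = 3L),
    exact$complex, cme), "proximal")

  # monotonicity: raising the cutoff never loses proximal calls
  cls8 <- vapply(seq_len(nrow(frs)), function(i)
    classify_fragment_proximal(frs[i, ], tc$complex, cm, cutoff = 8.5),
    character(1))
  expect_true(all(cls8[cls == "proximal"] == "proximal"))

  # fragments outside the resolved range are unresolved
  expect_equal(classify_fragment_proximal(
    data.frame(protein_id = "P1", start = 400L, end = 410L),
    tc$complex, cm), "unresolved")
  expect_equal(classify_fragment_proximal(
    data.frame(protein_id = "OTHER", start = 1L, end = 5L),
    tc$complex, cm), "unresolved")
})

test_that("no-contact complexes yield zero proximal fragments", {
  path <- tempfile(fileext = ".pdb")
  expect_error(simulate_complex(20, NULL, path, margin = 4), "margin")
  simulate_complex(20, NULL, path)
  # no RNA chain at all -> distance queries error, classification unresolvable
  cx <- read_structure(path)
  expect_equal(length(cx$rna_chains), 0L)
  expect_error(min_distance_to_rna(cx, "A", 5), "no RNA")
})

test_that("proximity enrichment matches closed forms and Fisher enumeration", {
  tc <- toy_complex(n = 100, contact = c(1, 50))
  cm <- data.frame(structure_id = tc$complex$structure_id, chain = "A",
                   struct_start = 1L, struct_end = 100L,
                   protein_id = "P1", offset = 0L)
  mkfr <- function(starts, w = 4L)
    data.frame(protein_id = "P1", start = starts, end = starts + w)
  # RBDpeps: 8 inside the contact, 2 outside; baseline: 5 and 5
  rbd <- mkfr(c(seq(1, 43, by = 6), 61, 71))
  all_ <- mkfr(c(seq(1, 25, by = 6), 56, 66, 76, 86, 95))
  rep_ <- proximity_enrichment(rbd, all_, list(tc$complex), cm)
  expect_equal(rep_$rbdpep_proximal_fraction, 0.8)
  expect_equal(rep_$baseline_proximal_fraction, 0.5)
  expect_equal(rep_$odds_ratio, (8 * 5) / (2 * 5))
  expect_equal(rep_$p_value,
               fisher_enum(8, 2, 5, 5), tolerance = 1e-9)

  # identical composition in both sets -> OR 1, p 1
  same <- proximity_enrichment(all_, all_, list(tc$complex), cm)
  expect_equal(same$odds_ratio, 1)
  expect_gt(same$p_value, 0.99)
})

test_that("Fisher p equals the hypergeometric tail sum on bigger tables", {
  p_pkg <- stats::fisher.test(matrix(c(70, 30, 50, 50), 2))$p.value
  expect_equal(p_pkg, fisher_enum(70, 30, 50, 50), tolerance = 1e-9)
})
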