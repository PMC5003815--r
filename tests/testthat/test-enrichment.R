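test_that("amino-acid enrichment matches the closed-form odds ratio", {
  # identical multisets: no enrichment anywhere
  same <- aa_enrichment("ACDEFGHIKL", "ACDEFGHIKL")
  expect_true(all(same$log2_odds == 0))
  expect_true(all(same$stars == ""))

  # disjoint compositions: K and G positive with Haldane-capped odds
  enr <- aa_enrichment(strrep("KG", 100), strrep("DE", 100))
  expect_gt(enr$log2_odds[enr$aa == "K"], 0)
  expect_gt(enr$log2_odds[enr$aa == "G"], 0)
  expect_lt(enr$log2_odds[enr$aa == "D"], 0)
  expect_true(all(is.finite(enr$log2_odds)))

  # closed form on a single (30,70,10,90) table
  bound <- paste0(strrep("K", 30), strrep("A", 70))
  released <- paste0(strrep("K", 10), strrep("A", 90))
  row <- aa_enrichment(bound, released)
  expect_equal(row$odds_ratio[row$aa == "K"], 27 / 7, tolerance = 1e-9)
  expect_equal(row$p[row$aa == "K"], fisher_enum(30, 70, 10, 90),
               tolerance = 1e-9)
  expect_error(aa_enrichment("", "ACD"), "empty")
})

test_that("surface enrichment separates planted proximal composition", {
  # lysines on the RNA-facing strand, aspartates far away
  path <- tempfile(fileext = ".pdb")
  simulate_complex(40, c(1, 20), path, seed = 4)
  lines <- readLines(path)
  is_atom <- grepl("^ATOM", lines) & grepl(" ALA ", lines)
  resno <- as.integer(substr(lines[is_atom], 23, 26))
  lines[is_atom] <- ifelse(resno <= 20,
                           sub(" ALA ", " LYS ", lines[is_atom]),
                           sub(" ALA ", " ASP ", lines[is_atom]))
  writeLines(lines, path)
  cx <- read_structure(path)
  enr <- surface_aa_enrichment(list(cx))
  expect_gt(enr$log2_odds[enr$aa == "K"], 0)
  expect_lt(enr$log2_odds[enr$aa == "D"], 0)

  # infinite cutoff leaves no distant class
  expect_error(surface_aa_enrichment(list(cx), cutoff = Inf),
               "insufficient")
})

test_that("feature odds ratios follow ad/bc with Haldane correction", {
  # point features: 10/90 bound hits vs 5/95 released
  ann <- data.frame(protein_id = c(sprintf("B%03d", 1:100),
                                   sprintf("R%03d", 1:100)),
                    category = "PTM", name = "phospho",
                    start = 50L, end = 50L)
  bound <- data.frame(protein_id = sprintf("B%03d", 1:10),
                      start = 40L, end = 60L)
  released <- data.frame(protein_id = sprintf("R%03d", 1:5),
                         start = 40L, end = 60L)
  fo <- feature_odds_ratio(ann, bound, released, "PTM")
  expect_equal(fo$bound_hit, 10)
  expect_equal(fo$released_hit, 5)
  # events: 200 sites total; per-row construction gives (10,190,5,195)
  expect_equal(fo$odds_ratio, (10 * 195) / (190 * 5), tolerance = 1e-9)

  # zero released hits -> Haldane keeps the odds finite and > 1
  fo2 <- feature_odds_ratio(ann, bound, released[0, ], "PTM")
  expect_true(is.finite(fo2$odds_ratio))
  expect_gt(fo2$odds_ratio, 1)

  expect_error(feature_odds_ratio(ann, bound, released, "domain"),
               "absent")
})

test_that("swapping bound and released inverts the odds ratio exactly", {
  ann <- data.frame(protein_id = c("P1", "P1", "P2"), category = "domain",
                    name = "RRM", start = c(10L, 60L, 5L),
                    end = c(40L, 90L, 25L))
  b <- data.frame(protein_id = c("P1", "P2"), start = c(1L, 1L),
                  end = c(50L, 30L))
  r <- data.frame(protein_id = c("P1", "P2"), start = c(51L, 31L),
                  end = c(100L, 60L))
  expect_equal(feature_odds_ratio(ann, b, r, "domain")$odds_ratio,
               1 / feature_odds_ratio(ann, r, b, "domain")$odds_ratio,
               tolerance = 1e-9)
})

test_that("disorder partition dichotomizes sites at the 50% rule", {
  sites <- data.frame(protein_id = c("P1", "P1", "P2", "P3"),
                      start = c(10L, 80L, 10L, 10L),
                      end = c(20L, 100L, 20L, 29L))
  disorder <- data.frame(protein_id = c("P1", "P3"),
                         start = c(75L, 1L), end = c(120L, 19L))
  expect_warning(dp <- disorder_partition(sites, disorder), "without disorder")
  # P1 site [10,20] globular, [80,100] disordered; P2 globular (no annot);
  # P3 [10,29]: 10/20 residues disordered -> at threshold, disordered
  expect_equal(unname(dp$site_counts), c(2L, 2L))
  expect_equal(unname(dp$protein_counts["both"]), 1L)
  expect_equal(unname(dp$protein_counts["globular_only"]), 1L)
  expect_equal(unname(dp$protein_counts["disordered_only"]), 1L)
})

test_that("isoelectric point matches a dense grid scan and monotonicity", {
  # grid-scan oracle on 100 random decapeptides
  set.seed(55)
  for (i in 1:100) {
    s <- random_sequence(10)
    expect_lt(abs(isoelectric_point(s) - grid_pI(s)), 0.011)
  }
  expect_gt(isoelectric_point(strrep("K", 10)),
            isoelectric_point(strrep("D", 10)))
  # appending an acidic residue lowers pI; a basic one raises it
  base <- isoelectric_point("ACGTMS")
  expect_lt(isoelectric_point("ACGTMSD"), base)
  expect_gt(isoelectric_point("ACGTMSK"), base)
})

test_that("group comparison reports all pairs with rank-test calibration", {
  same <- group_score_compare(list(a = 1:20 / 2, b = 1:20 / 2))
  expect_equal(diff(same$summary$mean), 0)
  expect_gt(same$pairs$p, 0.9)

  set.seed(66)
  g <- group_score_compare(list(x = rnorm(200), y = rnorm(200, 1),
                                z = rnorm(200)))
  expect_equal(nrow(g$pairs), 3L)
  expect_lt(g$pairs$fdr[g$pairs$group1 == "x" & g$pairs$group2 == "y"], 0.05)

  expect_error(group_score_compare(list(a = 1:2, b = 1:5)), "insufficient")
})

test_that("separated groups are detected at 5% FDR in >= 95% of seeds", {
  hits <- 0L
  for (seed in 1:100) {
    set.seed(seed)
    g <- group_score_compare(list(a = rnorm(200), b = rnorm(200, 1)))
    if (g$pairs$fdr <= 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("PTM context PWM columns are probabilities with honest flags", {
  proteome <- c(P1 = paste0("AAAAAA", "SGGGGK", strrep("M", 20)),
                P2 = "MAS")
  # five identical contexts: positions 7..18 window around residue 13
  prot <- stats::setNames(rep(paste0(strrep("L", 6), "S", strrep("G", 5),
                                     strrep("W", 8)), 5),
                          sprintf("C%d", 1:5))
  sites <- data.frame(protein_id = names(prot), category = "PTM",
                      name = "phospho", start = 7L, end = 7L)
  pwm <- ptm_context_pwm(sites, prot, "phospho")
  expect_true(all(abs(colSums(pwm$pwm) - 1) < 1e-9))
  expect_equal(pwm$n_sites, 5L)
  # the identical contexts flag exactly the one-hot pattern
  onehot <- matrix(FALSE, 20, 12, dimnames = dimnames(pwm$pwm))
  ctx <- strsplit(substr(prot[1], 1, 12), "")[[1]]
  for (j in 1:12) onehot[ctx[j], j] <- TRUE
  expect_identical(unname(pwm$flags), unname(onehot))

  # truncated windows are skipped with a tally
  sites2 <- rbind(sites, data.frame(protein_id = "C1", category = "PTM",
                                    name = "phospho", start = 3L, end = 3L))
  pwm2 <- ptm_context_pwm(sites2, prot, "phospho")
  expect_equal(pwm2$n_skipped, 1L)
  expect_equal(pwm2$n_sites, 5L)

  expect_error(ptm_context_pwm(sites[1:2, ], prot, "phospho"),
               "insufficient")
})

test_that("flag sets shrink when the PWM FDR tightens", {
  set.seed(77)
  prot <- stats::setNames(vapply(1:50, function(i) random_sequence(40),
                                 character(1)), sprintf("P%02d", 1:50))
  sites <- data.frame(protein_id = names(prot), category = "PTM",
                      name = "ac", start = 20L, end = 20L)
  loose <- ptm_context_pwm(sites, prot, "ac", flag_fdr = 0.10)
  tight <- ptm_context_pwm(sites, prot, "ac", flag_fdr = 0.01)
  expect_true(all(which(tight$flags) %in% which(loose$flags)))
})
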