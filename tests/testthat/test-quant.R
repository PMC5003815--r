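quant_row <- function(bound, released, nrep = length(bound)) {
  out <- data.frame(protein_id = "P", start = 1L, end = 10L)
  for (r in seq_len(nrep)) {
    out[[paste0("bound_rep", r)]] <- bound[r]
    out[[paste0("released_rep", r)]] <- released[r]
  }
  out
}

test_that("log ratios combine replicates by median and flag one-sided", {
  one <- compute_log_ratios(quant_row(200, 100), normalize = FALSE)
  expect_equal(one$log_ratio, 1)

  three <- compute_log_ratios(quant_row(c(2, 2^1.2, 2^0.8), c(1, 1, 1)),
                              normalize = FALSE)
  expect_equal(three$log_ratio, 1)

  os <- compute_log_ratios(quant_row(c(100, 100, 100), c(NA, NA, NA)),
                           normalize = FALSE)
  expect_true(os$one_sided)
  expect_true(is.na(os$log_ratio))
  expect_equal(os$n_num_only, 3L)

  expect_warning(
    dropped <- compute_log_ratios(
      rbind(quant_row(c(2, 2), c(1, 1)), quant_row(c(NA, NA), c(NA, NA))),
      normalize = FALSE),
    "dropped")
  expect_equal(nrow(dropped), 1L)

  expect_error(compute_log_ratios(quant_row(-5, 1), normalize = FALSE),
               "negative")
})

test_that("EM recovers a planted two-component mixture", {
  set.seed(2024)
  x <- c(rnorm(7000, 0, 1), rnorm(3000, 3, 1))
  fit <- fit_two_component_mixture(x)
  expect_false(fit$degenerate)
  expect_lt(abs(fit$weight_null - 0.7), 0.05)
  expect_lt(abs(fit$mean_null - 0), 0.1)
  expect_lt(abs(fit$mean_bound - 3), 0.1)
  expect_gt(fit$mean_bound, fit$mean_null)

  # independent cross-check: model-based clustering agrees on the means
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  mc <- Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_lt(abs(sort(mc$parameters$mean)[1] - fit$mean_null), 0.15)
  expect_lt(abs(sort(mc$parameters$mean)[2] - fit$mean_bound), 0.15)
})

test_that("mixture fit honors symmetry, degeneracy, and data floor", {
  set.seed(5)
  x <- c(rnorm(500, 0), rnorm(500, 3))
  a <- fit_two_component_mixture(x)
  b <- fit_two_component_mixture(-x)
  # agreement to within the EM stopping tolerance (absolute)
  expect_lt(abs(b$mean_null + a$mean_bound), 1e-3)
  expect_lt(abs(b$mean_bound + a$mean_null), 1e-3)
  expect_lt(abs(b$weight_null - a$weight_bound), 1e-3)

  expect_true(fit_two_component_mixture(rep(1.5, 100))$degenerate)
  expect_error(fit_two_component_mixture(rnorm(49)), "insufficient")
})

test_that("classification yields nested, monotone calls at 1%/10% FDR", {
  set.seed(77)
  lr <- c(rnorm(1400, 0, 1), rnorm(600, 3, 1))
  pep <- data.frame(log_ratio = lr, one_sided = FALSE, n_num_only = 0L)
  fit <- fit_two_component_mixture(lr)
  out <- classify_peptides(pep, fit)

  called1 <- which(out$class_label == "RBDpep")
  called10 <- which(out$class_label %in% c("RBDpep", "candidate_RBDpep"))
  expect_true(all(called1 %in% called10))
  expect_gt(length(called10), length(called1))
  expect_true(all(out$fdr[called1] <= 0.01))

  # fdr is non-increasing in log_ratio
  ord <- order(out$log_ratio)
  expect_true(all(diff(out$fdr[ord]) <= 1e-12))

  # a peptide at the null mean is released with near-maximal fdr
  at_null <- which.min(abs(out$log_ratio - fit$mean_null))
  expect_equal(out$class_label[at_null], "released")
  expect_gt(out$fdr[at_null], 0.5)
})

test_that("shift invariance: adding a constant moves means, not labels", {
  set.seed(8)
  lr <- c(rnorm(700, 0), rnorm(300, 3))
  pep <- data.frame(log_ratio = lr, one_sided = FALSE, n_num_only = 0L)
  f1 <- fit_two_component_mixture(lr)
  f2 <- fit_two_component_mixture(lr + 5)
  expect_equal(f2$mean_null, f1$mean_null + 5, tolerance = 1e-4)
  expect_equal(f2$mean_bound, f1$mean_bound + 5, tolerance = 1e-4)
  l1 <- classify_peptides(pep, f1)$class_label
  pep2 <- pep; pep2$log_ratio <- pep2$log_ratio + 5
  l2 <- classify_peptides(pep2, f2)$class_label
  expect_identical(l1, l2)
})

test_that("one-sided peptides need two-replicate support and stay candidates", {
  set.seed(9)
  lr <- c(rnorm(700, 0), rnorm(300, 3))
  pep <- data.frame(log_ratio = c(lr, NA, NA),
                    one_sided = c(rep(FALSE, 1000), TRUE, TRUE),
                    n_num_only = c(rep(0L, 1000), 1L, 3L))
  fit <- fit_two_component_mixture(lr)
  out <- classify_peptides(pep, fit)
  expect_equal(out$class_label[1001], "released")   # single-replicate artifact
  # supported one-sided: candidate tier, inherited minimum fdr
  expect_equal(out$class_label[1002], "candidate_RBDpep")
  expect_equal(out$fdr[1002], min(out$fdr[1:1000]))
  # promotion flag admits them to the top tier
  prom <- classify_peptides(pep, fit, one_sided_promote = TRUE)
  expect_equal(prom$class_label[1002], "RBDpep")
})

test_that("noUV-enriched peptides are background and never called", {
  tab <- quant_row(c(8, 8, 8), c(1, 1, 1))
  tab$noUV_rep1 <- 100; tab$noUV_rep2 <- 100; tab$noUV_rep3 <- 100
  tab$input_rep1 <- 1; tab$input_rep2 <- 1; tab$input_rep3 <- 1
  flagged <- filter_uv_specific(tab)
  expect_true(flagged$background)
  set.seed(10)
  lr <- c(rnorm(700, 0), rnorm(300, 3))
  pep <- data.frame(log_ratio = c(lr, 10), one_sided = FALSE, n_num_only = 0L,
                    background = c(rep(FALSE, 1000), TRUE))
  fit <- fit_two_component_mixture(lr)
  out <- classify_peptides(pep, fit)
  expect_equal(out$class_label[1001], "background")
})

test_that("replicate correlation behaves at the closed-form anchors", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(replicate_correlation(x, x), 1)
  expect_equal(replicate_correlation(x, -x), -1)
  set.seed(11)
  a <- rnorm(1000); b <- rnorm(1000)
  expect_lt(abs(replicate_correlation(a, b)), 0.1)
  expect_error(replicate_correlation(x, rep(1, 5)), "zero variance")
  expect_error(replicate_correlation(c(1, NA, NA, NA, 2),
                                     c(2, NA, NA, NA, 3)), "3 shared")
})
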