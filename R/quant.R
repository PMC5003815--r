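# Replicate ratio computation and bimodal mixture / FDR classification
# separating RNA-bound from released peptides.

FRACTIONS <- c("bound", "released", "input", "noUV")

#' Per-peptide combined log2 intensity ratios
#'
#' Computes per-replicate log2(numerator/denominator) ratios and combines
#' them by the median over replicates where both fractions were quantified.
#' Intensities are median-centered per (fraction, replicate) channel on the
#' log2 scale before ratio formation, so channel loading differences cancel.
#' Peptides detected only in the numerator fraction across all replicates
#' are flagged one-sided (no finite ratio is fabricated for them); peptides
#' detected in neither fraction are dropped with a warning.
#'
#' @param table Quant data.frame: identifier columns plus intensity columns
#'   named `<fraction>_rep<k>` (fractions `bound`, `released`, `input`,
#'   `noUV`). Missing intensities are `NA`; intensities must be >= 0
#'   (0 is treated as not detected).
#' @param pairing Character pair `c(numerator, denominator)`, default
#'   `c("bound", "released")`.
#' @param normalize Median-center each channel before ratios (default TRUE).
#' @return The input table (minus dropped rows) with added columns
#'   `log_ratio` (median over replicates; `NA` when one-sided),
#'   `one_sided` (logical), `n_pairs` (replicates with both values),
#'   `n_num_only` (replicates with numerator only), and per-replicate
#'   `ratio_rep<k>` columns.
#' @export
compute_log_ratios <- function(table, pairing = c("bound", "released"),
                               normalize = TRUE) {
  stopifnot(length(pairing) == 2L)
  num_cols <- grep(paste0("^", pairing[1], "_rep\\d+$"), names(table), value = TRUE)
  den_cols <- grep(paste0("^", pairing[2], "_rep\\d+$"), names(table), value = TRUE)
  if (length(num_cols) == 0L || length(den_cols) == 0L)
    stop("no intensity columns found for pairing ", pairing[1], "/", pairing[2])
  reps <- intersect(sub("^.*_rep", "", num_cols), sub("^.*_rep", "", den_cols))
  if (length(reps) == 0L) stop("no shared replicates for pairing")

  getlog <- function(fraction, rep) {
    v <- table[[paste0(fraction, "_rep", rep)]]
    if (any(v < 0, na.rm = TRUE)) stop("negative intensity in ", fraction, "_rep", rep)
    v[!is.na(v) & v == 0] <- NA
    lv <- log2(v)
    if (normalize) lv <- lv - stats::median(lv, na.rm = TRUE)
    lv
  }
  ratios <- sapply(reps, function(r) getlog(pairing[1], r) - getlog(pairing[2], r))
  ratios <- matrix(ratios, nrow = nrow(table),
                   dimnames = list(NULL, paste0("ratio_rep", reps)))
  num_only <- sapply(reps, function(r) {
    nv <- table[[paste0(pairing[1], "_rep", r)]]
    dv <- table[[paste0(pairing[2], "_rep", r)]]
    (!is.na(nv) & nv > 0) & (is.na(dv) | dv == 0)
  })
  num_only <- matrix(num_only, nrow = nrow(table))

  n_pairs <- rowSums(!is.na(ratios))
  n_num_only <- rowSums(num_only)
  out <- cbind(table, ratios)
  out$log_ratio <- apply(ratios, 1L, function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0L) NA_real_ else stats::median(x)
  })
  out$n_pairs <- n_pairs
  out$n_num_only <- n_num_only
  out$one_sided <- n_pairs == 0L & n_num_only > 0L
  drop <- n_pairs == 0L & n_num_only == 0L
  if (any(drop)) {
    warning(sum(drop), " peptide(s) without any quantified pair dropped")
    out <- out[!drop, , drop = FALSE]
  }
  out
}

#' Fit a two-component Gaussian mixture by EM
#'
#' The log2 bound/released ratios of a crosslinking capture experiment are
#' bimodal: a null mode of released peptides around zero and a high mode of
#' RNA-bound peptides. This fits w0*N(mean_null, sd_null) +
#' (1-w0)*N(mean_bound, sd_bound) by expectation-maximization and relabels
#' components so the bound mean is the larger one.
#'
#' @param log_ratios Numeric vector; non-finite values are excluded. At
#'   least 50 finite values are required.
#' @param tol Convergence tolerance on the log-likelihood change
#'   (default 1e-8).
#' @param max_iter Maximum EM iterations (default 500).
#' @return Object of class `rbd_mixture`: list with `weight_null`,
#'   `mean_null`, `sd_null`, `weight_bound`, `mean_bound`, `sd_bound`,
#'   `loglik`, `n`, `iterations`, `converged`, `degenerate` (a component
#'   weight collapsed below 1e-3), and `unimodal` (TRUE when a single
#'   Gaussian explains the data at least as well by BIC, or when the fit
#'   is degenerate; classification then refuses to call anything).
#' @examples
#' set.seed(1)
#' x <- c(rnorm(700), rnorm(300, 3))
#' fit_two_component_mixture(x)
#' @export
fit_two_component_mixture <- function(log_ratios, tol = 1e-8, max_iter = 500L) {
  x <- log_ratios[is.finite(log_ratios)]
  n <- length(x)
  if (n < 50L) stop("insufficient data: need >= 50 finite log-ratios, got ", n)

  if (stats::sd(x) == 0) {
    fit <- list(weight_null = 1, mean_null = x[1], sd_null = 0,
                weight_bound = 0, mean_bound = x[1], sd_bound = 0,
                loglik = NA_real_, n = n, iterations = 0L,
                converged = TRUE, degenerate = TRUE, unimodal = TRUE,
                bic_mixture = NA_real_, bic_single = NA_real_)
    class(fit) <- "rbd_mixture"
    return(fit)
  }

  # initialization robust to a small high-ratio component: seed the null at
  # the median and the bound component in the upper tail
  mu <- c(stats::median(x), stats::quantile(x, 0.95, names = FALSE))
  if (mu[2] - mu[1] < 1e-6) mu[2] <- mu[1] + stats::sd(x)
  sg <- rep(max(stats::sd(x) / 2, 1e-3), 2)
  w <- c(0.85, 0.15)
  ll_old <- -Inf; it <- 0L; converged <- FALSE
  sd_floor <- 1e-4
  repeat {
    it <- it + 1L
    d1 <- w[1] * stats::dnorm(x, mu[1], sg[1])
    d2 <- w[2] * stats::dnorm(x, mu[2], sg[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    ll <- sum(log(tot))
    g <- d1 / tot
    w <- c(mean(g), mean(1 - g))
    mu <- c(sum(g * x) / sum(g), sum((1 - g) * x) / sum(1 - g))
    sg <- sqrt(c(sum(g * (x - mu[1])^2) / sum(g),
                 sum((1 - g) * (x - mu[2])^2) / sum(1 - g)))
    sg <- pmax(sg, sd_floor)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) { converged <- TRUE; break }
    if (it >= max_iter) break
    ll_old <- ll
  }
  # bound component = high-mean component
  if (mu[1] > mu[2]) { mu <- rev(mu); sg <- rev(sg); w <- rev(w) }
  degenerate <- min(w) < 1e-3
  # model selection against a single Gaussian: on unimodal data the EM
  # happily splits one mode into two, so weight collapse alone cannot
  # detect the no-signal case
  ll1 <- sum(stats::dnorm(x, mean(x), stats::sd(x) * sqrt((n - 1) / n),
                          log = TRUE))
  bic_mix <- -2 * ll + 5 * log(n)
  bic_one <- -2 * ll1 + 2 * log(n)
  unimodal <- degenerate || bic_one <= bic_mix
  fit <- list(weight_null = w[1], mean_null = mu[1], sd_null = sg[1],
              weight_bound = w[2], mean_bound = mu[2], sd_bound = sg[2],
              loglik = ll, n = n, iterations = it, converged = converged,
              degenerate = degenerate, unimodal = unimodal,
              bic_mixture = bic_mix, bic_single = bic_one)
  class(fit) <- "rbd_mixture"
  fit
}

#' @export
print.rbd_mixture <- function(x, ...) {
  cat("Two-component Gaussian mixture (EM) on", x$n, "log2 ratios\n")
  cat(sprintf("  null : weight %.3f, mean %.3f, sd %.3f\n",
              x$weight_null, x$mean_null, x$sd_null))
  cat(sprintf("  bound: weight %.3f, mean %.3f, sd %.3f\n",
              x$weight_bound, x$mean_bound, x$sd_bound))
  cat(sprintf("  loglik %.2f after %d iterations (%s)%s%s\n", x$loglik,
              x$iterations, if (x$converged) "converged" else "not converged",
              if (x$degenerate) " [DEGENERATE]" else "",
              if (x$unimodal) " [UNIMODAL]" else ""))
  invisible(x)
}

#' @export
summary.rbd_mixture <- function(object, ...) {
  print(object)
  invisible(object)
}

#' Posterior null probability (local false discovery rate)
#'
#' @param object Fitted `rbd_mixture`.
#' @param newdata Numeric vector of log-ratios.
#' @param ... Unused.
#' @return Local fdr per value: weight_null * dnorm_null / mixture density.
#' @export
predict.rbd_mixture <- function(object, newdata, ...) {
  if (object$degenerate) return(rep(1, length(newdata)))
  d0 <- object$weight_null * stats::dnorm(newdata, object$mean_null, object$sd_null)
  d1 <- object$weight_bound * stats::dnorm(newdata, object$mean_bound, object$sd_bound)
  tot <- d0 + d1
  tot[tot == 0] <- .Machine$double.xmin
  pmin(d0 / tot, 1)
}

#' Classify peptides at FDR thresholds
#'
#' Converts local fdr to a q-value-style tail-averaged FDR: for each
#' peptide, the mean local fdr over all fitted peptides with log-ratio at
#' least as large, made monotone non-increasing in the log-ratio. Labels:
#' `RBDpep` at FDR <= thresholds[1] (default 1%), `candidate_RBDpep` at
#' <= thresholds[2] (default 10%), otherwise `released` (or `background`
#' for peptides flagged as crosslinking-independent, see
#' [filter_uv_specific()]). One-sided bound-only peptides inherit the
#' minimum FDR of fitted peptides provided they were detected bound-only in
#' at least `min_one_sided_reps` replicates; otherwise they stay unlabeled
#' (`released`). Because one-sided evidence is presence/absence only — a
#' missing released intensity can be a dropout rather than depletion — the
#' supported one-sided peptides enter the candidate tier, never the
#' top-stringency tier; set `one_sided_promote = TRUE` to let them carry
#' their inherited FDR into the top tier.
#'
#' @param peptides Data.frame from [compute_log_ratios()] (columns
#'   `log_ratio`, `one_sided`, `n_num_only`).
#' @param model Fitted `rbd_mixture`.
#' @param thresholds Ascending FDR thresholds, default `c(0.01, 0.10)`.
#' @param min_one_sided_reps Replicate support required to call a one-sided
#'   peptide (default 2).
#' @param one_sided_promote Allow supported one-sided peptides into the
#'   top-stringency class (default FALSE).
#' @return Input with added columns `fdr` and `class_label`.
#' @export
classify_peptides <- function(peptides, model, thresholds = c(0.01, 0.10),
                              min_one_sided_reps = 2L,
                              one_sided_promote = FALSE) {
  stopifnot(inherits(model, "rbd_mixture"), length(thresholds) == 2L,
            thresholds[1] <= thresholds[2])
  out <- peptides
  out$fdr <- NA_real_
  bg <- if (!is.null(out$background)) out$background else rep(FALSE, nrow(out))
  out$class_label <- ifelse(bg, "background", "released")
  if (model$degenerate || isTRUE(model$unimodal)) {
    out$fdr <- 1
    return(out)
  }
  fitted <- is.finite(out$log_ratio) & !bg
  x <- out$log_ratio[fitted]
  lfdr <- predict(model, x)
  # tail-average from the top: q(x) = mean lfdr of peptides with ratio >= x,
  # then enforce monotone non-increase in x via cummax down the ranking
  ord <- order(x, decreasing = TRUE)
  q <- cummax(cumsum(lfdr[ord]) / seq_along(ord))
  fdr <- numeric(length(x))
  fdr[ord] <- pmin(q, 1)
  out$fdr[fitted] <- fdr
  one_sided_ok <- !bg & out$one_sided & out$n_num_only >= min_one_sided_reps
  if (any(one_sided_ok)) out$fdr[one_sided_ok] <- min(fdr)
  called <- !is.na(out$fdr) & (fitted | one_sided_ok)
  out$class_label[called & out$fdr <= thresholds[2]] <- "candidate_RBDpep"
  top <- called & out$fdr <= thresholds[1]
  if (!one_sided_promote) top <- top & !one_sided_ok
  out$class_label[top] <- "RBDpep"
  out
}

#' Flag crosslinking-independent (background) peptides
#'
#' Peptides more intense without UV irradiation than with it cannot owe
#' their capture to a covalent crosslink; they are flagged `background` and
#' excluded from mixture fitting and calling.
#'
#' @param table Quant data.frame with `noUV_rep<k>` and `input_rep<k>` (or
#'   `bound_rep<k>`) columns.
#' @param uv_fraction Fraction compared against noUV, default `"input"`
#'   falling back to `"bound"`.
#' @return The table with a logical `background` column.
#' @export
filter_uv_specific <- function(table, uv_fraction = NULL) {
  if (is.null(uv_fraction)) {
    uv_fraction <- if (any(grepl("^input_rep", names(table)))) "input" else "bound"
  }
  if (!any(grepl("^noUV_rep", names(table)))) {
    table$background <- FALSE
    return(table)
  }
  table$.row <- seq_len(nrow(table))
  # raw (uncentered) comparison: centering would erase a global UV effect
  lr <- suppressWarnings(compute_log_ratios(table, pairing = c("noUV", uv_fraction),
                                            normalize = FALSE))
  bg <- rep(FALSE, nrow(table))
  # noUV-enriched or noUV-only peptides are crosslinking-independent
  bg[lr$.row] <- (is.finite(lr$log_ratio) & lr$log_ratio > 0) | lr$one_sided
  table$.row <- NULL
  table$background <- bg
  table
}

#' Pearson correlation between paired replicate ratio vectors
#'
#' @param x,y Numeric vectors of per-peptide ratios for the two members of
#'   the pair (replicate vs replicate, or protease vs protease).
#' @return Pearson r over entries finite in both vectors.
#' @export
replicate_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3L) stop("need >= 3 shared finite pairs")
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
    stop("undefined correlation: zero variance")
  stats::cor(x[ok], y[ok])
}
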