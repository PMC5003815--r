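# Composition, feature and annotation enrichment statistics for bound vs
# released fragment sets.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

aa_counts <- function(residues) {
  if (length(residues) == 1L && nchar(residues[1]) > 1L)
    residues <- strsplit(residues, "")[[1]]
  residues <- toupper(residues)
  table(factor(residues[residues %in% AA20], levels = AA20))
}

#' Amino-acid enrichment of bound over released fragments
#'
#' Per amino acid, the odds of that residue in the bound multiset versus
#' the released multiset, with a two-sided Fisher exact test per residue
#' and Benjamini-Hochberg correction across the 20 tests. Stars mark 10%
#' (`*`) and 1% (`**`) FDR.
#'
#' @param bound,released Character vectors of residues, or single strings
#'   (concatenated fragment sequences).
#' @return data.frame `aa`, `count_bound`, `count_released`, `odds_ratio`,
#'   `log2_odds`, `p`, `fdr`, `stars`.
#' @export
aa_enrichment <- function(bound, released) {
  cb <- aa_counts(bound); cr <- aa_counts(released)
  if (sum(cb) == 0L || sum(cr) == 0L) stop("empty residue multiset")
  tb <- sum(cb); tr <- sum(cr)
  rows <- lapply(AA20, function(a) {
    x <- cb[[a]]; y <- cr[[a]]
    or <- odds_ratio_2x2(x, tb - x, y, tr - y)
    p <- stats::fisher.test(matrix(c(x, tb - x, y, tr - y), 2))$p.value
    data.frame(aa = a, count_bound = x, count_released = y,
               odds_ratio = or, log2_odds = log2(or), p = p)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p, "BH")
  out$stars <- ifelse(out$fdr <= 0.01, "**", ifelse(out$fdr <= 0.10, "*", ""))
  out
}

#' Amino-acid enrichment of RNA-proximal protein surface
#'
#' Partitions structure-resolved residues by their minimum heavy-atom
#' distance to RNA at the contact cutoff, then compares proximal against
#' distant residue composition as in [aa_enrichment()].
#'
#' @param complexes List of `structure_complex` objects (each needs an RNA
#'   chain).
#' @param cutoff Contact cutoff in Angstrom (default 4.3).
#' @return As [aa_enrichment()] (bound = proximal, released = distant).
#' @export
surface_aa_enrichment <- function(complexes, cutoff = 4.3) {
  if (length(complexes) == 0L) stop("no complexes supplied")
  aa3to1 <- stats::setNames(bio3d::aa.table$aa1, bio3d::aa.table$aa3)
  prox <- character(0); dist <- character(0)
  for (cx in complexes) {
    at <- cx$atoms
    pres <- unique(at[at$type == "protein", c("chain", "resno", "resid")])
    for (i in seq_len(nrow(pres))) {
      a1 <- aa3to1[[toupper(pres$resid[i])]]
      if (is.null(a1) || is.na(a1) || !(a1 %in% AA20)) next
      d <- min_distance_to_rna(cx, pres$chain[i], pres$resno[i])
      if (d <= cutoff) prox <- c(prox, a1) else dist <- c(dist, a1)
    }
  }
  if (length(prox) == 0L) stop("insufficient data: no RNA-proximal residues")
  if (length(dist) == 0L) stop("insufficient data: no distant residues")
  aa_enrichment(prox, dist)
}

interval_overlap_len <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2) + 1L)
}

#' Feature enrichment odds ratios (domains, PTMs, variants)
#'
#' For each feature of a category, forms the 2x2 table of annotation hits
#' versus the bound and released interval spaces. For region categories
#' (`domain`, `disorder`) the unit is the residue (overlap lengths weight
#' the table); for point categories (`PTM`, `mendelian_variant`,
#' `natural_variant`) the unit is the annotation event (a site either falls
#' in a bound interval, a released interval, or neither).
#'
#' @param annotations data.frame `protein_id`, `category`, `name`, `start`,
#'   `end`.
#' @param bound_intervals,released_intervals data.frames `protein_id`,
#'   `start`, `end`.
#' @param category Category to test.
#' @return data.frame `name`, `bound_hit`, `bound_miss`, `released_hit`,
#'   `released_miss`, `odds_ratio`, `ci_low`, `ci_high`, `p`, `fdr`.
#' @export
feature_odds_ratio <- function(annotations, bound_intervals,
                               released_intervals, category) {
  ann <- annotations[annotations$category == category, , drop = FALSE]
  if (nrow(ann) == 0L) stop("category absent from annotation table: ", category)
  residue_unit <- category %in% c("domain", "disorder")
  space <- function(intervals) sum(intervals$end - intervals$start + 1L)
  hits_in <- function(feat, intervals) {
    tot <- 0L
    for (j in seq_len(nrow(feat))) {
      iv <- intervals[intervals$protein_id == feat$protein_id[j], , drop = FALSE]
      if (nrow(iv) == 0L) next
      ol <- interval_overlap_len(feat$start[j], feat$end[j], iv$start, iv$end)
      tot <- tot + if (residue_unit) sum(ol) else as.integer(any(ol > 0L))
    }
    tot
  }
  nb <- if (residue_unit) space(bound_intervals) else NA
  nr <- if (residue_unit) space(released_intervals) else NA
  rows <- lapply(split(ann, ann$name), function(feat) {
    bh <- hits_in(feat, bound_intervals)
    rh <- hits_in(feat, released_intervals)
    if (residue_unit) {
      bm <- nb - bh; rm <- nr - rh
    } else {
      n_ev <- nrow(feat)
      bm <- n_ev - bh; rm <- n_ev - rh
    }
    tab <- matrix(c(bh, bm, rh, rm), 2)
    ft <- stats::fisher.test(tab)
    data.frame(name = feat$name[1], bound_hit = bh, bound_miss = bm,
               released_hit = rh, released_miss = rm,
               odds_ratio = odds_ratio_2x2(bh, bm, rh, rm),
               ci_low = ft$conf.int[1], ci_high = ft$conf.int[2],
               p = ft$p.value)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p, "BH")
  rownames(out) <- NULL
  out[order(-out$odds_ratio), ]
}

#' Mendelian versus natural variant enrichment in bound fragments
#'
#' The 2x2 contrast (Mendelian, natural) x (bound, released): do
#' disease-linked substitutions fall into RNA-bound regions more often than
#' neutral polymorphisms do?
#'
#' @inheritParams feature_odds_ratio
#' @param per_protein Compute one table per protein and pool counts across
#'   proteins (default FALSE = pooled directly).
#' @return List `table`, `odds_ratio`, `p`.
#' @export
variant_contrast <- function(annotations, bound_intervals, released_intervals,
                             per_protein = FALSE) {
  count_in <- function(cat, intervals) {
    v <- annotations[annotations$category == cat, , drop = FALSE]
    if (nrow(v) == 0L) return(0L)
    sum(vapply(seq_len(nrow(v)), function(j) {
      iv <- intervals[intervals$protein_id == v$protein_id[j], , drop = FALSE]
      nrow(iv) > 0L &&
        any(interval_overlap_len(v$start[j], v$end[j], iv$start, iv$end) > 0L)
    }, logical(1)))
  }
  tab <- matrix(c(count_in("mendelian_variant", bound_intervals),
                  count_in("mendelian_variant", released_intervals),
                  count_in("natural_variant", bound_intervals),
                  count_in("natural_variant", released_intervals)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("mendelian", "natural"),
                                c("bound", "released")))
  list(table = tab,
       odds_ratio = odds_ratio_2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]),
       p = stats::fisher.test(tab)$p.value)
}

#' Partition binding sites by structural disorder
#'
#' A site is disordered when at least `threshold` of its residues fall in
#' disorder intervals (default 50%). Returns site-level counts and the
#' per-protein rollup (proteins whose sites are all globular, all
#' disordered, or mixed).
#'
#' @param sites data.frame `protein_id`, `start`, `end` (merged binding
#'   sites from [aggregate_sites()]).
#' @param disorder data.frame `protein_id`, `start`, `end` of disorder
#'   intervals.
#' @param threshold Disordered-residue fraction calling a site disordered
#'   (default 0.5).
#' @return List with `site_counts` (globular, disordered), `protein_counts`
#'   (globular_only, both, disordered_only), `sites` (input with a
#'   `disordered` flag and `disorder_fraction`).
#' @export
disorder_partition <- function(sites, disorder, threshold = 0.5) {
  if (nrow(sites) == 0L)
    return(list(site_counts = c(globular = 0L, disordered = 0L),
                protein_counts = c(globular_only = 0L, both = 0L,
                                   disordered_only = 0L),
                sites = sites))
  frac <- vapply(seq_len(nrow(sites)), function(i) {
    dv <- disorder[disorder$protein_id == sites$protein_id[i], , drop = FALSE]
    if (nrow(dv) == 0L) return(0)
    res <- sites$start[i]:sites$end[i]
    ind <- vapply(res, function(r) any(dv$start <= r & dv$end >= r), logical(1))
    mean(ind)
  }, numeric(1))
  missing_prot <- !(sites$protein_id %in% unique(disorder$protein_id))
  if (any(missing_prot))
    warning(sum(missing_prot),
            " site(s) on proteins without disorder annotation counted globular")
  sites$disorder_fraction <- frac
  sites$disordered <- frac >= threshold
  per_prot <- vapply(split(sites$disordered, sites$protein_id), function(d) {
    if (all(d)) "disordered_only" else if (any(d)) "both" else "globular_only"
  }, character(1))
  list(site_counts = c(globular = sum(!sites$disordered),
                       disordered = sum(sites$disordered)),
       protein_counts = c(globular_only = sum(per_prot == "globular_only"),
                          both = sum(per_prot == "both"),
                          disordered_only = sum(per_prot == "disordered_only")),
       sites = sites)
}

# Bjellqvist pKa set: side chains plus free termini
PKA_SIDE <- c(C = 9.00, D = 4.05, E = 4.45, H = 5.98, K = 10.00,
              R = 12.00, Y = 10.00)
PKA_NTERM <- 7.50
PKA_CTERM <- 3.55

peptide_net_charge <- function(counts, nc_term, pH) {
  pos <- nc_term * 10^(PKA_NTERM - pH) / (1 + 10^(PKA_NTERM - pH)) +
    sum(counts[c("K", "R", "H")] *
          10^(PKA_SIDE[c("K", "R", "H")] - pH) /
          (1 + 10^(PKA_SIDE[c("K", "R", "H")] - pH)))
  neg <- nc_term * 10^(pH - PKA_CTERM) / (1 + 10^(pH - PKA_CTERM)) +
    sum(counts[c("D", "E", "C", "Y")] *
          10^(pH - PKA_SIDE[c("D", "E", "C", "Y")]) /
          (1 + 10^(pH - PKA_SIDE[c("D", "E", "C", "Y")])))
  pos - neg
}

#' Isoelectric point of a peptide
#'
#' The pH of zero net charge under the Henderson-Hasselbalch equation with
#' the Bjellqvist pKa set (side chains of D, E, C, Y, H, K, R plus the free
#' N- and C-termini), solved by bisection on \[0, 14\].
#'
#' @param sequence Peptide string; nonstandard residues carry no charge.
#' @param tol Bisection tolerance in pH units (default 0.01).
#' @return pI in pH units.
#' @examples
#' isoelectric_point("KKKKKKKKKK") > isoelectric_point("DDDDDDDDDD")
#' @export
isoelectric_point <- function(sequence, tol = 0.01) {
  if (nchar(sequence) == 0L) stop("empty sequence")
  counts <- aa_counts(sequence)
  lo <- 0; hi <- 14
  # net charge is strictly decreasing in pH
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (peptide_net_charge(counts, 1, mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Group score comparison (means, SEMs, pairwise rank tests)
#'
#' Compares user-supplied per-item scores (mRNA abundance, conservation,
#' ...) across fragment groups: per-group mean and standard error, and a
#' two-sided Mann-Whitney test for every pair with Benjamini-Hochberg
#' correction.
#'
#' @param groups Named list of numeric score vectors (>= 2 groups, each
#'   >= 3 finite values).
#' @return List with `summary` (data.frame `group`, `n`, `mean`, `sem`)
#'   and `pairs` (data.frame `group1`, `group2`, `p`, `fdr`).
#' @export
group_score_compare <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  groups <- lapply(groups, function(x) x[is.finite(x)])
  if (any(lengths(groups) < 3L))
    stop("insufficient data: every group needs >= 3 scores")
  summ <- data.frame(group = names(groups), n = lengths(groups),
                     mean = vapply(groups, mean, numeric(1)),
                     sem = vapply(groups, function(x)
                       stats::sd(x) / sqrt(length(x)), numeric(1)),
                     row.names = NULL)
  cmb <- utils::combn(names(groups), 2)
  pairs <- data.frame(group1 = cmb[1, ], group2 = cmb[2, ],
                      p = apply(cmb, 2, function(g)
                        stats::wilcox.test(groups[[g[1]]], groups[[g[2]]],
                                           exact = FALSE)$p.value))
  pairs$fdr <- stats::p.adjust(pairs$p, "BH")
  list(summary = summ, pairs = pairs)
}

#' Position weight matrix of PTM sequence context
#'
#' Builds the 12-mer context (offsets -6..+5 around the modified residue)
#' position weight matrix for one modification, with a per-cell binomial
#' test against background amino-acid frequencies of the proteome and
#' Benjamini-Hochberg flags at the requested FDR.
#'
#' @param ptm_sites data.frame `protein_id`, `name`, `start` (modification
#'   position; `category == "PTM"` rows are used if a category column is
#'   present).
#' @param proteome Named character vector.
#' @param modification PTM name to select.
#' @param flag_fdr FDR level for cell flags (default 0.10).
#' @param pseudocount Column pseudocount (default 0.5).
#' @return Object of class `ptm_pwm`: list with `pwm` (20 x 12 probability
#'   matrix, columns sum to 1), `flags` (logical matrix, FDR <= flag_fdr),
#'   `fdr` (matrix), `n_sites`, `n_skipped`, `offsets`.
#' @export
ptm_context_pwm <- function(ptm_sites, proteome, modification,
                            flag_fdr = 0.10, pseudocount = 0.5) {
  if (!is.null(ptm_sites$category))
    ptm_sites <- ptm_sites[ptm_sites$category == "PTM", , drop = FALSE]
  ptm_sites <- ptm_sites[ptm_sites$name == modification, , drop = FALSE]
  offsets <- -6L:5L
  ctx <- character(0); skipped <- 0L
  for (i in seq_len(nrow(ptm_sites))) {
    seqs <- proteome[[ptm_sites$protein_id[i]]]
    if (is.null(seqs)) { skipped <- skipped + 1L; next }
    pos <- ptm_sites$start[i]
    lo <- pos + offsets[1]; hi <- pos + offsets[length(offsets)]
    if (lo < 1L || hi > nchar(seqs)) { skipped <- skipped + 1L; next }
    ctx <- c(ctx, substring(seqs, lo, hi))
  }
  if (length(ctx) < 5L)
    stop("insufficient data: need >= 5 sites with full 12-mer context, got ",
         length(ctx))
  m <- do.call(rbind, strsplit(ctx, ""))
  counts <- apply(m, 2, function(col) table(factor(col, levels = AA20)))
  pwm <- sweep(counts + pseudocount, 2, colSums(counts + pseudocount), "/")
  dimnames(pwm) <- list(AA20, paste0("p", offsets))
  # background frequencies from the whole proteome
  bgc <- aa_counts(paste(proteome, collapse = ""))
  bgf <- as.numeric(bgc) / sum(bgc)
  n <- nrow(m)
  pmat <- matrix(NA_real_, 20, length(offsets), dimnames = dimnames(pwm))
  for (j in seq_along(offsets)) for (k in seq_along(AA20)) {
    pmat[k, j] <- stats::binom.test(counts[k, j], n, bgf[k])$p.value
  }
  fdrm <- matrix(stats::p.adjust(pmat, "BH"), 20, length(offsets),
                 dimnames = dimnames(pwm))
  out <- list(pwm = pwm, flags = fdrm <= flag_fdr, fdr = fdrm,
              n_sites = n, n_skipped = skipped, offsets = offsets)
  class(out) <- "ptm_pwm"
  out
}

#' @export
print.ptm_pwm <- function(x, ...) {
  cat("PTM context PWM: offsets", min(x$offsets), "..", max(x$offsets),
      "around the modified residue\n")
  cat(" ", x$n_sites, "sites used,", x$n_skipped,
      "skipped (truncated window)\n")
  cat(" ", sum(x$flags), "cell(s) flagged at FDR\n")
  invisible(x)
}
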