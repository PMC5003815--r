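# End-to-end orchestration: quant -> mapping -> profiles -> structure ->
# enrichment, with a machine-readable run log.

#' Run configuration for the full workflow
#'
#' @param proteome Path to the proteome FASTA.
#' @param quant Path to the quant TSV (`protein_id`, `start`, `end` or
#'   `peptide_sequence`; `protease`; `<fraction>_rep<k>` intensity
#'   columns).
#' @param domains Path to the domain annotation TSV (optional).
#' @param structures Character vector of structure file paths (optional).
#' @param chain_map Path to the chain-map TSV (required with structures).
#' @param annotations Path to the annotation TSV (optional).
#' @param protease First-round protease (default `"LysC"`).
#' @param fdr_thresholds Ascending FDR thresholds (default
#'   `c(0.01, 0.10)`).
#' @param proximity_cutoff Contact cutoff in Angstrom (default 4.3).
#' @param bins_per_unit Profile bins per coordinate unit (default 50).
#' @param profile_families Families to profile (default: all in the domain
#'   table).
#' @param seed RNG seed recorded in the log (the pipeline itself is
#'   deterministic; default 1234).
#' @param out_dir Output directory.
#' @return List of class `run_config`.
#' @export
run_config <- function(proteome, quant, domains = NULL, structures = NULL,
                       chain_map = NULL, annotations = NULL,
                       protease = "LysC", fdr_thresholds = c(0.01, 0.10),
                       proximity_cutoff = 4.3, bins_per_unit = 50L,
                       profile_families = NULL, seed = 1234L, out_dir) {
  stopifnot(length(fdr_thresholds) == 2L,
            fdr_thresholds[1] <= fdr_thresholds[2],
            proximity_cutoff > 0)
  if (!is.null(structures) && is.null(chain_map))
    stop("structures require a chain_map")
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full workflow
#'
#' Stages run in order: peptide calling (ratios, mixture fit, FDR labels),
#' site mapping (RBDpep derivation, X-link inference, aggregation), domain
#' profiles, structure proximity, and annotation enrichment. Optional
#' stages are skipped when their inputs are absent; skipping never changes
#' upstream outputs. Each stage appends a structured entry (inputs, MD5
#' hashes, parameters, row counts) to `run_log.json`; a rerun on identical
#' inputs reproduces byte-identical outputs.
#'
#' @param config `run_config`.
#' @return Invisibly, a list of output paths and in-memory results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- list()
  stage <- function(name, inputs, params, n_rows) {
    hashes <- vapply(inputs, function(p)
      if (file.exists(p)) unname(tools::md5sum(p)) else NA_character_,
      character(1))
    # stage inputs living inside out_dir are logged relative to it, so a
    # rerun into a different directory stays byte-identical
    od <- paste0(normalizePath(config$out_dir), "/")
    shown <- vapply(inputs, function(p) {
      np <- normalizePath(p, mustWork = FALSE)
      if (startsWith(np, od)) substring(np, nchar(od) + 1L) else p
    }, character(1), USE.NAMES = FALSE)
    log[[name]] <<- list(inputs = as.list(stats::setNames(hashes, shown)),
                         params = params, rows = n_rows)
  }
  outputs <- list()
  set.seed(config$seed)

  ## stage: quant -------------------------------------------------------
  proteome <- read_proteome(config$proteome)
  quant <- utils::read.delim(config$quant, stringsAsFactors = FALSE,
                             check.names = FALSE)
  if (!all(c("protein_id", "start", "end") %in% names(quant))) {
    if (!("peptide_sequence" %in% names(quant)))
      stop("stage quant: table needs protein_id/start/end or peptide_sequence")
    loc <- do.call(rbind, lapply(quant$peptide_sequence, function(p) {
      h <- locate_peptide(p, proteome)
      if (nrow(h) == 1L) h[, c("protein_id", "start", "end")]
      else data.frame(protein_id = NA_character_, start = NA_integer_,
                      end = NA_integer_)
    }))
    quant <- cbind(loc, quant)
    quant <- quant[!is.na(quant$protein_id), , drop = FALSE]
  }
  quant <- filter_uv_specific(quant)
  quant <- compute_log_ratios(quant)
  fit <- fit_two_component_mixture(
    quant$log_ratio[is.finite(quant$log_ratio) & !quant$background])
  called <- classify_peptides(quant, fit, config$fdr_thresholds)
  outputs$called <- write_tsv(called, file.path(config$out_dir, "called_peptides.tsv"))
  stage("quant", c(config$proteome, config$quant),
        list(protease = config$protease, fdr = config$fdr_thresholds,
             mixture = unclass(fit)[c("weight_null", "mean_null", "sd_null",
                                      "mean_bound", "sd_bound")]),
        nrow(called))

  ## stage: mapping -----------------------------------------------------
  hits <- called[called$class_label %in% c("RBDpep", "candidate_RBDpep"), ,
                 drop = FALSE]
  sites <- if (nrow(hits) > 0L)
    build_sites(hits, proteome, config$protease)
  else data.frame(protein_id = character(0), rbdpep_start = integer(0),
                  rbdpep_end = integer(0), nlink_start = integer(0),
                  nlink_end = integer(0), xlink_intervals = character(0),
                  protease = character(0), fdr = numeric(0),
                  class_label = character(0))
  agg <- aggregate_sites(sites)
  outputs$sites <- write_tsv(sites, file.path(config$out_dir, "rbdpep_sites.tsv"))
  outputs$merged_sites <- write_tsv(agg$sites,
                                    file.path(config$out_dir, "binding_sites.tsv"))
  stage("mapping", outputs$called, list(protease = config$protease),
        c(sites = nrow(sites), merged = agg$n_sites,
          proteins = agg$n_proteins))

  ## stage: profiles ----------------------------------------------------
  results <- list(fit = fit, called = called, sites = sites, aggregate = agg)
  if (!is.null(config$domains)) {
    domains <- utils::read.delim(config$domains, stringsAsFactors = FALSE)
    released <- called[called$class_label == "released", c("protein_id", "start", "end")]
    fams <- config$profile_families
    if (is.null(fams)) fams <- unique(domains$family)
    profs <- list()
    for (f in fams) {
      pr <- tryCatch(build_profile(f, sites, released, domains,
                                   config$bins_per_unit),
                     error = function(e) NULL)
      if (!is.null(pr)) profs[[f]] <- pr
    }
    if (length(profs) > 0L) {
      ptab <- do.call(rbind, lapply(profs, function(p)
        cbind(family = p$family, p$table)))
      outputs$profiles <- write_tsv(ptab, file.path(config$out_dir, "profiles.tsv"))
    }
    results$profiles <- profs
    stage("profiles", c(config$domains),
          list(bins_per_unit = config$bins_per_unit, families = fams),
          length(profs))
  }

  ## stage: structure proximity -----------------------------------------
  if (!is.null(config$structures) && length(config$structures) > 0L) {
    complexes <- lapply(config$structures, read_structure)
    cm <- read_chain_map(config$chain_map)
    rb <- sites[sites$class_label == "RBDpep",
                c("protein_id", "rbdpep_start", "rbdpep_end")]
    names(rb) <- c("protein_id", "start", "end")
    allf <- digest_proteome(proteome, config$protease)
    prox <- proximity_enrichment(rb, allf, complexes, cm,
                                 config$proximity_cutoff)
    jsonlite::write_json(prox[c("rbdpep_proximal_fraction",
                                "baseline_proximal_fraction",
                                "odds_ratio", "p_value")],
                         file.path(config$out_dir, "proximity.json"),
                         auto_unbox = TRUE, digits = NA)
    outputs$proximity <- file.path(config$out_dir, "proximity.json")
    results$proximity <- prox
    stage("structure", c(config$structures, config$chain_map),
          list(cutoff = config$proximity_cutoff), sum(prox$table))
  }

  ## stage: enrichment --------------------------------------------------
  bound_iv <- sites[, c("protein_id", "rbdpep_start", "rbdpep_end")]
  names(bound_iv) <- c("protein_id", "start", "end")
  released_iv <- called[called$class_label == "released",
                        c("protein_id", "start", "end")]
  if (nrow(bound_iv) > 0L && nrow(released_iv) > 0L) {
    bseq <- substring(proteome[bound_iv$protein_id], bound_iv$start, bound_iv$end)
    rseq <- substring(proteome[released_iv$protein_id], released_iv$start,
                      released_iv$end)
    aa <- aa_enrichment(paste(bseq, collapse = ""), paste(rseq, collapse = ""))
    outputs$aa_enrichment <- write_tsv(aa, file.path(config$out_dir,
                                                     "aa_enrichment.tsv"))
    results$aa_enrichment <- aa
    pI <- data.frame(set = c("bound", "released"),
                     mean_pI = c(mean(vapply(bseq, isoelectric_point, numeric(1))),
                                 mean(vapply(rseq, isoelectric_point, numeric(1)))))
    outputs$pI <- write_tsv(pI, file.path(config$out_dir, "isoelectric.tsv"))
    results$pI <- pI
    if (!is.null(config$annotations)) {
      ann <- utils::read.delim(config$annotations, stringsAsFactors = FALSE)
      enr <- list()
      for (cat in intersect(unique(ann$category),
                            c("domain", "PTM", "mendelian_variant"))) {
        enr[[cat]] <- feature_odds_ratio(ann, bound_iv, released_iv, cat)
      }
      if ("disorder" %in% ann$category) {
        dis <- ann[ann$category == "disorder", ]
        results$disorder <- disorder_partition(agg$sites, dis)
      }
      if (length(enr) > 0L) {
        etab <- do.call(rbind, lapply(names(enr), function(nm)
          cbind(category = nm, enr[[nm]])))
        outputs$enrichment <- write_tsv(etab,
                                        file.path(config$out_dir, "enrichment.tsv"))
      }
      results$feature_enrichment <- enr
    }
    stage("enrichment", c(config$annotations),
          list(), nrow(bound_iv))
  }

  jsonlite::write_json(log, file.path(config$out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  outputs$run_log <- file.path(config$out_dir, "run_log.json")
  invisible(c(outputs, list(results = results)))
}
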