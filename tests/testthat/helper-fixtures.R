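# Shared simulated-input fixtures for pipeline-level tests.

write_sim_inputs <- function(dir, seed = 314L, n_proteins = 120L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- sim_config(n_proteins = n_proteins, seed = seed)
  sim <- simulate_proteome(cfg)
  exp <- simulate_experiment(sim, cfg)
  write_proteome(sim$proteome, file.path(dir, "proteome.fasta"))
  utils::write.table(sim$domains, file.path(dir, "domains.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ann <- simulate_annotations(sim$proteome, seed = seed)
  utils::write.table(ann, file.path(dir, "annotations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(exp$quant[, !(names(exp$quant) %in%
                                     c("true_bound", "true_log_ratio"))],
                     file.path(dir, "quant.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  # toy structures for the first three truth proteins, contacts planted
  cm <- NULL
  for (i in seq_len(min(3L, nrow(sim$truth)))) {
    pid <- sim$truth$protein_id[i]
    n <- nchar(sim$proteome[[pid]])
    simulate_complex(n, c(sim$truth$contact_start[i], sim$truth$contact_end[i]),
                     file.path(dir, sprintf("complex%d.pdb", i)),
                     seed = seed + i)
    cm <- rbind(cm, data.frame(structure_id = sprintf("complex%d", i),
                               chain = "A", struct_start = 1L,
                               struct_end = n, protein_id = pid,
                               offset = 0L))
  }
  utils::write.table(cm, file.path(dir, "chain_map.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

pipeline_cfg <- function(dir, out, with_structures = TRUE) {
  run_config(
    proteome = file.path(dir, "proteome.fasta"),
    quant = file.path(dir, "quant.tsv"),
    domains = file.path(dir, "domains.tsv"),
    annotations = file.path(dir, "annotations.tsv"),
    structures = if (with_structures)
      file.path(dir, sprintf("complex%d.pdb", 1:3)),
    chain_map = if (with_structures) file.path(dir, "chain_map.tsv"),
    out_dir = out)
}
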