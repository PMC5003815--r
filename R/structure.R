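# Structure-based validation: per-residue minimum heavy-atom distance to
# RNA and proximity classification at the 4.3 Angstrom contact cutoff.

RNA_RESIDUES <- c("A", "C", "G", "U",
                  # modified-ribonucleotide synonyms commonly seen in PDB
                  "1MA", "2MG", "5MC", "5MU", "7MG", "H2U", "M2G", "OMC",
                  "OMG", "PSU", "I", "UR3", "A23", "4SU")

#' Read a protein-RNA co-structure
#'
#' Parses a PDB or mmCIF file (by extension), keeps heavy atoms of model 1
#' with the highest-occupancy alternate conformer, drops waters and
#' non-RNA heteroatoms, and partitions chains into protein and RNA by
#' residue naming.
#'
#' @param path PDB (`.pdb`/`.ent`) or mmCIF (`.cif`) file.
#' @param structure_id Identifier; defaults to the file base name.
#' @return Object of class `structure_complex`: list with `structure_id`,
#'   `atoms` (data.frame `chain`, `resno`, `resid`, `elety`, `x`, `y`, `z`,
#'   `type` in {protein, rna}), `protein_chains`, `rna_chains`.
#' @export
read_structure <- function(path, structure_id = NULL) {
  if (is.null(structure_id))
    structure_id <- sub("\\.[^.]*$", "", basename(path))
  ext <- tolower(sub("^.*\\.", "", path))
  pdb <- if (ext == "cif") bio3d::read.cif(path, verbose = FALSE)
         else bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  # heavy atoms only; hydrogens carry element H or names starting H/D
  elesym <- if (!is.null(at$elesy)) toupper(trimws(at$elesy)) else ""
  is_h <- elesym %in% c("H", "D") |
    (elesym == "" & grepl("^[HD]", toupper(trimws(at$elety))))
  at <- at[!is_h & at$resid != "HOH", , drop = FALSE]
  # altloc: keep the highest-occupancy conformer per atom
  if (any(at$alt != "" & !is.na(at$alt))) {
    key <- paste(at$chain, at$resno, at$elety)
    occ <- if (!is.null(at$o)) ifelse(is.na(at$o), 1, at$o) else 1
    ord <- order(key, -occ)
    at <- at[ord, ][!duplicated(key[ord]), , drop = FALSE]
  }
  resid <- toupper(trimws(at$resid))
  std_aa <- bio3d::aa.table$aa3
  type <- ifelse(resid %in% RNA_RESIDUES, "rna",
                 ifelse(resid %in% std_aa | at$type == "ATOM", "protein", NA))
  at$type <- type
  at <- at[!is.na(at$type), c("chain", "resno", "resid", "elety",
                              "x", "y", "z", "type")]
  if (!all(is.finite(c(at$x, at$y, at$z)))) stop("non-finite coordinates")
  # a chain is RNA if its residues are nucleotides
  chain_type <- vapply(split(at$type, at$chain),
                       function(t) names(sort(table(t), decreasing = TRUE))[1],
                       character(1))
  obj <- list(structure_id = structure_id, atoms = at,
              protein_chains = names(chain_type)[chain_type == "protein"],
              rna_chains = names(chain_type)[chain_type == "rna"])
  if (length(obj$protein_chains) == 0L) stop("no protein chain in ", path)
  class(obj) <- "structure_complex"
  obj
}

#' @export
print.structure_complex <- function(x, ...) {
  cat("structure_complex", x$structure_id, "-",
      nrow(x$atoms), "heavy atoms;",
      "protein chains:", paste(x$protein_chains, collapse = ","),
      "| RNA chains:",
      if (length(x$rna_chains)) paste(x$rna_chains, collapse = ",") else "none",
      "\n")
  invisible(x)
}

rna_coords <- function(complex) {
  at <- complex$atoms
  as.matrix(at[at$type == "rna" & at$chain %in% complex$rna_chains,
               c("x", "y", "z")])
}

#' Minimum heavy-atom distance from a protein residue to RNA
#'
#' Brute-force minimum Euclidean distance over all pairs of the residue's
#' heavy atoms and all RNA heavy atoms of the complex.
#'
#' @param complex `structure_complex`.
#' @param chain Protein chain id.
#' @param residue Residue number within the chain (structure numbering).
#' @return Distance in Angstrom.
#' @export
min_distance_to_rna <- function(complex, chain, residue) {
  rna <- rna_coords(complex)
  if (nrow(rna) == 0L) stop("no RNA chain in structure ", complex$structure_id)
  at <- complex$atoms
  res <- at[at$chain == chain & at$resno == residue & at$type == "protein", ]
  if (nrow(res) == 0L)
    stop("residue ", residue, " not found in chain ", chain)
  p <- as.matrix(res[, c("x", "y", "z")])
  # all-pairs distance, minimized
  d2 <- outer(rowSums(p^2), rowSums(rna^2), "+") - 2 * p %*% t(rna)
  sqrt(max(min(d2), 0))
}

#' Map a proteome fragment into structure residues via a chain map
#'
#' @param fragment List/row with `protein_id`, `start`, `end` (proteome
#'   coordinates).
#' @param chain_map data.frame `structure_id`, `chain`, `struct_start`,
#'   `struct_end`, `protein_id`, `offset` where
#'   `proteome position = structure residue number + offset`.
#' @param structure_id Restrict to one structure (optional).
#' @return data.frame `structure_id`, `chain`, `resno` of the structure
#'   residues covered by the fragment (possibly 0 rows).
#' @export
map_fragment_to_structure <- function(fragment, chain_map, structure_id = NULL) {
  cm <- chain_map[chain_map$protein_id == fragment$protein_id, , drop = FALSE]
  if (!is.null(structure_id))
    cm <- cm[cm$structure_id == structure_id, , drop = FALSE]
  out <- lapply(seq_len(nrow(cm)), function(i) {
    lo <- max(fragment$start - cm$offset[i], cm$struct_start[i])
    hi <- min(fragment$end - cm$offset[i], cm$struct_end[i])
    if (lo > hi) return(NULL)
    data.frame(structure_id = cm$structure_id[i], chain = cm$chain[i],
               resno = lo:hi)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) data.frame(structure_id = character(0),
                               chain = character(0), resno = integer(0))
  else out
}

#' Classify a proteolytic fragment as RNA-proximal
#'
#' A fragment is proximal when any of its structure-resolved residues has
#' a minimum heavy-atom distance to RNA of at most `cutoff` (inclusive);
#' non-proximal when all resolved residues are farther; unresolved when no
#' residue maps into the structure.
#'
#' @param fragment List/row with `protein_id`, `start`, `end`.
#' @param complex `structure_complex`.
#' @param chain_map Chain-to-protein mapping table (see
#'   [map_fragment_to_structure()]).
#' @param cutoff Contact distance in Angstrom (default 4.3).
#' @return `"proximal"`, `"non_proximal"`, or `"unresolved"`.
#' @export
classify_fragment_proximal <- function(fragment, complex, chain_map,
                                       cutoff = 4.3) {
  res <- map_fragment_to_structure(fragment, chain_map, complex$structure_id)
  if (nrow(res) == 0L) return("unresolved")
  at <- complex$atoms
  resolved <- vapply(seq_len(nrow(res)), function(i)
    any(at$chain == res$chain[i] & at$resno == res$resno[i] &
          at$type == "protein"), logical(1))
  if (!any(resolved)) return("unresolved")
  res <- res[resolved, , drop = FALSE]
  d <- vapply(seq_len(nrow(res)), function(i)
    min_distance_to_rna(complex, res$chain[i], res$resno[i]), numeric(1))
  # inclusive boundary, guarded against floating-point ulp at the cutoff
  if (min(d) <= cutoff + 1e-9) "proximal" else "non_proximal"
}

#' Proximity enrichment of called binding peptides over all fragments
#'
#' Compares the proximal fraction among RBDpeps with the baseline proximal
#' fraction of the full fragment superset of the same structures, via a
#' 2x2 table, odds ratio (Haldane-corrected when a cell is zero) and
#' two-sided Fisher exact test.
#'
#' @param rbdpep_fragments,all_fragments Fragment data.frames
#'   (`protein_id`, `start`, `end`).
#' @param complexes List of `structure_complex` objects.
#' @param chain_map Mapping table.
#' @param cutoff Contact cutoff in Angstrom (default 4.3).
#' @return List with `table` (2x2), `rbdpep_proximal_fraction`,
#'   `baseline_proximal_fraction`, `odds_ratio`, `p_value`,
#'   `n_unresolved`.
#' @export
proximity_enrichment <- function(rbdpep_fragments, all_fragments, complexes,
                                 chain_map, cutoff = 4.3) {
  classify_set <- function(frags) {
    vapply(seq_len(nrow(frags)), function(i) {
      cls <- vapply(complexes, function(cx)
        classify_fragment_proximal(frags[i, ], cx, chain_map, cutoff),
        character(1))
      if (any(cls == "proximal")) "proximal"
      else if (any(cls == "non_proximal")) "non_proximal"
      else "unresolved"
    }, character(1))
  }
  a <- classify_set(rbdpep_fragments)
  b <- classify_set(all_fragments)
  n_unres <- sum(a == "unresolved") + sum(b == "unresolved")
  a <- a[a != "unresolved"]; b <- b[b != "unresolved"]
  if (length(a) == 0L || length(b) == 0L)
    stop("insufficient data: a fragment set is empty after unresolved exclusion")
  tab <- matrix(c(sum(a == "proximal"), sum(a == "non_proximal"),
                  sum(b == "proximal"), sum(b == "non_proximal")),
                nrow = 2, dimnames = list(c("proximal", "non_proximal"),
                                          c("RBDpep", "all")))
  list(table = tab,
       rbdpep_proximal_fraction = tab[1, 1] / sum(tab[, 1]),
       baseline_proximal_fraction = tab[1, 2] / sum(tab[, 2]),
       odds_ratio = odds_ratio_2x2(tab[1, 1], tab[2, 1], tab[1, 2], tab[2, 2]),
       p_value = stats::fisher.test(tab)$p.value,
       n_unresolved = n_unres)
}

# ad/bc odds ratio with Haldane-Anscombe 0.5 correction when any cell is 0
odds_ratio_2x2 <- function(a, b, c, d) {
  if (min(a, b, c, d) == 0) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
  (a * d) / (b * c)
}

#' Read a chain-to-protein mapping table
#' @param path TSV with columns structure_id, chain, struct_start,
#'   struct_end, protein_id, offset.
#' @return data.frame.
#' @export
read_chain_map <- function(path) {
  cm <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("structure_id", "chain", "struct_start", "struct_end",
            "protein_id", "offset")
  if (!all(need %in% names(cm))) stop("chain map missing columns: ",
                                      paste(setdiff(need, names(cm)), collapse = ", "))
  cm
}
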