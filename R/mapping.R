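# Anchoring MS-identified peptides on the proteome, extending them to
# LysC/ArgC cleavage boundaries (RBDpeps), and inferring the crosslinked
# (X-link) moiety by subtracting the MS-identified (N-link) part.

#' Locate a peptide sequence on a proteome
#'
#' Exact substring search of an MS-identified peptide against every protein.
#' Isoleucine and leucine are kept distinct (peptides and proteome come from
#' the same sequence build). Peptides shorter than `min_length` are rejected
#' to guard against spurious matches.
#'
#' @param peptide_sequence Peptide string.
#' @param proteome Named character vector of protein sequences.
#' @param min_length Minimum peptide length accepted (default 5).
#' @return data.frame of matches: `protein_id`, `start`, `end`, `ambiguous`
#'   (TRUE on every row when matches hit more than one distinct protein).
#'   Zero rows when the peptide is absent.
#' @export
locate_peptide <- function(peptide_sequence, proteome, min_length = 5L) {
  empty <- data.frame(protein_id = character(0), start = integer(0),
                      end = integer(0), ambiguous = logical(0))
  if (nchar(peptide_sequence) < min_length) {
    warning("peptide shorter than ", min_length, " residues rejected: ",
            peptide_sequence)
    return(empty)
  }
  hits <- lapply(names(proteome), function(id) {
    m <- gregexpr(peptide_sequence, proteome[[id]], fixed = TRUE)[[1]]
    if (m[1] == -1L) return(NULL)
    data.frame(protein_id = id, start = as.integer(m),
               end = as.integer(m) + nchar(peptide_sequence) - 1L)
  })
  hits <- do.call(rbind, hits)
  if (is.null(hits)) return(empty)
  hits$ambiguous <- length(unique(hits$protein_id)) > 1L
  hits
}

#' Derive the RBDpep interval from an MS-identified peptide
#'
#' Extends the N-link interval to the two nearest cleavage boundaries of the
#' first-round protease: the smallest interval \[a, b\] containing the
#' peptide such that a-1 is a cleavage site (or a = 1) and b is a cleavage
#' site (or the protein end). The result is always a proteolytic fragment
#' of the protein with >= 0 missed cleavages.
#'
#' @param nlink Integer pair `c(start, end)`, 1-based closed.
#' @param sequence Protein amino-acid string.
#' @param protease `"LysC"` or `"ArgC"`.
#' @return Integer pair `c(start, end)` of the RBDpep.
#' @examples
#' derive_rbdpep(c(12, 18), paste(c(rep("A", 9), "K", rep("A", 9), "K",
#'   rep("A", 5)), collapse = ""), "LysC")
#' @export
derive_rbdpep <- function(nlink, sequence, protease) {
  n <- nchar(sequence)
  stopifnot(length(nlink) == 2L)
  if (nlink[1] < 1L || nlink[2] > n || nlink[1] > nlink[2])
    stop("nlink interval out of protein bounds")
  sites <- cleavage_sites(sequence, protease)
  left <- sites[sites < nlink[1]]
  right <- sites[sites >= nlink[2]]
  a <- if (length(left)) max(left) + 1L else 1L
  b <- if (length(right)) min(right) else n
  c(start = a, end = b)
}

#' Infer the X-link moiety of an RBDpep
#'
#' The residues of the RBDpep not covered by the MS-identified N-link
#' peptide: the inferred location of the covalent protein-RNA crosslink,
#' returned as 0, 1 or 2 maximal closed intervals.
#'
#' @param rbdpep Integer pair `c(start, end)`.
#' @param nlink Integer pair `c(start, end)`; must lie within `rbdpep`.
#' @return data.frame with columns `start`, `end` (0-2 rows).
#' @export
infer_xlink <- function(rbdpep, nlink) {
  if (nlink[1] < rbdpep[1] || nlink[2] > rbdpep[2])
    stop("inconsistent site: nlink not contained in rbdpep")
  out <- data.frame(start = integer(0), end = integer(0))
  if (nlink[1] > rbdpep[1])
    out <- rbind(out, data.frame(start = rbdpep[1], end = nlink[1] - 1L))
  if (nlink[2] < rbdpep[2])
    out <- rbind(out, data.frame(start = nlink[2] + 1L, end = rbdpep[2]))
  out
}

#' Build RBDpep site records for called peptides
#'
#' For each called peptide (with proteome coordinates), derives the RBDpep
#' boundary, the X-link intervals, and carries the quant labels through.
#'
#' @param called Data.frame with `protein_id`, `start`, `end`, `fdr`,
#'   `class_label` (from [classify_peptides()] after location).
#' @param proteome Named character vector.
#' @param protease `"LysC"` or `"ArgC"`.
#' @return data.frame with columns `protein_id`, `rbdpep_start`,
#'   `rbdpep_end`, `nlink_start`, `nlink_end`, `xlink_intervals`
#'   (semicolon-separated `a-b`, empty string when N-link covers the whole
#'   RBDpep), `protease`, `fdr`, `class_label`.
#' @export
build_sites <- function(called, proteome, protease) {
  rows <- lapply(seq_len(nrow(called)), function(i) {
    id <- called$protein_id[i]
    seqs <- proteome[[id]]
    if (is.null(seqs)) stop("protein not in proteome: ", id)
    rb <- derive_rbdpep(c(called$start[i], called$end[i]), seqs, protease)
    xl <- infer_xlink(rb, c(called$start[i], called$end[i]))
    data.frame(protein_id = id,
               rbdpep_start = rb[1], rbdpep_end = rb[2],
               nlink_start = called$start[i], nlink_end = called$end[i],
               xlink_intervals = paste(sprintf("%d-%d", xl$start, xl$end),
                                       collapse = ";"),
               protease = protease,
               fdr = if (!is.null(called$fdr)) called$fdr[i] else NA_real_,
               class_label = if (!is.null(called$class_label))
                 called$class_label[i] else NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Parse `a-b;c-d` interval strings into a data.frame
#' @param s Character vector of semicolon-separated interval strings.
#' @return data.frame `start`, `end`, `row` (index into `s`).
#' @export
parse_intervals <- function(s) {
  out <- lapply(seq_along(s), function(i) {
    if (is.na(s[i]) || s[i] == "") return(NULL)
    parts <- strsplit(strsplit(s[i], ";")[[1]], "-")
    data.frame(start = as.integer(vapply(parts, `[`, "", 1L)),
               end = as.integer(vapply(parts, `[`, "", 2L)), row = i)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) data.frame(start = integer(0), end = integer(0),
                               row = integer(0)) else out
}

#' Merge RBDpeps into binding sites
#'
#' Overlapping or bookended (adjacent) RBDpep intervals on the same protein
#' merge into one binding site; by default merging pools both proteases.
#'
#' @param sites RBDpep site table (see [build_sites()]).
#' @param merge_proteases Pool LysC and ArgC sites before merging
#'   (default TRUE).
#' @param labels Class labels to keep (default `"RBDpep"`); use
#'   `c("RBDpep", "candidate_RBDpep")` for the 10% FDR set.
#' @return List with `sites` (data.frame `protein_id`, `start`, `end`,
#'   `n_peptides`, and `protease` when not pooling), `n_sites`,
#'   `n_proteins`.
#' @export
aggregate_sites <- function(sites, merge_proteases = TRUE,
                            labels = "RBDpep") {
  if (!is.null(sites$class_label)) sites <- sites[sites$class_label %in% labels, ]
  if (nrow(sites) == 0L)
    return(list(sites = data.frame(protein_id = character(0),
                                   start = integer(0), end = integer(0),
                                   n_peptides = integer(0)),
                n_sites = 0L, n_proteins = 0L))
  key <- if (merge_proteases) sites$protein_id
         else paste(sites$protein_id, sites$protease, sep = "\r")
  merged <- lapply(split(sites, key), function(g) {
    ord <- order(g$rbdpep_start, g$rbdpep_end)
    st <- g$rbdpep_start[ord]; en <- g$rbdpep_end[ord]
    ms <- st[1]; me <- en[1]; out <- NULL; np <- 1L
    for (i in seq_along(st)[-1]) {
      if (st[i] <= me + 1L) { me <- max(me, en[i]); np <- np + 1L }
      else {
        out <- rbind(out, data.frame(protein_id = g$protein_id[1],
                                     start = ms, end = me, n_peptides = np))
        ms <- st[i]; me <- en[i]; np <- 1L
      }
    }
    out <- rbind(out, data.frame(protein_id = g$protein_id[1],
                                 start = ms, end = me, n_peptides = np))
    if (!merge_proteases) out$protease <- g$protease[1]
    out
  })
  merged <- do.call(rbind, merged)
  merged <- merged[order(merged$protein_id, merged$start), , drop = FALSE]
  rownames(merged) <- NULL
  list(sites = merged, n_sites = nrow(merged),
       n_proteins = length(unique(merged$protein_id)))
}
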