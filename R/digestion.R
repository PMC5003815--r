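# Protease specificities. LysC cuts C-terminal of K (including K-P bonds);
# ArgC cuts C-terminal of R; trypsin cuts C-terminal of K or R unless the
# next residue is P. Nonstandard residues (X, U, B, Z, ...) are never
# cleavage sites.
PROTEASES <- c("LysC", "ArgC", "trypsin")

match_protease <- function(protease) {
  if (length(protease) != 1L || !is.character(protease))
    stop("protease must be a single string")
  hit <- match(tolower(protease), tolower(PROTEASES))
  if (is.na(hit)) stop("unknown protease: ", protease)
  PROTEASES[hit]
}

#' Internal cleavage-site positions of a sequence
#'
#' Positions i such that the peptide bond between residues i and i+1 is cut
#' by the protease. The last residue is never a site (there is no bond after
#' it), so sites are in 1..(n-1).
#'
#' @param sequence Amino-acid string.
#' @param protease One of `"LysC"`, `"ArgC"`, `"trypsin"` (case-insensitive).
#' @return Integer vector of 1-based residue positions after which cleavage
#'   occurs, possibly empty.
#' @export
cleavage_sites <- function(sequence, protease) {
  protease <- match_protease(protease)
  aa <- strsplit(toupper(sequence), "")[[1]]
  n <- length(aa)
  if (n == 0L) stop("empty sequence")
  if (n == 1L) return(integer(0))
  idx <- seq_len(n - 1L)
  sites <- switch(protease,
    LysC    = idx[aa[idx] == "K"],
    ArgC    = idx[aa[idx] == "R"],
    trypsin = idx[aa[idx] %in% c("K", "R") & aa[idx + 1L] != "P"]
  )
  as.integer(sites)
}

#' In silico proteolytic digestion
#'
#' Enumerates all proteolytic fragments of a protein with up to `max_missed`
#' missed cleavages. Zero-missed fragments tile the sequence exactly; a
#' k-missed fragment is the concatenation of k+1 adjacent zero-missed
#' fragments.
#'
#' @param sequence Amino-acid string, or a named list/character giving the
#'   protein sequence (a single element).
#' @param protease `"LysC"`, `"ArgC"` or `"trypsin"`.
#' @param max_missed Maximum number of missed cleavages (default 0).
#' @param protein_id Identifier recorded in the output (default `"protein"`).
#' @return data.frame with columns `protein_id`, `start`, `end`, `sequence`,
#'   `protease`, `missed_cleavages`, ordered by (start, end). Coordinates are
#'   1-based closed intervals.
#' @examples
#' digest("ACKDEFKGH", "LysC", max_missed = 1)
#' @export
digest <- function(sequence, protease, max_missed = 0L, protein_id = "protein") {
  if (length(sequence) != 1L || !is.character(sequence) || nchar(sequence) == 0L)
    stop("sequence must be a non-empty string")
  protease <- match_protease(protease)
  if (max_missed < 0L) stop("max_missed must be >= 0")
  n <- nchar(sequence)
  sites <- cleavage_sites(sequence, protease)
  # boundaries of the zero-missed tiling: [b_i + 1, b_{i+1}]
  bounds <- c(0L, sites, n)
  n0 <- length(bounds) - 1L
  starts <- integer(0); ends <- integer(0); mc <- integer(0)
  for (k in 0:max_missed) {
    m <- n0 - k
    if (m <= 0L) break
    i <- seq_len(m)
    starts <- c(starts, bounds[i] + 1L)
    ends <- c(ends, bounds[i + k + 1L])
    mc <- c(mc, rep.int(k, m))
  }
  ord <- order(starts, ends)
  data.frame(
    protein_id = protein_id,
    start = starts[ord], end = ends[ord],
    sequence = substring(sequence, starts[ord], ends[ord]),
    protease = protease,
    missed_cleavages = mc[ord],
    stringsAsFactors = FALSE
  )
}

#' Digest every protein of a proteome
#'
#' @param proteome Named character vector of sequences (names are protein
#'   ids), as returned by [read_proteome()].
#' @inheritParams digest
#' @return Row-bound fragment table (see [digest()]).
#' @export
digest_proteome <- function(proteome, protease, max_missed = 0L) {
  if (length(proteome) == 0L)
    return(data.frame(protein_id = character(0), start = integer(0),
                      end = integer(0), sequence = character(0),
                      protease = character(0), missed_cleavages = integer(0)))
  stopifnot(!is.null(names(proteome)))
  out <- lapply(names(proteome), function(id)
    digest(proteome[[id]], protease, max_missed, protein_id = id))
  do.call(rbind, out)
}

#' Fraction of peptides carrying at least one missed cleavage
#'
#' A peptide has a missed cleavage when an internal residue (any position
#' but the last) is a cleavage site of the protease.
#'
#' @param peptides Character vector of peptide sequences, or a fragment
#'   data.frame with a `sequence` column.
#' @param protease Protease name.
#' @return Fraction in \[0, 1\].
#' @export
missed_cleavage_rate <- function(peptides, protease) {
  if (is.data.frame(peptides)) peptides <- peptides$sequence
  if (length(peptides) == 0L) stop("empty peptide list")
  protease <- match_protease(protease)
  has_mc <- vapply(peptides, function(p) length(cleavage_sites(p, protease)) > 0L,
                   logical(1), USE.NAMES = FALSE)
  mean(has_mc)
}

#' Fragment length summary
#'
#' Mean, median, and integer-length histogram of proteolytic fragments;
#' the mean length of zero-missed LysC/ArgC fragments sets the spatial
#' resolution of the binding-region map (about 17 residues for human-like
#' lysine/arginine frequencies).
#'
#' @param fragments Fragment data.frame (needs `start` and `end`), or an
#'   integer vector of lengths.
#' @return List with `mean`, `median`, `n`, and `histogram` (a table keyed
#'   by residue count).
#' @export
fragment_length_summary <- function(fragments) {
  len <- if (is.data.frame(fragments)) fragments$end - fragments$start + 1L
         else as.integer(fragments)
  if (length(len) == 0L) stop("empty fragment list")
  list(mean = mean(len), median = stats::median(len), n = length(len),
       histogram = table(factor(len, levels = seq_len(max(len)))))
}

#' Read a proteome FASTA
#'
#' @param path FASTA file. The protein id is the first whitespace-delimited
#'   token of each header.
#' @return Named character vector of amino-acid sequences.
#' @export
read_proteome <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  seqs <- as.character(aa)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs))) stop("duplicate protein ids in ", path)
  seqs
}

#' Write a proteome FASTA
#' @param proteome Named character vector of sequences.
#' @param path Output file.
#' @export
write_proteome <- function(proteome, path) {
  x <- Biostrings::AAStringSet(unlist(proteome))
  names(x) <- names(proteome)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write a fragment table as TSV
#' @param fragments Fragment data.frame.
#' @param path Output file.
#' @export
write_fragments <- function(fragments, path) {
  utils::write.table(fragments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
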