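# Independent reference implementations used as oracles. These stay naive
# on purpose: scan-and-split digestion, dense grid scans, enumeration.

# naive digestion: walk the sequence, split after every cleavage residue,
# then join runs of adjacent pieces for missed cleavages
naive_digest <- function(sequence, protease, max_missed = 0L) {
  aa <- strsplit(sequence, "")[[1]]
  cut_after <- logical(length(aa))
  for (i in seq_along(aa)[-length(aa)]) {
    cut_after[i] <- switch(protease,
      LysC = aa[i] == "K",
      ArgC = aa[i] == "R",
      trypsin = aa[i] %in% c("K", "R") && aa[i + 1] != "P")
  }
  starts <- c(1L, which(cut_after) + 1L)
  ends <- c(which(cut_after), length(aa))
  out <- NULL
  for (k in 0:max_missed) {
    for (i in seq_along(starts)) {
      j <- i + k
      if (j > length(ends)) next
      out <- rbind(out, data.frame(start = starts[i], end = ends[j],
                                   missed_cleavages = k))
    }
  }
  out[order(out$start, out$end), ]
}

random_sequence <- function(n, letters = c("A", "C", "D", "E", "F", "G", "H",
                                           "I", "K", "L", "M", "N", "P", "Q",
                                           "R", "S", "T", "V", "W", "Y")) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

# brute-force minimum all-pairs distance between two coordinate matrices
brute_min_dist <- function(p, q) {
  best <- Inf
  for (i in seq_len(nrow(p))) for (j in seq_len(nrow(q)))
    best <- min(best, sqrt(sum((p[i, ] - q[j, ])^2)))
  best
}

# random rigid transform (rotation + translation) of an n x 3 matrix
rigid_transform <- function(xyz) {
  m <- matrix(rnorm(9), 3)
  qr_ <- qr(m)
  rot <- qr.Q(qr_)
  if (det(rot) < 0) rot[, 1] <- -rot[, 1]
  sweep(xyz %*% rot, 2, rnorm(3, 0, 20), "+")
}

# apply a rigid transform to the coordinates of a PDB file on disk
transform_pdb <- function(path_in, path_out) {
  lines <- readLines(path_in)
  is_atom <- grepl("^ATOM", lines)
  xyz <- do.call(rbind, lapply(lines[is_atom], function(l)
    as.numeric(c(substr(l, 31, 38), substr(l, 39, 46), substr(l, 47, 54)))))
  new <- rigid_transform(xyz)
  lines[is_atom] <- vapply(seq_len(nrow(new)), function(i) {
    l <- lines[is_atom][i]
    paste0(substr(l, 1, 30),
           sprintf("%8.3f%8.3f%8.3f", new[i, 1], new[i, 2], new[i, 3]),
           substr(l, 55, nchar(l)))
  }, character(1))
  writeLines(lines, path_out)
  path_out
}

# dense pH-grid oracle for the isoelectric point (Bjellqvist set), with the
# Henderson-Hasselbalch charge evaluated over the whole grid at once
grid_pI <- function(s, step = 1e-4) {
  aa <- strsplit(s, "")[[1]]
  cnt <- function(a) sum(aa == a)
  ph <- seq(0, 14, by = step)
  pos <- function(n, pka) n * 10^(pka - ph) / (1 + 10^(pka - ph))
  neg <- function(n, pka) n * 10^(ph - pka) / (1 + 10^(ph - pka))
  charge <- pos(1, 7.50) + pos(cnt("K"), 10.00) + pos(cnt("R"), 12.00) +
    pos(cnt("H"), 5.98) -
    (neg(1, 3.55) + neg(cnt("D"), 4.05) + neg(cnt("E"), 4.45) +
       neg(cnt("C"), 9.00) + neg(cnt("Y"), 10.00))
  ph[which.min(abs(charge))]
}

# two-sided Fisher exact p for a 2x2 table by hypergeometric enumeration
fisher_enum <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0L, k - n); hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
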