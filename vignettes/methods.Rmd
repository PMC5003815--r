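---
title: "Mapping RNA-binding regions from crosslinking proteomics: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping RNA-binding regions from crosslinking proteomics: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbdmapr)
```

## The problem

UV light crosslinks proteins covalently to the RNA they touch in living
cells. After oligo(dT) capture of polyadenylated RNA and partial
proteolysis (LysC or ArgC), a second capture splits the proteolytic
fragments into two pools: fragments still covalently attached to RNA
(the RNA-binding regions) and fragments released into the supernatant.
Tryptic digestion of the RNA-bound pool yields peptides adjacent to the
crosslink (N-link), identifiable by standard MS, while the crosslinked
peptide itself (X-link) carries a heterogeneous nucleotide adduct and
largely escapes identification. `rbdmapr` implements the computational
half of this experiment: from peptide-level quantification tables to
called RNA-bound peptides, reconstructed binding regions, positional
domain profiles, structure-based validation, and enrichment statistics —
plus a synthetic-data generator that plants ground truth so every stage
can be scored.

## In silico digestion

Cleavage rules: LysC cuts C-terminal of lysine (including Lys-Pro
bonds), ArgC C-terminal of arginine, and trypsin C-terminal of Lys or
Arg except before proline. Nonstandard residues (X, U, B, Z) are never
cleavage sites. Coordinates are 1-based closed intervals throughout, the
UniProt convention. Zero-missed fragments tile the protein exactly; a
k-missed fragment is the concatenation of k+1 adjacent tiles, so with S
internal sites and up to m missed cleavages the fragment count is
sum over k of max(0, S+1-k). The mean zero-missed LysC/ArgC fragment is
about 17 residues for human-like residue frequencies; that length is the
spatial resolution of the whole map.

## RBDpep reconstruction and X-link inference

An MS-identified tryptic peptide is located on the proteome by exact
substring match (peptides shorter than 5 residues are rejected as
spurious-match bait; matches in multiple proteins are flagged ambiguous
and excluded from statistics but retained in reports). The RNA-bound
region (RBDpep) is re-derived by extending the peptide to the nearest
first-round cleavage boundaries on both sides; the X-link moiety is the
set difference RBDpep minus N-link, at most two intervals. Three
algebraic laws pin this down and are property-tested: boundaries are
cleavage sites or termini, the extension is idempotent, and N-link and
X-link partition the RBDpep exactly. Overlapping or bookended RBDpeps on
one protein merge into a binding site; merging pools both proteases by
default (the most conservative deduplication), with a flag to keep them
separate.

## Bound/released classification

Per-replicate log2(bound/released) ratios are median-combined across
replicates quantified in both fractions, after median-centering each
channel on the log2 scale (centering can be disabled; on simulated data
without loading offsets it only shifts the scale). The combined ratios
are bimodal: a null mode of released peptides near zero and a high mode
of RNA-bound peptides. A two-component Gaussian mixture is fitted by EM
(tolerance 1e-8 on the log-likelihood, at most 500 iterations; the null
component is seeded at the median and the bound component at the 95th
percentile, which keeps a small bound mass from being swallowed by a
symmetric initialization). The per-peptide local false discovery rate
weight_null * phi_null(x) / f(x) is converted to a q-value-style FDR by
tail-averaging from the top and enforcing monotonicity; peptides are
labeled `RBDpep` at FDR <= 0.01 and `candidate_RBDpep` at <= 0.10, the
two stringency tiers of the method.

Two guards matter in practice:

* **Unimodality.** On data without signal the EM will happily split one
  Gaussian into two overlapping components; a component-weight collapse
  test alone never fires there. The fit is therefore also compared
  against a single Gaussian by BIC, and when the one-component model
  wins, the fit is flagged unimodal and nothing is called.
* **One-sided peptides.** Peptides detected in the bound fraction but
  never in the released fraction carry presence/absence evidence only.
  They inherit the minimum fitted FDR when supported by at least two
  replicates, but enter the candidate tier, not the top tier: under
  completely-at-random dropout (which the generator injects on purpose)
  a missing released intensity is as likely a dropout as a depletion,
  and simulation shows that promoting such peptides into the 1% tier
  inflates its realized FDR several-fold. `one_sided_promote = TRUE`
  restores promotion for data where bound-only detection is trusted.

Peptides more intense without UV than with it cannot owe their capture
to a crosslink; they are flagged `background` (uncentered comparison)
and excluded from fitting and calling.

## Positional domain profiles

Residues are mapped into a normalized frame per domain instance:
relative position (residue - start) / length, with the domain body on
[0, 1] and one domain-length of flank on each side, spanning [-1, 2]
(projections outside are tallied out-of-frame). The default grid is 50
bins per unit (150 bins), finer than the ~17-residue peptide resolution
for typical domain lengths. Each instance contributes an indicator track
per bin — X-link residues for the bound track (a flag switches to whole
RBDpeps for sensitivity analysis), released fragments for the reference
track — and tracks are summed over instances. The per-bin ratio uses a
pseudocount of 1 on both sides, since released coverage may be zero at
individual positions. The reported peak center is the centroid of the
contiguous half-maximum region around the argmax; on plateau-shaped
coverage the raw argmax wanders with bin-level noise while the centroid
recovers the planted contact center to within a few hundredths of a
coordinate unit.

The within/outside curve restricts to proteins harboring at least one
classical RNA-binding domain, calls a peptide "within" when any residue
overlaps such a domain, and reports the within-fraction among peptides
above each ratio threshold next to the all-peptide baseline. Position-
dependent binding makes the curve rise with stringency; permuted labels
leave it flat within sampling error.

## Structure-based validation

Protein-RNA co-structures (PDB or mmCIF, read with bio3d) are reduced to
heavy atoms of model 1 with the highest-occupancy alternate conformer;
waters and non-RNA heteroatoms are dropped, and RNA chains are
recognized by nucleotide residue names. A fragment is proximal when any
structure-resolved residue has minimum heavy-atom distance to RNA of at
most 4.3 Angstrom — the boundary is inclusive, guarded by a 1e-9
tolerance because a nominal coordinate difference of exactly 4.3 is not
representable in binary floating point. Fragments with no resolved
residues are unresolved and excluded from rates. Distances are computed
by a brute-force all-pairs scan (structures here are small; the scan is
also the reference an accelerated index would have to match), and are
isometry-invariant by construction. Enrichment of called peptides among
proximal fragments is summarized by a 2x2 table, an ad/bc odds ratio
with Haldane-Anscombe correction when a cell is zero, and a two-sided
Fisher exact test.

## Enrichment statistics

Amino-acid enrichment compares residue multisets of bound versus
released fragments (whole RBDpeps by default; an X-link-only flag
exists) with per-residue Fisher tests and Benjamini-Hochberg correction
across the 20 tests, starred at 10% and 1% FDR; the structure-surface
variant partitions resolved residues at the contact cutoff instead.
Feature odds ratios use residue-space 2x2 tables for region categories
(domains, disorder) and event counting for point categories (PTMs,
variants); the Mendelian-versus-natural variant contrast is the 2x2 of
variant class against bound/released location, pooled across proteins by
default with a per-protein option. A binding site counts as disordered
when at least 50% of its residues fall in disorder intervals — the
symmetric dichotomization of a rule the underlying experiment leaves
unstated. Isoelectric points solve the Henderson-Hasselbalch zero-charge
equation under the Bjellqvist pKa set by bisection on pH [0, 14] to 0.01
tolerance. PTM context uses the 12-mer window from offset -6 to +5
around the modified residue; column frequencies carry a 0.5 pseudocount,
and cells are flagged by binomial tests against proteome background
frequencies with BH correction at 10% FDR. Group score comparisons
(abundance, conservation — supplied as scores, never computed here)
report means, standard errors, and pairwise two-sided Mann-Whitney tests
with BH correction.

## The synthetic-data generator

The generator is the test substrate for every other module and its
defaults are the study conditions of the whole test suite:

* 1200 proteins of mean length 300 drawn from human-like amino-acid
  frequencies (Lys ~5.6%, which puts the mean zero-missed LysC fragment
  at 17-18 residues) — about 20,000 zero-missed fragments, the scale of
  a deep peptide-level experiment;
* 90% of proteins carry domains, about two per carrier (tandem
  architectures are the norm among RNA-binding proteins, which show
  roughly two binding sites per protein), families drawn from
  RRM/KH/DEAD with lengths 70-90; 80% of domains bind RNA, with the true
  contact subregion at relative [0.30, 0.45] of the domain body;
* fragments overlapping a true contact draw their log2 ratio from the
  bound component N(2.5, 1), all others from N(0, 1); with the defaults
  the bound mass lands near 12%, and the denser calibration
  configurations used in testing push it to the ~30% regime where the
  mixture is strongly identified;
* intensities are log-normal with three replicates, 0.3 sd log2
  replicate noise, an input fraction averaging both pools, a noUV
  fraction carrying no bound signal, and 5% completely-at-random
  missingness to exercise one-sided handling.

Toy protein-RNA complexes place one C-alpha pseudo-atom per residue;
contact residues sit 3 Angstrom from an RNA phosphate trace and all
others on a strand displaced beyond a configurable margin (default 8
Angstrom, necessarily above the cutoff). The geometry is deliberately
synthetic — a real chain cannot jump between strands — because the
property under test is the distance spectrum, which this construction
controls exactly.

What passing on this substrate does **not** show: real data have
correlated missingness (low intensities drop out preferentially, making
one-sided peptides informative rather than artifactual), non-Gaussian
ratio tails, shared peptides between paralogs, incomplete structures
(the experiment's structure superset covers about half of each protein),
and domain families with heterogeneous lengths. The generator makes no
attempt at crosslinking chemistry or residue-specific propensities.

## Numerical choices and degenerate inputs

Tolerances: EM 1e-8/500 iterations with a 1e-4 standard-deviation floor;
pI bisection 0.01 pH; proximity boundary inclusive with 1e-9 guard.
Problem sizes in the shipped tests — 1,000-sequence digestion oracles,
10,000 interval-algebra cases, five to twenty 20,000-peptide calibration
experiments, 10-seed profile recovery, 50-seed null-honesty batteries —
were chosen so the whole suite completes in a few minutes on one core
while keeping Monte-Carlo noise well inside the asserted margins. Empty
inputs error early with messages naming the offending precondition;
zero-variance data yield degenerate flags rather than NaNs; an empty
call set produces empty reports, not errors. All randomness flows
through explicit seeds; reruns of the pipeline on identical inputs are
byte-identical, and the run log records MD5 hashes, parameters, and row
counts per stage (paths inside the output directory are logged
relative, so runs into different directories compare equal).

## Known limitations

The classification is peptide-level; no protein-level rollup or
isobaric-label correction is attempted. X-link localization is bounded
by the first-round fragment (~17 residues); no attempt is made to name
the crosslinked residue. The mixture model assumes Gaussian components
on the log scale; strongly skewed null distributions would miscalibrate
the q-values (the BIC unimodality guard catches the no-signal case, not
skew). Chain maps are trusted as given; the optional alignment fallback
refuses to map below 95% identity rather than guessing.
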