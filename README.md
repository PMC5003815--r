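# rbdmapr

Proteome-wide mapping of RNA-binding regions from UV-crosslinking /
oligo(dT)-capture quantitative proteomics.

## What it does, and for whom

In an RNA interactome capture experiment, UV light covalently crosslinks
proteins to the RNA they contact in living cells. After oligo(dT)
purification and partial proteolysis with LysC or ArgC, a second capture
separates proteolytic fragments that remain covalently bound to RNA from
fragments released into the supernatant. Tryptic digestion of the bound
pool yields MS-identifiable peptides adjacent to the crosslink site
(N-link); the crosslinked peptide itself (X-link) carries a nucleotide
adduct and escapes standard identification. `rbdmapr` is for proteomics
and RNA-biology groups who have peptide-level quantification tables from
such an experiment (or want to benchmark callers on simulated ones) and
need the downstream computation:

1. **Digestion** — in silico LysC/ArgC/trypsin proteolysis with
   missed-cleavage enumeration and the fragment-length statistics that
   set the method's ~17-residue resolution.
2. **Calling** — per-replicate log2(bound/released) ratios, a
   two-component Gaussian mixture fitted by EM, and q-value-style FDR
   labels: `RBDpep` at 1% FDR, `candidate_RBDpep` at 10%.
3. **Mapping** — extension of each MS-identified peptide to the nearest
   first-round cleavage boundaries (the RBDpep), inference of the
   X-link moiety as RBDpep minus N-link, and merging into binding
   sites.
4. **Profiles** — X-link/released coverage ratios over normalized
   domain coordinates (domain body on [0, 1], one domain-length of
   flank each side), plus the within/outside classical-domain
   calibration curve.
5. **Structure validation** — minimum heavy-atom distance of fragments
   to RNA in protein–RNA co-structures (PDB/mmCIF), proximity at the
   inclusive 4.3 Å cutoff, and Fisher/odds-ratio enrichment.
6. **Enrichment** — amino-acid composition, domain/PTM/variant odds
   ratios, disorder partition, isoelectric points (Bjellqvist pKa set,
   bisection), PTM-context position weight matrices, and group score
   comparisons.
7. **Simulation** — a generator that plants domains, contact
   subregions, bimodal ratio structure, and toy co-structures with
   controlled distances, recording ground truth so every caller above
   can be scored end to end.

### The model at the core

Combined log2 bound/released ratios x follow a two-component mixture

    f(x) = w0 · N(x; mu0, sd0) + (1 − w0) · N(x; mu1, sd1),  mu1 > mu0,

fitted by EM. The local false discovery rate
lfdr(x) = w0 · phi0(x) / f(x) is tail-averaged from the top and made
monotone to give each peptide a q-value-style FDR; thresholds 0.01 and
0.10 define the two call tiers. A BIC comparison against a single
Gaussian flags unimodal (no-signal) data, in which case nothing is
called.

## Worked example

Simulate an experiment with planted binding regions, call peptides, and
reconstruct binding sites:

```r
library(rbdmapr)

cfg   <- sim_config(n_proteins = 200, seed = 42)
sim   <- simulate_proteome(cfg)          # proteome + domains + truth table
exp   <- simulate_experiment(sim, cfg)   # quant table, bound/released/input/noUV x 3 reps

quant <- compute_log_ratios(exp$quant)
fit   <- fit_two_component_mixture(quant$log_ratio[is.finite(quant$log_ratio)])
fit
#> Two-component Gaussian mixture (EM) on 3570 log2 ratios
#>   null : weight 0.864, mean -0.281, sd 1.042
#>   bound: weight 0.136, mean 2.202, sd 1.065
#>   loglik -6025.37 after 500 iterations (not converged)

called <- classify_peptides(quant, fit)
table(called$class_label)
#> candidate_RBDpep           RBDpep         released
#>              215               62             3294

sites <- build_sites(called[called$class_label == "RBDpep", ],
                     sim$proteome, "LysC")
agg <- aggregate_sites(sites)
c(agg$n_sites, agg$n_proteins)
#> [1] 60 56
```

Reading: the mixture fit found a bound mode 2.2 log2 units above the
released mode carrying ~14% of the peptides (the EM stops at its
500-iteration cap here; parameters are stable at the reported
precision). 62 peptides pass 1% FDR, a further 215 pass 10%, and the
1%-FDR peptides merge into 60 binding sites across 56 proteins. Since
the generator records truth, `mean(!called$true_bound[called$class_label
== "RBDpep"])` gives the realized false discovery proportion.

The same flow runs from files via `run_pipeline(run_config(...))`, which
writes called peptides, site tables, profiles, proximity and enrichment
reports, and a run log with per-stage input hashes; a thin CLI wrapper
lives at `inst/cli/rbdmap.R`.

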