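# tandemLBD

Comparative analysis of **tandem ligand-binding-domain (LBD) multiplications
in TGFβ-family receptors** (ACVR1, BMPR2, TGFBR2 and paralogs). Most
vertebrate TGFβ receptors carry a single extracellular LBD; in a number of
lineages — fish, amphibians, birds, mammals — that domain has been tandemly
duplicated or triplicated. For anyone studying such receptors this package
provides the downstream analyses as tested, reusable code:

* **Tandem-domain annotation** — iterative masked Smith–Waterman of a
  reference LBD against a receptor protein; copies labelled by membrane
  proximity (`out` / `mid` / `in`, N→C) and inter-domain linker lengths
  measured (the residues encoded at the junction of a duplicated exon pair).
* **Conservation scoring** — intra-protein percent identity of each copy
  relative to the membrane-proximal LBD`in`, and retention of
  ligand-contact epitope residues (contact positions supplied as data).
* **Molecular clock** — pairwise JTT+Γ maximum-likelihood amino-acid
  distances (pairwise deletion, site-bootstrap variances), a weighted
  regression of distance *d* on divergence time *T* whose slope is the
  clade rate *r* (subst·site⁻¹·Myr⁻¹, pairwise-path convention *d = r·T*),
  and the duplication-specific quantity *r₍dup₎ = d₍dup₎ / r* plus the
  dimensionless relative rate *d₍dup₎ / (r·t₍dup₎)* when a duplication age
  is given.
* **Linker geometry** — the octant embedding metric: a linker residue is
  *embedded* in the ligand dimer when ligand heavy atoms within 5 Å of its
  Cα occupy ≥ 5 of 8 octants; a model *threads* when any residue is
  embedded; `min_bivalent_linker()` finds the smallest linker length whose
  top-3 ranked models stop threading (the predicted cutoff for intra-ligand
  bivalency), with placement QC for misdocked models.
* **Synthetic data** — generators for clock-evolving domain clades (JTT +
  discrete gamma on a star tree, controllable internal duplication),
  multi-exon two-LBD gene models, and toy ligand/linker PDB structures with
  brute-force ground truth — every stage is testable offline.

See `vignettes/tandem-lbd-methods.Rmd` for the models, conventions
(rate convention, identity denominator, octant tie-breaks) and limitations.

## Worked example

Simulate a 5-taxon clade (100 Myr, *r* = 0.001 subst/site/Myr, 10,000
sites, Γ shape 1.0) whose taxon `t1` carries a duplicated domain copy at
expected divergence 0.25 — five-fold the clock expectation for a 50-Myr-old
duplication — then recover everything:

```r
library(tandemLBD)
spec <- clade_sim_spec(n_taxa = 5, divergence_times = 100, r_true = 0.001,
                       dup_taxon = "t1", d_dup_true = 0.25,
                       seq_length = 10000, gamma_alpha = 1.0, seed = 42)
sim  <- simulate_clade(spec)
dist <- pairwise_distances(sim$records[paste0("t", 1:5)], n_boot = 200, seed = 1)
fit  <- fit_clock(dist, sim$divergence_table)
fit
#> <clock_fit> clade: r=0.00103397 subst/site/Myr (se 2.2e-05), 10 pairs, inverse-variance
d_dup <- jtt_distance(sim$records$t1$sequence, sim$records$t1_dup$sequence)
duplication_rate(d_dup, fit, t_dup = 50, focal = "t1")
#> <duplication_rate> t1: d_dup=0.2542 r_clade=0.00103 r_dup=245.8 relative=4.92
```

The fitted clade rate (0.00103) recovers the true 0.001 within its standard
error, and the relative rate 4.92 recovers the simulated five-fold
acceleration — the signature that distinguishes a drifting duplicated
domain from copies conserved under the clade clock.

Tandem-domain annotation and linker arithmetic on a synthetic two-LBD gene
model (20-residue linker encoded at the duplicated exon junction):

```r
gm  <- make_gene_model(two_lbd = TRUE, linker_len = 20, seed = 7)
ref <- substr(gm$protein$sequence, gm$domains$start[1] + 1, gm$domains$end[1])
ann <- detect_tandem_domains(gm$protein, ref)
ann[, c("protein_id", "start_1based", "end_1based", "label", "score")]
#>           protein_id start_1based end_1based label score
#> 1 synthetic_receptor           26         85   out   320
#> 2 synthetic_receptor          106        165    in   320
linker_length_from_domains(ann)
#>   from_label to_label linker_length
#> 1        out       in            20
find_linker("SESVNNDMIVTDNNGAVKFP")$length   # the canonical linker core
#> [1] 20
```

A full demo pipeline (`run_pipeline()`) chains all stages on generated
data and writes TSV/JSON outputs plus a markdown report; a thin CLI lives
in `inst/cli/tandemlbd.R`.

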