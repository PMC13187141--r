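---
title: "Methods: tandem LBD evolution, molecular clocks, and linker geometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tandem LBD evolution, molecular clocks, and linker geometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tandemLBD)
```

# Scope and model

TGFβ-family receptors (ACVR1, BMPR2, TGFBR2 and their paralogs) normally
carry a single extracellular ligand-binding domain (LBD). In several
vertebrate lineages this domain has been tandemly duplicated or triplicated,
producing receptors with two to five LBD copies labelled by membrane
proximity: `in` (membrane-proximal), `out` (membrane-distal), and `mid`
copies in between. `tandemLBD` implements the comparative analyses such an
observation calls for:

1. **Annotation** — finding tandem LBD copies on a receptor protein by
   iterative masked local alignment against a reference domain.
2. **Conservation** — intra-protein percent-identity profiles relative to
   LBD`in`, and retention of ligand-contact epitope residues.
3. **Molecular clock** — pairwise JTT+Γ maximum-likelihood amino-acid
   distances with site-bootstrap variances, a weighted regression of
   distance on species divergence time, and a duplication-specific rate for
   the within-protein copy pair.
4. **Linker geometry** — an octant-occupancy metric deciding whether the
   inter-domain linker of a two-LBD receptor threads through a ligand dimer
   (which intra-ligand bivalency would require), and the minimal linker
   length at which top-ranked structural models stop threading.
5. **Synthetic data** — generators for clock-evolving domain clades,
   multi-exon gene models, and toy ligand/linker structures, each with
   ground truth, so that every stage is testable without external downloads.

Structure prediction, docking and interface-energy scoring are out of scope:
3-D models are an *input* here.

# Tandem-domain annotation

`detect_tandem_domains()` runs Smith–Waterman (BLOSUM62, affine gaps, open
10 / extend 1) of a reference LBD against the protein; each hit at or above
the score threshold is masked with `X` and the scan repeats. Masking
guarantees termination and non-overlap. Defaults — threshold = 40% of the
reference self-score, minimum hit length = 50% of the reference — are
deliberate design choices: the original screening used a conserved-domain
database search that publishes no thresholds, and a similarity floor that
would separate a degenerate LBD remnant from a lost domain is not known.
Both knobs are exposed and nothing is asserted about borderline hits.

Alignment conventions that other modules rely on: a gap run of length
$L$ costs $\mathrm{open} + (L-1)\,\mathrm{extend}$; ties break
deterministically (diagonal, then up, then left); coordinates are 0-based
half-open internally and 1-based inclusive in every report.

The inter-domain linker length is the number of residues strictly between
consecutive copies. For the exon-pair duplications of type II receptors this
stretch is encoded at the junction between the original and duplicated
exons, which is why the gene-model fixture (`make_gene_model()`) carries an
explicit exon structure and asserts translation consistency.

# Identity and epitope retention

`identity_pct()` is $100 \times$ identical columns / mutually ungapped
columns of the global alignment. The denominator matters: the source
analyses never define theirs, so the pairwise-deletion style denominator is
the default (consistent with the distance module) and the full-alignment
denominator is available behind a flag; both are worth reporting when they
differ. `epitope_retention()` takes the contact positions as *data* (a TSV
of reference positions grouped by site class such as finger 1, finger 3,
A-loop, C-terminus) because published contact sets come from docking figures
and cannot be transcribed reliably; the two specs shipped under
`inst/extdata/` are synthetic examples, clearly marked non-authoritative.
"Retained" defaults to strict identity; a positive-BLOSUM62 similarity mode
exists and is never smaller, position-wise.

# JTT+Γ distances and the clock

Distances maximize the site-wise log-likelihood
$\ell(d) = \sum_s \log \sum_k w_k\, \pi_{a_s} P_{a_s b_s}(d\, r_k)$
with $P(t) = e^{Qt}$ from the eigendecomposed JTT rate matrix calibrated to
one expected substitution per site per unit $d$, and $r_k$ a discrete gamma
(default shape $\alpha = 1.0$, $k = 4$, median category rates renormalized
to mean 1). This approximates, but does not bit-for-bit replicate, the MEGA
X implementation; differences are expected to be well under 1% at moderate
divergence. Columns where either sequence carries a gap or `X` are dropped
(pairwise deletion). Optimization is bounded scalar maximization on
$[0, 10]$ with tolerance $10^{-6}$; saturation at the bound is flagged, not
silently clipped. Variances come from site bootstrap (default 1000
replicates, resampled multinomially over site patterns), seeded and
reproducible.

**Rate convention.** The clade rate $r$ is defined on the *pairwise path*:
$d(a,b) = r\,T(a,b)$ where $T$ is the species divergence time. This mirrors
a regression of pairwise distance on divergence time, whose slope is the
clock rate. The source procedure never states the factor-of-two convention;
on a star tree each lineage therefore evolves $r\,t_i$ with tip age $t_i$
and $t_a + t_b = T(a,b)$. Anyone comparing to a per-lineage rate must halve.

**Regression.** `fit_clock()` is weighted least squares of $d$ on $T$,
through the origin by default (a clock forces $d \to 0$ as $T \to 0$; a
free-intercept mode exists because the source does not specify). Weights are
inverse bootstrap variances by default — "weighted" is otherwise undefined
in the source — with zero variances mapped to the largest finite weight
present.

**Standard error.** Pairwise distances on a star topology are not
independent: pairs sharing a taxon share that lineage's estimation error,
so the ordinary regression SE — which treats the pairs as independent —
undercovers far below its nominal level. `fit_clock()` therefore reports
`se_r` from a correlation-aware form: pair variances decompose as
$\mathrm{Var}(d_{ab}) = v_a + v_b$, the per-lineage components $v$ are
solved by least squares from the bootstrap variances, and the covariance
$\mathrm{Cov}(d_{ab}, d_{ac}) = v_a$ is propagated through the slope's
linear form. The recovery harness in the acceptance suite checks the
resulting coverage (true rate within $\pm 2\,\mathrm{se\_r}$ in at least
90% of seeded replicates); the naive value is kept as `se_naive`.

**Duplication-specific rate.** `duplication_rate()` divides the distance
between the two LBD copies by the clade rate, $r_{dup} = d_{dup}/r$. Note
the literal quantity has units of Myr (a distance divided by a rate); it is
reported as defined, and when a duplication age $t_{dup}$ is supplied the
dimensionless relative rate $d_{dup}/(r\,t_{dup})$ is also emitted — 1
means the copies diverged at the clade clock, 5 means five-fold
acceleration (the pattern seen for the zebrafish duplication). No
interpretation of the literal $r_{dup}$ is asserted.

# The octant embedding metric

For each linker residue, ligand heavy atoms (non-hydrogen atoms of the
designated ligand chains, waters excluded, HETATM included) within 5 Å of
its Cα are assigned to one of eight octants by the sign pattern of their
displacement; the residue is *embedded* when ≥ 5 octants are occupied. A
model *threads* through the dimer when at least one residue is embedded
(the source speaks of threading without a count threshold; the full
per-residue profile is always reported so alternative thresholds cost
nothing). The linker span is located by exact match of the core sequence
`SESVNNDMIVTDNNGAVKFP` extended through maximal G/S runs on both sides, or
supplied explicitly.

Numerical choices, all deterministic: the radius is inclusive (≤ 5.0 Å); an
atom on an octant plane goes to the positive half-space; octant axes are the
model's global axes by default. The octant frame is a known degree of
freedom — joint *rotation* can change counts (joint translation cannot, and
is tested exactly) — so a `ligand_pca` frame (octant axes = principal axes
of the ligand heavy atoms, signs fixed deterministically) provides a
rotation-covariant alternative.

`filter_misplaced_models()` implements the QC step of excluding models with
misplaced receptor domains: a model is kept iff every receptor LBD lies
within `max_dist` (default 8 Å, configurable) of its assigned ligand
epitope residues; exclusions are logged with the violating distance.
`min_bivalent_linker()` then returns the smallest linker length whose top
`top_n = 3` ranked models (rank is taken from the input, never recomputed)
all have zero embedded residues; with the series mirroring the source's
outcome this is 36 residues, and `compare_to_cutoff()` classifies natural
linkers inclusively (length ≥ cutoff is feasible, so 36 itself is feasible;
44 is, 20 is not).

# What the synthetic generator does and does not emulate

`simulate_clade()` evolves gap-free domain alignments from a stationary
JTT root on a star tree with discrete-gamma site rates, so the expected
estimator path length for each pair equals $r\,T(a,b)$ by construction —
the estimator's own model, which is exactly what makes recovery tests
well-posed. The duplicated copy of the focal taxon diverges from that
taxon's own domain by a controllable expected path length, with site rates
shared along the path. Divergence-time tables must be star-additive
($T(a,b) = t_a + t_b$); this is checked, and the two-taxon case takes the
minimum-norm split. Defaults (5 taxa, 100 Myr, $r = 10^{-3}$
subst/site/Myr, 10,000 sites, $\alpha = 1.0$) are the stated conditions of
the recovery harness; $r \cdot T = 0.1$ is a moderate divergence typical of
within-clade LBD comparisons.

Deliberately *not* emulated: indels (alignments are generated gap-free; gap
handling is exercised with hand-made gapped fixtures), nucleotide-level
processes, non-star topologies, lineage-specific frequencies, and selection.
A green recovery test therefore establishes that the estimator and
regression recover their own model's truth — not that real LBD alignments
satisfy that model. Likewise `make_linker_structure()` produces slab, shell
and two-lobe point-cloud ligands with straight threading or circular
wrapping Cα paths: good enough to ground-truth the octant metric exactly
(its truth labels come from an independent brute-force oracle), but not a
model of protein geometry.

# Runtime scaling in the test suite

The packaged defaults follow the published procedure (1000 bootstrap
replicates). The recovery harness and the demo pipeline use 100–200
replicates for the inverse-variance *weights* only, to stay inside the test
runtime budget; this affects weight noise, not the criterion thresholds,
and the bootstrap itself is validated separately (zero variance for
identical pairs, seed reproducibility, variance shrinking with sequence
length).

# Known limitations

* The octant frame and plane tie-breaks are package conventions; counts
  under joint rotation differ unless the PCA frame is used.
* `detect_tandem_domains()` trims hit boundaries to the locally optimal
  alignment, so annotated spans can be slightly shorter than the biological
  domain when termini have diverged; linker lengths inherit that
  uncertainty.
* The clock assumes one shared JTT matrix and stationary frequencies across
  lineages ("homogeneous substitution pattern"), a star topology, and
  star-additive times; none of these are inferred from data.
* External spot checks against public transcripts (e.g. the 98% identical
  chicken LBD pair) require network access and are not part of the test
  suite; the suite's claims are about the package's own stated world.
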