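---
title: "Homopolymeric amino-acid tracts and the timing of gene duplications: methods"
author: "hpaaphylo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homopolymeric amino-acid tracts and the timing of gene duplications: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

Lamprey and hagfish (cyclostome) gene families often resist confident
placement relative to their jawed-vertebrate (gnathostome) counterparts.
A recurring question for a family with several paralogs in both lineages
is *when* the duplications happened: before the cyclostome–gnathostome
split (so cyclostome and gnathostome paralogs are orthologous pairs) or
independently within each lineage (so each lineage's paralogs cluster
together). Sequence idiosyncrasies of lampreys — here, homopolymeric
amino-acid (HPAA) tracts such as long poly-alanine and poly-glutamine
runs acquired convergently by paralogs — can distort alignments and pull
the lineage's sequences together, mimicking within-lineage duplication.

`hpaaphylo` implements the full analytical chain needed to study this:

1. **HPAA scanning** of proteomes: maximal identical-residue runs at
   configurable length thresholds, with per-amino-acid peptide
   frequencies, residue proportions, long-tract fractions, and the
   associated chi-square and two-proportion tests.
2. **Exhaustive maximum-likelihood topology evaluation**: every unrooted
   topology over a small set of OTUs is scored under JTT(+Γ, +I, +F),
   with RELL bootstrap probabilities and one-sided Kishino–Hasegawa and
   Shimodaira–Hasegawa tests.
3. **Probabilistic duplication counting**: per-topology
   gene-tree/species-tree reconciliation against the species tree
   (outgroup,(cyclostome,gnathostome)), weighted by RELL bootstrap
   probabilities to give expected duplication counts N~bef~, N~aft~,
   N~cyc~ (and N~unk~ in rooting-agnostic mode).
4. **Alignment-sensitivity experiment**: delete the HPAA tracts, re-align
   with several aligners, trim at graded stringencies, and compare the
   summed RELL support for the suspect grouping between intact and
   tract-deleted (ΔHPAA) arms.
5. **Synthetic data** with known truth for every stage.

# Models and procedures

## HPAA tracts

A tract is a *maximal* run of identical standard residues of length at
least `min_len` (default 6; 8/10 for robustness checks, 12 for the
long-tract fraction). A run of length 8 is one tract of length 8, never
several overlapping shorter tracts. Ambiguity codes (B, Z, X, J), the
rare residues U and O, and gaps terminate runs and never form tracts.
Coordinates are reported 1-based inclusive. The "any amino acid" peptide
frequency counts a peptide once however many tract types it carries; the
per-amino-acid residue proportion divides residues inside that amino
acid's tracts by *all* residues, so the per-amino-acid rows sum to the
total row.

Statistical comparisons between species use the Pearson chi-square test
of homogeneity (no continuity correction, df = k−1 for k species) and
the pooled-variance two-proportion z test (two-tailed, no continuity
correction). Large proteome samples make continuity corrections
immaterial; omitting them keeps the statistics exactly reproducible from
the printed counts.

## Likelihood engine

Site log-likelihoods are computed by Felsenstein pruning under the JTT
exchangeabilities with either the model's stationary frequencies or
empirical (+F) frequencies (pseudocount 10^-6^). Rate heterogeneity uses
the discrete gamma approximation: `k` equal-probability categories (4 by
default), each represented by its conditional mean, rescaled to average
exactly 1. With a proportion `p_inv` of invariant sites the gamma rates
are divided by `1 − p_inv` so the overall mean rate stays 1, and the
invariant class contributes the stationary probability of the column's
shared state. Gaps and ambiguity codes are missing data (partial
likelihood 1 over all states); columns are never dropped by the engine —
trimming is an explicit, separate step. Likelihood is invariant under
re-rooting (checked to 10^-8^ in the tests), and the engine is verified
against an exhaustive sum over internal-node states on small trees.

Branch lengths for a fixed topology are optimized with the C-backed
machinery of **phangorn** (lower bound 10^-8^, log-likelihood tolerance
10^-6^); the per-site log-likelihood matrices handed to the resampling
tests come from this package's own pruning implementation evaluated at
those optimized lengths. When no gamma shape is fixed, it is estimated
once on a reference topology and reused for all topologies, mirroring
the behaviour of classical exhaustive-ML tools; printed shape values
(for example α = 0.37 or 1.17 for particular datasets) can instead be
supplied directly.

## Topology tests

The RELL bootstrap resamples alignment sites by drawing multinomial
column weights (no re-optimization) and records which topology attains
the maximal resampled total log-likelihood; ties split the replicate
equally. Defaults: 10,000 replicates and a mandatory user seed. The
one-sided KH test compares a topology to the maximum-likelihood one
using the centered RELL distribution of the log-likelihood difference
(a normal-approximation variant is available behind a flag); the SH test
centers every topology's resampled totals and compares the observed
difference to the maximal centered excess over shared resamples. Both
tests center resampled quantities at their *exact* expectations under
multinomial resampling — the observed totals — rather than at empirical
replicate means; the two coincide as the replicate count grows, but
exact centering removes an O(B^−1/2^) wobble of the rejection threshold
that matters on short alignments with coarse resample lattices. By
construction the best topology reports KH = SH = 1.00, and SH p-values
dominate KH p-values. Inside `topology_test_table()` one shared set of
resamples serves BP, KH and SH; the standalone functions draw their own.
Support for a grouping across the whole topology set is the sum of BP
over topologies containing it as an unrooted bipartition
(`clade_support()`).

## Duplication counting

Each enumerated topology is rooted on the outgroup edge (always possible
when the outgroup is a single collapsed OTU), the outgroup is removed,
and every internal node of the ingroup tree is mapped by the
last-common-ancestor rule onto the species tree
(cyclostome, gnathostome, and their ancestor V). A node is a duplication
when it maps to the same species-tree node as one of its children;
duplications are timed by that node: V → N~bef~, gnathostome → N~aft~,
cyclostome → N~cyc~. Gnathostome subtype OTUs count as one ancestral
gene each; within-OTU speciations are never counted. Bootstrap-weighted
counts are `N_x = Σ_T BP(T) · n_x(T)`.

The outgroup-rooted mode makes every duplication's timing determinate
(N~unk~ = 0 per topology). Because published tables report a nonzero
unknown class whose precise definition lives in earlier work, an
optional rooting-agnostic mode re-counts under every branch rooting,
credits each timing class with its minimum over the rootings that attain
the minimal total, and reports the remainder — duplications whose timing
depends on the rooting — as N~unk~. This reconstruction is a documented
best-effort interpretation, not a validated reimplementation of the
earlier method, and the default mode is outgroup rooting.

## Alignment, trimming, and the sensitivity grid

The builtin aligner is progressive: a guide tree from shared-3-mer
distances (average linkage) and profile–profile Needleman–Wunsch merges
under BLOSUM62 with affine gaps (open 10, extend 0.5; the dynamic
program is compiled code). It exists so the whole pipeline runs with no
external binaries; adapters shell out to MAFFT, ClustalW or T-Coffee at
default settings when those programs are on the PATH and fall back to
the builtin aligner with a warning otherwise. Every aligned row
de-gaps back to its input sequence.

Trimming first removes every column containing a gap (the experiments
all run in "no gap allowed" mode), then, for a similarity threshold
`st > 0`, removes columns whose mean pairwise residue similarity — under
BLOSUM62 rescaled to [0, 1] — falls below `st`. This reproduces the
semantics of similarity-threshold trimming (raising `st` can only shrink
the kept set, fully conserved columns always survive) without
reproducing any particular program's score scale, so absolute
kept-column counts from published analyses are matched only
approximately.

`run_sensitivity_grid()` fixes one substitution model and one seed
across all cells (aligner × trimming stringency × intact/ΔHPAA arm) so
cells differ only in alignment and trimming, then reports the summed
RELL support for the focal grouping and the retained-site count per
cell. A failing cell is marked failed without aborting the grid.

# The synthetic-data generator

The generator is first-class, tested code; its defaults are the study
conditions used throughout the test suite.

**Proteomes.** Peptides are i.i.d. residues drawn from a frequency
vector (default: the JTT stationary frequencies, a realistic average
composition), lengths uniform on a range. Tracts are *inserted* (spliced
in) per amino acid with a set probability, length = floor + geometric
excess, at a uniform position; all insertion points are drawn in
original coordinates first, so an inserted tract can never split another
one, and the returned truth table lists every tract with its final
coordinates. Chance runs still arise from the i.i.d. background at the
analytic rate `q^L (1 + (n − L)(1 − q))`, which the tests verify.

**Gene families.** Six leaves — three gnathostome paralogs (g1, g2, g3),
two cyclostome paralogs (cA, cB), one outgroup — evolve under JTT+Γ~4~
along one of two true histories. *Before-split*: two duplications on the
stem lineage (heights 0.6 and 0.5 substitutions/site) above the
cyclostome–gnathostome split (0.4), with the third cyclostome copy lost;
true counts (N~bef~, N~aft~, N~cyc~) = (2, 0, 0). *Independent*:
duplications inside each lineage (gnathostome at 0.3 and 0.2, cyclostome
at 0.25); true counts (0, 2, 1). The outgroup attaches at 0.8. These
depths keep every internal branch at 0.10–0.15 substitutions/site,
comfortably above the 0.05 floor the recovery experiments assume, at an
overall divergence typical of vertebrate gene families. Default length
is 300 sites with gamma shape α = 0.5. Sequences are simulated per rate
category (delegated to **phangorn**'s simulator), categories are drawn
multinomially and the columns shuffled.

**HPAA injection.** Tract gain is modelled as insertion after the
substitution process — mimicking expansion by replication slippage — at
fixed, plan-specified positions and lengths, for test determinism. The
artifact experiments inject an A-tract and a Q-tract of 20 residues
adjacently into the N-terminal region of both cyclostome paralogs,
matching the tract architecture observed in real lamprey homeobox
proteins (adjacent poly-A and poly-Q in the N-terminal domain). No
quantitative model of tract gain is claimed; lengths follow the observed
scale (≥ 10 residues) of documented cases.

**What the generator does not emulate.** Background indels, GC-content
and codon-usage bias, amino-acid compositional drift, rate variation
across lineages, and alignment uncertainty beyond what the aligners
produce. Passing recovery tests on these data therefore show that the
chain of methods is implemented correctly and has the claimed direction
of behaviour under clean conditions — not that real lamprey datasets are
free of other artifacts.

# Numerical choices

* Branch-length lower bound 10^-8^; optimization tolerance 10^-6^;
  RELL replicates 10,000 with mandatory seed; BP ties split equally at a
  10^-9^ comparison tolerance.
* Discrete-gamma category rates are conditional means renormalized to
  average exactly 1 (guards against quantile round-off).
* The Kimura protein distance `−ln(1 − p − p²/5)` saturates near
  p ≈ 0.85; beyond the domain an `NA` with a warning is returned rather
  than a number.
* Nei–Gojobori Ks counts synonymous sites per codon as the fraction of
  one-step changes preserving the amino acid (changes to stops count as
  nonsynonymous), averages differences equally over minimal mutational
  paths (stop-crossing paths excluded unless all cross a stop), and
  applies the Jukes–Cantor correction; `ps ≥ 3/4` yields a saturation
  marker. This is a documented, simpler estimator: no parity with
  codon-model ML tools is claimed.
* The reciprocal homolog filter scores pairs by Smith–Waterman
  (BLOSUM62, gap open 11 / extend 1) and converts raw scores to bits
  with gapped Karlin–Altschul constants λ = 0.267, k = 0.041. A pair
  counts when both directions reach the threshold; with the symmetric
  builtin scorer the two directions coincide and are computed once.
  "Reciprocal" is interpreted as any hit ≥ threshold in both directions
  (best-hit semantics are not imposed). The BLAST-based external backend
  is available for parity runs.
* Representative-isoform selection takes the longest peptide per gene;
  equal lengths break by lexicographically smaller id, making the result
  order-invariant.

# Problem sizes used in the shipped experiments

The recovery studies run 50 replicates per scenario (full 105-topology
exhaustive ML each) and the tract-artifact study 30 paired replicates,
at 300 sites; the scanner calibration uses 200 proteomes of 250 peptides
and 100 tract-free proteomes. These sizes give binomial standard errors
of a few percent on the reported rates while keeping a full suite run on
one CPU in the tens of minutes.

# Known limitations

* Only the JTT exchangeability family is embedded; model selection
  across matrices is out of scope.
* Exhaustive enumeration is guarded at 9 OTUs ((2n−5)!! growth); there
  is deliberately no heuristic tree search.
* The trimming score reproduces similarity-threshold *semantics*, not
  any specific program's scale, so kept-site counts are comparable only
  within this package.
* The rooting-agnostic N~unk~ is a best-effort interpretation (see
  above).
* The builtin aligner gaps long low-complexity insertions fairly
  cleanly; the tract-attraction artifact it produces after strict
  trimming is therefore directional but small, consistent with reports
  that modern aligners largely defuse the artifact that older
  progressive aligners showed strongly.
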