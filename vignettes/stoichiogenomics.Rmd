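---
title: "Methods: nitrogen allocation analysis of marine metagenome proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nitrogen allocation analysis of marine metagenome proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the model
behind each stage, the constants and why they have the values they do,
what the synthetic generator does and does not emulate, and the design
decisions taken where more than one defensible choice existed.

## 1. The scientific question

Surface-water nitrogen availability differs systematically between
open-ocean and coastal habitats. If selection for parsimonious nitrogen
allocation is strong enough to shape protein composition, communities
adapted to the nitrogen-poor open ocean should build proteins with
fewer side-chain nitrogen atoms than coastal communities — overall, in
every structural stratum of membrane proteins, and most strongly in the
least functionally constrained residues of the genes that are
up-regulated under nitrogen starvation (the NtcA-induced cascade),
while the arginine-biosynthesis genes, up-regulated under nitrogen
abundance, serve as a metabolic control in which no such localization
is expected.

The package measures all of these contrasts. Its unit quantity is the
nitrogen content of a sequence,

$$N_c = \frac{\sum_i n_i}{L},$$

the mean number of side-chain nitrogen atoms per residue: $n = 1$ for
Asn, Gln, Lys and Trp, $n = 2$ for His, $n = 3$ for Arg, $n = 0$ for
the other thirteen standard amino acids. $N_c$ ranges over $[0, 3]$
and equals 3 only for poly-arginine.

### Handling of non-standard residues

Metagenomic peptide sets contain ambiguity codes (`X B Z U O`) and
translated stops (`*`). The side-chain nitrogen count is defined only
for the 20 standard residues, so these codes are removed from both the
numerator and the denominator of $N_c$: the statistic stays a mean over
scorable residues rather than being silently biased toward zero. A
sequence with no scorable residue is an error, not a zero. This is a
documented package choice — how the original survey handled assembly
artifacts is not recorded anywhere we could follow.

### Filters

* Only proteins **longer than 100** residues are analyzed (strict
  `> 100`, a literal reading of the filter; the threshold is a config
  key). The filter applies to the full peptide, before signal-peptide
  removal, since the alternative ordering is nowhere specified.
* Membrane-protein domain analysis additionally requires **at least
  20** residues (inclusive) in each of the three domain kinds.
* Estuary samples are a sparse coastal subtype and are merged into the
  coastal group at load time; the original label is kept in a
  `habitat_original` column so the merge is reversible.

## 2. Membrane topology

Topology comes from Phobius-style short-format predictions — the
package parses and emits that format rather than re-deriving topology,
so real predictor output drops in. A prediction string is an optional
signal prefix `n<a>-<b>c<c>/<c+1>` (the signal segment ends at `c`,
the residue before the annotated cleavage point) followed by
alternating `i`/`o` side letters with `<start>-<end>` transmembrane
ranges between them. Coordinates are 1-based inclusive throughout.
Parsed segments must tile the sequence, alternate sides across TM
segments, and agree with the declared TM count; violations are errors
with line numbers.

A protein with at least one TM segment is a membrane protein;
single-spanning and multi-spanning proteins are analyzed separately.
`dissect_domains()` concatenates the residues of each kind in sequence
order — cytoplasmic, transmembrane, periplasmic/extracellular (one
kind: the two are not distinguishable in this data) — and drops signal
peptides from every output, so the three domains plus the signal
partition the sequence exactly.

## 3. Functional annotation

HMMER3 per-sequence (`--tblout`) tables are filtered at model-specific
noise cutoffs. The comparison is **inclusive** (`bitscore >= cutoff`),
matching the cutoff semantics of the HMM software itself. Each query is
then assigned to the gene of its highest-scoring surviving hit, with
ties broken toward the lexicographically smallest model accession — the
original analysis counts homologs per gene, which implies a unique
assignment but states no rule, so the best-hit rule is ours. Queries
whose best hit matches no model of either pathway stay unassigned.
Scores are per-sequence, not per-domain (also unstated upstream; a
documented choice). `recD` appears in the published NtcA-induced gene
list without explanation and is carried verbatim.

The shipped gene-to-model table (`pathway_models_synthetic.tsv`) maps
the 15 genes to **synthetic placeholder accessions** so tests and the
generator resolve; it is an editable TSV, and for real hmmscan output
one substitutes the curated TIGRFAM accessions.

## 4. Per-site evolutionary rates

Functional constraint is proxied by per-residue evolutionary rate,
estimated from each gene-family alignment alone:

1. **Column mask.** Columns with fewer than 10% ungapped residues are
   excluded (strict `<`; a column at exactly 10% stays in).
2. **Distances.** For each sequence pair, over sites where both carry a
   standard residue, the mismatch fraction $p$ is corrected for
   multiple hits by the 20-state Poisson formula
   $d = -\tfrac{19}{20}\ln(1 - \tfrac{20}{19}p)$ — the standard protein
   analogue of the nucleotide correction used for tree search by the
   reference tooling. The correction diverges at $p = 0.95$; such pairs
   saturate at a configurable ceiling (default 10 substitutions/site)
   with a warning.
3. **Tree.** Saitou–Nei neighbor joining on that matrix; NJ's
   occasional negative branch lengths are clamped to zero, and with no
   branch-length optimization the NJ lengths are final.
4. **Substitution model.** The JTT amino-acid model, embedded as the
   standard published exchangeabilities and equilibrium frequencies and
   rescaled to one expected substitution per site per unit branch
   length. Transition matrices come from the
   $\pi$-symmetrized eigendecomposition (computed once and cached), so
   $P(t, r) = e^{Qrt}$ is cheap for any branch length and rate.
5. **Rate prior.** A mean-one discrete gamma with $K$ equal-probability
   categories, category rates equal to the conditional means of the
   inter-quantile slices. The reference method says only that rates are
   estimated by empirical Bayesian inference; the discrete-gamma
   construction with $K = 16$ is the established way to realize that
   and is our documented choice. The shape $\alpha$ is estimated by
   maximizing the marginal likelihood over a default grid of 25
   log-spaced points in $[0.1, 5]$ (a boundary maximum warns), or fixed
   via config.
6. **Posterior mean rates.** Column likelihoods under each category
   rate come from Felsenstein pruning with gaps and ambiguity codes as
   missing data (all-ones partials) and the root placed at an arbitrary
   internal node — immaterial under a reversible model. The posterior
   mean $\hat r_s = \sum_k r_k p_k L_s(r_k) / \sum_k p_k L_s(r_k)$ is
   computed in log space throughout, with per-edge positive rescaling
   of the partials, so category-likelihood underflow cannot occur even
   on hundreds of taxa.
7. **Normalization and classes.** Rates are z-scored over included
   columns using the population (1/n) standard deviation — so mean 0,
   sd 1 exactly, and two columns normalize to $\pm 1$. Sites with
   $z \le -0.75$ are slow, $z \ge +0.75$ fast, boundaries inclusive
   ("as a cutoff for" read inclusively; both cutoffs are config keys).
   A zero-variance profile maps to all-zero scores rather than NaN.

Each ungapped position of a sequence inherits its column's class;
positions in masked columns are unclassified and excluded from masked
$N_c$. Classes are computed per column and mapped to sequences (whether
the reference computed against a designated query instead is unstated;
per-column is the symmetric choice).

## 5. Statistics

The test unit is the **per-sequence** $N_c$ (possibly masked to a
domain or rate class): sequences are the closer-to-independent sampling
unit, and the reference figures report both sequence and site counts
without fixing the unit — site-level values remain available through
the masked scorer. The default alternative is one-sided, "open ocean is
nitrogen-poorer"; pathway-wide scans use the two-sided variant,
mirroring how each figure-style analysis is captioned.

`wilcoxon_rank_sum()` offers three inference routes: exact enumeration
of all $\binom{m+n}{m}$ rank assignments (combined $n \le 20$;
reproduces the classical exact test on tie-free data and handles ties
through midranks), the normal approximation with tie and continuity
corrections, and Monte-Carlo label permutation with the add-one
estimator $p = (1 + \#\text{extreme})/(1 + B)$ — the "approximative"
test of the reference framework. No multiple-testing correction is
applied anywhere, matching the reference analysis; `p.adjust` can of
course be applied to any report table.

## 6. The synthetic generator

`generate_study()` writes a complete labeled study — FASTA, metadata
TSV, Phobius text, HMMER-style hit table with cutoffs, per-gene aligned
FASTA + Newick trees, truth TSVs and a YAML manifest — with every
stochastic stage seeded from one master seed through named substreams
(`substream_seed`), making regeneration byte-identical.

What it emulates, and how the defaults were chosen:

* **Habitat effect.** The open-ocean amino-acid profile multiplies the
  frequencies of the six N-bearing residues by a common tilt factor,
  found by bisection so the relative difference in expected $N_c$ hits
  the target within $10^{-6}$. Default target: **−5%**, the center of
  the 4–7% range the overall contrast is expected to show. Baseline
  frequencies are the JTT equilibrium, for consistency with the
  evolution model.
* **Proteome composition.** Default 2000 non-membrane plus 270
  membrane proteins per habitat (≈ 12% membrane, the share typical of
  marine metagenomes), lengths uniform on 101–500 so everything passes
  the length filter by construction.
* **Membrane proteins.** Segmental assembly: loops from the habitat
  profile, TM helices (15–30 residues) from a hydrophobic profile that
  receives the same habitat tilt, optional signal peptides; the emitted
  Phobius line re-parses to the true annotation.
* **Gene families.** A Yule tree per gene (mean root-to-tip depth 1.0
  substitutions/site), i.i.d. mean-one gamma(0.7) site rates, root from
  $\pi$, descendants via $P(r t)$. After evolution, at designated sites
  (the top 20% of the true rate distribution), open-habitat tips swap
  N-bearing residues to serine with probability 0.05 — an expected −5%
  local $N_c$ deficit exactly where the biology predicts it. Alignments
  are generated gap-free; gap handling is exercised by hand-built
  fixtures instead.
* **Gene-family size: a power analysis.** Detecting a −5% deficit in
  masked $N_c$ is hard: per-site side-chain counts have variance
  ≈ 0.58 under JTT frequencies, so over $m$ fast sites the
  between-sequence standard deviation of masked $N_c$ is
  $\approx 0.76/\sqrt{m}$ against a shift of only
  $0.05 \times 0.356 \approx 0.018$. For a one-sided test at
  $\alpha = 0.05$ with 90% power this requires roughly
  $n \gtrsim 2(2.93)^2/d^2$ sequences per group with
  $d = 0.023\sqrt{m}$. The defaults — 160 sequences per habitat, 1600
  columns, 20% designated — give $m \approx 350$ classified-fast sites
  and a predicted power ≈ 0.95, confirmed by a 24-replicate pilot
  (observed: 96% fast-class detections, 4% slow-class false positives).
  Smaller designs are genuinely underpowered for a 5% effect.
* **Replicate analyses fix $\alpha = 1$.** Rate classes depend only on
  the rank structure of the posterior means, which is insensitive to
  the prior shape (rate recovery Spearman ≈ 0.99 at the default sizes
  whether the shape is estimated or fixed); grid estimation would
  multiply the cost of every replicate ~25-fold for no change in
  classification. Single-study runs default to estimating $\alpha$.

What it does **not** emulate: real metagenome read simulation, assembly
or gene calling; indel evolution; among-site compositional
heterogeneity beyond the rate mixture; phylogenetic structure in the
proteome samples (non-membrane proteins are i.i.d. draws). Passing
tests therefore demonstrate the correctness and calibration of the
machinery under the stated generative model, not that the magnitudes of
a real ocean-scale survey are reproduced — those require multi-gigabyte
peptide sets and external predictors, and are out of scope.

## 7. Numerical choices, degenerate inputs, limitations

* Likelihood rescaling uses per-column sums (any positive factor is
  valid) accumulated in log space; results match exact arithmetic to
  well below $10^{-10}$ on enumerable sizes.
* Transition-matrix entries can go negative at the $10^{-16}$ level
  from eigen roundoff; pruning clamps them to zero.
* Distance saturation (ceiling 10) keeps NJ defined when unrelated
  sequences meet; two-taxon trees are built directly with the distance
  split evenly.
* Ties in pathway assignment break lexicographically; ties in ranks use
  midranks with the tie-corrected normal variance.
* Degenerate cases are contracts, not crashes: zero-variance rate
  profiles give all-intermediate sites and an empty-class report with
  no test; a stratum with a zero coastal mean reports `NA` relative
  difference; groups under 2 sequences are refused with an error
  (or skipped with a warning in the per-gene scan).
* Known limitations: NJ topology error at low divergence propagates
  into rate estimates (mitigated by the empirical-Bayes averaging);
  the habitat contrast ignores phylogenetic non-independence between
  sequences, as did the reference analysis; the i.i.d. residue model
  understates the compositional autocorrelation of real proteins, so
  real-data variances will be somewhat larger than synthetic ones.

## 8. Problem sizes used by the test suite

Unit tests run on alignments of 8–40 taxa and ≤ 400 columns; the
acceptance properties use 40 taxa × 400 columns × 10 seeds for rate
recovery and 100 replicates of the default gene-family conditions
(320 taxa × 1600 columns) for localization power; the acceptance script
builds one full default study. These sizes were chosen as the smallest
at which the distributional claims above are adequately powered.
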