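---
title: "Methods: profiling male reproductive developmental toxicity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: profiling male reproductive developmental toxicity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repromine)
```

# Scope and data model

`repromine` joins two evidence streams about a chemical's effect on the
developing male reproductive system:

* **In vivo**: animal-study endpoint tables, one row per chemical x study x
  endpoint observation with a lowest effect level (LEL, mg/kg/day). The
  controlled vocabulary covers 23 endpoint terms in five categories --
  malformations, testicular tumors, sperm effects, histological effects,
  and relative weight change in male reproductive organs.
* **In vitro**: high-throughput screening concentration-response series,
  one per chemical x assay, with an assay-to-gene map and a designated
  cytotoxicity assay panel.

The two streams meet in a weighted bipartite network connecting chemicals
flagged for male reproductive developmental toxicity (MRDT) to the
molecular targets on which they show selective bioactivity.

# In vivo profiling

## MRDT definition

A chemical is MRDT when it produces any male reproductive malformation, or
when a sperm, histological or organ-weight effect is observed *exclusively*
in developmental contexts. A developmental context is a prenatal
developmental or generational (one-/multigeneration) study type, or an
F-generation evaluation inside any study; adult-only subchronic/chronic
observations are nondevelopmental. An effect seen in both contexts gives no
credit: the adult observation could explain the finding without a
developmental etiology. Tumors never confer MRDT (the tumor types
detectable in these study designs arise from somatic mutation, typically
later in life). Positivity is dose-independent and inclusive across
studies: one positive study makes the chemical positive for that endpoint
even if comparable studies were negative. Flags derived from the database
can be unioned with a curated literature flag table
(`merge_literature_flags()`), with provenance recorded per chemical.

## cLEL aggregation, imputation, effect scores

The category LEL (cLEL) is the minimum LEL over all of a chemical's records
mapping into a category, across studies and subendpoints -- the natural
reading of "lowest effect level" at category granularity. Only the four
MRDT-relevant categories enter the potency matrix; tumors are tracked for
co-occurrence but not scored.

Missing cells are imputed at 10 times the chemical's highest observed cLEL.
The imputed value asserts no predicted effect; it completes the matrix for
clustering across a hypothetical syndrome, one decade beyond the doses at
which anything was seen. The `imputed` mask is carried alongside so
downstream consumers can distinguish observation from completion.

The effect score linearizes potency: each cell's cLEL becomes
$v = -\log_{10}(\mathrm{cLEL})$ and the whole matrix is min-max normalized
to $[0, 100]$, so 100 marks the most potent chemical-category pair and 0
the least potent. The normalization range includes imputed cells by
default, because the completed matrix is what gets clustered; with
`include_imputed = FALSE` the range anchors on observed cells and imputed
scores are clamped to the scale. A fully degenerate matrix (all cLELs
equal) scores all zero with a warning rather than failing -- there is no
potency contrast to express.

## Co-occurrence, concordance, clustering

`cooccurrence_summary()` counts positive chemicals per category under set
semantics (duplicated records cannot inflate counts), reports percentages
of the positive universe at two significant figures (the convention in
which 18 of 281 prints as 6.4%), tallies pairwise co-occurrence, and ranks
chemicals by association with the least common category first -- the
ordering that displays the phenotypic hierarchy. The logarithmic display
grouping seen in published co-occurrence figures is presentation, not
computation; the computed artifact is the ordering key plus the counts.

Concordance between strata (mouse vs rat species, parental P1 vs filial F1
generations) is the Pearson correlation of per-subendpoint
positive-chemical counts, taken over the 15 sperm + histology + weight
subendpoints when reproducing the published table (malformations and
tumors are generation-specific by design and carry NA cells).

Hierarchical clustering uses Euclidean distance with Ward's minimum
variance linkage in the "ward.D2" convention (Lance-Williams update on
squared Euclidean distances). The dialect matters only for branch heights,
not merge order, and ward.D2 is the variant that reproduces Ward's
criterion exactly on Euclidean input; the merge tree is exported as Newick
with merge heights as branch lengths, plus the deterministic leaf order
for heat-map display.

# In vitro scoring

## Concentration-response models

Three candidate models are fitted per series by bounded least squares:

* constant (baseline only),
* Hill: $y = \mathrm{top} / (1 + 10^{s(\mu - \log_{10} c)})$ with
  $\mu = \log_{10} \mathrm{AC}_{50}$,
* gain-loss: $y = \mathrm{top} \cdot g(c)\,(1 - l(c))$, an ascending gain
  gate times the complement of a descending loss gate sharing one
  amplitude -- the shape of responses quenched at cytotoxic
  concentrations. The loss AC50 is parameterized as gain AC50 plus a
  strictly positive log10 gap, so the loss phase provably sits above the
  gain phase.

The parameter box is: AC50 within two decades of the tested range, slope
in (0, 10], amplitude in [0, 1.2 x observed maximum response]. Fitting is
fully deterministic: a fixed coarse grid over (AC50, slope) -- with the
amplitude profiled analytically -- locates candidate basins, and the best
grid points are refined by L-BFGS-B with analytic gradients (finite
differences stall in the narrow correlated valley of amplitude x AC50 x
slope). No random initialization is used anywhere.

One identifiability caveat follows from the amplitude bound: when a curve
does not approach its plateau inside the tested range, the admissible box
truncates below the true asymptote, and the constrained optimum carries
AC50 bias. Recovery guarantees in the test suite therefore plant curves
whose AC50 sits far enough below the top tested concentration to
saturate; boundary curves are still detected as hits but their potency
estimate is a lower-confidence extrapolation, exactly as in real screening
data.

Model selection uses AICc on the least-squares likelihood,
$n \log(\mathrm{RSS}/n) + 2k + 2k(k+1)/(n-k-1)$, with $k$ the number of
mean-model parameters, ties resolved toward fewer parameters. Counting the
error variance in $k$ as well would make the 5-parameter gain-loss model
unselectable on an 8-point half-log series (its correction term alone
exceeds 80), so the lighter count is the one compatible with short
screening series; the constant model still wins comfortably on pure noise.

A **hit** is a series whose winning model is Hill or gain-loss *and* whose
modeled maximum over the tested range exceeds the critical response
threshold (default 20 on a 0-100 normalized scale; the threshold is a
required configuration value, not an estimate). Gain-loss hits report the
gain-phase AC50.

## Cytotoxicity-adjusted Z and gene scores

Nonspecific activity clusters near a chemical's cytotoxic concentration
(the "burst"). For each chemical $X$ with at least two hits on the
cytotoxicity panel, $m(X)$ is the median of the hit $\log_{10}
\mathrm{AC}_{50}$ values and the raw MAD (no 1.4826 consistency constant
-- the plain median absolute deviation) measures the burst's spread. With
fewer than two cytotoxicity hits, $m(X) = 3$: cytotoxicity is assumed at
1000 uM, the conventional anchor for "not cytotoxic in the tested range",
and no MAD is defined. $M_{\mathrm{global}}$ is the median of the defined
per-chemical MADs.

Each hit is standardized as
$$Z(X, A) = \frac{m(X) - \log_{10} \mathrm{AC}_{50}(X, A)}{M_{\mathrm{global}}},$$
the number of population-scale MAD units by which the hit's potency lies
*below* the chemical's cytotoxicity. Large $Z$ marks selective
bioactivity; $Z \approx 0$ marks hits riding the burst. The orientation
follows from the requirement that selective (sub-cytotoxic) activity score
high. $Z$ is invariant to a potency shift of the whole chemical: the
median shifts with the data and the MAD does not move.

The gene score condenses assay-level evidence:
$G(X, g)$ is by default the **maximum** $Z$ over the hit assays among the
assays mapped to gene $g$ -- conservative, provenance-preserving (the
contributing assay and its $Z$ are retained), and invariant to assay
duplication. A mean-over-hit-assays variant sits behind
`aggregation = "mean"` for sensitivity analysis; no downstream result in
this package depends on the choice. A pair with no hit among its mapped
assays has no score, which is what excludes most cytotoxicity-driven hits
while letting borderline cases through at the network-building threshold.
The modified gene score $G' = 10^{-G}$ re-expresses selectivity on a
micromolar-equivalent scale.

# Network assembly

`build_network()` draws one directed edge per chemical x gene pair with a
present gene score at or above `z_threshold`, weighting the edge by $G$
itself (linear in the score; published practice states proportionality
only). The default threshold 0 requires activity at or below cytotoxic
potency while keeping borderline cases. Gene nodes carry mode-of-action
class labels from an annotation table (functional-annotation enrichment is
an input here, not a computation); unannotated genes are labeled
`unmapped` and reported. Degree and strength summaries quantify
promiscuity per side. The layout is a seeded Fruchterman-Reingold
embedding: deterministic for a fixed seed, asserted only to place
connected nodes closer than random pairs -- no equivalence to any
published figure's geometry is claimed. Export goes to GraphML (igraph's
writer) and GEXF (a hand-rolled xml2 emitter, since igraph has no GEXF
support), both round-tripping node identities, weights, labels and
coordinates.

# The synthetic-data generator

The generator exists so that every pipeline stage is testable with planted
ground truth and no database access.

**In vivo** (`simulate_invivo()`): category positives follow a ladder of
marginal probabilities, default 0.80 / 0.45 / 0.20 / 0.10 / 0.06 for
weight ≥ histology ≥ sperm ≥ tumor ≥ malformation -- chosen to mimic the
broken phenotypic hierarchy observed in the real database (81/45/21/11/6.4
percent of positive chemicals). Nesting is generated by a coupling
construction: with probability equal to the nesting coefficient (default
0.9) a chemical draws all five categories from one shared uniform, which
makes its positives perfectly hierarchical; otherwise draws are
independent. Either way the marginal frequency of each category equals the
configured ladder exactly, so nesting strength and prevalence are
independently tunable. Each positive category receives a log-normal true
cLEL (defaults centered near 40-100 mg/kg/day, log10 SD 0.5, in the range
of reported mean cLELs) and an exposure context
(developmental-only / nondevelopmental-only / both, default 0.3/0.5/0.2);
records realize those assignments with the defining record carrying the
true cLEL exactly and satellite records at equal-or-higher doses, so
minimum-aggregation recovers the planted value to machine precision. True
MRDT status follows the same rule the profiler applies, which is what
makes the end-to-end confusion matrix an honest identity check of the
record realization rather than a tautology on the labels.

**In vitro** (`simulate_assays()`): a universe of 50 chemicals x 20 genes
(2 assays per gene) plus a 37-assay cytotoxicity panel, on one shared
8-point half-log grid from 0.01 to ~32 uM. Cytotoxic chemicals (90%) get a
log-normal burst location (log10 AC50 ~ N(1.0, 0.3), i.e. around 10 uM)
around which their cytotoxicity panel responds with within-chemical spread
0.2 log10 units. Planted selective pairs respond two decades below the
chemical's burst; a burst fraction of non-selective pairs responds *at*
the burst, providing the cytotoxicity-driven foil that the Z-score must
reject. Response amplitudes are 80 +/- 10 (clipped to [30, 100]) and
Gaussian response noise has SD 5 response units -- a noise level at which
single-series fits are visibly noisy but planted parameters remain
recoverable, comparable to normalized screening data.

What the generator does **not** emulate: per-assay concentration grids
(real screens vary them), plate artifacts and replicate structure,
chemical structure or class correlations, curation noise in literature
flags, and non-Hill response shapes. Passing recovery tests therefore
demonstrates correctness of the statistical machinery under the stated
generative model, not performance on raw screening data.

# Numerical conventions and degenerate inputs

* Medians of even-sized sets are the mean of the two middle values; MADs
  are raw (no consistency constant).
* All concentrations are uM and all logarithms base 10; doses are
  mg/kg/day.
* Clustering tie-breaks follow lowest item index; leaf order is
  deterministic for a given input.
* Degenerate effect-score matrices warn and return zeros; imputation on a
  chemical with no observed category is an error; a cytotoxicity scale is
  undefined (error) when no chemical has two cytotoxicity hits -- the
  pipeline runner degrades this to empty gene scores with a warning.
* The test suite's problem sizes -- 1,000 random matrices for the
  effect-score properties, 200 seeded series against dense grid oracles,
  1,000 chemicals for Z shift-invariance, the default 50 x 20 universe for
  selectivity recovery -- were chosen as the smallest sizes at which the
  properties are convincingly exercised.

# Known limitations

* LELs are taken as given; no in vivo dose-response modeling is attempted,
  and no real database dumps are parsed beyond the simplified schema.
* The gene-score aggregation body (max vs mean over hit assays) is a
  genuine design choice; max is the default for its provenance and
  robustness properties, and both are exposed.
* AC50 estimates for curves without an in-range plateau are
  bound-constrained extrapolations (see above).
* The force-directed layout is a generic embedding; published network
  figures used a different algorithm and will not be geometrically
  reproduced.
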