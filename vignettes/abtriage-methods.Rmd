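---
title: "Methods: how abtriage screens antibody libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: how abtriage screens antibody libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Therapeutic monoclonal antibodies fail late and expensively when their
*developability* is poor: aggregation, low thermostability, charge extremes,
immunogenicity. Repertoire sequencing now yields libraries of 10^4--10^5
paired heavy/light (V~H~/V~L~) variable-domain sequences, far more than can
be assessed experimentally. `abtriage` implements a two-layer triage: cheap
sequence statistics remove obvious outliers, then an unsupervised gate keeps
antibodies whose encoded sequences cluster with clinical-stage antibodies,
and finally a supervised classifier scores the survivors for resemblance to
market-approved (rather than discontinued) therapeutics.

The stages run in a fixed order -- filtering before numbering-heavy encoding
is what makes the pipeline cheap per sequence -- and each stage has a
stringency knob: a Z-score for the physicochemical filter, a Z-score (or
`"all"`) for the Layer-1 ellipse, and a probability threshold for Layer 2.

## Numbering and the fixed grids

All downstream machinery assumes every V~H~ maps onto a fixed list of 132
Chothia position labels and every V~L~ onto 122. The scheme's base positions
do not add up to those counts, and no canonical enumeration of the insertion
slots exists, so the package fixes one convention and ships it as data:

* heavy: H1..H113 plus H31A--B, H52A--C, H82A--C and H100A--K (113 + 19 = 132);
* light: L1..L107 plus L30A--G, L95A--G and L106A (107 + 15 = 122).

The slot counts are asserted when the grids load. A consequence worth
knowing: CDR-H3 (window H95--H102, insertions included) can hold at most 19
residues on this grid; longer loops are rejected as `GridOverflow` rather
than silently truncated, because truncation would corrupt every downstream
encoding.

Numbering itself is deterministic template alignment: the query is globally
aligned (BLOSUM62, gap open 25, extension 1) against a packaged full-grid
consensus -- one residue per slot, built from canonical human germline
sequences (an IGHV3-23/JH4-like heavy domain, IGKV1-39/JK1 kappa and
IGLV2-14/JL2 lambda light domains) with filler residues in the insertion
slots the germlines do not use. Light chains are aligned against both light
consensi and keep the better score, which is also how the kappa/lambda typer
works (framework-only identity, CDRs excluded, ties to kappa). After label
transfer, each CDR window is *repacked*: all residues landing in or
immediately adjacent to the window are reassigned in sequence order to the
window's slots -- base slots first, the post-insertion framework-side slots
filled from the loop's far end, sanctioned insertion letters absorbing the
middle. This reproduces the numbering convention (a 14-residue lambda CDR-L1
occupies L24--L30, L30A--C, L31--L34) and makes loop lengths independent of
where the aligner happened to open gaps inside a hypervariable window. Two
hard gates apply: sequence length must be in [70, 150], and the conserved
cysteines (H22/H92, L23/L88) must be present.

The high gap penalties are deliberate: with cheap gaps the aligner sometimes
"explains" a random CDR-H3 by a balanced insertion/deletion pair instead of
mismatches, which would spill loop residues off the grid. With open 25 the
only insertions that survive are structurally forced ones, and those are
exactly the `GridOverflow` cases.

## Physicochemical filtering

Five features are computed per pair, and a record passes when every active
feature lies within Z (default 2) sample standard deviations of a reference
set's mean -- by default the approved-antibody reference:

* **CDR-H3 length**: residues in H95--H102, insertions included.
* **Unfolding free energy** (V~H~, V~L~, and the two chains concatenated
  directly, no linker): a strictly additive per-residue model, the sum of
  `dH_i - T * dS_i` at T = 298.15 K. The shipped constants file is a
  **labelled synthetic stand-in** with the model's structure and a realistic
  spread; the experimentally derived tabulation is not redistributable, so
  absolute `dG` values from the default install should not be compared with
  published numbers (replace `inst/extdata/thermo_unfolding_synthetic.csv`,
  same schema, to do that). Every test of this module checks the additive
  contract against an independent summation oracle, which is valid for any
  table.
* **Mean isoelectric point**: the arithmetic mean of the two chains' pI
  values ("mean pI of V~H~/V~L~" is ambiguous between mean-of-pIs and
  pI-of-concatenation; the former is the default, the latter is available
  via `method = "concat"`). pI uses the EMBOSS pKa set in a
  Henderson-Hasselbalch charge sum. The published procedure iterates pH from
  6.5 until |net charge| <= 0.01; implemented as a guarded bisection on
  (0, 14) seeded at 6.5, which honours the same stopping contract but also
  converges to the charge-neutral pH itself -- for short peptides the raw
  |charge| <= 0.01 rule can stop 0.4 pH units from the true root, and the
  package promises agreement with a 0.001-step grid scan to within 0.01 pH.

A hard rule independent of Z: any chain with more than two cysteines is
excluded (the two conserved ones are expected; extras are an aggregation
liability). The rule is applied per chain by default since a normal variable
domain has exactly two; a CDR-H3-only scope is available.

Group comparisons use a two-tailed unpaired Mann-Whitney U test: exact
enumeration of the U distribution when the combined sample size is at most
12, otherwise the normal approximation with midrank ties, tie-corrected
variance and continuity correction (matching `wilcox.test` in both regimes,
which the tests verify).

## Encoding

A padded pair becomes one numeric vector: heavy grid then light grid,
position-major, `dim` channels per slot -- so a position-wise encoder with
per-residue dimension 512 yields (132 + 122) x 512 = 130,048 features, the
layout contract asserted for the AntiBERTy-style adapter. Published encoder
adapters are registry entries with their measured totals and padding
characters (`_`, `*`, `*`, `X`); their weights cannot ship, so requesting
one raises `AdapterUnavailable`, and nothing downstream depends on them.
The reported totals of the Sapiens- and ESM-style encoders are not integer
multiples of 254, so adapters declare measured totals rather than assuming
the position-wise formula.

All tests run on the **mock encoder**: one frozen embedding vector per
(slot, residue) drawn from a seeded generator, pad slots mapping to zero.
It is deterministic across processes, local (one residue change moves only
that slot's channels), and dimension-flexible, which is exactly what the
contracts need; it knows nothing about antibody biology, which is why no
test asserts biological signal in its embeddings.

## Layer 1: kernel PCA and the ellipse gate

The gate fits rbf kernel PCA (K~ij~ = exp(-γ ||x~i~ - x~j~||²), double-centred,
two components; eigenvalues must exceed 1e-12 of the leading one or the fit
aborts as `DegenerateKernel`; each component's largest-magnitude loading is
made positive for stable orientation). By default the fit set is library +
clinical + query, following the published protocol of projecting the test
data together with the reference sets; `frozen_fit` restricts the fit to
library + clinical, which makes repeated gating reproducible and monotone
across reruns at the cost of deviating from that protocol. γ defaults to
1/n_features at fit time; the published value of 500 was selected on real
language-model encodings and is meaningful only at that data scale.

The capture region is a rotated ellipse built from the clinical projections.
The component with the greater clinical range is the major axis. For numeric
Z, the endpoints are the two clinical points whose major-axis coordinates
are closest to mean ± Z·sd, the minor height is h = 2·Z·sd of the minor
coordinate, and the ellipse follows from the endpoints: major radius
a = |p2 - p1|/2, minor radius b = h/2, rotation θ = atan2(Δy, Δx), centre at
the midpoint. For `z = "all"` the endpoints are the extreme clinical points
and h grows to the smallest value that captures *every* clinical point --
that is the published definition of the "All" setting, and the property the
tests assert; the naive "full minor range" reading does not guarantee it.

Two deliberate deviations, both documented here because the source is
ambiguous: (1) containment is analytic -- translate by the centre, rotate by
-θ, test (x/a)² + (y/b)² <= 1 with the boundary inside -- rather than the
100-vertex polygon approximation used originally; the polygon is retained as
`ellipse_polygon()` and serves as the independent containment oracle in the
tests (agreement >= 99.9% away from the boundary). (2) The minor height uses
the moment-based sd, not "equivalent points" on the minor axis, which are
not well defined. Additionally, because data-point endpoints jitter the
ellipse's centre and rotation between Z levels, retained sets at increasing
Z are only *approximately* nested under the published endpoint rule; an
`endpoints = "moment"` mode places idealised on-axis endpoints at exactly
mean ± Z·sd, under which nesting is exact -- that mode is what the
monotonicity property test uses.

## Layer 2: approved versus discontinued

Features are ranked by univariate F-regression -- F = r²(n-2)/(1-r²) from
each feature's correlation with the binary labels, p from F(1, n-2),
constants ranked last, perfect correlates first, ties broken by index --
and the top k (default 2500) are kept. The classifier is a linear
squared-hinge margin model (a LinearSVC analogue, fitted by BFGS with
analytic gradients; ridge and logistic variants are available), on
internally standardised features. Because a margin classifier has no native
probability, decision scores are mapped through Platt's sigmoid with
smoothed targets, fitted on the training scores; this gives the 0.5 and 0.8
decision thresholds consistent semantics across classifier kinds. The
positive class is "approved".

Cross-validation is stratified, seeded, 10-fold by default, scored by MCC
(with the 0-on-degenerate-denominator convention), sensitivity and
specificity. Feature selection is refit inside every training fold; the
out-of-fold variant exists only behind an explicit flag because it is the
classic leakage pitfall -- on pure noise it manufactures near-perfect CV
scores, which the regression test demonstrates. Selected feature indices map
back to (chain, grid slot) through the encoder layout, giving the
feature-location histograms used to ask *where* in the sequence the signal
lives.

## The synthetic world

Everything is testable offline because the generators state a world and
stick to it:

* **Repertoires** are built on the packaged germline templates. CDR-H3
  lengths follow a discretised normal with mean 12.1 and sd 6.65 (the
  clinical-set values), truncated to [5, 19] -- 19 because that is the
  grid's window capacity; a wider truncation would contradict the promise
  that every generated record numbers cleanly. Framework positions mutate
  independently at 2% (a typical somatic-hypermutation load), never touching
  template cysteines or tryptophans, so anchors survive. Light chains are
  kappa with probability 0.6. Loop residues exclude cysteine (rare there in
  nature, and it keeps the cysteine rule orthogonal).
* **Embedding clouds** emulate the geometry the gate assumes: a compact
  isotropic reference cluster (sd r_ref) inside a background shell with
  radii uniform on (r_ref, r_bg), r_bg = 10·r_ref by default. The default
  dimension is 2 because the emulated structure is the *projected* radial
  pattern; in higher dimensions a 2-component projection dilutes radial
  contrast -- a property of the emulation, not of the pipeline. Gate checks
  on clouds set γ = 1/(2·r_bg²), the near-linear regime that preserves the
  radial ordering; large γ makes all distant points mutually invisible to
  the kernel and collapses the background toward the reference cluster.
* **Labelled features** plant k class-shifted Gaussian columns (standardised
  effect size as stated) among pure noise, returning the ground-truth
  indices for recovery tests.

What a green suite establishes: the numeric contracts (numbering round-trip,
grid layout, additivity, oracle agreement for kernel PCA / containment /
F-ranking / MCC / pI, recovery and null behaviour, stage monotonicity and
report consistency). What it does not establish: that the pipeline's
*biological* discrimination reproduces the published performance -- that
requires the real language-model encodings and the published sequence sets,
neither of which can ship with the package. The three acceptance tests that
reproduce published sequence statistics are implemented and run the moment
the supplementary tables are placed under `inst/extdata/supplementary/`;
until then they fail with an explanatory message by design. Null-control
and planted-recovery simulations in the default test run use 5--10 seeds
rather than 20 to stay inside the suite's time budget; the assertions are
unchanged.

## Numerical choices and edge cases

* Kernel PCA eigendecomposition: `eigen(symmetric = TRUE)`; components with
  eigenvalue below 1e-12 of the leading eigenvalue are rank-deficient.
* Ellipse: `z = 0` or coincident endpoints raise `DegenerateEllipse`;
  collinear references (zero minor spread) likewise. The boundary counts as
  inside, with a 1e-9 relative slack against floating-point ties.
* pI bisection: at most 200 iterations, interval refined below 1e-3 pH;
  non-convergence is an error, not a silent return.
* Mann-Whitney exact/approximate crossover at combined n = 12.
* Ridge uses a closed form; logistic tolerates separation (capped
  iterations); the margin model starts from zero weights, so all three are
  deterministic given the data.
* Library subsampling for the kernel fit (above `max_library` rows) and CV
  fold assignment draw from seeded substreams of the pipeline seed; reports
  echo the seed.

## Limitations

* The numbering backend is template alignment against packaged consensi; it
  is exact on the fixtures and robust to point mutations, but it is not a
  full profile-based numbering service, and unusual frameworks (camelid,
  heavily engineered) may fail the anchor gates.
* The shipped thermodynamic constants are synthetic stand-ins (see above).
* Only the linear-margin, ridge and logistic classifiers are implemented;
  the wider classifier sweep in the source work is out of scope.
* TAP scores, humanness scores and germline-gene assignment beyond the
  kappa/lambda typer are external tools and out of scope.
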