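---
title: "Guttman error maps: model, weighting and rendering choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Guttman error maps: model, weighting and rendering choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(guttmap)
```

## The model

A scale of k items measuring one construct is *scalable* in the Guttman
sense when the items form a cumulative hierarchy: endorsing a rarer
(higher-intensity) item implies endorsing every more common one. For a
dichotomous item pair ordered by endorsement, $p_a \ge p_b$, a respondent
with $X_a = 0, X_b = 1$ commits a Guttman error. `guttmap` quantifies these
errors relative to chance:

$$e_{ab} \;=\; \frac{F_{ab}}{E_{ab}}, \qquad
  F_{ab} = \sum_i w_i\,[X_{ia}=0][X_{ib}=1], \qquad
  E_{ab} = n_{\mathrm{eff}}\,(1-p_a)\,p_b,$$

with $n_{\mathrm{eff}} = \sum_i w_i$ and all proportions weighted. $E$ is
the error mass expected if the two items were statistically independent at
their observed margins, so $e = 0$ means a perfect pairwise hierarchy,
$e = 1$ (100 %) means "no better than independence", and $e > 1$ a reversed
hierarchy. Loevinger's coefficients are the complements,
$h_{ab} = 1 - e_{ab}$, aggregated as ratios of sums:
$h_i = 1 - \sum_j F_{ij} / \sum_j E_{ij}$ and
$H = 1 - \sum\sum F / \sum\sum E$ over unordered pairs. An equivalent form
used as the independent oracle in the test suite is
$h_{ab} = \mathrm{cov}(X_a, X_b) / \mathrm{cov}_{\max}$, where
$\mathrm{cov}_{\max} = p_b(1-p_a)$ is the covariance the pair would attain
under a perfect hierarchy with the same margins; the two agree to machine
precision by construction.

### Polytomous items

Items with $m+1$ ordered categories are decomposed into their *item steps*,
the indicators $X_j \ge s$ for $s = 1..m$. Every step pair of an item pair
contributes one observed-error count and one independence expectation, with
the more popular step of the pair playing the easy role, and $F$, $E$ are
summed over step pairs before forming $e$. Two properties pin this choice
down: with all items dichotomous it reduces exactly to the rule above, and
the summed form again satisfies the covariance identity
($\sum E - \sum F = n\,\mathrm{cov}$, $\sum E = n\,\mathrm{cov}_{\max}$ with
the comonotone maximum). Popularity ties between steps are resolved in
favour of the item earlier in the display ordering; the value of $e$ is
invariant to that resolution (both orientations give
$E - F = n\,\mathrm{cov}$).

### Degenerate pairs

An item endorsed by everyone or no one makes $E = 0$ for its pairs. Such
pairs are reported as *undefined* — blank cells, never a silent zero — and
are excluded from the $h_i$ and $H$ sums with a warning.

## Item ordering

Items are displayed left-to-right (and top-to-bottom) by decreasing
endorsement, the rarest — most intense — item last, so errors grow toward
the corner cells and fade with distance from the empty diagonal. Ties are
broken by input position (a stable sort), so re-running the same data gives
the same axes. `item_order = "custom"` bypasses the sort, which is useful
when several versions of a scale must share one layout. The ordering only
arranges the display and fixes each pair's easy/hard orientation; $e$ is
symmetric either way.

## Survey weights

Weighted data are supported through an integer internal weight:

$$sw_1 = \mathrm{round}\!\left(\frac{sw_{\mathrm{orig}} \cdot s}
  {sw_{\min}}\right),$$

where $sw_{\min}$ is the smallest original weight and $s$ (`scl`, default
1) a user scaling factor. Dividing by the minimum makes every observation
map to at least $\mathrm{round}(s)$ copies — naive rounding of raw weights
below 0.5 would silently drop observations — while $s$ controls how much of
the relative-weight resolution survives integer rounding (as
$s \to \infty$, $sw_1[i]/sw_1[j] \to sw_{\mathrm{orig}}[i]/
sw_{\mathrm{orig}}[j]$). Rounding is to the nearest integer with halves
away from zero; the transform is invariant to rescaling all weights by a
positive constant. `weight_diagnostics()` (the `sclmsg` output) reports the
ranges, the number of distinct integer weights and what naive rounding
would have lost, to guide the choice of `scl`.

Two equivalent engines consume $sw_1$. The default, `engine = "weighted"`,
counts with frequency weights directly — the error ratios depend only on
point estimates, so no expansion is needed. `engine = "expand"` replicates
row i $sw_1[i]$ times (capped at 5 × 10^6 rows by default) and counts
unweighted; it is retained because the expansion formulation defines the
procedure operationally and gives the test suite a second, independent
route. The suite verifies both engines agree to 1e-12 on every coefficient.

## Classification and colours

The error bands invert Mokken's h cutoffs into percentages: $e \le 50$ no
problems, $50 < e \le 60$ admissible with reservation, $60 < e \le 70$
borderline, $e > 70$ problematic. For coefficients, `classify_h()` uses
poor < 0.3 ≤ weak < 0.4 ≤ moderate < 0.5 ≤ strong; the published cutoffs
leave 0.5 itself unassigned ("0.4 to < 0.5", then "> 0.5") and we assign it
to *strong*, reading the intent as "0.5 and above". The two scales are
mutually consistent: band severity and h category agree in rank order
through $h = 1 - e/100$.

The colour gradient interpolates linearly (in RGB) between seven anchored
stops from green (0 %) through greenish-yellow (50 %), yellow (60 %) and
orange (70 %) to deep red (100 %); values above 100 % clamp to the deepest
red. The exact published palette RGBs are not recoverable from the source
figure, so the default stops are a documented approximation built from a
standard red–yellow–green diverging scheme; `band_scheme()` accepts any
replacement stops.

## Rendering and smoothing

The map is a square-cell ggplot2 heatmap drawn in both triangles with the
diagonal blank, annotated with `sprintf(valformat, e)` (default one
decimal; `valsize = 0` removes annotations entirely — the annotated numbers
always equal the matrix-report values under the same format). Font sizes
are passed to ggplot2 unchanged: title/axis sizes are point sizes and
`valsize` is the native `geom_text` size unit, matching the convention the
graphical defaults (18/12/12/3.5) were calibrated in.

`smooth` blends two value fields per pixel:

* `smooth = 0`: blockwise-constant — each pixel carries its cell's $e$;
* `smooth = 100`: bilinear interpolation of the cell-centre values, with
  the diagonal excluded from the interpolation support (corner weights are
  renormalised over the defined neighbours) and values clamped beyond the
  outer centres;
* intermediate $t$: the convex combination
  $(1 - t/100)\,\mathrm{discrete} + (t/100)\,\mathrm{continuous}$,
  computed in value space before colouring.

The blend definition for intermediate levels is this package's own choice;
a per-pixel convex combination was chosen because it is monotone in $t$ and
leaves both endpoints exactly as specified. Diagonal pixels are masked
after interpolation, so the empty diagonal survives every smoothing level.
Smoothing changes only the colour field, never the annotations. The
smoothed surface is drawn as small vector tiles (default 11 per cell side,
`res`), not as an embedded bitmap, which keeps SVG output byte-stable
across runs; repeated exports of the same figure are byte-identical.

Exports: SVG (default, convertible to editable objects downstream), PDF,
PNG, PS, JPG. Nothing is written unless a path is given. If the configured
font family is absent the graphics layer substitutes a default; a
`NULL`/`NA` family falls back to `"serif"` with a warning.

## Synthetic data

The generator suite produces all test inputs; none of it is a fixture on
disk.

* `generate_guttman(n, difficulties, error_rate, seed)` draws a latent
  trait uniform on (0, 1) and endorses item j iff the trait exceeds
  `difficulties[j]` — a deterministic scalogram — then flips each response
  independently with probability `error_rate`. The uniform latent model is
  the simplest one consistent with the scalogram definition; it is a
  documented, swappable choice. `error_rate = 0` yields $e \equiv 0$,
  $H = 1$ for every seed; `error_rate = 0.5` makes items independent of
  the trait, the independence limit where mean $e \to 100\%$.
* `emulate_dataset(rm, n_target, seed)` reproduces the three-step
  resampling used to publish confidentiality-preserving copies of real
  scales: adjust to `n_target` rows (trimming is interpreted as uniform
  random subsampling without replacement; expansion as resampling with
  replacement), then for each output row draw `n_target` candidates with
  replacement and select one uniformly. Steps 2–3 collapse to a single
  uniform draw; the literal procedure is implemented so it can be tested
  as stated, a `method = "direct"` shortcut is provided, and the suite
  verifies the two select base records from the same uniform distribution
  (chi-square goodness of fit, α = 0.01). Whole rows are resampled, so
  inter-item dependence — the overlap profile — is preserved in
  expectation.
* `generate_weights(n, low, high, seed)` draws log-uniform weights with
  the endpoints pinned into positions 1–2, so fixtures echo stated weight
  ranges exactly.

What the generators do *not* emulate: real scales have correlated,
item-specific error processes, differential item functioning, missing-data
mechanisms and clustered designs. Passing tests therefore demonstrate the
correctness of the computations under the stated models, not the
psychometric quality of any real instrument.

## Missing data and input validation

The missing-data policy is listwise deletion with a reported count — the
effective sample size printed under `obs = TRUE` refers to the analysed
rows. This is a deliberate, documented choice; no imputation is attempted.
Response codes must already be 0-based integers within each item's declared
range (dichotomous unless `n_categories` says otherwise); out-of-range
codes raise an error naming the row and item rather than being recoded.

## Problem sizes and numerical tolerances

The test suite checks the covariance identity on 500 random five-item
scales of n = 200 at 1e-12, engine equivalence on 100 weighted fixtures at
1e-12, the independence limit on twelve replicates of n = 50 000 within
three Monte-Carlo standard errors of 100 %, and the emulation margins over
200 seeds at n = 1000. These sizes were chosen to make sampling error
negligible relative to the assertions while keeping a full run in the tens
of seconds.

## Known limitations

* No standard errors or confidence intervals for the H coefficients, no
  automated item selection, and no monotonicity / invariant-item-ordering
  checks — the map is a descriptive diagnostic of point estimates.
* No design-based variance estimation: strata and PSUs are ignored beyond
  the weights themselves.
* A published worked example reports a transformed maximum of 2159 for
  weights 2.699–5828.684 at $s = 1$, while the printed formula gives
  round(2159.57) = 2160; this package follows the formula. The affected
  quantity is the maximum only; minima are unaffected.
* The colour palette is an approximation of the published legend, and
  colour-blind-safe alternatives must be supplied by the user via
  `band_scheme()`.
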