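---
title: "Methods: curve fitting, hit calling and potency estimation in concresp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: curve fitting, hit calling and potency estimation in concresp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(concresp)
```

## The modelling problem

Concentration–response screening tests a chemical sample against an assay
endpoint across a concentration range (typically 4–10 concentrations at
half-log spacing, 1–3 replicates) and asks two questions: is there a
concentration-dependent response (the hit call), and at what concentration
does it occur (potency)? `concresp` answers both from a single fitting
pass per series, bidirectionally — gain and loss of signal are handled by
the sign of the fitted scale parameter, so the same endpoint never needs
to be processed twice in mirrored directions.

## Error model and fitting

All models are fit by maximum likelihood under Student-t residuals with 4
degrees of freedom and scale $e^{er}$. The heavy-tailed likelihood keeps
single outlying wells — common in plate data — from dominating the fit.
The error parameter $er$ is estimated jointly with the shape parameters
and is counted in the AIC, $\mathrm{AIC} = 2k - 2\ell$.

Optimization is bounded quasi-Newton (L-BFGS-B) restarted from three
deterministic, data-derived starting points, so fits are exactly
reproducible with no random number use. Concentration-scale parameters
(`ga`, `la`, `b`) are optimized on $\log_{10}$ for conditioning. Box
bounds: `ga`, `la`, `b` within one decade beyond the tested range; powers
`p`, `q` in $[0.3, 8]$; $|tp|$, $|a|$ at most $12\times$ the largest
observed |response|; $er$ in $[-20, \log(\max|resp|) + 3]$. The lower
$er$ bound prevents a degenerate likelihood spike on exactly-replicated
responses. Under `gain_only`/`loss_only` the scale parameter is
constrained to the corresponding sign.

The gain–loss model's minimum width, $\log_{10}(la) - \log_{10}(ga) \ge
1.5$, is a hard constraint implemented by reparameterization
($la = ga \cdot 10^{1.5 + \delta}$, $\delta \ge 0$), chosen over a
penalty so fitted parameters can sit exactly on the boundary. Because the
width floor can push $la$ beyond the generic one-decade box, $la$
inherits its range from $ga$ and $\delta \le 5$ instead.

`poly2` is restricted to $b > 0$: negative $b$ creates non-monotone
shapes this model is not meant to describe, and the biphasic case is
already covered by `gnls`.

### Winner selection

The winner is the successful non-constant fit with the lowest AIC. The
constant model is always fit but can never win; its AIC feeds the hit
call. An exact AIC tie goes to the model with fewer parameters, and any
remaining tie to a fixed order (poly1, power, exp2, exp4, hill, exp3,
exp5, poly2, gnls) — arbitrary, but stable across runs. Series with fewer
than 4 distinct concentrations are not fit at all: winner `"none"`,
hit call 0.

The constant model is fixed at response $\equiv 0$ (its definition), not
at a fitted mean; normalized data are zero-centered by construction, and
a fitted-mean constant would absorb directional signal the AIC reference
should not absorb.

## The continuous hit call

The hit call is the product of three weights, each a confidence in
$[0,1]$; the published description of the pipeline states the three
criteria but not closed forms, so the forms below are fixed as this
package's definition and are tested against Monte-Carlo oracles:

* $w_{aic} = 1/(1 + e^{(\mathrm{AIC}_{win} - \mathrm{AIC}_{const})/2})$ —
  the two-model Akaike weight. A constant model better by 10 AIC forces
  $w_{aic} < 0.01$.
* $w_{median}$ — for each concentration group $i$ with $n_i$ replicates
  and observed median $m_i$, the two-sided tail probability
  $P(|m_i + s\,T_4/\sqrt{n_i}| > \mathrm{coff})$ with $s = e^{er}$;
  combined across concentrations as the maximum, not
  $1-\prod(1-p_i)$ — the two differ only in borderline cases, and the
  maximum keeps one clear exceedance from being diluted or double
  counted. The `v4.0_replicate` dialect scores each well individually
  ($n_i = 1$); the default `v4.1_median` dialect scores group medians.
  They coincide at one replicate per concentration.
* $w_{top}$ — a signed likelihood-root probability: refit the winner with
  its modeled |top| pinned at the cutoff (the scale parameter is solved
  from the constraint, all other parameters re-optimized), giving
  likelihood drop $\Lambda$; then $w_{top} = \Phi(\mathrm{sign}(|top| -
  \mathrm{coff})\sqrt{2\Lambda})$. At $|top| = \mathrm{coff}$ this is
  exactly 0.5, and it moves monotonically toward 0 or 1 as the evidence
  sharpens.

The product is binarized at 0.90 by default (user-settable); the
threshold reflects the strongly bimodal hit-call distributions seen in
screening practice.

## Baseline, cutoff and benchmark response

* BMAD: scaled median absolute deviation (consistency constant 1.4826,
  the conventional normal-consistent value) of baseline-representative
  responses, pooled across all samples of the endpoint. Baseline is
  either treatment wells at the two lowest concentration indices
  (default) or neutral-control wells. Pooling is per endpoint, not per
  plate; plate-level correction belongs upstream of this package.
* `onesd`: pooled sample SD of the same two-lowest-concentration wells;
  the benchmark response is fixed at $\mathrm{BMR} = 1.349 \times$
  `onesd` (the multiplier that corresponds to a ~10% tail shift for
  normal baseline noise). A neutral-control variant of the BMR is
  deliberately not a default.
* Cutoff: each assigned method yields a candidate — `bmad3` ($3\times$
  BMAD), `pc20` (20, percent scales), `fc1.2` ($\log_2 1.2$, for
  $\log_2$ fold-change endpoints; the "1.2 fold-change" phrasing is
  interpreted on the endpoint's own response scale as a declared unit
  dialect) — and the cutoff is the maximum over candidates.

## Potency estimates

Percent-of-maximum potencies (AC5/AC10/AC50/AC95) invert the winning
curve at fractions of its maximal response. For models with an asymptote
(hill, exp4, exp5: $tp$; gnls: the interior peak) the maximal response is
the asymptote, so the hill AC50 equals `ga` exactly and an AC95 can lie
beyond the tested range — which is exactly what the fit-category tree
uses to mark curves whose maximum activity was likely not observed. For
the unbounded monotone models the maximal response within the tested
range (the modeled top) anchors the percentages instead. The efficacy
comparisons in hit calling, fit categories and flags always use the
in-range top.

ACC inverts at the cutoff, ACB at $3\times$BMAD, BMD at the BMR. Root
finding runs on $\log_{10}$ concentration over a window extending beyond
the tested range (down to $c_{min}/10^4$, up to $100\,c_{max}$), so an
AC50 below the lowest tested concentration is representable; levels never
attained are reported absent rather than clamped.

### BMD confidence bounds

The 90% interval is profile likelihood: for a candidate BMD the winning
model is reparameterized so the scale parameter satisfies
$f(\mathrm{BMD}) = \pm\mathrm{BMR}$, all remaining parameters are
re-optimized, and a bound is where the profiled log-likelihood falls
$\chi^2_1(0.90)/2 \approx 1.3528$ below its maximum. The search walks
outward in 0.2-decade steps within $[c_{min}/100, 100\,c_{max}]$ and
brackets each crossing with a root finder; when no crossing is bracketed
(flat, very noisy series) the bound is absent, mirroring the practical
failure mode of such intervals.

Calibration: over 500 simulated exp4 series at the default design
($tp=50$, $ga=1$ µM, 8 concentrations from 0.03 µM at 0.5 log10 spacing,
3 replicates, t(4) noise scale 5), the acceptance script measures
empirical coverage near 89% against the nominal 90%. The BMR is estimated
per series from its own baseline wells, so the interval is conditional on
that benchmark response; coverage is therefore assessed against the true
curve's inverse at the same per-series BMR. Folding BMR-estimation noise
into the truth instead would test a quantity the interval is not designed
to cover.

## Fit categories

Curves split into cannot-determine (winner `"none"`), inactive
(hitc < 0.90; clear below $0.8\times$coff of modeled |top|, borderline at
or above — the boundary itself counts as borderline), and active.
Actives split on |top| $\le 1.2\times$coff (borderline) versus above
(moderate), then placed by potency: AC50 at or below the minimum tested
concentration (codes 36/40), else AC95 at or beyond the maximum tested
concentration (38/42), else both inside (37/41). The 36–42 codes are
conserved from the established numbering; the cannot-determine and two
inactive leaves have no published numbers, so the package assigns 2, 13
and 15 with the symbolic labels authoritative. An absent AC95 on an
active curve is treated as beyond the range. Comparisons use |top|, so
categories are invariant under response direction.

## Cautionary flags

Flags are pure annotations computed from the finished series record; they
never change a hit call or potency. Where the published one-line
descriptions leave thresholds open, the package fixes them as follows:
"baseline" for the single-point and multi-point flags is $3\times$BMAD
(consistent with the ACB default); `efficacy.50` uses 50 response units
on percent scales and $\log_2 1.5$ on $\log_2$ scales, selected by the
endpoint's declared scale; `modl.directionality.fail` fires when
concentration medians exceed $+\mathrm{coff}/2$ and $-\mathrm{coff}/2$ in
both directions (a documented heuristic for split-axis data);
`gnls.lowconc` compares the loss AC50 to the arithmetic mean of the
distinct tested concentrations.

## Cytotoxicity burst

The burst table is filtered to drop gain–loss winners and
cell-proliferation (gain-direction) rows, keeping only viability losses;
when the proliferation annotation is missing it is inferred from the sign
of the modeled top. Each chemical's burst point is the **median log10
AC50 over its active burst endpoints**, provided at least 3 qualify,
otherwise the 1000 µM default — the "median over assayed endpoints"
phrasing is read together with the 3-positive requirement, and both
thresholds (`min_active` for the point, `min_tested`/`min_hit_rate` for
the global MAD set) are exposed separately. The global MAD is the median
of per-chemical scaled MADs over chemicals tested in ≥ 60 burst endpoints
with an active hit rate above 5%; the lower bound is
median − 3 × global MAD. Active means hitc ≥ 0.90, configurable.

## The synthetic-data generator

`cr_sim_series()` emulates the screening design the pipeline targets:
8 concentrations from 0.03 µM at 0.5 log10 spacing, 3 replicates, t(4)
or normal noise, either response direction, fully reproducible under a
seed (default noise scale 5, a typical mid-single-digit percent-scale
baseline). `cr_sim_endpoint()` assembles multi-sample endpoint tables
(the two lowest concentration groups double as the baseline wells);
`cr_sim_burst()` plants per-chemical medians and dispersions for the
burst module. The generator does **not** emulate plate-position effects,
well-quality artifacts, concentration-index errors, or vendor-specific
normalizations — passing tests show the statistical machinery is correct
under the stated error model, not that real assay idiosyncrasies are
handled.

## Numerical choices and known limitations

* All root finding and profiling on $\log_{10}$ concentration; reported
  units are µM end to end.
* The gnls in-range top uses golden-section search seeded by a 100-point
  grid — robust and cheap for a single interior maximum.
* Exponential-model overflow is capped ($e^{z}$ at $z \le 700$) so the
  optimizer sees a finite, steeply penalized objective instead of `Inf`.
* Inversion of asymptotic curves within ~1% of the asymptote is
  ill-conditioned in double precision (the curve is numerically flat);
  tests therefore exercise the round-trip property away from that
  plateau.
* Model identifiability: with noise at 5% of top, the generating model
  stays within 2 AIC of the winner in ≈ 88–100% of series for
  poly1/power/hill/gnls/exp2/exp4/exp5 generators, but only ≈ 30% (poly2)
  and ≈ 66% (exp3), because power/exp2/exp5 rivals reproduce those shapes
  within noise. This is a property of the model family, not of the
  optimizer (truth-started refits change nothing); poly2/exp3 winners
  should be read as "curve shape of this class", not as mechanism.
* Test-suite problem sizes are chosen to exercise each property at
  adequate power while keeping the default run fast: 500 random series
  for winner-AIC minimality, 1000 draws for the inversion round trip,
  100 seeds per model for AC50 recovery (median error ≈ 4–5% at
  5%-of-top noise, so the 5% recovery check targets the central
  estimate), 500 simulations for BMD coverage, 25 seeds per generator
  for AIC competitiveness.
* Small-sample AIC correction (AICc), LOEC-style hit calling, model
  averaging, and u-shaped/multiphasic models beyond gnls/poly2 are out of
  scope.
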