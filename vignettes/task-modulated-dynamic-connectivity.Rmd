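---
title: "Task-modulated dynamic connectivity: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Task-modulated dynamic connectivity: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its own methods: the models it
fits, the parameters that matter, what the synthetic cohort generator
does and does not emulate, and the numerical and design choices that
were genuinely open.

## The estimation model

The pipeline treats each subject's data as a frames × regions matrix of
BOLD-like signals on a fixed acquisition grid (TR, `n_frames`). Dynamic
functional connectivity is estimated by a two-stage conditional-
correlation model:

**Stage 1 — marginal variance.** Each region's demeaned series gets a
Gaussian quasi-maximum-likelihood GARCH(1,1) fit,

$$h_t = \omega + \alpha\, x_{t-1}^2 + \beta\, h_{t-1},\qquad
\hat z_t = x_t / \sqrt{h_t},$$

with $h_1$ fixed at the sample variance (the least-informative warm-up)
and the constraint $\alpha + \beta < 1$ enforced through a logistic
reparameterization. Internally the series is scaled to unit variance
before optimization — this conditions the likelihood and makes the
estimator exactly scale-equivariant, so rescaling a region's signal
cannot change its correlations.

**Stage 2 — correlation dynamics.** Standardized residuals drive the
DCC(1,1) recursion with correlation targeting,

$$Q_t = (1-a-b)\,\bar Q + a\, z_{t-1} z_{t-1}^\top + b\, Q_{t-1},
\qquad R_t = \mathrm{diag}(Q_t)^{-1/2} Q_t\, \mathrm{diag}(Q_t)^{-1/2},$$

with $\bar Q$ fixed at the residuals' sample correlation and $Q_1 =
\bar Q$. No moving average or other temporal smoothing is applied at any
point: the output has exactly one correlation matrix per acquired frame.

**Joint versus pairwise.** `fit_dcc()` estimates one scalar $(a, b)$
jointly over all regions; `dcc_series()` instead defaults to a
*bivariate fit per region pair*. The reason is structural, not
numerical: a single innovation weight $a$ is a compromise across all
$p(p-1)/2$ pairs, and when only a subset of connections is genuinely
time-varying (the situation this analysis is designed to detect) the
many static pairs dominate the quasi-likelihood and drive the joint
$\hat a$ to zero, erasing the dynamics of the interesting pairs. We
verified this directly on generated cohorts: the joint optimum was the
static model even though individual NAcc–CEN pairs, fit bivariately,
recovered $a \approx 0.03$, $b \approx 0.96$ and tracked the latent
correlation with $r \approx 0.7$. Pairwise fitting also matches how
framewise conditional correlations are computed in practice at
hundreds-of-regions scale, where a joint $347$-dimensional fit is not
an option. The trade-off: a pairwise-assembled matrix is symmetric with
unit diagonal and entries in $[-1, 1]$, but only approximately positive
semi-definite. None of the downstream steps (pair averaging,
non-negative thresholding) requires PSD frames; the joint factorization
is available where exact PSD matters.

Optimization is Nelder–Mead on the transformed parameters: three
standard starts ((0.02, 0.95), (0.05, 0.90), (0.10, 0.80)) optimized in
full for the joint fit (ties broken by likelihood, then smaller $a$);
for the pairwise path the starts are screened by likelihood and the
best is optimized, which the smooth 2-D surface makes safe. Convergence
failures fall back to flagged static/homoskedastic parameters rather
than stopping a whole-cohort run.

## The task design layer

The canonical cue-exposure program is reconstructed exactly from its
arithmetic: 3 cue types × 12 trials × (20 s cue ON + 5 s rating + 20 s
washout) = 1620 s = 810 frames at TR 2 s, split as two 13.5-min
sessions concatenated on one frame axis. The trial order is a frozen
balanced pseudorandom interleaving, identical for every subject, as in
a fixed task program.

Regressors use the community-default double-gamma HRF (response peak
6 s, undershoot peak 16 s, unit dispersions, undershoot ratio 1/6,
32 s span), convolved on a grid oversampled 16× relative to TR and
sampled at frame midpoints; both choices avoid aliasing the 20-s blocks
and can be overridden (`oversample`, `t_ref`). The weighting series
H_task is deliberately **not** mean-centered; the 18-column task
nuisance design (3 cue types × ON/OFF/RATE × HRF and derivative) and
the 36-column confound expansion (6 motion + 3 physiological signals,
each as centered value, derivative, square and squared derivative, plus
FD > 0.5 mm spike indicators) are mean-centered as nuisance regressors
should be. Rating periods enter only as nuisance.

Trial windows are defined per trial: the frames where that trial's own
convolved response exceeds `epsilon` (10⁻⁶, a float-noise guard), inside
the condition's overall positive support (a neighbouring trial's
undershoot can cancel the tail), clipped at the next same-condition
onset and at the end of the scan. Clipping prevents frames from being
counted twice within a condition; the alternative (letting the HRF tail
run on) double-counts frames and was rejected. Windows are ~14 frames
on the canonical design, always ≥ 2.

## The variability statistic

For each measure trace $m(t)$ (a pair-averaged connection weight or a
topological index) and condition, with trial windows $t_2 = 1..T_2$ of
lengths $T_1$:

$$d_{SD} = \frac{1}{T_2}\sum_{t_2}
  \sqrt{\frac{\sum_{t_1}\bigl(m\,H - \overline{m\,H}\bigr)^2}{T_1-1}},$$

i.e. the pair average over $N_{Conn}$ happens per frame *before*
weighting, the SD is over frames within a trial, and trials are
averaged. (A looser prose reading — per-pair SDs averaged afterwards —
conflicts with the statistic's nesting and is not used.) Two documented
consequences of the multiplicative weighting: $d_{SD}$ is positively
homogeneous in the trace, and a constant shift of the trace *does*
change $d_{SD}$ whenever H varies within a window — the statistic mixes
the trace's within-window fluctuation with its level. With a flat
weighting it reduces to the plain per-trial SD. Unequal $T_1$ across
trials is allowed; each trial uses its own divisor.

## Graph metrics

Each frame's matrix is thresholded by zeroing negative weights (and the
diagonal); zero entries are non-edges. Weighted shortest paths use edge
lengths $1/w$, the standard transform for correlation-weighted graphs.
Global efficiency is the mean inverse distance over ordered pairs with
unreachable pairs contributing 0. Edge betweenness is Brandes'
fractional-sharing definition, unnormalized, each unordered pair counted
once; ties between equal-length paths are measure-zero for continuous
weights. The resilience index removes every edge with betweenness
strictly above 1 (so only edges that no shortest path, or exactly one,
crosses survive), recomputes efficiency, and reports efficiency loss per
removed edge scaled by $N_{total} = n(n-1)/2$; with nothing to remove
the index is 0 by convention, since the defining ratio is otherwise
undefined. Removal can only lower efficiency, so the index is never
positive.

"Deterministic modularity" is implemented as the exact integer-program
optimum of weighted Newman–Girvan Q (resolution 1) for graphs up to
`exact_max = 16` nodes, and the deterministic Newman leading-eigenvector
method above that. An exact optimum is the strongest reading of
"deterministic" and is what makes equality with exhaustive partition
search provable on small graphs; a refinement heuristic can be
deterministic yet still miss the optimum. Both routes return identical
results on repeated calls. Edgeless graphs have no defined modularity
and are recorded as missing frames with diagnostics rather than
poisoning a series.

## Group statistics

The inference layer mirrors a standard SPSS-style analysis. Per measure:
a Type III repeated-measures model over the six conditions with a
between-subject group factor and two covariates — age (grand-mean
centered; centering per group would absorb part of a group difference,
so the grand mean is the right default) and mean framewise displacement
(mean-centered per group). Reported are Mauchly's W, the
Greenhouse–Geisser epsilon and GG-adjusted task and interaction tests,
the between-subject group test, and a per-measure multivariate (Wilks)
task test; Bonferroni correction multiplies by the family size (12
connection measures, 3 topological). Mauchly/GG are also available as a
standalone closed-form function, cross-checked in the tests against the
model-based route.

A multivariate omnibus across a family needs error degrees of freedom
exceeding the number of response columns: the 12-DV group omnibus on
condition means works from about 16 subjects per group; the
12 × 5-contrast task omnibus needs over 64 subjects and is reported as
missing below that, with the per-measure multivariate tests standing in.

Craving correlations are Spearman partials: all variables
rank-transformed, covariate ranks removed by least squares, residuals
correlated, p from the t approximation with $n - 2 - q$ df. Craving
scores are z-normalized within the user group first (rank-invariant,
kept for scale fidelity). The multiple-comparison rule over each
measure × condition × score family is Benjamini–Hochberg at q ≤ 0.25
with the additional gate raw p < .050 — both conditions must hold.

## The synthetic cohort: what it emulates and what it does not

Each subject has five latent network factors (DMN, CEN, SN, Amyg, NAcc)
with baseline inter-factor correlation 0.30; regions are their factor
plus white noise (sd 0.8, i.e. within-network pairwise correlations
around 0.6) plus a stylized evoked response along the cue-ON regressors
(amplitude 0.3; DMN deactivates at gain −0.5). The NAcc–CEN factor
correlation is a stationary mean-reverting AR(1) with mean 0,
autoregression 0.95 (≈ 40 s fluctuation timescale at TR 2 s) and
stationary sd 0.15, multiplied by 2 in the user group and by a
subject-level mean-preserving lognormal trait factor (cv 0.2).
During-scan craving is the subject's realized latent variability
z-score plus N(0, 0.75²) noise; prescan craving is uncoupled noise. Age
is drawn to match the study-population summary (mean 29.4, sd 9.2);
mean FD comes from the simulated confound tables.

Three of these choices deserve their rationale spelled out:

- **Stationary AR(1), not a pure random walk.** A reflected random walk
  mixes toward the uniform distribution on its bounds over an 810-frame
  scan, so every subject's realized variability converges to the same
  saturated value and a group multiplier on the innovation scale stops
  mattering. A stationary process keeps "fluctuation scale" a
  well-defined subject property.
- **Zero mean NAcc–CEN coupling.** Because the weighting is
  multiplicative, $d_{SD}$ of a trace with mean level $\mu$ contains a
  term $\propto |\mu| \cdot SD(H)$ that dominates the within-window
  fluctuation when $\mu$ is large. A weak-mean, fluctuating
  subcortical–executive coupling puts the group difference where the
  statistic (and the scientific premise — variability, not mean,
  differs) actually is.
- **Trait heterogeneity.** A within-group craving–variability
  correlation can only exist if subjects within a group differ in true
  variability; the lognormal trait factor provides exactly that.

The fluctuation scale and noise level were calibrated once so that the
planted twofold group effect sits inside the estimator's sensitive band
(the DCC filter passes fluctuations slower than roughly its persistence
timescale), and then frozen.

What the generator does **not** emulate: realistic BOLD spectra,
scanner drift and physiological aliasing, spatial structure within
networks, condition-specific connectivity changes (the planted effect
is condition-unspecific, matching a group difference "across task
conditions"), or heavy-tailed motion artifacts. Passing the recovery
tests therefore shows the pipeline is correct and sensitive under its
own model class — not that real cue-exposure data carry effects of this
size.

## Problem sizes and determinism

Validation sizes were chosen to run on a single CPU: estimator recovery
uses 100 GARCH replicates at T = 5000 and DCC simulations at T = 2000;
graph-metric oracle equivalence uses 200 random graphs of 4–8 nodes
(exhaustive partition search and path enumeration stay exact there);
end-to-end recovery uses 20 + 20 subjects, 21 regions and 810 frames
per replicate, with 50 replicates per arm in the acceptance script and
16 fixed-seed replicates with one-sided binomial acceptance bounds in
the test suite. The full study scale (90 + 54 subjects, 347 regions) is
a documented configuration, not a tested one. All randomness flows from
explicit seeds: the cohort generator spawns per-subject child seeds
from its master seed, so any subject can be regenerated independently,
and identical seeds give bit-identical cohorts.

## Known limitations

- The pairwise DCC factorization loses the guarantee of jointly PSD
  frames (see above).
- The bivariate quasi-likelihood treats each pair in isolation;
  borrowing strength across pairs (e.g. shrinking $(a, b)$ toward a
  panel prior) might stabilize very short scans but is not implemented.
- Exact modularity switches to the spectral method above 16 nodes, so
  per-frame Q values on the 21-region cohort are deterministic lower
  bounds on the optimum, not the optimum itself.
- The RM-ANOVA layer assumes a balanced six-condition design per
  subject; subjects with missing cells are excluded listwise (and
  reported), not imputed.
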