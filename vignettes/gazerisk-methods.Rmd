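---
title: "Process models of risky choice constrained by eye fixations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Process models of risky choice constrained by eye fixations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazerisk)
```

## The problem

When people choose between two simple lotteries — win $x_1$ with probability
$p_1$ (otherwise nothing) versus $x_2$ with $p_2$ — how are amounts and
probabilities combined into a preference? Two broad accounts compete.
*Within-alternative* integration forms each option's overall value by
multiplying a subjective amount by a subjective probability weight, as
expected utility and cumulative prospect theory (CPT) assume.
*Within-attribute* comparison accumulates attribute-wise differences
(amount against amount, probability against probability), as heuristic and
sampling accounts assume. Eye fixations provide moment-to-moment leverage on
this question: each fixation marks which attribute is being sampled, and
attention is known to modulate the weight of the sampled information.

`gazerisk` implements both families as gaze-conditioned leaky accumulators
inside an integration-to-boundary framework, together with static benchmark
models, a two-step maximum-likelihood pipeline for choices and decision
times, the descriptive eye-movement analyses, and a synthetic-experiment
generator so that the entire pipeline runs and is tested without any
empirical data.

## The design

The stimulus space is a 5 × 5 grid of amounts (3, 6, 15, 24, 30 ILS) by win
probabilities (.1, .2, .5, .8, 1), giving 25 lotteries. All unordered pairs
in which neither option dominates the other (higher on both attributes) are
trade-off problems; brute-force enumeration gives exactly 100 of them and
200 dominated pairs. Ten dominated pairs are included as catch trials to
check task engagement. The experiment this package emulates used 94 of the
100 trade-off pairs; the six exclusions are not derivable from the dominance
rule, so the package default is the reproducible set of 100, with
`problem_subset` available for exact replication when a problem list is
available.

## The accumulator models

All variants share the same scaffolding. Each fixation is one integration
step. Accumulators decay by $(1-\lambda)$ per step ($\lambda \in [0,1]$ is
the leak; $\lambda = 0$ is perfect, drift-diffusion-like integration and
$\lambda = 1$ is memoryless). Unattended inputs are attenuated by
$\theta \in [0,1]$, as in the attentional drift-diffusion model. Attributes
that have not yet been fixated enter at mid-range default values
((min+max)/2 of the design levels, i.e. 16.5 ILS and .55) until their first
fixation, in every variant.

* **Within-attribute, normalized differences** — on a fixation to attribute
  $k$ of option $i$, the accumulators receive $\pm(v'_i - \theta v'_j)$,
  where $v'$ are min–max-normalized attribute values over the design ranges.
* **Within-attribute, categorical differences** — as above, but the winner
  of the comparison $v_i > \theta v_j$ (raw values) gains one unit; ties
  increment nothing.
* **One-layer within-alternative** — the fixated option's accumulator
  receives its CPT-style subjective utility
  $SU = x^{\alpha}\,\pi(p)$ with
  $\pi(p) = p^{\gamma}/(p^{\gamma}+(1-p)^{\gamma})^{1/\gamma}$; the other
  option's accumulator receives $\theta \cdot SU$.
* **Two-layer within-alternative** — a cascade: four attribute-level leaky
  units are updated with attentionally weighted subjective values (weight 1
  for the fixated attribute, $\theta$ otherwise); two option-level units
  then accumulate the *product* of their paired attribute activations. One
  shared leak serves both layers by default (`lam1` allows a separate
  first-layer leak).
* **Hybrid** — the two-layer cascade plus mutual inhibition $-\iota$ between
  same-attribute units of the two options, applied to previous-step
  activations and rectified at zero. With $\iota = 0$ it is bit-identical to
  the two-layer model.

Choices (Step 1) use the exponential Luce rule on the final accumulator
states, $P(A) = 1/(1+e^{-\beta(Y_A - Y_B)})$, with per-step noise switched
off. Decision times (Step 2) use an integration-to-boundary race: with
per-step Gaussian noise ($\sigma$ fixed at 1; its scale is absorbed by the
boundary), the trial terminates at the first fixation step where the larger
accumulator reaches the boundary. Two boundary families are implemented:
fixed ($b_0$; one new parameter) and collapsing
($b(t) = b_\infty + (b_0-b_\infty)e^{-t/\tau_c}$; three new parameters).
The exponential form is this package's choice; only the parameter counts
(one vs. three) are fixed by the modeling framework it implements.

### Numerical choices

Fitting is bounded multi-start Nelder–Mead on a logit-transformed parameter
space (bounds: $\alpha \in [0.1,2]$, $\gamma \in [0.2,2]$,
$\theta, \lambda, \iota \in [0,1]$, $\beta \in [0,50]$, $\tau \in [0,2]$),
with a polish restart from the incumbent and, for accumulator variants, one
start warm-loaded from a cheap CPT fit. Likelihood contributions are clipped
to $[10^{-10}, 1-10^{-10}]$. One-parameter models use golden-section search.
Step-2 likelihoods are Monte-Carlo: accumulator paths are simulated once per
trial under common random numbers and reused for every boundary evaluation,
which makes the Step-2 objective a deterministic function of the boundary
parameters; the probability of the observed (choice, fixation count) is
Laplace-smoothed as $(\text{hits}+1)/(M+2)$. Observed fixation sequences
exhausted before crossing are extended by resampling the trial's own
transition-category statistics. Exact ties (categorical comparisons, Luce
probabilities at exactly .5, simultaneous boundary crossings) resolve to
no-increment, half-credit accuracy, and a seeded coin flip respectively.

AIC is $2k - 2\log L$ with $k$ counting *all* fitted parameters including
$\beta$; the fit object reports $\beta$ separately from the process
parameters, so the alternative convention (counting only the four process
parameters) can be reconstructed if needed. Cross-validation is 5-fold, stratified by |ΔEV| quantile,
seeded; heuristics, having nothing to fit, carry their plain accuracy.

## The synthetic-data generator

The generator is a first-class module: it emulates the experiment well
enough that every analysis in the package has a meaningful input, and its
defaults are the descriptive statistics of the emulated study.

* **Fixation counts**: negative binomial with mean 9.05 and SD 3.56
  (overdispersed, matching the reported moments), truncated at 4 — fewer
  fixations cannot satisfy the all-attributes-viewed inclusion rule, which
  the analyses apply to real data too.
* **Durations**: log-normal with mean 407 ms and SD 244 ms.
* **AOI sequences**: a first-order Markov chain over the four attribute
  regions with no immediate repeats. Base category weights make
  within-alternative transitions more frequent than within-attribute ones,
  and those more frequent than diagonal ones. Two structural refinements
  emulate real scanpaths: a *novelty bonus* towards not-yet-visited AOIs
  (calibrated to reproduce the ~4% of trials that fail the coverage rule in
  the emulated experiment) and *inhibition of return* (a penalty on the AOI
  two steps back), which turns within-alternative scanning into the
  empirical pattern of visiting one option's amount–probability pair and
  then the other's rather than bouncing inside one option.
* **Gaze biases**: log-linear tilts towards amounts vs probabilities,
  towards the higher of the two amounts (range calibrated so the
  across-participant spread of the higher-amount fixation share resembles
  the published individual-difference figure), towards the higher
  probability, and a small value-dependence term (≈1% tilt of an amount's
  fixation probability with its own probability, matching the reported
  magnitude).
* **Choice consistency**: the population β range is calibrated so that
  mean generator self-consistency sits near the published ~87% prediction
  accuracy of the best-fitting model, with realistic spread.

### What the generator encodes versus what the model produces

Two individual-difference regularities deserve explicit caveats, because
they shape what a green test establishes.

First, the *gaze-to-risk* channel is mechanistic: fixating the higher
amount more often genuinely pushes the accumulator models towards riskier
choices (via attentional weighting), and simulations with shared group-mean
parameters reproduce the positive correlation between higher-amount
fixation share and risky-choice fraction from gaze heterogeneity alone.

Second, the *systematicity* channel is not mechanistic in these models:
organizing one's scanpath by alternative does not, by itself, make the
simulated chooser more EV-consistent (if anything, recency effects argue
the other way). Empirically, participants who scan within alternatives do
choose more in line with expected value. The population model therefore
encodes this as trait covariation: a latent "systematicity" factor couples
the within-alternative transition weight with attentional evenness (θ) and
choice sensitivity (β), and a latent "risk orientation" factor couples the
higher-amount gaze bias with utility curvature (α). A green
individual-difference test establishes that the pipeline *measures* these
population-level structures correctly — not that the accumulator alone
generates them.

## Parameter recovery

The recovery harness simulates one participant per generative parameter
set over the design's trade-off problems with model-generated gaze, refits,
and reports generative-vs-recovered correlations. Generative sets span the
fitting bounds but are screened to imply a mean choice consistency of at
least .75 on the design (the weakest accuracy any fitted compensatory model
attains on data of this kind). The screening matters: recovery exercises in
this paradigm use participants' *estimated* parameters — regimes that fit
real, reliable data — whereas unscreened uniform draws include near-random
choosers whose five-parameter MLE from ~100 binary choices is noise in
every direction (for such sets the recovered likelihood exceeds the
generative one, so no optimizer can repair them). With screening, seeded
30-set recovery yields correlations around .9 for α, γ, θ and λ.

## Known limitations

* Lotteries have a single non-zero outcome; losses, multi-outcome gambles
  and rank-dependent weighting beyond two outcomes are out of scope.
* Integration is per-fixation, not continuous within fixations; there is no
  non-decision time and no across-trial drift variability.
* The collapsing-boundary parameterization and the Step-2 noise source are
  this package's documented choices, constrained only by the stated
  parameter counts.
* Group-level inference is two-stage (per-participant fits plus group
  summaries); no hierarchical estimation.
* The mid-range default for unscanned attributes systematically inflates
  early evidence for options whose true amount is far below the mid-range;
  with near-deterministic choice rules this produces occasional dominated
  choices on weakly dominated catch pairs — visible in tests and faithful
  to the model definition.
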