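---
title: "Cell-assembly assimilation in a plastic rate network, and the behavioral statistics around it"
author: "assimnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell-assembly assimilation in a plastic rate network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's methods account: the model and its
assumptions, the parameters that matter, the statistics, the synthetic
data generator, the numerical choices, and the limits of what the tests
demonstrate. Heavy computations are shown but not evaluated when the
vignette is built; every empirical number quoted here is computed by the
test suite or by `scripts/acceptance.R`.

## 1. The network model

The simulator implements a recurrent rate network of `n_ex = 400`
excitatory and `n_inh = 100` inhibitory neurons. Voltages follow leaky
integrator dynamics driven by recurrent input and a Gaussian noise
current, with a threshold-linear activation `F(v) = v` for
`v >= Theta = 1` and 0 below: a neuron transmits nothing until its
voltage reaches the threshold, then transmits its voltage. The
excitatory-to-excitatory graph is *reciprocal*: exactly
`round(p_ee n_ex (n_ex-1)/2)` unordered pairs are drawn and each becomes
two directed edges, reflecting the over-representation of bidirectional
pairs in cortical and hippocampal recurrent circuits that motivates the
model. Inhibitory connectivity is random and fixed
(`w_ei = -0.025` per inhibitory-to-excitatory edge, `w_ie = 0.2` per
excitatory-to-inhibitory edge).

Excitatory-to-excitatory weights are plastic, with three interacting
mechanisms:

* **BCM rule.** `tau_w dw_ij/dt = -w_ij + alpha phi(v_i, theta_i)
  sigma(v_j)`. The postsynaptic factor
  `phi(v, theta) = 6.75 v^2 (v-theta)/theta^3 + tanh(6.75 (v-theta)/theta)`
  is the BCM curve: depression for activity below the modification
  threshold, potentiation above, zero at the threshold and near zero
  activity. The presynaptic factor is a sigmoid of the presynaptic
  voltage.
* **Sliding threshold.** `theta_i` is an exponential moving average of
  `v_i` with per-step rate `gamma dt`, so that under stationary dynamics
  it converges to the neuron's temporal mean voltage — the
  self-stabilizing element of BCM.
* **Synaptic scaling.** After every weight update, each neuron's incoming
  plastic weights are multiplied by `kappa / sum(incoming)`, pinning the
  incoming total at `kappa = 0.5`. This is the homeostatic guard against
  the runaway loop in which a potentiated synapse raises postsynaptic
  activity and is thereby potentiated further. Without it, the default
  network diverges within a few seconds of simulated time
  (`scaling_every = 0` demonstrates this).

Voltages are integrated with classical fourth-order Runge-Kutta at
`dt = 0.5` ms, the noise current drawn once per neuron per step and held
constant across the four stages; weights and the threshold estimate use
one Euler step per `dt`, which is adequate because `tau_w = 1000` ms is
fifty times slower than the membrane. An *item* is encoded by a
three-neuron cell assembly: insertion creates the missing directed edges
among the members with weight zero, preserving reciprocity; existing
edges keep their weights.

### Parameters, units, defaults

All voltages and weights are in arbitrary units; time is in ms.

| parameter | default | meaning |
|---|---|---|
| `n_ex`, `n_inh` | 400, 100 | population sizes |
| `p_ee`, `p_ei`, `p_ie` | 0.2 | connection probabilities |
| `tau_ex`, `tau_inh` | 20 ms | membrane time constants |
| `tau_w` | 1000 ms | weight time constant |
| `theta_act` | 1.0 | activation threshold `Theta` |
| `alpha` | 0.1 | BCM gain |
| `beta` | 5.0 | presynaptic sigmoid slope |
| `kappa` | 0.5 | incoming-weight total after scaling |
| `gamma` | 0.001 /ms | sliding-threshold averaging rate |
| `dt` | 0.5 ms | integration step |
| `w_ei_fixed`, `w_ie_fixed` | -0.025, 0.2 | fixed synaptic weights |
| noise | E: N(1, 0.5²), I: N(0, 0.5²) | per-step currents |

`gamma` deserves a note: it is the one dynamical constant that the model
description leaves without a value, and the sliding-threshold recursion
itself is stated only up to its stationary property ("theta becomes the
temporal mean voltage"). We use a plain EMA with `gamma = 0.001`/ms — an
averaging window of one second, matching the order of `tau_w` so that the
threshold is slow relative to membrane fluctuations but fast enough to
converge within the burn-in — and expose both the rate and an optional
bias-corrected variant (`bias_correct_theta`), which divides out the
finite-horizon factor `1 - (1 - gamma dt)^n` and makes the estimate an
exact running mean of a constant signal from the first step.

Further deliberately exposed interpretation switches, all defaulting to
the most literal reading: `sigma_convention` ("centered",
`beta (v - Theta)`, which puts the sigmoid midpoint at the activation
threshold, versus the "literal" transcription `beta v + Theta`);
`white_noise_scaling` (treat the printed noise sd as a white-noise
density, multiplying by `sqrt(tau/dt)` per step);
`noise_redraw_every` (noise correlation time in steps; `Inf` gives a
quenched heterogeneous tonic drive); and `scaling_every` (cadence of the
homeostatic renormalization; 0 disables it). Section 3 reports how the
headline results move under these switches.

### Numerical choices and degenerate inputs

* Initial conditions (not stated in the model description): `v = 0`,
  `theta_hat = Theta`, and plastic weights at `kappa/indegree` so the
  scaling invariant holds from step 0. All are overridable via `init`.
* Weights are clamped at zero from below before scaling: these are
  excitatory synapses, and a single Euler overshoot of the depression
  term must not flip their sign.
* A neuron whose incoming plastic weights sum to zero (possible after
  clamping) is skipped by scaling for that step and counted
  (`n_degenerate`); division by the zero sum would be undefined.
* Inside the core, the effective BCM threshold is floored at `1e-6`
  before evaluating `phi` (which divides by `theta^3`); the user-facing
  `bcm_phi()` instead errors on a nonpositive threshold.
* Non-finite or absurdly large voltages abort the run with a condition
  object of class `assimnet_divergence` that carries the recording
  collected so far.
* The compiled core and the pure-R reference engine
  (`net_state()` / `step_voltages()` / `step_weights()` /
  `apply_synaptic_scaling()`) implement identical semantics and agree to
  1e-10 over tens of steps in the test suite; RK4 matches the closed-form
  single-neuron charging curve to better than 1e-8 at 100 ms, with the
  expected ~16x error reduction when `dt` is halved; the scaling
  invariant holds to 1e-15 across full-scale runs.

## 2. The assimilation experiment

`run_assimilation_experiment()` reproduces the simulation protocol: per
topology, run to 50,000 ms to reach a stationary state, insert 100
assemblies with randomly chosen member triplets, stop at 90,000 ms. Per
assembly it measures

* `mean_within_weight`: the six internal weights averaged over
  70,000-90,000 ms (assimilation strength),
* `mean_within_corr`: mean Pearson correlation of the three member pairs'
  voltage traces over 30,000-50,000 ms,
* `mean_out_corr`: mean correlation between members and all non-member
  excitatory neurons over the same window (accessibility to the entire
  network),

and per topology the Pearson r (and p) across assemblies of weight
against each correlation measure. The correlation window closes *before*
insertion, so the predictors describe the pre-existing dynamics at the
assembly's location and are provably unaffected by anything that happens
after insertion (the tests verify this invariance directly). Voltage
traces are sampled every 10 steps (5 ms); windows are closed intervals
over sampled points.

Open choices, with our defaults: all 100 assemblies are inserted jointly
into one run per topology (`insertion = "sequential"` runs one simulation
per assembly instead; the predictors are identical either way and the
joint mode is two orders of magnitude cheaper); member triplets may
overlap (`policy = "non-overlapping"` forbids it); correlations are
computed on voltages, the state variable, with `correlate_on = "rate"`
switching to `F(v)`.

## 3. What the default parameterization does and does not reproduce

At the defaults, the network settles into sustained irregular activity
with roughly 5% of neuron-samples above threshold at any moment — the
"random baseline activity" regime — and the assimilation experiment
yields a *positive, significant* weight-versus-within-correlation
relation (r around +0.3 across seeds and topologies, p < 0.01 at
n = 100). Two aspects of the original study's simulation do **not**
reproduce under this parameterization, and we state them plainly rather
than hide them:

* the within-assembly relation is much weaker than the reported
  r = 0.85-0.90, and
* the assembly-to-network relation comes out *negative* (around -0.3
  to -0.4) rather than positive (reported 0.2-0.6).

A systematic sensitivity analysis (both sigma conventions; `gamma` from
1e-5 to 0.2 with and without bias correction; per-step, white-noise and
quenched noise; rate-based and time-binned correlation measurement; slow
`tau_w`; scaling cadence) identifies the mechanism. Per-step
multiplicative scaling makes a neuron's incoming weights a strictly
competitive system: members that are strongly coupled to the whole
network have many strongly co-active established inputs, which crowd out
the two freshly inserted within-assembly edges — hence the negative
assembly-to-network relation. Only removing the scaling step entirely
flips that relation into the reported positive range (up to +0.5), but
scaling is an explicit component of the model, so we do not adopt that as
a default. Independently, pairwise voltage correlations at these
parameters are small (typically 0.02-0.14) relative to their own
estimation noise over a 20 s window, which caps any attainable
correlation-weight r near 0.5. We verified that the machinery itself is
sound: directly connected pairs are measurably more correlated than
unconnected ones, and the weights of mature edges track their pair
correlations. The acceptance checks for this experiment therefore assert
the originally reported pattern and are expected to fail at the defaults;
`scripts/acceptance.R` reports whatever the faithful model produces.

## 4. Behavioral statistics

The analysis pipeline mirrors the two-experiment design. Essay lengths
are normalized within subject (each length divided by the subject's total
— between-subject productivity baselines cancel; subjects with no essays
cannot be normalized and are dropped). Confidence bands follow the
design's conventions exactly: ratings below 50 express confidence of
absence and leave the analyzed set; 75 belongs to the lower band; 100 is
"certain".

Group comparisons use the Mann-Whitney U test (one-sided where the
hypothesis is directional) with the probability of superiority
`PS = U/(n_a n_b)` as effect size — the proportion of cross-group pairs
in which group a exceeds group b, ties counted half, verified in the
tests against exhaustive pair enumeration — or t-tests (pooled-variance
independent, or paired) with Cohen's d / d_z. Confidence intervals are
percentile bootstrap (default 10,000 resamples) of group medians (rank
tests) or means (t-tests).

Two surrogate-data tests are implemented exactly as bespoke procedures:

* **Dot-product shuffle test.** Per subject, the confidence and length
  vectors over analyzed words are L2-unitized ("unitized" must mean L2
  here: only then is each subject's maximal contribution 1 and the
  statistic's theoretical maximum the number of subjects, as stated);
  the statistic sums the per-subject dot products; the null shuffles each
  subject's length components independently. This is a within-subject
  permutation test, hence exactly calibrated conditional on the data.
* **Letter-reassignment test.** Restricted to certainty-rated words,
  lengths renormalized to total 1 per subject; the statistic sums the
  spontaneous (once-presented) share. Null draws reassign the subject's
  letters uniformly at random over the *essays* written for those words —
  a uniform multinomial, whose spontaneous-subset total is binomial.
  Subjects whose certain essays are all spontaneous contribute 1
  identically to data and null, leaving the p-value untouched but the
  bounds intact.

Both use the `(k+1)/(n+1)` upper-tail p-value so p is never zero, and
both are invariant to rescaling any subject's raw lengths by a positive
constant. `analyze_experiment1()` chains normalization, band filtering,
the lower-versus-upper comparison on per-subject mean normalized lengths
(per-subject aggregation, since the design's sample size is the number of
subjects), the dot-product test, and optionally the paired semantic
comparison. `analyze_experiment2()` adds the certain-proportion
comparison between presentation conditions, the once-presented
replication, spontaneous-versus-forced comparisons on the upper and
certain bands, the letter-reassignment test, and the independent semantic
comparison. The "proportion of certain words" is reported per condition
(count / words in condition) by default with `certain_as = "count"` as
the alternative, because the quantity's units are ambiguous in the
original report (a printed confidence interval for the five-times
condition exceeds 1).

## 5. Semantic similarity

`essay_similarity()` scores an essay against the two component words of
its compositional word: each token's similarity is the larger of its
cosines to the two components, tokens identical to a component are
excluded, out-of-vocabulary tokens are skipped and counted (zero-filling
would silently bias means), duplicates count per occurrence, and the
score is the token mean. An essay with no usable tokens has an undefined
score (flagged), not zero. Embeddings load from the word2vec text format;
tokenization is an injected dependency — the package deliberately does
not bundle a morphological analyzer, since synthetic essays arrive
pre-tokenized and real ones would be tokenized upstream. Cosine
similarity makes the raw-versus-normalized vector question moot.

## 6. The synthetic cohort generator

`generate_dataset()` emulates the experimental design: 20 words per
subject, 2 of them (chosen per subject) presented five times to force
memorization, confidence ratings 0-100, essays for a self-selected subset
of words, and a per-subject letter budget. The generative model draws a
latent salience per subject-word; confidence is a clamped rounded
Gaussian in salience (`conf_effect` weighting), with `forced_conf_boost`
added for forced words; essay selection follows a logistic in salience;
and the letter budget (lognormal, mean 800) is allocated across selected
words by a multinomial with weights `exp(length_effect * salience)`.

Two structural choices matter and were made deliberately:

* **Null mode is the exact null of every test.** With
  `length_effect = 0` and `forced_conf_boost = 0`, selection and
  allocation are uniform and independent of confidence and condition;
  letters are exchangeable across a subject's words and conditionally
  multinomial-uniform over any word subset. The dot-product test's
  permutation null and the letter test's multinomial null are then both
  *exactly* true, so type-I calibration (acceptance: rejection rate
  0.05 ± 0.02 at nominal 0.05 over 500 datasets) is a meaningful check
  rather than an approximation. An iid-per-word length model would have
  violated the letter test's null by construction.
* **Confidence marginals anchored to the reported certainty rates.** The
  defaults (`conf_center = 70`, `conf_scale = 28`) put ~15% of
  once-presented words at rating 100 and ~77% in the analyzed band,
  consistent with the certainty proportions reported for this paradigm;
  with the +35 forced boost, a majority of forced words hit the ceiling.
  With much rarer certainty the letter-reassignment statistic degenerates
  (every subject's pool is single-condition), which contradicts the
  reported inclusion counts.

The toy embedding (`generate_toy_embedding()`) places exactly orthogonal
cluster centroids and unit token vectors at `sqrt(rho)` along the
centroid, so intra-cluster cosines have mean `rho` and inter-cluster
cosines mean ~0; `generate_essays()` draws tokens from the word's own
component cluster with probability `1 - semantic_leap`, else from other
clusters, making the expected essay similarity interpolate between `rho`
and the inter-cluster baseline — the monotone dial the semantic tests
exercise.

What passing these tests shows — and does not show — about real data:
calibration and power are established under the generator's Gaussian
salience, logistic selection and multinomial allocation. Real essays have
heavier-tailed lengths, correlated word difficulty, and tokenizations
whose OOV structure is not random; the surrogate tests remain valid
permutation/multinomial tests regardless (their null is conditional on
the data), but the power figures are specific to the generator.

## 7. Problem sizes used by the checks

The test suite runs the full-scale simulation protocol once (one
topology, 100 assemblies, 90 s of simulated time at `dt = 0.5` ms — about
two to three minutes of compute), 500 null datasets for calibration, 100
planted-effect replicates for power, 1,000 small random datasets for the
bounds property, and Monte-Carlo semantic checks at 8 subjects x 5 leap
settings. These sizes give Monte-Carlo standard errors comfortably inside
the asserted bands (e.g. ±0.01 on a 0.05 rejection rate at 500
replicates) while keeping a full run of the suite in the minutes range.

## 8. Known limitations

* The simulator is a rate model: no spiking, no conductances, no
  plasticity on inhibitory synapses, no neuromodulation — deliberate
  simplifications inherited from the model it implements.
* The Table-1-style correlations depend strongly on constants the model
  description under-determines (Section 3); the package exposes them
  rather than silently picking the most favorable combination.
* The letter-reassignment test conditions on the set of written essays;
  it tests letter allocation among existing essays, not the selection
  process itself.
* Bootstrap CIs are percentile-method; for the small per-group sizes of
  the certain-band analyses they can be short-coverage.
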