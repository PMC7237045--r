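---
title: "Emergent selectivity in random excitatory-inhibitory rate networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Emergent selectivity in random excitatory-inhibitory rate networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(selnet)
```

## The model

`selnet` simulates a sparse, randomly connected network of $N_E = 400$
excitatory and $N_I = 100$ inhibitory firing-rate units performing a
pulse-frequency discrimination task, and asks how much task structure —
single-neuron choice selectivity, selectivity-dependent functional
connectivity, linearly decodable category information — emerges from random
wiring alone, with no tuned or learned structure anywhere in the circuit.

Each unit follows the standard rate equations
$$\tau \dot{x} = J\,r + \mathbf{c}\, i(t) - x,\qquad r_i = g(x_i),\qquad
g(x) = \tfrac12\bigl(1 + \tanh(x - b)\bigr),$$
with all time measured in units of the membrane time constant $\tau = 1$
(an effective 20 ms for bookkeeping). The transfer bias $b = 2$ keeps
spontaneous rates at or below 0.05. The weight matrix $J$ is sparse (each
ordered pair connected with probability $p = 0.2$, no self-connections) and
signed by source: excitatory columns are drawn from a normal distribution
with mean $g_E = 0.18$, inhibitory columns with mean $g_I = -0.72$, both
with SD 0.045 and truncated at zero so every weight respects its sign
(Dale's principle). With these means, $N_E g_E + N_I g_I = 0$: excitation
and inhibition balance on average, and any selectivity must come from the
random fluctuations around that balance.

Two input-targeting variants exist. In the default, a fixed random 20% of
excitatory cells receive the stimulus current. In the `all_e_input`
variant every excitatory cell is driven and the weight means are set per
pool ($g_{E\leftarrow E} = g_{I\leftarrow E} = 0.2$,
$g_{E\leftarrow I} = -0.8$, $g_{I\leftarrow I} = -0.82$); the 2.5% stronger
I$\to$E weights offset the stimulus current that only excitatory cells
receive.

## The stimulus generator

The stimulus module is the package's synthetic-data generator, and its
defaults are the study's conditions rather than tunable knobs. A trial
lasts $50\tau$. A category is defined by a fixed per-trial pulse count (8
vs 16 for the main task, i.e. average frequencies 0.16 and 0.32 per $\tau$,
8 and 16 Hz at 20 ms; 10 vs 20 for the transfer task). Pulse times are
drawn uniformly without replacement from the $0.01\tau$ grid over the
trial, so trial-to-trial pulse timing is the *only* source of variability
in the whole simulation — there is no intrinsic noise. Pulses are filtered
into the input current
$$i(t) = \alpha \sum_{t_k < t} \frac{(t - t_k)^2}{a^2}
  e^{-(t - t_k)/a}, \qquad a = 0.5,$$
a causal bump peaking $2a$ after each pulse with a full width at half
maximum of about $1.7\tau$.

### Iso-rate amplitude calibration

Mean population rate must not carry category information, so the amplitude
$\alpha$ is calibrated per network and per frequency: a $5\times5$ grid of
(frequency, amplitude) combinations — frequencies 0.1–0.5 per $\tau$,
amplitudes geometrically spaced over 0.3–15 — is simulated, the time- and
neuron-averaged rate surface is spline-interpolated, and the highest
iso-rate contour defined across the rule's whole frequency span — low
frequencies 0.14–0.2 per $\tau$ together with their doubled partners — is
extracted; the task uses the two amplitudes on that contour at the two
task frequencies. The span is a property of the rule, not of the
requested pair: every task run on a network (including the 10 vs 20 Hz
transfer task) reads its amplitudes off the *same* contour, so the mean
firing rate is matched not only between categories but across tasks.
Because the $5\times5$ spline can misplace the contour near the
saturating top of the surface, each amplitude is then refined by up to
two Newton-type corrections against short validation simulations, which
holds the realized category rates within a couple of percent of the
contour level on every network. Amplitudes are geometrically spaced because the rate
surface saturates in $\alpha$; the spacing resolves the steep low-amplitude
region where the contours live. Ten trials per grid point suffice: the
rate statistic averages 500 neurons $\times$ 50 time bins, so its
trial-to-trial standard error is far below the network-to-network spread
of the resulting contour. Across networks, the calibrated low/high
amplitude ratio is about 2.1, and post-calibration category means agree
within a few percent.

```{r calibration}
net <- build_network(network_spec(), seed = 1)
cal <- calibrate_amplitudes(net, n_pulses = c(8, 16), seed = 2)
glance(cal)
autoplot(cal)
```

## Integration

Trials start at the zero-input fixed point $x^{(0)} = J\,g(x^{(0)})$
(solved to residual $<10^{-12}$ by fixed-point iteration, which contracts
because the linearized spectral radius is far below 1). Forward Euler with
$dt = 0.01\tau$ — the pulse-grid resolution — integrates all trials of a
stimulus set simultaneously: one matrix product per time step for the
whole batch. The C++ core keeps state in single precision and evaluates
the transfer function through a linearly interpolated lookup table
(absolute error $<10^{-7}$); both approximations sit orders of magnitude
below the Euler truncation error, which itself is orders of magnitude
below trial-to-trial variability. A double-precision pure-R reference
integrator backs the unit tests, and a step-halving check bounds the
discretization error. Rates are averaged on the fly into $1\tau$ bins, the
resolution every analysis uses. Any membrane excursion beyond $|x| = 50$
aborts with a diagnostic — with stable parameters, membrane potentials
stay orders of magnitude smaller.

## Selectivity analysis

A neuron's per-trial response is its activity at the end of the stimulus
period, time-averaged to one number per trial: the mean rate over the
final $5\tau$ of the window. The window matters — widening it to the last
half of the trial roughly doubles every selectivity statistic, because
the slowly accumulating pattern differences between categories then
dominate the average, whereas the terminal window reflects the
quasi-steady driven state that the decoding and correlation analyses also
probe. Selectivity is the ideal-observer
AUC between the two categories' response distributions, computed exactly
from midranks (identical to exhaustive pair counting, ties counted half).
Significance bounds are the 2.5–97.5 percentiles of 1000 label-shuffled
AUCs; 1000 shuffles stabilize those percentiles, and because a shuffle
only permutes which trials count as which category, all shuffled AUCs are
obtained from one rank matrix and one matrix product. The selectivity
index is $2|AUC - 0.5|$, averaged over *all* cells (selective or not).

Noise correlations subtract each category's mean time course from every
trial's end-of-stimulus activity and correlate the residuals between
neurons, pooling the window's time bins and the category's trials as
samples and averaging the two per-category matrices. Because the only
noise is the shared pulse train, these correlations are substantial
(typically above 0.5 for both pair classes) — far larger than in real
recordings; the structure of interest is the gap between same- and
opposite-selectivity pairs, not the absolute level. Collapsing each trial
to a scalar before correlating would average away the shared fast
fluctuations and roughly halve the opposite-pair correlations.

Pool connectivity splits significantly selective cells into E1/E2/I1/I2 by
type and preferred category and measures each directed pool-pair's
empirical connection probability, pooling the two same-selectivity counts
and the two opposite-selectivity counts (the symmetrization used in the
reference analysis). With selectivity assigned at random these
probabilities would all equal $p = 0.2$; the dynamics instead uncover a
small but systematic excess of I$\to$E wiring between opposite-selectivity
cells — functional structure without structural pools. Occasionally every
significant cell in a network prefers the same category, leaving one pool
empty; that network's affected pool probabilities are `NA` and drop out
of ensemble averages.

One bookkeeping note: the selectivity index used throughout the package
is $2|AUC - 0.5|$ (0 = non-selective, 1 = maximal). The all-E-input
variant's reference analysis reports the un-doubled $|AUC - 0.5|$; the
acceptance script divides by two for that one comparison.

## Decoding

Linear support-vector classifiers (unit regularization constant; the
results are robust to this choice and it is recorded in the decoder
object) read category from z-scored single-bin population activity.
Neurons receiving direct input are excluded (in the all-E-input variant
this rule would delete the entire excitatory population, so there it is
disabled — the reference analysis for that variant also decodes from
excitatory cells). The classifier is fit at the last $1\tau$ bin on a
stratified 50/50 split, evaluated at every bin on the held-out half, and
re-fit over 50 random splits; the headline accuracy averages the last-half
bins, and its error bar is the SD across splits. Z-scoring uses the sample
SD and always reuses training-set statistics on test trials. The z-space
rule $\xi \cdot z > \eta$ is converted back to raw rates via
$w_i = \xi_i/\sigma_i$, $b = \eta + \sum_i \xi_i \bar r_i / \sigma_i$,
which classifies every trial identically — an algebraic identity the test
suite checks exhaustively. The excitatory subset (100 cells, matching the
inhibitory count) is drawn once per network and held fixed across splits;
re-drawing it per split would mix subset variability into the split SD.

## Linearized spectrum

About the zero-input fixed point the dynamics linearize to
$\tau \dot{\delta x} = (\tilde J - I)\,\delta x + \mathbf{c}\,i(t)$ with
$\tilde J_{ij} = J_{ij}\, g'(x^{(0)}_j)$. The eigenmodes of $\tilde J$
with the largest real parts decay most slowly and dominate the response;
eigenvectors whose real or imaginary part correlates with the per-neuron
AUC vector (Pearson, two-sided $t$ test, Bonferroni threshold $0.05/N$)
identify the modes that carry the selectivity pattern. A conjugate pair is
counted once — its two eigenvectors carry identical correlation magnitudes,
so the count is invariant to the arbitrary phase and conjugation
conventions of the eigensolver. Eigenvalue densities are normalized by the
per-network spectral radius, smoothed with a Gaussian kernel of width 0.1
(one tenth of the radius) and zeroed outside the unit circle; the
selectivity-correlated subset concentrates at positive real parts.

## Task transfer

The same network is re-run on the 10 vs 20 Hz pair with freshly calibrated
amplitudes and fresh trials, and the shuffle-significance status of every
neuron is cross-tabulated across tasks. Both tasks use 400 trials per
category so the significance thresholds are comparable. The fraction of
neurons changing status in either direction is the headline number; a
re-run of the *same* task with fresh trials bounds how much of it is
re-test noise.

## Orchestration, seeding and problem sizes

`run_study()` executes the whole design: 6 default networks (selectivity,
correlations, pools, full-population and inhibitory decoding, spectra,
plus the transfer arm) and 4 all-E-input networks (with all/excitatory-
subset/inhibitory decoding and spectra). Every random draw — network,
input targets, calibration trials, task trials, shuffles, splits, subset
membership — flows from one master seed through a deterministic stream
hash (`derive_seed()`), so any stage can be reproduced in isolation and a
re-run with the same seed is bit-identical. The ensemble sizes (6/4, with
400 trials per category) are the package's standard desk-scale conditions;
they match the reference ensembles' scale (6–14 networks) while keeping a
full study within tens of minutes on one CPU. Reported spreads across 6
networks are accordingly coarse: a fraction-selective mean, whose
across-network SD is ~0.15, carries an SE of ~0.06 at this size.

## What the generator does and does not emulate

The stimulus generator reproduces the task's statistical structure:
fixed pulse counts per trial (not Poisson), uniform timing at $0.01\tau$
precision, exponential-family filtering, and amplitude normalization that
removes mean-rate cues. It does not emulate sensory adaptation (the
mechanism that would implement such normalization biologically), spiking,
synaptic delays, or trial-history effects; and because all noise is the
shared input, absolute correlation levels are far above experimental
values. Passing tests therefore certify the emergence mechanism under
these idealized conditions, not a quantitative match to any particular
recording.

## Numerical choices and degenerate inputs

* Truncated-normal weights are drawn by rejection; at $|g|/\sigma = 4$
  (excitatory) and 16 (inhibitory) the truncation's effect on the
  realized mean is negligible, and the pre-truncation parameters are used
  as-is.
* Zero-variance neurons are dropped (with a warning) from correlations
  and flagged in z-scoring; empty selectivity pools yield `NA`
  probabilities rather than errors.
* The calibration contour is read off a ladder of candidate levels with
  spacing 0.01 in rate units; the monotone (Hyman) spline is used when
  the rate-vs-amplitude profile is monotone, a natural spline otherwise.
* Equal requested frequencies trivially receive equal amplitudes; a
  contour that cannot span the requested frequencies is an error, not a
  silent extrapolation.
* AUC ties are handled by midranks, which is exact; significance uses
  strict exceedance of the shuffled percentiles.

## Collective significance swings

Because the pulse train is the only noise source and is shared by every
neuron, per-neuron AUC values co-fluctuate: a small finite-sample
difference in mean drive between the two categories of a particular trial
set shifts the whole AUC distribution together. The per-neuron
selectivity *pattern* is therefore highly reproducible across fresh trial
draws (AUC vectors correlate above 0.95), while the *fraction* of neurons
crossing the fixed shuffle threshold can swing substantially — which is
why the fraction selective varies so widely across networks and draws
(the reference ensembles span 0.14–0.82) and why a sizeable share of
neurons change significance status between tasks. Interpret
fraction-selective and status-change numbers at the ensemble level, not
per network.

## Known limitations

The eigen-spectrum analysis summarizes linear behaviour near the
spontaneous state; the driven network is weakly nonlinear, so mode-level
predictions are indicative rather than exact. The spectral radius of the
linearized connectivity runs a little below the reference value under
these conditions (the fixed point sits where the transfer slope is small,
and the radius is sensitive to exactly where the solver lands). Decoding
accuracy depends mildly on the SVM regularization constant at small
training sizes. Ensembles of 6 networks estimate across-network spreads
coarsely; all reported tolerances account for that.
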