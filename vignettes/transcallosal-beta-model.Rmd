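---
title: "A two-column neural mass model of transcallosal beta ERD/ERS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-column neural mass model of transcallosal beta ERD/ERS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`callosim` simulates the right and left sensorimotor areas as two
four-population cortical columns exchanging delayed excitation through the
corpus callosum, and measures how that exchange shapes beta-band
event-related desynchronization and synchronization (ERD/ERS) during a
motor-imagery-like task. This vignette documents the model, every
convention the implementation had to fix where more than one choice was
defensible, and what the simulated protocol does and does not say about
real EEG.

## The single column

Each column lumps four neural populations: pyramidal cells (`p`),
excitatory interneurons (`e`), slow inhibitory interneurons (`s`, GABA-A
slow kinetics) and fast inhibitory interneurons (`f`). Average membrane
potential is converted to average spike density by a sigmoid shared by all
populations,

$$z(v) = \frac{2 e_0}{1 + e^{r (s_0 - v)}},$$

with half-maximum rate $e_0 = 2.5$ pps, slope $r = 0.56$ /mV and centre
$s_0 = 6$ mV, so rates live in $(0, 5)$ pps. We speak of the *working
point* (WP) of a population: the mean rate around which it operates. Below
$z \approx 1$ the population is in low saturation, between 1 and 4
approximately linear, above 4 in high saturation; the WP decides how
strongly fluctuations of the input are passed through.

Synapses are critically damped second-order filters
$\ddot y = G\,\omega\,u - 2\omega \dot y - \omega^2 y$ with impulse
response $G \omega t e^{-\omega t}$ (`kernel_impulse_response()`). Three
kernels are distinguished — excitatory ($G_e, \omega_e$), slow inhibitory
($G_s, \omega_s$) and fast inhibitory ($G_f, \omega_f$) — and seven
dimensionless connectivity constants, all fixed multiples of $C = 135$,
wire the populations (`column_params()`). The pyramidal membrane
potential $v_p = C_{pe} y_e - C_{ps} y_s - C_{pf} y_f$ is the column
output, a surrogate of the local field potential seen by EEG.

Three kernel presets place the column's rhythm in the low (LB), medium
(MB) or high (HB) beta range:

| preset | $G_e$ | $\omega_e$ | $G_s$ | $\omega_s$ | $G_f$ | $\omega_f$ |
|--------|------:|-----------:|------:|-----------:|------:|-----------:|
| LB     | 3.9   | 55         | 4.3   | 25         | 25    | 250        |
| MB     | 3.9   | 75         | 4.3   | 33         | 25    | 330        |
| HB     | 4.3   | 90         | 4.6   | 36         | 29    | 380        |

The $\omega$ values are lumped rate constants in s$^{-1}$, used exactly as
tabulated. External input $u_p$ enters the excitatory synapse that feeds
the pyramidal population as $u_p / C_{pe}$: because the membrane potential
multiplies $y_e$ by $C_{pe}$, this makes the input gain into $v_p$
independent of $C_{pe}$ and is exactly the classic Jansen-Rit form after
rescaling of the state. A second external input $u_f$ reaches the fast
interneurons through an auxiliary excitatory kernel. Units of the
postsynaptic variables $y$ are millivolts throughout.

## Two columns and the transcallosal connection

Long-range projections originate from pyramidal cells only and are
excitatory; their *functional* sign depends on the target. A global gain
$K$ is split 30% onto the contralateral pyramidal input (excitatory
effect) and 70% onto the contralateral fast inhibitory interneurons (net
inhibitory effect), with a conduction delay $T = 13$ ms, the typical
transcallosal conduction time between motor cortices:

$$u_i(t) = n_i(t) + K_i\, z_p^{\text{other}}(t - T), \qquad
  K_p = 0.3K,\; K_f = 0.7K,\; K \in [0, 100].$$

Equilibria of the coupled system do not depend on $T$, but its dynamics
do; the delayed pyramidal rate is held in a circular buffer, pre-filled
with zeros at the start of the integration.

## Inputs

**Driving noise.** All unmodelled afferents are summarized as Gaussian
white noise: mean 40 pps into the pyramidal pathway and 3 pps into the
fast-inhibitory pathway of each column, with intensity $\sigma = 1$
pps/$\sqrt{\text{Hz}}$, four mutually independent streams (2 columns × 2
targets) derived from one master seed. The white-noise *bandwidth
convention* had to be fixed by us: a noise standard deviation alone does
not define a continuous-time process. We adopt the Euler-Maruyama
convention — each integration step draws $\mathcal N(m, \sigma^2/dt)$ — so
the band-limited noise power is independent of the step size and halving
$dt$ does not change any result. The alternative (per-step draws of fixed
variance) makes the effective noise power proportional to $dt$ and, at
$dt = 0.1$ ms, produces pyramidal-rate fluctuations of order 0.01 pps —
far too small to drive the stochastic transitions between working regimes
that the model is built to study. Under the adopted convention baseline
$z_p$ fluctuations are of order 0.2 pps and grow to order 1 pps in the
strongly coupled regime.

**Modulating input.** The imagery task is a smoothed trapezoid added to
the left (contralateral) column's pyramidal input: 4 s baseline, 2 s rise,
4 s plateau at 100 pps, 2 s fall, 4 s rest (16 s total). "Smoothed" is
realized with raised-cosine (half-Hann) ramps, making the waveform
continuously differentiable at every join; its integral is then exactly
`plateau_amp × (plateau_s + rise_s)`, which the test suite checks
analytically. The task amplitude saturates the target column
(equilibrium shift of about +7 mV on $v_p$).

## Integration

The 20 state variables (10 per column) are advanced by fixed-step
Euler-Maruyama at $dt = 10^{-4}$ s. The step is set by the fast inhibitory
kernel ($\omega_f$ up to 380 s$^{-1}$): at $dt = 10^{-4}$ the stiffest
mode has $\omega\,dt \approx 0.04$, comfortably stable, and a noise-free
run changes its mean $z_p$ by less than $10^{-3}$ pps when the step is
halved (checked in the suite). Outputs are decimated to 100 Hz by direct
subsampling; within a 1 ms output interval the recorded states are smooth,
so no anti-alias filter is applied by default. Each run starts from the
zero state with a 2 s warm-up that is excluded from every analysis window;
the warm-up is long compared to the slowest kernel time constant
(1/25 s) and lets the stochastic steady state establish itself. Non-finite
states abort with a diagnostic naming the offending step and state
variable. Given a master seed, runs are bit-reproducible, and swapping the
two columns' noise streams exactly swaps their trajectories (the model is
left/right symmetric; verified bit-exactly in the suite).

## The algebraic fixed point as an independent oracle

`fixed_point()` solves the equilibrium equations directly — noise replaced
by its mean, derivatives zeroed — by bracketed scalar root finding (one
column) or multi-start damped Newton iteration on both pyramidal
potentials (two columns). It shares no code with the integrator and serves
as the independent oracle for the working points: the uncoupled LB column
has a unique equilibrium at $z_p \approx 4.33$ pps (pyramidal near the
upper knee of the sigmoid), $z_e \approx 5.0$ (fully saturated),
$z_s \approx 4.6$ and $z_f \approx 0.47$ (low saturation), and the
noise-free simulation settles onto it to better than $10^{-3}$ pps. With
coupling, the solver returns *all* coexisting equilibria: beyond
$K \approx 7$–9 a symmetric equilibrium coexists with two mirror-image
asymmetric (winner/loser) ones — the structural basis of the three working
regions described below.

## Spectral analysis and ERD/ERS

PSDs use the modified periodogram: sliding 1 s Hamming windows advanced by
0.01 s (99% overlap), demeaned per window, scaled as one-sided density so
that the PSD integral reproduces signal variance (Parseval, verified to
1% on tones). The 0.01 s figure is interpreted as the hop, not as the
overlap; the literal alternative (0.01 s of overlap) would make the
time-resolved power maps 1 s coarse and unusable for a 2 s ramp. The taper
is configurable (`hamming`, `hann`, `rect`).

Band power $P(t)$ is the band-integrated power of each window, stamped at
the window centre, computed in the sub-band of the active preset (LB
14–19, MB 20–24, HB 25–30 Hz) — using the band the column was
parameterized for makes ERD/ERS comparable across presets. Then

$$\mathrm{ERD/ERS}(\%) = 100\,\frac{P(t) - P_B}{P_B},$$

with $P_B$ the mean over all windows lying entirely inside the 4 s
baseline; by construction the baseline-interior mean of every curve is 0%.
Trial-averaged curves use 20 independent seeds by default (configurable);
20 brings the Monte-Carlo error of a plateau mean to a few percentage
points.

## Working regions and boundary detection

Sweeping $K$ with driving noise only, the trial-mean $z_p$ of both columns
falls in three regions: (1) a concave decline out of high saturation, (2)
a convex decline through the linear region — where transmission between
the columns, and the oscillation amplitude, are largest — and (3)
winner-take-all: one column (decided by noise) collapses to silence while
the other returns to its uncoupled working point, $z_p < 0.5$ versus
$\approx 4.3$ pps. The inhibited column's residual output has only
low-frequency (2–7 Hz) spectral content.

Because the collapse within a finite 16 s trial is a stochastic escape,
the 2→3 boundary is not a sharp number: near the boundary only a fraction
of realizations collapse, and that fraction grows with $K$ over a window
of 10–20 K-units (widest for LB). `classify_regions()` therefore
estimates, per $K$, the probability that a trial ends winner-take-all
(loser mean below 0.5 pps, winner above 3 pps), regularizes it to be
monotone in $K$ by isotonic regression (the regime can only become more
reachable as $K$ grows), and places $k_{23}$ where this probability
reaches 0.4 — the point at which collapse stops being exceptional. For
winner/loser curves without per-trial records a threshold rule is used
instead (gap above 2 pps or loser below 0.5 pps). The 1→2 boundary
$k_{12}$ is the inflection of the column-averaged curve: the first
concave-to-convex sign change of its second difference after a 5-point
running-mean smoothing. On constructed curves with a known inflection and
collapse point both rules recover the boundaries exactly (unit-tested);
on simulated sweeps (K step 2, 5 trials per K) the detected $k_{23}$
varies by a few K-units across master seeds, more for LB whose escape
window is widest.

## What the simulations show, and where they deviate from expectation

The headline numbers recomputed by `scripts/acceptance.R` at the default
problem sizes: uncoupled working points $z_p \approx 4.32$,
$z_e \approx 5.00$, $z_f \approx 0.47$ pps, in agreement with the
algebraic fixed point to better than 0.01 pps; winner-take-all at $K = 70$
in every seeded run (winner $\approx 4.32$, loser $< 0.01$ pps, inhibited
column's spectral peak at 1–3 Hz); region-3 onset at $K \approx 14$–18
(HB) and 34–36 (LB); single-column spectral peaks at 13 (LB), 17 (MB) and
21–22 (HB) Hz from 20-seed averaged periodograms.

Two observed behaviours deserve honest flags. First, the measured spectral
peaks sit at the low edge of (or just below) their nominal sub-bands: the
columns' resonances under these kernel constants are a little slower than
the band labels suggest, and the driven spectrum's argmax sits a further
bin lower because the noise enters through the excitatory kernel's
low-pass, tilting power toward low frequencies. Second, the ipsilateral
ERS during the task is confined to small couplings: the task saturates the
target column, which both *increases* the inhibition it sends across
(pushing the ipsilateral WP into the high-gain linear region — the ERS
mechanism) and *silences* the fluctuations it transmits (removing drive —
an ERD mechanism). In this implementation the second effect wins from
single-digit $K$ upward in the LB pair, so clear ERS (tens of percent, cf.
the +43% HB example in the README) appears for $K \lesssim 7$ while larger
gains yield band-power loss on both sides. The contralateral ERD itself is
robust at all couplings, is weaker at the large-$K$ preset than at the
small one, and both sides return to baseline after the task.

## What the generator emulates — and what it does not

The synthetic protocol reproduces: stationary background drive, a
stereotyped 16 s imagery trial, hemispheric symmetry broken only by noise,
and EEG-like observation at 100 Hz of a field-potential surrogate. It does
not emulate: thalamic feedback (deliberately excluded; the model targets
cortically generated beta, not alpha/theta), synaptic plasticity, more
than two columns, coloured or non-stationary noise, task-timing jitter
across trials, volume conduction, measurement noise, or artifacts. Passing
tests therefore validate the mechanism — WP-dependent gain plus delayed
interhemispheric inhibition — not any claim that real EEG spectra or
single-subject ERD/ERS magnitudes are reproduced quantitatively.

## Numerical choices and degenerate inputs

* Sigmoid evaluation is overflow-safe for arbitrarily large |v| (logistic
  via `plogis`).
* `peak_frequency()` breaks ties toward the lower frequency bin.
* ERD/ERS with zero baseline power, empty analysis bands, bands above
  Nyquist, signals shorter than one window, and averaging over empty
  windows are all errors, not silent NaNs.
* The fixed-point solver reports every distinct root found from its
  multi-start grid and errors with the residual if nothing converges.
* Noise sd of 0 is a valid (deterministic) setting used by the oracle
  tests.

## Problem sizes

Default experiment sizes were chosen so a full check of the package runs
on a laptop in a few minutes: 16 s trials at $dt = 10^{-4}$ s; 10–20 seeds
for averaged spectra and working points; 20 seeds for winner-take-all
statistics and trial-averaged ERD/ERS; sweeps over $K$ in steps of 2 with
5 trials per value (the CLI's `--full` flag switches to 101 K-values and
20 trials). Unit tests use 2–4 s trials where the full protocol is not
needed.
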