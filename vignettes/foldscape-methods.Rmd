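---
title: "Methods: trajectory idealization, fluctuation analysis and landscape reconstruction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trajectory idealization, fluctuation analysis and landscape reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foldscape)
```

# The measurement and the model

A magnetic-tweezers equilibrium experiment holds a single protein domain at
constant force and records its end-to-end extension $z(t)$ at 1,000-1,500 Hz
for hours to days. Under these passive-clamp conditions the molecule hops
spontaneously between conformations; the extension time series is a 1D
projection of the folding free-energy landscape onto the pulling axis.
`foldscape` implements the full analysis chain for such recordings, built
around the talin R3 mechanosensor (110 residues, a four-helix bundle whose
coexistence force is about 8.5 pN):

1. **Idealization** — segment the recording into conformational dwells,
   excising transition paths (`estimate_levels()`, `label_and_excise()`).
2. **Fluctuation analysis** — convert per-conformation excess extension
   variance into unstructured contour length through the freely-jointed
   chain (FJC) model (`fragment_statistics()`, `summarize_state()`).
3. **Kinetics** — dwell statistics, kinetic-network tables, running
   unfolded fraction, proline-isomer switch detection, force-response and
   rescue-probability fits (`build_transition_table()` and friends).
4. **Landscape** — point-spread-function (PSF) estimation from a reference
   bead and Jansson deconvolution of the extension histogram followed by
   Boltzmann inversion (`estimate_psf()`, `reconstruct_landscape()`).
5. **Structural hypotheses** — enumeration and ranking of foldon (per-helix)
   configurations against measured offsets and contour lengths
   (`enumerate_configs()`, `rank_against_measurement()`).
6. **Simulation** — a continuous-time Markov jump-process generator with an
   FJC-consistent observation model (`simulate_state_path()`,
   `render_trajectory()`), so that every stage can be validated against
   known ground truth.

# Polymer model

The unstructured polypeptide is modeled as a freely-jointed chain with Kuhn
length $l_K = 1.1$ nm at thermal energy $kT = 4.11$ pN nm. With reduced
force $\beta = F l_K / kT$, the mean extension per unit contour length is
the Langevin function $\varphi(\beta) = \coth\beta - 1/\beta$, and the
one-axis extension variance per unit contour length is

$$ v(F) = l_K\left[\frac{1}{\beta^2} - \operatorname{csch}^2\beta\right], $$

which decreases from $l_K/3$ at zero force towards zero at high force. Only
unstructured chain contributes measurably to the fluctuations, so the
excess variance $\langle\Delta\sigma^2\rangle$ of a conformation relative
to the natively folded reference yields its unstructured contour length

$$ \Delta L_C = \frac{\langle\Delta\sigma^2\rangle}{v(F)} . $$

The quotient form is fixed by dimensional analysis (nm$^2$ over nm). Both
$\varphi$ and the bracket are evaluated by a series expansion below
$\beta = 0.15$ (crossover chosen where both branches agree to better than
$10^{-9}$) because $1/\beta^2 - \operatorname{csch}^2\beta$ suffers
catastrophic cancellation at small $\beta$. The constants live in
`fjc_params()` and are never hard-coded in operations.

**A documented inconsistency.** For talin R3 the tabulated unfolded-state
excess variance (5.8 nm$^2$) inserted at 8.5 pN gives
$\Delta L_C = 35.1$ nm, not the reported 42.5 nm increment; the per-molecule
forces behind the published average are not stated. The package therefore
keeps force an explicit argument everywhere and does not tune constants to
reconcile the two numbers. Recovery tests instead generate the unfolded
variance *from* the forward model ($42.5 \times v(8.5\,\mathrm{pN}) =
7.01$ nm$^2$), making the round trip self-consistent.

Similarly, three of the catalog's printed unstructured percentages (states
iii, iv and conformation M$_1$) are not equal to $100 L_c/42.5$ of their own
rows; `summarize_state()` always reports the ratio-consistent value.

# Idealization

Levels are estimated by fitting a Gaussian mixture to the (deterministically
thinned) extension histogram, with the component count given or selected by
BIC among 1-4. Thresholds are placed **at the component means** — the
conformations' average extensions — not at midpoints; a transition path (TP)
is the maximal run of samples between the last touch of the origin
conformation's mean and the first touch of the destination's mean. TP
samples are excluded from every downstream statistic because they are
diffusive barrier crossings, not dwell samples. Excursions beyond the home
mean that return without reaching another level's mean stay inside the
dwell, so the per-dwell sample distribution is unbiased.

Numerical choices:

* Adjacent mixture components must be resolvable; the fit is rejected when
  the overlap proxy $\Phi(-\mathrm{gap}/(\sigma_i+\sigma_j))$ exceeds 0.2.
* Dwells shorter than 3 samples (configurable) are absorbed into their
  neighbour: at 1,500 Hz this is the instrument's 1-2 ms resolution floor,
  below which apparent events are noise chatter.
* Segments are stored as 1-based inclusive sample ranges; the union of
  dwells and TPs reproduces the recording exactly (a tested invariant).
* The first and last dwells are duration-censored and excluded from mean
  dwell times but kept for occupancies.

Multi-level regions use the same rule pairwise: from level $j$, whichever
other level's mean is reached first terminates the dwell; with finite
sampling a jump can skip a level, in which case the farthest mean crossed in
that frame wins and the skipped visit is below resolution (such non-adjacent
events are tested to stay below 1% of adjacent ones under the tabulated
kinetics).

# Kinetics

`build_transition_table()` reports, per directed transition, the mean
waiting time in the origin conformation, its standard error and the event
count, pooled over recordings. The running unfolded fraction
$P_U = \langle t_U\rangle / (\langle t_U\rangle + \langle t_F\rangle)$ over
a sliding window of $n = 10$ transitions is the change-point statistic for
proline cis-trans isomer switches; a switch is declared by hysteresis
(defaults: onset at $P_U \ge 0.8$, offset at $P_U \le 0.6$, three
consecutive windows — only an "abrupt change" is prescribed by the
phenomenology, so the cutoffs are configuration-exposed). The intrinsic
isomerization rate is fitted through the origin from per-force switch rates,
$r(F) = P_U(F)\,k$, because isomerization is only available to the unfolded
chain and is otherwise force-independent.

The folded-fraction force response is fitted with a two-parameter logistic
in force (via a quasibinomial GLM), returning the coexistence force
$F_{0.5}$ and the width; occupancy (time fraction) defines the folded
fraction, matching the time-based definition of $P_U$. A rescue trial
counts as successful when at least 5 native transitions occur within 200 s
after the pulse (configurable).

In the simulator, each directed edge of the kinetic network is an
independent exponential clock with rate $1/\bar t$, the reciprocal of that
edge's tabulated mean transition time (competing-clocks interpretation; it
reproduces the observed ~1.3 s unfolded dwell while keeping rare entries
rare). Native folding edges carry Bell force sensitivity,
$k(F) = k_0 e^{\pm (F - F_{0.5})\Delta x / kT}$ with a total
distance-to-transition-state of 12 nm split symmetrically, which gives the
native response its steep ~1.5 pN (10-90%) width; rare-state entry and exit
clocks are force-independent by default because only their occupancies, not
their entry rates, are quantified force-resolved. Rare states attach to the
unfolded conformation only (the short-lived intermediate also connects to
the folded state).

# Landscape reconstruction

The PSF width is the standard deviation of a surface-attached reference
bead's trace after a zero-phase second-order Butterworth high-pass (default
2 Hz — above the drift band, three decades below Nyquist, so white noise is
attenuated by under 0.2%); an interquartile-range estimate cross-checks
Gaussianity. The default width is 0.85 nm.

The measured extension histogram (0.25 nm bins, at most a third of the PSF
width) is deconvolved with Jansson's iterative relaxation method:

$$ p \leftarrow p + r(p)\,(m - S p), \qquad
   r(p) = r_0\left(1 - \frac{2|p - A/2|}{A}\right), $$

with $S$ the Gaussian PSF operator (reflect-padded at the boundaries,
switchable to zero padding), $r_0 = 1$, at most 500 iterations, and an L1
residual-improvement stop at $10^{-6}$. The relaxation ceiling $A$ is set
to **twice** the running maximum of $p$: the weight then rises linearly
from zero at empty bins (softly enforcing non-negativity, with an explicit
clamp and re-normalization each iteration) to $r_0$ at the modal bin. A
ceiling at the current maximum itself would zero the weight exactly where
the deconvolved peaks must grow, and measurably stalls the iteration; with
the factor-two ceiling a blurred two-Gaussian density is recovered with a
greater than 60-fold L1 improvement within the default iteration budget.

Boltzmann inversion $G = -\ln p$ (density floored at $10^{-8}$) with the
minimum at zero yields the landscape; the barrier is the maximum of $G$
between the two deepest minima (required to be at least 2 nm apart) minus
the shallower minimum. For **histogram-estimated** densities the barrier
sits at the lowest-density bins, where deconvolution-amplified counting
noise makes the raw maximum over the inter-basin bins biased upward (the
maximum of many noisy values); `reconstruct_landscape()` therefore smooths
the free-energy curve with an order-2 Savitzky-Golay window of 3 nm before
reading off basins and barrier. The smoothing reproduces any locally
quadratic landscape exactly, is off by default in `landscape_from_density()`
(exact densities need no regularization), and its width is a parameter.

# Structural hypotheses

The four helices are treated as independently folding units (foldons). The
default topology splits the 110 residues into four 24-residue helices
separated by short loops (the true boundaries are not part of the analyzed
data; the topology is fully overridable). Each of the $2^4$ configurations
predicts: the released unstructured contour length (0.4 nm per residue of
unfolded helix — loops are unstructured in the native reference too, so
they cancel from the increment), the unstructured fraction (normalized by
the all-unfolded release), and the extension offset
$\Delta z = \Delta L_C\,\varphi(\beta)$ plus optional per-helix extension
contributions (default 0, the helix-axis-orthogonal assumption).
Configurations are ranked by weighted squared mismatch against a measured
$(\Delta z, \Delta L_C)$ pair, ties resolved toward fewer unfolded helices.
The output is a ranked list of *hypotheses compatible with the
measurements*, not structure determinations — distinct configurations with
equal helix sizes are prediction-degenerate by construction.

# What the simulator does and does not emulate

`simulate_state_path()` + `render_trajectory()` produce recordings with:
exponential dwells from competing clocks, Bell force rescaling under
arbitrary force protocols (holds, quenches, rescue pulses), per-conformation
Gaussian observation noise of sd $\sqrt{\sigma_\mathrm{PSF}^2 +
\Delta\sigma_i^2}$, optional linear/sinusoidal drift, optional AR(1) noise
correlation, and optional finite linear transition-path ramps (default:
instantaneous jumps; 2 ms ramps exercise the excision logic). The true
state path travels with the trajectory for recovery tests.

Not emulated: bead-image formation and tracking artifacts beyond a Gaussian
PSF, bead-magnet magnetostatics, linker compliance, genuinely diffusive
(non-linear) transition paths, and non-exponential dwell-time families.
Passing recovery tests therefore demonstrates the correctness of the
analysis chain under the stated noise model, not robustness to every
instrumental pathology; the drift and AR(1) options exist precisely to probe
sensitivity beyond the white-noise assumption.

Simulation-backed tests use fixed seeds and the tabulated study conditions:
dwell and step-size recovery uses 5,000 s at 1,500 Hz; contour-length
recovery 2,000 s; the coexistence-force fit five 1,000 s recordings between
7.5 and 9.5 pN; barrier recovery $10^6$ histogram samples. Region
classification is validated on a 100-stretch corpus spanning all six
regions, with multi-conformation regions simulated with balanced internal
kinetics (as when they are probed at forces where every conformation is
populated); sparsely populated levels (a ~2% occupancy conformation at
coexistence) are otherwise genuinely unresolvable by a mixture fit on a
short stretch, which the level estimator reports as an error rather than
guessing.

# Worked example

```{r example, eval = FALSE}
net <- talin_network("i")                      # native two-state hopping
path <- simulate_state_path(net, 300, force_pN = 8.5, seed = 11)
traj <- render_trajectory(path, observation_spec(sampling_rate_hz = 1000),
                          conformations = net$conformations, seed = 12)
th <- estimate_levels(traj, k_levels = 2)
ideal <- label_and_excise(traj, th)
dwell_statistics(ideal)$transitions
summarize_state(fragment_statistics(ideal, traj, "N"), force = 8.5)
```

# Known limitations

* Mean dwell times are empirical averages without censoring corrections;
  maximum-likelihood or Bayesian rate inference is out of scope.
* The idealization is a threshold algorithm, not a hidden-Markov fit; at
  low signal-to-noise the debounce length trades missed events against
  false ones and should be tuned with the sampling rate.
* Deconvolution settings (relaxation constant, iteration budget, binning)
  are configuration-exposed defaults; the method's source names no values.
* The foldon topology is a default guess; all structural output is
  hypothesis ranking under that topology.
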