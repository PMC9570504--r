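---
title: "Models and methods behind gjvolt"
author: "gjvolt authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gjvolt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gjvolt)
```

# Scope

gjvolt implements the analysis chain used to characterize gap junction (GJ)
channels in dual whole-cell voltage-clamp experiments: macroscopic
transjunctional-voltage (V~j~) gating summarized by a two-state Boltzmann
fit; single-channel amplitude, slope conductance and open dwell-time
analysis; rank-based group statistics; and a van der Waals clash scanner
for the amino-terminal (NT) / second-transmembrane-helix (TM2) packing
interface of connexin structures. A stochastic simulator generates
junctional current traces whose stationary behaviour follows the same
Boltzmann law, so every stage of the chain is testable end to end against
known ground truth.

# The gating model

## Stationary law

The macroscopic observable is the normalized steady-state conductance

$$G_{j,ss}(V_j) \;=\; G_{min} + \frac{G_{max} - G_{min}}
        {1 + \exp\!\big[A\,(|V_j| - V_0)\big]},$$

fitted separately for each V~j~ polarity with its own $(V_0, A)$. $V_0$
(mV, stored as an absolute value) is the voltage of half-deactivation,
$A$ (1/mV) the gating sensitivity, $G_{min}$ the voltage-insensitive
residual conductance and $G_{max}$ the plateau (≈1 after normalization).

## Kinetic embedding

The fitted law says nothing about kinetics, so the simulator embeds it in
the minimal scheme consistent with it. Each channel is a three-state chain

* **main open** (unitary conductance $\gamma_{main}$, pS),
* **residual** ($\gamma_{res} = G_{min}\gamma_{main}$),
* **fully closed** (0 pS),

with opening rate $\alpha = k_0 e^{-A(|V_j|-V_0)/2}$ and closing rate
$\beta = k_0 e^{+A(|V_j|-V_0)/2}$: the Boltzmann exponent is split
symmetrically, so $\alpha/(\alpha+\beta)$ equals the Boltzmann open
probability identically in $V_j$, and $k_0$ (1/s) — the rate at
$|V_j| = V_0$ — is a free time scale that the stationary law cannot
constrain. A closing event enters the fully closed state with probability
`p_fullclose`, else the residual state; both gated states reopen at rate
$\alpha$, which preserves the Boltzmann open-state occupancy when the two
gated states are lumped.

Two deliberate simplifications: a real GJ has two hemichannel gates in
series, but since each polarity is fitted independently, one effective gate
acting on $|V_j|$ with polarity-specific parameters reproduces the fitted
observable; and with `p_fullclose` $> 0$ the *macroscopic* conductance
floor becomes $G_{min}(1-p_{fullclose})$ rather than $G_{min}$, which is
why the macroscopic simulation regime routes all closures through the
residual state (see below). Neither simplification is asserted as channel
biology.

## Choosing the free kinetic parameters

`gj_preset()` ships published Boltzmann/γ~j~ parameter sets for wild-type
Cx46, Cx50 and their NT point variants. The invented kinetic parameters
are anchored as follows, and flagged as calibration choices:

* $k_0$ is derived from **beta60**, the closing rate at $|V_j| = 60$ mV
  ($k_0 = \beta_{60} e^{-A(60-V_0)/2}$). Anchoring the mid-protocol rate
  rather than $k_0$ keeps kinetics usable across constructs whose $A$
  spans 0.06–0.19 /mV; anchoring $k_0$ itself would make steep-gating
  constructs either never close at 40 mV or flicker sub-millisecond at
  100 mV.
* **Macro regime**: $\beta_{60} = 1.25$/s for every construct and
  `p_fullclose = 0`. Slow kinetics keep the 5 ms blank + 10 ms peak
  window (see below) nearly relaxation-free even at $|V_j| = 100$ mV, and
  the pure open↔residual scheme makes the lumped stationary conductance
  follow the Boltzmann law exactly, so the macroscopic pipeline can be
  validated against the generating parameters.
* **Single-channel regime**: per-construct $\beta_{60}$ (wild-type Cx46
  1.2/s; its variants 3/s; the Cx50 family 2/s) so that simulated mean
  open dwell times reproduce the qualitative ordering of the experimental
  report (wild-type Cx46 longest, its variants clearly shorter, Cx50 and
  variants intermediate and similar), and `p_fullclose = 0.8`, so an
  analyzed stretch reliably visits the zero-current level while residual
  sojourns still occur occasionally — matching the appearance of published
  all-point histograms, which always contain the fully closed peak and
  sometimes a subconductance peak.

## Discrete-time stepping and noise

Channels are stepped at the sampling interval (10 kHz default) with
per-sample transition probabilities $1 - e^{-r\,dt}$, initialized at the
stationary distribution of the holding potential; the guard
$dt \cdot \max(r) \le 0.1$ refuses simulations where first-order stepping
is inaccurate, and rates are clamped at $10^4$/s (with a warning) as an
overflow guard. Recording noise is white Gaussian (SD in pA) low-pass
filtered at the acquisition cutoff (1 kHz default) with the same Gaussian
filter used for analysis, mimicking an analog acquisition chain. Trace
current is $V_j \cdot (n_{open}\gamma_{main} + n_{res}\gamma_{res})/1000$
pA. The per-sample Markov core is compiled (Rcpp) and draws from R's RNG,
so traces are bit-reproducible given a seed.

# Macroscopic analysis

* **Peak current**: mean over `[t_on + 5 ms, t_on + 15 ms]`, baseline
  subtracted. The description "at the beginning of the current" leaves the
  window open; 5 ms skips the capacitive transient of a 1 kHz acquisition
  chain, and 10 ms of averaging is shorter than any plausible gating
  relaxation at the kinetic scales above.
* **Steady state**: mean of the final 500 ms of the step (the step must be
  at least that long). The default 7 s step leaves the final 500 ms at
  gating steady state for the default kinetics.
* **Conductances**: $g = i/V_j$ (pA/mV = nS) per step;
  $g_{norm} = g_{ss}/g_{peak}$ normalizes each step by its own peak. The
  pair conductance $g_j$ comes from the ±20 mV steps, where gating is
  weakest; a pair is *coupled* if $g_j > 0.01$ nS (≈3× the noise-limited
  conductance resolution at the default noise), and pairs with
  $g_j \ge 9$ nS are flagged for exclusion from gating analysis to limit
  voltage-clamp errors.
* **Boltzmann fit**: bounded Levenberg–Marquardt least squares
  (unweighted by default) with $0 \le G_{min}, G_{max} \le 1.5$,
  $0 \le A \le 1$, $0 \le V_0 \le 150$, multistarted over
  $V_0 \in \{20, 40, 60, 80\}$ mV; the best converged start wins.
  $G_{max}$ is free even though published tables omit it. At least four
  distinct $|V_j|$ per polarity are required; fits pinned at $A \approx 0$
  are flagged degenerate rather than reported as gating.

One subtlety the tests encode: with typical parameters
($V_0 \approx 39$ mV, $A \approx 0.09$), the true steady state at
±20 mV is already ~0.89–0.91 of the holding-potential stationary level, so
$g_{norm}(\pm 20)$ is expected slightly below 1; the normalization sanity
check therefore compares against the model's analytic ratio rather than
literal unity.

# Single-channel analysis

* **Filter**: Gaussian kernel with $\sigma_t = 0.1325/f_c$, which places
  the −3 dB point at $f_c$ (200 Hz default — the convention of standard
  single-channel software); reflection at the edges, length preserved.
* **All-point histogram**: first 2 s of the step by default
  (configurable). Bin width follows Freedman–Diaconis with a 0.05 pA
  floor, additionally capped so the occupied range gets at least ~50 bins:
  on strongly bimodal segments the IQR can straddle two conductance
  levels, and uncapped FD then yields a dozen bins — too coarse to carry a
  Gaussian decomposition.
* **Level fitting**: 2–4 Gaussian components, seeded by prominence-based
  peak detection, fitted by bounded least squares on the bin counts with
  component SDs capped at a quarter of the range (a conductance level is a
  narrow mode; the cap prevents one component from degenerating into a
  broad pedestal). The component nearest the zero-current reference is
  the baseline — but only if it lies within max(0.5 pA, 4 SD) of that
  reference: a stretch in which the channel never fully closed has no
  zero-current level, and silently taking the residual level as baseline
  would bias $i_j$ low by a factor $1 - G_{min}$. Such stretches are
  returned as "no events", exactly like unimodal histograms. The main
  open level is the component farthest from baseline carrying ≥5% of the
  samples; anything else is a subconductance level, reported but excluded
  from γ~j~.
* **Slope conductance**: within a pair, amplitudes at the same $|V_j|$
  (both polarities) are averaged; each pair contributes an ordinary
  least-squares slope of $i_j$ on $|V_j|$ with free intercept (the
  experimental description implies pooling across polarity but is silent
  on the intercept; leaving it free absorbs any baseline offset), and the
  per-pair mean ± SD plus a pooled regression on pair-averaged points are
  reported.
* **Idealization**: half-amplitude threshold between the baseline and
  main-open means on the 200 Hz-filtered record; sojourns shorter than the
  dead time $2 \times 0.3321/f_c$ (twice the filter rise time, ≈3.3 ms at
  200 Hz) are merged into their flanks, shortest first, so band-limited
  spikes never create events and merging can only reduce the event count.
  The event-detection method of the original analysis is unstated;
  half-amplitude thresholding with a fixed dead time is the standard
  transparent choice.
* **Dwell statistics**: arithmetic mean open duration per voltage with the
  event count; voltages with no open events are absent rather than zero.

When the full pipeline is validated against simulated ground truth, the
histogram window is lengthened at low voltages (whole step at 40 mV, 4 s
at 60 mV, 1 s at 80 mV in the test configuration): gating is slow at
40 mV, so a fixed 2 s window would often contain no full closure, whereas
at 80 mV the open state is gone after the first few hundred milliseconds.
This mirrors what an analyst does when boxing a stretch that shows both
the open and the closed level.

# Group statistics

The rank tests are implemented from first principles so group results
carry no dependency beyond base R's distribution functions: Kruskal–Wallis
H with tie correction against $\chi^2_{k-1}$; Dunn's post hoc z from
pooled ranks with tie correction, restricted to variant-versus-reference
comparisons, Bonferroni-adjusted over the comparisons performed (the
original analysis software applies some multiplicity control but does not
document which; Bonferroni is the conservative, switchable default — exact
published p-values are therefore not reproducible in general); the
Mann–Whitney U test with the full exact null distribution (computed by the
classical counting recurrence) whenever there are no ties and
$n_a n_b \le 400$, otherwise a tie-corrected normal approximation with
continuity correction; and the pooled-variance two-sided Student's t.
Degenerate inputs (all values identical; zero variance with equal means)
return p = 1 by convention.

The type-I error of all four tests is validated by simulation at
$\alpha = 0.05$ with n = 12 per group ($2 \times 10^4$ null replicates).
Twelve per group is the smallest size at which the nominal 5% level is
actually attainable by the discrete rank tests: at n = 6 the exact
Mann–Whitney test's largest attainable size below 0.05 is ≈0.041, so a
[0.04, 0.06] band would be testing the discreteness of the null
distribution, not the implementation.

# Clash screening

`read_structure()` parses ATOM/HETATM records (via bio3d), skips waters
and hydrogens, keeps the highest-occupancy alternate location and rejects
truncated records with the offending line number. `clash_scan()` evaluates
every inter-selection heavy-atom pair within 5 Å using a cell-list
neighbour search (cost proportional to contacts, not atom pairs), with van
der Waals radii C 1.70, N 1.55, O 1.52, S 1.80 Å (default 1.70 Å with a
warning for anything else) and a 0.4 Å clash tolerance — common
clash-screening practice; the original structural assessment was visual,
so no numeric threshold can be taken from it. Pairs within two covalent
bonds (distance-inferred bonding over the whole structure) are excluded;
a pair clashes when $d < r_1 + r_2 - tol$ and is a contact when
$d < r_1 + r_2 + 0.5$. The scan is validated for exact equality against a
brute-force all-pairs oracle on toy structures up to 500 atoms, and is
symmetric under selection swap and monotone in the tolerance.
`interface_profile()` tabulates minimal distances and classifications for
NT (4–17) × TM2 (85–95) residue pairs per subunit and against the adjacent
chain. Residue exchange/mutation modelling is out of scope: the scanner
reports the geometry of the coordinates it is given.

# What the simulator does and does not emulate

Emulated: Boltzmann-distributed stationary gating per polarity with
realistic parameter presets; main/residual/fully-closed conductance
levels; exponential sojourn times; channel-count scaling; Gaussian
recording noise shaped by a 1 kHz acquisition filter; the ±20…±100 mV
protocol; per-seed reproducibility.

Not emulated: two-hemichannel series (contingent) gating; hemichannel
currents in undocked connexons; chemical/pH/Ca^2+^ gating;
series-resistance and space-clamp artifacts (the 9 nS exclusion rule is
implemented, but the clamp error it protects against is not simulated);
heterotypic junctions; correlated or 1/f instrumentation noise; slow
drift. Passing end-to-end tests therefore demonstrates correctness of the
analysis chain under the stated model, not robustness to every artifact of
real recordings.

# Problem sizes and tolerances used in validation

The shipped validation uses: noiseless Boltzmann round trips on the five
protocol voltages (recovery to 10^−3^); the single-channel pipeline on
five conductance presets (93–220 pS), three simulated pairs × two sweeps ×
±{40, 60, 80} mV each, with recovery required within 5%; stationary
occupancy on a 2000 s single-channel record (≈2.6 × 10^4^ gating cycles,
agreement within 3 SE) and mean open dwell versus 1/β on ≥1000 events
(5%); 2 × 10^4^ null replicates for the type-I checks; and 60–500-atom
toys for the exact clash-scan comparisons. These sizes were chosen so
Monte-Carlo error sits well inside each tolerance.

# Known limitations

* The Boltzmann fitter reports a single best local optimum from its
  multistart; pathological point sets with fewer than four informative
  voltages are rejected rather than extrapolated.
* Steeply gating constructs relax within the 15 ms peak window at
  |V~j~| ≥ 80 mV for fast kinetic settings; the macro-regime default
  kinetics are deliberately slow, and peak-window bias should be
  re-examined if `beta60` is raised substantially.
* Dwell-time estimates carry the usual missed-event bias of fixed
  dead-time idealization; no first-latency correction is applied.
* `p_fullclose` is a single voltage-independent branching probability; real
  residual-state kinetics are richer.
* Exact Mann–Whitney p-values are computed only without ties; tied data
  fall back to the corrected normal approximation regardless of size.
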