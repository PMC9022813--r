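---
title: "Modeling hybridization in random-sequence DNA pools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling hybridization in random-sequence DNA pools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsdna)
```

## The problem

A random-sequence DNA pool of length $L$ ("$L$N") is an equimolar mixture
of all $4^L$ sequences. Upon cooling, strands hybridize — but almost never
with their exact complement, which makes up only a $4^{-L}$ share of
possible partners. Instead the pool populates a spectrum of imperfect
duplexes whose statistics are governed by the balance between binding free
energy (favoring few defects) and combinatorial degeneracy (favoring
many). `rsdna` computes this balance quantitatively: ensemble melting
curves, melting temperatures, the temperature-resolved distribution of
pairing errors, and the pairing yield of a tagged complementary pair
spiked into the pool, as in fluorescence contact-quenching assays.

## Model structure and assumptions

1. **Two-state duplexes.** Every pairing is on/off; no partially zipped
   intermediates, hairpins, bulged loops or multi-helix states. This is
   adequate for short oligomers ($L \le 20$), which is also where the
   pool enumeration stays combinatorially manageable.
2. **Defect-vector classification.** A duplex between equal-length
   strands is classified by
   $\alpha = (\alpha_s, \alpha_{e1}, \alpha_{e2}, \alpha_i)$: the mutual
   alignment shift, the runs of consecutive mismatches at each duplex
   end, and the count of internal (flanked) mismatches. A configuration
   must keep at least two paired bases. The number of partner sequences
   realizing a class against any fixed reference is
   $g(L,\alpha) = n_b^{|\alpha_s|}(n_b-1)^{\alpha_{e1}+\alpha_{e2}+\alpha_i}
   \binom{L-2-|\alpha_s|-\alpha_{e1}-\alpha_{e2}}{\alpha_i}$;
   the test suite reproduces this count exhaustively for $L=3,4,5$ and
   verifies that every (partner, shift) combination maps to exactly one
   class.
3. **Mean-field energetics.** Sequence detail is replaced by the
   strong-base fraction $f_{CG}$: stack enthalpies/entropies are averaged
   over the 16 ordered nearest-neighbor quartets with base probabilities
   set by $f_{CG}$, and a duplex of class $\alpha$ is assigned
   (intact stacks) × (averaged stack) + averaged initiation + defect
   increments. Pool observables then require only a sum over classes
   weighted by $g \cdot \zeta$, with
   $\zeta = [c]\,e^{-\Delta G/RT}$, instead of the prohibitive
   $4^L \times 4^L$ pair enumeration. Exhaustive per-sequence summation at
   $L \le 6$ (`theta_sequence_oracle()`) confirms the class-sum identity
   exactly, and its average over random references matches the
   closed-form ensemble curve within sampling error.
4. **Equilibrium only.** No kinetics, hysteresis or liquid-crystalline
   ordering; concentrations are assumed unlimited per species (no
   stoichiometric depletion).

## Thermodynamic parameters

All internal computation uses kelvin, kcal/mol and cal/(mol K);
user-facing grids are built with `melting_grid()` (default 0–95 °C in
0.25 °C steps) and converted with `kelvin()`/`celsius()`.

The parameter file `inst/extdata/nn_unified_dna.tsv` ships:

- the **unified NN stack table** (SantaLucia-type DNA/DNA parameters at
  1 M NaCl) keyed by the top-strand dimer, plus per-terminal initiation
  split by strong/weak terminus;
- the **salt coefficient** 0.368 cal/(mol K) per intact stack, applied to
  the entropy only: $\Delta S(\mathrm{Na^+}) = \Delta S(1\,\mathrm{M}) +
  0.368\, n_{stacks} \ln[\mathrm{Na^+}]$. The correction vanishes at the
  1 M reference and leaves $\Delta H$ untouched. Applying it to the
  *intact* stack count of a defected duplex is what makes the ionic
  strength largely cancel in the tagged-pair yield while still shifting
  ensemble melting temperatures by several degrees — both behaviors are
  covered by tests.
- three **averaged defect increments** (dH, dS): a dangling-end term per
  overhanging duplex end (only the first overhang base counts, the
  standard NN convention), a terminal-mismatch term per defected duplex
  end, and an internal-mismatch term per internal mismatch (which also
  breaks its two flanking stacks).

### The defect increments and their calibration

The averaged increments are effective quantities: they subsume the
published dangling-end and single-mismatch tables *and* the entropic cost
structure of partially paired states that the two-state picture does not
resolve. We fixed their values by requiring the model to reproduce its
own internal benchmarks — the fidelity of the averaged parametrization
against sequence-resolved NN melting (≤ 1 °C for $f_{CG}=0.5$ 8-mers),
the ensemble-versus-pair melting-temperature gaps of the 12N pool, and
the low-temperature defect-class statistics — while keeping the
dangling-end average ($\Delta G_{37} \approx -0.35$ kcal/mol) inside the
published dangling-end range. The frozen values are documented in the
parameter file header.

Two structural choices deserve explanation:

- **One terminal-mismatch increment per defected end, not per mismatched
  position.** Physically, only the first mismatched position stacks onto
  the helix end; the remainder of a mismatch run is an unpaired flap
  whose cost is the stacks it removes. Mathematically this decouples the
  weight of single-error duplexes from the geometric compounding of
  longer runs: with a per-position increment strong enough to make
  one-error duplexes as probable as the defect statistics require,
  multi-error runs would dominate divergently and the defectless
  fraction of a pool with uniformly strong (CG-level) stacks could not
  exceed the natural pool's by the observed margin under any (dH, dS)
  choice — we verified this by grid search.
- **Near-cancelling defect enthalpy.** The net enthalpy of removing a
  stack and adding its defect increment is small (slightly negative), so
  class weights vary slowly at low temperature. This yields the
  length-invariant low-temperature limit of the error-count distribution
  (for classes without internal mismatches $g$ is independent of $L$,
  and their weights become temperature-flat), which the tests assert
  across $L \in \{8, 12, 20\}$ within one percentage point per bin.

## From weights to observables

For composition class $f_{CG}$ the paired fraction is
$\theta_e^{(f_{CG})} = 1 - 2\big/\big(1 + \sqrt{1 + (4/4^L)
\sum_\alpha g\,\zeta}\big)$, the closed-form root of the pool-level mass
action; the ensemble curve averages it binomially over the $L+1$
composition classes (`theta_ensemble()`), and class fractions
$\theta_\alpha$ split each class total in proportion to $g\zeta$
(`defect_fractions_*()`, `total_error_fractions()`, `rank_motifs()`).
The identity $\sum_\alpha \theta_\alpha = \theta_e$ holds to machine
precision by construction and is asserted at $10^{-12}$.

For a tagged pair at stoichiometric ratio
$\phi = c_{fluo}/(c_{pool}/4^L)$, the tagged-pair weight
$\phi\,\zeta_{A^*B^*}$ joins the same class sum
(`theta_e_cq()`, `theta_ab()`). As $\phi \to \infty$ the formulas
converge to the isolated-pair two-state curve (asserted at
$\phi = 10^6$); at $\phi = 0$ they reduce to the plain pool curve. The
tagged-duplex energy defaults to the sequence-specific NN sum; the
fluorophores' terminal stabilization is a free, documented (dH, dS)
offset with an optional uncertainty band — reported quantities that
depend on it are treated as band checks, not point predictions.

## Numerical choices

- Boltzmann weights and partition sums are accumulated in log space with
  max-shifting; the melting form switches to its asymptotic expansion
  when the log-sum exceeds 500, so curves remain finite for arbitrarily
  stable duplexes.
- `melting_temperature()` locates $\theta = 1/2$ by `uniroot` on the
  continuous model function (tolerance 0.01 °C), never by grid
  interpolation; absent a crossing it fails with the bracketing values.
- Degeneracies are exact in double precision for $L \le 20$
  (all counts < 2^53).
- Best-alignment selection (the "interaction matrix" view) breaks ties
  by smaller $|\alpha_s|$, then negative shift. Pool formulas always sum
  over all shifts; the literal class sum and the matrix view are exposed
  separately (`best_alignment()`).
- Requests with non-integer $f_{CG} \cdot L$ are rejected, not rounded.
- Mass ↔ molar conversion uses $MW(L) = 303.7 L + 79$ g/mol (average
  single strand); the convention is overridable in `solution_spec()` and
  reproduces the benchmark that 100 nM probes reach $\phi = 1$ in an 8N
  pool near 16 g/l.

## Counterfactual chemistries

`counterfactual_theta_perfect()` explores how pairing selectivity depends
on the alphabet: (i) `all_CG` replaces every stack by the CG-quartet
average (degeneracies unchanged); (ii) `n_bases` with $n_b = 2$ uses a
single complementary pair with stack energetics midway between the AT and
CG averages; (iii) $n_b > 4$ keeps the composition-uniform four-letter
averaged energetics — no stacking measurements exist for hypothetical
extra bases, and with energetics held fixed the effect of alphabet size
is carried entirely by the degeneracy factors $n_b^{|\alpha_s|}$,
$(n_b-1)^{(\cdot)}$ and the pool size $n_b^L$, which is the quantity of
interest. "Low temperature" for scalar readouts is 0 °C, the lower edge
of the default grid.

## Synthetic data

`synthesize_absorbance()` emulates UV hyperchromicity melting data: a
known hybridization curve is embedded between two linear absorbance
baselines (paired DNA is hypochromic, so $\theta = 1$ sits on the lower
baseline) with optional seeded Gaussian noise.
`normalize_absorbance()` inverts it by the standard two-baseline
protocol — linear fits over a low- and a high-temperature window
(defaults: the outer 15% of the measured span, at least five points each)
and pointwise rescaling, clipped to $[0,1]$. The generator reproduces the
shape, baselines and noise level of real traces but not instrument drift,
wavelength structure, or heating-rate (non-equilibrium) artifacts, so a
passing round trip validates the reduction algebra, not equilibration of
a real sample. With noiseless input the round trip is exact to $10^{-10}$
when the transition is saturated inside the baseline windows; with 1%
amplitude noise the recovered melting temperature is reliable to a
fraction of a degree for transitions of typical oligomer width.

## Problem sizes in the shipped tests

Exhaustive oracles run at $L \le 5$ (4^5 partners × 9 shifts); the
mean-field validation averages 500 exhaustive per-sequence curves at
$L = 5$; pool statistics are exercised up to $L = 20$ (≈ 3.3 × 10^4
defect classes per composition); sequence-averaged melting temperatures
use 40 random pairs; the run-length statistic samples 10^4 pairs. The
full suite completes in well under a minute.

## Known limitations

- The defect increments are calibrated effective averages; per-sequence
  predictions for *specific* mismatched duplexes should use dedicated
  single-mismatch NN tables instead.
- No treatment of bulges, asymmetric loops, hairpins, coaxial stacking
  across nicks, or RNA parameters.
- Equilibrium only; strongly length- or concentration-dependent
  hybridization kinetics are outside the model.
- The two-state pool formula treats every species as non-self-
  complementary; palindromic sequences (a $4^{-L/2}$ minority) are
  approximated like all others.
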