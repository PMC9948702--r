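---
title: "The pool-well cycling model: assumptions, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The pool-well cycling model: assumptions, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolwell)
```

## The system

`poolwell` simulates a synthetic four-strain *Saccharomyces cerevisiae*
mutualism. Each strain carries a feedback-resistant mutation that makes it
overproduce one essential metabolite -- adenine (ADE), tryptophan (TRP),
histidine (HIS) or lysine (LYS) -- while remaining auxotrophic for the other
three. A strain therefore grows only where its three foreign requirements are
supplied, either by the *ecology* (the presence/absence state of the four
metabolites in its compartment, one of $2^4 = 16$ combinations) or by
cross-feeding partners co-inoculated with it.

The population alternates between two environments:

* **Pool phase** (duration $t_{\mathrm{pool}}$): an unstructured minimal
  medium reservoir in which all four strains cross-feed globally and grow
  exponentially, $\dot y_i = r_i\, y_i$. The defaults for $r_i$ are the
  measured rates $(0.804, 0.869, 1.157, 0.732)$ for (ADE, TRP, HIS, LYS);
  HIS-up is the fastest strain and dominates any long pool phase.
* **Well phase** (duration $t_{\mathrm{wells}}$): 96 compartments, each with
  an independently sampled ecology and an inoculum of total density $K/2$
  sampled from the pool (4 slots of density $K/8$ each, giving $4^4 = 256$
  ordered compositions). Within a well all strains share the carrying
  capacity $K$:
  $$\frac{dx_i}{dt} = x_i\, R_i(E, S)\Big(1 - \frac{\sum_k x_k}{K}\Big).$$
  $R_i(E,S)$ depends on the ecology $E$ and community $S$. If any member of
  the community cannot obtain one of its three requirements, the whole well
  is non-viable and every member grows at the death rate $d = -2$.

At the end of each well phase the per-strain totals over all wells are
renormalized to a fixed pool inoculum (total density 1), which seeds the next
pool phase. Compartmentalization is what maintains diversity: every viable
well saturates at $K$ regardless of its composition, so minority strains that
land in a permissive well return to the pool at full-well density, while a
long pool phase lets the single fitness peak (HIS-up) erode diversity.

## The growth-rate model

The experimentally measured per-condition growth-rate tables behind the
original system are not available in full; the package therefore uses a
two-level model:

* **Parametric rule.** In a viable well, strain $i$ grows at
  $\mathrm{base}_i \cdot c^{\,m}$ where $m$ is the number of its three
  requirements obtained *only* by cross-feeding (ecology supply shadows
  cross-feeding when both are present) and $c$ is the `crossfeed_factor`,
  default $0.95$. Cross-fed nutrition is assumed mildly inferior to direct
  supplementation; a strain's own product is free to itself.
* **Explicit overrides.** A CSV table of
  `(ecology_index, membership_mask, strain) -> rate` entries takes precedence
  over the rule and is the carrier for measured rates. The shipped table pins
  the barren ecology with all four strains to the measured vector
  $(0.804, 0.869, 1.157, 0.732)$.

The default base rates are that vector divided by $c^3$ (all three
requirements are cross-fed at the calibration point), so the parametric rule
and the shipped override agree exactly there. Both knobs are exposed through
`growth_params()` and the `growth_model:` config section; none of the
package's qualitative results depend on the precise value of $c$, but exact
per-cycle trajectories do depend on the full (unavailable) rate table, which
is why the test suite asserts analytic checkpoints and orderings rather than
bar heights.

## Ecology distributions

The canonical ecology index orders the 16 states by ascending richness, ties
broken by ascending binary value with ADE as the most significant bit. This
puts the two ecologies permissive for a HIS-up monoculture -- $(1,1,0,1)$ and
$(1,1,1,1)$ -- at indices 14 and 16, which is what makes index-based
weighting interpretable.

* `uniform_distribution()`: mass $1/16 = 0.0625$ everywhere.
* `poisson_distribution(mu)`: weight index $j$ by the Poisson PMF at $j-1$,
  truncated to the 16 indices and renormalized. Weighting over indices rather
  than over the five richness classes was chosen because it makes the
  combined mass at the two HIS-permissive indices grow smoothly and
  monotonically with $\mu$ (at $\mu = 1$ it is $\sim 10^{-10}$; at $\mu = 9$
  it is $\approx 0.071$), which is exactly the mechanism the niche-
  availability experiment probes. Note that even at $\mu = 9$ that mass
  remains below the uniform value $0.125$: what matters for survival is its
  orders-of-magnitude increase relative to small $\mu$, not its absolute
  level.
* `feedback_distribution(freqs)`: metabolic feedback. The metabolites
  secreted in one cycle bias the ecologies of the next; with no published
  functional form, the package uses the simplest construction consistent
  with the described behaviour: each metabolite is present independently
  with probability equal to its producer's pool frequency (product-Bernoulli
  over the 16 states). This reproduces both stated consequences: a balanced
  pool keeps all metabolites in play, and a HIS-dominated pool floods the
  ecologies with histidine alone -- ecologies in which HIS-up itself
  starves, the self-defeating skew that collapses late-intervention
  lineages. A `min(1, 4f)` rescaling is available (`feedback_scaling:
  "4x"`) for sensitivity analysis.
* `restrict_distribution(dist, "TRP")`: the keystone experiment; removes the
  8 TRP-containing ecologies and renormalizes (the well count stays 96),
  making TRP-up the only possible tryptophan source.

## Cycle mechanics and numerical choices

Within a cycle the order is: sample ecologies and inocula from the current
pool, integrate the wells, renormalize to the pool, grow the pool. The
initial pool is the configured initial proportions (0.25 each by default),
so the first thing that happens in a run is a well phase; recorded per-cycle
proportions are those *after* the pool phase, which are also the frequencies
the next cycle samples from (and the frequencies the feedback distribution
uses).

* **Integrator.** Fixed-step classical RK4 with default `dt = 0.01` time
  units for the well phase (the systems are smooth and low-dimensional; a
  step-halving test in the suite confirms $10^{-6}$-level agreement, and an
  independent adaptive integration cross-checks the four-strain case). The
  pool phase uses the exact exponential closed form.
* **Non-viable wells** integrate the same logistic equation with all rates
  equal to $d$; the saturation bracket then damps the decay. The rate is
  substituted, not the model. Pure exponential decay is available via
  `nonviable_mode: "exponential"`; it only accelerates the (already
  effectively complete) die-off over $t_{\mathrm{wells}} = 20$.
* **Clamping.** Densities below $10^{-12}$ are set to zero after each phase;
  a dead well's content ($\sim e^{-40}$ of its inoculum) therefore
  contributes exactly nothing, which is what makes whole-lineage extinction
  representable.
* **Extinction.** A lineage is extinct when the aggregated well output is
  zero or every strain frequency falls below `extinction_eps` ($10^{-6}$ by
  default; the original description never defines extinction numerically).
  Individual strains below the threshold are zeroed and the rest
  renormalized. After extinction, proportions are identically zero and the
  recorded per-cycle death rate is 1 (all of an extinct lineage's wells are
  dead), keeping cross-scenario mean-death comparisons well defined.
* **Inoculum.** Four ordered slot draws of density $K/8$, weighted by pool
  frequencies -- the only reading consistent with both the stated example
  compositions ($K/8$ quartets, $(K/2,0,0,0)$ monocultures) and the printed
  count of 256 ordered outcomes. A multinomial-individuals variant ($K/2$
  unit draws) is available via `inoculum_mode`. For the carrying-capacity
  contrast the slot density is pinned at the $K = 10$ value (1.25) across
  all $K$, because that experiment compares wells that start from the *same*
  densities and differ only in headroom.
* **Seeding.** One master seed per replicate set; run $r$ uses a
  deterministically derived seed, so adding replicates never perturbs
  earlier runs and a stored manifest reproduces `runs.csv` byte-identically.

## What the simulations show (and what they cannot)

With the shipped rate table the standard conditions reproduce, as orderings
and checkpoints computed by the test suite and `scripts/acceptance.R`:

* the analytic monoculture death ceiling $14/16 = 0.875$ and its empirical
  confirmation over resampled well phases;
* HIS-up takeover driven by pool fitness, strengthening with
  $t_{\mathrm{pool}}$ and with $K$, with the realized mean death rate
  approaching (from below) the 0.875 ceiling in the long run -- this
  checkpoint is evaluated on the mean over the last five cycles of a
  25-cycle run, because at cycle 10 the system is still converging under
  the parametric rate table (the measured value there is $\approx 0.78$);
* lower death rates under rich-skewed Poisson ecologies ($\mu = 9$ vs
  $\mu = 1$);
* the feedback-timing effect (early intervention spares lineages, late
  intervention collapses them) and both rescues (halving
  $t_{\mathrm{pool}}$; pulling all rates 50% toward their mean, which
  preserves the mean exactly);
* near-certain collapse of the single-well null model, and keystone
  persistence of TRP-up when tryptophan ecologies are banned.

Replicate counts are 50--100 runs of 10 cycles (25 for the long-run death
checkpoint) at 96 wells, which keeps the full suite in the minutes range on
one core while leaving Monte Carlo error well inside every asserted margin.

The generator emulates the *idealized* study system, not wet-lab data: boolean
metabolite availability (no concentrations, no Monod kinetics), a shared
deterministic death rate, no demographic noise inside wells (all
stochasticity lives in ecology/inoculum sampling), no migration between
wells, no mutation or evolution, and a growth-rate table that is parametric
except at the calibration point. Passing tests therefore validate the
cycling mechanism and its ecological feedbacks, not quantitative predictions
for any particular yeast experiment.

## A worked example

```{r example, eval = FALSE}
library(poolwell)

# the standard 10-cycle experiment, 100 replicate lineages
summ <- run_replicates(preset_baseline(), n_runs = 100, seed = 1)
print(summ)
plot(summ)

# late metabolic feedback collapses lineages; halving t_pool rescues them
late <- run_replicates(preset_feedback_interventions(9)$start_9,
                       n_runs = 100, seed = 1)
rescued <- run_replicates(preset_rescue_tpool(9)$start_9,
                          n_runs = 100, seed = 1)
c(late = late$extinction_fraction, rescued = rescued$extinction_fraction)
```
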