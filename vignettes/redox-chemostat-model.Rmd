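---
title: "A redox-constrained chemostat model of nitrogen loss versus retention"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A redox-constrained chemostat model of nitrogen loss versus retention}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nitrofate)
```

## The model

In anoxic waters the fate of bioavailable nitrogen hinges on the competition
between three anaerobic metabolisms for nitrite, the central branching
intermediate: heterotrophic denitrification (NO2- -> N2O -> N2, nitrogen
lost), heterotrophic nitrite ammonification (DNRA, NO2- -> NH4+, nitrogen
retained), and chemoautotrophic anammox (NH4+ + NO2- -> N2, nitrogen lost).
`nitrofate` represents each metabolism as a microbial functional type whose
traits are derived from the redox chemistry that fuels it, and couples the
types in a virtual chemostat to ask which pathways persist — and whether the
ecosystem ends up losing or retaining nitrogen — as a function of the
organic-matter (OM) to nitrite supply ratio.

### Stoichiometric budgets from electron balances

Each heterotrophic budget is generated, per mole of biomass nitrogen
synthesized, from three conservation statements. Writing `eeq(X) = 4C + H -
2O - 3N` for the electron equivalents of a formula (complete oxidation of C
to CO2 with organic N released at the ammonium level), the bulk marine OM
pool C6.6H10.9O2.6N carries 29.1 electrons per mole and biomass C5H7O2N
carries 20. A synthesis fraction `fs` routes donor electrons to biomass; the
remainder is respired onto the acceptor half reaction (`e` electrons per mol
N: 2 for NO3- -> NO2- and NO2- -> N2O, 6 for NO2- -> NH4+, 1 per N for N2O
-> N2):

* OM consumed = `20 / (fs * 29.1)`
* acceptor N consumed = `20 (1 - fs) / (fs * e)`
* NH4+ released = organic N liberated minus 1 (plus the reduced acceptor for
  ammonification); DIC closes the carbon balance.

`fs` stands in for the full free-energy calculation: rather than computing
it from tabulated Gibbs energies with in-situ concentration corrections, the
package calibrates it against the reference budgets. The ammonifier anchor
solves the unrounded OM coefficient from the published NH4+ coefficient
(35.5) via nitrogen balance, giving `fs = 0.10094`; the denitrifier anchor
infers its OM coefficient from the published DIC coefficient (22.5) via
carbon balance, giving `fs = 0.16495`. These two anchors regenerate every
printed coefficient of both budgets to one decimal:

```{r budgets}
metabolic_budgets(y_base = 0.25)
```

Coefficients are signed net productions (negative = consumed; N2O and N2 in
mol N). `budget_balances()` verifies N, C and electron closure to numerical
precision for every generated budget. Display rounding is one decimal,
half-up; internal arithmetic never rounds.

The anchors correspond to the midpoint (0.25 mol/mol) of the empirical
0.2–0.3 range of carbon-use efficiency on organic carbon; `fs` scales
linearly with that baseline (`fs(y_base) = fs(0.25) * y_base/0.25`), which
reproduces the endpoints of the published yield ranges for both
heterotrophs to within rounding.

**The N2O-reducing step.** No reference budget exists for the second
denitrification step. Its synthesis fraction defaults to 1.1 times the
first step's. Two reasons: the N2O/N2 couple is the most exergonic
denitrification step per electron, so its synthesis fraction should be
strictly higher; and, decisively, a strictly higher OM yield is *required*
for the pathway to function as a dynamical system. With exactly equal OM
yields the two steps share one OM subsistence concentration, the
steady state degenerates into a neutrally stable family of denit1/denit2
splits, and integration from small inocula settles on states that vent most
N2O through the outflow instead of reducing it. Steady-state community
fluxes are insensitive to the exact increment (N2 production is set by N2O
throughput, not by `fs`), so 1.1 is a structural choice, not a tuning knob;
it is configurable via `metabolic_budgets(fs_denit2 = )`.

**Anammox** uses a fixed, measured parameterization: 80.7 NO2- + 70.4 NH4+ +
5 DIC -> biomass N + 69.4 N2 + 11.3 NO3-, which balances nitrogen exactly.
Internally the budget decomposes into fixed anabolism (1 NH4+ into biomass,
5 DIC, 11.3 NO2- oxidized to NO3- as the electron source for carbon
fixation) plus a 1:1 NO2-/NH4+ catabolism; yield overrides rescale only the
catabolic part so nitrogen balance is preserved for any yield. The
trait-table nitrite yield (0.0133) differs from the budget value (1/80.7 =
0.0124); both sources are retained — the budget value is the default, the
trait-table value a documented switch (`anammox_y_n = 0.0133`) — because
neither can be shown to be the one used upstream.

### Traits: yields, subsistence concentrations, consumption vectors

Growth follows Liebig's law of the minimum over Monod terms,
`mu = min_j( y_j V R_j/(R_j + K_j) )`, with one maximum uptake rate `V` and
per-resource half-saturations `K_j` shared by all types, so that
competitive differences trace back to the redox-informed yields alone. At
dilution rate `d` a population subsists at `R* = K d/(y V - d)`; the
superior competitor for a limiting resource has the lower `R*`.

The kinetic parameters are not published. They are calibrated from the
published nitrite `R*` midpoints of the two nitrite-reducing heterotrophs
(0.0043 and 0.00775 uM) paired with the package's own midpoint yields — a
two-equation system with the unique solution `V = 41.76 d^-1`,
`K_NO2 = 0.0562 uM` at `d = 0.1 d^-1`. Two remarks on this choice:

* The system is ill-conditioned in its inputs: solving it with the
  *rounded* table yields (0.034, 0.0195) instead gives `V ~ 70 d^-1`.
  Internal consistency decides: with the calibrated kinetics and the
  trait-table anammox yield 0.0133, the implied anammox nitrite `R*` is
  0.01234 uM — the published 0.0123 to all printed digits. The
  rounded-input solution misses it (0.0118).
* The published OM `R*` pair admits *no* positive `(V, K)` solution at all
  (the required ratio of the two OM* values is outside the attainable
  range), so `K_OM` is instead anchored to the ammonifier's OM* midpoint
  (0.10 uM) at the shared `V`. This predicts the denitrifier OM* of 0.061
  uM independently — matching the published midpoint.

N2O and NH4+ reuse the nitrite half-saturation (kinetics are shared across
types and the package has no independent anchor for them).

The consumption vector of a heterotroph, `cv = y_N / y_OM`, is the slope of
its consumption in OM x NO2- supply space. For the two-step denitrification
pathway the relevant slope charges the OM consumed by both steps to each
mole of NO2- fully reduced (3 respired electrons per N):
`cv_denit,full = 3/(29.1 (1 - fs))`; `pathway_cv()` computes the realized
analogue from the community's actual budgets.

```{r traits}
comm <- community()
trait_table(comm)
```

### The virtual chemostat

State: four biomasses plus seven dissolved pools (OM, NO2-, NH4+, N2O-N,
N2-N, NO3-, DIC), all in uM N (DIC in uM C), time in days. Balances:
`dB_i/dt = (mu_i - d) B_i` and `dR_j/dt = d (R_in,j - R_j) + sum_i m_ij mu_i
B_i`, with `m_ij` the signed budget coefficients — uptake of limiting and
non-limiting resources alike is tied to growth through the budget, so total
N and C obey pure dilution dynamics exactly (the biological terms cancel by
construction; `mass_balance()` verifies this at every steady state).

Ammonium is co-supplied with nitrite at `NH4_in = r * NO2_in`, representing
the ammonium released by the implied upstream reduction of nitrate to the
supplied nitrite. `r` is derived from a generated NO3- -> NO2- budget at
the denitrifier synthesis fraction: `r = 0.0626` at the midpoint baseline
(overridable in `chemostat_config()`).

Numerical choices: stiff-capable integration (`deSolve::lsoda`, `rtol =
1e-8`, `atol = 1e-10`) in growing windows; convergence when the maximum
relative time derivative falls below `1e-8 d^-1`; populations below
`1e-10` uM N are clamped to zero between windows (competitive exclusion is
asymptotic in ODEs; a threshold realizes it in finite time); horizon capped
at 50,000 days, after which a record is flagged non-converged rather than
raising an error. Pools start at their inflow concentrations and all types
at `1e-3` uM N unless an inoculum is given; steady states are invariant to
the inoculum in the default scenario (a tested property), so initial
conditions are reporting detail, not science. Analyses in the package's
tests use a 40-point transect at 25 uM N incoming nitrite and a 10 x 10
supply sweep — sizes at which every run converges and regime boundaries are
resolved to a grid step.

## Competitive regimes and the net-zero point

Resource-ratio theory organizes the outcomes: denitrification excludes
ammonification below its full-pathway consumption vector (`rho = OM:NO2-
supply < 0.124`), ammonification excludes denitrification above its own CV
(`rho > 0.229`), and between the two the heterotrophs coexist, co-limited
by both resources. Accumulation mirrors the regimes: NO2- accumulates in
the OM-limited regime, OM (and NH4+) in the NO2--limited regime, neither in
the coexistence window. A pool is flagged "accumulating" when it exceeds
every surviving consumer's `R*` by a 0.1% margin (the margin exists because
a pinned resource sits exactly at an `R*`, where a strict comparison would
be decided by float noise). Anammox persists only in the OM-limited regime,
sustained by heterotroph-regenerated plus co-supplied NH4+, and is excluded
once NO2- becomes limiting — its nitrite `R*` (0.0135 uM) exceeds both
heterotrophs'.

**Net zero nitrogen loss** is the supply ratio where ammonium regeneration
by ammonification balances N2 production. Under equal steady-state growth
rates the balance reduces to the arithmetic mean of the two consumption
vectors, `rho0 = (cv_DNRA + cv_denit)/2` (the equation is arithmetic even
though it is sometimes described as a geometric mean; the equation is
implemented as written). In full-pathway mode at the baseline endpoints
this gives the interval [0.1715, 0.1816]. `net_zero_numeric()` locates the
balance in simulation by root-bracketing the difference of the two
pathways' NO2- fluxes; the numeric point (0.1807 at 25 uM N nitrite) sits
about 0.004 above the analytic ratio because the finite subsistence
concentrations offset the supply-to-flux proportionality that the analytic
form assumes. An alternative balance — total gross NH4+ production equal to
total N2-N production — is also available and lands about 0.003 below the
analytic ratio; the two definitions differ once heterotroph
remineralization and the external NH4+ supply are counted, which is why
both are exposed. At the balance point the ammonifier's biomass is close to
(in this parameterization, about 1.14 times) the combined biomass of the
two denitrification populations: near-equal abundance of the two guilds is
the observable signature of net-zero conditions.

## The anammox contribution

Across the OM-limited band of the default transect the anammox share of
nitrite consumption is not constant: it falls monotonically (from ~85% at
vanishing OM supply, where the co-supplied NH4+ dominates the flux budget,
to ~5% at the regime edge). A single representative point is therefore an
arbitrary summary. The package reports instead the flux-weighted share over
the band where anammox persists — total anammox flux divided by total flux,
summed across transect points — which is the natural reading of a statement
about the organism's share of turnover "in the chemostat". At the default
conditions this gives ~18% of NO2- consumption and ~28% of N2-N production.
A structural note: with the fixed anammox budget the two shares are locked
to one curve — a 20% nitrite share forces a ~30% N2 share and a 26% N2
share forces a ~17% nitrite share — so no evaluation point can realize the
pair (20%, 26%) simultaneously; the flux-weighted values are within a few
points of both.

## The superior-anammox scenario

`scenario("anammox-superior")` grants anammox a nitrite subsistence
concentration just below the ammonifier's (`anammox_advantage = 0.9` by
default), either by raising its nitrite yield (`mechanism = "yield"`) or by
lowering its nitrite half-saturation (`mechanism = "affinity"`). As
expected, anammox then persists throughout the supply domain: with
denitrification in the OM-limited regime, and with the ammonifier — relying
on its NH4+ release — in the NO2--limited regime.

The four-population steady state (both heterotroph guilds plus anammox)
exists in a narrow supply-ratio window (about 0.076–0.100 for the yield
mechanism at 25 uM N nitrite; `three_type_window()` maps it), but it is
dynamically *unstable* — for every advantage magnitude and both mechanisms
tested. The destabilizing loop is inherent to the stoichiometry: an anammox
excursion depresses NO2-, suppressing the NO2--limited denitrifier, freeing
OM for the OM-limited ammonifier, whose large NH4+ release (35.5 per
biomass N) feeds anammox further. The system is therefore bistable between
a denitrification+anammox state and a DNRA+anammox state, with a sharp
basin-boundary transition in supply-ratio space; `net_zero_numeric()`
locates that transition (~0.077), well below the default scenario's balance
point, so the qualitative conclusion — the loss/retention transition moves
to lower OM:NO2- supply when anammox competes for nitrite — holds even
though a stably coexisting three-guild community does not emerge from these
budgets. Outside the window, for supply ratios in the default coexistence
range, the four-population equilibrium is algebraically infeasible for any
NH4+ supply ratio (the denitrifier's synthesis rate would have to be
negative), so stable three-guild coexistence there is not a matter of
parameter choice. A mortality term that saturates competitive exclusion
(grazing, viral lysis) would be the natural extension to soften this.

## What the virtual chemostat does and does not emulate

The chemostat idealizes an anoxic water parcel with steady lateral supply:
constant dilution coupling supply and mortality, a single bulk OM pool of
fixed marine stoichiometry, strictly anoxic conditions, and no explicit
grazers, viruses, spatial structure, or time-varying forcing. Passing tests
therefore demonstrate internal consistency (balances, closed forms,
regime geometry) and the model's equilibrium logic — not that real anoxic
water columns quantitatively follow it. In particular, strict competitive
exclusion is sharper in the model than in nature, where density-dependent
mortality blurs regime boundaries; the C:N ratio of the OM supply shifts
all OM-axis quantities proportionally; and the NH4+ co-supply ratio, which
controls the anammox share at low OM supply, is a budget-derived default
rather than a measured quantity.

## Known limitations

* Yields rest on two printed-budget anchors plus linear baseline scaling,
  not on a free-energy calculation; alternative OM stoichiometries change
  the numbers (the electron-balance machinery accepts any formula).
* Kinetics are calibrated from two nitrite R* values and one OM* anchor;
  absolute rates (not ratios) inherit that uncertainty.
* The N2O-reducing step's synthesis fraction is a structural default (1.1x
  step 1), constrained only by an ordering argument.
* The three-guild coexistence reported for the superior-anammox variant
  exists only as an unstable equilibrium here; conclusions about its
  community composition should not be drawn from this package.
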