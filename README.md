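# nitrofate

Whether an anoxic water column **loses** bioavailable nitrogen (as N2, via
denitrification and anammox) or **retains** it (as NH4+, via dissimilatory
nitrite reduction to ammonium, DNRA) is set by the competition of a few
anaerobic microbial metabolisms for nitrite and organic matter. `nitrofate`
is an R package for biogeochemical modellers and microbial ecologists that
builds these metabolisms as redox-constrained functional types and couples
them in a virtual chemostat, so that the loss-versus-retention transition —
and the "net zero N loss" point where the two balance — can be computed from
first principles rather than from species-specific culture traits.

## The model in brief

Each heterotrophic metabolism is a stoichiometric budget per mole of biomass
N synthesized, derived from electron balance. With eeq(X) = 4C + H − 2O −
3N (so marine organic matter C6.6H10.9O2.6N carries 29.1 electrons, biomass
C5H7O2N carries 20) and a synthesis fraction *f*<sub>s</sub> of donor
electrons routed to biomass:

    OM consumed  = 20 / (fs · 29.1)
    acceptor N   = 20 (1 − fs) / (fs · e)      e = electrons per mol N

with *e* = 6 for NO2- → NH4+ (DNRA) and 2, then 1 for the two single-step
denitrification types NO2- → N2O → N2; chemoautotrophic anammox uses a
fixed measured budget (80.7 NO2- + 70.4 NH4+ + 5 DIC → biomass + 69.4 N2 +
11.3 NO3-). Growth follows Liebig's law of the minimum over Monod terms,
μ = min<sub>j</sub>( y<sub>j</sub> V R<sub>j</sub>/(R<sub>j</sub>+K<sub>j</sub>) ),
with shared uptake kinetics so that competition is decided by the
redox-informed yields through the subsistence concentrations
R\* = K d/(yV − d) and the consumption vectors cv = y<sub>N</sub>/y<sub>OM</sub>.
The net-zero supply ratio is the arithmetic mean of the two heterotroph
consumption vectors, ρ₀ = ½(cv<sub>DNRA</sub> + cv<sub>denit</sub>), with the
denitrification CV taken over the full two-step pathway (3 respired
electrons per N).

## Worked example

```r
library(nitrofate)

comm <- community()          # four functional types at baseline 0.25, d = 0.1/d
metabolic_budgets()          # signed coefficients per mol biomass N
#>   metabolism    om   no2    nh4 n2o_n  n2_n   no3   dic
#> 1 dnra       -6.81 -29.7  35.5    0     0     0    39.9
#> 2 denit1     -4.17 -50.6   3.17  50.6   0     0    22.5
#> 3 denit2     -3.79   0     2.79 -90.2  90.2   0    20
#> 4 anammox     0    -80.7 -70.4    0   139.   11.3  -5
```

The DNRA and denit1 rows are the budget equations of the source framework
(6.8 OM + 29.7 NO2- → biomass + 35.5 NH4+ + 39.9 DIC, and 4.2 OM + 50.6
NO2- → biomass + 50.6 N2O-N + 3.2 NH4+ + 22.5 DIC) recovered from the
electron balances. Traits follow:

```r
trait_table(comm)
#>   metabolism resource      y   rstar      cv
#> 1 dnra       om       0.147  0.1      0.229
#> 2 dnra       no2      0.0337 0.0043   0.229
#> 3 denit1     om       0.24   0.0608   0.0823
#> 4 denit1     no2      0.0198 0.00775  0.0823
#> ...
```

Denitrification is the better OM competitor (lower OM\*), DNRA the better
nitrite competitor (lower NO2-\*): the redox tradeoff emerges in the traits.
A steady state in the OM-limited regime (2 uM N OM, 25 uM N NO2- supplied):

```r
glance(steady_state(comm, om_in = 2, no2_in = 25))
#>   b_dnra b_denit1 b_denit2 b_anammox     om   no2    nh4
#> 1      0    0.308    0.173    0.0428 0.0608  5.94 0.0114
```

DNRA is excluded, nitrite accumulates (5.9 uM), OM is drawn to the
denitrifier's subsistence concentration, and anammox coexists
syntrophically on regenerated NH4+. The loss/retention balance point:

```r
net_zero_analytic(0.2); net_zero_analytic(0.3)
#> [1] 0.1715311
#> [1] 0.181568
net_zero_numeric(comm, no2_in = 25)$rho
#> [1] 0.180729
```

i.e. net zero N loss at an OM:NO2- supply ratio of ≈ 0.17–0.18 mol N (in
OM) per mol NO2-. `transect()`, `supply_sweep()`, `autoplot()` and
`anammox_contribution()` reproduce the regime maps, the transect figure and
the anammox uptake/production shares; `scenario("anammox-superior")`
explores the variant in which anammox outcompetes the heterotrophs for
nitrite. A command-line front end over the same functions is in
`inst/cli/nitrofate.R`.

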