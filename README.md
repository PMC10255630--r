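# algaescan

Closed-system scanning of small neural forecasting models for algal bloom
early warning in drinking-water source monitoring.

## The problem

A water utility watches weekly lab counts of algae (cells/L) alongside
high-frequency sensors: water temperature, pH, conductivity, turbidity and a
UV254 proxy for dissolved organic matter. Forecasting next week's algal
concentration — and the companion factors treatment control also needs —
raises a selection problem: *which* factors belong in a multivariate
forecasting model? Correlation screening cannot see interdependent groups,
and throwing everything at a network degrades it.

`algaescan` implements an exhaustive **scanning–focusing** answer. With six
candidate companion factors, every one of the 63 non-empty subsets is used
(together with the date and the algae history) as the joint input/output set
of a feedforward network with one tanh hidden layer; hidden sizes 1–10 are
scanned (630 conditions) and every condition is trained with 10 seeded
replicates (6300 trainings). The forecasting unit takes a 7-week input
window and predicts 1 week ahead; fit is summarized by the integrated
R² = 1 − Σ_f SSE_f / Σ_f SST_f pooled over all normalized outputs. Subsets
are then ranked on validation-period integrated R² and filtered by a
Granger-style retention rule: a subset is a **closed system** when every
member's removal costs more than a small tolerance and no outside factor
adds more than it. The empty subset (date + target only) is the traditional
SP baseline; the full subset is the blind BP baseline; both are ordinary
members of the grid, so the three-way comparison falls out of one scan.

Because dissolved CO₂ is computed rather than measured, the package also
ships a dilute-solution carbonate solver: with `H = 10^-pH` and
charge-balance alkalinity `Alk = [HCO3⁻] + 2[CO3²⁻] + [OH⁻] − [H⁺]`,

```
hco3 = (Alk − Kw/H + H) / (1 + 2·K2/H),  co3 = K2·hco3/H,  co2(aq) = H·hco3/K1
```

with Plummer–Busenberg K1/K2 and Harned–Owen Kw, plus the weekly-alkalinity ~
conductivity regression (nearest-in-time pairing, 6-hour cutoff) that lifts
CO₂ to sensor resolution. Cell counts convert to chlorophyll-a equivalents
(35 µg/L per 4·10⁶ cells/L) and band as safe (<10 µg/L), moderate (10–50)
and high (≥50).

The real multi-year utility record behind this design is restricted, so the
package includes a synthetic scenario generator with a planted dependency
structure — blooms gated on 3-week-lagged temperature, CO₂ drawn down by
photosynthesis, pH solved from carbonate equilibrium, decoy channels with no
causal link — so the entire pipeline is testable end to end. See the
methods vignette (`vignettes/closed-system-scanning.Rmd`) for the model,
the generator's assumptions and the design decisions.

## Worked example

```r
library(algaescan)

cfg    <- scenario_config(seed = condition_seed(1, "scenario", 1))  # 2015-2022
series <- generate_scenario(cfg, sensors = FALSE)
series <- inject_gap(series, 2021,                   # training/application gap
                     drift = c(pH = 0.05, conductivity = 0.5))
weekly <- to_weekly(series)

grid <- scan_grid(neurons = 1:5, replicates = 3,
                  base_seed = condition_seed(1, "scan", 1))
scan <- run_scan(grid, weekly, split_spec(), control = fnn_control(maxit = 120))
print(scan)
```

```
scan_result: 960 trainings over 320 conditions (64 subsets x 5 neuron counts x 3 replicates)
top subsets by mean validation integrated R^2 (at best neuron count):
  temperature                            n_hidden= 4  R2=0.948
  temperature+co2                        n_hidden= 3  R2=0.933
  temperature+pH                         n_hidden= 5  R2=0.911
  temperature+pH+co2                     n_hidden= 4  R2=0.908
  co2                                    n_hidden= 4  R2=0.836
```

Temperature-bearing subsets head the ranking — the generator plants
temperature as the lagged driver of blooms, with pH and CO2 carrying the
instantaneous bloom state through carbonate chemistry — while subsets built
on the decoy channels trail far behind.

```r
systems <- select_closed_systems(scan, top_k = 1)
print(systems)
```

```
closed_system {temperature}: n_hidden=4, validation integrated R^2=0.948, rank 1, property PASS
  temperature  member     delta R^2 = +0.118
  pH           non_member delta R^2 = -0.037
  conductivity non_member delta R^2 = -0.200
  turbidity    non_member delta R^2 = -0.334
  dom_uv254    non_member delta R^2 = -0.236
  co2          non_member delta R^2 = -0.015
```

The evidence table is the retention rule made explicit: removing the member
costs 0.12 R2 at the subset's best neuron count; no outside factor adds more
than the 0.01 tolerance. Finally, the Tables-style report compares the
selected system with the SP baseline per factor and period:

```r
report <- evaluate_models(
  list(SP = scan_best_model(scan, character(0)),
       CS = systems$systems[[1]]$model),
  weekly, split_spec(), scan$normalizer)
print(report)
```

```
== application period ==
method     |          algae R2 / RMSE |    temperature R2 / RMSE 
SP         |        0.621 /     0.218 |                         - 
CS         |        0.749 /     0.178 |        0.959 /     0.715
```

(Algae is modelled on the log10 scale, so its RMSE is in log10 cells/L;
temperature RMSE is in degrees C. Exact numbers vary with the seeds.) Across
the 2021 gap the closed system holds its algae accuracy (validation 0.904 to
application 0.749) better than the date-only SP (0.839 to 0.621): the
generator's slow warming trend shifts bloom amplitude between training and
application, which only a temperature-bearing model can track.

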