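# aggkin

Chemical-kinetics analysis of amyloid fibril and oligomer formation, for
researchers who measure protein aggregation with plate-reader assays,
electron-microscopy fibril lengths and single-molecule oligomer counting,
and want to identify the mechanism by which fibrils and oligomers
multiply.

## The models at the core

Bulk fibril formation is described by the standard moment equations for
fibril number *P* and mass *M* (monomer-equivalent µM, free monomer
*m* = *m*<sub>tot</sub> − *M*):

    dP/dt = kn·m^nc + k2·m^n2·M + k₋·M
    dM/dt = 2·k₊·m·P

covering primary nucleation (kn, nc), elongation (k₊), surface-catalysed
secondary nucleation (k2, n2; n2 = 0 encodes the saturated case) and
fragmentation (k₋). Bulk curves determine two composite rates: the
primary pathway rate λ = √(2k₊kn·m₀^nc) and the proliferation rate
κ = √(2k₊(k2·m₀^n2 + k₋)·m₀). Because order-0 secondary nucleation and
fragmentation enter κ identically, the package pairs bulk fitting with an
independent fragmentation bound from plateau-phase fibril lengths,

    L(t) = 1 / (k₋·t + 1/L_plateau),  κ(frag) = L_plateau·k₋,

and with the population dynamics of transient oligomers (concentration
*S*), whose origin is decided between a primary route
(dS/dt = k_form·m^n − k_diss·S) and a fibril-catalysed route
(dS/dt = k_form·m^n·M − k_diss·S·M) by joint fitting across unseeded and
seeded conditions. A photon-burst thresholding estimator turns confocal
timetraces into the relative oligomer concentrations those fits consume.
Synthetic-data generators for every input make the whole pipeline
testable end to end.

See `vignette("aggregation-kinetics", package = "aggkin")` for the
models, assumptions, parameter defaults and numerical choices.

## Worked example

Simulate the assay at its study conditions (100 µM monomer, seeds
0/0.25/1% of mass, 1% measurement noise), then run the full analysis:

```r
library(aggkin)

traces <- gen_kinetic_traces(noise = 0.01, seed = 1)
curves <- lapply(traces, normalize_trace)
sapply(curves, half_time)
#> [1] 24.177298 12.944837  9.598086
```

Half-times drop with seed concentration — the signature of secondary
processes. Global fitting quantifies the proliferation rate and model
comparison makes the verdict explicit:

```r
fit <- global_fit(curves, seed = 1)
fit
#> Global kinetic fit: primary_plus_secondary model
#>   kappa  = 0.4018 h^-1 at 100 uM
#>   lambda = 0.003851 h^-1 at 100 uM
#>   objective = 0.08772 over 3 traces (converged: TRUE)

compare_primary_vs_secondary(curves, seed = 1)
#> Model comparison: primary-only vs primary + secondary
#>   objective ratio = 278 (threshold 5)
#>   verdict: secondary required
```

Plateau fibril lengths bound what fragmentation alone could achieve, 40
times less than the fitted κ:

```r
frag <- fit_length_series(gen_length_samples(seed = 1), seed = 1)
frag
#> Plateau fibril-length fragmentation fit
#>   kminus     = 1.04e-05 h^-1 [9.164e-06, 1.157e-05]
#>   L_plateau  = 1028 [975.1, 1091]
#>   kappa_frag = 0.01069 h^-1 [0.009162, 0.01234]

proliferation_ratio(fit$kappa, frag$kappa_frag)
#> kappa / kappa_frag = 0.4018 / 0.01069 = 37.6-fold: fragmentation insufficient
```

Oligomer dynamics along the fitted bulk trajectory identify the oligomer
origin and the formation rate (here recovered at the generator's
4×10⁻⁵ s⁻¹ per µM fibril mass):

```r
bulk   <- simulate_fibril_mass(default_rates(), 100, 0, 0, seq(0, 40, by = 0.2))
bulk_s <- simulate_fibril_mass(default_rates(), 100, 1, 1/2000, seq(0, 40, by = 0.2))
ser    <- gen_oligomer_series(default_oligomer_params(), bulk,   seed = 1)
ser_s  <- gen_oligomer_series(default_oligomer_params(), bulk_s, seed = 2)

fit_oligomer_series(ser, bulk, "secondary", seed = 1)
#> Oligomer fit (secondary mode, n_o = 1)
#>   formation rate at 100 uM = 0.146 h^-1 (4.04e-05 s^-1) per uM fibril mass
#>   k_diss = 0.202, objective = 4.173

select_oligomer_model(ser, bulk, ser_s, bulk_s, seed = 1)
#> Oligomer origin model selection
#>   objective primary   = 1.791e+04
#>   objective secondary = 18.05
#>   selected: secondary (relative gap 991, margin 0.1)

oligomer_peak_time(ser, half_time = half_time(as_normalized_trace(bulk)))$ratio
#> [1] 0.7923989
```

The oligomer peak sits before the bulk half-time (ratio < 1), and shifts
with seeding — both hallmarks of fibril-catalysed (secondary) oligomer
formation.

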