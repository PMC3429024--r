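# rbcatp

Oxygen-dependent erythrocyte ATP release and its transport in capillary
networks.

Red blood cells release ATP when their hemoglobin desaturates, and the
released ATP triggers a conducted vasodilation that recruits blood flow to
hypoxic tissue. `rbcatp` is for microvascular physiologists and systems
biologists who want to simulate that control loop's two building blocks:

1. **A dynamic kinetic model of the release pathway** — desaturated
   hemoglobin (tHb = 1 − sO₂) activates the G-protein Gi, driving cAMP
   production by adenylyl cyclase, PKA activation, CFTR activation, and
   ATP efflux. Four ODEs with conserved pools:

   - d[GPa]/dt = k_GPf·[GPi]·tHb^α − k_GPr·[GPa]
   - d[cAMP]/dt = AC_base + k_cAMPf·[GPa]/(1 + k_cAMPi·[PKAa]) −
     v₀·PDE3_rel·[PKAa]·[cAMP]/(K_PDE3 + [cAMP])
   - d[PKAa]/dt = k_PKAf·[PKAi]·[cAMP] − k_PKAr·[PKAa]
   - d[CFTRa]/dt = k_CFTRf·[CFTRi]·[PKAa]^β − k_CFTRr·[CFTRa]
   - F_ATP = k_ATPflux·[CFTRa]

   PDE3 hydrolyzes cAMP; insulin raises PDE3 activity (PDE3_rel > 1),
   which is how hyperinsulinemia suppresses low-O₂ ATP release.

2. **A steady-state transport model on capillary networks** — plasma ATP
   on a directed graph of cylindrical segments:

   (1−H_T)·∂t[ATP] = −u(1−H_D)·∂z[ATP] + H_T·C₀(1 − C₁S) − (2/R)·k_d·[ATP]

   solved by an explicit upwind time-march with plasma-flow-weighted
   junction mixing, plus the conducted dilation signal
   σ_dilation = Σᵢ [ATP]ᵢ·exp(−(L−zᵢ)/λ), λ = 1 cm.

Because the measured rat-EDL capillary geometry behind the transport model
is not publicly archived, the package includes a seeded synthetic network
generator with the same statistical structure (208 segments,
84 × 169 × 342 μm domain, counter-current capillary, flow-conserving
hemodynamics) and a plain-text exchange format for real networks.

## Worked example

```r
library(rbcatp)

## 40 ms desaturation pulse from 100% to 15.7% sO2
traj <- simulate_pathway(pathway_params(), desaturation_pulse(0.157))
traj
#> Pathway trajectory: 4001 points over [0, 2] s
#>   cAMP peak  0.4072 at 50.3 ms
#>   F_ATP peak 0.5212 at 156.9 ms
#>   total release (area under F_ATP): 0.16018 model units
```

cAMP peaks ~51 ms and ATP flux ~157 ms after the stimulus — the dynamic
fingerprint of the cascade. Calibrating the arbitrary release units so the
15.7% pulse equals the measured 11.8 nmol ATP/4×10⁸ erythrocytes:

```r
dose_response(pathway_params(), c(0.618, 0.413, 0.216))
#>     sO2 release_model  release
#> 1 0.618    0.04302519  3.130068
#> 2 0.413    0.09442780  6.956559
#> 3 0.216    0.14570270 10.733950
```

— release grows as saturation falls (measured: 3.1, 7.1, 13.1; the last
point is capped by the 11.8 anchor in a monotone model). Scenario
predictions:

```r
gi_deficit_scenario(pathway_params(), 0.6)   # 40% less Gi protein
#> [1] 59.00832                                # ~60% less ATP release
find_pde3_recovery(pathway_params(), 0.6)    # PDE3 inhibition rescues it
#> [1] 0.6043327                               # at ~60% of normal activity
```

On the network side:

```r
net <- generate_network(network_spec(seed = 42))
sat <- compute_saturation(net, entrance_sO2 = 0.63, consumption = 1.5e-4)
field <- solve_atp_steady(net, sat, atp_in = 0)
mean_capillary_atp(field)        # uM, volume-weighted
#> [1] 0.04339374
dilation_signal(field)
#> sigma_dilation = 8.968e-09 mol/cm^3 over 208 segments (lambda = 1 cm)

insulin_network_scenario(net, sat, atp_in_uM = 0)[, c(1, 4, 7)]
#>   atp_in_uM mean_decrease_pct sigma_decrease_pct
#> 1         0                50                 50
```

Halving C₀ (the insulin effect) halves mean [ATP] and σ_dilation exactly
when the inlet carries no ATP — a geometry-independent consequence of
linearity.

A command-line wrapper is installed at `inst/cli/rbc-atp`
(`simulate-pathway`, `dose-response`, `scenario`, `solve-network`,
`generate-network`, `figure` subcommands).

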