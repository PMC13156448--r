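# hpauc

Kinetic interpretation of the lactate/pyruvate AUC ratio for dynamic
hyperpolarized [1-¹³C]-pyruvate MRI.

## The problem

After injection, a bolus of hyperpolarized (HP) pyruvate is delivered through
the vasculature, extravasates (rate `kve`, s⁻¹), crosses the cell membrane
(`kecP`), and is converted to lactate by LDH (`kPL`). The standard
semi-quantitative readout of such an exam — the lactate-to-pyruvate
area-under-the-curve ratio, AUC<sub>Lac</sub>/AUC<sub>Pyr</sub> — mixes all
three steps: it reflects intracellular metabolism only when intracellular
pyruvate dominates the visible signal, and otherwise reports transport or
perfusion. `hpauc` is for imaging scientists who want to know *which* step
their AUC ratio is actually measuring.

## The model

A simplified three-physical-compartment model (3PCs) tracks pyruvate in
intravascular (volume fraction `v_b`), extravascular/extracellular (`v_ee`),
and intracellular (`v_c`) spaces and lactate intracellularly, with effective
decay rates that pool exchange, T₁ relaxation, and RF losses, e.g.

    alphaPee = -(kve/vee + kecP/vee + 1/T1Pyr + (1 - cos(thetaPyr))/TR)

Evaluating the Laplace transform of the (linear, initially signal-free)
system at s = 0 gives each pool's signal AUC as a closed-form multiple of the
input-function AUC, hence a *parameterized*, input-independent AUC ratio

    AUC_Lac / AUC_Pyr = Theta * A_lac / (A_iv + A_ee + A_c),
    Theta = sin(thetaLac) / sin(thetaPyr)

with each `A` attenuated by `exp(-TE/T2*)` of its pool. From this closed form
the package derives pool fractions (which compartment holds the pyruvate
signal), dominant-pool classification, limiting-regime expressions, and
echo-time correction of measured ratios. A full 3PC model (reversible
exchange, bidirectional lactate transport, lactate washout by intravasation)
is provided for forward simulation, together with calibrated-noise synthesis,
multi-start bounded least-squares fitting (optionally L2-regularized), and
the Monte-Carlo experiments that characterize the method.

## A worked example

```r
library(hpauc)

acq  <- acquisition_params()        # TR 3 s, 60 frames, flips 20/30 deg
vifp <- vif_params()                # gamma-variate bolus, arrival at 15 s
p    <- table1_params("3pcs_c")     # intracellular-dominant reference set

unlist(pool_fractions(p, acq))
#>       f_iv       f_ee        f_c
#> 0.04971659 0.27332163 0.67696179

auc_ratio_parameterized(p, acq)
#> [1] 1.333457

classify_dominant_pool(p, acq)
#> [1] "intracellular"

# simulate a noisy acquisition and recover the kinetics
tc  <- add_noise(simulate_3pcs(p, acq, vifp), noise_spec(20, seed = 42))
fit <- fit_multistart(tc, vifp, "3pcs",
                      fit_spec(fixed_params = p, n_restarts = 25, seed = 1))
round(fit$free, 4)
#>       kPL      kecP       kve     betaL vif_scale
#>    0.2306    0.0790    0.1877    0.0686    1.1646
```

Here 67.7% of the pyruvate signal AUC arises from the intracellular pool, so
the AUC ratio of 1.33 is, for these kinetics, an honest surrogate for `kPL`;
the noisy refit recovers the generating `kPL = 0.2061` to about 12% at this
single SNR-20 noise draw (the Monte-Carlo CoV of `kPL` under these kinetics
is 0.13).

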