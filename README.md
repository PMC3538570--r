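# ftkin

Kinetic parameter estimation for dynamic emission tomography (PET/SPECT)
with the reversible two-tissue compartment model, aimed at researchers who
fit blood-input and tissue time-activity curves (TACs).

## The problem and the method

The model couples a blood input `B(t)` to two tissue compartments through
four rate constants `K1, k2, k3, k4` (min⁻¹); only the sum `C(t)` of the
compartments is measurable.  Classic weighted nonlinear least-squares
(NLS) curve fitting estimates the rates accurately but needs an initial
guess, and a bad guess can converge to a wrong solution even on noiseless
data.

`ftkin` implements a closed-form frequency-domain alternative.
Eliminating the hidden states gives the input–output ODE

    C'' = x1 B' + x2 B + x3 C' + x4 C,
    x1 = K1,  x2 = K1(k3+k4),  x3 = -(k2+k3+k4),  x4 = -k2 k4,

which in the Fourier domain is algebraic in `(x1, x2, x3, x4)`.  The
zero-frequency relation — the DC gain, equal to the volume of distribution
`VD = K1(k3+k4)/(k2 k4) = C̃(0)/B̃(0)` — is the most noise-robust equation
in the data and is enforced as a hard constraint, eliminating `x4`.  The
remaining coefficients minimise a quadratic over the lowest `k_c`
harmonics only (high frequencies are noise-dominated and discarded),
giving a symmetric 3×3 linear system, solved in closed form, and the rates
follow as

    K1 = x1,  k2 = -x2/x1 - x3,  k4 = x2 B̃(0) / (k2 C̃(0)),
    k3 = -k2 - k4 - x3.

No initial condition is needed and the solution is unique.  The estimate
can then seed the conventional NLS refinement (`combined_estimate()`),
combining the robustness of the closed form with the low bias of curve
fitting.  The package also ships the analytic forward model, an ODE
oracle, the standard simulation protocol (Feng arterial input, 83-frame
non-uniform schedule with overlapping 60-s integration windows,
count-statistics noise), a Monte-Carlo experiment harness, TAC text-file
I/O and a small CLI.

## Worked example

```r
library(ftkin)

truth <- rate_params(0.4, 0.3, 0.2, 0.1)
ds <- generate_dataset(truth, alpha = 0.1, seed = 1)  # noisy simulated study

stage1 <- fourier_estimate(ds$blood, ds$tissue)       # closed form, no init
stage1
#> Two-tissue compartment rates (min^-1)
#>     K1     k2     k3     k4
#> 0.3928 0.2942 0.2015 0.0974

res <- combined_estimate(ds$blood, ds$tissue)         # NLS refinement
res
#> Weighted NLS fit: F = 0.001566, converged in 4 iterations
#>     K1     k2     k3     k4
#> 0.4042 0.3132 0.2175 0.1034

round(macro_params(res$params), 3)
#>         vd         bp k3k4_ratio net_uptake
#>      4.006      2.715      2.104      0.166
```

The closed-form stage lands near the truth from the data alone; the
refinement stage tightens each rate; `vd` is the volume of distribution,
`bp` and `k3k4_ratio` the binding-potential-type macro-parameters, and
`net_uptake` is `K1*k3/(k2+k3)` in min⁻¹.

From a shell, the same pipeline:

```sh
Rscript inst/exec/ftkin simulate --out tacs.tsv --alpha 0.1 --seed 1
Rscript inst/exec/ftkin estimate --in tacs.tsv --cutoff 10
Rscript inst/exec/ftkin combined --in tacs.tsv
```

Monte-Carlo sweeps over noise levels and cutoff indices are driven by
`run_experiment()` or `ftkin experiment --spec exp.yaml --out table.csv`.

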