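# purefrag

Simulation and inverse problems for the **pure fragmentation equation** —
the population-balance model for protein filaments (amyloid fibrils,
prions) that divide but do not grow:

$$\partial_t u(t,x) = -\alpha x^{\gamma}\,u(t,x)
  + \alpha\int_x^{\infty}\tfrac{1}{y}\,\kappa(x/y)\,y^{\gamma}\,u(t,y)\,dy$$

`u(t,x)` is the number density of filaments of length `x`; a filament
breaks at the power-law rate `B(x) = α x^γ` into two daughters whose
relative sizes follow the kernel `κ(z)` (`∫κ = 2`, `∫zκ = 1`). The package
is for experimentalists and modelers who measure **time-point samples of
fibril lengths** (e.g. AFM/TEM imaging of a dilute, monomer-depleted
suspension) and want the division law back out of those measurements.

For `γ > 0` the rescaled solution converges to a universal steady profile
`g`, and every moment of the normalized length distribution decays on a
straight line in log-log time with slope `−q/γ`. That asymptotic structure
yields direct inversion formulae rather than model fitting:

* `γ` from the late-time slope of the mean length (piecewise fit
  `M_e = C·t_e^{−1/γ}` for `t ≤ t_e`, `C·t^{−1/γ}` after, minimizing the
  quadratic distance to the measured means);
* `α = 1 / (γ·Ĝ(1+γ))` from the Mellin transform `Ĝ` of the rescaled
  last-time profile (a consequence of binary fission, `K(1) = 2`);
* `κ` from the inverse Mellin transform of
  `K(s) = 1 + (2−s)Ĝ(s) / (αγ Ĝ(s+γ))` — ill-posed, regularized, and
  honest: only the kernel *class* (interior breakage, `κ(0)=κ(1)=0`,
  vs end breakage, `κ(0),κ(1)>0`) is reliably identifiable from late-time
  data.

What's in the box: a mass-conserving, positivity-preserving implicit solver
on a logarithmic length grid (Rcpp core), a monomer-resolved discrete
companion model, closed-form reference solutions for validation, moment
and Mellin observables, the full estimation pipeline, two-sample
Kolmogorov–Smirnov machinery for kernel discrimination, seeded synthetic
experiments, and an experimental-design helper (measure until `5·T_e`).
Everything user-facing takes and returns tibbles, and fitted objects
support `tidy()`, `glance()` and `autoplot()`.

## Worked example

Simulate a fragmentation experiment with `γ = 1.3`, `α = 1` and a
two-peaked Gaussian kernel from an exponential initial length
distribution, observe the (noiseless) length distributions at
`t = 5, 10, 20, 30, 40`, and run the estimator:

```r
library(purefrag)

dens <- simulate_experiment(frag_params(gamma = 1.3, alpha = 1),
                            make_kernel("two_peaked_gaussian"),
                            "exponential",
                            times = c(5, 10, 20, 30, 40), N = 0)
fit <- analyze_experiment(dens, estimate_kernel = FALSE)
glance(fit)
#> # A tibble: 1 × 8
#>   gamma alpha   t_e     C           E kernel_class   t_f n_times
#>   <dbl> <dbl> <dbl> <dbl>       <dbl> <chr>        <dbl>   <int>
#> 1  1.36  1.14  5.20 0.667 0.000000138 A               40       5
```

Reading the output: `gamma = 1.36` recovers the true exponent 1.3 with the
small upward bias every finite observation window carries (the log-log
moment curve is concave and is approached from steeper slopes);
`alpha = 1.14` recovers the rate scale 1 through the Mellin identity,
inheriting and amplifying the bias on `γ`; `t_e = 5.20` says the
self-similar regime was reached just after the first observation, so a
longer experiment would mostly add redundant points; `kernel_class = "A"`
correctly reports interior breakage (the two-peaked kernel vanishes at
both endpoints) read off the steady profile shape. `autoplot(fit)` draws
the log-log moment trajectory with the fitted asymptotic line.

With sampling noise instead of exact densities (`N = 200` filament lengths
per time point, the realistic imaging regime), the same pipeline runs on
`(time, length)` records via kernel-density reconstruction:

```r
samp <- simulate_experiment(frag_params(1, 1), make_kernel("uniform"),
                            "exponential", times = c(5, 10, 15, 20),
                            N = 200, seed = 12)
analyze_experiment(samp, estimate_kernel = FALSE)$gamma
#> [1] 1.146056
```

A thin command-line wrapper over these functions ships in
`inst/cli/purefrag.R` (subcommands `simulate`, `synth`, `estimate`,
`compare-kernels`, `validate`, `design`).

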