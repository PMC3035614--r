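# nichestates

Alternative stable states (ASS) in stage-structured consumer–resource systems
coupled by an **ontogenetic niche shift** — juveniles and adults of one
population exploiting different resources or habitats. The maturation flow
(juveniles → adults, proportional to juvenile food intake) and the
reproduction flow (adults → juveniles, proportional to adult intake) link the
two resource compartments through apparent-competition-like feedback: more
juvenile food promotes maturation, depresses the adult resource, suppresses
reproduction, and frees yet more juvenile food. That positive feedback can
hold the community in either a juvenile- or an adult-dominated state,
depending on history. `nichestates` is for theoretical ecologists who want to
map where such bistability exists when each stage uses **multiple resources**,
in three settings:

* **additional resources** — each stage has `n_J` / `n_A` independent
  logistic resources (optionally allochthonous subsidies with donor-controlled
  dynamics `dR/dt = I − lR − aRC`);
* **multiple habitats** — each stage colonises several habitats at random,
  one resource per habitat;
* **interstage resource sharing** — each stage also consumes the other
  stage's major resource.

## Model

For the additional-resources scenario (the others are variations):

```
dR_{J,i}/dt = r_{J,i} R_{J,i} (1 − R_{J,i}/K_{J,i}) − a_{J,i} R_{J,i} C_J
dR_{A,i}/dt = r_{A,i} R_{A,i} (1 − R_{A,i}/K_{A,i}) − a_{A,i} R_{A,i} C_A
dC_J/dt     = Σ_i b_{A,i} a_{A,i} R_{A,i} C_A − Σ_i b_{J,i} a_{J,i} R_{J,i} C_J − d_J C_J
dC_A/dt     = Σ_i b_{J,i} a_{J,i} R_{J,i} C_J − d_A C_A
```

with logistic resources, linear (mass-action) trophic interactions, and
food-proportional maturation and reproduction. Eliminating the resources at
steady state (`R* = K(1 − aC/r)`) gives two zero-net-growth isoclines
(ZNGIs) in the `(C_J*, C_A*)` plane — upward-convex quadratics through the
origin (rational functions under interstage sharing). Substituting one into
the other and factoring the trivial root reduces coexistence to a cubic

```
F(C_J*) = Λ1 C_J*³ + Λ2 C_J*² + Λ3 C_J* + Λ4 = 0,
```

so there are **at most three** coexistence equilibria. The analytic ASS
condition is that the cubic discriminant is positive (three distinct real
roots) and every root maps to a positive equilibrium; when it holds, the
middle equilibrium (by `C_J*`) is unstable. The package pairs this analytic
machinery with brute-force dynamics: `deSolve` integration, attractor
detection and clustering by time-averaged state, and boolean ASS maps over
two-parameter planes.

## Worked example

```r
library(nichestates)
p <- default_params("additional")   # r = 1, a = 0.1, b = 0.5, d = 0.1, two K = 10 resources per stage
coexistence_equilibria(p)
#> # A tibble: 3 × 6
#>     C_J   C_A stability lambda_max residual state
#>   <dbl> <dbl> <chr>          <dbl>    <dbl> <list>
#> 1 0.986  8.89 stable       -0.0194 9.85e-17 <dbl [6]>
#> 2 9.14   7.83 unstable      0.202  1.74e-14 <dbl [6]>
#> 3 9.87   1.28 unstable      0.0500 2.25e-14 <dbl [6]>

ass_condition(p)
#> <ASS diagnostics, scenario 'additional'>
#>   ass_exists: TRUE
#>   discriminant: 2777
#>   interior equilibria: 3
```

Three coexistence equilibria: an adult-dominated stable point
(`C_A = 8.89`), the unstable middle saddle, and a juvenile-dominated state
(`C_J = 9.87`) that satisfies the analytic condition but is a weakly
unstable focus (`λ_max = 0.05`) at these reference rates — the analytic
three-roots condition is necessary, not sufficient, for dynamic bistability
(see the methods vignette). Mapping the condition over the second-resource
productivities, and counting attractors under strong two-sided resource
sharing:

```r
sc <- scan_ass_region(p, "K_J[2]", seq(0.5, 30, length.out = 30),
                      "K_A[2]", seq(0.5, 30, length.out = 30))
ass_area_fraction(sc)
#> [1] 0.9666667
autoplot(sc)   # region map

ps <- set_param(set_param(default_params("sharing"), "a_JA", 0.3), "a_AJ", 0.3)
count_attractors(ps, initial_grid(ps, n = 4), transient = 3000)
#> <attractor set: 3 distinct attractor(s), 16/16 runs converged>
#> # A tibble: 3 × 7
#>   cluster kind        n_initials   R_J   R_A   C_J   C_A
#>     <int> <chr>            <int> <dbl> <dbl> <dbl> <dbl>
#> 1       1 fixed-point         11  0     2.53  1.22  4.64
#> 2       2 fixed-point          3  1.54  0     2.72  2.09
#> 3       3 boundary             2  0     0     0     0
```

With both cross-consumption rates large the stages have effectively
exchanged their major resources and bistability redevelops: two mirrored
stable states, each excluding the over-exploited minor resource.

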