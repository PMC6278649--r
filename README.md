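# bzfit

Thermodynamic modelling and fitting of the protein-induced B-Z transition
of DNA.

Z-DNA-binding proteins (ZBPs) — the Zα domains found in ADAR1, DAI, the
poxvirus E3L protein and fish PKZ — convert short B-form DNA duplexes into
the left-handed Z conformation. NMR titrations (imino-proton hydrogen
exchange, amide chemical-shift perturbation, Z-fraction measurements)
characterise this transition through a sequential four-state mechanism:

    B  ⇌  BP  ⇌  ZP  ⇌  ZP₂

one protein molecule binds B-DNA (dissociation constant *K*<sub>d,BP</sub>),
the bound duplex flips to the Z form
(*K*<sub>BZ,1</sub> = [ZP]/[BP]), and a second protein molecule stabilises
it (*K*<sub>d,ZP₂</sub>); α = *K*<sub>d,ZP₂</sub>/*K*<sub>d,BP</sub>
compares the two binding steps. Combining the equilibria with the DNA and
protein mass balances reduces the system to a monic cubic in the free
protein concentration,

  [P]³ + a[P]² + b[P] + c = 0,  a = 2[N]ₜ − [P]ₜ + (1 + 1/K_BZ,1)·K_d,ZP₂, …

which `bzfit` solves exactly (trigonometric closed form with Newton
polish, plus an independent bracketing solver as fallback and oracle).

The package is for structural-biology/biophysics users who want to

* **predict** species populations, Z-fractions and the three NMR
  observables for any mixture composition and constants
  (`titration_curve()`, `kex_vs_chi()`, `kex_bform_vs_fz()`,
  `kex_zform_vs_fz()`, `delta_obs()`);
* **fit** equilibrium constants from titration data, including the
  global multi-probe chemical-shift + Z-fraction fit that yields
  *absolute* binding constants rather than only their ratio
  (`fit_eq1()`, `fit_eq2()`, `fit_eq3()`, `global_fit_shifts()`,
  `bootstrap_uncertainty()`);
* **validate** every fitting path by seeded synthetic-data parameter
  recovery (`simulate_dataset()`, `recovery_study()`,
  `make_fixture_suite()`).

## Worked example

Forward modelling at the constants reported for the goldfish PKZ Zα
domain with d(TCGCGCG)₂ at pH 6.0, 10 mM NaCl:

```r
library(bzfit)
p <- bz_params(Kd_BP = 0.028, Kd_ZP2 = 0.345, K_BZ1 = 0.87)
titration_curve(p, N_total = 100, chi = c(0.5, 1, 1.5, 2))
#>   chi P_free      BP      ZP     ZP2 f_Z_dna
#> 1 0.5 0.0142 25.7475 22.4003  0.9190  0.2332
#> 2 1.0 0.1049 41.6415 36.2281 11.0128  0.4724
#> 3 1.5 0.7621 26.1192 22.7237 50.1975  0.7292
#> 4 2.0 8.2635  4.4030  3.8306 91.7514  0.9558
```

Concentrations are μM: at half a protein per duplex (χ = 0.5) the mixture
is dominated by the single-bound intermediates BP and ZP in their
0.87 : 1 conformational ratio, and 23% of the DNA is Z-form; by χ = 2 the
doubly-bound ZP₂ complex has taken over (92 μM of 100) and the duplex is
96% Z. Simulating a noisy multi-probe shift titration at these constants
and fitting it back recovers them:

```r
ds  <- simulate_dataset(simulation_spec("shift_and_fz",
         truth = list(params = p),
         noise = list(shift_sigma = 0.005, fz_sigma = 0.02), seed = 1))
fit <- global_fit_shifts(ds)
fit$estimates
#>       Kd_BP      Kd_ZP2       K_BZ1       alpha
#>  0.02771789  0.33851859  0.83935833 12.21299943
```

i.e. 0.0277 ± 0.0006 μM, 0.339 ± 0.009 μM and 0.839 ± 0.031 against the
generating 0.028 / 0.345 / 0.87 (`fit$se` holds the standard errors;
`alpha` is the derived ratio).

A thin command-line interface wraps the same functions:

```sh
Rscript inst/cli/bzfit simulate --eq 3 --seed 3 --out run.csv
Rscript inst/cli/bzfit fit      --eq 3 --data run.csv --out report.json
Rscript inst/cli/bzfit recover  --eq 1 --n 200 --seed 1 --out recovery.json
Rscript inst/cli/bzfit fixtures --seed 1 --out fixtures/
```

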