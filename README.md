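# admixabc

Forward-in-time simulation and machine-learning Approximate Bayesian
Computation (ABC) for reconstructing the admixture history of a population
founded from two sources — the classic setting of post-colonial admixed
populations with an African and a European source — plus a permutation test
for ancestry enrichment within long runs of homozygosity (ROH).

## What it does

An admixed population H is founded at generation 0 in proportions
*s*<sub>Afr,0</sub> / 1 − *s*<sub>Afr,0</sub> and evolves for 20 discrete
Wright–Fisher generations. After founding, each source contributes either
two discrete pulses or a monotonically non-increasing recurring period;
crossing the two regimes over the two sources gives four competing
scenarios. The reproductive size follows a rectangular-hyperbola trajectory
between *N*<sub>0</sub> and *N*<sub>20</sub> with steepness *u*<sub>N</sub>
(linear at *u*<sub>N</sub> = ½, step-like as *u*<sub>N</sub> → 0).

The package:

* simulates the process individual-by-individual from fixed **gamete
  reservoirs** that match each source's allele-frequency spectrum
  (bit-packed haplotypes; thousands of 21-generation simulations per
  minute), with genealogical tracking so samples contain no two
  individuals sharing a grandparent;
* summarises each dataset by **42 statistics**: within-H diversity (ASD,
  unbiased heterozygosity, inbreeding *F*), the full shape (moments +
  deciles) of the MDS-projected individual admixture fractions *α* and
  source–source angles *θ*, and between-population statistics
  (Weir–Cockerham F<sub>ST</sub>, cross-population ASD, and the
  *f*<sub>3</sub>(H; Eur, Afr) admixture statistic);
* chooses the scenario by **Random-Forest ABC** (votes, posterior
  probability via an error-regression forest, out-of-bag cross-validation)
  after a goodness-of-fit **prior check**, and estimates all scenario
  parameters jointly by **Neural-Network ABC** (rejection + logit
  transform + ensemble regression adjustment) with credibility intervals
  and cross-validation errors;
* tests whether **long ROH (≥ 1 cM)** carry an excess of one local
  ancestry relative to the genome-wide fraction, by randomly re-placing
  each individual's long ROH 10,000 times (*g* = 100/2*l* converts ROH
  length to the age of the shared ancestor: 1 cM ≈ 50 generations,
  0.25 cM ≈ 200);
* generates all inputs synthetically: Balding–Nichols source panels with
  controlled divergence, pseudo-observed datasets with known ground truth
  (optionally with per-allele ancestry instrumentation), and ancestry/ROH
  fixtures with a tunable ancestry–ROH association.

## Worked example

```r
library(admixabc)
set.seed(1)

# synthetic source panels at Fst ~ 0.15, fixed gamete reservoirs
freqs <- generate_source_frequencies(5000, divergence = 0.15)
res   <- build_reservoir_pair(freqs, R = 2000)

# a reference table: 100 simulations under each of the 4 scenarios
tab <- simulate_reference_table(freqs, prior = default_priors("desk"),
                                n_per_scenario = 100, n_admixed = 30,
                                seed = 2, reservoirs = res)

# a pseudo-observed dataset with a known strong-signal history:
# two large African pulses plus heavy recurring European flow
truth <- structure(list(
  scenario = "Afr2Pulses-EurRecurring", s_Afr_0 = 0.6,
  african  = list(kind = "pulse", source = "African",
                  t_p1 = 16L, t_p2 = 3L, s_p1 = 0.7, s_p2 = 0.5),
  european = list(kind = "recurring", source = "European",
                  t_t1 = 6L, t_t2 = 13L, s_t1 = 0.8, s_t2 = 0.45, u = 0.25),
  demography = list(N0 = 1000L, N20 = 1000L, uN = 0.3)),
  class = "admix_params")
obs <- generate_pseudo_observed(truth, res, n_admixed = 30, seed = 3)

fit <- run_inference(tab, obs$samples, default_priors("desk"),
                     tolerance = 0.25, seed = 4)
fit$scenario_choice
#> RF-ABC scenario choice
#>   selected: Afr2Pulses-EurRecurring (178/500 votes, posterior probability 0.486)
#>   out-of-bag prior error: 0.623
round(fit$posterior$summary["s_Afr_0", ], 3)
#>         median ci50_lo ci50_hi ci95_lo ci95_hi
#> s_Afr_0  0.726   0.631   0.860   0.152   0.935
```

The vote plurality picks the generating scenario, with the honest caveat
that at this reduced scale the four scenarios overlap heavily (out-of-bag
prior error ≈ 0.62 against the 0.75 chance level, echoing the "good but not
perfect" discrimination of the full-scale design; the two mixed scenarios
in particular are hard to tell apart — see the methods vignette). The 95%
interval for the founding proportion is wide — it is genuinely weakly
identified when later gene flow can overwrite the founding signal.

The `analysis/` directory runs the same pipeline as a narrated five-step
study (`01_simulate_reference.R` … `05_roh_permutation.R`), writing its
tables under `results/`.

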