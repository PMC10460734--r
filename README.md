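# corrdelta

Global sensitivity analysis (GSA) for models whose input parameters are
**correlated**, built around the moment-independent **delta sensitivity
index**, with a tumor-in-host pharmacometric case study built in.

## Who this is for

Modellers — pharmacometricians in particular — who need to know which
uncertain parameters drive the uncertainty of a model-derived quantity when
the parameters are statistically dependent (as estimation-stage parameters
always are). Variance-based Sobol indices lose their interpretation under
input correlation; the delta index does not.

## The method

For a scalar output $Y = g(\mathbf{X})$, the delta index of input $X_i$ is

$$\delta_i = \tfrac{1}{2} E_{X_i}\!\left[\int \lvert f_Y(y) -
f_{Y\mid X_i}(y \mid X_i)\rvert\, dy\right] \in [0, 1],$$

half the expected L1 distance between the output density and the output
density conditional on $X_i$; $\delta_i = 0$ iff $Y$ is independent of
$X_i$. It is estimated from a single Monte Carlo sample ("given data") by
equal-frequency partitioning of each input and kernel density estimation,
with bootstrap confidence intervals and a significance threshold calibrated
on a spurious standard-normal `Noise` input (97.5th percentile of its
bootstrap deltas).

The **two-stage protocol** runs the analysis twice: Step 1 samples the
inputs *independently* (same marginals), so significant deltas mark
**causal** effects; Step 2 samples from the full correlated joint
distribution, adding **indirect** effects inherited through correlations.
Crossing the two significance flags classifies every parameter as
`causal_and_indirect`, `indirect_only`, `causal_suppressed` or
`negligible`.

The built-in case study covers secondary metrics of a dynamic-energy-budget
tumor-growth-inhibition (DEB-TGI) model for xenografts: the exponential
tumor growth rate $\lambda = m g \mu_u / g_u - m_u$, the tumor volume
doubling time $\mathrm{TVDT} = \ln 2 / \lambda$, the eradication
concentration threshold $C_T = \lambda / k_2$, the food-supply coefficient
$\rho_b = 1/(1+R_b)$, and the control-vs-treated delay
$\Delta T_{\delta Vmax}$ in reaching the maximum structural-biomass
degradation rate (computed from user-supplied trajectories).

## Worked example

Propagate the low-uncertainty (CV1) parameter scenario to the eradication
threshold $C_T$, then rank the parameters:

```r
library(corrdelta)

# uncertainty analysis, correlations ignored
joint <- build_joint(table2_scenario("CV1"))
ua <- monte_carlo_summary(ct_model(), joint, n = 1e5, seed = 1,
                          independent = TRUE, output_name = "C_T")
print(ua)
#> C_T: n = 100000 (dropped 0), mean 4.217, median 4.127, 95% CI [2.712, 6.236] (independent sampling)

# two-stage GSA with the shipped correlation template (k2-IC50 = 0.95)
jc <- build_joint(table2_scenario("CV1"),
                  complete_correlation(correlation_template_paper()))
gsa <- run_two_stage(ct_model(), jc, n = 2e4, partitions = 30,
                     B = 200, seed = 1)
print(gsa)
#> Two-stage delta sensitivity analysis
#>   n = 20000, partitions = 30, B = 200, seed = 1
#>   noise thresholds: step1 = 0.0533, step2 = 0.0527
#>        name delta1_median delta1_significant delta2_median delta2_significant        effect_class
#>          k2        0.5848               TRUE        0.5848               TRUE causal_and_indirect
#>        IC50        0.0499              FALSE        0.4932               TRUE       indirect_only
#>        mu_u        0.0933               TRUE        0.0946               TRUE causal_and_indirect
#>         g_u        0.0917               TRUE        0.0920               TRUE causal_and_indirect
#>          Rb        0.0470              FALSE        0.0496              FALSE          negligible
#>         ...
```

Reading the output: the 95% interval of $C_T$ spans roughly 2.7–6.2 ng/ml,
about ±50% around its median — drug potency $k_2$ is the dominant causal
driver (delta ≈ 0.58), the tumor energetics parameters $\mu_u$ and $g_u$
have moderate causal effects, and the toxicity parameter
$\mathrm{IC}_{50}$ — absent from the $C_T$ formula — becomes the second
most important parameter once its strong correlation with $k_2$ is
considered (`indirect_only`). Every delta below the step's noise threshold
(≈ 0.05 at this sample size) is reported as zero.

The shipped host constants $m, g$ are synthetic stand-ins calibrated so
that the typical-parameter doubling time equals 1.3 days (only the product
$m \cdot g$ enters any metric); see `?host_constants` and the vignette
`vignettes/two-stage-gsa.Rmd` for all conventions and design choices. A
command-line front end is provided at `inst/cli/corrdelta.R`.

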