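# celldecide

Cells read noisy signals. When a fibroblast senses the cytokine TNF through
the nuclear concentrations of two transcription factors — NFκB and ATF-2 — it
can misjudge the input: act as if TNF were high when it is low (a **false
alarm**) or overlook a genuinely high dose (a **miss**). `celldecide`
quantifies these decision errors from single-cell measurements. It is aimed
at systems biologists with per-cell output concentrations across input
conditions (e.g. immunocytochemistry or flow cytometry) who want to know how
reliably the measured outputs discriminate input levels, and which output
carries the information.

## The model

Binary hypothesis test on the vector **z** of log output concentrations of a
cell:

- H₀: input level low, **z** | H₀ ~ N(μ₀, Σ₀)
- H₁: input level high, **z** | H₁ ~ N(μ₁, Σ₁)

The minimum-error rule decides H₁ when the likelihood ratio
L(**z**) = p(**z**|H₁)/p(**z**|H₀) exceeds γ = P(H₀)/P(H₁). Its errors are

    P_FA = P(decide H₁ | H₀),   P_M = P(decide H₀ | H₁),
    P_E  = P(H₀)·P_FA + P(H₁)·P_M

The boundary {**z** : ln L(**z**) = ln γ} is the root set of a quadratic: in
one dimension one or two scalar thresholds (P_FA, P_M then follow in closed
form via the Gaussian tail function Q); in two dimensions a conic **decision
threshold curve (DTC)** that the package traces numerically, with error
probabilities by Monte Carlo integration over the decision regions and,
independently, by counting discriminant-function comparisons
gᵢ(**z**) = ln p(**z**|Hᵢ) + ln P(Hᵢ) on the observed cells. A
minimum-redundancy maximum-relevance (MRMR) analysis scores each output's
contribution by mutual information.

Because the reference NFκB/ATF-2 dataset is not publicly deposited, the
package includes a synthetic generator (`default_tnf_scenario()`) emulating
its statistical structure: bivariate lognormal clusters per condition, dose-
dependent separation at 30 min, feedback-degraded separation at 4 h.

## Worked example

```r
library(celldecide)

tab <- default_tnf_scenario(seed = 42)        # 8 conditions x 3000 cells
res <- run_pipeline(list(
  data = tab, low = 0.013, high = c(0.082, 3.2, 50),
  timepoints = c(30, 240), mc_n = 1e5, mc_seed = 7))
res
#> <pipeline_result> 6 comparison(s), low = 0.013, outputs: NFkB, ATF2
#>   high 0.082 @ 30 min: P_FA = 0.273, P_M = 0.265, P_E = 0.269 (Monte Carlo), top output NFkB
#>   high 3.2 @ 30 min: P_FA = 0.077, P_M = 0.083, P_E = 0.080 (Monte Carlo), top output NFkB
#>   high 50 @ 30 min: P_FA = 0.041, P_M = 0.048, P_E = 0.045 (Monte Carlo), top output NFkB
#>   high 0.082 @ 240 min: P_FA = 0.365, P_M = 0.402, P_E = 0.384 (Monte Carlo), top output NFkB
#>   high 3.2 @ 240 min: P_FA = 0.218, P_M = 0.265, P_E = 0.241 (Monte Carlo), top output NFkB
#>   high 50 @ 240 min: P_FA = 0.235, P_M = 0.285, P_E = 0.260 (Monte Carlo), top output NFkB
```

Each line is one low-vs-high comparison: the chance a low-TNF cell is read as
high (P_FA), the chance a high-TNF cell is read as low (P_M), and their
prior-weighted sum (P_E). At 30 min the errors fall monotonically with dose —
a stronger signal is easier to detect; at 240 min every error is larger and
no longer monotone, the signature of negative feedback compressing the
responses.

```r
res[["high0.082_t30"]]$importance
#>   output rank relevance redundancy   miq  score
#> 1   NFkB    1    0.2276      0.127 1.788 0.2276
#> 2   ATF2    2    0.0417      0.127 0.328 0.0417
```

NFκB's importance score (mutual information with the hypothesis label, in
bits) dwarfs ATF-2's: the first output does most of the deciding.

`plot_dtc_heatmap()` draws the two class densities with the DTC overlaid;
`run_pipeline(... out_dir = "results/")` writes `results.json` (all error
reports with seeds and standard errors) plus one heatmap per comparison. A
command-line front end lives at `inst/cli/celldecide.R`
(`simulate` / `analyze` / `importance`).

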