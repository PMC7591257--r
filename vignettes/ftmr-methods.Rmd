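---
title: "Methods: one-sample Mendelian randomization of calculated free testosterone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: one-sample Mendelian randomization of calculated free testosterone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Testosterone products are widely prescribed to older men, but their
long-term causal effects on disease are poorly established: randomized
trials are short, small, and rarely powered for hard endpoints. Mendelian
randomization (MR) offers a complementary design. Genetic variants that
raise free testosterone are allocated at meiosis, independently of
lifestyle and environment, so men genetically randomized to higher
lifelong free testosterone form natural "treatment arms". `ftmr`
implements a complete one-sample MR pipeline for calculated free
testosterone (CFT) in a male cohort — free-hormone calculation, instrument
discovery, causal estimation with a full sensitivity suite, and a
genetic-risk-score (GRS) phenome scan — together with a synthetic-cohort
simulator so that every stage is testable without access to
individual-level biobank data.

## Free hormone model

Serum testosterone is partitioned between a free fraction, a high-affinity
pool bound to sex hormone-binding globulin (SHBG), and a low-affinity,
high-capacity pool bound to albumin. At mass-action equilibrium with
association constants $K_t$ (SHBG) and $K_a$ (albumin), total testosterone
satisfies

$$TT = FT \cdot N + \frac{K_t \, FT}{1 + K_t \, FT}\, SHBG,
\qquad N = 1 + K_a \, [\mathrm{Alb}],$$

with all concentrations in mol/L. Solving for the free fraction gives the
positive root of the quadratic

$$N K_t \, FT^2 + \bigl(N + K_t(SHBG - TT)\bigr) FT - TT = 0,$$

implemented in closed form by `cft_vermeulen()` and verified in the tests
against an independent bisection root-finder to $10^{-12}$ relative
accuracy. The binding constants are not universal physical constants;
we adopt the canonical parameterization $K_t = 1.0\times 10^9$ L/mol,
$K_a = 3.6\times 10^4$ L/mol and an albumin molar mass of 69,000 g/mol,
all overridable through `binding_constants()`. At typical male values
(TT = 11.9 nmol/L, SHBG = 40 nmol/L, albumin = 45 g/L) the model yields
CFT near 0.21 nmol/L, a free fraction of about 2%.

Phenotype construction (`prepare_phenotypes()`) excludes men on androgen
medication or missing any of the three serum inputs, then winsorizes CFT
at mean ± 4 SD computed on the post-exclusion male distribution, and
derives natural-log SHBG (SHBG is log-transformed before any association
testing) and hematocrit = RBC × MCV / 10 from red-cell indices. The order
— exclude first, winsorize second — is a deliberate choice: winsorization
statistics should describe the analysis population, not participants
already excluded on medication grounds.

## Instrument discovery

Variants pass QC when minor allele frequency is at least 1%, the
Hardy-Weinberg exact test (full enumeration of heterozygote counts
conditional on allele counts) gives $p \ge 10^{-10}$, imputation info (when
available) is at least 0.7, and the variant lies outside the extended HLA
region, for which we use the GRCh37 convention chr6:25–34 Mb since
pleiotropy in that region is pervasive. Each exclusion carries exactly one
primary reason, with priority region > MAF > HWE > info.

The exposure scan (`gwas_scan()`) is ordinary least squares of the trait
on effect-allele dosage adjusted for age, age², genotyping chip,
assessment centre and genetic principal components, computed by
Frisch–Waugh residualization so a thousand variants are fit in one matrix
operation. A mixed-model scan is unnecessary here because the simulator
generates unrelated individuals. Binary traits are analyzed with the same
linear model on 0/1 and converted to the log-odds scale downstream.
Genomic control is monitored by $\lambda$ = median $\chi^2$ / 0.4549364.

Candidate instruments are genome-wide-significant CFT hits
($p < 5\times10^{-8}$ at full scale; the threshold is a parameter because
synthetic cohorts are small), minus any variant associated with log SHBG
at $p < 0.05$. This stringent SHBG filter is central to the design:
variants acting through SHBG binding violate the free-hormone calculation
and risk pleiotropy through other sex hormones. The survivors are LD-pruned
by greedy clumping at $r^2 < 0.01$ (ties broken by p, chromosome, then
position, for deterministic output). LD is computed in-sample from the
cohort dosages rather than from an external reference panel — the honest
option when the cohort itself is the only genotype source. Joint
instrument strength is summarized by
$F = \frac{n-J-1}{J}\cdot\frac{R^2}{1-R^2}$; at the full-cohort scale
printed in the literature ($R^2 = 3.7\%$, $J = 93$, $n = 161{,}268$) this
arithmetic gives $F \approx 66$, and the pipeline warns prominently —
but continues, the check being diagnostic — whenever $F < 10$.

## Causal estimation and sensitivity suite

With per-allele effects $\gamma_j$ on CFT and $\Gamma_j$ on the outcome
(harmonized so every $\gamma_j > 0$), the estimators are implemented from
their definitions:

* **IVW**: $\hat\beta = \sum_j \gamma_j\Gamma_j/\sigma_{\Gamma j}^2 \big/
  \sum_j \gamma_j^2/\sigma_{\Gamma j}^2$, with multiplicative
  random-effects variance inflation $\max(1, RSS/(J-1))$ and a normal
  reference (J is large in practice; the choice is recorded in output
  metadata). At $J=1$ it reduces exactly to the Wald ratio
  $\Gamma/\gamma$ with delta-method standard error.
* **MR-Egger**: weighted least squares of $\Gamma$ on $\gamma$ with a free
  intercept estimating average directional pleiotropy; intercept tested
  two-sided against $t_{J-2}$, dispersion floored at 1.
* **MR-RAPS**: robust profile-score estimation with standardized residuals
  $t_j = (\Gamma_j-\beta\gamma_j)/\sqrt{\sigma_{\Gamma j}^2 +
  \beta^2\sigma_{\gamma j}^2 + \tau^2}$, Tukey biweight ($c=4.685$; Huber
  and $\ell_2$ available), and overdispersion $\tau^2 \ge 0$ solved from
  the Fisher-consistent second-moment condition
  $\sum_j[\psi(t_j)t_j - E_\Phi\psi(Z)Z]=0$ (pinned at zero when the
  condition is negative there). Roots are located by a deterministic
  201-point grid multi-start with bisection refinement, keeping the root
  minimizing the robust objective; in the $\ell_2$/no-overdispersion/
  error-free-exposure limit the estimate coincides with IVW, which the
  tests assert to $10^{-6}$.
* **MR-PRESSO**: the observed weighted residual sum of squares about
  leave-one-out IVW estimates, compared to a parametric simulation of the
  null (10,000 draws at full scale; smaller counts for desk-scale
  calibration runs), with add-one-corrected global p, per-variant outlier
  p-values Bonferroni-adjusted over J, outlier removal and IVW repetition
  when the global test rejects, and a distortion test whose null compares
  removal of random subsets of the same cardinality (1000 draws — the
  originating method leaves this resolution loose). Note an inherent
  resolution limit: the smallest achievable adjusted outlier p is
  $J/(n_{sim}+1)$, so outlier detection needs $n_{sim}$ well above
  $20\,J$.
* **Leave-one-out**: IVW repeated excluding each variant, flagging
  exclusions whose estimate escapes the full-set 95% CI.

Reporting rules: IVW is primary. When the PRESSO global test rejects at
0.05, outliers are removed and the analysis repeated on the survivors.
When the Egger intercept differs from zero at 0.05 — evaluated on the
analysis set in use, i.e. on the outlier-corrected set when correction
fired — the MR-Egger estimate is reported in place of IVW. Binary
outcomes analyzed on the linear-probability scale are converted with
$\log OR = \beta/(k(1-k))$, $k$ the case fraction, before estimation.
All effects are reported per 0.1 nmol/L of CFT, the approximate change
seen after starting testosterone treatment. The a priori outcome family
uses Bonferroni $\alpha = 0.05/22 = 2.27\times10^{-3}$; the phenome-wide
family $0.05/439 = 1.14\times10^{-4}$.

## Genetic risk score and phenome scan

The weighted GRS is $\sum_j \gamma_j \cdot \mathrm{dosage}_{ij}$ (signed
weights, equivalent to orienting every variant to its CFT-increasing
allele). The score is calibrated to hormone units by the
covariate-adjusted regression of CFT on the score — the one-sample
two-stage-least-squares structure — so a per-score-unit outcome effect
times $0.1/\mathrm{slope}$ is the effect per 0.1 nmol/L. The scan fits
linear or logistic regressions with the same covariates as the GWAS. A
negative control is built in: because SHBG-associated variants were
filtered, the GRS must not associate with log SHBG, which the analysis
verifies.

Rare outcomes are excluded by a power filter: with a score explaining
$R^2$ of exposure variance, the standard error of the log-OR per SD of
exposure is approximately $1/\sqrt{n\,k(1-k)R^2}$, so the minimal
detectable OR per 0.1 nmol/L at 80% power and two-sided $\alpha = 0.05$
follows after scaling by $0.1/\sigma_{CFT}$. Outcomes whose detectable-OR
interval is not contained in [0.5, 2] are dropped. The exact inputs behind
the published case cutoff are not printed anywhere, so every parameter is
exposed; with biobank-scale inputs ($n = 157{,}252$, $R^2 = 0.037$,
$\sigma_{CFT} = 0.07$ nmol/L) the induced cutoff computes to roughly 900
cases. Medication-exclusion sensitivity reruns repeat the scan on the
subsets free of blood-pressure or cholesterol medication and report sign
agreement with the full-cohort estimates.

## The synthetic cohort: what it emulates and what it does not

The simulator (`simulate_cohort()`) generates the statistical structure
the analysis assumes, with defaults fixed once as the study conditions:

| quantity | default | rationale |
|---|---|---|
| latent FT | mean 0.210, SD 0.07 nmol/L | male biobank mean CFT; SD consistent with the power-filter arithmetic |
| FT architecture | 93 signals, 3.7% variance | the reported male CFT architecture |
| SHBG | mean 40, SD 15 nmol/L; 20 signals, 15% variance | typical male SHBG distribution and heritability |
| albumin | N(45, 2.5) g/L | narrow physiologic distribution |
| total testosterone | forward binding equation | emerges near 11.9 nmol/L without tuning |
| assay noise | 5% CV on TT and SHBG | published within-laboratory CVs (4–8%) |
| SHBG-assay coupling | 0.02 per SD of SHBG | models assay interference so SHBG genetics leaks into computed CFT |
| exclusions | 1.1% androgen medication, 13% missing panel | the published exclusion flow |
| LD | Gaussian copula, AR(1) blocks, calibrated thresholds | target genotype correlation without coalescent machinery |
| FT residual | right-skewed centered lognormal (sdlog 0.5) | hormone residuals are right-skewed; the true distribution is unpublished, so this is configurable |
| confounder | one standard normal loading on FT and outcomes | minimal structure MR must be robust to |
| binary outcomes | liability threshold (exact prevalence) or logistic link | threshold for prevalence control; logistic when a target OR is simulated |

Genotypes are drawn as two haplotypes from a latent AR(1) Gaussian within
each LD block, thresholded at the allele frequency; the latent correlation
of each adjacent pair is calibrated (by solving the bivariate-normal
orthant probability) so the realized genotype correlation matches the
configured `ld_rho`, since naive thresholding attenuates it. Total
testosterone is generated by the forward binding equation, which makes
the Vermeulen inversion of the noise-free values exact to machine
precision — a round trip the tests assert at $10^{-10}$.

What the simulator does **not** emulate: realistic human LD maps,
imputation uncertainty, relatedness and population stratification, ICD
coding noise, sex-combined structure, selection into the cohort, and
assay artifacts beyond multiplicative noise with a linear SHBG coupling.
Passing tests therefore demonstrate that the pipeline's statistics behave
as designed under the assumed data-generating process, not that the
biological point estimates of any real cohort are reproduced — those
require the individual-level data, which cannot be redistributed.

## Numerical choices and problem sizes

Desk-scale defaults were chosen so the complete suite exercises every
stage in minutes: the demonstration pipeline uses 5,000 individuals and
500 variants with 5 equal-magnitude FT signals explaining 5% of variance
(each instrument individually strong at that n, keeping winner's-curse
selection bias negligible when discovering at the relaxed threshold
$10^{-4}$); the analysis-workflow cohort uses 20,000 individuals, 1,000
variants and 20 signals explaining 10%, discoverable at the full
$5\times10^{-8}$ threshold. Calibration experiments use 200–1500
summary-level replicates, sized so Monte-Carlo error is small relative to
the property asserted. All randomness flows from a single seed expanded
per stage, so one integer reproduces a full run byte-for-byte. Degenerate
inputs are handled explicitly: zero-variance dosages are skipped, an SD of
zero leaves winsorization a no-op, negative latent FT draws are floored at
0.001 nmol/L and logged, $\tau^2$ is pinned at zero when the moment
condition is negative, and PRESSO refuses to continue when every
instrument is flagged.

## Known limitations

One-sample MR with in-sample instrument discovery is subject to winner's
curse and weak-instrument bias toward the confounded estimate; the
pipeline mitigates (strong-instrument check, sensitivity suite) but does
not remove these. The linear-probability-to-log-odds conversion is a
first-order approximation that degrades for very common outcomes and
large effects. The power filter's normal approximation ignores covariate
adjustment. In-sample LD pruning can differ from reference-panel pruning
near block boundaries. MR-RAPS standard errors use the M-estimation
sandwich with the overdispersion treated as known, which is slightly
anticonservative at small J.
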