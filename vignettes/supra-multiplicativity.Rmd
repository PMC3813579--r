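---
title: "Testing SNP sets for supra-multiplicative risk-allele effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing SNP sets for supra-multiplicative risk-allele effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(supramult)
```

## The question the test answers

Genome-wide association studies describe each susceptibility SNP by a
marginal effect, and the default joint model multiplies those effects:
on the logit scale of a logistic regression, risks combine additively.
Limiting-pathway liability models predict something different — a set of
risk alleles whose joint effect is *fortified* when enough of them occur
in the same individual.  Under such a model an individual's risk is near a
baseline penetrance $f_0$ as long as their risk-allele load
$L = \sum_i w_i x_i$ (with $x_i \in \{0,1,2\}$ the count of externally
designated risk alleles) stays below a critical threshold $T^\*$, and
jumps to an elevated penetrance $p_1 > f_0$ at or above it.  Pairwise
interaction tests are nearly blind to this architecture because the
interaction mass is spread over all orders, each order contributing a
small coefficient.

The supra-multiplicativity test (SMT) implemented in `smt_test()`
addresses this with a single degree of freedom.  For a pre-specified set
of $n$ SNPs ($2 \le n \le 500$) and each valid load cut-off $T$ it
compares, by likelihood ratio,

$$\text{logit } P(\text{case}) = \beta_0 + \textstyle\sum_i \beta_i x_i
\quad\text{against}\quad
\beta_0 + \textstyle\sum_i \beta_i x_i + \pi\, I(L \ge T),$$

so the marginal SNP effects are covariates and $\pi$ captures any sharp
increase of risk at load $T$.  A cut-off is *valid* when individuals
exist on both sides of it; with $v$ valid cut-offs the final p-value is
the Bonferroni bound $p_\text{final} = \min(1, v \cdot \min_T p_T)$.
Because the per-threshold tests are positively dependent, this correction
is conservative — a property the type-I-error study below confirms — and
it needs no permutation machinery, which is why Bonferroni is the only
correction implemented.

Two assumptions delimit the test's power.  Effect *sizes* may depend on
the genotype background (that is what it detects), but effect
*directions* must not, because the load counts designated risk alleles.
And a substantial portion of the set must participate in the deviation;
a single interacting pair dilutes into a 500-SNP load.

## Orientation is external, always

`compute_allele_load()` counts the risk alleles named by a
`RiskAlleleSpec` (a `snp_id`/`risk_allele`/`weight` table), and
`read_genotypes()` flips any genotype column whose file-encoded counted
allele is not the designated risk allele.  The designation must come from
an outside source (a GWAS catalogue, a prior study): re-deriving risk
alleles from the analysis sample itself would align noise with the
phenotype and bias the load.  This is why none of the package's entry
points will orient alleles from marginal odds ratios.

## Threshold profile and reporting

`threshold_profile()`/`tidy()` expose, per cut-off: the indicator
estimate $\hat\pi_T$ and its standard error, the uncorrected p-value, the
above-threshold frequency among cases and controls, and the two-by-two
odds ratio of case status against load $\ge T$ with the standard error of
its logarithm (Haldane–Anscombe 0.5 correction on zero cells, flagged).
Under a genuine liability threshold the $\hat\pi_T$ curve rises to a
sharp maximum at $T^\*$; under gradual supra-multiplicativity it grows
smoothly.  `autoplot()` draws this curve.

The per-threshold p-values default to the likelihood-ratio test
(`test = "lrt"`); Wald p-values from $\hat\pi_T/\widehat{se}$ are
available via `test = "wald"` and the estimates are reported either way.
The likelihood ratio is the better-calibrated choice at the small
significance levels a threshold scan is corrected to, and it is invariant
to affine recodings of the genotype covariates, so the additive-coding
choice ($x_i \in \{0,1,2\}$ vs $\{-1,0,1\}$) cannot affect p-values.
Which of the two the original software reported is not recoverable;
both are exposed.

## Degenerate fits inside a scan

A 500-SNP scan must not die because one cut-off is pathological.  The
policy, implemented in the IRLS engine (`fit_logistic()`, compiled):

* convergence = relative log-likelihood change $< 10^{-10}$ within 100
  iterations, with step-halving;
* separation = fitted probabilities within $10^{-10}$ of 0/1 together
  with diverging coefficients; a separated or singular per-threshold fit
  contributes $p = 1$ (conservative) and is flagged in the profile;
* an empty cell of a threshold's status-by-side two-by-two table is
  quasi-complete separation for the indicator coefficient: its
  maximum-likelihood estimate is infinite, so $\hat\pi_T$ and its
  standard error are reported as `NA` there (a half-converged estimate
  with an exploding standard error would pollute the profile), while the
  likelihood-ratio p-value, which remains well-defined at the boundary,
  is kept;
* an indicator that exactly duplicates a covariate column is instead a
  hard error naming the threshold — that is a modelling mistake, not a
  data accident;
* all loads identical means no valid cut-off: $p_\text{final} = 1$ with
  a warning.

Individuals with any missing genotype in the set are excluded (counted in
`glance()$n_excluded`), because the load needs every SNP; imputed dosages
in $[0,2]$ are accepted instead, in which case the threshold grid
switches from the integer grid $\{\min L + 1, \dots, \max L\}$ to the
distinct observed load values, so each achievable split is tested once.

## Covariate adjustment

`smt_adjusted()` adds dominance (heterozygote-indicator) terms and
interaction products for nominated SNPs, pairs or triples to *both*
models of the scan.  For a pair, the four genotypic products spanning
$\{$additive, dominance$\}^2$ are added (plus the dominance mains they
need): this block absorbs an arbitrary pairwise interaction, including
double-recessive effects that a purely allelic product would miss, which
is what makes the adjusted level return to nominal in the semi-null
study.  Triples add the eight three-way products and all lower orders.

## Comparator battery

`single_marker_test()`, `dominance_test()`,
`pairwise_interaction_test()` and `threeway_interaction_test()` implement
the standard tests the SMT is benchmarked against: 1-d.f. additive tests,
1-d.f. dominance deviation, and interaction blocks of 1/4 d.f. (pairs)
or 1/8 d.f. (triples) in allelic mode (products of additive terms) or
genotypic mode (products spanning additive and dominance terms).  The
8-d.f. three-way block is the full $\{a,d\}^3$ product set beyond all
lower orders — the unique saturated-minus-lower-orders block of that
size.  Empty genotype cells that collapse the rank of a block drop the
dependent terms and reduce the degrees of freedom (flagged) rather than
aborting, because small simulated samples routinely empty the
triple-homozygote cell.  `best_of_set()` enumerates all members and
supports both decision rules found in practice: comparing the most
significant member against $\alpha$ directly, or against $\alpha/m$.

## The simulators and what they emulate

All test data are synthetic; `sample_case_control()` draws genotypes
under Hardy–Weinberg equilibrium and independence across SNPs, assigns
disease by the model's penetrance, and fills case/control quotas exactly.

* **Multiplicative null** (`multiplicative_model()`,
  `multiplicative_null_draw()`): penetrance
  $f_0 \prod_i RR_i^{x_i}$, risk-scale relative risks.  The study draws
  frequencies from $U(0.1, 0.9)$ and per-allele relative risks from
  $U(1.2, 1.5)$ afresh for every replicate — the printed endpoints of the
  reference design; the frequency range keeps every SNP informative.
* **Semi-null models** (`semi_null_b1_draw()`, `semi_null_b2_draw()`):
  30 SNPs of which 15 are purely recessive (homozygote relative risk
  `rr_hom`), or 7 disjoint pairs are double-recessive (relative risk
  `rr_double` for the 4-risk-allele two-locus genotype), everything else
  multiplicative.  The deviation effect sizes are not published, so they
  are required arguments; the test suite uses `rr_hom = 1.5` and
  `rr_double = 2` as plausible moderate deviations, and the semi-null
  level study is therefore a direction check, not a numeric reproduction.
* **LPLMs** (`lplm_model()`, `weighted_lplm_model()`): threshold
  calibrated by exact convolution of the load distribution
  (`calibrate_lplm_threshold()`) so that about 1.5% of the population
  lies at or above $T^\*$; baseline penetrance 0.03; elevated penetrance
  $p_1$ chosen from the study grid (0.1–0.7).  Per-SNP frequencies of the
  reference runs are not recoverable, so the default is $q = 0.5$ for all
  SNPs (the symmetric textbook liability model); this choice is why no
  numeric acceptance value depends on LPLM power.  For the weighted
  variant (loads weighted 0.5/1/2 in ordered thirds,
  `assign_modified_weights()`), the threshold is *recalibrated* on the
  weighted load: keeping the unweighted integer threshold would put
  roughly a fifth of the population above it, contradicting the 1.5%-tail
  design the models are defined by.
* **Recessive models** (`rez_model("A")`–`"D"`): three SNPs, baseline
  0.03, elevated penetrance only for the triple homozygous-risk genotype;
  all parameters as printed.  `marginal_allelic_effect()` reproduces the
  published per-SNP relative-risk brackets by exact enumeration.
* **LD tagging** (`make_tagged_proxies()`): each causal SNP is replaced
  by a proxy with equal allele frequency and haplotype correlation
  $\sqrt{r^2}$, sampled conditional on the causal allele copies; single
  proxies only, no haplotype-block structure.  Note that with proxy
  loads the $\hat\pi_T$ peak sits at the *proxy-scale image* of the
  causal threshold — by inverse regression,
  $E[L \mid L'] = 2np_0 + (p_1 - p_0)L'$, so the peak appears near
  $(T^\* - 2np_0)/(p_1 - p_0)$, about one load unit above $T^\*$ at
  $r^2 = 0.8$ for the 30-SNP model — rather than exactly at $T^\*$.

Penetrances of the multiplicative family are capped at 1; a
configuration that would cap more than 0.1% of the population is refused
at construction.  Because of this rule the default target prevalence of
the multiplicative family is 0.01: at 40–50 SNPs with relative risks up
to 1.5, a 5% prevalence would push several tenths of a percent of the
population over the cap, and the type-I-error properties depend on the
baseline only weakly while the cap rule does not.

Case/control sampling is exact with respect to the implied conditional
genotype distributions.  For the multiplicative family the cases are
drawn from the per-SNP (or per-pair) tilted distribution
$p(x)\,m(x)$ with an acceptance step $\min(f,1)/f$ that corrects for the
cap, and controls by thinning population draws with probability $1-f$;
for the three-SNP recessive models the 27 genotype combinations are
enumerated and drawn multinomially; liability models use plain
vectorised rejection.  All three routes target exactly the distribution
that naive rejection sampling ("draw, assign status, keep until quotas
are full") defines — the tilted and enumerated forms only remove its
waste, which is what makes thousand-replicate studies of 3,000 cases and
3,000 controls tractable on one CPU.

What the simulators do **not** emulate: linkage disequilibrium between
the set's SNPs (they are independent), population structure, genotyping
error and missingness patterns, and covariate confounding.  Tests passing
on this synthetic material therefore validate the statistical machinery,
not robustness to those real-data complications.

## Study runner and reproducibility

`run_level_study()`, `run_power_study()` and `run_subset_curve()`
estimate rejection rates over replicate simulations, with the binomial
Monte-Carlo standard error attached.  The master seed spawns one child
seed per replicate, so a single replicate can be re-run in isolation and
results do not depend on scheduling; per-replicate p-values ride along as
an attribute so further significance levels cost nothing
(`reject_at()`).  Subset curves re-test the *first* $k$ SNPs in
spec-file order while the data are generated under the full model —
spec-file order is the definition of "first".

The default replicate count is 1,000, matching the reference design;
the packaged test suite runs scaled-down studies (300 replicates for the
40-SNP level study, 400 for the recessive power studies, 100–150 for the
structural property checks) and widens every tolerance to three times the
combined Monte-Carlo standard error at the scales involved, floored at
the design tolerance for the quantity.  `scripts/acceptance.R` re-runs
the full thousand-replicate versions.

## Known limitations

* Quantitative traits are out of scope; the engine is binomial-logit
  only, without Firth penalisation.
* Genome-wide scanning over subsets is out of scope: the SMT answers a
  question about a *given* set.
* The Bonferroni factor counts every valid cut-off, including near-empty
  extremes whose fits separate and contribute $p = 1$; this makes the
  corrected test strictly conservative, and noticeably more so for wide
  load ranges.  How the original implementation handled such degenerate
  cut-offs is not recoverable from its description, and several of its
  published recessive-scenario power values (notably a power of 0.69 at
  $\alpha = 0.05$ for a scenario whose above-threshold enrichment is
  detected in essentially every replicate by any converged 1-d.f. test)
  sit below what the stated generative model implies for any of the
  per-threshold test variants exposed here.  The package reports what
  its own faithful implementation computes.
* With dosage data the dominance and interaction adjustments require
  hard calls; the load itself does not.
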