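---
title: "Genetic-model selection for SNP association meta-analysis: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetic-model selection for SNP association meta-analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genmodmeta)
```

Case-control studies of a biallelic SNP report three genotype counts per
arm. Which dichotomization of those genotypes — allelic, homozygote,
heterozygote, dominant, recessive or over-dominant — best describes the
SNP's relation to disease is usually unknown a priori, and picking one
after inspecting the results inflates false positives. This package
implements a combined evaluation that keeps all six models in play and
lets three independent lines of evidence (pairwise pooling, a Bayesian
network meta-analysis, and Thakkinstian's algorithm), disciplined by the
false positive report probability, converge on a *definitive* model. This
vignette records the statistical model behind each stage and the design
choices made where the procedure leaves room.

## Screening

Studies enter the analysis only if (i) their controls conform to
Hardy–Weinberg equilibrium, (ii) the combined sample has at least 300
subjects, and (iii) their methodological quality score on the 15-point,
seven-domain scale is at least 7 (scores ≥ 11 are labelled high quality,
7–10 medium). The HWE check is a Pearson chi-square on 1 df against the
expectation $((1-q)^2,\,2q(1-q),\,q^2)$ at the estimated variant-allele
frequency $q$; we default to $\alpha = 0.05$ (configurable), the field's
convention, since an exact test buys little at the sample sizes the size
filter already enforces. Monomorphic controls cannot deviate from HWE and
conform by convention. The variant allele is *declared by the input*,
never inferred from frequency: orientation flips (which allele a study
calls "variant") are a documented source of sign errors in this
literature, and silent re-orientation would hide them. Ethnicities other
than Asian and Caucasian map to `Other` and are excluded from ethnicity
subgroups. Quality scores are taken as data (the rubric is qualitative);
rows without scores are not filtered on quality.

## Per-study effects and pairwise pooling

Each genetic model reduces a study to a 2×2 table whose exposed group is
the variant-bearing grouping, so OR < 1 always reads "protective for the
variant". The log odds ratio gets Woolf's standard error
$\sqrt{1/a+1/b+1/c+1/d}$, with the Haldane–Anscombe 0.5 added to all four
cells when any cell is zero; tables with an empty margin have no defined
OR and are rejected. The allelic model counts alleles, so its denominators
are twice the subject counts.

Pooling is inverse-variance throughout. The fixed-effect estimate uses
weights $w_i = 1/\mathrm{se}_i^2$; Cochran's
$Q = \sum w_i (y_i - \hat y)^2$ on $k-1$ df and
$I^2 = \max(0, (Q - df)/Q)$ are computed from that fit. The
DerSimonian–Laird estimate uses
$\tau^2 = \max\!\big(0, (Q - df)\,/\,(\sum w_i - \sum w_i^2/\sum w_i)\big)$
and re-weights by $1/(\mathrm{se}_i^2 + \tau^2)$. The switching rule is:
fixed effects iff $p(Q) > 0.1$ **and** $I^2 < 50\%$, both strictly —
boundary cases ($I^2$ exactly 50) go random. We chose the
inverse-variance/Woolf chain over Mantel–Haenszel so that the Q statistic
driving the switch, the DL estimator and the pooled effect share one set
of weights; this makes the switch exactly reproducible from the reported
heterogeneity numbers.

Sensitivity and heterogeneity exploration follow standard practice:
leave-one-out re-pooling (k ≥ 3), subgroup analysis by ethnicity or
genotyping method with a between-stratum Q test on the stratum-pooled
effects (random-effects pooling per stratum by default, as subgroup
forest plots conventionally do; the switching rule is available), and
meta-regression on a dummy-coded moderator via `metafor::rma(method =
"DL")`, i.e. method-of-moments residual τ² with Wald tests — chosen over
REML for determinism and hand-checkability. Publication-bias tests
(Egger's regression of $y/\mathrm{se}$ on $1/\mathrm{se}$ with a t-test
on the intercept; Begg's Kendall τ between variance-standardized deviates
from the fixed-effect pool and the variances, normal approximation) are
not computed below 10 studies: underpowered funnel tests mislead more
than they inform.

## Bayesian network meta-analysis over genotype nodes

The engine the source procedure relied on leaves the network construction
implicit, so the package states one explicitly. Each study contributes up
to three arms — its genotype groups — with a binomial case-membership
outcome: events are the cases with that genotype, trials all subjects
with it. The hierarchical logistic model

$$\mathrm{logit}\,p_{ig} = \mu_i + \delta_{ig}, \qquad
\delta_{i,11} \equiv 0,\quad \delta_{ig} \sim N(d_g, \tau^2),$$

with $d_{11} \equiv 0$, makes $d_{12}$ and $d_{22}$ the population
heterozygote and homozygote log odds ratios (case-control sampling
fractions cancel in $\mu_i$). Priors are vague but proper: $N(0, 10^2)$
on $d$'s and $\mu$'s, half-$N(0,1)$ on the between-study SD $\tau$.
Defaults follow common practice — 4 chains, 20,000 burn-in, 50,000
retained iterations — and convergence is gated on the Gelman–Rubin PSRF
$\sqrt{\{W(n-1)/n + B/n\}/W} \le 1.1$ per basic parameter, with a warning
otherwise. Sampling is by JAGS with per-chain seeds derived from the
config seed, so runs are exactly reproducible.

Three genotype nodes (rather than one node per genetic model) avoid
double-counting subjects across overlapping dichotomizations. The four
composite models are *derived* per posterior draw: the pooled control
genotype mixture $p$ is tilted to the implied case mixture
$\propto p_g e^{d_g}$, and each composite model's log-OR is read off the
implied 2×2. The homozygote and heterozygote columns are identically
$d_{22}$ and $d_{12}$. A control mixture with a zero component makes the
composites undefined; they are skipped with a warning.

**Ranking criterion.** SUCRA needs a per-draw ranking of the six models.
Ranking by plain |log-OR| is direction-agnostic but has a structural
defect: generative processes of genuine interest tie it. Under a strictly
recessive process the recessive and homozygote contrasts share the same
true log-OR (both $\ln\psi$), under a dominant process the dominant and
homozygote contrasts do, so the top rank splits near 50/50 on posterior
noise and no criterion-consistent recovery is possible. The default
criterion therefore ranks by *standardized* association strength:
|log-OR| divided by the Woolf SE of the model's implied 2×2 at that
draw's case mixture (equal unit arms; the overall sample-size factor
cancels). This stays direction-agnostic while crediting the
dichotomization that uses the sample more efficiently — exactly the
property that separates "recessive" from "homozygote" when their effects
coincide. Plain |log-OR| ranking remains available
(`rank_models(..., criterion = "lor")`). SUCRA itself is
$\sum_{r=1}^{K-1} \mathrm{CumP}_k(r)/(K-1)$; its mean over models is
exactly 0.5 for any coherent rank matrix, which the tests assert. Exact
SUCRA ties (a measure-zero event with continuous draws) resolve by fixed
model order.

## Thakkinstian's algorithm

From pooled OR1 (22 vs 11), OR2 (12 vs 11) and OR3 (22 vs 12) — OR3
pooled directly from the per-study 22/12 tables, not derived algebraically
— the rules fire in order, first match wins: recessive when
OR1 = OR3 ≠ 1 and OR2 = 1; dominant when OR1 = OR2 ≠ 1 and OR3 = 1;
complete over-dominant when OR2 = 1/OR3 ≠ 1 and OR1 = 1; codominant when
OR1 > OR2 > 1 and OR1 > OR3 > 1 or the all-protective mirror; otherwise
undetermined. "= 1" means the 95% CI contains 1; "≠ 1" that it excludes
it. Equality between two ORs — the source algorithm operates on pooled
significance patterns but fixes no test — is judged by a two-sided z-test
on the difference of log-ORs with SE $\sqrt{se_1^2 + se_2^2}$ at α =
0.05 (configurable), and OR2 = 1/OR3 by the analogous z-test on
$\log OR_2 + \log OR_3$. The codominant chains use point-estimate
ordering with all three ORs individually significant in the same
direction. Jointly inverting all three ORs (an allele-label flip) leaves
the verdict class unchanged, which the tests verify by enumeration.

## FPRP

Wacholder's false positive report probability is
$\mathrm{FPRP} = \alpha(1-\pi)\,/\,[\alpha(1-\pi) + (1-\beta)\pi]$ with
$\alpha$ the observed two-sided p-value, $1-\beta$ the power to detect a
threshold OR of 1.5 (protective effects by $|\cdot|$ symmetry), and prior
$\pi$ over $\{0.1, 0.01, 10^{-3}, 10^{-4}, 10^{-5}\}$. The power
convention matters: we compute it *at the observed significance level*,
$1-\beta = \Phi(\delta/se - z_{obs}) + \Phi(-\delta/se - z_{obs})$ with
$\delta = |\ln 1.5|$, because this convention reproduces published
three-decimal FPRP values from their printed ORs and CIs (the
spreadsheet tradition for this statistic); the fixed-α variant
(`alpha_level = 0.05`) is exposed. Noteworthiness is FPRP < 0.2 at
π = 0.01 — we read "priors below 0.01" as evaluation at 0.01, the reading
that reproduces the published definitive/non-definitive split; the full
per-prior map is always emitted so stricter readings remain recoverable.
A null effect (log-OR = 0) gives α = 1 and power = 1, so FPRP stays
finite; π = 1 gives FPRP = 0 and π → 0 drives it to 1, both tested.

## Composite decision

Per SNP and stratum, with at least two studies: *candidates* = pairwise
significant models ∩ (NMA-best ∪ Thakkinstian-proposed); *definitive* =
candidates that are FPRP-noteworthy; direction hazardous/protective by
the pooled OR side. The Thakkinstian verdicts map onto the pairwise
models as recessive→recessive, dominant→dominant, complete
over-dominant→over-dominant, codominant→homozygote (the strongest
genotype contrast). If both selection stages are absent the decision is
flagged incomplete rather than silently empty. Several models passing all
criteria are all retained.

## Diagnostic-accuracy meta-analysis

For a definitive risk-conferring model, the same 2×2 is reread
diagnostically (TP = cases carrying the risk grouping, FP = controls
carrying it) — so DOR ≡ the model's OR, an identity the tests assert to
machine precision. Sensitivity and specificity are pooled on the logit
scale (bounded, variance-stabilized; the classical tool's raw-proportion
pooling can leave the unit interval, so it is not the default), DOR and
likelihood ratios on the log scale, all under the same fixed/random
switch. The Moses–Littenberg summary ROC fits
$D = a + bS$ by unweighted least squares (the classical default) on
$D = \mathrm{logit\,TPR} - \mathrm{logit\,FPR}$,
$S = \mathrm{logit\,TPR} + \mathrm{logit\,FPR}$; the curve
$\mathrm{logit\,TPR} = (a + (1+b)\,\mathrm{logit\,FPR})/(1-b)$ is
integrated by trapezoid quadrature on a 2001-point grid over the *full*
unit FPR interval (truncation to the observed FPR range is a
tool-compatibility variant, not the default; doubling the grid moves the
AUC by < 10⁻⁴, which is tested). The AUC standard error is a
nonparametric bootstrap over studies (200 seeded replicates). Degenerate
S spread fixes b = 0 (symmetric SROC) with a warning. The Spearman
threshold test correlates logit TPR with logit FPR, exact p below 10
studies. The bivariate (Reitsma) and HSROC models are the better modern
practice and are deliberately out of scope: the package reproduces the
classical procedure.

## The simulator: what it emulates and what it does not

`simulate_corpus()` draws, per study, a log-OR from
$N(\ln\psi, \tau^2)$, control genotypes multinomially from exact HWE
proportions, and case genotypes from the control distribution tilted by
per-genotype odds multipliers — recessive $(1,1,\psi)$, dominant
$(1,\psi,\psi)$, over-dominant $(1,\psi,1)$, homozygote/codominant
$(1,\psi^h,\psi)$ with $h = 0.5$ (log-additive) by default, allelic
$(1,\psi,\psi^2)$. The tilt construction is valid under case-control
sampling and makes the target contrast's OR *exact by construction*,
enabling sharp recovery tests. Defaults emulate a typical candidate-SNP
corpus: ~10 studies per SNP, per-arm sizes uniform on 160–1200 (totals
from the low hundreds to the low thousands, matching the span of real
corpora in this literature), MAF 0.3, τ = 0.1, a 70/30 Asian/Caucasian
split, genotyping methods 50/35/15 RFLP-PCR/TaqMan/Other, quality scores
weighted toward the medium band. Seeding is local: the session RNG stream
is untouched.

The simulator does **not** emulate genotyping error, population
stratification or cryptic relatedness, linkage between SNPs, selective
reporting/publication bias, or allele-orientation mistakes. Passing
recovery tests therefore demonstrate correctness of the estimators under
the stated sampling model, not robustness to those real-data pathologies.

## Validation problem sizes

The suite validates pooling against brute-force hand computation (and
`metafor` as an independent cross-check) to 10⁻¹²; CI coverage over 500
homogeneous corpora (k = 10, n = 1000 per arm, OR 1.5) within 90–98%;
end-to-end recessive recovery (ψ = 1.6, k = 10, τ = 0.05) and NMA
model recovery (ψ = 2, 8 studies of 800+800) over 50 seeded replicates
each, the NMA with 2 chains × 5,000 iterations after 1,000 burn-in —
sizes chosen so the full suite runs in a couple of minutes while leaving
the stochastic acceptance margins wide. The pipeline defaults keep the
full 4 × 50,000 settings.

## Known limitations

DerSimonian–Laird τ² is biased low for small k and the switch inherits
the known weaknesses of significance-gated model choice; Hartung–Knapp
adjustment and trim-and-fill are out of scope. The NMA assumes normal
random effects shared across genotype contrasts without within-study
correlation between the two non-reference arms. Thakkinstian equality
tests at α = 0.05 are conventions, not calibrated decisions. The Moses
SROC is descriptive, its AUC sensitive to the b estimate at extreme
asymmetry. Multi-allelic SNPs, X-linked adjustments and genotype phasing
are out of scope.
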