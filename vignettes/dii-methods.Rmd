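---
title: "Methods: from seven-day dietary records to an inflammatory proteome readout"
author: "DIIprofiler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from seven-day dietary records to an inflammatory proteome readout}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DIIprofiler)
```

# The analysis in one paragraph

DIIprofiler links the inflammatory potential of habitual diet to the plasma
inflammatory proteome. Seven-day weighed dietary records are resolved against
a food-composition table to obtain each subject's mean daily intake of
energy, macro- and micro-nutrients. Those intakes are scored into a Dietary
Inflammatory Index (DII): each nutrient is z-scored against a reference
population, mapped to a centered percentile, and weighted by a
literature-derived inflammatory effect score; the per-subject DII is the sum.
The cohort is dichotomised at the median DII, and Olink-style NPX protein
abundances (log2-scale) are compared between the high- and low-DII groups
protein by protein. The differential proteins then feed two downstream
readouts: a gradient-boosted classifier of DII group membership evaluated by
ROC on a held-out test set, and a hypergeometric over-representation analysis
against a gene-set annotation.

# The DII score

For a nutrient parameter $p$ with reference global mean $\mu_p$, SD
$\sigma_p$ and inflammatory effect score $w_p \in [-1, +1]$, a subject with
mean daily intake $x_p$ contributes

$$ c_p = \big(2\,\Phi\!\big(\tfrac{x_p - \mu_p}{\sigma_p}\big) - 1\big)\, w_p,
\qquad \mathrm{DII} = \sum_p c_p . $$

The centered percentile $2\Phi(z)-1$ is odd and strictly increasing, so the
DII is monotone in every intake (increasing for $w_p > 0$, decreasing for
$w_p < 0$) and strictly bounded by $\sum_p |w_p|$.

Three choices here were genuinely open:

* **Normal CDF vs empirical percentile.** The published algorithm doubles a
  percentile and subtracts one; since the percentile is obtained "by
  computing a z-score", we read the reference distribution as normal and use
  $\Phi$. A user holding the actual reference distribution can attach
  empirical quantiles per parameter to the `DIIReference` object, and those
  take precedence over the normal CDF.
* **Missing parameters.** Reference parameters absent from the intake
  profile are skipped by default and counted in `n_parameters_used`
  (policy `"error"` is available). Which of the algorithm's 45 literature
  parameters are derivable depends entirely on the composition source, so
  the reference table is user-supplied configuration; the packaged table is
  labelled illustrative and is used only by the synthetic generator.
* **No energy standardisation.** The DII is computed on unadjusted mean
  daily intakes; no per-1000-kcal variant is provided.

Units are declared once per nutrient (g, mg or ug) in the composition table
header and validated at load; profile/reference unit mismatches are hard
errors naming the parameter, and no automatic unit conversion is ever
attempted.

# Intake aggregation

Every record entry contributes `grams / 100 × amount_per_100g`; a subject's
mean daily intake divides the 7-day total by exactly 7, so days with no
entries count as zero consumption (the record is a complete log, absence
means no intake). Total energy comes from the composition table's own
kcal/100 g column. Percent-energy shares use configurable Atwater-style
factors (4 kcal/g carbohydrate and protein, 9 kcal/g all lipid classes,
7 kcal/g alcohol) against that composition-derived total, so the factors
apportion shares without redefining total energy. Foods missing from the
composition table are resolved only through an explicit substitution map
(missing id to nutritionally analogous id, chains allowed, cycles rejected)
— never by fuzzy name matching — to keep the resolution reproducible.
Multi-ingredient recipes must arrive pre-decomposed; apportioning them is
upstream dietitian work this package does not attempt.

# Median split

Subjects with DII at or above the sample median are labelled `high`
(tie-to-upper). For an odd cohort with distinct values this places the
median subject in the high group — e.g. 663 distinct values split 332/331 —
which is the convention consistent with the group sizes this design reports.

# Differential NPX testing

NPX is already log2-scale, so the log2 fold change is the difference of
group means; values are never re-logged. Per protein and per group, a
one-sample Kolmogorov–Smirnov test against a normal with the group's sample
mean and SD gates the comparison: Welch's t-test when neither group rejects
at $\alpha = 0.05$, Mann–Whitney U otherwise (a zero-variance group counts
as non-normal). The KS-with-estimated-parameters screen is the common
clinical usage and is conservative, which only makes the gate lenient
towards the t-test; the gate's $\alpha$ and per-protein-per-group
granularity are package defaults, since the upstream description names only
the test. Welch rather than Student is used for robustness to unequal
variances.

The Mann–Whitney p-value uses the exact null distribution (two-sided by the
doubling rule, capped at 1) when the pooled sample has at most 20
observations and no ties, and the normal approximation with continuity and
tie correction otherwise. Identical pooled values return p = 1.

Missing values are dropped pairwise; a protein with fewer than 3
observations in a group (2 when the test is forced) is flagged untestable
and excluded from the Benjamini–Hochberg adjustment, which runs across all
testable proteins. Two significance modes are always available: `fdr`
(q < 0.05, the principled default) and `paper` (raw p < 0.05, the
uncorrected convention some cohort reports use); both feed the same
downstream machinery so the analyst chooses explicitly.

# The boosted classifier

The classifier mirrors the reference design: a random stratified 60/40
train/test split (per class, `round(0.6 n)` subjects train; the split, fold
assignment and training all derive from one seed), features restricted to
the proteins flagged significant by the differential stage, and an XGBoost
binary model trained for 1000 rounds at learning rate 0.0005 (the design
says only "< 0.001"). Tree depth {2, 3, 4} and row subsampling {0.8, 1.0}
are tuned by stratified 5-fold cross-validated AUC inside the training set
only ("k-fold" with no k stated; 5 is the package default). Importance is
total gain per feature, normalized to shares summing to one — the upstream
figure labels this a "Random Forest classifier plot" while the model is
gradient boosting; gain from the boosted model is what is reported. There
is no default for "top n" features: the full ranking is always written, and
any cutoff (ties broken lexicographically) is an explicit argument.

Test-set AUC is computed by concordance counting with ties worth 1/2
(equivalently, through midranks — a rescaled Mann–Whitney U). The 95% CI is
a 2000-resample percentile bootstrap over test subjects, widened if
necessary to cover the point estimate; the p-value against AUC = 0.5 comes
from the rank-sum correspondence between the two classes' scores.

With so small a learning rate the 1000-tree ensemble is close to an average
of greedy trees fit to the initial residuals: predictions stay near 0.5 and
only their ordering is informative. ROC analysis is invariant to that
scaling, but the configuration underfits relative to, say, a penalised
linear readout — a property of the mirrored design worth knowing when
interpreting absolute AUCs (see the simulation notes below).

# Over-representation analysis

For a query of $n$ proteins against a term of size $K$ in a background of
$N$, the fold enrichment is $(k/n)/(K/N)$ and the p-value the exact
hypergeometric upper tail $P[X \ge k]$; BH adjustment runs across the
$k \ge 1$ terms and significance is FDR < 0.05. This is the plain
Fisher/hypergeometric statistic, chosen for exactness and testability;
DAVID's EASE-style modified score is deliberately not replicated, and no GO
graph propagation is done. The background defaults to the full measured
panel and is overridable; annotation arrives as GMT, with the description
column carried through as a category label so per-category tallies of
significant terms can be reported.

# The synthetic cohort generator

No cohort data are deposited for this design, so the generator produces
every input the pipeline consumes, from one seed: a food pool drawn around a
packaged catalogue of 15 subgroups (bread, pasta, leafy and other
vegetables, fruit, fatty and lean fish, red/processed meat, poultry, cheese,
milk, vegetable oils, animal fats, sweets, wine) with per-100 g nutrient
centroids, portion sizes and archetype preference weights; seven-day records
in which "western" subjects preferentially draw saturated-fat-rich foods
(meat, cheese, butter, sweets) and "prudent" subjects vegetables, fruit,
fish and vegetable oils; the matched illustrative DII reference, whose
global means are the closed-form expected intakes under an equal archetype
mix and whose SDs are 25% of the mean; and an NPX matrix
`baseline + subject offset + planted shift + noise` with Gaussian log2-scale
noise (SD 1), a per-subject offset (SD 0.2) representing sample-level
correlation, and an additive mean shift of 0.5 noise-SDs planted in 30 of
368 proteins (90% shifted up) for the exposed group. Exposure is archetype
membership by default (an indirect, realistic DII link); `dii-quantile` mode
ties it directly to the median split for sharper power studies. Defaults are
n = 400 subjects, half western.

What the generator emulates: the direction of the published contrasts
(higher saturated-fat energy share and lower PUFA/fiber/micronutrient intake
in the high-DII group), a DII separation between archetypes, and a sparse
planted NPX signal among nulls. What it does not emulate: real Italian
food-composition values, self-report measurement error, seasonal or weekday
structure, Olink LOD/plate effects, or correlated protein modules beyond the
shared subject offset. Passing tests therefore demonstrate the pipeline's
statistical machinery — calibration under the null, recovery of planted
effects, exactness of the small-sample statistics — not the reproduction of
any cohort-specific value.

Three simulation findings are worth recording as design notes. First, under
the global null the classifier stage can only run in the uncorrected
significance mode (FDR mode correctly yields ~no features). Second,
selecting features on the whole cohort — which is how the mirrored design
works for the headline analysis — is a selection-bias leak: on null cohorts
the false-positive features carry the test subjects' own fluke differences,
the test AUC becomes systematically optimistic, and its bootstrap CI covers
0.5 far less often than nominal. The packaged null-calibration study
therefore selects features on the training subjects only (the leakage-free
design); analysts applying the pipeline to real data should read the
held-out AUC with this caveat, since there the features are selected on all
subjects. Third, the shared subject offset is
common-mode noise across the significant-protein feature set; because the
design restricts features to significant proteins, no contrast against null
proteins is available to cancel it, and together with the ~3%
archetype/median-split label discordance this caps attainable test AUC below
what the planted per-protein effect sizes alone would suggest — even an
oracle linear readout sits near 0.86 under the default conditions, and the
prescribed low-learning-rate booster typically lands in the high 0.70s to
high 0.80s.

# Numerical and bookkeeping choices

* All randomness flows from explicit integer seeds; stage seeds are derived
  deterministically from one global seed, and RNG state is restored after
  every seeded operation.
* Exact branches: Mann–Whitney exact for pooled n ≤ 20 without ties;
  hypergeometric tails are closed-form at any size.
* Ties: tie-to-upper at the median; midranks (ties = 1/2) in AUC;
  lexicographic tie-breaks in importance rankings.
* Degenerate inputs fail fast with named offenders: duplicate food ids,
  unknown units, unresolvable foods (subject/day/food), zero-energy
  subjects, single-class test sets, sub-minimum group sizes.
* Problem sizes in the packaged studies: unit tests run a 20-subject,
  40-protein tiny bundle; the acceptance studies run the default conditions
  (300–663 subjects, 368 proteins) with 20 seeded replicates for the null
  and planted studies.

# Limitations

The DII reference shipped here is illustrative: absolute DII values from it
are not comparable to published DII scores, only to each other. The
pipeline performs no covariate adjustment (none is part of the mirrored
design), no Olink QC, and no recipe decomposition. The enrichment stage
tests a user-supplied annotation; results are only as current as that file.
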