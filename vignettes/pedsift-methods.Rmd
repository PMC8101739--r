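---
title: "Tiered variant prioritization in multiplex families: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tiered variant prioritization in multiplex families: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedsift)
```

# The problem

Recurrent benign paroxysmal positional vertigo (BPPV) and similar
late-onset conditions often cluster in families in a pattern consistent
with autosomal-dominant inheritance and reduced penetrance: multiple
affected relatives across generations, occasional unaffected carriers,
and sporadic cases of non-genetic origin (phenocopies). With exomes from
a modest number of multiplex families, one cannot run a powered
genome-wide association study; instead the standard strategy is a
*segregation funnel*: use each family's internal structure to discard
variants incompatible with dominant transmission, then population
annotations to discard common or benign variation, and finally
cross-family evidence and biological priors to rank what is left.
`pedsift` implements that funnel, the associated statistics, a
relatedness screen, and a simulator that generates cohorts with exactly
the structure the funnel assumes.

# The selection model

A variant survives the funnel for a family when the family's genotypes
are consistent with a fully penetrant dominant allele *within the
sequenced members*:

* every affected member carries it in the **same zygosity state**
  (all dosage 1 or all dosage 2), and
* every unaffected member has dosage 0.

Requiring a common zygosity state, rather than mere carriage, is
deliberate: a dominant allele transmitted from one founder is
heterozygous in essentially all carriers, so a het/hom mixture among
affected relatives is evidence against a single transmitted allele. A
relaxed carrier-based mode (`zygosity_strict = FALSE`) is available for
sensitivity analyses.

Treating unaffected relatives as obligate non-carriers is a strong
assumption under reduced penetrance — a 95%-penetrant allele produces an
unaffected carrier in 1 of 20 carriers. The funnel accepts that risk
per family (it is what makes the filter sharp), and the enrollment
convention that unaffected relatives be old enough to have passed the
risk window keeps the misclassification rate low. The same logic drives
tier 4 (cross-family exclusion): carriage by *any* unaffected subject or
independent control cohort-wide contradicts a dominant candidate. An
alternative, stricter reading — counting an affected member of another
nominating family who *lacks* the variant as a contradiction — is
implemented behind `cross_family_mode = "any_contradiction"` but is not
the default, because it contradicts the genetic-heterogeneity premise
(different families may carry different causal genes).

Families with no sequenced unaffected members borrow the cohort's
independent controls as unaffecteds, and the assignment is explicit
(the `CONTROL` column of the PED file / the reserved `CTRL` family),
never guessed.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `maf_threshold` | 0.05 | keep variants rarer than this (frequency) |
| `cadd_threshold` | 9 | or more deleterious than this (CADD, phred-like) |
| `dropped_impacts` | LOW, MODIFIER | consequence classes removed up front |
| `min_sharing_families` | 2 | families sharing a variant for the multi-family flag |
| `zygosity_strict` | TRUE | identical state among affecteds vs any carriage |
| `missing_policy` | exclude_variant | a missing call removes the variant for that family |
| `cross_family_mode` | unaffected_only | what counts as a cross-family contradiction |

The MAF/CADD disjunction (`rare OR deleterious`) is intentionally
permissive — with genetic heterogeneity and a 10% lifetime-prevalence
phenotype, a strict conjunction would discard true positives at the
first screening stage. A variant with no recorded population frequency
is treated as novel (passes the MAF clause); a variant with no CADD
score fails the CADD clause, so unscored common variants are not rescued
by the disjunction.

The default missing-genotype policy is conservative: under
`exclude_variant`, one missing call among a family's considered members
removes the variant from that family's candidate set, never inventing a
genotype. `treat_as_noncarrier` is available when call rates are high
and loss of candidates matters more.

# Association statistics

One proband per family enters the carrier table, so family size never
inflates the case count. Proband designation is deterministic: the
explicit flag, else the earliest-onset affected member, else the
lexicographically first affected member (first member overall in
control families).

The exact two-tailed Fisher p-value is computed by hypergeometric
enumeration with the minimum-likelihood convention — the two-sided
p-value is the sum of the point probabilities of all tables with the
observed margins whose probability does not exceed the observed table's
(within relative tolerance 1e-7, guarding against ties lost to floating
point). Point probabilities are evaluated with `dhyper(log = TRUE)` and
summed in log space, so a carrier table against thousands of database
controls (p-values down to 1e-19 and beyond) is computed without
underflow. The implementation is verified in the test suite against an
independent factorial-based full-enumeration oracle on every 2×2 table
with grand total ≤ 40, and against `stats::fisher.test` on random
tables.

Odds ratios use the cross-product estimate with the Haldane–Anscombe
0.5 correction applied (and flagged) only when a zero cell occurs.

Penetrance is estimated definitionally: affected carriers over all
genotyped carriers of known phenotype, cohort-wide; unknown-status
carriers are excluded from both numerator and denominator. This is one
reading of "penetrance" in a family cohort; because ascertainment
enriches for affected carriers, the estimate from an ascertained sample
is an upper bound, which is why the simulator's calibration checks run
on unascertained draws (below).

Onset-age comparisons default to the pooled-variance (Student) t-test,
accepting either raw ages or printed summary triples (mean, sd, n);
a Welch option exists. The one-way ANOVA layer is the standard
fixed-effects F test plus all pairwise pooled t-tests with p-values
multiplied by the number of pairs (capped at 1) — the classical
Bonferroni convention.

# The kinship screen

Between-family relatedness is screened with the KING-robust moment
estimator. For samples $i, j$ over markers called in both:

$$\hat\varphi_{ij} = \frac{N_{het,het} - 2N_{opp}}{2\,\min(N^i_{het}, N^j_{het})}
  + \frac12 - \frac{N^i_{het} + N^j_{het}}{4\,\min(N^i_{het}, N^j_{het})}$$

where $N_{het,het}$ counts markers at which both samples are
heterozygous, $N_{opp}$ opposite homozygotes, and $N^i_{het}$ the
per-sample heterozygote counts. The estimator uses only observed
genotype counts — no assumed allele frequencies — which is what makes it
robust to population structure. Expected values are 0.5 for duplicates
(exact, by algebra: the correction terms cancel), 0.25 for first-degree,
0.125 for second-degree and ~0 for unrelated pairs; the screen flags
cross-family pairs above 0.125, i.e. anything closer than third degree.

Two numerical notes. First, markers with cohort minor allele frequency
below 0.01 are excluded per pair: rare markers contribute almost nothing
to the heterozygote-count denominator while adding noise. Second, the
$\min$ in the denominator — which the estimator needs to stay robust
when one sample is inbred, and which makes duplicate pairs land on 0.5
exactly — carries a small negative finite-sample bias of order
$E|N^i_{het} - N^j_{het}|\,/\,(4\min N_{het})$, about 0.001–0.004 at
10,000 markers. This is the familiar reason kinship tools report
slightly negative values for unrelated pairs. The bias shrinks with
marker count like the sampling noise itself, so it is irrelevant for
relationship classification (the class boundaries are 0.044–0.354
apart), but it is visible when averaging many replicates; the
calibration tests document it rather than hide it.

# The simulator

`simulate_cohort()` models the data-generating process the filter
assumes:

* **Variants.** Unlinked background variants on one synthetic contig;
  MAFs from a 70/30 mixture of a rare component Beta(0.2, 8) and a
  common component Uniform(0.05, 0.5); impact classes with probabilities
  HIGH 0.03 / MODERATE 0.25 / LOW 0.30 / MODIFIER 0.42; CADD
  Uniform(0, 40). The causal variant is an anchor-base insertion with
  HIGH impact, population frequency 0.005 and a CADD draw in 20–35.
* **Transmission.** Founder genotypes in Hardy–Weinberg proportions at
  each variant; children receive each parental allele with probability
  dosage/2 (Mendelian gene drop). No linkage disequilibrium is
  simulated — no implemented analysis step uses it.
* **Phenotype.** Affection is Bernoulli with probability equal to the
  penetrance (default 0.95) for carriers of a causal mechanism and the
  phenocopy rate (default 0.02) otherwise. Penetrance attaches to the
  *variant*, not the family: a member of any family who carries the
  shared causal allele (which segregates at its population frequency
  outside the designated carrier families) is penetrant at the same
  rate. Non-designated case families receive a family-private rare
  deleterious variant as their mechanism, modelling genetic
  heterogeneity; the default plants the shared causal variant in 4 of
  12 case families, matching a cohort where roughly a third of families
  carry the lead candidate.
* **Ascertainment.** By default, case families are redrawn until at
  least two members are affected, control families and independent
  controls until none is, and only a sequenced subset is emitted (2–3
  affected plus 0–2 unaffected per case family; 2–3 members per control
  family; 7 singleton controls) — the shape of a real family study.
  `ascertain = FALSE` disables all of this and emits every member of
  every family as drawn; that is the mode in which carrier affection
  rates converge to the configured penetrance and founder genotypes are
  exact Hardy–Weinberg draws, and it is what the calibration tests use.
  Ascertained cohorts deliberately do *not* have these properties.
* **Demographics.** Onset ages Normal(44, 14) for affected causal
  carriers vs Normal(54.4, 16.1) for affected non-carriers (truncated at
  18); unaffected current ages Normal(66.4, 10); P(female) = 0.68
  (≈ 2.1:1), reflecting the female predominance reported for BPPV.
* **Noise.** Optional per-call genotype missingness and error rates,
  both 0 by default.

Everything is deterministic given the mandatory seed, down to
byte-identical output files.

What the simulator does **not** emulate: linkage and recombination,
sequencing-level artifacts (allelic dropout, depth-dependent error),
population stratification, age-dependent penetrance, X-linked or
recessive inheritance, and relatives shared across families. Passing
tests on simulated cohorts therefore demonstrate the pipeline's logic
and calibration under its own assumptions, not robustness to every
pathology of real exome data.

# Discovery vs association cohorts

The tiered filter runs on the *discovery* subset — the case families
plus the independent controls, i.e. the samples that would actually be
exome-sequenced — via `ped_discovery_subset()`. The control families
enter only the association stage, as carrier counts at the focal
variant. This split mirrors study practice (control families are
genotyped for the candidate, not exome-filtered) and has a substantive
consequence: an unaffected carrier in a control family (expected under
reduced penetrance, and present in the motivating study design) does
not silently destroy the candidate during filtering, but does count in
the association table and the penetrance estimate.

# Problem sizes and numerical choices

Simulation-backed tests in the package run at deliberately modest sizes
chosen to make their statistical assertions sharp, not marginal:
recovery checks use 100 replicate cohorts of 12 case families over ~500
background variants with full penetrance and no noise (under which
recovery must be exact, and is); kinship calibration uses 200 replicate
pairs at 10,000 markers; penetrance calibration uses unascertained
cohorts with ≥ 1000 carriers; Hardy–Weinberg checks use ≥ 500 founders
at 20 common variants. Tie-breaks in prioritization are total (flag
count, family sharing, CADD with missing scores last, then genomic
position), so output order is reproducible under any input permutation.
Degenerate inputs fail loudly and early: empty gene sets, zero affected
genotyped members, zero grand totals, zero-variance t-tests with unequal
means and zero carriers at a focal variant are all errors, not NAs.

# Known limitations

* The within-family filter assumes the dominant model throughout; a
  recessive or X-linked candidate never survives tier 2.
* Under reduced penetrance, an unaffected carrier *inside a case
  family's sequenced members* removes the true variant for that family;
  the multi-family design is the mitigation, not a per-family rescue.
* The penetrance estimator is ascertainment-naive by design and should
  be read as descriptive for ascertained cohorts.
* Public-database carrier counts are taken verbatim as
  positive/negative unit counts; no attempt is made to reconcile allele
  vs individual counting across sources.
* The Bonferroni pairwise layer uses pooled two-sample t-tests, not the
  ANOVA residual variance; with strongly unequal group variances the
  Welch option on individual pairs is the better tool.
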