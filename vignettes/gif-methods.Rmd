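---
title: "Testing excess relatedness in genealogies: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing excess relatedness in genealogies: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famgif)
```

## The scientific problem

When a phenotype has a heritable component, affected individuals are more
related to one another than matched members of the population. In deep
population genealogies this can be tested directly, without genotype data:
compute the average pairwise kinship of the cases and ask whether random
matched draws from the population ever reach it. A significant excess at
close *and* distant relationships is the classic signature of shared
predisposition alleles rather than shared household environment, which
decays quickly with genetic distance.

A second question follows: when the phenotype is clinically heterogeneous,
*which subset* of cases carries the familial signal? A subset that clusters
significantly more than the case cohort at large is a candidate homogeneous
genetic subtype — the natural target for pedigree-based gene mapping,
because heterogeneity inside pedigrees otherwise swamps the signal of rare
segregating variants. This package provides both tests, the per-distance
decomposition used to interpret them, and a per-founder observed/expected
test that flags the individual high-risk pedigrees worth studying.

## Kinship and genetic distance

The Malécot kinship coefficient φ(a, b) is the probability that one allele
sampled at random from each individual is identical by descent. It is
evaluated by the standard recursion over parent links (founders mutually
unrelated and non-inbred; a missing parent contributes zero), which handles
inbreeding loops exactly. Three independent routes are implemented and
cross-checked in the test suite:

1. a memoized pairwise recursion (`kinship()`), the reference definition;
2. a tabular dynamic program over the ancestor closure in generation-depth
   order (`kinship_matrix()`), used by the resampling machinery because a
   single analysis needs 10^4–10^6 coefficients;
3. a gene-dropping Monte Carlo oracle (`kinship_mc_oracle()`): founders get
   unique allele labels, alleles are transmitted by fair coin flips, and
   the IBD fraction of the four cross-pairings is averaged over replicates.
   This estimates the defining probability directly and shares no code with
   the recursion.

Genetic distance is the minimum meiosis count over all genealogical paths
through a common ancestor (either member may be the ancestor). We read the
relationship ladder — 1 parent/offspring, 2 siblings or
grandparent/grandchild, 3 avuncular, 4 first cousins, 5 first cousins once
removed — as path lengths, the only reading consistent with those worked
examples. Distances are computed from per-individual ancestor-distance
maps; for a pair, the minimum of summed depths over shared ancestors.

## The GIF statistic and its empirical significance

For a case set S with n members,

GIF(S) = 10^5 × Σ over unordered pairs φ(a, b) / (n(n−1)/2).

The 10^5 scale is a display convention from the familiality literature (it
puts deep-registry population values near 5); it is exposed as the constant
`GIF_SCALE` and cancels from all comparisons.

Significance is by matched-control resampling. Each of R (default 1000)
replicates draws, without replacement within the replicate, one control per
case matching the case's key: sex, five-year birth cohort
(`floor(year/5)*5`), and in-state birth; designs defined from
death-certificate data additionally restrict the pool to individuals with a
linked death record, because record linkage itself selects for data
quality. The empirical significance is the fraction of control sets whose
GIF is at least the case GIF; ties count as exceedances (conservative), and
zero exceedances are reported as below resolution and displayed `<1/R`.

Two design choices the literature leaves open are exposed as switches, with
these defaults:

- **Cases stay in the control pool** (`include_cases = TRUE`): the null
  hypothesis is that the case set is an ordinary matched draw from the
  pool, so excluding cases would bias the null downward. For the subset
  test this is what makes the degenerate subset (= all cases) exactly null.
- **Cohort widening**: if a matching stratum cannot supply enough controls,
  the birth-cohort window widens stepwise by ±5 years; every widening is
  recorded on the result, and exhaustion after maximal widening is a hard
  error rather than a silent mismatch.

The per-distance decomposition attributes each related pair's kinship to
its genetic distance; entries are additive and sum exactly to the GIF
(asserted to 10⁻⁹ relative in the tests). It is computed for the case set
and averaged over control replicates, and is the basis of the package's
distance plots. Because it requires pair distances for every control
member, it is skippable (`by_distance = FALSE`) in large resampling
studies.

### The subset test

`subset_gif_test()` is the same machinery with the control pool replaced by
the full case cohort (or its death-certificate-linked part). The subset's
own GIF is unchanged from the population analysis — the pairs are the same
— only the reference distribution moves up, since random case draws are
more related than random population draws whenever the phenotype clusters
at all.

## High-risk pedigrees

For each founder, the observed case count among eligible descendants is
compared with the sum of the descendants' (sex × five-year cohort) case
rates, computed internally from the analysed population (person-based,
registry-style; no external incidence tables). The excess probability is
the exact upper Poisson tail P(X ≥ observed). The Poisson model was chosen
because the canonical published observed/expected pairs for such pedigrees
— (56, 36), (173, 131), (76, 51.5) — reproduce their printed probabilities
(0.001, 0.0003, 0.0008) to one significant figure under it; a binomial
tail on the descendant count is nearly identical at these sizes.
Probabilities are reported raw; testing many founders calls for a
multiplicity correction the package deliberately leaves to the analyst,
since the usual practice is to treat the ranking as hypothesis generation.

## Eligibility filter

Relatedness analysis is only meaningful for individuals whose recent
ancestry is actually recorded, so all analyses restrict to individuals born
before a cutoff year (default 1972) with both parents, all four
grandparents, and at least six of eight great-grandparent slots recorded.
Slots are counted positionally through the parent links, so in an inbred
genealogy one person filling two slots counts twice — a deliberate,
documented convention; the alternative (distinct-person counting) differs
only in heavily inbred genealogies.

## The simulator: what it emulates, what it does not

`simulate_genealogy()` builds an open founder population: founder couples
(birth years ≈ N(1850, 5)), Poisson(2.6) offspring per couple, a 27 ± 4
year generation gap, 85% marriage, spouses paired within generation subject
to a kinship ceiling of 1/16 (outbred population), and a 30% immigrant
spouse rate — immigrants enter as new unrelated founders, mimicking an open
historical population. Native-born individuals are in-state by
construction; founders are in-state with probability 0.3; death-record
linkage is Bernoulli(0.75).

`assign_phenotypes()` drops a biallelic dominant variant from founders
(allele frequency `variant_founder_freq`) through Mendelian inheritance and
assigns a male-only phenotype with penetrance 0.7 (carrier) vs 0.08
baseline by default; equal penetrances give an exact null in which case
status is independent of pedigree. Clinical attributes (diagnosis age, BMI,
Gleason, survival, metastasis, cause-of-death flag) are drawn with
carrier-dependent early-onset and lethality enrichment, and BMI is observed
for only 65% of cases, mirroring the incompleteness of linked
drivers-license data. These values were fixed from the registry literature's
orders of magnitude before any testing and are deliberately not tuned.

What the simulator does **not** emulate: realistic demographic change,
mortality and left truncation, assortative mating, polygenic liability,
secular trends in diagnosis, or registry record-linkage error. Passing
calibration and power tests on these cohorts therefore shows the machinery
is correct and the design has power under a clean rare-variant
alternative; it does not certify performance on any real registry.

## Validation experiments and problem sizes

The package validates itself with four simulation experiments, run by the
ordinary test suite (sizes chosen to keep the whole suite in the tens of
minutes on one core):

- **Oracle agreement.** Recursion vs gene-dropping oracle at 10⁵ replicates
  on six constructed relationship fixtures and the most-related pair of 10
  random pedigrees, within 3 standard errors.
- **Conservation.** Per-distance contributions sum to the GIF (10⁻⁹
  relative) on every constructed and random case set, and for both case and
  mean-control decompositions of full test objects.
- **Null calibration.** 400 cohorts (40 founder couples, 5 generations,
  ≈1000 individuals), 25 cases drawn uniformly from the eligible male pool,
  R = 200; the rejection rate of both tests at α ∈ {0.05, 0.1} must lie
  within 3 binomial standard errors of α. Note the attainable values are
  slightly above α by discreteness: with R controls, P(p ≤ α) =
  ⌈αR+1⌉/(R+1) under exchangeability.
- **Power.** 100 cohorts under `power_config()` — 80 founder couples, 6
  generations, Poisson(3) offspring, founder allele frequency 0.005,
  penetrance 0.9 vs 0.10, lethality 0.9 vs 0.05. Power is assessed
  conditional on the alternative being present: cohorts are redrawn until
  the variant segregates into the eligible cases (≥6 carrier cases, lethal
  subset ≥5, cases ≥ 2× subset — `simulate_power_cohort()`), because a
  cohort where the variant died out contains no signal for any method. The
  lethal subset must be rejected at 0.05 in at least 80% of runs.

The first power design we tried used a tenfold-commoner allele (frequency
0.03) in a smaller population; it made carriers roughly *half* of all
cases, so control draws from "all cases" were as related as the subset and
the contrast was degenerate — a useful reminder that the subset test's
alternative is a clustered *minority* subtype, not a wholesale shift of the
cohort.

## Numerical and degenerate-input conventions

- Kinship recursion is memoized per unordered pair; evaluation order is by
  generation depth, which terminates on any acyclic genealogy and is exact
  under inbreeding.
- The tabular route fills the matrix in one topological pass; both routes
  agree to machine precision and with the oracle statistically.
- GIF requires n ≥ 2; empirical p requires R ≥ 1; `p·R` is always an
  integer exceedance count.
- Unreachable pairs have φ = 0 and distance ∞, contribute 0 to the GIF and
  appear in no distance bin.
- Missing attributes exclude an individual from a subset (no imputation);
  missing matching variables exclude a control candidate (logged) and are a
  hard error on a case.
- Structural defects of a pedigree file — duplicate ids, dangling or
  self-parent links, father/mother sex inconsistencies, cycles — are load
  errors naming an offending individual.

## Known limitations

Kinship is autosomal only (no X-linked or mitochondrial variants); the
expectation in the pedigree test is person-based, not person-year; control
matching does not condition on death *year*, only on the presence of a
death record; and founders are assumed unrelated, so registry truncation
that hides real founder kinship deflates all φ values equally in cases and
controls but leaves the contrast conservative rather than anticonservative.
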