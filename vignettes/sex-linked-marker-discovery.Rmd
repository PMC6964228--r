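---
title: "Discovering sex-linked markers from RAD-seq presence/absence data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering sex-linked markers from RAD-seq presence/absence data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radsexing)
```

## The problem

In dioecious species with an XY system, loci on the Y-specific region are
hemizygous: they occur only in males. Reduced-representation sequencing
(ddRAD) samples tens of thousands of short loci genome-wide, so Y-hemizygous
loci should show up as contigs that are present in every male library and
absent from every female library. The difficulty is that RAD data are full
of stochastic locus dropout — library-quality differences, restriction-site
polymorphism, low coverage — so at any moderate sample size thousands of
autosomal contigs are *also* missing from all females (or all males) purely
by chance. Naively intersecting presence/absence patterns therefore produces
overwhelmingly false candidate lists, especially when the true sex-linked
fraction of the genome is tiny (on the order of 10^-5 to 10^-4 of all
contigs in the system this package was built around).

`radsexing` implements the subsampling procedure known as privacy
rarefaction to separate genuine sex-linkage from dropout noise, plus the
downstream steps a molecular-sexing study needs: consensus and ranking of
candidate markers across alternative de novo assemblies, PCR sexing-assay
call logic with positive controls, exact binomial sex-ratio statistics, and
the Loiselle kinship estimator used to ask whether parental relatedness
influences offspring sex.

## Privacy rarefaction

Let the data be a presence/absence matrix over contigs and individuals
(presence = at least `min_reads` mapped reads; default 1). At *stringency*
level $s$ we repeatedly draw $s$ males and $s$ females uniformly without
replacement. In one draw, a contig is **male-private** if it is present in
all $s$ drawn males and absent in all $s$ drawn females; female-private is
the mirror image. Privacy is strict — no tolerance fraction — because the
target loci are expected to occur in one sex exclusively.

Two quantities are tracked per level:

* the number of private candidates per draw (summarised by its mean over
  draws, with median and quantiles alongside), and
* each contig's **bootstrap support**: the fraction of the `n_boot` draws in
  which it was private to a given sex.

For an autosomal contig missing from $k$ of $n$ females by chance, the
probability of looking male-private decays roughly like
$\binom{k}{s}/\binom{n}{s}$, so artefacts are rapidly eliminated as $s$
grows, while a true Y-hemizygous locus is limited only by its own dropout in
the sampled males. In a species with sex chromosomes the two candidate-count
curves therefore *diverge* with stringency: one sex's curve flattens out at
the number of real hemizygous loci, the other's collapses to zero.

```{r scan}
coh <- simulate_cohort(n_males = 10, n_females = 10, n_contigs = 500,
                       n_y_loci = 3, dropout_prob = 0.1, seed = 1)
pm <- build_presence_matrix(coh)
scan <- privacy_rarefaction(pm, coh$sexes, n_boot = 100, seed = 2)
scan
```

Candidates are retained with the rule used in the original study: bootstrap
support of at least 50% for one sex at any stringency level of at least 3.
Stringency 1 and 2 are dominated by dropout artefacts; from level 3 upwards
support concentrates on genuine loci.

```{r candidates}
candidate_contigs(scan, min_support = 0.5, min_stringency = 3)
```

### Heterogamety classification

`classify_heterogamety()` looks at the mean candidate counts at the maximal
evaluated stringency: XY-like if male-private candidates persist (mean > 0)
while female-private candidates round to zero (mean < 0.5), ZW-like in the
mirror case, `none` otherwise (including the ambiguous case where both
curves persist).

A note on the choice of the evaluation stringency. At the full stringency
$s = \min(\#M, \#F)$ every draw uses the whole cohort, so the rule becomes
brittle in both directions: with 20 males and 10% dropout each true Y locus
survives all 20 males with probability $0.9^{20} \approx 0.12$, so all
planted loci can vanish simultaneously; conversely a single stray private
draw in a null scan flips "none" to a sex-linked label because the test is
`mean > 0`. The classification scenarios used in this package's validation
therefore scan to a maximal stringency of 10 — comparing 10 individuals per
sex, the depth at which marker incidence was also quoted in the motivating
study — which makes both error modes negligible while leaving at least
three levels for the divergence diagnostic.

### Incidence reporting

`incidence_report()` expresses the mean number of sex-private candidates at
a chosen stringency as a percentage of the assembly size, printed at 2
significant figures: a mean of 5.29 male-private candidates among 94,968
contigs is 0.0056%.

## Cross-assembly consensus and ranking

Because candidate discovery can be sensitive to the arbitrary choices of a
de novo assembler, the scan is run against several alternative assemblies of
the same reads and the candidate lists are merged:

1. `collapse_identical()` groups candidates at 100% identity: two sequences
   group if one (or its reverse complement) equals or is an exact substring
   of the other, with transitive closure; the representative is the longest
   member. Exact string matching is used deliberately — no alignment
   heuristics, no mismatches — so the collapse is fully reproducible.
2. `cumulative_support_rank()` scores each group by the sum of passed
   stringency levels over all member candidates (so a locus recovered at
   levels {3,4,5} in one assembly and {3} in another scores 15). Ties are
   broken by the best single-member support, then by representative id,
   fixing a total order that the source study leaves unspecified.
3. `extend_contig()` lengthens candidates using reads that match an end
   exactly over at least `min_overlap` bases on either strand, stopping at
   the first position where two supporting reads disagree. Stop-at-conflict
   was chosen over majority voting for reproducibility; the input is always
   a substring of the output, and re-extension is a fixed point.
4. `select_top()` exports the top k (default 11, a primer-design shortlist)
   with deterministic FASTA headers.

## The sexing assay

A PCR assay with two male-linked markers and a positive control yields, per
sample, two amplification calls and a control status. `call_sex()` applies:
control failed → `failed`; any male marker amplified → `male` (with a
discordance flag if the markers disagree); neither → `female`. An OR-rule
with a flag was preferred over an AND-rule because individually dropped-out
Y markers are expected; the flag retains the information the AND-rule would
have used. The one error mode the assay cannot see internally — a male whose
markers both fail while the control passes — is exactly what
`validate_assay()` quantifies against known-sex individuals.

## Sex-ratio statistics

`binom_test_two_sided()` implements the exact two-sided binomial test with
the point-probability convention: the p-value sums $P(X=i)$ over all
outcomes whose point probability is at most that of the observed outcome,
with a relative tolerance of $1+10^{-7}$ on the comparison. This convention
is required to reproduce published values such as $p = 1.00$ for 34/69 and
$p = 0.02$ for 11/13. Point probabilities are compared in log space, so the
test is stable to $n$ of at least $10^4$. Clopper-Pearson 95% intervals are
emitted as an extension beyond the published tables.

`group_sexratio_report()` applies the test per group (sub-population, age
cohort, mother, median-split class) with deterministic row order;
`median_split()` partitions on a covariate with ties at the median assigned
to the "low" (≤ median) group, matching the ≤/> convention of the pollen
distance and kinship analyses; `p_from_r()` reproduces summary-level Pearson
p-values via $t = r\sqrt{n-2}/\sqrt{1-r^2}$.

## Loiselle kinship

`loiselle_kinship()` estimates the pairwise kinship coefficient $F$ from
multi-allelic codominant genotypes relative to a reference sample. Per locus
$l$ with reference frequencies $\bar p_{la}$ over $n_l$ gene copies:

$$num_l = \sum_a (p_{ia}-\bar p_{la})(p_{ja}-\bar p_{la})
        + \frac{\sum_a \bar p_{la}(1-\bar p_{la})}{n_l-1},
\qquad den_l = \sum_a \bar p_{la}(1-\bar p_{la})$$

with $p_{ia} \in \{0, 0.5, 1\}$ the allele dosage over 2. The multilocus
estimate is the ratio of sums $\sum_l num_l / \sum_l den_l$ (not the mean of
per-locus ratios), the standard weighting in this estimator family: loci
with little variability contribute little to either sum instead of adding
noisy ratios. $n_l$ is counted in gene copies (2 × non-missing individuals),
the convention of the kinship software the estimator is best known from.
Reference frequencies include the tested pair when the whole sample is the
reference, and missingness is handled per locus (pairwise-complete).
Expected values: ~0.25 for parent–offspring and full sibs, ~0.125 for half
sibs, ~0 for pairs unrelated relative to the reference.

## The synthetic cohort generator

Real inputs to this pipeline are produced by read mapping and presence
counting; the package instead generates them with known ground truth:

* `simulate_cohort()` plants Y- (and optionally W-) hemizygous loci into a
  contig × individual read-count table. Present cells draw counts from a
  zero-truncated Poisson (default mean 20) so the presence threshold is a
  real decision, then dropout independently zeroes each cell. Defaults — 20
  males + 20 females, 2000 contigs, 10 planted Y loci, 10% dropout — mirror
  the motivating study's cohort with the contig catalogue scaled down by
  ~20× to keep simulations fast; the planted incidence (0.5%) is
  correspondingly higher than the real 10^-5–10^-4 so that recovery
  statistics are estimable from 10 loci.
* `simulate_assemblies()` emulates alternative de novo assemblies: each true
  locus has one fixed master sequence, appearing per assembly either intact
  or (with probability `split_prob`) as two overlapping fragments.
* `simulate_assay_calls()` models assay failure as a per-individual
  DNA-quality event hitting both male markers jointly — matching the
  observed failure mode where one male sample failed every primer pair —
  with an independent positive-control failure.
* `simulate_offspring_table()` and `simulate_genotypes()` generate offspring
  records (sexes Bernoulli or forced to exact per-cohort counts; pollen
  distances log-normal with median 21.9 m; parent kinship normal around
  0.068 — the published medians of those covariates) and Hardy-Weinberg
  founders with Mendelian inheritance down a pedigree.

All generators run from one explicit seed through a local RNG that neither
reads nor perturbs the caller's random state.

What the generator does **not** emulate: read-level errors and quality
scores, restriction-site polymorphism (dropout is i.i.d. per cell rather
than locus- or individual-structured), assembly errors other than clean
locus splitting, null alleles or genotyping error in microsatellites, and
mortality or selection in the cohorts. Passing tests on these synthetics
demonstrates the statistical machinery is correct, not that any particular
real dataset will behave as cleanly; in particular real per-individual
missingness is overdispersed relative to the i.i.d. model, which the
original privacy-rarefaction design defeats by construction (subsampling
cannot be fooled by individuals, only by cells, in the i.i.d. model).

## Numerical and design choices

* Bootstrap support is defined as the fraction of the `n_boot` draws at a
  level in which the contig was private; the candidate-count summary is the
  mean over draws (a published fractional count like "5.29" implies a mean).
* Subsampling streams are keyed to each sex group's sorted individual ids,
  not to the M/F label. This makes two invariants exact rather than
  statistical: relabelling all males as females and vice versa swaps the
  male- and female-private outputs identically (same seed), and permuting
  row/column order changes nothing.
* An exhaustive mode enumerates every (male-subset, female-subset) pair for
  small cohorts and is used to validate the Monte-Carlo supports.
* `min_reads` defaults to 1; `n_boot` defaults to 200.
* Degenerate inputs fail loudly: monomorphic loci, all-identical covariates
  for a median split, empty groups, cyclic pedigrees and out-of-range
  probabilities are rejected with explanatory errors; a constant seed trait
  yields means with zero SE and no correlation test rather than an error.

## Validation problem sizes

The packaged checks use deliberately desk-scale designs: planted-marker
recovery uses 50 replicate cohorts of 20+20 individuals × 2000 contigs with
200 bootstrap draws; heterogamety classification uses 100 replicates of a
planted-Y cohort (500 contigs), its label-swapped mirror, and a 10+10 null
cohort; kinship recovery uses 100 replicate 500-founder panels at 30 loci
and a 200-individual unrelated panel at 20 loci. Each block runs in well
under a minute on one core.

## Known limitations

* The recovery rate of planted loci under 10% dropout is limited by a hard
  combinatorial fact: a Y locus carried by $K \sim \mathrm{Bin}(20, 0.9)$
  of 20 males has stringency-3 support $\binom{K}{3}/\binom{20}{3}$, which
  falls below the 50% retention threshold for $K \le 16$. Cohorts of this
  size therefore retain each planted locus with probability ≈ 0.9, and a
  10-locus cohort recovers all-but-one or better in roughly three quarters
  of replicates, not almost always. Larger cohorts, lower dropout or a
  lower support threshold all raise this, but the packaged defaults keep
  the study-design values.
* Strict privacy (no tolerance fraction) means a single contaminated or
  mislabelled individual can suppress a true marker at high stringency; the
  per-level support curves in `PrivacyRarefactionResult` are the diagnostic
  for that situation.
* `collapse_identical()` is quadratic in the number of candidates; that is
  adequate for candidate lists (tens to hundreds) but it is not a general
  clustering tool.
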