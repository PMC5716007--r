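---
title: "Detecting allele-frequency shifts in small exome cohorts"
author: "exomeFreq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting allele-frequency shifts in small exome cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exomeFreq)
```

## The problem and the model

Some clinically important phenotypes — severe drug reactions are the
archetype — require both an environmental trigger and a genetic
predisposition. The predisposing genotypes are typically common SNP alleles
that are silent until the trigger occurs, so they never segregate as
Mendelian traits, and the effect sizes are far too large (and the risk
alleles too enriched among affected individuals) for them to need
genome-wide association cohorts of thousands. exomeFreq implements the
intermediate design: take a modest cohort (tens to a couple of hundred
exomes) of individuals sharing the phenotype, and ask, for every common SNP
an exome assays, whether its rare-allele frequency in the cohort differs
from the frequency recorded in a reference population catalogue.

For one SNP with catalogue rare-allele frequency $q$, cohort rare-allele
count $r$ and observed allele total $t$, the test is the Pearson
goodness-of-fit chi-squared on the two allele classes, without Yates'
continuity correction:

$$\chi^2 \;=\; \frac{(r - qt)^2}{qt} + \frac{\big((t-r) - (1-q)t\big)^2}{(1-q)t},
\qquad p = \Pr\!\left(\chi^2_1 \ge \chi^2\right).$$

The df = 1 upper tail is two-sided on the frequency scale — deviation in
either direction inflates the statistic — so no halving or doubling is
applied; the direction (enriched or depleted) is reported separately. When
the catalogue's own allele count $N$ is known, a `two_sample` mode instead
forms the 2×2 allele-count table cohort-vs-catalogue (again without Yates);
as $N \to \infty$ it converges to the goodness-of-fit p-value, and the test
suite checks that convergence at $N = 10^6$.

Because one screen tests every catalogued SNP, raw p-values are corrected:
Bonferroni ($\min(1, m\,p)$) and Benjamini–Hochberg step-up q-values, with
the significance call made on the Bonferroni value at $\alpha = 0.01$ by
default. The correction denominator $m$ is the number of SNPs actually
tested for that catalogue (SNPs with no observed alleles spend no
correction budget); `correctByCatalogue`/`m` switch to the full catalogue
size for users who prefer correcting over the intended screen. The
$\alpha = 0.01$ default is deliberate: it is the "corrected p < 0.01"
operating point of the design this package implements, and it is a plain
argument everywhere it appears.

## Allele counting

Cohort genotypes arrive as one variant-only VCF per individual. Each
catalogue SNP in each sample resolves to one of three states:

* **called** — a usable GT genotype covers the site; the rare-allele copy
  count is read off directly. Genotypes containing a half-call or missing
  allele (`./.`, `./1`) are *unknown*; genotypes carrying a non-catalogue
  alternate allele contribute their non-rare alleles normally.
* **ref_assumed** — the SNP is absent from the VCF. Variant-only VCFs omit
  homozygous-reference sites, so absence is read as hom-common by default
  (`absentPolicy = "unknown"` flips this for pipelines that emit explicit
  `0/0` records).
* **unknown** — no usable evidence; the site's alleles enter the
  frequency bounds rather than the point estimate.

Allele totals are sex-aware: two alleles per individual on autosomes, one
(male) or two (female) on the non-pseudoautosomal X, one/zero on Y.
X SNPs inside the GRCh37 pseudoautosomal intervals (PAR1
X:60001–2,699,520, PAR2 X:154,931,044–155,260,560) are diploid in both
sexes and excluded from sex inference. Because a mis-sexed sample corrupts
every X-linked allele total, the package infers each sample's sex from its
non-PAR X heterozygosity fraction $h$ (males are hemizygous, so genuine
heterozygous X calls should be absent): $h < 0.05$ infers male, $h > 0.20$
female, anything between — or fewer than 50 usable X calls — is ambiguous.
The two thresholds and the minimum call count are pragmatic defaults (they
sit far on either side of the error rates seen in practice) and are
arguments to `inferSex()`; panels much smaller than an exome need a lower
`minCalls`. Inferred counts are checked against the declared male/female
totals (`verifySexCounts()`); disagreement is a warning, or an error under
`strictSex`. Samples whose sex cannot be resolved have their X/Y alleles
counted as unknown at the maximum possible ploidy (2 on X, 1 on Y), which
keeps the bounds conservative.

## Coverage and the 20× cutoff

A heterozygote cannot be called reliably below roughly 20 reads, so
`applyDepthFilter()` demotes any call — genotyped or assumed-reference —
whose per-base depth falls below the cutoff (default 20) to unknown, and
conversely confirms absent-but-covered sites as hom-common. Depth is
consumed as a three-column per-base table (chromosome, 1-based position,
depth), the dialect standard per-base depth tools emit; a position missing
from the table counts as depth 0. Only depth is checked: no base- or
mapping-quality model is implemented, because none is defined for this
design. `exonCoverageCensus()` provides the complementary census — per-exon
and per-gene mean depth over one or more samples, with genes flagged
adequately covered when their exonic mean strictly exceeds 19 reads
(overlapping exons of a gene are deduplicated before averaging).

## Frequency bounds and bound p-values

With $u$ unknown alleles at a SNP, the cohort frequency is only known to
lie in
$$\left[\frac{r}{t+u},\; \frac{r+u}{t+u}\right],$$
the allocations with every unknown allele common or rare respectively.
`boundPvalues()` reports the test repeated at those two extreme allocations
(`p_raw_lower`, `p_raw_upper` — the p-values at the frequency lower and
upper bound), and additionally the exact attainable p-value *range* over
every integer allocation (`p_range_min`, `p_range_max`). The distinction
matters: $\chi^2$ is convex in the allocated rare count, so its maximum over
the allocation interval is at an endpoint, but its minimum can sit strictly
inside — if $q(t+u)$ lies between $r$ and $r+u$, some intermediate
allocation matches the expectation exactly and its p-value is 1, larger
than either endpoint p. The range columns are therefore computed from the
endpoints plus the interior optimum (floor/ceiling of $q(t+u)$), and the
test suite verifies by exhaustive enumeration (all allocations, $u \le 6$)
that they bracket every intermediate allocation tightly. The headline
`p_raw` always remains the observed-alleles-only test.

## Consequence filtering

The design targets protein-altering alleles, so results can be restricted
to SNPs annotated as nonsense, start-loss, stop-loss, canonical splice
(the ±2 intronic dinucleotides) or damaging missense. The missense
pathogenicity call is consumed as a boolean input column — no predictor is
run or re-implemented — and `includeAll = TRUE` bypasses the filter for
users who want the full table. The consequence vocabulary is closed; an
unknown string is an error rather than a silent drop.

## The power simulation

`runPowerGrid()` compares this design against an idealised case-control
association study under a configurable generative model. Per scenario:
`nCohort` affected individuals, of whom a fraction `1 − nongeneticFraction`
are genetic cases; each genetic case is caused, with probability
`penetrance`, by one of `k` interchangeable causative SNPs chosen uniformly
at random, and carries one rare allele of that SNP (heterozygous, dominant
model); every chromosome not carrying a causal allele draws the rare allele
independently at the background frequency `q`. The cohort test applies the
goodness-of-fit chi-squared against `q` with Bonferroni correction over
`mCorrection` SNPs (default 121,000, a full exome screen) at corrected
$\alpha$ = 0.01; the association comparator draws an equal-sized control
cohort at `q` and applies the 2×2 allele chi-squared at raw
$p < 10^{-8}$. A scenario family counts as detecting `k` causative SNPs
when every one of them reaches per-SNP power > 0.5 (alternative criteria
are selectable); the grid summary reports the largest detected `k` per
family.

The uniform case assignment, heterozygous-dominant carriers, background
carriage at `q`, the equal-sized control group and the all-SNPs-above-half
detection rule are this package's own modelling choices — the published
boundary figures this module is inspired by do not come with a recoverable
generative recipe — and all of them are explicit scenario parameters so
alternative designs can be expressed. Two consequences are worth knowing.
First, at 1000 replicates the Monte-Carlo standard error of a power near
0.5 is ~0.016, so boundary `k` values can wobble by one between seeds.
Second, under any natural version of this model an association comparator
with 100 cases and 100 controls has overwhelming power at `k` = 1 (50 of
200 case alleles rare versus ~2 of 200 control alleles); a published claim
that such a comparator detects nothing at that size cannot be reproduced
here and is reported as measured, not matched.

## The synthetic-data generator

`makeFixture()` emits a complete, self-consistent synthetic study from a
seed: a catalogue (TSV and sites-VCF dialects), one variant-only VCF per
sample, per-base depth tables, an exon table, consequence annotations, a
sample manifest and a ground-truth table of the realised allele counts.
Males are generated haploid on non-PAR X (never heterozygous), so sex
inference is exactly recoverable. Null SNPs draw cohort genotypes at
exactly the catalogue frequency; `spikes` inject SNPs whose cohort
frequency differs from the catalogue's — the signal the pipeline should
flag. Missingness is emulated jointly: a masked call is withheld from the
VCF *and* written with sub-cutoff depth, so the pipeline must discover it
through the depth filter. Unmasked depths are drawn as
`20 + Poisson(meanDepth − 20)`, guaranteeing that non-missing calls always
survive the filter and that zero-missingness fixtures reproduce the ground
truth *exactly* (a property the acceptance tests assert). The generator
fixes every byte from the seed — the on-disk manifest stores relative
paths precisely so two runs of the same spec are checksum-identical.

What the generator does **not** emulate: linkage disequilibrium between
SNPs, genotyping error, batch effects between capture kits, population
substructure between cohort and catalogue, or realistic read-level noise.
Passing tests on these fixtures therefore demonstrate the correctness of
the counting, bounding, testing and correction machinery — not robustness
to the confounders real cohort studies face, of which catalogue/cohort
ancestry mismatch is the most dangerous (and the reason
`compareCatalogues()` exists: two catalogues disagreeing by more than five
percentage points on a SNP is a warning about the catalogue, not the
cohort).

## Numerical and design notes

* Ties and edge cases: a catalogue frequency difference of exactly the
  5% threshold is concordant (strict inequality); a gene exonic mean of
  exactly 19 reads is *not* adequately covered (strict `> 19`); depth
  exactly at the cutoff passes (`≥ 20`); `chi2 = 0` gives `p = 1` exactly.
* Catalogue entries with frequency above 0.5 are normalised (alleles
  swapped, frequency flipped) with a warning — reference catalogues almost
  always list the common allele first, but not always. Multi-allelic sites
  are expanded to one entry per alternate allele; `evsLowestAllele = TRUE`
  reproduces, for comparison purposes, a known export defect that kept
  only the lowest-frequency allele.
* Expected cells below 1.0 flag the result `low_expected` rather than
  switching tests: the chi-squared is the method, and the flag tells the
  reader where its approximation is doubtful.
* SNPs with `q` of exactly 0 or 1, or with no observed alleles, are
  reported `untestable` and excluded from `m`.
* All integer count arithmetic inside the statistics is done in double
  precision; 2×2 margin products overflow 32-bit integers already at a few
  thousand samples.
* Problem sizes in the shipped test-suite: fixtures of 5–44 samples and
  30–300 SNPs, 10⁴ random tables for the brute-force chi-squared check,
  1000 Monte-Carlo replicates per power scenario, and 100 seeded null runs
  for the type-I-error check — sizes chosen so the whole suite documents
  the claims it makes while running in well under a minute.

## Limitations

The method tests marginal allele frequencies: it cannot see haplotype
effects, recessive models (a carrier count, not genotype count, is
compared), or interactions, and it inherits every bias of the chosen
catalogue. Joint multi-sample VCFs are out of scope by design — the unit
of input is one individual's exome VCF. Mitochondrial sites are not part
of an exome as consumed here.
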