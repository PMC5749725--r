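---
title: "Somatic mutation analysis across successive steps of tumor progression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Somatic mutation analysis across successive steps of tumor progression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutsteps)
```

## The setting

`mutsteps` analyses somatic mutations called in several tumor samples from
the same patient — pre-invasive lesion (DCIS), primary tumor, axillary
lymph-node (ALN) metastasis, asynchronous distant metastasis — against a
matched normal. The questions it addresses are (i) which deep-sequencing
calls survive multi-sample validation, (ii) where along the progression
each validated mutation arose, (iii) whether the mutation spectrum shows
positive selection and how many driver mutations that implies, (iv) which
pathways are over-represented at each progression step, and (v) which
individual mutations are credible drivers of metastatic progression.

## Multi-sample validation filtering

A candidate mutation is accepted when, within its patient:

* the matched normal's B-allele frequency (BAF, alt reads / depth) is
  **strictly below 0.02** — higher values indicate germline origin or
  contamination;
* **every** sample (normal included) has depth **at least 50×** — the
  criterion speaks of all samples, and we read that literally; a
  sensitivity analysis can relax it via `min_depth_all`;
* at least one tumor sample has BAF **at least 0.05**;
* the variant is exonic or splicing, has population allele frequency at
  most 1% (above that it is a known SNP), is not blacklisted and carries
  no curation flag.

Once a mutation is accepted, its *presence* in each further tumor sample
uses a rescue rule: BAF ≥ 0.05, or BAF ≥ 0.025 when that sample's depth
**exceeds 200×**. The relaxed bound reflects that at >200× even a 2.5%
allele fraction is supported by enough reads to be trusted. Boundary
semantics (strict vs inclusive) follow the wording of each criterion;
none of the bounds has a stated operator, so wording is the only guide
and every bound is configurable in `filter_config()`.

Two curation steps that are manual in practice are modelled as data:
visual-inspection exclusions enter as a BED blacklist, and dense local
variant clusters (a misalignment signature) are flagged by
`flag_clusters()`, quantified as **≥ 3 variants within ±10 bp** — the
qualitative notion of "many adjacent variants" needs a number to be
reproducible, and these defaults are deliberately conservative and
configurable. Sex chromosomes are treated like autosomes.

The filter obeys three laws that the test suite checks as properties:
raising thresholds never grows the retained set, degenerate thresholds
pass every unflagged mutation through, and verdicts are independent of
mutation order.

## Progression categories

Validated protein-altering mutations (all consequence classes except
synonymous) are partitioned by their post-rescue presence vector:

* **Category 1** — present in DCIS and/or primary, in no metastasis;
* **Category 2** — present in at least one early sample and at least one
  metastasis (ALN or distant);
* **Category 3** — present only in metastases.

ALN and distant metastases are pooled when deciding "metastasis": a
mutation found only in an ALN metastasis is metastasis-specific. Category
assignment uses the post-rescue presence because the shared/exclusive
calls in deep-sequencing data are made on exactly those allele fractions.
Where a sampled DCIS exists, Category 1 does not additionally require
presence in it — "any early sample, no metastasis" is the rule.
Concordance (`concordance_counts()`) tabulates the full Venn partition of
presence patterns; recurrence tables count **distinct genomic variants**
per (gene, patient, sample) and genes hit in multiple patients.

## The NS:S selection test

For coding point mutations, in the absence of selection non-synonymous
(NS) and synonymous (S) variants persist in proportion to their rate of
creation, ~2:1 across the exome. With $n = NS + S$ observed coding SNVs
and neutral non-synonymous fraction $p_0 = 2/3$, the one-tailed exact
binomial p-value is

$$P = \Pr(X \ge NS), \qquad X \sim \mathrm{Bin}(n, 2/3),$$

and the implied driver count is the non-synonymous excess
$\max(NS - 2S, 0)$ (clipped at zero: real data never go negative in the
published tables, simulated data can). The tail is summed exactly with
log-space terms (`lchoose`); the test suite verifies it against
brute-force pmf summation for every $0 \le k \le n \le 200$ to $10^{-12}$.

Two conventions matter for reproducing printed tables:

* **NS counts missense + stopgain + stoploss SNVs only**; splice-site
  mutations and indels are excluded from both counts by default because
  the 2:1 expectation is a statement about point mutations. Both
  inclusions are config switches (`include_splice_in_ns`,
  `include_indels_in_ns`) so the alternative reading is testable.
* **Displayed ratios are truncated**, not rounded, to two decimals
  (177/47 = 3.7659 prints as 3.76). Full precision is kept internally;
  `trunc_decimals()` is display-only.

The test is discrete and therefore conservative: at $n$ around 100–220
the achievable size at nominal $\alpha = 0.05$ is about 0.041–0.048. The
calibration check accordingly asks that the empirical type-I rate lie
within three binomial standard errors of 0.05, which the conservative
exact test satisfies at these group sizes.

## Over-representation analysis

A query of $n$ genes (gene-level: a gene mutated twice counts once) from
a universe of $N$ genes is tested against each stored set of size $K$
with the exact hypergeometric upper tail $\Pr(X \ge k)$, again summed in
log space and verified against enumeration. Benjamini–Hochberg FDR is
applied with an **explicit family size** $m$: the number of sets tested,
not the number with non-zero overlap — zero-overlap sets are dropped from
the output but stay in the denominator. Defaults are $N = 45{,}956$ and
$m = 186$. Neither number is printed in the published tables this
pipeline reproduces; both were recovered from them (the q/p ratio of the
top row is exactly $m$, and the hypergeometric with this $N$ reproduces
the printed p-values) and both are exposed in `enrich()` and
`read_gmt(collection_size =)`. This is the single most consequential
unstated parameter of the enrichment reproduction; any other universe
shifts every p-value.

## Driver triage

A Category 2 or 3 mutation is called a putative progression driver iff it
is **frameshift, stopgain or splice-site**, or a per-mutation score flags
it as a driver. The scoring model behind the published analysis is an
external classifier ensemble that is not reproducible offline, so it is
abstracted as a scorer interface: any `function(mutations) ->
(score, is_driver)` plugs in, `scorer_from_table()` reads a precomputed
score table for exact tests, and `scorer_truncating_only` is the
conservative fallback. Splice-site mutations qualify by consequence class
regardless of score. Cancer-gene-census or cancer-pathway membership is
reported as annotation and never used as a qualifying rule.

## The synthetic cohort generator

`simulate_cohort()` produces cohorts in the pipeline's input format with
full ground truth, emulating the study design: per patient a normal plus
up to four tumor stages; truncal mutations present in every tumor sample,
branch-private mutations confined to one stage. Consequence classes are
drawn neutrally with NS fraction 2/3 (missense:stopgain 9:1 within NS, an
arbitrary but fixed convention, configurable); injected drivers are
forced non-synonymous. Reads follow depth ~ negative binomial (default
mean 465×, matching deep targeted validation; dispersion 10) and
alt reads ~ binomial(depth, 0.5 × purity) in carrying samples (diploid
heterozygous sites), binomial(depth, 0.001) elsewhere and always in the
normal. Germline SNP contaminants (high BAF everywhere, population AF
over 1%) and blacklist artefacts are mixed in at configurable rates.
Identical seed and configuration give byte-identical output.

What the generator does **not** emulate — and hence what passing tests do
not establish about real data: copy-number alteration and
loss-of-heterozygosity (allele fractions are purely diploid-heterozygous),
subclonal structure within a sample beyond the truncal/private dichotomy,
FFPE artefacts, mapping error correlated across samples, and a realistic
gene-length distribution (genes are sampled uniformly from a 5,000-gene
pool). The recovery results on simulated cohorts validate the pipeline's
logic, not the biology of any particular dataset.

## Numerical and design choices

* Coordinates are 1-based fully closed (VCF convention); BED blacklists
  are converted from 0-based half-open on ingestion. Indels are taken as
  given, with no re-normalisation.
* BAF is plain `alt_reads / depth`, undefined (an error) at zero depth;
  filters treat zero-depth samples through the depth criterion instead.
* Duplicate caller reports are merged by the (patient, chrom, pos, ref,
  alt) key; the merged cohort is canonicalised so that input row order
  never matters.
* BH q-values use the step-up `cummin` form; ties share ranks by sorted
  order and output order matches input order. `p.adjust(..., n = m)` is
  the cross-check oracle in the tests, not the implementation.
* Driver estimates use `round(null_ratio * s)` before subtraction so that
  non-integer null ratios remain usable.
* Group sizes in the shipped checks: type-I calibration uses 2,000
  neutral replicates of a 150-mutation single-patient cohort; driver
  recovery 200 replicates with 50 injected drivers; category recovery a
  six-patient, four-stage cohort of ~100 mutations per patient. These
  mirror the scale of a six-patient validation study while keeping the
  default check run fast.

## Known limitations

* The NS:S model is the flat 2:1 expectation; trinucleotide-context
  mutation-rate corrections (full dN/dS machinery) are out of scope, so
  selection inferences inherit the flat-rate assumption.
* Phasing of recurrent mutations within a gene (cis vs trans) and
  subclonal deconvolution are not attempted.
* The enrichment module ships no pathway database; users supply GMT
  files, and the family size of a truncated collection must be given
  explicitly for the FDR to be faithful.
* VCF ingestion maps depth/allelic-depth FORMAT fields only; consequence
  annotation is consumed from the variant table, never computed.
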