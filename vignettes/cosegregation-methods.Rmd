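---
title: "Methods: cosegregation scanning and rare-variant filtering in a dominant family"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cosegregation scanning and rare-variant filtering in a dominant family}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cosegr)
```

## The problem and the model

`cosegr` implements candidate-gene discovery for a single family segregating a
rare autosomal-dominant trait — the motivating case is hereditary
developmental colour agnosia, a disorder of colour naming and recognition with
intact colour perception, known from one six-member, three-generation family
with three affected and three unaffected sequenced members. With one family
and no replication cohort, the analysis is not a statistical test but a
deterministic elimination argument built on three assumptions:

1. **Dominant inheritance with complete penetrance**: carrier status and
   affection coincide. The pedigree check (`dominant_consistency()`) labels an
   affection pattern `consistent` when every affected non-founder can have
   inherited the allele from an affected parent, `de_novo_required` otherwise.
   Complete penetrance is an assumption, not an inference; incomplete
   penetrance would relax the "absent in unaffected" filters and is out of
   scope.
2. **Cosegregation**: the causal allele is carried (heterozygously) by every
   affected and by no unaffected member. This drives both the region scan and
   the variant filters.
3. **Rarity**: a trait this rare cannot be caused by an allele common in the
   population, hence the strict allele-frequency threshold.

## The region scan

The scan (`scan_regions()`) operates on unphased genotypes of SNP markers
ordered along each chromosome. A marker is *compatible*
(`marker_compatible()`) when some allele is carried by every affected and by
no unaffected sequenced member. Reported regions are maximal windows of
compatible markers with endpoints on compatible markers, tolerating at most
`max_errors` incompatible markers inside a window and containing at least
`min_markers` compatible ones. All maximal windows are enumerated with a
two-pointer sweep and overlapping windows are merged. We chose enumeration
plus merging over one-pass greedy absorption deliberately: greedy merging is
not monotone in the error budget (a larger budget can swallow the head of a
downstream run and strand its tail, so a reported region could *shrink* when
the tolerance grows), whereas every maximal window at tolerance *k* is
contained in a maximal window at *k + 1*, and merging preserves that
containment. At `max_errors = 0` the output is exactly the set of maximal
all-compatible runs, which is how the test suite cross-checks the scan
against a brute-force run enumeration.

Boundary handling is configurable: `inner` (default) reports the first/last
compatible marker of a window; `outer` extends to the flanking incompatible
markers (or the chromosome's terminal markers). Published coordinates of
linked regions rarely state which convention was used, so the packaged region
table is treated as data, not as a reproduction target for the scan.

A note on informativeness: with biallelic markers, single-marker
compatibility is a weak signal — even at a fully linked marker, the allele
shared by the three affected members is often also carried by an unaffected
member by chance, so only a minority of truly linked markers test compatible.
Array-based linkage tools work on haplotype segments and do not have this
limitation. The simulator therefore includes the causal site itself as a
perfectly informative marker row, which is what makes error-free recovery a
construction guarantee rather than a probabilistic one; recovery analyses run
the scan with `min_markers = 1` so that this marker is never discarded as a
singleton. The `scan_params()` default stays at `min_markers = 3`, which is
the sensible setting for real array data where no such tag marker exists.

## The filter cascade

`run_cascade()` applies six stages in a fixed order, recording a full audit
trail (`FilterTrace`-style): a variant failing stage *k* is never evaluated
at later stages, survivor counts are non-increasing by construction, and the
result is independent of input order.

| stage | rule | defaults |
|---|---|---|
| `qc` | every sequenced carrier call passes genotype QC | see below |
| `class_rarity` | consequence in {nonsense, frameshift indel, missense, splice site}, indel ≤ 7 nt, in-house count ≤ 2 | |
| `absent_unaffected` | no unaffected member carries the allele | |
| `present_affected` | every affected member heterozygous | |
| `popfreq` | AC/AN < 0.002 (strict) in every reporting database | |
| `region` | position inside a linked region (1-based inclusive) | |

Genotype QC (`qc_pass()`) requires at least 2 seed-supporting reads (the
first 25 bp of a read, its higher-quality portion), at least 10 reads of
coverage, and a non-reference allele fraction between 15% and 80%, both ends
inclusive. The 80% ceiling encodes the heterozygous dominant model: a
near-100% alt fraction indicates a homozygous call or a systematic artefact,
neither of which fits a dominant heterozygous variant. Clonal reads (reads
sharing an identical start site beyond the first, typically PCR duplicates)
are capped at 5 counted reads per site: the cap is applied to the
*denominator* (effective depth = depth − max(0, clonal − 5)), so a clonal
pile-up fails through the coverage or fraction thresholds rather than through
a separate rule. This mirrors how duplicate-aware callers discount rather
than reject clonal evidence.

Two interpretation decisions deserve emphasis:

* **Rarity direction.** The source description of the frequency filter is
  ambiguous (it can be read as *excluding* rare variants). The cascade's
  intent — and every retained candidate's observed frequency — makes clear
  that rare variants are *retained*: we keep a variant when AC/AN < 0.002 in
  every database that reports it. At the denominator 13,000 used by one
  exome-variant database this admits allele counts 0 through 25 and nothing
  higher, which the acceptance suite verifies through the filter itself.
* **Missing evidence.** A database with no entry for a variant is treated as
  *no evidence of commonness* (pass) by default, distinct from an explicit
  AC = 0; `missing_freq_policy = "fail"` flips this for conservative runs.
  Missing genotype calls fail the variant by default
  (`missing_call_policy = "fail_variant"`), because a cosegregation claim
  cannot be verified on an unobserved genotype; `"ignore_sample"` drops the
  sample from the test instead.

The packaged example data exercise the cascade end to end: the 11 candidate
variants (heterozygous in all three affected, absent in all three unaffected,
published gnomAD v2.1.1 allele counts all below 0.002) plus a deterministic
decoy set in which each decoy violates exactly one stage. One genuine
curiosity of the published tables surfaces here and is reproduced rather than
patched: the candidate on chromosome 8 lies ~1.8 Mb beyond the end of the
printed chr8 linked interval, so the faithful cascade reports 10 of the 11
candidates when the printed region table is used verbatim — the audit trace
names the region stage as the culprit, which is exactly what the trace is
for. Similarly, the per-gene annotation table carries two GoNL frequency
strings (2/996 and 4/996) that are not below 0.002 despite those genes being
retained; these strings are carried through as report columns, not used as
filter inputs.

## The synthetic family generator

`simulate_family()` stands in for the study's raw data, which are not
publicly deposited. It emulates the statistical structure the analysis
assumes, with one seeded RNG stream governing everything (identical seed and
configuration give byte-identical outputs):

* **Pedigree**: the six-member template (three affected in a
  grandparent–parent–child chain, three unaffected), all sequenced.
* **Recombination**: Haldane model — crossover counts Poisson with mean equal
  to the chromosome's map length in Morgans, placed uniformly; no
  interference. Map positions are linear in bp at 1 cM/Mb. Defaults: three
  chromosomes of 150/130/110 Mb.
* **Conditioning**: one founder carries the causal allele heterozygously;
  each gamete from a carrier parent is resampled until the child's causal
  allele matches the template affection. Gamete-level rejection is equivalent
  to family-level rejection because meioses are independent, and it is what
  ties carrier status to affection (complete penetrance) while leaving
  linked-marker transmission intact — which is precisely the linkage signal.
* **Markers**: 120 per chromosome by default, biallelic, founder allele
  frequencies uniform on (0.2, 0.8), plus the causal-site marker row
  discussed above.
* **Exome variants**: 150 background variants with allele frequencies drawn
  from an equal-weight mixture of a rare component (uniform on (0, 0.002))
  and a common component (uniform on (0.01, 0.5)), so the rarity threshold
  is straddled from both sides. The same frequency is reused as the simulated
  population-database annotation (AN fixed at 280,000, AC rounded from AF),
  deliberately coupling simulation truth to filter inputs so the frequency
  filter is testable.
* **Read support**: depth Poisson(40); heterozygous alt reads
  Binomial(depth, 0.5); non-carrier alt reads Binomial(depth, 0.001); seed
  support is 80% of alt reads (rounded up); clonal reads
  Binomial(depth, 0.02); optional genotype dropout with a configurable rate.
  These rates are artefact choices placed around the QC cut-offs, not
  estimates of any particular instrument.

What the simulator does *not* model: read-level errors with haplotype
structure, mapping artefacts, copy-number variation, interference in
recombination, population structure in the database frequencies. Passing
tests on synthetic families therefore demonstrate the pipeline's logic —
recovery guarantees, monotonicity, determinism — not its robustness to real
sequencing pathology.

## Prioritisation and the report

`damage_tier()` collapses the two damage predictors into a concordance tier
(`concordant_damaging` when Polyphen is not benign *and* SIFT is deleterious;
`concordant_benign` when benign and tolerated; `undefined` when either is
missing, as for splice-site variants; otherwise `discordant`). Conservation
labels are carried through verbatim, never recomputed.

`developmental_window_flag()` formalises "elevated expression during
development": per gene, expression is log2-transformed (pseudocount 1),
z-scored across samples, and the gene is flagged when the mean z inside the
age window exceeds the mean outside by more than `z_threshold`. The default
window 0.1–2.4 years targets early postnatal cortical maturation; the default
threshold 1.0 z is a labelled artefact choice — the test suite shows how to
calibrate it against a permutation null (shuffle sample ages, take the 95th
percentile of the null contrast). The statistic is invariant to positive
power-law rescaling of a gene's values, and a zero-variance gene is never
flagged. This is one formalisation of a qualitative criterion and the report
labels it as such; the literature-driven grouping of candidates into
neural/indirect/unlikely classes is not computed, because no algorithm exists
for it.

## Numerical and interface choices

* Coordinates are 1-based inclusive throughout; interval length is defined as
  `end - start` (not `end - start + 1`) because that convention reproduces
  every printed length in the packaged linked-region table. BED export
  converts to 0-based half-open.
* Multi-allelic VCF records are decomposed to one record per ALT before
  filtering; each alt is filtered independently.
* Missing annotations stay missing (`NA`); they are never silently defaulted.
* Problem sizes in the test and acceptance suites (two chromosomes of
  80/60 Mb, 40 markers each, 10–30 background variants, 100 seeded
  replicates, 10,000 gametes for the crossover check) were chosen as the
  smallest sizes at which the construction guarantees and Monte-Carlo trends
  are unambiguous.

## Known limitations

* Marker-level set logic is weaker than haplotype-based linkage; real-array
  regions should be produced by a dedicated linkage tool and supplied via
  `read_regions()`.
* Complete penetrance and autosomal inheritance are hard assumptions;
  X-linked logic and penetrance parameters are not implemented.
* The cascade performs no multiple-testing correction, because it is an
  elimination argument, not hypothesis testing.
* Sanger confirmation is representable only as an upstream annotation, not
  as computation.
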