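---
title: "Federated variant queries: model, privacy tiers, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Federated variant queries: model, privacy tiers, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fedvarq)
```

## The problem

Rare-variant interpretation needs context: a heterozygous variant found in
three patients means something different if it also occurs, on the same
allele, in dozens of unaffected individuals elsewhere. But personal genome
data cannot simply be pooled — it is identifying by nature, and
pseudonymization alone does not make it non-personal. `fedvarq` models a
federation in which raw reads never leave their center; queries travel to
the data, and what travels back is either (a) full per-sample genotype
records for samples the user is explicitly authorized to inspect, or (b)
aggregate statistics plus a pseudonymous backlink for everyone else.

Working from aligned reads rather than pre-called VCFs is deliberate: legacy
VCFs called with different pipelines at different times are not comparable,
and standard VCFs usually omit reference calls, so one cannot tell a
confident hom-ref from a position that was never covered. Genotyping every
queried sample at query time, including reference sites, makes the
denominator of every frequency honest.

## The genotype model

The built-in caller is the classical site-independent diploid model. Per
read with observed base $b$ and phred quality $Q$: $e = 10^{-Q/10}$,
$P(b \mid a) = 1-e$ if $b = a$ and $e/3$ otherwise; under genotype
$a_1/a_2$ each read is an even mixture of the two alleles; the site
likelihood is the product over reads. We report, per sample and site:

* **GT** — the likelihood argmax over {hom-ref, het, hom-alt}, ties broken
  toward more reference alleles (0/0 over 0/1 over 1/1), which is the
  conservative choice when the data cannot distinguish genotypes;
* **PL** — `round(-10 * (log10 L - log10 L_max))`, so the called genotype
  has PL 0;
* **GQ** — the second-smallest PL (the confidence margin of the call),
  capped at 99;
* **QUAL** — `-10 log10 posterior(hom-ref)` under a uniform genotype prior:
  the phred-scaled confidence that the site is non-reference. No population
  prior is used; at desk scale a uniform prior keeps the caller
  self-contained and exactly testable.

Numerical choices: error probabilities are clamped to `[1e-10, 0.75]` so a
Q0 base cannot produce infinite log-likelihoods and a single terrible base
carries bounded information; likelihoods are summed in log10 space; the PL
rounding happens once, and GQ is derived from the rounded PLs so the
emitted triple is always self-consistent (`min(PL) == 0`,
`GQ == sorted(PL)[2]` capped). An independent brute-force enumeration of
the per-read product (linear space, explicit loops) is kept in the test
suite and must agree *exactly* — calls, PLs, and GQs — on a thousand random
pileup columns per run.

Sites are treated as biallelic: the alternate allele is the non-reference
base with the greatest summed base quality, pooled across the center's
samples so all of a center's records at a site describe the same allele
pair; remaining non-reference bases count toward DP but not AD. Multiallelic
sites, indels, and local reassembly are out of scope.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `min_base_qual` | 0 | phred floor for a base to enter the pileup; 0 = no filtering by default |
| `min_qual`, `min_dp`, `min_gq`, `min_pl` | unset | optional record filters, inclusive bounds; `min_pl` tests the second-smallest PL (the call's margin) |
| `mode` | per query | `all_sites` emits hom-ref and no-call records (reference-site genotyping); `variants_only` emits carriers only |
| `mean_depth`, `base_error_rate` | 20, 0.001 | simulator: Poisson (or fixed) depth, per-base error; base qualities encode the error rate, capped at Q60 when the rate is 0 |

Filters never delete records: filtered calls are demoted to no-call for
counting, so partition sizes are conserved and raising a threshold can only
shrink the polymorphic count (a tested monotonicity invariant).

## Privacy tiers

The registry pseudonymizes every sample at insertion (`SID-` + 8 hex
characters, a salted keyed hash of center and insertion counter —
deterministic and opaque, but *not* an anonymization: genome data stays
personal regardless). Access is gated by **dataset activation**: a user has
at most one active dataset; its members are the only samples whose detail
rows appear. The singular active dataset is a deliberate simplification —
the result views compare "active" against "control" and "whole population",
and a single activation keeps those three partitions well defined. With no
activation, detail sections are empty and only summaries are returned.

`privacy_filter()` re-derives the access tier for every detail row and
additionally scans the serialized view for any registered local sample
name, failing loudly rather than leaking. The test suite fuzzes this over
100 random registry/ACL configurations per run.

## Build harmonization

Samples may be aligned to different genome builds. Centers genotype in
their native frame (the query is translated into each center's build via
the inverted chain at dispatch), and the coordinator lifts the returned
records onto the target build — by default the majority build of the
queried samples. The chain reader implements the UCSC format (0-based
half-open, target strand always `+`, minus-strand query coordinates in the
reversed frame); only the reader speaks 0-based, every public API is
1-based inclusive. Unmappable positions are never silently dropped: they go
to a drop report and `records_in == records_out + records_dropped` is a
tested invariant, as is exact agreement with `rtracklayer::liftOver` on
fixture chains. Allele re-referencing across builds (ref/alt swaps at
lifted positions) is explicitly out of scope.

## What the simulator does and does not emulate

`simulate_cohort()` draws unplanted genotypes under Hardy–Weinberg
equilibrium (`Binomial(2, f)` per sample), which is the simplest defensible
model for unrelated individuals; planted overrides take precedence, so
scenario tests state their truth exactly. `simulate_pileups()` draws depth
Poisson (or fixed) and corrupts bases uniformly at the stated error rate,
with base qualities set to that rate's phred value.

It does **not** emulate mapping ambiguity, indels, strand or cycle bias,
duplicates, contamination, or related individuals. A green end-to-end test
therefore establishes that the pipeline — genotyping, liftover,
partitioning, counting, redaction — is arithmetically correct on data whose
truth is known, *not* that the caller is robust to real-sequencing
artifacts; defaults (depth 20, error 0.001) were chosen once as typical
exome-like values and error 0 / fixed depth is used where tests assert
exact recovery.

## Degenerate inputs and tie-breaks

* Empty pileup column: `no_data` error at the likelihood level; the caller
  emits `./.` with DP 0 (only in all-sites mode).
* Unknown reference base: record flagged `REF_N`, no call.
* Zero genotyped samples in a partition: MAF is `NA` ("no data"), never 0.
* Likelihood ties: resolved toward the reference (first maximum in
  hom-ref, het, hom-alt order).
* A center failing mid-query: its task is marked FAILED with a reason;
  other centers' results aggregate normally, and the failure is named in
  the view.
* Duplicate pending access requests are idempotent; task states only move
  forward (PENDING → RUNNING → DONE/FAILED).

## Open design points, decided

* **Liftover location**: at the coordinator. Centers stay build-native and
  the per-center interface stays minimal; the price is that the coordinator
  must hold chains for every build pair in use (a missing pair is a loud
  configuration error).
* **Queries target all centers**; restricting to a subset is a deployment
  concern, not modeled.
* **Sample in multiple datasets across owners after a grant**: allowed.
  Tiers are computed per user and activation, so multiple membership cannot
  widen anyone's access.
* **Whole-population denominators** exclude records lost to liftover (they
  are listed in the drop report); samples at failed centers are reported
  under the failure note rather than silently counted.
* **Persistence** is plain text (JSON registry, TSV manifests and reports,
  JSON-lines audit log) — a deliberate desk-scale substitute for an
  embedded relational store, keeping every artifact diffable and the
  deliverable text-only.
* **Association scoring is deliberately absent**: the whole population
  mixes cases and controls without phenotype labels, so any case/control
  statistic computed from it would be meaningless; the framework stops at
  frequencies and co-carrier structure.

## Known limitations

Single-nucleotide substitutions only; one caller engine (the external-caller
hook accepts a drop-in replacement producing the same record schema, but no
second engine ships); minus-strand chains cannot be inverted for dispatch
translation (records can still be *collected* through them); the in-process
dispatcher executes centers sequentially — the contract tested is failure
isolation, not concurrency.
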