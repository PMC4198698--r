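# fedvarq — federated variant querying with privacy-tiered aggregation

`fedvarq` is a desk-scale R framework for the problem faced by clinical and
research sequencing centers that want to compare variants across sites
without exchanging raw personal genome data: *"at chr9:2115841, how many
samples anywhere carry the alternate allele — and may I see details for
mine?"*

Each center keeps its aligned reads locally. A coordinator sends point or
area queries to every center; each center genotypes the requested positions
directly from its own reads and returns VCF-like per-sample records; the
coordinator lifts records from centers aligned to different genome builds
onto one target build and aggregates them under **privacy tiers**:

* **detailed** — full genotype records, but only for samples in the user's
  currently *active dataset*;
* **summary only** — for every other sample, only non-personal aggregate
  statistics (genotype counts, minor allele frequency, quality statistics)
  plus a pseudonymous sample id as a backlink for negotiating access with
  the owning PI.

## The model at the core

Genotyping is classical site-independent diploid likelihood calling. For a
read with base $b$ and phred quality $Q$, the error probability is
$e = 10^{-Q/10}$ and

$$P(b \mid a) = \begin{cases} 1-e & b = a \\ e/3 & b \ne a \end{cases},
\qquad
P(b \mid a_1/a_2) = \tfrac12 P(b\mid a_1) + \tfrac12 P(b \mid a_2),$$

with the site likelihood the product over reads. The three genotype
likelihoods (hom-ref, het, hom-alt) are phred-normalized into **PL** (best
genotype has PL 0); **GQ** is the margin to the second-best genotype capped
at 99; the site **QUAL** is the phred-scaled posterior probability, under a
uniform prior, that the site is non-reference. Reference sites can be
genotyped too (all-sites mode), so a confident hom-ref is distinguishable
from absent coverage — which keeps MAF denominators honest:

$$\mathrm{MAF} = \min(p,\, 1-p), \qquad
p = \frac{n_{het} + 2\,n_{homalt}}{2\,n_{genotyped}}.$$

Coordinate harmonization uses UCSC chain files (0-based half-open
internally; every public API is 1-based inclusive, VCF convention).

## Worked example

A 2-center synthetic federation of 40 exome-like samples with a single
heterozygote planted at chr9:2115841 (outside the querying user's active
dataset):

```r
library(fedvarq)
dir <- tempfile("demo-")
sites <- data.frame(chrom = "chr9", pos = 2115841L, ref = "G", alt = "A",
                    freq = 0, id = "rs281875187")
truth <- simulate_cohort(40, sites, seed = 1,
                         plant_overrides = data.frame(sample = 40, site = 1, gt = 1))
dep <- build_federation(truth, dir, n_centers = 2, mean_depth = 20,
                        base_error_rate = 0, depth_model = "fixed", seed = 1)
reg <- dep$registry
s <- registry_samples(reg)
create_dataset(reg, "my_cases", owner_user_id = "user1",
               member_sample_ids = s$system_sample_id[s$center_id == "C1"][1:10])
activate_dataset(reg, "user1", "my_cases")
view <- run_query(dep, "user1", query_point("chr9", 2115841, mode = "all_sites"))
view
```

```
== point query result (build hg19) ==
  chr9:2115841
-- Summary --
 center_id n_queried same_as_ref different qual_min qual_max qual_mean
        C1        20          20         0        0     0.00     0.000
        C2        20          19         1        0   781.82    39.091
-- Statistics --
        partition n_queried n_genotyped n_no_call hom_ref het hom_alt    maf
           active        10          10         0      10   0       0 0.0000
          control         0           0         0       0   0       0     NA
 whole_population        40          40         0      39   1       0 0.0125
-- Detail: 10 accessible record(s) --
-- Sample-to-SNV: 1 cluster(s) --
```

Reading it: the variant is absent from the user's 10 active samples, but one
of the 40 samples federation-wide is heterozygous (whole-population
MAF = 1/80 = 0.0125). The `Detail` section holds full records only for the
10 active-dataset samples. The carrier surfaces solely as a pseudonym:

```r
cl <- view$SampleToSNV[[1]]
cl$members
#   system_sample_id accessible
# 1     SID-1621da78      FALSE
```

`SID-1621da78` at center C2 (PI_B) is the contact handle for requesting
access (`request_access()` / `grant_access()`); the sample's local name
never appears in any serialized result.

Area queries work the same way (`query_area(gene_name = "...")` resolves
against a BED gene table); `co_carrier_counts()` compares het carriers
across two positions to test whether two variants are consistent with lying
on the same allele; `apply_filters()` implements the optional
quality/depth/GQ/PL thresholds (no filtering is applied by default). A thin
CLI (`fedvarq_cli()`, `inst/cli/fedvarq`) drives the same operations against
a deployment directory.

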