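test_that("pileup_at returns the fixture column, applies base-quality cut", {
  path <- write_pileup_fixture(list(
    uniform_row("chr1", 100, "A", "A", 10, 30L),
    list(chrom = "chr1", pos = 200, ref = "C",
         bases = c("C", "C", "T"), quals = c(30L, 10L, 25L)),
    list(chrom = "chr1", pos = 300, ref = "G", bases = character(), quals = integer())
  ))
  src <- alignment_source(path)
  col <- pileup_at(src, "chr1", 100)
  expect_identical(col$bases, rep("A", 10))
  expect_identical(col$quals, rep(30L, 10))
  expect_identical(col$ref_base, "A")
  # threshold excludes the Q10 base
  col2 <- pileup_at(src, "chr1", 200, min_base_qual = 20)
  expect_identical(length(col2$bases), 2L)
  expect_false(any(col2$quals < 20))
  # uncovered position and position absent from the fixture -> depth 0
  expect_identical(length(pileup_at(src, "chr1", 300)$bases), 0L)
  expect_identical(length(pileup_at(src, "chr1", 999)$bases), 0L)
  # missing contig is flagged
  expect_identical(pileup_at(src, "chrZ", 1)$flag, "contig_missing")
})

test_that("genotype_likelihoods matches hand-derived cases", {
  # 4 ref + 4 alt at Q30: het strictly most likely
  ll <- genotype_likelihoods(rep(c("A", "C"), each = 4), "A", "C",
                             quals = rep(30L, 8))
  expect_identical(unname(which.max(ll)), 2L)
  expect_identical(ll, genotype_likelihoods(
    rep(c("C", "A"), each = 4), "A", "C", quals = rep(30L, 8))) # permutation invariant
  # pure reference: hom-ref wins, PL(hom-ref) == 0
  ll2 <- genotype_likelihoods(rep("A", 10), "A", "C", quals = rep(30L, 10))
  expect_identical(unname(which.max(ll2)), 1L)
  expect_identical(call_genotype(ll2)$pl[1], 0L)
  # single very poor read: genotypes barely distinguishable, GQ < 10
  ll3 <- genotype_likelihoods("C", "A", "C", quals = 3L)
  expect_lt(call_genotype(ll3)$gq, 10)
  expect_true(all(is.finite(ll3)))
  # contracts
  expect_error(genotype_likelihoods(character(), "A", "C", quals = integer()),
               class = "fv_no_data")
  expect_error(genotype_likelihoods("A", "A", "A", quals = 30L),
               class = "fv_validation")
})

test_that("call_genotype: PL normalization, GQ, and ref-ward tie-break", {
  # stated tie case: (-1, -1, -5) -> 0/0 by tie-break, pl (0, 0, 40)
  cg <- call_genotype(c(-1, -1, -5))
  expect_identical(cg$gt, "0/0")
  expect_identical(cg$pl, c(0L, 0L, 40L))
  # symmetric het: pl (100, 0, 100), gq capped at 99
  cg2 <- call_genotype(c(-10, 0, -10))
  expect_identical(cg2$gt, "0/1")
  expect_identical(cg2$pl, c(100L, 0L, 100L))
  expect_identical(cg2$gq, 99L)
  # property over random triples: min(pl) == 0, gq == sorted(pl)[2] capped
  set.seed(42)
  for (i in 1:1000) {
    ll <- -10 * runif(3)
    cg <- call_genotype(ll)
    expect_identical(min(cg$pl), 0L)
    expect_identical(cg$gq, min(99L, sort(cg$pl)[2]))
  }
})

test_that("caller agrees exactly with the brute-force oracle", {
  set.seed(7)
  for (i in 1:300) {
    rc <- random_column()
    ll <- genotype_likelihoods(rc$bases, rc$ref, rc$alt, quals = rc$quals)
    got <- call_genotype(ll)
    want <- oracle_call(rc$bases, rc$quals, rc$ref, rc$alt)
    expect_identical(got$gt, want$gt)
    expect_identical(got$pl, want$pl)
    expect_identical(got$gq, want$gq)
  }
})

test_that("call_site emits per mode: variants_only vs all_sites", {
  path <- write_pileup_fixture(list(
    uniform_row("chr1", 100, "A", "A", 12),                       # hom-ref
    list(chrom = "chr1", pos = 200, ref = "A",
         bases = rep(c("A", "G"), each = 8), quals = rep(30L, 16)), # het
    list(chrom = "chr1", pos = 300, ref = "C", bases = character(),
         quals = integer())                                        # no coverage
  ))
  src <- alignment_source(path)
  expect_null(call_site(src, "chr1", 100, "A", mode = "variants_only"))
  rec <- call_site(src, "chr1", 100, "A", mode = "all_sites")
  expect_identical(rec$gt, "0/0")
  expect_identical(rec$alt, ".")
  expect_false(anyNA(c(rec$pl_rr, rec$pl_ra, rec$pl_aa)))  # full PL triple
  expect_identical(rec$pl_rr, 0L)

  het <- call_site(src, "chr1", 200, "A", mode = "variants_only")
  expect_identical(het$gt, "0/1")
  expect_identical(het$alt, "G")
  expect_identical(het$ad_ref + het$ad_alt, het$dp)

  expect_null(call_site(src, "chr1", 300, "C", mode = "variants_only"))
  nocov <- call_site(src, "chr1", 300, "C", mode = "all_sites")
  expect_identical(nocov$gt, "./.")
  expect_identical(nocov$dp, 0L)
  # unknown reference base
  refn <- call_site(src, "chr1", 100, "N", mode = "all_sites")
  expect_identical(refn$filter, "REF_N")
  expect_identical(refn$gt, "./.")
})

test_that("run_center_query recovers planted genotypes and isolates failures", {
  dirs <- withr::local_tempdir()
  gts <- c("0/0", "0/1", "1/1")
  paths <- vapply(seq_along(gts), function(i) {
    bases <- switch(gts[i], "0/0" = rep("G", 20),
                    "0/1" = rep(c("G", "A"), 10), "1/1" = rep("A", 20))
    write_pileup_fixture(list(list(chrom = "chr9", pos = 2115841, ref = "G",
                                   bases = bases, quals = rep(30L, 20))),
                         file.path(dirs, paste0("s", i, ".tsv")))
  }, character(1))
  cc <- list(
    center_id = "C1",
    samples = data.frame(system_sample_id = paste0("SID-", 1:3),
                         data_path = paths, source_build = "hg19",
                         stringsAsFactors = FALSE),
    reference = data.frame(chrom = "chr9", pos = 2115841L, ref = "G",
                           stringsAsFactors = FALSE),
    dbsnp = data.frame(chrom = "chr9", pos = 2115841L, id = "rs281875187",
                       stringsAsFactors = FALSE))
  recs <- run_center_query(cc, query_point("chr9", 2115841, mode = "all_sites"))
  expect_identical(recs$gt, gts)
  expect_identical(unique(recs$dbsnp_id), "rs281875187")
  expect_identical(recs$system_sample_id, paste0("SID-", 1:3))  # sorted
  expect_identical(unique(recs$alt[recs$gt != "0/0"]), "A")

  # one corrupt sample among them: others unaffected, failure entry present
  cc$samples <- rbind(cc$samples, data.frame(
    system_sample_id = "SID-4", data_path = file.path(dirs, "absent.tsv"),
    source_build = "hg19", stringsAsFactors = FALSE))
  recs2 <- run_center_query(cc, query_point("chr9", 2115841, mode = "all_sites"))
  expect_identical(nrow(recs2), 3L)
  fails <- attr(recs2, "failures")
  expect_identical(fails$system_sample_id, "SID-4")
})

test_that("area queries emit only carriers in variants_only, n*m in all_sites", {
  dirs <- withr::local_tempdir()
  sites <- test_sites(n = 5, chrom = "chr2", start = 500L, freq = 0)
  truth <- simulate_cohort(4, sites, seed = 11,
                           plant_overrides = data.frame(sample = 2, site = 3, gt = 1))
  paths <- simulate_pileups(truth, dirs, mean_depth = 25, base_error_rate = 0,
                            seed = 5, depth_model = "fixed")
  cc <- list(center_id = "C1",
             samples = data.frame(system_sample_id = truth$sample_names,
                                  data_path = unname(paths), source_build = "hg19",
                                  stringsAsFactors = FALSE),
             reference = truth$sites[, c("chrom", "pos", "ref")])
  q <- query_area("chr2", 500, 1000, mode = "variants_only")
  recs <- run_center_query(cc, q)
  expect_identical(nrow(recs), 1L)
  expect_identical(recs$system_sample_id, "SAMPLE_0002")
  expect_identical(recs$pos, sites$pos[3])
  expect_identical(recs$gt, "0/1")
  # all_sites: exactly n sites x m samples records
  qa <- query_area("chr2", 500, 1000, mode = "all_sites")
  expect_identical(nrow(run_center_query(cc, qa)), 5L * 4L)
})

test_that("records round-trip to VCF text", {
  recs <- make_records(c("0/0", "0/1", "./."))
  recs$alt[1] <- "."
  p <- tempfile(fileext = ".vcf")
  write_vcf(recs, p)
  lines <- readLines(p)
  body <- lines[!startsWith(lines, "#")]
  expect_identical(length(body), 3L)
  f <- strsplit(body[2], "\t")[[1]]
  expect_identical(f[1], "chr9")
  expect_identical(f[5], "A")
  expect_identical(f[9], "GT:AD:DP:GQ:PL")
  expect_match(f[10], "^0/1:10,10:20:99:99,0,99$")
  expect_match(f[8], "SID=SID-0002")
  # no-call record serializes missing values as '.'
  expect_match(strsplit(body[3], "\t")[[1]][10], "^\\./\\.:")
})
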