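test_that("partition_samples: active/control/whole with correct containment", {
  reg <- make_test_registry(n_per_center = 5)
  s <- registry_samples(reg)
  active_ids <- s$system_sample_id[1:3]
  control_ids <- s$system_sample_id[6:8]
  create_dataset(reg, "D1", owner_user_id = "user1", member_sample_ids = active_ids)
  create_dataset(reg, "ctrl", owner_user_id = "PI_B", member_sample_ids = control_ids,
                 is_control = TRUE)
  # no activation: active empty, whole population unchanged
  p0 <- partition_samples(reg, "user1")
  expect_identical(p0$active, character(0))
  expect_identical(sort(p0$whole_population), sort(s$system_sample_id))
  activate_dataset(reg, "user1", "D1")
  p <- partition_samples(reg, "user1")
  expect_setequal(p$active, active_ids)
  expect_setequal(p$control, control_ids)
  expect_identical(length(p$whole_population), 10L)
  expect_true(all(p$active %in% p$whole_population))
})

test_that("apply_filters: defaults pass everything; thresholds are inclusive", {
  recs <- make_records(c("0/0", "0/1", "0/1", "1/1", "./."),
                       qual = c(50, 10, 80, 80, NA),
                       dp = c(20L, 10L, 9L, 30L, 0L),
                       gq = c(99L, 60L, 99L, 20L, NA))
  # no thresholds: kept == input, removed empty
  f0 <- apply_filters(recs, list())
  expect_identical(f0$kept, recs)
  expect_identical(nrow(f0$removed), 0L)
  # boundary inclusive on dp
  f1 <- apply_filters(recs, list(min_dp = 10))
  expect_true(all(f1$kept$dp[f1$kept$gt %in% c("0/1", "1/1")] >= 10))
  expect_identical(f1$removed$dp, 9L)
  # hom-ref and no-call are never filter subjects
  f2 <- apply_filters(recs, list(min_qual = 60))
  expect_true(all(c("0/0", "./.") %in% f2$kept$gt))
  expect_identical(sum(f2$removed$gt == "0/1"), 1L)
  # min_pl compares the second-smallest PL (the call's confidence margin)
  recs2 <- make_records(c("0/1", "0/1"), pl = list(c(60L, 0L, 600L), c(70L, 0L, 700L)))
  f3 <- apply_filters(recs2, list(min_pl = 70))
  expect_identical(nrow(f3$removed), 1L)
  expect_identical(f3$removed$pl_rr, 60L)
  expect_identical(f3$kept$pl_rr, 70L)   # inclusive boundary
  expect_error(apply_filters(recs, list(min_dp = -1)), class = "fv_validation")
})

test_that("compute_maf folds and excludes no-calls from the denominator", {
  expect_equal(compute_maf(make_records(c("0/1", rep("0/0", 9)))), 0.05)
  expect_equal(compute_maf(make_records(c(rep("0/1", 22), rep("0/0", 345)))),
               22 / 734, tolerance = 1e-12)
  expect_equal(round(compute_maf(make_records(c(rep("0/1", 22), rep("0/0", 345)))), 2),
               0.03)
  expect_equal(compute_maf(make_records(rep("1/1", 5))), 0)   # p = 1 folds to 0
  expect_true(is.na(compute_maf(make_records(rep("./.", 4)))))
  # no-calls excluded: 1 het among 4 genotyped, not among 6 queried
  expect_equal(compute_maf(make_records(c("0/1", "0/0", "0/0", "0/0", "./.", "./."))),
               1 / 8)
  # restriction to a sample set
  r <- make_records(c("0/1", "0/1", "0/0", "0/0"))
  expect_equal(compute_maf(r, r$system_sample_id[3:4]), 0)
})

test_that("summarize_point mirrors the single-carrier scenario", {
  reg <- make_test_registry(n_per_center = 5)
  s <- registry_samples(reg)
  active_ids <- s$system_sample_id[s$center_id == "C1"][1:4]
  create_dataset(reg, "D1", owner_user_id = "user1", member_sample_ids = active_ids)
  activate_dataset(reg, "user1", "D1")
  # one het in the whole population, outside the active dataset
  carrier <- s$system_sample_id[s$center_id == "C2"][1]
  gts <- setNames(rep("0/0", 10), s$system_sample_id)
  gts[carrier] <- "0/1"
  recs <- make_records(unname(gts), sid = names(gts),
                       center = s$center_id, qual = 60)
  parts <- partition_samples(reg, "user1")
  out <- summarize_point(recs, parts)
  stats <- out$Statistics
  expect_identical(stats$het[stats$partition == "active"], 0L)
  expect_identical(stats$het[stats$partition == "whole_population"], 1L)
  expect_identical(stats$n_queried[stats$partition == "whole_population"], 10L)
  expect_equal(stats$maf[stats$partition == "whole_population"], 0.05)
  expect_equal(stats$maf[stats$partition == "active"], 0)
  # empty control partition: reported empty (NA maf), not zero-MAF
  expect_identical(stats$n_queried[stats$partition == "control"], 0L)
  expect_true(is.na(stats$maf[stats$partition == "control"]))
  # per-center summary: same-as-ref vs different
  expect_identical(out$Summary$different[out$Summary$center_id == "C2"], 1L)
  expect_identical(out$Summary$same_as_ref[out$Summary$center_id == "C1"], 5L)
  # quality stats equal an independent pass
  genotyped <- recs$qual[recs$gt != "./."]
  wp <- stats[stats$partition == "whole_population", ]
  expect_equal(c(wp$qual_min, wp$qual_max, wp$qual_mean),
               c(min(genotyped), max(genotyped), mean(genotyped)))
})

test_that("conservation holds per partition and counts sum across centers", {
  set.seed(12)
  reg <- make_test_registry(n_per_center = 10)
  s <- registry_samples(reg)
  gts <- sample(c("0/0", "0/1", "1/1", "./."), 20, replace = TRUE)
  recs <- make_records(gts, sid = s$system_sample_id, center = s$center_id)
  parts <- partition_samples(reg, "user1")
  stats <- summarize_point(recs, parts)$Statistics
  for (i in seq_len(nrow(stats))) {
    expect_identical(stats$hom_ref[i] + stats$het[i] + stats$hom_alt[i] +
                       stats$n_no_call[i], stats$n_queried[i])
  }
  # whole-population genotype counts == sum over centers
  summ <- summarize_point(recs, parts)$Summary
  wp <- stats[stats$partition == "whole_population", ]
  expect_identical(sum(summ$same_as_ref), wp$hom_ref)
  expect_identical(sum(summ$different), wp$het + wp$hom_alt)
})

test_that("summarize_area sections respect privacy tiers", {
  reg <- make_test_registry(n_per_center = 3)
  s <- registry_samples(reg)
  recs <- rbind(
    make_records(c("0/1", "0/0", "0/0", "0/0", "0/0", "1/1"),
                 sid = s$system_sample_id, center = s$center_id, pos = 1000L),
    make_records(rep("0/0", 6), sid = s$system_sample_id, center = s$center_id,
                 pos = 1100L, dbsnp = "rs0002"))
  parts0 <- partition_samples(reg, "user1")     # nothing active
  out0 <- summarize_area(recs, parts0, reg, "user1")
  expect_identical(nrow(out0$SampleToPosition), 0L)     # no access, no details
  expect_identical(nrow(out0$PositionToSample), 2L)     # counts still populated
  expect_identical(out0$PositionToSample$het[1], 1L)
  expect_identical(out0$PositionToSample$hom_alt[1], 1L)
  expect_identical(out0$Summary$n_accessible, c(0L, 0L))
  # with an active dataset covering the het carrier
  create_dataset(reg, "D1", owner_user_id = "user1",
                 member_sample_ids = s$system_sample_id[1])
  activate_dataset(reg, "user1", "D1")
  out1 <- summarize_area(recs, partition_samples(reg, "user1"), reg, "user1")
  expect_identical(out1$SampleToPosition$system_sample_id, s$system_sample_id[1])
  expect_identical(out1$SampleToPosition$pos, 1000L)
})

test_that("cluster_sample_to_snv groups by (gt, id, center, PI) and flags access", {
  reg <- make_test_registry(n_per_center = 3)
  s <- registry_samples(reg)
  c1 <- s$system_sample_id[s$center_id == "C1"]
  c2 <- s$system_sample_id[s$center_id == "C2"]
  recs <- make_records(c("0/1", "0/1", "0/1", "1/1", "0/0"),
                       sid = c(c1, c2[1], c2[2]),
                       center = c("C1", "C1", "C1", "C2", "C2"))
  create_dataset(reg, "D1", owner_user_id = "user1", member_sample_ids = c1[1])
  activate_dataset(reg, "user1", "D1")
  cl <- cluster_sample_to_snv(recs, reg, "user1")
  expect_identical(length(cl), 2L)   # 3 het C1/PI_A + 1 hom-alt C2/PI_B
  sizes <- sort(vapply(cl, function(x) nrow(x$members), integer(1)))
  expect_identical(sizes, c(1L, 3L))
  # union of members == polymorphic samples, no loss or duplication
  members <- unlist(lapply(cl, function(x) x$members$system_sample_id))
  expect_setequal(members, recs$system_sample_id[recs$gt %in% c("0/1", "1/1")])
  expect_identical(anyDuplicated(members), 0L)
  # accessibility per check_access; inaccessible members expose pseudonym+center+PI only
  big <- cl[[which(vapply(cl, function(x) nrow(x$members), integer(1)) == 3L)]]
  acc <- setNames(big$members$accessible, big$members$system_sample_id)
  expect_true(acc[[c1[1]]])
  expect_false(acc[[c1[2]]])
})

test_that("co_carrier_counts detects same-allele consistency", {
  carriers <- sprintf("SID-%04d", 1:22)
  others <- sprintf("SID-%04d", 23:367)
  a <- make_records(c(rep("0/1", 22), rep("0/0", 345)), sid = c(carriers, others))
  b <- make_records(c(rep("0/1", 22), rep("0/0", 345)), sid = c(carriers, others),
                    pos = 108397495L)
  cc <- co_carrier_counts(a, b)
  expect_identical(cc$both_het, 22L)
  expect_identical(cc$only_A, 0L)
  expect_identical(cc$only_B, 0L)
  expect_true(cc$same_allele_consistent)
  # disjoint carrier sets
  b2 <- make_records(c(rep("0/0", 22), rep("0/1", 5), rep("0/0", 340)),
                     sid = c(carriers, others))
  cc2 <- co_carrier_counts(a, b2)
  expect_identical(cc2$both_het, 0L)
  expect_false(cc2$same_allele_consistent)
  # strict subset is not consistent
  b3 <- make_records(c(rep("0/1", 10), rep("0/0", 357)), sid = c(carriers, others))
  cc3 <- co_carrier_counts(a, b3)
  expect_identical(cc3$both_het, 10L)
  expect_identical(cc3$only_A, 12L)
  expect_false(cc3$same_allele_consistent)
})

test_that("filtering monotonicity: raising thresholds never adds polymorphics", {
  set.seed(5)
  recs <- make_records(sample(c("0/0", "0/1", "1/1"), 50, replace = TRUE),
                       qual = round(runif(50, 5, 95)),
                       dp = sample(1:40, 50, replace = TRUE),
                       gq = sample(1:99, 50, replace = TRUE))
  poly_count <- function(th) {
    d <- fedvarq:::demote_filtered(recs, th)
    sum(d$gt %in% c("0/1", "1/1"))
  }
  for (th_name in c("min_qual", "min_dp", "min_gq")) {
    vals <- c(0, 5, 10, 20, 40, 80)
    counts <- vapply(vals, function(v) poly_count(setNames(list(v), th_name)), numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})
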