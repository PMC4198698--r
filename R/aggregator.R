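# Aggregation of harmonized per-sample records into privacy-tiered result
# views: partition summaries (active / control / whole population), minor
# allele frequency, quality statistics, quality filtering, sample-to-SNV
# clustering, and co-carrier analysis across two positions. Detail rows are
# shown only for samples in the user's active dataset; every other sample
# appears solely inside aggregate counts or as a pseudonymous backlink
# (system sample id + center + PI) — never under its local name.

POLYMORPHIC_GTS <- c("0/1", "1/1")

#' Partition the registered samples for a user
#'
#' Three partitions drive every statistics view: `active` — members of the
#' user's currently active dataset (empty when none is activated);
#' `control` — the union of datasets flagged as control cohorts (unaffected,
#' unrelated individuals); `whole_population` — every sample registered at
#' any center, which by construction contains the active partition.
#'
#' @param reg registry.
#' @param user_id user.
#' @return list of character vectors of system sample ids:
#'   `active`, `control`, `whole_population`.
#' @export
partition_samples <- function(reg, user_id) {
  u <- reg$users[[user_id]]
  if (is.null(u)) fv_stop("fv_lookup", sprintf("unknown user '%s'", user_id))
  active <- character()
  if (!is.null(u$active_dataset_id))
    active <- reg$datasets[[u$active_dataset_id]]$member_sample_ids
  control_ds <- Filter(function(d) isTRUE(d$is_control), reg$datasets)
  control <- unique(unlist(lapply(control_ds, `[[`, "member_sample_ids"), use.names = FALSE))
  list(active = active, control = control %||% character(),
       whole_population = reg$samples$system_sample_id)
}

#' Apply quality-filter thresholds to records
#'
#' By default no quality filtering is performed; users may require minimum
#' site quality, depth, genotype quality, and/or PL margin. A non-hom-ref
#' record is kept iff, for every supplied threshold, `qual >= min_qual`,
#' `dp >= min_dp`, `gq >= min_gq`, and its second-smallest PL (the
#' phred-scaled confidence margin of the called genotype) is
#' `>= min_pl`. Boundaries are inclusive. Hom-ref and no-call records pass
#' through untouched. Removed records are not deleted: downstream counting
#' demotes them to no-calls.
#'
#' @param records SiteRecord data.frame.
#' @param thresholds named list; any of `min_qual`, `min_dp`, `min_gq`,
#'   `min_pl`. Negative values are a validation error.
#' @return list with `kept` and `removed` data.frames.
#' @export
apply_filters <- function(records, thresholds = list()) {
  validate_thresholds(thresholds)
  if (nrow(records) == 0L || length(thresholds) == 0L)
    return(list(kept = records, removed = records[0, , drop = FALSE]))
  subject <- records$gt %in% POLYMORPHIC_GTS
  ok <- rep(TRUE, nrow(records))
  if (!is.null(thresholds$min_qual))
    ok <- ok & (!subject | (!is.na(records$qual) & records$qual >= thresholds$min_qual))
  if (!is.null(thresholds$min_dp))
    ok <- ok & (!subject | (!is.na(records$dp) & records$dp >= thresholds$min_dp))
  if (!is.null(thresholds$min_gq))
    ok <- ok & (!subject | (!is.na(records$gq) & records$gq >= thresholds$min_gq))
  if (!is.null(thresholds$min_pl)) {
    second_pl <- apply(cbind(records$pl_rr, records$pl_ra, records$pl_aa), 1L,
                       function(p) if (anyNA(p)) NA_integer_ else sort(p)[2L])
    ok <- ok & (!subject | (!is.na(second_pl) & second_pl >= thresholds$min_pl))
  }
  list(kept = records[ok, , drop = FALSE], removed = records[!ok, , drop = FALSE])
}

# records with filter-removed calls demoted to "./." for counting
demote_filtered <- function(records, thresholds = list()) {
  f <- apply_filters(records, thresholds)
  if (nrow(f$removed) > 0L) {
    idx <- rownames(records) %in% rownames(f$removed)
    records$gt[idx] <- "./."
  }
  records
}

#' Minor allele frequency over a sample set
#'
#' `p = alt alleles / (2 * genotyped samples)`, folded to `min(p, 1 - p)` so
#' the value always lies in [0, 0.5]. No-calls are excluded from the
#' denominator: knowing whether a sample is hom-ref or simply not covered is
#' what makes the denominator honest. With zero genotyped samples the MAF is
#' undefined and reported as `NA`.
#'
#' @param records SiteRecords restricted to one position.
#' @param sample_set system sample ids to restrict to (default: all samples
#'   in `records`).
#' @return numeric in [0, 0.5], or `NA`.
#' @export
compute_maf <- function(records, sample_set = NULL) {
  if (!is.null(sample_set))
    records <- records[records$system_sample_id %in% sample_set, , drop = FALSE]
  gt <- records$gt
  n_geno <- sum(gt %in% c("0/0", "0/1", "1/1"))
  if (n_geno == 0L) return(NA_real_)
  p <- (sum(gt == "0/1") + 2 * sum(gt == "1/1")) / (2 * n_geno)
  min(p, 1 - p)
}

partition_summary <- function(records, member_ids, name, queried_samples,
                              implicit_hom_ref = FALSE) {
  queried <- intersect(queried_samples, member_ids)
  recs <- records[records$system_sample_id %in% member_ids, , drop = FALSE]
  counts <- c(hom_ref = sum(recs$gt == "0/0"), het = sum(recs$gt == "0/1"),
              hom_alt = sum(recs$gt == "1/1"))
  if (implicit_hom_ref)  # variants_only: samples without a record are hom-ref
    counts["hom_ref"] <- counts["hom_ref"] +
      length(setdiff(queried, recs$system_sample_id))
  n_genotyped <- sum(counts)
  n_queried <- length(queried)
  quals <- recs$qual[recs$gt %in% c("0/0", "0/1", "1/1") & !is.na(recs$qual)]
  maf <- if (n_genotyped == 0L) NA_real_ else {
    p <- (counts[["het"]] + 2 * counts[["hom_alt"]]) / (2 * n_genotyped)
    min(p, 1 - p)
  }
  data.frame(
    partition = name, n_queried = n_queried, n_genotyped = n_genotyped,
    n_no_call = n_queried - n_genotyped,
    hom_ref = counts[["hom_ref"]], het = counts[["het"]], hom_alt = counts[["hom_alt"]],
    maf = maf,
    qual_min = if (length(quals)) min(quals) else NA_real_,
    qual_max = if (length(quals)) max(quals) else NA_real_,
    qual_mean = if (length(quals)) mean(quals) else NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Point-query summary and statistics sections
#'
#' `Summary`: per center, the number of samples queried and how many were
#' genotyped the same as vs different from the homozygous reference, plus
#' quality extremes. `Statistics`: one row per partition (active / control /
#' whole population) with genotype counts, no-calls, MAF, and min/max/mean
#' site quality over genotyped records.
#'
#' @param records harmonized SiteRecords at one position (after filter
#'   demotion if thresholds were requested).
#' @param partitions list from [partition_samples()].
#' @param queried_samples ids the query targeted; defaults to the samples
#'   appearing in `records`.
#' @param implicit_hom_ref treat queried samples without a record as hom-ref
#'   (for variants_only batches; with all-sites records leave FALSE).
#' @return list with data.frames `Summary` and `Statistics`.
#' @export
summarize_point <- function(records, partitions, queried_samples = NULL,
                            implicit_hom_ref = FALSE) {
  queried_samples <- queried_samples %||% unique(records$system_sample_id)
  stats <- do.call(rbind, Map(partition_summary,
    name = c("active", "control", "whole_population"),
    member_ids = partitions[c("active", "control", "whole_population")],
    MoreArgs = list(records = records, queried_samples = queried_samples,
                    implicit_hom_ref = implicit_hom_ref)))
  rownames(stats) <- NULL
  centers <- sort(unique(records$center_id))
  summary <- do.call(rbind, lapply(centers, function(ct) {
    r <- records[records$center_id == ct, , drop = FALSE]
    data.frame(center_id = ct, n_queried = length(unique(r$system_sample_id)),
               same_as_ref = sum(r$gt == "0/0"),
               different = sum(r$gt %in% POLYMORPHIC_GTS),
               qual_min = if (any(!is.na(r$qual))) min(r$qual, na.rm = TRUE) else NA_real_,
               qual_max = if (any(!is.na(r$qual))) max(r$qual, na.rm = TRUE) else NA_real_,
               qual_mean = if (any(!is.na(r$qual))) mean(r$qual, na.rm = TRUE) else NA_real_,
               stringsAsFactors = FALSE)
  })) %||% data.frame()
  list(Summary = summary, Statistics = stats)
}

#' Area-query sections
#'
#' `Summary`: per center, total samples queried and how many of them are
#' accessible to the user at the detail tier. `Sample-to-Position`: for each
#' accessible sample, its non-hom-ref positions. `Position-to-Sample`: for
#' each position in the region, how frequently each genotype is observed
#' across all samples from all centers (aggregate counts only, no
#' identities).
#'
#' @param records harmonized SiteRecords over one region.
#' @param partitions list from [partition_samples()].
#' @param reg registry (for access tiers).
#' @param user_id querying user.
#' @return list with data.frames `Summary`, `SampleToPosition`,
#'   `PositionToSample`.
#' @export
summarize_area <- function(records, partitions, reg, user_id) {
  accessible <- partitions$active
  centers <- sort(unique(records$center_id))
  summary <- do.call(rbind, lapply(centers, function(ct) {
    ids <- unique(records$system_sample_id[records$center_id == ct])
    data.frame(center_id = ct, n_queried = length(ids),
               n_accessible = length(intersect(ids, accessible)),
               stringsAsFactors = FALSE)
  })) %||% data.frame()
  poly <- records[records$gt %in% POLYMORPHIC_GTS, , drop = FALSE]
  s2p <- poly[poly$system_sample_id %in% accessible,
              c("system_sample_id", "chrom", "pos", "dbsnp_id", "ref", "alt",
                "gt", "dp", "gq", "qual"), drop = FALSE]
  s2p <- s2p[order(s2p$system_sample_id, s2p$chrom, s2p$pos), , drop = FALSE]
  rownames(s2p) <- NULL
  key <- unique(records[, c("chrom", "pos"), drop = FALSE])
  key <- key[order(key$chrom, key$pos), , drop = FALSE]
  p2s <- do.call(rbind, lapply(seq_len(nrow(key)), function(i) {
    r <- records[records$chrom == key$chrom[i] & records$pos == key$pos[i], , drop = FALSE]
    alt <- setdiff(unique(r$alt), ".")
    ids <- setdiff(unique(r$dbsnp_id), ".")
    data.frame(chrom = key$chrom[i], pos = key$pos[i],
               dbsnp_id = if (length(ids)) ids[1L] else ".",
               ref = r$ref[1L], alt = if (length(alt)) alt[1L] else ".",
               hom_ref = sum(r$gt == "0/0"), het = sum(r$gt == "0/1"),
               hom_alt = sum(r$gt == "1/1"), no_call = sum(r$gt == "./."),
               maf = compute_maf(r), stringsAsFactors = FALSE)
  })) %||% data.frame()
  rownames(p2s) <- NULL
  list(Summary = summary, SampleToPosition = s2p, PositionToSample = p2s)
}

#' Cluster polymorphic samples for the Sample-to-SNV section
#'
#' Samples carrying the variant at one position, grouped by genotype,
#' annotation id, center, and PI. Members the user may not see in detail are
#' flagged inaccessible (rendered grey in a UI) and expose only their
#' pseudonym, center, and PI — the backlink for negotiating access.
#'
#' @param records SiteRecords at one position, filters already applied.
#' @param reg registry.
#' @param user_id viewing user.
#' @return list of clusters: each has `genotype`, `dbsnp_id`, `center_id`,
#'   `pi_name`, and `members` (data.frame system_sample_id, accessible).
#' @export
cluster_sample_to_snv <- function(records, reg, user_id) {
  poly <- records[records$gt %in% POLYMORPHIC_GTS, , drop = FALSE]
  if (nrow(poly) == 0L) return(list())
  pi <- reg$samples$pi_name[match(poly$system_sample_id, reg$samples$system_sample_id)]
  poly$pi_name <- ifelse(is.na(pi), "<unknown>", pi)
  keyv <- paste(poly$gt, poly$dbsnp_id, poly$center_id, poly$pi_name, sep = "\x1f")
  unname(lapply(split(seq_len(nrow(poly)), keyv), function(idx) {
    r <- poly[idx, , drop = FALSE]
    list(genotype = r$gt[1L], dbsnp_id = r$dbsnp_id[1L],
         center_id = r$center_id[1L], pi_name = r$pi_name[1L],
         members = data.frame(
           system_sample_id = r$system_sample_id,
           accessible = vapply(r$system_sample_id, function(s)
             check_access(reg, user_id, s) == "detailed", logical(1)),
           row.names = NULL, stringsAsFactors = FALSE))
  }))
}

#' Co-carrier analysis across two positions
#'
#' Counts samples heterozygous at both positions vs only one. When every
#' carrier of either variant carries both (`only_A == only_B == 0`,
#' `both_het > 0`), the two variants are consistent with lying on the same
#' allele — two heterozygous variants on the same allele cannot compound a
#' recessive disorder.
#'
#' @param recordsA,recordsB SiteRecords at the two positions, filters
#'   already applied (filter-removed calls demoted to no-call).
#' @return list: `both_het`, `only_A`, `only_B`, `same_allele_consistent`,
#'   plus `carriers_both` (pseudonyms).
#' @export
co_carrier_counts <- function(recordsA, recordsB) {
  hetA <- unique(recordsA$system_sample_id[recordsA$gt == "0/1"])
  hetB <- unique(recordsB$system_sample_id[recordsB$gt == "0/1"])
  both <- intersect(hetA, hetB)
  list(both_het = length(both),
       only_A = length(setdiff(hetA, hetB)),
       only_B = length(setdiff(hetB, hetA)),
       same_allele_consistent = length(both) > 0L &&
         length(setdiff(hetA, hetB)) == 0L && length(setdiff(hetB, hetA)) == 0L,
       carriers_both = both)
}

#' Assemble the point-query result view
#'
#' Sections: `Summary`, `Detail` (full VCF-like rows, active-dataset samples
#' only), `Statistics` (per-partition), `SampleToSNV` (clusters). The view
#' is passed through [privacy_filter()] before being returned.
#'
#' @param reg registry.
#' @param user_id querying user.
#' @param spec resolved `fv_query`.
#' @param collected output of [collect_results()].
#' @return an `fv_result_view`.
#' @export
build_point_view <- function(reg, user_id, spec, collected) {
  records <- demote_filtered(collected$records, spec$filter_thresholds %||% list())
  partitions <- partition_samples(reg, user_id)
  sections <- summarize_point(records, partitions,
                              implicit_hom_ref = identical(spec$mode, "variants_only"))
  detail <- records[records$system_sample_id %in% partitions$active, , drop = FALSE]
  rownames(detail) <- NULL
  view <- structure(list(
    kind = "point", user_id = user_id, spec = spec,
    Summary = sections$Summary, Detail = detail, Statistics = sections$Statistics,
    SampleToSNV = cluster_sample_to_snv(records, reg, user_id),
    dropped = collected$dropped, failed_centers = collected$failed_centers,
    target_build = collected$target_build
  ), class = "fv_result_view")
  privacy_filter(reg, user_id, view)
}

#' Assemble the area-query result view
#'
#' Sections: `Summary`, `SampleToPosition` (accessible samples only),
#' `PositionToSample` (aggregate counts for everyone). Passed through
#' [privacy_filter()].
#'
#' @inheritParams build_point_view
#' @return an `fv_result_view`.
#' @export
build_area_view <- function(reg, user_id, spec, collected) {
  records <- demote_filtered(collected$records, spec$filter_thresholds %||% list())
  partitions <- partition_samples(reg, user_id)
  sections <- summarize_area(records, partitions, reg, user_id)
  view <- structure(list(
    kind = "area", user_id = user_id, spec = spec,
    Summary = sections$Summary, SampleToPosition = sections$SampleToPosition,
    PositionToSample = sections$PositionToSample,
    dropped = collected$dropped, failed_centers = collected$failed_centers,
    target_build = collected$target_build
  ), class = "fv_result_view")
  privacy_filter(reg, user_id, view)
}

#' Enforce the privacy tiers on a result view
#'
#' Guarantees, independently of how the view was assembled, that detail rows
#' are restricted to samples the user may see at the detailed tier, that
#' inaccessible samples appear only as pseudonym + center + PI, and that no
#' local sample name occurs anywhere in the view.
#'
#' @param reg registry.
#' @param user_id viewing user.
#' @param view an `fv_result_view`.
#' @return the redacted view.
#' @export
privacy_filter <- function(reg, user_id, view) {
  detailed <- function(s) check_access(reg, user_id, s) == "detailed"
  if (!is.null(view$Detail) && nrow(view$Detail) > 0L) {
    keep <- vapply(view$Detail$system_sample_id, detailed, logical(1))
    view$Detail <- view$Detail[keep, , drop = FALSE]
    rownames(view$Detail) <- NULL
  }
  if (!is.null(view$SampleToPosition) && nrow(view$SampleToPosition) > 0L) {
    keep <- vapply(view$SampleToPosition$system_sample_id, detailed, logical(1))
    view$SampleToPosition <- view$SampleToPosition[keep, , drop = FALSE]
    rownames(view$SampleToPosition) <- NULL
  }
  # belt-and-braces: a local name must never survive serialization
  local_names <- reg$samples$sample_local_name
  txt <- serialize_view(view)
  hits <- local_names[nzchar(local_names) &
                        vapply(local_names, function(nm) grepl(nm, txt, fixed = TRUE), logical(1))]
  if (length(hits))
    fv_stop("fv_privacy", sprintf("local sample name would leak into results: %s",
                                  paste(unique(hits), collapse = ", ")))
  view
}

#' Serialize a result view as JSON
#'
#' @param view an `fv_result_view`.
#' @return JSON string.
#' @export
serialize_view <- function(view) {
  v <- unclass(view)
  v$spec <- unclass(v$spec)
  as.character(jsonlite::toJSON(v, dataframe = "rows",
                                auto_unbox = TRUE, na = "null", digits = NA))
}

#' @export
print.fv_result_view <- function(x, ...) {
  cat(sprintf("== %s query result (build %s) ==\n", x$kind, x$target_build %||% "?"))
  if (x$kind == "point")
    cat(sprintf("  %s:%d\n", x$spec$chrom, x$spec$pos))
  else
    cat(sprintf("  %s:%d-%d%s\n", x$spec$chrom, x$spec$start, x$spec$end,
                if (!is.null(x$spec$gene_name)) paste0(" (", x$spec$gene_name, ")") else ""))
  for (sec in intersect(c("Summary", "Statistics", "PositionToSample"), names(x))) {
    cat("-- ", sec, " --\n", sep = "")
    print(x[[sec]], row.names = FALSE)
  }
  if (!is.null(x$Detail))
    cat(sprintf("-- Detail: %d accessible record(s) --\n", nrow(x$Detail)))
  if (!is.null(x$SampleToSNV))
    cat(sprintf("-- Sample-to-SNV: %d cluster(s) --\n", length(x$SampleToSNV)))
  if (length(x$failed_centers))
    cat("!! failed centers:", paste(names(x$failed_centers), collapse = ", "), "\n")
  invisible(x)
}
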