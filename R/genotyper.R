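# Built-in diploid genotype-likelihood caller.
#
# The model is the classical site-independent diploid one: a read carrying
# base b with phred quality Q has error probability e = 10^(-Q/10);
# P(b | allele a) = 1 - e if b == a, else e/3; under genotype a1/a2 each read
# is an even mixture, P(b | a1/a2) = (P(b|a1) + P(b|a2)) / 2; the site
# likelihood is the product over reads. Likelihoods are computed for hom-ref,
# het, and hom-alt, phred-normalized into PLs (best genotype has PL 0), with
# GQ the margin to the second-best genotype (capped at 99) and the site
# quality the phred-scaled posterior probability, under a uniform genotype
# prior, that the site is non-reference.
#
# This caller stands in for external tools; run_center_query() accepts a
# pluggable caller hook producing records with the same schema.

GT_LABELS <- c("0/0", "0/1", "1/1")

# error-probability clamp: keeps log-likelihoods finite at Q0 and bounds the
# information content of a single very bad base (cf. common caller practice)
ERR_MIN <- 1e-10
ERR_MAX <- 0.75

#' Diploid genotype log10-likelihoods for one pileup column
#'
#' @param column an `fv_pileup_column`, or a character vector of bases (then
#'   `quals` must be given).
#' @param ref_base,alt_base the two alleles; must differ.
#' @param quals phred base qualities when `column` is a bare base vector.
#' @return named numeric of length 3: log10-likelihoods for genotypes
#'   `0/0` (hom-ref), `0/1` (het), `1/1` (hom-alt). Invariant under read
#'   permutation; errors with class `fv_no_data` on an empty column.
#' @export
genotype_likelihoods <- function(column, ref_base, alt_base, quals = NULL) {
  if (inherits(column, "fv_pileup_column")) {
    bases <- column$bases; quals <- column$quals
  } else {
    bases <- column
  }
  if (length(bases) == 0L) fv_stop("fv_no_data", "no_data: empty pileup column")
  if (identical(ref_base, alt_base))
    fv_stop("fv_validation", "ref and alt alleles must differ")
  e <- pmin(pmax(10^(-quals / 10), ERR_MIN), ERR_MAX)
  p_ref <- ifelse(bases == ref_base, 1 - e, e / 3)
  p_alt <- ifelse(bases == alt_base, 1 - e, e / 3)
  ll <- c(
    sum(log10(p_ref)),
    sum(log10((p_ref + p_alt) / 2)),
    sum(log10(p_alt))
  )
  names(ll) <- GT_LABELS
  ll
}

#' Turn genotype likelihoods into a call
#'
#' PLs are `round(-10 * (log10 L - log10 L_max))`; the called genotype is the
#' likelihood argmax with ties broken toward more reference alleles
#' (`0/0` over `0/1` over `1/1`). GQ is the second-smallest PL, capped at
#' 99. The site quality is `-10 log10 posterior(hom-ref)` under a uniform
#' genotype prior — the phred-scaled confidence that the site is
#' non-reference.
#'
#' @param ll numeric length-3 log10-likelihoods (hom-ref, het, hom-alt).
#' @return list with `gt`, `pl` (integer triple), `gq`, `site_qual`.
#' @export
call_genotype <- function(ll) {
  stopifnot(length(ll) == 3L, all(is.finite(ll)))
  best <- which.max(ll)        # first max: ordering encodes the tie-break
  pl <- as.integer(round(-10 * (ll - max(ll))))
  gq <- min(99L, sort(pl)[2L])
  post <- 10^(ll - max(ll)); post <- post / sum(post)
  site_qual <- round(min(-10 * log10(max(post[1L], 1e-300)), 9999), 2)
  list(gt = GT_LABELS[best], pl = pl, gq = gq, site_qual = site_qual)
}

# non-ref base with the greatest summed base quality; ties alphabetical.
# NULL when the column holds no non-reference base.
choose_alt <- function(bases, quals, ref_base) {
  nonref <- bases != ref_base & bases %in% c("A", "C", "G", "T")
  if (!any(nonref)) return(NULL)
  sums <- tapply(quals[nonref], bases[nonref], sum)
  names(sums)[order(-sums, names(sums))][1L]
}

# placeholder alt for pure-reference columns so hom-ref records still carry a
# full PL triple (reference-site genotyping)
placeholder_alt <- function(ref_base) setdiff(c("A", "C", "G", "T"), ref_base)[1L]

#' Genotype one sample at one site
#'
#' In `all_sites` mode a record is always emitted: hom-ref records carry
#' ALT `"."` with full PLs (reference-site genotyping, distinguishing a
#' confident hom-ref from absence of coverage), and uncovered positions yield
#' a `./.` no-call with depth 0. In `variants_only` mode a record is emitted
#' only for het / hom-alt calls. An unknown reference base (`N`) yields a
#' no-call record flagged `REF_N` (emitted in `all_sites` mode).
#'
#' @param src alignment source ([alignment_source()]).
#' @param chrom,pos site (1-based).
#' @param ref_base reference base from the reference lookup table.
#' @param mode `"variants_only"` or `"all_sites"`.
#' @param alt_base alternate allele; when `NULL`, the non-reference base with
#'   the greatest summed base quality in this column is used.
#' @param min_base_qual minimum base quality (default 0: no filtering).
#' @param dbsnp_id annotation id or `"."`.
#' @param system_sample_id,center_id,source_build provenance stamped on the
#'   record.
#' @param caller caller tag stored in the record (default `"builtin"`).
#' @return one-row SiteRecord data.frame, or `NULL` when nothing is emitted.
#' @export
call_site <- function(src, chrom, pos, ref_base,
                      mode = c("variants_only", "all_sites"),
                      alt_base = NULL, min_base_qual = 0, dbsnp_id = ".",
                      system_sample_id = NA_character_,
                      center_id = NA_character_,
                      source_build = NA_character_, caller = "builtin") {
  mode <- match.arg(mode)
  col <- pileup_at(src, chrom, pos, min_base_qual)
  meta <- list(chrom = chrom, pos = as.integer(pos), dbsnp_id = dbsnp_id,
               system_sample_id = system_sample_id, center_id = center_id,
               source_build = source_build, caller = caller)
  if (!ref_base %in% c("A", "C", "G", "T")) {
    if (mode == "variants_only") return(NULL)
    return(site_record(meta, ref = ref_base, alt = ".", qual = NA_real_,
                       filter = "REF_N", gt = "./.", dp = length(col$bases),
                       ad = c(NA_integer_, NA_integer_),
                       gq = NA_integer_, pl = rep(NA_integer_, 3)))
  }
  if (length(col$bases) == 0L) {
    if (mode == "variants_only") return(NULL)
    return(site_record(meta, ref = ref_base, alt = ".", qual = NA_real_,
                       filter = ".", gt = "./.", dp = 0L,
                       ad = c(0L, 0L), gq = NA_integer_, pl = rep(NA_integer_, 3)))
  }
  observed_alt <- choose_alt(col$bases, col$quals, ref_base)
  alt <- alt_base %||% observed_alt %||% placeholder_alt(ref_base)
  ll <- genotype_likelihoods(col, ref_base, alt)
  call <- call_genotype(ll)
  if (mode == "variants_only" && call$gt %in% c("0/0", "./.")) return(NULL)
  alt_out <- if (call$gt == "0/0" && is.null(observed_alt) && is.null(alt_base)) "." else alt
  site_record(meta, ref = ref_base, alt = alt_out, qual = call$site_qual,
              filter = ".", gt = call$gt, dp = length(col$bases),
              ad = c(sum(col$bases == ref_base), sum(col$bases == alt)),
              gq = call$gq, pl = call$pl)
}

site_record <- function(meta, ref, alt, qual, filter, gt, dp, ad, gq, pl) {
  data.frame(
    chrom = meta$chrom, pos = meta$pos, dbsnp_id = meta$dbsnp_id,
    ref = ref, alt = alt, qual = qual, filter = filter, gt = gt,
    dp = as.integer(dp), ad_ref = as.integer(ad[1L]), ad_alt = as.integer(ad[2L]),
    gq = as.integer(gq), pl_rr = as.integer(pl[1L]), pl_ra = as.integer(pl[2L]),
    pl_aa = as.integer(pl[3L]),
    system_sample_id = meta$system_sample_id, center_id = meta$center_id,
    source_build = meta$source_build, caller = meta$caller,
    stringsAsFactors = FALSE
  )
}

#' Run a query at one center
#'
#' The per-center engine: for every sample in the center's sample sheet and
#' every requested site, extracts the pileup and emits a genotype record.
#' For an area query the callable positions are those present in the
#' center's reference table within the region. The alternate allele at each
#' site is chosen once per center as the non-reference base with the
#' greatest summed base quality pooled across that center's samples. An
#' unreadable sample file yields a per-sample failure entry and never
#' affects the other samples.
#'
#' @param center_config list with `center_id`, `samples` (data.frame with
#'   `system_sample_id`, `data_path`, `source_build`), `reference` (data.frame
#'   or TSV path: chrom, pos, ref), optional `dbsnp` (data.frame: chrom, pos,
#'   id), optional `data_root` prefix, optional `caller_fun` hook with the
#'   same signature/schema as [call_site()].
#' @param query a query spec from [query_point()] / [query_area()] (with
#'   explicit coordinates; gene names are resolved upstream).
#' @return SiteRecord data.frame sorted by (chrom, pos, system_sample_id),
#'   with attribute `failures`: data.frame (system_sample_id, reason).
#' @export
run_center_query <- function(center_config, query) {
  cc <- center_config
  stopifnot(!is.null(cc$center_id), !is.null(cc$samples))
  ref_table <- if (is.character(cc$reference)) read_reference_table(cc$reference) else cc$reference
  sites <- query_sites(query, ref_table)
  mode <- query$mode %||% "variants_only"
  mbq <- query$filter_thresholds$min_base_qual %||% 0
  samples <- cc$samples
  failures <- data.frame(system_sample_id = character(), reason = character(),
                         stringsAsFactors = FALSE)
  sources <- setNames(vector("list", nrow(samples)), samples$system_sample_id)
  for (i in seq_len(nrow(samples))) {
    path <- samples$data_path[i]
    if (!is.null(cc$data_root) && !file.exists(path))
      path <- file.path(cc$data_root, path)
    sources[i] <- list(tryCatch(alignment_source(path), error = function(e) {
      failures <<- rbind(failures, data.frame(
        system_sample_id = samples$system_sample_id[i],
        reason = conditionMessage(e), stringsAsFactors = FALSE))
      NULL
    }))
  }
  out <- list()
  for (k in seq_len(nrow(sites))) {
    chrom <- sites$chrom[k]; pos <- sites$pos[k]; ref <- sites$ref[k]
    dbsnp <- dbsnp_at(cc$dbsnp, chrom, pos)
    # pool non-ref evidence across samples to fix this site's alt allele
    alt <- site_alt_pooled(sources, chrom, pos, ref, mbq)
    for (i in seq_len(nrow(samples))) {
      src <- sources[[i]]
      if (is.null(src)) next
      rec <- tryCatch(
        (cc$caller_fun %||% call_site)(
          src, chrom, pos, ref, mode = mode, alt_base = alt,
          min_base_qual = mbq, dbsnp_id = dbsnp,
          system_sample_id = samples$system_sample_id[i],
          center_id = cc$center_id,
          source_build = samples$source_build[i],
          caller = cc$caller_name %||% "builtin"),
        error = function(e) {
          failures <<- rbind(failures, data.frame(
            system_sample_id = samples$system_sample_id[i],
            reason = conditionMessage(e), stringsAsFactors = FALSE))
          NULL
        })
      out[[length(out) + 1L]] <- rec
    }
  }
  recs <- rbind_records(out)
  recs <- recs[order(recs$chrom, recs$pos, recs$system_sample_id), , drop = FALSE]
  rownames(recs) <- NULL
  attr(recs, "failures") <- failures
  recs
}

site_alt_pooled <- function(sources, chrom, pos, ref, mbq) {
  bases <- character(); quals <- integer()
  for (src in sources) {
    if (is.null(src)) next
    col <- tryCatch(pileup_at(src, chrom, pos, mbq), error = function(e) NULL)
    if (is.null(col)) next
    bases <- c(bases, col$bases); quals <- c(quals, col$quals)
  }
  if (length(bases) == 0L) return(NULL)
  choose_alt(bases, quals, ref)
}

dbsnp_at <- function(dbsnp, chrom, pos) {
  if (is.null(dbsnp)) return(".")
  hit <- dbsnp$id[dbsnp$chrom == chrom & dbsnp$pos == pos]
  if (length(hit) == 0L) "." else hit[1L]
}

query_sites <- function(query, ref_table) {
  if (query$kind == "point") {
    ref <- ref_base_at(ref_table, query$chrom, query$pos)
    return(data.frame(chrom = query$chrom, pos = as.integer(query$pos), ref = ref,
                      stringsAsFactors = FALSE))
  }
  if (is.null(query$start) || is.null(query$end))
    fv_stop("fv_validation", "area query must carry resolved start/end coordinates")
  hit <- ref_table[ref_table$chrom == query$chrom &
                     ref_table$pos >= query$start & ref_table$pos <= query$end, ,
                   drop = FALSE]
  hit <- hit[order(hit$pos), , drop = FALSE]
  rownames(hit) <- NULL
  hit
}

#' Write site records as a VCF
#'
#' VCF 4.2 text with one line per (sample, site) record, FORMAT
#' `GT:AD:DP:GQ:PL`; the sample's pseudonym, center, and source build travel
#' in INFO (`SID`, `CENTER`, `SRCBUILD`). Hom-ref and no-call records use the
#' symbolic ALT `"."` (reference-site genotyping); their PL triple, when
#' present, refers to REF and the placeholder alternate documented in the
#' header.
#'
#' @param records SiteRecord data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_vcf <- function(records, path) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths (ref,alt)\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=PL,Number=G,Type=Integer,Description=\"Phred-scaled genotype likelihoods\">",
    "##INFO=<ID=SID,Number=1,Type=String,Description=\"Pseudonymous system sample id\">",
    "##INFO=<ID=CENTER,Number=1,Type=String,Description=\"Originating center\">",
    "##INFO=<ID=SRCBUILD,Number=1,Type=String,Description=\"Genome build of the source alignment\">",
    "##ALT_CONVENTION=hom-ref/no-call records carry ALT '.'; PLs then refer to a placeholder alternate",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tSAMPLE"
  )
  fmt_num <- function(x) ifelse(is.na(x), ".", as.character(x))
  lines <- vapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    info <- sprintf("SID=%s;CENTER=%s;SRCBUILD=%s", r$system_sample_id, r$center_id, r$source_build)
    pl <- if (is.na(r$pl_rr)) "." else paste(r$pl_rr, r$pl_ra, r$pl_aa, sep = ",")
    ad <- if (is.na(r$ad_ref)) "." else paste(r$ad_ref, r$ad_alt, sep = ",")
    val <- paste(r$gt, ad, r$dp, fmt_num(r$gq), pl, sep = ":")
    paste(r$chrom, r$pos, r$dbsnp_id, r$ref, r$alt, fmt_num(r$qual), r$filter,
          info, "GT:AD:DP:GQ:PL", val, sep = "\t")
  }, character(1))
  writeLines(c(hdr, lines), path)
  invisible(path)
}
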