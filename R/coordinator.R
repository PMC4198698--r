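# The coordinator accepts queries, resolves gene names to regions, assigns
# request ids, dispatches one task per registered center, tracks per-center
# progress, and collects results for aggregation. Centers communicate with
# the coordinator only through their per-center result staging (mirroring a
# one-database-per-center federation topology); a failed center never blocks
# the others.

TASK_STATES <- c("PENDING", "RUNNING", "DONE", "FAILED")

#' Build a point or area query specification
#'
#' Point queries genotype a single position, optionally in `all_sites` mode
#' (reference-site genotyping / allSitePLs: hom-ref and no-coverage records
#' are emitted too). Area queries take explicit coordinates or a gene name
#' resolved against the deployment's gene table.
#'
#' @param chrom chromosome.
#' @param pos position (1-based) for a point query.
#' @param mode `"variants_only"` or `"all_sites"`.
#' @param caller_name caller tag recorded on emitted records.
#' @param filter_thresholds optional named list: any of `min_qual`,
#'   `min_dp`, `min_gq`, `min_pl` (applied at aggregation) and
#'   `min_base_qual` (applied at pileup extraction). Default: none — no
#'   quality filtering is performed unless requested.
#' @return a list of class `fv_query`.
#' @export
query_point <- function(chrom, pos, mode = c("all_sites", "variants_only"),
                        caller_name = "builtin", filter_thresholds = list()) {
  mode <- match.arg(mode)
  validate_thresholds(filter_thresholds)
  structure(list(kind = "point", chrom = as.character(chrom), pos = as.integer(pos),
                 mode = mode, caller_name = caller_name,
                 filter_thresholds = filter_thresholds),
            class = "fv_query")
}

#' @rdname query_point
#' @param start,end region bounds (1-based inclusive) for an area query;
#'   give either these or `gene_name`.
#' @param gene_name gene symbol resolved against the gene table
#'   (case-insensitive).
#' @export
query_area <- function(chrom = NULL, start = NULL, end = NULL, gene_name = NULL,
                       mode = c("variants_only", "all_sites"),
                       caller_name = "builtin", filter_thresholds = list()) {
  mode <- match.arg(mode)
  validate_thresholds(filter_thresholds)
  has_coords <- !is.null(start) && !is.null(end) && !is.null(chrom)
  has_gene <- !is.null(gene_name)
  if (has_coords == has_gene)
    fv_stop("fv_validation", "area query needs either (chrom, start, end) or gene_name")
  if (has_coords && start > end)
    fv_stop("fv_validation", "area query needs start <= end")
  structure(list(kind = "area", chrom = if (has_coords) as.character(chrom) else NULL,
                 start = if (has_coords) as.integer(start) else NULL,
                 end = if (has_coords) as.integer(end) else NULL,
                 gene_name = gene_name, mode = mode, caller_name = caller_name,
                 filter_thresholds = filter_thresholds),
            class = "fv_query")
}

validate_thresholds <- function(th) {
  bad <- names(th)[vapply(th, function(v) is.numeric(v) && v < 0, logical(1))]
  if (length(bad))
    fv_stop("fv_validation", sprintf("negative filter threshold(s): %s",
                                     paste(bad, collapse = ", ")))
  unknown <- setdiff(names(th), c("min_qual", "min_dp", "min_gq", "min_pl", "min_base_qual"))
  if (length(unknown))
    fv_stop("fv_validation", sprintf("unknown filter threshold(s): %s",
                                     paste(unknown, collapse = ", ")))
  invisible(th)
}

#' Load a gene table from BED
#'
#' BED is 0-based half-open; intervals are converted to 1-based inclusive at
#' this boundary (rtracklayer does the conversion).
#'
#' @param path BED file with at least 4 columns (name in column 4).
#' @return data.frame with columns gene, chrom, start, end (1-based
#'   inclusive).
#' @export
load_gene_table <- function(path) {
  gr <- as.data.frame(rtracklayer::import(path, format = "BED"))
  data.frame(gene = gr$name, chrom = as.character(gr$seqnames),
             start = gr$start, end = gr$end, stringsAsFactors = FALSE)
}

#' Resolve a query's region
#'
#' Explicit coordinates pass through unchanged; a gene name is matched
#' case-insensitively against the gene table and must hit exactly one
#' interval.
#'
#' @param spec an `fv_query` (area specs with a gene name get resolved;
#'   everything else is returned as-is).
#' @param gene_table data.frame from [load_gene_table()].
#' @return the spec with concrete `chrom`, `start`, `end`.
#' @export
resolve_region <- function(spec, gene_table = NULL) {
  if (spec$kind != "area" || is.null(spec$gene_name)) return(spec)
  if (is.null(gene_table))
    fv_stop("fv_configuration", "gene-name query needs a gene table (BED)")
  hit <- gene_table[tolower(gene_table$gene) == tolower(spec$gene_name), , drop = FALSE]
  if (nrow(hit) == 0L)
    fv_stop("fv_resolution", sprintf("unknown gene '%s'", spec$gene_name))
  if (nrow(hit) > 1L)
    fv_stop("fv_resolution", sprintf(
      "gene '%s' is ambiguous: %s", spec$gene_name,
      paste(sprintf("%s:%d-%d", hit$chrom, hit$start, hit$end), collapse = "; ")))
  spec$chrom <- hit$chrom[1L]
  spec$start <- hit$start[1L]
  spec$end <- hit$end[1L]
  spec
}

#' Assemble a federation deployment
#'
#' Ties together the registry, the per-center configurations, the gene
#' table, and the liftover maps; holds submitted requests and their staged
#' results.
#'
#' @param registry an `fv_registry`.
#' @param centers named list (by center id) of center configs as taken by
#'   [run_center_query()]; sample sheets default to the registry's samples
#'   for that center.
#' @param gene_table optional data.frame from [load_gene_table()].
#' @param maps named list of liftover maps keyed `"<from>-><to>"`.
#' @param target_build default aggregation build; `NULL` means "majority
#'   build of the queried samples".
#' @return an object of class `fv_deployment` (environment-backed).
#' @export
new_deployment <- function(registry, centers, gene_table = NULL, maps = list(),
                           target_build = NULL) {
  dep <- new.env(parent = emptyenv())
  dep$registry <- registry
  dep$centers <- centers
  dep$gene_table <- gene_table
  dep$maps <- maps
  dep$target_build <- target_build
  dep$requests <- list()
  dep$req_counter <- 0L
  dep$audit <- list()
  dep$audit_path <- NULL
  class(dep) <- "fv_deployment"
  dep
}

#' @export
print.fv_deployment <- function(x, ...) {
  cat(sprintf("<fv_deployment> %d center(s), %d request(s)\n",
              length(x$centers), length(x$requests)))
  invisible(x)
}

# fill each center config from the registry: sample sheet + reference paths
center_config <- function(dep, center_id) {
  cc <- dep$centers[[center_id]]
  cc$center_id <- cc$center_id %||% center_id
  if (is.null(cc$samples)) {
    s <- registry_samples(dep$registry, center_id)
    cc$samples <- data.frame(system_sample_id = s$system_sample_id,
                             data_path = s$data_path,
                             source_build = s$reference_build,
                             stringsAsFactors = FALSE)
  }
  cc
}

#' Submit a query to the federation
#'
#' Validates and resolves the spec, assigns a unique request id (date prefix
#' plus zero-padded counter), and creates one PENDING task per registered
#' center.
#'
#' @param dep deployment.
#' @param user_id submitting user.
#' @param spec an `fv_query`.
#' @return the request (list with `request_id`, `spec`, `tasks`).
#' @export
submit_query <- function(dep, user_id, spec) {
  stopifnot(inherits(dep, "fv_deployment"), inherits(spec, "fv_query"))
  if (!user_id %in% names(dep$registry$users))
    fv_stop("fv_lookup", sprintf("unknown user '%s'", user_id))
  if (length(dep$centers) == 0L) fv_stop("fv_validation", "no_centers: no registered centers")
  spec <- resolve_region(spec, dep$gene_table)
  dep$req_counter <- dep$req_counter + 1L
  rid <- sprintf("%s-%06d", format(Sys.Date(), "%Y%m%d"), dep$req_counter)
  req <- list(
    request_id = rid, user_id = user_id, spec = spec,
    tasks = setNames(rep("PENDING", length(dep$centers)), names(dep$centers)),
    reasons = setNames(rep("", length(dep$centers)), names(dep$centers)),
    staged = list(), failures = list(),
    created_at = as.character(Sys.time())
  )
  dep$requests[[rid]] <- req
  audit_append(dep, user_id, "submit_query", list(request_id = rid, kind = spec$kind))
  req
}

set_task <- function(dep, rid, center, state, reason = "") {
  cur <- dep$requests[[rid]]$tasks[[center]]
  if (match(state, TASK_STATES) < match(cur, TASK_STATES))
    fv_stop("fv_state", sprintf("task %s/%s cannot move %s -> %s", rid, center, cur, state))
  dep$requests[[rid]]$tasks[[center]] <- state
  dep$requests[[rid]]$reasons[[center]] <- reason
}

#' Run a request's per-center tasks
#'
#' Each center's task moves PENDING -> RUNNING -> DONE (results staged per
#' center) or FAILED (with a reason); centers are independent and one
#' failure never blocks the rest. Re-dispatching a finished request is a
#' no-op.
#'
#' @param dep deployment.
#' @param request_id request id.
#' @return the per-center task states, invisibly.
#' @export
dispatch <- function(dep, request_id) {
  req <- dep$requests[[request_id]]
  if (is.null(req)) fv_stop("fv_lookup", sprintf("unknown request '%s'", request_id))
  for (center in names(dep$centers)) {
    if (req$tasks[[center]] != "PENDING") next   # idempotent re-dispatch
    set_task(dep, request_id, center, "RUNNING")
    res <- tryCatch({
      cc <- center_config(dep, center)
      spec <- translate_query(req$spec, dep, cc)
      recs <- run_center_query(cc, spec)
      dep$requests[[request_id]]$staged[[center]] <- recs
      dep$requests[[request_id]]$failures[[center]] <- attr(recs, "failures")
      "DONE"
    }, error = function(e) conditionMessage(e))
    if (identical(res, "DONE")) set_task(dep, request_id, center, "DONE")
    else set_task(dep, request_id, center, "FAILED", reason = res)
  }
  audit_append(dep, req$user_id, "dispatch", list(request_id = request_id))
  invisible(dep$requests[[request_id]]$tasks)
}

# Queries arrive in the deployment's target-build frame; a center aligned to
# another build genotypes in its own frame, so the query coordinates are
# translated through the (inverted) chain before dispatch. Records come back
# in the center's native build and are lifted onto the target at collection.
translate_query <- function(spec, dep, cc) {
  qframe <- dep$target_build
  cbuild <- center_build(dep, cc$center_id)
  if (is.null(qframe) || is.null(cbuild) || identical(qframe, cbuild)) return(spec)
  map <- dep$maps[[paste0(qframe, "->", cbuild)]]
  if (is.null(map)) {
    back <- dep$maps[[paste0(cbuild, "->", qframe)]]
    if (is.null(back))
      fv_stop("fv_configuration",
              sprintf("no liftover map for build pair '%s->%s'", qframe, cbuild))
    map <- invert_map(back)
  }
  shift <- function(chrom, pos) {
    lifted <- lift_position(map, chrom, pos)
    if (!lifted$mapped)
      fv_stop("fv_configuration", sprintf(
        "query position %s:%d unmapped on build %s (%s)", chrom, pos, cbuild, lifted$reason))
    lifted
  }
  if (spec$kind == "point") {
    l <- shift(spec$chrom, spec$pos)
    spec$chrom <- l$chrom; spec$pos <- l$pos
  } else {
    l1 <- shift(spec$chrom, spec$start); l2 <- shift(spec$chrom, spec$end)
    spec$chrom <- l1$chrom; spec$start <- l1$pos; spec$end <- l2$pos
  }
  spec
}

center_build <- function(dep, center_id) {
  c_reg <- dep$registry$centers[[center_id]]
  b <- dep$centers[[center_id]]$build %||% c_reg$build_default
  b
}

#' Per-center progress of a request
#'
#' Pure read: returns each center's task state without changing anything.
#'
#' @param dep deployment.
#' @param request_id request id.
#' @return named character vector of states (PENDING/RUNNING/DONE/FAILED).
#' @export
track_status <- function(dep, request_id) {
  req <- dep$requests[[request_id]]
  if (is.null(req)) fv_stop("fv_lookup", sprintf("unknown request '%s'", request_id))
  req$tasks
}

#' Collect and harmonize a finished request's results
#'
#' Concatenates all DONE centers' staged batches, lifts every record onto
#' the target build (the majority build of the queried samples unless the
#' deployment or call pins one), and reports liftover drops and per-center /
#' per-sample failures. Record conservation holds: staged-in equals
#' harmonized-out plus dropped.
#'
#' @param dep deployment.
#' @param request_id request id; all tasks must be terminal (DONE/FAILED).
#' @param target_build override the aggregation build.
#' @return list: `records` (harmonized SiteRecords), `dropped` (liftover
#'   drop report), `failed_centers` (named reasons), `sample_failures`
#'   (data.frame), `target_build`.
#' @export
collect_results <- function(dep, request_id, target_build = NULL) {
  req <- dep$requests[[request_id]]
  if (is.null(req)) fv_stop("fv_lookup", sprintf("unknown request '%s'", request_id))
  if (!all(req$tasks %in% c("DONE", "FAILED")))
    fv_stop("fv_state", "not_ready: request has non-terminal tasks")
  staged <- rbind_records(unname(req$staged))
  tb <- target_build %||% dep$target_build %||% majority_build(staged)
  harm <- harmonize_records(staged, tb, dep$maps)
  failed <- req$reasons[req$tasks == "FAILED"]
  sample_failures <- do.call(rbind, c(unname(req$failures),
                                      list(make.row.names = FALSE)))
  audit_append(dep, req$user_id, "collect_results", list(request_id = request_id))
  list(records = harm$records, dropped = harm$dropped,
       failed_centers = failed, sample_failures = sample_failures,
       target_build = tb)
}

majority_build <- function(records) {
  if (nrow(records) == 0L) return("hg19")
  names(sort(table(records$source_build), decreasing = TRUE))[1L]
}

#' Submit, dispatch, collect, and aggregate in one call
#'
#' Convenience wrapper producing the privacy-filtered result view the user
#' would see.
#'
#' @param dep deployment.
#' @param user_id querying user.
#' @param spec an `fv_query`.
#' @param target_build optional aggregation build override.
#' @return an `fv_result_view` (see [build_point_view()] /
#'   [build_area_view()]).
#' @export
run_query <- function(dep, user_id, spec, target_build = NULL) {
  req <- submit_query(dep, user_id, spec)
  dispatch(dep, req$request_id)
  col <- collect_results(dep, req$request_id, target_build)
  spec_resolved <- dep$requests[[req$request_id]]$spec
  view <- if (spec$kind == "point")
    build_point_view(dep$registry, user_id, spec_resolved, col)
  else
    build_area_view(dep$registry, user_id, spec_resolved, col)
  view$request_id <- req$request_id
  view
}
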