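#' @keywords internal
"_PACKAGE"

#' @importFrom stats rbinom rpois runif setNames
#' @importFrom utils read.delim write.table head tail
NULL

fv_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "fv_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_chr <- function(x) is.character(x) && length(x) == 1L && !is.na(x) && nzchar(x)

#' Append an entry to a registry or deployment audit log
#'
#' Every mutating operation is tracked: the log records who did what, when,
#' with a digest of the arguments. The log is append-only; if the owning
#' object was created with a file path, entries are also written as JSON
#' lines.
#'
#' @param obj a registry or deployment (environment-backed).
#' @param user acting user id.
#' @param op operation name.
#' @param args named list of arguments worth recording.
#' @return invisibly, the new log length.
#' @keywords internal
audit_append <- function(obj, user, op, args = list()) {
  entry <- list(
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3%z"),
    user = user,
    op = op,
    args_digest = fv_hash32(paste(names(args), unlist(lapply(args, paste, collapse = ",")),
                                  sep = "=", collapse = ";"))
  )
  obj$audit[[length(obj$audit) + 1L]] <- entry
  if (!is.null(obj$audit_path)) {
    cat(jsonlite::toJSON(entry, auto_unbox = TRUE), "\n",
        sep = "", file = obj$audit_path, append = TRUE)
  }
  invisible(length(obj$audit))
}

#' Retrieve the audit log
#'
#' @param obj a registry or deployment.
#' @return data.frame with columns timestamp, user, op, args_digest.
#' @export
audit_log <- function(obj) {
  if (length(obj$audit) == 0L) {
    return(data.frame(timestamp = character(), user = character(),
                      op = character(), args_digest = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(obj$audit, function(e) {
    data.frame(timestamp = e$timestamp, user = e$user, op = e$op,
               args_digest = e$args_digest, stringsAsFactors = FALSE)
  }))
}

# Empty SiteRecord data.frame: the canonical column set used everywhere.
empty_records <- function() {
  data.frame(
    chrom = character(), pos = integer(), dbsnp_id = character(),
    ref = character(), alt = character(), qual = numeric(),
    filter = character(), gt = character(), dp = integer(),
    ad_ref = integer(), ad_alt = integer(), gq = integer(),
    pl_rr = integer(), pl_ra = integer(), pl_aa = integer(),
    system_sample_id = character(), center_id = character(),
    source_build = character(), caller = character(),
    stringsAsFactors = FALSE
  )
}

rbind_records <- function(lst) {
  lst <- Filter(function(x) !is.null(x) && nrow(x) > 0L, lst)
  if (length(lst) == 0L) return(empty_records())
  do.call(rbind, c(lst, list(make.row.names = FALSE)))
}
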