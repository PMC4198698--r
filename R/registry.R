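# The registry holds centers, users, PIs, samples, datasets, and access
# requests for one federation deployment, and answers "who may see what at
# which tier". It is an environment-backed S3 object; persistence is
# plain-text (JSON/TSV) and every mutating operation appends to an
# append-only audit log.

MANIFEST_COLS <- c("SampleLocalName", "PIName", "SampleType", "SampleReferenceVersion")
SAMPLE_TYPES <- c("Research", "Diagnostics")
USER_ROLES <- c("system_admin", "local_admin", "pi", "researcher")

#' Create an empty federation registry
#'
#' @param salt deployment-secret salt used for pseudonym generation.
#' @param audit_path optional path; when given, audit entries are also
#'   appended there as JSON lines.
#' @return an object of class `fv_registry` (environment-backed; mutating
#'   operations modify it in place).
#' @seealso [register_sample()], [create_dataset()], [check_access()]
#' @export
new_registry <- function(salt = "fedvarq-dev-salt", audit_path = NULL) {
  reg <- new.env(parent = emptyenv())
  reg$salt <- salt
  reg$centers <- list()
  reg$users <- list()
  reg$samples <- data.frame(
    system_sample_id = character(), sample_local_name = character(),
    pi_name = character(), sample_type = character(),
    reference_build = character(), center_id = character(),
    data_path = character(), stringsAsFactors = FALSE
  )
  reg$datasets <- list()
  reg$counters <- list()              # per-center insertion counters
  reg$access_requests <- list()       # request_id -> record
  reg$grants <- data.frame(user_id = character(), system_sample_id = character(),
                           stringsAsFactors = FALSE)
  reg$audit <- list()
  reg$audit_path <- audit_path
  class(reg) <- "fv_registry"
  reg
}

#' @export
print.fv_registry <- function(x, ...) {
  cat(sprintf("<fv_registry> %d center(s), %d user(s), %d sample(s), %d dataset(s)\n",
              length(x$centers), length(x$users), nrow(x$samples), length(x$datasets)))
  invisible(x)
}

#' Register a sequencing center
#'
#' Each center is the custodian of its own aligned-read data; its database /
#' staging area is the only channel between the center and the coordinator.
#' Every center must have at least one local admin.
#'
#' @param reg registry.
#' @param center_id short unique token.
#' @param name human-readable name.
#' @param local_admins character vector of user ids (at least one); users are
#'   created with role `local_admin` if not yet present.
#' @param data_root path to that center's read data.
#' @param build_default genome-build label, e.g. `"hg19"`.
#' @param actor acting user id, for the audit log.
#' @return the registry, invisibly.
#' @export
add_center <- function(reg, center_id, name = center_id, local_admins,
                       data_root = NULL, build_default = "hg19",
                       actor = "system_admin") {
  stopifnot(inherits(reg, "fv_registry"), is_scalar_chr(center_id))
  if (center_id %in% names(reg$centers))
    fv_stop("fv_conflict", sprintf("center '%s' already registered", center_id))
  if (missing(local_admins) || length(local_admins) == 0L)
    fv_stop("fv_validation", "a center needs at least one local admin")
  reg$centers[[center_id]] <- list(
    center_id = center_id, name = name,
    local_admins = unique(local_admins),
    data_root = data_root, build_default = build_default
  )
  for (u in local_admins) {
    if (!u %in% names(reg$users)) add_user(reg, u, "local_admin", center_id, actor = actor)
  }
  reg$counters[[center_id]] <- 0L
  audit_append(reg, actor, "add_center", list(center_id = center_id))
  invisible(reg)
}

#' Register a user
#'
#' @param reg registry.
#' @param user_id user id.
#' @param role one of `system_admin`, `local_admin`, `pi`, `researcher`.
#' @param center_id optional home center.
#' @param actor acting user id.
#' @return the registry, invisibly.
#' @export
add_user <- function(reg, user_id, role = "researcher", center_id = NULL,
                     actor = "system_admin") {
  stopifnot(inherits(reg, "fv_registry"), is_scalar_chr(user_id))
  role <- match.arg(role, USER_ROLES)
  if (user_id %in% names(reg$users))
    fv_stop("fv_conflict", sprintf("user '%s' already exists", user_id))
  reg$users[[user_id]] <- list(
    user_id = user_id, role = role, center_id = center_id,
    accessible_dataset_ids = character(), active_dataset_id = NULL
  )
  audit_append(reg, actor, "add_user", list(user_id = user_id, role = role))
  invisible(reg)
}

user_role <- function(reg, user_id) {
  u <- reg$users[[user_id]]
  if (is.null(u)) fv_stop("fv_lookup", sprintf("unknown user '%s'", user_id))
  u$role
}

#' Register one sample from a manifest row
#'
#' The four compulsory manifest fields are `SampleLocalName`, `PIName`,
#' `SampleType` (Research or Diagnostics) and `SampleReferenceVersion` (the
#' genome build the sample was aligned to; used later to harmonize query
#' results across builds). A pseudonymous system sample id is assigned at
#' insertion and is the only identifier other users ever see. The sample is
#' auto-assigned to its PI's implicit dataset (`pi::<PIName>`), created on
#' first use.
#'
#' @param reg registry.
#' @param center_id center the sample belongs to.
#' @param manifest_row named list or one-row data.frame with at least the
#'   compulsory columns; `DataPath` optional. Extra columns are ignored.
#' @param actor acting user; must be a local admin of the center or a system
#'   admin.
#' @return one-row data.frame: the stored sample record (with
#'   `system_sample_id`).
#' @export
register_sample <- function(reg, center_id, manifest_row, actor = "system_admin") {
  stopifnot(inherits(reg, "fv_registry"))
  if (!center_id %in% names(reg$centers))
    fv_stop("fv_lookup", sprintf("unknown center '%s'", center_id))
  if (!actor %in% names(reg$users) ||
      !(user_role(reg, actor) == "system_admin" ||
        (user_role(reg, actor) == "local_admin" &&
         actor %in% reg$centers[[center_id]]$local_admins)))
    fv_stop("fv_authorization",
            sprintf("user '%s' may not register samples at center '%s'", actor, center_id))
  row <- as.list(manifest_row)
  for (f in MANIFEST_COLS) {
    v <- row[[f]]
    if (is.null(v) || is.na(v) || !nzchar(as.character(v)))
      fv_stop("fv_validation", sprintf("missing compulsory field '%s'", pretty_field(f)),
              field = pretty_field(f))
  }
  if (!row$SampleType %in% SAMPLE_TYPES)
    fv_stop("fv_validation", sprintf("Sample Type must be one of %s",
                                     paste(SAMPLE_TYPES, collapse = ", ")))
  local_name <- as.character(row$SampleLocalName)
  dup <- reg$samples$center_id == center_id & reg$samples$sample_local_name == local_name
  if (any(dup))
    fv_stop("fv_conflict", sprintf("sample '%s' already registered at center '%s'",
                                   local_name, center_id))
  reg$counters[[center_id]] <- reg$counters[[center_id]] + 1L
  sid <- make_pseudonym(center_id, reg$counters[[center_id]], reg$salt)
  rec <- data.frame(
    system_sample_id = sid, sample_local_name = local_name,
    pi_name = as.character(row$PIName), sample_type = as.character(row$SampleType),
    reference_build = as.character(row$SampleReferenceVersion),
    center_id = center_id,
    data_path = as.character(row$DataPath %||% NA_character_),
    stringsAsFactors = FALSE
  )
  reg$samples <- rbind(reg$samples, rec)
  # implicit per-PI dataset: a PI's samples are collected there on registration
  pi_ds <- paste0("pi::", rec$pi_name)
  if (!pi_ds %in% names(reg$datasets)) {
    if (!rec$pi_name %in% names(reg$users)) add_user(reg, rec$pi_name, "pi", center_id, actor)
    create_dataset(reg, pi_ds, name = paste("Samples of", rec$pi_name),
                   owner_user_id = rec$pi_name, actor = actor)
  }
  reg$datasets[[pi_ds]]$member_sample_ids <-
    union(reg$datasets[[pi_ds]]$member_sample_ids, sid)
  audit_append(reg, actor, "register_sample", list(center_id = center_id, sid = sid))
  rec
}

pretty_field <- function(f) {
  switch(f,
    SampleLocalName = "Sample Local Name", PIName = "PI Name",
    SampleType = "Sample Type", SampleReferenceVersion = "Sample Reference Version", f)
}

#' Register all samples from a manifest file
#'
#' The manifest dialect is a header-bearing TSV with columns
#' `SampleLocalName`, `PIName`, `SampleType`, `SampleReferenceVersion`,
#' `DataPath`; extra columns are preserved but ignored.
#'
#' @inheritParams register_sample
#' @param path manifest TSV path.
#' @return data.frame of the stored sample records.
#' @export
register_manifest <- function(reg, center_id, path, actor = "system_admin") {
  man <- read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(MANIFEST_COLS, names(man))
  if (length(missing_cols))
    fv_stop("fv_validation", sprintf("manifest lacks column(s): %s",
                                     paste(missing_cols, collapse = ", ")))
  recs <- lapply(seq_len(nrow(man)), function(i)
    register_sample(reg, center_id, man[i, , drop = FALSE], actor = actor))
  do.call(rbind, c(recs, list(make.row.names = FALSE)))
}

#' Create a dataset
#'
#' Datasets group samples for activation and sharing. They are `private`
#' (accessible only to users the owner grants) or `public` (accessible to
#' every user). Control cohorts — unaffected, unrelated individuals used as a
#' frequency reference — are flagged with `is_control`.
#'
#' @param reg registry.
#' @param dataset_id token; must be unique.
#' @param name display name.
#' @param owner_user_id owning user.
#' @param visibility `"private"` or `"public"`.
#' @param member_sample_ids system sample ids; must exist.
#' @param is_control logical.
#' @param actor acting user.
#' @return the registry, invisibly.
#' @export
create_dataset <- function(reg, dataset_id, name = dataset_id, owner_user_id,
                           visibility = c("private", "public"),
                           member_sample_ids = character(), is_control = FALSE,
                           actor = owner_user_id) {
  stopifnot(inherits(reg, "fv_registry"), is_scalar_chr(dataset_id))
  visibility <- match.arg(visibility)
  if (dataset_id %in% names(reg$datasets))
    fv_stop("fv_conflict", sprintf("dataset '%s' already exists", dataset_id))
  unknown <- setdiff(member_sample_ids, reg$samples$system_sample_id)
  if (length(unknown))
    fv_stop("fv_lookup", sprintf("unknown sample id(s): %s", paste(unknown, collapse = ", ")))
  reg$datasets[[dataset_id]] <- list(
    dataset_id = dataset_id, name = name, owner_user_id = owner_user_id,
    visibility = visibility, member_sample_ids = unique(member_sample_ids),
    is_control = isTRUE(is_control)
  )
  if (owner_user_id %in% names(reg$users)) {
    reg$users[[owner_user_id]]$accessible_dataset_ids <-
      union(reg$users[[owner_user_id]]$accessible_dataset_ids, dataset_id)
  }
  audit_append(reg, actor, "create_dataset", list(dataset_id = dataset_id))
  invisible(reg)
}

#' Add samples to a dataset
#'
#' The actor must own the dataset and must own (be PI of) or have been granted
#' each sample.
#'
#' @param reg registry.
#' @param dataset_id dataset.
#' @param sample_ids system sample ids.
#' @param actor acting user.
#' @return the registry, invisibly.
#' @export
add_to_dataset <- function(reg, dataset_id, sample_ids, actor) {
  ds <- reg$datasets[[dataset_id]]
  if (is.null(ds)) fv_stop("fv_lookup", sprintf("unknown dataset '%s'", dataset_id))
  if (!identical(ds$owner_user_id, actor) && user_role(reg, actor) != "system_admin")
    fv_stop("fv_authorization", sprintf("user '%s' does not own dataset '%s'", actor, dataset_id))
  for (sid in sample_ids) {
    s <- reg$samples[reg$samples$system_sample_id == sid, ]
    if (nrow(s) == 0L) fv_stop("fv_lookup", sprintf("unknown sample id '%s'", sid))
    granted <- any(reg$grants$user_id == actor & reg$grants$system_sample_id == sid)
    if (!identical(s$pi_name, actor) && !granted && user_role(reg, actor) != "system_admin")
      fv_stop("fv_authorization",
              sprintf("user '%s' has no access grant for sample '%s'", actor, sid))
  }
  reg$datasets[[dataset_id]]$member_sample_ids <-
    union(ds$member_sample_ids, sample_ids)
  audit_append(reg, actor, "add_to_dataset",
               list(dataset_id = dataset_id, n = length(sample_ids)))
  invisible(reg)
}

#' Grant a user access to a dataset
#'
#' @param reg registry.
#' @param user_id receiving user.
#' @param dataset_id dataset; the actor must own it (or be system admin).
#' @param actor acting user.
#' @return the registry, invisibly.
#' @export
grant_dataset <- function(reg, user_id, dataset_id, actor) {
  ds <- reg$datasets[[dataset_id]]
  if (is.null(ds)) fv_stop("fv_lookup", sprintf("unknown dataset '%s'", dataset_id))
  if (!user_id %in% names(reg$users))
    fv_stop("fv_lookup", sprintf("unknown user '%s'", user_id))
  if (!identical(ds$owner_user_id, actor) && user_role(reg, actor) != "system_admin")
    fv_stop("fv_authorization", sprintf("user '%s' does not own dataset '%s'", actor, dataset_id))
  reg$users[[user_id]]$accessible_dataset_ids <-
    union(reg$users[[user_id]]$accessible_dataset_ids, dataset_id)
  audit_append(reg, actor, "grant_dataset", list(user_id = user_id, dataset_id = dataset_id))
  invisible(reg)
}

accessible_datasets <- function(reg, user_id) {
  u <- reg$users[[user_id]]
  if (is.null(u)) fv_stop("fv_lookup", sprintf("unknown user '%s'", user_id))
  public <- names(Filter(function(d) d$visibility == "public", reg$datasets))
  union(u$accessible_dataset_ids, public)
}

#' Activate a dataset for a user
#'
#' Dataset activation gates the detail tier of query results: only samples in
#' the currently active dataset are shown in full. A user has at most one
#' active dataset at a time; activating replaces any previous activation.
#' With no active dataset, detail views are empty and only summary statistics
#' are returned.
#'
#' @param reg registry.
#' @param user_id user.
#' @param dataset_id dataset to activate; must be accessible to the user.
#'   `NULL` deactivates.
#' @return the updated user record, invisibly.
#' @export
activate_dataset <- function(reg, user_id, dataset_id) {
  u <- reg$users[[user_id]]
  if (is.null(u)) fv_stop("fv_lookup", sprintf("unknown user '%s'", user_id))
  if (!is.null(dataset_id)) {
    if (!dataset_id %in% accessible_datasets(reg, user_id))
      fv_stop("fv_authorization",
              sprintf("dataset '%s' is not accessible to user '%s'", dataset_id, user_id))
  }
  reg$users[[user_id]]$active_dataset_id <- dataset_id
  audit_append(reg, user_id, "activate_dataset", list(dataset_id = dataset_id %||% "<none>"))
  invisible(reg$users[[user_id]])
}

#' Access tier of a user for a sample
#'
#' `"detailed"` iff the sample is a member of the user's currently active
#' dataset; otherwise `"summary_only"` — the user then sees only aggregate
#' statistics plus the sample's pseudonym, center, and PI as a backlink.
#' Pure: no state change.
#'
#' @param reg registry.
#' @param user_id user.
#' @param system_sample_id sample.
#' @return `"detailed"` or `"summary_only"`.
#' @export
check_access <- function(reg, user_id, system_sample_id) {
  u <- reg$users[[user_id]]
  if (is.null(u)) fv_stop("fv_lookup", sprintf("unknown user '%s'", user_id))
  if (!system_sample_id %in% reg$samples$system_sample_id)
    fv_stop("fv_lookup", sprintf("unknown sample id '%s'", system_sample_id))
  ad <- u$active_dataset_id
  if (!is.null(ad) && system_sample_id %in% reg$datasets[[ad]]$member_sample_ids)
    "detailed" else "summary_only"
}

#' Request access to another group's sample
#'
#' The request is visible to the sample's PI, who must review and grant or
#' deny it. All transitions are audited. A duplicate pending request is an
#' idempotent no-op (the existing request is returned).
#'
#' @param reg registry.
#' @param user_id requesting user; must not be the sample's PI.
#' @param system_sample_id sample.
#' @return the access request record (list with `request_id`, `status`, ...).
#' @export
request_access <- function(reg, user_id, system_sample_id) {
  s <- reg$samples[reg$samples$system_sample_id == system_sample_id, ]
  if (nrow(s) == 0L) fv_stop("fv_lookup", sprintf("unknown sample id '%s'", system_sample_id))
  if (!user_id %in% names(reg$users))
    fv_stop("fv_lookup", sprintf("unknown user '%s'", user_id))
  if (identical(s$pi_name, user_id))
    fv_stop("fv_validation", "requester already owns this sample")
  existing <- Filter(function(r) r$requester_user_id == user_id &&
                       r$system_sample_id == system_sample_id &&
                       r$status == "pending", reg$access_requests)
  if (length(existing)) return(existing[[1L]])
  rid <- sprintf("AR-%04d", length(reg$access_requests) + 1L)
  req <- list(request_id = rid, requester_user_id = user_id,
              system_sample_id = system_sample_id, owner = s$pi_name,
              status = "pending", created_at = as.character(Sys.time()),
              resolved_at = NA_character_)
  reg$access_requests[[rid]] <- req
  audit_append(reg, user_id, "request_access", list(request_id = rid, sid = system_sample_id))
  req
}

#' Grant or deny a pending access request
#'
#' Only the sample's owner (its PI) or a system admin may resolve a request.
#' On grant, the sample becomes assignable to the requester's datasets.
#'
#' @param reg registry.
#' @param request_id request id.
#' @param actor resolving user.
#' @return the updated request record.
#' @export
grant_access <- function(reg, request_id, actor) {
  resolve_access(reg, request_id, actor, "granted")
}

#' @rdname grant_access
#' @export
deny_access <- function(reg, request_id, actor) {
  resolve_access(reg, request_id, actor, "denied")
}

resolve_access <- function(reg, request_id, actor, status) {
  req <- reg$access_requests[[request_id]]
  if (is.null(req)) fv_stop("fv_lookup", sprintf("unknown access request '%s'", request_id))
  if (!identical(req$owner, actor) && user_role(reg, actor) != "system_admin")
    fv_stop("fv_authorization", sprintf("user '%s' may not resolve request '%s'", actor, request_id))
  if (req$status != "pending")
    fv_stop("fv_validation", sprintf("request '%s' already %s", request_id, req$status))
  req$status <- status
  req$resolved_at <- as.character(Sys.time())
  reg$access_requests[[request_id]] <- req
  if (status == "granted") {
    reg$grants <- rbind(reg$grants, data.frame(
      user_id = req$requester_user_id, system_sample_id = req$system_sample_id,
      stringsAsFactors = FALSE))
  }
  audit_append(reg, actor, paste0("access_", status), list(request_id = request_id))
  req
}

#' Look up registered samples
#'
#' @param reg registry.
#' @param center_id optional filter.
#' @return data.frame of sample records.
#' @export
registry_samples <- function(reg, center_id = NULL) {
  s <- reg$samples
  if (!is.null(center_id)) s <- s[s$center_id == center_id, , drop = FALSE]
  s
}

#' Persist / restore a registry as JSON
#'
#' Plain-text persistence for desk-scale deployments; the audit log travels
#' with the registry.
#'
#' @param reg registry.
#' @param path file path.
#' @return `save_registry`: the path, invisibly. `load_registry`: a registry.
#' @export
save_registry <- function(reg, path) {
  obj <- list(
    salt = reg$salt, centers = reg$centers, users = reg$users,
    samples = reg$samples, datasets = reg$datasets,
    counters = reg$counters, access_requests = reg$access_requests,
    grants = reg$grants, audit = reg$audit
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, null = "null", na = "null",
                       digits = NA)
  invisible(path)
}

#' @rdname save_registry
#' @export
load_registry <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  reg <- new_registry(salt = obj$salt)
  reg$centers <- lapply(obj$centers, function(cc) {
    cc$local_admins <- unlist(cc$local_admins); cc
  })
  reg$users <- lapply(obj$users, function(u) {
    u$accessible_dataset_ids <- as.character(unlist(u$accessible_dataset_ids))
    u$active_dataset_id <- u$active_dataset_id %||% NULL
    u
  })
  reg$samples <- list_of_rows_to_df(obj$samples, empty = new_registry()$samples)
  reg$datasets <- lapply(obj$datasets, function(d) {
    d$member_sample_ids <- as.character(unlist(d$member_sample_ids)); d
  })
  reg$counters <- lapply(obj$counters, as.integer)
  reg$access_requests <- obj$access_requests
  reg$grants <- list_of_rows_to_df(obj$grants, empty = new_registry()$grants)
  reg$audit <- obj$audit
  reg
}

list_of_rows_to_df <- function(x, empty) {
  if (length(x) == 0L) return(empty)
  out <- do.call(rbind, c(lapply(x, function(r) {
    r[vapply(r, is.null, logical(1))] <- NA
    as.data.frame(r, stringsAsFactors = FALSE)
  }), list(make.row.names = FALSE)))
  for (nm in intersect(names(empty), names(out))) {  # all-NA columns lose type in JSON
    out[[nm]] <- switch(class(empty[[nm]])[1],
                        character = as.character(out[[nm]]),
                        integer = as.integer(out[[nm]]),
                        numeric = as.numeric(out[[nm]]),
                        out[[nm]])
  }
  out
}
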