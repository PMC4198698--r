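# Coordinate liftover between genome builds via UCSC chain files, so that
# records from samples aligned to different builds aggregate on one target
# build.
#
# Chain-file semantics follow the UCSC specification: coordinates in the
# file are 0-based half-open; in a "<from>To<to>" chain the *target* (t)
# side is the source build and the *query* (q) side is the destination
# build; tStrand is always '+', qStrand may be '-' with coordinates given on
# the reversed strand. Only this reader speaks 0-based: every public API in
# the package is 1-based inclusive.

#' Parse a UCSC chain file into a liftover map
#'
#' All aligned segments are materialized into a per-chromosome, sorted,
#' binary-searchable block table. Malformed lines are rejected with their
#' line numbers; inconsistent block arithmetic (chain ends not matching the
#' header) is a parse error.
#'
#' @param chain chain-file path, or the chain text itself (character vector
#'   of lines or a single string with newlines).
#' @param from_build,to_build build labels stored on the map (for
#'   bookkeeping; the chain itself is authoritative for coordinates).
#' @return object of class `fv_liftover_map`.
#' @export
load_chain <- function(chain, from_build = "source", to_build = "target") {
  lines <- if (length(chain) == 1L && file.exists(chain)) readLines(chain)
           else unlist(strsplit(chain, "\n", fixed = TRUE))
  blocks <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    line <- trimws(lines[i])
    if (!nzchar(line)) { i <- i + 1L; next }
    if (!startsWith(line, "chain"))
      fv_stop("fv_parse", sprintf("chain parse error at line %d: expected 'chain' header", i))
    hdr <- strsplit(line, "\\s+")[[1L]]
    if (length(hdr) < 12L)
      fv_stop("fv_parse", sprintf("chain parse error at line %d: truncated header", i))
    t_chrom <- hdr[3L]; t_size <- as.numeric(hdr[4L])
    t_start <- as.numeric(hdr[6L]); t_end <- as.numeric(hdr[7L])
    q_chrom <- hdr[8L]; q_size <- as.numeric(hdr[9L])
    q_strand <- hdr[10L]
    q_start <- as.numeric(hdr[11L]); q_end <- as.numeric(hdr[12L])
    if (hdr[5L] != "+")
      fv_stop("fv_parse", sprintf("chain parse error at line %d: tStrand must be '+'", i))
    if (anyNA(c(t_size, t_start, t_end, q_size, q_start, q_end)))
      fv_stop("fv_parse", sprintf("chain parse error at line %d: non-numeric field", i))
    t_pos <- t_start; q_pos <- q_start
    i <- i + 1L
    repeat {
      if (i > n) fv_stop("fv_parse", sprintf("chain parse error at line %d: unterminated chain", i))
      row <- trimws(lines[i])
      if (!nzchar(row)) fv_stop("fv_parse", sprintf("chain parse error at line %d: blank line inside chain", i))
      f <- suppressWarnings(as.numeric(strsplit(row, "\\s+")[[1L]]))
      if (anyNA(f) || !length(f) %in% c(1L, 3L))
        fv_stop("fv_parse", sprintf("chain parse error at line %d: expected 'size [dt dq]'", i))
      size <- f[1L]
      blocks[[length(blocks) + 1L]] <- data.frame(
        s_chrom = t_chrom, s_start = t_pos, s_end = t_pos + size,
        q_chrom = q_chrom, q_start = q_pos, q_end = q_pos + size,
        q_strand = q_strand, q_size = q_size, stringsAsFactors = FALSE)
      t_pos <- t_pos + size; q_pos <- q_pos + size
      i <- i + 1L
      if (length(f) == 1L) break
      t_pos <- t_pos + f[2L]; q_pos <- q_pos + f[3L]
    }
    if (t_pos != t_end || q_pos != q_end)
      fv_stop("fv_parse", sprintf(
        "chain parse error before line %d: block arithmetic inconsistent (t %g!=%g or q %g!=%g)",
        i, t_pos, t_end, q_pos, q_end))
  }
  tab <- if (length(blocks)) do.call(rbind, blocks) else
    data.frame(s_chrom = character(), s_start = numeric(), s_end = numeric(),
               q_chrom = character(), q_start = numeric(), q_end = numeric(),
               q_strand = character(), q_size = numeric(), stringsAsFactors = FALSE)
  by_chrom <- split(tab, tab$s_chrom)
  by_chrom <- lapply(by_chrom, function(d) {
    d <- d[order(d$s_start), , drop = FALSE]; rownames(d) <- NULL; d
  })
  structure(list(from_build = from_build, to_build = to_build, blocks = by_chrom),
            class = "fv_liftover_map")
}

#' @export
print.fv_liftover_map <- function(x, ...) {
  cat(sprintf("<fv_liftover_map %s -> %s: %d block(s) on %d chrom(s)>\n",
              x$from_build, x$to_build,
              sum(vapply(x$blocks, nrow, integer(1))), length(x$blocks)))
  invisible(x)
}

#' Lift one position between builds
#'
#' Public coordinates are 1-based inclusive; conversion to the chain's
#' 0-based frame happens internally. Positions falling in a gap between
#' aligned segments are UNMAPPED (`reason = "gap"`); chromosomes absent from
#' the chain are UNMAPPED (`reason = "chrom_absent"`). Minus-strand segments
#' reverse position within the block.
#'
#' @param map an `fv_liftover_map`.
#' @param chrom,pos source position (1-based).
#' @return list with `mapped` (logical), `chrom`, `pos` (1-based; NA when
#'   unmapped), `reason` (`""`, `"gap"`, or `"chrom_absent"`).
#' @export
lift_position <- function(map, chrom, pos) {
  stopifnot(inherits(map, "fv_liftover_map"))
  d <- map$blocks[[chrom]]
  if (is.null(d))
    return(list(mapped = FALSE, chrom = NA_character_, pos = NA_integer_,
                reason = "chrom_absent"))
  p0 <- pos - 1                         # to 0-based
  k <- findInterval(p0, d$s_start)      # last block starting at or before p0
  if (k == 0L || p0 >= d$s_end[k])
    return(list(mapped = FALSE, chrom = NA_character_, pos = NA_integer_,
                reason = "gap"))
  off <- p0 - d$s_start[k]
  q0 <- d$q_start[k] + off
  if (d$q_strand[k] == "-") q0 <- d$q_size[k] - 1 - q0
  list(mapped = TRUE, chrom = d$q_chrom[k], pos = as.integer(q0 + 1), reason = "")
}

#' Invert a liftover map
#'
#' Swaps source and destination so that positions can be translated in the
#' opposite direction (used by the coordinator to express a query in each
#' center's native build). Only plus-strand chains are invertible here;
#' minus-strand blocks raise a configuration error.
#'
#' @param map an `fv_liftover_map`.
#' @return an `fv_liftover_map` mapping `to_build -> from_build`.
#' @export
invert_map <- function(map) {
  stopifnot(inherits(map, "fv_liftover_map"))
  tab <- do.call(rbind, unname(map$blocks))
  if (nrow(tab) > 0L && any(tab$q_strand != "+"))
    fv_stop("fv_configuration", "cannot invert a chain with minus-strand blocks")
  inv <- data.frame(
    s_chrom = tab$q_chrom, s_start = tab$q_start, s_end = tab$q_end,
    q_chrom = tab$s_chrom, q_start = tab$s_start, q_end = tab$s_end,
    q_strand = "+", q_size = NA_real_, stringsAsFactors = FALSE)
  by_chrom <- split(inv, inv$s_chrom)
  by_chrom <- lapply(by_chrom, function(d) {
    d <- d[order(d$s_start), , drop = FALSE]; rownames(d) <- NULL; d
  })
  structure(list(from_build = map$to_build, to_build = map$from_build,
                 blocks = by_chrom), class = "fv_liftover_map")
}

#' Harmonize site records onto one target build
#'
#' Records whose `source_build` already equals the target pass through
#' unchanged. Others are lifted through the map for their build pair;
#' positions that do not map are routed to a drop report (never silently
#' lost), so `nrow(records) == nrow(kept) + nrow(dropped)` always. Genotype
#' fields are untouched; the original build stays in `source_build`.
#'
#' @param records SiteRecord data.frame.
#' @param target_build build label to harmonize onto.
#' @param maps named list of `fv_liftover_map`s keyed `"<from>-><to>"` (e.g.
#'   `"hg38->hg19"`).
#' @return list with `records` (harmonized) and `dropped` (data.frame chrom,
#'   pos, system_sample_id, reason).
#' @export
harmonize_records <- function(records, target_build, maps = list()) {
  dropped <- data.frame(chrom = character(), pos = integer(),
                        system_sample_id = character(), reason = character(),
                        stringsAsFactors = FALSE)
  if (nrow(records) == 0L) return(list(records = records, dropped = dropped))
  keep <- logical(nrow(records))
  for (i in seq_len(nrow(records))) {
    b <- records$source_build[i]
    if (is.na(b) || identical(b, target_build)) { keep[i] <- TRUE; next }
    key <- paste0(b, "->", target_build)
    map <- maps[[key]]
    if (is.null(map))
      fv_stop("fv_configuration",
              sprintf("no liftover map configured for build pair '%s'", key))
    lifted <- lift_position(map, records$chrom[i], records$pos[i])
    if (!lifted$mapped) {
      dropped <- rbind(dropped, data.frame(
        chrom = records$chrom[i], pos = records$pos[i],
        system_sample_id = records$system_sample_id[i], reason = lifted$reason,
        stringsAsFactors = FALSE))
      next
    }
    records$chrom[i] <- lifted$chrom
    records$pos[i] <- lifted$pos
    keep[i] <- TRUE
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(records = out, dropped = dropped)
}

#' @rdname harmonize_records
#' @param record a one-row SiteRecord data.frame.
#' @return `harmonize_record`: the lifted one-row record, or `NULL` with the
#'   drop reason in attribute `"dropped"`.
#' @export
harmonize_record <- function(record, target_build, maps = list()) {
  res <- harmonize_records(record, target_build, maps)
  if (nrow(res$records) == 1L) return(res$records)
  structure(NULL, dropped = res$dropped)
}

#' Write a liftover drop report
#'
#' @param dropped drop data.frame from [harmonize_records()].
#' @param path TSV output path.
#' @return the path, invisibly.
#' @export
write_drop_report <- function(dropped, path) {
  write.table(dropped, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
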