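# Synthetic federation fixtures: cohorts with planted genotypes, pileups
# with a controlled per-base error rate, manifests, reference tables, gene
# tables, chain files, and complete multi-center deployments. Everything is
# deterministic from (seed, parameters), so every other module is testable
# fully offline and planted truth is exactly recoverable.
#
# Population model: unplanted genotypes are drawn under Hardy-Weinberg
# equilibrium (genotype ~ Binomial(2, allele frequency)) — the simplest
# defensible model for independent, unrelated samples. Read depth is
# Poisson around the requested mean (overridable to a fixed depth for exact
# tests); each read draws one of the sample's two alleles uniformly and is
# corrupted to a uniformly chosen other base with the stated per-base error
# probability; base qualities encode that error rate on the phred scale
# (capped at Q60 for error rate 0).

#' Simulate a cohort's genotype truth table
#'
#' @param n_samples number of samples.
#' @param sites data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `freq` (alternate-allele frequency in [0,1]); optional `id` (dbSNP-style
#'   annotation).
#' @param seed RNG seed; the table is fully reproducible from it.
#' @param plant_overrides optional data.frame (`sample`, `site`, `gt`):
#'   sample index (or name), site index, and genotype in {0,1,2} (alternate
#'   allele count), taking precedence over sampling.
#' @return list of class `fv_truth`: `sites`, `genotypes` (samples x sites
#'   integer matrix, values 0/1/2), `sample_names`, `seed`.
#' @export
simulate_cohort <- function(n_samples, sites, seed = 1L, plant_overrides = NULL) {
  stopifnot(n_samples >= 1, all(sites$freq >= 0), all(sites$freq <= 1))
  set.seed(seed)
  g <- vapply(sites$freq, function(f) rbinom(n_samples, 2L, f), integer(n_samples))
  g <- matrix(as.integer(g), nrow = n_samples, ncol = nrow(sites))
  sample_names <- sprintf("SAMPLE_%04d", seq_len(n_samples))
  rownames(g) <- sample_names
  colnames(g) <- sprintf("%s:%d", sites$chrom, sites$pos)
  if (!is.null(plant_overrides)) {
    for (i in seq_len(nrow(plant_overrides))) {
      s <- plant_overrides$sample[i]
      si <- if (is.character(s)) match(s, sample_names) else as.integer(s)
      k <- as.integer(plant_overrides$site[i])
      if (is.na(si) || si < 1L || si > n_samples || k < 1L || k > nrow(sites))
        fv_stop("fv_validation",
                sprintf("plant override %d references unknown sample/site", i))
      g[si, k] <- as.integer(plant_overrides$gt[i])
    }
  }
  structure(list(sites = sites, genotypes = g, sample_names = sample_names,
                 seed = seed), class = "fv_truth")
}

#' @export
print.fv_truth <- function(x, ...) {
  cat(sprintf("<fv_truth> %d sample(s) x %d site(s), seed %d\n",
              nrow(x$genotypes), nrow(x$sites), x$seed))
  invisible(x)
}

qual_for_error <- function(base_error_rate) {
  if (base_error_rate <= 0) 60L else as.integer(round(-10 * log10(base_error_rate)))
}

#' Simulate per-sample pileup fixtures from a truth table
#'
#' Writes one pileup TSV per sample (the dialect consumed by
#' [alignment_source()]) into `dir`. Deterministic: sample i is generated
#' under seed `seed + i`.
#'
#' @param truth an `fv_truth`.
#' @param dir output directory (created if needed).
#' @param mean_depth mean read depth (> 0).
#' @param base_error_rate per-base error probability in [0, 0.5).
#' @param seed base RNG seed.
#' @param depth_model `"poisson"` (default) or `"fixed"` (exactly
#'   `mean_depth` reads everywhere, for exact tests).
#' @return named character vector of file paths (by sample name).
#' @export
simulate_pileups <- function(truth, dir, mean_depth = 20, base_error_rate = 0.001,
                             seed = 1L, depth_model = c("poisson", "fixed")) {
  depth_model <- match.arg(depth_model)
  stopifnot(mean_depth > 0, base_error_rate >= 0, base_error_rate < 0.5)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  q <- qual_for_error(base_error_rate)
  sites <- truth$sites
  other <- list(A = c("C","G","T"), C = c("A","G","T"),
                G = c("A","C","T"), T = c("A","C","G"))
  paths <- setNames(character(nrow(truth$genotypes)), truth$sample_names)
  for (i in seq_len(nrow(truth$genotypes))) {
    set.seed(seed + i)
    rows <- character(nrow(sites))
    for (k in seq_len(nrow(sites))) {
      d <- if (depth_model == "poisson") rpois(1L, mean_depth) else as.integer(mean_depth)
      gt <- truth$genotypes[i, k]
      alleles <- c(rep(sites$ref[k], 2L - gt), rep(sites$alt[k], gt))
      bases <- if (d > 0L) sample(alleles, d, replace = TRUE) else character()
      if (d > 0L && base_error_rate > 0) {
        err <- runif(d) < base_error_rate
        if (any(err))
          bases[err] <- vapply(bases[err], function(b)
            sample(other[[b]], 1L), character(1))
      }
      rows[k] <- paste(sites$chrom[k], sites$pos[k], sites$ref[k],
                       paste(bases, collapse = ""),
                       paste(rep(q, d), collapse = ","), sep = "\t")
    }
    paths[i] <- file.path(dir, paste0(truth$sample_names[i], ".pileup.tsv"))
    writeLines(c("chrom\tpos\tref\tbases\tquals", rows), paths[i])
  }
  paths
}

#' Write a reference lookup table for a truth table's sites
#'
#' @param truth an `fv_truth`.
#' @param path TSV output path.
#' @return the path, invisibly.
#' @export
write_reference_table <- function(truth, path) {
  write.table(truth$sites[, c("chrom", "pos", "ref")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Generate a simple offset chain fixture between two builds
#'
#' One chain per chromosome: positions below `insert_at` map unchanged;
#' positions at or above it map shifted by `offset` (a target-side
#' insertion/deletion), leaving the bases in `gap_width` source positions
#' before `insert_at` unmapped when `gap_width > 0`. Useful as a
#' hand-checkable liftover fixture; `invert = TRUE` writes the exact inverse
#' chain for round-trip tests.
#'
#' @param chroms chromosome names.
#' @param length_bp source extent covered per chromosome.
#' @param insert_at 0-based source position where the offset starts.
#' @param offset signed shift applied from `insert_at` on.
#' @param gap_width source bases immediately before `insert_at` that map
#'   nowhere.
#' @param invert write the inverse mapping instead.
#' @return character vector of chain-file lines.
#' @export
make_offset_chain <- function(chroms, length_bp = 10000, insert_at = 500,
                              offset = 10, gap_width = 0, invert = FALSE) {
  stopifnot(insert_at > gap_width, insert_at < length_bp)
  lines <- character()
  id <- 0L
  for (ch in chroms) {
    id <- id + 1L
    seg1 <- insert_at - gap_width            # [0, seg1) maps identity
    seg2 <- length_bp - insert_at            # [insert_at, length) maps +offset
    if (!invert) {
      t_size <- length_bp; q_size <- length_bp + offset
      dt <- gap_width; dq <- gap_width + offset
    } else {
      t_size <- length_bp + offset; q_size <- length_bp
      dt <- gap_width + offset; dq <- gap_width
    }
    t_end <- seg1 + dt + seg2; q_end <- seg1 + dq + seg2
    lines <- c(lines,
      sprintf("chain 1000 %s %d + 0 %d %s %d + 0 %d %d",
              ch, t_size, t_end, ch, q_size, q_end, id),
      sprintf("%d %d %d", seg1, dt, dq),
      sprintf("%d", seg2),
      "")
  }
  lines
}

#' Materialize a multi-center federation deployment
#'
#' Builds a complete runnable deployment under `dir`: a registry with one
#' center per split group (each with a local admin), per-center manifests
#' (TSV) and pileup data roots, a shared reference table, optional gene
#' table (BED) and chain file, and a deployment config (JSON). Samples at a
#' center are tagged with that center's genome build; when builds differ,
#' `chain_lines` must map the non-target builds onto the first center's
#' build, and the generated coordinates of non-target-build centers are
#' shifted accordingly so that lifting returns them to the planted
#' positions.
#'
#' @param truth an `fv_truth`.
#' @param dir deployment directory.
#' @param n_centers number of centers.
#' @param split integer vector assigning every sample to a center in
#'   `1..n_centers`; default round-robin. Orphan or out-of-range assignments
#'   are an error.
#' @param builds character vector of per-center build labels (recycled);
#'   default all `"hg19"`.
#' @param chain_lines optional chain text (e.g. from [make_offset_chain()])
#'   mapping `builds[i] -> builds[1]` for every non-target build; the same
#'   `chain_offset` must describe its shift.
#' @param chain_offset integer coordinate shift of the non-target build
#'   relative to the target build (matches the chain).
#' @param mean_depth,base_error_rate,depth_model passed to
#'   [simulate_pileups()].
#' @param pi_names PI display names (recycled over centers).
#' @param seed base seed.
#' @return an `fv_deployment` wired to the generated files; the registry
#'   contains one researcher user `"user1"` (no active dataset).
#' @export
build_federation <- function(truth, dir, n_centers = 2, split = NULL,
                             builds = "hg19", chain_lines = NULL,
                             chain_offset = 0, mean_depth = 20,
                             base_error_rate = 0.001,
                             depth_model = "poisson",
                             pi_names = c("PI_A", "PI_B", "PI_C"), seed = 1L) {
  n <- nrow(truth$genotypes)
  split <- split %||% (((seq_len(n) - 1L) %% n_centers) + 1L)
  if (length(split) != n || anyNA(split) || any(split < 1L | split > n_centers))
    fv_stop("fv_validation", "split must assign every sample to a center in 1..n_centers")
  builds <- rep_len(builds, n_centers)
  pi_names <- rep_len(pi_names, n_centers)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  reg <- new_registry(salt = paste0("salt-", truth$seed))
  add_user(reg, "sysadmin", "system_admin")
  target_build <- builds[1L]
  ref_path <- file.path(dir, "reference.tsv")
  write_reference_table(truth, ref_path)

  centers <- list()
  for (ci in seq_len(n_centers)) {
    cid <- sprintf("C%d", ci)
    croot <- file.path(dir, cid)
    add_center(reg, cid, name = sprintf("Center %d", ci),
               local_admins = sprintf("admin_%s", cid),
               data_root = croot, build_default = builds[ci])
    idx <- which(split == ci)
    sub <- structure(list(
      sites = truth$sites, genotypes = truth$genotypes[idx, , drop = FALSE],
      sample_names = truth$sample_names[idx], seed = truth$seed),
      class = "fv_truth")
    # a center on another build stores its pileups in that build's frame
    local_ref <- ref_path
    if (builds[ci] != target_build) {
      sub$sites$pos <- sub$sites$pos + chain_offset
      local_ref <- file.path(croot, "reference.tsv")
      dir.create(croot, recursive = TRUE, showWarnings = FALSE)
      write_reference_table(sub, local_ref)
    }
    paths <- simulate_pileups(sub, croot, mean_depth = mean_depth,
                              base_error_rate = base_error_rate,
                              seed = seed + ci * 10000L,
                              depth_model = depth_model)
    man <- data.frame(
      SampleLocalName = sub$sample_names, PIName = pi_names[ci],
      SampleType = "Research", SampleReferenceVersion = builds[ci],
      DataPath = unname(paths), stringsAsFactors = FALSE)
    man_path <- file.path(dir, sprintf("manifest_%s.tsv", cid))
    write.table(man, man_path, sep = "\t", quote = FALSE, row.names = FALSE)
    register_manifest(reg, cid, man_path, actor = sprintf("admin_%s", cid))
    dbsnp <- NULL
    if ("id" %in% names(truth$sites)) {
      dbsnp <- data.frame(chrom = sub$sites$chrom, pos = sub$sites$pos,
                          id = truth$sites$id, stringsAsFactors = FALSE)
    }
    centers[[cid]] <- list(center_id = cid, data_root = croot,
                           reference = local_ref, dbsnp = dbsnp)
  }
  add_user(reg, "user1", "researcher")

  maps <- list()
  if (!is.null(chain_lines)) {
    chain_path <- file.path(dir, "liftover.chain")
    writeLines(chain_lines, chain_path)
    for (b in setdiff(unique(builds), target_build))
      maps[[paste0(b, "->", target_build)]] <-
        load_chain(chain_path, from_build = b, to_build = target_build)
  }
  gene_path <- file.path(dir, "genes.bed")
  gene_table <- NULL
  if (nrow(truth$sites) > 0L) {
    span <- stats::aggregate(pos ~ chrom, truth$sites, range)
    bed <- data.frame(chrom = span$chrom,
                      start = pmax(span$pos[, 1] - 51L, 0L),
                      end = span$pos[, 2] + 50L,
                      name = paste0("GENE_", span$chrom))
    write.table(bed, gene_path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    gene_table <- data.frame(gene = bed$name, chrom = bed$chrom,
                             start = bed$start + 1L, end = bed$end,
                             stringsAsFactors = FALSE)
  }
  config <- list(
    target_build = target_build,
    centers = lapply(centers, function(cc)
      list(center_id = cc$center_id, data_root = cc$data_root,
           reference = cc$reference)),
    genes = if (!is.null(gene_table)) gene_path else NULL,
    chains = if (!is.null(chain_lines))
      lapply(setdiff(unique(builds), target_build), function(b)
        list(path = file.path(dir, "liftover.chain"), from = b, to = target_build)),
    seed = seed)
  jsonlite::write_json(config, file.path(dir, "deployment.json"),
                       auto_unbox = TRUE, null = "null")
  save_registry(reg, file.path(dir, "registry.json"))
  dep <- new_deployment(reg, centers, gene_table = gene_table, maps = maps,
                        target_build = target_build)
  dep$truth <- truth
  dep$split <- split
  dep
}
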