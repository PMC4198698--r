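# Shared fixture builders and independent oracles. All fixtures are built in
# code at test time; nothing binary ships with the package.

# -- independent brute-force diploid caller ---------------------------------
# Enumerates the per-read product directly in linear space, no logs, no
# vectorization: deliberately a different computational path from the
# package's caller.
oracle_likelihoods <- function(bases, quals, ref, alt) {
  e <- 10^(-quals / 10)
  p_base <- function(b, a, e1) if (b == a) 1 - e1 else e1 / 3
  gts <- list(c(ref, ref), c(ref, alt), c(alt, alt))
  lik <- numeric(3)
  for (g in 1:3) {
    L <- 1
    for (j in seq_along(bases)) {
      L <- L * 0.5 * (p_base(bases[j], gts[[g]][1], e[j]) +
                      p_base(bases[j], gts[[g]][2], e[j]))
    }
    lik[g] <- L
  }
  log10(lik)
}

oracle_call <- function(bases, quals, ref, alt) {
  ll <- oracle_likelihoods(bases, quals, ref, alt)
  pl <- as.integer(round(-10 * (ll - max(ll))))
  best <- 1L
  for (g in 2:3) if (ll[g] > ll[best]) best <- g   # first max = ref-ward tie-break
  list(gt = c("0/0", "0/1", "1/1")[best], pl = pl, gq = min(99L, sort(pl)[2]))
}

random_column <- function(depth = sample(1:30, 1)) {
  ref <- sample(c("A", "C", "G", "T"), 1)
  alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
  other <- sample(setdiff(c("A", "C", "G", "T"), c(ref, alt)), 1)
  w <- runif(3); w <- w / sum(w)
  bases <- sample(c(ref, alt, other), depth, replace = TRUE, prob = w)
  quals <- sample(2:40, depth, replace = TRUE)
  list(ref = ref, alt = alt, bases = bases, quals = quals)
}

# -- pileup fixture writer ---------------------------------------------------
# rows: list of list(chrom, pos, ref, bases (chr vector), quals (int vector))
write_pileup_fixture <- function(rows, path = tempfile(fileext = ".tsv")) {
  lines <- vapply(rows, function(r) {
    paste(r$chrom, r$pos, r$ref, paste(r$bases, collapse = ""),
          paste(r$quals, collapse = ","), sep = "\t")
  }, character(1))
  writeLines(c("chrom\tpos\tref\tbases\tquals", lines), path)
  path
}

uniform_row <- function(chrom, pos, ref, base, depth, qual = 30L) {
  list(chrom = chrom, pos = pos, ref = ref,
       bases = rep(base, depth), quals = rep(qual, depth))
}

# -- small registry with two centers, three PIs ------------------------------
make_test_registry <- function(n_per_center = 3) {
  reg <- new_registry(salt = "test-salt")
  add_user(reg, "sysadmin", "system_admin")
  for (cid in c("C1", "C2")) {
    add_center(reg, cid, local_admins = paste0("adm_", cid))
    for (i in seq_len(n_per_center)) {
      register_sample(reg, cid, list(
        SampleLocalName = sprintf("%s-LOCAL-%03d", cid, i),
        PIName = if (cid == "C1") "PI_A" else "PI_B",
        SampleType = "Research", SampleReferenceVersion = "hg19"),
        actor = paste0("adm_", cid))
    }
  }
  add_user(reg, "user1", "researcher")
  reg
}

# records data.frame builder for aggregator-level tests
make_records <- function(gt, sid = sprintf("SID-%04d", seq_along(gt)),
                         center = "C1", chrom = "chr9", pos = 2115841L,
                         qual = 50, dp = 20L, gq = 99L,
                         pl = NULL, dbsnp = "rs0001", build = "hg19") {
  n <- length(gt)
  pls <- t(vapply(seq_len(n), function(i) {
    if (!is.null(pl)) return(as.integer(pl[[min(i, length(pl))]]))
    switch(gt[i],
      "0/0" = c(0L, 99L, 990L), "0/1" = c(99L, 0L, 99L),
      "1/1" = c(990L, 99L, 0L), c(NA_integer_, NA_integer_, NA_integer_))
  }, integer(3)))
  data.frame(
    chrom = chrom, pos = pos, dbsnp_id = dbsnp, ref = "G",
    alt = ifelse(gt %in% c("0/1", "1/1"), "A", "."),
    qual = rep_len(qual, n), filter = ".", gt = gt, dp = rep_len(dp, n),
    ad_ref = 10L, ad_alt = 10L, gq = rep_len(gq, n),
    pl_rr = pls[, 1], pl_ra = pls[, 2], pl_aa = pls[, 3],
    system_sample_id = sid, center_id = rep_len(center, n),
    source_build = build, caller = "builtin", stringsAsFactors = FALSE
  )
}

# default small sites table
test_sites <- function(n = 3, chrom = "chr9", start = 1000L, freq = 0.2) {
  data.frame(chrom = chrom, pos = start + (seq_len(n) - 1L) * 100L,
             ref = rep(c("G", "A", "C"), length.out = n),
             alt = rep(c("A", "T", "G"), length.out = n),
             freq = rep_len(freq, n),
             id = sprintf("rs%04d", seq_len(n)), stringsAsFactors = FALSE)
}
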