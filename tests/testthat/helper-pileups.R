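`%||%` <- function(a, b) if (is.null(a)) b else a

# small builders used across the test files

empty_counts <- function() {
  stats::setNames(rep(0L, 8),
                  c("A_fwd", "A_rev", "C_fwd", "C_rev",
                    "G_fwd", "G_rev", "T_fwd", "T_rev"))
}

# one pileup row; counts given as e.g. A = c(10, 12) (fwd, rev)
pileup_row <- function(sample_id = "s1", np = 100L, ref = NULL, ...) {
  cnt <- empty_counts()
  dots <- list(...)
  for (b in names(dots)) {
    v <- dots[[b]]
    if (length(v) == 1) v <- c(ceiling(v / 2), floor(v / 2))
    cnt[paste0(b, "_fwd")] <- as.integer(v[1])
    cnt[paste0(b, "_rev")] <- as.integer(v[2])
  }
  out <- tibble::tibble(sample_id = sample_id, np = as.integer(np))
  if (!is.null(ref)) out$ref <- ref
  dplyr::bind_cols(out, tibble::as_tibble(as.list(cnt)))
}

# a quartet manifest for one family
quartet_manifest <- function(family_id = "FAM1") {
  tibble::tibble(
    sample_id = paste0(family_id, c("-MBu", "-MBl", "-CBu", "-CBl")),
    family_id = family_id,
    role = c("mother", "mother", "child", "child"),
    tissue = c("buccal", "blood", "buccal", "blood")
  )
}

# pileup for one family at one position: minor fractions per slot (order
# mother-buccal, mother-blood, child-buccal, child-blood), fixed coverage
quartet_pileup <- function(fracs, family_id = "FAM1", np = 1000L,
                           coverage = 10000L, ref = "A", alt = "G") {
  mf <- quartet_manifest(family_id)
  rows <- lapply(seq_len(4), function(i) {
    minor <- as.integer(round(fracs[i] * coverage))
    args <- list(sample_id = mf$sample_id[i], np = np, ref = ref)
    args[[ref]] <- coverage - minor
    args[[alt]] <- minor
    do.call(pileup_row, args)
  })
  dplyr::bind_rows(rows)
}

# a classification table with zero rows, produced through the real pipeline
empty_sites_for_test <- function() {
  cfg <- filter_config()
  pl <- quartet_pileup(rep(0.001, 4))
  classify_sites(call_variants(pl, cfg), quartet_manifest(), cfg)
}

# independent re-statement of the three definitions, tested verbatim against
# the reported/not-reported slot pattern (mb, ml, cb, cl)
oracle_label <- function(mb, ml, cb, cl) {
  mother_any <- mb || ml
  child_any <- cb || cl
  if (mother_any && child_any) return("shared")
  if ((mb && ml && !cb && !cl) || (cb && cl && !mb && !ml)) {
    return("differentiating")
  }
  if (sum(c(mb, ml, cb, cl)) == 1) return("random")
  NA_character_
}
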