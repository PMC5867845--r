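slot_names <- c("mother_buccal", "mother_blood", "child_buccal", "child_blood")

check_manifest <- function(manifest) {
  need <- c("sample_id", "family_id", "role", "tissue")
  miss <- setdiff(need, names(manifest))
  if (length(miss)) {
    abort(sprintf("manifest is missing column(s): %s",
                  paste(miss, collapse = ", ")))
  }
  if (!all(manifest$role %in% c("mother", "child"))) {
    abort("manifest `role` must be 'mother' or 'child'")
  }
  if (!all(manifest$tissue %in% c("buccal", "blood"))) {
    abort("manifest `tissue` must be 'buccal' or 'blood'")
  }
  if (anyDuplicated(manifest$sample_id)) {
    abort("manifest `sample_id` values must be unique")
  }
  key <- paste(manifest$family_id, manifest$role, manifest$tissue)
  if (anyDuplicated(key)) {
    abort("manifest has more than one sample for the same (family, role, tissue) slot")
  }
  invisible(manifest)
}

# Pure pattern rule for the three-way label, given which of the four slots
# carry a reported call. Patterns with no reported slot yield no site (NA).
label_from_pattern <- function(mother_buccal, mother_blood,
                               child_buccal, child_blood) {
  m <- mother_buccal | mother_blood
  c_ <- child_buccal | child_blood
  n <- mother_buccal + mother_blood + child_buccal + child_blood
  dplyr::case_when(
    n == 0L ~ NA_character_,
    m & c_ ~ "shared",
    n == 1L ~ "random",
    TRUE ~ "differentiating"   # both tissues of exactly one member
  )
}

#' Classify heteroplasmic sites across mother-child quartets
#'
#' For every (family, position) where at least one of the family's four
#' samples (mother/child x buccal/blood) has a reported heteroplasmy call,
#' assigns one of three labels:
#'
#' * **shared** - reported in at least one tissue of *both* mother and child;
#' * **differentiating** - reported in both tissues of exactly one family
#'   member, absent from both tissues of the other;
#' * **random** - reported in exactly one of the four samples.
#'
#' "Absent" is held to a stricter standard than mere non-report: the other
#' member's minor fraction must lie below the reporting threshold in both
#' tissues *and* coverage there must be adequate for reporting (detection
#' floor at or below the reporting threshold, i.e. coverage >= 2000 at the
#' defaults). A would-be differentiating site that cannot be certified this
#' way is labelled `unclassifiable` and excluded from tallies. Sites are
#' identified by position only, so a site heteroplasmic towards the
#' reference in one member and towards the variant in the other still
#' matches. Families with a missing slot at a position are skipped with a
#' warning (absence cannot be certified without data).
#'
#' @param calls Output of [call_variants()] covering every sample and
#'   position of interest (unreported rows carry the coverage needed to
#'   certify absence).
#' @param manifest Tibble `sample_id`, `family_id`, `role`, `tissue`.
#' @param config The [filter_config()] used for calling.
#' @return A tibble with one row per classified (family, np): `family_id`,
#'   `np`, `label`, `carrier` (`"mother"`/`"child"`, `NA` for shared),
#'   `carrier_tissue` (random sites), the four per-slot minor frequencies in
#'   percent (`NA` = not detected), the four per-slot major alleles,
#'   `variant_allele`, `primary_haplotype_change`, and annotation columns
#'   `gene`, `region_category`, `synonymous`, `aa_change`.
#' @export
classify_sites <- function(calls, manifest, config = filter_config()) {
  check_manifest(manifest)
  need <- c("sample_id", "np", "total_coverage", "major_allele",
            "minor_allele", "minor_freq", "status", "reported")
  miss <- setdiff(need, names(calls))
  if (length(miss)) {
    abort(sprintf("`calls` is missing column(s): %s",
                  paste(miss, collapse = ", ")))
  }

  dat <- dplyr::inner_join(calls, manifest, by = "sample_id") |>
    dplyr::mutate(slot = paste(.data$role, .data$tissue, sep = "_"))

  cand <- dat |>
    dplyr::filter(.data$reported) |>
    dplyr::distinct(.data$family_id, .data$np)
  if (nrow(cand) == 0) {
    return(empty_sites())
  }

  wide <- dat |>
    dplyr::semi_join(cand, by = c("family_id", "np")) |>
    dplyr::mutate(
      floor = pmax(config$analytical_threshold,
                   ifelse(.data$total_coverage > 0,
                          config$min_variant_reads / .data$total_coverage,
                          Inf)),
      adequate = .data$floor <= config$reporting_threshold,
      absent_certified = !.data$reported &
        !is.na(.data$minor_freq) &
        .data$minor_freq < config$reporting_threshold &
        .data$adequate
    ) |>
    tidyr::pivot_wider(
      id_cols = c("family_id", "np"),
      names_from = "slot",
      values_from = c("reported", "minor_freq", "major_allele",
                      "minor_allele", "absent_certified"),
      names_glue = "{.value}.{slot}"
    )

  # families missing a slot at a position cannot certify absence: skip
  rep_cols <- paste0("reported.", slot_names)
  missing_slot <- setdiff(rep_cols, names(wide))
  for (cl in missing_slot) wide[[cl]] <- NA
  incomplete <- !stats::complete.cases(wide[rep_cols])
  if (any(incomplete)) {
    warn(sprintf(
      "skipping %d candidate site(s) in families with a missing sample slot",
      sum(incomplete)))
    wide <- wide[!incomplete, ]
    if (nrow(wide) == 0) return(empty_sites())
  }

  g <- function(what, slot) wide[[paste0(what, ".", slot)]] %||%
    rep(NA, nrow(wide))

  rep_mb <- g("reported", "mother_buccal")
  rep_ml <- g("reported", "mother_blood")
  rep_cb <- g("reported", "child_buccal")
  rep_cl <- g("reported", "child_blood")
  label <- label_from_pattern(rep_mb, rep_ml, rep_cb, rep_cl)

  carrier <- dplyr::case_when(
    label == "differentiating" & rep_mb ~ "mother",
    label == "differentiating" ~ "child",
    label == "random" & (rep_mb | rep_ml) ~ "mother",
    label == "random" ~ "child",
    TRUE ~ NA_character_
  )
  carrier_tissue <- dplyr::case_when(
    label == "random" & (rep_mb | rep_cb) ~ "buccal",
    label == "random" ~ "blood",
    TRUE ~ NA_character_
  )

  # differentiating requires certified absence in the non-carrier
  noncarrier_ok <- dplyr::case_when(
    label != "differentiating" ~ TRUE,
    carrier == "mother" ~ g("absent_certified", "child_buccal") &
      g("absent_certified", "child_blood"),
    TRUE ~ g("absent_certified", "mother_buccal") &
      g("absent_certified", "mother_blood")
  )
  n_down <- sum(label == "differentiating" & !noncarrier_ok, na.rm = TRUE)
  if (n_down > 0) {
    inform(sprintf(
      "%d differentiating candidate(s) downgraded to unclassifiable (absence not certified in the other family member)",
      n_down))
  }
  label[label == "differentiating" & !noncarrier_ok] <- "unclassifiable"

  freq_pct <- function(slot) {
    ifelse(g("reported", slot), 100 * g("minor_freq", slot), NA_real_)
  }

  # the site's variant allele: the reported minor allele (majority vote
  # across reported slots); used for annotation together with the reference
  minor_mat <- cbind(
    ifelse(rep_mb, g("minor_allele", "mother_buccal"), NA),
    ifelse(rep_ml, g("minor_allele", "mother_blood"), NA),
    ifelse(rep_cb, g("minor_allele", "child_buccal"), NA),
    ifelse(rep_cl, g("minor_allele", "child_blood"), NA)
  )
  site_minor <- apply(minor_mat, 1, function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) NA_character_ else names(sort(table(x),
                                                  decreasing = TRUE))[1]
  })

  maj_mb <- g("major_allele", "mother_buccal")
  maj_ml <- g("major_allele", "mother_blood")
  maj_cb <- g("major_allele", "child_buccal")
  maj_cl <- g("major_allele", "child_blood")
  phc <- primary_haplotype_change(maj_mb, maj_ml, maj_cb, maj_cl)

  genome <- mt_genome()
  ref <- substring(genome, wide$np, wide$np)
  variant <- ifelse(site_minor == ref | is.na(site_minor),
                    ifelse(maj_mb == ref | is.na(maj_mb),
                           ifelse(is.na(maj_cb) | maj_cb == ref,
                                  NA_character_, maj_cb),
                           maj_mb),
                    site_minor)

  ann_ok <- !is.na(variant) & variant != ref & wide$np != 3107L
  ann <- tibble(np = wide$np, region_category = NA_character_,
                gene = NA_character_, synonymous = NA,
                aa_change = NA_character_)
  reg <- mt_region_of(wide$np)
  ann$region_category <- reg$category
  ann$gene <- reg$gene
  if (any(ann_ok)) {
    eff <- mt_substitution_effect(wide$np[ann_ok], ref[ann_ok],
                                  variant[ann_ok])
    ann$synonymous[ann_ok] <- eff$synonymous
    ann$aa_change[ann_ok] <- eff$aa_change
  }

  tibble(
    family_id = wide$family_id,
    np = as.integer(wide$np),
    label = label,
    carrier = carrier,
    carrier_tissue = carrier_tissue,
    mother_buccal_freq = freq_pct("mother_buccal"),
    mother_blood_freq = freq_pct("mother_blood"),
    child_buccal_freq = freq_pct("child_buccal"),
    child_blood_freq = freq_pct("child_blood"),
    mother_buccal_major = maj_mb,
    mother_blood_major = maj_ml,
    child_buccal_major = maj_cb,
    child_blood_major = maj_cl,
    ref = ref,
    variant_allele = variant,
    primary_haplotype_change = phc,
    region_category = ann$region_category,
    gene = ann$gene,
    synonymous = ann$synonymous,
    aa_change = ann$aa_change
  ) |>
    dplyr::arrange(.data$family_id, .data$np)
}

empty_sites <- function() {
  tibble(
    family_id = character(), np = integer(), label = character(),
    carrier = character(), carrier_tissue = character(),
    mother_buccal_freq = numeric(), mother_blood_freq = numeric(),
    child_buccal_freq = numeric(), child_blood_freq = numeric(),
    mother_buccal_major = character(), mother_blood_major = character(),
    child_buccal_major = character(), child_blood_major = character(),
    ref = character(), variant_allele = character(),
    primary_haplotype_change = logical(),
    region_category = character(), gene = character(),
    synonymous = logical(), aa_change = character()
  )
}

#' Primary haplotype change between mother and child
#'
#' TRUE when the consensus (major) allele of the mother differs from that of
#' the child in at least one like-for-like tissue comparison. A change of
#' primary haplotype at a heteroplasmic position is the signature of severe
#' germline drift: the variant that is the minority in one relative has
#' become the majority in the other.
#'
#' @param mother_buccal,mother_blood,child_buccal,child_blood Major
#'   (consensus) alleles per slot; `NA` where no call is available.
#' @return Logical vector.
#' @export
#' @examples
#' primary_haplotype_change("A", "A", "G", "G")  # majority flipped
primary_haplotype_change <- function(mother_buccal, mother_blood,
                                     child_buccal, child_blood) {
  cmp <- function(a, b) !is.na(a) & !is.na(b) & a != b
  cmp(mother_buccal, child_buccal) | cmp(mother_blood, child_blood)
}

#' Tissue comparison for differentiating sites
#'
#' For each differentiating site, compares the carrier's minor-variant
#' frequency between buccal and blood: the fold difference
#' (`max / min`), whether buccal runs higher, and the 10% frequency band
#' (`both<10%`, `both>10%`, `mixed`).
#'
#' @param sites Output of [classify_sites()].
#' @return A tibble `family_id`, `np`, `carrier`, `buccal_minor_freq`,
#'   `blood_minor_freq` (percent), `fold_difference`, `buccal_higher`,
#'   `band`.
#' @export
site_comparison <- function(sites) {
  d <- dplyr::filter(sites, .data$label == "differentiating")
  bu <- ifelse(d$carrier == "mother", d$mother_buccal_freq,
               d$child_buccal_freq)
  bl <- ifelse(d$carrier == "mother", d$mother_blood_freq,
               d$child_blood_freq)
  if (any(is.na(bu) | is.na(bl))) {
    abort("differentiating sites must carry frequencies in both carrier tissues")
  }
  zero <- bu == 0 | bl == 0
  if (any(zero)) warn("zero carrier frequency: fold difference undefined there")
  tibble(
    family_id = d$family_id, np = d$np, carrier = d$carrier,
    buccal_minor_freq = bu, blood_minor_freq = bl,
    fold_difference = ifelse(zero, NA_real_,
                             pmax(bu, bl) / pmin(bu, bl)),
    buccal_higher = bu > bl,
    band = dplyr::case_when(
      bu < 10 & bl < 10 ~ "both<10%",
      bu > 10 & bl > 10 ~ "both>10%",
      TRUE ~ "mixed"
    )
  )
}

#' Cohort tallies for classified heteroplasmy
#'
#' Aggregates classified sites into the cohort-level counts used for
#' reporting: pairs and distinct positions per label, carrier and tissue
#' breakdowns, and the control-region/coding split.
#'
#' @param sites Output of [classify_sites()].
#' @param n_families Total number of families screened (defaults to the
#'   number of families appearing in `sites`; pass the manifest count so
#'   that families without heteroplasmy enter the denominators).
#' @return A nested list, JSON-serializable.
#' @export
cohort_summary <- function(sites, n_families = dplyr::n_distinct(sites$family_id)) {
  by_label <- function(lbl) {
    s <- dplyr::filter(sites, .data$label == lbl)
    list(
      n_pairs = dplyr::n_distinct(s$family_id),
      n_sites = nrow(s),
      n_distinct_np = dplyr::n_distinct(s$np),
      n_coding = sum(s$region_category != "control_region"),
      n_control_region = sum(s$region_category == "control_region")
    )
  }
  s <- by_label("shared"); d <- by_label("differentiating")
  r <- by_label("random")
  rnd <- dplyr::filter(sites, .data$label == "random")
  diff_ <- dplyr::filter(sites, .data$label == "differentiating")
  list(
    n_families = n_families,
    shared = s,
    differentiating = c(d, list(
      carrier_mother = sum(diff_$carrier == "mother"),
      carrier_child = sum(diff_$carrier == "child"))),
    random = c(r, list(
      carrier_mother = sum(rnd$carrier == "mother"),
      carrier_child = sum(rnd$carrier == "child"),
      tissue_buccal = sum(rnd$carrier_tissue == "buccal"),
      tissue_blood = sum(rnd$carrier_tissue == "blood"))),
    unclassifiable = sum(sites$label == "unclassifiable"),
    primary_haplotype_changes = sum(sites$primary_haplotype_change &
                                      sites$label != "unclassifiable")
  )
}
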