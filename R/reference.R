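#' The packaged mitochondrial reference sequence
#'
#' Returns the 16,569-base human mitochondrial reference on the L-strand,
#' in rCRS coordinates (GenBank NC_012920.1 numbering). The packaged copy is
#' a verified synthetic reconstruction of the rCRS (see the file header of
#' `inst/extdata/rCRS_synthetic.fasta`); position 3107 carries the historical
#' placeholder `N` that keeps rCRS numbering and is never treated as a
#' callable base.
#'
#' @return A single character string of length 16,569.
#' @export
#' @examples
#' substr(mt_genome(), 3107, 3107)  # the numbering placeholder
mt_genome <- function() {
  if (is.null(the$genome)) {
    fa <- system.file("extdata", "rCRS_synthetic.fasta", package = "mitohet",
                      mustWork = TRUE)
    seq <- as.character(Biostrings::readDNAStringSet(fa)[[1]])
    stopifnot(nchar(seq) == 16569L)
    the$genome <- seq
  }
  the$genome
}

#' Length of the mitochondrial genome in rCRS coordinates
#' @export
mt_genome_length <- function() 16569L

#' The mitochondrial gene map
#'
#' Feature table of the human mitochondrial genome in rCRS coordinates:
#' the control region (which wraps the origin: 16024..16569 joined with
#' 1..576), the two rRNAs, 22 tRNAs and 13 protein-coding genes, plus the
#' short intergenic spacers (category `non_coding`) so that every position
#' maps to exactly one region category. `frame_start` is the first position
#' of codon 1 for protein genes; light-strand genes (ND6 and several tRNAs)
#' have `strand == "L"` and, for ND6, `frame_start` is the *last* L-strand
#' position (the first base of codon 1 on the coding strand).
#'
#' @return A tibble with columns `name`, `category`, `start`, `end`,
#'   `strand`, `frame_start`.
#' @export
mt_gene_map <- function() {
  if (is.null(the$gene_map)) {
    path <- system.file("extdata", "mt_gene_map.tsv", package = "mitohet",
                        mustWork = TRUE)
    gm <- readr::read_tsv(path, progress = FALSE, na = "NA",
                          col_types = readr::cols(
                            name = "c", category = "c", start = "i",
                            end = "i", strand = "c", frame_start = "i"))
    # fill intergenic gaps so the map tiles 1..16569
    covered <- rep(FALSE, 16569L)
    covered[c(16024:16569, 1:576)] <- TRUE
    for (i in which(gm$name != "CR")) {
      covered[gm$start[i]:gm$end[i]] <- TRUE
    }
    gap <- which(!covered)
    if (length(gap)) {
      brk <- cumsum(c(TRUE, diff(gap) != 1L))
      nc <- dplyr::bind_rows(lapply(split(gap, brk), function(g) {
        tibble(name = paste0("NC_", min(g)), category = "non_coding",
               start = min(g), end = max(g), strand = "H",
               frame_start = NA_integer_)
      }))
      gm <- dplyr::bind_rows(gm, nc)
    }
    the$gene_map <- gm
  }
  the$gene_map
}

check_np <- function(np, arg = "np") {
  if (!is.numeric(np) || anyNA(np) || any(np != floor(np)) ||
      any(np < 1L) || any(np > 16569L)) {
    abort(sprintf("`%s` must contain integer positions in 1..16569", arg))
  }
  as.integer(np)
}

# circular index into rCRS coordinates
circ_np <- function(i) ((i - 1L) %% 16569L) + 1L

#' Map positions to mitochondrial features
#'
#' Assigns each position to the feature containing it. The control region is
#' defined as 16024..16569 together with 1..576 (the standard rCRS
#' convention), so positions 577..16023 are never `control_region`; in the
#' tables of this package everything outside the control region is the
#' "coding region" in the loose sense used for whole-mtgenome reporting.
#' Where annotated features overlap by a few bases (e.g. ATP8/ATP6), the
#' first feature in map order wins, deterministically.
#'
#' @param np Integer vector of positions (1..16569).
#' @return A tibble with one row per input position: `np`, `gene`,
#'   `category`, `strand`.
#' @export
#' @examples
#' mt_region_of(c(16320, 2746, 577))
mt_region_of <- function(np) {
  np <- check_np(np)
  gm <- mt_gene_map()
  in_cr <- np >= 16024L | np <= 576L
  rest <- gm[gm$name != "CR", ]
  idx <- vapply(np, function(p) {
    which(rest$start <= p & rest$end >= p)[1]
  }, integer(1))
  out <- tibble(
    np = np,
    gene = ifelse(in_cr, "CR", rest$name[idx]),
    category = ifelse(in_cr, "control_region", rest$category[idx]),
    strand = ifelse(in_cr, "H", rest$strand[idx])
  )
  out
}

# vertebrate mitochondrial genetic code (ATA=Met, TGA=Trp, AGA/AGG=stop)
mito_code <- function() {
  if (is.null(the$code)) {
    std <- c(TTT = "F", TTC = "F", TTA = "L", TTG = "L",
             CTT = "L", CTC = "L", CTA = "L", CTG = "L",
             ATT = "I", ATC = "I", ATA = "I", ATG = "M",
             GTT = "V", GTC = "V", GTA = "V", GTG = "V",
             TCT = "S", TCC = "S", TCA = "S", TCG = "S",
             CCT = "P", CCC = "P", CCA = "P", CCG = "P",
             ACT = "T", ACC = "T", ACA = "T", ACG = "T",
             GCT = "A", GCC = "A", GCA = "A", GCG = "A",
             TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
             CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
             AAT = "N", AAC = "N", AAA = "K", AAG = "K",
             GAT = "D", GAC = "D", GAA = "E", GAG = "E",
             TGT = "C", TGC = "C", TGA = "*", TGG = "W",
             CGT = "R", CGC = "R", CGA = "R", CGG = "R",
             AGT = "S", AGC = "S", AGA = "R", AGG = "R",
             GGT = "G", GGC = "G", GGA = "G", GGG = "G")
    std[c("ATA", "TGA", "AGA", "AGG")] <- c("M", "W", "*", "*")
    the$code <- std
  }
  the$code
}

aa3 <- c("A" = "Ala", "R" = "Arg", "N" = "Asn", "D" = "Asp", "C" = "Cys",
         "Q" = "Gln", "E" = "Glu", "G" = "Gly", "H" = "His", "I" = "Ile",
         "L" = "Leu", "K" = "Lys", "M" = "Met", "F" = "Phe", "P" = "Pro",
         "S" = "Ser", "T" = "Thr", "W" = "Trp", "Y" = "Tyr", "V" = "Val",
         "*" = "Ter")

revcomp <- function(x) {
  chartr("ACGTN", "TGCAN",
         vapply(strsplit(x, ""), function(s) paste(rev(s), collapse = ""),
                character(1)))
}

#' Effect of a single-nucleotide substitution
#'
#' Annotates substitutions with their containing feature and, for
#' protein-coding genes, whether the change is synonymous under the
#' vertebrate mitochondrial genetic code. All alleles are given on the
#' L-strand; light-strand genes (ND6) are reverse-complemented before codon
#' extraction so the effect is strand-consistent. Amino acids are reported
#' as 3-letter codes.
#'
#' @param np,ref,alt Equal-length vectors: position, reference base at that
#'   position (L-strand), and alternate base. `ref` must match the packaged
#'   genome; position 3107 (the numbering placeholder) is rejected.
#' @return A tibble with columns `np`, `ref`, `alt`, `region_category`,
#'   `gene`, `synonymous` (logical; `NA` outside protein-coding genes),
#'   `aa_ref`, `aa_alt`, `aa_change` (e.g. `"Val to Ala"`, or `"Gln"` for a
#'   synonymous change, matching report conventions).
#' @export
#' @examples
#' mt_substitution_effect(c(9179, 14040), c("T", "G"), c("C", "A"))
mt_substitution_effect <- function(np, ref, alt) {
  np <- check_np(np)
  ref <- toupper(ref); alt <- toupper(alt)
  stopifnot(length(ref) == length(np), length(alt) == length(np))
  if (any(np == 3107L)) {
    abort("position 3107 is the rCRS numbering placeholder ('N') and has no callable substitution effect")
  }
  genome <- mt_genome()
  gref <- substring(genome, np, np)
  if (any(bad <- gref != ref)) {
    abort(sprintf("`ref` does not match the reference genome at np %s",
                  paste(np[bad], collapse = ", ")))
  }
  if (any(alt == ref)) abort("`alt` must differ from `ref`")
  if (!all(alt %in% c("A", "C", "G", "T"))) abort("`alt` must be A, C, G or T")

  reg <- mt_region_of(np)
  gm <- mt_gene_map()
  code <- mito_code()

  n <- length(np)
  syn <- rep(NA, n)
  aa_ref <- aa_alt <- aa_change <- rep(NA_character_, n)
  for (i in which(reg$category == "protein_coding")) {
    g <- gm[gm$name == reg$gene[i], ]
    if (g$strand == "H") {
      off <- np[i] - g$frame_start
      cs <- g$frame_start + 3L * (off %/% 3L)
      if (cs + 2L > g$end) next  # incomplete terminal codon
      codon <- substring(genome, cs, cs + 2L)
      pos <- off %% 3L + 1L
      codon_alt <- codon
      substr(codon_alt, pos, pos) <- alt[i]
    } else {
      off <- g$frame_start - np[i]
      ce <- g$frame_start - 3L * (off %/% 3L)  # L-strand end of codon
      if (ce - 2L < g$start) next
      tri <- substring(genome, ce - 2L, ce)
      codon <- revcomp(tri)
      pos_l <- 3L - off %% 3L  # position within the L-strand triplet
      tri_alt <- tri
      substr(tri_alt, pos_l, pos_l) <- alt[i]
      codon_alt <- revcomp(tri_alt)
    }
    a1 <- unname(code[codon]); a2 <- unname(code[codon_alt])
    syn[i] <- a1 == a2
    aa_ref[i] <- unname(aa3[a1]); aa_alt[i] <- unname(aa3[a2])
    aa_change[i] <- if (a1 == a2) aa3[a1] else
      paste(aa3[a1], "to", aa3[a2])
  }
  tibble(np = np, ref = ref, alt = alt,
         region_category = reg$category, gene = reg$gene,
         synonymous = syn, aa_ref = aa_ref, aa_alt = aa_alt,
         aa_change = aa_change)
}

#' Flanking sequence around a position
#'
#' Returns the L-strand sequence surrounding a position with the site marked
#' by `*`: three nucleotides to each side, except that when the base
#' adjacent to the site opens a homopolymer run of three or more identical
#' bases the entire run is given as that flank. Coordinates are circular,
#' so flanks wrap across the origin.
#'
#' @param np Integer vector of positions.
#' @param flank Width of the basic flanking window (default 3).
#' @return Character vector of context strings such as `"CTT*CCCC"`.
#' @export
#' @examples
#' mt_adjacent_sequence(2487)
mt_adjacent_sequence <- function(np, flank = 3L) {
  np <- check_np(np)
  genome <- mt_genome()
  base_at <- function(i) substring(genome, circ_np(i), circ_np(i))
  one_side <- function(p, dir) {
    # dir = -1 for the left flank, +1 for the right flank; when the base
    # adjacent to the site opens a homopolymer run of >= 3 the whole run is
    # given, otherwise the plain `flank`-base window
    b <- base_at(p + dir)
    run <- 1L
    while (run < 20L && base_at(p + dir * (run + 1L)) == b) run <- run + 1L
    ext <- if (run >= 3L) run else flank
    out <- vapply(p + dir * seq_len(ext), base_at, character(1))
    if (dir < 0) paste(rev(out), collapse = "") else paste(out, collapse = "")
  }
  vapply(np, function(p) {
    paste0(one_side(p, -1L), "*", one_side(p, +1L))
  }, character(1))
}

#' Sequence-motif flags for an error-site context
#'
#' Tests whether a context string produced by [mt_adjacent_sequence()] has a
#' run of at least three A's, at least three C's, or the trinucleotide GGT
#' immediately adjacent to the marked site. These are the motif classes
#' associated with elevated substitution error in deep amplicon sequencing.
#'
#' @param context Character vector of context strings with one `*` marking
#'   the site.
#' @return A tibble with columns `context`, `poly_a`, `poly_c`, `ggt`.
#' @export
#' @examples
#' mt_motif_flags(c("AAA*TAC", "GGT*AAAAAAA", "ACG*TCA"))
mt_motif_flags <- function(context) {
  if (!is.character(context)) abort("`context` must be a character vector")
  parts <- strsplit(context, "*", fixed = TRUE)
  ok <- lengths(regmatches(context, gregexpr("*", context, fixed = TRUE))) == 1L &
    grepl("^[ACGTN]*\\*[ACGTN]*$", context)
  if (any(!ok)) {
    abort(sprintf("malformed context string(s): %s",
                  paste(context[!ok], collapse = ", ")))
  }
  left <- vapply(parts, `[`, character(1), 1)
  right <- vapply(parts, function(p) if (length(p) > 1) p[2] else "",
                  character(1))
  tibble(
    context = context,
    poly_a = grepl("A{3,}$", left) | grepl("^A{3,}", right),
    poly_c = grepl("C{3,}$", left) | grepl("^C{3,}", right),
    ggt = grepl("GGT$", left) | grepl("^GGT", right)
  )
}
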