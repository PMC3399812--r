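# SNP calling: per-column base counts, the pooled >1% minor-allele frequency
# rule, IUPAC coding of the allele set, rCRS annotation, the per-subject
# genotype table, and lookup against known disease-associated D-loop variants.

BASES <- c("A", "C", "G", "T")

#' Per-column base counts by group
#'
#' Counts each nucleotide (A, C, G, T) at every alignment column, separately
#' for cases and controls and pooled. Ambiguity codes and gap characters are
#' counted as unresolved, not as any base.
#'
#' @param cohort A cohort tibble (see [as_cohort()]).
#' @return A tibble of class `site_counts` with one row per (column, base):
#'   `column`, `base`, `n_case`, `n_control`, `n_pooled`, plus the per-column
#'   unresolved counts `n_unresolved_case`, `n_unresolved_control`,
#'   `n_unresolved` repeated across the column's rows. Attributes `n_case`
#'   and `n_control` hold the group sizes.
#' @export
count_sites <- function(cohort) {
  cohort <- as_cohort(cohort)
  m <- sequence_matrix(cohort)
  is_case <- cohort$group == "case"
  n_col <- ncol(m)
  count_group <- function(rows) {
    sub <- m[rows, , drop = FALSE]
    matrix(vapply(BASES, function(b) colSums(sub == b), numeric(n_col)),
           nrow = n_col, dimnames = list(NULL, BASES))
  }
  cs <- count_group(is_case)      # n_col x 4
  ct <- count_group(!is_case)
  unres_case <- sum(is_case) - rowSums(cs)
  unres_ctrl <- sum(!is_case) - rowSums(ct)
  out <- tibble::tibble(
    column = rep(seq_len(n_col), each = length(BASES)),
    base = rep(BASES, times = n_col),
    n_case = as.integer(t(cs)),
    n_control = as.integer(t(ct))
  )
  out$n_pooled <- out$n_case + out$n_control
  out$n_unresolved_case <- rep(as.integer(unres_case), each = length(BASES))
  out$n_unresolved_control <- rep(as.integer(unres_ctrl), each = length(BASES))
  out$n_unresolved <- out$n_unresolved_case + out$n_unresolved_control
  structure(out,
            n_case = sum(is_case), n_control = sum(!is_case),
            class = c("site_counts", class(out)))
}

#' Call SNPs by the pooled minor-allele frequency rule
#'
#' A column is called a SNP when at least two bases each have pooled frequency
#' strictly greater than `maf_threshold`, with frequency defined as pooled base
#' count over the pooled resolved count at that column. The allele set is
#' exactly those bases, summarised by its IUPAC code; sub-threshold bases stay
#' visible in the site counts but are excluded from the allele set. The
#' indicator allele is the allele whose relative frequency exceeds the
#' controls' by the most (ties broken by case frequency, then alphabetically);
#' it is the genotype coded 1 in downstream models. The 2x2 table per SNP is
#' indicator versus all other resolved bases, by group.
#'
#' @param counts A `site_counts` tibble from [count_sites()].
#' @param map Optional `coord_map` used to annotate each SNP with its rCRS
#'   position.
#' @param maf_threshold Pooled frequency a base must strictly exceed to enter
#'   the allele set; default 0.01.
#' @return A tibble of class `snp_table`, one row per SNP: `snp_no`, `column`,
#'   `rcrs_pos`, `iupac`, `alleles` (e.g. `"C/T"`), `n_alleles`, `indicator`,
#'   the 2x2 counts `n_case_ind`, `n_case_other`, `n_control_ind`,
#'   `n_control_other`, and `allele_counts` (a list-column of per-allele
#'   per-group counts).
#' @export
call_snps <- function(counts, map = NULL, maf_threshold = 0.01) {
  stopifnot(inherits(counts, "site_counts"))
  if (!(maf_threshold > 0 && maf_threshold < 0.5)) {
    stop("maf_threshold must lie in (0, 0.5)", call. = FALSE)
  }
  counts <- dplyr::arrange(counts, .data$column, .data$base)
  n_col <- max(counts$column)
  stopifnot(nrow(counts) == n_col * length(BASES))
  case_m <- matrix(counts$n_case, nrow = n_col, byrow = TRUE,
                   dimnames = list(NULL, BASES))
  ctrl_m <- matrix(counts$n_control, nrow = n_col, byrow = TRUE,
                   dimnames = list(NULL, BASES))
  pooled_m <- case_m + ctrl_m
  res_case <- rowSums(case_m)
  res_ctrl <- rowSums(ctrl_m)
  resolved <- res_case + res_ctrl
  ok <- pooled_m / pmax(resolved, 1L) > maf_threshold
  is_snp <- resolved > 0 & rowSums(ok) >= 2
  cols <- which(is_snp)
  rows <- lapply(cols, function(j) {
    al <- tibble::tibble(base = BASES[ok[j, ]],
                         n_case = as.integer(case_m[j, ok[j, ]]),
                         n_control = as.integer(ctrl_m[j, ok[j, ]]),
                         n_pooled = as.integer(pooled_m[j, ok[j, ]]))
    diff <- al$n_case / res_case[j] - al$n_control / res_ctrl[j]
    ord <- order(-diff, -al$n_case, al$base)
    ind <- al$base[ord[1]]
    a <- al$n_case[al$base == ind]
    c_ <- al$n_control[al$base == ind]
    tibble::tibble(
      column = j,
      iupac = iupac_code(al$base),
      alleles = paste(al$base, collapse = "/"),
      n_alleles = nrow(al),
      indicator = ind,
      n_case_ind = as.integer(a),
      n_case_other = as.integer(res_case[j] - a),
      n_control_ind = as.integer(c_),
      n_control_other = as.integer(res_ctrl[j] - c_),
      allele_counts = list(al)
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(column = integer(), iupac = character(),
                          alleles = character(), n_alleles = integer(),
                          indicator = character(), n_case_ind = integer(),
                          n_case_other = integer(), n_control_ind = integer(),
                          n_control_other = integer(), allele_counts = list())
  }
  out <- dplyr::arrange(out, .data$column)
  out$snp_no <- seq_len(nrow(out))
  out$rcrs_pos <- if (!is.null(map) && nrow(out)) align_to_rcrs(map, out$column) else NA_integer_
  out <- dplyr::relocate(out, "snp_no", "column", "rcrs_pos")
  structure(out, maf_threshold = maf_threshold,
            class = c("snp_table", class(out)))
}

#' Per-subject genotype table at the called SNPs
#'
#' @param cohort The cohort the SNPs were called from.
#' @param snps A `snp_table` from [call_snps()].
#' @return A long tibble: `subject_id`, `group`, `snp_no`, `column`,
#'   `rcrs_pos`, `base` (the subject's base at that column; `NA` when
#'   ambiguous or gap).
#' @export
build_genotype_table <- function(cohort, snps) {
  cohort <- as_cohort(cohort)
  m <- sequence_matrix(cohort)
  purrr::pmap_dfr(
    snps[, c("snp_no", "column", "rcrs_pos")],
    function(snp_no, column, rcrs_pos) {
      b <- unname(m[, column])
      b[!b %in% BASES] <- NA_character_
      tibble::tibble(subject_id = cohort$subject_id, group = cohort$group,
                     snp_no = snp_no, column = column, rcrs_pos = rcrs_pos,
                     base = b)
    }
  )
}

#' Indicator-coded design matrix for the called SNPs
#'
#' One column per SNP, coded 1 for the indicator allele, 0 for any other
#' resolved base, `NA` for unresolved; plus `subject_id`, `group` and the
#' binary outcome `case` (1 = case).
#'
#' @param genotypes Long genotype tibble from [build_genotype_table()].
#' @param snps The matching `snp_table`.
#' @return A wide tibble with columns `subject_id`, `group`, `case`, and
#'   `SNP<k>` per SNP.
#' @export
snp_design <- function(genotypes, snps) {
  g <- dplyr::left_join(genotypes,
                        snps[, c("snp_no", "indicator")], by = "snp_no")
  g$value <- ifelse(is.na(g$base), NA_integer_, as.integer(g$base == g$indicator))
  g$term <- paste0("SNP", g$snp_no)
  wide <- tidyr::pivot_wider(g[, c("subject_id", "group", "term", "value")],
                             names_from = "term", values_from = "value")
  wide$case <- as.integer(wide$group == "case")
  dplyr::relocate(wide, "subject_id", "group", "case")
}

#' Known disease-associated D-loop variants
#'
#' The seven control-region variants reported in MITOMAP as disease-associated
#' at the time of the study: C114T, C150T, T195C, C309CC (a poly-C insertion),
#' T16189C, A16300G and C16519T.
#'
#' @return A tibble with columns `label`, `rcrs_pos`, `ref`, `alt` (`alt` is
#'   `NA` for the length variant C309CC).
#' @export
known_dloop_variants <- function() {
  tibble::tibble(
    label = c("C114T", "C150T", "T195C", "C309CC", "T16189C", "A16300G", "C16519T"),
    rcrs_pos = c(114L, 150L, 195L, 309L, 16189L, 16300L, 16519L),
    ref = c("C", "C", "T", "C", "T", "A", "C"),
    alt = c("T", "T", "C", NA, "C", "G", "T")
  )
}

#' Annotate called SNPs with known variants
#'
#' Flags each SNP whose rCRS position matches a known variant, noting whether
#' the known reference and alternate alleles are both inside the SNP's allele
#' set.
#'
#' @param snps A `snp_table`.
#' @param known Tibble of known variants as from [known_dloop_variants()].
#' @return `snps` with columns `known_label` (`NA` when unmatched) and
#'   `allele_match` appended.
#' @export
annotate_known <- function(snps, known = known_dloop_variants()) {
  if (nrow(known) == 0) {
    snps$known_label <- NA_character_
    snps$allele_match <- NA
    return(snps)
  }
  idx <- match(snps$rcrs_pos, known$rcrs_pos)
  snps$known_label <- known$label[idx]
  snps$allele_match <- purrr::map2_lgl(seq_len(nrow(snps)), idx, function(i, j) {
    if (is.na(j) || is.na(known$alt[j])) return(NA)
    al <- strsplit(snps$alleles[i], "/")[[1]]
    known$ref[j] %in% al && known$alt[j] %in% al
  })
  snps
}
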