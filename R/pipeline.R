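# End-to-end orchestration: read -> mask -> trim -> count -> call -> screen ->
# backward-eliminate -> adjust -> subgroups, with table-shaped TSV reports and
# a JSON run summary.

#' Run the full D-loop association study
#'
#' Executes the whole cascade on an aligned cohort: poly-C masking, trimming
#' to the analysis window, per-column counting, SNP calling by the pooled >1%
#' rule, per-SNP chi-square/odds-ratio screening, backward-elimination
#' logistic regression over the shortlisted indicators, and — when a covariate
#' table is supplied — covariate-adjusted odds ratios and subgroup reruns.
#'
#' @param cohort A cohort tibble (see [read_cohort()]).
#' @param covariates Optional covariate tibble (see [read_covariates()]).
#' @param ref Control-region reference; required for masking.
#' @param map Coordinate map for the cohort's columns; defaults to the map
#'   attached to the cohort, else [default_coordinate_map()].
#' @param tracts Poly-C tract spans ([polyc_tracts()]); an empty tibble skips
#'   masking.
#' @param keep Analysis-window spans for [trim_window()].
#' @param maf_threshold,alpha_screen,min_cell,alpha_stay Pipeline parameters
#'   (defaults: pooled frequency > 1%, screen at 0.05 with every 2x2 cell at
#'   least 4, stay criterion 0.05).
#' @param subgroups Logical; run the subgroup reruns (needs covariates).
#' @param verbose Print a structured log line per stage.
#' @return An object of class `dloop_study` bundling every stage's output;
#'   see [write_reports()].
#' @export
run_study <- function(cohort, covariates = NULL, ref = synthetic_reference(),
                      map = NULL, tracts = polyc_tracts(),
                      keep = list(c(16000L, 16569L), c(1L, 485L)),
                      maf_threshold = 0.01, alpha_screen = 0.05, min_cell = 4,
                      alpha_stay = 0.05, subgroups = !is.null(covariates),
                      verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  cohort <- as_cohort(cohort)
  if (is.null(map)) map <- cohort_map(cohort)
  if (is.null(map)) map <- default_coordinate_map()
  cohort <- set_cohort_map(cohort, map)
  say("stage=read records=%d cases=%d controls=%d length=%d",
      nrow(cohort), sum(cohort$group == "case"), sum(cohort$group == "control"),
      cohort_length(cohort))

  cohort <- mask_polyc(cohort, ref, tracts = tracts)
  say("stage=mask tracts=%d length=%d", nrow(tracts), cohort_length(cohort))
  cohort <- trim_window(cohort, keep = keep)
  map <- cohort_map(cohort)
  say("stage=trim length=%d", cohort_length(cohort))

  counts <- count_sites(cohort)
  snps <- snp_assoc(call_snps(counts, map = map, maf_threshold = maf_threshold))
  say("stage=call snps=%d threshold=%g", nrow(snps), maf_threshold)
  snps <- annotate_known(snps)

  shortlist <- screen_candidates(snps, alpha = alpha_screen, min_cell = min_cell)
  say("stage=screen candidates=%d alpha=%g min_cell=%d", nrow(shortlist),
      alpha_screen, min_cell)

  selection <- NULL
  design <- NULL
  adjusted <- NULL
  subgroup_tbl <- NULL
  if (nrow(shortlist) > 0) {
    genotypes <- build_genotype_table(cohort, shortlist)
    design <- snp_design(genotypes, shortlist)
    selection <- backward_eliminate(design, paste0("SNP", shortlist$snp_no),
                                    alpha_stay = alpha_stay)
    say("stage=select retained=%d of %d", length(selection$retained), nrow(shortlist))
    if (!is.null(covariates) && length(selection$retained) > 0) {
      adjusted <- tryCatch(
        adjusted_or(design, covariates, selection$retained),
        error = function(e) {
          warning("adjusted model failed: ", conditionMessage(e), call. = FALSE)
          NULL
        })
      say("stage=adjust terms=%d", length(selection$retained))
    }
    if (isTRUE(subgroups) && !is.null(covariates)) {
      subgroup_tbl <- suppressWarnings(
        subgroup_analysis(design, covariates, paste0("SNP", shortlist$snp_no),
                          alpha_stay = alpha_stay))
      say("stage=subgroups strata=%d", length(unique(paste(subgroup_tbl$stratifier,
                                                           subgroup_tbl$level))))
    }
  }

  structure(list(
    cohort_n = table(cohort$group),
    map = map,
    counts = counts,
    snps = snps,
    shortlist = shortlist,
    selection = selection,
    design = design,
    adjusted = adjusted,
    subgroups = subgroup_tbl,
    params = list(maf_threshold = maf_threshold, alpha_screen = alpha_screen,
                  min_cell = min_cell, alpha_stay = alpha_stay,
                  keep = keep, tracts = tracts)
  ), class = "dloop_study")
}

#' @export
print.dloop_study <- function(x, ...) {
  cat(sprintf("<dloop_study> %d case(s) / %d control(s); %d SNP(s) called, %d screened",
              x$cohort_n[["case"]], x$cohort_n[["control"]],
              nrow(x$snps), nrow(x$shortlist)))
  if (!is.null(x$selection)) {
    cat(sprintf(", %d retained (%s)", length(x$selection$retained),
                paste(x$selection$retained, collapse = ", ")))
  }
  cat("\n")
  invisible(x)
}

#' Final-model odds ratios of a study
#'
#' The joint odds ratios (from the multivariable final fit) and, when
#' available, the covariate-adjusted odds ratios for each retained SNP.
#'
#' @param study A `dloop_study`.
#' @return A tibble: `term`, `or`, `ci_low`, `ci_high`, `p`, `aor`,
#'   `aor_low`, `aor_high`, `aor_p`.
#' @export
study_model_table <- function(study) {
  if (is.null(study$selection) || length(study$selection$retained) == 0) {
    return(tibble::tibble(term = character(), or = double(), ci_low = double(),
                          ci_high = double(), p = double(), aor = double(),
                          aor_low = double(), aor_high = double(), aor_p = double()))
  }
  td <- tidy(study$selection)
  out <- tibble::tibble(term = td$term, or = td$or, ci_low = td$ci_low,
                        ci_high = td$ci_high, p = td$p.value)
  if (!is.null(study$adjusted)) {
    at <- tidy(study$adjusted)
    idx <- match(out$term, at$term)
    out$aor <- at$or[idx]
    out$aor_low <- at$ci_low[idx]
    out$aor_high <- at$ci_high[idx]
    out$aor_p <- at$p.value[idx]
  } else {
    out$aor <- out$aor_low <- out$aor_high <- out$aor_p <- NA_real_
  }
  out
}

#' Write table-shaped reports for a study
#'
#' Emits `snp_positions.tsv` (SNP number, alignment column, rCRS position,
#' IUPAC code, alleles), `snp_assoc.tsv` (per-SNP genotype counts, percentages
#' to 1 dp and chi-square p to 4 dp), `screen.tsv`, `model.tsv` (OR and AOR
#' per retained SNP), `subgroups.tsv` when computed, and `summary.json`.
#'
#' @param study A `dloop_study`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_reports <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  w <- function(df, name) {
    p <- file.path(dir, name)
    readr::write_tsv(df, p, na = "NA")
    paths <<- c(paths, p)
  }
  w(study$snps[, c("snp_no", "column", "rcrs_pos", "iupac", "alleles",
                   "known_label")], "snp_positions.tsv")
  assoc_tbl <- dplyr::mutate(
    study$snps[, c("snp_no", "rcrs_pos", "iupac", "indicator", "n_case_ind",
                   "n_case_other", "n_control_ind", "n_control_other", "chi2", "p")],
    pct_case = round(100 * .data$n_case_ind /
                       (.data$n_case_ind + .data$n_case_other), 1),
    pct_control = round(100 * .data$n_control_ind /
                          (.data$n_control_ind + .data$n_control_other), 1),
    p = round(.data$p, 4), chi2 = round(.data$chi2, 4)
  )
  w(assoc_tbl, "snp_assoc.tsv")
  w(assoc_tbl[assoc_tbl$snp_no %in% study$shortlist$snp_no, ], "screen.tsv")
  w(study_model_table(study), "model.tsv")
  if (!is.null(study$subgroups)) w(study$subgroups, "subgroups.tsv")
  summary_path <- file.path(dir, "summary.json")
  jsonlite::write_json(list(
    n_case = unname(study$cohort_n[["case"]]),
    n_control = unname(study$cohort_n[["control"]]),
    n_snps = nrow(study$snps),
    n_screened = nrow(study$shortlist),
    retained = if (is.null(study$selection)) character(0) else study$selection$retained,
    params = study$params[c("maf_threshold", "alpha_screen", "min_cell", "alpha_stay")]
  ), summary_path, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, summary_path))
}

#' Run a simulation experiment and write its summary
#'
#' Thin wrapper over [recovery_experiment()] that writes the per-site summary
#' (`summary.tsv`), per-replicate detail (`replicates.tsv`) and run metadata
#' (`truth.json`).
#'
#' @param spec A `cohort_spec`.
#' @param replicates Number of replicate cohorts.
#' @param dir Output directory.
#' @param ... Passed to [recovery_experiment()].
#' @return The `recovery_summary`, invisibly.
#' @export
run_simulation <- function(spec, replicates, dir, ...) {
  res <- recovery_experiment(spec, replicates, ...)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(res$sites, file.path(dir, "summary.tsv"))
  readr::write_tsv(res$replicates, file.path(dir, "replicates.tsv"))
  jsonlite::write_json(c(res$params, list(
    n_cases = spec$n_cases, n_controls = spec$n_controls,
    sites = nrow(spec$snps))), file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(res)
}
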