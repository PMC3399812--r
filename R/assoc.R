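# Case-control association cascade: per-SNP chi-square screens, cross-product
# odds ratios with Wald intervals, backward-elimination logistic regression,
# covariate-adjusted odds ratios, and subgroup reruns.
#
# All chi-square statistics are Pearson WITHOUT continuity correction and
# without switching to exact tests at small expected counts; this is the
# convention the study tables follow (their small-cell rows reproduce exactly
# only under plain Pearson).

#' Pearson chi-square for a 2x2 table
#'
#' Cells are `(a, b, c, d)` = (case-indicator, case-other, control-indicator,
#' control-other). Equivalent to the closed form
#' `n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` with 1 df and no continuity
#' correction.
#'
#' @param a,b,c,d Non-negative counts; all four margins must be positive.
#' @return A one-row tibble: `a`, `b`, `c`, `d`, `chi2`, `df`, `p`.
#' @export
#' @examples
#' chi2_2x2(185, 8, 692, 12)$p # 0.0419 at 4 dp
chi2_2x2 <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0) {
    stop("chi-square undefined: a zero margin in the 2x2 table", call. = FALSE)
  }
  ht <- suppressWarnings(
    stats::chisq.test(matrix(c(a, b, c, d), nrow = 2, byrow = TRUE), correct = FALSE)
  )
  tibble::tibble(a = a, b = b, c = c, d = d,
                 chi2 = unname(ht$statistic), df = 1L, p = unname(ht$p.value))
}

#' Pearson chi-square for an r x c contingency table
#'
#' @param tab Numeric matrix of counts with at least two rows and two columns,
#'   all margins positive.
#' @return A one-row tibble: `chi2`, `df`, `p`.
#' @export
chi2_rxc <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2 || ncol(tab) < 2) stop("table must be at least 2x2", call. = FALSE)
  if (any(tab < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("chi-square undefined: a zero margin", call. = FALSE)
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  tibble::tibble(chi2 = unname(ht$statistic), df = as.integer(ht$parameter),
                 p = unname(ht$p.value))
}

#' Cross-product odds ratio with 95% Wald interval
#'
#' `OR = ad / (bc)`, with the interval
#' `exp(log OR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))` (Woolf). When any cell
#' is zero the Haldane-Anscombe correction (0.5 added to every cell) is
#' applied and flagged.
#'
#' @param a,b,c,d Non-negative counts, laid out as in [chi2_2x2()].
#' @param conf_level Confidence level of the Wald interval.
#' @return A one-row tibble: `or`, `ci_low`, `ci_high`, `continuity_applied`.
#' @export
odds_ratio <- function(a, b, c, d, conf_level = 0.95) {
  counts <- c(a, b, c, d)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  corrected <- any(counts == 0)
  if (corrected) counts <- counts + 0.5
  lo <- log(counts[1]) + log(counts[4]) - log(counts[2]) - log(counts[3])
  se <- sqrt(sum(1 / counts))
  z <- qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(or = exp(lo), ci_low = exp(lo - z * se), ci_high = exp(lo + z * se),
                 continuity_applied = corrected)
}

#' Per-SNP 2x2 association statistics
#'
#' For every called SNP, the chi-square test and cross-product odds ratio of
#' the indicator-versus-other 2x2 table by group.
#'
#' @param snps A `snp_table` from [call_snps()].
#' @return `snps` with `chi2`, `p`, `or`, `ci_low`, `ci_high`,
#'   `continuity_applied` appended (the study's per-SNP screen table).
#' @export
snp_assoc <- function(snps) {
  a <- as.numeric(snps$n_case_ind)
  b <- as.numeric(snps$n_case_other)
  c_ <- as.numeric(snps$n_control_ind)
  d <- as.numeric(snps$n_control_other)
  n <- a + b + c_ + d
  chi2 <- n * (a * d - b * c_)^2 /
    ((a + b) * (c_ + d) * (a + c_) * (b + d))
  corrected <- a == 0 | b == 0 | c_ == 0 | d == 0
  ah <- a + 0.5 * corrected
  bh <- b + 0.5 * corrected
  ch <- c_ + 0.5 * corrected
  dh <- d + 0.5 * corrected
  lo <- log(ah) + log(dh) - log(bh) - log(ch)
  se <- sqrt(1 / ah + 1 / bh + 1 / ch + 1 / dh)
  z <- qnorm(0.975)
  dplyr::bind_cols(snps, tibble::tibble(
    chi2 = chi2, p = pchisq(chi2, 1, lower.tail = FALSE),
    or = exp(lo), ci_low = exp(lo - z * se), ci_high = exp(lo + z * se),
    continuity_applied = corrected
  ))
}

#' Screen SNPs for the multivariable model
#'
#' Shortlists the SNPs whose 2x2 chi-square p-value is below `alpha` and whose
#' 2x2 table has all four cells at least `min_cell` ("significant differences
#' and sufficient cell sizes").
#'
#' @param snps A `snp_table` (association columns are added if absent).
#' @param alpha Significance level of the screen; default 0.05.
#' @param min_cell Minimum count required in every 2x2 cell; default 4.
#' @return The shortlist rows of [snp_assoc()] output.
#' @export
screen_candidates <- function(snps, alpha = 0.05, min_cell = 4) {
  if (nrow(snps) == 0) return(dplyr::bind_cols(snps))
  if (!"p" %in% names(snps)) snps <- snp_assoc(snps)
  keep <- snps$p < alpha &
    pmin(snps$n_case_ind, snps$n_case_other,
         snps$n_control_ind, snps$n_control_other) >= min_cell
  keep[is.na(keep)] <- FALSE
  snps[keep, , drop = FALSE]
}

# --- logistic regression ----------------------------------------------------

#' Logistic regression fit (maximum likelihood, complete cases)
#'
#' Fits `outcome ~ terms` by IRLS on the complete-case rows, with Wald z tests
#' per term. SNP indicator predictors are coded 1 = indicator allele; binary
#' covariates 1 = yes; continuous covariates enter untransformed. Perfect
#' separation and non-convergence are flagged, and a singular design (e.g. a
#' constant predictor) is an error.
#'
#' @param data Data frame containing `outcome` (0/1) and every term.
#' @param terms Character vector of predictor column names.
#' @param outcome Name of the binary outcome column; default `"case"`.
#' @return An object of class `dloop_logit`; see [tidy.dloop_logit()].
#' @export
logistic_fit <- function(data, terms, outcome = "case") {
  stopifnot(length(terms) >= 1)
  missing_cols <- setdiff(c(outcome, terms), names(data))
  if (length(missing_cols)) {
    stop("columns not found: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  d <- data[, c(outcome, terms), drop = FALSE]
  d <- d[complete.cases(d), , drop = FALSE]
  if (nrow(d) < length(terms) + 2) {
    stop("too few complete-case rows for the number of parameters", call. = FALSE)
  }
  y <- d[[outcome]]
  if (length(unique(y)) < 2) stop("outcome has a single class", call. = FALSE)
  fml <- stats::as.formula(paste(outcome, "~", paste(sprintf("`%s`", terms), collapse = " + ")))
  separation <- FALSE
  fit <- withCallingHandlers(
    glm(fml, family = binomial(), data = d),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (anyNA(coef(fit))) {
    stop("singular design: aliased/constant predictor(s): ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "), call. = FALSE)
  }
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  z <- est / se
  res <- tibble::tibble(
    term = sub("^`(.*)`$", "\\1", names(est)),
    estimate = unname(est), std.error = unname(se), statistic = unname(z),
    p.value = 2 * stats::pnorm(-abs(z)),
    or = exp(unname(est)),
    ci_low = exp(unname(est - qnorm(0.975) * se)),
    ci_high = exp(unname(est + qnorm(0.975) * se))
  )
  structure(list(tidy = res, terms = terms, outcome = outcome,
                 converged = fit$converged, separation = separation,
                 n_used = nrow(d), deviance = fit$deviance, aic = fit$aic,
                 glm = fit),
            class = "dloop_logit")
}

#' @export
print.dloop_logit <- function(x, ...) {
  cat(sprintf("<dloop_logit> %s ~ %d term(s), n = %d%s%s\n", x$outcome,
              length(x$terms), x$n_used,
              if (!x$converged) ", NOT CONVERGED" else "",
              if (x$separation) ", possible separation" else ""))
  print(x$tidy)
  invisible(x)
}

#' Tidy a logistic fit
#'
#' @param x A `dloop_logit`.
#' @param ... Unused.
#' @return A tibble with one row per model term: `term`, `estimate` (log
#'   odds), `std.error`, `statistic` (Wald z), `p.value`, and the implied
#'   `or`, `ci_low`, `ci_high`.
#' @method tidy dloop_logit
#' @export
tidy.dloop_logit <- function(x, ...) x$tidy

#' One-row model summary of a logistic fit
#'
#' @param x A `dloop_logit`.
#' @param ... Unused.
#' @return A tibble: `n_used`, `converged`, `separation`, `deviance`, `aic`.
#' @method glance dloop_logit
#' @export
glance.dloop_logit <- function(x, ...) {
  tibble::tibble(n_used = x$n_used, converged = x$converged,
                 separation = x$separation, deviance = x$deviance, aic = x$aic)
}

#' Backward elimination of SNP terms
#'
#' Repeatedly refits the logistic model and removes the candidate with the
#' largest Wald p-value while it exceeds `alpha_stay`; `forced` terms (e.g.
#' adjustment covariates) are never removed. Ties are broken deterministically
#' by removing the later-listed candidate. Every retained candidate satisfies
#' `p <= alpha_stay` in the final fit.
#'
#' @param data Data frame with the outcome and all terms.
#' @param candidates Character vector of candidate term names, in order.
#' @param forced Character vector of terms always kept.
#' @param alpha_stay Stay criterion; default 0.05.
#' @param outcome Binary outcome column name.
#' @return An object of class `dloop_selection`: retained terms, the
#'   elimination trace, and the final `dloop_logit` (`NULL` when nothing
#'   remains to fit).
#' @export
backward_eliminate <- function(data, candidates, forced = character(),
                               alpha_stay = 0.05, outcome = "case") {
  stopifnot(length(candidates) >= 1)
  current <- candidates
  trace <- tibble::tibble(step = integer(), term = character(), p_at_removal = double())
  step <- 0L
  final <- NULL
  repeat {
    terms <- c(current, forced)
    if (length(terms) == 0) break
    final <- logistic_fit(data, terms, outcome = outcome)
    if (length(current) == 0) break
    td <- final$tidy[final$tidy$term %in% current, , drop = FALSE]
    p <- td$p.value[match(current, td$term)]
    worst_p <- max(p)
    if (worst_p <= alpha_stay) break
    ties <- which(p == worst_p)
    drop_idx <- ties[length(ties)]        # later-listed candidate goes first
    step <- step + 1L
    trace <- dplyr::bind_rows(trace, tibble::tibble(
      step = step, term = current[drop_idx], p_at_removal = worst_p))
    current <- current[-drop_idx]
    if (length(current) == 0 && length(forced) == 0) {
      final <- NULL
      break
    }
  }
  structure(list(retained = current, eliminated = trace, alpha_stay = alpha_stay,
                 forced = forced, final = final),
            class = "dloop_selection")
}

#' @export
print.dloop_selection <- function(x, ...) {
  cat(sprintf("<dloop_selection> retained %d of %d candidate(s) at alpha = %g\n",
              length(x$retained), length(x$retained) + nrow(x$eliminated), x$alpha_stay))
  if (length(x$retained)) cat("  retained:", paste(x$retained, collapse = ", "), "\n")
  if (nrow(x$eliminated)) {
    cat("  eliminated (in order):",
        paste(sprintf("%s (p=%.4g)", x$eliminated$term, x$eliminated$p_at_removal),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tidy a backward-selection result
#'
#' @param x A `dloop_selection`.
#' @param ... Unused.
#' @return The tidy coefficient table of the final fit restricted to retained
#'   and forced terms (empty tibble when nothing was retained).
#' @method tidy dloop_selection
#' @export
tidy.dloop_selection <- function(x, ...) {
  if (is.null(x$final)) {
    return(tibble::tibble(term = character(), estimate = double(),
                          std.error = double(), statistic = double(),
                          p.value = double(), or = double(),
                          ci_low = double(), ci_high = double()))
  }
  td <- tidy(x$final)
  td[td$term %in% c(x$retained, x$forced), , drop = FALSE]
}

#' One-row summary of a backward-selection result
#'
#' @param x A `dloop_selection`.
#' @param ... Unused.
#' @return A tibble: `n_candidates`, `n_retained`, `n_eliminated`,
#'   `alpha_stay`, `n_used`.
#' @method glance dloop_selection
#' @export
glance.dloop_selection <- function(x, ...) {
  tibble::tibble(
    n_candidates = length(x$retained) + nrow(x$eliminated),
    n_retained = length(x$retained),
    n_eliminated = nrow(x$eliminated),
    alpha_stay = x$alpha_stay,
    n_used = if (is.null(x$final)) NA_integer_ else x$final$n_used
  )
}

# --- covariates and adjustment ---------------------------------------------

#' Standard adjustment covariates
#'
#' The eleven demographic / laboratory covariates of the adjusted models:
#' sex, diabetes mellitus, coronary heart disease, smoking, hypertension,
#' age, body mass index, TBARS, thiols, triglyceride and cholesterol.
#'
#' @return Character vector of design column names.
#' @export
adjustment_covariates <- function() {
  c("sex", "dm", "chd", "smoke", "ht", "age", "bmi", "tbars", "thiols", "tg", "chol")
}

#' Numeric design columns for a covariate table
#'
#' Recodes a covariate tibble for regression: `sex` 1 = female, the yes/no
#' comorbidity and smoking flags 1 = yes, continuous covariates untransformed.
#' Missing values stay `NA` (complete-case handling happens at fit time).
#'
#' @param covariates Tibble with columns `subject_id`, `sex`
#'   (female/male), `age`, `dm`, `chd`, `ht`, `smoke` (yes/no), `bmi`,
#'   `tbars`, `thiols`, `tg`, `chol`.
#' @return A tibble with `subject_id` and the numeric columns of
#'   [adjustment_covariates()].
#' @export
covariate_design <- function(covariates) {
  yn <- function(x) {
    x <- tolower(as.character(x))
    out <- ifelse(x %in% c("y", "yes", "1", "true"), 1L,
                  ifelse(x %in% c("n", "no", "0", "false"), 0L, NA_integer_))
    out
  }
  tibble::tibble(
    subject_id = as.character(covariates$subject_id),
    sex = ifelse(tolower(as.character(covariates$sex)) == "female", 1L,
                 ifelse(tolower(as.character(covariates$sex)) == "male", 0L, NA_integer_)),
    dm = yn(covariates$dm), chd = yn(covariates$chd), smoke = yn(covariates$smoke),
    ht = yn(covariates$ht),
    age = as.numeric(covariates$age), bmi = as.numeric(covariates$bmi),
    tbars = as.numeric(covariates$tbars), thiols = as.numeric(covariates$thiols),
    tg = as.numeric(covariates$tg), chol = as.numeric(covariates$chol)
  )
}

#' Read a per-subject covariate table
#'
#' Tab-separated with header
#' `subject_id group sex age dm chd ht smoke bmi tbars thiols tg chol` and
#' `NA` for missing cells.
#'
#' @param path Path to the TSV file.
#' @return A tibble.
#' @export
read_covariates <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    subject_id = readr::col_character(), group = readr::col_character(),
    sex = readr::col_character(), age = readr::col_double(),
    dm = readr::col_character(), chd = readr::col_character(),
    ht = readr::col_character(), smoke = readr::col_character(),
    bmi = readr::col_double(), tbars = readr::col_double(),
    thiols = readr::col_double(), tg = readr::col_double(),
    chol = readr::col_double()
  ), na = "NA")
}

#' Covariate-adjusted odds ratios for selected SNPs
#'
#' Complete-case logistic fit of case status on the selected SNP indicators
#' plus the adjustment covariates; the exponentiated SNP coefficients are the
#' adjusted odds ratios (AORs).
#'
#' @param design SNP design tibble from [snp_design()].
#' @param covariates Covariate tibble (see [read_covariates()]), joined by
#'   `subject_id`.
#' @param snp_terms Character vector of SNP columns to adjust (e.g.
#'   `c("SNP55", "SNP56", "SNP64")`).
#' @param covariate_terms Covariates entering the model; default all eleven
#'   standard covariates. An empty vector reduces to the unadjusted joint fit.
#' @return A `dloop_logit`.
#' @export
adjusted_or <- function(design, covariates, snp_terms,
                        covariate_terms = adjustment_covariates()) {
  cd <- covariate_design(covariates)
  d <- dplyr::left_join(design, cd, by = "subject_id")
  logistic_fit(d, c(snp_terms, covariate_terms))
}

# --- subgroups --------------------------------------------------------------

#' Default subgroup definitions
#'
#' Strata over the basic demographic characteristics: sex (female/male), age
#' dichotomised at 50 years, and presence/absence of diabetes, coronary heart
#' disease, smoking and hypertension. Each entry names the stratifying design
#' column and the rule that assigns a subject to the stratum level.
#'
#' @param age_cut Age threshold in years; default 50 ("age <= 50" vs
#'   "age > 50").
#' @return A tibble: `stratifier`, `level`, and a predicate list-column
#'   `rule` over the joined design.
#' @export
subgroup_definitions <- function(age_cut = 50) {
  mk <- function(stratifier, level, f) {
    tibble::tibble(stratifier = stratifier, level = level, rule = list(f))
  }
  dplyr::bind_rows(
    mk("sex", "female", function(d) d$sex == 1),
    mk("sex", "male", function(d) d$sex == 0),
    mk("age", sprintf("age<=%g", age_cut), function(d) d$age <= age_cut),
    mk("age", sprintf("age>%g", age_cut), function(d) d$age > age_cut),
    mk("dm", "no_dm", function(d) d$dm == 0),
    mk("dm", "dm", function(d) d$dm == 1),
    mk("chd", "no_chd", function(d) d$chd == 0),
    mk("chd", "chd", function(d) d$chd == 1),
    mk("smoke", "non_smoker", function(d) d$smoke == 0),
    mk("smoke", "smoker", function(d) d$smoke == 1),
    mk("ht", "no_ht", function(d) d$ht == 0),
    mk("ht", "ht", function(d) d$ht == 1)
  )
}

#' Subgroup association reruns
#'
#' Within each stratum, reruns backward elimination over the candidate SNP
#' terms, reports the unadjusted (joint) odds ratios of the retained terms,
#' and then recomputes adjusted odds ratios adding the standard covariates
#' minus the stratifying variable. Strata with a single outcome class (or too
#' few complete cases to fit) are skipped with a warning.
#'
#' @param design SNP design tibble from [snp_design()].
#' @param covariates Covariate tibble joined by `subject_id`.
#' @param candidates Candidate SNP term names.
#' @param strata Subgroup definitions as from [subgroup_definitions()]; the
#'   degenerate one-row definition `stratifier = "all"` reproduces the
#'   unstratified analysis.
#' @param alpha_stay Stay criterion for elimination.
#' @return A tibble with one row per stratum x retained term: `stratifier`,
#'   `level`, `n`, `term`, `or`, `ci_low`, `ci_high`, `p`, `aor`, `aor_low`,
#'   `aor_high`, `aor_p`. Strata retaining nothing contribute a single row
#'   with `term = NA`.
#' @export
subgroup_analysis <- function(design, covariates, candidates,
                              strata = subgroup_definitions(), alpha_stay = 0.05) {
  cd <- covariate_design(covariates)
  d <- dplyr::left_join(design, cd, by = "subject_id")
  purrr::pmap_dfr(strata, function(stratifier, level, rule) {
    keep <- if (identical(stratifier, "all")) rep(TRUE, nrow(d)) else rule(d)
    keep[is.na(keep)] <- FALSE
    sub <- d[keep, , drop = FALSE]
    base <- tibble::tibble(stratifier = stratifier, level = level, n = nrow(sub))
    if (length(unique(sub$case)) < 2) {
      warning("stratum ", level, " has a single outcome class; skipped", call. = FALSE)
      return(dplyr::mutate(base, term = NA_character_, or = NA_real_,
                           ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
                           aor = NA_real_, aor_low = NA_real_, aor_high = NA_real_,
                           aor_p = NA_real_))
    }
    sel <- tryCatch(
      backward_eliminate(sub, candidates, alpha_stay = alpha_stay),
      error = function(e) {
        warning("stratum ", level, ": ", conditionMessage(e), call. = FALSE)
        NULL
      }
    )
    if (is.null(sel) || length(sel$retained) == 0) {
      return(dplyr::mutate(base, term = NA_character_, or = NA_real_,
                           ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
                           aor = NA_real_, aor_low = NA_real_, aor_high = NA_real_,
                           aor_p = NA_real_))
    }
    td <- tidy(sel)
    adj_terms <- setdiff(adjustment_covariates(), stratifier)
    adj <- tryCatch(logistic_fit(sub, c(sel$retained, adj_terms)),
                    error = function(e) NULL)
    at <- if (is.null(adj)) NULL else tidy(adj)
    purrr::map_dfr(sel$retained, function(tm) {
      r <- td[td$term == tm, ]
      ar <- if (is.null(at)) NULL else at[at$term == tm, ]
      dplyr::mutate(base, term = tm, or = r$or, ci_low = r$ci_low,
                    ci_high = r$ci_high, p = r$p.value,
                    aor = if (is.null(ar) || nrow(ar) == 0) NA_real_ else ar$or,
                    aor_low = if (is.null(ar) || nrow(ar) == 0) NA_real_ else ar$ci_low,
                    aor_high = if (is.null(ar) || nrow(ar) == 0) NA_real_ else ar$ci_high,
                    aor_p = if (is.null(ar) || nrow(ar) == 0) NA_real_ else ar$p.value)
    })
  })
}
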