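# Contingency statistics, odds ratios, logistic fits, backward elimination,
# adjustment and subgroups.

closed_form_chi2 <- function(a, b, c, d) {
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

test_that("chi2_2x2 matches the closed form on random tables", {
  set.seed(101)
  for (i in 1:50) {
    t <- rpois(4, lambda = sample(c(5, 50, 300), 1)) + 1
    got <- chi2_2x2(t[1], t[2], t[3], t[4])
    expect_equal(got$chi2, closed_form_chi2(t[1], t[2], t[3], t[4]), tolerance = 1e-10)
    expect_equal(got$p, pchisq(got$chi2, 1, lower.tail = FALSE))
  }
  null <- chi2_2x2(10, 10, 10, 10)
  expect_equal(null$chi2, 0)
  expect_equal(null$p, 1)
  expect_error(chi2_2x2(0, 0, 5, 5), "zero margin")
  expect_error(chi2_2x2(-1, 2, 3, 4), "non-negative")
})

test_that("chi2_2x2 is invariant under row and column swaps", {
  got <- chi2_2x2(14, 179, 11, 693)
  expect_equal(chi2_2x2(11, 693, 14, 179)$chi2, got$chi2)   # row swap
  expect_equal(chi2_2x2(179, 14, 693, 11)$chi2, got$chi2)   # indicator flip
  expect_equal(chi2_2x2(179, 14, 693, 11)$p, got$p)
})

test_that("chi2_rxc reduces to chi2_2x2 and matches the expected-count oracle", {
  set.seed(202)
  for (i in 1:20) {
    t <- matrix(rpois(4, 40) + 1, 2)
    expect_equal(chi2_rxc(t)$chi2, chi2_2x2(t[1, 1], t[1, 2], t[2, 1], t[2, 2])$chi2)
  }
  flat <- chi2_rxc(matrix(10, 2, 3))
  expect_equal(flat$chi2, 0)
  expect_equal(flat$df, 2L)
  expect_equal(flat$p, 1)
  for (i in 1:20) {
    t <- matrix(rpois(8, 25) + 1, 2)
    e <- outer(rowSums(t), colSums(t)) / sum(t)
    expect_equal(chi2_rxc(t)$chi2, sum((t - e)^2 / e), tolerance = 1e-10)
  }
  expect_error(chi2_rxc(matrix(c(0, 0, 3, 4), 2)), "zero margin")
})

test_that("odds_ratio computes the cross-product with Wald CI and Haldane correction", {
  expect_equal(round(odds_ratio(14, 179, 11, 693)$or, 2), 4.93)
  expect_equal(round(odds_ratio(5, 188, 4, 700)$or, 2), 4.65)
  expect_equal(odds_ratio(5, 5, 5, 5)$or, 1)
  hand <- odds_ratio(119, 74, 369, 335)
  lo <- log(119 * 335 / (74 * 369))
  se <- sqrt(1 / 119 + 1 / 74 + 1 / 369 + 1 / 335)
  expect_equal(hand$ci_low, exp(lo - qnorm(0.975) * se))
  expect_equal(hand$ci_high, exp(lo + qnorm(0.975) * se))
  z <- odds_ratio(0, 20, 5, 15)
  expect_true(z$continuity_applied)
  expect_true(is.finite(z$or) && z$or > 0)
  expect_false(odds_ratio(1, 20, 5, 15)$continuity_applied)
})

test_that("exp(univariate logistic coefficient) equals the cross-product OR", {
  set.seed(303)
  for (i in 1:20) {
    n <- 400
    x <- rbinom(n, 1, runif(1, 0.2, 0.6))
    y <- rbinom(n, 1, stats::plogis(-0.5 + 0.8 * x))
    a <- sum(y == 1 & x == 1); b <- sum(y == 1 & x == 0)
    c_ <- sum(y == 0 & x == 1); d <- sum(y == 0 & x == 0)
    if (min(a, b, c_, d) == 0) next
    fit <- logistic_fit(tibble::tibble(case = y, x = x), "x")
    expect_equal(fit$tidy$or[fit$tidy$term == "x"], a * d / (b * c_),
                 tolerance = 1e-6)
  }
})

test_that("logistic_fit flags degenerate designs and drops incomplete rows", {
  d <- sim_logit_data(300, freqs = c(0.4, 0.3), betas = c(1, 0), seed = 7)
  d$x1[1:10] <- NA
  fit <- logistic_fit(d, c("x1", "x2"))
  expect_equal(fit$n_used, 290)
  expect_true(fit$converged)
  expect_error(logistic_fit(dplyr::mutate(d, flat = 1), c("x1", "flat")),
               "singular design")
  expect_error(logistic_fit(dplyr::mutate(d, case = 1), "x1"), "single class")
  expect_error(logistic_fit(d[1:3, ], c("x1", "x2")), "too few complete-case")
  g <- glance(fit)
  expect_equal(g$n_used, 290)
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "p.value", "or") %in% names(td)))
  expect_equal(td$or, exp(td$estimate))
})

test_that("a null predictor yields small coefficients and calibrated p-values", {
  set.seed(404)
  ps <- replicate(100, {
    d <- tibble::tibble(case = rbinom(500, 1, 0.3), x = rbinom(500, 1, 0.4))
    logistic_fit(d, "x")$tidy$p.value[2]
  })
  # under the null, Wald p-values are approximately uniform
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
  expect_gt(mean(ps < 0.05), 0.0 - 1e-9)
  expect_lt(mean(ps < 0.05), 0.15)
})

test_that("backward elimination drops null terms and keeps the stay criterion", {
  # one strong planted effect among nine null candidates
  set.seed(505)
  hits <- replicate(100, {
    d <- sim_logit_data(900, freqs = rep(0.3, 10),
                        betas = c(log(5), rep(0, 9)), intercept = -1.5,
                        seed = sample.int(1e6, 1))
    sel <- backward_eliminate(d, paste0("x", 1:10))
    "x1" %in% sel$retained
  })
  expect_gte(mean(hits), 0.9)
})

test_that("backward elimination honours forced terms, ties and the final-fit invariant", {
  d <- sim_logit_data(600, freqs = c(0.4, 0.3, 0.35), betas = c(1.2, 0, 0), seed = 11)
  sel <- backward_eliminate(d, c("x2", "x3"), forced = "x1")
  expect_true("x1" %in% sel$final$terms)
  td <- tidy(sel)
  retained_p <- td$p.value[td$term %in% sel$retained]
  expect_true(all(retained_p <= sel$alpha_stay))
  # eliminated terms were above the stay criterion when removed
  expect_true(all(sel$eliminated$p_at_removal > sel$alpha_stay))
  # single candidate with p > 0.05 leaves nothing retained
  d2 <- tibble::tibble(case = rbinom(400, 1, 0.3), x = rbinom(400, 1, 0.5))
  set.seed(12)
  d2$case <- rbinom(400, 1, 0.3)
  sel2 <- backward_eliminate(d2, "x")
  if (logistic_fit(d2, "x")$tidy$p.value[2] > 0.05) {
    expect_length(sel2$retained, 0)
    expect_equal(nrow(tidy(sel2)), 0)
  }
})

test_that("screen_candidates applies both the alpha and the cell-size rule", {
  snps <- tibble::tibble(
    snp_no = 1:3, column = 1:3, rcrs_pos = 1:3, iupac = "Y", alleles = "C/T",
    n_alleles = 2L, indicator = "T",
    n_case_ind = c(8L, 3L, 20L), n_case_other = c(185L, 190L, 173L),
    n_control_ind = c(12L, 2L, 80L), n_control_other = c(692L, 702L, 624L)
  )
  class(snps) <- c("snp_table", class(snps))
  out <- screen_candidates(snps, alpha = 0.05, min_cell = 4)
  # row 2 is significant-ish but has cells below 4; row 3 is non-significant
  expect_true(1 %in% out$snp_no)
  expect_false(2 %in% out$snp_no)
  expect_equal(nrow(screen_candidates(snps[0, ])), 0)
})

test_that("adjustment recovers the unadjusted OR under independence and shrinks it under confounding", {
  set.seed(606)
  n <- 2000
  # independent covariate: AOR ~ OR
  x <- rbinom(n, 1, 0.3)
  z <- rnorm(n)
  y <- rbinom(n, 1, stats::plogis(-1 + 1.1 * x))
  d <- tibble::tibble(case = y, SNP1 = x, age = z)
  fit_u <- logistic_fit(d, "SNP1")
  fit_a <- logistic_fit(d, c("SNP1", "age"))
  or_u <- fit_u$tidy$or[2]; or_a <- fit_a$tidy$or[2]
  expect_lt(abs(log(or_a) - log(or_u)), 0.15)
  # confounder drives both exposure and outcome: adjustment attenuates
  u <- rbinom(n, 1, 0.5)
  x2 <- rbinom(n, 1, stats::plogis(-1.5 + 2 * u))
  y2 <- rbinom(n, 1, stats::plogis(-1.5 + 2 * u + 0.3 * x2))
  d2 <- tibble::tibble(case = y2, SNP1 = x2, conf = u)
  or_crude <- logistic_fit(d2, "SNP1")$tidy$or[2]
  or_adj <- logistic_fit(d2, c("SNP1", "conf"))$tidy$or[2]
  expect_lt(or_adj, or_crude)
})

test_that("adjusted_or joins covariates and equals a plain fit with no covariates", {
  spec <- cohort_spec(n_cases = 120, n_controls = 200, seed = 31)
  sim <- simulate_cohort(spec)
  cov <- simulate_covariates(spec)
  snps <- snp_assoc(call_snps(count_sites(mask_polyc(sim$cohort, synthetic_reference())),
                              map = window_map()))
  sl <- utils::head(dplyr::arrange(snps, p), 2)
  design <- snp_design(build_genotype_table(sim$cohort, sl), sl)
  terms <- paste0("SNP", sl$snp_no)
  plain <- logistic_fit(design, terms)
  viacov <- adjusted_or(design, cov, terms, covariate_terms = character(0))
  expect_equal(tidy(viacov)$estimate, tidy(plain)$estimate, tolerance = 1e-8)
  full <- adjusted_or(design, cov, terms)
  expect_true(all(terms %in% tidy(full)$term))
  expect_true(all(adjustment_covariates() %in% tidy(full)$term))
  expect_lte(full$n_used, nrow(design))
})

test_that("covariate_design recodes sex, yes/no flags and keeps NA", {
  cov <- tibble::tibble(
    subject_id = c("a", "b", "c"), sex = c("female", "male", NA),
    age = c(40, 60, NA), dm = c("yes", "no", NA), chd = c("no", "no", "yes"),
    ht = c("Y", "N", NA), smoke = c("no", "yes", "no"),
    bmi = c(22, 25, NA), tbars = c(1, 1.2, 1), thiols = c(1.5, 2, 2),
    tg = c(150, 120, 110), chol = c(190, 200, 210)
  )
  d <- covariate_design(cov)
  expect_identical(d$sex, c(1L, 0L, NA))
  expect_identical(d$dm, c(1L, 0L, NA))
  expect_identical(d$ht, c(1L, 0L, NA))
  expect_true(is.na(d$age[3]))
})

test_that("the degenerate full-cohort stratum reproduces the unstratified analysis", {
  spec <- cohort_spec(n_cases = 150, n_controls = 400, seed = 77)
  sim <- simulate_cohort(spec)
  cov <- simulate_covariates(spec)
  snps <- snp_assoc(call_snps(count_sites(mask_polyc(sim$cohort, synthetic_reference())),
                              map = window_map()))
  sl <- utils::head(dplyr::arrange(snps, p), 3)
  design <- snp_design(build_genotype_table(sim$cohort, sl), sl)
  terms <- paste0("SNP", sl$snp_no)
  all_stratum <- tibble::tibble(stratifier = "all", level = "all",
                                rule = list(function(d) rep(TRUE, nrow(d))))
  sub <- suppressWarnings(subgroup_analysis(design, cov, terms, strata = all_stratum))
  sel <- backward_eliminate(dplyr::left_join(design, covariate_design(cov),
                                             by = "subject_id"), terms)
  expect_setequal(stats::na.omit(sub$term), sel$retained)
  if (length(sel$retained)) {
    td <- tidy(sel)
    for (tm in sel$retained) {
      expect_equal(sub$or[sub$term == tm], td$or[td$term == tm], tolerance = 1e-8)
    }
  }
})

test_that("a sex-specific planted effect is retained in the carrier stratum", {
  set.seed(808)
  n <- 1600
  female <- rbinom(n, 1, 0.5)
  x <- rbinom(n, 1, 0.25)
  eta <- -1.6 + ifelse(female == 1, log(6), 0) * x
  design <- tibble::tibble(
    subject_id = sprintf("s%04d", 1:n),
    group = NA_character_, case = rbinom(n, 1, stats::plogis(eta)),
    SNP1 = x
  )
  design$group <- ifelse(design$case == 1, "case", "control")
  cov <- tibble::tibble(
    subject_id = design$subject_id,
    sex = ifelse(female == 1, "female", "male"),
    age = rnorm(n, 50, 10), dm = "no", chd = "no", ht = "no", smoke = "no",
    bmi = rnorm(n, 23, 3), tbars = rnorm(n, 1, 0.5), thiols = rnorm(n, 1.8, 0.4),
    tg = rnorm(n, 140, 60), chol = rnorm(n, 195, 35)
  )
  strata <- subgroup_definitions()[1:2, ]   # female / male
  out <- suppressWarnings(subgroup_analysis(design, cov, "SNP1", strata = strata))
  expect_true("SNP1" %in% out$term[out$level == "female"])
  female_or <- out$or[out$level == "female" & out$term == "SNP1"]
  expect_gt(female_or, 2)
})
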