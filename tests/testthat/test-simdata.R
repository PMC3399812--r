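# The synthetic-cohort generator: determinism, planted truth, covariates and
# the recovery experiment harness.

test_that("identical spec and seed give byte-identical cohorts, different seeds differ", {
  spec <- cohort_spec(n_cases = 20, n_controls = 30, seed = 99)
  a <- simulate_cohort(spec)
  b <- simulate_cohort(spec)
  expect_identical(a$cohort$sequence, b$cohort$sequence)
  expect_identical(a$cohort$subject_id, b$cohort$subject_id)
  expect_identical(simulate_covariates(spec), simulate_covariates(spec))
  spec2 <- cohort_spec(n_cases = 20, n_controls = 30, seed = 100)
  c_ <- simulate_cohort(spec2)
  expect_false(identical(a$cohort$sequence, c_$cohort$sequence))
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(1234)
  before <- .Random.seed
  invisible(simulate_cohort(cohort_spec(n_cases = 5, n_controls = 5, seed = 3)))
  expect_identical(.Random.seed, before)
})

test_that("with no planted sites, noise or jitter, every sequence is the backbone", {
  ref <- synthetic_reference()
  map <- window_map()
  spec <- cohort_spec(n_cases = 3, n_controls = 4,
                      snps = snp_spec(integer(0), character(0), numeric(0), numeric(0)),
                      ambiguity_rate = 0, polyc_jitter = 0, seed = 1)
  sim <- simulate_cohort(spec, ref = ref, map = map)
  backbone <- ref_base(ref, map$rcrs_pos)
  # poly-C tracts are rewritten as pure C runs; elsewhere the backbone
  expected <- backbone
  for (i in seq_len(nrow(polyc_tracts()))) {
    t <- polyc_tracts()[i, ]
    expected[rcrs_to_align(map, seq.int(t$rcrs_start, t$rcrs_end))] <- "C"
  }
  expect_true(all(sim$cohort$sequence == paste(expected, collapse = "")))
})

test_that("truth carries the expected per-group carrier counts", {
  spec <- cohort_spec(seed = 5)   # defaults: 193 cases, 704 controls
  sim <- simulate_cohort(spec)
  t185 <- sim$truth$sites[sim$truth$sites$rcrs_pos == 185L, ]
  expect_equal(t185$expected_case, 193 * 14 / 193)
  expect_equal(t185$expected_control, 704 * 11 / 704)
  expect_true(t185$planted_effect)
  expect_equal(sum(sim$truth$sites$planted_effect), 9)
  expect_equal(nrow(dplyr::distinct(sim$truth$sites, rcrs_pos)), 77)
})

test_that("planted sites land on the right alignment columns with the right alleles", {
  ref <- synthetic_reference()
  map <- window_map()
  spec <- cohort_spec(n_cases = 250, n_controls = 250,
                      snps = snp_spec(16300L, "G", 0.5, 0.1),
                      ambiguity_rate = 0, polyc_jitter = 0, seed = 17)
  # spec alternate must differ from the backbone; pick accordingly
  alt <- setdiff(c("A", "C", "G", "T"), ref_base(ref, 16300L))[1]
  spec$snps$alt <- alt
  sim <- simulate_cohort(spec, ref = ref, map = map)
  m <- do.call(rbind, strsplit(sim$cohort$sequence, ""))
  col <- rcrs_to_align(map, 16300L)
  ca <- m[sim$cohort$group == "case", col]
  co <- m[sim$cohort$group == "control", col]
  expect_lt(abs(mean(ca == alt) - 0.5), 4 * sqrt(0.5 * 0.5 / 250))
  expect_lt(abs(mean(co == alt) - 0.1), 4 * sqrt(0.1 * 0.9 / 250))
  # a site inside a masked tract or outside the window is rejected
  bad <- cohort_spec(snps = snp_spec(16189L, "A", 0.1, 0.1))
  expect_error(simulate_cohort(bad), "poly-C tract")
  bad2 <- cohort_spec(snps = snp_spec(550L, "A", 0.1, 0.1))
  expect_error(simulate_cohort(bad2, map = map), "outside the mapped window")
})

test_that("adding a site to the spec does not perturb draws at existing sites", {
  ref <- synthetic_reference()
  map <- window_map()
  base <- snp_spec(16100L, setdiff(c("A", "C", "G", "T"), ref_base(ref, 16100L))[1],
                   0.3, 0.3)
  extra_alt <- setdiff(c("A", "C", "G", "T"), ref_base(ref, 400L))[1]
  wider <- snp_spec(c(16100L, 400L),
                    c(base$alt, extra_alt), c(0.3, 0.2), c(0.3, 0.2))
  s1 <- cohort_spec(n_cases = 30, n_controls = 30, snps = base,
                    ambiguity_rate = 0, polyc_jitter = 0, seed = 8)
  s2 <- cohort_spec(n_cases = 30, n_controls = 30, snps = wider,
                    ambiguity_rate = 0, polyc_jitter = 0, seed = 8)
  col <- rcrs_to_align(map, 16100L)
  m1 <- do.call(rbind, strsplit(simulate_cohort(s1, ref, map)$cohort$sequence, ""))
  m2 <- do.call(rbind, strsplit(simulate_cohort(s2, ref, map)$cohort$sequence, ""))
  expect_identical(m1[, col], m2[, col])
})

test_that("simulated covariates match their spec distributions", {
  spec <- cohort_spec(n_cases = 800, n_controls = 800, seed = 44)
  cov <- simulate_covariates(spec)
  expect_identical(cov$subject_id, simulate_cohort(spec)$cohort$subject_id)
  # binary proportion within 4 binomial SDs
  p <- 115 / 193
  p_hat <- mean(cov$sex[cov$group == "case"] == "female", na.rm = TRUE)
  expect_lt(abs(p_hat - p), 4 * sqrt(p * (1 - p) / 800))
  # continuous mean within 4 standard errors
  m_hat <- mean(cov$age[cov$group == "control"], na.rm = TRUE)
  expect_lt(abs(m_hat - 51.9), 4 * 12.9 / sqrt(800))
  # missingness only where the spec allows it
  expect_false(anyNA(cov$sex))
  expect_false(anyNA(cov$smoke))
  expect_gt(sum(is.na(cov$dm[cov$group == "control"])), 0)
  expect_equal(sum(is.na(cov$dm[cov$group == "case"])), 0)
  # a zero-missingness spec yields no NA at all
  cs <- spec
  cs$covariates$miss_case <- 0
  cs$covariates$miss_control <- 0
  expect_false(anyNA(simulate_covariates(cs)))
})

test_that("simulated cohorts pass validation and round-trip through FASTA", {
  spec <- cohort_spec(n_cases = 8, n_controls = 8, seed = 2)
  sim <- simulate_cohort(spec)
  expect_s3_class(sim$cohort, "dloop_cohort")
  ca <- withr::local_tempfile(fileext = ".fasta")
  co <- withr::local_tempfile(fileext = ".fasta")
  write_cohort(sim$cohort, ca, co)
  back <- read_cohort(ca, co)
  expect_identical(back$sequence, sim$cohort$sequence)
  cv <- withr::local_tempfile(fileext = ".tsv")
  write_covariates(simulate_covariates(spec), cv)
  expect_identical(read_covariates(cv)$subject_id, sim$cohort$subject_id)
})

test_that("snp_spec rejects inconsistent frequency tables", {
  expect_error(snp_spec(100L, "A", 1.2, 0.1), "\\[0, 1\\]")
  expect_error(snp_spec(c(100L, 100L), c("A", "G"), c(0.6, 0.6), c(0.1, 0.1)),
               "sum to at most 1")
  expect_error(snp_spec(c(100L, 100L), c("A", "A"), c(0.1, 0.1), c(0.1, 0.1)),
               "duplicate")
})

test_that("the null spec equalises group frequencies at the pooled value", {
  s <- study_snp_spec()
  n <- null_snp_spec()
  expect_identical(n$rcrs_pos, s$rcrs_pos)
  expect_equal(n$case_freq, n$control_freq)
  expect_equal(n$case_freq, (193 * s$case_freq + 704 * s$control_freq) / 897)
  expect_false(any(n$planted_effect))
})

test_that("recovery_experiment summarises one replicate coherently", {
  ref <- synthetic_reference()
  alt1 <- setdiff(c("A", "C", "G", "T"), ref_base(ref, 16050L))[1]
  alt2 <- setdiff(c("A", "C", "G", "T"), ref_base(ref, 450L))[1]
  spec <- cohort_spec(
    n_cases = 200, n_controls = 300,
    snps = snp_spec(c(16050L, 450L), c(alt1, alt2),
                    case_freq = c(0.40, 0.05), control_freq = c(0.10, 0.05)),
    ambiguity_rate = 0, seed = 13
  )
  out <- recovery_experiment(spec, replicates = 2)
  expect_s3_class(out, "recovery_summary")
  expect_equal(nrow(out$sites), 2)
  expect_equal(out$sites$n_reps, c(2L, 2L))
  expect_true(all(out$sites$call_rate >= 0 & out$sites$call_rate <= 1))
  strong <- out$sites[out$sites$rcrs_pos == 16050L, ]
  expect_equal(strong$call_rate, 1)
  expect_equal(strong$true_or, (0.4 / 0.6) / (0.1 / 0.9))
  expect_equal(nrow(out$replicates), 4)
  # rates are consistent with the per-replicate detail
  agg <- dplyr::summarise(dplyr::group_by(out$replicates, rcrs_pos),
                          sr = mean(screened), .groups = "drop")
  expect_equal(out$sites$screen_rate, agg$sr)
})
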