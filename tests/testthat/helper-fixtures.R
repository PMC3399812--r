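# In-code fixtures shared across the suite.

# An identity coordinate map over columns 1..n (rCRS positions 1..n).
identity_map <- function(n = 10L) {
  build_coordinate_map(data.frame(align_pos = c(1L, n), rcrs_pos = c(1L, n)))
}

# A small cohort built from explicit sequence vectors.
make_cohort <- function(case_seqs, control_seqs, map = NULL) {
  co <- as_cohort(tibble::tibble(
    subject_id = c(sprintf("ca%02d", seq_along(case_seqs)),
                   sprintf("co%02d", seq_along(control_seqs))),
    group = c(rep("case", length(case_seqs)), rep("control", length(control_seqs))),
    sequence = c(case_seqs, control_seqs)
  ))
  if (!is.null(map)) attr(co, "map") <- map
  co
}

# A cohort with a single column holding given base counts per group; used to
# reconstruct printed genotype-distribution rows exactly.
one_column_cohort <- function(case_bases, control_bases) {
  make_cohort(case_bases, control_bases)
}

# Expand c(C = 185, T = 8) into a base vector.
expand_counts <- function(counts) {
  rep(names(counts), times = counts)
}

# Simulate a case-control design-level dataset from a logistic model:
# p(case) = plogis(intercept + beta . x), predictors Bernoulli(freq).
sim_logit_data <- function(n, freqs, betas, intercept = -1, seed = 1) {
  stopifnot(length(freqs) == length(betas))
  set.seed(seed)
  x <- vapply(freqs, function(f) rbinom(n, 1, f), numeric(n))
  colnames(x) <- paste0("x", seq_along(freqs))
  eta <- intercept + as.vector(x %*% betas)
  d <- tibble::as_tibble(as.data.frame(x))
  d$case <- rbinom(n, 1, stats::plogis(eta))
  d
}
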