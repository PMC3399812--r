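# Synthetic case/control cohorts with known truth: haploid control-region
# sequences on a reference backbone with planted per-site, per-group allele
# frequencies, ambiguity noise, poly-C length jitter, and Table-style
# covariates. Everything is reproducible from a single root seed via labelled
# substreams, so adding a site to a spec does not perturb earlier draws.

#' Build a SNP spec table
#'
#' One row per planted alternate allele: rCRS position, the alternate base,
#' and its case/control frequencies. Multiple rows may share a position
#' (multi-allelic site) as long as each group's frequencies sum to at most 1.
#'
#' @param rcrs_pos,alt,case_freq,control_freq Parallel vectors.
#' @return A validated tibble.
#' @export
snp_spec <- function(rcrs_pos, alt, case_freq, control_freq) {
  out <- tibble::tibble(rcrs_pos = as.integer(rcrs_pos), alt = toupper(alt),
                        case_freq = case_freq, control_freq = control_freq)
  if (any(out$case_freq < 0 | out$case_freq > 1 |
          out$control_freq < 0 | out$control_freq > 1)) {
    stop("allele frequencies must lie in [0, 1]", call. = FALSE)
  }
  sums <- dplyr::summarise(dplyr::group_by(out, .data$rcrs_pos),
                           sc = sum(.data$case_freq), st = sum(.data$control_freq))
  if (any(sums$sc > 1 | sums$st > 1)) {
    stop("per-group alternate frequencies at a position must sum to at most 1",
         call. = FALSE)
  }
  if (anyDuplicated(out[, c("rcrs_pos", "alt")])) {
    stop("duplicate (position, allele) row in SNP spec", call. = FALSE)
  }
  out
}

#' The study-emulating SNP spec
#'
#' Plants alternate alleles at the 77 polymorphic D-loop positions of the
#' anchor table. The nine positions with significantly different genotype
#' distributions carry the study's observed per-group carrier frequencies
#' (e.g. nt185 A at 14/193 in cases vs 11/704 in controls); the remaining 68
#' positions are null sites with equal case/control frequencies, spread
#' log-uniformly over 1.2%-40% to emulate the range of minor-allele
#' frequencies a >1% screen retains.
#'
#' @param ref An `rcrs_ref` supplying the backbone base at each position (the
#'   planted alternate is chosen different from it).
#' @return A SNP spec tibble with an extra `planted_effect` flag.
#' @export
study_snp_spec <- function(ref = synthetic_reference()) {
  sig <- tibble::tibble(
    rcrs_pos = c(16108L, 16172L, 16223L, 16274L, 16278L, 16463L, 16519L, 185L, 189L),
    case_n = c(8, 36, 97, 6, 5, 5, 74, 14, 9),
    control_n = c(12, 90, 297, 7, 49, 4, 335, 11, 14)
  )
  sig$case_freq <- sig$case_n / 193
  sig$control_freq <- sig$control_n / 704
  anchors <- dloop_anchors()
  null_pos <- setdiff(anchors$rcrs_pos, sig$rcrs_pos)
  f <- 0.012 * (0.40 / 0.012)^(seq(0, 1, length.out = length(null_pos)))
  nulls <- tibble::tibble(rcrs_pos = null_pos, case_freq = f, control_freq = f)
  spec <- dplyr::bind_rows(
    dplyr::mutate(sig[, c("rcrs_pos", "case_freq", "control_freq")],
                  planted_effect = TRUE),
    dplyr::mutate(nulls, planted_effect = FALSE)
  )
  backbone <- ref_base(ref, spec$rcrs_pos)
  nxt <- c(A = "G", C = "T", G = "A", T = "C")   # a transition, as most mtDNA variants are
  spec$alt <- unname(nxt[backbone])
  out <- snp_spec(spec$rcrs_pos, spec$alt, spec$case_freq, spec$control_freq)
  out$planted_effect <- spec$planted_effect
  dplyr::arrange(out, unroll_rcrs(.data$rcrs_pos))
}

#' A null SNP spec (equal case/control frequencies)
#'
#' The study-emulating spec with every site's case frequency set equal to its
#' control frequency; used for type-I-error experiments.
#'
#' @param ref Backbone reference.
#' @return A SNP spec tibble.
#' @export
null_snp_spec <- function(ref = synthetic_reference()) {
  s <- study_snp_spec(ref)
  pooled <- (193 * s$case_freq + 704 * s$control_freq) / 897
  s$case_freq <- pooled
  s$control_freq <- pooled
  s$planted_effect <- FALSE
  s
}

#' The study-emulating covariate spec
#'
#' Per-covariate distributions matching the cohorts' demographics: binary
#' covariates as per-group proportions, continuous as per-group mean/SD, with
#' the observed missingness (diabetes, coronary heart disease and hypertension
#' status each missing for a small fraction of controls).
#'
#' @return A tibble: `name`, `type`, `case_p`, `control_p`, `case_mean`,
#'   `case_sd`, `control_mean`, `control_sd`, `miss_case`, `miss_control`.
#' @export
study_covariate_spec <- function() {
  b <- function(name, cp, tp, mc = 0, mt = 0) {
    tibble::tibble(name = name, type = "binary", case_p = cp, control_p = tp,
                   case_mean = NA_real_, case_sd = NA_real_,
                   control_mean = NA_real_, control_sd = NA_real_,
                   miss_case = mc, miss_control = mt)
  }
  ct <- function(name, cm, cs, tm, ts) {
    tibble::tibble(name = name, type = "continuous", case_p = NA_real_,
                   control_p = NA_real_, case_mean = cm, case_sd = cs,
                   control_mean = tm, control_sd = ts,
                   miss_case = 0, miss_control = 0)
  }
  dplyr::bind_rows(
    b("sex", 115 / 193, 312 / 704),                     # proportion female
    ct("age", 49.0, 13.9, 51.9, 12.9),
    b("dm", 32 / 193, 12 / 687, 0, 17 / 704),
    b("chd", 23 / 193, 11 / 695, 0, 9 / 704),
    b("ht", 84 / 193, 211 / 695, 0, 9 / 704),
    b("smoke", 23 / 193, 176 / 704),
    ct("bmi", 22.3, 3.8, 24.5, 3.5),
    ct("tbars", 1.1, 0.6, 1.2, 0.8),
    ct("thiols", 1.5, 0.5, 2.0, 0.4),
    ct("tg", 169.5, 128.1, 130.4, 85.7),
    ct("chol", 189.4, 35.7, 202.1, 37.9)
  )
}

#' Build a cohort simulation spec
#'
#' @param n_cases,n_controls Group sizes (default the study's 193 and 704).
#' @param snps SNP spec tibble (see [snp_spec()]); default [study_snp_spec()].
#' @param covariates Covariate spec tibble; default [study_covariate_spec()].
#' @param ambiguity_rate Per-base probability of emitting `N` (sequencing
#'   ambiguity); default 0.001.
#' @param polyc_jitter Maximum shortening, in bases, of each poly-C run
#'   relative to its tract span (per-subject uniform draw); default 3.
#' @param tracts Poly-C tract table, as [polyc_tracts()].
#' @param seed Root seed; every draw derives from it through labelled
#'   substreams.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_cases = 193, n_controls = 704,
                        snps = study_snp_spec(), covariates = study_covariate_spec(),
                        ambiguity_rate = 0.001, polyc_jitter = 3,
                        tracts = polyc_tracts(), seed = 1L) {
  stopifnot(n_cases >= 1, n_controls >= 1,
            ambiguity_rate >= 0, ambiguity_rate < 1, polyc_jitter >= 0)
  structure(list(n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
                 snps = snps, covariates = covariates,
                 ambiguity_rate = ambiguity_rate, polyc_jitter = as.integer(polyc_jitter),
                 tracts = tracts, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("<cohort_spec> %d cases / %d controls, %d planted allele(s), seed %d\n",
              x$n_cases, x$n_controls, nrow(x$snps), x$seed))
  invisible(x)
}

sim_subject_ids <- function(n_cases, n_controls) {
  c(sprintf("case_%04d", seq_len(n_cases)),
    sprintf("control_%04d", seq_len(n_controls)))
}

#' Simulate an aligned case/control cohort
#'
#' Each subject's sequence is the reference backbone over the map's window;
#' at every spec site an allele is drawn independently per subject from the
#' subject's group frequencies. Optional ambiguity noise replaces bases with
#' `N` at `ambiguity_rate`, and poly-C tracts are rewritten per subject as a
#' pure C-run of jittered length padded with gap characters — exactly the
#' alignment artefact that [mask_polyc()] exists to remove. Identical spec and
#' seed give byte-identical output.
#'
#' @param spec A `cohort_spec`.
#' @param ref Backbone reference (`rcrs_ref`).
#' @param map Alignment map for the simulated columns; default the trimmed
#'   analysis window via [window_map()]. Every spec site must be mapped and
#'   outside the masked tracts.
#' @return A list: `cohort` (tibble with the map attached) and `truth` (the
#'   spec plus the per-site expected carrier counts).
#' @export
simulate_cohort <- function(spec, ref = synthetic_reference(), map = window_map()) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_cases + spec$n_controls
  is_case <- c(rep(TRUE, spec$n_cases), rep(FALSE, spec$n_controls))
  backbone <- ref_base(ref, map$rcrs_pos)
  m <- matrix(rep(backbone, each = n), nrow = n)

  snps <- spec$snps
  if (nrow(snps) > 0) {
    if (nrow(spec$tracts) > 0) {
      in_tract <- purrr::map_lgl(snps$rcrs_pos, function(p) {
        any(p >= spec$tracts$rcrs_start & p <= spec$tracts$rcrs_end)
      })
      if (any(in_tract)) {
        stop("spec site(s) inside a masked poly-C tract: ",
             paste(snps$rcrs_pos[in_tract], collapse = ", "), call. = FALSE)
      }
    }
    cols <- rcrs_to_align(map, snps$rcrs_pos)
    if (anyNA(cols)) {
      stop("spec site(s) outside the mapped window: ",
           paste(snps$rcrs_pos[is.na(cols)], collapse = ", "), call. = FALSE)
    }
    for (pos in unique(snps$rcrs_pos)) {
      rows <- snps[snps$rcrs_pos == pos, , drop = FALSE]
      col <- cols[match(pos, snps$rcrs_pos)]
      refb <- backbone[match(col, map$align_pos)]
      if (any(rows$alt == refb)) {
        stop("spec alternate allele equals the backbone base at nt", pos, call. = FALSE)
      }
      alleles <- c(refb, rows$alt)
      pc <- c(1 - sum(rows$case_freq), rows$case_freq)
      pt <- c(1 - sum(rows$control_freq), rows$control_freq)
      draw <- with_seed(substream_seed(spec$seed, paste0("site", pos)), {
        u <- runif(n)
        ifelse(is_case,
               alleles[findInterval(u, cumsum(pc), left.open = TRUE) + 1L],
               alleles[findInterval(u, cumsum(pt), left.open = TRUE) + 1L])
      })
      m[, col] <- draw
    }
  }

  if (spec$ambiguity_rate > 0) {
    hit <- with_seed(substream_seed(spec$seed, "ambiguity"),
                     runif(length(m)) < spec$ambiguity_rate)
    m[hit] <- "N"
  }

  if (nrow(spec$tracts) > 0) {
    for (i in seq_len(nrow(spec$tracts))) {
      tc <- tract_columns(map, spec$tracts$rcrs_start[i], spec$tracts$rcrs_end[i])
      len <- length(tc$columns)
      deltas <- if (spec$polyc_jitter > 0) {
        with_seed(substream_seed(spec$seed, paste0("polyc", i)),
                  sample.int(spec$polyc_jitter + 1L, n, replace = TRUE) - 1L)
      } else {
        rep(0L, n)
      }
      run_len <- pmax(1L, len - deltas)
      block <- t(vapply(run_len, function(L) {
        c(rep("C", L), rep("-", len - L))
      }, character(len)))
      m[, tc$columns] <- block
    }
  }

  cohort <- as_cohort(tibble::tibble(
    subject_id = sim_subject_ids(spec$n_cases, spec$n_controls),
    group = ifelse(is_case, "case", "control"),
    sequence = collapse_matrix(m)
  ))
  cohort <- set_cohort_map(cohort, map)
  truth <- list(
    spec = spec,
    sites = dplyr::mutate(spec$snps,
                          expected_case = spec$n_cases * .data$case_freq,
                          expected_control = spec$n_controls * .data$control_freq)
  )
  list(cohort = cohort, truth = truth)
}

#' Simulate a per-subject covariate table
#'
#' Binary covariates are Bernoulli draws with per-group proportions,
#' continuous covariates normal with per-group mean/SD; missingness is applied
#' per group at the spec rates. Subject ids match [simulate_cohort()] output
#' for the same spec.
#'
#' @param spec A `cohort_spec`.
#' @return A covariate tibble in the [read_covariates()] layout.
#' @export
simulate_covariates <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_cases + spec$n_controls
  is_case <- c(rep(TRUE, spec$n_cases), rep(FALSE, spec$n_controls))
  out <- tibble::tibble(
    subject_id = sim_subject_ids(spec$n_cases, spec$n_controls),
    group = ifelse(is_case, "case", "control")
  )
  for (i in seq_len(nrow(spec$covariates))) {
    cv <- spec$covariates[i, ]
    vals <- with_seed(substream_seed(spec$seed, paste0("cov_", cv$name)), {
      v <- if (cv$type == "binary") {
        p <- ifelse(is_case, cv$case_p, cv$control_p)
        rbinom(n, 1, p)
      } else {
        rnorm(n, mean = ifelse(is_case, cv$case_mean, cv$control_mean),
              sd = ifelse(is_case, cv$case_sd, cv$control_sd))
      }
      miss <- runif(n) < ifelse(is_case, cv$miss_case, cv$miss_control)
      v[miss] <- NA
      v
    })
    if (cv$type == "binary") {
      vals <- if (cv$name == "sex") {
        ifelse(is.na(vals), NA_character_, ifelse(vals == 1, "female", "male"))
      } else {
        ifelse(is.na(vals), NA_character_, ifelse(vals == 1, "yes", "no"))
      }
    }
    out[[cv$name]] <- vals
  }
  out
}

#' Write a simulated covariate table to TSV
#'
#' @param covariates Tibble from [simulate_covariates()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_covariates <- function(covariates, path) {
  readr::write_tsv(covariates, path, na = "NA")
  invisible(path)
}

#' Replicated pipeline-recovery experiment
#'
#' Runs the full pipeline (simulate, mask, count, call, screen, backward
#' selection) on fresh cohorts drawn from `spec`, and summarises per planted
#' site: how often it is called, the recovered pooled/per-group allele
#' frequencies, the chi-square screen rejection rate, how often backward
#' selection retains it, and the cross-product odds-ratio estimates. Replicate
#' r uses the substream seed derived from `spec$seed` and label `rep<r>`.
#'
#' @param spec A `cohort_spec`.
#' @param replicates Number of replicate cohorts.
#' @param maf_threshold,alpha,min_cell,alpha_stay Pipeline parameters (the
#'   defaults are the study's).
#' @param ref,map Backbone and alignment map passed to [simulate_cohort()].
#' @return A list of class `recovery_summary`: `sites` (per-site summary
#'   tibble) and `replicates` (per-replicate, per-site detail).
#' @export
recovery_experiment <- function(spec, replicates, maf_threshold = 0.01,
                                alpha = 0.05, min_cell = 4, alpha_stay = 0.05,
                                ref = synthetic_reference(), map = window_map()) {
  stopifnot(inherits(spec, "cohort_spec"), replicates >= 1)
  per_rep <- purrr::map_dfr(seq_len(replicates), function(r) {
    rspec <- spec
    rspec$seed <- substream_seed(spec$seed, paste0("rep", r))
    sim <- simulate_cohort(rspec, ref = ref, map = map)
    cohort <- mask_polyc(sim$cohort, ref, tracts = spec$tracts)
    snps <- snp_assoc(call_snps(count_sites(cohort), map = map,
                                maf_threshold = maf_threshold))
    shortlist <- screen_candidates(snps, alpha = alpha, min_cell = min_cell)
    retained_pos <- integer(0)
    if (nrow(shortlist) > 0) {
      genos <- build_genotype_table(cohort, shortlist)
      design <- snp_design(genos, shortlist)
      sel <- backward_eliminate(design, paste0("SNP", shortlist$snp_no),
                                alpha_stay = alpha_stay)
      retained_pos <- shortlist$rcrs_pos[match(sel$retained,
                                               paste0("SNP", shortlist$snp_no))]
    }
    truth_sites <- dplyr::distinct(spec$snps, .data$rcrs_pos)
    idx <- match(truth_sites$rcrs_pos, snps$rcrs_pos)
    freq_of <- function(i, grp_n, grp_col) {
      if (is.na(i)) return(NA_real_)
      ac <- snps$allele_counts[[i]]
      alt <- spec$snps$alt[spec$snps$rcrs_pos == snps$rcrs_pos[i]][1]
      sum(ac[[grp_col]][ac$base == alt]) / grp_n
    }
    tibble::tibble(
      rep = r,
      rcrs_pos = truth_sites$rcrs_pos,
      called = !is.na(idx),
      case_freq_hat = vapply(idx, freq_of, numeric(1), grp_n = spec$n_cases,
                             grp_col = "n_case"),
      control_freq_hat = vapply(idx, freq_of, numeric(1), grp_n = spec$n_controls,
                                grp_col = "n_control"),
      p = ifelse(is.na(idx), NA_real_, snps$p[idx]),
      or_hat = ifelse(is.na(idx), NA_real_, snps$or[idx]),
      screened = truth_sites$rcrs_pos %in% shortlist$rcrs_pos,
      retained = truth_sites$rcrs_pos %in% retained_pos
    )
  })
  truth <- dplyr::summarise(
    dplyr::group_by(spec$snps, .data$rcrs_pos),
    case_freq = sum(.data$case_freq), control_freq = sum(.data$control_freq),
    .groups = "drop"
  )
  sites <- dplyr::summarise(
    dplyr::group_by(per_rep, .data$rcrs_pos),
    n_reps = dplyr::n(),
    call_rate = mean(.data$called),
    mean_case_freq_hat = mean(.data$case_freq_hat, na.rm = TRUE),
    mean_control_freq_hat = mean(.data$control_freq_hat, na.rm = TRUE),
    rejection_rate = mean(.data$p < alpha, na.rm = TRUE),
    screen_rate = mean(.data$screened),
    retention_rate = mean(.data$retained),
    median_or_hat = median(.data$or_hat, na.rm = TRUE),
    .groups = "drop"
  )
  sites <- dplyr::left_join(sites, truth, by = "rcrs_pos")
  sites$true_or <- with(sites, (case_freq / (1 - case_freq)) /
                          (control_freq / (1 - control_freq)))
  structure(list(sites = sites, replicates = per_rep,
                 params = list(seed = spec$seed, n_replicates = replicates,
                               alpha = alpha, min_cell = min_cell,
                               alpha_stay = alpha_stay, maf_threshold = maf_threshold)),
            class = "recovery_summary")
}

#' @export
print.recovery_summary <- function(x, ...) {
  cat(sprintf("<recovery_summary> %d site(s) x %d replicate(s)\n",
              nrow(x$sites), x$params$n_replicates))
  print(x$sites)
  invisible(x)
}
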