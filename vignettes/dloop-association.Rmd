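---
title: "Methods: D-loop SNP discovery and case-control association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: D-loop SNP discovery and case-control association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(dloopsnp)
```

## The problem

The mitochondrial D-loop (control region) is the most polymorphic stretch of
human mtDNA. A standard epidemiological design sequences it in a patient
group and a control group, calls the polymorphic positions, and asks which
variants are associated with case status. This package implements that whole
cascade as composable, tested functions:

1. map alignment columns to revised Cambridge Reference Sequence (rCRS)
   coordinates,
2. mask the two homopolymeric cytosine tracts and trim to the analysis
   window,
3. call SNPs by a pooled minor-allele frequency rule and code allele sets
   with IUPAC symbols,
4. screen each SNP with a chi-square test and cross-product odds ratio,
   fit a backward-elimination logistic model, adjust for covariates, and
   rerun within subgroups,
5. simulate cohorts with known truth so every stage's operating
   characteristics can be measured.

All tabular inputs and outputs are tibbles, so every stage pipes into the
next and into dplyr.

## Coordinates on a circular genome

The rCRS is circular with 16 569 positions; the control region spans
nt15911–16569 followed by nt1–602 across the origin. Internally positions
are *unrolled* onto a single increasing axis (`unroll_rcrs()`), so interval
logic never has to special-case the wrap.

Alignment columns are tied to rCRS positions through an anchor table — a set
of (column, position) pairs — interpolated linearly between anchors
(`build_coordinate_map()`). When the coordinate offset changes between two
anchors, the intervening rCRS positions are absent from the alignment
(deletions relative to the reference, or alignment conventions). The map
records them as *skipped*: `rcrs_to_align()` returns `NA` for them, and
`skipped_rcrs()` lists them. Where the anchor table does not pin down which
positions were skipped, a documented convention applies: known skip
positions are used when exactly the right number of them falls in the gap;
otherwise the skipped positions are taken immediately after the left anchor.
This convention is explicit, deterministic, and tested — but it is a
convention; anchor tables dense enough to pin every offset change are
preferable.

```{r}
map <- default_coordinate_map()
align_to_rcrs(map, c(51L, 662L))
rcrs_to_align(map, 16051L)
head(skipped_rcrs(map))
```

## Poly-C tracts and the analysis window

Two homopolymeric cytosine tracts (nt16184–16193 with a T at nt16189, and
nt303–315 with a T at nt310) show length heteroplasmy that sequencers and
aligners resolve inconsistently. Length variation there is real biology but
is not a SNP, so `mask_polyc()` overwrites those columns with the reference
bases for every subject before calling. Some workflows prefer a slightly
wider first tract (nt16180–16195); `polyc_tracts()` takes the spans as
arguments so either choice is explicit in the code that makes it.

`trim_window()` then restricts to the analysis window — by default
nt16000–16569 plus nt1–485, the region where typical D-loop reads give full
double-stranded coverage — and recalibrates the attached coordinate map so
downstream annotation stays correct.

## Calling SNPs

`count_sites()` tallies A/C/G/T per column, separately for cases and
controls; ambiguity codes and gap characters count as *unresolved*, never as
a base. `call_snps()` declares a column a SNP when at least two bases each
have pooled frequency strictly greater than `maf_threshold` (default 0.01),
with frequency defined over the pooled *resolved* count. The allele set is
exactly those bases, summarised by its IUPAC code. The *indicator* allele —
the one coded 1 in models — is the allele whose relative frequency exceeds
the controls' by the most (ties broken by case frequency, then
alphabetically), and each SNP's 2×2 table is indicator versus all other
resolved bases, by group.

The strict inequality matters at the boundary: with 897 subjects a base
carried by exactly 1% of them is not called. The threshold is a parameter,
not a constant, precisely so sensitivity analyses can move it.

## Association cascade

* `chi2_2x2()` / `chi2_rxc()` are Pearson chi-square tests **without**
  continuity correction — the convention under which the golden values in
  the test suite reproduce exactly.
* `odds_ratio()` is the cross-product estimate with a Wald (log-scale)
  confidence interval, applying the Haldane–Anscombe 0.5 correction only
  when a cell is zero (and flagging that it did).
* `screen_candidates()` keeps SNPs with p < `alpha` whose 2×2 cells are all
  at least `min_cell` (default 4), the usual guard against chi-square
  approximation failure in sparse tables.
* `backward_eliminate()` starts from all screened indicators, repeatedly
  refits and removes the term with the largest Wald p-value above
  `alpha_stay` (default 0.05), and stops when every remaining term stays.
  Forced terms are never removed. The elimination trace is kept so the path,
  not just the endpoint, is inspectable.
* `adjusted_or()` refits the retained SNPs together with the covariate set
  (sex, age, diabetes, coronary heart disease, smoking, hypertension, BMI,
  lipid and oxidative-stress measures) on complete cases, yielding adjusted
  odds ratios.
* `subgroup_analysis()` reruns screen-and-select within strata (sex, age
  group, each binary covariate's levels), dropping the stratifier from the
  adjustment set inside its own strata.

`run_study()` orchestrates all of it and `write_reports()` emits TSV/JSON
reports with percentages to one decimal and p-values to four, matching how
such tables are conventionally printed.

```{r}
spec <- cohort_spec(n_cases = 120, n_controls = 200, seed = 11)
sim <- simulate_cohort(spec)
study <- run_study(sim$cohort, covariates = simulate_covariates(spec))
study
```

## The generator, and what it is good for

`simulate_cohort()` draws haploid sequences on a reference backbone with
per-site, per-group planted allele frequencies, sprinkles ambiguity calls at
`ambiguity_rate`, and rewrites the poly-C tracts as jittered-length C-runs
padded with gaps — exactly the artefact masking exists to remove. Because
mtDNA is haploid and maternally inherited, a per-subject, per-site
independent draw is the natural generating model; what the generator does
*not* model is linkage between D-loop sites (haplogroup structure), so it is
a tool for validating the machinery's operating characteristics, not for
emulating population genetics.

The default spec mirrors the motivating study design: 193 cases versus 704
controls, 77 polymorphic sites, nine of them with group-differential carrier
frequencies, and a covariate table with realistic group differences and
missingness. `null_snp_spec()` equalises all frequencies for type-I-error
experiments. All randomness flows from one root seed through labelled
substreams (`substream_seed()`), so adding a site to a spec does not perturb
the draws at existing sites, and replicate r of an experiment is
reproducible in isolation.

`recovery_experiment()` runs the full cascade on replicate cohorts and
summarises, per site: call rate, recovered allele frequencies, screen
rejection rate, and how often backward selection retains it. The test suite
uses it to check that null sites are rejected at close to the nominal 5%,
that a strong planted effect (7.3% versus 1.6% carriers) is retained in the
majority of replicates, and that recovered frequencies sit within binomial
error of the planted values.

## Numerical and design choices

* Pearson chi-square without Yates correction, because that is the
  convention the golden values verify; `min_cell` guards the sparse-table
  regime instead.
* Haldane–Anscombe rather than exact methods for zero cells: it keeps the
  estimate finite and is flagged, and screening (not the corrected CI)
  decides what enters the model.
* Wald intervals and Wald-based elimination: standard, fast, and adequate at
  these sample sizes; separation is detected and flagged on the fit object.
* Group sizes, window, tracts, thresholds are all parameters whose defaults
  are the motivating design's values — nothing is hard-coded.

## Limitations

* No linkage/haplogroup structure in the generator (see above).
* The coordinate-skip convention can misplace a skipped position within a
  gap if the anchor table is sparse there; annotation, not inference, is
  affected.
* Backward elimination inherits all the usual caveats of stepwise selection;
  the package reports the trace and the screen so the full path is visible.
* The bundled reference is synthetic (reproducibly generated, with the
  correct tract structure); statistics depend on it only through masking,
  which overwrites tract columns identically for every subject.
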