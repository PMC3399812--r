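# Cohort ingestion and preprocessing: aligned, equal-length D-loop sequences
# for cases and controls, poly-C masking, and trimming to the analysis window.

COHORT_ALPHABET <- c("A", "C", "G", "T",
                     "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N", "-")

#' Construct / validate an aligned cohort
#'
#' A cohort is a tibble with one row per subject: `subject_id` (unique),
#' `group` (`"case"` or `"control"`) and `sequence` (the aligned sequence,
#' over A/C/G/T, IUPAC ambiguity codes, N and `-`). All sequences must have
#' identical length.
#'
#' @param df Data frame with columns `subject_id`, `group`, `sequence`.
#' @return A validated cohort tibble (class `dloop_cohort`).
#' @export
as_cohort <- function(df) {
  df <- tibble::as_tibble(df)
  stopifnot(all(c("subject_id", "group", "sequence") %in% names(df)))
  if (nrow(df) == 0) stop("cohort has no records", call. = FALSE)
  df$subject_id <- as.character(df$subject_id)
  df$group <- as.character(df$group)
  df$sequence <- toupper(as.character(df$sequence))
  dup <- df$subject_id[duplicated(df$subject_id)]
  if (length(dup)) {
    stop("duplicate subject id(s): ", paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  if (!all(df$group %in% c("case", "control"))) {
    stop("group must be 'case' or 'control'", call. = FALSE)
  }
  lens <- nchar(df$sequence)
  if (length(unique(lens)) != 1) {
    ref_len <- as.integer(names(sort(table(lens), decreasing = TRUE))[1])
    bad <- df$subject_id[lens != ref_len]
    stop("aligned sequences must share one length; deviant record(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  chars <- unique(strsplit(paste(df$sequence, collapse = ""), "")[[1]])
  bad <- setdiff(chars, COHORT_ALPHABET)
  if (length(bad)) {
    stop("sequences contain characters outside A/C/G/T, IUPAC codes, N, '-': ",
         paste(bad, collapse = " "), call. = FALSE)
  }
  class(df) <- unique(c("dloop_cohort", class(df)))
  df
}

#' Read an aligned case/control cohort from two FASTA files
#'
#' Sequences are uppercased and U is converted to T; gap (`-`) and IUPAC
#' ambiguity characters are preserved. The group label is assigned by source
#' file. Records of unequal length or duplicate ids are a hard error naming
#' the offending record.
#'
#' @param case_fasta,control_fasta Paths to aligned FASTA files of patients
#'   and controls.
#' @return A cohort tibble with columns `subject_id`, `group`, `sequence`.
#' @export
read_cohort <- function(case_fasta, control_fasta) {
  read_one <- function(path, group) {
    s <- Biostrings::readBStringSet(path)
    if (length(s) == 0) stop("no FASTA records in ", path, call. = FALSE)
    tibble::tibble(
      subject_id = sub("\\s.*$", "", names(s)),
      group = group,
      sequence = chartr("U", "T", toupper(as.character(s)))
    )
  }
  as_cohort(dplyr::bind_rows(read_one(case_fasta, "case"),
                             read_one(control_fasta, "control")))
}

#' Write a cohort back to FASTA (one file per group)
#'
#' @param cohort A cohort tibble.
#' @param case_fasta,control_fasta Output paths.
#' @return Invisibly, the two paths.
#' @export
write_cohort <- function(cohort, case_fasta, control_fasta) {
  cohort <- as_cohort(cohort)
  write_one <- function(rows, path) {
    x <- Biostrings::BStringSet(rows$sequence)
    names(x) <- rows$subject_id
    Biostrings::writeXStringSet(x, path)
  }
  write_one(dplyr::filter(cohort, .data$group == "case"), case_fasta)
  write_one(dplyr::filter(cohort, .data$group == "control"), control_fasta)
  invisible(c(case_fasta, control_fasta))
}

cohort_length <- function(cohort) nchar(cohort$sequence[1])

#' Coordinate map attached to a cohort
#'
#' [trim_window()] attaches the recalibrated map to its result; this accessor
#' retrieves it.
#'
#' @param cohort A cohort tibble.
#' @return A `coord_map` or `NULL`.
#' @export
cohort_map <- function(cohort) attr(cohort, "map")

set_cohort_map <- function(cohort, map) {
  attr(cohort, "map") <- map
  cohort
}

# Map a tract's rCRS span to a contiguous run of alignment columns, or error.
tract_columns <- function(map, rcrs_start, rcrs_end) {
  pos <- roll_rcrs(seq.int(unroll_rcrs(rcrs_start), unroll_rcrs(rcrs_end)))
  cols <- rcrs_to_align(map, pos)
  if (anyNA(cols)) {
    stop(sprintf("poly-C tract nt%d-%d is not fully inside the mapped window",
                 rcrs_start, rcrs_end), call. = FALSE)
  }
  if (any(diff(cols) != 1L)) {
    stop(sprintf("poly-C tract nt%d-%d does not map to contiguous columns",
                 rcrs_start, rcrs_end), call. = FALSE)
  }
  list(columns = cols, rcrs = pos)
}

#' Replace poly-C tract columns with reference bases
#'
#' The length of the control region's homopolymeric cytosine tracts varies
#' between subjects and disturbs alignment, so before SNP calling the columns
#' covering each tract are overwritten, in every sequence, with the reference
#' bases for those rCRS positions. Sequence length and all other columns are
#' unchanged.
#'
#' @param cohort A cohort tibble.
#' @param ref An `rcrs_ref`.
#' @param map A `coord_map` for the cohort's columns (defaults to the map
#'   attached to the cohort).
#' @param tracts Tibble of tract spans as from [polyc_tracts()]; an empty
#'   tibble leaves the cohort unchanged.
#' @return The masked cohort.
#' @export
mask_polyc <- function(cohort, ref, map = cohort_map(cohort), tracts = polyc_tracts()) {
  cohort <- as_cohort(cohort)
  if (is.null(map)) stop("no coordinate map supplied or attached to the cohort", call. = FALSE)
  if (nrow(tracts) == 0) return(cohort)
  m <- sequence_matrix(cohort)
  for (i in seq_len(nrow(tracts))) {
    tc <- tract_columns(map, tracts$rcrs_start[i], tracts$rcrs_end[i])
    m[, tc$columns] <- matrix(ref_base(ref, tc$rcrs), nrow = nrow(m),
                              ncol = length(tc$columns), byrow = TRUE)
  }
  out <- cohort
  out$sequence <- collapse_matrix(m)
  set_cohort_map(as_cohort(out), map)
}

#' Trim a cohort to the analysis window
#'
#' Restricts the alignment to the columns whose rCRS positions fall inside the
#' kept spans (default nt16000-16569 and nt1-485, the window left after
#' removing the poor-quality 5' and 3' ends) and recalibrates the coordinate
#' map so column 1 is the first kept column. Idempotent on already-trimmed
#' input.
#'
#' @param cohort A cohort tibble.
#' @param map A `coord_map` for the cohort's columns (defaults to the map
#'   attached to the cohort).
#' @param keep List of length-2 vectors of rCRS spans to keep.
#' @return The trimmed cohort with the recalibrated map attached (see
#'   [cohort_map()]).
#' @export
trim_window <- function(cohort, map = cohort_map(cohort),
                        keep = list(c(16000L, 16569L), c(1L, 485L))) {
  cohort <- as_cohort(cohort)
  if (is.null(map)) stop("no coordinate map supplied or attached to the cohort", call. = FALSE)
  n_col <- cohort_length(cohort)
  in_keep <- function(pos) {
    Reduce(`|`, lapply(keep, function(s) pos >= s[1] & pos <= s[2]))
  }
  rows <- map[map$align_pos <= n_col & in_keep(map$rcrs_pos), , drop = FALSE]
  if (nrow(rows) == 0) stop("trim window keeps no columns", call. = FALSE)
  cols <- sort(rows$align_pos)
  m <- sequence_matrix(cohort)[, cols, drop = FALSE]
  out <- cohort
  out$sequence <- collapse_matrix(m)
  new_map <- tibble::tibble(
    align_pos = seq_along(cols),
    rcrs_pos = rows$rcrs_pos[order(rows$align_pos)]
  )
  old_skips <- attr(map, "skipped_rcrs")
  new_map <- structure(new_map,
                       skipped_rcrs = old_skips[in_keep(old_skips)],
                       anchors = attr(map, "anchors"),
                       class = c("coord_map", class(new_map)))
  set_cohort_map(as_cohort(out), new_map)
}
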