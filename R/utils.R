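#' Evaluate code under a given RNG seed, restoring the caller's stream
#'
#' Sets the seed, evaluates `code`, and restores (or removes) the caller's
#' `.Random.seed` afterwards, so reproducible draws never clobber the session
#' stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

#' Derive a labelled substream seed from a root seed
#'
#' A counter-based scheme mapping (root seed, stream label) to a 31-bit seed,
#' so that independent stages of a run draw from independent streams and,
#' e.g., adding SNP sites to a spec does not perturb the draws of earlier
#' sites.
#'
#' @param seed Integer root seed.
#' @param label Character stream label.
#' @return An integer in `[1, 2^31 - 1)`.
#' @export
substream_seed <- function(seed, label) {
  h <- 0
  for (ch in utf8ToInt(paste0(label, ":", seed))) {
    h <- (h * 31 + ch) %% 2147483629
  }
  as.integer(h + 1)
}

# Split cohort sequences into a subjects x columns character matrix.
sequence_matrix <- function(cohort) {
  m <- do.call(rbind, strsplit(cohort$sequence, ""))
  rownames(m) <- cohort$subject_id
  m
}

# Reassemble a character matrix into sequence strings.
collapse_matrix <- function(m) {
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}
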