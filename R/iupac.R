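# IUPAC degenerate nucleotide codes: the 15 non-empty subsets of {A,C,G,T}.
IUPAC_TABLE <- c(
  A = "A", C = "C", G = "G", T = "T",
  AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K",
  ACG = "V", ACT = "H", AGT = "D", CGT = "B", ACGT = "N"
)

#' IUPAC degenerate code for an allele set
#'
#' Maps a non-empty set of nucleotides to the single-letter IUPAC symbol for
#' exactly that set (e.g. `{A,G}` is R, `{C,T}` is Y, `{A,C,T}` is H,
#' `{A,C,G,T}` is N; singletons map to themselves).
#'
#' @param alleles Character vector of distinct bases drawn from A/C/G/T
#'   (order and case irrelevant).
#' @return A single character.
#' @export
#' @examples
#' iupac_code(c("A", "G")) # "R"
iupac_code <- function(alleles) {
  alleles <- unique(toupper(as.character(alleles)))
  if (length(alleles) == 0) stop("allele set is empty", call. = FALSE)
  if (!all(alleles %in% c("A", "C", "G", "T"))) {
    stop("allele set contains non-nucleotide member(s): ",
         paste(setdiff(alleles, c("A", "C", "G", "T")), collapse = ", "), call. = FALSE)
  }
  unname(IUPAC_TABLE[[paste(sort(alleles), collapse = "")]])
}

#' Allele set encoded by an IUPAC symbol
#'
#' Inverse of [iupac_code()].
#'
#' @param code A single IUPAC character (one of the 15 symbols).
#' @return Character vector of bases, alphabetical.
#' @export
iupac_alleles <- function(code) {
  code <- toupper(as.character(code))
  stopifnot(length(code) == 1)
  key <- names(IUPAC_TABLE)[match(code, IUPAC_TABLE)]
  if (is.na(key)) stop("not an IUPAC nucleotide symbol: ", code, call. = FALSE)
  strsplit(key, "")[[1]]
}
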