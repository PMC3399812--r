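# Reference coordinate system: the human mitochondrial control region (D-loop)
# in rCRS (NC_012920) coordinates. The mtDNA molecule is circular and the
# control region straddles the origin, so the reference window is the pair of
# 1-based, inclusive spans 15911-16569 and 1-602, with position 16569 adjacent
# to position 1. All coordinates in this package are 1-based inclusive.

RCRS_WRAP <- 16569L
RCRS_WINDOW <- list(c(15911L, 16569L), c(1L, 602L))

# Unroll the circular coordinate so the window is a single increasing segment:
# positions >= 15911 keep their value; positions in 1..602 get + 16569.
unroll_rcrs <- function(pos) {
  pos <- as.integer(pos)
  ifelse(pos >= RCRS_WINDOW[[1]][1], pos, pos + RCRS_WRAP)
}

roll_rcrs <- function(u) {
  u <- as.integer(u)
  ifelse(u > RCRS_WRAP, u - RCRS_WRAP, u)
}

in_rcrs_window <- function(pos) {
  (pos >= RCRS_WINDOW[[1]][1] & pos <= RCRS_WINDOW[[1]][2]) |
    (pos >= RCRS_WINDOW[[2]][1] & pos <= RCRS_WINDOW[[2]][2])
}

#' Default homopolymeric cytosine tracts of the D-loop
#'
#' The two poly-C tracts of the control region whose variable length disturbs
#' alignment and is masked with reference bases before SNP calling. The default
#' spans are nt16184-16193 (the HVS-I tract, interrupted by T at nt16189) and
#' nt303-315 (the HVS-II / D310 tract, interrupted by T at nt310). A wider
#' HVS-I definition (nt16180-16195) is also in circulation; pass it explicitly
#' if preferred.
#'
#' @param hvs1 Length-2 integer vector, rCRS start/end of the HVS-I tract.
#' @param hvs2 Length-2 integer vector, rCRS start/end of the HVS-II tract.
#' @return A tibble with columns `tract`, `rcrs_start`, `rcrs_end`.
#' @export
#' @examples
#' polyc_tracts()
polyc_tracts <- function(hvs1 = c(16184L, 16193L), hvs2 = c(303L, 315L)) {
  stopifnot(length(hvs1) == 2, length(hvs2) == 2)
  out <- tibble::tibble(
    tract = c("HVS1", "HVS2"),
    rcrs_start = as.integer(c(hvs1[1], hvs2[1])),
    rcrs_end = as.integer(c(hvs1[2], hvs2[2]))
  )
  if (any(out$rcrs_start > out$rcrs_end) || !all(in_rcrs_window(out$rcrs_start)) ||
      !all(in_rcrs_window(out$rcrs_end))) {
    stop("poly-C tract spans must satisfy start <= end and lie inside the reference window",
         call. = FALSE)
  }
  out
}

#' Control-region reference object
#'
#' Holds one base per rCRS position over the control-region window
#' (15911-16569 and 1-602). Lookup is defined exactly for that window and
#' errors elsewhere.
#'
#' @param bases Character vector of single bases (A/C/G/T), one per window
#'   position in window order (15911..16569 then 1..602).
#' @return An object of class `rcrs_ref`.
#' @seealso [synthetic_reference()], [read_reference()], [ref_base()]
#' @export
rcrs_reference <- function(bases) {
  positions <- c(seq.int(RCRS_WINDOW[[1]][1], RCRS_WINDOW[[1]][2]),
                 seq.int(RCRS_WINDOW[[2]][1], RCRS_WINDOW[[2]][2]))
  bases <- toupper(as.character(bases))
  if (length(bases) != length(positions)) {
    stop(sprintf("reference must supply %d bases (window 15911-16569 + 1-602), got %d",
                 length(positions), length(bases)), call. = FALSE)
  }
  if (!all(bases %in% c("A", "C", "G", "T"))) {
    stop("reference bases must all be A/C/G/T", call. = FALSE)
  }
  structure(list(positions = positions, bases = bases), class = "rcrs_ref")
}

#' @export
print.rcrs_ref <- function(x, ...) {
  cat("<rcrs_ref> control-region reference, window 15911-16569 + 1-602 (",
      length(x$bases), " bases)\n", sep = "")
  invisible(x)
}

#' Look up reference bases by rCRS position
#'
#' @param ref An `rcrs_ref` object.
#' @param positions Integer vector of rCRS positions; all must lie inside the
#'   stored window.
#' @return Character vector of bases.
#' @export
ref_base <- function(ref, positions) {
  stopifnot(inherits(ref, "rcrs_ref"))
  positions <- as.integer(positions)
  if (!all(in_rcrs_window(positions))) {
    stop("rCRS position(s) outside the reference window 15911-16569 + 1-602: ",
         paste(positions[!in_rcrs_window(positions)], collapse = ", "), call. = FALSE)
  }
  idx <- match(positions, ref$positions)
  ref$bases[idx]
}

#' Read a control-region reference from FASTA
#'
#' The FASTA must contain a single record whose sequence covers the window
#' 15911-16569 followed by 1-602 (1261 bases), in that order.
#'
#' @param path Path to a FASTA file.
#' @return An `rcrs_ref` object.
#' @export
read_reference <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) != 1) {
    stop("reference FASTA must contain exactly one record", call. = FALSE)
  }
  rcrs_reference(strsplit(as.character(seqs[[1]]), "")[[1]])
}

#' Synthetic control-region reference
#'
#' A deterministic synthetic stand-in for the rCRS control-region sequence,
#' for simulation and testing: it has the correct window length and realistic
#' homopolymer structure at the two poly-C tracts (C-runs interrupted by T at
#' nt16189 and nt310, as in rCRS), with pseudo-random bases elsewhere. It is
#' NOT the NC_012920 sequence; analyses of real data should load the genuine
#' reference with [read_reference()]. No association statistic in this package
#' depends on the reference base identities.
#'
#' @param seed Integer seed for the deterministic base draw.
#' @return An `rcrs_ref` object.
#' @export
synthetic_reference <- function(seed = 16569L) {
  positions <- c(seq.int(RCRS_WINDOW[[1]][1], RCRS_WINDOW[[1]][2]),
                 seq.int(RCRS_WINDOW[[2]][1], RCRS_WINDOW[[2]][2]))
  bases <- with_seed(seed, sample(c("A", "C", "G", "T"), length(positions),
                                  replace = TRUE, prob = c(0.31, 0.31, 0.13, 0.25)))
  set_at <- function(b, pos, val) {
    b[match(pos, positions)] <- val
    b
  }
  bases <- set_at(bases, 16184:16193, c(rep("C", 5), "T", rep("C", 4)))
  bases <- set_at(bases, 303:315, c(rep("C", 7), "T", rep("C", 5)))
  rcrs_reference(bases)
}

# --- coordinate map ---------------------------------------------------------

#' Build an alignment-to-rCRS coordinate map from anchor pairs
#'
#' The map between 1-based alignment columns and rCRS positions is data-driven:
#' an ordered table of anchor pairs is interpolated linearly within each
#' segment. Where consecutive anchors imply that rCRS advances faster than the
#' alignment (a change in the column-minus-position offset), the surplus rCRS
#' positions are absent from the alignment and are recorded as skipped. When a
#' gap of size d contains exactly d of the `known_skips`, those documented
#' positions are used; otherwise the d positions immediately after the left
#' anchor are skipped (a stated convention, since anchors alone cannot locate
#' the gap). The circular wrap 16569 -> 1 is handled transparently.
#'
#' @param anchors Data frame with integer columns `align_pos` (strictly
#'   increasing) and `rcrs_pos` (strictly increasing within each of the two
#'   window segments).
#' @param known_skips Integer vector of rCRS positions documented as absent
#'   from the alignment (default nt249, nt353, nt354).
#' @param extend_left If `TRUE`, extend the map at the first anchor's offset
#'   down to alignment column 1.
#' @param extend_right_to Optional rCRS position; extend the map past the last
#'   anchor at its offset up to this position.
#' @return A `coord_map` object: a tibble of `(align_pos, rcrs_pos)` covering
#'   every mapped column, with attributes `skipped_rcrs` and `anchors`.
#' @export
#' @examples
#' m <- build_coordinate_map(data.frame(align_pos = 1:10, rcrs_pos = 1:10))
#' align_to_rcrs(m, 5)
build_coordinate_map <- function(anchors, known_skips = c(249L, 353L, 354L),
                                 extend_left = FALSE, extend_right_to = NULL) {
  anchors <- tibble::as_tibble(anchors)
  if (nrow(anchors) == 0) stop("anchor table is empty", call. = FALSE)
  stopifnot(all(c("align_pos", "rcrs_pos") %in% names(anchors)))
  ap <- as.integer(anchors$align_pos)
  rp <- as.integer(anchors$rcrs_pos)
  if (any(diff(ap) <= 0)) stop("anchor align positions must be strictly increasing", call. = FALSE)
  if (!all(in_rcrs_window(rp))) stop("anchor rCRS positions outside the reference window", call. = FALSE)
  u <- unroll_rcrs(rp)
  if (any(diff(u) <= 0)) {
    stop("anchor rCRS positions must be strictly increasing along the (unrolled) circle",
         call. = FALSE)
  }
  ku <- unroll_rcrs(known_skips)

  cols <- ap[1]
  us <- u[1]
  skips <- integer(0)
  if (length(ap) > 1) {
    pieces_c <- vector("list", length(ap) - 1)
    pieces_u <- vector("list", length(ap) - 1)
    for (i in seq_len(length(ap) - 1)) {
      dc <- ap[i + 1] - ap[i]
      du <- u[i + 1] - u[i]
      if (du < dc) {
        stop(sprintf(paste0("anchors (%d,%d) and (%d,%d) imply the alignment advancing ",
                            "faster than rCRS (negative gap); only rCRS positions may be skipped"),
                     ap[i], rp[i], ap[i + 1], rp[i + 1]), call. = FALSE)
      }
      d <- du - dc
      gap_u <- seq.int(u[i] + 1L, u[i + 1])
      if (d > 0) {
        cand <- intersect(ku, gap_u[-length(gap_u)])
        sk <- if (length(cand) == d) cand else gap_u[seq_len(d)]
        skips <- c(skips, sk)
        gap_u <- setdiff(gap_u, sk)
      }
      pieces_c[[i]] <- seq.int(ap[i] + 1L, ap[i + 1])
      pieces_u[[i]] <- gap_u
    }
    cols <- c(cols, unlist(pieces_c))
    us <- c(us, unlist(pieces_u))
  }
  if (isTRUE(extend_left) && cols[1] > 1L) {
    n_ext <- cols[1] - 1L
    ext_u <- seq.int(us[1] - n_ext, us[1] - 1L)
    if (any(ext_u < unroll_rcrs(RCRS_WINDOW[[1]][1]))) {
      stop("extending left would leave the reference window", call. = FALSE)
    }
    cols <- c(seq_len(n_ext), cols)
    us <- c(ext_u, us)
  }
  if (!is.null(extend_right_to)) {
    tgt <- unroll_rcrs(extend_right_to)
    if (tgt > us[length(us)]) {
      n_ext <- tgt - us[length(us)]
      cols <- c(cols, seq.int(cols[length(cols)] + 1L, cols[length(cols)] + n_ext))
      us <- c(us, seq.int(us[length(us)] + 1L, tgt))
    }
  }
  out <- tibble::tibble(align_pos = as.integer(cols), rcrs_pos = roll_rcrs(us))
  structure(out,
            skipped_rcrs = roll_rcrs(sort(skips)),
            anchors = tibble::tibble(align_pos = ap, rcrs_pos = rp),
            class = c("coord_map", class(out)))
}

#' The study's default coordinate map
#'
#' Built from the 77 anchor pairs shipped with the package (alignment column
#' versus rCRS D-loop position for every called SNP), extended to alignment
#' column 1 on the left and rCRS nt485 on the right, covering the trimmed
#' analysis window nt16001-16569 + nt1-485.
#'
#' @return A `coord_map` object.
#' @export
default_coordinate_map <- function() {
  build_coordinate_map(dloop_anchors(), extend_left = TRUE, extend_right_to = 485L)
}

#' The shipped alignment/rCRS anchor table
#'
#' One row per called SNP: SNP number, alignment column, rCRS D-loop position
#' and the IUPAC code of its allele set.
#'
#' @return A tibble with columns `snp_no`, `align_pos`, `rcrs_pos`, `iupac`.
#' @export
dloop_anchors <- function() {
  path <- system.file("extdata", "dloop_anchors.tsv", package = "dloopsnp", mustWork = TRUE)
  readr::read_tsv(path, col_types = readr::cols(
    snp_no = readr::col_integer(), align_pos = readr::col_integer(),
    rcrs_pos = readr::col_integer(), iupac = readr::col_character()
  ))
}

#' A gapless map for a set of rCRS spans
#'
#' Maps alignment columns 1..N onto the concatenation of the given rCRS spans
#' with no skipped positions; the backbone used by the cohort simulator.
#'
#' @param spans List of length-2 integer vectors of rCRS start/end positions,
#'   in alignment order.
#' @return A `coord_map` object.
#' @export
window_map <- function(spans = list(c(16001L, 16569L), c(1L, 485L))) {
  lens <- vapply(spans, function(s) s[2] - s[1] + 1L, integer(1))
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  anchors <- tibble::tibble(
    align_pos = as.integer(rbind(starts, ends)),
    rcrs_pos = as.integer(unlist(lapply(spans, function(s) c(s[1], s[2]))))
  )
  build_coordinate_map(anchors)
}

#' @export
print.coord_map <- function(x, ...) {
  sk <- attr(x, "skipped_rcrs")
  cat(sprintf("<coord_map> %d columns (%d-%d), %d skipped rCRS position(s)\n",
              nrow(x), min(x$align_pos), max(x$align_pos), length(sk)))
  if (length(sk)) cat("  skipped:", paste(sk, collapse = ", "), "\n")
  invisible(x)
}

#' Convert alignment columns to rCRS positions
#'
#' @param map A `coord_map`.
#' @param columns Integer vector of 1-based alignment columns; all must be
#'   mapped.
#' @return Integer vector of rCRS positions.
#' @export
#' @examples
#' align_to_rcrs(default_coordinate_map(), c(51, 662, 1019))
align_to_rcrs <- function(map, columns) {
  stopifnot(inherits(map, "coord_map"))
  columns <- as.integer(columns)
  idx <- match(columns, map$align_pos)
  if (anyNA(idx)) {
    stop("alignment column(s) outside the mapped range: ",
         paste(columns[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  map$rcrs_pos[idx]
}

#' Convert rCRS positions to alignment columns
#'
#' Inverse of [align_to_rcrs()]. Positions inside the reference window that are
#' absent from the alignment (skipped positions, or positions outside the
#' mapped columns) return `NA`; positions outside the window are an error.
#'
#' @param map A `coord_map`.
#' @param positions Integer vector of rCRS positions.
#' @return Integer vector of 1-based alignment columns, `NA` where absent.
#' @export
rcrs_to_align <- function(map, positions) {
  stopifnot(inherits(map, "coord_map"))
  positions <- as.integer(positions)
  if (!all(in_rcrs_window(positions))) {
    stop("rCRS position(s) outside the reference window 15911-16569 + 1-602: ",
         paste(positions[!in_rcrs_window(positions)], collapse = ", "), call. = FALSE)
  }
  map$align_pos[match(positions, map$rcrs_pos)]
}

#' Skipped rCRS positions of a coordinate map
#'
#' @param map A `coord_map`.
#' @return Integer vector of rCRS positions absent from the alignment.
#' @export
skipped_rcrs <- function(map) {
  stopifnot(inherits(map, "coord_map"))
  attr(map, "skipped_rcrs")
}
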