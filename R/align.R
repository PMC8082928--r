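#' Pairwise sequence alignment with affine gaps
#'
#' Banded dynamic-programming aligner used throughout the package: star-MSA
#' consensus building (`mode = "endsfree"`), breakpoint-flank anatomy
#' (`mode = "local"`), consensus remap validation (`mode = "fit"`), and the
#' miniature viral mapper.  Default scores are match 1, mismatch -2,
#' gap-open -2, gap-extend -1; the band half-width is
#' `max(min_band, band_frac * max(nchar(a), nchar(b)))`, widened
#' automatically by the length difference so that truncated segments stay
#' inside the band.
#'
#' @param a,b character scalars (subject and query).
#' @param mode one of `"global"`, `"endsfree"` (overhangs of either sequence
#'   free; used for possibly truncated segments), `"fit"` (all of `b`
#'   aligned somewhere inside `a`), `"local"` (Smith-Waterman).
#' @param match,mismatch,gap_open,gap_ext integer scores (penalties
#'   negative); the first base of a gap costs `gap_open`, each further base
#'   `gap_ext`.
#' @param band_frac band half-width as a fraction of the longer sequence;
#'   `>= 1` disables banding.
#' @param min_band minimum band half-width in bp.
#' @return a list with `score`, 0-based half-open aligned intervals
#'   `a_start`/`a_end`/`b_start`/`b_end`, run-length encoded `ops`
#'   (`"M"`/`"I"`/`"D"`, `I` consumes `b` only) with `lens`, `nmatch`,
#'   `aln_len`, and `identity` (`nmatch / aln_len`).
#' @export
align_pair <- function(a, b, mode = c("global", "endsfree", "fit", "local"),
                       match = 1L, mismatch = -2L, gap_open = -2L,
                       gap_ext = -1L, band_frac = 0.2, min_band = 50L) {
  mode <- match.arg(mode)
  stopifnot(is.character(a), length(a) == 1L, is.character(b), length(b) == 1L)
  # keep the true path inside the band when lengths differ (truncations)
  mb <- max(as.integer(min_band), abs(nchar(a) - nchar(b)) + 50L)
  if (mode %in% c("local", "fit")) band_frac <- 1  # diagonal unknown
  res <- .cpp_align(toupper(a), toupper(b),
                    match = as.integer(match), mismatch = as.integer(mismatch),
                    gap_open = as.integer(gap_open), gap_ext = as.integer(gap_ext),
                    band_frac = band_frac, min_band = mb, mode = mode)
  res$ops <- c("M", "I", "D")[res$ops + 1L]
  res$identity <- if (res$aln_len > 0) res$nmatch / res$aln_len else NA_real_
  res
}

#' Reverse complement of a plain character sequence
#' @noRd
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
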