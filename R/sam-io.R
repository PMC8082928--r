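#' Parse long-read alignments from SAM or BAM
#'
#' Reads a coordinate-sortable SAM or BAM file into the package's flat
#' alignment table: one row per mapped record (primary and supplementary),
#' with secondary alignments dropped.  Split segments of one read share a
#' `read_id` and are distinguished by `is_primary`.  Records below
#' `min_mapq` are retained but their `mapq` column lets downstream filters
#' (the low-mapping-quality region filter needs them) see them.
#'
#' Read-interval columns (`read_start`, `read_end`, 0-based half-open) are
#' in the coordinates of the original read: for minus-strand records the
#' clip lengths are swapped accordingly, and hard clips are counted so that
#' supplementary records reconstruct their interval without the SA tag.
#'
#' @param sam_source path to a SAM (`.sam`) or BAM file.
#' @param min_mapq records below this mapping quality are flagged via the
#'   `low_mapq` column (never dropped).  Default 20.
#' @param keep_seq keep the SEQ field (needed for inserted-sequence capture
#'   and consensus building).  Default `TRUE`.
#' @return a `data.frame` of class `svlr_alignments` with columns
#'   `read_id`, `chrom`, `start`, `end` (0-based half-open reference
#'   interval), `strand`, `mapq`, `low_mapq`, `cigar`, `read_length`,
#'   `left_clip`, `right_clip`, `read_start`, `read_end`, `is_primary`,
#'   `seq`; attributes `sq` (named contig lengths) and `n_skipped`
#'   (malformed records dropped with a warning).
#' @export
parse_alignments <- function(sam_source, min_mapq = 20L, keep_seq = TRUE) {
  stopifnot(file.exists(sam_source))
  bam <- sam_source
  n_malformed <- 0L
  if (grepl("\\.sam$", sam_source, ignore.case = TRUE)) {
    hdr <- readLines(sam_source, n = 200L)
    if (!any(startsWith(hdr, "@SQ"))) {
      stop("SAM header has no @SQ lines: ", sam_source)
    }
    # count mapped records with missing/invalid CIGARs before conversion:
    # htslib silently demotes them to unmapped
    lines <- readLines(sam_source)
    lines <- lines[!startsWith(lines, "@")]
    if (length(lines)) {
      f <- strsplit(lines, "\t", fixed = TRUE)
      flag <- vapply(f, function(x) as.integer(x[2]), 0L)
      cig <- vapply(f, function(x) x[6], "")
      mapped <- bitwAnd(flag, 4L) == 0L
      bad <- mapped & (cig == "*" | !grepl("^([0-9]+[MIDNSHP=X])+$", cig))
      n_malformed <- sum(bad)
      if (n_malformed > 0) {
        warning(n_malformed,
                " mapped record(s) with malformed or missing CIGAR skipped")
      }
    }
    bam <- Rsamtools::asBam(sam_source,
                            destination = tempfile(fileext = ""),
                            overwrite = TRUE, indexDestination = FALSE)
  }
  what <- c("qname", "flag", "rname", "strand", "pos", "mapq", "cigar")
  if (keep_seq) what <- c(what, "seq")
  p <- Rsamtools::ScanBamParam(
    what = what,
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE))
  res <- Rsamtools::scanBam(bam, param = p)[[1]]
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  n <- length(res$qname)
  if (n == 0L) {
    out <- empty_alignments()
    attr(out, "sq") <- hdr
    attr(out, "n_skipped") <- n_malformed
    return(out)
  }
  cig <- as.character(res$cigar)
  bad <- is.na(cig) | cig == "*" |
    !grepl("^([0-9]+[MIDNSHP=X])+$", cig)
  if (any(bad)) {
    warning(sum(bad), " record(s) with malformed or missing CIGAR skipped")
  }
  keep <- !bad
  cig <- cig[keep]
  ops  <- GenomicAlignments::explodeCigarOps(cig)
  lens <- GenomicAlignments::explodeCigarOpLengths(cig)
  ref_w  <- GenomicAlignments::cigarWidthAlongReferenceSpace(cig)
  qry_w  <- GenomicAlignments::cigarWidthAlongQuerySpace(cig,
                                                         after.soft.clipping = TRUE)
  first_op <- vapply(ops, function(o) o[1], "")
  last_op  <- vapply(ops, function(o) o[length(o)], "")
  first_len <- vapply(lens, function(l) l[1], 0L)
  last_len  <- vapply(lens, function(l) l[length(l)], 0L)
  second_op <- vapply(ops, function(o) if (length(o) > 1) o[2] else "", "")
  second_len <- vapply(lens, function(l) if (length(l) > 1) l[2] else 0L, 0L)
  penu_op  <- vapply(ops, function(o) if (length(o) > 1) o[length(o) - 1] else "", "")
  penu_len <- vapply(lens, function(l) if (length(l) > 1) l[length(l) - 1] else 0L, 0L)
  # clips: leading/trailing H then S
  lc <- ifelse(first_op %in% c("S", "H"), first_len, 0L) +
    ifelse(first_op == "H" & second_op == "S", second_len, 0L)
  rc <- ifelse(last_op %in% c("S", "H"), last_len, 0L) +
    ifelse(last_op == "H" & penu_op == "S", penu_len, 0L)
  read_len <- qry_w + lc + rc
  strand <- as.character(res$strand)[keep]
  pos0 <- res$pos[keep] - 1L
  rs <- ifelse(strand == "+", lc, rc)
  re <- rs + qry_w
  flag <- res$flag[keep]
  out <- data.frame(
    read_id = as.character(res$qname)[keep],
    chrom = as.character(res$rname)[keep],
    start = pos0,
    end = pos0 + ref_w,
    strand = strand,
    mapq = as.integer(res$mapq)[keep],
    cigar = cig,
    read_length = as.integer(read_len),
    left_clip = as.integer(lc),
    right_clip = as.integer(rc),
    read_start = as.integer(rs),
    read_end = as.integer(re),
    is_primary = !bitwAnd(flag, 2048L) > 0L,
    stringsAsFactors = FALSE
  )
  out$low_mapq <- out$mapq < min_mapq
  out$seq <- if (keep_seq) as.character(res$seq)[keep] else NA_character_
  class(out) <- c("svlr_alignments", "data.frame")
  attr(out, "sq") <- hdr
  attr(out, "n_skipped") <- n_malformed + sum(bad)
  out
}

#' @noRd
empty_alignments <- function() {
  out <- data.frame(read_id = character(), chrom = character(),
                    start = integer(), end = integer(), strand = character(),
                    mapq = integer(), cigar = character(),
                    read_length = integer(), left_clip = integer(),
                    right_clip = integer(), read_start = integer(),
                    read_end = integer(), is_primary = logical(),
                    low_mapq = logical(), seq = character(),
                    stringsAsFactors = FALSE)
  class(out) <- c("svlr_alignments", "data.frame")
  out
}

#' Write an alignment table back to SAM
#'
#' Inverse of [parse_alignments()] over the modeled fields; used for
#' round-trip checks and by the simulator.  Records are written sorted by
#' contig then position.
#'
#' @param alignments alignment table as returned by [parse_alignments()],
#'   or any data.frame with the same columns (`sa` column, if present, is
#'   written as the SA tag).
#' @param sq named integer vector of contig lengths for the `@SQ` header.
#' @param path output path.
#' @param extra_header optional character vector of additional header lines
#'   (e.g. `@PG`/`@CO` provenance).
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, sq, path, extra_header = character()) {
  a <- as.data.frame(alignments)
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(sq), as.integer(sq)),
           extra_header)
  if (nrow(a) > 0) {
    a <- a[order(match(a$chrom, names(sq)), a$start), , drop = FALSE]
    flag <- ifelse(a$strand == "-", 16L, 0L) +
      ifelse(a$is_primary, 0L, 2048L)
    seq <- if ("seq" %in% names(a)) ifelse(is.na(a$seq), "*", a$seq) else "*"
    tags <- if ("sa" %in% names(a)) {
      ifelse(is.na(a$sa) | a$sa == "", "", paste0("\tSA:Z:", a$sa))
    } else ""
    rec <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*%s",
                   a$read_id, flag, a$chrom, a$start + 1L, a$mapq,
                   a$cigar, seq, tags)
  } else rec <- character()
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Walk a CIGAR string and return per-operation coordinates
#'
#' @param cigar CIGAR string.
#' @param ref_start 0-based reference start of the record.
#' @return data.frame with `op`, `len`, `ref_pos` (0-based reference
#'   position at the start of the op) and `qry_pos` (0-based position in
#'   the record's query, soft clips included).
#' @noRd
cigar_walk <- function(cigar, ref_start = 0L) {
  op <- GenomicAlignments::explodeCigarOps(cigar)[[1]]
  len <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1]]
  ref_consume <- op %in% c("M", "D", "N", "=", "X")
  qry_consume <- op %in% c("M", "I", "S", "=", "X")
  ref_pos <- ref_start + cumsum(c(0L, (len * ref_consume)[-length(len)]))
  qry_pos <- cumsum(c(0L, (len * qry_consume)[-length(len)]))
  data.frame(op = op, len = len, ref_pos = ref_pos, qry_pos = qry_pos,
             stringsAsFactors = FALSE)
}

#' Query-coordinate of a reference position within one record
#'
#' @return 0-based offset into the record's query (soft clips included), or
#'   NA if `ref_pos` is outside the aligned span.
#' @noRd
ref_to_query_pos <- function(cigar, record_ref_start, ref_pos) {
  w <- cigar_walk(cigar, record_ref_start)
  ref_c <- w$op %in% c("M", "D", "N", "=", "X")
  hit <- which(ref_c & w$ref_pos <= ref_pos & ref_pos < w$ref_pos + w$len)
  if (length(hit) == 0) {
    # position exactly at the end of the alignment
    last <- max(which(ref_c))
    if (ref_pos == w$ref_pos[last] + w$len[last]) {
      qc <- w$op[last] %in% c("M", "I", "S", "=", "X")
      return(w$qry_pos[last] + if (qc) w$len[last] else 0L)
    }
    return(NA_integer_)
  }
  hit <- hit[1]
  off <- ref_pos - w$ref_pos[hit]
  if (w$op[hit] %in% c("M", "=", "X")) w$qry_pos[hit] + off else w$qry_pos[hit]
}
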