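#' Collect support-read segments around an SV breakpoint
#'
#' For every support read of a call, extracts the read subsequence spanning
#' the breakpoint plus `flank` bases on each side (in read coordinates),
#' oriented to the reference strand.  For insertions the inserted bases sit
#' between the flanks; for deletions the two flanks meet at the junction.
#' Truncated segments (reads ending inside the window) are retained — the
#' ends-free multiple alignment absorbs them.
#'
#' @param call one row of a call table (with `read_ids` list-column).
#' @param alignments alignment table carrying `seq` for primary records.
#'   Support reads pooled from several samples may be supplied by
#'   row-binding the samples' alignment tables.
#' @param flank flank length in bp (default 500).
#' @return character vector of segments (named by read id); zero-length if
#'   no support read carries sequence.
#' @export
collect_segments <- function(call, alignments, flank = 500L) {
  a <- as.data.frame(alignments)
  a <- a[a$is_primary & !is.na(a$seq), , drop = FALSE]
  reads <- call$read_ids[[1]]
  segs <- character()
  for (rid in reads) {
    r <- a[a$read_id == rid, , drop = FALSE]
    if (nrow(r) == 0) next
    r <- r[1, ]
    q1 <- ref_to_query_pos(r$cigar, r$start, call$pos1)
    if (is.na(q1)) next
    if (call$sv_type == "INS") {
      # the insertion occupies read bases immediately after q1
      w <- cigar_walk(r$cigar, r$start)
      ii <- which(w$op == "I" & abs(w$ref_pos - call$pos1) <= 50)
      ins_len <- call$length
      if (length(ii)) {
        k <- ii[which.min(abs(w$ref_pos[ii] - call$pos1))]
        ins_len <- w$len[k]
        q1 <- w$qry_pos[k]
      }
      lo <- max(0L, q1 - flank)
      hi <- min(nchar(r$seq), q1 + ins_len + flank)
    } else {
      q2 <- ref_to_query_pos(r$cigar, r$start, call$pos2)
      if (is.na(q2)) q2 <- q1
      lo <- max(0L, min(q1, q2) - flank)
      hi <- min(nchar(r$seq), max(q1, q2) + flank)
    }
    if (hi - lo < 50L) next
    seg <- substr(r$seq, lo + 1L, hi)
    # SAM SEQ is stored in reference orientation already
    segs[rid] <- seg
  }
  segs
}

#' Build a majority-vote consensus from segments
#'
#' Star multiple alignment: the median-length segment is the backbone and
#' every other segment is aligned to it with an ends-free banded affine
#' alignment (match 1 / mismatch -2 / gap-open -2 / gap-extend -1, band
#' 0.2 of the longer length).  Per backbone column, the symbol with at
#' least 50% of the votes among covering segments is emitted (gap-majority
#' columns emit nothing, ties resolve toward the backbone symbol, then
#' lexicographically); insertions relative to the backbone are emitted when
#' more than half of the covering segments insert at that junction, with a
#' per-position majority over the inserted strings.
#'
#' @param segments character vector of segments (first-come order is kept
#'   deterministic; names optional).
#' @param config scoring parameters (see [svlr_config()]).
#' @param refine number of polishing passes: after the initial star MSA the
#'   vote is repeated with the current consensus as backbone, which
#'   recovers bases lost to backbone sequencing errors (default 1).
#' @return object of class `svlr_consensus`: list with `sequence`,
#'   `n_support`, `column_depths`, `low_confidence` (single segment),
#'   `accepted` (`NA` until [validate_consensus()]), `remap_distance`.
#' @export
build_consensus <- function(segments, config = svlr_config(), refine = 1L) {
  segments <- toupper(unname(unlist(segments)))
  segments <- segments[nzchar(segments)]
  n <- length(segments)
  if (n == 0) stop("no segments to build a consensus from")
  if (n == 1) {
    return(structure(list(sequence = segments[1], n_support = 1L,
                          column_depths = rep(1L, nchar(segments[1])),
                          low_confidence = TRUE, accepted = NA,
                          remap_distance = NA_real_),
                     class = "svlr_consensus"))
  }
  lens <- nchar(segments)
  bb_i <- order(lens)[ceiling(n / 2)]  # median length, deterministic tie-break
  res <- star_vote(segments[bb_i], segments[-bb_i], config,
                   backbone_votes = TRUE)
  for (k in seq_len(max(0L, refine))) {
    res <- star_vote(res$sequence, segments, config, backbone_votes = FALSE)
  }
  structure(list(sequence = res$sequence, n_support = n,
                 column_depths = res$depths, low_confidence = FALSE,
                 accepted = NA, remap_distance = NA_real_),
            class = "svlr_consensus")
}

#' One star-MSA voting pass against a backbone
#' @noRd
star_vote <- function(bb, segments, config, backbone_votes = TRUE) {
  L <- nchar(bb)
  syms <- c("A", "C", "G", "T", "N", "-")
  votes <- matrix(0, nrow = 6L, ncol = L, dimnames = list(syms, NULL))
  covered <- integer(L)
  ins_at <- vector("list", L + 1L)   # junction j sits before 1-based col j
  jn_cov <- integer(L + 1L)
  pre_strs <- character(0)           # overhangs before the backbone start
  bbv <- strsplit(bb, "")[[1]]
  bb_code <- match(bbv, syms)
  if (backbone_votes) {
    votes[cbind(bb_code, seq_len(L))] <- 1
    covered <- covered + 1L
    jn_cov <- jn_cov + 1L
  }
  for (seg in segments) {
    al <- align_pair(bb, seg, mode = "endsfree",
                     match = config$msa_match, mismatch = config$msa_mismatch,
                     gap_open = config$msa_gap_open,
                     gap_ext = config$msa_gap_ext,
                     band_frac = config$msa_band_frac)
    if (al$a_end <= al$a_start) next
    covered[(al$a_start + 1L):al$a_end] <-
      covered[(al$a_start + 1L):al$a_end] + 1L
    if (al$a_end >= al$a_start + 2L) {
      jj <- (al$a_start + 2L):al$a_end
      jn_cov[jj] <- jn_cov[jj] + 1L
    }
    # segment overhangs beyond the backbone ends extend the consensus
    # (prefix strings share their END with the boundary -> right-aligned)
    if (al$a_start == 0L) {
      jn_cov[1L] <- jn_cov[1L] + 1L
      if (al$b_start > 0L) {
        pre_strs <- c(pre_strs, substr(seg, 1L, al$b_start))
      }
    }
    if (al$a_end == L) {
      jn_cov[L + 1L] <- jn_cov[L + 1L] + 1L
      if (al$b_end < nchar(seg)) {
        ins_at[[L + 1L]] <- c(ins_at[[L + 1L]],
                              substr(seg, al$b_end + 1L, nchar(seg)))
      }
    }
    sv <- strsplit(seg, "")[[1]]
    sv_code <- match(sv, syms)
    sv_code[is.na(sv_code)] <- 5L
    bp <- al$a_start; sp <- al$b_start
    for (k in seq_along(al$ops)) {
      op <- al$ops[k]; ln <- al$lens[k]
      if (op == "M") {
        idx <- cbind(sv_code[(sp + 1L):(sp + ln)], (bp + 1L):(bp + ln))
        votes[idx] <- votes[idx] + 1
        bp <- bp + ln; sp <- sp + ln
      } else if (op == "D") {
        cols <- (bp + 1L):(bp + ln)
        votes[6L, cols] <- votes[6L, cols] + 1
        bp <- bp + ln
      } else {
        # left-normalize the insertion (rotate through equal backbone
        # bases) so homopolymer placements coalesce on one junction
        s <- substr(seg, sp + 1L, sp + ln)
        j <- bp
        while (j > al$a_start && bbv[j] == substr(s, ln, ln)) {
          s <- paste0(substr(s, ln, ln), substr(s, 1L, ln - 1L))
          j <- j - 1L
        }
        ins_at[[j + 1L]] <- c(ins_at[[j + 1L]], s)
        sp <- sp + ln
      }
    }
  }
  # per-column majority, ties toward the backbone then lexicographic
  vb <- votes
  vb[cbind(bb_code, seq_len(L))] <- vb[cbind(bb_code, seq_len(L))] + 0.25
  sym <- syms[max.col(t(vb), ties.method = "first")]
  # Junction insertions.  A read whose own deletion error lies within a few
  # bases of a backbone-deleted site absorbs the expected insertion op into
  # mismatches (the shift path scores better under the affine scheme), so
  # true missing-base junctions collect well under 100% of the votes while
  # junctions created by isolated read insertion errors collect only 1-2.
  # Emit when a majority inserts, or at least a third of the crossing
  # segments (minimum 3) agree.
  ins_str <- character(L + 1L)
  if (length(pre_strs)) {
    ins_at[[1L]] <- vapply(strsplit(pre_strs, ""), function(v)
      paste(rev(v), collapse = ""), "")
  }
  has_ins <- which(lengths(ins_at) > 0)
  for (jn in has_ins) {
    strs <- ins_at[[jn]]
    need <- min(ceiling(jn_cov[jn] / 2), max(3L, ceiling(jn_cov[jn] / 3)))
    if (length(strs) < need) next
    maxk <- max(nchar(strs))
    resk <- character(0)
    for (k in seq_len(maxk)) {
      ch <- substr(strs, k, k)
      ch <- ch[nzchar(ch)]
      if (length(ch) < need) break
      tb <- table(ch)
      top <- sort(names(tb)[tb == max(tb)])[1]
      resk <- c(resk, top)
    }
    ins_str[jn] <- paste(resk, collapse = "")
  }
  if (length(pre_strs) && nzchar(ins_str[1L])) {
    ins_str[1L] <- paste(rev(strsplit(ins_str[1L], "")[[1]]), collapse = "")
  }
  base_out <- ifelse(sym == "-", "", sym)
  parts <- character(2L * L + 1L)
  parts[seq(1L, 2L * L + 1L, by = 2L)] <- ins_str
  parts[seq(2L, 2L * L, by = 2L)] <- base_out
  # depths reported for backbone-derived columns (insertions take the
  # junction coverage); interleave to match the emitted sequence
  depth_parts <- vector("list", 2L * L + 1L)
  depth_parts[seq(1L, 2L * L + 1L, by = 2L)] <-
    lapply(seq_len(L + 1L), function(j) rep(jn_cov[j], nchar(ins_str[j])))
  depth_parts[seq(2L, 2L * L, by = 2L)] <-
    lapply(seq_len(L), function(p) if (sym[p] == "-") integer() else covered[p])
  list(sequence = paste(parts, collapse = ""),
       depths = as.integer(unlist(depth_parts)))
}

#' @export
print.svlr_consensus <- function(x, ...) {
  cat(sprintf("<svlr_consensus> %d bp from %d segment(s)%s%s\n",
              nchar(x$sequence), x$n_support,
              if (isTRUE(x$low_confidence)) ", low-confidence" else "",
              if (!is.na(x$accepted)) paste0(", accepted=", x$accepted) else ""))
  invisible(x)
}

#' Validate a consensus by remapping it to the reference
#'
#' Deletion consensuses are rejected when the remapped location does not
#' overlap the original call; insertion consensuses are rejected when the
#' remapped insertion point lies more than `max_dist` bp (default 100) from
#' the original location.  Mapping uses either supplied PSL records (BLAT
#' output, query names matching `call$id`) or the internal aligner against
#' a local reference window.
#'
#' @param consensus `svlr_consensus` object.
#' @param call the call row the consensus belongs to.
#' @param ref reference `DNAStringSet` (named by chromosome); unused when
#'   `psl` is given.
#' @param psl optional PSL table from [read_psl()].
#' @param config thresholds (`consensus_flank`, `remap_max_dist`,
#'   `min_remap_identity`).
#' @return the consensus with `accepted` and `remap_distance` filled in.
#' @export
validate_consensus <- function(consensus, call, ref = NULL, psl = NULL,
                               config = svlr_config()) {
  flank <- config$consensus_flank
  if (isTRUE(consensus$low_confidence) && consensus$n_support < 2) {
    consensus$accepted <- FALSE
    return(consensus)
  }
  if (!is.null(psl)) {
    h <- psl[psl$qName == call$id, , drop = FALSE]
    h <- h[h$matches / pmax(1, h$qSize) >= config$min_remap_identity |
             h$matches >= 0.7 * (h$qEnd - h$qStart), , drop = FALSE]
    if (nrow(h) == 0) { consensus$accepted <- FALSE; return(consensus) }
    h <- h[which.max(h$matches), ]
    if (call$sv_type == "DEL") {
      ok <- h$tName == call$chrom1 && h$tStart < call$pos2 && h$tEnd > call$pos1
      consensus$accepted <- isTRUE(ok)
      consensus$remap_distance <- if (ok) 0 else NA_real_
    } else {
      # insertion point implied by the left aligned block boundary
      ins_pos <- h$tStart + flank
      consensus$remap_distance <- abs(ins_pos - call$pos1)
      consensus$accepted <- consensus$remap_distance <= config$remap_max_dist
    }
    return(consensus)
  }
  stopifnot(!is.null(ref))
  chrom <- as.character(call$chrom1)
  cs <- consensus$sequence
  Lc <- nchar(cs)
  wlo <- max(0L, call$pos1 - Lc - 1000L)
  whi <- min(Biostrings::width(ref[chrom]), call$pos2 + Lc + 1000L)
  window <- as.character(Biostrings::subseq(ref[[chrom]], wlo + 1L, whi))
  left <- substr(cs, 1L, min(flank, Lc))
  right <- substr(cs, max(1L, Lc - flank + 1L), Lc)
  al <- align_pair(window, left, mode = "local")
  ar <- align_pair(window, right, mode = "local")
  if (al$identity < config$min_remap_identity ||
      is.na(al$identity) || al$aln_len < 0.5 * nchar(left)) {
    consensus$accepted <- FALSE
    return(consensus)
  }
  if (call$sv_type == "DEL") {
    if (ar$identity < config$min_remap_identity || ar$aln_len < 0.5 * nchar(right)) {
      consensus$accepted <- FALSE
      return(consensus)
    }
    m_start <- wlo + al$a_start
    m_end <- wlo + ar$a_end
    ok <- m_start < call$pos2 && m_end > call$pos1
    consensus$accepted <- isTRUE(ok)
    consensus$remap_distance <- if (ok) 0 else NA_real_
  } else {
    # implied insertion point: reference position where the left flank ends
    ins_pos <- wlo + al$a_end
    consensus$remap_distance <- abs(ins_pos - call$pos1)
    consensus$accepted <- consensus$remap_distance <= config$remap_max_dist
  }
  consensus
}
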