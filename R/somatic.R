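#' Build a normal panel from germline callsets
#'
#' Pools the germline calls of all normal samples into one table queryable
#' under the same-locus rule; used to strip recurrent artifacts and
#' polymorphisms from somatic candidates.
#'
#' @param callsets list of per-sample germline call tables (all candidates,
#'   not only passing ones, so recurrent artifacts are represented).
#' @return data.frame of panel entries.
#' @export
build_normal_panel <- function(callsets) {
  cols <- c("sv_type", "chrom1", "pos1", "chrom2", "pos2", "length")
  out <- do.call(rbind, lapply(callsets, function(x) as.data.frame(x)[, cols]))
  if (is.null(out)) out <- data.frame(sv_type = character(),
                                      chrom1 = character(), pos1 = integer(),
                                      chrom2 = character(), pos2 = integer(),
                                      length = integer())
  rownames(out) <- NULL
  out
}

#' Call somatic SVs by tumor/normal subtraction
#'
#' Tumor candidates are removed when (i) at least one read in the matched
#' normal supports the same SV under the same-locus rule (any quality —
#' normal evidence is taken from raw clusters, not filtered calls), (ii)
#' the SV is present in the normal panel, or (iii) the matched-normal depth
#' at either breakpoint is below `min_normal_depth`.  Region filters are
#' re-applied with the somatic extensions: the 80% short-repeat filter also
#' covers deletions, and the segmental-duplication filter covers all types.
#' Inter-chromosomal translocation breakends are merged within 500 bp
#' upstream of this function (the germline merge stage handles it via
#' `merge_window_tra`).
#'
#' @param tumor_calls tumor call table (from [call_germline()] on the tumor
#'   sample; support thresholds are reused unchanged).
#' @param tumor_alignments tumor alignment table (for the re-applied
#'   somatic region filters).
#' @param normal_clusters cluster table of the matched normal (attribute
#'   `clusters` of its [call_germline()] result), or `NULL`.
#' @param panel normal panel from [build_normal_panel()], or `NULL`.
#' @param normal_alignments alignment table of the matched normal.
#' @param repeats,segdups optional annotations (see
#'   [apply_region_filters()]).
#' @param config threshold list.
#' @return tumor call table restricted to candidates, with columns
#'   `normal_support`, `normal_depth`, updated `filter`/`pass`; somatic
#'   calls are the `pass` rows.
#' @export
call_somatic <- function(tumor_calls, tumor_alignments,
                         normal_clusters = NULL, panel = NULL,
                         normal_alignments, repeats = NULL, segdups = NULL,
                         config = svlr_config()) {
  tc <- as.data.frame(tumor_calls)
  if (nrow(tc) == 0) {
    tc$normal_support <- integer(); tc$normal_depth <- integer()
    return(tc)
  }
  na <- as.data.frame(normal_alignments)
  na <- na[na$is_primary, , drop = FALSE]
  ngr <- GenomicRanges::GRanges(na$chrom, IRanges::IRanges(na$start + 1L, na$end))
  same_as <- function(tab, i) {
    if (is.null(tab) || nrow(tab) == 0) return(rep(FALSE, 0))
    vapply(seq_len(nrow(tab)), function(j)
      tab$sv_type[j] == tc$sv_type[i] &&
        sv_same_locus(tc$sv_type[i], tc$chrom1[i], tc$pos1[i], tc$chrom2[i],
                      tc$pos2[i], tc$length[i], tab$chrom1[j], tab$pos1[j],
                      tab$chrom2[j], tab$pos2[j], tab$length[j],
                      config$merge_window_ins, config$merge_window_other,
                      config$merge_window_tra, config$merge_min_overlap),
      TRUE)
  }
  nsup <- integer(nrow(tc)); ndep <- integer(nrow(tc))
  flags_add <- character(nrow(tc))
  for (i in seq_len(nrow(tc))) {
    m <- same_as(normal_clusters, i)
    nsup[i] <- if (any(m)) max(normal_clusters$support[m]) else 0L
    bp <- GenomicRanges::GRanges(
      c(tc$chrom1[i], tc$chrom2[i]),
      IRanges::IRanges(c(tc$pos1[i], tc$pos2[i]) + 1L,
                       c(tc$pos1[i], tc$pos2[i]) + 1L))
    ov <- GenomicRanges::findOverlaps(ngr, bp)
    d1 <- length(unique(na$read_id[S4Vectors::queryHits(ov)[
      S4Vectors::subjectHits(ov) == 1L]]))
    d2 <- length(unique(na$read_id[S4Vectors::queryHits(ov)[
      S4Vectors::subjectHits(ov) == 2L]]))
    ndep[i] <- min(d1, d2)
    fl <- character()
    if (nsup[i] > 0) fl <- c(fl, "in_normal")
    if (any(same_as(panel, i))) fl <- c(fl, "in_panel")
    if (ndep[i] < config$somatic_min_normal_depth) fl <- c(fl, "low_normal_depth")
    flags_add[i] <- paste(fl, collapse = ",")
  }
  tc$normal_support <- nsup
  tc$normal_depth <- ndep
  tc$filter <- vapply(seq_len(nrow(tc)), function(i) {
    old <- if (nzchar(tc$filter[i])) strsplit(tc$filter[i], ",")[[1]] else character()
    new <- if (nzchar(flags_add[i])) strsplit(flags_add[i], ",")[[1]] else character()
    paste(union(old, new), collapse = ",")
  }, "")
  # somatic region filters: repeat80 extends to deletions, segdup to all
  tc <- apply_region_filters(tc, tumor_alignments, repeats = repeats,
                             segdups = segdups, min_vaf = config$min_vaf,
                             mq_window = config$mq_window,
                             low_mq_thresh = config$low_mq_thresh,
                             low_mq_frac = config$low_mq_frac,
                             repeat80_types = c("DEL", "INV", "DUP", "TRA"),
                             segdup_types = c("DEL", "INS", "INV", "DUP", "TRA"))
  tc$pass <- !nzchar(tc$filter)
  tc
}

#' Map reads to small viral genomes with a k-mer seed-and-extend mapper
#'
#' Desk-scale mapper for viral genomes of a few kb: exact k-mer seeds vote
#' for a (strand, diagonal) placement per viral reference; the best-voted
#' placement is refined with a banded local alignment.  Intended for the
#' bundled simulator's synthetic genomes; production use should supply
#' externally produced alignments instead.
#'
#' @param reads named character vector of read sequences.
#' @param viral_refs named character vector (or `DNAStringSet`) of viral
#'   genome sequences.
#' @param k seed length (default 13).
#' @param min_seed_votes minimum k-mer votes to attempt extension
#'   (default 3).
#' @param min_score minimum local alignment score to report (default 50).
#' @return data.frame: `read_id`, `virus`, `v_start`, `v_end` (0-based
#'   half-open), `read_start`, `read_end` (original read coordinates),
#'   `strand`, `score`, `identity`.
#' @export
map_reads_to_virus <- function(reads, viral_refs, k = 13L,
                               min_seed_votes = 3L, min_score = 50L) {
  if (inherits(viral_refs, "DNAStringSet")) {
    viral_refs <- setNames(as.character(viral_refs), names(viral_refs))
  }
  # k-mer index per virus
  idx <- lapply(viral_refs, function(v) {
    n <- nchar(v) - k + 1L
    if (n < 1) return(list())
    km <- substring(v, seq_len(n), seq_len(n) + k - 1L)
    split(seq_len(n) - 1L, km)
  })
  hits <- list()
  for (rid in names(reads)) {
    for (ori in c("+", "-")) {
      rseq <- if (ori == "+") reads[[rid]] else revcomp(reads[[rid]])
      n <- nchar(rseq) - k + 1L
      if (n < 1) next
      step <- max(1L, k %/% 2L)
      starts <- seq(1L, n, by = step)
      km <- substring(rseq, starts, starts + k - 1L)
      for (vn in names(idx)) {
        vp <- idx[[vn]][km]
        got <- !vapply(vp, is.null, TRUE)
        if (sum(got) < min_seed_votes) next
        diag <- unlist(lapply(which(got), function(ii)
          (starts[ii] - 1L) - vp[[ii]]), use.names = FALSE)
        dtab <- table(round(diag / 50))
        best_d <- as.integer(names(dtab)[which.max(dtab)]) * 50L
        if (max(dtab) < min_seed_votes) next
        # banded local alignment of read vs virus
        aln <- align_pair(viral_refs[[vn]], rseq, mode = "local")
        if (aln$score < min_score) next
        rs <- aln$b_start; re <- aln$b_end
        if (ori == "-") {
          L <- nchar(reads[[rid]])
          tmp <- rs; rs <- L - re; re <- L - tmp
        }
        hits[[length(hits) + 1L]] <- data.frame(
          read_id = rid, virus = vn, v_start = aln$a_start,
          v_end = aln$a_end, read_start = rs, read_end = re, strand = ori,
          score = aln$score, identity = aln$identity,
          stringsAsFactors = FALSE)
        break  # one orientation hit per read/virus is enough
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(read_id = character(), virus = character(),
                      v_start = integer(), v_end = integer(),
                      read_start = integer(), read_end = integer(),
                      strand = character(), score = integer(),
                      identity = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, hits)
}

#' Detect virus integration sites from chimeric reads
#'
#' Selects the viral reference with the most mapped reads as the best
#' reference for the sample, then pairs each read's viral segment with its
#' human alignment: the human-side breakend adjacent (in read coordinates)
#' to the viral segment defines an integration junction.  Junctions are
#' clustered within `window` bp and sites supported by at least
#' `min_support` reads are reported.
#'
#' @param viral_hits viral alignment table from [map_reads_to_virus()] or
#'   [parse_alignments()] on a read-vs-virus SAM (columns `read_id`,
#'   `chrom`→`virus` or `virus`, `read_start`, `read_end`, plus
#'   `start`/`v_start`).
#' @param human_alignments human alignment table of the same reads.
#' @param window junction clustering window in bp (default 500).
#' @param min_support minimum chimeric reads per site (default 2).
#' @return data.frame of integration sites: `human_chrom`, `human_pos`,
#'   `virus`, `virus_pos`, `orientation` (`left`/`right`: side of the human
#'   junction the virus attaches to), `support`; attribute `best_virus`.
#' @export
detect_virus_integrations <- function(viral_hits, human_alignments,
                                      window = 500L, min_support = 2L) {
  vh <- as.data.frame(viral_hits)
  if (!"virus" %in% names(vh) && "chrom" %in% names(vh)) {
    vh$virus <- vh$chrom
    vh$v_start <- vh$start
    vh$v_end <- vh$end
  }
  empty <- data.frame(human_chrom = character(), human_pos = integer(),
                      virus = character(), virus_pos = integer(),
                      orientation = character(), support = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(vh) == 0) return(empty)
  cnt <- tapply(vh$read_id, vh$virus, function(x) length(unique(x)))
  best <- names(cnt)[which.max(cnt)]  # ties: first by order
  vh <- vh[vh$virus == best, , drop = FALSE]
  ha <- as.data.frame(human_alignments)
  ha <- ha[ha$is_primary | TRUE, , drop = FALSE]
  junc <- list()
  for (i in seq_len(nrow(vh))) {
    hr <- ha[ha$read_id == vh$read_id[i], , drop = FALSE]
    if (nrow(hr) == 0) next
    for (j in seq_len(nrow(hr))) {
      h <- hr[j, ]
      # which side of the human segment (in read coordinates) does the
      # viral segment sit on?
      if (vh$read_start[i] >= h$read_end - 20L) {
        hpos <- if (h$strand == "+") h$end else h$start
        side <- "right"
        vpos <- if (h$strand == "+") vh$v_start[i] else vh$v_end[i]
      } else if (vh$read_end[i] <= h$read_start + 20L) {
        hpos <- if (h$strand == "+") h$start else h$end
        side <- "left"
        vpos <- if (h$strand == "+") vh$v_end[i] else vh$v_start[i]
      } else next
      junc[[length(junc) + 1L]] <- data.frame(
        read_id = vh$read_id[i], human_chrom = h$chrom, human_pos = hpos,
        virus = best, virus_pos = vpos, orientation = side,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(junc)) return(empty)
  jd <- do.call(rbind, junc)
  jd <- jd[order(jd$human_chrom, jd$orientation, jd$human_pos), , drop = FALSE]
  brk <- c(TRUE, diff(jd$human_pos) > window |
             jd$human_chrom[-1] != jd$human_chrom[-nrow(jd)] |
             jd$orientation[-1] != jd$orientation[-nrow(jd)])
  cid <- cumsum(brk)
  out <- do.call(rbind, lapply(split(jd, cid), function(g) data.frame(
    human_chrom = g$human_chrom[1],
    human_pos = as.integer(round(median(g$human_pos))),
    virus = g$virus[1], virus_pos = as.integer(round(median(g$virus_pos))),
    orientation = names(which.max(table(g$orientation))),
    support = length(unique(g$read_id)), stringsAsFactors = FALSE)))
  out <- out[out$support >= min_support, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "best_virus") <- best
  out
}
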