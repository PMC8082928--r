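#' Cluster SV signatures along the genome
#'
#' Single-linkage clustering of same-type signatures: sorted by `pos1`, a
#' signature joins the open cluster when both breakpoints are within the
#' type-specific window of the previous member (50 bp for insertions and
#' deletions, 100 bp for inversions and translocations).  A cluster becomes
#' a candidate when supported by at least `min_support` distinct reads with
#' mapping quality at or above `min_mapq`.
#'
#' @param signatures signature table from [extract_signatures()].
#' @param window_indel clustering window for INS/DEL in bp (default 50).
#' @param window_other clustering window for INV/DUP/TRA/CLIP (default 100).
#' @param min_support candidate support threshold in distinct high-quality
#'   reads (default 2).
#' @param min_mapq mapping quality counted as high-quality (default 20).
#' @return data.frame of clusters: `cluster_id`, `sv_type`, `chrom1`,
#'   `pos1`, `chrom2`, `pos2`, `length` (member medians), `support`
#'   (distinct reads), `n_hq`, `mean_mapq`, `candidate`, `chimeric`,
#'   list-columns `member_idx` (row indices into `signatures`) and
#'   `read_ids`.
#' @export
cluster_signatures <- function(signatures, window_indel = 50L,
                               window_other = 100L, min_support = 2L,
                               min_mapq = 20L) {
  s <- as.data.frame(signatures)
  if (nrow(s) == 0) return(empty_clusters())
  s$.row <- seq_len(nrow(s))
  key <- paste(s$sv_type, s$chrom1, s$chrom2,
               ifelse(is.na(s$clip_side), "", s$clip_side))
  groups <- split(s, key)
  out <- list()
  for (g in groups) {
    win <- if (g$sv_type[1] %in% c("INS", "DEL")) window_indel else window_other
    g <- g[order(g$pos1, g$pos2), , drop = FALSE]
    brk <- c(TRUE, diff(g$pos1) > win | abs(diff(g$pos2)) > win)
    cid <- cumsum(brk)
    for (cl in split(g, cid)) {
      out[[length(out) + 1L]] <- summarize_cluster(cl, min_mapq, min_support)
    }
  }
  res <- do.call(rbind, out)
  res$cluster_id <- seq_len(nrow(res))
  rownames(res) <- NULL
  res
}

#' @noRd
summarize_cluster <- function(members, min_mapq, min_support) {
  hq <- members[members$mapq >= min_mapq, , drop = FALSE]
  chim <- length(unique(members$read_offset_fraction)) == 1L &&
    members$source[1] == "split" && nrow(members) > 1L
  data.frame(
    cluster_id = NA_integer_,
    sv_type = members$sv_type[1],
    chrom1 = members$chrom1[1],
    pos1 = as.integer(round(median(members$pos1))),
    chrom2 = members$chrom2[1],
    pos2 = as.integer(round(median(members$pos2))),
    length = as.integer(round(median(members$length))),
    support = length(unique(members$read_id)),
    n_hq = length(unique(hq$read_id)),
    mean_mapq = mean(members$mapq),
    candidate = length(unique(hq$read_id)) >= min_support,
    chimeric = chim,
    member_idx = I(list(members$.row)),
    read_ids = I(list(unique(members$read_id))),
    stringsAsFactors = FALSE)
}

#' @noRd
empty_clusters <- function() {
  data.frame(cluster_id = integer(), sv_type = character(),
             chrom1 = character(), pos1 = integer(), chrom2 = character(),
             pos2 = integer(), length = integer(), support = integer(),
             n_hq = integer(), mean_mapq = numeric(), candidate = logical(),
             chimeric = logical(), member_idx = I(list()),
             read_ids = I(list()), stringsAsFactors = FALSE)
}

#' Do two SV loci denote the same variant?
#'
#' The cross-cluster / cross-sample / panel identity rule: same type, same
#' chromosomes, both breakpoints within the window (300 bp insertions,
#' 1000 bp others, 500 bp inter-chromosomal translocation breakends), and a
#' reciprocal interval overlap of at least `min_overlap` (insertions: length
#' ratio at least `min_overlap`; translocation breakends: windows only).
#'
#' @param type,c1a,p1a,c2a,p2a,lena first locus; `typeb,...` second locus.
#' @keywords internal
#' @noRd
sv_same_locus <- function(type, c1a, p1a, c2a, p2a, lena,
                          c1b, p1b, c2b, p2b, lenb,
                          window_ins = 300L, window_other = 1000L,
                          window_tra = 500L, min_overlap = 0.8) {
  if (c1a != c1b || c2a != c2b) return(FALSE)
  win <- switch(type, INS = window_ins, TRA = window_tra, window_other)
  if (abs(p1a - p1b) > win || abs(p2a - p2b) > win) return(FALSE)
  if (type == "INS") {
    if (lena == 0 || lenb == 0) return(TRUE)
    return(min(lena, lenb) / max(lena, lenb) >= min_overlap)
  }
  if (type == "TRA") return(TRUE)
  lo <- max(p1a, p1b); hi <- min(p2a, p2b)
  ov <- max(0, hi - lo)
  span_a <- max(1L, p2a - p1a); span_b <- max(1L, p2b - p1b)
  (ov / span_a >= min_overlap) && (ov / span_b >= min_overlap)
}

#' Merge nearby candidate clusters of the same SV
#'
#' Candidate clusters of one type are merged when their breakpoints are
#' within 300 bp (insertions) or 1000 bp (other types) of each other and
#' the SV intervals overlap reciprocally by at least 80% (insertions are
#' compared by length ratio).  Support becomes the union of read ids and
#' representative coordinates are recomputed as member medians.
#'
#' @param clusters cluster table from [cluster_signatures()].
#' @param signatures the signature table the clusters were built from.
#' @inheritParams sv_same_locus
#' @return merged cluster table of the same shape.
#' @export
merge_candidate_breakpoints <- function(clusters, signatures,
                                        window_ins = 300L,
                                        window_other = 1000L,
                                        window_tra = 500L,
                                        min_overlap = 0.8) {
  cl <- as.data.frame(clusters)
  if (nrow(cl) <= 1) return(cl)
  s <- as.data.frame(signatures)
  s$.row <- seq_len(nrow(s))
  # union-find over clusters
  parent <- seq_len(nrow(cl))
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  ord <- order(cl$sv_type, cl$chrom1, cl$pos1)
  for (ii in seq_along(ord)[-1]) {
    i <- ord[ii]
    for (jj in (ii - 1):max(1, ii - 25)) {
      j <- ord[jj]
      if (cl$sv_type[j] != cl$sv_type[i] || cl$chrom1[j] != cl$chrom1[i]) break
      if (cl$pos1[i] - cl$pos1[j] > max(window_ins, window_other)) break
      if (sv_same_locus(cl$sv_type[i], cl$chrom1[i], cl$pos1[i], cl$chrom2[i],
                        cl$pos2[i], cl$length[i], cl$chrom1[j], cl$pos1[j],
                        cl$chrom2[j], cl$pos2[j], cl$length[j],
                        window_ins, window_other, window_tra, min_overlap)) {
        parent[find(i)] <- find(j)
      }
    }
  }
  roots <- vapply(seq_len(nrow(cl)), find, 0L)
  out <- list()
  for (grp in split(seq_len(nrow(cl)), roots)) {
    idx <- unique(unlist(cl$member_idx[grp]))
    members <- s[idx, , drop = FALSE]
    cs <- summarize_cluster(members, min_mapq = 0L, min_support = 1L)
    # candidate status and HQ counts are inherited from the parts
    cs$n_hq <- max(cl$n_hq[grp])
    cs$candidate <- any(cl$candidate[grp])
    cs$chimeric <- all(cl$chimeric[grp])
    out[[length(out) + 1L]] <- cs
  }
  res <- do.call(rbind, out)
  res$cluster_id <- seq_len(nrow(res))
  rownames(res) <- NULL
  res
}

#' Apply read-level and support-count filters to clusters
#'
#' Reads whose signature falls within the terminal `edge_frac` of the read
#' are discarded before support counting; deletion support reads carrying a
#' nearby insertion (within `ins_near_bp` of a breakpoint, with length at
#' least 10% of the deletion for deletions under 1000 bp or 30% for longer
#' ones) are discarded.  Support thresholds: deletions 100-500 bp need 4
#' reads, 501-1000 bp need 3, over 1000 bp need 2; insertions up to 1000 bp
#' need 3 insertion-containing reads, larger ones 2 (or at least 2 clipped
#' reads on each side); inversions and translocations need 2.  Calls
#' failing their threshold carry the `low_support` flag; chimeric-looking
#' clusters carry `chimeric`.
#'
#' @param clusters cluster table (post-merge).
#' @param signatures signature table (with its `minor_ins` attribute, or
#'   pass `minor_ins` explicitly).
#' @param sample_id sample label stamped on the calls.
#' @param minor_ins data.frame of sub-threshold insertions per read.
#' @param edge_frac terminal fraction of the read treated as unreliable
#'   (default 0.1).
#' @param ins_near_bp window around deletion breakpoints searched for
#'   accompanying insertions (default 30).
#' @return call table: `id`, `sample_id`, `sv_type`, coordinates, `length`,
#'   `support`, `filter` (comma string, `""` when clean), plus list-column
#'   `read_ids` of surviving support reads.
#' @export
apply_support_filters <- function(clusters, signatures, sample_id = "S1",
                                  minor_ins = attr(signatures, "minor_ins"),
                                  edge_frac = 0.1, ins_near_bp = 30L) {
  cl <- as.data.frame(clusters)
  s <- as.data.frame(signatures)
  if (is.null(minor_ins)) {
    minor_ins <- data.frame(read_id = character(), chrom = character(),
                            pos = integer(), len = integer())
  }
  # all insertion evidence per read (sub-threshold and full signatures)
  ins_evid <- rbind(
    minor_ins[, c("read_id", "chrom", "pos", "len")],
    if (nrow(s)) {
      si <- s[s$sv_type == "INS", , drop = FALSE]
      data.frame(read_id = si$read_id, chrom = si$chrom1, pos = si$pos1,
                 len = si$length, stringsAsFactors = FALSE)
    })
  clip_cl <- cl[cl$sv_type == "CLIP", , drop = FALSE]
  calls <- list()
  for (i in seq_len(nrow(cl))) {
    cc <- cl[i, ]
    if (cc$sv_type == "CLIP") next
    mem <- s[cc$member_idx[[1]], , drop = FALSE]
    keep <- mem$read_offset_fraction >= edge_frac &
      mem$read_offset_fraction <= 1 - edge_frac
    mem <- mem[keep, , drop = FALSE]
    if (cc$sv_type == "DEL" && nrow(mem) > 0) {
      drop <- logical(nrow(mem))
      for (k in seq_len(nrow(mem))) {
        ev <- ins_evid[ins_evid$read_id == mem$read_id[k] &
                         ins_evid$chrom == mem$chrom1[k], , drop = FALSE]
        if (nrow(ev) == 0) next
        near <- pmin(abs(ev$pos - mem$pos1[k]), abs(ev$pos - mem$pos2[k])) <= ins_near_bp
        lim <- if (mem$length[k] < 1000) 0.10 else 0.30
        drop[k] <- any(near & ev$len >= lim * mem$length[k])
      }
      mem <- mem[!drop, , drop = FALSE]
    }
    support <- length(unique(mem$read_id))
    L <- cc$length
    need <- switch(cc$sv_type,
                   DEL = if (L <= 500) 4L else if (L <= 1000) 3L else 2L,
                   INS = if (L <= 1000) 3L else 2L,
                   2L)
    ok <- support >= need
    if (!ok && cc$sv_type == "INS" && L > 1000 && nrow(clip_cl) > 0) {
      # >= 2 soft-clipped reads on each side corroborate a large insertion
      near <- clip_cl[clip_cl$chrom1 == cc$chrom1 &
                        abs(clip_cl$pos1 - cc$pos1) <= 300, , drop = FALSE]
      if (nrow(near) > 0) {
        sides <- vapply(near$member_idx, function(ix) s$clip_side[ix[1]], "")
        ok <- any(near$support[sides == "left"] >= 2) &&
          any(near$support[sides == "right"] >= 2)
      }
    }
    flags <- character()
    if (!ok) flags <- c(flags, "low_support")
    if (isTRUE(cc$chimeric)) flags <- c(flags, "chimeric")
    calls[[length(calls) + 1L]] <- data.frame(
      id = sprintf("%s_%s_%d", sample_id, cc$sv_type, length(calls) + 1L),
      sample_id = sample_id, sv_type = cc$sv_type, chrom1 = cc$chrom1,
      pos1 = cc$pos1, chrom2 = cc$chrom2, pos2 = cc$pos2, length = cc$length,
      support = support, filter = paste(flags, collapse = ","),
      read_ids = I(list(unique(mem$read_id))), stringsAsFactors = FALSE)
  }
  if (!length(calls)) return(empty_calls())
  res <- do.call(rbind, calls)
  rownames(res) <- NULL
  res
}

#' @noRd
empty_calls <- function() {
  data.frame(id = character(), sample_id = character(), sv_type = character(),
             chrom1 = character(), pos1 = integer(), chrom2 = character(),
             pos2 = integer(), length = integer(), support = integer(),
             filter = character(), read_ids = I(list()),
             stringsAsFactors = FALSE)
}

#' Apply region-level filters: VAF, low-MAPQ regions, repeats, segdups
#'
#' Depth at a breakpoint is the number of distinct reads whose primary
#' alignment spans it (any mapping quality); `vaf = support / depth`.
#' Flags: `low_vaf` below `min_vaf`; `low_mq_region` when at least
#' `low_mq_frac` of the reads within `mq_window` of a breakpoint have
#' mapping quality below `low_mq_thresh`; `repeat80` when at least 80% of
#' the SV span is covered by short repeats (inversions/duplications/
#' translocations at the germline stage; pass `repeat80_types` to extend to
#' deletions for somatic calling); `segdup` when the two breakpoints fall
#' in different segments of the same segmental duplication.
#'
#' @param calls call table from [apply_support_filters()].
#' @param alignments alignment table of the same sample.
#' @param repeats optional repeat intervals (from [parse_repeat_files()])
#'   on the reference.
#' @param segdups optional segmental-duplication table with `chrom`,
#'   `start`, `end`, `name` (segments of one duplication share a name).
#' @param min_vaf minimum variant allele frequency (default 0.03).
#' @param mq_window half-width of the low-MAPQ window in bp (default 500).
#' @param low_mq_thresh,low_mq_frac the "30% of reads below MAPQ 30" rule.
#' @param repeat80_types SV types subject to the 80% short-repeat filter.
#' @param segdup_types SV types subject to the segdup filter.
#' @return the call table with `depth`, `vaf`, updated `filter` and a
#'   logical `pass` column (`pass` iff no flags).
#' @export
apply_region_filters <- function(calls, alignments, repeats = NULL,
                                 segdups = NULL, min_vaf = 0.03,
                                 mq_window = 500L, low_mq_thresh = 30L,
                                 low_mq_frac = 0.3,
                                 repeat80_types = c("INV", "DUP", "TRA"),
                                 segdup_types = c("INV", "DUP", "TRA")) {
  cc <- as.data.frame(calls)
  if (nrow(cc) == 0) {
    cc$depth <- integer(); cc$vaf <- numeric(); cc$pass <- logical()
    return(cc)
  }
  a <- as.data.frame(alignments)
  # depth is read-level: a read spans a breakpoint when any of its aligned
  # segments does (for a homozygous inversion the inverted segment is
  # usually supplementary)
  agr <- GenomicRanges::GRanges(a$chrom, IRanges::IRanges(a$start + 1L, a$end))
  short_gr <- NULL
  if (!is.null(repeats) && nrow(repeats) > 0) {
    sr <- repeats[repeats$repeat_class %in% c("Simple/Tandem", "Low_complexity"), ,
                  drop = FALSE]
    if (nrow(sr) > 0) {
      short_gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
        sr$seq_id, IRanges::IRanges(sr$start + 1L, sr$end)))
    }
  }
  depth <- integer(nrow(cc)); vaf <- numeric(nrow(cc))
  filt <- cc$filter
  for (i in seq_len(nrow(cc))) {
    bp <- GenomicRanges::GRanges(cc$chrom1[i],
                                 IRanges::IRanges(cc$pos1[i] + 1L, cc$pos1[i] + 1L))
    hits <- S4Vectors::queryHits(GenomicRanges::findOverlaps(agr, bp))
    depth[i] <- length(unique(a$read_id[hits]))
    vaf[i] <- if (depth[i] > 0) min(1, cc$support[i] / depth[i]) else 0
    flags <- character()
    if (vaf[i] < min_vaf) flags <- c(flags, "low_vaf")
    # low-MAPQ region around either breakpoint
    win <- GenomicRanges::GRanges(
      c(cc$chrom1[i], cc$chrom2[i]),
      IRanges::IRanges(pmax(1L, c(cc$pos1[i], cc$pos2[i]) - mq_window + 1L),
                       c(cc$pos1[i], cc$pos2[i]) + mq_window))
    wh <- unique(S4Vectors::queryHits(GenomicRanges::findOverlaps(agr, win)))
    if (length(wh) > 0) {
      rmq <- tapply(a$mapq[wh], a$read_id[wh], max)
      if (mean(rmq < low_mq_thresh) >= low_mq_frac) {
        flags <- c(flags, "low_mq_region")
      }
    }
    if (!is.null(short_gr) && cc$sv_type[i] %in% repeat80_types &&
        cc$chrom1[i] == cc$chrom2[i] && cc$pos2[i] > cc$pos1[i]) {
      span <- GenomicRanges::GRanges(cc$chrom1[i],
                                     IRanges::IRanges(cc$pos1[i] + 1L, cc$pos2[i]))
      cov <- sum(IRanges::width(GenomicRanges::intersect(short_gr, span))) /
        IRanges::width(span)
      if (cov >= 0.8) flags <- c(flags, "repeat80")
    }
    if (!is.null(segdups) && nrow(segdups) > 0 &&
        cc$sv_type[i] %in% segdup_types) {
      s1 <- segdups$name[segdups$chrom == cc$chrom1[i] &
                           segdups$start <= cc$pos1[i] & cc$pos1[i] < segdups$end]
      s2i <- segdups$chrom == cc$chrom2[i] &
        segdups$start <= cc$pos2[i] & cc$pos2[i] < segdups$end
      s2 <- segdups$name[s2i]
      shared <- intersect(s1, s2)
      if (length(shared) > 0) {
        # same duplication, different segments?
        diff_seg <- any(vapply(shared, function(nm) {
          seg1 <- which(segdups$name == nm & segdups$chrom == cc$chrom1[i] &
                          segdups$start <= cc$pos1[i] & cc$pos1[i] < segdups$end)
          seg2 <- which(segdups$name == nm & s2i)
          length(setdiff(seg2, seg1)) > 0
        }, TRUE))
        if (diff_seg) flags <- c(flags, "segdup")
      }
    }
    old <- if (nzchar(filt[i])) strsplit(filt[i], ",")[[1]] else character()
    filt[i] <- paste(union(old, flags), collapse = ",")
  }
  cc$depth <- depth
  cc$vaf <- vaf
  cc$filter <- filt
  cc$pass <- !nzchar(filt)
  cc
}

#' Allele count contributed by one carrier
#'
#' Maps a per-sample VAF to a diploid allele count: homozygous (2) at or
#' above `hom_vaf`, heterozygous (1) below.
#' @param vaf variant allele frequency in the carrier.
#' @param hom_vaf homozygosity threshold (default 0.7).
#' @return integer allele count.
#' @export
genotype_allele_count <- function(vaf, hom_vaf = 0.7) {
  ifelse(vaf >= hom_vaf, 2L, 1L)
}

#' Merge per-sample callsets into a population callset
#'
#' Calls are pooled across samples and grouped under the same-locus rule
#' (breakpoints within 300 bp for insertions / 1000 bp otherwise and 80%
#' reciprocal overlap).  Each carrier contributes 1 or 2 alleles via
#' [genotype_allele_count()]; SVs with allele frequency at or above
#' `min_af` over `2 * n_samples` alleles are retained.
#'
#' @param callsets list of per-sample call tables (pass calls, with `vaf`).
#' @param n_samples cohort size the allele frequency is computed over.
#' @param min_af minimum population allele frequency (default 0.1).
#' @inheritParams sv_same_locus
#' @return data.frame of population SVs: representative coordinates,
#'   `carriers` (list), `allele_count`, `allele_frequency`, sorted by
#'   coordinate.
#' @export
merge_across_samples <- function(callsets, n_samples, min_af = 0.1,
                                 window_ins = 300L, window_other = 1000L,
                                 window_tra = 500L, min_overlap = 0.8) {
  all <- do.call(rbind, lapply(callsets, function(x)
    as.data.frame(x)[, c("sample_id", "sv_type", "chrom1", "pos1", "chrom2",
                         "pos2", "length", "vaf")]))
  if (is.null(all) || nrow(all) == 0) {
    return(data.frame(sv_type = character(), chrom1 = character(),
                      pos1 = integer(), chrom2 = character(), pos2 = integer(),
                      length = integer(), n_carriers = integer(),
                      carriers = I(list()), allele_count = integer(),
                      allele_frequency = numeric(), stringsAsFactors = FALSE))
  }
  all <- all[order(all$sv_type, all$chrom1, all$pos1), , drop = FALSE]
  parent <- seq_len(nrow(all))
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (i in seq_len(nrow(all))[-1]) {
    for (j in (i - 1):max(1, i - 25)) {
      if (all$sv_type[j] != all$sv_type[i] || all$chrom1[j] != all$chrom1[i]) break
      if (all$pos1[i] - all$pos1[j] > max(window_ins, window_other)) break
      if (sv_same_locus(all$sv_type[i], all$chrom1[i], all$pos1[i],
                        all$chrom2[i], all$pos2[i], all$length[i],
                        all$chrom1[j], all$pos1[j], all$chrom2[j],
                        all$pos2[j], all$length[j],
                        window_ins, window_other, window_tra, min_overlap)) {
        parent[find(i)] <- find(j)
      }
    }
  }
  roots <- vapply(seq_len(nrow(all)), find, 0L)
  out <- list()
  for (grp in split(seq_len(nrow(all)), roots)) {
    g <- all[grp, , drop = FALSE]
    carriers <- unique(g$sample_id)
    ac <- sum(vapply(carriers, function(sm)
      genotype_allele_count(max(g$vaf[g$sample_id == sm])), 0L))
    out[[length(out) + 1L]] <- data.frame(
      sv_type = g$sv_type[1], chrom1 = g$chrom1[1],
      pos1 = as.integer(round(median(g$pos1))), chrom2 = g$chrom2[1],
      pos2 = as.integer(round(median(g$pos2))),
      length = as.integer(round(median(g$length))),
      n_carriers = length(carriers), carriers = I(list(carriers)),
      allele_count = ac, allele_frequency = ac / (2 * n_samples),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- res[res$allele_frequency >= min_af, , drop = FALSE]
  res <- res[order(res$chrom1, res$pos1, res$sv_type), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Germline SV calling for one sample
#'
#' Runs the full per-sample germline stage: signature extraction,
#' clustering, candidate selection, breakpoint merging, support filters and
#' region filters.
#'
#' @param alignments alignment table from [parse_alignments()], or a path
#'   to SAM/BAM.
#' @param sample_id sample label.
#' @param repeats,segdups optional annotation tables (see
#'   [apply_region_filters()]).
#' @param config threshold list from [svlr_config()].
#' @return call table with `pass` column; attribute `clusters` and
#'   `signatures` retain the intermediate stages.
#' @export
call_germline <- function(alignments, sample_id = "S1", repeats = NULL,
                          segdups = NULL, config = svlr_config()) {
  if (is.character(alignments)) {
    alignments <- parse_alignments(alignments, min_mapq = config$min_mapq)
  }
  sig <- extract_signatures(alignments, min_indel = config$min_indel,
                            min_clip = config$min_clip)
  cl <- cluster_signatures(sig, window_indel = config$cluster_window_indel,
                           window_other = config$cluster_window_other,
                           min_support = config$candidate_min_support,
                           min_mapq = config$min_mapq)
  cand <- cl[cl$candidate | cl$sv_type == "CLIP", , drop = FALSE]
  cand <- merge_candidate_breakpoints(cand, sig,
                                      window_ins = config$merge_window_ins,
                                      window_other = config$merge_window_other,
                                      window_tra = config$merge_window_tra,
                                      min_overlap = config$merge_min_overlap)
  calls <- apply_support_filters(cand, sig, sample_id = sample_id,
                                 edge_frac = config$edge_frac,
                                 ins_near_bp = config$ins_near_bp)
  calls <- apply_region_filters(calls, alignments, repeats = repeats,
                                segdups = segdups, min_vaf = config$min_vaf,
                                mq_window = config$mq_window,
                                low_mq_thresh = config$low_mq_thresh,
                                low_mq_frac = config$low_mq_frac)
  attr(calls, "clusters") <- cl
  attr(calls, "signatures") <- sig
  calls
}
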