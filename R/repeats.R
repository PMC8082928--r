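#' Parse RepeatMasker .out and Tandem Repeat Finder .dat files
#'
#' Both are standard column formats: RepeatMasker `.out` has three header
#' lines then whitespace-separated hits (query coordinates 1-based
#' inclusive, strand `+` or `C`, repeat class/family such as `SINE/Alu`);
#' TRF `.dat` (from `-d`) carries `Sequence:` headers and
#' whitespace-separated records per tandem repeat.  Unparseable lines are
#' skipped and counted.
#'
#' @param rm_out path to a RepeatMasker `.out` file, or `NULL`.
#' @param trf_dat path to a TRF `.dat` file, or `NULL`.
#' @return data.frame of repeat intervals: `seq_id`, `start`, `end`
#'   (0-based half-open), `repeat_class` (`SINE`, `LINE`, `LTR`, `DNA`,
#'   `Simple/Tandem`, `Low_complexity`, `Other`), `family`, `strand`,
#'   `rep_begin`, `rep_end`, `rep_left` (position in the repeat consensus;
#'   NA for TRF), `source` (`rm`/`trf`).  Attribute `n_skipped`.
#' @export
parse_repeat_files <- function(rm_out = NULL, trf_dat = NULL) {
  out <- list()
  n_skip <- 0L
  if (!is.null(rm_out) && file.exists(rm_out)) {
    lines <- readLines(rm_out)
    lines <- lines[!grepl("^\\s*$", lines)]
    lines <- lines[!grepl("^\\s*(SW|score|bit)", lines)]  # header rows
    for (ln in lines) {
      f <- strsplit(trimws(ln), "\\s+")[[1]]
      if (length(f) < 14 || is.na(suppressWarnings(as.integer(f[6])))) {
        n_skip <- n_skip + 1L
        next
      }
      strand <- if (f[9] == "C") "-" else "+"
      cls_raw <- strsplit(f[11], "/")[[1]][1]
      cls <- switch(cls_raw,
                    SINE = "SINE", LINE = "LINE", LTR = "LTR", DNA = "DNA",
                    Simple_repeat = "Simple/Tandem",
                    Satellite = "Simple/Tandem",
                    Low_complexity = "Low_complexity",
                    "Other")
      strip <- function(x) suppressWarnings(as.integer(gsub("[()]", "", x)))
      if (strand == "+") {
        rb <- strip(f[12]); re_ <- strip(f[13]); rl <- strip(f[14])
      } else {
        rl <- strip(f[12]); re_ <- strip(f[13]); rb <- strip(f[14])
      }
      out[[length(out) + 1L]] <- data.frame(
        seq_id = f[5], start = as.integer(f[6]) - 1L, end = as.integer(f[7]),
        repeat_class = cls, family = f[10], strand = strand,
        rep_begin = rb, rep_end = re_, rep_left = rl, source = "rm",
        stringsAsFactors = FALSE)
    }
  }
  if (!is.null(trf_dat) && file.exists(trf_dat)) {
    cur <- NA_character_
    for (ln in readLines(trf_dat)) {
      if (grepl("^Sequence:", ln)) {
        cur <- trimws(sub("^Sequence:", "", ln))
        cur <- strsplit(cur, "\\s+")[[1]][1]
        next
      }
      if (!grepl("^[0-9]+ [0-9]+ ", ln)) next
      f <- strsplit(trimws(ln), "\\s+")[[1]]
      if (length(f) < 13 || is.na(cur)) {
        n_skip <- n_skip + 1L
        next
      }
      out[[length(out) + 1L]] <- data.frame(
        seq_id = cur, start = as.integer(f[1]) - 1L, end = as.integer(f[2]),
        repeat_class = "Simple/Tandem",
        family = paste0("TRF(", f[14], ")"), strand = "+",
        rep_begin = NA_integer_, rep_end = NA_integer_,
        rep_left = NA_integer_, source = "trf", stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else data.frame(
    seq_id = character(), start = integer(), end = integer(),
    repeat_class = character(), family = character(), strand = character(),
    rep_begin = integer(), rep_end = integer(), rep_left = integer(),
    source = character(), stringsAsFactors = FALSE)
  attr(res, "n_skipped") <- n_skip
  res
}

#' Fraction of a sequence covered by a set of intervals
#'
#' Interval-union coverage over `[0, seq_len)`; intervals are clipped to
#' the sequence.
#' @param intervals data.frame with `start`, `end` (0-based half-open).
#' @param seq_len sequence length.
#' @return scalar in `[0, 1]`.
#' @export
interval_coverage <- function(intervals, seq_len) {
  if (is.null(intervals) || nrow(intervals) == 0 || seq_len <= 0) return(0)
  ir <- IRanges::IRanges(pmax(intervals$start, 0L) + 1L,
                         pmin(intervals$end, seq_len))
  ir <- ir[IRanges::width(ir) > 0]
  if (length(ir) == 0) return(0)
  sum(IRanges::width(IRanges::reduce(ir))) / seq_len
}

#' Classify an SV consensus sequence by repeat content
#'
#' Categories (mutually exclusive, checked in order): sequences at least
#' 50% covered by short repeats (Simple/Tandem + Low_complexity) are
#' `short_repeat_excluded`; a single transposon interval covering at least
#' 80% gives `single_SINE`/`single_LINE`; at least 80% joint coverage by
#' two or more transposon intervals gives `multi_repeat`; any transposon
#' overlap below 80% gives `repeat_included`; otherwise `non_repeat`.
#' Twin priming is flagged when two LINE intervals lie on opposite strands;
#' a poly(A)/poly(T) tail is flagged when at least `polya_min` terminal
#' A (or T) bases, allowing one mismatch, are absent from the reference
#' flank at that position.
#'
#' @param consensus_seq consensus sequence (character scalar).
#' @param repeats repeat intervals on the consensus (same `seq_id`), as
#'   from [parse_repeat_files()].
#' @param seq_id which `seq_id` in `repeats` annotates this sequence;
#'   defaults to all rows.
#' @param ref_flank optional reference sequence at the insertion point used
#'   to decide whether a terminal poly(A) is non-reference.
#' @param config thresholds (`repeat_cover`, `short_repeat_cover`,
#'   `polya_min`).
#' @return data.frame (one row): `category`, `covered_fraction` per class,
#'   `families`, `strands`, `truncation_5prime`, `twin_priming`,
#'   `polyA_tail`.
#' @export
classify_sv_sequence <- function(consensus_seq, repeats, seq_id = NULL,
                                 ref_flank = NULL, config = svlr_config()) {
  L <- nchar(consensus_seq)
  r <- as.data.frame(repeats)
  if (!is.null(seq_id)) r <- r[r$seq_id == seq_id, , drop = FALSE]
  short <- r[r$repeat_class %in% c("Simple/Tandem", "Low_complexity"), , drop = FALSE]
  tp <- r[r$repeat_class %in% c("SINE", "LINE", "LTR", "DNA"), , drop = FALSE]
  cov_short <- interval_coverage(short, L)
  cov_tp <- interval_coverage(tp, L)
  per_int_cov <- if (nrow(tp)) (pmin(tp$end, L) - pmax(tp$start, 0L)) / L else numeric()
  category <- if (cov_short >= config$short_repeat_cover) {
    "short_repeat_excluded"
  } else if (nrow(tp) > 0 && max(per_int_cov) >= config$repeat_cover) {
    dom <- tp$repeat_class[which.max(per_int_cov)]
    switch(dom, SINE = "single_SINE", LINE = "single_LINE", "multi_repeat")
  } else if (cov_tp >= config$repeat_cover && nrow(tp) >= 2) {
    "multi_repeat"
  } else if (cov_tp > 0) {
    "repeat_included"
  } else {
    "non_repeat"
  }
  lines_ <- tp[tp$repeat_class == "LINE", , drop = FALSE]
  twin <- nrow(lines_) >= 2 && length(unique(lines_$strand)) == 2
  # 5' truncation of the dominant element, from its consensus coordinates
  trunc5 <- NA_integer_
  if (nrow(tp) > 0) {
    dom <- tp[which.max(per_int_cov), ]
    if (!is.na(dom$rep_begin)) trunc5 <- max(0L, dom$rep_begin - 1L)
  }
  polya <- has_nonref_polya(consensus_seq, ref_flank, config$polya_min)
  data.frame(
    category = category,
    cov_short = cov_short, cov_transposon = cov_tp,
    families = paste(unique(tp$family), collapse = ","),
    strands = paste(tp$strand, collapse = ","),
    truncation_5prime = trunc5,
    twin_priming = twin, polyA_tail = polya,
    stringsAsFactors = FALSE)
}

#' @noRd
has_nonref_polya <- function(seq, ref_flank, min_len = 10L) {
  tail_run <- function(x, base) {
    v <- rev(strsplit(x, "")[[1]])
    mism <- 0L; n <- 0L
    for (ch in v) {
      if (ch == base) n <- n + 1L
      else { mism <- mism + 1L; if (mism > 1L) break; n <- n + 1L }
    }
    n
  }
  head_run <- function(x, base) tail_run(paste(rev(strsplit(x, "")[[1]]), collapse = ""), base)
  runs <- c(tail_run(seq, "A"), head_run(seq, "T"),
            tail_run(seq, "T"), head_run(seq, "A"))
  if (max(runs) < min_len) return(FALSE)
  if (is.null(ref_flank)) return(TRUE)
  # present in the reference at that position? then not novel
  ref_runs <- c(tail_run(ref_flank, "A"), head_run(ref_flank, "T"),
                tail_run(ref_flank, "T"), head_run(ref_flank, "A"))
  max(ref_runs) < min_len
}

#' Read BLAT PSL alignments
#'
#' Standard 21-column PSL; a `psLayout` header block is skipped if present.
#' @param path PSL file.
#' @return data.frame with the PSL columns (`matches`, `strand`, `qName`,
#'   `qSize`, `qStart`, `qEnd`, `tName`, `tSize`, `tStart`, `tEnd`,
#'   `blockCount`, `blockSizes`, `qStarts`, `tStarts`, ...).
#' @export
read_psl <- function(path) {
  lines <- readLines(path)
  dat <- grepl("^[0-9]+\t", lines)
  cols <- c("matches", "misMatches", "repMatches", "nCount", "qNumInsert",
            "qBaseInsert", "tNumInsert", "tBaseInsert", "strand", "qName",
            "qSize", "qStart", "qEnd", "tName", "tSize", "tStart", "tEnd",
            "blockCount", "blockSizes", "qStarts", "tStarts")
  if (!any(dat)) {
    df <- as.data.frame(setNames(replicate(21, character(), simplify = FALSE), cols))
    for (nm in setdiff(cols, c("strand", "qName", "tName", "blockSizes",
                               "qStarts", "tStarts"))) df[[nm]] <- integer()
    return(df)
  }
  df <- read.table(text = lines[dat], sep = "\t", stringsAsFactors = FALSE)
  names(df)[seq_len(min(ncol(df), 21))] <- cols[seq_len(min(ncol(df), 21))]
  df
}

#' Classify a non-repeat insertion by its remap hits
#'
#' Uses PSL hits of the inserted sequence against the reference: a hit
#' adjacent to the insertion site (within `near_bp`) is a tandem
#' duplication; a hit split across two or more exon blocks of one gene, or
#' an exonic hit together with a non-reference poly(A) tail, is a processed
#' pseudogene; any other contiguous hit is a template insertion; no hit at
#' 70% identity or better gives `none`.
#'
#' @param call the insertion call row (`chrom1`, `pos1`).
#' @param psl PSL hits of the inserted sequence (`qName` matching
#'   `call$id`).
#' @param genes optional gene model: data.frame with `gene`, `chrom`,
#'   `start`, `end` per exon (0-based half-open), e.g. flattened BED12.
#' @param polyA_tail logical from [classify_sv_sequence()].
#' @param near_bp adjacency window for tandem duplications (default 1000).
#' @param min_identity minimum remap identity (default 0.7).
#' @return one of `"tandem_dup"`, `"template_insertion"`,
#'   `"processed_pseudogene"`, `"none"`.
#' @export
classify_nonrepeat_insertion <- function(call, psl, genes = NULL,
                                         polyA_tail = FALSE, near_bp = 1000L,
                                         min_identity = 0.7) {
  h <- psl[psl$qName == call$id, , drop = FALSE]
  if (nrow(h) > 0) {
    ident <- h$matches / pmax(1L, h$qEnd - h$qStart)
    h <- h[ident >= min_identity, , drop = FALSE]
  }
  if (nrow(h) == 0) return("none")
  h <- h[order(-h$matches), , drop = FALSE]
  best <- h[1, ]
  # exon analysis on the best hit's blocks
  if (!is.null(genes) && nrow(genes) > 0) {
    bs <- as.integer(strsplit(as.character(best$blockSizes), ",")[[1]])
    ts <- as.integer(strsplit(as.character(best$tStarts), ",")[[1]])
    n_exon_blocks <- 0L
    gene_hit <- character()
    for (b in seq_along(bs)) {
      g <- genes[genes$chrom == best$tName & genes$start < ts[b] + bs[b] &
                   genes$end > ts[b], , drop = FALSE]
      if (nrow(g) > 0) {
        n_exon_blocks <- n_exon_blocks + 1L
        gene_hit <- c(gene_hit, g$gene)
      }
    }
    same_gene <- length(unique(gene_hit)) == 1 && length(gene_hit) >= 1
    if (same_gene && (n_exon_blocks >= 2 || (n_exon_blocks >= 1 && polyA_tail))) {
      return("processed_pseudogene")
    }
  }
  if (best$tName == call$chrom1 &&
      min(abs(c(best$tStart, best$tEnd) - call$pos1)) <= near_bp) {
    return("tandem_dup")
  }
  "template_insertion"
}
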