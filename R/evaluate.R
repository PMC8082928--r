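#' Match a callset against a truth set by breakpoint distance
#'
#' Greedy one-to-one matching: candidate pairs must have the same SV type
#' and breakpoint distance below `max_dist` (default 500 bp); pairs are
#' accepted in order of increasing distance, each call and truth record
#' matched at most once.  Distance is the larger of the two breakpoint
#' distances (`both_ends = TRUE`) or the first-breakpoint distance only.
#' Matched pairs are the "common" set, unmatched truth records are false
#' negatives and unmatched calls false positives;
#' `F = 2PR / (P + R)`.
#'
#' @param calls,truth call-like tables (`sv_type`, `chrom1`, `pos1`,
#'   `chrom2`, `pos2`).
#' @param max_dist maximum breakpoint distance in bp (exclusive bound).
#' @param both_ends use the maximum over both breakpoints (default) or
#'   `pos1` only.
#' @param strata optional named list of annotation tables (`chrom`,
#'   `start`, `end`) used to stratify truth records (e.g. tandem-repeat and
#'   segmental-duplication/self-chain regions).
#' @return list of class `svlr_match`: `common` (data.frame of matched
#'   index pairs with distances), `truth_only`, `calls_only` (row indices),
#'   `precision`, `recall`, `f_measure`, `degenerate` flag (empty side),
#'   and `strata` (per-stratum counts) when `strata` given.
#' @export
match_callsets <- function(calls, truth, max_dist = 500L, both_ends = TRUE,
                           strata = NULL) {
  cc <- as.data.frame(calls)
  tt <- as.data.frame(truth)
  norm_type <- function(x) {
    x <- toupper(x)
    x[x %in% c("TRA_INTRA", "TANDEM_DUP")] <- "DUP"
    x[x %in% c("TRA_INTER", "BND")] <- "TRA"
    x
  }
  pairs <- NULL
  if (nrow(cc) > 0 && nrow(tt) > 0) {
    ctype <- norm_type(cc$sv_type); ttype <- norm_type(tt$sv_type)
    cand <- list()
    for (i in seq_len(nrow(cc))) {
      j <- which(ttype == ctype[i] & tt$chrom1 == cc$chrom1[i] &
                   tt$chrom2 == cc$chrom2[i])
      if (!length(j)) next
      d1 <- abs(tt$pos1[j] - cc$pos1[i])
      d2 <- abs(tt$pos2[j] - cc$pos2[i])
      d <- if (both_ends) pmax(d1, d2) else d1
      ok <- d < max_dist
      if (any(ok)) {
        cand[[length(cand) + 1L]] <- data.frame(call = i, truth = j[ok],
                                                dist = d[ok])
      }
    }
    if (length(cand)) {
      cand <- do.call(rbind, cand)
      cand <- cand[order(cand$dist, cand$call, cand$truth), , drop = FALSE]
      used_c <- logical(nrow(cc)); used_t <- logical(nrow(tt))
      keep <- logical(nrow(cand))
      for (k in seq_len(nrow(cand))) {
        if (!used_c[cand$call[k]] && !used_t[cand$truth[k]]) {
          keep[k] <- TRUE
          used_c[cand$call[k]] <- TRUE
          used_t[cand$truth[k]] <- TRUE
        }
      }
      pairs <- cand[keep, , drop = FALSE]
    }
  }
  if (is.null(pairs)) {
    pairs <- data.frame(call = integer(), truth = integer(), dist = numeric())
  }
  n_common <- nrow(pairs)
  truth_only <- setdiff(seq_len(nrow(tt)), pairs$truth)
  calls_only <- setdiff(seq_len(nrow(cc)), pairs$call)
  degenerate <- nrow(cc) == 0 || nrow(tt) == 0
  precision <- if (nrow(cc) > 0) n_common / nrow(cc) else 0
  recall <- if (nrow(tt) > 0) n_common / nrow(tt) else 0
  f <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  out <- list(common = pairs, truth_only = truth_only,
              calls_only = calls_only, precision = precision,
              recall = recall, f_measure = f, degenerate = degenerate)
  if (!is.null(strata) && nrow(tt) > 0) {
    grs <- lapply(strata, function(s) GenomicRanges::GRanges(
      s$chrom, IRanges::IRanges(s$start + 1L, s$end)))
    tgr <- GenomicRanges::GRanges(tt$chrom1,
                                  IRanges::IRanges(tt$pos1 + 1L,
                                                   pmax(tt$pos1 + 1L, tt$pos2)))
    inset <- vapply(grs, function(g)
      IRanges::overlapsAny(tgr, g), logical(nrow(tt)))
    if (is.null(dim(inset))) inset <- matrix(inset, nrow = nrow(tt))
    lab <- apply(inset, 1, function(z) {
      if (all(z)) "both" else if (!any(z)) "non_repeat"
      else names(strata)[which(z)[1]]
    })
    matched <- seq_len(nrow(tt)) %in% pairs$truth
    out$strata <- as.data.frame(table(stratum = lab, matched = matched))
  }
  class(out) <- c("svlr_match", "list")
  out
}

#' @export
print.svlr_match <- function(x, ...) {
  cat(sprintf(paste0("<svlr_match> common %d | truth-only %d | calls-only ",
                     "%d\n  precision %.3f  recall %.3f  F %.3f%s\n"),
              nrow(x$common), length(x$truth_only), length(x$calls_only),
              x$precision, x$recall, x$f_measure,
              if (x$degenerate) "  [degenerate: empty input]" else ""))
  invisible(x)
}
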