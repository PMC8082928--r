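#' Measure breakpoint homology and junction insertion
#'
#' The reference sequences covering the upstream and downstream breakpoints
#' are aligned locally to the consensus junction sequence.  The homology
#' length is the length of the consensus interval covered by BOTH flank
#' alignments (their overlap across the junction); the junction insertion
#' is the consensus stretch covered by neither.  The two are mutually
#' exclusive by construction.  If either flank aligns at below
#' `flank_min_identity` the anatomy is undefined and the mechanism will be
#' `unclassified`.
#'
#' @param consensus_seq consensus sequence across the junction (character).
#' @param ref_up_flank reference sequence covering the upstream breakpoint
#'   (e.g. breakpoint +/- 500 bp).
#' @param ref_down_flank same for the downstream breakpoint.
#' @param config thresholds (`flank_min_identity`).
#' @details The measurement anchors the junction with two fit alignments —
#' the upstream flank's pre-breakpoint half locates where the upstream
#' reference ends on the consensus, the downstream flank's post-breakpoint
#' half locates where the downstream reference resumes — then extends
#' exact matching across the junction in both directions: the upstream
#' flank's post-breakpoint half forward from the junction and the
#' downstream flank's pre-breakpoint half backward.  The summed extension
#' is the homology (the length of consensus covered by both flanks); the
#' consensus stretch between the two anchors that neither flank covers is
#' the junction insertion.  A raw local alignment would overshoot by
#' chance matches; anchored exact extension keeps blunt junctions at
#' exactly zero.
#' @return data.frame (one row): `homology_len`, `junction_insertion`
#'   (string), `insertion_len`, `up_identity`, `down_identity`, `defined`.
#' @export
measure_breakpoint <- function(consensus_seq, ref_up_flank, ref_down_flank,
                               config = svlr_config()) {
  half_u <- nchar(ref_up_flank) %/% 2L
  half_d <- nchar(ref_down_flank) %/% 2L
  up_pre <- substr(ref_up_flank, 1L, half_u)
  up_post <- substr(ref_up_flank, half_u + 1L, nchar(ref_up_flank))
  dn_pre <- substr(ref_down_flank, 1L, half_d)
  dn_post <- substr(ref_down_flank, half_d + 1L, nchar(ref_down_flank))
  up <- align_pair(consensus_seq, up_pre, mode = "fit")
  dn <- align_pair(consensus_seq, dn_post, mode = "fit")
  undef <- data.frame(homology_len = NA_integer_,
                      junction_insertion = NA_character_,
                      insertion_len = NA_integer_,
                      up_identity = up$identity, down_identity = dn$identity,
                      defined = FALSE, stringsAsFactors = FALSE)
  if (is.na(up$identity) || is.na(dn$identity) ||
      up$identity < config$flank_min_identity ||
      dn$identity < config$flank_min_identity ||
      up$aln_len < 30 || dn$aln_len < 30) {
    return(undef)
  }
  j_up <- up$a_end     # consensus position where the upstream side ends
  j_dn <- dn$a_start   # consensus position where the downstream side resumes
  csv <- strsplit(toupper(consensus_seq), "")[[1]]
  lcp <- function(x, y) {
    m <- min(length(x), length(y))
    if (m == 0) return(0L)
    neq <- which(x[seq_len(m)] != y[seq_len(m)])
    if (length(neq) == 0) m else neq[1] - 1L
  }
  # forward extension of the upstream flank past the downstream anchor
  h_right <- lcp(csv[seq_len(nchar(consensus_seq)) > j_dn],
                 strsplit(toupper(up_post), "")[[1]])
  # backward extension of the downstream flank before the upstream anchor
  h_left <- lcp(rev(csv[seq_len(j_up)]),
                rev(strsplit(toupper(dn_pre), "")[[1]]))
  hom <- as.integer(h_right + h_left)
  ins <- ""
  if (j_dn > j_up) ins <- substr(consensus_seq, j_up + 1L, j_dn)
  if (hom > 0L) ins <- ""   # mutually exclusive by construction
  data.frame(homology_len = hom, junction_insertion = ins,
             insertion_len = nchar(ins), up_identity = up$identity,
             down_identity = dn$identity, defined = TRUE,
             stringsAsFactors = FALSE)
}

#' Classify the repair mechanism behind a junction
#'
#' Decision bands: homology above `nahr_min_homology` (default 100 bp) is
#' NAHR; homology from `alt_ej_min_homology` (default 2 bp) up to the NAHR
#' bound is alternative end joining; at most 1 bp homology with a junction
#' insertion below `fostes_min_insertion` (default 10 bp, including none)
#' is NHEJ; a junction insertion at or above that bound is FoSTeS/MMBIR.
#' Undefined anatomies are `unclassified`.
#'
#' @param homology_len homology length in bp (NA for undefined).
#' @param insertion_len junction insertion length in bp.
#' @param config thresholds.
#' @return character vector of mechanism labels in
#'   `{NAHR, alt_EJ, NHEJ, FoSTeS_MMBIR, unclassified}`.
#' @export
classify_mechanism <- function(homology_len, insertion_len,
                               config = svlr_config()) {
  n <- max(length(homology_len), length(insertion_len))
  homology_len <- rep_len(homology_len, n)
  insertion_len <- rep_len(insertion_len, n)
  insertion_len[is.na(insertion_len)] <- 0L
  out <- rep("unclassified", n)
  ok <- !is.na(homology_len)
  out[ok & homology_len > config$nahr_min_homology] <- "NAHR"
  out[ok & homology_len <= config$nahr_min_homology &
        homology_len >= config$alt_ej_min_homology] <- "alt_EJ"
  low <- ok & homology_len < config$alt_ej_min_homology
  out[low & insertion_len >= config$fostes_min_insertion] <- "FoSTeS_MMBIR"
  out[low & insertion_len < config$fostes_min_insertion] <- "NHEJ"
  out
}

#' Infer the ancestral event behind a reference-based indel
#'
#' The breakpoint flanks (100 bp each side) are lifted to the chimpanzee
#' assembly and the ratio
#' `(pantro_dist - 200) / (grch38_dist - 200)` is computed from the
#' distances between the lifted anchors.  For reference-based deletions a
#' ratio in `[-0.3, 0.3]` means the chimpanzee carries the deletion — the
#' human reference gained the sequence, so the variant arose by an
#' insertion event — and a ratio in `[0.7, 1.3]` means a deletion event.
#' For reference-based insertions the mapping is reversed.  Ratios outside
#' both bands are unclassified.
#'
#' @param sv_type `"DEL"` or `"INS"` (reference-based status), vectorized.
#' @param grch38_dist,pantro_dist distances in bp between the outer flank
#'   anchors in the human and chimpanzee assemblies.
#' @return data.frame with `ratio` and `event` in
#'   `{insertion_event, deletion_event, unclassified}`.
#' @export
infer_ancestral_event <- function(sv_type, grch38_dist, pantro_dist) {
  n <- max(length(sv_type), length(grch38_dist), length(pantro_dist))
  sv_type <- rep_len(sv_type, n)
  grch38_dist <- rep_len(as.numeric(grch38_dist), n)
  pantro_dist <- rep_len(as.numeric(pantro_dist), n)
  ratio <- (pantro_dist - 200) / (grch38_dist - 200)
  in_low <- ratio >= -0.3 & ratio <= 0.3   # chimp lacks the extra sequence
  in_one <- ratio >= 0.7 & ratio <= 1.3    # chimp matches the human ref
  event <- rep("unclassified", n)
  del <- sv_type == "DEL"
  event[del & in_low] <- "insertion_event"
  event[del & in_one] <- "deletion_event"
  event[!del & in_one] <- "deletion_event"
  event[!del & in_low] <- "insertion_event"
  data.frame(ratio = ratio, event = event, stringsAsFactors = FALSE)
}

#' Read a lifted-coordinate table and classify ancestral events
#'
#' @param path TSV with columns `indel_id`, `sv_type`, `grch38_dist`,
#'   `pantro_dist` (as written by the simulator or produced with liftOver
#'   upstream).
#' @return the table with `ratio` and `event` columns appended.
#' @export
ancestral_events_from_table <- function(path) {
  t <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  cbind(t, infer_ancestral_event(t$sv_type, t$grch38_dist, t$pantro_dist))
}

#' Summarize mechanism proportions and compare two groups
#'
#' Tabulates mechanism labels (excluding `unclassified`) and, when two
#' groups are given (e.g. germline deletions vs somatic SVs), runs a
#' chi-square test on the contingency table.
#'
#' @param mechanisms character vector of mechanism labels.
#' @param mechanisms2 optional second group.
#' @return list with `counts` (and `counts2`), `proportions`, and `chisq`
#'   (htest or NULL).
#' @export
mechanism_summary <- function(mechanisms, mechanisms2 = NULL) {
  lv <- c("NAHR", "alt_EJ", "NHEJ", "FoSTeS_MMBIR")
  t1 <- table(factor(mechanisms[mechanisms != "unclassified"], levels = lv))
  out <- list(counts = t1, proportions = prop.table(t1), chisq = NULL)
  if (!is.null(mechanisms2)) {
    t2 <- table(factor(mechanisms2[mechanisms2 != "unclassified"], levels = lv))
    out$counts2 <- t2
    keep <- (t1 + t2) > 0
    out$chisq <- suppressWarnings(chisq.test(rbind(t1[keep], t2[keep])))
  }
  out
}
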