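#' Extract per-read SV signatures from an alignment table
#'
#' Scans CIGAR strings for insertions/deletions at or above `min_indel`,
#' long soft/hard clips at or above `min_clip` (breakend evidence for large
#' insertions), and split alignments for inversions (same chromosome,
#' opposite strands), tandem-duplication-like intra-chromosomal
#' translocations (same strand, reference order contradicting read order or
#' reference gap beyond `tra_intra_gap`), inter-chromosomal translocations,
#' and split-supported indels from colinear segment gaps.
#'
#' Split pairs whose read intervals overlap by more than half of the
#' shorter interval are discarded as likely ligation chimeras (overlaps of
#' up to 20 bp are trimmed silently).
#'
#' @param alignments table from [parse_alignments()].
#' @param min_indel minimum insertion/deletion length in bp (default 100).
#' @param min_clip minimum clip length to emit a CLIP breakend (default 500).
#' @param min_small_ins insertions at or above this length but below
#'   `min_indel` are recorded in the `minor_ins` attribute for the
#'   deletion-with-insertion support filter (default 10).
#' @param tra_intra_gap reference gap beyond which two colinear same-strand
#'   segments are treated as an intra-chromosomal translocation rather than
#'   a deletion candidate (default 1e5).
#' @return data.frame with columns `read_id`, `sv_type` (`INS`, `DEL`,
#'   `INV`, `DUP` for intra-chromosomal translocation / tandem duplication,
#'   `TRA` for inter-chromosomal, `CLIP`), `chrom1`, `pos1`, `chrom2`,
#'   `pos2` (0-based), `length`, `inserted_seq`, `read_offset_fraction`,
#'   `source` (`cigar`/`split`/`clip`), `mapq`, `clip_side`.  Attribute
#'   `minor_ins`: data.frame of sub-threshold insertions (`read_id`,
#'   `chrom`, `pos`, `len`).  Attribute `n_chimeric`: split pairs dropped.
#' @export
extract_signatures <- function(alignments, min_indel = 100L, min_clip = 500L,
                               min_small_ins = 10L, tra_intra_gap = 1e5) {
  a <- as.data.frame(alignments)
  sig <- list()
  minor <- list()
  n_chim <- 0L

  if (nrow(a) > 0) {
    ## --- CIGAR indels and clips (primary records only: supplementary
    ## records repeat the same query bases) ---
    prim <- a[a$is_primary, , drop = FALSE]
    for (i in seq_len(nrow(prim))) {
      r <- prim[i, ]
      w <- cigar_walk(r$cigar, r$start)
      idx <- which((w$op == "I" & w$len >= min_small_ins) |
                     (w$op == "D" & w$len >= min_indel))
      for (j in idx) {
        qpos <- w$qry_pos[j]
        # original-read coordinate of the event
        rd <- if (r$strand == "+") qpos else r$read_length - qpos
        frac <- rd / r$read_length
        if (w$op[j] == "I") {
          if (w$len[j] < min_indel) {
            minor[[length(minor) + 1L]] <- data.frame(
              read_id = r$read_id, chrom = r$chrom, pos = w$ref_pos[j],
              len = w$len[j], stringsAsFactors = FALSE)
            next
          }
          ins <- if (!is.na(r$seq)) substr(r$seq, qpos + 1L, qpos + w$len[j]) else NA_character_
          sig[[length(sig) + 1L]] <- data.frame(
            read_id = r$read_id, sv_type = "INS", chrom1 = r$chrom,
            pos1 = w$ref_pos[j], chrom2 = r$chrom, pos2 = w$ref_pos[j],
            length = w$len[j], inserted_seq = ins,
            read_offset_fraction = frac, source = "cigar", mapq = r$mapq,
            clip_side = NA_character_, stringsAsFactors = FALSE)
        } else {
          sig[[length(sig) + 1L]] <- data.frame(
            read_id = r$read_id, sv_type = "DEL", chrom1 = r$chrom,
            pos1 = w$ref_pos[j], chrom2 = r$chrom,
            pos2 = w$ref_pos[j] + w$len[j], length = w$len[j],
            inserted_seq = NA_character_, read_offset_fraction = frac,
            source = "cigar", mapq = r$mapq, clip_side = NA_character_,
            stringsAsFactors = FALSE)
        }
      }
      # long clips -> CLIP breakends (left/right in reference orientation)
      if (r$left_clip >= min_clip) {
        sig[[length(sig) + 1L]] <- clip_signature(r, side = "left")
      }
      if (r$right_clip >= min_clip) {
        sig[[length(sig) + 1L]] <- clip_signature(r, side = "right")
      }
    }

    ## --- split-alignment signatures ---
    multi <- split(a, a$read_id)
    multi <- multi[vapply(multi, nrow, 0L) >= 2L]
    for (segs in multi) {
      segs <- segs[order(segs$read_start), , drop = FALSE]
      for (k in seq_len(nrow(segs) - 1L)) {
        s1 <- segs[k, ]; s2 <- segs[k + 1L, ]
        ov <- s1$read_end - s2$read_start
        if (ov > 20L) {
          if (ov > 0.5 * min(s1$read_end - s1$read_start,
                             s2$read_end - s2$read_start)) {
            n_chim <- n_chim + 1L
            next
          }
        }
        junc_rd <- (s1$read_end + s2$read_start) / 2
        frac <- junc_rd / s1$read_length
        mq <- min(s1$mapq, s2$mapq)
        if (s1$chrom != s2$chrom) {
          # inter-chromosomal translocation: read-adjacent breakends
          p1 <- if (s1$strand == "+") s1$end else s1$start
          p2 <- if (s2$strand == "+") s2$start else s2$end
          sig[[length(sig) + 1L]] <- data.frame(
            read_id = s1$read_id, sv_type = "TRA", chrom1 = s1$chrom,
            pos1 = p1, chrom2 = s2$chrom, pos2 = p2, length = 0L,
            inserted_seq = NA_character_, read_offset_fraction = frac,
            source = "split", mapq = mq, clip_side = NA_character_,
            stringsAsFactors = FALSE)
        } else if (s1$strand != s2$strand) {
          # inversion junction: both records' read-adjacent ends recover the
          # two inversion edges
          p1 <- if (s1$strand == "+") s1$end else s1$start
          p2 <- if (s2$strand == "+") s2$start else s2$end
          sig[[length(sig) + 1L]] <- data.frame(
            read_id = s1$read_id, sv_type = "INV",
            chrom1 = s1$chrom, pos1 = min(p1, p2), chrom2 = s2$chrom,
            pos2 = max(p1, p2), length = abs(p2 - p1),
            inserted_seq = NA_character_, read_offset_fraction = frac,
            source = "split", mapq = mq, clip_side = NA_character_,
            stringsAsFactors = FALSE)
        } else {
          # same chromosome, same strand
          fwd <- s1$strand == "+"
          ref_gap <- if (fwd) s2$start - s1$end else s1$start - s2$end
          read_gap <- s2$read_start - s1$read_end
          # the next segment maps upstream of where colinearity predicts:
          # tandem-duplication-like junction (20 bp microhomology slack)
          order_inverted <- ref_gap < -20L
          if (order_inverted || ref_gap > tra_intra_gap) {
            # tandem-duplication-like intra-chromosomal translocation
            p1 <- if (fwd) s1$end else s1$start
            p2 <- if (fwd) s2$start else s2$end
            sig[[length(sig) + 1L]] <- data.frame(
              read_id = s1$read_id, sv_type = "DUP", chrom1 = s1$chrom,
              pos1 = min(p1, p2), chrom2 = s1$chrom, pos2 = max(p1, p2),
              length = abs(p2 - p1), inserted_seq = NA_character_,
              read_offset_fraction = frac, source = "split", mapq = mq,
              clip_side = NA_character_, stringsAsFactors = FALSE)
          } else if (ref_gap - read_gap >= min_indel) {
            p1 <- if (fwd) s1$end else s2$end
            sig[[length(sig) + 1L]] <- data.frame(
              read_id = s1$read_id, sv_type = "DEL", chrom1 = s1$chrom,
              pos1 = p1, chrom2 = s1$chrom, pos2 = p1 + (ref_gap - read_gap),
              length = ref_gap - read_gap, inserted_seq = NA_character_,
              read_offset_fraction = frac, source = "split", mapq = mq,
              clip_side = NA_character_, stringsAsFactors = FALSE)
          } else if (read_gap - max(ref_gap, 0L) >= min_indel) {
            p1 <- if (fwd) s1$end else s2$end
            sig[[length(sig) + 1L]] <- data.frame(
              read_id = s1$read_id, sv_type = "INS", chrom1 = s1$chrom,
              pos1 = p1, chrom2 = s1$chrom, pos2 = p1,
              length = read_gap - max(ref_gap, 0L),
              inserted_seq = NA_character_, read_offset_fraction = frac,
              source = "split", mapq = mq, clip_side = NA_character_,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }

  out <- if (length(sig)) do.call(rbind, sig) else data.frame(
    read_id = character(), sv_type = character(), chrom1 = character(),
    pos1 = integer(), chrom2 = character(), pos2 = integer(),
    length = integer(), inserted_seq = character(),
    read_offset_fraction = numeric(), source = character(), mapq = integer(),
    clip_side = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "minor_ins") <- if (length(minor)) do.call(rbind, minor) else
    data.frame(read_id = character(), chrom = character(), pos = integer(),
               len = integer(), stringsAsFactors = FALSE)
  attr(out, "n_chimeric") <- n_chim
  out
}

#' @noRd
clip_signature <- function(r, side) {
  # reference-side coordinate of the clipped end
  pos <- if (side == "left") r$start else r$end
  clen <- if (side == "left") r$left_clip else r$right_clip
  # read coordinate of the junction, in original-read orientation
  rd <- if (side == "left") {
    if (r$strand == "+") r$read_start else r$read_length - r$read_start
  } else {
    if (r$strand == "+") r$read_end else r$read_length - r$read_end
  }
  data.frame(read_id = r$read_id, sv_type = "CLIP", chrom1 = r$chrom,
             pos1 = pos, chrom2 = r$chrom, pos2 = pos, length = clen,
             inserted_seq = NA_character_,
             read_offset_fraction = rd / r$read_length, source = "clip",
             mapq = r$mapq, clip_side = side, stringsAsFactors = FALSE)
}
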