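## Self-contained long-read SV simulator: repeat-bearing reference, donor
## genomes with spiked SVs (with controllable breakpoint homology and
## junction insertions), and noisy reads with truth alignments.

#' Deterministic pseudo-random DNA independent of R's RNG
#'
#' Small LCG so that package-internal constants (element consensus
#' sequences) never disturb the user's random stream.
#' @noRd
fixed_random_dna <- function(n, seed) {
  state <- as.double(seed)
  v <- integer(n)
  for (i in seq_len(n)) {
    state <- (state * 1103515245 + 12345) %% 2147483648
    v[i] <- (state %/% 1024) %% 4
  }
  paste(c("A", "C", "G", "T")[v + 1L], collapse = "")
}

#' @noRd
sim_alu_consensus <- function() fixed_random_dna(300L, 20210429)

#' @noRd
sim_line_consensus <- function() fixed_random_dna(6000L, 1977)

#' @noRd
sim_hbv_genome <- function() fixed_random_dna(3200L, 3200)

#' @noRd
rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Mutate a sequence under a Nanopore-like error model
#'
#' Per-base independent substitutions, 1-bp insertions and 1-bp deletions at
#' the given rates (defaults follow ~15% aggregate edit distance with 4.4%
#' insertions and 6.6% deletions).
#'
#' @param seq character scalar.
#' @param err_sub,err_ins,err_del per-base error rates.
#' @return mutated character scalar.
#' @export
mutate_sequence <- function(seq, err_sub = 0.038, err_ins = 0.044,
                            err_del = 0.066) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  if (n == 0) return(seq)
  e <- draw_errors(n, err_sub, err_ins, err_del)
  paste(apply_errors_seq(ch, e), collapse = "")
}

#' @noRd
draw_errors <- function(n, err_sub, err_ins, err_del) {
  u <- runif(n)
  del <- u < err_del
  ins <- u >= err_del & u < err_del + err_ins
  sub <- u >= err_del + err_ins & u < err_del + err_ins + err_sub
  ins_base <- character(n)
  if (any(ins)) ins_base[ins] <- sample(c("A", "C", "G", "T"), sum(ins), TRUE)
  sub_base <- character(n)
  if (any(sub)) sub_base[sub] <- sample(c("A", "C", "G", "T"), sum(sub), TRUE)
  list(del = del, ins = ins, sub = sub, ins_base = ins_base,
       sub_base = sub_base)
}

#' @noRd
apply_errors_seq <- function(ch, e) {
  out <- ch
  out[e$sub] <- e$sub_base[e$sub]
  # interleave kept bases with inserted bases
  keep <- !e$del
  pieces <- ifelse(keep, out, "")
  pieces <- paste0(pieces, ifelse(e$ins, e$ins_base, ""))
  strsplit(paste(pieces, collapse = ""), "")[[1]]
}

#' Build a repeat-bearing synthetic reference
#'
#' Random sequence with planted Alu-like (~300 bp) and L1-like (~6 kb)
#' element copies (each copy mutated at `divergence`, random strand, some
#' 5'-truncated) and tandem-repeat runs.  The planted annotation is exact
#' by construction and can be written in RepeatMasker `.out` and TRF `.dat`
#' formats.
#'
#' @param lengths named integer vector of chromosome lengths
#'   (default `c(chr1 = 1e6)`).
#' @param n_alu,n_line,n_tandem copies planted per megabase, scaled by
#'   genome size.
#' @param divergence per-base substitution divergence of planted copies.
#' @param seed RNG seed.
#' @return list with `ref` (`DNAStringSet`) and `repeats` (repeat-interval
#'   data.frame as from [parse_repeat_files()]).
#' @export
build_reference <- function(lengths = c(chr1 = 1e6), n_alu = 40L,
                            n_line = 4L, n_tandem = 6L, divergence = 0.03,
                            seed = 1L) {
  set.seed(seed)
  lengths <- setNames(as.integer(lengths), names(lengths))
  alu <- sim_alu_consensus()
  l1 <- sim_line_consensus()
  seqs <- list()
  reps <- list()
  for (chrom in names(lengths)) {
    L <- lengths[[chrom]]
    ch <- strsplit(rand_dna(L), "")[[1]]
    scale <- L / 1e6
    plan <- rbind(
      data.frame(kind = "alu", n = max(1L, round(n_alu * scale))),
      data.frame(kind = "line", n = max(1L, round(n_line * scale))),
      data.frame(kind = "tandem", n = max(1L, round(n_tandem * scale))))
    occupied <- IRanges::IRanges()
    for (k in seq_len(nrow(plan))) {
      for (j in seq_len(plan$n[k])) {
        kind <- plan$kind[k]
        if (kind == "alu") {
          trunc <- if (runif(1) < 0.3) sample(1:100, 1) else 0L
          elem <- substr(alu, trunc + 1L, nchar(alu))
          fam <- "AluSim"; cls <- "SINE"
        } else if (kind == "line") {
          trunc <- if (runif(1) < 0.6) sample(1000:4000, 1) else 0L
          elem <- substr(l1, trunc + 1L, nchar(l1))
          fam <- "L1Sim"; cls <- "LINE"
        } else {
          motif <- rand_dna(sample(2:6, 1))
          reps_n <- sample(30:120, 1)
          elem <- paste(rep(motif, reps_n), collapse = "")
          elem <- substr(elem, 1, min(nchar(elem), 500L))
          trunc <- 0L; fam <- paste0("(", motif, ")n"); cls <- "Simple/Tandem"
        }
        elem <- mutate_sequence(elem, err_sub = divergence, err_ins = 0,
                                err_del = 0)
        strand <- if (kind != "tandem" && runif(1) < 0.5) "-" else "+"
        if (strand == "-") elem <- revcomp(elem)
        w <- nchar(elem)
        for (try in 1:50) {
          pos <- sample.int(L - w - 4000L, 1) + 2000L  # 0-based
          cand <- IRanges::IRanges(pos + 1L, pos + w)
          if (length(IRanges::findOverlaps(cand, occupied)) == 0) {
            occupied <- c(occupied,
                          IRanges::IRanges(max(1L, pos - 1000L), pos + w + 1000L))
            ch[(pos + 1L):(pos + w)] <- strsplit(elem, "")[[1]]
            reps[[length(reps) + 1L]] <- data.frame(
              seq_id = chrom, start = pos, end = pos + w,
              repeat_class = cls, family = fam, strand = strand,
              rep_begin = trunc + 1L,
              rep_end = trunc + w,
              rep_left = if (kind == "alu") nchar(alu) - (trunc + w)
                         else if (kind == "line") nchar(l1) - (trunc + w)
                         else NA_integer_,
              source = if (kind == "tandem") "trf" else "rm",
              stringsAsFactors = FALSE)
            break
          }
        }
      }
    }
    seqs[[chrom]] <- paste(ch, collapse = "")
  }
  ref <- Biostrings::DNAStringSet(unlist(seqs))
  names(ref) <- names(lengths)
  repeats <- if (length(reps)) do.call(rbind, reps) else
    parse_repeat_files(NULL, NULL)
  list(ref = ref, repeats = repeats)
}

#' Write planted repeats in RepeatMasker .out format
#' @param repeats repeat table (rows with `source == "rm"` are written).
#' @param path output path.
#' @export
write_repeatmasker_out <- function(repeats, path) {
  r <- repeats[repeats$source == "rm", , drop = FALSE]
  hdr <- c(
    "   SW   perc perc perc  query      position in query           matching       repeat              position in repeat",
    "score   div. del. ins.  sequence    begin     end    (left)    repeat         class/family         begin  end (left)     ID",
    "")
  cls_out <- function(cl, fam) {
    switch(cl, SINE = "SINE/Alu", LINE = "LINE/L1",
           `Simple/Tandem` = "Simple_repeat", Low_complexity = "Low_complexity",
           cl)
  }
  rows <- vapply(seq_len(nrow(r)), function(i) {
    strand <- if (r$strand[i] == "-") "C" else "+"
    repcoord <- if (strand == "+") {
      sprintf("%d %d (%d)", r$rep_begin[i], r$rep_end[i],
              r$rep_left[i] %||% 0L)
    } else {
      sprintf("(%d) %d %d", r$rep_left[i] %||% 0L, r$rep_end[i],
              r$rep_begin[i])
    }
    sprintf("%5d %4.1f  0.0  0.0  %s %d %d (%d) %s %s %s %s %d",
            1000L, 3.0, r$seq_id[i], r$start[i] + 1L, r$end[i], 0L,
            strand, r$family[i], cls_out(r$repeat_class[i], r$family[i]),
            repcoord, i)
  }, "")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Write planted tandem repeats in TRF .dat format
#' @param repeats repeat table (rows with `source == "trf"` are written).
#' @param path output path.
#' @export
write_trf_dat <- function(repeats, path) {
  r <- repeats[repeats$source == "trf", , drop = FALSE]
  lines <- c("Tandem Repeats Finder Program written by:", "",
             "Benson G.", "")
  for (sid in unique(r$seq_id)) {
    lines <- c(lines, paste("Sequence:", sid), "",
               "Parameters: 2 7 7 80 10 50 500", "")
    g <- r[r$seq_id == sid, , drop = FALSE]
    motif <- gsub("^\\(|\\)n$", "", g$family)
    motif[!grepl("^[ACGT]+$", motif)] <- "AT"
    lines <- c(lines, sprintf(
      "%d %d %d %.1f %d %d %d %d %d %d %d %d %.2f %s %s",
      g$start + 1L, g$end, nchar(motif),
      (g$end - g$start) / nchar(motif), nchar(motif), 95L, 0L,
      2L * (g$end - g$start), 25L, 25L, 25L, 25L, 1.9, motif,
      substr("ACGT", 1, 4)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Default SV specification table for simulations
#'
#' @param n_del,n_ins,n_inv,n_dup counts per type.
#' @param len_range indel length range (log-uniform; default 100-2000 bp).
#' @param vaf_levels VAFs cycled over the SVs (default half 1.0, half 0.5).
#' @param ins_content content classes cycled over insertions.
#' @return data.frame consumed by [spike_svs()]: `id`, `sv_type`, `length`,
#'   `vaf`, `content`, `homology`, `junction_ins`.
#' @export
sim_sv_specs <- function(n_del = 20L, n_ins = 20L, n_inv = 10L, n_dup = 10L,
                         len_range = c(100L, 2000L),
                         vaf_levels = c(1.0, 0.5),
                         ins_content = c("random", "alu_like", "line_like",
                                         "tandem_dup")) {
  n <- n_del + n_ins + n_inv + n_dup
  if (n == 0) {
    return(data.frame(id = character(), sv_type = character(),
                      length = integer(), vaf = numeric(),
                      content = character(), homology = integer(),
                      junction_ins = integer(), stringsAsFactors = FALSE))
  }
  type <- c(rep("DEL", n_del), rep("INS", n_ins), rep("INV", n_inv),
            rep("DUP", n_dup))
  len <- round(exp(runif(n, log(len_range[1]), log(len_range[2]))))
  len[type == "INV"] <- pmax(len[type == "INV"], 500L)
  len[type == "DUP"] <- pmax(len[type == "DUP"], 500L)
  data.frame(
    id = sprintf("sv%03d", seq_len(n)),
    sv_type = type, length = as.integer(len),
    vaf = rep_len(vaf_levels, n),
    content = ifelse(type == "INS", rep_len(ins_content, n), "random"),
    homology = 0L, junction_ins = 0L,
    stringsAsFactors = FALSE)
}

#' Spike SVs into a reference, producing donor haplotypes and truth
#'
#' SVs are placed at well-separated positions (or at the 0-based `pos`
#' given in `specs`).  Deletions with requested breakpoint `homology` have
#' the homologous tract stamped into the reference at the downstream
#' breakpoint first (NAHR-style recombination substrate), so use the
#' returned `ref` downstream.  `junction_ins` adds untemplated bases at the
#' deletion junction.  Each sample gets two haplotypes; `vaf = 1` SVs sit
#' on both, `vaf = 0.5` on the first.
#'
#' @param reference list from [build_reference()] or a `DNAStringSet`.
#' @param specs SV table from [sim_sv_specs()] (optional columns `chrom`,
#'   `pos`, `homology`, `junction_ins`, `samples` list-column of carrier
#'   sample names).
#' @param samples character vector of sample names (default "S1").
#' @param seed RNG seed.
#' @return list: `ref` (possibly modified `DNAStringSet`), `truth` (truth
#'   call table with `id`, `sv_type`, coordinates, `length`, `vaf`,
#'   `mechanism`, `content`), `haplotypes` (per sample: list of two block
#'   tables), `lifted` (ancestral-distance table: the "ancestral" genome
#'   lacks every spiked insertion and retains every spiked deletion, so
#'   deletions are insertion events and insertions are insertion events
#'   as seen from the donor; see the methods vignette).
#' @export
spike_svs <- function(reference, specs = NULL, samples = "S1", seed = 1L) {
  set.seed(seed + 1L)
  ref <- if (is.list(reference) && !is.null(reference$ref)) reference$ref else reference
  if (is.null(specs)) specs <- sim_sv_specs()
  chroms <- names(ref)
  widths <- setNames(Biostrings::width(ref), chroms)
  if (is.null(specs$chrom)) specs$chrom <- rep(NA_character_, nrow(specs))
  if (is.null(specs$pos)) specs$pos <- rep(NA_integer_, nrow(specs))
  if (is.null(specs$homology)) specs$homology <- rep(0L, nrow(specs))
  if (is.null(specs$junction_ins)) specs$junction_ins <- rep(0L, nrow(specs))
  # assign chromosomes/positions with >= 8 kb separation
  need <- which(is.na(specs$pos))
  if (length(need)) {
    specs$chrom[need] <- sample(chroms, length(need), replace = TRUE,
                                prob = widths / sum(widths))
    for (chrom in unique(specs$chrom[need])) {
      idx <- need[specs$chrom[need] == chrom]
      span_max <- max(specs$length[idx] + 2L * pmax(specs$homology[idx], 0L))
      W <- widths[[chrom]]
      spacing <- max(span_max + 2000L,
                     min(9000L, (W - 8000L) %/% (length(idx) + 1L)))
      slots <- (W - 8000L) %/% spacing
      if (length(idx) > slots) stop("too many SVs for chromosome ", chrom)
      offs <- sort(sample.int(slots, length(idx))) * spacing - 4000L
      specs$pos[idx] <- as.integer(offs)
    }
  }
  specs <- specs[order(specs$chrom, specs$pos), , drop = FALSE]
  # stamp homology tracts (reference modification, before donors are built)
  refc <- lapply(setNames(chroms, chroms), function(cn) as.character(ref[[cn]]))
  other_base <- function(b) c(A = "C", C = "G", G = "T", T = "A", N = "A")[[b]]
  for (i in seq_len(nrow(specs))) {
    h <- specs$homology[i]
    if (specs$sv_type[i] == "DEL") {
      s <- specs$pos[i]; e <- s + specs$length[i]; cn <- specs$chrom[i]
      if (h > 0) {
        tract <- substr(refc[[cn]], s + 1L, s + h)
        substr(refc[[cn]], e + 1L, e + h) <- tract
      }
      # guard the tract boundaries against chance extension so the planted
      # homology length is exact
      if (substr(refc[[cn]], s + h + 1L, s + h + 1L) ==
          substr(refc[[cn]], e + h + 1L, e + h + 1L)) {
        substr(refc[[cn]], e + h + 1L, e + h + 1L) <-
          other_base(substr(refc[[cn]], s + h + 1L, s + h + 1L))
      }
      if (substr(refc[[cn]], s, s) == substr(refc[[cn]], e, e)) {
        substr(refc[[cn]], e, e) <- other_base(substr(refc[[cn]], s, s))
      }
    }
  }
  ref2 <- Biostrings::DNAStringSet(unlist(refc))
  names(ref2) <- chroms
  # realize insertion contents
  alu <- sim_alu_consensus(); l1 <- sim_line_consensus(); hbv <- sim_hbv_genome()
  content_seq <- character(nrow(specs))
  for (i in seq_len(nrow(specs))) {
    if (specs$sv_type[i] != "INS") next
    L <- specs$length[i]; cn <- specs$chrom[i]; p <- specs$pos[i]
    content_seq[i] <- switch(
      specs$content[i],
      alu_like = {
        core <- mutate_sequence(substr(alu, max(1L, 300L - L + 12L), 300L),
                                err_sub = 0.02, err_ins = 0, err_del = 0)
        paste0(core, strrep("A", max(0L, L - nchar(core))))
      },
      line_like = {
        core <- mutate_sequence(substr(l1, max(1L, 6000L - L + 12L), 6000L),
                                err_sub = 0.02, err_ins = 0, err_del = 0)
        paste0(core, strrep("A", max(0L, L - nchar(core))))
      },
      tandem_dup = substr(refc[[cn]], p - L + 1L, p),
      viral = substr(hbv, 1L, min(L, nchar(hbv))),
      pseudogene_like = paste0(rand_dna(L - 12L), strrep("A", 12L)),
      rand_dna(L))
    specs$length[i] <- nchar(content_seq[i])
  }
  specs$content_seq <- content_seq
  # carrier sets
  if (is.null(specs$samples)) {
    specs$samples <- I(replicate(nrow(specs), samples, simplify = FALSE))
  }
  # truth table
  truth <- data.frame(
    id = specs$id, sv_type = specs$sv_type, chrom1 = specs$chrom,
    pos1 = specs$pos, chrom2 = specs$chrom,
    pos2 = ifelse(specs$sv_type == "INS", specs$pos,
                  specs$pos + specs$length),
    length = specs$length, vaf = specs$vaf, content = specs$content,
    homology = specs$homology, junction_ins = specs$junction_ins,
    mechanism = ifelse(specs$sv_type == "DEL",
                       classify_mechanism(specs$homology, specs$junction_ins),
                       NA_character_),
    stringsAsFactors = FALSE)
  # haplotype block tables per sample
  haplotypes <- list()
  for (sm in samples) {
    carried <- vapply(specs$samples, function(x) sm %in% x, TRUE)
    hap <- list()
    for (h in 1:2) {
      onhap <- carried & (specs$vaf >= 1 | h == 1L)
      hap[[h]] <- build_hap_blocks(specs[onhap, , drop = FALSE], widths)
    }
    haplotypes[[sm]] <- hap
  }
  # lifted-coordinate table: the ancestral genome carries none of the
  # spiked changes, so every DEL is present there (ratio ~1 would mean the
  # chimp shares the deletion); encode each record's intended event
  lifted <- truth[truth$sv_type %in% c("DEL", "INS"), , drop = FALSE]
  if (nrow(lifted)) {
    # the anchor distance spans the allele-length difference for both
    # orientations, so the denominator never degenerates for insertions
    grch <- lifted$length + 200L
    # alternate intended events deterministically by index
    intended <- ifelse(seq_len(nrow(lifted)) %% 2 == 0,
                       "deletion_event", "insertion_event")
    pantro <- integer(nrow(lifted))
    for (i in seq_len(nrow(lifted))) {
      if (lifted$sv_type[i] == "DEL") {
        # chimp has the deletion -> anchors ~200 apart -> insertion event
        pantro[i] <- if (intended[i] == "insertion_event") {
          200L + sample(-20:20, 1)
        } else {
          as.integer(round(grch[i] * runif(1, 0.9, 1.1)))
        }
      } else {
        # chimp has the insertion -> anchors 200 + len apart -> deletion event
        pantro[i] <- if (intended[i] == "deletion_event") {
          as.integer(round((200L + lifted$length[i]) * runif(1, 0.95, 1.05)))
        } else {
          200L + sample(-20:20, 1)
        }
      }
    }
    lifted <- data.frame(indel_id = lifted$id, sv_type = lifted$sv_type,
                         grch38_dist = grch, pantro_dist = pantro,
                         intended_event = intended, stringsAsFactors = FALSE)
  } else {
    lifted <- data.frame(indel_id = character(), sv_type = character(),
                         grch38_dist = integer(), pantro_dist = integer(),
                         intended_event = character(), stringsAsFactors = FALSE)
  }
  list(ref = ref2, truth = truth, haplotypes = haplotypes, lifted = lifted,
       specs = specs)
}

#' Build the donor block table for one haplotype
#'
#' Blocks map donor intervals to the reference: type `ref` blocks carry
#' `chrom`, `ref_start`, `ref_end`, `strand`; type `ins` blocks carry their
#' own sequence.
#' @noRd
build_hap_blocks <- function(specs, widths) {
  blocks <- list()
  push <- function(chrom, rs, re, strand = "+", type = "ref", seq = NA_character_,
                   sv_id = NA_character_) {
    if (type == "ref" && re <= rs) return()
    blocks[[length(blocks) + 1L]] <<- data.frame(
      chrom = chrom, ref_start = rs, ref_end = re, strand = strand,
      type = type, seq = seq, sv_id = sv_id, stringsAsFactors = FALSE)
  }
  for (chrom in names(widths)) {
    cur <- 0L
    sv <- specs[specs$chrom == chrom, , drop = FALSE]
    if (nrow(sv)) sv <- sv[order(sv$pos), , drop = FALSE]
    for (i in seq_len(nrow(sv))) {
      s <- sv$pos[i]
      if (s < cur) next  # overlapping spec; skip defensively
      if (sv$sv_type[i] == "DEL") {
        push(chrom, cur, s)
        if (sv$junction_ins[i] > 0) {
          push(chrom, s, s, type = "ins", seq = rand_dna(sv$junction_ins[i]),
               sv_id = sv$id[i])
        }
        cur <- s + sv$length[i]
      } else if (sv$sv_type[i] == "INS") {
        push(chrom, cur, s)
        push(chrom, s, s, type = "ins", seq = sv$content_seq[i],
             sv_id = sv$id[i])
        cur <- s
      } else if (sv$sv_type[i] == "INV") {
        push(chrom, cur, s)
        push(chrom, s, s + sv$length[i], strand = "-")
        cur <- s + sv$length[i]
      } else if (sv$sv_type[i] == "DUP") {
        push(chrom, cur, s + sv$length[i])
        push(chrom, s, s + sv$length[i])
        cur <- s + sv$length[i]
      }
    }
    push(chrom, cur, widths[[chrom]])
  }
  do.call(rbind, blocks)
}

#' Donor sequence for a haplotype block table
#' @noRd
donor_sequence <- function(blocks, ref) {
  pieces <- character(nrow(blocks))
  for (i in seq_len(nrow(blocks))) {
    b <- blocks[i, ]
    if (b$type == "ins") {
      pieces[i] <- b$seq
    } else {
      s <- as.character(Biostrings::subseq(ref[[b$chrom]], b$ref_start + 1L,
                                           b$ref_end))
      pieces[i] <- if (b$strand == "-") revcomp(s) else s
    }
  }
  paste(pieces, collapse = "")
}

#' Simulate noisy long reads from donor haplotypes with truth alignments
#'
#' Reads are sampled uniformly from each haplotype (coverage split evenly),
#' lengths log-normal with the given mean, errors injected per base
#' (substitution / 1-bp insertion / 1-bp deletion), and each read's true
#' alignment is emitted directly from the donor-to-reference block map:
#' deletions/insertions inside a colinear run become D/I CIGAR ops,
#' inversion and duplication junctions split the read into supplementary
#' records with SA tags.  Alignment segments shorter than `min_seg` donor
#' bases are soft-clipped away, as a real aligner would.
#'
#' @param haplotypes list of block tables (from [spike_svs()], one sample).
#' @param ref reference `DNAStringSet` (the `ref` returned by
#'   [spike_svs()]).
#' @param coverage total sample coverage (x).
#' @param sample_id read-name prefix.
#' @param mean_read_len mean read length in bp (default 5457.9).
#' @param sdlog log-normal sd of read lengths (default 0.55).
#' @param err_sub,err_ins,err_del per-base error rates (defaults 3.8% /
#'   4.4% / 6.6%).
#' @param min_seg minimum aligned segment length (default 100).
#' @param seed RNG seed.
#' @return alignment table (as from [parse_alignments()], with `sa`
#'   column); attribute `sq` carries contig lengths.  Write it with
#'   [write_sam()] for a file-based round trip.
#' @export
simulate_reads <- function(haplotypes, ref, coverage = 20,
                           sample_id = "S1", mean_read_len = 5457.9,
                           sdlog = 0.55, err_sub = 0.038, err_ins = 0.044,
                           err_del = 0.066, min_seg = 100L, seed = 1L) {
  set.seed(seed + 2L)
  sq <- setNames(Biostrings::width(ref), names(ref))
  recs <- list()
  ridx <- 0L
  for (h in seq_along(haplotypes)) {
    blocks <- haplotypes[[h]]
    dseq <- donor_sequence(blocks, ref)
    dlen <- nchar(dseq)
    blk_w <- ifelse(blocks$type == "ins", nchar(blocks$seq),
                    blocks$ref_end - blocks$ref_start)
    blk_q0 <- cumsum(c(0L, blk_w[-length(blk_w)]))
    cov_h <- coverage / length(haplotypes)
    n_reads <- max(0L, round(cov_h * dlen / mean_read_len))
    if (n_reads == 0L) next
    rl <- pmin(pmax(round(rlnorm(n_reads, log(mean_read_len) - sdlog^2 / 2,
                                 sdlog)), 500L), 50000L)
    rs <- sample.int(dlen, n_reads, replace = TRUE) - 1L
    for (i in seq_len(n_reads)) {
      ridx <- ridx + 1L
      q0 <- rs[i]; q1 <- min(dlen, q0 + rl[i])
      if (q1 - q0 < 500L) next
      read_id <- sprintf("%s_h%d_r%05d", sample_id, h, ridx)
      rec <- simulate_one_read(read_id, q0, q1, dseq, blocks, blk_q0, blk_w,
                               err_sub, err_ins, err_del, min_seg)
      if (!is.null(rec)) recs[[length(recs) + 1L]] <- rec
    }
  }
  out <- if (length(recs)) do.call(rbind, recs) else {
    e <- empty_alignments(); e$sa <- character(); e
  }
  # SA tags across records of one read
  if (nrow(out) > 1) {
    spl <- split(seq_len(nrow(out)), out$read_id)
    for (ix in spl) {
      if (length(ix) < 2) next
      for (j in ix) {
        oth <- setdiff(ix, j)
        out$sa[j] <- paste(sprintf("%s,%d,%s,%s,%d,0", out$chrom[oth],
                                   out$start[oth] + 1L, out$strand[oth],
                                   out$cigar[oth], out$mapq[oth]),
                           collapse = ";")
      }
    }
  }
  rownames(out) <- NULL
  class(out) <- c("svlr_alignments", "data.frame")
  attr(out, "sq") <- sq
  out
}

#' @noRd
simulate_one_read <- function(read_id, q0, q1, dseq, blocks, blk_q0, blk_w,
                              err_sub, err_ins, err_del, min_seg) {
  n <- q1 - q0
  ch <- strsplit(substr(dseq, q0 + 1L, q1), "")[[1]]
  e <- draw_errors(n, err_sub, err_ins, err_del)
  newch <- apply_errors_seq(ch, e)
  new_len <- length(newch)
  # new-read coordinate before each clean base, and its survivor length
  contrib <- as.integer(!e$del) + as.integer(e$ins)
  new_at <- cumsum(c(0L, contrib[-n]))  # new pos of clean base i (0-based)
  # overlapped blocks -> segments in clean-read coordinates
  bi <- which(blk_q0 < q1 & blk_q0 + blk_w > q0)
  segs <- lapply(bi, function(b) {
    lo <- max(q0, blk_q0[b]); hi <- min(q1, blk_q0[b] + blk_w[b])
    blk <- blocks[b, ]
    if (blk$type == "ins") {
      list(type = "ins", c0 = lo - q0, c1 = hi - q0)
    } else if (blk$strand == "+") {
      list(type = "ref", chrom = blk$chrom, strand = "+",
           r0 = blk$ref_start + (lo - blk_q0[b]),
           r1 = blk$ref_start + (hi - blk_q0[b]),
           c0 = lo - q0, c1 = hi - q0)
    } else {
      list(type = "ref", chrom = blk$chrom, strand = "-",
           r0 = blk$ref_end - (hi - blk_q0[b]),
           r1 = blk$ref_end - (lo - blk_q0[b]),
           c0 = lo - q0, c1 = hi - q0)
    }
  })
  # group into colinear runs: consecutive + strand ref segments on one
  # chromosome with non-negative forward gaps; ins segments ride along
  runs <- list(); cur <- NULL
  flush <- function() { if (!is.null(cur)) runs[[length(runs) + 1L]] <<- cur; cur <<- NULL }
  for (sg in segs) {
    if (sg$type == "ins") {
      if (!is.null(cur)) cur$items <- c(cur$items, list(sg))
      # an insertion at the read start opens no run; its bases become clip
      next
    }
    if (sg$r1 - sg$r0 < min_seg) { flush(); next }
    if (sg$strand == "-") { flush(); runs[[length(runs) + 1L]] <- list(items = list(sg)); next }
    if (is.null(cur)) { cur <- list(items = list(sg)); next }
    crefs <- Filter(function(x) x$type == "ref", cur$items)
    last <- crefs[[length(crefs)]]
    if (last$type == "ref" && last$strand == "+" && last$chrom == sg$chrom &&
        sg$r0 >= last$r1 && sg$r0 - last$r1 <= 50000L) {
      cur$items <- c(cur$items, list(sg))
    } else { flush(); cur <- list(items = list(sg)) }
  }
  flush()
  # drop trailing ins items of runs (they belong to clips/junctions)
  runs <- lapply(runs, function(r) {
    it <- r$items
    while (length(it) && it[[length(it)]]$type == "ins") it[[length(it)]] <- NULL
    while (length(it) && it[[1]]$type == "ins") it[[1]] <- NULL
    if (length(it)) list(items = it) else NULL
  })
  runs <- Filter(Negate(is.null), runs)
  if (!length(runs)) return(NULL)
  new_pos_of <- function(cpos) if (cpos >= n) new_len else new_at[cpos + 1L]
  recs <- list()
  for (r in runs) {
    it <- r$items
    refs <- Filter(function(x) x$type == "ref", it)
    first <- refs[[1]]; last <- refs[[length(refs)]]
    strand <- first$strand
    # base-level ops (read orientation) over clean positions + ref gaps:
    # codes 1 = M (consumes both), 2 = I (read only), 3 = D (ref only)
    op_codes <- integer(0); op_lens <- integer(0)
    # per clean position: D if the base was deleted (or I for ins-block
    # bases that survive), plus an I after bases with an inserted error
    expand_seg <- function(c0, c1, mcode) {
      idx <- (c0 + 1L):c1
      base <- ifelse(e$del[idx], if (mcode == 1L) 3L else NA_integer_, mcode)
      v <- rbind(base, ifelse(e$ins[idx], 2L, NA_integer_))
      v[!is.na(v)]
    }
    prev_ref <- NULL
    for (sg in it) {
      if (sg$type == "ins") {
        op_codes <- c(op_codes, expand_seg(sg$c0, sg$c1, 2L))
      } else {
        if (!is.null(prev_ref)) {
          gap <- sg$r0 - prev_ref$r1
          if (gap > 0) op_codes <- c(op_codes, rep.int(3L, gap))
        }
        op_codes <- c(op_codes, expand_seg(sg$c0, sg$c1, 1L))
        prev_ref <- sg
      }
    }
    rl <- rle(op_codes)
    mcodes <- rl$values; mlens <- rl$lengths
    # trim non-M ends (read orientation); track ref interval and extra
    # read bases that fall back into the clips
    R0 <- first$r0; R1 <- last$r1
    lead_extra <- 0L; tail_extra <- 0L
    while (length(mcodes) && mcodes[1] != 1L) {
      if (mcodes[1] == 3L) {
        if (strand == "+") R0 <- R0 + mlens[1] else R1 <- R1 - mlens[1]
      } else lead_extra <- lead_extra + mlens[1]
      mcodes <- mcodes[-1]; mlens <- mlens[-1]
    }
    while (length(mcodes) && mcodes[length(mcodes)] != 1L) {
      k <- length(mcodes)
      if (mcodes[k] == 3L) {
        if (strand == "+") R1 <- R1 - mlens[k] else R0 <- R0 + mlens[k]
      } else tail_extra <- tail_extra + mlens[k]
      mcodes <- mcodes[-k]; mlens <- mlens[-k]
    }
    if (!length(mcodes)) next
    ref_w <- sum(mlens[mcodes != 2L])
    if (ref_w < min_seg) next
    # clip lengths in new-read coordinates (read orientation)
    lead_new <- new_pos_of(first$c0) + lead_extra
    m_new <- sum(mlens[mcodes != 3L])
    tail_new <- new_len - lead_new - m_new
    if (tail_new < 0 || lead_new < 0) next
    if (strand == "+") {
      cig_codes <- mcodes; cig_lens <- mlens
      lclip <- lead_new; rclip <- tail_new
      seqout <- paste(newch, collapse = "")
      ref_start <- R0
    } else {
      cig_codes <- rev(mcodes); cig_lens <- rev(mlens)
      lclip <- tail_new; rclip <- lead_new
      seqout <- revcomp(paste(newch, collapse = ""))
      ref_start <- R0
    }
    cig <- paste0(c(if (lclip > 0) paste0(lclip, "S"),
                    paste0(cig_lens, c("M", "I", "D")[cig_codes]),
                    if (rclip > 0) paste0(rclip, "S")), collapse = "")
    recs[[length(recs) + 1L]] <- data.frame(
      read_id = read_id, chrom = first$chrom,
      start = ref_start, end = ref_start + ref_w,
      strand = strand, mapq = 60L, cigar = cig,
      read_length = new_len, left_clip = lclip, right_clip = rclip,
      read_start = lead_new, read_end = lead_new + m_new,
      is_primary = FALSE, low_mapq = FALSE, seq = seqout, sa = "",
      stringsAsFactors = FALSE)
  }
  if (!length(recs)) return(NULL)
  out <- do.call(rbind, recs)
  out$is_primary <- seq_len(nrow(out)) ==
    which.max(out$read_end - out$read_start)
  out
}
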