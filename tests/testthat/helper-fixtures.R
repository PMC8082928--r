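# Shared fixture builders.  Heavy simulations are cached per test run so
# several test files can reuse one object.

rnd_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# A deletion-junction fixture with exactly the requested breakpoint homology
# and junction insertion: reference left | tract | mid | tract | right with
# boundary bases guarded against chance extension of the homology.
make_junction_fixture <- function(h, ins_len, flank = 500L, mid_len = 800L) {
  repeat {
    left <- rnd_dna(flank + 100L)
    tract <- rnd_dna(h)
    mid <- rnd_dna(mid_len)
    right <- rnd_dna(flank + 100L)
    refseq <- paste0(left, tract, mid, tract, right)
    s <- nchar(left)                 # deletion start (0-based)
    e <- s + h + mid_len             # deletion end; ref[e..e+h) == tract
    # guard against chance homology at both boundaries
    if (substr(refseq, s + h + 1L, s + h + 1L) ==
        substr(refseq, e + h + 1L, e + h + 1L)) next
    if (substr(refseq, s, s) == substr(refseq, e, e)) next
    ju <- if (ins_len > 0) rnd_dna(ins_len) else ""
    # junction insertion must not extend an apparent homology
    if (ins_len > 0 &&
        (substr(ju, 1L, 1L) == substr(refseq, e + 1L, e + 1L) ||
         substr(ju, ins_len, ins_len) == substr(refseq, s, s))) next
    consensus <- paste0(substr(refseq, 1L, s), ju,
                        substr(refseq, e + 1L, nchar(refseq)))
    return(list(consensus = consensus,
                up = substr(refseq, s - flank + 1L, s + flank),
                dn = substr(refseq, e - flank + 1L, e + flank),
                refseq = refseq, s = s, e = e))
  }
}

# One hand-written SAM file from a record table.
write_sam_fixture <- function(records, sq, path = tempfile(fileext = ".sam")) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(sq), as.integer(sq)))
  writeLines(c(hdr, records), path)
  path
}

# ---- cached heavy simulations ----------------------------------------------

.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache)) {
    assign(key, force(expr), envir = .sim_cache)
  }
  get(key, envir = .sim_cache)
}

# Criterion-style spike-in study: 1 Mb reference, 60 SVs (20 DEL / 20 INS /
# 10 INV / 10 DUP, VAF 0.5 or 1.0), 20x coverage, Nanopore-like error rates.
get_spikein_run <- function() {
  cached("spikein", {
    refobj <- build_reference(lengths = c(chr1 = 5e5, chr2 = 5e5), seed = 101)
    set.seed(101)
    specs <- sim_sv_specs(n_del = 20, n_ins = 20, n_inv = 10, n_dup = 10)
    sim <- spike_svs(refobj, specs, samples = "S1", seed = 101)
    aln <- simulate_reads(sim$haplotypes$S1, sim$ref, coverage = 20,
                          sample_id = "S1", seed = 101)
    calls <- call_germline(aln, "S1")
    list(refobj = refobj, sim = sim, aln = aln, calls = calls)
  })
}

# Tumor/normal pair sharing 20 germline SVs with 10 tumor-private SVs
# (VAF 0.5), error-free reads at 30x.
get_somatic_run <- function() {
  cached("somatic", {
    refobj <- build_reference(lengths = c(chr1 = 3e5), seed = 11)
    set.seed(11)
    shared <- sim_sv_specs(n_del = 8, n_ins = 8, n_inv = 2, n_dup = 2)
    priv <- sim_sv_specs(n_del = 4, n_ins = 4, n_inv = 1, n_dup = 1)
    priv$id <- paste0("p_", priv$id)
    priv$vaf <- 0.5
    specs <- rbind(shared, priv)
    specs$samples <- I(c(replicate(nrow(shared), c("T", "N"), simplify = FALSE),
                         replicate(nrow(priv), "T", simplify = FALSE)))
    sim <- spike_svs(refobj, specs, samples = c("T", "N"), seed = 11)
    alnT <- simulate_reads(sim$haplotypes$T, sim$ref, coverage = 30,
                           sample_id = "T", err_sub = 0, err_ins = 0,
                           err_del = 0, seed = 11)
    alnN <- simulate_reads(sim$haplotypes$N, sim$ref, coverage = 30,
                           sample_id = "N", err_sub = 0, err_ins = 0,
                           err_del = 0, seed = 12)
    ct <- call_germline(alnT, "T")
    cn <- call_germline(alnN, "N")
    som <- call_somatic(ct, alnT, normal_clusters = attr(cn, "clusters"),
                        panel = NULL, normal_alignments = alnN)
    list(sim = sim, alnT = alnT, alnN = alnN, tumor_calls = ct,
         normal_calls = cn, somatic = som)
  })
}

# Signature table builder for unit fixtures.
sig_row <- function(read_id, sv_type, pos1, pos2 = NULL, length = NULL,
                    chrom = "chr1", mapq = 60L, offset = 0.5,
                    source = "cigar") {
  if (is.null(pos2)) {
    pos2 <- if (sv_type == "INS") pos1 else pos1 + length
  }
  if (is.null(length)) length <- abs(pos2 - pos1)
  data.frame(read_id = read_id, sv_type = sv_type, chrom1 = chrom,
             pos1 = as.integer(pos1), chrom2 = chrom,
             pos2 = as.integer(pos2), length = as.integer(length),
             inserted_seq = NA_character_, read_offset_fraction = offset,
             source = source, mapq = as.integer(mapq),
             clip_side = NA_character_, stringsAsFactors = FALSE)
}
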