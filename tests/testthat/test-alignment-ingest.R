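# SAM ingestion and per-read signature extraction.

test_that("empty and minimal SAM files parse correctly", {
  sq <- c(chr1 = 100000L)
  p <- write_sam_fixture(character(), sq)
  a <- parse_alignments(p)
  expect_s3_class(a, "svlr_alignments")
  expect_equal(nrow(a), 0L)
  expect_equal(attr(a, "sq"), sq)

  rec <- sprintf("r1\t0\tchr1\t1001\t60\t100M\t*\t0\t0\t%s\t*", rnd_dna(100))
  p <- write_sam_fixture(rec, sq)
  a <- parse_alignments(p)
  expect_equal(nrow(a), 1L)
  expect_equal(a$start, 1000L)
  expect_equal(a$end, 1100L)
  expect_equal(a$mapq, 60L)
  expect_equal(a$read_length, 100L)
  expect_true(a$is_primary)
})

test_that("a SA-linked supplementary becomes a sibling segment of its read", {
  sq <- c(chr1 = 100000L, chr2 = 100000L)
  seq1 <- rnd_dna(200)
  recs <- c(
    sprintf("r1\t0\tchr1\t1001\t60\t100M100S\t*\t0\t0\t%s\t*\tSA:Z:chr2,5001,+,100S100M,60,0", seq1),
    sprintf("r1\t2048\tchr2\t5001\t60\t100S100M\t*\t0\t0\t%s\t*\tSA:Z:chr1,1001,+,100M100S,60,0", seq1))
  p <- write_sam_fixture(recs, sq)
  a <- parse_alignments(p)
  expect_equal(nrow(a), 2L)
  expect_equal(sum(a$is_primary), 1L)
  expect_equal(sort(unique(a$read_id)), "r1")
  # read intervals partition the read
  expect_setequal(a$read_start, c(0L, 100L))
  expect_setequal(a$read_end, c(100L, 200L))
})

test_that("malformed CIGAR records are skipped with a warning, header missing is fatal", {
  sq <- c(chr1 = 100000L)
  recs <- c(sprintf("r1\t0\tchr1\t1001\t60\t100M\t*\t0\t0\t%s\t*", rnd_dna(100)),
            "r2\t0\tchr1\t2001\t60\t*\t*\t0\t0\t*\t*")
  p <- write_sam_fixture(recs, sq)
  expect_warning(a <- parse_alignments(p), "CIGAR")
  expect_equal(nrow(a), 1L)
  expect_equal(attr(a, "n_skipped"), 1L)

  bad <- tempfile(fileext = ".sam")
  writeLines("r1\t0\tchr1\t1001\t60\t100M\t*\t0\t0\t*\t*", bad)
  expect_error(parse_alignments(bad), "@SQ")
})

test_that("writing alignments back to SAM and re-parsing is identity on modeled fields", {
  refobj <- build_reference(lengths = c(chr1 = 1e5), seed = 2)
  set.seed(2)
  sim <- spike_svs(refobj, sim_sv_specs(n_del = 2, n_ins = 2, n_inv = 1,
                                        n_dup = 1), samples = "S1", seed = 2)
  aln <- simulate_reads(sim$haplotypes$S1, sim$ref, coverage = 6,
                        sample_id = "S1", seed = 2)
  f <- tempfile(fileext = ".sam")
  write_sam(aln, attr(aln, "sq"), f)
  aln2 <- parse_alignments(f)
  fields <- c("read_id", "chrom", "start", "end", "strand", "mapq", "cigar",
              "read_length", "left_clip", "right_clip", "read_start",
              "read_end", "is_primary", "seq")
  a1 <- as.data.frame(aln)[order(aln$read_id, aln$start), fields]
  a2 <- as.data.frame(aln2)[order(aln2$read_id, aln2$start), fields]
  rownames(a1) <- rownames(a2) <- NULL
  expect_equal(a1, a2)
})

test_that("CIGAR indel signatures come out at the walked coordinates", {
  sq <- c(chr1 = 100000L)
  # 200M 150I 200M starting at 0-based 1000: insertion point at 1200
  ins_seq <- rnd_dna(150)
  seq <- paste0(rnd_dna(200), ins_seq, rnd_dna(200))
  rec <- sprintf("r1\t0\tchr1\t1001\t60\t200M150I200M\t*\t0\t0\t%s\t*", seq)
  a <- parse_alignments(write_sam_fixture(rec, sq))
  s <- extract_signatures(a)
  expect_equal(nrow(s), 1L)
  expect_equal(s$sv_type, "INS")
  expect_equal(s$pos1, 1200L)
  expect_equal(s$length, 150L)
  expect_equal(s$inserted_seq, ins_seq)

  rec <- sprintf("r2\t0\tchr1\t1001\t60\t200M300D200M\t*\t0\t0\t%s\t*", rnd_dna(400))
  s <- extract_signatures(parse_alignments(write_sam_fixture(rec, sq)))
  expect_equal(s$sv_type, "DEL")
  expect_equal(s$pos1, 1200L)
  expect_equal(s$pos2, 1500L)
  expect_equal(s$length, 300L)

  # a plain match yields nothing
  rec <- sprintf("r3\t0\tchr1\t1001\t60\t500M\t*\t0\t0\t%s\t*", rnd_dna(500))
  s <- extract_signatures(parse_alignments(write_sam_fixture(rec, sq)))
  expect_equal(nrow(s), 0L)
})

test_that("opposite-strand split segments yield one inversion signature", {
  sq <- c(chr1 = 100000L)
  seq <- rnd_dna(400)
  recs <- c(
    sprintf("r1\t0\tchr1\t1001\t60\t200M200S\t*\t0\t0\t%s\t*\tSA:Z:chr1,5001,-,200M200S,60,0", seq),
    sprintf("r1\t2064\tchr1\t5001\t60\t200M200S\t*\t0\t0\t%s\t*\tSA:Z:chr1,1001,+,200M200S,60,0",
            as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))))
  a <- parse_alignments(write_sam_fixture(recs, sq))
  s <- extract_signatures(a)
  s <- s[s$sv_type != "CLIP", ]
  expect_equal(nrow(s), 1L)
  expect_equal(s$sv_type, "INV")
  expect_equal(s$source, "split")
})

test_that("signature extraction is per-read and order independent", {
  run <- get_spikein_run()
  a <- as.data.frame(run$aln)[1:400, ]
  s_fwd <- extract_signatures(a)
  s_rev <- extract_signatures(a[rev(seq_len(nrow(a))), ])
  key <- function(s) {
    k <- paste(s$read_id, s$sv_type, s$pos1, s$pos2, s$length)
    sort(k)
  }
  expect_equal(key(s_fwd), key(s_rev))
})

test_that("simulated error-free deletions give exactly one DEL signature at truth", {
  refobj <- build_reference(lengths = c(chr1 = 1e5), seed = 9)
  set.seed(9)
  specs <- data.frame(id = "d1", sv_type = "DEL", length = 400L, vaf = 1,
                      content = "random", homology = 0L, junction_ins = 0L,
                      chrom = "chr1", pos = 50000L)
  sim <- spike_svs(refobj, specs, samples = "S1", seed = 9)
  aln <- simulate_reads(sim$haplotypes$S1, sim$ref, coverage = 10,
                        sample_id = "S1", err_sub = 0, err_ins = 0,
                        err_del = 0, seed = 9)
  s <- extract_signatures(aln)
  s <- s[s$sv_type == "DEL", ]
  expect_true(nrow(s) >= 3)
  expect_true(all(s$pos1 == 50000L))
  expect_true(all(s$pos2 == 50400L))
  # one signature per spanning read, no spurious ones
  expect_equal(anyDuplicated(s$read_id), 0L)
})
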