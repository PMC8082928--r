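# Majority-vote consensus and remap validation.

test_that("consensus of identical segments is the input for any k", {
  set.seed(21)
  seq <- rnd_dna(800)
  for (k in c(1, 2, 5)) {
    cons <- build_consensus(rep(seq, k))
    expect_equal(cons$sequence, seq)
    expect_equal(cons$n_support, k)
    if (k == 1) expect_true(cons$low_confidence)
  }
})

test_that("a column with votes (A, A, C) emits A and ties go to the backbone", {
  set.seed(22)
  base <- rnd_dna(300)
  v1 <- base
  v2 <- base
  substr(v2, 150, 150) <- "C"
  # backbone is median length = all same length; A wins 2:1 regardless
  cons <- build_consensus(c(v1, v1, v2))
  expect_equal(cons$sequence, base)
  # 1:1 tie between backbone symbol and another base resolves to backbone
  cons <- build_consensus(c(v1, v2), refine = 0)
  expect_equal(cons$sequence, base)
})

test_that("truncated segments are retained and absorbed by the ends-free MSA", {
  set.seed(23)
  seq <- rnd_dna(1200)
  segs <- c(seq, seq, substr(seq, 1, 700), substr(seq, 301, 1200))
  cons <- build_consensus(segs)
  expect_equal(cons$sequence, seq)
})

test_that("consensus length stays between the extreme segment lengths", {
  set.seed(24)
  truth <- rnd_dna(1500)
  segs <- vapply(1:8, function(i) mutate_sequence(truth), "")
  cons <- build_consensus(segs)
  expect_gte(nchar(cons$sequence), min(nchar(segs)) - 50)
  expect_lte(nchar(cons$sequence), max(nchar(segs)) + 50)
})

test_that("insertion consensus remap accepts within 100 bp and rejects beyond", {
  set.seed(25)
  ref <- Biostrings::DNAStringSet(c(chr1 = rnd_dna(20000)))
  ins <- rnd_dna(300)
  refc <- as.character(ref[[1]])
  cons_seq <- paste0(substr(refc, 9501, 10000), ins, substr(refc, 10001, 10500))
  cons <- structure(list(sequence = cons_seq, n_support = 5,
                         low_confidence = FALSE, accepted = NA,
                         remap_distance = NA_real_),
                    class = "svlr_consensus")
  call <- data.frame(id = "c1", sv_type = "INS", chrom1 = "chr1",
                     pos1 = 10000L, chrom2 = "chr1", pos2 = 10000L,
                     length = 300L)
  v <- validate_consensus(cons, call, ref)
  expect_true(v$accepted)
  expect_lte(v$remap_distance, 100)
  call$pos1 <- call$pos2 <- 10040L   # 40 bp off: still accepted
  v <- validate_consensus(cons, call, ref)
  expect_true(v$accepted)
  call$pos1 <- call$pos2 <- 10250L   # 250 bp off: rejected
  v <- validate_consensus(cons, call, ref)
  expect_false(v$accepted)
})

test_that("deletion consensus must remap over the original call interval", {
  set.seed(26)
  ref <- Biostrings::DNAStringSet(c(chr1 = rnd_dna(20000)))
  refc <- as.character(ref[[1]])
  # true deletion [10000, 10600)
  cons_seq <- paste0(substr(refc, 9501, 10000), substr(refc, 10601, 11100))
  cons <- structure(list(sequence = cons_seq, n_support = 5,
                         low_confidence = FALSE, accepted = NA,
                         remap_distance = NA_real_),
                    class = "svlr_consensus")
  call <- data.frame(id = "d1", sv_type = "DEL", chrom1 = "chr1",
                     pos1 = 10000L, chrom2 = "chr1", pos2 = 10600L,
                     length = 600L)
  expect_true(validate_consensus(cons, call, ref)$accepted)
  # a call far away does not overlap the remapped junction
  call$pos1 <- 3000L; call$pos2 <- 3600L
  expect_false(validate_consensus(cons, call, ref)$accepted)
})

test_that("PSL-based validation applies the same rules", {
  psl <- data.frame(matches = 950L, misMatches = 10L, repMatches = 0L,
                    nCount = 0L, qNumInsert = 0L, qBaseInsert = 0L,
                    tNumInsert = 0L, tBaseInsert = 0L, strand = "+",
                    qName = "c1", qSize = 1300L, qStart = 0L, qEnd = 1300L,
                    tName = "chr1", tSize = 1e6L, tStart = 9500L,
                    tEnd = 10500L, blockCount = 2L, blockSizes = "500,500",
                    qStarts = "0,800", tStarts = "9500,10000",
                    stringsAsFactors = FALSE)
  call <- data.frame(id = "c1", sv_type = "INS", chrom1 = "chr1",
                     pos1 = 10040L, chrom2 = "chr1", pos2 = 10040L,
                     length = 300L)
  cons <- structure(list(sequence = strrep("A", 1300), n_support = 3,
                         low_confidence = FALSE, accepted = NA,
                         remap_distance = NA_real_),
                    class = "svlr_consensus")
  v <- validate_consensus(cons, call, psl = psl)
  expect_true(v$accepted)                 # implied point 10000, 40 bp away
  call$pos1 <- 10250L
  expect_false(validate_consensus(cons, call, psl = psl)$accepted)
})

test_that("segments are collected around the breakpoint from support reads", {
  refobj <- build_reference(lengths = c(chr1 = 1e5), seed = 27)
  set.seed(27)
  specs <- data.frame(id = "i1", sv_type = "INS", length = 400L, vaf = 1,
                      content = "random", homology = 0L, junction_ins = 0L,
                      chrom = "chr1", pos = 50000L)
  sim <- spike_svs(refobj, specs, samples = "S1", seed = 27)
  aln <- simulate_reads(sim$haplotypes$S1, sim$ref, coverage = 10,
                        sample_id = "S1", err_sub = 0, err_ins = 0,
                        err_del = 0, seed = 27)
  calls <- call_germline(aln, "S1")
  call <- calls[calls$sv_type == "INS", ][1, ]
  segs <- collect_segments(call, aln)
  expect_gte(length(segs), 3)
  # full-span segments carry flank + insertion + flank
  expect_true(any(nchar(segs) == 1400))
  # a read not supporting the call is excluded
  expect_true(all(names(segs) %in% call$read_ids[[1]]))
  # error-free segments give back the donor junction sequence exactly
  cons <- build_consensus(segs)
  don <- donor <- svlr:::donor_sequence(sim$haplotypes$S1[[1]], sim$ref)
  expect_true(grepl(cons$sequence, don, fixed = TRUE))
})
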