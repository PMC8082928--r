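# Clustering, merging, support and region filters, population merge.

test_that("clustering windows split at the documented distances", {
  # 49 bp apart -> one cluster; 51 bp apart -> two (deletion window 50)
  s <- rbind(sig_row("r1", "DEL", 1000, length = 300),
             sig_row("r2", "DEL", 1049, length = 300))
  expect_equal(nrow(cluster_signatures(s)), 1L)
  s <- rbind(sig_row("r1", "DEL", 1000, length = 300),
             sig_row("r2", "DEL", 1051, length = 300))
  expect_equal(nrow(cluster_signatures(s)), 2L)
  # singleton: a cluster but not a candidate
  cl <- cluster_signatures(sig_row("r1", "DEL", 1000, length = 300))
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$support, 1L)
  expect_false(cl$candidate)
  # inversion window is 100
  s <- rbind(sig_row("r1", "INV", 1000, 3000, source = "split", offset = 0.4),
             sig_row("r2", "INV", 1090, 3090, source = "split", offset = 0.6))
  expect_equal(nrow(cluster_signatures(s)), 1L)
})

test_that("candidates need two reads at mapping quality >= 20", {
  s <- rbind(sig_row("r1", "DEL", 1000, length = 300, mapq = 19),
             sig_row("r2", "DEL", 1010, length = 300, mapq = 19),
             sig_row("r3", "DEL", 1020, length = 300, mapq = 60))
  cl <- cluster_signatures(s)
  expect_false(cl$candidate)
  s$mapq[1] <- 20L
  expect_true(cluster_signatures(s)$candidate)
})

test_that("breakpoint merging honors the 300/1000 bp windows and 80% overlap", {
  mk <- function(p1, p2, reads) {
    do.call(rbind, lapply(reads, function(r)
      sig_row(r, "DEL", p1, p2, offset = 0.5)))
  }
  # two DEL clusters 900 bp apart with ~85% reciprocal overlap -> merged
  s <- rbind(mk(10000, 20000, c("a", "b")), mk(10900, 20500, c("c", "d")))
  cl <- cluster_signatures(s)
  expect_equal(nrow(cl), 2L)
  m <- merge_candidate_breakpoints(cl, s)
  expect_equal(nrow(m), 1L)
  expect_setequal(m$read_ids[[1]], c("a", "b", "c", "d"))
  # same overlap but 1100 bp apart -> not merged
  s <- rbind(mk(10000, 21000, c("a", "b")), mk(11100, 21200, c("c", "d")))
  m <- merge_candidate_breakpoints(cluster_signatures(s), s)
  expect_equal(nrow(m), 2L)
  # good distance but < 80% reciprocal overlap -> not merged
  s <- rbind(mk(10000, 10800, c("a", "b")), mk(10600, 11000, c("c", "d")))
  m <- merge_candidate_breakpoints(cluster_signatures(s), s)
  expect_equal(nrow(m), 2L)
  # identical clusters merge idempotently with unioned support
  s <- rbind(mk(10000, 20000, c("a", "b")), mk(10000, 20000, c("b", "c")))
  m <- merge_candidate_breakpoints(cluster_signatures(s), s)
  expect_equal(nrow(m), 1L)
  expect_equal(m$support, 3L)
  m2 <- merge_candidate_breakpoints(m, s)
  expect_equal(m2$pos1, m$pos1)
  expect_equal(m2$support, m$support)
})

test_that("insertion merging uses the length-ratio analogue of overlap", {
  s <- rbind(sig_row("a", "INS", 10000, length = 500),
             sig_row("b", "INS", 10000, length = 500),
             sig_row("c", "INS", 10200, length = 450),
             sig_row("d", "INS", 10200, length = 450))
  m <- merge_candidate_breakpoints(cluster_signatures(s), s)
  expect_equal(nrow(m), 1L)   # ratio 0.9, distance 200 <= 300
  s$length[3:4] <- 100L       # ratio 0.2 -> distinct insertions
  s$pos2 <- s$pos1
  m <- merge_candidate_breakpoints(cluster_signatures(s), s)
  expect_equal(nrow(m), 2L)
})

test_that("support thresholds follow the per-size rules", {
  mk_del <- function(n, len) {
    s <- do.call(rbind, lapply(seq_len(n), function(i)
      sig_row(paste0("r", i), "DEL", 10000, length = len)))
    cl <- cluster_signatures(s)
    apply_support_filters(cl, s)
  }
  expect_match(mk_del(3, 300)$filter, "low_support")  # 100-500 bp needs 4
  expect_equal(mk_del(4, 300)$filter, "")
  expect_match(mk_del(2, 800)$filter, "low_support")  # 501-1000 needs 3
  expect_equal(mk_del(3, 800)$filter, "")
  expect_equal(mk_del(2, 1500)$filter, "")            # > 1000 needs 2
  mk_ins <- function(n, len) {
    s <- do.call(rbind, lapply(seq_len(n), function(i)
      sig_row(paste0("r", i), "INS", 10000, length = len)))
    apply_support_filters(cluster_signatures(s), s)
  }
  expect_match(mk_ins(2, 500)$filter, "low_support")  # <= 1000 needs 3
  expect_equal(mk_ins(3, 500)$filter, "")
  expect_equal(mk_ins(2, 1500)$filter, "")            # > 1000 needs 2
})

test_that("read-edge and deletion-with-insertion reads are discarded before counting", {
  # signature in the terminal 10% of the read does not count as support
  s <- rbind(sig_row("r1", "INS", 10000, length = 300, offset = 0.05),
             sig_row("r2", "INS", 10000, length = 300),
             sig_row("r3", "INS", 10000, length = 300),
             sig_row("r4", "INS", 10000, length = 300))
  calls <- apply_support_filters(cluster_signatures(s), s)
  expect_equal(calls$support, 3L)
  expect_false("r1" %in% calls$read_ids[[1]])

  # an 800 bp deletion support read with an 85 bp insertion 20 bp from the
  # breakpoint is dropped (85 >= 10% of 800); with a 75 bp insertion it stays
  s <- do.call(rbind, lapply(1:4, function(i)
    sig_row(paste0("r", i), "DEL", 10000, length = 800)))
  minor <- data.frame(read_id = "r1", chrom = "chr1", pos = 10020L, len = 85L)
  calls <- apply_support_filters(cluster_signatures(s), s, minor_ins = minor)
  expect_equal(calls$support, 3L)
  minor$len <- 75L
  calls <- apply_support_filters(cluster_signatures(s), s, minor_ins = minor)
  expect_equal(calls$support, 4L)
  # >= 1000 bp deletions use the 30% bound
  s <- do.call(rbind, lapply(1:4, function(i)
    sig_row(paste0("r", i), "DEL", 10000, length = 1200)))
  minor <- data.frame(read_id = "r1", chrom = "chr1", pos = 10020L, len = 200L)
  calls <- apply_support_filters(cluster_signatures(s), s, minor_ins = minor)
  expect_equal(calls$support, 4L)   # 200 < 0.3 * 1200
  minor$len <- 400L
  calls <- apply_support_filters(cluster_signatures(s), s, minor_ins = minor)
  expect_equal(calls$support, 3L)
})

test_that("VAF and low-MAPQ region filters flag as specified", {
  mk_aln <- function(n, n_low) {
    data.frame(read_id = paste0("d", seq_len(n)), chrom = "chr1",
               start = 9000L, end = 11000L, strand = "+",
               mapq = c(rep(20L, n_low), rep(60L, n - n_low)),
               cigar = "2000M", read_length = 2000L, left_clip = 0L,
               right_clip = 0L, read_start = 0L, read_end = 2000L,
               is_primary = TRUE, low_mapq = FALSE, seq = NA_character_,
               stringsAsFactors = FALSE)
  }
  call <- data.frame(id = "c1", sample_id = "S", sv_type = "DEL",
                     chrom1 = "chr1", pos1 = 10000L, chrom2 = "chr1",
                     pos2 = 10300L, length = 300L, support = 1L,
                     filter = "", read_ids = I(list("d1")),
                     stringsAsFactors = FALSE)
  # support 1 over depth 50 -> vaf 0.02 -> low_vaf
  out <- apply_region_filters(call, mk_aln(50, 0))
  expect_equal(out$vaf, 0.02)
  expect_match(out$filter, "low_vaf")
  # 4 of 10 spanning reads at MAPQ 20 -> 40% below 30 -> low_mq_region
  call$support <- 5L
  out <- apply_region_filters(call, mk_aln(10, 4))
  expect_match(out$filter, "low_mq_region")
  out <- apply_region_filters(call, mk_aln(10, 2))
  expect_false(grepl("low_mq_region", out$filter))
  expect_true(out$pass)
})

test_that("the 80% short-repeat and segdup filters apply to the right types", {
  aln <- data.frame(read_id = paste0("d", 1:10), chrom = "chr1",
                    start = 8000L, end = 14000L, strand = "+", mapq = 60L,
                    cigar = "6000M", read_length = 6000L, left_clip = 0L,
                    right_clip = 0L, read_start = 0L, read_end = 6000L,
                    is_primary = TRUE, low_mapq = FALSE, seq = NA_character_,
                    stringsAsFactors = FALSE)
  reps <- data.frame(seq_id = "chr1", start = 10000L, end = 10450L,
                     repeat_class = "Simple/Tandem", family = "(AT)n",
                     strand = "+", rep_begin = NA, rep_end = NA,
                     rep_left = NA, source = "trf")
  call <- data.frame(id = "c1", sample_id = "S", sv_type = "INV",
                     chrom1 = "chr1", pos1 = 10000L, chrom2 = "chr1",
                     pos2 = 10500L, length = 500L, support = 5L, filter = "",
                     read_ids = I(list("d1")), stringsAsFactors = FALSE)
  out <- apply_region_filters(call, aln, repeats = reps)   # 90% covered
  expect_match(out$filter, "repeat80")
  call$sv_type <- "DEL"                                    # germline: DEL exempt
  out <- apply_region_filters(call, aln, repeats = reps)
  expect_false(grepl("repeat80", out$filter))
  reps$end <- 10350L                                       # 70% covered
  call$sv_type <- "INV"
  out <- apply_region_filters(call, aln, repeats = reps)
  expect_false(grepl("repeat80", out$filter))

  # both breakpoints in different segments of one segdup
  segdups <- data.frame(chrom = "chr1", start = c(9900L, 10400L),
                        end = c(10100L, 10600L), name = "sd1")
  out <- apply_region_filters(call, aln, segdups = segdups)
  expect_match(out$filter, "segdup")
  segdups$name <- c("sd1", "sd2")
  out <- apply_region_filters(call, aln, segdups = segdups)
  expect_false(grepl("segdup", out$filter))
})

test_that("population merge applies the allele-frequency selection", {
  mk_call <- function(sample, vaf, pos = 10000L) {
    data.frame(id = paste0(sample, "_1"), sample_id = sample,
               sv_type = "DEL", chrom1 = "chr1", pos1 = pos,
               chrom2 = "chr1", pos2 = pos + 300L, length = 300L,
               support = 5L, filter = "", vaf = vaf,
               stringsAsFactors = FALSE)
  }
  # 3 of 11 samples, all heterozygous: AF 3/22 >= 0.1 -> retained
  pop <- merge_across_samples(list(mk_call("s1", 0.5), mk_call("s2", 0.5),
                                   mk_call("s3", 0.5)), n_samples = 11)
  expect_equal(nrow(pop), 1L)
  expect_equal(pop$allele_count, 3L)
  expect_equal(pop$allele_frequency, 3 / 22)
  # 2 heterozygous carriers: 2/22 < 0.1 -> dropped
  pop <- merge_across_samples(list(mk_call("s1", 0.5), mk_call("s2", 0.5)),
                              n_samples = 11)
  expect_equal(nrow(pop), 0L)
  # one homozygous carrier: 2 alleles but still 2/22 -> dropped
  pop <- merge_across_samples(list(mk_call("s1", 0.95)), n_samples = 11)
  expect_equal(nrow(pop), 0L)
  # genotype rule boundary
  expect_equal(genotype_allele_count(c(0.69, 0.7, 1)), c(1L, 2L, 2L))
})

test_that("raising thresholds never grows the pass set (monotonicity)", {
  run <- get_spikein_run()
  base <- run$calls
  stricter <- apply_region_filters(
    base[, setdiff(names(base), c("depth", "vaf", "pass"))],
    run$aln, min_vaf = 0.2)
  expect_true(all(stricter$pass <= base$pass))
  expect_true(sum(stricter$pass) <= sum(base$pass))
})

test_that("every emitted call's support reads exist in the input alignments", {
  run <- get_spikein_run()
  rids <- unique(run$aln$read_id)
  expect_true(all(unlist(run$calls$read_ids) %in% rids))
})
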