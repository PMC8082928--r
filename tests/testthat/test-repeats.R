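# RepeatMasker / TRF parsing, interval coverage, repeat classification.

rm_line <- paste0(" 1306 15.6  6.2  0.0  chr1 10001 10300 (989700) + ",
                  "AluYa5 SINE/Alu 1 300 (11) 1")
trf_text <- c("Tandem Repeats Finder Program written by:", "", "Benson G.",
              "", "Sequence: consensus_1", "",
              "Parameters: 2 7 7 80 10 50 500", "",
              "101 400 2 150.0 2 95 0 600 25 25 25 25 1.90 AT ACGT")

test_that("RepeatMasker .out and TRF .dat lines parse to intervals", {
  rm_f <- tempfile(); writeLines(c("   SW  perc ...", "score  div ...", "",
                                   rm_line), rm_f)
  trf_f <- tempfile(); writeLines(trf_text, trf_f)
  r <- parse_repeat_files(rm_f, trf_f)
  expect_equal(nrow(r), 2L)
  rm_r <- r[r$source == "rm", ]
  expect_equal(rm_r$seq_id, "chr1")
  expect_equal(rm_r$start, 10000L)      # 1-based inclusive -> 0-based
  expect_equal(rm_r$end, 10300L)
  expect_equal(rm_r$repeat_class, "SINE")
  expect_equal(rm_r$family, "AluYa5")
  expect_equal(rm_r$strand, "+")
  trf_r <- r[r$source == "trf", ]
  expect_equal(trf_r$seq_id, "consensus_1")
  expect_equal(trf_r$start, 100L)
  expect_equal(trf_r$end, 400L)
  expect_equal(trf_r$repeat_class, "Simple/Tandem")
  # empty files -> empty table
  e1 <- tempfile(); writeLines(character(), e1)
  expect_equal(nrow(parse_repeat_files(e1, e1)), 0L)
})

test_that("the simulator's annotation writers round-trip through the parsers", {
  refobj <- build_reference(lengths = c(chr1 = 1e5), seed = 41)
  rm_f <- tempfile(); trf_f <- tempfile()
  write_repeatmasker_out(refobj$repeats, rm_f)
  write_trf_dat(refobj$repeats, trf_f)
  r <- parse_repeat_files(rm_f, trf_f)
  truth <- refobj$repeats
  expect_equal(nrow(r), nrow(truth))
  r <- r[order(r$start), ]; truth <- truth[order(truth$start), ]
  expect_equal(r$start, truth$start)
  expect_equal(r$end, truth$end)
  expect_equal(r$repeat_class, truth$repeat_class)
  expect_equal(r$strand, truth$strand)
})

test_that("interval coverage equals the per-base bitmap oracle", {
  set.seed(42)
  for (i in 1:25) {
    L <- sample(50:2000, 1)
    n <- sample(0:8, 1)
    iv <- if (n > 0) {
      st <- sample(0:(L - 1), n, replace = TRUE)
      data.frame(start = st, end = pmin(L, st + sample(1:500, n, TRUE)))
    } else data.frame(start = integer(), end = integer())
    bitmap <- logical(L)
    for (k in seq_len(nrow(iv))) {
      bitmap[(iv$start[k] + 1):iv$end[k]] <- TRUE
    }
    expect_equal(interval_coverage(iv, L), mean(bitmap))
  }
})

test_that("repeat categories partition as specified", {
  mk_rep <- function(start, end, cls, family = "X", strand = "+",
                     rep_begin = 1L) {
    data.frame(seq_id = "c1", start = start, end = end, repeat_class = cls,
               family = family, strand = strand, rep_begin = rep_begin,
               rep_end = rep_begin + (end - start) - 1L, rep_left = 0L,
               source = "rm", stringsAsFactors = FALSE)
  }
  seq300 <- strrep("A", 300)
  # a single SINE covering 290/300
  p <- classify_sv_sequence(seq300, mk_rep(5, 295, "SINE", "AluYa5"))
  expect_equal(p$category, "single_SINE")
  expect_equal(p$families, "AluYa5")
  # two opposite-strand LINEs jointly covering 85% -> multi_repeat + twin priming
  r <- rbind(mk_rep(0, 130, "LINE", "L1HS", "+"),
             mk_rep(135, 255, "LINE", "L1HS", "-"))
  p <- classify_sv_sequence(seq300, r)
  expect_equal(p$category, "multi_repeat")
  expect_true(p$twin_priming)
  # 60% tandem repeat -> excluded before everything else
  r <- rbind(mk_rep(0, 180, "Simple/Tandem"), mk_rep(200, 290, "SINE"))
  p <- classify_sv_sequence(seq300, r)
  expect_equal(p$category, "short_repeat_excluded")
  # transposon overlap below 80% -> repeat_included
  p <- classify_sv_sequence(seq300, mk_rep(0, 150, "SINE"))
  expect_equal(p$category, "repeat_included")
  # nothing -> non_repeat
  p <- classify_sv_sequence(seq300, mk_rep(0, 0, "SINE")[0, ])
  expect_equal(p$category, "non_repeat")
  # every consensus gets exactly one category
  cats <- c("single_SINE", "multi_repeat", "short_repeat_excluded",
            "repeat_included", "non_repeat")
  expect_true(all(p$category %in% c(cats, "single_LINE")))
})

test_that("5' truncation and poly(A) flags are derived from the annotation", {
  r <- data.frame(seq_id = "c1", start = 0L, end = 250L,
                  repeat_class = "LINE", family = "L1HS", strand = "+",
                  rep_begin = 3001L, rep_end = 3250L, rep_left = 2750L,
                  source = "rm", stringsAsFactors = FALSE)
  seq <- paste0(rnd_dna(240), strrep("A", 14))
  p <- classify_sv_sequence(seq, r)
  expect_equal(p$truncation_5prime, 3000L)
  expect_true(p$polyA_tail)
  # the same tail present in the reference flank is not novel
  p <- classify_sv_sequence(seq, r, ref_flank = paste0(rnd_dna(20), strrep("A", 14)))
  expect_false(p$polyA_tail)
})

test_that("non-repeat insertions classify by their remap hits", {
  psl <- data.frame(matches = 290L, misMatches = 5L, repMatches = 0L,
                    nCount = 0L, qNumInsert = 0L, qBaseInsert = 0L,
                    tNumInsert = 0L, tBaseInsert = 0L, strand = "+",
                    qName = "q1", qSize = 300L, qStart = 0L, qEnd = 300L,
                    tName = "chr1", tSize = 1e6L, tStart = 9800L,
                    tEnd = 10100L, blockCount = 1L, blockSizes = "300",
                    qStarts = "0", tStarts = "9800", stringsAsFactors = FALSE)
  call <- data.frame(id = "q1", chrom1 = "chr1", pos1 = 10000L)
  # hit adjacent to the insertion point -> tandem duplication
  expect_equal(classify_nonrepeat_insertion(call, psl), "tandem_dup")
  # hit far away -> template insertion
  psl$tStart <- 500000L; psl$tEnd <- 500300L; psl$tStarts <- "500000"
  expect_equal(classify_nonrepeat_insertion(call, psl), "template_insertion")
  # split across two exons of one gene -> processed pseudogene
  psl$blockCount <- 2L; psl$blockSizes <- "150,150"
  psl$tStarts <- "500000,520000"
  genes <- data.frame(gene = "G1", chrom = "chr1",
                      start = c(499900L, 519900L), end = c(500400L, 520400L))
  expect_equal(classify_nonrepeat_insertion(call, psl, genes),
               "processed_pseudogene")
  # no hit at 70% identity -> none
  psl$matches <- 100L
  expect_equal(classify_nonrepeat_insertion(call, psl), "none")
})

test_that("PSL reading skips headers and returns the 21 columns", {
  f <- tempfile()
  writeLines(c("psLayout version 3", "", "match\tmis...", "----------",
               paste(c(290, 5, 0, 0, 0, 0, 0, 0, "+", "q1", 300, 0, 300,
                       "chr1", 1e6, 9800, 10100, 1, "300,", "0,", "9800,"),
                     collapse = "\t")), f)
  p <- read_psl(f)
  expect_equal(nrow(p), 1L)
  expect_equal(p$qName, "q1")
  expect_equal(p$tStart, 9800L)
})
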