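# Determinism, coordinate bookkeeping, error-rate calibration.

test_that("identical seeds give byte-identical references and reads", {
  r1 <- build_reference(lengths = c(chr1 = 5e4), seed = 61)
  r2 <- build_reference(lengths = c(chr1 = 5e4), seed = 61)
  expect_equal(as.character(r1$ref), as.character(r2$ref))
  expect_equal(r1$repeats, r2$repeats)
  set.seed(61); s1 <- sim_sv_specs(n_del = 2, n_ins = 2, n_inv = 1, n_dup = 1)
  set.seed(61); s2 <- sim_sv_specs(n_del = 2, n_ins = 2, n_inv = 1, n_dup = 1)
  sim1 <- spike_svs(r1, s1, samples = "S1", seed = 61)
  sim2 <- spike_svs(r2, s2, samples = "S1", seed = 61)
  a1 <- simulate_reads(sim1$haplotypes$S1, sim1$ref, coverage = 4,
                       sample_id = "S1", seed = 61)
  a2 <- simulate_reads(sim2$haplotypes$S1, sim2$ref, coverage = 4,
                       sample_id = "S1", seed = 61)
  expect_equal(as.data.frame(a1), as.data.frame(a2))
})

test_that("spiking applies exact coordinate arithmetic to the donors", {
  refobj <- build_reference(lengths = c(chr1 = 1e5), seed = 62)
  W <- 1e5
  # no SVs -> donor equals the reference
  sim0 <- spike_svs(refobj, sim_sv_specs(0, 0, 0, 0)[0, ], samples = "S1",
                    seed = 62)
  don <- svlr:::donor_sequence(sim0$haplotypes$S1[[1]], sim0$ref)
  expect_equal(don, as.character(sim0$ref[[1]]))
  # one 500 bp deletion -> donor 500 bp shorter
  specs <- data.frame(id = "d", sv_type = "DEL", length = 500L, vaf = 1,
                      content = "random", homology = 0L, junction_ins = 0L,
                      chrom = "chr1", pos = 40000L)
  sim <- spike_svs(refobj, specs, samples = "S1", seed = 62)
  don <- svlr:::donor_sequence(sim$haplotypes$S1[[1]], sim$ref)
  expect_equal(nchar(don), W - 500L)
  # one 500 bp tandem duplication -> donor 500 bp longer
  specs$sv_type <- "DUP"
  sim <- spike_svs(refobj, specs, samples = "S1", seed = 62)
  don <- svlr:::donor_sequence(sim$haplotypes$S1[[1]], sim$ref)
  expect_equal(nchar(don), W + 500L)
  # an inversion keeps the length and reverse-complements the interval
  specs$sv_type <- "INV"
  sim <- spike_svs(refobj, specs, samples = "S1", seed = 62)
  don <- svlr:::donor_sequence(sim$haplotypes$S1[[1]], sim$ref)
  expect_equal(nchar(don), W)
  refc <- as.character(sim$ref[[1]])
  expect_equal(substr(don, 40001, 40500),
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(substr(refc, 40001, 40500)))))
})

test_that("zero error rates give exact substrings; zero coverage gives no reads", {
  refobj <- build_reference(lengths = c(chr1 = 5e4), seed = 63)
  sim <- spike_svs(refobj, sim_sv_specs(0, 0, 0, 0)[0, ], samples = "S1",
                   seed = 63)
  aln <- simulate_reads(sim$haplotypes$S1, sim$ref, coverage = 2,
                        sample_id = "S1", err_sub = 0, err_ins = 0,
                        err_del = 0, seed = 63)
  refc <- as.character(sim$ref[[1]])
  for (i in head(seq_len(nrow(aln)), 20)) {
    expect_equal(aln$seq[i], substr(refc, aln$start[i] + 1, aln$end[i]))
  }
  a0 <- simulate_reads(sim$haplotypes$S1, sim$ref, coverage = 0,
                       sample_id = "S1", seed = 63)
  expect_equal(nrow(a0), 0L)
})

test_that("empirical per-base error rates match the requested profile within 10%", {
  refobj <- build_reference(lengths = c(chr1 = 6e4), seed = 64)
  sim <- spike_svs(refobj, sim_sv_specs(0, 0, 0, 0)[0, ], samples = "S1",
                   seed = 64)
  aln <- simulate_reads(sim$haplotypes$S1, sim$ref, coverage = 18,
                        sample_id = "S1", seed = 64)   # ~1 Mb of bases
  ops <- GenomicAlignments::explodeCigarOps(aln$cigar)
  lens <- GenomicAlignments::explodeCigarOpLengths(aln$cigar)
  tot <- tapply(unlist(lens), unlist(ops), sum)
  aligned <- tot[["M"]] + tot[["D"]]
  ins_rate <- tot[["I"]] / aligned
  del_rate <- tot[["D"]] / aligned
  expect_gt(aligned, 9e5)
  expect_lt(abs(ins_rate - 0.044) / 0.044, 0.1)
  expect_lt(abs(del_rate - 0.066) / 0.066, 0.1)
})

test_that("support reads scale with VAF times coverage", {
  run <- get_spikein_run()
  truth <- run$sim$truth
  calls <- run$calls
  m <- match_callsets(calls, truth)
  matched <- m$common
  sup <- calls$support[matched$call]
  vaf <- truth$vaf[matched$truth]
  # homozygous SVs should roughly double heterozygous support
  expect_gt(mean(sup[vaf == 1]), 1.4 * mean(sup[vaf == 0.5]))
  # binomial sanity: per-SV support within wide bounds of vaf * coverage
  expect_true(all(sup >= 2))
  expect_true(all(sup <= 45))
})

test_that("the truth VCF round-trips through the package reader", {
  refobj <- build_reference(lengths = c(chr1 = 1e5), seed = 65)
  set.seed(65)
  sim <- spike_svs(refobj, sim_sv_specs(2, 2, 1, 1), samples = "S1",
                   seed = 65)
  f <- tempfile(fileext = ".vcf")
  tr <- sim$truth
  tr$support <- NA_integer_
  tr$filter <- ""
  sq <- setNames(Biostrings::width(sim$ref), names(sim$ref))
  write_sv_vcf(tr, f, sq)
  back <- read_sv_vcf(f)
  expect_equal(nrow(back), nrow(tr))
  tr_s <- tr[order(tr$pos1), ]
  expect_equal(back$sv_type, tr_s$sv_type)
  expect_equal(back$pos1, tr_s$pos1)
  expect_equal(back$id, tr_s$id)
  # symbolic END round-trips the second breakpoint
  expect_equal(back$pos2[back$sv_type == "DEL"],
               tr_s$pos2[tr_s$sv_type == "DEL"])
})
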