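#' Run pipeline stages from a declarative configuration
#'
#' Thin orchestration over the package functions.  Subcommands:
#' \describe{
#'   \item{simulate}{build a reference, spike SVs, simulate reads; writes
#'     `ref.fa`, `reads.sam`, `truth.vcf`, `repeats.out`, `repeats.dat`,
#'     `lifted.tsv`.}
#'   \item{germline}{call germline SVs from a SAM/BAM; writes a VCF and a
#'     BEDPE.}
#'   \item{somatic}{tumor/normal subtraction; writes a somatic VCF and a
#'     review table of per-call read evidence.}
#'   \item{evaluate}{benchmark a callset VCF against a truth VCF; writes a
#'     TSV/JSON report.}
#' }
#' Every output directory gets a `manifest.json` with the tool version,
#' configuration hash and seed; reruns with the same configuration and seed
#' are byte-identical.
#'
#' @param subcommand one of `"simulate"`, `"germline"`, `"somatic"`,
#'   `"evaluate"`.
#' @param args named list of subcommand arguments (file paths and
#'   overrides); see the package vignette.
#' @param config an [svlr_config()] list.
#' @return invisibly, a list of produced file paths.
#' @export
run_pipeline <- function(subcommand = c("simulate", "germline", "somatic",
                                        "evaluate"),
                         args = list(), config = svlr_config()) {
  subcommand <- match.arg(subcommand)
  outdir <- args$outdir %||% "."
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  produced <- character()
  emit <- function(...) file.path(outdir, paste0(...))
  if (subcommand == "simulate") {
    seed <- as.integer(args$seed %||% config$seed)
    lengths <- args$lengths %||% c(chr1 = 5e5, chr2 = 5e5)
    refobj <- build_reference(lengths = lengths, seed = seed)
    set.seed(seed)
    specs <- args$specs %||% sim_sv_specs()
    sim <- spike_svs(refobj, specs, samples = args$samples %||% "S1",
                     seed = seed)
    Biostrings::writeXStringSet(sim$ref, emit("ref.fa"))
    write_repeatmasker_out(refobj$repeats, emit("repeats.out"))
    write_trf_dat(refobj$repeats, emit("repeats.dat"))
    sq <- setNames(Biostrings::width(sim$ref), names(sim$ref))
    for (sm in names(sim$haplotypes)) {
      aln <- simulate_reads(sim$haplotypes[[sm]], sim$ref,
                            coverage = args$coverage %||% 20,
                            sample_id = sm, seed = seed)
      write_sam(aln, sq, emit(sm, ".sam"))
      produced <- c(produced, emit(sm, ".sam"))
    }
    tr <- sim$truth
    tr$support <- NA_integer_; tr$filter <- ""
    write_sv_vcf(tr, emit("truth.vcf"), sq, sample_id = "truth",
                 config = config)
    write.table(sim$lifted, emit("lifted.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    produced <- c(produced, emit("ref.fa"), emit("truth.vcf"),
                  emit("repeats.out"), emit("repeats.dat"), emit("lifted.tsv"))
  } else if (subcommand == "germline") {
    aln <- parse_alignments(args$bam, min_mapq = config$min_mapq)
    reps <- if (!is.null(args$repeats) || !is.null(args$trf)) {
      parse_repeat_files(args$repeats, args$trf)
    } else NULL
    segdups <- if (!is.null(args$segdup)) {
      sd <- read.table(args$segdup, sep = "\t", stringsAsFactors = FALSE)
      names(sd)[1:4] <- c("chrom", "start", "end", "name")
      sd
    } else NULL
    calls <- call_germline(aln, sample_id = args$sample %||% "S1",
                           repeats = reps, segdups = segdups,
                           config = config)
    sq <- attr(aln, "sq")
    write_sv_vcf(calls, args$out %||% emit("germline.vcf"), sq,
                 sample_id = args$sample %||% "S1", config = config)
    write_bedpe(calls, sub("\\.vcf$", ".bedpe", args$out %||% emit("germline.vcf")))
    produced <- c(produced, args$out %||% emit("germline.vcf"))
  } else if (subcommand == "somatic") {
    taln <- parse_alignments(args$tumor, min_mapq = config$min_mapq)
    naln <- parse_alignments(args$normal, min_mapq = config$min_mapq)
    reps <- if (!is.null(args$repeats) || !is.null(args$trf)) {
      parse_repeat_files(args$repeats, args$trf)
    } else NULL
    tcalls <- call_germline(taln, sample_id = args$sample %||% "T",
                            repeats = reps, config = config)
    ncalls <- call_germline(naln, sample_id = paste0(args$sample %||% "T", "N"),
                            repeats = reps, config = config)
    panel <- if (!is.null(args$panel)) read_sv_vcf(args$panel) else NULL
    som <- call_somatic(tcalls, taln,
                        normal_clusters = attr(ncalls, "clusters"),
                        panel = panel, normal_alignments = naln,
                        repeats = reps, config = config)
    sq <- attr(taln, "sq")
    write_sv_vcf(som, args$out %||% emit("somatic.vcf"), sq,
                 sample_id = args$sample %||% "T", config = config)
    # machine-readable review report: per-call read evidence
    rev <- do.call(rbind, lapply(seq_len(nrow(som)), function(i) {
      rid <- som$read_ids[[i]]
      if (!length(rid)) return(NULL)
      data.frame(id = som$id[i], read_id = rid, stringsAsFactors = FALSE)
    }))
    if (is.null(rev)) rev <- data.frame(id = character(), read_id = character())
    write.table(rev, emit("somatic_review.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    produced <- c(produced, args$out %||% emit("somatic.vcf"),
                  emit("somatic_review.tsv"))
  } else if (subcommand == "evaluate") {
    calls <- read_sv_vcf(args$calls)
    truth <- read_sv_vcf(args$truth)
    m <- match_callsets(calls[calls$pass | !nzchar(calls$filter), ], truth,
                        max_dist = config$bench_max_dist)
    rep_df <- data.frame(metric = c("common", "truth_only", "calls_only",
                                    "precision", "recall", "f_measure"),
                         value = c(nrow(m$common), length(m$truth_only),
                                   length(m$calls_only), m$precision,
                                   m$recall, m$f_measure))
    write.table(rep_df, args$out %||% emit("evaluation.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    produced <- c(produced, args$out %||% emit("evaluation.tsv"))
  }
  manifest <- list(tool = "svlr", version = svlr_version(),
                   subcommand = subcommand,
                   config_hash = config_hash(config), seed = config$seed,
                   files = produced)
  writeLines(yaml::as.yaml(manifest), file.path(outdir, "manifest.yaml"))
  invisible(produced)
}
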