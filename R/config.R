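#' Pipeline configuration with published defaults
#'
#' Every threshold in the calling, consensus, mechanism and benchmarking
#' stages, collected in one list so the zero-argument call is the
#' recommended parameterization for ~20x Nanopore-scale data.
#'
#' @param ... named overrides of any default below.
#' @return a named list of class `svlr_config`.
#' @details Defaults: minimum indel length 100 bp and clip length 500 bp;
#' clustering windows 50 bp (indels) / 100 bp (inversions and
#' translocations); candidates need 2 reads at MAPQ >= 20; merge windows
#' 300 bp (insertions) / 1000 bp (others) / 500 bp (inter-chromosomal
#' breakends) at 80% reciprocal overlap; read-edge fraction 0.1;
#' deletion-with-insertion window 30 bp; VAF floor 0.03; low-MAPQ region
#' rule 30% of reads below MAPQ 30 within 500 bp; population allele
#' frequency floor 0.1 with homozygosity at VAF 0.7; somatic matched-normal
#' depth floor 9; consensus flank 500 bp with remap distance 100 bp;
#' mechanism bands NAHR > 100 bp homology, alt-EJ 2-100 bp, NHEJ insertion
#' <= 9 bp, FoSTeS/MMBIR >= 10 bp; benchmark match distance 500 bp.
#' @export
svlr_config <- function(...) {
  cfg <- list(
    min_indel = 100L, min_clip = 500L, min_mapq = 20L,
    cluster_window_indel = 50L, cluster_window_other = 100L,
    candidate_min_support = 2L,
    merge_window_ins = 300L, merge_window_other = 1000L,
    merge_window_tra = 500L, merge_min_overlap = 0.8,
    edge_frac = 0.1, ins_near_bp = 30L,
    min_vaf = 0.03, mq_window = 500L, low_mq_thresh = 30L, low_mq_frac = 0.3,
    pop_min_af = 0.1, hom_vaf = 0.7,
    somatic_min_normal_depth = 9L,
    consensus_flank = 500L, remap_max_dist = 100L, min_remap_identity = 0.7,
    msa_match = 1L, msa_mismatch = -2L, msa_gap_open = -2L,
    msa_gap_ext = -1L, msa_band_frac = 0.2,
    nahr_min_homology = 100L, alt_ej_min_homology = 2L,
    fostes_min_insertion = 10L,
    flank_min_identity = 0.8,
    repeat_cover = 0.8, short_repeat_cover = 0.5, polya_min = 10L,
    bench_max_dist = 500L,
    seed = 1L
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = c("svlr_config", "list"))
}

#' Read / write a configuration as YAML
#' @param path YAML file.
#' @return [svlr_config()] list.
#' @export
read_config <- function(path) {
  do.call(svlr_config, yaml::read_yaml(path))
}

#' @rdname read_config
#' @param config configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Stable hash of a configuration (stamped into output headers)
#' @noRd
config_hash <- function(config) {
  txt <- paste(names(config), vapply(config, function(x)
    paste(format(x), collapse = ","), ""), sep = "=", collapse = ";")
  # small polynomial rolling hash; provenance only, not cryptographic
  h <- 5381
  for (ch in utf8ToInt(txt)) h <- (h * 33 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}
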