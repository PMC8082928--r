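#' Write SV calls as VCF 4.2 with symbolic ALT alleles
#'
#' Positions convert from the internal 0-based convention to 1-based VCF.
#' `INFO` carries `SVTYPE`, `END`, `SVLEN`, `SUPPORT`, `VAF` and, when an
#' inserted sequence is known, `SEQ`.  The header stamps the tool version,
#' configuration hash and seed so identical runs produce byte-identical
#' files.
#'
#' @param calls call table (`sv_type`, `chrom1`, `pos1`, `chrom2`, `pos2`,
#'   `length`, optional `support`, `vaf`, `filter`, `inserted_seq`, `id`).
#' @param path output path.
#' @param sq named contig lengths.
#' @param sample_id sample name stamped in the header.
#' @param config configuration whose hash and seed are stamped.
#' @return `path`, invisibly.
#' @export
write_sv_vcf <- function(calls, path, sq, sample_id = "S1",
                         config = svlr_config()) {
  cc <- as.data.frame(calls)
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=svlr %s", svlr_version()),
    sprintf("##svlr_config_hash=%s", config_hash(config)),
    sprintf("##svlr_seed=%s", config$seed),
    sprintf("##svlr_sample=%s", sample_id),
    sprintf("##contig=<ID=%s,length=%d>", names(sq), as.integer(sq)),
    "##ALT=<ID=DEL,Description=\"Deletion\">",
    "##ALT=<ID=INS,Description=\"Insertion\">",
    "##ALT=<ID=INV,Description=\"Inversion\">",
    "##ALT=<ID=DUP,Description=\"Tandem duplication (intra-chromosomal translocation)\">",
    "##ALT=<ID=TRA,Description=\"Inter-chromosomal translocation breakend\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End of the SV\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
    "##INFO=<ID=CHR2,Number=1,Type=String,Description=\"Mate chromosome for translocations\">",
    "##INFO=<ID=SUPPORT,Number=1,Type=Integer,Description=\"Supporting reads\">",
    "##INFO=<ID=VAF,Number=1,Type=Float,Description=\"Variant allele frequency\">",
    "##INFO=<ID=SEQ,Number=1,Type=String,Description=\"Inserted sequence\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  rows <- character()
  if (nrow(cc) > 0) {
    cc <- cc[order(match(cc$chrom1, names(sq)), cc$pos1), , drop = FALSE]
    for (i in seq_len(nrow(cc))) {
      r <- cc[i, ]
      svlen <- if (r$sv_type == "DEL") -r$length else r$length
      info <- sprintf("SVTYPE=%s;END=%d;SVLEN=%d", r$sv_type,
                      r$pos2 + 1L, svlen)
      if (r$sv_type == "TRA") info <- paste0(info, ";CHR2=", r$chrom2)
      if (!is.null(r$support) && !is.na(r$support)) {
        info <- paste0(info, ";SUPPORT=", r$support)
      }
      if (!is.null(cc$vaf) && !is.na(r$vaf)) {
        info <- paste0(info, sprintf(";VAF=%.4f", r$vaf))
      }
      if (!is.null(cc$inserted_seq) && !is.na(r$inserted_seq) &&
          nzchar(r$inserted_seq)) {
        info <- paste0(info, ";SEQ=", r$inserted_seq)
      }
      filt <- if (is.null(cc$filter) || is.na(r$filter) || !nzchar(r$filter)) {
        "PASS"
      } else gsub(",", ";", r$filter)
      id <- if (!is.null(cc$id) && !is.na(r$id)) r$id else sprintf("sv%d", i)
      rows <- c(rows, sprintf("%s\t%d\t%s\tN\t<%s>\t.\t%s\t%s",
                              r$chrom1, r$pos1 + 1L, id, r$sv_type, filt, info))
    }
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read an svlr-style SV VCF back into a call table
#'
#' Parses symbolic-ALT SV records (as written by [write_sv_vcf()] and
#' compatible callers) back to the internal 0-based representation.
#'
#' @param path VCF file.
#' @return call table with `id`, `sv_type`, `chrom1`, `pos1`, `chrom2`,
#'   `pos2`, `length`, `support`, `vaf`, `filter`, `inserted_seq`, `pass`.
#' @export
read_sv_vcf <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  empty <- data.frame(id = character(), sv_type = character(),
                      chrom1 = character(), pos1 = integer(),
                      chrom2 = character(), pos2 = integer(),
                      length = integer(), support = integer(),
                      vaf = numeric(), filter = character(),
                      inserted_seq = character(), pass = logical(),
                      stringsAsFactors = FALSE)
  if (!length(lines)) return(empty)
  f <- strsplit(lines, "\t")
  info_get <- function(info, key) {
    m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]+)"), info))[[1]]
    if (length(m) == 2) m[2] else NA_character_
  }
  out <- lapply(f, function(x) {
    info <- x[8]
    svtype <- info_get(info, "SVTYPE")
    if (is.na(svtype)) svtype <- gsub("[<>]", "", x[5])
    end <- suppressWarnings(as.integer(info_get(info, "END")))
    svlen <- suppressWarnings(as.integer(info_get(info, "SVLEN")))
    chr2 <- info_get(info, "CHR2")
    pos1 <- as.integer(x[2]) - 1L
    data.frame(
      id = x[3], sv_type = svtype, chrom1 = x[1], pos1 = pos1,
      chrom2 = if (!is.na(chr2)) chr2 else x[1],
      pos2 = if (!is.na(end)) end - 1L else pos1,
      length = abs(svlen),
      support = suppressWarnings(as.integer(info_get(info, "SUPPORT"))),
      vaf = suppressWarnings(as.numeric(info_get(info, "VAF"))),
      filter = if (x[7] %in% c("PASS", ".")) "" else gsub(";", ",", x[7]),
      inserted_seq = info_get(info, "SEQ"),
      pass = x[7] %in% c("PASS", "."), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write calls as BEDPE
#'
#' Ten-column BEDPE mirror of the VCF output (both breakpoints as 1-bp
#' intervals, score = supporting reads).
#' @param calls call table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedpe <- function(calls, path) {
  cc <- as.data.frame(calls)
  if (nrow(cc) == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%d\t%s\t%s\t+\t+",
                   cc$chrom1, cc$pos1, cc$pos1 + 1L, cc$chrom2, cc$pos2,
                   cc$pos2 + 1L,
                   if (!is.null(cc$id)) cc$id else sprintf("sv%d", seq_len(nrow(cc))),
                   if (!is.null(cc$support)) cc$support else ".")
  writeLines(lines, path)
  invisible(path)
}
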