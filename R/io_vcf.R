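# Minimal VCF 4.2 emission/ingestion for the package's own call records.
# Indels are written anchored (anchor base in both REF and ALT, left-aligned
# upstream of here); INFO round-trips pool id, depth, variant frequency and
# p-value losslessly.

VCF_INFO_HEADER <- c(
  '##INFO=<ID=POOL,Number=1,Type=String,Description="Pool identifier">',
  '##INFO=<ID=DP,Number=1,Type=Integer,Description="Filtered read depth">',
  '##INFO=<ID=AC,Number=1,Type=Integer,Description="Alt-supporting read count">',
  '##INFO=<ID=VF,Number=1,Type=Float,Description="Variant allele frequency">',
  '##INFO=<ID=PV,Number=1,Type=Float,Description="Binomial error-model p-value">',
  '##INFO=<ID=ADF,Number=1,Type=Integer,Description="Alt reads on forward strand">',
  '##INFO=<ID=ADR,Number=1,Type=Integer,Description="Alt reads on reverse strand">'
)

#' Write variant calls to VCF 4.2
#'
#' @param calls variant-call data frame (see [call_pool]); must be sorted
#'   by contig then position
#' @param path output file
#' @param reference_meta optional named vector of contig lengths for
#'   `##contig` header lines
#' @return `path`, invisibly
#' @export
write_vcf <- function(calls, path, reference_meta = NULL) {
  if (nrow(calls) > 0) {
    o <- order(calls$contig, calls$pos)
    if (!identical(o, seq_len(nrow(calls))))
      stopf("calls must be sorted by (contig, pos) before writing VCF")
  }
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##source=poolvar %s",
                   as.character(utils::packageVersion("poolvar"))),
           VCF_INFO_HEADER)
  if (!is.null(reference_meta))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(reference_meta), as.integer(reference_meta)))
  hdr <- c(hdr, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- character(0)
  if (nrow(calls) > 0) {
    info <- sprintf("POOL=%s;DP=%d;AC=%d;VF=%s;PV=%s;ADF=%d;ADR=%d",
                    calls$pool_id, calls$depth, calls$alt_count,
                    format(calls$var_freq, digits = 15, scientific = FALSE,
                           trim = TRUE),
                    format(calls$p_value, digits = 15, trim = TRUE),
                    calls$alt_fwd, calls$alt_rev)
    body <- paste(calls$contig, calls$pos, ".", calls$ref, calls$alt,
                  ".", "PASS", info, sep = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a poolvar VCF back into a call data frame
#'
#' Inverse of [write_vcf] for the fields that writer emits.
#'
#' @param path VCF file
#' @return variant-call data frame
#' @export
read_vcf <- function(path) {
  assert_that(file.exists(path), "file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || !grepl("^##fileformat=VCF", lines[1]))
    stopf("not a VCF file: %s", path)
  body <- lines[!grepl("^#", lines)]
  if (length(body) == 0) return(empty_calls())
  f <- strsplit(body, "\t", fixed = TRUE)
  info <- vapply(f, `[[`, "", 8)
  get_info <- function(key) {
    m <- regexpr(paste0("(^|;)", key, "=[^;]*"), info)
    if (any(m < 0)) stopf("VCF record missing INFO key %s", key)
    sub(paste0("^;?", key, "="), "", regmatches(info, m))
  }
  ref <- vapply(f, `[[`, "", 4)
  alt <- vapply(f, `[[`, "", 5)
  vtype <- ifelse(nchar(ref) == 1 & nchar(alt) == 1, "SNV",
                  ifelse(nchar(alt) > nchar(ref), "insertion", "deletion"))
  data.frame(
    contig = vapply(f, `[[`, "", 1),
    pos = as.integer(vapply(f, `[[`, "", 2)),
    ref = ref, alt = alt, vtype = vtype,
    depth = as.integer(get_info("DP")),
    alt_count = as.integer(get_info("AC")),
    var_freq = as.numeric(get_info("VF")),
    alt_fwd = as.integer(get_info("ADF")),
    alt_rev = as.integer(get_info("ADR")),
    p_value = as.numeric(get_info("PV")),
    pool_id = get_info("POOL"),
    stringsAsFactors = FALSE
  )
}

empty_calls <- function() {
  data.frame(contig = character(), pos = integer(), ref = character(),
             alt = character(), vtype = character(), depth = integer(),
             alt_count = integer(), var_freq = numeric(),
             alt_fwd = integer(), alt_rev = integer(), p_value = numeric(),
             pool_id = character(), stringsAsFactors = FALSE)
}

#' Read BLAST tabular (outfmt 6) similarity hits
#'
#' Standard 12 columns: qseqid, sseqid, pident, length, mismatch, gapopen,
#' qstart, qend, sstart, send, evalue, bitscore.  Coverages are computed
#' from the aligned span over each sequence's length, so `lengths` must
#' cover every id in the file.
#'
#' @param path tabular hits file
#' @param lengths named integer vector: sequence id -> sequence length
#' @return similarity-edge data frame (`query_id`, `subject_id`,
#'   `pct_identity`, `cov_query`, `cov_subject`, `evalue`, `score`)
#' @export
read_blast_tab <- function(path, lengths) {
  assert_that(file.exists(path), "file not found: %s", path)
  d <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                         col.names = c("qseqid", "sseqid", "pident", "length",
                                       "mismatch", "gapopen", "qstart", "qend",
                                       "sstart", "send", "evalue", "bitscore"))
  missing <- setdiff(unique(c(d$qseqid, d$sseqid)), names(lengths))
  if (length(missing) > 0)
    stopf("no sequence length for id(s): %s",
          paste(head(missing, 3), collapse = ", "))
  data.frame(
    query_id = d$qseqid, subject_id = d$sseqid, pct_identity = d$pident,
    cov_query = (abs(d$qend - d$qstart) + 1) / lengths[d$qseqid],
    cov_subject = (abs(d$send - d$sstart) + 1) / lengths[d$sseqid],
    evalue = d$evalue, score = d$bitscore,
    stringsAsFactors = FALSE, row.names = NULL
  )
}
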