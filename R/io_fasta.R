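# FASTA and GFF3 I/O.  Genomes are held as plain R lists (one per contig)
# because downstream code does heavy substr() work on the sequence string;
# Biostrings objects are built on demand where translation is needed.

#' Construct a genome sequence record
#'
#' @param contig_id contig name
#' @param sequence DNA string over A/C/G/T/N (uppercase)
#' @param topology "linear" or "circular"
#' @return an object of class `genome_seq`
#' @export
genome_seq <- function(contig_id, sequence, topology = "linear") {
  assert_that(nzchar(sequence), "sequence for %s is empty", contig_id)
  assert_that(topology %in% c("linear", "circular"),
              "topology must be linear or circular")
  bad <- regmatches(sequence, regexpr("[^ACGTN]", sequence))
  if (length(bad) > 0)
    stopf("contig %s contains non-ACGTN character '%s'", contig_id, bad)
  structure(list(contig_id = contig_id, sequence = sequence,
                 topology = topology),
            class = "genome_seq")
}

#' @export
length.genome_seq <- function(x) nchar(x$sequence)

#' @export
print.genome_seq <- function(x, ...) {
  cat(sprintf("<genome_seq> %s: %s bp (%s)\n", x$contig_id,
              format(nchar(x$sequence), big.mark = ","), x$topology))
  invisible(x)
}

#' Read a FASTA file into genome sequence records
#'
#' Sequences are uppercased, U is normalized to T, and any residual
#' non-ACGTN character is an error naming the offending character.
#'
#' @param path FASTA file
#' @param topology topology recorded on every contig
#' @return named list of [genome_seq] records in file order
#' @export
read_fasta <- function(path, topology = "linear") {
  assert_that(file.exists(path), "file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stopf("empty FASTA file: %s", path)
  hdr <- grepl("^>", lines)
  if (!hdr[1]) stopf("not FASTA: %s does not start with '>'", path)
  ids <- sub("^>\\s*(\\S+).*$", "\\1", lines[hdr])
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) stopf("duplicate FASTA id: %s", dup[1])
  grp <- cumsum(hdr)
  seqs <- vapply(seq_along(ids), function(i) {
    paste(lines[grp == i & !hdr], collapse = "")
  }, character(1))
  seqs <- chartr("u", "t", toupper(seqs))
  seqs <- chartr("U", "T", seqs)
  out <- Map(genome_seq, ids, seqs, topology)
  names(out) <- ids
  out
}

#' Write genome sequence records to FASTA
#'
#' @param genomes list of [genome_seq] (or a single record)
#' @param path output file
#' @param width line wrap width
#' @return `path`, invisibly
#' @export
write_fasta <- function(genomes, path, width = 70) {
  if (inherits(genomes, "genome_seq")) genomes <- list(genomes)
  con <- file(path, "w")
  on.exit(close(con))
  for (g in genomes) {
    writeLines(paste0(">", g$contig_id), con)
    n <- nchar(g$sequence)
    starts <- seq(1, n, by = width)
    writeLines(substring(g$sequence, starts, pmin(starts + width - 1, n)), con)
  }
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Only `gene` and `CDS` features carrying an `ID` attribute are consumed;
#' all other feature types are skipped with a message giving the count.
#' Coordinates stay 1-based inclusive as in the file.
#'
#' @param path GFF3 file
#' @return data frame with columns `gene_id`, `contig_id`, `start`, `end`,
#'   `strand`, `is_cds`, `category_label`, `product`
#' @export
read_gff3 <- function(path) {
  assert_that(file.exists(path), "file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  if (length(lines) == 0) {
    return(empty_gene_models())
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(f) < 9)
  if (length(bad) > 0) stopf("GFF3 line %d has fewer than 9 columns", bad[1])
  type <- vapply(f, `[[`, "", 3)
  keep <- type %in% c("gene", "CDS")
  n_skip <- sum(!keep)
  if (n_skip > 0)
    message(sprintf("read_gff3: skipped %d non-gene/CDS feature(s)", n_skip))
  f <- f[keep]
  type <- type[keep]
  attr_field <- vapply(f, `[[`, "", 9)
  get_attr <- function(key) {
    m <- regmatches(attr_field,
                    regexpr(paste0("(^|;)", key, "=[^;]*"), attr_field))
    val <- rep(NA_character_, length(attr_field))
    hit <- attr_field %in% m | grepl(paste0("(^|;)", key, "="), attr_field)
    val[hit] <- sub(paste0("^.*?(^|;)", key, "=([^;]*).*$"), "\\2",
                    attr_field[hit])
    val
  }
  ids <- get_attr("ID")
  has_id <- !is.na(ids)
  if (any(!has_id))
    message(sprintf("read_gff3: skipped %d feature(s) without ID", sum(!has_id)))
  out <- data.frame(
    gene_id = ids[has_id],
    contig_id = vapply(f, `[[`, "", 1)[has_id],
    start = as.integer(vapply(f, `[[`, "", 4)[has_id]),
    end = as.integer(vapply(f, `[[`, "", 5)[has_id]),
    strand = vapply(f, `[[`, "", 7)[has_id],
    is_cds = (type == "CDS")[has_id],
    category_label = get_attr("category")[has_id],
    product = get_attr("product")[has_id],
    stringsAsFactors = FALSE
  )
  assert_that(all(out$start <= out$end), "GFF3 feature with start > end")
  out
}

empty_gene_models <- function() {
  data.frame(gene_id = character(), contig_id = character(),
             start = integer(), end = integer(), strand = character(),
             is_cds = logical(), category_label = character(),
             product = character(), stringsAsFactors = FALSE)
}

#' Write gene models to GFF3
#'
#' @param models gene-model data frame as returned by [read_gff3]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_gff3 <- function(models, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(models) > 0) {
    attrs <- paste0("ID=", models$gene_id)
    has_cat <- !is.na(models$category_label)
    attrs[has_cat] <- paste0(attrs[has_cat], ";category=",
                             models$category_label[has_cat])
    has_prod <- !is.na(models$product)
    attrs[has_prod] <- paste0(attrs[has_prod], ";product=",
                              models$product[has_prod])
    writeLines(paste(models$contig_id, "poolvar",
                     ifelse(models$is_cds, "CDS", "gene"),
                     models$start, models$end, ".", models$strand,
                     ifelse(models$is_cds, "0", "."), attrs, sep = "\t"), con)
  }
  invisible(path)
}
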