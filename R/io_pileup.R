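# samtools text-pileup (6/7-column) reader and writer.
#
# The 6-column dialect is canonical: chrom, pos, ref, depth, read bases,
# base qualities; an optional 7th column carries per-read mapping qualities
# (one phred+33 char per read base, parallel to the quality string).
# Read-base decoding follows samtools semantics: . / , are the reference on
# the forward/reverse strand, ACGT/acgt alternate bases by strand, ^X marks
# a read start (X = mapq char, not a base), $ a read end, * a deleted-base
# placeholder, and +N[SEQ] / -N[SEQ] an insertion/deletion carried by the
# preceding read base.  Indel events have no quality char of their own.
#
# Depth accounting: depth is the number of retained allele-bearing bases
# (placeholders excluded).  An indel allele annotates a subset of those
# reads -- its carrier base still counts under its base allele -- so depth
# equals the sum of base-allele counts, and an indel's variant frequency is
# its carrier count over that depth (VarScan-style).

BYTE_DOT <- utf8ToInt(".")
BYTE_COMMA <- utf8ToInt(",")
BYTE_STAR <- utf8ToInt("*")
BYTE_CARET <- utf8ToInt("^")
BYTE_DOLLAR <- utf8ToInt("$")
BYTE_PLUS <- utf8ToInt("+")
BYTE_MINUS <- utf8ToInt("-")
BYTES_UPPER <- vapply(c("A", "C", "G", "T", "N"), utf8ToInt, 0L)
BYTES_LOWER <- vapply(c("a", "c", "g", "t", "n"), utf8ToInt, 0L)
BASES_UPPER <- c("A", "C", "G", "T", "N")

#' Read a samtools-style text pileup
#'
#' Bases with quality below `min_baseq` are excluded and the site depth
#' recomputed; when the optional 7th mapping-quality column is present,
#' reads with mapping quality below `min_mapq` are excluded as well.
#'
#' @param path pileup file (6 or 7 tab/space-separated columns)
#' @param min_baseq minimum phred base quality to retain a base
#' @param min_mapq minimum phred mapping quality (only applied when the
#'   7th column is present; upstream alignment filtering is assumed
#'   otherwise)
#' @return a `pileup` object: list with `sites` (one row per position:
#'   `contig`, `pos`, `ref_base`, `depth`, `mean_baseq`) and `alleles`
#'   (one row per observed allele per site: `site`, `allele`, `fwd`,
#'   `rev`; indel alleles are spelled `+SEQ` / `-SEQ`)
#' @export
read_pileup <- function(path, min_baseq = 20, min_mapq = 10) {
  assert_that(file.exists(path), "file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  decode_pileup_lines(lines, min_baseq, min_mapq)
}

decode_pileup_lines <- function(lines, min_baseq = 20, min_mapq = 10) {
  n <- length(lines)
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  bad <- which(nf < 6)
  if (length(bad) > 0)
    stopf("pileup line %d has %d column(s); expected 6 or 7", bad[1], nf[bad[1]])
  contig <- vapply(fields, `[[`, "", 1)
  pos <- as.integer(vapply(fields, `[[`, "", 2))
  ref <- toupper(vapply(fields, `[[`, "", 3))
  bases <- vapply(fields, `[[`, "", 5)
  quals <- vapply(fields, `[[`, "", 6)
  mapqs <- ifelse(nf >= 7, vapply(fields, function(f) {
    if (length(f) >= 7) f[[7]] else ""
  }, character(1)), NA_character_)

  depth <- integer(n)
  mbq <- numeric(n)
  al_allele <- vector("list", n)
  al_fwd <- vector("list", n)
  al_rev <- vector("list", n)
  for (i in seq_len(n)) {
    dec <- decode_pileup_line(bases[i], quals[i], mapqs[i], ref[i],
                              min_baseq, min_mapq, i)
    depth[i] <- dec$depth
    mbq[i] <- dec$mean_baseq
    al_allele[[i]] <- dec$allele
    al_fwd[[i]] <- dec$fwd
    al_rev[[i]] <- dec$rev
  }
  alleles <- data.frame(
    site = rep.int(seq_len(n), lengths(al_allele)),
    allele = unlist(al_allele, use.names = FALSE),
    fwd = unlist(al_fwd, use.names = FALSE),
    rev = unlist(al_rev, use.names = FALSE),
    stringsAsFactors = FALSE)
  if (nrow(alleles) == 0)
    alleles <- data.frame(site = integer(), allele = character(),
                          fwd = integer(), rev = integer())
  structure(list(
    sites = data.frame(contig = contig, pos = pos, ref_base = ref,
                       depth = depth, mean_baseq = mbq,
                       stringsAsFactors = FALSE),
    alleles = alleles
  ), class = "pileup")
}

# Decode one read-base string.  Returns base-allele counts, indel-allele
# counts, recomputed depth and mean retained base quality.
decode_pileup_line <- function(bases, quals, mapq_str, ref,
                               min_baseq, min_mapq, line_no) {
  b <- utf8ToInt(bases)
  q <- utf8ToInt(quals) - 33L
  m <- if (!is.na(mapq_str)) utf8ToInt(mapq_str) - 33L else NULL

  has_marker <- any(b == BYTE_CARET | b == BYTE_DOLLAR |
                    b == BYTE_PLUS | b == BYTE_MINUS)
  if (!has_marker) {
    if (length(b) != length(q))
      stopf("pileup line %d: %d base symbols but %d quality chars",
            line_no, length(b), length(q))
    sym <- b
    qual <- q
    mq <- m
    indels <- NULL
  } else {
    # state machine over the marker-bearing string
    nb <- length(b)
    sym <- integer(0); qual <- integer(0); mq <- integer(0)
    indels <- list()
    i <- 1L; qi <- 1L
    while (i <= nb) {
      ch <- b[i]
      if (ch == BYTE_CARET) {
        i <- i + 2L            # ^ plus the mapq char that follows it
      } else if (ch == BYTE_DOLLAR) {
        i <- i + 1L
      } else if (ch == BYTE_PLUS || ch == BYTE_MINUS) {
        # indel rides on the previous base symbol
        j <- i + 1L
        while (j <= nb && b[j] >= 48L && b[j] <= 57L) j <- j + 1L
        len <- as.integer(intToUtf8(b[(i + 1L):(j - 1L)]))
        if (j + len - 1L > nb)
          stopf("pileup line %d: truncated indel specification", line_no)
        seq_raw <- intToUtf8(b[j:(j + len - 1L)])
        if (length(sym) == 0)
          stopf("pileup line %d: indel with no carrier base", line_no)
        indels[[length(indels) + 1L]] <- list(
          kind = if (ch == BYTE_PLUS) "+" else "-",
          seq = toupper(seq_raw),
          fwd = seq_raw == toupper(seq_raw),
          carrier = length(sym))
        i <- j + len
      } else {
        if (qi > length(q))
          stopf("pileup line %d: more base symbols than quality chars", line_no)
        sym <- c(sym, ch)
        qual <- c(qual, q[qi])
        if (!is.null(m)) mq <- c(mq, m[qi])
        qi <- qi + 1L
        i <- i + 1L
      }
    }
    if (qi != length(q) + 1L)
      stopf("pileup line %d: %d base symbols but %d quality chars",
            line_no, qi - 1L, length(q))
  }

  placeholder <- sym == BYTE_STAR
  keep <- !placeholder & qual >= min_baseq
  if (!is.null(m) && length(mq) == length(sym)) keep <- keep & mq >= min_mapq

  ksym <- sym[keep]
  kq <- qual[keep]
  is_fwd <- ksym == BYTE_DOT | ksym %in% BYTES_UPPER
  base <- character(length(ksym))
  base[ksym == BYTE_DOT | ksym == BYTE_COMMA] <- ref
  for (k in seq_along(BYTES_UPPER)) {
    base[ksym == BYTES_UPPER[k]] <- BASES_UPPER[k]
    base[ksym == BYTES_LOWER[k]] <- BASES_UPPER[k]
  }
  ok <- nzchar(base)
  if (any(!ok))
    stopf("pileup line %d: unrecognized base symbol '%s'",
          line_no, intToUtf8(ksym[!ok][1]))

  ub <- unique(base)
  a_allele <- ub
  a_fwd <- vapply(ub, function(x) sum(is_fwd & base == x), 0L,
                  USE.NAMES = FALSE)
  a_rev <- vapply(ub, function(x) sum(!is_fwd & base == x), 0L,
                  USE.NAMES = FALSE)
  base_depth <- sum(a_fwd) + sum(a_rev)

  if (!is.null(indels) && length(indels) > 0) {
    keep_idx <- which(keep)
    carried <- vapply(indels, function(x) x$carrier %in% keep_idx, TRUE)
    indels <- indels[carried]
    if (length(indels) > 0) {
      key <- vapply(indels, function(x) paste0(x$kind, x$seq), "")
      fwd <- vapply(indels, function(x) x$fwd, TRUE)
      uk <- unique(key)
      a_allele <- c(a_allele, uk)
      a_fwd <- c(a_fwd, vapply(uk, function(x) sum(fwd & key == x), 0L,
                               USE.NAMES = FALSE))
      a_rev <- c(a_rev, vapply(uk, function(x) sum(!fwd & key == x), 0L,
                               USE.NAMES = FALSE))
    }
  }
  list(depth = base_depth,
       mean_baseq = if (length(kq) > 0) mean(kq) else 0,
       allele = a_allele, fwd = a_fwd, rev = a_rev)
}

#' Write a pileup object back to the samtools text dialect
#'
#' Round-trips through [read_pileup] losslessly for all typed fields when
#' qualities are uniform (per-base qualities are collapsed to the site
#' mean, the only quality statistic the object retains).
#'
#' @param pu `pileup` object
#' @param path output file
#' @return `path`, invisibly
#' @export
write_pileup <- function(pu, path) {
  s <- pu$sites
  al <- pu$alleles
  lines <- character(nrow(s))
  for (i in seq_len(nrow(s))) {
    a <- al[al$site == i, , drop = FALSE]
    is_ind <- grepl("^[+-]", a$allele)
    syms_f <- character(0); syms_r <- character(0)
    for (j in which(!is_ind)) {
      symf <- if (a$allele[j] == s$ref_base[i]) "." else a$allele[j]
      symr <- if (a$allele[j] == s$ref_base[i]) "," else tolower(a$allele[j])
      syms_f <- c(syms_f, rep.int(symf, a$fwd[j]))
      syms_r <- c(syms_r, rep.int(symr, a$rev[j]))
    }
    # indel events are attached to reference-base symbols (their carriers)
    for (j in which(is_ind)) {
      seq <- substr(a$allele[j], 2, nchar(a$allele[j]))
      spec_f <- paste0(substr(a$allele[j], 1, 1), nchar(seq), seq)
      spec_r <- paste0(substr(a$allele[j], 1, 1), nchar(seq), tolower(seq))
      tf <- which(syms_f == "." & !grepl("[+-]", syms_f))[seq_len(a$fwd[j])]
      tr <- which(syms_r == "," & !grepl("[+-]", syms_r))[seq_len(a$rev[j])]
      if (anyNA(tf) || anyNA(tr))
        stopf("site %d: indel %s has more carriers than reference reads",
              i, a$allele[j])
      syms_f[tf] <- paste0(syms_f[tf], spec_f)
      syms_r[tr] <- paste0(syms_r[tr], spec_r)
    }
    base_str <- paste0(paste(syms_f, collapse = ""),
                       paste(syms_r, collapse = ""))
    qch <- intToUtf8(rep.int(33L + as.integer(round(s$mean_baseq[i])),
                             s$depth[i]))
    lines[i] <- paste(s$contig[i], s$pos[i], s$ref_base[i], s$depth[i],
                      if (s$depth[i] > 0) base_str else "*",
                      if (s$depth[i] > 0) qch else "*", sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}
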