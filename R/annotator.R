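# Gene-based functional classification of variant calls.
#
# Every variant receives exactly one region class from the fixed
# vocabulary:
#   intergenic, upstream, downstream, upstream;downstream,
#   synonymous SNV, nonsynonymous SNV, frameshift insertion,
#   frameshift deletion, nonframeshift insertion, nonframeshift deletion,
#   stopgain SNV, stoploss SNV
# Precedence: CDS overlap wins; otherwise strand-aware 300-bp windows on
# the 5' (upstream) and 3' (downstream) sides of genes decide
# upstream/downstream/"upstream;downstream"; anything else is intergenic.
# Translation uses the bacterial genetic code (table 11).

REGION_CLASSES <- c("intergenic", "upstream", "downstream",
                    "upstream;downstream", "synonymous SNV",
                    "nonsynonymous SNV", "frameshift insertion",
                    "frameshift deletion", "nonframeshift insertion",
                    "nonframeshift deletion", "stopgain SNV", "stoploss SNV")

AA_CHANGING_CLASSES <- c("nonsynonymous SNV", "frameshift insertion",
                         "frameshift deletion", "nonframeshift insertion",
                         "nonframeshift deletion", "stopgain SNV",
                         "stoploss SNV")

NEAR_GENE_CLASSES <- c("upstream", "downstream", "upstream;downstream")

# most severe first, used when a variant hits several overlapping CDSs
SEVERITY_ORDER <- c("stopgain SNV", "stoploss SNV", "frameshift insertion",
                    "frameshift deletion", "nonsynonymous SNV",
                    "nonframeshift insertion", "nonframeshift deletion",
                    "synonymous SNV")

GENETIC_CODE_11 <- Biostrings::getGeneticCode("11")

translate_codon <- function(codon) {
  aa <- GENETIC_CODE_11[[codon]]
  if (is.null(aa)) NA_character_ else aa
}

#' Classify one variant against gene models
#'
#' @param call one-row variant-call data frame (anchored ref/alt)
#' @param genome the [genome_seq] the call lies on
#' @param models gene-model data frame
#' @param window_bp near-gene window size on each side (default 300)
#' @param ignore_strand treat both gene flanks as both upstream and
#'   downstream (windows without strand awareness)
#' @return one-row annotated data frame: the call columns plus
#'   `region_class`, `gene_ids` (semicolon-joined), `aa_change`,
#'   `cds_change`, `window_bp`
#' @export
classify_variant <- function(call, genome, models, window_bp = 300,
                             ignore_strand = FALSE) {
  assert_that(call$pos >= 1 && call$pos <= nchar(genome$sequence),
              "variant at %d lies outside contig %s", call$pos,
              genome$contig_id)
  m <- models[models$contig_id == call$contig & models$is_cds, , drop = FALSE]
  span <- variant_span(call)
  hit <- which(m$start <= span[2] & m$end >= span[1])
  if (length(hit) > 0) {
    anns <- lapply(hit, function(i)
      coding_effect(call, genome, m[i, , drop = FALSE]))
    cls <- vapply(anns, `[[`, "", "region_class")
    best <- which.min(match(cls, SEVERITY_ORDER))
    ann <- anns[[best]]
    ann$gene_ids <- paste(m$gene_id[hit], collapse = ";")
  } else {
    ann <- noncoding_class(call, m, window_bp, ignore_strand)
  }
  out <- call
  out$region_class <- ann$region_class
  out$gene_ids <- ann$gene_ids
  out$aa_change <- ann$aa_change %||% NA_character_
  out$cds_change <- ann$cds_change %||% NA_character_
  out$window_bp <- window_bp
  out
}

# genomic footprint of a call: SNV = pos; insertion = between pos, pos+1;
# deletion = deleted bases (anchor excluded so a pure upstream anchor does
# not drag a downstream-only deletion into a gene)
variant_span <- function(call) {
  if (call$vtype == "SNV") c(call$pos, call$pos)
  else if (call$vtype == "insertion") c(call$pos, call$pos + 1L)
  else c(call$pos + 1L, call$pos + nchar(call$ref) - 1L)
}

coding_effect <- function(call, genome, gene) {
  if (call$vtype == "SNV") {
    snv_effect(call, genome, gene)
  } else {
    indel_len <- abs(nchar(call$ref) - nchar(call$alt))
    shift <- indel_len %% 3L != 0L
    kind <- if (call$vtype == "insertion") "insertion" else "deletion"
    cls <- paste(if (shift) "frameshift" else "nonframeshift", kind)
    list(region_class = cls, gene_ids = gene$gene_id,
         aa_change = NULL, cds_change = cds_change_string(call, gene))
  }
}

snv_effect <- function(call, genome, gene) {
  if (gene$strand == "+") {
    cds_pos <- call$pos - gene$start + 1L
  } else {
    cds_pos <- gene$end - call$pos + 1L
  }
  codon_idx <- (cds_pos - 1L) %/% 3L       # 0-based codon index
  off <- (cds_pos - 1L) %% 3L              # 0-based within codon
  if (gene$strand == "+") {
    c_start <- gene$start + codon_idx * 3L
    codon <- substr(genome$sequence, c_start, c_start + 2L)
    ref_b <- call$ref; alt_b <- call$alt
  } else {
    c_end <- gene$end - codon_idx * 3L
    codon <- revcomp(substr(genome$sequence, c_end - 2L, c_end))
    ref_b <- comp_chars(call$ref); alt_b <- comp_chars(call$alt)
  }
  mut <- codon
  substr(mut, off + 1L, off + 1L) <- alt_b
  aa_ref <- translate_codon(codon)
  aa_alt <- translate_codon(mut)
  cls <- if (aa_ref == aa_alt) "synonymous SNV"
  else if (aa_ref != "*" && aa_alt == "*") "stopgain SNV"
  else if (aa_ref == "*" && aa_alt != "*") "stoploss SNV"
  else "nonsynonymous SNV"
  aa_change <- if (cls == "synonymous SNV") NA_character_ else
    paste0(aa_ref, codon_idx + 1L, aa_alt)
  list(region_class = cls, gene_ids = gene$gene_id,
       aa_change = aa_change, cds_change = NULL)
}

# CDS-coordinate indel notation, e.g. "261_262insCC" / "261_266del"
cds_change_string <- function(call, gene) {
  to_cds <- function(g) if (gene$strand == "+") g - gene$start + 1L
                        else gene$end - g + 1L
  if (call$vtype == "insertion") {
    ins <- substr(call$alt, 2, nchar(call$alt))
    if (gene$strand == "+") {
      lo <- to_cds(call$pos); hi <- lo + 1L
    } else {
      hi <- to_cds(call$pos); lo <- hi - 1L
      ins <- revcomp(ins)
    }
    sprintf("%d_%dins%s", lo, hi, ins)
  } else {
    g_lo <- call$pos + 1L
    g_hi <- call$pos + nchar(call$ref) - 1L
    cds <- sort(c(to_cds(g_lo), to_cds(g_hi)))
    if (cds[1] == cds[2]) sprintf("%ddel", cds[1])
    else sprintf("%d_%ddel", cds[1], cds[2])
  }
}

noncoding_class <- function(call, m, window_bp, ignore_strand) {
  pos <- call$pos
  gene_ids <- character(0)
  up <- FALSE; down <- FALSE
  up_d <- Inf; down_d <- Inf
  up_genes <- character(0); down_genes <- character(0)
  if (window_bp > 0 && nrow(m) > 0) {
    left_d <- m$start - pos    # gene lies right of the variant
    right_d <- pos - m$end     # gene lies left of the variant
    for (i in seq_len(nrow(m))) {
      if (left_d[i] >= 1 && left_d[i] <= window_bp) {
        side <- if (ignore_strand || m$strand[i] == "+") "up" else "down"
        if (side == "up") {
          up <- TRUE
          if (left_d[i] < up_d) up_d <- left_d[i]
          up_genes <- c(up_genes, m$gene_id[i])
        } else {
          down <- TRUE
          if (left_d[i] < down_d) down_d <- left_d[i]
          down_genes <- c(down_genes, m$gene_id[i])
        }
      }
      if (right_d[i] >= 1 && right_d[i] <= window_bp) {
        side <- if (ignore_strand || m$strand[i] == "+") "down" else "up"
        if (side == "down") {
          down <- TRUE
          if (right_d[i] < down_d) down_d <- right_d[i]
          down_genes <- c(down_genes, m$gene_id[i])
        } else {
          up <- TRUE
          if (right_d[i] < up_d) up_d <- right_d[i]
          up_genes <- c(up_genes, m$gene_id[i])
        }
      }
    }
  }
  if (up && down) {
    both <- union(up_genes, down_genes)
    if (length(both) == 1) {
      # same single gene on both sides: resolve by the smaller distance
      cls <- if (up_d <= down_d) "upstream" else "downstream"
      list(region_class = cls, gene_ids = both)
    } else {
      list(region_class = "upstream;downstream",
           gene_ids = paste(both, collapse = ";"))
    }
  } else if (up) {
    list(region_class = "upstream", gene_ids = paste(unique(up_genes),
                                                     collapse = ";"))
  } else if (down) {
    list(region_class = "downstream", gene_ids = paste(unique(down_genes),
                                                       collapse = ";"))
  } else {
    list(region_class = "intergenic", gene_ids = "")
  }
}

#' Annotate a set of variant calls
#'
#' Elementwise [classify_variant]; input order is preserved.
#'
#' @inheritParams classify_variant
#' @param calls variant-call data frame
#' @return annotated data frame, one row per call
#' @export
annotate_set <- function(calls, genome, models, window_bp = 300,
                         ignore_strand = FALSE) {
  if (nrow(calls) == 0) {
    out <- calls
    out$region_class <- character(0)
    out$gene_ids <- character(0)
    out$aa_change <- character(0)
    out$cds_change <- character(0)
    out$window_bp <- numeric(0)
    return(out)
  }
  rows <- lapply(seq_len(nrow(calls)), function(i)
    classify_variant(calls[i, , drop = FALSE], genome, models, window_bp,
                     ignore_strand))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
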