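# Mutagenized strain pools and pooled pileup simulation.
#
# Pools are simulated at the allele-count level: the study's inference
# starts at the pileup, so no read-level simulation (or aligner) is
# involved.  Each strain mutates independently; pooling equal amounts of
# gDNA from n strains makes a variant carried by k strains segregate at
# pooled frequency k/n exactly.

#' Mutagenize one pool of strains
#'
#' Draws each strain's SNVs and indels independently (Poisson counts at the
#' configured per-bp rates; a `transition_bias` fraction of SNVs are forced
#' G:C->A:T transitions), left-normalizes indels against the reference, and
#' aggregates per-variant carrier counts into a truth set.  Truth records
#' whose position falls inside another truth deletion's footprint are
#' dropped with a message (their pileup evidence would be ambiguous).
#' Deterministic given `seed`.
#'
#' @param genome a [genome_seq]
#' @param models gene models (unused by the draw itself; kept in the
#'   signature so callers can thread one object pair through the pipeline)
#' @param config a [simulation_config]
#' @param pool_id pool label, e.g. "L" or "H"
#' @param seed seed for this pool's draws (default derives from the config
#'   seed so the two pools differ)
#' @return list with `strain_variants` (one data frame per strain) and
#'   `truth` (data frame `contig`, `pos`, `ref`, `alt`, `vtype`, `pool_id`,
#'   `k`, `f` with `f = k / n_strains_per_pool`)
#' @export
mutagenize_pool <- function(genome, models, config, pool_id,
                            seed = config$seed + match(pool_id, c("L", "H"),
                                                       nomatch = 3L)) {
  L <- nchar(genome$sequence)
  chars <- strsplit(genome$sequence, "", fixed = TRUE)[[1]]
  gc_pos <- which(chars %in% c("G", "C"))
  with_seed(seed, {
    strains <- vector("list", config$n_strains_per_pool)
    for (s in seq_len(config$n_strains_per_pool)) {
      strains[[s]] <- draw_strain_variants(genome, chars, gc_pos, config)
    }
    truth <- aggregate_truth(strains, config, pool_id)
    list(strain_variants = strains, truth = truth)
  })
}

draw_strain_variants <- function(genome, chars, gc_pos, config) {
  L <- length(chars)
  out <- list()
  n_snv <- rpois(1, config$snv_rate * L)
  if (n_snv > 0) {
    is_trans <- runif(n_snv) < config$transition_bias
    pos <- integer(n_snv)
    alt <- character(n_snv)
    n_tr <- sum(is_trans)
    if (n_tr > 0 && length(gc_pos) > 0) {
      p <- sample(gc_pos, n_tr, replace = FALSE)
      pos[is_trans] <- p
      alt[is_trans] <- ifelse(chars[p] == "G", "A", "T")
    }
    n_ot <- sum(!is_trans)
    if (n_ot > 0) {
      p <- sample.int(L, n_ot)
      pos[!is_trans] <- p
      alt[!is_trans] <- vapply(chars[p], function(r) {
        sample(setdiff(c("A", "C", "G", "T"), r), 1)
      }, character(1))
    }
    out$snv <- data.frame(pos = pos, ref = chars[pos], alt = alt,
                          vtype = "SNV", stringsAsFactors = FALSE)
  }
  n_ind <- rpois(1, config$indel_rate * L)
  if (n_ind > 0) {
    lens <- sample(seq(config$indel_length_range[1],
                       config$indel_length_range[2]), n_ind, replace = TRUE)
    is_ins <- runif(n_ind) < 0.5
    recs <- vector("list", n_ind)
    for (i in seq_len(n_ind)) {
      if (is_ins[i]) {
        p <- sample(seq(2L, L - 1L), 1)
        ins <- paste(rand_bases(lens[i], config$gc_content), collapse = "")
        ref <- chars[p]
        alt <- paste0(ref, ins)
        vt <- "insertion"
      } else {
        p <- sample(seq(2L, L - lens[i] - 1L), 1)
        ref <- paste(chars[p:(p + lens[i])], collapse = "")
        alt <- chars[p]
        vt <- "deletion"
      }
      nv <- normalize_variant(genome$sequence, p, ref, alt)
      recs[[i]] <- data.frame(pos = nv$pos, ref = nv$ref, alt = nv$alt,
                              vtype = vt, stringsAsFactors = FALSE)
    }
    out$indel <- do.call(rbind, recs)
  }
  v <- if (length(out) > 0) do.call(rbind, out) else
    data.frame(pos = integer(), ref = character(), alt = character(),
               vtype = character(), stringsAsFactors = FALSE)
  v <- v[!duplicated(paste(v$pos, v$ref, v$alt)), , drop = FALSE]
  v$contig <- rep(genome$contig_id, nrow(v))
  rownames(v) <- NULL
  v[order(v$pos), c("contig", "pos", "ref", "alt", "vtype")]
}

#' Left-normalize a variant against the reference
#'
#' Standard VCF-style normalization: trim shared trailing bases (extending
#' to the left through the reference when an allele empties), then trim
#' shared leading bases.  SNVs pass through unchanged; indels end up
#' left-aligned with a single anchor base.
#'
#' @param refseq reference sequence string
#' @param pos 1-based position of the first base of `ref`
#' @param ref reference allele
#' @param alt alternate allele
#' @return list(pos, ref, alt)
#' @export
normalize_variant <- function(refseq, pos, ref, alt) {
  repeat {
    nr <- nchar(ref); na <- nchar(alt)
    if (nr > 0 && na > 0 &&
        substr(ref, nr, nr) == substr(alt, na, na) &&
        !(nr == 1 && na == 1)) {
      ref <- substr(ref, 1, nr - 1L)
      alt <- substr(alt, 1, na - 1L)
      if (nchar(ref) == 0 || nchar(alt) == 0) {
        if (pos == 1) {
          # cannot extend left of the contig; re-anchor on the right
          ext <- substr(refseq, pos + nchar(ref), pos + nchar(ref))
          ref <- paste0(ref, ext); alt <- paste0(alt, ext)
          break
        }
        pos <- pos - 1L
        b <- substr(refseq, pos, pos)
        ref <- paste0(b, ref); alt <- paste0(b, alt)
      }
    } else break
  }
  while (nchar(ref) >= 2 && nchar(alt) >= 2 &&
         substr(ref, 1, 1) == substr(alt, 1, 1)) {
    ref <- substr(ref, 2, nchar(ref))
    alt <- substr(alt, 2, nchar(alt))
    pos <- pos + 1L
  }
  list(pos = pos, ref = ref, alt = alt)
}

aggregate_truth <- function(strains, config, pool_id) {
  all <- do.call(rbind, strains)
  if (is.null(all) || nrow(all) == 0) {
    return(data.frame(contig = character(), pos = integer(),
                      ref = character(), alt = character(),
                      vtype = character(), pool_id = character(),
                      k = integer(), f = numeric(), stringsAsFactors = FALSE))
  }
  key <- paste(all$contig, all$pos, all$ref, all$alt, sep = ":")
  tab <- table(key)
  first <- !duplicated(key)
  truth <- all[first, , drop = FALSE]
  truth$k <- as.integer(tab[paste(truth$contig, truth$pos, truth$ref,
                                  truth$alt, sep = ":")])
  truth$pool_id <- pool_id
  truth$f <- truth$k / config$n_strains_per_pool
  truth <- truth[order(truth$pos), ]
  # drop truth whose position lies inside another truth deletion's footprint
  del <- truth[truth$vtype == "deletion", , drop = FALSE]
  if (nrow(del) > 0) {
    inside <- rep(FALSE, nrow(truth))
    for (i in seq_len(nrow(del))) {
      lo <- del$pos[i] + 1L
      hi <- del$pos[i] + nchar(del$ref[i]) - 1L
      inside <- inside | (truth$pos >= lo & truth$pos <= hi)
    }
    if (any(inside)) {
      message(sprintf(
        "mutagenize_pool: dropped %d truth record(s) inside deletion footprints",
        sum(inside)))
      truth <- truth[!inside, , drop = FALSE]
    }
  }
  rownames(truth) <- NULL
  truth[, c("contig", "pos", "ref", "alt", "vtype", "pool_id", "k", "f")]
}

#' Simulate a pooled pileup over the whole genome
#'
#' Per site, depth ~ Poisson(`mean_depth`); at a truth site with pooled
#' frequency f, alt-supporting reads ~ Binomial(depth, f(1-e) + (1-f)e/3)
#' with e = `base_error`; every other read is the reference except for
#' miscalls scattered uniformly over the remaining bases at rate e.  Each
#' read is assigned a strand with probability 1/2.  Base qualities are
#' uniform at the phred equivalent of `base_error` (Q40 when e = 0), so the
#' caller's error model sees the rate that generated the data.  Indel
#' truth records place `+SEQ`/`-SEQ` events on reference-carrying reads at
#' the anchor position.  Deterministic given `seed`.
#'
#' @param genome a [genome_seq]
#' @param truth truth set for one pool (from [mutagenize_pool])
#' @param config a [simulation_config]
#' @param seed seed for the sequencing draws
#' @return list with `lines` (character vector in the 6-column samtools
#'   pileup dialect) and `site_truth` (truth rows annotated with simulated
#'   depth and alt counts)
#' @export
simulate_pileup <- function(genome, truth, config,
                            seed = config$seed + 17L) {
  L <- nchar(genome$sequence)
  bad <- truth$pos < 1 | truth$pos > L
  assert_that(!any(bad), "truth key at position %s lies off the genome",
              paste(head(truth$pos[bad], 1)))
  chars <- strsplit(genome$sequence, "", fixed = TRUE)[[1]]
  e <- config$base_error
  qch <- intToUtf8(33L + if (e > 0) as.integer(round(-10 * log10(e))) else 40L)
  with_seed(seed, {
    depth <- rpois(L, config$mean_depth)
    nerr <- if (e > 0) rbinom(L, depth, e) else integer(L)
    # plain sites first, vectorized
    fwd <- rbinom(L, depth, 0.5)
    base_str <- paste0(strrep(".", fwd), strrep(",", depth - fwd))
    qual_str <- strrep(qch, depth)

    special <- unique(c(which(nerr > 0), truth$pos))
    truth_by_pos <- split(seq_len(nrow(truth)), truth$pos)
    site_truth <- truth
    site_truth$sim_depth <- depth[truth$pos]
    site_truth$sim_alt <- rep(0L, nrow(truth))

    for (p in special) {
      d <- depth[p]
      if (d == 0) next
      ref <- chars[p]
      rows <- truth_by_pos[[as.character(p)]]
      remaining <- d
      counts <- list()        # allele -> count (base alleles)
      indel_counts <- list()  # +SEQ/-SEQ -> count
      if (!is.null(rows)) {
        for (ri in rows) {
          f <- truth$f[ri]
          p_alt <- f * (1 - e) + (1 - f) * e / 3
          n_alt <- rbinom(1, d, p_alt)
          if (truth$vtype[ri] == "SNV") {
            a <- truth$alt[ri]
            n_alt <- min(n_alt, remaining)
            if (n_alt > 0) counts[[a]] <- (counts[[a]] %||% 0L) + n_alt
            remaining <- remaining - n_alt
          } else {
            spec <- indel_allele(truth$ref[ri], truth$alt[ri])
            if (n_alt > 0) indel_counts[[spec]] <- (indel_counts[[spec]] %||% 0L) + n_alt
          }
          site_truth$sim_alt[ri] <- n_alt
        }
      }
      if (e > 0 && remaining > 0) {
        n_e <- rbinom(1, remaining, e)
        if (n_e > 0) {
          others <- setdiff(c("A", "C", "G", "T"), c(ref, names(counts)))
          if (length(others) > 0) {
            eb <- sample(others, n_e, replace = TRUE)
            for (a in unique(eb))
              counts[[a]] <- (counts[[a]] %||% 0L) + sum(eb == a)
            remaining <- remaining - n_e
          }
        }
      }
      # indel carriers ride on reference reads; cap at the ref count
      total_ind <- if (length(indel_counts) > 0)
        sum(unlist(indel_counts)) else 0L
      if (total_ind > remaining) {
        scale_keep <- remaining
        nm <- names(indel_counts)
        kept <- integer(length(nm))
        for (i in seq_along(nm)) {
          kept[i] <- min(indel_counts[[i]], scale_keep)
          scale_keep <- scale_keep - kept[i]
        }
        indel_counts <- as.list(setNames(kept, nm))
      }
      parts <- character(0)
      qn <- remaining + sum(vapply(counts, identity, 0L))
      ref_f <- rbinom(1, remaining, 0.5)
      ref_syms_f <- rep.int(".", ref_f)
      ref_syms_r <- rep.int(",", remaining - ref_f)
      # attach indels to ref reads
      if (length(indel_counts) > 0) {
        ptr_f <- 1L; ptr_r <- 1L
        for (spec in names(indel_counts)) {
          kc <- indel_counts[[spec]]
          kf <- rbinom(1, kc, 0.5)
          kr <- kc - kf
          # shift carriers between strands if one side lacks ref reads
          if (kf > length(ref_syms_f) - ptr_f + 1L) {
            kr <- kr + (kf - (length(ref_syms_f) - ptr_f + 1L))
            kf <- length(ref_syms_f) - ptr_f + 1L
          }
          if (kr > length(ref_syms_r) - ptr_r + 1L) {
            kf2 <- min(kr - (length(ref_syms_r) - ptr_r + 1L),
                       length(ref_syms_f) - ptr_f + 1L - kf)
            kf <- kf + max(kf2, 0L)
            kr <- length(ref_syms_r) - ptr_r + 1L
          }
          seqs <- substr(spec, 2, nchar(spec))
          tag_f <- paste0(substr(spec, 1, 1), nchar(seqs), seqs)
          tag_r <- paste0(substr(spec, 1, 1), nchar(seqs), tolower(seqs))
          if (kf > 0) {
            idx <- ptr_f:(ptr_f + kf - 1L)
            ref_syms_f[idx] <- paste0(ref_syms_f[idx], tag_f)
            ptr_f <- ptr_f + kf
          }
          if (kr > 0) {
            idx <- ptr_r:(ptr_r + kr - 1L)
            ref_syms_r[idx] <- paste0(ref_syms_r[idx], tag_r)
            ptr_r <- ptr_r + kr
          }
        }
      }
      parts <- c(parts, ref_syms_f, ref_syms_r)
      for (a in names(counts)) {
        ca <- counts[[a]]
        cf <- rbinom(1, ca, 0.5)
        parts <- c(parts, rep.int(a, cf), rep.int(tolower(a), ca - cf))
      }
      base_str[p] <- paste(parts, collapse = "")
      qual_str[p] <- strrep(qch, qn)
      depth[p] <- qn
    }
    zero <- depth == 0
    base_str[zero] <- "*"
    qual_str[zero] <- "*"
    lines <- paste(genome$contig_id, seq_len(L), chars, depth,
                   base_str, qual_str, sep = "\t")
    list(lines = lines, site_truth = site_truth)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# anchored (ref, alt) pair -> pileup indel spelling (+SEQ / -SEQ)
indel_allele <- function(ref, alt) {
  if (nchar(alt) > nchar(ref)) paste0("+", substr(alt, 2, nchar(alt)))
  else paste0("-", substr(ref, 2, nchar(ref)))
}

#' Write a truth set as TSV
#' @param truth truth data frame
#' @param path output file
#' @return `path`, invisibly
#' @export
write_truth_tsv <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a truth-set TSV written by [write_truth_tsv]
#' @param path TSV file
#' @return truth data frame
#' @export
read_truth_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE,
                    colClasses = c(contig = "character", ref = "character",
                                   alt = "character", pool_id = "character"))
}
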