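# Synthetic multi-species proteomes with planted pan-genome structure.
#
# S species descend from a common ancestor proteome; each ancestral
# protein is retained or lost per species, retained copies diverge by
# i.i.d. residue substitution, and each species gains novel random
# proteins.  The realized presence/absence pattern defines the planted
# core/dispensable/specific labels that clustering should recover.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
          "M", "F", "P", "S", "T", "W", "Y", "V")

rand_protein <- function(len) paste(sample(AA20, len, replace = TRUE),
                                    collapse = "")

mutate_protein <- function(seq, rate) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(ch)) < rate)
  if (length(hit) > 0)
    ch[hit] <- vapply(ch[hit], function(a) sample(setdiff(AA20, a), 1), "")
  paste(ch, collapse = "")
}

#' Simulate proteomes of related species with known family structure
#'
#' @param n_species number of species in the panel
#' @param n_ancestral ancestral protein families
#' @param protein_length_range min/max protein length (aa)
#' @param divergence per-residue substitution probability per species
#'   (orthologs stay well above 50% identity at the default)
#' @param loss_prob probability a species loses an ancestral family
#' @param gain_per_species novel (species-specific) proteins per species
#' @param chrom_length nominal chromosome length for placement (bp)
#' @param seed integer seed
#' @return list with `proteins` (protein_id, species_id, sequence,
#'   chrom_pos, chrom_length, truth_family) and `truth_classes`
#'   (truth_family -> planted core/dispensable/specific label from the
#'   realized presence pattern)
#' @export
simulate_proteomes <- function(n_species = 5, n_ancestral = 60,
                               protein_length_range = c(80, 300),
                               divergence = 0.05, loss_prob = 0.10,
                               gain_per_species = 15,
                               chrom_length = 8e6, seed = 1) {
  with_seed(seed, {
    lens <- sample(seq(protein_length_range[1], protein_length_range[2]),
                   n_ancestral, replace = TRUE)
    ancestors <- vapply(lens, rand_protein, "")
    species <- sprintf("sp%02d", seq_len(n_species))
    present <- matrix(runif(n_ancestral * n_species) >= loss_prob,
                      nrow = n_ancestral)
    rows <- list()
    for (s in seq_len(n_species)) {
      kept <- which(present[, s])
      for (i in kept) {
        rows[[length(rows) + 1L]] <- data.frame(
          protein_id = sprintf("%s_anc%03d", species[s], i),
          species_id = species[s],
          sequence = mutate_protein(ancestors[i], divergence),
          truth_family = sprintf("anc%03d", i), stringsAsFactors = FALSE)
      }
      for (j in seq_len(gain_per_species)) {
        rows[[length(rows) + 1L]] <- data.frame(
          protein_id = sprintf("%s_new%03d", species[s], j),
          species_id = species[s],
          sequence = rand_protein(sample(seq(protein_length_range[1],
                                             protein_length_range[2]), 1)),
          truth_family = sprintf("%s_new%03d", species[s], j),
          stringsAsFactors = FALSE)
      }
    }
    proteins <- do.call(rbind, rows)
    # novel genes concentrate at the chromosome arms, ancestral genes in
    # the central core region (mirrors the biology the density plot shows)
    n <- nrow(proteins)
    is_novel <- grepl("_new", proteins$protein_id)
    pos <- numeric(n)
    pos[!is_novel] <- runif(sum(!is_novel), 0.2, 0.8)
    arm <- runif(sum(is_novel)) < 0.5
    pos[is_novel] <- ifelse(arm, runif(sum(is_novel), 0, 0.2),
                            runif(sum(is_novel), 0.8, 1))
    proteins$chrom_pos <- pmax(1, round(pos * chrom_length))
    proteins$chrom_length <- chrom_length
    presence_count <- rowSums(present)
    anc_class <- ifelse(presence_count == n_species, "core",
                        ifelse(presence_count == 1L, "specific",
                               ifelse(presence_count == 0L, "lost",
                                      "dispensable")))
    truth_classes <- c(
      setNames(anc_class, sprintf("anc%03d", seq_len(n_ancestral))),
      setNames(rep("specific", sum(is_novel)),
               proteins$truth_family[is_novel]))
    truth_classes <- truth_classes[truth_classes != "lost"]
    list(proteins = proteins, truth_classes = truth_classes)
  })
}
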