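test_that("identical and truncated sequences give the expected similarity", {
  a <- strrep("MKVLAWTTFREGHILKMNPQ", 5)   # 100 aa
  s <- pairwise_similarity(a, a)
  expect_equal(s$pct_identity, 100.0)
  expect_equal(s$cov_query, 1.0)
  expect_equal(s$cov_subject, 1.0)

  half <- substr(a, 1, 50)
  s <- pairwise_similarity(a, half)
  expect_equal(s$cov_subject, 1.0)
  expect_equal(s$cov_query, 0.5, tolerance = 0.02)
  expect_error(pairwise_similarity("", a), "empty")
})

test_that("alignment score and identity match an exhaustive DP oracle", {
  set.seed(51)
  AA <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
          "M", "F", "P", "S", "T", "W", "Y", "V")
  for (r in 1:12) {
    x <- paste(sample(AA, 30, replace = TRUE), collapse = "")
    ych <- strsplit(x, "")[[1]]
    pos <- sample(30, sample(2:5, 1))
    ych[pos] <- sample(AA, length(pos), replace = TRUE)
    y <- paste(ych, collapse = "")
    got <- pairwise_similarity(x, y)
    want <- sw_oracle(x, y)
    expect_equal(got$score, want$score)
    expect_equal(got$pct_identity, want$identity, tolerance = 1e-9)
  }
})

fam_of <- function(membership, pid) {
  membership$family_id[membership$protein_id == pid]
}

test_that("clustering forms single-linkage components with stable ids", {
  prot <- data.frame(protein_id = c("pA", "pB", "pC", "pD"),
                     species_id = c("s1", "s1", "s2", "s2"),
                     stringsAsFactors = FALSE)
  edge <- function(q, s, id = 80, cq = 0.9, cs = 0.9, e = 1e-20)
    data.frame(query_id = q, subject_id = s, pct_identity = id,
               cov_query = cq, cov_subject = cs, evalue = e, score = 100,
               stringsAsFactors = FALSE)

  # no qualifying edges: all singletons
  fam <- cluster_families(prot, edge("pA", "pB", id = 30))
  expect_equal(length(unique(fam$family_id)), 4L)

  # chain A-B, B-C: one family by transitivity, labelled by smallest member
  fam <- cluster_families(prot, rbind(edge("pA", "pB"), edge("pB", "pC")))
  expect_equal(fam_of(fam, "pA"), "pA")
  expect_equal(fam_of(fam, "pC"), "pA")
  expect_equal(fam_of(fam, "pD"), "pD")

  # identity and coverage thresholds are exclusive
  fam <- cluster_families(prot, edge("pA", "pB", id = 50))
  expect_equal(length(unique(fam$family_id)), 4L)
  fam <- cluster_families(prot, edge("pA", "pB", cq = 0.70))
  expect_equal(length(unique(fam$family_id)), 4L)
  # E-value gate applies to ingested hits
  fam <- cluster_families(prot, edge("pA", "pB", e = 1e-3))
  expect_equal(length(unique(fam$family_id)), 4L)
  # unknown protein in an edge is an error
  expect_error(cluster_families(prot, edge("pA", "pZ")), "pZ")
})

test_that("components equal a union-find oracle on random graphs", {
  set.seed(52)
  for (r in 1:30) {
    n <- sample(10:50, 1)
    ids <- sprintf("p%03d", seq_len(n))
    prot <- data.frame(protein_id = ids,
                       species_id = sample(c("s1", "s2", "s3"), n, TRUE),
                       stringsAsFactors = FALSE)
    ne <- sample(5:120, 1)
    from <- sample(ids, ne, replace = TRUE)
    to <- sample(ids, ne, replace = TRUE)
    edges <- data.frame(query_id = from, subject_id = to,
                        pct_identity = 90, cov_query = 0.9,
                        cov_subject = 0.9, evalue = 1e-30, score = 100,
                        stringsAsFactors = FALSE)
    fam <- cluster_families(prot, edges)
    keep <- from != to
    want <- union_find_oracle(ids, from[keep], to[keep])
    expect_identical(setNames(fam$family_id, fam$protein_id), want)
  }
})

# membership table with prescribed per-species core/specific counts
make_membership <- function(n_core_fam, core_genes, specific_genes) {
  species <- names(core_genes)
  rows <- list()
  for (sp in species) {
    base <- sprintf("fam%05d", seq_len(n_core_fam))
    extra <- core_genes[[sp]] - n_core_fam
    fams <- c(base, sample(base, extra, replace = TRUE))
    rows[[sp]] <- data.frame(
      protein_id = sprintf("%s_c%05d", sp, seq_along(fams)),
      species_id = sp, family_id = fams, stringsAsFactors = FALSE)
    if (specific_genes[[sp]] > 0) {
      rows[[paste0(sp, "_s")]] <- data.frame(
        protein_id = sprintf("%s_s%05d", sp, seq_len(specific_genes[[sp]])),
        species_id = sp,
        family_id = sprintf("%s_sf%05d", sp, seq_len(specific_genes[[sp]])),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

test_that("expansion rates and specific/core ratios match printed figures", {
  set.seed(53)
  # two-species panel shaped like the published extremes: one species with
  # 3105 core genes over 1980 core families, the other with 3985 core
  # genes and 2172 specific genes
  memb <- make_membership(1980,
                          core_genes = c(SCN = 3105, SAZ = 3985),
                          specific_genes = c(SCN = 0, SAZ = 2172))
  meta <- data.frame(species_id = c("SCN", "SAZ"))
  s <- classify_and_summarize(memb, meta)
  scn <- s$per_species[s$per_species$species_id == "SCN", ]
  saz <- s$per_species[s$per_species$species_id == "SAZ", ]
  expect_equal(scn$expansion_rate, 1.56)          # 3105 / 1980
  expect_equal(saz$specific_core_ratio, 0.545)    # 2172 / 3985
  expect_equal(sum(s$families$class == "core"), 1980)
})

test_that("degenerate panels classify cleanly", {
  # every species one protein, all one family: a single core family
  memb <- data.frame(protein_id = c("a", "b", "c"),
                     species_id = c("s1", "s2", "s3"),
                     family_id = "fam1", stringsAsFactors = FALSE)
  s <- classify_and_summarize(memb, data.frame(species_id = c("s1", "s2", "s3")))
  expect_equal(s$families$class, "core")
  expect_true(all(s$per_species$expansion_rate == 1.00))
  expect_true(all(s$per_species$specific_genes == 0))
  # a single species has no defined classes
  expect_error(classify_and_summarize(memb[1, ],
                                      data.frame(species_id = "s1")),
               "two species")
})

test_that("counts lying on a line give a perfect genome-size correlation", {
  set.seed(54)
  memb <- make_membership(10, core_genes = c(s1 = 10, s2 = 20, s3 = 30),
                          specific_genes = c(s1 = 0, s2 = 0, s3 = 0))
  meta <- data.frame(species_id = c("s1", "s2", "s3"),
                     genome_size = c(8e6, 9e6, 1e7))
  s <- classify_and_summarize(memb, meta)
  core_row <- s$correlations[s$correlations$count == "core_genes", ]
  expect_equal(core_row$r_squared, 1.0, tolerance = 1e-12)
})

test_that("density profiles bin correctly and sum to one per class", {
  set.seed(55)
  memb <- data.frame(protein_id = sprintf("p%02d", 1:10),
                     species_id = rep(c("s1", "s2"), each = 5),
                     family_id = c(rep("fam1", 5), rep("fam1", 2),
                                   sprintf("sf%d", 1:3)),
                     stringsAsFactors = FALSE)
  prot <- data.frame(protein_id = memb$protein_id,
                     species_id = memb$species_id,
                     chrom_pos = c(seq(1e5, 9e5, length.out = 5),
                                   2e5, 3e5, 1e5, 2e5, 3e5),
                     chrom_length = 2e6, stringsAsFactors = FALSE)
  meta <- data.frame(species_id = c("s1", "s2"))
  d <- density_profile(prot, memb, meta, bin_bp = 4e5)
  sums <- tapply(d$proportion, paste(d$species_id, d$class), sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  # all of s2's specific genes lie in the first bin
  s2s <- d[d$species_id == "s2" & d$class == "specific", ]
  expect_equal(s2s$proportion[1], 1.0)
  expect_true(all(s2s$proportion[-1] == 0))

  # chromosome shorter than the bin: a single full bin
  prot1 <- data.frame(protein_id = c("p01", "p06"),
                      species_id = c("s1", "s2"),
                      chrom_pos = c(100, 150), chrom_length = 1000,
                      stringsAsFactors = FALSE)
  memb1 <- memb[memb$protein_id %in% c("p01", "p06"), ]
  d1 <- density_profile(prot1, memb1, meta, bin_bp = 4e5)
  expect_true(all(d1$proportion == 1.0))
  expect_true(all(d1$bin == 1))

  # missing positions are an error naming the protein
  prot_bad <- prot; prot_bad$chrom_pos[2] <- NA
  expect_error(density_profile(prot_bad, memb, meta), "p02")
})

test_that("planted core/specific structure is recovered from sequences", {
  sim <- simulate_proteomes(n_species = 3, n_ancestral = 25,
                            gain_per_species = 6, divergence = 0.05,
                            loss_prob = 0.12, seed = 56)
  edges <- all_vs_all_similarity(sim$proteins)
  memb <- cluster_families(sim$proteins, edges)
  s <- classify_and_summarize(memb,
                              data.frame(species_id =
                                           unique(sim$proteins$species_id)))
  called <- s$families$class[match(memb$family_id, s$families$family_id)]
  truth <- unname(sim$truth_classes[sim$proteins$truth_family])
  expect_gte(mean(called == truth), 0.95)
})
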