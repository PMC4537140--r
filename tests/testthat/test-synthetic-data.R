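test_that("invalid simulation configurations are rejected", {
  expect_error(sim_config(n_genes = 100, n_background = 50),
               "n_genes must not exceed n_background")
  expect_error(sim_config(detection_prob = 1.5), "\\[0, 1\\]")
  expect_error(sim_config(noise_rate = -0.1), "\\[0, 1\\]")
  expect_error(sim_config(synaptic_overlap_odds = 0), "positive")
  expect_error(sim_config(planted_clusters = list(1L)), ">=2 distinct")
  expect_error(sim_config(n_studies = 4, planted_clusters = list(c(1L, 9L))),
               "study indices")
  expect_error(sim_config(planted_terms = list(c(term_size = 0,
                                                 target_fe = 2))),
               "term_size")
})

test_that("identical seed and config reproduce byte-identical outputs", {
  cfg <- small_cfg(seed = 33L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_all(cfg, d1)
  generate_all(cfg, d2)
  rel <- list.files(d1, recursive = TRUE)
  expect_setequal(rel, list.files(d2, recursive = TRUE))
  for (f in rel) {
    expect_identical(readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))),
                     label = paste("bytes of", f))
  }
})

test_that("mapping database construction guarantees resolvability", {
  sim <- clean_sim()
  db <- sim$db$db
  # one reviewed entry per species per gene
  rev <- db[db$reviewed, ]
  expect_identical(nrow(rev), 3L * sim$cfg$n_background)
  expect_false(anyDuplicated(db$entry_name) > 0)
  # reviewed and unreviewed duplicates share the symbol, flags distinguish
  unrev <- db[!db$reviewed, ]
  expect_true(all(unrev$gene_symbol %in% rev$gene_symbol))
  # ground truth covers every database identifier and resolves uniquely
  truth <- sim$db$truth
  per_id <- tapply(truth$gene_symbol, truth$identifier,
                   function(g) length(unique(g)))
  expect_true(all(per_id == 1L))
})

test_that("ground-truth closure: every emitted identifier is in the truth map", {
  sim <- noisy_sim()
  truth_ids <- sim$db$truth$identifier
  for (tab in sim$st$studies) {
    rows <- sim$st$rows[sim$st$rows$study_id == attr(tab, "study_id"), ]
    clean <- rows$corruption %in% c("none")
    ids <- sub("\\.[0-9]+$", "", tab$identifier[clean])
    expect_true(all(ids %in% truth_ids),
                label = paste("closure of", attr(tab, "study_id")))
  }
})

test_that("exhaustive noise-free detection yields identical study gene sets", {
  cfg <- sim_config(seed = 5L, n_genes = 40L, n_background = 120L,
                    n_studies = 2L, detection_prob = 1, noise_rate = 0,
                    planted_clusters = list(),
                    planted_terms = list(), n_decoy_terms = 4L,
                    synaptic_list_size = 30L)
  db <- generate_mapping_db(cfg)
  st <- generate_study_tables(cfg, db)
  expect_setequal(st$gene_sets[[1L]], st$gene_sets[[2L]])
  expect_setequal(st$gene_sets[[1L]], db$latent_genes)
})

test_that("planted-cluster studies have the smallest pairwise distance", {
  sim <- noisy_sim()  # cluster planted on studies 2 and 3
  sets <- sim$st$gene_sets
  S <- length(sets)
  d <- matrix(0, S, S)
  for (i in seq_len(S)) {
    for (j in seq_len(S)) {
      d[i, j] <- set_distance_oracle(sets[[i]], sets[[j]])
    }
  }
  off <- d[upper.tri(d)]
  expect_identical(d[2L, 3L], min(off))
  expect_identical(sets[[2L]], sets[[3L]])  # shared Bernoulli profile
})

test_that("decoy annotation terms have mean fold enrichment near 1", {
  bg <- sprintf("B%04d", seq_len(400L))
  comp <- bg[seq_len(80L)]
  fes <- vapply(seq_len(200L), function(i) {
    cfg <- sim_config(seed = 1000L + i, n_genes = 80L, n_background = 400L,
                      n_studies = 3L, planted_clusters = list(),
                      planted_terms = list(), n_decoy_terms = 1L,
                      synaptic_list_size = 30L)
    ann <- generate_annotation_sets(cfg, bg, comp)
    k <- length(intersect(ann$sets[[1L]], comp))
    fold_enrichment(k, length(ann$sets[[1L]]), length(comp), length(bg))
  }, 0)
  se <- sd(fes) / sqrt(length(fes))
  expect_lt(abs(mean(fes) - 1), 3 * se + 1e-12)
})

test_that("unattainable planted fold enrichments raise configuration errors", {
  bg <- sprintf("B%04d", seq_len(100L))
  comp <- bg[seq_len(50L)]
  cfg <- sim_config(seed = 2L, n_genes = 50L, n_background = 100L,
                    n_studies = 3L, planted_clusters = list(),
                    planted_terms = list(c(term_size = 10, target_fe = 6)),
                    n_decoy_terms = 0L, synaptic_list_size = 20L)
  # FE * n / N = 6 * 50 / 100 = 3 > 1: no sampling scheme can reach it
  expect_error(generate_annotation_sets(cfg, bg, comp), "unattainable")
})

test_that("synaptic list generation respects the planted overlap", {
  sim <- noisy_sim()
  bg <- unique(sim$db$db$gene_symbol)
  syn <- generate_synaptic_list(sim$cfg, bg, sim$db$latent_genes)
  expect_length(syn$genes, sim$cfg$synaptic_list_size)
  expect_true(all(syn$genes %in% bg))
  expect_identical(length(intersect(syn$genes, sim$db$latent_genes)),
                   as.integer(syn$truth$overlap))
})

test_that("sequence generator plants motifs consistent with its truth table", {
  mot <- generate_sequences_and_mutations(small_cfg(seed = 7L))
  expect_length(mot$sequences, 6L)
  # every truth class is present
  expect_setequal(unique(mot$truth$class),
                  c("known_palmitoylated", "predicted", "di_cys_adjacent",
                    "cys_rich_region", "no_evidence", "not_cysteine",
                    "ref_mismatch"))
  # reference residues agree with the sequence except for planted mismatches
  for (i in seq_len(nrow(mot$mutations))) {
    p <- parse_substitution(mot$mutations$substitution[i])
    actual <- substr(mot$sequences[[mot$mutations$gene[i]]], p$position,
                     p$position)
    if (mot$truth$class[i] == "ref_mismatch") {
      expect_false(actual == p$ref)
    } else {
      expect_identical(actual, p$ref)
    }
  }
  # evidence positions are cysteines within the sequences
  for (i in seq_len(nrow(mot$evidence))) {
    s <- mot$sequences[[mot$evidence$gene[i]]]
    expect_identical(substr(s, mot$evidence$position[i],
                            mot$evidence$position[i]), "C")
  }
})
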