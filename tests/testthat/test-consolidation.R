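test_that("mapping database loader enforces the schema", {
  db <- tiny_db()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_mapping_db(db, path)
  loaded <- load_mapping_database(path)
  expect_identical(nrow(loaded), nrow(db))
  expect_identical(loaded$entry_name, db$entry_name)
  expect_identical(loaded$reviewed, db$reviewed)

  dup <- rbind(as.data.frame(db), as.data.frame(db)[1L, ])
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write.table(dup, path2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_mapping_database(path2), "integrity error.*duplicated")

  path3 <- withr::local_tempfile(fileext = ".tsv")
  file.create(path3)
  expect_error(load_mapping_database(path3), "format error")

  path4 <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(entry_name = "X_HUMAN", gene_symbol = "X"), path4,
              sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_mapping_database(path4), "missing columns")
})

test_that("namespace detection follows the pattern-majority rule", {
  expect_identical(as.character(detect_namespace(c("SODC_HUMAN",
                                                   "NPC1_HUMAN"))),
                   "uniprot_entry_name")
  expect_identical(as.character(detect_namespace("ENSG00000000003")),
                   "ensembl_gene")
  expect_identical(as.character(detect_namespace(c("NP_001234.2",
                                                   "NP_000445"))),
                   "refseq_accession")
  expect_identical(as.character(detect_namespace(c("123456", "99999"))),
                   "ncbi_gi")
  expect_identical(as.character(detect_namespace(c("SOD1", "Npc1", "LGI1"))),
                   "gene_symbol")
  expect_error(detect_namespace(c("12345", "SOD1")), "ambiguity error")
  expect_error(detect_namespace(character(0)), "empty")
})

test_that("identifier resolution honours reviewed priority and fallbacks", {
  db <- tiny_db()
  idx <- db_index(db)
  # case-insensitive symbol + reviewed priority over the TrEMBL duplicate
  r <- resolve_identifier("sod1", "gene_symbol", db, species_hint = "human",
                          index = idx)
  expect_identical(r$entry_name, "SODC_HUMAN")
  expect_true(r$reviewed)
  # symbol present only as an unreviewed entry still resolves
  r2 <- resolve_identifier("ABCX9", "gene_symbol", db, index = idx)
  expect_identical(r2$entry_name, "Q00002_HUMAN")
  expect_false(r2$reviewed)
  # synonym and full-name routes
  expect_identical(resolve_identifier("IPOA", "gene_symbol", db,
                                      index = idx)$route, "synonym")
  rf <- resolve_identifier("NPC intracellular cholesterol transporter 1",
                           "gene_symbol", db, index = idx)
  expect_identical(rf$route, "full_name")
  expect_identical(rf$gene_symbol, "NPC1")
  # cross-reference routes, with RefSeq version stripping
  expect_identical(resolve_identifier("ENSG00000142168", "ensembl_gene", db,
                                      index = idx)$entry_name, "SODC_HUMAN")
  expect_identical(resolve_identifier("NP_000445.3", "refseq_accession", db,
                                      index = idx)$entry_name, "SODC_HUMAN")
  expect_identical(resolve_identifier("20892", "ncbi_gi", db,
                                      index = idx)$entry_name, "SODC_MOUSE")
  # miss is a return state, not an error
  expect_null(resolve_identifier("NOSUCH", "gene_symbol", db, index = idx))
  # ambiguous multi-species symbol without a hint: deterministic tie-break
  expect_warning(
    amb <- resolve_identifier("Sod1", "gene_symbol", db, index = idx),
    "ambiguous identifier")
  expect_identical(amb$entry_name, "SODC_HUMAN")  # lexicographic minimum
})

test_that("match_study computes the match rate over matched and unmatched", {
  db <- tiny_db()
  tab <- data.frame(
    identifier = c("SOD1", "sod1", "NPC1", "npc1", "ABCX9", "IPOA", "SOD",
                   "NPC1", "SOD1", "ZZZNOPE"),
    stringsAsFactors = FALSE)
  attr(tab, "namespace") <- "gene_symbol"
  attr(tab, "species") <- "human"
  res <- suppressMessages(match_study(tab, db))
  expect_identical(res$match_rate, 0.9)
  expect_identical(res$unmatched, "ZZZNOPE")
  expect_true(all(res$matched$entry_name %in% db$entry_name))
})

test_that("noise-free consolidation recovers the generator truth exactly", {
  sim <- clean_sim()
  idx <- db_index(sim$db$db)
  for (sid in names(sim$st$studies)) {
    res <- suppressMessages(match_study(sim$st$studies[[sid]], sim$db$db,
                                        index = idx))
    expect_identical(res$match_rate, 1)
    expect_setequal(unique(res$matched$gene_symbol), sim$st$gene_sets[[sid]])
  }
})

test_that("resolution is invariant to input row order", {
  sim <- noisy_sim()
  idx <- db_index(sim$db$db)
  tab <- sim$st$studies[[1L]]
  perm <- tab[rev(seq_len(nrow(tab))), , drop = FALSE]
  for (a in c("study_id", "namespace", "species")) {
    attr(perm, a) <- attr(tab, a)
  }
  r1 <- suppressMessages(suppressWarnings(match_study(tab, sim$db$db,
                                                      index = idx)))
  r2 <- suppressMessages(suppressWarnings(match_study(perm, sim$db$db,
                                                      index = idx)))
  expect_setequal(unique(r1$matched$gene_symbol),
                  unique(r2$matched$gene_symbol))
  expect_identical(r1$match_rate, r2$match_rate)
})

test_that("noisy matching stays above the expected floor", {
  sim <- noisy_sim()  # noise_rate 0.117, 20% of which is unmappable
  idx <- db_index(sim$db$db)
  rates <- vapply(sim$st$studies, function(tab)
    suppressMessages(suppressWarnings(match_study(tab, sim$db$db,
                                                  index = idx)))$match_rate,
    0)
  expect_gt(mean(rates), 0.90)
  expect_gt(min(rates), 0.85)
})

test_that("homolog unification collapses species and fills entry names", {
  db <- tiny_db()
  idx <- db_index(db)
  m_h <- suppressMessages(match_study(
    structure(data.frame(identifier = c("SODC_HUMAN", "NPC1_HUMAN")),
              namespace = "uniprot_entry_name", study_id = "h"), db,
    index = idx))
  m_m <- suppressMessages(match_study(
    structure(data.frame(identifier = "SODC_MOUSE"),
              namespace = "uniprot_entry_name", study_id = "m"), db,
    index = idx))
  uh <- unify_homologs(list(m_h, m_m), db)
  expect_setequal(uh$gene_keys$gene_symbol, c("SOD1", "NPC1"))
  sod <- uh$gene_keys[uh$gene_keys$gene_symbol == "SOD1", ]
  # reported in human and mouse; rat homolog inferred from the database
  expect_identical(sod$entry_name_human, "SODC_HUMAN")
  expect_identical(sod$entry_name_mouse, "SODC_MOUSE")
  expect_identical(sod$entry_name_rat, "SODC_RAT")
  npc <- uh$gene_keys[uh$gene_keys$gene_symbol == "NPC1", ]
  expect_true(is.na(npc$entry_name_mouse))  # no mouse NPC1 in this fixture
  expect_setequal(uh$study_genes$h, c("SOD1", "NPC1"))
  expect_identical(uh$study_genes$m, "SOD1")
})

test_that("case differences across studies collapse to a single gene key", {
  db <- tiny_db()
  m1 <- suppressMessages(match_study(
    structure(data.frame(identifier = "SOD1"), namespace = "gene_symbol",
              species = "human", study_id = "a"), db))
  m2 <- suppressMessages(match_study(
    structure(data.frame(identifier = "Sod1"), namespace = "gene_symbol",
              species = "mouse", study_id = "b"), db))
  uh <- unify_homologs(list(m1, m2), db)
  expect_identical(nrow(uh$gene_keys), 1L)
  expect_identical(uh$gene_keys$gene_symbol, "SOD1")
})
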