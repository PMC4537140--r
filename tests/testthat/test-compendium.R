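two_study_manifest <- function() {
  data.frame(study_id = c("A", "B"),
             species = c("human", "mouse"),
             namespace = "gene_symbol",
             tissue = c("HeLa", "brain"),
             fraction = "total",
             neuronal = c(FALSE, TRUE),
             methods = c("ABE", "acyl_RAC"),
             stringsAsFactors = FALSE)
}

test_that("exclusion rules remove flagged rows and warn on misses", {
  tab <- structure(data.frame(identifier = c("SUSD3_HUMAN", "SODC_HUMAN"),
                              description = c("x", "y"),
                              stringsAsFactors = FALSE),
                   study_id = "Dowal")
  rules <- data.frame(study_id = "Dowal", raw_identifier = "SUSD3_HUMAN",
                      reason = "labelled disproved in the source study",
                      stringsAsFactors = FALSE)
  out <- suppressMessages(apply_exclusions(tab, rules))
  expect_identical(out$identifier, "SODC_HUMAN")
  # empty rule set is the identity
  expect_identical(apply_exclusions(tab, rules[0L, ]), tab)
  # rule matching nothing warns but does not error
  miss <- data.frame(study_id = "Dowal", raw_identifier = "ABSENT",
                     reason = "r", stringsAsFactors = FALSE)
  expect_warning(out2 <- apply_exclusions(tab, miss), "matched no rows")
  expect_identical(nrow(out2), 2L)
  # rules must cite a reason
  bad <- data.frame(study_id = "Dowal", raw_identifier = "X", reason = "",
                    stringsAsFactors = FALSE)
  expect_error(apply_exclusions(tab, bad), "reason")
})

test_that("compendium merge unions studies with per-study flags", {
  man <- two_study_manifest()
  comp <- build_compendium(list(A = c("G1", "G2"), B = c("G2", "G3")), man)
  expect_identical(nrow(comp), 3L)
  g2 <- comp[comp$gene_symbol == "G2", ]
  expect_identical(g2$n_studies, 2L)
  expect_identical(g2$study_A + g2$study_B, 2L)
  expect_identical(g2$source_class, "both")
  expect_identical(comp[comp$gene_symbol == "G1", ]$source_class,
                   "non_neuronal_only")
  expect_identical(comp[comp$gene_symbol == "G3", ]$source_class,
                   "neuronal_only")
  # duplicate within one study: flag still 1, n_studies unchanged
  comp2 <- build_compendium(list(A = c("G1", "G1", "G1"), B = "G2"), man)
  expect_identical(comp2[comp2$gene_symbol == "G1", ]$study_A, 1L)
  expect_identical(comp2[comp2$gene_symbol == "G1", ]$n_studies, 1L)
  # single-study input: everything single_study
  comp3 <- build_compendium(list(A = c("G1", "G2")), man)
  expect_true(all(comp3$confidence_tier == "single_study"))
  expect_true(all(comp3$n_studies == 1L))
  # unknown study: configuration error
  expect_error(build_compendium(list(ZZ = "G1"), man), "configuration error")
})

test_that("confidence tiers follow the method/study rule order", {
  expect_identical(assign_confidence(3, c("ABE", "bioorthogonal_HAM")),
                   "multi_method_with_HAM")
  expect_identical(assign_confidence(2, c("ABE", "acyl_RAC")),
                   "multi_method")
  expect_identical(assign_confidence(2, "ABE"), "multi_study")
  expect_identical(assign_confidence(1, "ABE"), "single_study")
  expect_error(assign_confidence(1, character(0)), "non-empty")
})

test_that("source partition is a disjoint cover of the compendium", {
  man <- two_study_manifest()
  comp <- build_compendium(list(A = c("G1", "G2"), B = c("G2", "G3")), man)
  p <- partition_by_source(comp)
  expect_identical(sum(p$counts), nrow(comp))
  expect_identical(p$any_non_neuronal,
                   p$counts[["non_neuronal_only"]] + p$counts[["both"]])
  # all-neuronal manifest: nothing can be non-neuronal-only
  man2 <- man
  man2$neuronal <- c(TRUE, TRUE)
  p2 <- partition_by_source(build_compendium(list(A = "G1", B = "G2"), man2))
  expect_identical(p2$counts[["non_neuronal_only"]], 0L)
})

test_that("flag conservation holds on simulated compendia", {
  sim <- clean_sim()
  idx <- db_index(sim$db$db)
  matches <- lapply(sim$st$studies, function(tab)
    suppressMessages(match_study(tab, sim$db$db, index = idx)))
  keys <- suppressMessages(unify_homologs(matches, sim$db$db))
  comp <- build_compendium(keys$study_genes, sim$st$manifest, keys$gene_keys)
  expect_identical(sum(comp$n_studies),
                   sum(vapply(keys$study_genes, length, 1L)))
  for (sid in names(keys$study_genes)) {
    expect_identical(sum(comp[[paste0("study_", sid)]]),
                     length(keys$study_genes[[sid]]))
  }
  # noise-free: the compendium is exactly the union of the generator truth
  expect_setequal(comp$gene_symbol, unique(unlist(sim$st$gene_sets)))
})

test_that("compendium round-trips losslessly and rebuild is idempotent", {
  man <- default_manifest(small_cfg())
  sets <- list()
  for (i in seq_len(nrow(man))) {
    sets[[man$study_id[i]]] <- sprintf("G%03d", seq_len(20L) + 3L * i)
  }
  comp <- build_compendium(sets, man)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_compendium(comp, path)
  rt <- read_compendium(path)
  strip <- function(d) {
    d <- as.data.frame(d)
    attr(d, "manifest") <- NULL
    attr(d, "study_ids") <- NULL
    d
  }
  expect_identical(strip(rt), strip(comp))
  # rebuilding from the round-tripped flags reproduces flags and tiers
  sets2 <- lapply(attr(rt, "study_ids"), function(sid)
    rt$gene_symbol[rt[[paste0("study_", sid)]] == 1L])
  names(sets2) <- attr(rt, "study_ids")
  comp2 <- build_compendium(sets2, man)
  expect_identical(comp2$n_studies, comp$n_studies)
  expect_identical(comp2$confidence_tier, comp$confidence_tier)
  expect_identical(comp2$source_class, comp$source_class)
})

test_that("compendium ordering is invariant to study input order", {
  man <- two_study_manifest()
  c1 <- build_compendium(list(A = c("G1", "G2"), B = c("G2", "G3")), man)
  c2 <- build_compendium(list(B = c("G3", "G2"), A = c("G2", "G1")), man)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
})

test_that("malformed compendium files raise format errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_symbol\tn_studies\tconfidence_tier\tsource_class",
               "G1\t1\tsingle_study\tboth"), path)
  expect_error(read_compendium(path), "no study_ columns")
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_symbol\tstudy_A\tn_studies\tconfidence_tier\tsource_class",
               "G1\t2\t1\tsingle_study\tboth"), path2)
  expect_error(read_compendium(path2), "non-binary.*line 2")
})
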