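test_that("background construction appends missing compendium genes", {
  bg <- suppressMessages(build_background(
    list(ms1 = sprintf("G%03d", 1:80), ms2 = sprintf("G%03d", 41:100)),
    compendium = c(sprintf("G%03d", 1:3), "X1", "X2", "X3", "X4", "X5")))
  expect_identical(bg$N, 105L)
  expect_setequal(bg$appended, c("X1", "X2", "X3", "X4", "X5"))
  # compendium subset of the union: nothing appended
  bg2 <- suppressMessages(build_background(list(sprintf("G%03d", 1:50)),
                                           sprintf("G%03d", 1:10)))
  expect_identical(bg2$N, 50L)
  expect_length(bg2$appended, 0L)
  # duplicates across lists count once
  bg3 <- suppressMessages(build_background(list(c("A", "B"), c("B", "A")),
                                           "A"))
  expect_identical(bg3$N, 2L)
  expect_error(build_background(list(character(0)), "A"), "empty proteome")
})

test_that("hypergeometric tail matches exhaustive enumeration", {
  expect_equal(hypergeometric_p(4, 4, 5, 10), 6 / 252, tolerance = 1e-12)
  expect_identical(hypergeometric_p(0, 4, 5, 10), 1)
  expect_identical(hypergeometric_p(5, 5, 5, 5), 1)  # degenerate universe
  expect_error(hypergeometric_p(6, 4, 5, 10), "validation error")
  # spot sweep against the draw-enumeration oracle
  for (N in c(7L, 10L)) {
    for (n in 1:N) {
      for (K in 0:N) {
        for (k in 0:min(K, n)) {
          expect_equal(hypergeometric_p(k, K, n, N), hyper_oracle(k, K, n, N),
                       tolerance = 1e-12,
                       label = sprintf("p(k=%d,K=%d,n=%d,N=%d)", k, K, n, N))
        }
      }
    }
  }
})

test_that("Benjamini-Hochberg adjustment follows the step-up formula", {
  expect_equal(bh_fdr(c(0.005, 0.01, 0.03, 0.04)),
               c(0.02, 0.02, 0.04, 0.04))
  expect_identical(bh_fdr(0.37), 0.37)          # m = 1: unchanged
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))  # symmetry
  expect_error(bh_fdr(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_fdr(c(0.5, 1.2)), "\\(0, 1\\]")
  # grouped adjustment equals per-group p.adjust
  p <- c(0.001, 0.02, 0.5, 0.003, 0.04)
  g <- c("a", "a", "a", "b", "b")
  expect_equal(bh_fdr(p, g),
               c(p.adjust(p[1:3], "BH"), p.adjust(p[4:5], "BH")))
  # output is monotone non-decreasing in p-value order and bounded by 1
  set.seed(1)
  p0 <- runif(50)
  q <- bh_fdr(p0)
  expect_true(all(q <= 1))
  expect_true(all(diff(q[order(p0)]) >= -1e-12))
})

test_that("fold enrichment is the ratio of proportions", {
  expect_equal(fold_enrichment(4, 4, 5, 10), 2)
  expect_equal(fold_enrichment(10, 20, 50, 100), 1)  # k/n == K/N
  expect_equal(fold_enrichment(0, 4, 5, 10), 0)
  expect_error(fold_enrichment(1, 0, 5, 10), "positive")
})

test_that("significance requires both the FDR and the FE condition", {
  uni <- sprintf("G%04d", 1:1000)
  comp <- uni[1:500]
  bg <- suppressMessages(build_background(list(uni), comp))
  sets <- list(
    # k/n = 75/500, K/N = 100/1000: FE = 1.5, p astronomically small
    high_p_low_fe = c(comp[1:75], uni[501:525]),
    # FE = (40/500)/(50/1000) = 1.6 < 2: also not significant
    mid = c(comp[1:40], uni[526:535]),
    # FE = (45/500)/(50/1000) = 1.8; k high: still fails FE rule
    strong_overlap = c(comp[101:145], uni[536:540]),
    # FE = (30/500)/(30/1000) * ... = 2.0 with tiny p: significant
    planted = comp[201:230])
  res <- suppressMessages(run_enrichment(comp, sets, bg))
  expect_false(res$significant[res$term_id == "high_p_low_fe"])
  expect_lt(res$fdr[res$term_id == "high_p_low_fe"], 1e-4)
  expect_false(res$significant[res$term_id == "strong_overlap"])
  expect_true(res$significant[res$term_id == "planted"])
  expect_equal(res$fe[res$term_id == "planted"], 2)
  # counts are consistent
  expect_true(all(res$k <= pmin(res$K, res$n)))
  expect_true(all(res$p > 0 & res$p <= 1))
})

test_that("terms below the minimum size and outside genes are dropped", {
  uni <- sprintf("G%04d", 1:200)
  comp <- uni[1:50]
  bg <- suppressMessages(build_background(list(uni), comp))
  sets <- list(tiny = uni[1:2], ok = uni[1:20],
               outside = c(uni[3:12], "NOT_IN_BG"))
  res <- suppressMessages(run_enrichment(comp, sets, bg))
  expect_false("tiny" %in% res$term_id)
  expect_identical(res$K[res$term_id == "outside"], 10L)
  # query genes outside the background are dropped with a message
  expect_message(run_enrichment(c(comp, "ALIEN"), sets, bg),
                 "outside the background")
})

test_that("disease terms roll up to broad classes by first keyword match", {
  df <- data.frame(
    name = c("Schizophrenia", "Pancreatic ductal carcinoma", "Neuroblastoma",
             "Huntington disease", "Hepatitis C infection",
             "Hemolytic anemia", "Inflammatory bowel disease",
             "Restless legs syndrome"),
    category = "disease", significant = TRUE, stringsAsFactors = FALSE)
  cls <- suppressMessages(classify_disease_terms(df))
  got <- setNames(cls$table$class, cls$table$name)
  expect_identical(unname(got["Schizophrenia"]), "nervous_system")
  expect_identical(unname(got["Pancreatic ductal carcinoma"]), "cancer")
  expect_identical(unname(got["Neuroblastoma"]), "cancer")
  expect_identical(unname(got["Huntington disease"]), "nervous_system")
  expect_identical(unname(got["Hepatitis C infection"]), "infection")
  expect_identical(unname(got["Hemolytic anemia"]), "anemia")
  expect_identical(unname(got["Inflammatory bowel disease"]),
                   "gastrointestinal")
  expect_identical(unname(got["Restless legs syndrome"]), "other")
  # 14 + 14 of 40 mirrors a 35%/35% rollup
  df40 <- data.frame(
    name = c(sprintf("Epilepsy variant %d", 1:14),
             sprintf("Carcinoma subtype %d", 1:14),
             sprintf("Sepsis form %d", 1:12)),
    category = "disease", significant = TRUE, stringsAsFactors = FALSE)
  cls40 <- classify_disease_terms(df40)
  expect_identical(cls40$counts[["nervous_system"]], 14L)
  expect_identical(cls40$counts[["cancer"]], 14L)
  expect_equal(cls40$fractions[["nervous_system"]], 0.35)
  expect_equal(cls40$fractions[["cancer"]], 0.35)
})

test_that("GMT files round-trip and agree with the fgsea reader", {
  sets <- list(T1 = c("A", "B", "C"), T2 = c("B", "D", "E", "F"))
  meta <- data.frame(term_id = c("T1", "T2"), name = c("term one", "two"),
                     category = c("disease", "go_bp"),
                     stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path, meta)
  rt <- read_gmt(path)
  expect_identical(rt$sets, sets)
  expect_identical(rt$meta$category, meta$category)
  expect_identical(rt$meta$name, meta$name)
  via_fgsea <- fgsea::gmtPathways(path)
  expect_identical(lapply(via_fgsea, unname), sets)
  # malformed line
  path2 <- withr::local_tempfile(fileext = ".gmt")
  writeLines("onlyid\tdesc", path2)
  expect_error(read_gmt(path2), "fewer than 3 fields")
})
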