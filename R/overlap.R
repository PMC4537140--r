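#' Build the 2x2 contingency table for a gene-list overlap
#'
#' Membership is evaluated over the background universe only: list genes
#' outside the background are dropped with a logged count, as are compendium
#' genes outside the background. The four cells are disjoint and exhaustive
#' over the universe: `a` (in list and compendium), `b` (list only), `c`
#' (compendium only), `d` (neither).
#'
#' @param compendium Character vector of compendium genes.
#' @param list_genes Character vector (e.g. synaptic genes).
#' @param background An `enrich_background` or a plain character universe.
#' @return 2x2 integer matrix, rows = list membership, columns = compendium
#'   membership.
#' @export
build_contingency <- function(compendium, list_genes, background) {
  uni <- if (inherits(background, "enrich_background")) background$universe
         else unique(.norm_id(background))
  lst <- unique(.norm_id(list_genes))
  comp <- unique(.norm_id(compendium))
  drop_l <- sum(!lst %in% uni)
  if (drop_l > 0L) {
    message(sprintf("[overlap] %d list gene(s) outside the background dropped",
                    drop_l))
  }
  lst <- lst[lst %in% uni]
  comp <- comp[comp %in% uni]
  .assert(length(lst) > 0L,
          "validation error: gene list does not intersect the background")
  a <- length(intersect(lst, comp))
  b <- length(lst) - a
  cc <- length(comp) - a
  d <- length(uni) - a - b - cc
  m <- base::matrix(c(a, cc, b, d), nrow = 2L,
                    dimnames = list(list = c("in_list", "out_list"),
                                    compendium = c("in_compendium",
                                                   "out_compendium")))
  m
}

#' Two-sided Fisher exact p-value (point-probability rule)
#'
#' Sums, over all tables with the observed margins, the probabilities of
#' those whose point probability does not exceed the observed table's
#' (within a relative tolerance of 1e-7, the conventional exact-test rule).
#' Point probabilities are evaluated on log scale, so the sum is stable for
#' extreme tables.
#'
#' @param table 2x2 matrix of non-negative counts (e.g. from
#'   [build_contingency()]).
#' @return The two-sided p-value in (0, 1].
#' @examples
#' fisher_exact_two_sided(matrix(c(3, 1, 1, 3), 2))  # 34/70
#' @export
fisher_exact_two_sided <- function(table) {
  tab <- .check_2x2(table)
  a <- tab[1L, 1L]; b <- tab[1L, 2L]; cc <- tab[2L, 1L]; d <- tab[2L, 2L]
  N <- a + b + cc + d
  row1 <- a + b
  col1 <- a + cc
  support <- max(0L, row1 + col1 - N):min(row1, col1)
  lp <- dhyper(support, col1, N - col1, row1, log = TRUE)
  lobs <- dhyper(a, col1, N - col1, row1, log = TRUE)
  keep <- lp <= lobs + log(1 + 1e-7)
  min(1, exp(log_sum_exp(lp[keep])))
}

#' @noRd
.check_2x2 <- function(table) {
  .assert(is.matrix(table) && all(dim(table) == c(2L, 2L)),
          "validation error: need a 2x2 table")
  .assert(all(table >= 0) && all(table == round(table)),
          "validation error: cells must be non-negative integers")
  storage.mode(table) <- "integer"
  table
}

#' Odds ratio with exact confidence interval for a 2x2 table
#'
#' Reports the sample (cross-product) odds ratio `ad/bc`, with a Haldane 0.5
#' continuity correction only when some cell is zero, alongside the
#' conditional maximum-likelihood odds ratio and the exact conditional
#' confidence interval obtained by inverting the noncentral hypergeometric
#' tail tests (both via [stats::fisher.test()]).
#'
#' @param table 2x2 count matrix.
#' @param level Confidence level (default 0.95).
#' @return List with `or_sample`, `or_cmle`, `ci` (length-2 vector), and
#'   `note` when margins are degenerate.
#' @export
odds_ratio_ci <- function(table, level = 0.95) {
  tab <- .check_2x2(table)
  a <- tab[1L, 1L]; b <- tab[1L, 2L]; cc <- tab[2L, 1L]; d <- tab[2L, 2L]
  if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)) {
    return(list(or_sample = NA_real_, or_cmle = NA_real_,
                ci = c(NA_real_, NA_real_),
                note = "degenerate margins: odds ratio undefined"))
  }
  h <- if (any(tab == 0L)) 0.5 else 0
  or_sample <- ((a + h) * (d + h)) / ((b + h) * (cc + h))
  ft <- fisher.test(tab, conf.level = level)
  list(or_sample = or_sample, or_cmle = unname(ft$estimate),
       ci = as.numeric(ft$conf.int))
}

#' Overlap analysis between the compendium and an external gene list
#'
#' Builds the 2x2 table over the background, runs the two-sided exact test,
#' and reports effect sizes in both directions: the enrichment of compendium
#' genes in the list (e.g. palmitoylated genes among synaptic genes) and the
#' converse enrichment of list genes in the compendium. The fold ratio in a
#' direction is the in-group frequency over the background frequency, e.g.
#' `(a/(a+b)) / ((a+c)/N)` for the forward direction.
#'
#' @inheritParams build_contingency
#' @param level Confidence level for the odds-ratio interval.
#' @return Object of class `overlap_result`: list with `table`, `p_two_sided`,
#'   `odds` (see [odds_ratio_ci()]), and per-direction lists
#'   `forward`/`converse` each holding `percent_overlap` and `fold`.
#' @export
overlap_summary <- function(compendium, list_genes, background,
                            level = 0.95) {
  tab <- build_contingency(compendium, list_genes, background)
  a <- tab[1L, 1L]; b <- tab[1L, 2L]; cc <- tab[2L, 1L]; d <- tab[2L, 2L]
  N <- sum(tab)
  p <- fisher_exact_two_sided(tab)
  or <- odds_ratio_ci(tab, level)
  fwd <- list(n_list = a + b, n_overlap = a,
              percent_overlap = 100 * a / (a + b),
              fold = (a / (a + b)) / ((a + cc) / N))
  con <- list(n_compendium = a + cc, n_overlap = a,
              percent_overlap = if (a + cc > 0) 100 * a / (a + cc) else 0,
              fold = if (a + cc > 0 && (a + b) > 0)
                (a / (a + cc)) / ((a + b) / N) else NA_real_)
  out <- list(table = tab, p_two_sided = p, odds = or,
              forward = fwd, converse = con, N = N)
  class(out) <- "overlap_result"
  out
}

#' @export
print.overlap_result <- function(x, ...) {
  a <- x$table[1L, 1L]
  cat("Overlap analysis (two-sided Fisher exact test)\n")
  cat(sprintf("  overlap: %d of %d list genes (%.0f%%); compendium in background: %d of N = %d\n",
              a, x$forward$n_list, x$forward$percent_overlap,
              x$converse$n_compendium, x$N))
  cat(sprintf("  p = %.3g; sample OR = %.2f; CMLE OR = %.2f (95%% CI %.2f-%.2f)\n",
              x$p_two_sided, x$odds$or_sample, x$odds$or_cmle,
              x$odds$ci[1L], x$odds$ci[2L]))
  cat(sprintf("  fold (list direction) = %.2f; fold (converse) = %.2f\n",
              x$forward$fold, x$converse$fold))
  invisible(x)
}
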