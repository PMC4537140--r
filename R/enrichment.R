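#' Construct the enrichment background universe
#'
#' The background is the union of MS-proteome gene lists; compendium genes
#' absent from that union (detected by the palmitoyl-proteomics studies but
#' not in the reference proteomes) are appended so the compendium is always
#' a subset of the background. Conditioning on MS-detectability this way
#' keeps detection bias out of the enrichment test.
#'
#' @param proteome_lists List of character vectors (gene lists).
#' @param compendium Character vector of compendium genes.
#' @return Object of class `enrich_background`: list with `universe`
#'   (character), `N` (its size), `appended` (genes added from the
#'   compendium) and `provenance` (list sizes).
#' @examples
#' bg <- build_background(list(A = c("G1", "G2"), B = c("G2", "G3")),
#'                        compendium = c("G1", "G4"))
#' bg$N          # 4
#' bg$appended   # "G4"
#' @export
build_background <- function(proteome_lists, compendium) {
  .assert(length(proteome_lists) > 0L,
          "configuration error: no proteome lists supplied")
  uni <- unique(.norm_id(unlist(proteome_lists, use.names = FALSE)))
  uni <- uni[nzchar(uni)]
  .assert(length(uni) > 0L, "configuration error: empty proteome union")
  comp <- unique(.norm_id(compendium))
  appended <- setdiff(comp, uni)
  universe <- c(uni, appended)
  message(sprintf(
    "[background] union of %d list(s): %d genes; %d compendium gene(s) appended; N = %d",
    length(proteome_lists), length(uni), length(appended), length(universe)))
  out <- list(universe = universe, N = length(universe), appended = appended,
              provenance = list(list_sizes = lengths(proteome_lists),
                                n_union = length(uni),
                                n_appended = length(appended)))
  class(out) <- "enrich_background"
  out
}

#' Hypergeometric over-representation probability
#'
#' Upper-tail probability `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`:
#' the chance of drawing at least `k` annotated genes when `n` genes are
#' drawn without replacement from a universe of `N` containing `K`
#' annotated ones. Computed through [stats::phyper()], which works on log
#' scale internally and is stable for extreme tails.
#'
#' @param k Observed overlap (query genes carrying the annotation).
#' @param K Annotated genes in the universe.
#' @param n Query (compendium) size.
#' @param N Universe size.
#' @return The p-value in (0, 1].
#' @examples
#' hypergeometric_p(4, 4, 5, 10)  # 6/252
#' @export
hypergeometric_p <- function(k, K, n, N) {
  .assert(all(c(k, K, n, N) >= 0) && K <= N && n <= N && k <= min(K, n),
          "validation error: need 0 <= k <= min(K, n), K <= N, n <= N")
  if (k == 0) return(1)
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg false discovery rate, optionally within groups
#'
#' Step-up BH adjustment via [stats::p.adjust()]. With a grouping factor the
#' correction is applied separately within each group (here: annotation
#' category), matching per-category reporting of enrichment tables.
#'
#' @param p_values Numeric vector in (0, 1].
#' @param grouping Optional factor/character of the same length.
#' @return Adjusted values in the original order.
#' @examples
#' bh_fdr(c(0.005, 0.01, 0.03, 0.04))  # 0.02 0.02 0.04 0.04
#' @export
bh_fdr <- function(p_values, grouping = NULL) {
  .assert(all(p_values > 0 & p_values <= 1),
          "validation error: p-values must lie in (0, 1]")
  if (is.null(grouping)) return(p.adjust(p_values, method = "BH"))
  .assert(length(grouping) == length(p_values),
          "validation error: grouping length mismatch")
  out <- numeric(length(p_values))
  for (g in unique(grouping)) {
    i <- grouping == g
    out[i] <- p.adjust(p_values[i], method = "BH")
  }
  out
}

#' Fold enrichment
#'
#' Ratio of the annotation's frequency among query genes to its frequency in
#' the background: `FE = (k/n) / (K/N)`.
#'
#' @inheritParams hypergeometric_p
#' @return Non-negative fold enrichment (0 when `k = 0`).
#' @export
fold_enrichment <- function(k, K, n, N) {
  .assert(K > 0 && n > 0 && N > 0,
          "validation error: K, n and N must be positive")
  (k / n) / (K / N)
}

#' Run the over-representation analysis
#'
#' Intersects every term with the background, drops terms below the minimum
#' size and query genes outside the background (logged), computes the
#' hypergeometric upper-tail p, the within-category BH FDR and the fold
#' enrichment for each surviving term, and flags terms significant when
#' `FDR < fdr_threshold` and `FE >= fe_threshold` (both conditions
#' required). Results are sorted by FDR within category.
#'
#' @param compendium Character vector of query (compendium) genes.
#' @param sets Named list of term gene vectors (see [read_gmt()]).
#' @param background An `enrich_background` from [build_background()].
#' @param meta Optional data.frame `term_id`, `name`, `category`.
#' @param min_term_size Minimum in-background term size (default 3).
#' @param fdr_threshold FDR cut-off (default 0.001).
#' @param fe_threshold Fold-enrichment cut-off (default 2).
#' @return An `enrichment_result` data.frame: `term_id`, `name`, `category`,
#'   `k`, `K`, `n`, `N`, `p`, `fdr`, `fe`, `significant`.
#' @export
run_enrichment <- function(compendium, sets, background, meta = NULL,
                           min_term_size = 3L, fdr_threshold = 0.001,
                           fe_threshold = 2) {
  .assert(inherits(background, "enrich_background"),
          "validation error: background must come from build_background()")
  .assert(length(sets) > 0L && !is.null(names(sets)),
          "validation error: sets must be a non-empty named list")
  uni <- background$universe
  N <- background$N
  comp <- unique(.norm_id(compendium))
  dropped <- sum(!comp %in% uni)
  if (dropped > 0L) {
    message(sprintf("[enrich] %d query gene(s) outside the background dropped",
                    dropped))
  }
  comp <- comp[comp %in% uni]
  n <- length(comp)
  .assert(n > 0L, "validation error: no query genes inside the background")

  sets_bg <- lapply(sets, function(g) intersect(unique(.norm_id(g)), uni))
  K <- lengths(sets_bg)
  keep <- K >= min_term_size
  if (any(!keep)) {
    message(sprintf("[enrich] %d term(s) below min size %d dropped",
                    sum(!keep), min_term_size))
  }
  sets_bg <- sets_bg[keep]
  K <- K[keep]
  .assert(length(sets_bg) > 0L,
          "validation error: no terms survive the size filter")
  k <- vapply(sets_bg, function(g) length(intersect(g, comp)), 0L)
  p <- vapply(seq_along(k), function(i)
    hypergeometric_p(k[i], K[i], n, N), 0)
  fe <- vapply(seq_along(k), function(i)
    fold_enrichment(k[i], K[i], n, N), 0)

  ids <- names(sets_bg)
  if (is.null(meta)) {
    meta <- data.frame(term_id = ids, name = ids,
                       category = "uncategorized", stringsAsFactors = FALSE)
  }
  mi <- match(ids, meta$term_id)
  category <- ifelse(is.na(mi), "uncategorized", meta$category[mi])
  name <- ifelse(is.na(mi), ids, meta$name[mi])
  fdr <- bh_fdr(p, category)
  res <- data.frame(term_id = ids, name = name, category = category,
                    k = as.integer(k), K = as.integer(K), n = n, N = N,
                    p = p, fdr = fdr, fe = fe,
                    significant = fdr < fdr_threshold & fe >= fe_threshold,
                    row.names = NULL, stringsAsFactors = FALSE)
  res <- res[order(res$category, res$fdr, res$term_id, method = "radix"), ]
  rownames(res) <- NULL
  class(res) <- c("enrichment_result", "data.frame")
  attr(res, "thresholds") <- c(fdr = fdr_threshold, fe = fe_threshold)
  res
}

#' Default disease-class keyword map
#'
#' Ordered, case-insensitive regular expressions classifying disease
#' annotation names into broad classes. The cancer pattern is applied first
#' so histology names built on neural tissues (e.g. neuroblastoma) are not
#' routed to the nervous-system class; unmatched names fall through to
#' `other`.
#'
#' @return Named character vector of patterns in match order.
#' @export
default_disease_keywords <- function() {
  c(cancer = "carcinom|cancer|leukemi|lymphom|melanom|gliom|blastom|sarcom|adenom|tumor|myelom",
    nervous_system = "schizophren|huntington|scleros|epilep|parkinson|alzheimer|ataxia|dementia|neurodegener|nervous|palsy|dystonia|autism|bipolar|depress|neuropath",
    infection = "infect|viral|virus|bacteri|sepsis|hepatitis|influenza|tubercul|malaria",
    anemia = "anaemi|anemi",
    gastrointestinal = "gastro|colitis|bowel|crohn|intestin|gastric|esophag|pancreatitis")
}

#' Roll significant disease terms up to broad disease classes
#'
#' Assigns each significant disease-category term to exactly one class by
#' first matching keyword pattern (see [default_disease_keywords()]);
#' unmapped terms are classed `other` and logged.
#'
#' @param results An `enrichment_result` (or any data.frame with `name`,
#'   `category`, `significant`).
#' @param keyword_map Named vector of patterns in match order.
#' @return List with `table` (term -> class), `counts` and `fractions` over
#'   significant disease terms.
#' @examples
#' df <- data.frame(name = c("Schizophrenia", "Pancreatic ductal carcinoma"),
#'                  category = "disease", significant = TRUE)
#' classify_disease_terms(df)$table$class
#' @export
classify_disease_terms <- function(results,
                                   keyword_map = default_disease_keywords()) {
  .assert(all(c("name", "category", "significant") %in% names(results)),
          "format error: results need name, category, significant columns")
  dis <- results[results$category == "disease" & results$significant, ,
                 drop = FALSE]
  classes <- c(names(keyword_map), "other")
  if (nrow(dis) == 0L) {
    return(list(table = data.frame(name = character(), class = character()),
                counts = stats::setNames(integer(length(classes)), classes),
                fractions = stats::setNames(numeric(length(classes)),
                                            classes)))
  }
  cls <- rep("other", nrow(dis))
  for (i in rev(seq_along(keyword_map))) {
    hit <- grepl(keyword_map[[i]], dis$name, ignore.case = TRUE)
    cls[hit] <- names(keyword_map)[i]
  }
  n_other <- sum(cls == "other")
  if (n_other > 0L) {
    message(sprintf("[enrich] %d disease term(s) without keyword match classed 'other'",
                    n_other))
  }
  counts <- table(factor(cls, levels = classes))
  counts <- stats::setNames(as.integer(counts), classes)
  list(table = data.frame(name = dis$name, class = cls,
                          stringsAsFactors = FALSE),
       counts = counts, fractions = counts / nrow(dis))
}
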