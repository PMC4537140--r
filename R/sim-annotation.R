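# Internal pools of realistic annotation-term names. Disease names are chosen
# so that the shipped disease-class keyword map recovers the intended class.
.disease_name_pool <- list(
  nervous_system = c("Schizophrenia", "Huntington disease",
                     "Amyotrophic lateral sclerosis", "Parkinson disease",
                     "Temporal lobe epilepsy", "Spinocerebellar ataxia",
                     "Frontotemporal dementia", "Multiple sclerosis"),
  cancer = c("Pancreatic ductal carcinoma", "Neuroblastoma",
             "Hepatocellular carcinoma", "Acute myeloid leukemia",
             "Colorectal cancer", "Glioblastoma", "Cutaneous melanoma",
             "Breast carcinoma"),
  infection = c("Hepatitis C infection", "Influenza virus infection",
                "Bacterial sepsis", "Tuberculosis"),
  anemia = c("Hemolytic anemia", "Aplastic anemia"),
  gastrointestinal = c("Inflammatory bowel disease", "Gastric ulcer",
                       "Crohn disease of the intestine"),
  other = c("Dilated cardiomyopathy", "Nephrotic syndrome",
            "Systemic amyloidosis"))

#' Generate annotation gene sets with planted fold enrichments
#'
#' Builds a gene-set collection (GMT-style) over the background universe.
#' Each planted term of size K draws its number of compendium genes
#' k ~ Binomial(K, FE * n / N), so the expected fold enrichment of compendium
#' genes in the term equals the target FE; decoy terms are sampled uniformly
#' from the background (expected FE = 1). Terms are spread across the five
#' annotation categories (disease, pathway map, process network, GO
#' biological process, metabolic network); disease terms receive names drawn
#' from realistic disease-name pools.
#'
#' @param config A [sim_config()] object (supplies `planted_terms`,
#'   `n_decoy_terms` and the seed).
#' @param background Character vector: the background gene universe.
#' @param compendium Character vector: the query (compendium) genes; must be
#'   a subset of `background`.
#' @return Object of class `sim_annotation`: list with `sets` (named list of
#'   gene vectors) and `meta` (data.frame: `term_id`, `name`, `category`,
#'   `planted_fe`, `k_planted`, and for disease terms `planted_class`).
#' @export
generate_annotation_sets <- function(config, background, compendium) {
  validate_sim_config(config)
  .assert(all(compendium %in% background),
          "validation error: compendium must be a subset of the background")
  set.seed(config$seed + 201L)
  N <- length(background)
  n <- length(compendium)
  outside <- setdiff(background, compendium)

  plan <- c(lapply(config$planted_terms, function(pt)
              list(K = as.integer(pt[["term_size"]]),
                   fe = as.numeric(pt[["target_fe"]]), planted = TRUE)),
            lapply(seq_len(config$n_decoy_terms), function(i)
              list(K = sample(20:min(200L, N), 1L), fe = 1, planted = FALSE)))
  cats <- rep_len(c("disease", "pathway_map", "process_network", "go_bp",
                    "metabolic_network"), length(plan))
  pool_cycle <- rep_len(names(.disease_name_pool), sum(cats == "disease"))

  sets <- vector("list", length(plan))
  meta <- vector("list", length(plan))
  d_i <- 0L
  for (i in seq_along(plan)) {
    K <- plan[[i]]$K
    fe <- plan[[i]]$fe
    .assert(K >= 1L, "configuration error: term_size must be positive")
    p_in <- fe * n / N
    .assert(p_in <= 1,
            sprintf("configuration error: target FE %.3g unattainable for term size %d (FE*n/N > 1)",
                    fe, K))
    k <- rbinom(1L, K, p_in)
    .assert(k <= n && (K - k) <= length(outside),
            sprintf("configuration error: target FE %.3g unattainable for term size %d",
                    fe, K))
    genes <- c(if (k > 0L) sample(compendium, k),
               if (K - k > 0L) sample(outside, K - k))
    term_id <- sprintf("%s%03d", if (plan[[i]]$planted) "PT" else "DT", i)
    if (cats[i] == "disease") {
      d_i <- d_i + 1L
      cls <- pool_cycle[d_i]
      pool <- .disease_name_pool[[cls]]
      name <- paste0(pool[(d_i - 1L) %/% length(.disease_name_pool) %%
                            length(pool) + 1L],
                     if (d_i > length(unlist(.disease_name_pool)))
                       sprintf(" (%d)", d_i) else "")
    } else {
      cls <- NA_character_
      name <- sprintf("%s annotation %03d", gsub("_", " ", cats[i]), i)
    }
    sets[[i]] <- genes
    meta[[i]] <- data.frame(term_id = term_id, name = name,
                            category = cats[i],
                            planted_fe = fe, k_planted = k,
                            planted_class = cls, stringsAsFactors = FALSE)
  }
  meta <- do.call(rbind, meta)
  names(sets) <- meta$term_id
  out <- list(sets = sets, meta = meta)
  class(out) <- "sim_annotation"
  out
}

#' Generate a synaptic-style gene list with planted overlap odds
#'
#' Draws a gene list of the configured size from the background so that the
#' odds of compendium membership inside versus outside the list equal
#' `synaptic_overlap_odds`. The overlap count is sampled from Fisher's
#' noncentral hypergeometric distribution via its exact log-density, so an
#' odds of 1 reduces exactly to the central hypergeometric null.
#'
#' @inheritParams generate_annotation_sets
#' @return List with `genes` (the list) and `truth`
#'   (`overlap`, `odds`, `list_size`).
#' @export
generate_synaptic_list <- function(config, background, compendium) {
  validate_sim_config(config)
  .assert(all(compendium %in% background),
          "validation error: compendium must be a subset of the background")
  set.seed(config$seed + 301L)
  N <- length(background)
  n <- length(compendium)
  L <- min(config$synaptic_list_size, N)
  odds <- config$synaptic_overlap_odds

  support <- max(0L, L - (N - n)):min(L, n)
  lw <- lchoose(n, support) + lchoose(N - n, L - support) +
    support * log(odds)
  a <- if (length(support) == 1L) support else
    sample(support, 1L, prob = exp(lw - max(lw)))
  outside <- setdiff(background, compendium)
  genes <- c(if (a > 0L) sample(compendium, a),
             if (L - a > 0L) sample(outside, L - a))
  list(genes = sample(genes),
       truth = list(overlap = a, odds = odds, list_size = L))
}
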