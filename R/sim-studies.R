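#' Default study manifest for the simulated meta-analysis
#'
#' For the default 15-study configuration the manifest mirrors the design of
#' the published mammalian palmitoylome meta-analysis: nine human, five mouse
#' and one rat study; three neuronal sample sources (a mouse neural stem cell
#' study, a mouse brain study and the rat synaptosome study); identifier
#' namespaces split across UniProt entry names, Ensembl gene IDs, gene
#' symbols, RefSeq accessions and NCBI GI numbers; detection methods drawn
#' from ABE, acyl-RAC and bioorthogonal labeling (with and without the
#' hydroxylamine negative control). Other study counts get a generic manifest
#' with the same species proportions.
#'
#' @param config A [sim_config()] object.
#' @return Data.frame with columns `study_id`, `species`, `namespace`,
#'   `tissue`, `fraction`, `neuronal` (logical), `methods` (comma-separated).
#' @export
default_manifest <- function(config) {
  validate_sim_config(config)
  if (config$n_studies == 15L) {
    man <- data.frame(
      study_id = c("Dowal2011", "Forrester2011", "Wei2011", "Martin2010",
                   "Ivaldi2012", "Marin2012", "Wilson2011", "Yang2010",
                   "Zhang2008", "Li2012", "Martin2012", "Wan2013",
                   "Yount2010", "Merrick2011", "Kang2008"),
      species = c(rep("human", 9L), rep("mouse", 5L), "rat"),
      namespace = c("uniprot_entry_name", "uniprot_entry_name",
                    "uniprot_entry_name", "ensembl_gene", "gene_symbol",
                    "gene_symbol", "gene_symbol", "gene_symbol",
                    "refseq_accession", "gene_symbol", "gene_symbol",
                    "gene_symbol", "gene_symbol", "ncbi_gi", "gene_symbol"),
      tissue = c("platelet", "HEK293", "endothelial cell", "Jurkat T cell",
                 "HeLa", "endothelial cell", "HeLa", "DU145 prostate",
                 "Jurkat T cell", "neural stem cell", "T cell hybridoma",
                 "brain", "dendritic cell", "liver", "synaptosome"),
      fraction = "total",
      neuronal = c(rep(FALSE, 9L), TRUE, FALSE, TRUE, FALSE, FALSE, TRUE),
      methods = c("ABE", "acyl_RAC", "ABE", "bioorthogonal", "ABE",
                  "acyl_RAC", "bioorthogonal,bioorthogonal_HAM", "ABE",
                  "ABE", "bioorthogonal,bioorthogonal_HAM",
                  "bioorthogonal,bioorthogonal_HAM", "acyl_RAC",
                  "bioorthogonal", "ABE", "ABE"),
      stringsAsFactors = FALSE)
    return(man)
  }
  n <- config$n_studies
  sp <- rep(c("human", "mouse", "rat"),
            times = pmax(1L, round(n * c(9, 5, 1) / 15)))[seq_len(n)]
  ns <- rep_len(.namespace_levels, n)
  # Keep namespaces consistent with the species that actually carry them.
  ns[ns %in% c("ensembl_gene", "refseq_accession") & sp != "human"] <-
    "gene_symbol"
  ns[ns == "ncbi_gi" & sp != "mouse"] <- "gene_symbol"
  data.frame(
    study_id = sprintf("study%02d", seq_len(n)),
    species = sp,
    namespace = ns,
    tissue = ifelse(seq_len(n) %% 5L == 0L, "brain", "cell line"),
    fraction = "total",
    neuronal = seq_len(n) %% 5L == 0L,
    methods = rep_len(c("ABE", "acyl_RAC", "bioorthogonal",
                        "bioorthogonal,bioorthogonal_HAM"), n),
    stringsAsFactors = FALSE)
}

#' Generate per-study palmitoyl-protein tables with ground truth
#'
#' Each study samples genes from the latent palmitoylome with its detection
#' probability; studies within a planted cluster share one Bernoulli
#' detection profile (identical true gene sets). Detected genes are rendered
#' in the study's identifier namespace and species, then corrupted at
#' `noise_rate`: 50% case perturbation, 30% synonym substitution (gene-symbol
#' studies only; falls back to case perturbation elsewhere), 20% unmappable
#' token.
#'
#' @param config A [sim_config()] object.
#' @param sim_db Output of [generate_mapping_db()] for the same config.
#' @return Object of class `sim_studies`: list with `studies` (named list of
#'   data.frames with columns `identifier`, `description`, carrying
#'   attributes `study_id`, `namespace`, `species`), `manifest`, and ground
#'   truth `gene_sets` (named list of true gene-symbol sets per study) and
#'   `rows` (per-row identifier provenance).
#' @export
generate_study_tables <- function(config, sim_db) {
  validate_sim_config(config)
  .assert(inherits(sim_db, "sim_mapping"),
          "configuration error: sim_db must come from generate_mapping_db()")
  set.seed(config$seed + 101L)
  man <- default_manifest(config)
  genes <- sim_db$latent_genes
  G <- length(genes)
  p <- rep_len(config$detection_prob, config$n_studies)

  det <- matrix(0L, nrow = G, ncol = config$n_studies)
  clustered <- unlist(config$planted_clusters)
  for (grp in config$planted_clusters) {
    prof <- rbinom(G, 1L, p[grp[1L]])
    det[, grp] <- prof
  }
  for (s in setdiff(seq_len(config$n_studies), clustered)) {
    det[, s] <- rbinom(G, 1L, p[s])
  }

  db <- sim_db$db
  # Per-species reviewed records for the latent genes, keyed by symbol.
  sp_rows <- lapply(.species_levels, function(sp) {
    d <- db[db$reviewed & db$species == sp, ]
    d[match(genes, d$gene_symbol), ]
  })
  names(sp_rows) <- .species_levels
  syn_first <- vapply(strsplit(sp_rows$human$synonyms, "|", fixed = TRUE),
                      function(s) if (length(s)) s[[1L]] else NA_character_, "")

  studies <- vector("list", config$n_studies)
  truth_rows <- vector("list", config$n_studies)
  for (s in seq_len(config$n_studies)) {
    idx <- which(det[, s] == 1L)
    recs <- sp_rows[[man$species[s]]][idx, ]
    ns <- man$namespace[s]
    id <- switch(ns,
      uniprot_entry_name = recs$entry_name,
      gene_symbol = recs$gene_symbol,
      ensembl_gene = recs$ensembl_id,
      refseq_accession = paste0(recs$refseq_id, ".",
                                sample(1:3, length(idx), replace = TRUE)),
      ncbi_gi = recs$gi_number)
    corruption <- rep("none", length(idx))
    if (config$noise_rate > 0 && length(idx)) {
      hit <- which(runif(length(idx)) < config$noise_rate)
      kind <- sample(c("case", "synonym", "unmappable"), length(hit),
                     replace = TRUE, prob = c(0.5, 0.3, 0.2))
      if (ns != "gene_symbol") kind[kind == "synonym"] <- "case"
      for (j in seq_along(hit)) {
        i <- hit[j]
        if (kind[j] == "synonym") {
          syn <- syn_first[idx[i]]
          if (is.na(syn)) kind[j] <- "case" else id[i] <- syn
        }
        if (kind[j] == "case") id[i] <- tolower(id[i])
        if (kind[j] == "unmappable") {
          id[i] <- sprintf("ZZZ%06d", sample.int(999999L, 1L))
        }
      }
      corruption[hit] <- kind
    }
    tab <- data.frame(identifier = id, description = recs$full_name,
                      stringsAsFactors = FALSE)
    attr(tab, "study_id") <- man$study_id[s]
    attr(tab, "namespace") <- ns
    attr(tab, "species") <- man$species[s]
    class(tab) <- c("study_table", "data.frame")
    studies[[s]] <- tab
    truth_rows[[s]] <- data.frame(study_id = man$study_id[s],
                                  raw_identifier = id,
                                  gene_symbol = genes[idx],
                                  corruption = corruption,
                                  stringsAsFactors = FALSE)
  }
  names(studies) <- man$study_id
  gene_sets <- lapply(seq_len(config$n_studies),
                      function(s) genes[det[, s] == 1L])
  names(gene_sets) <- man$study_id
  out <- list(studies = studies, manifest = man, gene_sets = gene_sets,
              rows = do.call(rbind, truth_rows))
  class(out) <- "sim_studies"
  out
}

#' @export
print.sim_studies <- function(x, ...) {
  sizes <- vapply(x$studies, nrow, 1L)
  cat(sprintf("Synthetic study tables: %d studies, %d-%d rows each\n",
              length(sizes), min(sizes), max(sizes)))
  invisible(x)
}
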