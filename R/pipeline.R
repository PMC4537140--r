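#' Configure an end-to-end pipeline run
#'
#' Collects the input paths (the layout written by [generate_all()], or any
#' directory following it), the analysis thresholds and the seed, and
#' validates that every referenced input exists before any stage runs.
#'
#' @param input_dir Directory holding `mapping_db.tsv`, `manifest.tsv`,
#'   `studies/`, `gene_sets.gmt`, `proteome_ms1.txt`, `proteome_ms2.txt`,
#'   `synaptic.txt`, `sequences.fasta`, `mutations.tsv`, `evidence.tsv` and
#'   optionally `exclusions.tsv`.
#' @param output_dir Directory for stage outputs (created if needed).
#' @param fdr_threshold,fe_threshold Enrichment significance rule
#'   (defaults 0.001 and 2).
#' @param n_boot Bootstrap samplings per scale (default 5000).
#' @param scales Multiscale-bootstrap scale factors.
#' @param min_term_size Minimum in-background term size.
#' @param window,min_cys Cysteine-rich rule parameters.
#' @param seed Integer seed for the bootstrap stage.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(input_dir, output_dir,
                            fdr_threshold = 0.001, fe_threshold = 2,
                            n_boot = 5000L,
                            scales = seq(0.5, 1.4, by = 0.1),
                            min_term_size = 3L, window = 10L, min_cys = 3L,
                            seed = 1L) {
  .assert(fdr_threshold > 0 && fdr_threshold < 1,
          "configuration error: fdr_threshold must lie in (0, 1)")
  .assert(fe_threshold > 0 && n_boot > 0,
          "configuration error: thresholds must be positive")
  paths <- list(
    mapping_db = file.path(input_dir, "mapping_db.tsv"),
    manifest = file.path(input_dir, "manifest.tsv"),
    studies = file.path(input_dir, "studies"),
    gene_sets = file.path(input_dir, "gene_sets.gmt"),
    proteome_ms1 = file.path(input_dir, "proteome_ms1.txt"),
    proteome_ms2 = file.path(input_dir, "proteome_ms2.txt"),
    synaptic = file.path(input_dir, "synaptic.txt"),
    sequences = file.path(input_dir, "sequences.fasta"),
    mutations = file.path(input_dir, "mutations.tsv"),
    evidence = file.path(input_dir, "evidence.tsv"))
  for (nm in names(paths)) {
    .assert(file.exists(paths[[nm]]),
            sprintf("configuration error: missing input '%s': %s", nm,
                    paths[[nm]]))
  }
  paths$exclusions <- file.path(input_dir, "exclusions.tsv")
  cfg <- list(input_dir = input_dir, output_dir = output_dir, paths = paths,
              fdr_threshold = fdr_threshold, fe_threshold = fe_threshold,
              n_boot = as.integer(n_boot), scales = scales,
              min_term_size = as.integer(min_term_size),
              window = as.integer(window), min_cys = as.integer(min_cys),
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' @noRd
.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the whole meta-analysis pipeline
#'
#' Executes the six stages in order - curate (identifier consolidation),
#' compendium, cluster, enrich, overlap, mine - writing each stage's outputs
#' under `output_dir` (match reports, the compendium TSV, distance matrix,
#' Newick tree and support table, enrichment and disease-class tables, the
#' overlap JSON, the mutation-mining report) plus a machine-readable
#' `summary.json` carrying the seed, thresholds, package version and the
#' headline numbers of every stage. A stage failure aborts the run naming
#' the stage; outputs of completed stages are preserved. With a fixed seed
#' the whole run is byte-reproducible.
#'
#' @param config A [pipeline_config()] object.
#' @param quiet Suppress per-stage progress messages (default TRUE).
#' @return The run summary list, invisibly.
#' @export
run_pipeline <- function(config, quiet = TRUE) {
  .assert(inherits(config, "pipeline_config"),
          "configuration error: config must come from pipeline_config()")
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  note <- if (quiet) suppressMessages else identity

  # stage 1: curate -------------------------------------------------------
  matches <- .stage("curate", note({
    db <- load_mapping_database(config$paths$mapping_db)
    man <- .read_tsv(config$paths$manifest)
    man$neuronal <- toupper(man$neuronal) %in% c("TRUE", "1", "YES")
    rules <- if (file.exists(config$paths$exclusions))
      .read_tsv(config$paths$exclusions) else NULL
    idx <- db_index(db)
    res <- vector("list", nrow(man))
    reports <- file.path(config$output_dir, "match_reports")
    dir.create(reports, showWarnings = FALSE)
    for (i in seq_len(nrow(man))) {
      sid <- man$study_id[i]
      tab <- .read_tsv(file.path(config$paths$studies, paste0(sid, ".tsv")))
      attr(tab, "study_id") <- sid
      attr(tab, "namespace") <- man$namespace[i]
      attr(tab, "species") <- man$species[i]
      tab <- apply_exclusions(tab, rules)
      mr <- match_study(tab, db, index = idx)
      rep_df <- rbind(
        cbind(mr$matched[, c("raw_identifier", "route", "entry_name",
                             "gene_symbol", "entrez_id")],
              status = "matched", stringsAsFactors = FALSE),
        if (length(mr$unmatched))
          data.frame(raw_identifier = mr$unmatched, route = "",
                     entry_name = "", gene_symbol = "", entrez_id = NA,
                     status = "unmatched", stringsAsFactors = FALSE))
      .write_tsv(rep_df, file.path(reports, paste0(sid, "_match.tsv")))
      res[[i]] <- mr
    }
    list(db = db, manifest = man, matches = res)
  }))

  # stage 2: compendium ---------------------------------------------------
  comp <- .stage("compendium", note({
    keys <- unify_homologs(matches$matches, matches$db)
    cp <- build_compendium(keys$study_genes, matches$manifest,
                           keys$gene_keys)
    write_compendium(cp, file.path(config$output_dir, "compendium.tsv"))
    cp
  }))

  # stage 3: cluster ------------------------------------------------------
  clust <- .stage("cluster", note({
    bm <- to_binary_matrix(comp)
    d <- binary_distance(bm)
    .write_tsv(data.frame(study = rownames(d), round(d, 6),
                          check.names = FALSE),
               file.path(config$output_dir, "distance.tsv"))
    tree <- average_linkage(d)
    supp <- bootstrap_support(bm, tree, n_samplings = config$n_boot,
                              scales = config$scales, seed = config$seed)
    to_newick(tree, supp, file.path(config$output_dir, "tree.nwk"))
    .write_tsv(as.data.frame(supp),
               file.path(config$output_dir, "support.tsv"))
    list(tree = tree, support = supp)
  }))

  # stage 4: enrich -------------------------------------------------------
  enr <- .stage("enrich", note({
    bg <- build_background(
      list(ms1 = read_gene_list(config$paths$proteome_ms1),
           ms2 = read_gene_list(config$paths$proteome_ms2)),
      comp$gene_symbol)
    gmt <- read_gmt(config$paths$gene_sets)
    res <- run_enrichment(comp$gene_symbol, gmt$sets, bg, gmt$meta,
                          min_term_size = config$min_term_size,
                          fdr_threshold = config$fdr_threshold,
                          fe_threshold = config$fe_threshold)
    .write_tsv(as.data.frame(res),
               file.path(config$output_dir, "enrichment.tsv"))
    dis <- classify_disease_terms(res)
    .write_tsv(dis$table,
               file.path(config$output_dir, "disease_classes.tsv"))
    list(background = bg, results = res, disease = dis)
  }))

  # stage 5: overlap ------------------------------------------------------
  ovl <- .stage("overlap", note({
    syn <- read_gene_list(config$paths$synaptic)
    ov <- overlap_summary(comp$gene_symbol, syn, enr$background)
    jsonlite::write_json(
      list(cells = as.integer(ov$table), p_two_sided = ov$p_two_sided,
           or_sample = ov$odds$or_sample, or_cmle = ov$odds$or_cmle,
           ci_95 = ov$odds$ci, forward = ov$forward,
           converse = ov$converse),
      file.path(config$output_dir, "overlap.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    ov
  }))

  # stage 6: mine ---------------------------------------------------------
  mine <- .stage("mine", note({
    seqs <- read_fasta(config$paths$sequences)
    muts <- .read_tsv(config$paths$mutations)
    evid <- .read_tsv(config$paths$evidence)
    mr <- classify_mutations(muts, seqs, evid, window = config$window,
                             min_cys = config$min_cys)
    .write_tsv(as.data.frame(mr), file.path(config$output_dir, "mining.tsv"))
    mr
  }))

  part <- partition_by_source(comp)
  rates <- vapply(matches$matches, `[[`, 0, "match_rate")
  sig <- enr$results[enr$results$significant, ]
  summary <- list(
    package = "palmeta",
    version = as.character(utils::packageVersion("palmeta")),
    seed = config$seed,
    thresholds = list(fdr = config$fdr_threshold, fe = config$fe_threshold,
                      n_boot = config$n_boot),
    match_rates = list(mean = mean(rates), min = min(rates)),
    compendium = list(n_genes = nrow(comp),
                      source_counts = as.list(part$counts),
                      tiers = as.list(table(comp$confidence_tier))),
    clustering = local({
      nonroot <- clust$support[-nrow(clust$support), , drop = FALSE]
      top <- nonroot[which.max(nonroot$bp), , drop = FALSE]
      list(max_bp = top$bp[1L], top_members = top$members[1L])
    }),
    enrichment = list(
      n_terms = nrow(enr$results),
      n_significant_by_category = as.list(table(sig$category)),
      disease_classes = as.list(enr$disease$counts)),
    overlap = list(p = ovl$p_two_sided,
                   percent = ovl$forward$percent_overlap,
                   or_sample = ovl$odds$or_sample),
    mining = as.list(table(mine$classification, useNA = "no")))
  jsonlite::write_json(summary,
                       file.path(config$output_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
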