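#' Generate every pipeline input on disk, with ground truth
#'
#' Runs all synthetic generators for one configuration and writes the full
#' input layout the pipeline consumes:
#'
#' * `mapping_db.tsv` - the identifier-mapping database;
#' * `manifest.tsv` - study metadata (species, namespace, tissue, neuronal
#'   flag, detection methods);
#' * `studies/<study_id>.tsv` - per-study identifier tables;
#' * `exclusions.tsv` - curation exclusion rules (one planted "disproved"
#'   record is appended to the first study and flagged for removal);
#' * `proteome_ms1.txt`, `proteome_ms2.txt` - two overlapping MS proteome
#'   gene lists whose union forms the enrichment background (a handful of
#'   latent genes are withheld so the background-append step is exercised);
#' * `gene_sets.gmt` - annotation terms with planted fold enrichments;
#' * `synaptic.txt` - synaptic-style gene list with planted overlap odds;
#' * `sequences.fasta`, `mutations.tsv`, `evidence.tsv` - mutation-mining
#'   inputs;
#' * `truth/` - ground-truth tables for every generated artifact.
#'
#' Identical `(seed, config)` reproduce byte-identical files.
#'
#' @param config A [sim_config()] object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the generated in-memory objects and `dir`.
#' @export
generate_all <- function(config, dir) {
  validate_sim_config(config)
  dir.create(file.path(dir, "studies"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)

  sim_db <- generate_mapping_db(config)
  st <- generate_study_tables(config, sim_db)
  write_mapping_db(sim_db$db, file.path(dir, "mapping_db.tsv"))
  .write_tsv(st$manifest, file.path(dir, "manifest.tsv"))

  # Plant one "disproved" record in the first study and a matching
  # exclusion rule, exercising the curation-exclusion stage.
  set.seed(config$seed + 501L)
  all_sym <- unique(sim_db$db$gene_symbol)
  disproved_sym <- setdiff(all_sym, sim_db$latent_genes)[1L]
  first_id <- st$manifest$study_id[1L]
  first <- st$studies[[first_id]]
  dis_row <- sim_db$db[sim_db$db$gene_symbol == disproved_sym &
                         sim_db$db$species == st$manifest$species[1L] &
                         sim_db$db$reviewed, ][1L, ]
  dis_ident <- switch(st$manifest$namespace[1L],
    uniprot_entry_name = dis_row$entry_name,
    gene_symbol = dis_row$gene_symbol,
    ensembl_gene = dis_row$ensembl_id,
    refseq_accession = paste0(dis_row$refseq_id, ".1"),
    ncbi_gi = dis_row$gi_number)
  first <- rbind(as.data.frame(first),
                 data.frame(identifier = dis_ident,
                            description = dis_row$full_name,
                            stringsAsFactors = FALSE))
  exclusions <- data.frame(study_id = first_id, raw_identifier = dis_ident,
                           reason = "reported as disproved in source study",
                           stringsAsFactors = FALSE)
  .write_tsv(exclusions, file.path(dir, "exclusions.tsv"))
  for (sid in names(st$studies)) {
    tab <- if (sid == first_id) first else as.data.frame(st$studies[[sid]])
    .write_tsv(tab, file.path(dir, "studies", paste0(sid, ".tsv")))
  }

  # Background proteome lists: withhold up to 32 latent genes so the
  # compendium-append step of background construction has work to do.
  holdout <- sample(sim_db$latent_genes, min(32L, config$n_genes))
  pool <- setdiff(all_sym, holdout)
  r <- runif(length(pool))
  ms1 <- pool[r < 0.7]
  ms2 <- pool[r >= 0.3]
  write_gene_list(sort_c(ms1), file.path(dir, "proteome_ms1.txt"))
  write_gene_list(sort_c(ms2), file.path(dir, "proteome_ms2.txt"))

  # Annotation terms and the synaptic list are planted against the latent
  # palmitoylome; detection thins the realized compendium uniformly, which
  # leaves expected fold enrichments unchanged.
  ann <- generate_annotation_sets(config, all_sym, sim_db$latent_genes)
  write_gmt(ann$sets, file.path(dir, "gene_sets.gmt"), ann$meta)
  syn <- generate_synaptic_list(config, all_sym, sim_db$latent_genes)
  write_gene_list(syn$genes, file.path(dir, "synaptic.txt"))

  mot <- generate_sequences_and_mutations(config)
  write_fasta(mot$sequences, file.path(dir, "sequences.fasta"))
  .write_tsv(mot$mutations, file.path(dir, "mutations.tsv"))
  .write_tsv(mot$evidence, file.path(dir, "evidence.tsv"))

  .write_tsv(sim_db$truth, file.path(dir, "truth", "mapping_truth.tsv"))
  .write_tsv(st$rows, file.path(dir, "truth", "study_rows.tsv"))
  gs <- data.frame(
    study_id = rep(names(st$gene_sets), lengths(st$gene_sets)),
    gene_symbol = unlist(st$gene_sets, use.names = FALSE),
    stringsAsFactors = FALSE)
  .write_tsv(gs, file.path(dir, "truth", "study_gene_sets.tsv"))
  .write_tsv(ann$meta, file.path(dir, "truth", "annotation_meta.tsv"))
  jsonlite::write_json(syn$truth, file.path(dir, "truth", "synaptic.json"),
                       auto_unbox = TRUE, digits = NA)
  .write_tsv(mot$truth, file.path(dir, "truth", "mutation_truth.tsv"))
  write_gene_list(sim_db$latent_genes,
                  file.path(dir, "truth", "latent_genes.txt"))
  write_gene_list(holdout, file.path(dir, "truth", "background_holdout.txt"))

  invisible(list(dir = dir, mapping = sim_db, studies = st,
                 annotation = ann, synaptic = syn, motifs = mot,
                 exclusions = exclusions))
}
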