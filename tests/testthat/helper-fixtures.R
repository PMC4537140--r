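# Shared fixtures, built in code and cached per test run.

.fixtures <- new.env(parent = emptyenv())

small_cfg <- function(seed = 11L, noise_rate = 0.117) {
  sim_config(seed = seed, n_genes = 80L, n_background = 400L, n_studies = 6L,
             detection_prob = 0.35, noise_rate = noise_rate,
             planted_clusters = list(c(2L, 3L)),
             planted_terms = list(c(term_size = 30, target_fe = 3)),
             n_decoy_terms = 8L, synaptic_list_size = 60L,
             synaptic_overlap_odds = 5)
}

# Small noise-free simulation: matching must recover the truth exactly.
clean_sim <- function() {
  if (is.null(.fixtures$clean)) {
    cfg <- small_cfg(seed = 21L, noise_rate = 0)
    db <- generate_mapping_db(cfg)
    st <- generate_study_tables(cfg, db)
    .fixtures$clean <- list(cfg = cfg, db = db, st = st)
  }
  .fixtures$clean
}

# Small noisy simulation for end-to-end behaviour.
noisy_sim <- function() {
  if (is.null(.fixtures$noisy)) {
    cfg <- small_cfg(seed = 11L)
    db <- generate_mapping_db(cfg)
    st <- generate_study_tables(cfg, db)
    .fixtures$noisy <- list(cfg = cfg, db = db, st = st)
  }
  .fixtures$noisy
}

# Hand-built six-record mapping database exercising reviewed priority,
# synonyms, full names, cross-references and species tie-breaks.
tiny_db <- function() {
  as_mapping_db(data.frame(
    entry_name = c("SODC_HUMAN", "SODC_MOUSE", "SODC_RAT", "Q00001_HUMAN",
                   "NPC1_HUMAN", "Q00002_HUMAN"),
    gene_symbol = c("SOD1", "Sod1", "Sod1", "SOD1", "NPC1", "ABCX9"),
    synonyms = c("SOD|IPOA", "", "", "", "", ""),
    full_name = c("Superoxide dismutase", "Superoxide dismutase",
                  "Superoxide dismutase", "Superoxide dismutase",
                  "NPC intracellular cholesterol transporter 1",
                  "Uncharacterized protein ABCX9"),
    entrez_id = c(6647L, 20655L, 24786L, 6647L, 4864L, 999L),
    species = c("human", "mouse", "rat", "human", "human", "human"),
    reviewed = c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE),
    ensembl_id = c("ENSG00000142168", "", "", "", "ENSG00000141458", ""),
    refseq_id = c("NP_000445", "", "", "", "NP_000262", ""),
    gi_number = c("", "20892", "", "", "", ""),
    stringsAsFactors = FALSE))
}

# Universe/list construction reproducing the published contingency counts:
# list of 1,028 with 419 overlapping a 1,838-gene compendium in N = 17,858.
published_overlap_sets <- function() {
  if (is.null(.fixtures$pub_sets)) {
    uni <- sprintf("G%05d", seq_len(17858L))
    comp <- uni[seq_len(1838L)]
    lst <- c(uni[seq_len(419L)], uni[1839L:(1838L + 609L)])
    .fixtures$pub_sets <- list(universe = uni, compendium = comp,
                                 list_genes = lst)
  }
  .fixtures$pub_sets
}
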