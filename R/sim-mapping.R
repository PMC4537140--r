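#' Generate a UniProt-style mapping database with ground truth
#'
#' Emulates a Swiss-Prot/TrEMBL identifier-mapping database for human, mouse
#' and rat. Every background gene receives one reviewed entry per species
#' (entry names follow the `NAME_SPECIES` convention and share the `NAME`
#' mnemonic across species); genes of the latent palmitoylome additionally
#' receive 0-2 unreviewed (TrEMBL-style) duplicate entries and 0-3 synonyms.
#' Human reviewed entries carry Ensembl gene and RefSeq protein
#' cross-references, mouse reviewed entries carry NCBI GI numbers, so every
#' study namespace is resolvable. A ground-truth table maps every emitted
#' identifier to its gene.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `sim_mapping`: list with elements `db` (the
#'   mapping database, a data.frame usable wherever a loaded mapping database
#'   is expected), `truth` (identifier -> gene table covering every emitted
#'   identifier), and `latent_genes` (character vector of latent palmitoylome
#'   gene symbols).
#' @examples
#' sim <- generate_mapping_db(sim_config(seed = 1, n_genes = 20,
#'                                       n_background = 100, n_studies = 4))
#' head(sim$db)
#' @export
generate_mapping_db <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  N <- config$n_background
  n_lat <- config$n_genes
  .assert(N + 3L * n_lat <= 400000L,
          "configuration error: n_background too large for the token space")

  tok <- .tok4(sample.int(26L^4, N + 3L * n_lat))
  symbols <- paste0(tok[seq_len(N)], sample(1:9, N, replace = TRUE))
  syn_pool <- tok[(N + 1L):(N + 3L * n_lat)]

  latent_idx <- sort(sample.int(N, n_lat))
  full_names <- paste("Protein", symbols)

  # Synonyms: 0-3 per latent gene, pipe-separated, shared by all of the
  # gene's database entries.
  syn_str <- character(N)
  n_syn <- integer(N)
  n_syn[latent_idx] <- sample(0:3, n_lat, replace = TRUE)
  take <- 0L
  for (i in latent_idx) {
    if (n_syn[i] > 0L) {
      syn_str[i] <- paste(syn_pool[(take + 1L):(take + n_syn[i])],
                          collapse = "|")
      take <- take + n_syn[i]
    }
  }

  entrez_base <- c(human = 1000L, mouse = 100000L, rat = 300000L)
  one_species <- function(sp) {
    data.frame(
      entry_name = paste0(symbols, "_", .species_suffix[[sp]]),
      gene_symbol = symbols,
      synonyms = syn_str,
      full_name = full_names,
      entrez_id = entrez_base[[sp]] + seq_len(N),
      species = sp,
      reviewed = TRUE,
      ensembl_id = if (sp == "human") sprintf("ENSG%011d", seq_len(N)) else
        NA_character_,
      refseq_id = if (sp == "human") sprintf("NP_%06d", seq_len(N)) else
        NA_character_,
      gi_number = if (sp == "mouse") as.character(500000000L + seq_len(N)) else
        NA_character_,
      stringsAsFactors = FALSE)
  }
  db <- rbind(one_species("human"), one_species("mouse"), one_species("rat"))

  # Unreviewed (TrEMBL-style) duplicates for latent genes: accession-style
  # entry names, same gene symbol, no cross-references.
  n_unrev <- sample(0:2, n_lat, replace = TRUE)
  if (sum(n_unrev) > 0L) {
    gi <- rep(latent_idx, n_unrev)
    sp <- sample(.species_levels, sum(n_unrev), replace = TRUE)
    acc <- sprintf("Q%05d", seq_len(sum(n_unrev)))
    unrev <- data.frame(
      entry_name = paste0(acc, "_", .species_suffix[sp]),
      gene_symbol = symbols[gi],
      synonyms = syn_str[gi],
      full_name = full_names[gi],
      entrez_id = entrez_base[sp] + gi,
      species = sp,
      reviewed = FALSE,
      ensembl_id = NA_character_,
      refseq_id = NA_character_,
      gi_number = NA_character_,
      stringsAsFactors = FALSE)
    db <- rbind(db, unrev)
  }
  rownames(db) <- NULL

  truth <- .mapping_truth(db, symbols, syn_str)
  out <- list(db = as_mapping_db(db), truth = truth,
              latent_genes = symbols[latent_idx])
  class(out) <- "sim_mapping"
  out
}

#' @noRd
.mapping_truth <- function(db, symbols, syn_str) {
  rows <- list(
    data.frame(identifier = db$entry_name, namespace = "uniprot_entry_name",
               gene_symbol = db$gene_symbol, species = db$species,
               stringsAsFactors = FALSE),
    data.frame(identifier = symbols, namespace = "gene_symbol",
               gene_symbol = symbols, species = NA_character_,
               stringsAsFactors = FALSE))
  has_syn <- which(syn_str != "")
  if (length(has_syn)) {
    syns <- strsplit(syn_str[has_syn], "|", fixed = TRUE)
    rows[[length(rows) + 1L]] <- data.frame(
      identifier = unlist(syns), namespace = "gene_symbol",
      gene_symbol = rep(symbols[has_syn], lengths(syns)),
      species = NA_character_, stringsAsFactors = FALSE)
  }
  for (col_ns in list(c("ensembl_id", "ensembl_gene"),
                      c("refseq_id", "refseq_accession"),
                      c("gi_number", "ncbi_gi"))) {
    keep <- !is.na(db[[col_ns[1L]]])
    rows[[length(rows) + 1L]] <- data.frame(
      identifier = db[[col_ns[1L]]][keep], namespace = col_ns[2L],
      gene_symbol = db$gene_symbol[keep], species = db$species[keep],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.sim_mapping <- function(x, ...) {
  cat(sprintf(
    "Synthetic mapping database: %d entries (%d reviewed), %d genes, %d latent\n",
    nrow(x$db), sum(x$db$reviewed), length(unique(x$db$gene_symbol)),
    length(x$latent_genes)))
  invisible(x)
}
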