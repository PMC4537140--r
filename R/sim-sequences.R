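#' Generate protein sequences, site evidence and disease mutations
#'
#' Builds synthetic protein sequences whose backbones contain no cysteine,
#' then plants, on a 40-residue grid with random jitter: one known
#' palmitoylation-site cysteine, one predictor-reported cysteine, the
#' configured number of adjacent di-cysteine pairs and cysteine-rich windows
#' (three cysteines within five residues), and one evidence-free cysteine.
#' The mutation table holds one cysteine substitution per planted site (for
#' di-Cys pairs the downstream cysteine is mutated) plus, per protein, a
#' non-cysteine decoy substitution and a record whose claimed reference
#' residue mismatches the sequence. The truth table records the expected
#' classification of every record.
#'
#' @param config A [sim_config()] object (uses `motif_spec` and the seed).
#' @param genes Optional character vector of gene names for the proteins;
#'   defaults to `PALM1`, `PALM2`, ...
#' @return Object of class `sim_motifs`: list with `sequences` (named
#'   character vector), `mutations` (data.frame `gene`, `substitution`,
#'   `disease`), `evidence` (data.frame `gene`, `position`, `tier`), and
#'   `truth` (data.frame `gene`, `substitution`, `class`).
#' @export
generate_sequences_and_mutations <- function(config, genes = NULL) {
  validate_sim_config(config)
  set.seed(config$seed + 401L)
  ms <- config$motif_spec
  np <- ms$n_proteins
  len <- ms$seq_length
  genes <- genes %||% sprintf("PALM%d", seq_len(np))
  .assert(length(genes) == np && !anyDuplicated(genes),
          "configuration error: need one distinct gene name per protein")
  aa_bg <- setdiff(AA_STANDARD, "C")
  alt_pool <- c("F", "R", "Y", "G", "W", "S")
  diseases <- c("ALS", "Niemann-Pick disease type C",
                "Temporal lobe epilepsy", "Spastic paraplegia",
                "Episodic ataxia", "Primary dystonia")

  sequences <- character(np)
  mut <- list()
  evid <- list()
  truth <- list()
  for (i in seq_len(np)) {
    s <- sample(aa_bg, len, replace = TRUE)
    kinds <- c("known", "predicted", rep("di_cys", ms$di_cys),
               rep("cys_rich", ms$cys_rich), "none")
    kinds <- sample(kinds)  # shuffle layout order along the sequence
    pos <- 30L + 40L * (seq_along(kinds) - 1L) +
      sample(0:8, length(kinds), replace = TRUE)
    for (j in seq_along(kinds)) {
      p <- pos[j]
      cls <- switch(kinds[j],
        known = { s[p] <- "C"
                  evid[[length(evid) + 1L]] <- data.frame(
                    gene = genes[i], position = p, tier = "known",
                    stringsAsFactors = FALSE)
                  "known_palmitoylated" },
        predicted = { s[p] <- "C"
                      evid[[length(evid) + 1L]] <- data.frame(
                        gene = genes[i], position = p, tier = "predicted",
                        stringsAsFactors = FALSE)
                      "predicted" },
        di_cys = { s[c(p - 1L, p)] <- "C"; "di_cys_adjacent" },
        cys_rich = { s[c(p - 2L, p, p + 2L)] <- "C"; "cys_rich_region" },
        none = { s[p] <- "C"; "no_evidence" })
      sub <- sprintf("C%d%s", p, sample(alt_pool, 1L))
      mut[[length(mut) + 1L]] <- data.frame(
        gene = genes[i], substitution = sub,
        disease = sample(diseases, 1L), stringsAsFactors = FALSE)
      truth[[length(truth) + 1L]] <- data.frame(
        gene = genes[i], substitution = sub, class = cls,
        stringsAsFactors = FALSE)
    }
    # Decoys: a non-cysteine substitution and a reference mismatch.
    p_dec <- 15L
    ref <- s[p_dec]
    sub_dec <- sprintf("%s%d%s", ref, p_dec, if (ref == "V") "I" else "V")
    mut[[length(mut) + 1L]] <- data.frame(gene = genes[i],
                                          substitution = sub_dec,
                                          disease = sample(diseases, 1L),
                                          stringsAsFactors = FALSE)
    truth[[length(truth) + 1L]] <- data.frame(gene = genes[i],
                                              substitution = sub_dec,
                                              class = "not_cysteine",
                                              stringsAsFactors = FALSE)
    p_mm <- 20L  # backbone position, never cysteine
    sub_mm <- sprintf("C%dR", p_mm)
    mut[[length(mut) + 1L]] <- data.frame(gene = genes[i],
                                          substitution = sub_mm,
                                          disease = sample(diseases, 1L),
                                          stringsAsFactors = FALSE)
    truth[[length(truth) + 1L]] <- data.frame(gene = genes[i],
                                              substitution = sub_mm,
                                              class = "ref_mismatch",
                                              stringsAsFactors = FALSE)
    sequences[i] <- paste(s, collapse = "")
  }
  names(sequences) <- genes
  out <- list(sequences = sequences,
              mutations = do.call(rbind, mut),
              evidence = do.call(rbind, evid),
              truth = do.call(rbind, truth))
  class(out) <- "sim_motifs"
  out
}
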