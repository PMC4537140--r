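#' Configuration for the synthetic palmitoylome study generator
#'
#' Defines the study conditions emulated by the synthetic-data module: a
#' latent "true" palmitoylome inside a larger background proteome, a set of
#' proteomics studies that each detect latent genes with some probability and
#' report them in their own identifier namespace with curation noise, planted
#' study clusters that share a detection profile, annotation terms with
#' planted fold enrichments, a synaptic-style gene list with a planted
#' compendium-membership odds ratio, and protein sequences carrying planted
#' cysteine motifs.
#'
#' Defaults mirror the curated meta-analysis this package models: a
#' 1,838-gene palmitoylome inside a 17,858-gene MS-detectable background,
#' 15 studies (9 human, 5 mouse, 1 rat; three neuronal), per-study detection
#' probability 0.2 (yielding roughly 250-450 genes per study), and a noise
#' rate whose unrecoverable fraction reproduces a ~97.7% average
#' identifier-match rate.
#'
#' @param seed Integer seed; identical seed + config reproduce byte-identical
#'   outputs.
#' @param n_genes Size of the latent true palmitoylome.
#' @param n_background Size of the background gene universe; must be at least
#'   `n_genes`.
#' @param n_studies Number of studies to simulate.
#' @param detection_prob Per-study probability that a latent gene is detected;
#'   scalar or vector of length `n_studies`, each in \[0, 1\].
#' @param noise_rate Fraction of reported identifiers corrupted. Corruptions
#'   are 50% case perturbation, 30% synonym substitution (gene-symbol studies
#'   only), 20% unmappable token.
#' @param planted_clusters List of integer vectors of study indices; studies
#'   within a group share one Bernoulli detection profile (identical true
#'   gene sets), planting a recoverable cluster.
#' @param planted_terms List of named numeric vectors
#'   `c(term_size = K, target_fe = FE)` describing annotation terms whose
#'   expected fold enrichment for compendium genes equals `target_fe`.
#' @param n_decoy_terms Number of unenriched decoy terms (expected fold
#'   enrichment 1).
#' @param synaptic_list_size Size of the generated synaptic-style gene list.
#' @param synaptic_overlap_odds Odds ratio of compendium membership inside
#'   versus outside the synaptic list; positive real. 1 plants the null.
#' @param motif_spec Named list: `n_proteins`, `seq_length`, `di_cys`
#'   (planted adjacent di-cysteine pairs per sequence), `cys_rich` (planted
#'   cysteine-rich windows per sequence).
#'
#' @return An object of class `sim_config`.
#' @examples
#' cfg <- sim_config(seed = 1, n_genes = 60, n_background = 300,
#'                   n_studies = 6)
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 1838L,
                       n_background = 17858L,
                       n_studies = 15L,
                       detection_prob = 0.2,
                       noise_rate = 0.117,
                       planted_clusters = list(c(10L, 11L)),
                       planted_terms = list(c(term_size = 50, target_fe = 6),
                                            c(term_size = 100, target_fe = 3),
                                            c(term_size = 80, target_fe = 2.5)),
                       n_decoy_terms = 40L,
                       synaptic_list_size = 1028L,
                       synaptic_overlap_odds = 7,
                       motif_spec = list()) {
  ms <- utils::modifyList(
    list(n_proteins = 6L, seq_length = 400L, di_cys = 1L, cys_rich = 1L),
    motif_spec)
  cfg <- list(seed = as.integer(seed),
              n_genes = as.integer(n_genes),
              n_background = as.integer(n_background),
              n_studies = as.integer(n_studies),
              detection_prob = as.numeric(detection_prob),
              noise_rate = as.numeric(noise_rate),
              planted_clusters = lapply(planted_clusters, as.integer),
              planted_terms = planted_terms,
              n_decoy_terms = as.integer(n_decoy_terms),
              synaptic_list_size = as.integer(synaptic_list_size),
              synaptic_overlap_odds = as.numeric(synaptic_overlap_odds),
              motif_spec = ms)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @noRd
validate_sim_config <- function(cfg) {
  .assert(inherits(cfg, "sim_config"), "configuration error: not a sim_config")
  with(cfg, {
    .assert(length(seed) == 1L && is.finite(seed),
            "configuration error: seed must be a single integer")
    .assert(n_genes >= 1L, "configuration error: n_genes must be positive")
    .assert(n_genes <= n_background,
            "configuration error: n_genes must not exceed n_background")
    .assert(n_studies >= 1L, "configuration error: n_studies must be positive")
    .assert(length(detection_prob) %in% c(1L, n_studies),
            "configuration error: detection_prob must be scalar or one per study")
    .assert(all(detection_prob >= 0 & detection_prob <= 1),
            "configuration error: detection_prob must lie in [0, 1]")
    .assert(noise_rate >= 0 && noise_rate <= 1,
            "configuration error: noise_rate must lie in [0, 1]")
    for (g in planted_clusters) {
      .assert(length(g) >= 2L && all(g >= 1L & g <= n_studies) &&
                !anyDuplicated(g),
              "configuration error: planted_clusters must hold >=2 distinct study indices")
    }
    .assert(!anyDuplicated(unlist(planted_clusters)),
            "configuration error: planted_clusters must be disjoint")
    for (pt in planted_terms) {
      .assert(all(c("term_size", "target_fe") %in% names(pt)),
              "configuration error: planted term needs term_size and target_fe")
      .assert(pt[["term_size"]] >= 1,
              "configuration error: term_size must be positive")
      .assert(pt[["target_fe"]] > 0,
              "configuration error: target_fe must be positive")
    }
    .assert(n_decoy_terms >= 0L, "configuration error: n_decoy_terms < 0")
    .assert(synaptic_overlap_odds > 0,
            "configuration error: synaptic_overlap_odds must be positive")
    .assert(synaptic_list_size >= 1L,
            "configuration error: synaptic_list_size must be positive")
    .assert(motif_spec$n_proteins >= 1L && motif_spec$seq_length >= 120L,
            "configuration error: motif_spec needs n_proteins >= 1, seq_length >= 120")
    .assert(motif_spec$di_cys >= 0L && motif_spec$cys_rich >= 0L,
            "configuration error: motif counts must be non-negative")
    # Planted sites are laid out on a 40-residue grid; make sure they fit.
    n_sites <- 3L + motif_spec$di_cys + motif_spec$cys_rich
    .assert(motif_spec$seq_length >= 40L * n_sites + 60L,
            "configuration error: seq_length too short for requested motif counts")
  })
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic palmitoylome simulation configuration\n")
  cat(sprintf("  seed: %d\n", x$seed))
  cat(sprintf("  latent palmitoylome: %d genes in background of %d\n",
              x$n_genes, x$n_background))
  cat(sprintf("  studies: %d (detection_prob %s, noise_rate %.3f)\n",
              x$n_studies, paste(signif(unique(x$detection_prob), 3),
                                 collapse = "/"), x$noise_rate))
  cat(sprintf("  planted clusters: %s\n",
              if (length(x$planted_clusters)) paste(vapply(x$planted_clusters,
                paste, "", collapse = ","), collapse = "; ") else "none"))
  cat(sprintf("  planted terms: %d (+%d decoys); synaptic odds: %.2f\n",
              length(x$planted_terms), x$n_decoy_terms,
              x$synaptic_overlap_odds))
  invisible(x)
}
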