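#' Apply curation exclusion rules to a study table
#'
#' Removes rows flagged by the meta-analysis curation rules (e.g. entries a
#' source study itself later labelled disproved, or rows enriched in
#' negative controls). Rules for other studies are ignored; a rule matching
#' zero rows raises a warning, not an error. Every rule must cite a reason.
#'
#' @param table Study table (data.frame with column `identifier` and,
#'   ideally, a `study_id` attribute).
#' @param rules Data.frame with columns `study_id`, `raw_identifier`,
#'   `reason`.
#' @return The table with matching rows removed; attributes preserved.
#' @export
apply_exclusions <- function(table, rules) {
  if (is.null(rules) || nrow(rules) == 0L) return(table)
  .assert(all(c("study_id", "raw_identifier", "reason") %in% names(rules)),
          "format error: exclusion rules need study_id, raw_identifier, reason")
  .assert(all(nzchar(rules$reason)),
          "validation error: every exclusion rule must cite a reason")
  sid <- attr(table, "study_id") %||% "study"
  mine <- rules[rules$study_id == sid, , drop = FALSE]
  if (nrow(mine) == 0L) return(table)
  keep <- rep(TRUE, nrow(table))
  for (i in seq_len(nrow(mine))) {
    hit <- table$identifier == mine$raw_identifier[i]
    if (!any(hit)) {
      warning(sprintf("exclusion rule for '%s' in %s matched no rows",
                      mine$raw_identifier[i], sid), call. = FALSE)
    } else {
      message(sprintf("[curate] %s: excluding %d row(s) for '%s' (%s)",
                      sid, sum(hit), mine$raw_identifier[i], mine$reason[i]))
      keep <- keep & !hit
    }
  }
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  for (a in c("study_id", "namespace", "species")) {
    attr(out, a) <- attr(table, a)
  }
  out
}

#' Assign a confidence tier to a compendium gene
#'
#' Genes identified in more than one study, and particularly by more than
#' one method, are more likely to be truly palmitoylated; detections backed
#' by the hydroxylamine-cleavage negative control carry the most weight.
#' Rule order: `multi_method_with_HAM` if at least two methods including
#' `bioorthogonal_HAM`; else `multi_method` if at least two methods; else
#' `multi_study` if at least two studies; else `single_study`.
#'
#' @param n_studies Number of studies the gene was identified in.
#' @param methods Character vector of detection methods across those
#'   studies.
#' @return The tier label.
#' @examples
#' assign_confidence(3, c("ABE", "bioorthogonal_HAM"))
#' @export
assign_confidence <- function(n_studies, methods) {
  methods <- unique(methods)
  .assert(length(methods) >= 1L, "validation error: methods must be non-empty")
  if (length(methods) >= 2L && "bioorthogonal_HAM" %in% methods) {
    "multi_method_with_HAM"
  } else if (length(methods) >= 2L) {
    "multi_method"
  } else if (n_studies >= 2L) {
    "multi_study"
  } else {
    "single_study"
  }
}

#' Build the annotated palmitoylome compendium
#'
#' Merges per-study consolidated gene sets into one entry per gene with a
#' per-study 0/1 flag (annotated once per study regardless of how many times
#' the study identified the gene), per-method 0/1 flags, the number of
#' studies observed in, the neuronal/non-neuronal source class, and a
#' confidence tier. Output rows are sorted by gene symbol for reproducible
#' files.
#'
#' @param study_genes Named list: study id -> character vector of gene
#'   symbols (duplicates tolerated), e.g. `unify_homologs()$study_genes`.
#' @param manifest Study manifest (see [default_manifest()]); every study in
#'   `study_genes` must have metadata here.
#' @param gene_keys Optional gene-key data.frame
#'   (`unify_homologs()$gene_keys`) used to fill per-species entry names and
#'   Entrez IDs.
#' @return A `palm_compendium` data.frame: `gene_symbol`, entry name and
#'   Entrez columns, one `study_<id>` column per study, one `method_<m>`
#'   column per method, `n_studies`, `confidence_tier`, `source_class`.
#' @examples
#' man <- default_manifest(sim_config(n_studies = 2, n_genes = 5,
#'                                    n_background = 10))
#' build_compendium(list(study01 = c("A", "B"), study02 = c("B", "C")), man)
#' @export
build_compendium <- function(study_genes, manifest, gene_keys = NULL) {
  .assert(length(study_genes) > 0L && !is.null(names(study_genes)),
          "validation error: study_genes must be a non-empty named list")
  missing <- setdiff(names(study_genes), manifest$study_id)
  .assert(length(missing) == 0L,
          "configuration error: no manifest metadata for study: ",
          paste(missing, collapse = ", "))
  sids <- manifest$study_id[manifest$study_id %in% names(study_genes)]
  study_genes <- lapply(study_genes[sids], function(g) unique(.norm_id(g)))
  genes <- sort_c(unique(unlist(study_genes, use.names = FALSE)))
  .assert(length(genes) > 0L, "validation error: no genes to merge")

  flags <- vapply(study_genes, function(g) as.integer(genes %in% g),
                  integer(length(genes)))
  flags <- matrix(flags, nrow = length(genes),
                  dimnames = list(genes, sids))
  meth_by_study <- strsplit(manifest$methods[match(sids, manifest$study_id)],
                            ",", fixed = TRUE)
  method_mat <- vapply(.method_levels, function(m) {
    use <- vapply(meth_by_study, function(mm) m %in% trimws(mm), TRUE)
    as.integer(flags[, use, drop = FALSE] %*% rep(1L, sum(use)) > 0L)
  }, integer(length(genes)))
  method_mat <- matrix(method_mat, nrow = length(genes),
                       dimnames = list(genes, .method_levels))

  n_studies <- as.integer(rowSums(flags))
  neuronal <- manifest$neuronal[match(sids, manifest$study_id)]
  any_neu <- rowSums(flags[, neuronal, drop = FALSE]) > 0L
  any_non <- rowSums(flags[, !neuronal, drop = FALSE]) > 0L
  source_class <- ifelse(any_neu & any_non, "both",
                         ifelse(any_neu, "neuronal_only", "non_neuronal_only"))
  n_methods <- rowSums(method_mat > 0L)
  tier <- ifelse(n_methods >= 2L & method_mat[, "bioorthogonal_HAM"] > 0L,
                 "multi_method_with_HAM",
                 ifelse(n_methods >= 2L, "multi_method",
                        ifelse(n_studies >= 2L, "multi_study",
                               "single_study")))

  key_cols <- c("entry_name_human", "entry_name_mouse", "entry_name_rat",
                "entrez_human", "entrez_mouse", "entrez_rat")
  keys <- if (!is.null(gene_keys)) {
    gene_keys[match(genes, .norm_id(gene_keys$gene_symbol)), key_cols]
  } else {
    data.frame(entry_name_human = NA_character_,
               entry_name_mouse = NA_character_,
               entry_name_rat = NA_character_,
               entrez_human = NA_integer_, entrez_mouse = NA_integer_,
               entrez_rat = NA_integer_)[rep(1L, length(genes)), ]
  }
  comp <- data.frame(gene_symbol = genes, keys, stringsAsFactors = FALSE,
                     row.names = NULL)
  comp <- cbind(comp,
                stats::setNames(as.data.frame(flags, row.names = NULL),
                                paste0("study_", sids)),
                stats::setNames(as.data.frame(method_mat, row.names = NULL),
                                paste0("method_", .method_levels)))
  comp$n_studies <- n_studies
  comp$confidence_tier <- tier
  comp$source_class <- source_class
  rownames(comp) <- NULL
  class(comp) <- c("palm_compendium", "data.frame")
  attr(comp, "study_ids") <- sids
  attr(comp, "manifest") <- manifest
  comp
}

#' Partition the compendium by neuronal versus non-neuronal source
#'
#' @param compendium A `palm_compendium` data.frame.
#' @return List with `counts` and `fractions` over the three disjoint
#'   classes (`neuronal_only`, `non_neuronal_only`, `both`), the compendium
#'   size `n`, and `any_non_neuronal` (genes with at least one non-neuronal
#'   source, i.e. `non_neuronal_only + both`).
#' @export
partition_by_source <- function(compendium) {
  .assert("source_class" %in% names(compendium),
          "format error: not a compendium (no source_class column)")
  lv <- c("neuronal_only", "non_neuronal_only", "both")
  counts <- table(factor(compendium$source_class, levels = lv))
  counts <- stats::setNames(as.integer(counts), lv)
  n <- nrow(compendium)
  list(counts = counts, fractions = counts / n, n = n,
       any_non_neuronal = counts[["non_neuronal_only"]] + counts[["both"]])
}

#' Write and read the compendium TSV
#'
#' Lossless round-trip of all compendium fields; `read_compendium(write_compendium(x)) == x`.
#' Study and method flag columns are identified by their `study_` /
#' `method_` prefixes. Malformed files raise a format error naming the first
#' offending line.
#'
#' @param compendium A `palm_compendium` data.frame.
#' @param path File path.
#' @return `write_compendium` returns the path invisibly; `read_compendium`
#'   the compendium.
#' @export
write_compendium <- function(compendium, path) {
  .write_tsv(as.data.frame(compendium), path)
}

#' @rdname write_compendium
#' @export
read_compendium <- function(path) {
  .assert(file.exists(path), "format error: no such file: ", path)
  df <- .read_tsv(path)
  fixed <- c("gene_symbol", "n_studies", "confidence_tier", "source_class")
  missing <- setdiff(fixed, names(df))
  .assert(length(missing) == 0L, "format error: compendium file missing columns: ",
          paste(missing, collapse = ", "))
  study_cols <- grep("^study_", names(df), value = TRUE)
  .assert(length(study_cols) > 0L,
          "format error: compendium file has no study_ columns")
  for (cc in c(study_cols, grep("^method_", names(df), value = TRUE))) {
    ok <- df[[cc]] %in% c("0", "1")
    .assert(all(ok), sprintf(
      "format error: non-binary value in column %s at line %d", cc,
      if (any(!ok)) which(!ok)[1L] + 1L else 0L))
    df[[cc]] <- as.integer(df[[cc]])
  }
  df$n_studies <- as.integer(df$n_studies)
  for (cc in grep("^entrez_", names(df), value = TRUE)) {
    df[[cc]] <- suppressWarnings(as.integer(df[[cc]]))
  }
  for (cc in grep("^entry_name_", names(df), value = TRUE)) {
    df[[cc]][!nzchar(df[[cc]])] <- NA_character_
  }
  chk <- rowSums(df[, study_cols, drop = FALSE])
  bad <- which(chk != df$n_studies)
  .assert(length(bad) == 0L, sprintf(
    "format error: n_studies inconsistent with study flags at line %d",
    if (length(bad)) bad[1L] + 1L else 0L))
  class(df) <- c("palm_compendium", "data.frame")
  attr(df, "study_ids") <- sub("^study_", "", study_cols)
  df
}

#' @export
print.palm_compendium <- function(x, ...) {
  p <- partition_by_source(x)
  cat(sprintf("Palmitoylome compendium: %d genes, %d studies\n", nrow(x),
              length(grep("^study_", names(x)))))
  cat(sprintf("  neuronal-only %d (%.0f%%), non-neuronal-only %d (%.0f%%), both %d (%.0f%%)\n",
              p$counts[["neuronal_only"]], 100 * p$fractions[["neuronal_only"]],
              p$counts[["non_neuronal_only"]],
              100 * p$fractions[["non_neuronal_only"]],
              p$counts[["both"]], 100 * p$fractions[["both"]]))
  cat(sprintf("  tiers: %s\n",
              paste(names(table(x$confidence_tier)),
                    table(x$confidence_tier), sep = "=", collapse = ", ")))
  invisible(x)
}
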