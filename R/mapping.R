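.mapping_cols <- c("entry_name", "gene_symbol", "synonyms", "full_name",
                   "entrez_id", "species", "reviewed", "ensembl_id",
                   "refseq_id", "gi_number")

#' Validate and class a mapping database
#'
#' Checks the invariants every identifier-resolution step relies on: unique
#' entry names, species derivable from the `NAME_SPECIES` suffix, and at
#' least one of gene symbol, synonyms or full name populated per record.
#'
#' @param df Data.frame with columns `entry_name`, `gene_symbol`,
#'   `synonyms` (pipe-separated), `full_name`, `entrez_id`, `species`,
#'   `reviewed`, and cross-reference columns `ensembl_id`, `refseq_id`,
#'   `gi_number`.
#' @return The validated data.frame with class `mapping_db` prepended.
#' @export
as_mapping_db <- function(df) {
  df <- as.data.frame(df)
  missing <- setdiff(.mapping_cols, names(df))
  .assert(length(missing) == 0L,
          "format error: mapping database is missing columns: ",
          paste(missing, collapse = ", "))
  .assert(nrow(df) > 0L, "format error: mapping database has no records")
  dup <- df$entry_name[duplicated(df$entry_name)]
  .assert(length(dup) == 0L,
          "integrity error: duplicated entry_name in mapping database: ",
          paste(utils::head(dup, 3L), collapse = ", "))
  df$entrez_id <- as.integer(df$entrez_id)
  df$reviewed <- as.logical(df$reviewed)
  for (cc in c("ensembl_id", "refseq_id", "gi_number", "synonyms")) {
    df[[cc]][is.na(df[[cc]])] <- ""
  }
  .assert(all(df$species %in% .species_levels),
          "integrity error: species must be one of ",
          paste(.species_levels, collapse = "/"))
  suf_ok <- mapply(function(e, sp) endsWith(e, paste0("_", .species_suffix[[sp]])),
                   df$entry_name, df$species)
  .assert(all(suf_ok),
          "integrity error: entry_name suffix inconsistent with species")
  some <- nzchar(df$gene_symbol) | nzchar(df$synonyms) | nzchar(df$full_name)
  .assert(all(some),
          "integrity error: record with no gene_symbol, synonyms or full_name")
  if (!inherits(df, "mapping_db")) class(df) <- c("mapping_db", "data.frame")
  df
}

#' Load a mapping database from TSV
#'
#' @param path Path to a tab-separated file with the schema described in
#'   [as_mapping_db()].
#' @return A validated `mapping_db` data.frame.
#' @export
load_mapping_database <- function(path) {
  .assert(file.exists(path), "format error: no such file: ", path)
  .assert(file.size(path) > 0L, "format error: empty mapping database file: ",
          path)
  df <- tryCatch(.read_tsv(path),
                 error = function(e) stop("format error: ", conditionMessage(e),
                                          call. = FALSE))
  .assert(nrow(df) > 0L, "format error: mapping database has no data rows")
  if ("reviewed" %in% names(df)) {
    df$reviewed <- toupper(df$reviewed) %in% c("TRUE", "1", "YES")
  }
  as_mapping_db(df)
}

#' Build hash indexes over a mapping database
#'
#' Pre-computes case-normalized lookup tables for every resolution route so
#' per-identifier resolution is O(1). Called once per database by
#' [match_study()]; expose it to reuse across studies.
#'
#' @param db A `mapping_db` data.frame.
#' @return A list of route indexes, class `mapping_index`.
#' @export
db_index <- function(db) {
  db <- as_mapping_db(db)
  n <- nrow(db)
  syn <- strsplit(db$synonyms, "|", fixed = TRUE)
  syn_rows <- rep(seq_len(n), lengths(syn))
  idx <- list(
    entry = .key_index(.norm_id(db$entry_name)),
    symbol = .key_index(.norm_id(db$gene_symbol)),
    synonym = .key_index(.norm_id(unlist(syn)), syn_rows),
    full_name = .key_index(.norm_id(db$full_name)),
    ensembl = .key_index(.norm_id(db$ensembl_id)),
    refseq = .key_index(.norm_id(db$refseq_id)),
    gi = .key_index(.norm_id(db$gi_number)))
  structure(idx, class = "mapping_index")
}

.namespace_patterns <- c(
  uniprot_entry_name = "^[A-Z0-9]{1,10}_[A-Z0-9]{1,5}$",
  ensembl_gene = "^ENS[A-Z]{0,4}G[0-9]{11}$",
  refseq_accession = "^[NXY]P_[0-9]+(\\.[0-9]+)?$",
  ncbi_gi = "^(GI[:|])?[0-9]+$",
  gene_symbol = "^[A-Z][A-Z0-9-]{0,14}$")

#' Detect the identifier namespace of a study table
#'
#' Applies case-insensitive pattern rules for the five namespaces used
#' across the source studies and returns the namespace matched by the
#' majority of identifiers. Patterns are tried in specificity order (entry
#' name, Ensembl gene, RefSeq, GI, gene symbol) so identifiers matching
#' several rules are credited to the most specific one.
#'
#' @param identifiers Non-empty character vector.
#' @return The namespace name, with attribute `fraction` (the match
#'   fraction). If no namespace exceeds 50%, an ambiguity error naming the
#'   top two candidates is raised.
#' @examples
#' detect_namespace(c("SODC_HUMAN", "NPC1_HUMAN"))
#' @export
detect_namespace <- function(identifiers) {
  .assert(length(identifiers) > 0L,
          "validation error: empty identifier list")
  ids <- .norm_id(identifiers)
  hit <- matrix(FALSE, length(ids), length(.namespace_patterns),
                dimnames = list(NULL, names(.namespace_patterns)))
  for (ns in names(.namespace_patterns)) {
    hit[, ns] <- grepl(.namespace_patterns[[ns]], ids)
  }
  # Most specific namespace wins per identifier.
  first <- apply(hit, 1L, function(h) if (any(h)) which(h)[1L] else NA_integer_)
  frac <- vapply(seq_along(.namespace_patterns),
                 function(i) mean(!is.na(first) & first == i), 0)
  names(frac) <- names(.namespace_patterns)
  ord <- order(-frac)
  if (frac[ord[1L]] <= 0.5) {
    stop(sprintf(
      "ambiguity error: no namespace matches a majority of identifiers (top candidates: %s %.0f%%, %s %.0f%%)",
      names(frac)[ord[1L]], 100 * frac[ord[1L]],
      names(frac)[ord[2L]], 100 * frac[ord[2L]]), call. = FALSE)
  }
  structure(names(frac)[ord[1L]], fraction = unname(frac[ord[1L]]))
}

#' Resolve one identifier against the mapping database
#'
#' Builds the candidate set for the identifier's namespace (entry-name,
#' Ensembl, RefSeq and GI identifiers resolve by their own cross-reference
#' route; gene symbols try primary symbol, then synonyms, then full name -
#' first non-empty route wins). Matching is case-insensitive after
#' whitespace trimming; RefSeq versions are stripped. When both reviewed
#' (Swiss-Prot-style) and unreviewed candidates exist, only reviewed ones
#' are kept; a species hint then prefers same-species candidates. If more
#' than one candidate survives, the lexicographically smallest entry name is
#' kept with a warning.
#'
#' @param raw Identifier string.
#' @param namespace One of `uniprot_entry_name`, `ensembl_gene`,
#'   `gene_symbol`, `refseq_accession`, `ncbi_gi`.
#' @param db A `mapping_db` data.frame.
#' @param species_hint Optional species (`human`/`mouse`/`rat`).
#' @param index Optional pre-built [db_index()]; computed on the fly if
#'   missing.
#' @return A one-row data.frame (`raw_identifier`, `entry_name`,
#'   `gene_symbol`, `entrez_id`, `species`, `reviewed`, `route`), or `NULL`
#'   when unmatched (a return state, not an error).
#' @export
resolve_identifier <- function(raw, namespace, db, species_hint = NULL,
                               index = NULL) {
  .assert(namespace %in% .namespace_levels,
          "validation error: unknown namespace: ", namespace)
  index <- index %||% db_index(db)
  key <- .norm_id(raw)
  if (is.na(key) || !nzchar(key)) return(NULL)
  rows <- NULL
  route <- "exact"
  if (namespace == "uniprot_entry_name") {
    rows <- index$entry[[key]]
  } else if (namespace == "ensembl_gene") {
    rows <- index$ensembl[[key]]
  } else if (namespace == "refseq_accession") {
    rows <- index$refseq[[sub("\\.[0-9]+$", "", key)]]
  } else if (namespace == "ncbi_gi") {
    rows <- index$gi[[sub("^GI[:|]", "", key)]]
  } else {
    rows <- index$symbol[[key]]
    if (is.null(rows)) {
      rows <- index$synonym[[key]]
      route <- "synonym"
    }
    if (is.null(rows)) {
      rows <- index$full_name[[key]]
      route <- "full_name"
    }
  }
  if (is.null(rows) || length(rows) == 0L) return(NULL)
  cand <- db[rows, , drop = FALSE]
  if (any(cand$reviewed) && any(!cand$reviewed)) {
    cand <- cand[cand$reviewed, , drop = FALSE]
  }
  if (!is.null(species_hint) && any(cand$species == species_hint)) {
    cand <- cand[cand$species == species_hint, , drop = FALSE]
  }
  if (nrow(cand) > 1L) {
    cand <- cand[order(cand$entry_name, method = "radix"), , drop = FALSE]
    warning(sprintf("ambiguous identifier '%s': %d candidates, keeping %s",
                    raw, nrow(cand), cand$entry_name[1L]), call. = FALSE)
  }
  data.frame(raw_identifier = as.character(raw),
             entry_name = cand$entry_name[1L],
             gene_symbol = cand$gene_symbol[1L],
             entrez_id = cand$entrez_id[1L],
             species = cand$species[1L],
             reviewed = cand$reviewed[1L],
             route = route,
             stringsAsFactors = FALSE)
}

#' Match every identifier of one study against the mapping database
#'
#' Applies [resolve_identifier()] row-wise; unmatched identifiers are
#' reported, not errors. Ambiguity tie-break warnings are counted and
#' summarised rather than emitted per row.
#'
#' @param table Study table: data.frame with column `identifier` (optionally
#'   `description`), ideally carrying attributes `study_id`, `namespace`,
#'   `species` (as produced by [generate_study_tables()] or the pipeline
#'   loader). The namespace is detected with [detect_namespace()] when
#'   absent.
#' @param db A `mapping_db` data.frame.
#' @param index Optional pre-built [db_index()].
#' @return Object of class `match_result`: list with `study_id`,
#'   `namespace`, `matched` (data.frame incl. resolution route), `unmatched`
#'   (character), `match_rate`, `n_ambiguous`.
#' @export
match_study <- function(table, db, index = NULL) {
  .assert(is.data.frame(table) && "identifier" %in% names(table),
          "format error: study table needs an 'identifier' column")
  .assert(nrow(table) > 0L, "validation error: study table has no rows")
  study_id <- attr(table, "study_id") %||% "study"
  ns <- attr(table, "namespace") %||% detect_namespace(table$identifier)
  hint <- attr(table, "species")
  index <- index %||% db_index(db)
  n_amb <- 0L
  res <- withCallingHandlers(
    lapply(table$identifier, resolve_identifier, namespace = ns, db = db,
           species_hint = hint, index = index),
    warning = function(w) {
      if (grepl("ambiguous identifier", conditionMessage(w))) {
        n_amb <<- n_amb + 1L
        invokeRestart("muffleWarning")
      }
    })
  ok <- !vapply(res, is.null, TRUE)
  matched <- if (any(ok)) do.call(rbind, res[ok]) else
    data.frame(raw_identifier = character(), entry_name = character(),
               gene_symbol = character(), entrez_id = integer(),
               species = character(), reviewed = logical(),
               route = character(), stringsAsFactors = FALSE)
  out <- list(study_id = study_id, namespace = as.character(ns),
              matched = matched,
              unmatched = as.character(table$identifier[!ok]),
              match_rate = mean(ok), n_ambiguous = n_amb)
  class(out) <- "match_result"
  message(sprintf("[curate] %s: %d/%d identifiers matched (%.2f%%)%s",
                  study_id, sum(ok), length(ok), 100 * mean(ok),
                  if (n_amb) sprintf(", %d ambiguous (tie-broken)", n_amb)
                  else ""))
  out
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("Match result for %s (%s): %.2f%% matched, %d unmatched\n",
              x$study_id, x$namespace, 100 * x$match_rate,
              length(x$unmatched)))
  invisible(x)
}

#' Collapse matched records into cross-species gene keys
#'
#' Records resolving to the same uppercased gene symbol - or, for records
#' without a symbol, to entry names sharing the prefix before `_` - collapse
#' into one gene key. Where an entry-name prefix group spans two different
#' symbols, the symbol route wins and the conflict is logged. Per-species
#' entry names and Entrez IDs are then filled from the database's reviewed
#' records wherever the symbol exists in that species, inferring homologs
#' for genes not reported in all three species.
#'
#' @param matches A `match_result` or list of them.
#' @param db A `mapping_db` data.frame.
#' @return Object of class `gene_key_set`: list with `gene_keys`
#'   (data.frame: `gene_symbol`, per-species entry names and Entrez IDs) and
#'   `study_genes` (named list mapping study id -> character vector of
#'   canonical gene symbols).
#' @export
unify_homologs <- function(matches, db) {
  if (inherits(matches, "match_result")) matches <- list(matches)
  .assert(length(matches) > 0L, "validation error: no match results")
  db <- as_mapping_db(db)
  rec <- do.call(rbind, lapply(matches, function(m) {
    if (nrow(m$matched) == 0L) return(NULL)
    cbind(m$matched, study_id = m$study_id, stringsAsFactors = FALSE)
  }))
  .assert(!is.null(rec) && nrow(rec) > 0L,
          "validation error: no matched records to unify")
  sym <- .norm_id(rec$gene_symbol)
  prefix <- sub("_[^_]*$", "", .norm_id(rec$entry_name))
  key <- ifelse(nzchar(sym), sym, prefix)
  # Entry-name prefixes spanning several symbols: symbol route wins.
  pf_tab <- unique(data.frame(prefix = prefix, key = key,
                              stringsAsFactors = FALSE))
  conflicts <- unique(pf_tab$prefix[duplicated(pf_tab$prefix)])
  if (length(conflicts)) {
    message(sprintf(
      "[curate] %d entry-name prefix group(s) span multiple gene symbols; symbol grouping kept",
      length(conflicts)))
  }
  keys <- sort_c(unique(key))

  rev_db <- db[db$reviewed, ]
  fill <- function(sp, what) {
    d <- rev_db[rev_db$species == sp, ]
    d[[what]][match(keys, .norm_id(d$gene_symbol))]
  }
  gene_keys <- data.frame(
    gene_symbol = keys,
    entry_name_human = fill("human", "entry_name"),
    entry_name_mouse = fill("mouse", "entry_name"),
    entry_name_rat = fill("rat", "entry_name"),
    entrez_human = fill("human", "entrez_id"),
    entrez_mouse = fill("mouse", "entrez_id"),
    entrez_rat = fill("rat", "entrez_id"),
    stringsAsFactors = FALSE)
  study_genes <- lapply(split(key, rec$study_id), function(k)
    sort_c(unique(k)))
  out <- list(gene_keys = gene_keys, study_genes = study_genes)
  class(out) <- "gene_key_set"
  out
}
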