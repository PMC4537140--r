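#' Read and write gene-set collections in GMT format
#'
#' One term per line: term id, description, then member genes, tab-separated.
#' The description field carries `category|name`, which this pipeline uses to
#' group the false-discovery-rate correction by annotation category;
#' `read_gmt` recovers both (a description without `|` becomes the name, with
#' category `uncategorized`).
#'
#' @param sets Named list of character vectors (term id -> genes).
#' @param path File path.
#' @param meta Optional data.frame with columns `term_id`, `name`,
#'   `category` matched by term id.
#' @return `write_gmt` returns the path invisibly; `read_gmt` returns a list
#'   with `sets` (named list) and `meta` (data.frame `term_id`, `name`,
#'   `category`).
#' @export
write_gmt <- function(sets, path, meta = NULL) {
  .assert(length(sets) > 0L && !is.null(names(sets)),
          "format error: sets must be a non-empty named list")
  desc <- if (is.null(meta)) rep("uncategorized|", length(sets)) else {
    i <- match(names(sets), meta$term_id)
    .assert(!anyNA(i), "format error: meta is missing some term ids")
    paste0(meta$category[i], "|", meta$name[i])
  }
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], desc[i], sets[[i]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  .assert(file.exists(path), "format error: no such GMT file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  .assert(length(lines) > 0L, "format error: empty GMT file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  .assert(length(bad) == 0L,
          sprintf("format error: GMT line %d has fewer than 3 fields",
                  if (length(bad)) bad[1L] else 0L))
  ids <- vapply(parts, `[[`, "", 1L)
  desc <- vapply(parts, `[[`, "", 2L)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- ids
  has_cat <- grepl("|", desc, fixed = TRUE)
  meta <- data.frame(
    term_id = ids,
    name = ifelse(has_cat, sub("^[^|]*\\|", "", desc), desc),
    category = ifelse(has_cat, sub("\\|.*$", "", desc), "uncategorized"),
    stringsAsFactors = FALSE)
  list(sets = sets, meta = meta)
}

#' Read and write plain gene lists
#'
#' One gene per line; blank lines and `#` comment lines are skipped on read.
#'
#' @param genes Character vector.
#' @param path File path.
#' @return `read_gene_list` returns a character vector.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}

#' @rdname write_gene_list
#' @export
read_gene_list <- function(path) {
  .assert(file.exists(path), "format error: no such file: ", path)
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Read and write protein FASTA files
#'
#' Thin wrappers over [Biostrings::readAAStringSet()] /
#' [Biostrings::writeXStringSet()] returning plain named character vectors,
#' the representation the mutation-mining functions consume.
#'
#' @param sequences Named character vector of amino-acid sequences.
#' @param path File path.
#' @return `read_fasta` returns a named character vector.
#' @export
write_fasta <- function(sequences, path) {
  .assert(!is.null(names(sequences)),
          "format error: sequences must be named")
  Biostrings::writeXStringSet(Biostrings::AAStringSet(sequences), path,
                              width = 60L)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  .assert(file.exists(path), "format error: no such FASTA file: ", path)
  x <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write a mapping database to TSV
#'
#' Companion to [load_mapping_database()]; synonyms are pipe-separated,
#' missing cross-references are empty fields.
#'
#' @param db Mapping database data.frame.
#' @param path File path.
#' @export
write_mapping_db <- function(db, path) {
  .write_tsv(as.data.frame(db), path)
}
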