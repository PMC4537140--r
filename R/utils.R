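# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Twenty standard amino-acid one-letter codes.
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

.species_levels <- c("human", "mouse", "rat")
.species_suffix <- c(human = "HUMAN", mouse = "MOUSE", rat = "RAT")
.namespace_levels <- c("uniprot_entry_name", "ensembl_gene", "gene_symbol",
                       "refseq_accession", "ncbi_gi")
.method_levels <- c("ABE", "acyl_RAC", "bioorthogonal", "bioorthogonal_HAM")

.assert <- function(cond, ...) {
  if (!isTRUE(cond)) stop(..., call. = FALSE)
  invisible(TRUE)
}

log_sum_exp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

# Locale-independent sort (C collation) so signatures and file output are
# byte-reproducible across machines.
sort_c <- function(x) sort(x, method = "radix")

# Map 1-based indices in 1..26^4 to unique 4-letter tokens, vectorised.
.tok4 <- function(idx) {
  i <- idx - 1L
  paste0(LETTERS[i %/% 17576L %% 26L + 1L],
         LETTERS[i %/% 676L %% 26L + 1L],
         LETTERS[i %/% 26L %% 26L + 1L],
         LETTERS[i %% 26L + 1L])
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "", fileEncoding = "UTF-8")
  invisible(path)
}

.read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE,
             colClasses = "character", na.strings = NULL,
             check.names = FALSE, ...)
}

# Hash-backed lookup table: named list mapping key -> integer row indices.
.key_index <- function(keys, rows = seq_along(keys)) {
  keep <- !is.na(keys) & keys != ""
  split(rows[keep], keys[keep])
}

.norm_id <- function(x) toupper(trimws(x))
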