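.mining_tiers <- c("known_palmitoylated", "predicted", "di_cys_adjacent",
                   "cys_rich_region", "no_evidence", "not_cysteine",
                   "ref_mismatch")

#' @noRd
.get_sequence <- function(sequences, gene) {
  if (!gene %in% names(sequences)) return(NULL)
  sequences[[gene]]
}

#' Parse a protein substitution token
#'
#' Tokens follow the `C6F` convention: reference amino acid, 1-based
#' protein position, alternate amino acid.
#'
#' @param text Substitution token.
#' @return List with `ref`, `position`, `alt`.
#' @examples
#' parse_substitution("C1168Y")
#' @export
parse_substitution <- function(text) {
  m <- regmatches(text, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$",
                                as.character(text)))[[1L]]
  .assert(length(m) == 4L, "parse error: malformed substitution token: '",
          text, "'")
  ref <- toupper(m[2L]); alt <- toupper(m[4L])
  pos <- as.integer(m[3L])
  .assert(ref %in% AA_STANDARD && alt %in% AA_STANDARD,
          "parse error: non-standard amino acid in '", text, "'")
  .assert(pos >= 1L, "parse error: position must be >= 1 in '", text, "'")
  .assert(ref != alt, "parse error: reference equals alternate in '", text,
          "'")
  list(ref = ref, position = pos, alt = alt)
}

#' Partition mutation records by the cysteine filter
#'
#' Records with a cysteine reference residue confirmed by the sequence pass;
#' substitutions whose claimed reference residue disagrees with the sequence
#' (or whose position lies beyond it) are flagged `ref_mismatch`; other
#' residues are flagged `not_cysteine`. Records for genes without a supplied
#' sequence are flagged `no_sequence`.
#'
#' @param records Data.frame with columns `gene`, `substitution` (optionally
#'   `disease`).
#' @param sequences Named character vector of protein sequences (see
#'   [read_fasta()]).
#' @return The records with added columns `ref`, `position`, `alt`,
#'   `status` (`pass`, `not_cysteine`, `ref_mismatch`, `no_sequence`).
#' @export
filter_cysteine_mutations <- function(records, sequences) {
  .assert(all(c("gene", "substitution") %in% names(records)),
          "format error: records need gene and substitution columns")
  parsed <- lapply(records$substitution, parse_substitution)
  records$ref <- vapply(parsed, `[[`, "", "ref")
  records$position <- vapply(parsed, `[[`, 1L, "position")
  records$alt <- vapply(parsed, `[[`, "", "alt")
  status <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    seq <- .get_sequence(sequences, records$gene[i])
    if (is.null(seq) || is.na(seq)) {
      status[i] <- "no_sequence"
      next
    }
    pos <- records$position[i]
    if (pos > nchar(seq)) {
      status[i] <- "ref_mismatch"          # position beyond sequence length
    } else if (substr(seq, pos, pos) != records$ref[i]) {
      status[i] <- "ref_mismatch"
    } else if (records$ref[i] != "C") {
      status[i] <- "not_cysteine"
    } else {
      status[i] <- "pass"
    }
  }
  records$status <- status
  records
}

#' Detect an adjacent di-cysteine motif
#'
#' TRUE when the residue immediately before or after a cysteine is also a
#' cysteine (1-based, bounds-checked). Adjacent cysteine pairs are frequent
#' palmitoylation sites.
#'
#' @param sequence Protein sequence string.
#' @param position 1-based position of a cysteine in `sequence`.
#' @return Logical flag.
#' @export
detect_di_cys <- function(sequence, position) {
  n <- nchar(sequence)
  .assert(position >= 1L && position <= n,
          "validation error: position outside the sequence")
  .assert(substr(sequence, position, position) == "C",
          "validation error: residue at position is not cysteine")
  (position > 1L && substr(sequence, position - 1L, position - 1L) == "C") ||
    (position < n && substr(sequence, position + 1L, position + 1L) == "C")
}

#' Detect a cysteine-rich region around a position
#'
#' TRUE when some window of `window` consecutive residues containing
#' `position` holds at least `min_cys` cysteines. Windows larger than the
#' sequence clamp to the whole sequence.
#'
#' @param sequence Protein sequence string.
#' @param position 1-based position of a cysteine.
#' @param window Window length in residues (default 10).
#' @param min_cys Minimum cysteines within the window (default 3).
#' @return Logical flag.
#' @examples
#' detect_cys_rich("AAACCACCAA", 5)  # 4 Cys within one 10-residue window
#' @export
detect_cys_rich <- function(sequence, position, window = 10L, min_cys = 3L) {
  n <- nchar(sequence)
  .assert(position >= 1L && position <= n,
          "validation error: position outside the sequence")
  .assert(substr(sequence, position, position) == "C",
          "validation error: residue at position is not cysteine")
  w <- min(as.integer(window), n)
  is_c <- strsplit(sequence, "", fixed = TRUE)[[1L]] == "C"
  cum <- c(0L, cumsum(is_c))
  starts <- max(1L, position - w + 1L):min(position, n - w + 1L)
  any(cum[starts + w] - cum[starts] >= min_cys)
}

#' Classify mutations against palmitoylation-site evidence tiers
#'
#' Applies the cysteine filter, then classifies each passing record by the
#' evidence precedence known > predicted > di-Cys adjacent > Cys-rich
#' region > no evidence, mirroring the published mutation-table tiers
#' ("Yes" / "Predicted" / "Not predicted but di-Cys likely" / "Not
#' predicted but in Cys-rich region so likely"). A 21-residue sequence
#' context window (clamped at the termini) is attached to every record.
#'
#' @param records Mutation data.frame (`gene`, `substitution`, optionally
#'   `disease`).
#' @param sequences Named character vector of protein sequences.
#' @param evidence Optional data.frame `gene`, `position`, `tier`
#'   (`known`/`predicted`), e.g. literature-annotated and
#'   predictor-reported sites.
#' @param window,min_cys Cysteine-rich rule parameters (see
#'   [detect_cys_rich()]).
#' @return A `mining_result` data.frame: the input plus `ref`, `position`,
#'   `alt`, `classification` and `context`.
#' @export
classify_mutations <- function(records, sequences, evidence = NULL,
                               window = 10L, min_cys = 3L) {
  rec <- filter_cysteine_mutations(records, sequences)
  if (!is.null(evidence)) {
    .assert(all(c("gene", "position", "tier") %in% names(evidence)),
            "format error: evidence needs gene, position, tier columns")
    evidence$position <- as.integer(evidence$position)
    .assert(all(evidence$tier %in% c("known", "predicted")),
            "format error: evidence tier must be 'known' or 'predicted'")
  }
  cls <- character(nrow(rec))
  ctx <- character(nrow(rec))
  for (i in seq_len(nrow(rec))) {
    seq <- .get_sequence(sequences, rec$gene[i])
    pos <- rec$position[i]
    if (rec$status[i] != "pass") {
      cls[i] <- if (rec$status[i] == "no_sequence") NA_character_ else
        rec$status[i]
      ctx[i] <- if (!is.null(seq) && !is.na(seq) && pos <= nchar(seq)) {
        substr(seq, max(1L, pos - 10L), min(nchar(seq), pos + 10L))
      } else ""
      next
    }
    ev <- if (is.null(evidence)) NULL else
      evidence[evidence$gene == rec$gene[i], , drop = FALSE]
    cls[i] <- if (!is.null(ev) && pos %in% ev$position[ev$tier == "known"]) {
      "known_palmitoylated"
    } else if (!is.null(ev) && pos %in% ev$position[ev$tier == "predicted"]) {
      "predicted"
    } else if (detect_di_cys(seq, pos)) {
      "di_cys_adjacent"
    } else if (detect_cys_rich(seq, pos, window, min_cys)) {
      "cys_rich_region"
    } else {
      "no_evidence"
    }
    ctx[i] <- substr(seq, max(1L, pos - 10L), min(nchar(seq), pos + 10L))
  }
  rec$classification <- cls
  rec$context <- ctx
  class(rec) <- c("mining_result", "data.frame")
  rec
}
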