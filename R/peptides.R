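## peptides: anchored-peptide parsing, window extraction, formatting, cleaning.

#' Construct a peptide set from windows
#'
#' A peptide set holds equal-length anchored windows over the 20 amino acids
#' plus the padding symbol `X`, which may appear only as a contiguous prefix
#' and/or suffix of a window (termini padding). The anchor column (0-based,
#' equal to the upstream offset) is stored as an attribute together with the
#' window length `L` and the upstream/downstream offsets.
#'
#' @param windows Character vector of equal-length windows.
#' @param anchor_column 0-based column index of the anchoring residue.
#' @param protein_ids Optional per-window source protein IDs.
#' @param anchor_pos Optional per-window 1-based anchor position in the source
#'   protein.
#' @return A tibble of class `peptide_set` with columns `protein_id`,
#'   `anchor_pos` and `window`.
#' @export
peptide_set <- function(windows, anchor_column, protein_ids = NULL,
                        anchor_pos = NULL) {
  windows <- toupper(as.character(windows))
  if (length(windows) == 0) {
    abort("A peptide set needs at least one window.")
  }
  L <- unique(nchar(windows))
  if (length(L) != 1) {
    abort(paste0("Windows have unequal lengths: ",
                 paste(sort(L), collapse = ", "), "."))
  }
  anchor_column <- as.integer(anchor_column)
  if (anchor_column < 0 || anchor_column >= L) {
    abort("`anchor_column` must lie inside the window (0-based).")
  }
  check_window_alphabet(windows)
  core <- gsub("^X+|X+$", "", windows)
  if (any(grepl("X", core, fixed = TRUE))) {
    bad <- which(grepl("X", core, fixed = TRUE))
    abort(paste0("Interior X padding in window(s): ",
                 paste(head(bad, 5), collapse = ", "),
                 ". X may only pad termini."))
  }
  anchor_res <- substr(windows, anchor_column + 1, anchor_column + 1)
  if (any(!anchor_res %in% AA20)) {
    abort("Anchor column must hold a standard amino acid in every window.")
  }
  out <- tibble(
    protein_id = if (is.null(protein_ids)) NA_character_ else
      as.character(protein_ids),
    anchor_pos = if (is.null(anchor_pos)) NA_integer_ else
      as.integer(anchor_pos),
    window = windows
  )
  attr(out, "anchor_column") <- anchor_column
  attr(out, "upstream") <- anchor_column
  attr(out, "downstream") <- L - 1L - anchor_column
  attr(out, "L") <- L
  class(out) <- c("peptide_set", class(tibble()))
  out
}

check_window_alphabet <- function(windows) {
  ## non-standard residues (U, B, Z, *) are allowed and non-countable
  ok <- grepl(paste0("^[", paste(c(AA20, PAD, "UBZ"), collapse = ""),
                     "*]+$"), windows)
  if (any(!ok)) {
    abort(paste0("Window(s) with characters outside the amino-acid alphabet",
                 " + X: rows ", paste(head(which(!ok), 5), collapse = ", "),
                 "."))
  }
  invisible(windows)
}

#' @export
print.peptide_set <- function(x, ...) {
  cat("# A peptide set: ", nrow(x), " window(s) of length ", attr(x, "L"),
      ", anchor column ", attr(x, "anchor_column"),
      " (offsets -", attr(x, "upstream"), "..+", attr(x, "downstream"), ")\n",
      sep = "")
  NextMethod()
}

#' Parse a single anchored peptide string
#'
#' Anchors are marked either by a lowercase letter (`"ASTRSkSSTD"`) or by an
#' uppercase letter followed by an asterisk (`"ASTRSK*SSTD"`). All anchors are
#' reported as 1-based positions within the cleaned (upper-case,
#' asterisk-free) sequence.
#'
#' @param raw Peptide string with anchor marks.
#' @return A list with `clean_sequence` and integer vector `anchor_indices`.
#' @export
#' @examples
#' parse_anchored_sequence("ASTRSkSSTD")
#' parse_anchored_sequence("ASTRSK*SSTD")
parse_anchored_sequence <- function(raw) {
  if (length(raw) != 1 || !is.character(raw) || is.na(raw) || !nzchar(raw)) {
    abort("`raw` must be a single non-empty string.")
  }
  chars <- strsplit(raw, "", fixed = TRUE)[[1]]
  if (any(!grepl("^[A-Za-z*]$", chars))) {
    abort(paste0("Invalid character in anchored peptide: ", raw))
  }
  if (chars[1] == "*") {
    abort("Asterisk anchor mark cannot open a peptide; it must follow a letter.")
  }
  star <- chars == "*"
  if (any(star & c(FALSE, star[-length(star)]))) {
    abort("Consecutive asterisks are not a valid anchor mark.")
  }
  letters_only <- chars[!star]
  if (all(grepl("[a-z]", letters_only))) {
    abort(paste0("All residues are lowercase in \"", raw,
                 "\": anchor marks are ambiguous."))
  }
  ## An anchor is a lowercase letter, or any letter followed by "*".
  followed_by_star <- c(star[-1], FALSE)
  is_anchor <- (!star) & (grepl("[a-z]", chars) | followed_by_star)
  if (!any(is_anchor)) {
    abort(paste0("No anchor mark (lowercase letter or trailing *) in \"",
                 raw, "\"."))
  }
  clean_index <- cumsum(!star)
  list(
    clean_sequence = toupper(paste(chars[!star], collapse = "")),
    anchor_indices = clean_index[is_anchor]
  )
}

#' Resolve a positional anchor token against a proteome
#'
#' Positional anchors name the residue and its 1-based position in the full
#' protein, e.g. `"K123"` for lysine at residue 123. The residue identity is
#' verified against the protein sequence.
#'
#' @param token Anchor token, `<AA letter><1-based position>`.
#' @param proteome A proteome tibble.
#' @param protein_id Protein to resolve against.
#' @return A one-row tibble with `protein_id`, `anchor_pos` and `residue`.
#' @export
resolve_position_anchor <- function(token, proteome, protein_id) {
  if (!grepl("^[A-Za-z][0-9]+$", token)) {
    abort(paste0("Positional anchor must be <letter><position>, got \"",
                 token, "\"."))
  }
  res <- toupper(substr(token, 1, 1))
  pos <- as.integer(sub("^[A-Za-z]", "", token))
  row <- match(protein_id, proteome$protein_id)
  if (is.na(row)) {
    row <- match(protein_id, proteome$accession)
  }
  if (is.na(row)) {
    abort(paste0("Protein \"", protein_id, "\" not found in proteome."))
  }
  seq <- proteome$sequence[row]
  if (pos < 1 || pos > nchar(seq)) {
    abort(paste0("Anchor position ", pos, " is outside protein \"",
                 protein_id, "\" (length ", nchar(seq), ")."))
  }
  found <- substr(seq, pos, pos)
  if (found != res) {
    abort(paste0("Anchor residue mismatch at position ", pos, " of \"",
                 protein_id, "\": expected ", res, ", found ", found, "."))
  }
  tibble(protein_id = proteome$protein_id[row], anchor_pos = pos,
         residue = res)
}

## Vectorised fixed-width window extraction with X padding at termini.
window_at <- function(seqs, pos, upstream, downstream) {
  start <- pos - upstream
  end <- pos + downstream
  n <- nchar(seqs)
  core <- substr(seqs, pmax(start, 1L), pmin(end, n))
  paste0(strrep(PAD, pmax(0L, 1L - start)), core,
         strrep(PAD, pmax(0L, end - n)))
}

#' Extract anchored windows from a proteome
#'
#' Each window spans `upstream` residues before the anchor through
#' `downstream` residues after it; columns beyond the protein termini are
#' padded with `X`. Non-standard residues (U, B, Z, `*`) inside a window are
#' retained but treated as non-countable by all statistics, like padding; an
#' anchor falling on a non-standard residue is rejected.
#'
#' @param proteome A proteome tibble.
#' @param anchors A data frame with columns `protein_id` and `anchor_pos`
#'   (1-based position in the full protein).
#' @param upstream,downstream Non-negative residue counts flanking the anchor.
#' @return A [peptide_set()] with windows of length
#'   `upstream + 1 + downstream` and `anchor_column = upstream`.
#' @export
#' @examples
#' p <- as_proteome(data.frame(protein_id = "p1", sequence = "MKKD"))
#' extract_windows(p, data.frame(protein_id = "p1", anchor_pos = 3),
#'                 upstream = 2, downstream = 2)$window
extract_windows <- function(proteome, anchors, upstream, downstream) {
  validate_proteome(proteome)
  if (upstream < 0 || downstream < 0) {
    abort("`upstream` and `downstream` must be non-negative.")
  }
  missing_ids <- setdiff(unique(anchors$protein_id), proteome$protein_id)
  if (length(missing_ids) > 0) {
    abort(paste0("Anchor protein ID(s) absent from proteome: ",
                 paste(head(missing_ids, 10), collapse = ", "), "."))
  }
  row <- match(anchors$protein_id, proteome$protein_id)
  seqs <- proteome$sequence[row]
  pos <- as.integer(anchors$anchor_pos)
  if (any(pos < 1 | pos > nchar(seqs))) {
    bad <- which(pos < 1 | pos > nchar(seqs))
    abort(paste0("Anchor position out of range for row(s): ",
                 paste(head(bad, 5), collapse = ", "), "."))
  }
  anchor_res <- substr(seqs, pos, pos)
  if (any(!anchor_res %in% AA20)) {
    bad <- which(!anchor_res %in% AA20)
    abort(paste0("Anchor falls on a non-standard residue for row(s): ",
                 paste(head(bad, 5), collapse = ", "),
                 "; anchors must be testable residues."))
  }
  windows <- window_at(seqs, pos, upstream, downstream)
  peptide_set(windows, anchor_column = upstream,
              protein_ids = anchors$protein_id, anchor_pos = pos)
}

#' Build a peptide set from pre-aligned equal-length sequences
#'
#' @param sequences Character vector of equal-length aligned windows
#'   (upper-case amino acids, `X` padding at termini only).
#' @param anchor_column 0-based anchor column index.
#' @param protein_ids Optional source protein IDs.
#' @return A [peptide_set()].
#' @export
format_aligned <- function(sequences, anchor_column, protein_ids = NULL) {
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1) {
    off <- which(lens != lens[1])
    abort(paste0("Aligned input has ragged lengths; offending row(s): ",
                 paste(head(off, 10), collapse = ", "), "."))
  }
  peptide_set(sequences, anchor_column = anchor_column,
              protein_ids = protein_ids)
}

#' Clean a raw anchored-peptide table
#'
#' Drops rows without an anchor mark on one of `anchor_aa`, collapses exact
#' duplicate `(protein_id, peptide)` rows, and expands rows carrying several
#' anchors into one row per anchor (single lowercase anchor re-annotated).
#' A report of kept/dropped/expanded counts is attached as the `"report"`
#' attribute and printed as a message.
#'
#' @param rows Data frame with columns `protein_id` and `peptide` (anchored
#'   syntax: lowercase or asterisk marks).
#' @param anchor_aa Character vector of anchoring amino acids, e.g. `c("S","T")`.
#' @param quiet Suppress the report message.
#' @return A tibble with columns `protein_id`, `peptide` (single-anchor,
#'   lowercase mark), `clean_sequence` and `anchor_index`.
#' @export
#' @examples
#' clean_peptides(data.frame(protein_id = "p1", peptide = "AkTkC"),
#'                anchor_aa = "K")
clean_peptides <- function(rows, anchor_aa, quiet = FALSE) {
  if (length(anchor_aa) == 0) {
    abort("`anchor_aa` must name at least one anchoring amino acid.")
  }
  anchor_aa <- toupper(anchor_aa)
  rows <- as_tibble(rows)[, c("protein_id", "peptide")]
  n_in <- nrow(rows)
  rows <- dplyr::distinct(rows)
  n_dedup <- n_in - nrow(rows)

  parsed <- purrr::map(rows$peptide, function(p) {
    out <- tryCatch(parse_anchored_sequence(p), error = function(e) NULL)
    if (is.null(out)) return(NULL)
    keep <- substr(out$clean_sequence, out$anchor_indices,
                   out$anchor_indices) %in% anchor_aa
    out$anchor_indices <- out$anchor_indices[keep]
    if (length(out$anchor_indices) == 0) NULL else out
  })
  usable <- !purrr::map_lgl(parsed, is.null)
  n_dropped <- sum(!usable)
  expanded <- purrr::map2_dfr(
    which(usable), parsed[usable],
    function(i, p) {
      tibble(
        protein_id = rows$protein_id[i],
        peptide = purrr::map_chr(p$anchor_indices, function(k) {
          s <- strsplit(p$clean_sequence, "")[[1]]
          s[k] <- tolower(s[k])
          paste(s, collapse = "")
        }),
        clean_sequence = p$clean_sequence,
        anchor_index = p$anchor_indices
      )
    }
  )
  if (nrow(expanded) == 0) {
    abort("No usable peptides after cleaning.")
  }
  report <- c(input = n_in, deduplicated = n_dedup, dropped = n_dropped,
              output = nrow(expanded))
  if (!quiet) {
    inform(paste0("clean_peptides: ", n_in, " row(s) in, ", n_dedup,
                  " duplicate(s) removed, ", n_dropped,
                  " without usable anchor dropped, ", nrow(expanded),
                  " single-anchor row(s) out."))
  }
  attr(expanded, "report") <- report
  expanded
}

#' Fetch anchored windows for a peptide table
#'
#' End-to-end convenience wrapper: cleans the raw table, locates each cleaned
#' peptide in its source protein, converts the in-peptide anchor to a protein
#' coordinate, and extracts fixed-width windows. When a peptide occurs more
#' than once in its protein the first occurrence is used (with a warning).
#'
#' @inheritParams clean_peptides
#' @inheritParams extract_windows
#' @return A [peptide_set()].
#' @export
fetch_windows <- function(proteome, rows, anchor_aa, upstream, downstream,
                          quiet = FALSE) {
  cleaned <- clean_peptides(rows, anchor_aa = anchor_aa, quiet = quiet)
  row <- match(cleaned$protein_id, proteome$protein_id)
  alias <- is.na(row)
  row[alias] <- match(cleaned$protein_id[alias], proteome$accession)
  if (any(is.na(row))) {
    missing_ids <- unique(cleaned$protein_id[is.na(row)])
    abort(paste0("Peptide protein ID(s) absent from proteome: ",
                 paste(head(missing_ids, 10), collapse = ", "), "."))
  }
  seqs <- proteome$sequence[row]
  hit <- stringr::str_locate(seqs, stringr::fixed(cleaned$clean_sequence))[, "start"]
  if (any(is.na(hit))) {
    bad <- which(is.na(hit))
    abort(paste0("Peptide(s) not found in their protein: row(s) ",
                 paste(head(bad, 10), collapse = ", "), "."))
  }
  multi <- stringr::str_count(seqs, stringr::fixed(cleaned$clean_sequence)) > 1
  if (any(multi)) {
    warn(paste0(sum(multi), " peptide(s) occur more than once in their",
                " protein; first occurrence used."))
  }
  anchors <- tibble(
    protein_id = proteome$protein_id[row],
    anchor_pos = as.integer(hit + cleaned$anchor_index - 1L)
  )
  extract_windows(proteome, anchors, upstream = upstream,
                  downstream = downstream)
}

#' Column labels for an anchored window
#'
#' `"offset"` labels columns `-upstream ... 0 ... +downstream` with 0 at the
#' anchor; `"protease"` uses substrate nomenclature, P{x} for columns at and
#' N-terminal to the anchor (anchor = P1) and P{x}' C-terminal to it.
#'
#' @param peptides_or_result A `peptide_set` or `dau_result`.
#' @param style `"offset"` or `"protease"`.
#' @return Character vector of `L` labels.
#' @export
position_labels <- function(peptides_or_result,
                            style = c("offset", "protease")) {
  style <- match.arg(style)
  if (inherits(peptides_or_result, "dau_result")) {
    up <- peptides_or_result$metadata$anchor_column
    L <- peptides_or_result$metadata$L
  } else {
    up <- attr(peptides_or_result, "anchor_column")
    L <- attr(peptides_or_result, "L")
  }
  offs <- seq_len(L) - 1L - up
  if (style == "offset") {
    ifelse(offs > 0, paste0("+", offs), as.character(offs))
  } else {
    ifelse(offs <= 0, paste0("P", 1L - offs), paste0("P", offs, "'"))
  }
}
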