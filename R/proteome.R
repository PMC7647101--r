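## proteome_io: reading, writing and preprocessing protein sequence collections.

#' Construct a proteome from a data frame
#'
#' A proteome is a tibble with one row per protein and columns `protein_id`,
#' `accession` (UniProt accession when the FASTA header is in
#' `sp|ACC|NAME` / `tr|ACC|NAME` style, otherwise `NA`) and `sequence`.
#' Sequences are stored upper-case over the 20 standard amino acids plus the
#' non-standard codes `U`, `B`, `Z` and `*`, which are retained but treated as
#' non-countable by all downstream statistics.
#'
#' @param x A data frame with at least `protein_id` and `sequence` columns.
#' @param species Optional species label stored as an attribute.
#' @param source Optional provenance tag (file path or generator name).
#' @return A tibble of class `proteome`.
#' @export
as_proteome <- function(x, species = NA_character_, source = NA_character_) {
  if (!is.data.frame(x)) {
    abort("`x` must be a data frame with columns `protein_id` and `sequence`.")
  }
  missing_cols <- setdiff(c("protein_id", "sequence"), names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("`x` lacks required column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  out <- as_tibble(x)
  if (!"accession" %in% names(out)) {
    out$accession <- NA_character_
  }
  out <- out[, c("protein_id", "accession", "sequence")]
  out$protein_id <- as.character(out$protein_id)
  out$sequence <- toupper(as.character(out$sequence))
  validate_proteome(out)
  attr(out, "species") <- species
  attr(out, "source") <- source
  class(out) <- c("proteome", class(tibble()))
  out
}

validate_proteome <- function(x) {
  if (nrow(x) == 0) {
    abort("Proteome contains zero records.")
  }
  dup <- unique(x$protein_id[duplicated(x$protein_id)])
  if (length(dup) > 0) {
    abort(paste0("Duplicate protein ID(s): ",
                 paste(head(dup, 5), collapse = ", "), "."))
  }
  if (any(!nzchar(x$sequence))) {
    abort("Proteome contains empty sequence(s).")
  }
  allowed <- c(AA20, PAD, AA_NONSTANDARD)
  bad <- !grepl(paste0("^[", paste(gsub("\\*", "\\\\*", allowed), collapse = ""),
                       "]+$"),
                x$sequence)
  if (any(bad)) {
    abort(paste0("Sequence(s) with unsupported characters for protein(s): ",
                 paste(head(x$protein_id[bad], 5), collapse = ", "), "."))
  }
  invisible(x)
}

#' Read a proteome from a FASTA file
#'
#' Headers are parsed up to the first whitespace to give `protein_id`; UniProt
#' style `sp|ACC|NAME` and `tr|ACC|NAME` IDs additionally expose the accession
#' `ACC` as an alias in the `accession` column. Wrapped sequence lines are
#' joined and sequences upper-cased.
#'
#' @param path Path to a FASTA file.
#' @param species Optional species label.
#' @return A [as_proteome()] tibble.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1", "MKKD", ">sp|P12345|TEST", "MA", "SA"), fa)
#' read_proteome(fa)
read_proteome <- function(path, species = NA_character_) {
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path))
  }
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0) {
    abort(paste0("No FASTA records in ", path, "."))
  }
  headers <- names(seqs)
  ids <- sub("\\s.*$", "", headers)
  acc <- ifelse(grepl("^(sp|tr)\\|[^|]+\\|", ids),
                sub("^(sp|tr)\\|([^|]+)\\|.*$", "\\2", ids),
                NA_character_)
  as_proteome(
    tibble(protein_id = ids, accession = acc,
           sequence = as.character(seqs)),
    species = species, source = path
  )
}

#' Write a proteome to a FASTA file
#'
#' @param proteome A proteome tibble.
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_proteome <- function(proteome, path, width = 60L) {
  validate_proteome(proteome)
  x <- Biostrings::AAStringSet(setNames(proteome$sequence, proteome$protein_id))
  Biostrings::writeXStringSet(x, filepath = path, width = width)
  invisible(path)
}

#' Remove initiator methionines from a proteome
#'
#' N-terminal Met processing matters when anchoring on mature protein
#' N-termini (e.g. N-terminal acetylation substrates). Two rules are offered:
#' `"all"` strips a leading `M` from every sequence; `"biological"` strips it
#' only when the second residue is one of G, A, S, T, C, P or V, mimicking
#' co-translational methionine aminopeptidase cleavage.
#'
#' Sequences that become empty are dropped with a warning reporting the count.
#'
#' @param proteome A proteome tibble.
#' @param mode `"all"` or `"biological"`.
#' @return A new proteome tibble.
#' @export
#' @examples
#' p <- as_proteome(data.frame(protein_id = c("a", "b"),
#'                             sequence = c("MGAT", "MMAT")))
#' cleave_initiator_met(p, mode = "all")$sequence
#' cleave_initiator_met(p, mode = "biological")$sequence
cleave_initiator_met <- function(proteome, mode = c("all", "biological")) {
  mode <- match.arg(mode)
  validate_proteome(proteome)
  seqs <- proteome$sequence
  second <- substr(seqs, 2, 2)
  strip <- startsWith(seqs, "M")
  if (mode == "biological") {
    strip <- strip & second %in% c("G", "A", "S", "T", "C", "P", "V")
  }
  seqs[strip] <- substr(seqs[strip], 2, nchar(seqs[strip]))
  keep <- nzchar(seqs)
  if (any(!keep)) {
    warn(paste0(sum(!keep),
                " sequence(s) became empty after initiator-Met removal",
                " and were dropped."))
  }
  out <- proteome[keep, , drop = FALSE]
  out$sequence <- seqs[keep]
  as_proteome(out,
              species = attr(proteome, "species"),
              source = attr(proteome, "source"))
}

#' @export
print.proteome <- function(x, ...) {
  cat("# A proteome: ", nrow(x), " protein(s)",
      if (!is.na(attr(x, "species"))) paste0(", species: ", attr(x, "species")),
      "\n", sep = "")
  NextMethod()
}
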