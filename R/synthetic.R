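## fixtures: synthetic proteomes and peptide sets with known structure.

#' Amino-acid frequency vectors for the synthetic generator
#'
#' `aa_freqs_uniform()` assigns 0.05 to each of the 20 amino acids.
#' `aa_freqs_human()` is a human-proteome-like composition based on published
#' Swiss-Prot proteome-wide averages (values per 100 residues: A 8.25, R 5.53,
#' N 4.06, D 5.45, C 1.38, Q 3.93, E 6.75, G 7.07, H 2.27, I 5.96, L 9.66,
#' K 5.84, M 2.42, F 3.86, P 4.70, S 6.56, T 5.34, W 1.08, Y 2.92, V 6.87),
#' renormalized to sum to one.
#'
#' @return Named numeric vector over the 20 amino acids, summing to 1.
#' @export
aa_freqs_uniform <- function() {
  setNames(rep(1 / 20, 20), AA20)
}

#' @rdname aa_freqs_uniform
#' @export
aa_freqs_human <- function() {
  v <- c(A = 8.25, R = 5.53, N = 4.06, D = 5.45, C = 1.38, Q = 3.93,
         E = 6.75, G = 7.07, H = 2.27, I = 5.96, L = 9.66, K = 5.84,
         M = 2.42, F = 3.86, P = 4.70, S = 6.56, T = 5.34, W = 1.08,
         Y = 2.92, V = 6.87)
  v <- v[AA20]
  v / sum(v)
}

check_aa_freqs <- function(aa_freqs) {
  if (is.null(names(aa_freqs))) {
    if (length(aa_freqs) != 20) {
      abort("Unnamed `aa_freqs` must have 20 entries in alphabetical AA order.")
    }
    names(aa_freqs) <- AA20
  }
  if (!setequal(names(aa_freqs), AA20)) {
    abort("`aa_freqs` must be named by the 20 standard amino acids.")
  }
  aa_freqs <- aa_freqs[AA20]
  if (any(aa_freqs < 0) || abs(sum(aa_freqs) - 1) > 1e-6) {
    abort("`aa_freqs` must be non-negative and sum to 1.")
  }
  aa_freqs
}

#' Generate a synthetic proteome
#'
#' Proteins have i.i.d. residues drawn from `aa_freqs` and lengths uniform on
#' `length_range`. Deterministic given `seed`.
#'
#' @param n_proteins Number of proteins.
#' @param length_range Integer `c(min, max)` protein length.
#' @param aa_freqs Residue frequencies (see [aa_freqs_uniform()]).
#' @param seed Integer seed.
#' @return A proteome tibble with IDs `SYN0001, ...`.
#' @export
synth_proteome <- function(n_proteins = 500, length_range = c(100, 300),
                           aa_freqs = aa_freqs_uniform(), seed = 1) {
  aa_freqs <- check_aa_freqs(aa_freqs)
  if (n_proteins < 1) abort("`n_proteins` must be at least 1.")
  withr::with_seed(seed, {
    lens <- sample.int(length_range[2] - length_range[1] + 1L, n_proteins,
                       replace = TRUE) + length_range[1] - 1L
    chars <- sample(AA20, sum(lens), replace = TRUE, prob = aa_freqs)
    seqs <- vapply(split(chars, rep.int(seq_len(n_proteins), lens)),
                   paste, collapse = "", FUN.VALUE = character(1))
  })
  as_proteome(
    tibble(protein_id = sprintf("SYN%04d", seq_len(n_proteins)),
           sequence = unname(seqs)),
    species = "synthetic", source = "synth_proteome"
  )
}

#' Specify a planted motif
#'
#' Effects plant a symbol at a column with a target frequency; at effect
#' columns the remaining probability mass is shared among the unspecified
#' amino acids in proportion to the baseline. Columns without effects draw
#' from the baseline.
#'
#' @param L Window length.
#' @param anchor_column 0-based anchor column.
#' @param effects Data frame with columns `column` (0-based), `symbol`
#'   (amino acid) and `target` (frequency in \[0, 1\]); may be empty.
#' @param baseline Named baseline frequency vector over the 20 amino acids.
#' @return A list of class `motif_spec`.
#' @export
motif_spec <- function(L, anchor_column, effects = NULL,
                       baseline = aa_freqs_uniform()) {
  baseline <- check_aa_freqs(baseline)
  if (anchor_column < 0 || anchor_column >= L) {
    abort("`anchor_column` must be a 0-based column inside the window.")
  }
  if (is.null(effects) || nrow(effects) == 0) {
    effects <- tibble(column = integer(), symbol = character(),
                      target = numeric())
  } else {
    effects <- as_tibble(effects)[, c("column", "symbol", "target")]
    effects$symbol <- toupper(effects$symbol)
    if (any(!effects$symbol %in% AA20)) {
      abort("Effect symbols must be standard amino acids.")
    }
    if (any(effects$column < 0 | effects$column >= L)) {
      abort("Effect columns must be 0-based indices inside the window.")
    }
    if (anyDuplicated(effects[, c("column", "symbol")])) {
      abort("Duplicate (column, symbol) effects.")
    }
    if (any(effects$target < 0 | effects$target > 1)) {
      abort("Effect targets must be in [0, 1].")
    }
    sums <- tapply(effects$target, effects$column, sum)
    if (any(sums > 1 + 1e-9)) {
      abort("Effect targets at a column must not sum beyond 1.")
    }
  }
  structure(list(L = as.integer(L), anchor_column = as.integer(anchor_column),
                 effects = effects, baseline = baseline),
            class = "motif_spec")
}

## Per-column residue distributions implied by a motif spec.
motif_column_probs <- function(spec) {
  probs <- matrix(rep(spec$baseline, spec$L), nrow = spec$L, byrow = TRUE,
                  dimnames = list(NULL, AA20))
  for (col in unique(spec$effects$column)) {
    eff <- spec$effects[spec$effects$column == col, ]
    p <- spec$baseline
    p[eff$symbol] <- 0
    rest <- sum(p)
    mass_left <- 1 - sum(eff$target)
    p <- if (rest > 0) p / rest * mass_left else p * 0
    p[eff$symbol] <- eff$target
    probs[col + 1L, ] <- p
  }
  probs
}

#' Plant a motif into synthetic peptide windows
#'
#' Draws `n` windows whose columns follow the distributions implied by the
#' motif spec, and returns them with a truth table of the planted effects.
#' Window provenance (`protein_id`) is sampled from the proteome; window
#' content is synthesized from the spec, not copied from the proteins.
#'
#' @param proteome A proteome tibble (provenance for `protein_id`s).
#' @param spec A [motif_spec()].
#' @param n Number of windows.
#' @param seed Integer seed.
#' @return A list with `peptides` (a `peptide_set`) and `truth` (a tibble of
#'   planted `(column, offset, symbol, target, baseline, direction)`).
#' @export
plant_motif_peptides <- function(proteome, spec, n, seed = 1) {
  if (!inherits(spec, "motif_spec")) {
    abort("`spec` must be created with motif_spec().")
  }
  if (n < 1) abort("`n` must be at least 1.")
  probs <- motif_column_probs(spec)
  withr::with_seed(seed, {
    cols <- lapply(seq_len(spec$L), function(l) {
      sample(AA20, n, replace = TRUE, prob = probs[l, ])
    })
    ids <- sample(proteome$protein_id, n, replace = TRUE)
  })
  windows <- do.call(paste0, cols)
  truth <- spec$effects
  truth$offset <- truth$column - spec$anchor_column
  truth$baseline <- unname(spec$baseline[truth$symbol])
  truth$direction <- sign(truth$target - truth$baseline)
  truth <- truth[, c("column", "offset", "symbol", "target", "baseline",
                     "direction")]
  list(
    peptides = peptide_set(windows, anchor_column = spec$anchor_column,
                           protein_ids = ids),
    truth = truth
  )
}

#' Draw null peptide windows from a proteome
#'
#' Windows are sampled exactly as the anywhere-unanchored background sampler
#' does (uniformly over residues of the whole proteome, `X`-padded at
#' termini), for type-I error calibration against a background built from the
#' same proteome.
#'
#' @param proteome A proteome tibble.
#' @param n Number of windows.
#' @param L Window length.
#' @param anchor_column 0-based anchor column; defaults to the central column.
#' @param seed Integer seed.
#' @return A `peptide_set`.
#' @export
null_peptides <- function(proteome, n, L, anchor_column = (L - 1L) %/% 2L,
                          seed = 1) {
  anchor_column <- as.integer(anchor_column)
  config <- bg_config(proteome_space = "wholeProteome",
                      positional_space = "anywhere", anchored = FALSE,
                      upstream = anchor_column,
                      downstream = L - 1L - anchor_column,
                      test = "ztest", boot_size = n)
  windows <- sample_windows(proteome, config, n, seed = seed)
  peptide_set(windows, anchor_column = anchor_column)
}

#' Write fixture files for a synthetic study
#'
#' Emits the proteome as FASTA and the peptide windows (plus optional truth
#' table) as TSV, so synthetic fixtures exercise the package's real I/O paths.
#'
#' @param proteome A proteome tibble.
#' @param peptides A `peptide_set`.
#' @param truth Optional truth tibble from [plant_motif_peptides()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_fixture_files <- function(proteome, peptides, truth = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(proteome = file.path(dir, "proteome.fasta"),
             peptides = file.path(dir, "peptides.tsv"))
  write_proteome(proteome, paths[["proteome"]])
  readr::write_tsv(
    tibble(protein_id = peptides$protein_id,
           anchor_column = attr(peptides, "anchor_column"),
           window = peptides$window),
    paths[["peptides"]]
  )
  if (!is.null(truth)) {
    paths <- c(paths, truth = file.path(dir, "truth.tsv"))
    readr::write_tsv(truth, paths[["truth"]])
  }
  invisible(paths)
}

#' Read aligned peptide windows from a fixture TSV
#'
#' Reads the TSV written by [write_fixture_files()] (columns `protein_id`,
#' `anchor_column`, `window`) back into a `peptide_set`.
#'
#' @param path TSV file path.
#' @return A `peptide_set`.
#' @export
read_windows_tsv <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  for (col in c("anchor_column", "window")) {
    if (!col %in% names(x)) {
      abort(paste0("Windows TSV lacks column \"", col, "\"."))
    }
  }
  format_aligned(x$window, anchor_column = x$anchor_column[1],
                 protein_ids = x$protein_id)
}
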