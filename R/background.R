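## background: the twelve proteome-derived background models.
##
## A background model estimates, for every window position l and alphabet
## symbol, the frequency expected under the chosen sampling space. In Z mode
## this is done by bootstrapping T background sets of N windows each and
## recording the mean frequency and its binomial standard error
## sqrt(p(1-p)/N); in Fisher mode a single (exhaustive or capped) background
## set is stored as counts.

#' Background model configuration
#'
#' Valid configurations combine a proteome-level space (`"wholeProteome"`,
#' `"inputSet"`, `"nonInputSet"`) with a positional space (`"nterm"`,
#' `"cterm"`, `"anywhere"`), where `"anywhere"` may additionally be anchored
#' on a set of residues — 3 x 4 = 12 models in total.
#'
#' @param proteome_space One of `"wholeProteome"`, `"inputSet"`,
#'   `"nonInputSet"`.
#' @param positional_space One of `"nterm"`, `"cterm"`, `"anywhere"`.
#' @param anchored Logical; only meaningful with `positional_space =
#'   "anywhere"`.
#' @param anchor_aa Anchoring residues, required when `anchored = TRUE`.
#' @param upstream,downstream Window offsets around the anchor; the window
#'   length is `upstream + 1 + downstream`.
#' @param test `"ztest"` (bootstrap) or `"fisher"` (exhaustive counts).
#' @param n_boot Number of bootstrap sets T (Z mode).
#' @param boot_size Windows per bootstrap set N (Z mode); `NULL` defers to the
#'   input-set size at build time.
#' @param max_windows Cap on the exhaustive Fisher background for `"anywhere"`
#'   spaces; beyond it a seeded subsample of this size is used.
#' @return A list of class `bg_config`.
#' @export
bg_config <- function(proteome_space = c("wholeProteome", "inputSet",
                                         "nonInputSet"),
                      positional_space = c("anywhere", "nterm", "cterm"),
                      anchored = FALSE, anchor_aa = NULL,
                      upstream, downstream,
                      test = c("ztest", "fisher"),
                      n_boot = 300L, boot_size = NULL,
                      max_windows = 2e5) {
  proteome_space <- match.arg(proteome_space)
  positional_space <- match.arg(positional_space)
  test <- match.arg(test)
  if (anchored && positional_space != "anywhere") {
    abort("`anchored = TRUE` is only valid with positional_space = \"anywhere\".")
  }
  if (anchored && (is.null(anchor_aa) || length(anchor_aa) == 0)) {
    abort("Anchored backgrounds require non-empty `anchor_aa`.")
  }
  if (!anchored) anchor_aa <- NULL
  if (!is.null(anchor_aa)) {
    anchor_aa <- toupper(anchor_aa)
    bad <- setdiff(anchor_aa, AA20)
    if (length(bad) > 0) {
      abort(paste0("`anchor_aa` outside the 20-AA alphabet: ",
                   paste(bad, collapse = ", "), "."))
    }
  }
  if (upstream < 0 || downstream < 0) {
    abort("`upstream` and `downstream` must be non-negative.")
  }
  if (test == "ztest") {
    if (n_boot < 2) abort("Z-mode backgrounds need at least 2 bootstrap sets.")
    if (!is.null(boot_size) && boot_size < 1) {
      abort("`boot_size` must be at least 1.")
    }
  }
  structure(
    list(proteome_space = proteome_space,
         positional_space = positional_space,
         anchored = isTRUE(anchored),
         anchor_aa = anchor_aa,
         upstream = as.integer(upstream),
         downstream = as.integer(downstream),
         L = as.integer(upstream + 1 + downstream),
         test = test,
         n_boot = as.integer(n_boot),
         boot_size = if (is.null(boot_size)) NULL else as.integer(boot_size),
         max_windows = max_windows),
    class = "bg_config"
  )
}

#' Enumerate the valid background configurations
#'
#' @return A 12-row tibble of `(proteome_space, positional_space, anchored)`.
#' @export
valid_bg_configs <- function() {
  tidyr::expand_grid(
    proteome_space = c("wholeProteome", "inputSet", "nonInputSet"),
    positional = tibble(
      positional_space = c("nterm", "cterm", "anywhere", "anywhere"),
      anchored = c(FALSE, FALSE, FALSE, TRUE)
    )
  ) |> tidyr::unpack("positional")
}

## Restrict a proteome to the configured proteome-level space.
restrict_proteome <- function(proteome, config, input_ids) {
  if (config$proteome_space == "wholeProteome") {
    out <- proteome
  } else {
    if (is.null(input_ids) || length(input_ids) == 0) {
      abort(paste0("proteome_space = \"", config$proteome_space,
                   "\" needs `input_ids`."))
    }
    hit <- proteome$protein_id %in% input_ids |
      (!is.na(proteome$accession) & proteome$accession %in% input_ids)
    out <- if (config$proteome_space == "inputSet") proteome[hit, ] else
      proteome[!hit, ]
  }
  if (nrow(out) == 0) {
    abort(paste0("No proteins left after restricting to ",
                 config$proteome_space, "."))
  }
  out
}

## Precompute the anchor pool for repeated draws.
bg_pool <- function(proteome, config, input_ids = NULL) {
  prot <- restrict_proteome(proteome, config, input_ids)
  seqs <- prot$sequence
  if (config$positional_space == "nterm" || config$positional_space == "cterm") {
    pos <- if (config$positional_space == "nterm") rep(1L, length(seqs)) else
      nchar(seqs)
    ok <- substr(seqs, pos, pos) %in% AA20
    if (!any(ok)) {
      abort("No proteins with a standard terminal residue to anchor on.")
    }
    list(type = "fixed", seqs = seqs[ok], pos = pos[ok],
         size = sum(ok), config = config)
  } else if (config$anchored) {
    pattern <- paste0("[", paste(config$anchor_aa, collapse = ""), "]")
    hits <- gregexpr(pattern, seqs)
    n_hits <- purrr::map_int(hits, ~ if (.x[1] == -1L) 0L else length(.x))
    if (sum(n_hits) == 0) {
      abort(paste0("No residues matching anchor set {",
                   paste(config$anchor_aa, collapse = ","),
                   "} in the background space."))
    }
    prot_idx <- rep.int(seq_along(seqs), n_hits)
    pos <- unlist(hits[n_hits > 0], use.names = FALSE)
    list(type = "enumerated", seqs = seqs, prot_idx = prot_idx,
         pos = as.integer(pos), size = length(pos), config = config)
  } else {
    lens <- nchar(seqs)
    list(type = "residues", seqs = seqs, cum = cumsum(lens),
         size = sum(lens), config = config)
  }
}

## Index sampling; the hash algorithm avoids an O(pool) permutation when
## drawing a small subset without replacement from a large pool.
sample_idx <- function(size, n, replace) {
  if (replace) {
    sample.int(size, n, replace = TRUE)
  } else if (n <= size %/% 2) {
    sample.int(size, n, useHash = TRUE)
  } else {
    sample.int(size, n)
  }
}

## Draw n anchors from a pool; without replacement when the pool allows.
## Returns windows. `state` is an environment used to warn at most once.
draw_pool_windows <- function(pool, n, state = NULL) {
  replace <- pool$size < n
  if (replace && !is.null(state) && !isTRUE(state$warned)) {
    warn(paste0("Background pool (", pool$size, ") smaller than requested ",
                n, " windows; sampling with replacement."))
    state$warned <- TRUE
  }
  cfg <- pool$config
  if (pool$type == "fixed") {
    i <- sample_idx(pool$size, n, replace)
    window_at(pool$seqs[i], pool$pos[i], cfg$upstream, cfg$downstream)
  } else if (pool$type == "enumerated") {
    i <- sample_idx(pool$size, n, replace)
    window_at(pool$seqs[pool$prot_idx[i]], pool$pos[i],
              cfg$upstream, cfg$downstream)
  } else {
    ## Uniform over all residue positions; anchors on non-standard residues
    ## are rejected and redrawn (they cannot serve as testable anchors).
    draw <- function(m) {
      r <- sample_idx(pool$size, m, replace)
      prot <- findInterval(r - 1L, pool$cum) + 1L
      pos <- r - c(0L, pool$cum)[prot]
      list(prot = prot, pos = as.integer(pos))
    }
    d <- draw(n)
    res <- substr(pool$seqs[d$prot], d$pos, d$pos)
    bad <- !res %in% AA20
    guard <- 0L
    while (any(bad)) {
      guard <- guard + 1L
      if (guard > 100L) {
        abort("Could not draw standard-residue anchors; pool appears to be all non-standard.")
      }
      d2 <- draw(sum(bad))
      d$prot[bad] <- d2$prot
      d$pos[bad] <- d2$pos
      res <- substr(pool$seqs[d$prot], d$pos, d$pos)
      bad <- !res %in% AA20
    }
    window_at(pool$seqs[d$prot], d$pos, cfg$upstream, cfg$downstream)
  }
}

#' Sample background windows from a proteome
#'
#' Draws `n` windows under the configuration's sampling rules: `"nterm"` /
#' `"cterm"` anchor at each protein's first/last residue (padded with `X` as
#' needed); `"anywhere"` draws anchors uniformly over all residues of the
#' restricted proteome, optionally constrained to the anchoring residues.
#'
#' @param proteome A proteome tibble.
#' @param config A [bg_config()].
#' @param n Number of windows.
#' @param input_ids Protein IDs of the input set, needed for the
#'   `"inputSet"`/`"nonInputSet"` spaces.
#' @param seed Optional seed for reproducible draws.
#' @return Character vector of `n` windows.
#' @export
sample_windows <- function(proteome, config, n, input_ids = NULL,
                           seed = NULL) {
  if (n < 1) abort("`n` must be at least 1.")
  pool <- bg_pool(proteome, config, input_ids)
  run <- function() draw_pool_windows(pool, n)
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

## Per-position, per-symbol, per-set counts for a vector of windows.
## Windows are decoded to bytes once (utf8ToInt over the concatenation) and
## mapped to symbol indices through a 256-entry lookup table; padding and any
## byte outside the scheme maps to 0 (non-countable).
## Returns list(counts = L x K x n_sets array, totals = L x n_sets matrix).
count_window_sets <- function(windows, set_id, n_sets, scheme) {
  L <- nchar(windows[1])
  symbols <- scheme$symbol
  K <- length(symbols)
  map <- scheme_map(scheme)
  aa <- setdiff(names(map), PAD)
  lut <- integer(256)
  lut[vapply(aa, utf8ToInt, integer(1))] <- match(map[aa], symbols)
  code <- lut[utf8ToInt(paste(windows, collapse = ""))]
  dim(code) <- c(L, length(windows))
  counts <- array(0, dim = c(L, K, n_sets),
                  dimnames = list(NULL, symbols, NULL))
  totals <- matrix(0, nrow = L, ncol = n_sets)
  base <- (set_id - 1L) * K
  for (l in seq_len(L)) {
    cl <- code[l, ]
    keep <- cl > 0L
    cnt <- tabulate(base[keep] + cl[keep], nbins = n_sets * K)
    cnt <- matrix(cnt, nrow = K, ncol = n_sets)
    counts[l, , ] <- cnt
    totals[l, ] <- colSums(cnt)
  }
  list(counts = counts, totals = totals)
}

#' Build a background model
#'
#' In Z mode, draws `config$n_boot` bootstrap sets of `N` windows each
#' (`N = config$boot_size`, defaulting to the input-set size), collapses
#' residues onto the scheme symbols *before* computing frequencies, and stores
#' the per-position mean frequency together with its binomial standard error
#' `sqrt(p(1-p)/N)`. In Fisher mode, stores the counts of one exhaustive
#' background set (capped at `config$max_windows` for `"anywhere"` spaces).
#' Padding `X` and non-standard residues are excluded from both numerator and
#' denominator of every frequency.
#'
#' Sampling is with replacement across bootstrap sets and without replacement
#' within a set whenever the pool allows (with a warning otherwise).
#'
#' @param proteome A proteome tibble.
#' @param config A [bg_config()].
#' @param scheme An `aa_scheme`; frequencies are over its symbols.
#' @param input A `peptide_set`, used to default `boot_size` and to derive
#'   `input_ids`; optional if both are given explicitly.
#' @param input_ids Protein IDs of the input set (for
#'   `"inputSet"`/`"nonInputSet"` spaces).
#' @param seed Seed recorded in the model; all sampling is driven by it.
#' @param keep_boot Retain the per-bootstrap frequency array (`boot_freq`).
#' @return A list of class `dau_background`.
#' @export
build_background <- function(proteome, config, scheme = aa_scheme("identity"),
                             input = NULL, input_ids = NULL, seed = NULL,
                             keep_boot = FALSE) {
  validate_scheme(scheme)
  if (!inherits(config, "bg_config")) {
    abort("`config` must be created with bg_config().")
  }
  if (is.null(input_ids) && !is.null(input)) {
    input_ids <- unique(stats::na.omit(input$protein_id))
  }
  run <- function() {
    pool <- bg_pool(proteome, config, input_ids)
    state <- new.env(parent = emptyenv())
    if (config$test == "ztest") {
      N <- config$boot_size %||% (if (!is.null(input)) nrow(input) else NULL)
      if (is.null(N)) {
        abort("Z-mode backgrounds need `boot_size` in the config or an `input` peptide set.")
      }
      N <- as.integer(N)
      T_ <- config$n_boot
      if (T_ * N == 0) abort("T x N must be positive.")
      windows <- unlist(lapply(seq_len(T_), function(t) {
        draw_pool_windows(pool, N, state)
      }), use.names = FALSE)
      set_id <- rep.int(seq_len(T_), rep.int(N, T_))
      cw <- count_window_sets(windows, set_id, T_, scheme)
      freq <- cw$counts
      for (t in seq_len(T_)) {
        tot <- cw$totals[, t]
        freq[, , t] <- cw$counts[, , t] / ifelse(tot > 0, tot, NA_real_)
      }
      mean_freq <- apply(freq, c(1, 2), mean, na.rm = TRUE)
      mean_freq[is.nan(mean_freq)] <- NA_real_
      se <- sqrt(mean_freq * (1 - mean_freq) / N)
      list(mean_freq = mean_freq, se = se, N = N, T = T_,
           boot_freq = if (keep_boot) freq else NULL,
           counts = NULL, totals = NULL, n_windows = T_ * N,
           pool_size = pool$size)
    } else {
      n_all <- pool$size
      capped <- FALSE
      if (pool$type == "residues" || pool$type == "enumerated") {
        if (n_all > config$max_windows) {
          n_all <- as.integer(config$max_windows)
          capped <- TRUE
        }
      }
      windows <- if (capped) {
        draw_pool_windows(pool, n_all, state)
      } else if (pool$type == "fixed") {
        window_at(pool$seqs, pool$pos, config$upstream, config$downstream)
      } else if (pool$type == "enumerated") {
        window_at(pool$seqs[pool$prot_idx], pool$pos,
                  config$upstream, config$downstream)
      } else {
        lens <- nchar(pool$seqs)
        prot <- rep.int(seq_along(pool$seqs), lens)
        pos <- sequence(lens)
        res <- substr(pool$seqs[prot], pos, pos)
        ok <- res %in% AA20
        window_at(pool$seqs[prot[ok]], pos[ok],
                  config$upstream, config$downstream)
      }
      cw <- count_window_sets(windows, rep(1L, length(windows)), 1L, scheme)
      counts <- cw$counts[, , 1, drop = TRUE]
      if (is.null(dim(counts))) {
        counts <- matrix(counts, nrow = config$L,
                         dimnames = list(NULL, scheme$symbol))
      }
      totals <- cw$totals[, 1]
      mean_freq <- counts / ifelse(totals > 0, totals, NA_real_)
      list(mean_freq = mean_freq, se = NULL, N = NULL, T = NULL,
           boot_freq = NULL, counts = counts, totals = totals,
           n_windows = length(windows), pool_size = pool$size)
    }
  }
  parts <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  structure(
    c(list(config = config,
           scheme_name = attr(scheme, "name"),
           symbols = scheme$symbol,
           seed = seed),
      parts),
    class = "dau_background"
  )
}

#' @export
print.dau_background <- function(x, ...) {
  cat("# A DAU background model (", x$config$test, " mode)\n",
      "  space: ", x$config$proteome_space, " / ",
      x$config$positional_space,
      if (x$config$anchored)
        paste0(" anchored on {", paste(x$config$anchor_aa, collapse = ","), "}"),
      "\n  window: L = ", x$config$L, " (-", x$config$upstream, "..+",
      x$config$downstream, "), scheme: ", x$scheme_name, "\n", sep = "")
  if (x$config$test == "ztest") {
    cat("  bootstrap: T = ", x$T, " sets of N = ", x$N, " windows\n", sep = "")
  } else {
    cat("  background set: ", x$n_windows, " windows (pool ", x$pool_size,
        ")\n", sep = "")
  }
  invisible(x)
}

#' Tidy a background model into a long tibble
#'
#' @param x A `dau_background`.
#' @param ... Unused.
#' @return A tibble with one row per (position, symbol): `column` (1-based),
#'   `offset` (0 at the anchor), `symbol`, `mean_freq`, and `se` (Z mode) or
#'   `count` and `total` (Fisher mode).
#' @exportS3Method generics::tidy
tidy.dau_background <- function(x, ...) {
  L <- x$config$L
  offs <- seq_len(L) - 1L - x$config$upstream
  base <- tidyr::expand_grid(column = seq_len(L), symbol = x$symbols)
  base$offset <- offs[base$column]
  base$mean_freq <- as.vector(t(x$mean_freq))
  if (x$config$test == "ztest") {
    base$se <- as.vector(t(x$se))
  } else {
    base$count <- as.vector(t(x$counts))
    base$total <- x$totals[base$column]
  }
  base[, c("column", "offset", "symbol",
           setdiff(names(base), c("column", "offset", "symbol")))]
}

#' Binomial standard error of a proportion
#'
#' `sqrt(p * (1 - p) / n)`, the standard error attached to every background
#' mean frequency in Z mode.
#'
#' @param p Proportion(s).
#' @param n Number of sequences per background set.
#' @return Numeric vector of standard errors.
#' @export
#' @examples
#' binomial_se(0.5, 100) # 0.05
binomial_se <- function(p, n) {
  sqrt(p * (1 - p) / n)
}

#' Serialize / read a background model as JSON
#'
#' The JSON carries the full configuration, alphabet, matrices and seed, so a
#' model can be reused across sessions or command-line invocations.
#'
#' @param bg A `dau_background`.
#' @param path JSON file path.
#' @return `write_background_json()` returns `path` invisibly;
#'   `read_background_json()` returns a `dau_background`.
#' @export
write_background_json <- function(bg, path) {
  payload <- list(
    config = unclass(bg$config),
    scheme_name = bg$scheme_name,
    symbols = bg$symbols,
    seed = bg$seed,
    N = bg$N, T = bg$T, n_windows = bg$n_windows, pool_size = bg$pool_size,
    mean_freq = apply(bg$mean_freq, 1, as.numeric, simplify = FALSE),
    se = if (!is.null(bg$se))
      apply(bg$se, 1, as.numeric, simplify = FALSE),
    counts = if (!is.null(bg$counts))
      apply(bg$counts, 1, as.numeric, simplify = FALSE),
    totals = if (!is.null(bg$totals)) as.numeric(bg$totals)
  )
  jsonlite::write_json(payload[!purrr::map_lgl(payload, is.null)], path,
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_background_json
#' @export
read_background_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- x$config
  config <- bg_config(
    proteome_space = cfg$proteome_space,
    positional_space = cfg$positional_space,
    anchored = isTRUE(cfg$anchored),
    anchor_aa = cfg$anchor_aa,
    upstream = cfg$upstream, downstream = cfg$downstream,
    test = cfg$test, n_boot = cfg$n_boot %||% 300L,
    boot_size = cfg$boot_size,
    max_windows = cfg$max_windows %||% 2e5
  )
  to_matrix <- function(rows) {
    m <- if (is.matrix(rows)) rows else do.call(rbind, rows)
    dimnames(m) <- list(NULL, x[["symbols"]])
    m
  }
  structure(
    list(config = config, scheme_name = x[["scheme_name"]],
         symbols = x[["symbols"]],
         seed = x[["seed"]],
         mean_freq = to_matrix(x[["mean_freq"]]),
         se = if (!is.null(x[["se"]])) to_matrix(x[["se"]]),
         N = x[["N"]], T = x[["T"]],
         boot_freq = NULL,
         counts = if (!is.null(x[["counts"]])) to_matrix(x[["counts"]]),
         totals = if (!is.null(x[["totals"]])) as.numeric(x[["totals"]]),
         n_windows = x[["n_windows"]], pool_size = x[["pool_size"]]),
    class = "dau_background"
  )
}
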