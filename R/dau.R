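## dau: per-position, per-symbol differential usage tests.

#' Position-specific symbol frequencies of a peptide set
#'
#' Counts scheme symbols per window column; `X` padding (and masked
#' non-standard residues) are excluded from both numerator and denominator.
#' Columns whose countable total is zero have undefined frequencies and are
#' flagged.
#'
#' @param peptides A `peptide_set`.
#' @param scheme An `aa_scheme`.
#' @return A list of class `dau_freq` with `counts` and `freq` (L x K
#'   matrices), `totals` (per-column countable totals) and the scheme name.
#' @export
#' @examples
#' ps <- format_aligned(c("AK", "AD"), anchor_column = 0)
#' position_frequencies(ps, aa_scheme("identity"))$freq
position_frequencies <- function(peptides, scheme) {
  if (!inherits(peptides, "peptide_set") || nrow(peptides) == 0) {
    abort("`peptides` must be a non-empty peptide_set.")
  }
  validate_scheme(scheme)
  cw <- count_window_sets(peptides$window, rep(1L, nrow(peptides)), 1L, scheme)
  counts <- cw$counts[, , 1, drop = TRUE]
  if (is.null(dim(counts))) {
    counts <- matrix(counts, nrow = attr(peptides, "L"),
                     dimnames = list(NULL, scheme$symbol))
  }
  totals <- cw$totals[, 1]
  structure(
    list(counts = counts,
         freq = counts / ifelse(totals > 0, totals, NA_real_),
         totals = totals,
         n = nrow(peptides),
         L = attr(peptides, "L"),
         anchor_column = attr(peptides, "anchor_column"),
         scheme_name = attr(scheme, "name"),
         symbols = scheme$symbol),
    class = "dau_freq"
  )
}

#' Two-sided Fisher exact p-value for a 2x2 table
#'
#' Exact hypergeometric test of the table `[[a, b], [c, d]]` using the
#' point-probability two-sided convention: the p-value is the sum of the
#' probabilities of all tables with the same margins whose point probability
#' does not exceed that of the observed table (within a relative tolerance of
#' 1e-7, the convention also used by [stats::fisher.test()]).
#'
#' @param a,b,c,d Non-negative integer cells of the 2x2 table.
#' @return The two-sided p-value.
#' @export
#' @examples
#' fisher_exact_p(10, 0, 0, 10) # 2 / choose(20, 10)
fisher_exact_p <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) abort("Table cells must be non-negative.")
  m <- a + b
  n2 <- c + d
  k <- a + c
  if (m == 0 || n2 == 0 || k == 0 || (b + d) == 0) {
    return(1) # degenerate margin: only one table possible
  }
  lo <- max(0, k - n2)
  hi <- min(k, m)
  x <- lo:hi
  logp <- dhyper(x, m, n2, k, log = TRUE)
  obs <- dhyper(a, m, n2, k, log = TRUE)
  sum(exp(logp[logp <= obs + log(1 + 1e-7)]))
}

## Shared result assembly.
new_dau_result <- function(table, metadata) {
  structure(list(table = table, metadata = metadata), class = "dau_result")
}

cells_grid <- function(freqs) {
  offs <- seq_len(freqs$L) - 1L - freqs$anchor_column
  g <- tidyr::expand_grid(column = seq_len(freqs$L), symbol = freqs$symbols)
  g$offset <- offs[g$column]
  g
}

check_bg_match <- function(freqs, bg, mode) {
  if (bg$config$test != mode) {
    abort(paste0("Background model is in \"", bg$config$test,
                 "\" mode; expected \"", mode, "\"."))
  }
  if (!identical(freqs$symbols, bg$symbols) ||
      !identical(freqs$scheme_name, bg$scheme_name)) {
    abort(paste0("Scheme mismatch: input uses \"", freqs$scheme_name,
                 "\" over {", paste(freqs$symbols, collapse = ","),
                 "} but the background was built with \"", bg$scheme_name,
                 "\"."))
  }
  if (freqs$L != bg$config$L) {
    abort(paste0("Window length mismatch: input L = ", freqs$L,
                 ", background L = ", bg$config$L, "."))
  }
}

#' Z-test of differential usage against a bootstrap background
#'
#' For every cell (position l, symbol) computes
#' `Z = (p - p_bar) / se` where `p` is the input frequency, `p_bar` the
#' bootstrap mean background frequency and `se = sqrt(p_bar (1 - p_bar) / N)`,
#' and refers `Z` to the standard normal for a two-sided p-value. Cells with
#' `se = 0` and `p != p_bar` are assigned infinite `Z`, `p = 0`, and flagged
#' degenerate; columns with zero countable input total are reported as NA
#' cells.
#'
#' @param freqs A `dau_freq` from [position_frequencies()].
#' @param bg A Z-mode `dau_background`.
#' @param alpha Significance level for the `significant` flag (raw p-values).
#' @param adjust `"none"` (default) or `"BH"` for Benjamini-Hochberg across
#'   all cells; when adjusted, `significant` uses the adjusted p-values.
#' @return A `dau_result`.
#' @export
ztest_dau <- function(freqs, bg, alpha = 0.05, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  check_bg_match(freqs, bg, "ztest")
  g <- cells_grid(freqs)
  p <- as.vector(t(freqs$freq))
  pbar <- as.vector(t(bg$mean_freq))
  se <- as.vector(t(bg$se))
  diff <- p - pbar
  z <- ifelse(se > 0, diff / se,
              ifelse(abs(diff) < .Machine$double.eps, 0, Inf * sign(diff)))
  pval <- ifelse(is.infinite(z), 0, 2 * pnorm(-abs(z)))
  g$input_freq <- p
  g$bg_freq <- pbar
  g$diff <- diff
  g$statistic <- z
  g$p_value <- pval
  g$note <- dplyr::case_when(
    is.na(p) ~ "no countable input residues",
    is.na(pbar) ~ "no countable background residues",
    is.infinite(z) ~ "degenerate: zero background SE",
    TRUE ~ NA_character_
  )
  finish_dau(g, freqs, bg, alpha, adjust, test = "ztest")
}

#' Fisher exact test of differential usage against an exhaustive background
#'
#' For every cell builds the 2x2 table `[[a, b], [c, d]]` with `a` the input
#' count of the symbol at the position, `b` the remaining countable input
#' total, `c` the background count and `d` the remaining background total, and
#' computes the two-sided exact p-value (see [fisher_exact_p()]). The reported
#' statistic is the sample odds ratio `(a d) / (b c)`; `diff` is the input
#' frequency minus the background frequency. Zero-margin tables get
#' `p = 1`, `diff = 0` and a note.
#'
#' @inheritParams ztest_dau
#' @param bg A Fisher-mode `dau_background`.
#' @return A `dau_result`.
#' @export
fisher_dau <- function(freqs, bg, alpha = 0.05, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  check_bg_match(freqs, bg, "fisher")
  g <- cells_grid(freqs)
  a <- as.vector(t(freqs$counts))
  in_tot <- freqs$totals[g$column]
  b <- in_tot - a
  cc <- as.vector(t(bg$counts))
  bg_tot <- bg$totals[g$column]
  d <- bg_tot - cc
  p_in <- as.vector(t(freqs$freq))
  p_bg <- as.vector(t(bg$mean_freq))
  zero_margin <- (a + b) == 0 | (cc + d) == 0 | (a + cc) == 0 | (b + d) == 0
  pval <- numeric(nrow(g))
  for (i in seq_len(nrow(g))) {
    pval[i] <- if (zero_margin[i]) 1 else
      fisher_exact_p(a[i], b[i], cc[i], d[i])
  }
  g$input_freq <- p_in
  g$bg_freq <- p_bg
  g$diff <- ifelse(zero_margin, 0, p_in - p_bg)
  g$statistic <- ifelse(zero_margin, NA_real_, (a * d) / (b * cc))
  g$p_value <- pval
  g$count <- a
  g$bg_count <- cc
  na_col <- in_tot == 0 | bg_tot == 0
  g$p_value[na_col] <- NA_real_
  g$note <- dplyr::case_when(
    na_col ~ "no countable residues in column",
    zero_margin ~ "zero-margin table",
    TRUE ~ NA_character_
  )
  finish_dau(g, freqs, bg, alpha, adjust, test = "fisher")
}

finish_dau <- function(g, freqs, bg, alpha, adjust, test) {
  if (adjust == "BH") {
    g$p_adjust <- p.adjust(g$p_value, method = "BH")
    g$significant <- !is.na(g$p_adjust) & g$p_adjust < alpha
  } else {
    g$significant <- !is.na(g$p_value) & g$p_value < alpha
  }
  first <- c("column", "offset", "symbol", "input_freq", "bg_freq", "diff",
             "statistic", "p_value")
  g <- g[, c(first, setdiff(names(g), first))]
  metadata <- list(
    test = test, alpha = alpha, adjust = adjust,
    scheme = freqs$scheme_name, symbols = freqs$symbols,
    L = freqs$L, anchor_column = freqs$anchor_column,
    n_input = freqs$n,
    bg_config = bg$config,
    bg_digest = rlang::hash(list(bg$config, bg$mean_freq, bg$counts,
                                 bg$seed)),
    bg_seed = bg$seed
  )
  new_dau_result(g, metadata)
}

#' Test differential amino-acid (group) usage of a peptide set
#'
#' Computes position-specific symbol frequencies of the input and dispatches
#' to [ztest_dau()] or [fisher_dau()] according to the background model's
#' mode. The scheme must be the one the background was built with.
#'
#' @param peptides A `peptide_set`.
#' @param bg A `dau_background`.
#' @param scheme An `aa_scheme`; defaults to the background's scheme when that
#'   is a built-in or registered name.
#' @param alpha Significance level (raw, per-cell).
#' @param adjust `"none"` or `"BH"`.
#' @return A `dau_result`; see [tidy.dau_result()].
#' @export
test_dau <- function(peptides, bg, scheme = NULL, alpha = 0.05,
                     adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (is.null(scheme)) {
    scheme <- aa_scheme(bg$scheme_name)
  }
  freqs <- position_frequencies(peptides, scheme)
  if (bg$config$test == "ztest") {
    ztest_dau(freqs, bg, alpha = alpha, adjust = adjust)
  } else {
    fisher_dau(freqs, bg, alpha = alpha, adjust = adjust)
  }
}

#' @export
print.dau_result <- function(x, ...) {
  md <- x$metadata
  n_up <- sum(x$table$significant & x$table$diff > 0, na.rm = TRUE)
  n_dn <- sum(x$table$significant & x$table$diff < 0, na.rm = TRUE)
  cat("# DAU test (", md$test, "), scheme ", md$scheme, ", L = ", md$L,
      ", n = ", md$n_input, "\n",
      "  significant at alpha = ", md$alpha, ": ", n_up,
      " over-represented, ", n_dn, " under-represented cell(s)\n", sep = "")
  print(x$table, ...)
  invisible(x)
}

#' Tidy a DAU result
#'
#' @param x A `dau_result`.
#' @param ... Unused.
#' @return The per-cell results tibble: `column` (1-based), `offset` (0 at
#'   the anchor), `symbol`, `input_freq`, `bg_freq`, `diff`, `statistic`
#'   (Z-score or odds ratio), `p_value`, `significant`, `note`.
#' @exportS3Method generics::tidy
tidy.dau_result <- function(x, ...) {
  x$table
}

#' One-row summary of a DAU result
#'
#' @param x A `dau_result`.
#' @param ... Unused.
#' @return A one-row tibble with the test mode, scheme, window geometry,
#'   input size, and significant cell counts.
#' @exportS3Method generics::glance
glance.dau_result <- function(x, ...) {
  md <- x$metadata
  tibble(
    test = md$test, scheme = md$scheme, L = md$L,
    anchor_column = md$anchor_column, n_input = md$n_input,
    alpha = md$alpha,
    n_cells = nrow(x$table),
    n_significant = sum(x$table$significant, na.rm = TRUE),
    n_over = sum(x$table$significant & x$table$diff > 0, na.rm = TRUE),
    n_under = sum(x$table$significant & x$table$diff < 0, na.rm = TRUE),
    min_p = suppressWarnings(min(x$table$p_value, na.rm = TRUE))
  )
}

#' Export a DAU result as TSV / JSON
#'
#' The TSV carries one row per cell with columns `position` (offset, 0 at the
#' anchor), `symbol`, `diff`, `statistic`, `p_value`, `significant`. The JSON
#' adds the full metadata block (test mode, alpha, scheme, background
#' configuration digest).
#'
#' @param result A `dau_result`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dau_tsv <- function(result, path) {
  out <- result$table
  out <- tibble(position = out$offset, symbol = out$symbol, diff = out$diff,
                statistic = out$statistic, p_value = out$p_value,
                significant = out$significant)
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_dau_tsv
#' @export
write_dau_json <- function(result, path) {
  md <- result$metadata
  md$bg_config <- unclass(md$bg_config)
  jsonlite::write_json(
    list(metadata = md, cells = result$table),
    path, auto_unbox = TRUE, digits = NA, na = "null", null = "null",
    pretty = TRUE
  )
  invisible(path)
}
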