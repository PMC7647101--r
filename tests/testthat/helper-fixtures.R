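## Shared test fixtures and independent oracles.

## Write a FASTA file from named sequences; returns the path.
tmp_fasta <- function(seqs, header = names(seqs)) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  writeLines(rbind(paste0(">", header), unname(seqs)), path)
  path
}

mini_proteome <- function(seqs = c(p1 = "MKKDEFGHIK", p2 = "MASAKDLKWW")) {
  as_proteome(data.frame(protein_id = names(seqs), sequence = unname(seqs)))
}

## Independent two-sided Fisher p: exhaustive enumeration over all tables
## with the observed margins, using lchoose arithmetic (no dhyper).
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b
  n2 <- c + d
  k <- a + c
  if (m == 0 || n2 == 0 || k == 0 || (b + d) == 0) {
    return(1)
  }
  x <- max(0, k - n2):min(k, m)
  lp <- lchoose(m, x) + lchoose(n2, k - x) - lchoose(m + n2, k)
  obs <- lchoose(m, a) + lchoose(n2, k - a) - lchoose(m + n2, k)
  sum(exp(lp[lp <= obs + log(1 + 1e-7)]))
}

## Fabricated frequency object for direct arithmetic checks of the tests.
fake_freq <- function(freq, counts = NULL, totals = NULL,
                      scheme_name = "fake", anchor_column = 0L) {
  L <- nrow(freq)
  structure(
    list(counts = counts,
         freq = freq,
         totals = totals %||% rep(1L, L),
         n = if (is.null(totals)) 1L else max(totals),
         L = L,
         anchor_column = anchor_column,
         scheme_name = scheme_name,
         symbols = colnames(freq)),
    class = "dau_freq"
  )
}

## Fabricated Z-mode background with stated mean/se matrices.
fake_zbg <- function(mean_freq, se, N, scheme_name = "fake") {
  L <- nrow(mean_freq)
  structure(
    list(config = bg_config(upstream = 0L, downstream = L - 1L,
                            test = "ztest", boot_size = N),
         scheme_name = scheme_name, symbols = colnames(mean_freq),
         seed = NULL, mean_freq = mean_freq, se = se, N = N, T = 300L,
         boot_freq = NULL, counts = NULL, totals = NULL,
         n_windows = 300L * N, pool_size = NA_integer_),
    class = "dau_background"
  )
}

## Fabricated Fisher-mode background with stated counts.
fake_fbg <- function(counts, totals, scheme_name = "fake") {
  L <- nrow(counts)
  structure(
    list(config = bg_config(upstream = 0L, downstream = L - 1L,
                            test = "fisher"),
         scheme_name = scheme_name, symbols = colnames(counts),
         seed = NULL,
         mean_freq = counts / ifelse(totals > 0, totals, NA_real_),
         se = NULL, N = NULL, T = NULL, boot_freq = NULL,
         counts = counts, totals = totals,
         n_windows = max(totals), pool_size = NA_integer_),
    class = "dau_background"
  )
}

`%||%` <- rlang::`%||%`

AA20_test <- function() {
  strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
}
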