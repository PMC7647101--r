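test_that("position frequencies count symbols and exclude padding", {
  id <- aa_scheme("identity")
  f1 <- position_frequencies(format_aligned(c("AK", "AD"), 0), id)
  expect_equal(unname(f1$freq[1, "A"]), 1)
  expect_equal(unname(f1$freq[2, c("K", "D")]), c(0.5, 0.5))
  f2 <- position_frequencies(format_aligned(c("XA", "AA"), 1), id)
  expect_equal(unname(f2$totals), c(1, 2))
  expect_equal(unname(f2$freq[1, "A"]), 1)
  f3 <- position_frequencies(format_aligned("DK", 0), aa_scheme("charge3"))
  expect_equal(unname(f3$freq[1, "-"]), 1)
  expect_equal(unname(f3$freq[2, "+"]), 1)
})

test_that("the Z statistic is the standardized frequency difference", {
  sym <- matrix(0.3, 1, 1, dimnames = list(NULL, "D"))
  freqs <- fake_freq(sym)
  bg <- fake_zbg(matrix(0.1, 1, 1, dimnames = list(NULL, "D")),
                 se = matrix(0.05, 1, 1, dimnames = list(NULL, "D")),
                 N = 100)
  res <- ztest_dau(freqs, bg)
  expect_equal(res$table$statistic, 4)
  expect_equal(res$table$diff, 0.2)
  expect_equal(res$table$p_value, 2 * pnorm(-4))
  ## null case: p equal to the background mean
  res0 <- ztest_dau(fake_freq(matrix(0.1, 1, 1,
                                     dimnames = list(NULL, "D"))), bg)
  expect_equal(res0$table$statistic, 0)
  expect_equal(res0$table$p_value, 1)
  ## the 5% two-sided critical value
  crit <- fake_freq(matrix(0.1 + 1.959964 * 0.05, 1, 1,
                           dimnames = list(NULL, "D")))
  expect_equal(ztest_dau(crit, bg)$table$p_value, 0.05, tolerance = 1e-4)
})

test_that("a zero background SE is flagged as a degenerate cell", {
  bg0 <- fake_zbg(matrix(0, 1, 1, dimnames = list(NULL, "D")),
                  se = matrix(0, 1, 1, dimnames = list(NULL, "D")),
                  N = 100)
  res <- ztest_dau(fake_freq(matrix(0.2, 1, 1,
                                    dimnames = list(NULL, "D"))), bg0)
  expect_true(is.infinite(res$table$statistic))
  expect_equal(res$table$p_value, 0)
  expect_match(res$table$note, "degenerate")
})

test_that("the two-sided Fisher p matches exhaustive enumeration", {
  expect_equal(fisher_exact_p(10, 0, 0, 10), 2 / choose(20, 10),
               tolerance = 1e-14)
  expect_equal(fisher_exact_p(5, 5, 5, 5), 1)
  expect_equal(fisher_exact_p(8, 2, 2, 8), oracle_fisher_p(8, 2, 2, 8),
               tolerance = 1e-12)
})

test_that("Fisher p agrees with stats::fisher.test on random tables", {
  withr::with_seed(31, {
    for (i in 1:200) {
      m <- sample(1:40, 2, replace = TRUE)
      a <- sample(0:m[1], 1)
      cc <- sample(0:m[2], 1)
      tab <- matrix(c(a, m[1] - a, cc, m[2] - cc), 2, byrow = TRUE)
      expect_equal(fisher_exact_p(tab[1, 1], tab[1, 2],
                                  tab[2, 1], tab[2, 2]),
                   stats::fisher.test(tab)$p.value, tolerance = 1e-12)
    }
  })
})

test_that("with fixed margins, stronger association never raises the p", {
  for (margins in list(c(12, 14, 10), c(8, 8, 8), c(20, 5, 7))) {
    m1 <- margins[1]; m2 <- margins[2]; k <- margins[3]
    a_range <- max(0, k - m2):min(k, m1)
    p <- vapply(a_range, function(a)
      fisher_exact_p(a, m1 - a, k - a, m2 - k + a), numeric(1))
    det <- vapply(a_range, function(a)
      abs(a * (m2 - k + a) - (m1 - a) * (k - a)), numeric(1))
    ord <- order(det)
    expect_true(all(diff(p[ord]) <= 1e-12))
  }
})

test_that("test_dau dispatches by mode and keeps the full cell grid", {
  proteome <- synth_proteome(60, c(60, 120), seed = 41)
  planted <- plant_motif_peptides(
    proteome,
    motif_spec(9, 4, data.frame(column = 4, symbol = "D", target = 0.6)),
    n = 200, seed = 42
  )
  zcfg <- bg_config(upstream = 4, downstream = 4, test = "ztest",
                    n_boot = 60, boot_size = 200)
  zbg <- build_background(proteome, zcfg, seed = 43)
  zres <- test_dau(planted$peptides, zbg)
  expect_equal(nrow(zres$table), 9 * 20)
  expect_equal(zres$metadata$test, "ztest")
  fcfg <- bg_config(upstream = 4, downstream = 4, test = "fisher")
  fbg <- build_background(proteome, fcfg, scheme = aa_scheme("charge3"),
                          seed = 43)
  fres <- test_dau(planted$peptides, fbg)
  expect_equal(nrow(fres$table), 9 * 3)
  expect_equal(fres$metadata$test, "fisher")
  ## the planted aspartate dominates its column in the Z results
  col5 <- zres$table[zres$table$column == 5, ]
  expect_equal(col5$symbol[which.min(col5$p_value)], "D")
  expect_true(col5$significant[col5$symbol == "D"])
  expect_true(col5$diff[col5$symbol == "D"] > 0)
  ## scheme mismatch between input and background is an error
  expect_error(test_dau(planted$peptides, zbg, scheme = aa_scheme("size5")),
               "mismatch")
})

test_that("columns without countable residues stay in the grid as NA", {
  windows <- c("XAK", "XAD") # first column entirely padding
  ps <- format_aligned(windows, anchor_column = 1)
  freqs <- position_frequencies(ps, aa_scheme("identity"))
  bg20 <- fake_fbg(matrix(2L, 3, 20,
                          dimnames = list(NULL, aa_scheme("identity")$symbol)),
                   totals = rep(40, 3), scheme_name = "identity")
  res <- fisher_dau(freqs, bg20)
  first_col <- res$table[res$table$column == 1, ]
  expect_equal(nrow(first_col), 20L)
  expect_true(all(is.na(first_col$p_value)))
  expect_false(any(first_col$significant))
  expect_match(first_col$note[1], "no countable")
})

test_that("Benjamini-Hochberg adjustment is available behind a flag", {
  proteome <- synth_proteome(40, c(60, 100), seed = 51)
  ps <- null_peptides(proteome, n = 150, L = 5, seed = 52)
  cfg <- bg_config(upstream = 2, downstream = 2, test = "ztest",
                   n_boot = 40, boot_size = 150)
  bg <- build_background(proteome, cfg, seed = 53)
  raw <- test_dau(ps, bg)
  adj <- test_dau(ps, bg, adjust = "BH")
  expect_true("p_adjust" %in% names(adj$table))
  expect_equal(adj$table$p_adjust, p.adjust(raw$table$p_value, "BH"))
  expect_lte(sum(adj$table$significant), sum(raw$table$significant))
})

test_that("DAU results export to TSV and JSON with metadata", {
  sym <- matrix(c(0.3, 0.7), 1, 2, dimnames = list(NULL, c("D", "E")))
  freqs <- fake_freq(sym, totals = 10L)
  bg <- fake_zbg(matrix(c(0.1, 0.9), 1, 2,
                        dimnames = list(NULL, c("D", "E"))),
                 se = matrix(0.05, 1, 2, dimnames = list(NULL, c("D", "E"))),
                 N = 100)
  res <- ztest_dau(freqs, bg)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_dau_tsv(res, tsv)
  back <- readr::read_tsv(tsv, show_col_types = FALSE)
  expect_equal(names(back), c("position", "symbol", "diff", "statistic",
                              "p_value", "significant"))
  expect_equal(back$statistic, res$table$statistic)
  js <- withr::local_tempfile(fileext = ".json")
  write_dau_json(res, js)
  parsed <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(parsed$metadata$test, "ztest")
  expect_equal(parsed$cells$statistic, res$table$statistic)
})

test_that("tidy and glance summarize results in broom style", {
  sym <- matrix(c(0.3, 0.7), 1, 2, dimnames = list(NULL, c("D", "E")))
  bg <- fake_zbg(matrix(c(0.1, 0.9), 1, 2,
                        dimnames = list(NULL, c("D", "E"))),
                 se = matrix(0.05, 1, 2, dimnames = list(NULL, c("D", "E"))),
                 N = 100)
  res <- ztest_dau(fake_freq(sym), bg)
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("column", "offset", "symbol", "diff", "statistic",
                    "p_value", "significant") %in% names(td)))
  gl <- glance(res)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$n_cells, 2L)
  expect_equal(gl$test, "ztest")
})
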