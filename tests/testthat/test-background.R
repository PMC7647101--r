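test_that("exactly twelve background configurations are valid", {
  grid <- valid_bg_configs()
  expect_equal(nrow(grid), 12L)
  expect_equal(nrow(dplyr::distinct(grid)), 12L)
  for (i in seq_len(nrow(grid))) {
    expect_s3_class(
      bg_config(proteome_space = grid$proteome_space[i],
                positional_space = grid$positional_space[i],
                anchored = grid$anchored[i],
                anchor_aa = if (grid$anchored[i]) "K",
                upstream = 2, downstream = 2, boot_size = 10),
      "bg_config"
    )
  }
  expect_error(bg_config(positional_space = "nterm", anchored = TRUE,
                         anchor_aa = "K", upstream = 1, downstream = 1),
               "only valid")
  expect_error(bg_config(anchored = TRUE, upstream = 1, downstream = 1),
               "non-empty")
})

test_that("terminal sampling anchors at protein ends with X padding", {
  p <- mini_proteome(c(p1 = "MK"))
  nt <- bg_config(positional_space = "nterm", upstream = 0, downstream = 4,
                  boot_size = 3)
  expect_equal(unique(sample_windows(p, nt, 3, seed = 1)), "MKXXX")
  ct <- bg_config(positional_space = "cterm", upstream = 3, downstream = 0,
                  boot_size = 3)
  expect_equal(unique(sample_windows(p, ct, 3, seed = 1)), "XXMK")
})

test_that("anchored sampling returns only windows with the anchor residue", {
  p <- synth_proteome(20, c(40, 60), seed = 2)
  cfg <- bg_config(anchored = TRUE, anchor_aa = "K",
                   upstream = 3, downstream = 3, boot_size = 50)
  w <- sample_windows(p, cfg, 50, seed = 9)
  expect_true(all(substr(w, 4, 4) == "K"))
  all_a <- mini_proteome(c(p1 = "AAAA"))
  expect_error(sample_windows(all_a, cfg, 5, seed = 1), "\\{K\\}")
})

test_that("proteome-space restriction distinguishes input from non-input", {
  p <- synth_proteome(10, c(30, 40), seed = 4)
  ids <- p$protein_id[1:3]
  cfg_in <- bg_config(proteome_space = "inputSet", upstream = 1,
                      downstream = 1, boot_size = 5)
  expect_error(sample_windows(p, cfg_in, 5, seed = 1), "input_ids")
  pool_in <- unique(nchar(p$sequence[1:3]))
  w_in <- sample_windows(p, cfg_in, 30, input_ids = ids, seed = 1)
  expect_equal(length(w_in), 30L)
  cfg_non <- bg_config(proteome_space = "nonInputSet", upstream = 1,
                       downstream = 1, boot_size = 5)
  expect_silent(sample_windows(p, cfg_non, 10, input_ids = ids, seed = 1))
  expect_error(sample_windows(p, cfg_non, 5,
                              input_ids = p$protein_id, seed = 1),
               "No proteins left")
})

test_that("a degenerate proteome gives unit frequency and zero SE", {
  p <- as_proteome(data.frame(protein_id = c("a", "b"),
                              sequence = c("AAAAAAAA", "AAAAAAAA")))
  cfg <- bg_config(upstream = 2, downstream = 2, test = "ztest",
                   n_boot = 10, boot_size = 6)
  bg <- build_background(p, cfg, seed = 3)
  expect_equal(unname(bg$mean_freq[, "A"]), rep(1, 5))
  expect_equal(unname(bg$se[, "A"]), rep(0, 5))
  expect_equal(unname(rowSums(bg$mean_freq)), rep(1, 5))
})

test_that("the binomial standard error follows sqrt(p(1-p)/N)", {
  expect_equal(binomial_se(0.5, 100), 0.05)
  expect_equal(binomial_se(0, 10), 0)
  p <- synth_proteome(50, c(60, 100), seed = 8)
  cfg <- bg_config(upstream = 2, downstream = 2, test = "ztest",
                   n_boot = 20, boot_size = 50)
  bg <- build_background(p, cfg, seed = 5, keep_boot = TRUE)
  ## Eq-level: stored SE is exactly the binomial SE of the stored mean
  expect_equal(bg$se, binomial_se(bg$mean_freq, bg$N))
  ## the stored mean is exactly the average of the per-bootstrap frequencies
  expect_equal(bg$mean_freq,
               apply(bg$boot_freq, c(1, 2), mean),
               tolerance = 1e-12)
  ## SE is bounded by 0.5/sqrt(N)
  expect_true(all(bg$se <= 0.5 / sqrt(bg$N) + 1e-12))
})

test_that("background construction is deterministic under a seed", {
  p <- synth_proteome(30, c(50, 80), seed = 1)
  cfg <- bg_config(upstream = 3, downstream = 3, test = "ztest",
                   n_boot = 25, boot_size = 40)
  b1 <- build_background(p, cfg, seed = 7)
  b2 <- build_background(p, cfg, seed = 7)
  b3 <- build_background(p, cfg, seed = 8)
  expect_identical(b1$mean_freq, b2$mean_freq)
  expect_identical(b1$se, b2$se)
  expect_false(identical(b1$mean_freq, b3$mean_freq))
})

test_that("bootstrap means track the generator frequencies", {
  q <- aa_freqs_human()
  p <- synth_proteome(200, c(150, 250), aa_freqs = q, seed = 12)
  cfg <- bg_config(upstream = 2, downstream = 2, test = "ztest",
                   n_boot = 60, boot_size = 200)
  bg <- build_background(p, cfg, seed = 13)
  ## tolerance combines bootstrap error (T*N draws) and the finite-proteome
  ## deviation of the realized composition from q
  R <- sum(nchar(p$sequence))
  tol <- 3 * (sqrt(q * (1 - q) / (cfg$n_boot * 200)) +
                sqrt(q * (1 - q) / R))
  mid <- bg$mean_freq[3, AA20] # central column, no padding effects
  expect_true(all(abs(mid - q) <= tol))
})

test_that("Fisher-mode counts sum to the countable windows per position", {
  p <- mini_proteome(c(a = "MKDE", b = "GH", c = "WYSTV"))
  cfg <- bg_config(positional_space = "nterm", upstream = 0, downstream = 4,
                   test = "fisher")
  bg <- build_background(p, cfg)
  ## columns beyond a protein's end are padding: totals shrink with position
  ## windows: MKDEX / GHXXX / WYSTV
  expect_equal(unname(bg$totals), c(3, 3, 2, 2, 1))
  expect_equal(unname(rowSums(bg$counts)), unname(bg$totals))
  expect_equal(bg$n_windows, 3L)
})

test_that("small pools fall back to replacement sampling with a warning", {
  p <- mini_proteome(c(a = "MKDE"))
  cfg <- bg_config(positional_space = "nterm", upstream = 0, downstream = 2,
                   test = "ztest", n_boot = 5, boot_size = 10)
  expect_warning(build_background(p, cfg, seed = 2), "replacement")
})

test_that("background JSON serialization round-trips", {
  p <- synth_proteome(30, c(40, 60), seed = 21)
  cfg <- bg_config(upstream = 2, downstream = 2, test = "ztest",
                   n_boot = 10, boot_size = 30, anchored = TRUE,
                   anchor_aa = c("S", "T"))
  bg <- build_background(p, cfg, seed = 22)
  path <- withr::local_tempfile(fileext = ".json")
  write_background_json(bg, path)
  back <- read_background_json(path)
  expect_equal(back$mean_freq, bg$mean_freq, tolerance = 1e-15)
  expect_equal(back$se, bg$se, tolerance = 1e-15)
  expect_equal(back$config$anchor_aa, cfg$anchor_aa)
  expect_equal(back$config$test, "ztest")
  expect_equal(back$N, bg$N)
  ## Fisher-mode model round-trips its counts
  cfgf <- bg_config(upstream = 1, downstream = 1, test = "fisher")
  bgf <- build_background(p, cfgf, seed = 23)
  pathf <- withr::local_tempfile(fileext = ".json")
  write_background_json(bgf, pathf)
  backf <- read_background_json(pathf)
  expect_equal(backf$counts, bgf$counts)
  expect_equal(backf$totals, bgf$totals)
})
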