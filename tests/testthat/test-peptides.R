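test_that("anchored-sequence syntax parses lowercase and asterisk marks", {
  expect_equal(parse_anchored_sequence("ASTRSkSSTD"),
               list(clean_sequence = "ASTRSKSSTD", anchor_indices = 6L))
  expect_equal(parse_anchored_sequence("ASTRSK*SSTD"),
               list(clean_sequence = "ASTRSKSSTD", anchor_indices = 6L))
  expect_equal(parse_anchored_sequence("AkTkC"),
               list(clean_sequence = "AKTKC", anchor_indices = c(2L, 4L)))
})

test_that("anchored-sequence syntax rejects malformed input", {
  expect_error(parse_anchored_sequence("ASTR"), "No anchor")
  expect_error(parse_anchored_sequence("astrsk"), "ambiguous")
  expect_error(parse_anchored_sequence("*AST"), "cannot open")
  expect_error(parse_anchored_sequence("AS**T"), "Consecutive")
})

test_that("parsing then re-annotating the anchor is a round trip", {
  raws <- c("ASTRSkSSTD", "AkTkC", "mKDD", "ASK*D")
  for (raw in raws) {
    parsed <- parse_anchored_sequence(raw)
    for (k in parsed$anchor_indices) {
      s <- strsplit(parsed$clean_sequence, "")[[1]]
      s[k] <- tolower(s[k])
      re <- parse_anchored_sequence(paste(s, collapse = ""))
      expect_equal(re$clean_sequence, parsed$clean_sequence)
      expect_true(k %in% re$anchor_indices)
    }
  }
})

test_that("positional anchors are verified against the protein", {
  p <- mini_proteome(c(p1 = "MAKDE"))
  hit <- resolve_position_anchor("K3", p, "p1")
  expect_equal(hit$anchor_pos, 3L)
  expect_equal(hit$residue, "K")
  expect_error(resolve_position_anchor("K4", p, "p1"), "expected K, found D")
  expect_error(resolve_position_anchor("K123", p, "p1"), "outside")
  expect_error(resolve_position_anchor("K3", p, "missing"), "not found")
})

test_that("window extraction pads with X beyond the termini", {
  p <- mini_proteome(c(p1 = "MKKD"))
  w1 <- extract_windows(p, data.frame(protein_id = "p1", anchor_pos = 3),
                        upstream = 2, downstream = 2)
  expect_equal(w1$window, "MKKDX")
  expect_equal(attr(w1, "anchor_column"), 2L)
  w2 <- extract_windows(p, data.frame(protein_id = "p1", anchor_pos = 1),
                        upstream = 2, downstream = 1)
  expect_equal(w2$window, "XXMK")
  expect_error(
    extract_windows(p, data.frame(protein_id = "p9", anchor_pos = 1), 1, 1),
    "p9"
  )
})

test_that("extracted windows equal naive slicing and satisfy invariants", {
  proteome <- synth_proteome(30, c(5, 60), seed = 11)
  withr::with_seed(99, {
    idx <- sample.int(nrow(proteome), 200, replace = TRUE)
    pos <- vapply(idx, function(i)
      sample.int(nchar(proteome$sequence[i]), 1), integer(1))
  })
  anchors <- tibble::tibble(protein_id = proteome$protein_id[idx],
                            anchor_pos = pos)
  up <- 4L; down <- 6L
  ps <- extract_windows(proteome, anchors, up, down)
  L <- up + 1L + down
  expect_true(all(nchar(ps$window) == L))
  ## oracle: per-character naive slicing
  for (j in seq_len(nrow(ps))) {
    seq <- proteome$sequence[match(ps$protein_id[j], proteome$protein_id)]
    expected <- vapply(seq_len(L), function(col) {
      at <- ps$anchor_pos[j] - up + col - 1L
      if (at < 1 || at > nchar(seq)) "X" else substr(seq, at, at)
    }, character(1))
    expect_equal(ps$window[j], paste(expected, collapse = ""))
  }
  ## X only as contiguous prefix/suffix
  core <- gsub("^X+|X+$", "", ps$window)
  expect_false(any(grepl("X", core)))
  ## anchor column holds the anchor residue
  expect_equal(substr(ps$window, up + 1, up + 1),
               substr(proteome$sequence[match(ps$protein_id,
                                              proteome$protein_id)],
                      ps$anchor_pos, ps$anchor_pos))
})

test_that("non-standard residues stay in windows but never count or anchor", {
  p <- as_proteome(data.frame(protein_id = "p1", sequence = "MKUDE"))
  w <- extract_windows(p, data.frame(protein_id = "p1", anchor_pos = 4),
                       upstream = 2, downstream = 1)
  expect_equal(w$window, "KUDE")
  ## the U column contributes nothing to counts or totals
  f <- position_frequencies(w, aa_scheme("identity"))
  expect_equal(unname(f$totals), c(1, 0, 1, 1))
  expect_error(
    extract_windows(p, data.frame(protein_id = "p1", anchor_pos = 3), 1, 1),
    "non-standard"
  )
})

test_that("pre-aligned input is validated and carries offsets", {
  ps <- format_aligned(c("RRAST", "KRASA"), anchor_column = 3)
  expect_equal(attr(ps, "L"), 5L)
  expect_equal(attr(ps, "upstream"), 3L)
  expect_equal(attr(ps, "downstream"), 1L)
  expect_error(format_aligned(c("RRAST", "KRAS"), anchor_column = 3),
               "ragged")
  expect_error(format_aligned("RXAST", anchor_column = 3), "Interior X")
})

test_that("peptide cleaning drops, dedupes and expands anchors", {
  out <- clean_peptides(
    data.frame(protein_id = c("p1", "p2", "p1", "p1"),
               peptide = c("AkTkC", "ASTR", "AsT", "AsT")),
    anchor_aa = c("K", "S"), quiet = TRUE
  )
  ## p1 AkTkC expands to two rows; duplicated AsT collapses to one;
  ## ASTR (no mark) is dropped
  expect_equal(nrow(out), 3L)
  expect_equal(out$anchor_index[out$clean_sequence == "AKTKC"], c(2L, 4L))
  expect_equal(sum(out$clean_sequence == "AST"), 1L)
  rep <- attr(out, "report")
  expect_equal(unname(rep["deduplicated"]), 1)
  expect_equal(unname(rep["dropped"]), 1)
  expect_error(
    clean_peptides(data.frame(protein_id = "p1", peptide = "ASTR"),
                   anchor_aa = "K", quiet = TRUE),
    "No usable peptides"
  )
})

test_that("fetch_windows locates peptides and extracts around their anchors", {
  p <- mini_proteome(c(p1 = "MAKDEAKTKC", p2 = "GGGSSTGGG"))
  ps <- fetch_windows(p,
                      data.frame(protein_id = c("p1", "p2"),
                                 peptide = c("AkTKC", "GsST")),
                      anchor_aa = c("K", "S"),
                      upstream = 2, downstream = 2, quiet = TRUE)
  ## p1: AKTKC starts at 6, anchor K at in-peptide 2 -> protein position 7
  expect_equal(ps$window[1], substr("MAKDEAKTKC", 5, 9))
  expect_equal(ps$anchor_pos[1], 7L)
  ## p2: GSST starts at 3, anchor S at position 4
  expect_equal(ps$anchor_pos[2], 4L)
})

test_that("protease-style position labels map P-numbering onto columns", {
  ps <- format_aligned(strrep("A", 30), anchor_column = 14)
  lab <- position_labels(ps, style = "protease")
  expect_equal(lab[1], "P15")
  expect_equal(lab[15], "P1")
  expect_equal(lab[16], "P1'")
  expect_equal(lab[30], "P15'")
  off <- position_labels(ps, style = "offset")
  expect_equal(off[15], "0")
  expect_equal(off[16], "+1")
})
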