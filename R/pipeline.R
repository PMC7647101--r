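## cli: end-to-end pipeline and command-line entry point.

#' Run the full differential-usage pipeline
#'
#' Reads a proteome (FASTA) and a peptide table (TSV), builds the requested
#' background model, tests differential usage, and writes the results
#' (TSV + JSON), the background model (JSON), the resolved configuration
#' (JSON), and optionally logo/heatmap figures into `output_dir`.
#'
#' The peptide TSV is interpreted according to `input_format`:
#' `"anchored"` expects columns `protein_id`, `peptide` (lowercase or
#' asterisk anchor marks); `"site"` expects `protein_id`, `site` (positional
#' tokens such as `"K123"`); `"aligned"` expects `anchor_column`, `window`
#' (pre-aligned equal-length windows, as written by [write_fixture_files()]).
#'
#' @param proteome_fasta Path to the proteome FASTA.
#' @param peptides_tsv Path to the peptide TSV.
#' @param output_dir Output directory (created if needed).
#' @param input_format `"anchored"`, `"site"` or `"aligned"`.
#' @param anchor_aa Anchoring residues for `"anchored"` input.
#' @param upstream,downstream Window offsets (ignored for `"aligned"`).
#' @param scheme Scheme name, or path to a scheme JSON file.
#' @param bg_space,bg_region,bg_anchored,bg_anchor_aa Background model axes
#'   (see [bg_config()]); `bg_anchor_aa` defaults to `anchor_aa` when
#'   `bg_anchored` is `TRUE`.
#' @param test `"ztest"` or `"fisher"`.
#' @param n_boot,boot_size Bootstrap geometry for Z mode; `boot_size = NULL`
#'   uses the input-set size.
#' @param max_windows Fisher-mode background cap for `"anywhere"` spaces.
#' @param alpha Significance level.
#' @param adjust `"none"` or `"BH"`.
#' @param seed Integer seed driving all sampling.
#' @param cleave_met `"none"`, `"all"` or `"biological"` initiator-Met
#'   handling applied to the proteome before any windowing.
#' @param figures Render logo and heatmap figures.
#' @param figure_format `"svg"`, `"png"` or `"pdf"`.
#' @param label_style `"offset"` or `"protease"` column labels.
#' @param quiet Suppress progress messages.
#' @return A list with `result`, `background`, `peptides` and `paths`
#'   (named vector of files written), invisibly.
#' @export
run_dau_pipeline <- function(proteome_fasta, peptides_tsv, output_dir,
                             input_format = c("anchored", "site", "aligned"),
                             anchor_aa = NULL,
                             upstream = 7L, downstream = 7L,
                             scheme = "identity",
                             bg_space = "wholeProteome",
                             bg_region = "anywhere",
                             bg_anchored = FALSE,
                             bg_anchor_aa = NULL,
                             test = c("ztest", "fisher"),
                             n_boot = 300L, boot_size = NULL,
                             max_windows = 2e5,
                             alpha = 0.05, adjust = "none", seed = 1L,
                             cleave_met = c("none", "all", "biological"),
                             figures = TRUE, figure_format = "svg",
                             label_style = "offset", quiet = FALSE) {
  input_format <- match.arg(input_format)
  test <- match.arg(test)
  cleave_met <- match.arg(cleave_met)
  say <- function(...) if (!quiet) inform(paste0(...))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)

  say("Reading proteome: ", proteome_fasta)
  proteome <- read_proteome(proteome_fasta)
  if (cleave_met != "none") {
    proteome <- cleave_initiator_met(proteome, mode = cleave_met)
  }

  scheme_obj <- if (file.exists(scheme)) read_scheme_json(scheme) else
    aa_scheme(scheme)

  say("Reading peptides: ", peptides_tsv, " (", input_format, ")")
  tab <- readr::read_tsv(peptides_tsv, show_col_types = FALSE)
  peptides <- switch(
    input_format,
    anchored = {
      if (is.null(anchor_aa)) {
        abort("`anchor_aa` is required for anchored input.")
      }
      fetch_windows(proteome, tab, anchor_aa = anchor_aa,
                    upstream = upstream, downstream = downstream,
                    quiet = quiet)
    },
    site = {
      anchors <- purrr::map2_dfr(tab$site, tab$protein_id, function(s, id) {
        resolve_position_anchor(s, proteome, id)
      })
      extract_windows(proteome, anchors, upstream = upstream,
                      downstream = downstream)
    },
    aligned = {
      format_aligned(tab$window, anchor_column = tab$anchor_column[1],
                     protein_ids = tab$protein_id)
    }
  )
  say("Input set: ", nrow(peptides), " windows of length ",
      attr(peptides, "L"))

  config <- bg_config(
    proteome_space = bg_space, positional_space = bg_region,
    anchored = bg_anchored,
    anchor_aa = if (bg_anchored) (bg_anchor_aa %||% anchor_aa),
    upstream = attr(peptides, "upstream"),
    downstream = attr(peptides, "downstream"),
    test = test, n_boot = n_boot, boot_size = boot_size,
    max_windows = max_windows
  )
  say("Building ", test, " background (", bg_space, "/", bg_region,
      if (bg_anchored) " anchored", "), seed ", seed)
  bg <- build_background(proteome, config, scheme = scheme_obj,
                         input = peptides, seed = seed)
  result <- test_dau(peptides, bg, scheme = scheme_obj, alpha = alpha,
                     adjust = adjust)

  paths <- c(result_tsv = file.path(output_dir, "dau_result.tsv"),
             result_json = file.path(output_dir, "dau_result.json"),
             background_json = file.path(output_dir, "background.json"),
             config_json = file.path(output_dir, "run_config.json"))
  write_dau_tsv(result, paths[["result_tsv"]])
  write_dau_json(result, paths[["result_json"]])
  write_background_json(bg, paths[["background_json"]])
  resolved <- list(
    proteome_fasta = proteome_fasta, peptides_tsv = peptides_tsv,
    output_dir = output_dir, input_format = input_format,
    anchor_aa = anchor_aa, upstream = attr(peptides, "upstream"),
    downstream = attr(peptides, "downstream"),
    scheme = if (file.exists(scheme)) scheme else attr(scheme_obj, "name"),
    bg_space = bg_space, bg_region = bg_region, bg_anchored = bg_anchored,
    bg_anchor_aa = if (bg_anchored) (bg_anchor_aa %||% anchor_aa),
    test = test, n_boot = n_boot,
    boot_size = bg$N, max_windows = max_windows, alpha = alpha,
    adjust = adjust, seed = seed, cleave_met = cleave_met,
    label_style = label_style,
    config_digest = result$metadata$bg_digest
  )
  jsonlite::write_json(resolved[!purrr::map_lgl(resolved, is.null)],
                       paths[["config_json"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  if (figures) {
    paths <- c(paths,
               logo = file.path(output_dir, paste0("logo.", figure_format)),
               heatmap = file.path(output_dir,
                                   paste0("heatmap.", figure_format)))
    render_logo(result, paths[["logo"]], labels = label_style)
    render_heatmap(result, paths[["heatmap"]],
                   value = if (test == "ztest") "statistic" else "diff",
                   labels = label_style)
  }
  n_sig <- sum(result$table$significant, na.rm = TRUE)
  say("Done: ", n_sig, " significant cell(s) at alpha = ", alpha,
      "; outputs in ", output_dir)
  if (n_sig == 0) say("Note: no significant differential usage detected.")
  invisible(list(result = result, background = bg, peptides = peptides,
                 paths = paths))
}

cli_spec <- function() {
  list(
    simulate = "Generate a synthetic proteome + planted peptide windows",
    background = "Build a background model and save it as JSON",
    run = "Full pipeline: proteome + peptides -> tests + figures",
    test = "Full pipeline without figures",
    logo = "Render a logo from a saved dau_result.json",
    heatmap = "Render a heatmap from a saved dau_result.json"
  )
}

cli_usage <- function() {
  spec <- cli_spec()
  paste0("usage: pepdau <subcommand> [options]\n\nsubcommands:\n",
         paste0("  ", format(names(spec), width = 12), spec,
                collapse = "\n"),
         "\n\nRun pepdau <subcommand> --help for options.\n")
}

#' Command-line entry point
#'
#' Thin subcommand dispatcher over the package functions, used by the
#' `inst/cli/pepdau.R` script. Returns the process exit status (0 success,
#' 2 usage/configuration error) instead of quitting, so it can be driven
#' in-process.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit status, invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0 || args[1] %in% c("-h", "--help", "help")) {
    cat(cli_usage())
    return(invisible(0L))
  }
  sub <- args[1]
  rest <- args[-1]
  if (!sub %in% names(cli_spec())) {
    message("Unknown subcommand: ", sub, "\n", cli_usage())
    return(invisible(2L))
  }
  status <- tryCatch({
    switch(sub,
           simulate = cli_simulate(rest),
           background = cli_background(rest),
           run = cli_run(rest, figures = TRUE),
           test = cli_run(rest, figures = FALSE),
           logo = cli_render(rest, kind = "logo"),
           heatmap = cli_render(rest, kind = "heatmap"))
    0L
  }, error = function(e) {
    message("pepdau ", sub, ": ", conditionMessage(e))
    2L
  })
  invisible(status)
}

cli_parse <- function(args, option_list, usage) {
  parser <- optparse::OptionParser(usage = usage, option_list = option_list)
  optparse::parse_args(parser, args = args)
}

cli_simulate <- function(args) {
  opts <- cli_parse(args, list(
    optparse::make_option("--out", type = "character",
                          help = "Output directory"),
    optparse::make_option("--n-proteins", type = "integer", default = 500L,
                          dest = "n_proteins"),
    optparse::make_option("--min-length", type = "integer", default = 100L,
                          dest = "min_length"),
    optparse::make_option("--max-length", type = "integer", default = 300L,
                          dest = "max_length"),
    optparse::make_option("--n-peptides", type = "integer", default = 416L,
                          dest = "n_peptides"),
    optparse::make_option("--window", type = "integer", default = 30L,
                          help = "Window length L"),
    optparse::make_option("--anchor-column", type = "integer", default = 14L,
                          dest = "anchor_column", help = "0-based"),
    optparse::make_option("--effects", type = "character", default = "",
                          help = "Comma-separated col:AA:target triples, e.g. 14:D:0.8"),
    optparse::make_option("--baseline", type = "character",
                          default = "uniform",
                          help = "uniform or human"),
    optparse::make_option("--seed", type = "integer", default = 1L)
  ), "pepdau simulate --out DIR [options]")
  if (is.null(opts$out)) abort("--out is required.")
  effects <- NULL
  if (nzchar(opts$effects)) {
    triples <- strsplit(strsplit(opts$effects, ",")[[1]], ":")
    effects <- purrr::map_dfr(triples, function(t) {
      if (length(t) != 3) abort("Effects must be col:AA:target triples.")
      tibble(column = as.integer(t[1]), symbol = t[2],
             target = as.numeric(t[3]))
    })
  }
  baseline <- if (opts$baseline == "human") aa_freqs_human() else
    aa_freqs_uniform()
  proteome <- synth_proteome(opts$n_proteins,
                             c(opts$min_length, opts$max_length),
                             aa_freqs = baseline, seed = opts$seed)
  spec <- motif_spec(opts$window, opts$anchor_column, effects = effects,
                     baseline = baseline)
  planted <- plant_motif_peptides(proteome, spec, n = opts$n_peptides,
                                  seed = opts$seed + 1L)
  paths <- write_fixture_files(proteome, planted$peptides, planted$truth,
                               dir = opts$out)
  inform(paste0("Wrote ", paste(paths, collapse = ", ")))
}

cli_bg_options <- function() {
  list(
    optparse::make_option("--space", type = "character",
                          default = "wholeProteome"),
    optparse::make_option("--region", type = "character",
                          default = "anywhere"),
    optparse::make_option("--anchored", type = "character", default = "",
                          help = "Anchor AAs, e.g. K or ST; empty = unanchored"),
    optparse::make_option("--mode", type = "character", default = "ztest",
                          help = "ztest or fisher"),
    optparse::make_option("--n-boot", type = "integer", default = 300L,
                          dest = "n_boot"),
    optparse::make_option("--boot-size", type = "integer", default = NULL,
                          dest = "boot_size"),
    optparse::make_option("--max-windows", type = "double", default = 2e5,
                          dest = "max_windows")
  )
}

cli_background <- function(args) {
  opts <- cli_parse(args, c(list(
    optparse::make_option("--proteome", type = "character"),
    optparse::make_option("--out", type = "character"),
    optparse::make_option("--upstream", type = "integer", default = 7L),
    optparse::make_option("--downstream", type = "integer", default = 7L),
    optparse::make_option("--scheme", type = "character",
                          default = "identity"),
    optparse::make_option("--seed", type = "integer", default = 1L)
  ), cli_bg_options()),
  "pepdau background --proteome FASTA --out JSON [options]")
  if (is.null(opts$proteome) || is.null(opts$out)) {
    abort("--proteome and --out are required.")
  }
  if (opts$mode == "ztest" && is.null(opts$boot_size)) {
    abort("--boot-size is required for ztest mode.")
  }
  proteome <- read_proteome(opts$proteome)
  scheme_obj <- if (file.exists(opts$scheme)) read_scheme_json(opts$scheme)
  else aa_scheme(opts$scheme)
  config <- bg_config(
    proteome_space = opts$space, positional_space = opts$region,
    anchored = nzchar(opts$anchored),
    anchor_aa = if (nzchar(opts$anchored))
      strsplit(opts$anchored, "")[[1]],
    upstream = opts$upstream, downstream = opts$downstream,
    test = opts$mode, n_boot = opts$n_boot, boot_size = opts$boot_size,
    max_windows = opts$max_windows
  )
  bg <- build_background(proteome, config, scheme = scheme_obj,
                         seed = opts$seed)
  write_background_json(bg, opts$out)
  inform(paste0("Wrote ", opts$out))
}

cli_run <- function(args, figures) {
  opts <- cli_parse(args, c(list(
    optparse::make_option("--proteome", type = "character"),
    optparse::make_option("--peptides", type = "character"),
    optparse::make_option("--out", type = "character"),
    optparse::make_option("--format", type = "character",
                          default = "aligned",
                          help = "anchored, site or aligned"),
    optparse::make_option("--anchor-aa", type = "character", default = "",
                          dest = "anchor_aa"),
    optparse::make_option("--upstream", type = "integer", default = 7L),
    optparse::make_option("--downstream", type = "integer", default = 7L),
    optparse::make_option("--scheme", type = "character",
                          default = "identity"),
    optparse::make_option("--alpha", type = "double", default = 0.05),
    optparse::make_option("--adjust", type = "character", default = "none"),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--cleave-met", type = "character",
                          default = "none", dest = "cleave_met"),
    optparse::make_option("--figure-format", type = "character",
                          default = "svg", dest = "figure_format"),
    optparse::make_option("--labels", type = "character",
                          default = "offset")
  ), cli_bg_options()),
  "pepdau run --proteome FASTA --peptides TSV --out DIR [options]")
  if (is.null(opts$proteome) || is.null(opts$peptides) || is.null(opts$out)) {
    abort("--proteome, --peptides and --out are required.")
  }
  run_dau_pipeline(
    proteome_fasta = opts$proteome, peptides_tsv = opts$peptides,
    output_dir = opts$out, input_format = opts$format,
    anchor_aa = if (nzchar(opts$anchor_aa))
      strsplit(opts$anchor_aa, "")[[1]],
    upstream = opts$upstream, downstream = opts$downstream,
    scheme = opts$scheme,
    bg_space = opts$space, bg_region = opts$region,
    bg_anchored = nzchar(opts$anchored),
    bg_anchor_aa = if (nzchar(opts$anchored))
      strsplit(opts$anchored, "")[[1]],
    test = opts$mode, n_boot = opts$n_boot, boot_size = opts$boot_size,
    max_windows = opts$max_windows, alpha = opts$alpha,
    adjust = opts$adjust, seed = opts$seed, cleave_met = opts$cleave_met,
    figures = figures, figure_format = opts$figure_format,
    label_style = opts$labels
  )
}

cli_render <- function(args, kind) {
  opts <- cli_parse(args, list(
    optparse::make_option("--result", type = "character",
                          help = "dau_result.json from a previous run"),
    optparse::make_option("--out", type = "character"),
    optparse::make_option("--metric", type = "character",
                          default = "diff_pct"),
    optparse::make_option("--value", type = "character",
                          default = "statistic"),
    optparse::make_option("--labels", type = "character",
                          default = "offset")
  ), paste0("pepdau ", kind, " --result JSON --out FILE [options]"))
  if (is.null(opts$result) || is.null(opts$out)) {
    abort("--result and --out are required.")
  }
  result <- read_dau_json(opts$result)
  if (kind == "logo") {
    render_logo(result, opts$out, metric = opts$metric,
                labels = opts$labels)
  } else {
    render_heatmap(result, opts$out, value = opts$value,
                   labels = opts$labels)
  }
  inform(paste0("Wrote ", opts$out))
}

#' Read a DAU result written by [write_dau_json()]
#'
#' @param path JSON file path.
#' @return A `dau_result`.
#' @export
read_dau_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  md <- x$metadata
  cfg <- md$bg_config
  md$bg_config <- bg_config(
    proteome_space = cfg$proteome_space,
    positional_space = cfg$positional_space,
    anchored = isTRUE(cfg$anchored), anchor_aa = cfg$anchor_aa,
    upstream = cfg$upstream, downstream = cfg$downstream,
    test = cfg$test, n_boot = cfg$n_boot %||% 300L,
    boot_size = cfg$boot_size, max_windows = cfg$max_windows %||% 2e5
  )
  new_dau_result(as_tibble(x$cells), md)
}
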