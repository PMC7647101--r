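## alphabets: reduced amino-acid alphabets (grouping schemes) and collapsing.

#' Construct an amino-acid grouping scheme
#'
#' A grouping scheme is a total partition of the 20 standard amino acids into
#' named groups, each displayed as one single-character symbol with a color.
#' `X` is reserved for padding and cannot be a group symbol.
#'
#' @param name Scheme name.
#' @param groups A data frame with columns `symbol` (single character),
#'   `label`, `color` (hex string) and `members` (list column of character
#'   vectors of amino acids).
#' @return A tibble of class `aa_scheme`.
#' @export
new_scheme <- function(name, groups) {
  groups <- as_tibble(groups)
  needed <- c("symbol", "label", "color", "members")
  missing_cols <- setdiff(needed, names(groups))
  if (length(missing_cols) > 0) {
    abort(paste0("Scheme groups lack column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  groups <- groups[, needed]
  groups$members <- purrr::map(groups$members, ~ toupper(as.character(.x)))
  out <- groups
  attr(out, "name") <- name
  class(out) <- c("aa_scheme", class(tibble()))
  validate_scheme(out)
  out
}

#' Validate a grouping scheme
#'
#' Checks that group symbols are unique single characters (not `X`), and that
#' the member sets are disjoint and jointly cover all 20 standard amino acids.
#'
#' @param scheme An `aa_scheme`.
#' @return The scheme, invisibly; errors name missing/duplicated amino acids.
#' @export
validate_scheme <- function(scheme) {
  if (any(nchar(scheme$symbol) != 1)) {
    abort("Scheme symbols must be single characters.")
  }
  if (anyDuplicated(scheme$symbol)) {
    abort(paste0("Duplicate scheme symbol(s): ",
                 paste(unique(scheme$symbol[duplicated(scheme$symbol)]),
                       collapse = ", "), "."))
  }
  if (PAD %in% scheme$symbol) {
    abort("\"X\" is reserved for padding and cannot be a group symbol.")
  }
  all_members <- unlist(scheme$members)
  dup <- unique(all_members[duplicated(all_members)])
  if (length(dup) > 0) {
    abort(paste0("Amino acid(s) assigned to more than one group: ",
                 paste(dup, collapse = ", "), "."))
  }
  missing_aa <- setdiff(AA20, all_members)
  if (length(missing_aa) > 0) {
    abort(paste0("Scheme does not cover all 20 amino acids; missing: ",
                 paste(missing_aa, collapse = ", "), "."))
  }
  extra <- setdiff(all_members, AA20)
  if (length(extra) > 0) {
    abort(paste0("Scheme members outside the 20-AA alphabet: ",
                 paste(extra, collapse = ", "), "."))
  }
  invisible(scheme)
}

## Session registry for user schemes.
.scheme_registry <- new.env(parent = emptyenv())

#' Built-in and registered grouping schemes
#'
#' `"identity"` keeps all 20 amino acids as singleton groups.
#' `"hydrophobicity3"` groups by hydrophobicity: hydrophobic
#' \{W,F,Y,L,I,V,M,C\}, neutral \{H,A,T,P,G,N,S,Q\}, hydrophilic \{R,K,D,E\}.
#' `"charge3"` groups by charge at physiological pH: positive \{H,K,R\},
#' neutral (the remaining 15), negative \{D,E\}. `"size5"` groups by
#' side-chain size: tiny \{G,S,A\}, small \{D,N,C,E,H\}, medium \{R,Q,K,T\},
#' large \{M,P,Y,F\}, gigantic \{I,L,V,W\}. Schemes added with
#' [register_scheme()] are also retrievable by name.
#'
#' @param name Scheme name.
#' @return An `aa_scheme` tibble.
#' @export
#' @examples
#' aa_scheme("charge3")
aa_scheme <- function(name) {
  if (exists(name, envir = .scheme_registry, inherits = FALSE)) {
    return(get(name, envir = .scheme_registry))
  }
  builtin <- builtin_schemes()
  if (!name %in% names(builtin)) {
    abort(paste0("Unknown scheme \"", name, "\". Available: ",
                 paste(c(names(builtin),
                         ls(.scheme_registry)), collapse = ", "), "."))
  }
  builtin[[name]]()
}

builtin_schemes <- function() {
  list(
    identity = function() {
      pal <- grDevices::hcl.colors(20, "Dark 3")
      new_scheme("identity", tibble(
        symbol = AA20, label = AA20, color = pal,
        members = as.list(AA20)
      ))
    },
    hydrophobicity3 = function() {
      new_scheme("hydrophobicity3", tibble(
        symbol = c("H", "n", "p"),
        label = c("hydrophobic", "neutral", "hydrophilic"),
        color = c("#1B9E77", "#7570B3", "#D95F02"),
        members = list(
          c("W", "F", "Y", "L", "I", "V", "M", "C"),
          ## Caption typo in the source groupings lists A twice and omits Q;
          ## Q belongs here so the three groups partition the 20 AAs.
          c("H", "A", "T", "P", "G", "N", "S", "Q"),
          c("R", "K", "D", "E")
        )
      ))
    },
    charge3 = function() {
      new_scheme("charge3", tibble(
        symbol = c("+", "0", "-"),
        label = c("positive", "neutral", "negative"),
        color = c("#2166AC", "#999999", "#B2182B"),
        members = list(
          c("H", "K", "R"),
          c("A", "C", "F", "G", "I", "L", "M", "N", "P", "Q", "S", "T",
            "V", "W", "Y"),
          c("D", "E")
        )
      ))
    },
    size5 = function() {
      new_scheme("size5", tibble(
        symbol = c("t", "s", "m", "L", "G"),
        label = c("tiny", "small", "medium", "large", "gigantic"),
        color = c("#66C2A5", "#FC8D62", "#8DA0CB", "#E78AC3", "#A6D854"),
        members = list(
          c("G", "S", "A"),
          c("D", "N", "C", "E", "H"),
          c("R", "Q", "K", "T"),
          c("M", "P", "Y", "F"),
          c("I", "L", "V", "W")
        )
      ))
    }
  )
}

#' Register a custom grouping scheme
#'
#' Validates the scheme and stores it in the session registry under its name,
#' after which [aa_scheme()] can retrieve it. Registering under a built-in
#' name shadows the built-in for the session.
#'
#' @param scheme An `aa_scheme` (see [new_scheme()]).
#' @return The scheme name, invisibly.
#' @export
register_scheme <- function(scheme) {
  validate_scheme(scheme)
  name <- attr(scheme, "name")
  if (is.null(name) || !nzchar(name)) {
    abort("Scheme must carry a non-empty name.")
  }
  assign(name, scheme, envir = .scheme_registry)
  invisible(name)
}

#' Read / write a grouping scheme as JSON
#'
#' The JSON schema is `{"name": ..., "groups": [{"symbol", "label", "color",
#' "members": [...]}, ...]}` and is validated strictly on read.
#'
#' @param path JSON file path.
#' @return `read_scheme_json()` returns an `aa_scheme`; `write_scheme_json()`
#'   returns `path` invisibly.
#' @export
read_scheme_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(x$name) || is.null(x$groups)) {
    abort("Scheme JSON must have top-level \"name\" and \"groups\".")
  }
  groups <- purrr::map_dfr(x$groups, function(g) {
    for (f in c("symbol", "label", "color", "members")) {
      if (is.null(g[[f]])) {
        abort(paste0("Scheme JSON group lacks field \"", f, "\"."))
      }
    }
    tibble(symbol = g$symbol, label = g$label, color = g$color,
           members = list(unlist(g$members)))
  })
  new_scheme(x$name, groups)
}

#' @rdname read_scheme_json
#' @param scheme An `aa_scheme`.
#' @export
write_scheme_json <- function(scheme, path) {
  validate_scheme(scheme)
  jsonlite::write_json(
    list(name = attr(scheme, "name"),
         groups = purrr::pmap(scheme, function(symbol, label, color, members) {
           list(symbol = symbol, label = label, color = color,
                members = as.list(members))
         })),
    path, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}

## Named map from residue character to group symbol; X maps to X.
scheme_map <- function(scheme) {
  map <- setNames(rep(scheme$symbol, lengths(scheme$members)),
                  unlist(scheme$members))
  c(map, setNames(PAD, PAD))
}

#' Collapse sequences or counts onto a reduced alphabet
#'
#' Each amino acid is replaced by its group symbol; `X` padding is preserved.
#' For count matrices/vectors (named by amino acid), counts are summed over
#' group members.
#'
#' @param x A character vector of windows/sequences, or a named numeric vector
#'   or matrix with amino-acid columns.
#' @param scheme An `aa_scheme`.
#' @return Collapsed sequences, or counts over group symbols.
#' @export
#' @examples
#' collapse_to_scheme("DKE", aa_scheme("charge3"))
#' collapse_to_scheme(c(D = 3, E = 2, K = 1), aa_scheme("charge3"))
collapse_to_scheme <- function(x, scheme) {
  validate_scheme(scheme)
  map <- scheme_map(scheme)
  if (is.character(x)) {
    chars <- strsplit(x, "", fixed = TRUE)
    purrr::map_chr(chars, function(ch) {
      sym <- map[ch]
      if (anyNA(sym)) {
        abort(paste0("Residue(s) not covered by scheme \"",
                     attr(scheme, "name"), "\": ",
                     paste(unique(ch[is.na(sym)]), collapse = ", "), "."))
      }
      paste(sym, collapse = "")
    })
  } else if (is.matrix(x)) {
    bad <- setdiff(colnames(x), names(map))
    if (length(bad) > 0) {
      abort(paste0("Count column(s) not covered by scheme: ",
                   paste(bad, collapse = ", "), "."))
    }
    groups <- map[colnames(x)]
    out <- t(rowsum(t(x), group = groups))
    out[, intersect(c(scheme$symbol, PAD), colnames(out)), drop = FALSE]
  } else if (is.numeric(x) && !is.null(names(x))) {
    m <- collapse_to_scheme(matrix(x, nrow = 1, dimnames = list(NULL, names(x))),
                            scheme)
    setNames(as.numeric(m), colnames(m))
  } else {
    abort("`x` must be character sequences or named counts.")
  }
}
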