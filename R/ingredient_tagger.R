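#' Compile a sugar-ingredient lexicon
#'
#' Loads and validates the regular-expression lexicon used to tag ingredients
#' as added sugar, dairy sugar source, or fruit/vegetable sugar source.
#' Exclusion patterns veto a match (non-caloric sweeteners, sugar alcohols,
#' plant-based "milks"). The package ships a curated English default under
#' \code{system.file("extdata", "sugar_lexicon.yaml", package = "carbquality")};
#' users may supply their own file, e.g. for other languages or to enrich the
#' term list.
#'
#' @param source path to a YAML file with keys \code{added_sugar},
#'   \code{dairy}, \code{fruit_veg} (each a non-empty list of case-insensitive
#'   regex strings) and optionally \code{exclusions}; or a list with those
#'   elements. \code{NULL} (default) loads the shipped lexicon.
#' @return an object of class \code{sugar_lexicon}: a list with character
#'   vectors \code{added_sugar}, \code{dairy}, \code{fruit_veg},
#'   \code{exclusions}, order-preserving and deduplicated.
#' @examples
#' lex <- sugar_lexicon()
#' length(lex$added_sugar) >= 40
#' @export
sugar_lexicon <- function(source = NULL) {
  if (is.null(source)) {
    source <- system.file("extdata", "sugar_lexicon.yaml",
                          package = "carbquality")
  }
  raw <- if (is.character(source)) yaml::read_yaml(source) else source
  for (key in c("added_sugar", "dairy", "fruit_veg")) {
    if (is.null(raw[[key]]) || length(raw[[key]]) == 0L) {
      stop("lexicon is missing a non-empty '", key, "' pattern list",
           call. = FALSE)
    }
  }
  raw$exclusions <- raw$exclusions %||% character(0)
  lex <- lapply(raw[c("added_sugar", "dairy", "fruit_veg", "exclusions")],
                function(x) as.character(unlist(x)))
  # every pattern must compile and must not match the empty string
  for (key in names(lex)) {
    for (p in lex[[key]]) {
      ok <- tryCatch({grepl(p, "probe", perl = TRUE); TRUE},
                     error = function(e) FALSE,
                     warning = function(w) FALSE)
      if (!ok) stop("invalid regex in '", key, "': ", p, call. = FALSE)
      if (grepl(p, "", perl = TRUE)) {
        stop("pattern matches the empty string in '", key, "': ", p,
             call. = FALSE)
      }
    }
    if (anyDuplicated(lex[[key]])) {
      warning("duplicate patterns removed from '", key, "'", call. = FALSE)
      lex[[key]] <- lex[[key]][!duplicated(lex[[key]])]
    }
  }
  structure(lex, class = "sugar_lexicon")
}

#' @export
print.sugar_lexicon <- function(x, ...) {
  cat("<sugar_lexicon> ",
      length(x$added_sugar), " added-sugar, ",
      length(x$dairy), " dairy, ",
      length(x$fruit_veg), " fruit/veg, ",
      length(x$exclusions), " exclusion patterns\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Parse a label ingredient list into ordered ingredient names
#'
#' Splits raw label text on top-level commas and semicolons, ignoring
#' separators inside balanced parentheses or brackets. Parenthetical
#' annotations (percentages, compound sub-ingredient lists) are dropped from
#' each name, as are stand-alone percentage annotations and leading
#' qualifiers such as "organic" or "enriched". Order is preserved — label
#' convention lists ingredients in descending order of quantity, so position
#' carries signal.
#'
#' @param text raw ingredient-list string.
#' @param expand_compound if \code{TRUE}, sub-ingredients inside parentheses
#'   are appended after their parent instead of being dropped. Default
#'   \code{FALSE}: label position semantics refer to the top-level list.
#' @return character vector of ingredient names (possibly empty).
#' @examples
#' parse_ingredient_list("water, sugar (12%), cocoa (cocoa mass, cocoa butter), salt")
#' @export
parse_ingredient_list <- function(text, expand_compound = FALSE) {
  if (is.null(text) || is.na(text) || !nzchar(trimws(text))) {
    return(character(0))
  }
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  tokens <- character(0)
  buf <- character(0)
  for (ch in chars) {
    if (ch %in% c("(", "[")) depth <- depth + 1L
    if (ch %in% c(")", "]")) depth <- max(0L, depth - 1L)
    if (depth == 0L && ch %in% c(",", ";")) {
      tokens <- c(tokens, paste(buf, collapse = ""))
      buf <- character(0)
    } else {
      buf <- c(buf, ch)
    }
  }
  tokens <- c(tokens, paste(buf, collapse = ""))

  out <- character(0)
  for (tok in tokens) {
    sub_names <- character(0)
    if (expand_compound) {
      inner <- regmatches(tok, gregexpr("\\(([^()]*)\\)|\\[([^\\[\\]]*)\\]",
                                        tok, perl = TRUE))[[1]]
      inner <- gsub("^[\\(\\[]|[\\)\\]]$", "", inner, perl = TRUE)
      # only expand when the parenthetical looks like a sub-list, not "12%"
      inner <- inner[!grepl("^\\s*[0-9.]+\\s*%\\s*$", inner)]
      if (length(inner)) {
        sub_names <- unlist(lapply(inner, parse_ingredient_list,
                                   expand_compound = FALSE))
      }
    }
    out <- c(out, clean_ingredient_name(tok), sub_names)
  }
  out[nzchar(out)]
}

# strip parentheticals, percentage annotations, leading qualifiers, stray
# punctuation; collapse whitespace
clean_ingredient_name <- function(x) {
  # iterate: nested parentheses removed inside-out
  repeat {
    y <- gsub("\\([^()]*\\)|\\[[^\\[\\]]*\\]", " ", x, perl = TRUE)
    if (identical(y, x)) break
    x <- y
  }
  x <- gsub("[0-9.]+\\s*%", " ", x)
  x <- gsub("[*.:]+", " ", x)
  x <- gsub("\\s+", " ", x)
  x <- trimws(x)
  x <- sub("^(organic|enriched|certified organic)\\s+", "", x,
           ignore.case = TRUE)
  trimws(x)
}

#' Tag the first six ingredients against a sugar lexicon
#'
#' For each of the first six parsed ingredient names, sets three flags:
#' added sugar, dairy sugar source, fruit/vegetable sugar source. A name
#' matching any exclusion pattern (e.g. a non-caloric sweetener) gets no
#' flags. Flags are not mutually exclusive: "fruit juice concentrate" is both
#' a fruit term and, under the WHO free-sugar definition, an added sugar —
#' the added-sugar flag governs the free-sugar classification downstream.
#' Positions beyond the sixth ingredient never influence the result; products
#' with fewer than six ingredients are padded with all-false flags.
#'
#' @param names ordered character vector of parsed ingredient names (from
#'   \code{\link{parse_ingredient_list}}).
#' @param lexicon a \code{\link{sugar_lexicon}}.
#' @return integer vector of length 18 (0/1), named
#'   \code{pos<k>_added}, \code{pos<k>_dairy}, \code{pos<k>_fruit_veg} for
#'   k = 1..6, with attribute \code{n_ingredients_parsed}.
#' @examples
#' lex <- sugar_lexicon()
#' tag_ingredients(c("milk", "sugar", "strawberry"), lex)
#' @export
tag_ingredients <- function(names, lexicon) {
  stopifnot(inherits(lexicon, "sugar_lexicon"))
  flags <- matrix(0L, nrow = 6L, ncol = 3L,
                  dimnames = list(NULL, c("added", "dairy", "fruit_veg")))
  n <- length(names)
  for (i in seq_len(min(6L, n))) {
    nm <- trimws(names[[i]])
    if (!nzchar(nm)) next
    if (matches_any(nm, lexicon$exclusions)) next
    flags[i, "added"]     <- as.integer(matches_any(nm, lexicon$added_sugar))
    flags[i, "dairy"]     <- as.integer(matches_any(nm, lexicon$dairy))
    flags[i, "fruit_veg"] <- as.integer(matches_any(nm, lexicon$fruit_veg))
  }
  out <- as.integer(t(flags))
  names(out) <- paste0("pos", rep(1:6, each = 3L),
                       "_", c("added", "dairy", "fruit_veg"))
  attr(out, "n_ingredients_parsed") <- n
  out
}

matches_any <- function(x, patterns) {
  if (length(patterns) == 0L) return(FALSE)
  any(vapply(patterns, function(p) {
    grepl(p, x, ignore.case = TRUE, perl = TRUE)
  }, logical(1)))
}

#' Tag every product in a data frame
#'
#' Convenience wrapper: parses \code{ingredient_text} and tags the first six
#' ingredients for each row, returning the 18-column 0/1 tag matrix.
#'
#' @param products product data frame with an \code{ingredient_text} column.
#' @param lexicon a \code{\link{sugar_lexicon}}.
#' @param expand_compound passed to \code{\link{parse_ingredient_list}}.
#' @return integer matrix, one row per product, 18 tag columns.
#' @export
tag_products <- function(products, lexicon, expand_compound = FALSE) {
  stopifnot(is.data.frame(products), "ingredient_text" %in% names(products))
  flag_names <- paste0("pos", rep(1:6, each = 3L),
                       "_", c("added", "dairy", "fruit_veg"))
  out <- t(vapply(products$ingredient_text, function(txt) {
    tag_ingredients(parse_ingredient_list(txt, expand_compound), lexicon)
  }, integer(18L), USE.NAMES = FALSE))
  if (nrow(products) == 0L) out <- matrix(integer(0), ncol = 18L)
  dimnames(out) <- list(products$product_id, flag_names)
  out
}
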