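#' Read packaged-food product records
#'
#' Loads product records from CSV (header row, RFC 4180, UTF-8) or JSON-lines
#' into the canonical per-100 g data frame used throughout the package. Rows
#' whose mandatory numeric fields cannot be parsed are dropped with a logged
#' reason rather than aborting the read; a missing mandatory \emph{column} is
#' a configuration error and does abort.
#'
#' Canonical columns: \code{product_id}, \code{market}, \code{category},
#' \code{sub_category}, \code{launch_year}, \code{serving_size_g},
#' \code{ingredient_text}, the eight panel nutrients per 100 g
#' (\code{energy} kcal, \code{total_fat}, \code{saturated_fat},
#' \code{carbohydrate}, \code{fiber}, \code{total_sugars}, \code{protein} in
#' g, \code{sodium} in mg), optional \code{declared_added_sugars} (g/100 g,
#' NA when not declared) and \code{claims} (pipe-separated string).
#'
#' @param path file to read.
#' @param format \code{"csv"}, \code{"jsonl"}, or \code{"auto"} (by file
#'   extension).
#' @param mapping optional named character vector mapping canonical column
#'   names to the file's column names (e.g. \code{c(carbohydrate = "carbs_g")}),
#'   or the path of a YAML file holding such a mapping.
#' @return data frame of products, row order preserved, with attribute
#'   \code{"rejections"}: a data frame (\code{row}, \code{product_id},
#'   \code{reason}) of dropped rows.
#' @seealso [clean_products()] for semantic filtering, [write_products()].
#' @export
read_products <- function(path, format = c("auto", "csv", "jsonl"),
                          mapping = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.(jsonl|ndjson|json)$", path, ignore.case = TRUE))
      "jsonl" else "csv"
  }
  if (is.character(mapping) && length(mapping) == 1L && file.exists(mapping)) {
    mapping <- unlist(yaml::read_yaml(mapping))
  }
  raw <- if (format == "csv") {
    read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
             colClasses = "character")
  } else {
    jsonlite::stream_in(file(path), verbose = FALSE, simplifyDataFrame = TRUE)
  }
  if (!is.null(mapping)) {
    for (canon in names(mapping)) {
      if (!mapping[[canon]] %in% names(raw)) {
        stop("mapped column '", mapping[[canon]], "' not present in file",
             call. = FALSE)
      }
      names(raw)[names(raw) == mapping[[canon]]] <- canon
    }
  }
  mandatory <- c("product_id", "category", "ingredient_text",
                 "serving_size_g", NUTRIENT_COLS)
  missing_cols <- setdiff(mandatory, names(raw))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (opt in c("market", "sub_category", "claims")) {
    if (!opt %in% names(raw)) raw[[opt]] <- ""
  }
  if (!"launch_year" %in% names(raw)) raw$launch_year <- NA
  if (!"declared_added_sugars" %in% names(raw)) raw$declared_added_sugars <- NA

  num_cols <- c("serving_size_g", "launch_year", NUTRIENT_COLS,
                "declared_added_sugars")
  parsed <- raw
  for (col in num_cols) parsed[[col]] <- suppress_numeric(raw[[col]])

  # a row is rejected when a mandatory numeric is unparseable/absent;
  # declared_added_sugars and launch_year may be missing (optional fields)
  must_num <- c("serving_size_g", NUTRIENT_COLS)
  bad <- rep(FALSE, nrow(parsed))
  reason <- rep(NA_character_, nrow(parsed))
  for (col in rev(must_num)) {
    miss <- is.na(parsed[[col]])
    reason[miss] <- paste0("missing nutrient",
                           if (col == "serving_size_g") "" else
                             paste0(" (", col, ")"))
    reason[miss & col == "serving_size_g"] <- "missing serving size"
    bad <- bad | miss
  }
  rejections <- data.frame(row = which(bad),
                           product_id = parsed$product_id[bad],
                           reason = reason[bad],
                           stringsAsFactors = FALSE)
  kept <- parsed[!bad, canonical_cols(), drop = FALSE]
  rownames(kept) <- NULL
  attr(kept, "rejections") <- rejections
  kept
}

canonical_cols <- function() {
  c("product_id", "market", "category", "sub_category", "launch_year",
    "serving_size_g", "ingredient_text", NUTRIENT_COLS,
    "declared_added_sugars", "claims")
}

suppress_numeric <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  x <- trimws(as.character(x))
  x[!nzchar(x)] <- NA
  suppressWarnings(as.numeric(x))
}

#' Write product records
#'
#' Writes the canonical product data frame as CSV or JSON-lines; the inverse
#' of [read_products()] (round-trips losslessly up to numeric formatting).
#'
#' @param products canonical product data frame.
#' @param path output file.
#' @param format \code{"csv"}, \code{"jsonl"}, or \code{"auto"}.
#' @return \code{path}, invisibly.
#' @export
write_products <- function(products, path, format = c("auto", "csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(jsonl|ndjson|json)$", path, ignore.case = TRUE))
      "jsonl" else "csv"
  }
  cols <- intersect(canonical_cols(), names(products))
  out <- products[, cols, drop = FALSE]
  if (format == "csv") {
    write.csv(out, path, row.names = FALSE, na = "")
  } else {
    con <- file(path, open = "w")
    on.exit(close(con))
    jsonlite::stream_out(out, con, verbose = FALSE, digits = NA)
  }
  invisible(path)
}

#' Rescale per-serving nutrient amounts to per 100 g
#'
#' Linear rescaling by \code{100 / serving_size_g}; unit conventions are
#' preserved (sodium stays in mg, energy in kcal).
#'
#' @param values named numeric vector (or single-row data frame) of nutrient
#'   amounts per serving.
#' @param serving_size_g serving size in grams, must be positive.
#' @return numeric vector of the same names, per 100 g.
#' @examples
#' normalize_to_100g(c(carbohydrate = 15, sodium = 120), 50)
#' @export
normalize_to_100g <- function(values, serving_size_g) {
  if (!is.numeric(serving_size_g) || length(serving_size_g) != 1L ||
      is.na(serving_size_g) || serving_size_g <= 0) {
    stop("invalid serving size: must be a single positive number",
         call. = FALSE)
  }
  if (is.data.frame(values)) values <- unlist(values[1, , drop = TRUE])
  values * (100 / serving_size_g)
}

#' Default cleaning rules for product records
#'
#' The rule set enforced by [clean_products()]. Defaults reproduce the spirit
#' of "complete, internally consistent on-pack information": non-negativity,
#' sugars and fiber each at most carbohydrate + 0.5 g, saturated fat at most
#' total fat + 0.5 g, macronutrient sum at most 105 g/100 g, and an Atwater
#' 4/9/4 energy-consistency check at 25\% relative tolerance (label rounding
#' and country-specific tolerances are absorbed by the slack).
#'
#' @param tol_g absolute slack (g) on the pairwise nutrient inequalities.
#' @param macro_sum_max maximum allowed fat + carbohydrate + protein (g/100 g).
#' @param energy_rel_tol relative tolerance of the Atwater energy check
#'   \eqn{|E - (4C + 9F + 4P)| \le tol \cdot E}.
#' @param year_min,year_max accepted launch-year window (records without a
#'   launch year are kept).
#' @return a named list of rules.
#' @export
cleaning_rules <- function(tol_g = 0.5, macro_sum_max = 105,
                           energy_rel_tol = 0.25,
                           year_min = 2014, year_max = 2024) {
  list(tol_g = tol_g, macro_sum_max = macro_sum_max,
       energy_rel_tol = energy_rel_tol,
       year_min = year_min, year_max = year_max)
}

#' Filter product records to internally consistent panels
#'
#' Partitions records into kept and rejected sets. Kept records have a
#' complete non-negative panel satisfying all pairwise constraints and the
#' Atwater energy check, a positive serving size, at least one parseable
#' ingredient, a launch year inside the configured window (when present),
#' and — when declared — added sugars not exceeding total sugars + 0.5 g.
#' Filtering is idempotent and conserving: kept and rejected always
#' partition the input.
#'
#' @param products canonical product data frame.
#' @param rules rule set from [cleaning_rules()].
#' @return list with \code{kept}, \code{rejected} (with a \code{reason}
#'   column) and \code{counts} (a named rejection-reason table).
#' @export
clean_products <- function(products, rules = cleaning_rules()) {
  stopifnot(is.data.frame(products))
  n <- nrow(products)
  reason <- rep(NA_character_, n)
  note <- function(cond, why) {
    cond[is.na(cond)] <- FALSE
    reason[is.na(reason) & cond] <<- why
  }
  p <- products
  panel <- as.matrix(p[, NUTRIENT_COLS, drop = FALSE])

  note(apply(panel, 1L, function(r) any(is.na(r))), "missing nutrient")
  note(apply(panel, 1L, function(r) any(!is.finite(r) | r < 0)),
       "negative or non-finite nutrient")
  note(is.na(p$serving_size_g) | p$serving_size_g <= 0, "invalid serving size")
  note(p$saturated_fat > p$total_fat + rules$tol_g,
       "saturated fat exceeds total fat")
  note(p$total_sugars > p$carbohydrate + rules$tol_g,
       "sugars exceed carbohydrate")
  note(p$fiber > p$carbohydrate + rules$tol_g, "fiber exceeds carbohydrate")
  note(p$total_fat + p$carbohydrate + p$protein > rules$macro_sum_max,
       "macronutrient sum exceeds limit")
  atwater <- 4 * p$carbohydrate + 9 * p$total_fat + 4 * p$protein
  note(abs(p$energy - atwater) > rules$energy_rel_tol * p$energy,
       "energy inconsistent with macronutrients")
  n_ingr <- vapply(p$ingredient_text,
                   function(t) length(parse_ingredient_list(t)), integer(1),
                   USE.NAMES = FALSE)
  note(n_ingr == 0L, "no parseable ingredient")
  note(!is.na(p$launch_year) &
         (p$launch_year < rules$year_min | p$launch_year > rules$year_max),
       "launch year outside window")
  note(!is.na(p$declared_added_sugars) &
         (p$declared_added_sugars < 0 |
            p$declared_added_sugars > p$total_sugars + rules$tol_g),
       "declared added sugars exceed total sugars")

  bad <- !is.na(reason)
  rejected <- p[bad, , drop = FALSE]
  if (nrow(rejected)) rejected$reason <- reason[bad]
  else rejected$reason <- character(0)
  kept <- p[!bad, , drop = FALSE]
  rownames(kept) <- rownames(rejected) <- NULL
  list(kept = kept, rejected = rejected,
       counts = table(factor(reason[bad])))
}

#' Write a rejection report
#'
#' @param cleaned result of [clean_products()].
#' @param path CSV output path (\code{product_id}, \code{reason}).
#' @return \code{path}, invisibly.
#' @export
write_rejection_report <- function(cleaned, path) {
  write.csv(cleaned$rejected[, c("product_id", "reason")], path,
            row.names = FALSE)
  invisible(path)
}
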