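#' Category overrides for free-sugar assignment
#'
#' Categories and sub-categories whose sugars are free sugars essentially by
#' definition (juices, soft drinks, sweeteners, confectionery, honey,
#' syrups, ...): for these, total sugars is taken as the free-sugar value
#' regardless of any declared or predicted added-sugar amount.
#'
#' @param categories character vector of category names.
#' @param subcategories character vector of sub-category names.
#' @param source optional YAML file with keys \code{categories} and
#'   \code{subcategories}; overrides the two arguments.
#' @return object of class \code{override_rules}.
#' @export
override_rules <- function(
    categories = c("Juice Drinks", "Carbonated Soft Drinks",
                   "Sweeteners & Sugar", "Sugar & Gum Confectionery"),
    subcategories = c("Flavoured Water", "Honey", "Syrups",
                      "Ready To Drink (Iced) Tea",
                      "Water Based Ice Lollies, Pops & Sorbets"),
    source = NULL) {
  if (!is.null(source)) {
    raw <- yaml::read_yaml(source)
    categories <- as.character(unlist(raw$categories))
    subcategories <- as.character(unlist(raw$subcategories))
  }
  structure(list(categories = categories, subcategories = subcategories),
            class = "override_rules")
}

norm_label <- function(x) tolower(gsub("\\s+", " ", trimws(x)))

#' Assign free-sugar values to products
#'
#' Resolves a free-sugar estimate per product: products in an override
#' category or sub-category get their total sugars
#' (\code{source = "total_sugar_override"}); otherwise the declared
#' added-sugar value is used when present and \code{prefer_declared} is set
#' (\code{source = "declared"}); otherwise the model prediction
#' (\code{source = "predicted"}). Products with no available source are left
#' unresolved (\code{source = NA}) and are excluded — and counted — by
#' [score_dataset()].
#'
#' @param products canonical product data frame.
#' @param prediction optional prediction data frame from
#'   [predict.sugar_model()], aligned row-for-row with \code{products}.
#' @param rules an [override_rules()] object.
#' @param prefer_declared use the declared value over the prediction when
#'   both exist (merging declared and predicted values). Default TRUE.
#' @return \code{products} with columns \code{free_sugars} (g/100 g) and
#'   \code{free_sugars_source} appended.
#' @export
assign_free_sugars <- function(products, prediction = NULL,
                               rules = override_rules(),
                               prefer_declared = TRUE) {
  n <- nrow(products)
  if (!is.null(prediction) && nrow(prediction) != n) {
    stop("prediction must align row-for-row with products", call. = FALSE)
  }
  fs <- rep(NA_real_, n)
  src <- rep(NA_character_, n)

  in_override <- norm_label(products$category) %in%
    norm_label(rules$categories) |
    norm_label(products$sub_category) %in% norm_label(rules$subcategories)
  fs[in_override] <- products$total_sugars[in_override]
  src[in_override] <- "total_sugar_override"

  open <- !in_override
  decl <- open & prefer_declared & !is.na(products$declared_added_sugars)
  fs[decl] <- products$declared_added_sugars[decl]
  src[decl] <- "declared"

  open <- open & is.na(src)
  if (!is.null(prediction)) {
    pred <- open & !is.na(prediction$added_sugars_pred)
    fs[pred] <- prediction$added_sugars_pred[pred]
    src[pred] <- "predicted"
    open <- open & is.na(src)
  }
  # fall back to declared even when prefer_declared = FALSE and no prediction
  decl2 <- open & !is.na(products$declared_added_sugars)
  fs[decl2] <- products$declared_added_sugars[decl2]
  src[decl2] <- "declared"

  products$free_sugars <- fs
  products$free_sugars_source <- src
  products
}

#' Evaluate the 10:1|1:2 carbohydrate-quality criterion
#'
#' For a product (or any fixed mass basis — the test is scale-invariant):
#' \itemize{
#'   \item \strong{10:1} — at least 1 g of fiber per 10 g of carbohydrate:
#'     \code{fiber >= carbohydrate / 10} (inclusive).
#'   \item \strong{1:2} — less than 2 g of free sugars per 1 g of fiber:
#'     \code{free_sugars < 2 * fiber} (strict), with zero free sugars
#'     defined as meeting the limit (configurable).
#' }
#' The combined verdict is the conjunction. Zero-carbohydrate products meet
#' 10:1 vacuously.
#'
#' @param carbohydrate,fiber,free_sugars non-negative numeric vectors
#'   (recycled), in grams on a common basis.
#' @param zero_fs_meets_1_2 whether free_sugars = 0 with fiber = 0 satisfies
#'   the 1:2 limit (default TRUE: zero free sugars cannot violate a
#'   free-sugar limit).
#' @return data frame with logical columns \code{meets_10_1},
#'   \code{meets_1_2}, \code{meets_combined}.
#' @examples
#' meets_carb_ratio(66.0, 8.8, 10.2)  # meets both
#' meets_carb_ratio(10, 1, 2)         # 1:2 is strict: 2 is not < 2
#' @export
meets_carb_ratio <- function(carbohydrate, fiber, free_sugars,
                             zero_fs_meets_1_2 = TRUE) {
  k <- max(length(carbohydrate), length(fiber), length(free_sugars))
  carbohydrate <- rep_len(carbohydrate, k)
  fiber <- rep_len(fiber, k)
  free_sugars <- rep_len(free_sugars, k)
  if (any(is.na(carbohydrate) | is.na(fiber) | is.na(free_sugars)) ||
      any(carbohydrate < 0 | fiber < 0 | free_sugars < 0)) {
    stop("carbohydrate, fiber and free_sugars must be non-negative",
         call. = FALSE)
  }
  m10 <- fiber >= carbohydrate / 10
  m12 <- if (zero_fs_meets_1_2) {
    free_sugars == 0 | free_sugars < 2 * fiber
  } else {
    free_sugars < 2 * fiber
  }
  data.frame(meets_10_1 = m10, meets_1_2 = m12,
             meets_combined = m10 & m12)
}

#' Score a dataset against the 10:1|1:2 criterion
#'
#' Applies [meets_carb_ratio()] to every resolved product (one with a
#' non-missing \code{free_sugars}, normally from [assign_free_sugars()]).
#' Unresolved products are excluded and counted. Zero-carbohydrate products
#' are scored by the same formula by default (10:1 vacuously true, 1:2 true
#' iff free sugars are zero); set \code{exclude_zero_carb} to drop them
#' instead.
#'
#' @param products product data frame with \code{free_sugars} assigned.
#' @param exclude_zero_carb drop products with carbohydrate = 0 rather than
#'   scoring them. Default FALSE.
#' @param zero_fs_meets_1_2 passed to [meets_carb_ratio()].
#' @return list with \code{scored} (products plus the three verdict
#'   columns), \code{excluded} (unresolved or zero-carb rows), and
#'   \code{n_unresolved}.
#' @export
score_dataset <- function(products, exclude_zero_carb = FALSE,
                          zero_fs_meets_1_2 = TRUE) {
  if (!"free_sugars" %in% names(products)) {
    stop("products must carry a free_sugars column; ",
         "run assign_free_sugars() first", call. = FALSE)
  }
  unresolved <- is.na(products$free_sugars)
  drop <- unresolved
  if (exclude_zero_carb) drop <- drop | products$carbohydrate == 0
  scored <- products[!drop, , drop = FALSE]
  verdict <- meets_carb_ratio(scored$carbohydrate, scored$fiber,
                              scored$free_sugars,
                              zero_fs_meets_1_2 = zero_fs_meets_1_2)
  scored <- cbind(scored, verdict)
  rownames(scored) <- NULL
  list(scored = scored,
       excluded = products[drop, , drop = FALSE],
       n_unresolved = sum(unresolved))
}
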