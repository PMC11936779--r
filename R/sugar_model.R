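FEATURE_CONTRACT_VERSION <- "1"

#' Build the 26-element feature matrix
#'
#' Assembles the model's feature representation: 18 binary ingredient-tag
#' flags (six label positions x added / dairy / fruit-veg) followed by the
#' eight per-100 g panel nutrients. The declared added-sugar label never
#' enters the features, so there is no target leakage by construction.
#'
#' @param products cleaned canonical product data frame.
#' @param lexicon a [sugar_lexicon()]; must be the same lexicon version at
#'   train and predict time.
#' @param tags optional precomputed tag matrix from [tag_products()].
#' @return numeric matrix, one row per product, 26 named columns.
#' @export
build_features <- function(products, lexicon = sugar_lexicon(), tags = NULL) {
  if (is.null(tags)) tags <- tag_products(products, lexicon)
  nutr <- as.matrix(products[, NUTRIENT_COLS, drop = FALSE])
  if (any(is.na(nutr)) || any(!is.finite(nutr))) {
    stop("missing or non-finite nutrient values; run clean_products() first",
         call. = FALSE)
  }
  x <- cbind(tags, nutr)
  rownames(x) <- products$product_id
  x
}

#' Stratified train/validation/test split
#'
#' Splits labelled records into disjoint, exhaustive subsets, stratified by
#' presence of added sugars (declared value > 0) so each subset carries the
#' global prevalence. Reproducible under the seed.
#'
#' @param products data frame where every row has a non-missing
#'   \code{declared_added_sugars}.
#' @param fractions numeric length-3 vector (train, validation, test) summing
#'   to 1.
#' @param seed integer RNG seed.
#' @return list with elements \code{train}, \code{validation}, \code{test}.
#' @export
split_dataset <- function(products, fractions = c(0.8, 0.1, 0.1), seed) {
  stopifnot(length(fractions) == 3L, abs(sum(fractions) - 1) < 1e-8)
  if (any(is.na(products$declared_added_sugars))) {
    stop("all records must have declared_added_sugars to be split",
         call. = FALSE)
  }
  strata <- products$declared_added_sugars > 0
  if (length(unique(strata)) < 2L && nrow(products) > 0L) {
    # a single stratum is fine; an *empty* stratum only matters if both exist
  }
  n <- nrow(products)
  target <- largest_remainder(fractions * n)
  assign <- integer(n)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  for (s in unique(strata)) {
    idx <- sample(which(strata == s))
    k <- length(idx)
    sizes <- largest_remainder(fractions * k)
    assign[idx] <- rep(1:3, times = sizes)
  }
  # reconcile rounding drift between per-stratum and global targets
  for (grp in 1:3) {
    excess <- sum(assign == grp) - target[grp]
    while (excess > 0) {
      short <- which(tabulate(assign, 3) < target)[1]
      mv <- which(assign == grp)[1]
      assign[mv] <- short
      excess <- excess - 1
    }
  }
  out <- lapply(1:3, function(g) {
    d <- products[assign == g, , drop = FALSE]; rownames(d) <- NULL; d
  })
  names(out) <- c("train", "validation", "test")
  out
}

largest_remainder <- function(x) {
  fl <- floor(x)
  rem <- round(sum(x)) - sum(fl)
  if (rem > 0) {
    ord <- order(x - fl, decreasing = TRUE)
    fl[ord[seq_len(rem)]] <- fl[ord[seq_len(rem)]] + 1
  }
  as.integer(fl)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' Control parameters for [sugar_model()]
#'
#' @param num_trees_class trees per forest-type presence classifier.
#' @param xgb_nrounds_class boosting rounds for the boosted presence
#'   classifier.
#' @param num_trees_reg trees for the forest base regressor.
#' @param xgb_nrounds_reg boosting rounds for the boosted base regressor.
#' @param xgb_eta learning rate for the boosted models.
#' @param max_depth tree depth for the boosted models.
#' @param presence_cut declared amount (g/100 g) strictly above which a
#'   product counts as containing added sugars. Default 0.
#' @param threshold_grid candidate probability thresholds; the presence
#'   decision threshold is tuned on the validation set to maximize balanced
#'   accuracy of the majority vote.
#' @param combination how the three classifier decisions combine:
#'   \code{"majority"} (vote of thresholded probabilities) or
#'   \code{"mean_prob"} (threshold the mean probability).
#' @param min_positive minimum number of added-sugar-positive training
#'   records required to fit the quantity stack.
#' @return named list of settings.
#' @export
sugar_model_control <- function(num_trees_class = 300L,
                                xgb_nrounds_class = 150L,
                                num_trees_reg = 500L,
                                xgb_nrounds_reg = 300L,
                                xgb_eta = 0.1,
                                max_depth = 6L,
                                presence_cut = 0,
                                threshold_grid = seq(0.1, 0.9, by = 0.05),
                                combination = c("majority", "mean_prob"),
                                min_positive = 200L) {
  list(num_trees_class = num_trees_class,
       xgb_nrounds_class = xgb_nrounds_class,
       num_trees_reg = num_trees_reg,
       xgb_nrounds_reg = xgb_nrounds_reg,
       xgb_eta = xgb_eta, max_depth = max_depth,
       presence_cut = presence_cut,
       threshold_grid = threshold_grid,
       combination = match.arg(combination),
       min_positive = as.integer(min_positive))
}

#' Fit the gated two-stage added-sugar model
#'
#' Fits the package's core estimator on products declaring added sugars:
#' \enumerate{
#'   \item \strong{Presence stage} — three binary tree-based classifiers
#'     (random forest, bagged trees, gradient-boosted trees) predict whether
#'     a product contains added sugars; their thresholded decisions combine
#'     by majority vote, with the common threshold tuned on the validation
#'     set to maximize balanced accuracy.
#'   \item \strong{Quantity stage} — on added-sugar-positive records only,
#'     two base tree-ensemble regressors (random forest, gradient boosting)
#'     are stacked: their predictions on the held-out validation positives
#'     fit a linear meta-regressor, which combines them at predict time.
#' }
#' Predictions are gated (presence-negative products get exactly 0 g) and
#' clipped to \code{[0, total_sugars]}; see [predict.sugar_model()].
#'
#' @param train training products (each with \code{declared_added_sugars}).
#' @param validation validation products, disjoint from \code{train}; used
#'   for threshold tuning and meta-regressor stacking. If \code{NULL}, a
#'   stratified 85/15 split of \code{train} is taken internally.
#' @param lexicon a [sugar_lexicon()] used to tag ingredients.
#' @param control fitting settings, see [sugar_model_control()].
#' @param seed integer seed controlling every stochastic step; recorded in
#'   the fit's metadata.
#' @return an object of class \code{sugar_model}.
#' @seealso [predict.sugar_model()], [knn_baseline()], [evaluate()]
#' @export
sugar_model <- function(train, validation = NULL, lexicon = sugar_lexicon(),
                        control = sugar_model_control(), seed = 1L) {
  if (is.null(validation)) {
    sp <- split_dataset(train, c(0.85, 0.15, 0), seed = seed + 1000L)
    train <- sp$train
    validation <- sp$validation
  }
  x_tr <- build_features(train, lexicon)
  x_va <- build_features(validation, lexicon)
  y_tr <- train$declared_added_sugars
  y_va <- validation$declared_added_sugars
  if (any(is.na(y_tr)) || any(is.na(y_va))) {
    stop("training and validation records must declare added sugars",
         call. = FALSE)
  }
  pos_tr <- y_tr > control$presence_cut
  pos_va <- y_va > control$presence_cut
  if (sum(pos_tr) < control$min_positive) {
    stop("insufficient data: need at least ", control$min_positive,
         " added-sugar-positive training records, have ", sum(pos_tr),
         call. = FALSE)
  }

  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  p <- ncol(x_tr)

  # --- presence stage: three classifier families ---
  df_tr <- as.data.frame(x_tr)
  cls_rf <- ranger::ranger(x = df_tr, y = factor(pos_tr),
                           probability = TRUE,
                           num.trees = control$num_trees_class,
                           seed = seed + 1L, num.threads = 1L)
  cls_bag <- ranger::ranger(x = df_tr, y = factor(pos_tr),
                            probability = TRUE, mtry = p,
                            num.trees = control$num_trees_class,
                            seed = seed + 2L, num.threads = 1L)
  set.seed(seed + 3L)
  cls_gbt <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", eta = control$xgb_eta,
                  max_depth = control$max_depth, nthread = 1L,
                  seed = seed + 3L),
    data = xgboost::xgb.DMatrix(x_tr, label = as.numeric(pos_tr)),
    nrounds = control$xgb_nrounds_class, verbose = 0)

  probs_va <- classifier_probs(list(cls_rf, cls_bag, cls_gbt), x_va)
  threshold <- tune_threshold(probs_va, pos_va, control$threshold_grid,
                              control$combination)

  # --- quantity stage: stacked regressors on positives only ---
  xp_tr <- x_tr[pos_tr, , drop = FALSE]
  yp_tr <- y_tr[pos_tr]
  reg_rf <- ranger::ranger(x = as.data.frame(xp_tr), y = yp_tr,
                           num.trees = control$num_trees_reg,
                           seed = seed + 4L, num.threads = 1L)
  set.seed(seed + 5L)
  reg_gbt <- xgboost::xgb.train(
    params = list(objective = "reg:squarederror", eta = control$xgb_eta,
                  max_depth = control$max_depth, nthread = 1L,
                  seed = seed + 5L),
    data = xgboost::xgb.DMatrix(xp_tr, label = yp_tr),
    nrounds = control$xgb_nrounds_reg, verbose = 0)

  # meta-regressor fitted on held-out validation positives (classic stacking:
  # base-model predictions on data they were not trained on)
  if (sum(pos_va) >= 3L) {
    xp_va <- x_va[pos_va, , drop = FALSE]
    base_va <- cbind(
      rf  = predict(reg_rf, as.data.frame(xp_va),
                    num.threads = 1L)$predictions,
      gbt = predict(reg_gbt, xgboost::xgb.DMatrix(xp_va)))
    meta <- lm(y ~ rf + gbt,
               data = data.frame(y = y_va[pos_va], base_va))
    meta_coef <- coef(meta)
  } else {
    meta_coef <- c(`(Intercept)` = 0, rf = 0.5, gbt = 0.5)
  }
  meta_coef[is.na(meta_coef)] <- 0

  fit <- structure(list(
    presence_classifiers = list(rf = cls_rf, bagged = cls_bag, gbt = cls_gbt),
    threshold = threshold,
    combination = control$combination,
    base_regressors = list(rf = reg_rf, gbt = reg_gbt),
    meta_coef = meta_coef,
    feature_names = colnames(x_tr),
    contract_version = FEATURE_CONTRACT_VERSION,
    lexicon = lexicon,
    control = control,
    metadata = list(seed = seed,
                    n_train = nrow(train), n_validation = nrow(validation),
                    n_train_positive = sum(pos_tr),
                    fitted_at = format(Sys.time(), "%Y-%m-%d"))
  ), class = "sugar_model")

  # validation diagnostics (gated predictions on the full validation set)
  val_pred <- predict(fit, validation)
  fit$validation <- list(
    products = validation,
    prediction = val_pred,
    report = evaluate(y_va, val_pred$added_sugars_pred),
    presence_accuracy = mean((val_pred$has_added_sugar) == pos_va))
  fit
}

classifier_probs <- function(classifiers, x) {
  cbind(
    rf  = predict(classifiers[[1]], as.data.frame(x),
                  num.threads = 1L)$predictions[, "TRUE"],
    bag = predict(classifiers[[2]], as.data.frame(x),
                  num.threads = 1L)$predictions[, "TRUE"],
    gbt = predict(classifiers[[3]], xgboost::xgb.DMatrix(x)))
}

combine_presence <- function(probs, threshold, combination) {
  if (combination == "mean_prob") {
    rowMeans(probs) >= threshold
  } else {
    rowSums(probs >= threshold) >= 2L
  }
}

tune_threshold <- function(probs, truth, grid, combination) {
  balacc <- vapply(grid, function(th) {
    dec <- combine_presence(probs, th, combination)
    sens <- if (any(truth)) mean(dec[truth]) else NA_real_
    spec <- if (any(!truth)) mean(!dec[!truth]) else NA_real_
    mean(c(sens, spec), na.rm = TRUE)
  }, numeric(1))
  grid[which.max(balacc)]
}

#' Predict added sugars for new products
#'
#' Applies the gated two-stage model: the three presence classifiers vote;
#' presence-negative products receive exactly 0 g/100 g, presence-positive
#' products receive the stacked regression estimate clipped to
#' \code{[0, total_sugars]}.
#'
#' @param object a fitted [sugar_model()].
#' @param newdata canonical product data frame (ingredients are re-tagged
#'   with the model's own lexicon), or a prebuilt 26-column feature matrix —
#'   in which case \code{total_sugars} is taken from its nutrient block.
#' @param ... unused.
#' @return data frame with one row per product: \code{presence_probability}
#'   (mean classifier probability), \code{has_added_sugar},
#'   \code{added_sugars_pred} (g/100 g), and \code{clipped}.
#' @export
predict.sugar_model <- function(object, newdata, ...) {
  if (is.matrix(newdata)) {
    x <- newdata
  } else {
    x <- build_features(newdata, object$lexicon)
  }
  if (ncol(x) != length(object$feature_names) ||
      !identical(colnames(x), object$feature_names)) {
    stop("feature contract mismatch: expected ",
         length(object$feature_names), " columns (contract version ",
         object$contract_version, ")", call. = FALSE)
  }
  total_sugars <- x[, "total_sugars"]
  probs <- classifier_probs(object$presence_classifiers, x)
  present <- combine_presence(probs, object$threshold, object$combination)

  base <- cbind(
    rf  = predict(object$base_regressors$rf, as.data.frame(x),
                  num.threads = 1L)$predictions,
    gbt = predict(object$base_regressors$gbt, xgboost::xgb.DMatrix(x)))
  mc <- object$meta_coef
  raw <- mc[["(Intercept)"]] + base[, "rf"] * mc[["rf"]] +
    base[, "gbt"] * mc[["gbt"]]

  pred <- ifelse(present, pmin(pmax(raw, 0), total_sugars), 0)
  clipped <- present & (raw < 0 | raw > total_sugars)
  data.frame(presence_probability = rowMeans(probs),
             has_added_sugar = present,
             added_sugars_pred = pred,
             clipped = clipped,
             row.names = NULL)
}

#' @export
print.sugar_model <- function(x, ...) {
  cat("Gated two-stage added-sugar model\n")
  cat("  presence: 3 tree-based classifiers (",
      paste(names(x$presence_classifiers), collapse = ", "),
      "), ", x$combination, " @ threshold ", x$threshold, "\n", sep = "")
  cat("  quantity: stacked ", paste(names(x$base_regressors), collapse = " + "),
      " -> linear meta-regressor\n", sep = "")
  cat("  trained on ", x$metadata$n_train, " products (",
      x$metadata$n_train_positive, " with added sugars), seed ",
      x$metadata$seed, "\n", sep = "")
  if (!is.null(x$validation)) {
    r <- x$validation$report
    cat(sprintf("  validation: MAE %.3f g/100 g, R2 %.3f, presence accuracy %.3f\n",
                r$mae, r$r2, x$validation$presence_accuracy))
  }
  invisible(x)
}

#' @export
summary.sugar_model <- function(object, ...) {
  structure(list(fit = object), class = "summary.sugar_model")
}

#' @export
print.summary.sugar_model <- function(x, ...) {
  print(x$fit)
  cat("\nMeta-regressor coefficients:\n")
  print(x$fit$meta_coef)
  if (!is.null(x$fit$validation)) {
    cat("\nValidation residual summary (g/100 g):\n")
    print(x$fit$validation$report$residual_summary)
  }
  invisible(x)
}

#' @export
coef.sugar_model <- function(object, ...) object$meta_coef

#' @export
residuals.sugar_model <- function(object, ...) {
  if (is.null(object$validation)) {
    stop("no validation set stored with this fit", call. = FALSE)
  }
  object$validation$products$declared_added_sugars -
    object$validation$prediction$added_sugars_pred
}

#' @export
plot.sugar_model <- function(x, ...) {
  if (is.null(x$validation)) stop("no validation set stored", call. = FALSE)
  truth <- x$validation$products$declared_added_sugars
  pred <- x$validation$prediction$added_sugars_pred
  plot(truth, pred, xlab = "Declared added sugars (g/100 g)",
       ylab = "Predicted added sugars (g/100 g)",
       main = "Validation: predicted vs declared", pch = 16,
       col = grgb(0, 0, 0, 0.3), ...)
  abline(0, 1, col = "red3")
  invisible(x)
}

grgb <- function(r, g, b, a) grDevices::rgb(r, g, b, alpha = a)

#' Save / load a fitted sugar model
#'
#' Serializes the fitted bundle to a single file. Loading refuses bundles
#' written under a different feature-contract version; predictions from a
#' reloaded bundle are identical to the original's.
#'
#' @param object a fitted [sugar_model()].
#' @param path file path.
#' @return `write_sugar_model` returns \code{path} invisibly;
#'   `read_sugar_model` returns the fitted model.
#' @export
write_sugar_model <- function(object, path) {
  stopifnot(inherits(object, "sugar_model"))
  saveRDS(object, path)
  invisible(path)
}

#' @rdname write_sugar_model
#' @export
read_sugar_model <- function(path) {
  object <- readRDS(path)
  if (!inherits(object, "sugar_model") ||
      !identical(object$contract_version, FEATURE_CONTRACT_VERSION)) {
    stop("incompatible model bundle (feature contract version mismatch)",
         call. = FALSE)
  }
  object
}

#' k-nearest-neighbour baseline on panel nutrients
#'
#' The comparison baseline: predicts added sugars as the mean declared value
#' of the k nearest training products under Euclidean distance on the eight
#' panel nutrients, standardized by the training mean and standard deviation.
#' Uses no ingredient information — the gap between this and [sugar_model()]
#' measures what the ingredient tags contribute.
#'
#' @param train labelled training products.
#' @param query products (or nutrient matrix with the eight panel columns)
#'   to predict for.
#' @param k number of neighbours (1 <= k <= nrow(train)).
#' @return numeric vector of predictions, g/100 g.
#' @export
knn_baseline <- function(train, query, k = 5L) {
  if (k < 1L) stop("k must be at least 1", call. = FALSE)
  if (k > nrow(train)) {
    stop("k exceeds the number of training records", call. = FALSE)
  }
  xt <- as.matrix(train[, NUTRIENT_COLS, drop = FALSE])
  xq <- if (is.data.frame(query)) {
    as.matrix(query[, NUTRIENT_COLS, drop = FALSE])
  } else {
    as.matrix(query)[, NUTRIENT_COLS, drop = FALSE]
  }
  y <- train$declared_added_sugars
  mu <- colMeans(xt)
  sdv <- apply(xt, 2L, sd)
  sdv[sdv == 0 | is.na(sdv)] <- 1
  zt <- sweep(sweep(xt, 2L, mu), 2L, sdv, "/")
  zq <- sweep(sweep(xq, 2L, mu), 2L, sdv, "/")
  # squared Euclidean distances, query x train
  d2 <- outer(rowSums(zq^2), rowSums(zt^2), "+") - 2 * tcrossprod(zq, zt)
  unname(apply(d2, 1L, function(row) mean(y[order(row)[seq_len(k)]])))
}

#' Prediction-error report
#'
#' Computes the standard regression metrics used to judge added-sugar
#' predictions: MAE (mean absolute error, g/100 g), MAPE (mean absolute
#' percentage error, computed only over truths > 0), and R-squared
#' (\eqn{1 - SS_{res}/SS_{tot}}; reported as NA when all truths are equal),
#' with optional per-group breakdowns.
#'
#' @param truth numeric vector of true values.
#' @param prediction numeric vector of predictions, same length.
#' @param groups optional grouping labels (e.g. category) for a per-group
#'   breakdown.
#' @return object of class \code{sugar_eval}: list with \code{mae},
#'   \code{mape} (percent), \code{r2}, \code{n}, \code{residual_summary},
#'   and \code{by_group} (data frame or NULL).
#' @examples
#' evaluate(c(10, 20, 0), c(12, 18, 1))
#' @export
evaluate <- function(truth, prediction, groups = NULL) {
  stopifnot(length(truth) == length(prediction), length(truth) > 0L)
  res <- truth - prediction
  mae <- mean(abs(res))
  posi <- truth > 0
  mape <- if (any(posi)) {
    100 * mean(abs(res[posi]) / truth[posi])
  } else NA_real_
  sstot <- sum((truth - mean(truth))^2)
  r2 <- if (sstot > 0) 1 - sum(res^2) / sstot else NA_real_
  by_group <- NULL
  if (!is.null(groups)) {
    by_group <- do.call(rbind, lapply(split(seq_along(truth), groups),
      function(idx) {
        g <- evaluate(truth[idx], prediction[idx])
        data.frame(group = groups[idx[1]], n = g$n, mae = g$mae,
                   mape = g$mape, r2 = g$r2, stringsAsFactors = FALSE)
      }))
    rownames(by_group) <- NULL
  }
  structure(list(mae = mae, mape = mape, r2 = r2, n = length(truth),
                 residual_summary = quantile(res, c(0, .25, .5, .75, 1)),
                 by_group = by_group),
            class = "sugar_eval")
}

#' @export
print.sugar_eval <- function(x, ...) {
  cat(sprintf("n = %d  MAE = %.3f g/100 g  MAPE = %s  R2 = %s\n",
              x$n, x$mae,
              if (is.na(x$mape)) "NA" else sprintf("%.1f%%", x$mape),
              if (is.na(x$r2)) "NA" else sprintf("%.3f", x$r2)))
  if (!is.null(x$by_group)) {
    cat("\nPer-group:\n")
    print(x$by_group, digits = 3)
  }
  invisible(x)
}
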