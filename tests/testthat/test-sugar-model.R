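lex <- sugar_lexicon()

test_that("build_features assembles the 26-vector with no label leakage", {
  p <- make_product("A", ingredient_text = "milk, sugar, strawberry",
                    declared_added_sugars = 4)
  x <- build_features(p, lex)
  expect_equal(dim(x), c(1L, 26L))
  expect_equal(rownames(x), "A")
  # hand-assembled expectation: pos1 dairy, pos2 added, pos3 fruit, rest 0
  expected_tags <- setNames(rep(0, 18),
                            paste0("pos", rep(1:6, each = 3), "_",
                                   c("added", "dairy", "fruit_veg")))
  expected_tags[c("pos1_dairy", "pos2_added", "pos3_fruit_veg")] <- 1
  expect_equal(x[1, 1:18], expected_tags)
  expect_equal(unname(x[1, 19:26]),
               unname(unlist(p[1, c("energy", "total_fat", "saturated_fat",
                                    "carbohydrate", "fiber", "total_sugars",
                                    "protein", "sodium")])))
  expect_false("declared_added_sugars" %in% colnames(x))
})

test_that("ingredients beyond position six do not change the features", {
  base <- make_product("A", ingredient_text =
    "water, flour, salt, yeast, oil, oats, sugar, honey, raisins")
  perm <- make_product("A", ingredient_text =
    "water, flour, salt, yeast, oil, oats, raisins, sugar, honey")
  expect_equal(build_features(base, lex), build_features(perm, lex))
})

test_that("build_features refuses records with missing nutrients", {
  p <- make_product("A")
  p$fiber <- NA_real_
  expect_error(build_features(p, lex), "missing")
})

test_that("split_dataset is exact, disjoint, stratified, and reproducible", {
  sim <- generate_products(gen_config(100L, seed = 5L))
  sp <- split_dataset(sim$products, c(0.8, 0.1, 0.1), seed = 7L)
  expect_equal(vapply(sp, nrow, integer(1)),
               c(train = 80L, validation = 10L, test = 10L))
  ids <- unname(unlist(lapply(sp, `[[`, "product_id")))
  expect_equal(sort(ids), sort(sim$products$product_id))
  sp2 <- split_dataset(sim$products, c(0.8, 0.1, 0.1), seed = 7L)
  expect_equal(sp, sp2)
  sim2 <- generate_products(gen_config(5000L, seed = 8L))
  sp3 <- split_dataset(sim2$products, c(0.8, 0.1, 0.1), seed = 9L)
  prev <- function(d) 100 * mean(d$declared_added_sugars > 0)
  global <- prev(sim2$products)
  for (part in sp3) expect_lt(abs(prev(part) - global), 2)
})

test_that("split_dataset requires labels", {
  p <- make_products(make_product("A"), make_product("B"))
  expect_error(split_dataset(p, seed = 1), "declared_added_sugars")
})

test_that("knn baseline agrees with brute-force neighbour enumeration", {
  train <- make_products(
    make_product("A", carbohydrate = 10, total_sugars = 2, fiber = 1,
                 declared_added_sugars = 1),
    make_product("B", carbohydrate = 50, total_sugars = 25, fiber = 2,
                 declared_added_sugars = 20),
    make_product("C", carbohydrate = 55, total_sugars = 30, fiber = 3,
                 declared_added_sugars = 28))
  # k = 1 at a training point returns that point's label
  expect_equal(knn_baseline(train, train[2, ], k = 1), 20)
  # k = n returns the global mean
  expect_equal(knn_baseline(train, train[1, ], k = 3), mean(c(1, 20, 28)))
  # k = 2: brute-force standardized distances
  nut <- c("energy", "total_fat", "saturated_fat", "carbohydrate", "fiber",
           "total_sugars", "protein", "sodium")
  xt <- as.matrix(train[, nut])
  z <- scale(xt, center = colMeans(xt), scale = apply(xt, 2, sd))
  z[is.nan(z)] <- 0
  query <- make_product("Q", carbohydrate = 48, total_sugars = 22,
                        fiber = 2)
  zq <- (unlist(query[, nut]) - colMeans(xt)) / apply(xt, 2, sd)
  zq[!is.finite(zq)] <- 0
  d <- sqrt(colSums((t(z) - zq)^2))
  expected <- mean(train$declared_added_sugars[order(d)[1:2]])
  expect_equal(knn_baseline(train, query, k = 2), expected)
  expect_error(knn_baseline(train, query, k = 4), "exceeds")
  expect_error(knn_baseline(train, query, k = 0), "at least 1")
})

test_that("evaluate computes MAE, MAPE over positive truths, and R2", {
  expect_equal(evaluate(c(1, 0), c(3, 0))$mae, 1)
  ident <- evaluate(c(3, 7, 1), c(3, 7, 1))
  expect_equal(ident$mae, 0)
  expect_equal(ident$r2, 1)
  r <- evaluate(c(10, 20, 0), c(12, 18, 1), groups = c("a", "a", "b"))
  expect_equal(r$mae, 5 / 3)
  expect_equal(r$mape, 15)  # mean(20%, 10%) over positive truths
  expect_equal(nrow(r$by_group), 2L)
  expect_true(is.na(evaluate(c(2, 2), c(1, 3))$r2))
  expect_true(is.na(evaluate(c(0, 0), c(1, 3))$mape))
})

test_that("the fitted model gates, clips, serializes, and is deterministic", {
  sim <- generate_products(gen_config(1200L, seed = 21L))
  sp <- split_dataset(sim$products, c(0.75, 0.25, 0), seed = 21L)
  fit <- sugar_model(sp$train, sp$validation, lexicon = lex,
                     control = small_control(), seed = 21L)
  expect_s3_class(fit, "sugar_model")
  expect_equal(fit$metadata$seed, 21L)

  pred <- predict(fit, sp$validation)
  # gating: presence-negative products get exactly 0
  expect_true(all(pred$added_sugars_pred[!pred$has_added_sugar] == 0))
  # range: never negative, never above total sugars
  expect_true(all(pred$added_sugars_pred >= 0))
  expect_true(all(pred$added_sugars_pred <=
                    sp$validation$total_sugars + 1e-9))
  expect_true(all(pred$presence_probability >= 0 &
                    pred$presence_probability <= 1))

  # determinism: same data, config, seed -> identical fit and predictions
  fit2 <- sugar_model(sp$train, sp$validation, lexicon = lex,
                      control = small_control(), seed = 21L)
  expect_equal(fit2$validation$report$mae, fit$validation$report$mae)
  expect_equal(predict(fit2, sp$validation), pred)

  # serialization round-trip reproduces predictions exactly
  path <- withr::local_tempfile(fileext = ".rds")
  write_sugar_model(fit, path)
  reloaded <- read_sugar_model(path)
  expect_equal(predict(reloaded, sp$validation), pred)

  # label non-leakage: shuffling labels at predict time changes nothing
  shuffled <- sp$validation
  shuffled$declared_added_sugars <-
    sample(shuffled$declared_added_sugars)
  expect_equal(predict(fit, shuffled), pred)

  # feature-contract errors
  x <- build_features(sp$validation, lex)
  expect_error(predict(fit, x[, 1:20]), "feature contract")

  # standard S3 surface
  expect_output(print(fit), "Gated two-stage")
  expect_output(print(summary(fit)), "Meta-regressor")
  expect_named(coef(fit), c("(Intercept)", "rf", "gbt"))
  expect_length(residuals(fit), nrow(fit$validation$products))
})

test_that("clipping to total sugars is flagged", {
  # force clipping through the exported surface: a product whose nutrient
  # panel promises much added sugar but whose total_sugars is tiny
  sim <- generate_products(gen_config(1200L, seed = 22L))
  sp <- split_dataset(sim$products, c(0.75, 0.25, 0), seed = 22L)
  fit <- sugar_model(sp$train, sp$validation, lexicon = lex,
                     control = small_control(), seed = 22L)
  sweet <- sp$validation[which(
    sp$validation$declared_added_sugars > 10)[1], ]
  squeezed <- sweet
  squeezed$total_sugars <- 0.4
  squeezed$carbohydrate <- sweet$carbohydrate
  p <- predict(fit, squeezed)
  if (p$has_added_sugar) {
    expect_lte(p$added_sugars_pred, 0.4)
    expect_true(p$clipped)
  }
  expect_error(
    sugar_model(sp$train[1:60, ], sp$validation, lexicon = lex,
                control = small_control(), seed = 1L),
    "insufficient data")
})
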