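# Ingredient term pools used by the generator. Terms deliberately match the
# shipped lexicon (dairy/fruit terms) or deliberately avoid it (fillers), so
# position-based tagging carries real signal. sugar_frac is the sugar mass
# fraction credited per gram of the ingredient.
generator_terms <- function() {
  list(
    added = data.frame(
      term = c("sugar", "cane sugar", "brown sugar", "glucose syrup",
               "high fructose corn syrup", "invert sugar", "dextrose",
               "honey", "molasses", "fruit juice concentrate"),
      sugar_frac = c(1, 1, 1, 1, 1, 1, 1, 0.8, 0.75, 0.65),
      stringsAsFactors = FALSE),
    dairy = data.frame(
      term = c("milk", "skimmed milk powder", "whole milk powder",
               "whey powder", "cream", "yogurt", "buttermilk"),
      sugar_frac = c(0.05, 0.5, 0.38, 0.7, 0.03, 0.04, 0.04),
      stringsAsFactors = FALSE),
    fruit = data.frame(
      term = c("apple puree", "strawberries", "raisins", "dates", "banana",
               "orange", "tomato paste", "carrot", "apple", "mango"),
      sugar_frac = c(0.11, 0.05, 0.6, 0.63, 0.12, 0.09, 0.2, 0.05, 0.11,
                     0.14),
      stringsAsFactors = FALSE),
    filler = c("water", "wheat flour", "whole wheat flour", "rice flour",
               "corn starch", "vegetable oil", "palm oil", "salt", "yeast",
               "baking powder", "soy lecithin", "natural flavouring",
               "citric acid", "oats", "cocoa powder", "peanuts", "almonds",
               "egg", "modified starch", "pea protein", "xanthan gum",
               "sunflower oil", "maize", "potato starch", "spices"))
}

# Category vocabulary with generation parameters. add_lo/add_hi bound the
# label position of added-sugar ingredients (earlier position = more mass,
# by the descending-quantity label convention); solids scales ingredient
# mass for beverages; starch/fat/protein ranges shape the rest of the panel.
default_category_table <- function() {
  tb <- function(category, sub_category, weight, added_prev, add_lo, add_hi,
                 dairy_p, fruit_p, fiber_mean, starch_lo, starch_hi,
                 fat_lo, fat_hi, prot_lo, prot_hi, solids, beverage) {
    data.frame(category = category, sub_category = sub_category,
               weight = weight, added_prev = added_prev,
               add_lo = add_lo, add_hi = add_hi, dairy_p = dairy_p,
               fruit_p = fruit_p, fiber_mean = fiber_mean,
               starch_lo = starch_lo, starch_hi = starch_hi,
               fat_lo = fat_lo, fat_hi = fat_hi,
               prot_lo = prot_lo, prot_hi = prot_hi,
               solids = solids, beverage = beverage,
               stringsAsFactors = FALSE)
  }
  rbind(
    tb("Bread & Bread Products", "Bread", 0.11, 0.55, 4, 6, 0.10, 0.05,
       3.5, 30, 48, 1, 6, 7, 12, 1, FALSE),
    tb("Cold Cereals", "Breakfast Cereal", 0.10, 0.80, 2, 4, 0.05, 0.25,
       7.0, 35, 55, 1, 8, 6, 12, 1, FALSE),
    tb("Hot Cereals", "Oatmeal", 0.06, 0.50, 3, 5, 0.10, 0.30,
       9.0, 40, 55, 2, 8, 8, 14, 1, FALSE),
    tb("Sweet Biscuits/Cookies", "Cookies", 0.11, 0.95, 1, 3, 0.25, 0.10,
       2.5, 25, 45, 12, 26, 4, 8, 1, FALSE),
    tb("Snack/Cereal/Energy Bars", "Cereal Bars", 0.09, 0.90, 2, 4,
       0.15, 0.50, 6.5, 15, 35, 5, 18, 6, 14, 1, FALSE),
    tb("Flavoured Milk", "Flavoured Milk", 0.05, 0.85, 2, 3, 1.00, 0.05,
       0.3, 0, 3, 1, 3.5, 3, 4, 0.3, TRUE),
    tb("Juice", "Fruit Juice", 0.05, 0.15, 4, 6, 0.00, 1.00,
       0.3, 0, 2, 0, 0.5, 0, 1, 0.35, TRUE),
    tb("Soup", "Wet Soup", 0.07, 0.30, 4, 6, 0.10, 0.35,
       1.2, 3, 9, 0.5, 4, 1, 4, 1, FALSE),
    tb("Spoonable Yogurt", "Spoonable Yogurt", 0.07, 0.70, 2, 3, 1.00, 0.30,
       0.4, 0, 6, 1, 8, 3, 6, 0.6, FALSE),
    tb("Fruit Snacks", "Dried Fruit", 0.06, 0.60, 2, 4, 0.00, 1.00,
       5.5, 5, 25, 0.5, 5, 2, 5, 1, FALSE),
    # override categories / sub-categories
    tb("Juice Drinks", "Juice Drinks", 0.05, 0.90, 2, 2, 0.00, 0.80,
       0.1, 0, 1, 0, 0.5, 0, 0.5, 0.4, TRUE),
    tb("Carbonated Soft Drinks", "Cola", 0.06, 0.90, 2, 2, 0.00, 0.05,
       0.0, 0, 0.5, 0, 0.2, 0, 0.3, 0.4, TRUE),
    tb("Sweeteners & Sugar", "Table Sugar", 0.02, 1.00, 1, 1, 0.00, 0.00,
       0.0, 0, 1, 0, 0.2, 0, 0.3, 1, FALSE),
    tb("Sweeteners & Sugar", "Honey", 0.01, 1.00, 1, 1, 0.00, 0.00,
       0.0, 0, 1, 0, 0.2, 0, 0.3, 0.8, FALSE),
    tb("Sweeteners & Sugar", "Syrups", 0.01, 1.00, 1, 1, 0.00, 0.00,
       0.0, 0, 2, 0, 0.2, 0, 0.3, 0.7, FALSE),
    tb("Sugar & Gum Confectionery", "Candy", 0.05, 0.97, 1, 2, 0.05, 0.15,
       0.2, 5, 25, 0, 8, 0, 3, 1, FALSE),
    tb("Water", "Flavoured Water", 0.01, 0.50, 2, 2, 0.00, 0.20,
       0.0, 0, 0.3, 0, 0.1, 0, 0.2, 0.15, TRUE),
    tb("RTDs", "Ready To Drink (Iced) Tea", 0.01, 0.80, 2, 2, 0.00, 0.10,
       0.0, 0, 0.3, 0, 0.1, 0, 0.2, 0.3, TRUE),
    tb("Desserts & Ice Cream", "Water Based Ice Lollies, Pops & Sorbets",
       0.01, 0.90, 2, 2, 0.00, 0.40, 0.2, 0, 3, 0, 2, 0, 1, 0.6, FALSE))
}

default_markets <- function() {
  list(
    list(name = "US", weight = 1, years = 2014:2024, declared = TRUE,
         claim_prevalence = 0.30))
}

#' Configuration for the synthetic label generator
#'
#' Bundles everything [generate_products()] needs: the category vocabulary
#' (with per-category added-sugar prevalence, ingredient-position ranges and
#' panel parameters — the defaults cover every override category and
#' sub-category plus staple categories), the market strata (year window,
#' whether added sugars are declared, claim prevalence), the position-decay
#' factor mapping ingredient rank to quantity share, the measurement noise
#' on declared values, and the fraction of records deliberately corrupted
#' with a named panel-invariant violation (for testing the cleaning step).
#'
#' @param n_products number of records to generate.
#' @param seed integer seed; identical configs generate identical data.
#' @param categories category parameter table (see
#'   \code{carbquality:::default_category_table} for the expected columns).
#' @param markets list of market strata, each a list with \code{name},
#'   \code{weight}, \code{years}, \code{declared}, \code{claim_prevalence}.
#' @param position_decay factor in (0, 1): ingredient at label position i
#'   carries quantity share proportional to \code{position_decay^(i-1)}.
#' @param noise_sd truncated-normal noise (g/100 g) added to declared values.
#' @param corruption_rate fraction of records given one named invariant
#'   violation (flagged in the truth sidecar).
#' @return object of class \code{gen_config}.
#' @export
gen_config <- function(n_products, seed = 1L,
                       categories = default_category_table(),
                       markets = default_markets(),
                       position_decay = 0.55,
                       noise_sd = 0.5,
                       corruption_rate = 0) {
  stopifnot(position_decay > 0, position_decay < 1,
            noise_sd >= 0, corruption_rate >= 0, corruption_rate <= 1,
            all(categories$weight >= 0), sum(categories$weight) > 0,
            all(categories$added_prev >= 0 & categories$added_prev <= 1))
  structure(list(n_products = as.integer(n_products), seed = as.integer(seed),
                 categories = categories, markets = markets,
                 position_decay = position_decay, noise_sd = noise_sd,
                 corruption_rate = corruption_rate),
            class = "gen_config")
}

#' Expected added-sugar prevalence under a generator config
#'
#' The category-weighted mean of per-category added-sugar prevalences — the
#' population prevalence the generated data is drawn from.
#'
#' @param config a [gen_config()].
#' @return numeric scalar in [0, 1].
#' @export
expected_prevalence <- function(config) {
  w <- config$categories$weight / sum(config$categories$weight)
  sum(w * config$categories$added_prev)
}

#' Generate synthetic packaged-food product records with known ground truth
#'
#' Simulates label-realistic product records: an ordered ingredient list
#' drawn from sugar/dairy/fruit/filler term pools with quantity shares
#' decaying by label position, an internally consistent nutrition panel
#' (sugars within carbohydrate, Atwater 4/9/4 energy with no fiber energy),
#' category-dependent added-sugar prevalence, market/year strata, and
#' optional corrupted records violating one named panel invariant. The true
#' added- and free-sugar values are returned in a separate truth sidecar,
#' keyed by product id, and never appear in the visible record — declared
#' values are the truth plus truncated-normal noise, present only in markets
#' configured as declaring.
#'
#' @param config a [gen_config()].
#' @return list with \code{products} (canonical data frame accepted by
#'   every other function in the package) and \code{truth} (data frame:
#'   \code{product_id}, \code{true_added_sugars}, \code{true_free_sugars},
#'   \code{corrupted}, \code{corruption_reason}).
#' @export
generate_products <- function(config) {
  stopifnot(inherits(config, "gen_config"))
  n <- config$n_products
  terms <- generator_terms()
  cats <- config$categories
  cat_w <- cats$weight / sum(cats$weight)
  mk_w <- vapply(config$markets, `[[`, numeric(1), "weight")
  mk_w <- mk_w / sum(mk_w)
  ovr <- override_rules()
  decay <- config$position_decay

  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(config$seed)

  empty <- function(cols) {
    df <- as.data.frame(setNames(rep(list(character(0)), length(cols)),
                                 cols), stringsAsFactors = FALSE)
    df
  }
  if (n == 0L) {
    return(list(products = empty(canonical_cols()),
                truth = empty(c("product_id", "true_added_sugars",
                                "true_free_sugars", "corrupted",
                                "corruption_reason"))))
  }
  rows <- vector("list", n)
  truths <- vector("list", n)
  for (i in seq_len(n)) {
    ci <- cats[sample.int(nrow(cats), 1L, prob = cat_w), ]
    mk <- config$markets[[sample.int(length(config$markets), 1L,
                                     prob = mk_w)]]
    year <- sample(mk$years, 1L)

    n_ing <- sample(4:9, 1L)
    slot <- rep(NA_character_, n_ing)
    frac <- rep(0, n_ing)
    kind <- rep("filler", n_ing)
    if (ci$beverage) slot[1] <- "water"

    has_added <- runif(1) < ci$added_prev
    if (has_added) {
      lo <- min(ci$add_lo, n_ing)
      hi <- min(ci$add_hi, 6L, n_ing)
      allowed <- setdiff(seq(min(lo, hi), hi), which(!is.na(slot)))
      if (!length(allowed)) allowed <- which(is.na(slot))[1]
      n_add <- min(1L + (runif(1) < 0.25), length(allowed))
      pos <- if (length(allowed) == 1L) allowed else
        sample(allowed, n_add)
      pick <- terms$added[sample.int(nrow(terms$added), length(pos)), ]
      slot[pos] <- pick$term
      frac[pos] <- pick$sugar_frac
      kind[pos] <- "added"
    }
    if (runif(1) < ci$dairy_p) {
      free <- which(is.na(slot))
      if (length(free)) {
        pos <- if (length(free) == 1L) free else sample(free, 1L)
        pick <- terms$dairy[sample.int(nrow(terms$dairy), 1L), ]
        slot[pos] <- pick$term
        frac[pos] <- pick$sugar_frac
        kind[pos] <- "natural"
      }
    }
    if (runif(1) < ci$fruit_p) {
      free <- which(is.na(slot))
      if (length(free)) {
        k <- min(1L + (runif(1) < 0.3), length(free))
        pos <- if (length(free) == 1L) free else sample(free, k)
        pick <- terms$fruit[sample.int(nrow(terms$fruit), length(pos)), ]
        slot[pos] <- pick$term
        frac[pos] <- pick$sugar_frac
        kind[pos] <- "natural"
      }
    }
    free <- which(is.na(slot))
    pool <- setdiff(terms$filler, slot)
    slot[free] <- sample(pool, length(free))

    q <- decay^(seq_len(n_ing) - 1L)
    q <- q / sum(q)
    mass <- 100 * ci$solids * q
    true_added <- round(sum(mass[kind == "added"] * frac[kind == "added"]), 2)
    natural <- round(sum(mass[kind == "natural"] * frac[kind == "natural"]), 2)
    total_sugars <- true_added + natural

    fiber <- round(min(rgamma(1L, shape = 2, scale = ci$fiber_mean / 2), 15),
                   1)
    if (ci$fiber_mean == 0) fiber <- 0
    starch <- runif(1L, ci$starch_lo, ci$starch_hi)
    if (total_sugars + fiber + starch > 85) {
      starch <- max(0, 85 - total_sugars - fiber)
    }
    carbohydrate <- round(total_sugars + fiber + starch, 2)
    fat <- round(runif(1L, ci$fat_lo, ci$fat_hi), 1)
    protein <- round(runif(1L, ci$prot_lo, ci$prot_hi), 1)
    if (fat + carbohydrate + protein > 100) {
      fat <- round(max(0, 100 - carbohydrate - protein), 1)
    }
    saturated <- round(fat * runif(1L, 0.2, 0.6), 2)
    # panel energy is Atwater-exact so the cleaning check holds by
    # construction even for near-zero panels
    energy <- 4 * carbohydrate + 9 * fat + 4 * protein
    sodium <- round(rlnorm(1L, meanlog = if (ci$beverage) 3 else 5.2,
                           sdlog = 0.5))

    text_terms <- slot
    if (runif(1) < 0.15) {
      text_terms[1] <- paste0(text_terms[1], " (",
                              round(100 * q[1]), "%)")
    }
    if (runif(1) < 0.10) {
      j <- sample(n_ing, 1L)
      text_terms[j] <- paste("organic", text_terms[j])
    }
    ingredient_text <- paste(text_terms, collapse = ", ")

    declared <- NA_real_
    if (isTRUE(mk$declared)) {
      declared <- true_added + rnorm(1L, 0, config$noise_sd)
      declared <- min(max(declared, 0), total_sugars)
    }

    claims <- ""
    if (runif(1) < mk$claim_prevalence) {
      claims <- paste(sample(carb_quality_claims(),
                             1L + (runif(1) < 0.3)), collapse = "|")
    } else if (runif(1) < 0.2) {
      claims <- sample(c("Gluten Free", "Vegan", "Kosher"), 1L)
    }

    corrupted <- runif(1) < config$corruption_rate
    reason <- NA_character_
    if (corrupted) {
      reason <- sample(c("sugars exceed carbohydrate",
                         "saturated fat exceeds total fat",
                         "energy inconsistent with macronutrients",
                         "negative or non-finite nutrient",
                         "no parseable ingredient"), 1L)
      switch(reason,
        "sugars exceed carbohydrate" = {
          total_sugars <- carbohydrate + 5
        },
        "saturated fat exceeds total fat" = {
          saturated <- fat + 2
        },
        "energy inconsistent with macronutrients" = {
          energy <- energy * 2 + 50
        },
        "negative or non-finite nutrient" = {
          fiber <- -1
        },
        "no parseable ingredient" = {
          ingredient_text <- ""
        })
    }

    in_override <- norm_label(ci$category) %in% norm_label(ovr$categories) ||
      norm_label(ci$sub_category) %in% norm_label(ovr$subcategories)
    true_free <- if (in_override) total_sugars else true_added

    rows[[i]] <- data.frame(
      product_id = sprintf("P%06d", i), market = mk$name,
      category = ci$category, sub_category = ci$sub_category,
      launch_year = year,
      serving_size_g = sample(c(30, 40, 50, 100, 250), 1L),
      ingredient_text = ingredient_text,
      energy = energy, total_fat = fat, saturated_fat = saturated,
      carbohydrate = carbohydrate, fiber = fiber,
      total_sugars = total_sugars, protein = protein, sodium = sodium,
      declared_added_sugars = declared, claims = claims,
      stringsAsFactors = FALSE)
    truths[[i]] <- data.frame(
      product_id = sprintf("P%06d", i),
      true_added_sugars = true_added, true_free_sugars = true_free,
      corrupted = corrupted, corruption_reason = reason,
      stringsAsFactors = FALSE)
  }
  products <- do.call(rbind, rows)[, canonical_cols()]
  truth <- do.call(rbind, truths)
  list(products = products, truth = truth)
}

#' Write a ground-truth sidecar file
#'
#' Writes the generator's truth table as JSON-lines keyed by product id,
#' keeping ground truth out of the feature-visible record files.
#'
#' @param truth truth data frame from [generate_products()].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_truth_sidecar <- function(truth, path) {
  con <- file(path, open = "w")
  on.exit(close(con))
  jsonlite::stream_out(truth, con, verbose = FALSE, digits = NA)
  invisible(path)
}

#' Fixed-recipe synthetic benchmark
#'
#' Generates the standard evaluation setup mirroring a
#' train-on-one-declared-market, test-elsewhere protocol: 5,000 training and
#' 1,000 validation products from a single "US-like" market where added
#' sugars are declared, and 1,000 test products from three other markets
#' where they are not (the test truth lives in the sidecar). Declared noise
#' is 0.5 g/100 g; no corrupted records.
#'
#' @param seed integer seed.
#' @return list with \code{train}, \code{validation}, \code{test} (product
#'   data frames), \code{truth} (sidecar for all three), and \code{config}
#'   (the generating [gen_config()] of the training market).
#' @export
make_benchmark <- function(seed = 42L) {
  cfg_us <- gen_config(6000L, seed = seed,
                       noise_sd = 0.5, corruption_rate = 0)
  us <- generate_products(cfg_us)
  sp <- split_dataset(us$products, c(5000 / 6000, 1000 / 6000, 0),
                      seed = seed + 1L)
  other_markets <- list(
    list(name = "Brazil", weight = 1, years = 2014:2024, declared = FALSE,
         claim_prevalence = 0.19),
    list(name = "France", weight = 1, years = 2014:2024, declared = FALSE,
         claim_prevalence = 0.15),
    list(name = "Malaysia", weight = 1, years = 2014:2024, declared = FALSE,
         claim_prevalence = 0.15))
  cfg_other <- gen_config(1000L, seed = seed + 2L, markets = other_markets,
                          noise_sd = 0.5, corruption_rate = 0)
  other <- generate_products(cfg_other)
  # test ids share the P-prefix space; disambiguate by market suffix
  other$products$product_id <- paste0(other$products$product_id, "-X")
  other$truth$product_id <- paste0(other$truth$product_id, "-X")
  list(train = sp$train, validation = sp$validation,
       test = other$products,
       truth = rbind(us$truth, other$truth),
       config = cfg_us)
}
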