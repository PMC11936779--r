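# Hand-buildable product records with internally consistent panels.
make_product <- function(product_id = "P1", market = "US",
                         category = "Bread & Bread Products",
                         sub_category = "Bread", launch_year = 2020,
                         serving_size_g = 50,
                         ingredient_text = "wheat flour, water, sugar, salt",
                         total_fat = 3, saturated_fat = 1, carbohydrate = 50,
                         fiber = 3, total_sugars = 5, protein = 9,
                         sodium = 400,
                         energy = 4 * carbohydrate + 9 * total_fat +
                           4 * protein,
                         declared_added_sugars = NA_real_, claims = "") {
  data.frame(product_id = product_id, market = market, category = category,
             sub_category = sub_category, launch_year = launch_year,
             serving_size_g = serving_size_g,
             ingredient_text = ingredient_text, energy = energy,
             total_fat = total_fat, saturated_fat = saturated_fat,
             carbohydrate = carbohydrate, fiber = fiber,
             total_sugars = total_sugars, protein = protein, sodium = sodium,
             declared_added_sugars = declared_added_sugars, claims = claims,
             stringsAsFactors = FALSE)
}

make_products <- function(...) do.call(rbind, list(...))

# fast settings for fitting in unit tests
small_control <- function() {
  sugar_model_control(num_trees_class = 100L, xgb_nrounds_class = 60L,
                      num_trees_reg = 150L, xgb_nrounds_reg = 100L,
                      min_positive = 50L)
}
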