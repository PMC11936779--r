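scored_fixture <- function(n = 200, seed = 17L) {
  sim <- generate_products(gen_config(n, seed = seed))
  prods <- assign_free_sugars(sim$products)
  score_dataset(prods[!is.na(prods$free_sugars), ])$scored
}

test_that("summarize_groups reports n, mean±SD and the three percentages", {
  prods <- make_products(
    make_product("A", market = "US", carbohydrate = 40, fiber = 5),
    make_product("B", market = "US", carbohydrate = 30, fiber = 0.5),
    make_product("C", market = "BR", carbohydrate = 50, fiber = 6))
  prods$free_sugars <- c(2, 10, 3)
  sc <- score_dataset(prods)$scored
  g <- summarize_groups(sc, by = "market")
  us <- g[g$market == "US", ]
  expect_equal(us$n, 2L)
  expect_equal(us$pct_meeting_combined, 50)
  expect_equal(us$carbohydrate_mean, 35)
  expect_equal(us$carbohydrate_sd, sd(c(40, 30)))
  # single-product group: SD is missing, not zero
  br <- g[g$market == "BR", ]
  expect_true(is.na(br$carbohydrate_sd))
  expect_equal(br$n, 1L)
})

test_that("group sums conserve the global totals and combined <= components", {
  sc <- scored_fixture(500, seed = 19L)
  g <- summarize_groups(sc, by = c("market", "category"))
  expect_equal(sum(g$n), nrow(sc))
  expect_equal(sum(g$n * g$pct_meeting_combined / 100),
               sum(sc$meets_combined))
  expect_true(all(g$pct_meeting_combined <=
                    pmin(g$pct_meeting_10_1, g$pct_meeting_1_2) + 1e-9))
})

test_that("the pooled z-test matches its closed form and prop.test", {
  r <- proportion_ztest(5, 100, 5, 100)
  expect_equal(r$p_value, 1)
  expect_equal(r$z, 0)
  # symmetry
  a <- proportion_ztest(20, 80, 30, 120)
  b <- proportion_ztest(30, 120, 20, 80)
  expect_equal(a$p_value, b$p_value)
  expect_equal(a$z, -b$z)
  # independent textbook implementation: chi-square without correction,
  # chi2 with 1 df equals z^2
  withr::with_seed(101, {
    for (i in 1:1000) {
      na <- sample(5:500, 1); nb <- sample(5:500, 1)
      ca <- sample(0:na, 1); cb <- sample(0:nb, 1)
      mine <- proportion_ztest(ca, na, cb, nb)
      if (ca / na == cb / nb) {
        expect_equal(mine$p_value, 1)
      } else if ((ca + cb) > 0 && (ca + cb) < (na + nb)) {
        ref <- suppressWarnings(
          stats::prop.test(c(ca, cb), c(na, nb), correct = FALSE))
        expect_equal(mine$z^2, unname(ref$statistic), tolerance = 1e-12)
        expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
      }
    }
  })
  expect_error(proportion_ztest(1, 0, 1, 5), "at least 1")
  expect_error(proportion_ztest(6, 5, 1, 5), "counts")
})

test_that("counts are recovered uniquely from printed percentages", {
  expect_equal(recover_count_from_percent(32.0, 485), 155L)
  expect_equal(recover_count_from_percent(0.0, 19), 0L)
  expect_equal(recover_count_from_percent(100.0, 19), 19L)
  # 3 products cannot print as 50.0%
  expect_error(recover_count_from_percent(50.0, 3), "impossible")
  # integer-precision percents can be ambiguous at large n
  expect_error(recover_count_from_percent(50, 1000, digits = 0),
               "ambiguous")
  # round-trip property at 1 dp for moderate n
  withr::with_seed(3, {
    for (i in 1:200) {
      n <- sample(1:600, 1)
      k <- sample(0:n, 1)
      pct <- floor(1000 * k / n + 0.5) / 10
      got <- tryCatch(recover_count_from_percent(pct, n),
                      error = function(e) NA_integer_)
      if (!is.na(got)) expect_equal(got, k)
    }
  })
})

test_that("recomputed table p-values match the printed surveillance tables", {
  # category rows: n = 485 at 32.0% vs 33.4%; n = 433 at 3.7% vs 3.5%
  cold <- proportion_ztest(recover_count_from_percent(32.0, 485), 485,
                           recover_count_from_percent(33.4, 485), 485)
  expect_equal(round(cold$p_value, 2), 0.63)
  cakes <- proportion_ztest(recover_count_from_percent(3.7, 433), 433,
                            recover_count_from_percent(3.5, 433), 433)
  expect_equal(round(cakes$p_value, 2), 0.85)
  # country rows: n = 256 at 9.8% vs 9.4%; n = 904 at 20.5% vs 20.5%
  my <- proportion_ztest(recover_count_from_percent(9.8, 256), 256,
                         recover_count_from_percent(9.4, 256), 256)
  expect_equal(round(my$p_value, 2), 0.88)
  br <- proportion_ztest(recover_count_from_percent(20.5, 904), 904,
                         recover_count_from_percent(20.5, 904), 904)
  expect_equal(round(br$p_value, 2), 1.00)
})

test_that("cumulative trend accumulates and ends at the window proportion", {
  prods <- make_products(
    make_product("A", launch_year = 2014, fiber = 6, carbohydrate = 40),
    make_product("B", launch_year = 2014, fiber = 0, carbohydrate = 40),
    make_product("C", launch_year = 2015, fiber = 0, carbohydrate = 40),
    make_product("D", launch_year = 2015, fiber = 0, carbohydrate = 40))
  prods$free_sugars <- c(1, 30, 30, 30)
  sc <- score_dataset(prods)$scored
  tr <- trend_by_year(sc, window = c(2014, 2015))
  expect_equal(tr$cumulative_n, c(2L, 4L))
  expect_equal(tr$cumulative_pct_meeting, c(50, 25))
  # single-year window equals the plain proportion
  one <- trend_by_year(sc[sc$launch_year == 2014, ], c(2014, 2014))
  expect_equal(one$cumulative_pct_meeting, 50)
  # final-year cumulative equals the whole-window group summary
  sc2 <- scored_fixture(400, seed = 23L)
  tr2 <- trend_by_year(sc2, window = c(2014, 2024), by = "market")
  g <- summarize_groups(sc2, by = "market")
  final <- tr2[tr2$year == 2024, ]
  expect_equal(final$cumulative_pct_meeting[match(g$market, final$market)],
               g$pct_meeting_combined)
  expect_equal(final$cumulative_n[match(g$market, final$market)], g$n)
})

test_that("claim counting uses set semantics per product", {
  prods <- make_products(
    make_product("A", claims = "Wholegrain|No Added Sugar"),
    make_product("B", claims = "Gluten Free"),
    make_product("C", claims = ""),
    make_product("D", market = "BR", claims = "wholegrain"))
  got <- count_claim_products(prods)
  us <- got[got$market == "US", ]
  expect_equal(us$n_with_claim, 1L)  # A counted once despite two claims
  expect_equal(us$n, 3L)
  br <- got[got$market == "BR", ]
  expect_equal(br$pct_with_claim, 100)  # case-insensitive match
})

test_that("claim prevalence is recovered from generator ground truth", {
  cfg <- gen_config(2000L, seed = 11L,
                    markets = list(list(name = "US", weight = 1,
                                        years = 2014:2024, declared = TRUE,
                                        claim_prevalence = 0.30)))
  sim <- generate_products(cfg)
  got <- count_claim_products(sim$products)
  expect_lt(abs(got$pct_with_claim - 30), 3)
})
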