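test_that("rmse matches direct arithmetic and is symmetric", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(1, 2, 3), c(2, 3, 4)), 1)
  set.seed(3)
  a <- rnorm(40); b <- rnorm(40); c_ <- rnorm(40)
  expect_equal(rmse(a, b), rmse(b, a))
  ## triangle-like bound over seeded triples
  for (i in 1:20) {
    x <- rnorm(15); y <- rnorm(15); z <- rnorm(15)
    expect_lte(rmse(x, z), rmse(x, y) + rmse(y, z) + 1e-12)
  }
  expect_error(rmse(1:3, 1:4), "length")
})

test_that("pearson matches a two-pass textbook formula", {
  expect_equal(pearson(1:10, 2 * (1:10) + 3), 1)
  expect_equal(pearson(1:10, -(1:10)), -1)
  set.seed(7)
  a <- rnorm(50); b <- 0.3 * a + rnorm(50)
  two_pass <- {
    am <- a - mean(a); bm <- b - mean(b)
    sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
  }
  expect_equal(pearson(a, b), two_pass, tolerance = 1e-12)
  expect_error(pearson(rep(1, 5), 1:5), "constant")
})

test_that("correlation categories follow the published bands", {
  expect_equal(categorize_rho(0.95), "excellent")
  expect_equal(categorize_rho(0.35), "weak")        # boundary inclusive
  expect_equal(categorize_rho(0.67), "moderate")
  expect_equal(categorize_rho(0.9), "strong")
  expect_equal(categorize_rho(0.36), "moderate")
  expect_equal(categorize_rho(0.91), "excellent")
  expect_equal(categorize_rho(-0.20), "weak")       # negatives: lowest band
  expect_equal(categorize_rho(-1), "weak")
  expect_equal(categorize_rho(1), "excellent")
  expect_error(categorize_rho(1.2), "rho")
  ## total monotone step function
  grid <- seq(-1, 1, by = 0.01)
  lev <- match(vapply(grid, categorize_rho, character(1)),
               c("weak", "moderate", "strong", "excellent"))
  expect_true(all(diff(lev) >= 0))
})

test_that("load error percentages are scale-free ratios", {
  expect_equal(load_error_percent(0, 90), 0)
  expect_equal(load_error_percent(45, 90), 50)
  expect_equal(load_error_percent(45 * 3, 90 * 3), 50)
  expect_error(load_error_percent(10, 0), "mean")
})

test_that("compare_traces assembles the per-channel table", {
  set.seed(1)
  ref <- data.frame(FE = seq(35, 90, length.out = 20),
                    F_ankle = 90 + rnorm(20))
  sim <- data.frame(FE = ref$FE + 0.5, F_ankle = ref$F_ankle)
  tab <- compare_traces(sim, ref, channels = c("FE", "F_ankle"))
  expect_equal(tab$rmse[tab$channel == "FE"], 0.5, tolerance = 1e-12)
  expect_equal(tab$rho_category[tab$channel == "FE"], "excellent")
  expect_equal(tab$load_error_pct[tab$channel == "F_ankle"], 0, tolerance = 1e-12)
})
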