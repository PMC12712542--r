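test_that("bias vectors are elementwise differences, lengths checked", {
  b <- bias_vectors(c(1, 2), c(0.9, 2.0), c(5, 6), c(5, 5.5))
  expect_equal(b$theta, c(0.1, 0))
  expect_equal(b$omega, c(0, 0.5))
  expect_error(bias_vectors(1:3, 1:2, 1:3, 1:3), "same length")
})

test_that("slope decomposition reproduces the direct starred slope", {
  x <- c(1, 2, 3, 4); y <- c(2, 4, 6, 8)
  theta <- c(0.1, 0, -0.1, 0.2); omega <- rep(0, 4)
  d <- slope_decomposition(x, y, theta, omega)
  # oracle: hand OLS on x* = x - theta -> cov(x*,y)/var(x*) = 9.8/4.85
  expect_equal(d$slope_direct, 9.8 / 4.85)
  expect_equal(d$slope_direct, 2.020619, tolerance = 1e-6)
  expect_equal(d$slope_reconstructed, d$slope_direct, tolerance = 1e-10)
  expect_equal(d$slope_unbiased, 2)
  # bias-free case collapses everything to the unbiased slope
  d0 <- slope_decomposition(x, y, rep(0, 4), rep(0, 4))
  expect_equal(d0$slope_direct, 2)
  expect_equal(d0$slope_reconstructed, 2)
  expect_equal(unname(unlist(d0[c("var_theta", "cov_x_theta",
                                  "cov_theta_y", "cov_theta_omega")])),
               rep(0, 4))
})

test_that("correlation decomposition reproduces the direct Pearson r", {
  x <- c(1, 2, 3, 4); y <- c(2, 4, 6, 8)
  theta <- c(0.1, 0, -0.1, 0.2); omega <- rep(0, 4)
  d <- correlation_decomposition(x, y, theta, omega)
  expect_equal(d$corr_direct, cor(x - theta, y))
  expect_equal(d$corr_reconstructed, d$corr_direct, tolerance = 1e-10)
  # perfect linearity without bias
  expect_equal(correlation_decomposition(x, 2 * x, rep(0, 4),
                                         rep(0, 4))$corr_direct, 1)
  expect_equal(correlation_decomposition(x, -x, rep(0, 4),
                                         rep(0, 4))$corr_direct, -1)
  expect_error(correlation_decomposition(x, rep(1, 4) + c(0, 0, 0, 0),
                                         rep(0, 4), rep(0, 4)),
               "var\\(y\\*\\)")
})

test_that("decomposition identity is exact for random quadruples under
           both divisor conventions", {
  set.seed(1005)
  for (i in 1:60) {
    n <- sample(3:50, 1)
    x <- rnorm(n); y <- rnorm(n)
    theta <- rnorm(n, sd = 0.3); omega <- rnorm(n, sd = 0.3)
    for (div in c("n-1", "n")) {
      d <- slope_decomposition(x, y, theta, omega, divisor = div)
      expect_equal(d$slope_reconstructed, d$slope_direct,
                   tolerance = 1e-10)
      expect_equal(d$corr_reconstructed, d$corr_direct,
                   tolerance = 1e-10)
      expect_true(abs(d$corr_direct) <= 1 + 1e-12)
    }
  }
})

test_that("a constant mean bias does not move the starred slope", {
  set.seed(77)
  x <- rnorm(20); y <- 1.5 * x + rnorm(20, sd = 0.2)
  theta <- rnorm(20, sd = 0.1); omega <- rnorm(20, sd = 0.1)
  d1 <- slope_decomposition(x, y, theta, omega)
  d2 <- slope_decomposition(x, y, theta + 5, omega - 3)
  expect_equal(d2$slope_direct, d1$slope_direct)
  expect_equal(d2$slope_reconstructed, d1$slope_reconstructed,
               tolerance = 1e-10)
  expect_equal(d2$corr_direct, d1$corr_direct)
})

test_that("degenerate inputs raise errors", {
  expect_error(slope_decomposition(1:2, 1:2, c(0, 0), c(0, 0)),
               "at least 3")
  expect_error(slope_decomposition(rep(1, 4), 1:4, rep(0, 4), rep(0, 4)),
               "degenerate regressor")
})

test_that("compare_aggregation_orders collapses when the orders coincide", {
  # one individual per species: both orders give the same species value
  tab1 <- make_table(list(S1 = list(D = 0.2, SRL = 40),
                          S2 = list(D = 0.35, SRL = 15),
                          S3 = list(D = 0.5, SRL = 9),
                          S4 = list(D = 0.28, SRL = 22)))
  d <- compare_aggregation_orders(tab1, "D", "SRL", get_transform("log"),
                                  get_transform("log"))
  expect_equal(d$var_theta, 0)
  expect_equal(d$var_omega, 0)
  expect_equal(d$slope_direct, d$slope_unbiased)

  # zero within-species spread: same collapse at n > 1
  tab2 <- make_table(list(S1 = list(D = rep(0.2, 3), SRL = rep(40, 3)),
                          S2 = list(D = rep(0.35, 2), SRL = rep(15, 2)),
                          S3 = list(D = rep(0.5, 4), SRL = rep(9, 4))))
  d2 <- compare_aggregation_orders(tab2, "D", "SRL", get_transform("log"),
                                   get_transform("log"))
  expect_equal(d2$slope_direct, d2$slope_unbiased)
})

test_that("compare_aggregation_orders aligns species, drops the
           unmatched, and detects real bias", {
  cfg <- small_config(seed = 13)
  tab <- simulate_trait_table(cfg)
  d <- compare_aggregation_orders(tab, "D", "RTD", get_transform("log"),
                                  get_transform("log"))
  expect_equal(d$slope_reconstructed, d$slope_direct, tolerance = 1e-10)
  # within-species spread exists, so the orders must disagree
  expect_gt(d$var_theta, 0)
  expect_false(isTRUE(all.equal(d$slope_direct, d$slope_unbiased,
                                tolerance = 1e-8)))

  # species lacking one trait are excluded with a message
  extra <- rbind(as.data.frame(tab),
                 data.frame(species = "ZZZ", individual = "ZZZ_I01",
                            trait = "D", value = 0.4))
  expect_message(
    d2 <- compare_aggregation_orders(trait_table(extra), "D", "RTD",
                                     get_transform("log"),
                                     get_transform("log")),
    "1 species lack")
  expect_false("ZZZ" %in% attr(d2, "species"))

  expect_error(
    compare_aggregation_orders(
      make_table(list(S1 = list(D = 1, RTD = 1),
                      S2 = list(D = 2, RTD = 2))),
      "D", "RTD", get_transform("log"), get_transform("log")),
    "need >= 3")
})

test_that("reference labelling can be flipped", {
  cfg <- small_config(seed = 5)
  tab <- simulate_trait_table(cfg)
  a <- compare_aggregation_orders(tab, "D", "RTD", get_transform("log"),
                                  get_transform("log"))
  b <- compare_aggregation_orders(tab, "D", "RTD", get_transform("log"),
                                  get_transform("log"),
                                  reference = "aggregate_first")
  # flipping the labels swaps which slope is "unbiased" vs "direct"
  expect_equal(b$slope_direct, a$slope_unbiased, tolerance = 1e-12)
  expect_equal(b$slope_unbiased, a$slope_direct, tolerance = 1e-12)
})
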