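test_that("config validation rejects impossible settings", {
  expect_error(simulation_config(n_species = 10, total_individuals = 5,
                                 n_per_species = c(1L, 3L)),
               "infeasible")
  expect_error(simulation_config(n_species = 10, total_individuals = 50,
                                 n_per_species = c(1L, 3L)),
               "infeasible")
  expect_error(trait_spec("D", 0, -1, 0.1), "log_sd")
  expect_error(trait_spec("D", 0, 1, c(0.5, 0.1)), "lo <= hi")
  expect_error(simulation_config(traits = list(1)), "trait_spec")
})

test_that("defaults reproduce the target scale exactly", {
  cfg <- simulation_config(seed = 1)
  expect_equal(cfg$n_species, 368L)
  expect_equal(cfg$total_individuals, 1920L)
  tab <- simulate_trait_table(cfg)
  expect_equal(length(unique(tab$species)), 368L)
  expect_equal(length(unique(tab$individual)), 1920L)
  # every individual carries both traits in shared mode
  expect_equal(nrow(tab), 2L * 1920L)
  counts <- table(tab$species[tab$trait == "RTD"])
  expect_true(all(counts >= 1 & counts <= 10))
})

test_that("identical seeds give identical tables; different seeds differ", {
  cfg <- small_config(seed = 42)
  t1 <- simulate_trait_table(cfg)
  t2 <- simulate_trait_table(cfg)
  expect_identical(t1, t2)
  t3 <- simulate_trait_table(small_config(seed = 43))
  expect_false(identical(t1$value, t3$value))
})

test_that("zero within-species SD collapses individuals onto the species
           value", {
  cfg <- small_config(seed = 4, within = 0)
  tab <- simulate_trait_table(cfg)
  spread <- tapply(tab$value, paste(tab$species, tab$trait), function(v)
    diff(range(v)))
  expect_true(all(spread == 0))
})

test_that("between-species moments are recovered at scale", {
  cfg <- simulation_config(
    n_species = 2000, total_individuals = 10000,
    traits = list(trait_spec("D", log_mean = -1, log_sd = 0.4,
                             within_log_sd = 0)),
    n_per_species = c(1L, 10L), seed = 99)
  tab <- simulate_trait_table(cfg)
  sp_log_means <- tapply(log(tab$value), tab$species, mean)
  expect_equal(unname(sd(sp_log_means)), 0.4, tolerance = 0.05)
  expect_equal(unname(mean(sp_log_means)), -1, tolerance = 0.05)
})

test_that("disjoint mode splits individuals between traits, odd one to
           the first trait", {
  cfg <- simulation_config(
    n_species = 6, total_individuals = 30,
    traits = list(trait_spec("RTD", log(0.25), 0.4, 0.2),
                  trait_spec("D", log(0.35), 0.4, 0.2)),
    n_per_species = c(5L, 5L), shared_individuals = FALSE, seed = 12)
  tab <- simulate_trait_table(cfg)
  for (s in unique(tab$species)) {
    rtd_ind <- tab$individual[tab$species == s & tab$trait == "RTD"]
    d_ind <- tab$individual[tab$species == s & tab$trait == "D"]
    expect_length(intersect(rtd_ind, d_ind), 0)
    expect_equal(length(rtd_ind), 3L)  # ceiling(5/2)
    expect_equal(length(d_ind), 2L)
  }
})

test_that("coupled traits obey the power law exactly without noise", {
  cfg <- small_config(seed = 21)
  tab <- simulate_coupled_traits(cfg, a = 1, b = 1)
  x <- tab$value[tab$trait == "RTD"]
  y <- tab$value[tab$trait == "D"]
  expect_equal(y, x)
  tab2 <- simulate_coupled_traits(cfg, a = 2, b = 0)
  expect_true(all(tab2$value[tab2$trait == "D"] == 2))
  # log-log individual relation exact; mean-of-log regression recovers it
  tab3 <- simulate_coupled_traits(cfg, a = 4 / pi, b = -2)
  lg <- get_transform("log")
  sx <- summarize_trait(tab3, "RTD", lg)
  sy <- summarize_trait(tab3, "D", lg)
  fit <- ols_fit(sy$mean_transformed, list(lnx = sx$mean_transformed))
  expect_equal(unname(fit$coefficients), c(log(4 / pi), -2),
               tolerance = 1e-8)
  expect_gte(fit$r_squared, 1 - 1e-10)
  expect_error(simulate_coupled_traits(cfg, a = -1, b = 2), "positive")
})

test_that("with shared individuals and no within-species spread the
           coupled traits produce zero bias vectors", {
  cfg <- small_config(seed = 33, within = 0)
  tab <- simulate_coupled_traits(cfg, a = 0.8, b = 1.7)
  d <- compare_aggregation_orders(tab, "RTD", "D", get_transform("log"),
                                  get_transform("log"))
  expect_equal(d$var_theta, 0, tolerance = 1e-24)
  expect_equal(d$var_omega, 0, tolerance = 1e-24)
  expect_equal(d$slope_direct, d$slope_unbiased, tolerance = 1e-12)
})

test_that("mean-coupled heterogeneous within-species SD inflates the
           slope distortion relative to the homogeneous case", {
  seed <- 42
  hom <- simulation_config(
    traits = list(trait_spec("RTD", log(0.25), 0.45, 0.45),
                  trait_spec("D", log(0.35), 0.40, 0.45)),
    seed = seed)
  het <- simulation_config(
    traits = list(trait_spec("RTD", log(0.25), 0.45, c(0.05, 0.85)),
                  trait_spec("D", log(0.35), 0.40, c(0.05, 0.85))),
    seed = seed)
  dev <- function(cfg) {
    tab <- derive_srl_column(simulate_trait_table(cfg))
    d <- compare_aggregation_orders(tab, "D", "SRL", get_transform("log"),
                                    get_transform("log"))
    abs(d$slope_direct - d$slope_unbiased)
  }
  expect_gt(dev(het), dev(hom))
})
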