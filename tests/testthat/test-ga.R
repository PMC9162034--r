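make_instance <- function(n_agents = 4, n_steps = 6, n_bins = 10, seed = 1) {
  simulate_diffusion(n_agents, 2, n_steps, n_bins, seed = seed)
}

test_that("identical seeds give bit-identical fits", {
  sim <- make_instance()
  ctrl <- ga_control(max_iter = 3000)
  f1 <- fit_degroot(sim$observed, sim$adjacency, 10, ctrl, seed = 5)
  f2 <- fit_degroot(sim$observed, sim$adjacency, 10, ctrl, seed = 5)
  expect_identical(f1$weights, f2$weights)
  expect_identical(f1$fitness, f2$fitness)
  expect_identical(f1$generations, f2$generations)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$solved, f2$solved)
})

test_that("the elite objective never increases across generations", {
  sim <- make_instance()
  fit <- fit_degroot(sim$observed, sim$adjacency, 10,
                     ga_control(max_iter = 3000), seed = 9)
  expect_true(all(diff(fit$history$elite) <= 0))
})

test_that("with all operator probabilities zero the population only changes
          through gene swaps", {
  set.seed(51)
  sim <- make_instance(n_agents = 3, n_bins = 5, seed = 3)
  X <- matrix(forward_transform(as.vector(panel_matrix(sim$observed)), 5),
              6, 3)
  pop <- initialize_population(sim$adjacency, 5)
  sel <- select_elite(pop, X, 5)
  parents <- sel$rest
  # blending, crossover, mutation all disabled: offspring equal parents
  off <- parents
  for (j in seq_along(off)) {
    off[[j]] <- crossover(off[[j]], 0, sim$adjacency)
    off[[j]] <- mutate(off[[j]], 0, 0.5, sim$adjacency)
  }
  expect_equal(off, parents)
  surv <- survive(parents, off, X, 5)
  expect_equal(surv, parents)  # ties go to the parents
})

test_that("the run stops at the generation cap when no perfect solution
          exists", {
  # opinions leap from bin 1 to bin 5: impossible under any convex update
  Y <- rbind(c(1, 1), c(5, 5))
  A <- full_adjacency(2)
  fit <- fit_degroot(Y, A, 5, ga_control(max_iter = 1000), seed = 2)
  expect_identical(fit$generations, 1000L)
  expect_false(fit$solved)
  expect_gt(fit$fitness$total, 0)
})

test_that("the solution check happens only at thousand-generation blocks", {
  sim <- make_instance(n_bins = 30)
  fit <- fit_degroot(sim$observed, sim$adjacency, 30,
                     ga_control(max_iter = 5000), seed = 1)
  expect_identical(fit$generations %% 1000L, 0L)
  expect_length(fit$block_times, fit$generations / 1000)
})

test_that("a solvable instance is solved and recovers parameters better than
          a random baseline", {
  sim <- make_instance(n_bins = 30, seed = 4)
  fit <- fit_degroot(sim$observed, sim$adjacency, 30, seed = 4)
  expect_true(fit$solved)
  expect_equal(fit$fitness$total, 0)
  expect_identical(nrow(validate_weight_matrix(fit$weights, sim$adjacency)),
                   0L)
  rmse_fit <- recovery_rmse(sim$weights, fit$weights, sim$adjacency)
  set.seed(4)
  baseline <- initialize_population(sim$adjacency, 3)[[1]]
  rmse_base <- recovery_rmse(sim$weights, baseline, sim$adjacency)
  expect_lt(rmse_fit, rmse_base)
})

test_that("fit input validation catches mismatched panels", {
  sim <- make_instance()
  expect_error(fit_degroot(sim$observed, full_adjacency(3), 10),
               "disagree")
  bad <- panel_matrix(sim$observed)
  bad[1, 1] <- 99
  expect_error(fit_degroot(bad, sim$adjacency, 10), "1\\.\\.10")
})

test_that("tidy, glance and autoplot summarise a fit", {
  sim <- make_instance()
  fit <- fit_degroot(sim$observed, sim$adjacency, 10,
                     ga_control(max_iter = 1000), seed = 6)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_identical(nrow(td), 16L)
  expect_named(td, c("agent", "source", "weight", "free"))
  expect_false(any(td$weight[!td$free] != 0))
  gl <- glance(fit)
  expect_identical(nrow(gl), 1L)
  expect_equal(gl$objective, fit$fitness$total)
  expect_equal(gl$n_agents, 4L)
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})

test_that("hyperparameter configuration round-trips through JSON", {
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(
    list(chromosomes = 5, prob_sigma = "high", iter = 1000, sigma = 0.3),
    f, auto_unbox = TRUE)
  ctrl <- read_ga_config(f)
  expect_equal(ctrl$chromosomes, 5)
  expect_equal(ctrl$probb, 0.2)   # high preset
  expect_equal(ctrl$sigma, 0.3)   # explicit override beats the preset
  expect_equal(ctrl$iterb, 1000)
  expect_equal(ctrl$iterr, 1000)
  jsonlite::write_json(list(bogus = 1), f, auto_unbox = TRUE)
  expect_error(read_ga_config(f), "unknown configuration")
})

test_that("hyperparameter validation enforces the documented constraints", {
  expect_error(ga_control(chromosomes = 4), "odd")
  expect_error(ga_control(factorb = 0.5), "factorb")
  expect_error(ga_control(factors = 2), "factors")
  expect_error(ga_control(sigma = 0), "sigma")
  expect_error(ga_control(probb = 0.9, maxb = 0.5), "maxb")
  # preset tables carry the documented values
  expect_equal(ga_control(prob_sigma = "low")$probb, 0.01)
  expect_equal(ga_control(min_max = "extreme")$maxb, 0.2)
  expect_equal(ga_control(mult_factor = "rapid")$factorb, 10)
})
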