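test_that("recovery RMSE matches hand summation over non-zero positions", {
  A <- full_adjacency(2)
  W <- matrix(0.5, 2, 2)
  expect_equal(recovery_rmse(W, W, A), 0)
  W_hat <- rbind(c(0.6, 0.4), c(0.5, 0.5))
  # two cells off by 0.1 over P = 4 positions: sqrt(0.02 / 4) = sqrt(0.005)
  expect_equal(recovery_rmse(W, W_hat, A), sqrt(0.005))
  # relabelling agents consistently leaves the RMSE unchanged
  set.seed(71)
  A5 <- simulate_network(5, 2)
  Wt <- simulate_weight_matrix(A5)
  Wh <- random_weights(A5)
  p <- sample(5)
  expect_equal(recovery_rmse(Wt, Wh, A5),
               recovery_rmse(Wt[p, p], Wh[p, p], A5[p, p]))
  # structural zeros must hold in both matrices
  A0 <- rbind(c(1, 0), c(0, 1))
  expect_error(recovery_rmse(rbind(c(0.9, 0.1), c(0, 1)), diag(2), A0),
               "structural zeros")
})

test_that("the study design drops infeasible cells and keeps stable ids", {
  expect_message(des <- study_design(), "infeasible")
  # N = 4 with mean degree 5 or 9 is impossible; everything else remains
  expect_false(any(des$n_agents == 4 & des$mean_degree > 2))
  expect_equal(nrow(des), 34020)
  expect_identical(anyDuplicated(des$cell_id), 0L)
  small <- suppressMessages(
    study_design(n_agents = 4, mean_degree = 2, n_steps = 2, n_bins = 5,
                 chromosomes = 5, prob_sigma = "low", min_max = "minimal",
                 mult_factor = "slow", iter = 200))
  expect_identical(nrow(small), 1L)
})

test_that("cells run deterministically with fresh data per replicate", {
  des <- suppressMessages(
    study_design(n_agents = 4, mean_degree = 2, n_steps = 3, n_bins = 10,
                 chromosomes = 5, prob_sigma = "medium",
                 min_max = "moderate", mult_factor = "moderate", iter = 200))
  r1 <- run_cell(des[1, ], replicates = 2, base_seed = 3, max_iter = 1000)
  expect_identical(nrow(r1), 2L)
  expect_false(identical(r1$rmse[1], r1$rmse[2]))  # distinct datasets
  r2 <- run_cell(des[1, ], replicates = 2, base_seed = 3, max_iter = 1000)
  drop_time <- function(d) d[setdiff(names(d), "seconds")]
  expect_identical(drop_time(r1), drop_time(r2))
  expect_true(all(is.na(r1$error)))
  expect_true(all(r1$blocks == ceiling(r1$generations / 1000)))
})

test_that("run_study subsamples by cell and resumes from partial output", {
  des <- suppressMessages(
    study_design(n_agents = 4, mean_degree = 2, n_steps = 2,
                 n_bins = c(5, 10), chromosomes = 5,
                 prob_sigma = "medium", min_max = "moderate",
                 mult_factor = "moderate", iter = c(200, 1000)))
  expect_identical(nrow(des), 4L)
  res <- run_study(des, replicates = 2, max_iter = 1000, base_seed = 5)
  expect_identical(nrow(res), 8L)  # cells x replicates

  half <- run_study(des, replicates = 2, subsample = 0.5, max_iter = 1000,
                    base_seed = 5)
  expect_identical(nrow(half), 4L)

  # resume: first run writes, second skips completed cells
  out <- withr::local_tempfile(fileext = ".csv")
  run_study(des[1:2, ], replicates = 1, max_iter = 1000, base_seed = 5,
            out = out)
  before <- tibble::as_tibble(read.csv(out))
  full <- run_study(des, replicates = 1, max_iter = 1000, base_seed = 5,
                    out = out)
  expect_identical(nrow(full), 4L)
  expect_setequal(full$cell_id, des$cell_id)
  expect_equal(dplyr::semi_join(full, before, by = "cell_id")$rmse,
               before$rmse)
})

test_that("study summaries agree with an independent aggregation", {
  set.seed(72)
  toy <- tidyr::expand_grid(
    iter = c(200, 5000), prob_sigma = c("low", "high"), n_steps = c(2, 6),
    chromosomes = c(5, 21), replicate = 1:3)
  toy$rmse <- runif(nrow(toy), 0, 0.3)
  toy$solved <- rep(c(TRUE, TRUE, FALSE), nrow(toy) / 3)
  toy$generations <- ifelse(toy$solved, 1000, 20000)
  toy$seconds <- toy$generations * 1e-4
  toy$error <- NA_character_
  sm <- summarize_study(toy)
  overall <- sm[sm$grouping == "overall", ]
  expect_equal(overall$prop_solved_1000, mean(toy$solved))
  expect_equal(overall$prop_unsolved, 1 / 3)
  # brute-force grouped means straight off the raw table
  for (g in c("iter", "n_steps", "chromosomes")) {
    got <- sm[sm$grouping == g, c("level", "mean_rmse")]
    want <- tapply(toy$rmse, as.character(toy[[g]]), mean)
    expect_equal(got$mean_rmse[order(got$level)],
                 as.numeric(want[order(names(want))]))
  }
  expect_error(summarize_study(toy[0, ]), "empty")
})

test_that("runs solving in the first block are summarised as such", {
  toy <- tibble::tibble(
    iter = 200, prob_sigma = "medium", n_steps = 6, chromosomes = 21,
    rmse = c(0.1, 0.2), solved = TRUE, generations = c(1000, 1000),
    seconds = 0.1, error = NA_character_)
  sm <- summarize_study(toy)
  expect_equal(sm$prop_solved_1000[sm$grouping == "overall"], 1)
  expect_equal(sm$prop_unsolved[sm$grouping == "overall"], 0)
})
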