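test_that("population initialization builds valid chromosomes plus identity", {
  A <- full_adjacency(2)
  set.seed(41)
  pop <- initialize_population(A, 3)
  expect_length(pop, 3)
  expect_equal(pop[[3]], diag(2))
  for (W in pop) expect_identical(nrow(validate_weight_matrix(W, A)), 0L)
  expect_error(initialize_population(A, 4), "odd")
  expect_error(initialize_population(A, 1), "odd")

  # structural zeros propagate to every chromosome
  A0 <- rbind(c(1, 0, 1), c(0, 1, 1), c(1, 1, 1))
  pop0 <- initialize_population(A0, 5)
  for (W in pop0) {
    expect_identical(nrow(validate_weight_matrix(W, A0)), 0L)
    expect_equal(W[1, 2], 0)
    expect_equal(W[2, 1], 0)
  }
})

test_that("blending reproduces the convex row combination exactly", {
  A <- full_adjacency(3)
  set.seed(42)
  B <- random_weights(A); C <- random_weights(A)
  set.seed(99)
  got <- blend_pair(B, C, 1)
  set.seed(99)
  want <- blend_oracle(B, C, 1)
  expect_equal(got$B, want$B)
  expect_equal(got$C, want$C)
  # beta = 0.5 averages; row sums always preserved
  expect_equal(rowSums(got$B), rep(1, 3))
  expect_equal(rowSums(got$C), rep(1, 3))
  # p_b = 0: untouched
  expect_equal(blend_pair(B, C, 0)$B, B)
})

test_that("crossover permutes evolvable values within a row", {
  A <- rbind(c(1, 1, 0), c(1, 1, 1), c(0, 1, 1))
  set.seed(43)
  W <- random_weights(A)
  expect_equal(crossover(W, 0, A), W)
  set.seed(7)
  got <- crossover(W, 1, A)
  set.seed(7)
  want <- crossover_oracle(W, 1, A)
  expect_equal(got, want)
  for (i in 1:3) {
    expect_equal(sort(got[i, ]), sort(W[i, ]))  # same multiset
    expect_equal(sum(got[i, ]), 1)
  }
  # a row with a single evolvable position cannot change
  A1 <- rbind(c(1, 0), c(0, 1))
  W1 <- diag(2)
  for (s in 1:5) {
    set.seed(s)
    expect_equal(crossover(W1, 1, A1), W1)
  }
})

test_that("mutation boundary rules match the hand-worked cases", {
  free2 <- c(TRUE, TRUE)
  # overshoot above 1: all mass onto the selected weight
  expect_equal(mutate_row_oracle(c(0.3, 0.7), free2, 2, 0.5), c(0, 1))
  # selected weight held the entire mass: excess spread evenly
  expect_equal(mutate_row_oracle(c(0, 1), free2, 2, -0.4), c(0.4, 0.6))
  # interior move: others rescaled multiplicatively
  expect_equal(mutate_row_oracle(c(0.2, 0.3, 0.5), rep(TRUE, 3), 3, -0.1),
               c(0.24, 0.36, 0.4))
  # undershoot below 0: clamp then rescale
  expect_equal(mutate_row_oracle(c(0.3, 0.7), free2, 1, -0.5),
               c(0, 1))
})

test_that("compiled mutation agrees with the replayed oracle", {
  A <- rbind(c(1, 1, 0, 1), c(1, 1, 1, 1), c(0, 1, 1, 1), c(1, 1, 1, 1))
  set.seed(44)
  W <- random_weights(A)
  for (sigma in c(0.05, 0.5, 2)) {
    for (s in 1:20) {
      set.seed(1000 + s)
      got <- mutate(W, 1, sigma, A)
      set.seed(1000 + s)
      want <- mutate_oracle(W, 1, sigma, A)
      expect_equal(got, want)
      expect_identical(nrow(validate_weight_matrix(got, A)), 0L)
    }
  }
  # edge-case row (0, 1): even redistribution branch
  W2 <- rbind(c(0, 1), c(0.5, 0.5))
  A2 <- full_adjacency(2)
  for (s in 1:20) {
    set.seed(2000 + s)
    got <- mutate(W2, 1, 0.5, A2)
    set.seed(2000 + s)
    expect_equal(got, mutate_oracle(W2, 1, 0.5, A2))
  }
})

test_that("gene swap imports a strictly fitter gene and reverts otherwise", {
  set.seed(45)
  A <- full_adjacency(2)
  W_true <- random_weights(A)
  y0 <- c(3, 9)
  xhat <- panel_matrix(degroot_trajectory(W_true, forward_transform(y0, 10), 4))
  Y <- matrix(back_transform(as.vector(xhat), 10), 4, 2)
  X <- matrix(forward_transform(as.vector(Y), 10), 4, 2)
  stopifnot(chromosome_fitness(W_true, X, 10)$total == 0)

  # best: perfect except row 1; donor holds the generating row 1
  best <- W_true
  best[1, ] <- c(0.95, 0.05)
  f_best <- chromosome_fitness(best, X, 10)
  stopifnot(f_best$per_gene[1] > 0)  # the perturbation must hurt row 1
  sw <- gene_swap(best, list(W_true), X, 10)
  expect_true(sw$accepted)
  expect_true(sw$total < f_best$total)
  expect_equal(sw$best[1, ], W_true[1, ])
  # the donor received best's old row
  expect_equal(sw$donors[[1]][1, ], best[1, ])

  # no donor gene strictly fitter: nothing happens
  sw2 <- gene_swap(W_true, list(best), X, 10)
  expect_false(sw2$accepted)
  expect_equal(sw2$best, W_true)
  expect_equal(sw2$donors[[1]], best)
})

test_that("selection picks the fittest chromosome, ties to the lowest index", {
  set.seed(46)
  A <- full_adjacency(2)
  W_true <- random_weights(A)
  xhat <- panel_matrix(degroot_trajectory(W_true, c(0.25, 0.85), 4))
  Y <- matrix(back_transform(as.vector(xhat), 10), 4, 2)
  X <- matrix(forward_transform(as.vector(Y), 10), 4, 2)
  other <- random_weights(A)
  sel <- select_elite(list(other, W_true, other), X, 10)
  expect_equal(sel$fitness, 0)
  expect_length(sel$rest, 2)
  # zero-fitness chromosome is elite; duplicated minima take the lower index
  sel2 <- select_elite(list(W_true, W_true, other), X, 10)
  expect_equal(sel2$elite, W_true)
})

test_that("survival keeps the fitter of each parent/offspring pair", {
  set.seed(47)
  A <- full_adjacency(2)
  W_true <- random_weights(A)
  xhat <- panel_matrix(degroot_trajectory(W_true, c(0.15, 0.65), 4))
  Y <- matrix(back_transform(as.vector(xhat), 10), 4, 2)
  X <- matrix(forward_transform(as.vector(Y), 10), 4, 2)
  bad <- diag(2)
  f_bad <- chromosome_fitness(bad, X, 10)$total
  stopifnot(f_bad > 0)
  surv <- survive(list(W_true, bad), list(bad, W_true), X, 10)
  expect_equal(surv[[1]], W_true)
  expect_equal(surv[[2]], W_true)
  # tie goes to the parent (incumbent)
  surv2 <- survive(list(W_true), list(W_true + 0), X, 10)
  expect_equal(surv2[[1]], W_true)
  # survivor is never worse than either member of the pair
  set.seed(48)
  parents <- replicate(4, random_weights(A), simplify = FALSE)
  offspring <- replicate(4, random_weights(A), simplify = FALSE)
  surv3 <- survive(parents, offspring, X, 10)
  for (j in 1:4) {
    fs <- chromosome_fitness(surv3[[j]], X, 10)$total
    fp <- chromosome_fitness(parents[[j]], X, 10)$total
    fo <- chromosome_fitness(offspring[[j]], X, 10)$total
    expect_lte(fs, min(fp, fo))
  }
  expect_error(survive(parents, offspring[1:2], X, 10), "same length")
})

test_that("control parameters adapt multiplicatively and clamp", {
  ctrl <- ga_control(mult_factor = "slow")  # factorb = 2
  ct <- list(p_b = 0.1, p_c = 0.1, p_m = 0.1, sigma = 0.5)
  # threshold fires: one multiplication each
  got <- adapt_controls(ct, ctrl, 200)
  expect_equal(got$p_b, 0.2)
  expect_equal(got$p_c, 0.05)
  expect_equal(got$p_m, 0.05)
  expect_equal(got$sigma, 0.25)
  # non-multiple stagnation: unchanged
  expect_equal(adapt_controls(ct, ctrl, 150), ct)
  expect_equal(adapt_controls(ct, ctrl, 0), ct)
  # repeated triggers saturate at the bounds
  for (i in 1:10) ct <- adapt_controls(ct, ctrl, 200)
  expect_equal(ct$p_b, ctrl$maxb)
  expect_equal(ct$p_c, ctrl$minc)
  expect_equal(ct$sigma, ctrl$mins)
})

test_that("reintroduction replaces the worst chromosome", {
  set.seed(49)
  A <- full_adjacency(2)
  W_true <- random_weights(A)
  xhat <- panel_matrix(degroot_trajectory(W_true, c(0.35, 0.75), 4))
  Y <- matrix(back_transform(as.vector(xhat), 10), 4, 2)
  X <- matrix(forward_transform(as.vector(Y), 10), 4, 2)
  near <- W_true; near[1, ] <- near[1, c(2, 1)]
  pop <- list(near, diag(2), near)
  f_id <- chromosome_fitness(diag(2), X, 10)$total
  f_near <- chromosome_fitness(near, X, 10)$total
  stopifnot(f_id != f_near)
  worst_is_identity <- f_id > f_near
  got <- reintroduce_chromosome(pop, W_true, "elite", X, 10)
  idx <- if (worst_is_identity) 2 else 3  # ties break to highest index
  expect_equal(got[[idx]], W_true)
  got_id <- reintroduce_chromosome(pop, W_true, "identity", X, 10,
                                   adjacency = A)
  expect_equal(got_id[[idx]], diag(2))
  # worst-fitness tie: highest index replaced
  pop_tie <- list(W_true, diag(2), diag(2))
  got_tie <- reintroduce_chromosome(pop_tie, W_true, "elite", X, 10)
  expect_equal(got_tie[[3]], W_true)
  expect_equal(got_tie[[2]], diag(2))
})
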