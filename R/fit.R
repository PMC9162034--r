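#' Fit a DeGroot opinion-diffusion model with the adaptive genetic algorithm
#'
#' Estimates the row-stochastic influence-weight matrix `W` of the DeGroot
#' model `X(t+1) = W X(t)` from an ordinal opinion panel observed on a known
#' social network. The ordinal panel is forward-transformed to bin centres,
#' and a population of candidate weight matrices (chromosomes) evolves under
#' selection with elitism, gene swapping, blending, crossover, mutation and
#' survival, minimising the bin-weighted objective
#' ([chromosome_fitness()]). Control parameters adapt multiplicatively
#' whenever the elite objective stagnates, shifting the search from
#' exploration (including edge-case solutions on the simplex boundary) to
#' exploitation. The run stops at a perfect ordinal solution (objective
#' <= `min_dev`, checked every 1000 generations) or at the generation cap.
#'
#' With a fixed `seed` the run is fully reproducible: every random draw
#' (population initialization, pairing, operator coins, blending betas,
#' mutation positions and noise) comes from R's RNG stream in a documented
#' order.
#'
#' @param opinions Ordinal opinion panel: a panel tibble (see
#'   [as_opinion_panel()]) or T x N matrix of integers in `1:n_bins`, rows =
#'   time steps.
#' @param adjacency Binary symmetric N x N adjacency matrix with self-links
#'   (missing self-links are added with a warning).
#' @param n_bins Number of points of the ordinal scale.
#' @param control Hyperparameters from [ga_control()].
#' @param seed Integer seed; `NULL` leaves the RNG state untouched.
#' @param fixed Optional fixed-value matrix (`NA` = evolvable); structural
#'   zeros from `adjacency` are always fixed at 0.
#' @param record_history Keep the per-generation elite objective and control
#'   parameters? (Disable for large batch studies.)
#' @return An object of class `"degroot_fit"`: a list with `weights` (the
#'   estimated matrix), `fitness` (`total`, `per_gene`), `generations`,
#'   `solved`, `block_times` (seconds per 1000-generation block), `history`
#'   (tibble, if recorded), `controls` (final control parameters),
#'   `control`, `adjacency`, `n_bins` and `seed`.
#' @examples
#' sim <- simulate_diffusion(n_agents = 4, mean_degree = 2, n_steps = 6,
#'                           n_bins = 10, seed = 1)
#' fit <- fit_degroot(sim$observed, sim$adjacency, n_bins = 10,
#'                    control = ga_control(max_iter = 2000), seed = 1)
#' glance(fit)
#' @export
fit_degroot <- function(opinions, adjacency, n_bins,
                        control = ga_control(), seed = NULL, fixed = NULL,
                        record_history = TRUE) {
  n_bins <- check_n_bins(n_bins)
  validate_ga_control(control)
  Y <- panel_matrix(opinions)
  st <- weight_structure(adjacency, fixed)
  N <- nrow(st$adjacency)
  if (ncol(Y) != N)
    stop("opinion panel and adjacency matrix disagree on the number of ",
         "agents", call. = FALSE)
  if (any(!is.finite(Y)) || any(Y != floor(Y)) || any(Y < 1) ||
      any(Y > n_bins))
    stop("ordinal opinions must be integers in 1..", n_bins, call. = FALSE)
  X <- matrix(forward_transform(as.vector(Y), n_bins), nrow(Y), N)

  if (!is.null(seed)) set.seed(seed)
  pop <- initialize_population(st$adjacency, control$chromosomes, fixed)
  res <- cpp_run_ga(pop, st$free, st$fixed_values, X, n_bins,
                    unclass(control), record_history)

  history <- NULL
  if (record_history) {
    h <- res$history
    history <- tibble::tibble(
      generation = seq_len(nrow(h)),
      elite = h[, 1], p_b = h[, 2], p_c = h[, 3], p_m = h[, 4],
      sigma = h[, 5])
  }
  W <- res$best
  dimnames(W) <- dimnames(st$adjacency)
  structure(list(
    weights = W,
    fitness = list(total = res$total, per_gene = as.numeric(res$per_gene)),
    generations = res$generations,
    solved = res$solved,
    block_times = as.numeric(res$block_times),
    history = history,
    controls = as.list(res$controls),
    stagnation = res$stagnation,
    control = control,
    adjacency = st$adjacency,
    fixed = fixed,
    n_bins = n_bins,
    observed = as_opinion_panel(Y),
    seed = seed
  ), class = "degroot_fit")
}

#' @export
print.degroot_fit <- function(x, ...) {
  cat("<degroot_fit>\n")
  cat(sprintf("  %d agents, %d time steps, %d-point ordinal scale\n",
              nrow(x$weights), nrow(x$observed), x$n_bins))
  cat(sprintf("  %s after %d generations (objective %.6g)\n",
              if (x$solved) "solved" else "not solved",
              x$generations, x$fitness$total))
  cat("  estimated weights:\n")
  print(round(x$weights, 3))
  invisible(x)
}

#' Tidy the estimated weight matrix of a fitted model
#'
#' Returns one row per weight-matrix entry: the influenced agent, the
#' influencing agent, the estimated weight, and whether the position was
#' evolvable (not a structural zero or user-fixed value).
#'
#' @param x A `"degroot_fit"` object.
#' @param ... Unused.
#' @return A tibble with columns `agent`, `source`, `weight`, `free`.
#' @export
tidy.degroot_fit <- function(x, ...) {
  st <- weight_structure(x$adjacency, x$fixed)
  N <- nrow(x$weights)
  labels <- colnames(x$weights) %||% paste0("agent_", seq_len(N))
  tibble::tibble(
    agent = rep(labels, times = N),
    source = rep(labels, each = N),
    weight = as.vector(x$weights),
    free = as.vector(st$free) == 1
  )
}

#' One-row summary of a fitted model
#'
#' @inheritParams tidy.degroot_fit
#' @return A tibble with one row: `n_agents`, `n_steps`, `n_bins`,
#'   `objective`, `solved`, `generations`, `blocks` (thousand-generation
#'   increments used), `seconds` (total elapsed), and the final control
#'   parameters.
#' @export
glance.degroot_fit <- function(x, ...) {
  tibble::tibble(
    n_agents = nrow(x$weights),
    n_steps = nrow(x$observed),
    n_bins = x$n_bins,
    objective = x$fitness$total,
    solved = x$solved,
    generations = x$generations,
    blocks = ceiling(x$generations / 1000),
    seconds = sum(x$block_times),
    p_b = x$controls$p_b, p_c = x$controls$p_c, p_m = x$controls$p_m,
    sigma = x$controls$sigma
  )
}

#' Convergence plot for a fitted model
#'
#' Plots the elite objective per generation (log10 + 1 scale) together with
#' the adapting control parameters.
#'
#' @param object A `"degroot_fit"` object with recorded history.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.degroot_fit <- function(object, ...) {
  if (is.null(object$history))
    stop("fit was run with `record_history = FALSE`", call. = FALSE)
  long <- tidyr::pivot_longer(object$history, -"generation",
                              names_to = "series", values_to = "value")
  long$series <- factor(long$series,
                        levels = c("elite", "p_b", "p_c", "p_m", "sigma"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$generation,
                                     y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "generation", y = NULL,
                  title = "Elite objective and control parameters")
}
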