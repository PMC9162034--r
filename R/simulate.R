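#' Simulate a connected Erdős–Rényi social network
#'
#' Draws a G(N, p) network with edge probability `p = mean_degree / (N - 1)`
#' (so the expected degree equals the target), rejecting draws until the
#' network is connected -- which also guarantees every node at least one
#' neighbour -- then adds self-links. Draw order: one Unif(0, 1) per
#' upper-triangle pair (column-major order) per attempt.
#'
#' @param n_agents Number of agents N >= 2.
#' @param mean_degree Target mean degree `d`, with `1 <= d < N`.
#' @param max_tries Rejection budget before giving up.
#' @return Binary N x N adjacency matrix with unit diagonal.
#' @export
simulate_network <- function(n_agents, mean_degree, max_tries = 10000) {
  if (n_agents < 2) stop("`n_agents` must be >= 2", call. = FALSE)
  if (mean_degree < 1 || mean_degree >= n_agents)
    stop("`mean_degree` must satisfy 1 <= d < n_agents", call. = FALSE)
  N <- n_agents
  p <- mean_degree / (N - 1)
  upper <- which(upper.tri(matrix(0, N, N)))
  for (try in seq_len(max_tries)) {
    A <- matrix(0, N, N)
    A[upper] <- as.numeric(runif(length(upper)) < p)
    A <- A + t(A)
    if (is_connected(A)) {
      diag(A) <- 1
      return(A)
    }
  }
  stop("failed to draw a connected network in ", max_tries, " attempts",
       call. = FALSE)
}

# breadth-first reachability on a symmetric 0/1 matrix (diagonal ignored)
is_connected <- function(A) {
  N <- nrow(A)
  seen <- logical(N)
  frontier <- 1L
  seen[1] <- TRUE
  while (length(frontier) > 0) {
    nb <- which(rowSums(A[, frontier, drop = FALSE]) > 0 & !seen)
    seen[nb] <- TRUE
    frontier <- nb
  }
  all(seen)
}

#' Simulate a ground-truth influence-weight matrix
#'
#' For each agent the self-weight is drawn from a beta distribution with
#' mean `self_weight_mean` and concentration `kappa` (`alpha = kappa * mean`,
#' `beta = kappa * (1 - mean)`; the defaults give Beta(2, 2) with mean 0.5).
#' The remaining weights of the row are Unif(0, 1) draws on the agent's
#' neighbours, rescaled to sum to `1 - w_ii`. Structural zeros stay 0; an
#' isolated agent (self-link only) receives `w_ii = 1` with a message. This
#' process almost surely produces no boundary (edge-case) rows, so the
#' ground truth is biased against edge-case solutions. Draw order: per row,
#' one beta draw then one uniform per neighbour.
#'
#' @param adjacency Binary adjacency matrix with self-links.
#' @param self_weight_mean Target self-weight in (0, 1); default 0.5.
#' @param kappa Beta concentration `alpha + beta`; default 4.
#' @return Row-stochastic N x N weight matrix respecting the adjacency
#'   structure.
#' @export
simulate_weight_matrix <- function(adjacency, self_weight_mean = 0.5,
                                   kappa = 4) {
  A <- check_adjacency(adjacency, quiet = TRUE)
  if (self_weight_mean <= 0 || self_weight_mean >= 1)
    stop("`self_weight_mean` must lie in (0, 1)", call. = FALSE)
  N <- nrow(A)
  W <- matrix(0, N, N)
  for (i in seq_len(N)) {
    nb <- which(A[i, ] == 1 & seq_len(N) != i)
    if (length(nb) == 0) {
      message("agent ", i, " is isolated; self-weight set to 1")
      W[i, i] <- 1
      next
    }
    wii <- rbeta(1, kappa * self_weight_mean, kappa * (1 - self_weight_mean))
    u <- runif(length(nb))
    W[i, i] <- wii
    W[i, nb] <- u / sum(u) * (1 - wii)
  }
  dimnames(W) <- dimnames(A)
  W
}

#' Simulate an opinion-diffusion dataset
#'
#' Reproduces the full data-generating process behind the calibration
#' study: a connected Erdős–Rényi network ([simulate_network()]), a
#' ground-truth weight matrix ([simulate_weight_matrix()]), initial
#' opinions X(0) ~ Unif(0, 1), the deterministic DeGroot trajectory over
#' `n_steps` time steps, and ordinal observation of every latent opinion on
#' an `n_bins`-point scale via [back_transform()]. The whole dataset is a
#' pure function of `seed`.
#'
#' @inheritParams simulate_network
#' @param n_steps Number of observed time steps T >= 2.
#' @param n_bins Number of points of the ordinal scale (>= 2).
#' @inheritParams simulate_weight_matrix
#' @param seed Integer seed; `NULL` leaves the RNG state untouched.
#' @return An object of class `"degroot_sim"`: a list with `adjacency`,
#'   `weights` (the ground truth), `latent` (continuous panel tibble),
#'   `observed` (ordinal panel tibble) and `spec` (the generator settings).
#' @examples
#' sim <- simulate_diffusion(4, 2, n_steps = 3, n_bins = 5, seed = 42)
#' sim$observed
#' @export
simulate_diffusion <- function(n_agents, mean_degree, n_steps, n_bins,
                               self_weight_mean = 0.5, kappa = 4,
                               seed = NULL) {
  if (n_steps < 2) stop("`n_steps` must be >= 2", call. = FALSE)
  n_bins <- check_n_bins(n_bins)
  if (n_bins < 2) stop("`n_bins` must be >= 2", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  A <- simulate_network(n_agents, mean_degree)
  W <- simulate_weight_matrix(A, self_weight_mean, kappa)
  x0 <- runif(n_agents)
  latent <- degroot_trajectory(W, x0, n_steps)
  Xm <- panel_matrix(latent)
  Ym <- matrix(back_transform(as.vector(Xm), n_bins), nrow(Xm), ncol(Xm))
  colnames(Ym) <- colnames(Xm)
  structure(list(
    adjacency = A,
    weights = W,
    latent = latent,
    observed = as_opinion_panel(Ym),
    spec = list(n_agents = n_agents, mean_degree = mean_degree,
                n_steps = n_steps, n_bins = n_bins,
                self_weight_mean = self_weight_mean, kappa = kappa,
                seed = seed)
  ), class = "degroot_sim")
}

#' @export
print.degroot_sim <- function(x, ...) {
  s <- x$spec
  cat("<degroot_sim>\n")
  cat(sprintf("  %d agents, mean degree %g, %d time steps, %d-point scale\n",
              s$n_agents, s$mean_degree, s$n_steps, s$n_bins))
  cat("  observed ordinal panel:\n")
  print(x$observed)
  invisible(x)
}

#' Write a simulated dataset to plain-text files
#'
#' Emits `adjacency.csv`, `weights.csv` (ground truth), `latent.csv`,
#' `observed.csv` and `spec.json` into `dir`.
#'
#' @param sim A `"degroot_sim"` object.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_weight_matrix(sim$adjacency, file.path(dir, "adjacency.csv"))
  write_weight_matrix(sim$weights, file.path(dir, "weights.csv"))
  write.csv(as.data.frame(panel_matrix(sim$latent)),
            file.path(dir, "latent.csv"), row.names = FALSE)
  write.csv(as.data.frame(panel_matrix(sim$observed)),
            file.path(dir, "observed.csv"), row.names = FALSE)
  jsonlite::write_json(sim$spec, file.path(dir, "spec.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(dir)
}
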