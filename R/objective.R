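#' Predicted opinion trajectory under a candidate weight matrix
#'
#' Seeds the prediction at the observed initial opinions and free-runs the
#' DeGroot update: `X^(0) = X(0)`, `X^(t+1) = W X^(t)`. The observed panel is
#' the forward-transformed ordinal panel (bin centres).
#'
#' @inheritParams degroot_step
#' @param observed Continuous observed panel: a panel tibble (see
#'   [as_opinion_panel()]) or T x N matrix of values in \[0, 1\].
#' @return A panel tibble of predicted opinions, same shape as `observed`.
#' @export
predict_opinions <- function(W, observed, adjacency = NULL) {
  X <- panel_matrix(observed)
  W <- as.matrix(W)
  if (ncol(X) != nrow(W))
    stop("observed panel and `W` disagree on the number of agents",
         call. = FALSE)
  traj <- degroot_trajectory(W, X[1, ], nrow(X), adjacency)
  out <- panel_matrix(traj)
  colnames(out) <- colnames(X)
  as_opinion_panel(out)
}

#' Objective function: bin-weighted deviation of predicted from observed
#'
#' The fitness of a candidate weight matrix is
#' `sum_i sum_t B(x^_i(t), x_i(t)) * |x^_i(t) - x_i(t)|`, where `B` is the
#' deviation in bins ([bin_deviation()]) and `x^` is the free-run prediction
#' of [predict_opinions()]. Continuous deviation is penalised only when the
#' prediction lands in the wrong bin, so the objective is zero exactly when
#' every predicted opinion matches the observed opinion on the ordinal
#' scale. The per-agent summands (`per_gene`) drive the gene-swapping
#' operator; they add up to `total` by construction.
#'
#' @inheritParams predict_opinions
#' @param n_bins Number of points of the ordinal scale.
#' @return `chromosome_fitness()`: a list with `total` (non-negative scalar)
#'   and `per_gene` (length-N vector of per-agent contributions).
#' @examples
#' A <- matrix(1, 2, 2)
#' Y <- rbind(c(4, 4), c(2, 4))       # ordinal panel, 5-point scale
#' X <- forward_transform(Y, 5)
#' chromosome_fitness(diag(2), X, 5)  # total 0.8, per agent c(0.8, 0)
#' @export
chromosome_fitness <- function(W, observed, n_bins, adjacency = NULL) {
  n_bins <- check_n_bins(n_bins)
  W <- as.matrix(W)
  stop_if_invalid_weights(W, adjacency)
  X <- panel_matrix(observed)
  if (ncol(X) != nrow(W))
    stop("observed panel and `W` disagree on the number of agents",
         call. = FALSE)
  f <- cpp_fitness(W, X, n_bins)
  list(total = f$total, per_gene = as.numeric(f$per_gene))
}

#' Per-agent (gene-level) fitness
#'
#' The contribution of one agent to the objective, evaluated against a
#' chromosome's own full predicted trajectory: a gene's fitness depends on
#' the other genes through the predictions, but is summed for a single
#' agent.
#'
#' @param predicted Predicted continuous panel (from [predict_opinions()]).
#' @inheritParams chromosome_fitness
#' @param agent Agent index in `1:N`.
#' @return Non-negative scalar.
#' @export
gene_fitness <- function(predicted, observed, n_bins, agent) {
  n_bins <- check_n_bins(n_bins)
  Xh <- panel_matrix(predicted)
  X <- panel_matrix(observed)
  if (!all(dim(Xh) == dim(X)))
    stop("predicted and observed panels must have the same shape",
         call. = FALSE)
  if (length(agent) != 1 || agent < 1 || agent > ncol(X))
    stop("`agent` must be a single index in 1..", ncol(X), call. = FALSE)
  B <- abs(back_transform(Xh[, agent], n_bins) -
             back_transform(X[, agent], n_bins))
  sum(B * abs(Xh[, agent] - X[, agent]))
}
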