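#' Parameter-recovery RMSE between true and estimated weight matrices
#'
#' The root-mean-square difference over the P positions not fixed at zero by
#' the adjacency structure (self-links included):
#' `sqrt(sum_{a_ij = 1} (w_ij - w^_ij)^2 / P)`.
#'
#' @param w_true,w_hat Weight matrices respecting the structural zeros of
#'   `adjacency`.
#' @param adjacency Binary adjacency matrix with self-links.
#' @return Non-negative scalar RMSE.
#' @examples
#' A <- matrix(1, 2, 2)
#' recovery_rmse(matrix(0.5, 2, 2),
#'               matrix(c(0.6, 0.5, 0.4, 0.5), 2), A) # sqrt(0.02 / 4)
#' @export
recovery_rmse <- function(w_true, w_hat, adjacency) {
  A <- check_adjacency(adjacency, quiet = TRUE)
  w_true <- as.matrix(w_true)
  w_hat <- as.matrix(w_hat)
  if (!all(dim(w_true) == dim(A)) || !all(dim(w_hat) == dim(A)))
    stop("matrix dimensions do not match the adjacency matrix",
         call. = FALSE)
  if (any(w_true[A == 0] != 0) || any(w_hat[A == 0] != 0))
    stop("structural zeros violated", call. = FALSE)
  keep <- A == 1
  sqrt(sum((w_true[keep] - w_hat[keep])^2) / sum(keep))
}

#' Factorial design of the hyperparameter calibration study
#'
#' Builds the full crossed grid of network, data and hyperparameter factors
#' used to calibrate the algorithm, dropping infeasible cells (target mean
#' degree >= network size) with a message. Each row is one design cell,
#' identified by `cell_id` (stable across subsetting, so subsampled studies
#' remain reproducible and resumable).
#'
#' @param n_agents,mean_degree,n_steps,n_bins Network and data factors.
#' @param chromosomes Population sizes.
#' @param prob_sigma,min_max,mult_factor Grouped hyperparameter levels (see
#'   [ga_control()]).
#' @param iter Stagnation-threshold levels, applied to all five `iter*`
#'   hyperparameters within a run.
#' @return A tibble of feasible design cells with a `cell_id` column.
#' @export
study_design <- function(n_agents = c(4, 20, 50),
                         mean_degree = c(2, 5, 9),
                         n_steps = c(2, 3, 6),
                         n_bins = c(5, 7, 10, 20, 30),
                         chromosomes = c(5, 21, 51, 99),
                         prob_sigma = c("low", "medium", "high"),
                         min_max = c("minimal", "moderate", "extreme"),
                         mult_factor = c("slow", "moderate", "rapid"),
                         iter = c(200, 1000, 5000)) {
  grid <- tidyr::expand_grid(
    n_agents = n_agents, mean_degree = mean_degree, n_steps = n_steps,
    n_bins = n_bins, chromosomes = chromosomes, prob_sigma = prob_sigma,
    min_max = min_max, mult_factor = mult_factor, iter = iter)
  grid <- dplyr::mutate(grid, cell_id = dplyr::row_number())
  feasible <- grid$mean_degree < grid$n_agents
  if (any(!feasible))
    message(sum(!feasible), " infeasible cells dropped (mean degree >= ",
            "network size)")
  dplyr::relocate(grid[feasible, ], "cell_id")
}

# deterministic per-run seeds below 2^31, distinct for the dataset draw and
# the GA run
run_seed <- function(base_seed, cell_id, replicate, component) {
  (base_seed * 2654435.0 + cell_id * 97003.0 + replicate * 101.0 +
     component) %% 2147483629 + 1
}

#' Run all replicates of one design cell
#'
#' For each replicate a fresh synthetic dataset (new network, weight matrix
#' and opinions) is generated and the GA run with the cell's
#' hyperparameters; seeds are derived deterministically from `base_seed`,
#' the cell id and the replicate. A failed replicate is recorded (with an
#' `error` message) rather than aborting the cell.
#'
#' @param cell One-row data frame from [study_design()].
#' @param replicates Number of runs of the cell.
#' @param base_seed Integer base seed of the study.
#' @param max_iter Generation cap.
#' @return A tibble with one row per replicate: the design factors plus
#'   `replicate`, `seed`, `objective`, `solved`, `generations`, `blocks`,
#'   `seconds`, `rmse`.
#' @export
run_cell <- function(cell, replicates = 10, base_seed = 1,
                     max_iter = 100000) {
  cell <- as.list(cell)
  ctrl <- ga_control(chromosomes = cell$chromosomes,
                     prob_sigma = cell$prob_sigma,
                     min_max = cell$min_max,
                     mult_factor = cell$mult_factor,
                     iter = cell$iter,
                     max_iter = max_iter)
  purrr::map_dfr(seq_len(replicates), function(r) {
    sim_seed <- run_seed(base_seed, cell$cell_id, r, 1)
    fit_seed <- run_seed(base_seed, cell$cell_id, r, 2)
    rec <- tibble::tibble(
      cell_id = cell$cell_id, n_agents = cell$n_agents,
      mean_degree = cell$mean_degree, n_steps = cell$n_steps,
      n_bins = cell$n_bins, chromosomes = cell$chromosomes,
      prob_sigma = cell$prob_sigma, min_max = cell$min_max,
      mult_factor = cell$mult_factor, iter = cell$iter,
      replicate = r, seed = fit_seed)
    out <- tryCatch({
      sim <- simulate_diffusion(cell$n_agents, cell$mean_degree,
                                cell$n_steps, cell$n_bins, seed = sim_seed)
      fit <- fit_degroot(sim$observed, sim$adjacency, cell$n_bins,
                         control = ctrl, seed = fit_seed,
                         record_history = FALSE)
      tibble::tibble(
        objective = fit$fitness$total, solved = fit$solved,
        generations = fit$generations,
        blocks = ceiling(fit$generations / 1000),
        seconds = sum(fit$block_times),
        rmse = recovery_rmse(sim$weights, fit$weights, sim$adjacency),
        error = NA_character_)
    }, error = function(e) {
      tibble::tibble(objective = NA_real_, solved = NA,
                     generations = NA_integer_, blocks = NA_real_,
                     seconds = NA_real_, rmse = NA_real_,
                     error = conditionMessage(e))
    })
    dplyr::bind_cols(rec, out)
  })
}

#' Run the calibration study
#'
#' Iterates the feasible design cells -- optionally a seeded uniform
#' subsample of them -- running [run_cell()] for each, and returns (and
#' optionally writes) the concatenated run records. When `out` names an
#' existing CSV, cells already present in it are skipped and the new
#' records appended, so an interrupted study can resume. The full results
#' table is a pure function of the design, `replicates`, `subsample`,
#' `max_iter` and `base_seed`.
#'
#' @param design Tibble from [study_design()].
#' @param replicates Runs per cell.
#' @param subsample Fraction of cells to run (uniform, seeded by
#'   `base_seed`); 1 runs the full design.
#' @param max_iter Generation cap per run.
#' @param base_seed Integer base seed.
#' @param out Optional path of a CSV to write/resume.
#' @param progress Print a line per cell?
#' @return A tibble of run records (see [run_cell()]).
#' @export
run_study <- function(design, replicates = 10, subsample = 1,
                      max_iter = 100000, base_seed = 1, out = NULL,
                      progress = FALSE) {
  stopifnot_msg(subsample > 0 && subsample <= 1,
                "`subsample` must lie in (0, 1]")
  cells <- design
  if (subsample < 1) {
    set.seed(base_seed)
    keep <- sort(sample(nrow(cells), max(1, round(subsample * nrow(cells)))))
    cells <- cells[keep, ]
  }
  done <- NULL
  if (!is.null(out) && file.exists(out)) {
    done <- tibble::as_tibble(read.csv(out))
    cells <- cells[!(cells$cell_id %in% done$cell_id), ]
  }
  records <- vector("list", nrow(cells))
  for (q in seq_len(nrow(cells))) {
    if (progress)
      message("cell ", cells$cell_id[q], " (", q, "/", nrow(cells), ")")
    records[[q]] <- run_cell(cells[q, ], replicates, base_seed, max_iter)
    if (!is.null(out)) {
      all_so_far <- dplyr::bind_rows(done, dplyr::bind_rows(records))
      write.csv(all_so_far, out, row.names = FALSE)
    }
  }
  dplyr::bind_rows(done, dplyr::bind_rows(records))
}

#' Summarise a calibration-study results table
#'
#' Computes the study's headline aggregates as one tidy tibble with a row
#' per (grouping, level): the overall proportion of runs solving within the
#' first 1000 generations and the proportion still unsolved at the
#' generation cap, plus recovery-RMSE summaries grouped by stagnation
#' threshold (`iter`), initial control parameters (`prob_sigma`), number of
#' time steps and number of chromosomes, and generation/time summaries by
#' number of chromosomes.
#'
#' @param results Run-record tibble from [run_study()].
#' @return A tibble with columns `grouping`, `level`, `n_runs`,
#'   `prop_solved_1000`, `prop_unsolved`, `mean_rmse`, `median_rmse`,
#'   `mean_generations`, `median_generations`, `median_seconds`.
#' @export
summarize_study <- function(results) {
  if (is.null(results) || nrow(results) == 0)
    stop("`results` is empty", call. = FALSE)
  ok <- dplyr::filter(results, is.na(.data$error) | .data$error == "")
  summarise_group <- function(df, grouping, level_col) {
    df <- dplyr::group_by(df, level = as.character({{ level_col }}))
    out <- dplyr::summarise(
      df,
      n_runs = dplyr::n(),
      prop_solved_1000 = mean(.data$solved & .data$generations <= 1000),
      prop_unsolved = mean(!.data$solved),
      mean_rmse = mean(.data$rmse),
      median_rmse = stats::median(.data$rmse),
      mean_generations = mean(.data$generations),
      median_generations = stats::median(.data$generations),
      median_seconds = stats::median(.data$seconds),
      .groups = "drop")
    dplyr::bind_cols(tibble::tibble(grouping = rep(grouping, nrow(out))),
                     out)
  }
  dplyr::bind_rows(
    summarise_group(dplyr::mutate(ok, all = "all"), "overall", .data$all),
    summarise_group(ok, "iter", .data$iter),
    summarise_group(ok, "prob_sigma", .data$prob_sigma),
    summarise_group(ok, "n_steps", .data$n_steps),
    summarise_group(ok, "chromosomes", .data$chromosomes)
  )
}

#' Diagnostic plot of calibration-study recovery
#'
#' Boxplots of parameter-recovery RMSE by a chosen design factor.
#'
#' @param results Run-record tibble from [run_study()].
#' @param by Factor column to group by (default `"iter"`).
#' @return A ggplot object.
#' @export
plot_study_rmse <- function(results, by = "iter") {
  ggplot2::ggplot(results,
                  ggplot2::aes(x = factor(.data[[by]]), y = .data$rmse)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = by, y = "recovery RMSE")
}
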