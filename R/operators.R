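#' Initialize a GA population of weight matrices
#'
#' Builds `chromosomes - 1` random chromosomes plus one identity matrix. For
#' each random chromosome an N x N matrix of Unif(0, 1) draws is generated
#' (column-major, one matrix per chromosome), non-evolvable positions are
#' zeroed, and each row is rescaled so its evolvable weights sum to
#' `1 - w_fixed` (the total fixed weight of the row). The identity matrix
#' places the whole evolvable mass of each row on the diagonal.
#'
#' @param adjacency Binary symmetric adjacency matrix with self-links
#'   (missing self-links are added).
#' @param chromosomes Odd population size >= 3.
#' @param fixed Optional fixed-value matrix (`NA` = evolvable), see
#'   [validate_weight_matrix()].
#' @return A list of `chromosomes` weight matrices (identity last).
#' @export
initialize_population <- function(adjacency, chromosomes = 21, fixed = NULL) {
  if (chromosomes < 3 || chromosomes %% 2 == 0)
    stop("`chromosomes` must be an odd integer >= 3", call. = FALSE)
  st <- weight_structure(adjacency, fixed)
  N <- nrow(st$adjacency)
  pop <- vector("list", chromosomes)
  for (c in seq_len(chromosomes - 1)) {
    U <- matrix(runif(N * N), N, N)
    U[st$free == 0] <- 0
    s <- rowSums(U)
    W <- st$fixed_values
    scale <- ifelse(s > 0, (1 - st$wfix) / s, 0)
    W <- W + U * scale
    pop[[c]] <- W
  }
  pop[[chromosomes]] <- identity_chromosome(st)
  pop
}

identity_chromosome <- function(st) {
  N <- nrow(st$adjacency)
  W <- st$fixed_values
  if (any(st$free[cbind(1:N, 1:N)] == 0 & st$wfix < 1 - 1e-12))
    stop("identity chromosome requires evolvable diagonal entries",
         call. = FALSE)
  W[cbind(1:N, 1:N)] <- W[cbind(1:N, 1:N)] + (1 - st$wfix)
  W
}

#' Selection with elitism and gene swapping
#'
#' Identifies the fittest chromosome (lowest objective, ties to the lowest
#' index), then attempts [gene_swap()] between it and the remaining
#' population. The (possibly row-swapped) elite is exempted from the
#' remaining operators of the generation.
#'
#' @param population List of weight matrices.
#' @param observed Continuous observed panel (bin centres).
#' @param n_bins Number of ordinal scale points.
#' @return A list with `elite` (weight matrix), `rest` (even-sized list),
#'   `swap_accepted` (logical) and `fitness` (elite total).
#' @export
select_elite <- function(population, observed, n_bins) {
  n_bins <- check_n_bins(n_bins)
  X <- panel_matrix(observed)
  tot <- vapply(population, function(W) cpp_fitness(W, X, n_bins)$total,
                numeric(1))
  ei <- which.min(tot)
  sw <- gene_swap(population[[ei]], population[-ei], observed, n_bins)
  list(elite = sw$best, rest = sw$donors, swap_accepted = sw$accepted,
       fitness = sw$total)
}

#' Gene swapping between a best chromosome and donor chromosomes
#'
#' For each gene (row) position, the donor gene with the strictly lowest
#' per-agent fitness -- evaluated within its own chromosome's predicted
#' trajectory -- is identified; every position where a donor gene beats the
#' best chromosome's gene is exchanged simultaneously. The modified best
#' chromosome is re-evaluated: if its total objective strictly improved, all
#' swaps are kept (the contributing donors receive the replaced rows),
#' otherwise everything reverts.
#'
#' @param best Weight matrix of the current best chromosome.
#' @param donors List of donor weight matrices.
#' @inheritParams select_elite
#' @return A list with `best`, `donors`, `accepted`, `total`, `per_gene`.
#' @export
gene_swap <- function(best, donors, observed, n_bins) {
  n_bins <- check_n_bins(n_bins)
  X <- panel_matrix(observed)
  res <- cpp_gene_swap(as.matrix(best), lapply(donors, as.matrix), X, n_bins)
  res$per_gene <- as.numeric(res$per_gene)
  res
}

#' Blending operator
#'
#' For each gene (row) independently with probability `p_b`, a blending
#' factor beta ~ Unif(0, 1) is drawn and the paired rows are replaced by
#' their convex combinations `beta * B_i + (1 - beta) * C_i` and
#' `(1 - beta) * B_i + beta * C_i`. Row sums and fixed values are preserved
#' exactly. Draw order per row: one uniform coin, then (only if blending
#' fires) one uniform beta.
#'
#' @param B,C Weight matrices sharing adjacency/fixed structure.
#' @param p_b Blending probability in \[0, 1\].
#' @return A list with the two blended matrices `B` and `C`.
#' @export
blend_pair <- function(B, C, p_b) {
  B <- as.matrix(B); C <- as.matrix(C)
  if (!all(dim(B) == dim(C)))
    stop("`B` and `C` must have the same dimensions", call. = FALSE)
  cpp_blend_pair(B, C, p_b)
}

#' Crossover operator
#'
#' For each gene (row) independently with probability `p_c`, the evolvable
#' weight values of the row are uniformly reshuffled among the evolvable
#' positions (Fisher-Yates), preserving the sum-to-one constraint and all
#' fixed values. Rows with fewer than two evolvable positions are
#' unchanged.
#'
#' @param W Weight matrix.
#' @param p_c Crossover probability in \[0, 1\].
#' @inheritParams initialize_population
#' @return The (possibly) recombined weight matrix.
#' @export
crossover <- function(W, p_c, adjacency, fixed = NULL) {
  st <- weight_structure(adjacency, fixed)
  cpp_crossover(as.matrix(W), p_c, st$free)
}

#' Mutation operator
#'
#' For each gene (row) independently with probability `p_m`, one evolvable
#' weight is selected uniformly and perturbed by epsilon ~ Normal(0,
#' sigma^2). Boundary rules: a perturbed weight below 0 is clamped to 0; one
#' above `1 - w_fixed` is clamped to `1 - w_fixed` with all other evolvable
#' weights in the row set to 0 (an edge-case solution); if the selected
#' weight held the entire evolvable mass, the excess is distributed evenly
#' over the other evolvable positions; otherwise the other evolvable weights
#' are rescaled multiplicatively so the row sums to one again. Rows with
#' fewer than two evolvable positions are skipped. Draw order per row: one
#' uniform coin, then (if mutation fires on a mutable row) one uniform
#' position draw and one normal epsilon.
#'
#' @inheritParams crossover
#' @param p_m Mutation probability in \[0, 1\].
#' @param sigma Mutation noise standard deviation.
#' @return The (possibly) mutated weight matrix.
#' @export
mutate <- function(W, p_m, sigma, adjacency, fixed = NULL) {
  st <- weight_structure(adjacency, fixed)
  cpp_mutate(as.matrix(W), p_m, sigma, st$free, st$fixed_values)
}

#' Survival operator
#'
#' Pairs parent and offspring chromosomes by position index. Within each
#' pair the fitter chromosome (ties to the parent, the incumbent) attempts
#' [gene_swap()] with the other chromosome as sole donor, and the (possibly
#' improved) fitter chromosome survives.
#'
#' @param parents,offspring Lists of weight matrices of equal length.
#' @inheritParams select_elite
#' @return A list of surviving weight matrices, same length as `parents`.
#' @export
survive <- function(parents, offspring, observed, n_bins) {
  if (length(parents) != length(offspring))
    stop("`parents` and `offspring` must have the same length", call. = FALSE)
  n_bins <- check_n_bins(n_bins)
  X <- panel_matrix(observed)
  out <- vector("list", length(parents))
  for (j in seq_along(parents)) {
    fp <- cpp_fitness(as.matrix(parents[[j]]), X, n_bins)$total
    fo <- cpp_fitness(as.matrix(offspring[[j]]), X, n_bins)$total
    if (fp <= fo) {
      sw <- cpp_gene_swap(as.matrix(parents[[j]]),
                          list(as.matrix(offspring[[j]])), X, n_bins)
    } else {
      sw <- cpp_gene_swap(as.matrix(offspring[[j]]),
                          list(as.matrix(parents[[j]])), X, n_bins)
    }
    out[[j]] <- sw$best
  }
  out
}

#' Adapt control parameters during stagnation
#'
#' Applies the multiplicative adjustment to each control parameter whose
#' stagnation threshold divides the current stagnation count: the blending
#' probability grows (`p_b <- min(factorb * p_b, maxb)`) while the crossover
#' and mutation probabilities and the mutation noise SD shrink towards their
#' lower bounds. A stagnation count of 0 leaves everything unchanged.
#'
#' @param controls Named list or vector with `p_b`, `p_c`, `p_m`, `sigma`.
#' @param control A [ga_control()] object supplying factors, bounds and
#'   thresholds.
#' @param stagnation Number of consecutive generations without improvement.
#' @return Updated named list of control parameters.
#' @export
adapt_controls <- function(controls, control, stagnation) {
  stopifnot_msg(stagnation >= 0, "`stagnation` must be >= 0")
  ct <- as.list(controls)
  hp <- control
  fires <- function(thr) stagnation > 0 && stagnation %% thr == 0
  if (fires(hp$iterb)) ct$p_b <- min(hp$factorb * ct$p_b, hp$maxb)
  if (fires(hp$iterc)) ct$p_c <- max(hp$factorc * ct$p_c, hp$minc)
  if (fires(hp$iterm)) ct$p_m <- max(hp$factorm * ct$p_m, hp$minm)
  if (fires(hp$iters)) ct$sigma <- max(hp$factors * ct$sigma, hp$mins)
  ct
}

#' Reintroduce a chromosome during stagnation
#'
#' Replaces the least fit chromosome of the (non-elite) population with a
#' clone of the elite chromosome (`mode = "elite"`, nudging the search
#' towards exploitation) or with an identity matrix (`mode = "identity"`,
#' reasserting a prior of self-reliant agents). Worst-fitness ties are
#' broken towards the highest index.
#'
#' @inheritParams select_elite
#' @param elite Elite weight matrix.
#' @param mode `"elite"` or `"identity"`.
#' @inheritParams initialize_population
#' @return The population list with one chromosome replaced.
#' @export
reintroduce_chromosome <- function(population, elite, mode = c("elite",
                                                               "identity"),
                                   observed, n_bins, adjacency = NULL,
                                   fixed = NULL) {
  mode <- match.arg(mode)
  n_bins <- check_n_bins(n_bins)
  X <- panel_matrix(observed)
  tot <- vapply(population, function(W) cpp_fitness(as.matrix(W), X,
                                                    n_bins)$total,
                numeric(1))
  worst <- max(which(tot == max(tot)))
  population[[worst]] <- if (mode == "elite") {
    as.matrix(elite)
  } else {
    if (is.null(adjacency))
      stop("`adjacency` is required for identity reintroduction",
           call. = FALSE)
    identity_chromosome(weight_structure(adjacency, fixed))
  }
  population
}
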