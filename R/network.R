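#' Opinion panels as tibbles
#'
#' Opinion panels (observed ordinal opinions or continuous opinions /
#' trajectories) travel as wide tibbles: a `time` column counting time steps
#' from 0, plus one column per agent. `as_opinion_panel()` builds such a
#' tibble from a T x N matrix; `panel_matrix()` recovers the T x N matrix
#' (dropping the `time` column) from a panel tibble, a data frame or a
#' matrix.
#'
#' @param x A T x N matrix (rows = time steps 0..T-1, columns = agents), or
#'   for `panel_matrix()` a panel tibble/data frame.
#' @param agents Optional character vector of agent labels; defaults to the
#'   matrix column names or `agent_1..agent_N`.
#' @return `as_opinion_panel()` a tibble with columns `time`, agents;
#'   `panel_matrix()` a numeric matrix.
#' @export
as_opinion_panel <- function(x, agents = NULL) {
  x <- as.matrix(x)
  if (is.null(agents)) agents <- colnames(x)
  if (is.null(agents)) agents <- paste0("agent_", seq_len(ncol(x)))
  colnames(x) <- agents
  tibble::as_tibble(cbind(data.frame(time = seq_len(nrow(x)) - 1L),
                          as.data.frame(x)))
}

#' @rdname as_opinion_panel
#' @export
panel_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  x <- as.data.frame(x)
  x$time <- NULL
  as.matrix(x)
}

#' One DeGroot opinion update
#'
#' Applies the DeGroot diffusion update `x(t+1) = W x(t)`: each agent's new
#' opinion is the convex combination of current opinions weighted by the
#' agent's row of the influence-weight matrix `W`. Because rows of `W` are
#' non-negative and sum to one, the output stays within the range of the
#' input opinions.
#'
#' @param W Row-stochastic N x N weight matrix.
#' @param x Numeric vector of N opinions in \[0, 1\].
#' @param adjacency Optional binary adjacency matrix; if supplied, `W` is
#'   additionally checked against its structural zeros.
#' @return Numeric vector of N updated opinions.
#' @examples
#' W <- matrix(c(0.5, 0.25, 0.5, 0.75), 2)
#' degroot_step(W, c(0, 1)) # c(0.5, 0.75)
#' @export
degroot_step <- function(W, x, adjacency = NULL) {
  W <- as.matrix(W)
  if (length(x) != nrow(W) || nrow(W) != ncol(W))
    stop("`x` must have one opinion per row of the square matrix `W`",
         call. = FALSE)
  stop_if_invalid_weights(W, adjacency)
  as.numeric(W %*% x)
}

#' DeGroot trajectory over several time steps
#'
#' Iterates [degroot_step()] from initial opinions `x0`, returning the panel
#' `(X(0), ..., X(n_steps - 1))` as a wide tibble (see [as_opinion_panel()]).
#' Row `time = 0` is `x0` itself, so `n_steps = 1` performs no update.
#'
#' @inheritParams degroot_step
#' @param x0 Numeric vector of initial opinions in \[0, 1\].
#' @param n_steps Number of observed time steps T >= 1 (including time 0).
#' @return A panel tibble with `n_steps` rows.
#' @export
degroot_trajectory <- function(W, x0, n_steps, adjacency = NULL) {
  if (length(n_steps) != 1 || !is.finite(n_steps) || n_steps < 1 ||
      n_steps != floor(n_steps))
    stop("`n_steps` must be a single integer >= 1", call. = FALSE)
  W <- as.matrix(W)
  if (length(x0) != nrow(W) || nrow(W) != ncol(W))
    stop("`x0` must have one opinion per row of the square matrix `W`",
         call. = FALSE)
  stop_if_invalid_weights(W, adjacency)
  out <- matrix(NA_real_, n_steps, length(x0))
  out[1, ] <- x0
  if (n_steps > 1) {
    for (t in 2:n_steps) out[t, ] <- as.numeric(W %*% out[t - 1, ])
  }
  as_opinion_panel(out, agents = colnames(W))
}

#' Check a weight matrix against its constraints
#'
#' Reports every violated constraint of an influence-weight matrix: rows must
#' sum to one (within `tol`), entries must lie in \[0, 1\], entries must be 0
#' wherever the adjacency matrix has no link (structural zeros), and
#' user-fixed entries must hold their fixed values exactly.
#'
#' @inheritParams degroot_step
#' @param fixed Optional N x N numeric matrix with `NA` at evolvable
#'   positions and fixed values elsewhere (structural zeros need not be
#'   listed; they are implied by `adjacency`).
#' @param tol Row-sum tolerance (default 1e-9).
#' @return A tibble with columns `constraint`, `row`, `col`, `value`; zero
#'   rows if and only if `W` is valid.
#' @export
validate_weight_matrix <- function(W, adjacency = NULL, fixed = NULL,
                                   tol = 1e-9) {
  W <- as.matrix(W)
  N <- nrow(W)
  if (ncol(W) != N) stop("`W` must be square", call. = FALSE)
  bad <- list()
  note <- function(constraint, row, col, value) {
    bad[[length(bad) + 1]] <<- tibble::tibble(
      constraint = constraint, row = as.integer(unname(row)),
      col = as.integer(unname(col)), value = as.numeric(unname(value)))
  }
  rs <- rowSums(W)
  for (i in which(abs(rs - 1) > tol))
    note("row_sum", i, NA_integer_, rs[i])
  oob <- which(W < 0 | W > 1, arr.ind = TRUE)
  for (q in seq_len(nrow(oob)))
    note("range", oob[q, 1], oob[q, 2], W[oob[q, 1], oob[q, 2]])
  if (!is.null(adjacency)) {
    A <- check_adjacency(adjacency, quiet = TRUE)
    if (nrow(A) != N) stop("adjacency dimensions do not match `W`",
                           call. = FALSE)
    sz <- which(A == 0 & W != 0, arr.ind = TRUE)
    for (q in seq_len(nrow(sz)))
      note("structural_zero", sz[q, 1], sz[q, 2], W[sz[q, 1], sz[q, 2]])
  }
  if (!is.null(fixed)) {
    fixed <- as.matrix(fixed)
    fx <- which(!is.na(fixed) & fixed != W, arr.ind = TRUE)
    for (q in seq_len(nrow(fx)))
      note("fixed_value", fx[q, 1], fx[q, 2], W[fx[q, 1], fx[q, 2]])
  }
  if (length(bad) == 0)
    tibble::tibble(constraint = character(), row = integer(),
                   col = integer(), value = numeric())
  else
    dplyr::bind_rows(bad)
}

# error when W violates row-sum/range (and structural zeros, if A given)
stop_if_invalid_weights <- function(W, adjacency = NULL, tol = 1e-9) {
  rep <- validate_weight_matrix(W, adjacency, tol = tol)
  if (nrow(rep) > 0)
    stop("invalid weight matrix: ",
         paste(unique(rep$constraint), collapse = ", "),
         " constraint violated", call. = FALSE)
  invisible(W)
}

#' Read and write network matrices as CSV
#'
#' `read_adjacency()` reads a square 0/1 CSV (optional header row of agent
#' labels), checks symmetry and binariness, and adds missing self-links with
#' a warning (every agent is assumed to weigh their own current opinion).
#' `read_weight_matrix()`/`write_weight_matrix()` do the same for real-valued
#' weight matrices, and `read_opinion_panel()` reads a T x N integer panel of
#' ordinal opinions.
#'
#' @param path Path to a CSV file.
#' @param header Does the file carry a header row of agent labels?
#' @return A matrix (`read_adjacency()`, `read_weight_matrix()`) or a panel
#'   tibble (`read_opinion_panel()`).
#' @export
read_adjacency <- function(path, header = NA) {
  m <- read_square_csv(path, header)
  check_adjacency(m)
}

#' @rdname read_adjacency
#' @export
read_weight_matrix <- function(path, header = NA) {
  read_square_csv(path, header)
}

#' @rdname read_adjacency
#' @param W Weight matrix to write.
#' @export
write_weight_matrix <- function(W, path) {
  write.csv(as.data.frame(as.matrix(W)), path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_adjacency
#' @export
read_opinion_panel <- function(path, header = NA) {
  first <- readLines(path, n = 1)
  has_header <- if (is.na(header)) grepl("[A-Za-z]", first) else header
  d <- read.csv(path, header = has_header)
  m <- as.matrix(d)
  if (any(!is.finite(m)) || any(m != floor(m)))
    stop("opinion panel must contain integers", call. = FALSE)
  as_opinion_panel(m, agents = if (has_header) colnames(d) else NULL)
}

read_square_csv <- function(path, header = NA) {
  first <- readLines(path, n = 1)
  has_header <- if (is.na(header)) grepl("[A-Za-z]", first) else header
  d <- read.csv(path, header = has_header)
  m <- as.matrix(d)
  if (nrow(m) != ncol(m))
    stop("expected a square matrix in ", path, call. = FALSE)
  dimnames(m) <- if (has_header) list(colnames(d), colnames(d)) else NULL
  storage.mode(m) <- "double"
  m
}

# validate/normalize an adjacency matrix: symmetric, binary, self-linked
check_adjacency <- function(A, quiet = FALSE) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) stop("adjacency matrix must be square",
                               call. = FALSE)
  if (any(!(A %in% c(0, 1))))
    stop("adjacency entries must be exactly 0 or 1", call. = FALSE)
  if (!isTRUE(all.equal(A, t(A), check.attributes = FALSE)))
    stop("adjacency matrix must be symmetric", call. = FALSE)
  if (any(diag(A) == 0)) {
    if (!quiet)
      warning("adding missing self-links (diagonal set to 1)", call. = FALSE)
    diag(A) <- 1
  }
  storage.mode(A) <- "double"
  A
}

# evolvable-position mask and fixed-value matrix from adjacency + user spec.
# fixed: NA = evolvable, value = fixed. Structural zeros are always fixed 0.
weight_structure <- function(adjacency, fixed = NULL) {
  A <- check_adjacency(adjacency, quiet = TRUE)
  N <- nrow(A)
  fixed_values <- matrix(0, N, N)
  free <- A == 1
  if (!is.null(fixed)) {
    fixed <- as.matrix(fixed)
    if (!all(dim(fixed) == N))
      stop("`fixed` dimensions must match the adjacency matrix",
           call. = FALSE)
    user <- !is.na(fixed)
    if (any(user & A == 0 & fixed != 0))
      stop("cannot fix a non-zero weight at a structural zero",
           call. = FALSE)
    free <- free & !user
    fixed_values[user] <- fixed[user]
  }
  wfix <- rowSums(fixed_values)
  if (any(wfix > 1 + 1e-9))
    stop("fixed weights in a row exceed 1", call. = FALSE)
  full <- rowSums(free) == 0
  if (any(full & abs(wfix - 1) > 1e-9))
    stop("a fully fixed row must have fixed values summing to 1",
         call. = FALSE)
  list(adjacency = A, free = free * 1, fixed_values = fixed_values,
       wfix = wfix)
}
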