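#' Ordinal / continuous opinion transformations
#'
#' Opinions measured on an `n_bins`-point ordinal scale are mapped to the
#' continuous interval \[0, 1\] and back by dividing \[0, 1\] into `n_bins`
#' equal-width sub-intervals ("bins"). `forward_transform()` sends ordinal
#' value `y` to the centre of the y-th bin, `(y - 0.5) / n_bins`;
#' `back_transform()` sends a continuous opinion `x` to `ceiling(n_bins * x)`,
#' with `x = 0` mapping to bin 1. Bins are therefore lower-exclusive: a value
#' exactly on a boundary (e.g. 0.6 with 5 bins) belongs to the lower bin.
#'
#' Continuous values a hair below 0 or above 1 (within 1e-12), as produced by
#' floating-point diffusion updates, are clamped to the interval before
#' transforming; anything further outside is an error.
#'
#' @param y Integer vector of ordinal opinions in `1:n_bins`.
#' @param x Numeric vector of continuous opinions in \[0, 1\].
#' @param n_bins Number of points of the ordinal scale (a single integer,
#'   at least 1).
#'
#' @return `forward_transform()` returns bin centres in (0, 1);
#'   `back_transform()` returns integer bin indices in `1:n_bins`.
#'
#' @examples
#' forward_transform(4, 5)        # 0.7, the centre of (0.6, 0.8]
#' back_transform(0.7, 5)         # 4
#' back_transform(0, 5)           # edge case: 1
#' @export
forward_transform <- function(y, n_bins) {
  n_bins <- check_n_bins(n_bins)
  if (length(y) == 0) return(numeric(0))
  if (any(!is.finite(y)) || any(y != floor(y)))
    stop("ordinal opinions must be integers", call. = FALSE)
  if (any(y < 1) || any(y > n_bins))
    stop("ordinal opinions must lie in 1..", n_bins, call. = FALSE)
  (y - 0.5) / n_bins
}

#' @rdname forward_transform
#' @export
back_transform <- function(x, n_bins) {
  n_bins <- check_n_bins(n_bins)
  if (length(x) == 0) return(integer(0))
  if (any(!is.finite(x)))
    stop("continuous opinions must be finite", call. = FALSE)
  x[x < 0 & x >= -1e-12] <- 0
  x[x > 1 & x <= 1 + 1e-12] <- 1
  if (any(x < 0) || any(x > 1))
    stop("continuous opinions must lie in [0, 1]", call. = FALSE)
  b <- as.integer(ceiling(x * n_bins))
  b[b < 1L] <- 1L
  b[b > n_bins] <- n_bins
  b
}

#' Deviation between two continuous opinions, measured in bins
#'
#' The absolute difference between the ordinal images of two continuous
#' opinions under [back_transform()]: the term weighting continuous deviations
#' in the model-fitting objective. It is symmetric and bounded by
#' `n_bins - 1`.
#'
#' @param x_hat,x Numeric vectors of continuous opinions in \[0, 1\].
#' @inheritParams forward_transform
#' @return Non-negative integer vector of bin deviations.
#' @examples
#' bin_deviation(0.3, 0.7, 5)   # |2 - 4| = 2
#' bin_deviation(0.61, 0.79, 5) # both in bin 4: 0
#' @export
bin_deviation <- function(x_hat, x, n_bins) {
  abs(back_transform(x_hat, n_bins) - back_transform(x, n_bins))
}

check_n_bins <- function(n_bins) {
  if (length(n_bins) != 1 || !is.finite(n_bins) || n_bins != floor(n_bins) ||
      n_bins < 1)
    stop("`n_bins` must be a single integer >= 1", call. = FALSE)
  as.integer(n_bins)
}
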