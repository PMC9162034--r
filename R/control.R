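#' Hyperparameter presets
#'
#' The grouped hyperparameter levels used throughout the calibration study:
#' `prob_sigma` sets the initial control parameters (blending, crossover and
#' mutation probabilities and the mutation noise SD sigma); `min_max` sets
#' the clamping bounds the adaptive adjustments may not cross; `mult_factor`
#' sets the multiplicative adjustment factors (blending grows, the others
#' shrink).
#'
#' @name ga_presets
#' @keywords internal
NULL

.prob_sigma_levels <- list(
  low    = list(probb = 0.01, probc = 0.05, probm = 0.05, sigma = 0.2),
  medium = list(probb = 0.10, probc = 0.10, probm = 0.10, sigma = 0.5),
  high   = list(probb = 0.20, probc = 0.20, probm = 0.20, sigma = 1.0)
)

.min_max_levels <- list(
  minimal  = list(maxb = 1.0, minc = 0.00, minm = 0.00, mins = 0.00),
  moderate = list(maxb = 0.5, minc = 0.01, minm = 0.01, mins = 0.01),
  extreme  = list(maxb = 0.2, minc = 0.05, minm = 0.05, mins = 0.05)
)

.mult_factor_levels <- list(
  slow     = list(factorb = 2,  factorc = 0.5, factorm = 0.5, factors = 0.5),
  moderate = list(factorb = 5,  factorc = 0.2, factorm = 0.2, factors = 0.2),
  rapid    = list(factorb = 10, factorc = 0.1, factorm = 0.1, factors = 0.1)
)

#' Genetic-algorithm hyperparameters
#'
#' Builds the full set of user-facing hyperparameters controlling the
#' adaptive GA. The grouped arguments `prob_sigma` (initial control
#' parameters), `min_max` (bounds) and `mult_factor` (adaptation factors)
#' expand named preset levels; `iter` sets all five stagnation thresholds
#' (`iterb`, `iterc`, `iterm`, `iters`, `iterr`) at once. Any individual
#' hyperparameter passed explicitly overrides its preset value.
#'
#' Defaults are the recommended starting configuration: 21 chromosomes,
#' `medium` initial control parameters, `moderate` bounds and factors, all
#' stagnation thresholds at 200 generations, a 100,000-generation cap,
#' stopping at a perfect ordinal solution (`min_dev = 0`, checked every 1000
#' generations), and reintroduction of an elite clone.
#'
#' @param chromosomes Odd population size >= 3.
#' @param prob_sigma `"low"`, `"medium"` or `"high"` initial control values.
#' @param min_max `"minimal"`, `"moderate"` or `"extreme"` clamping bounds.
#' @param mult_factor `"slow"`, `"moderate"` or `"rapid"` adjustment factors.
#' @param iter Stagnation threshold (generations without improvement) applied
#'   to all five `iter*` hyperparameters.
#' @param probb,probc,probm Initial blending / crossover / mutation
#'   probabilities.
#' @param sigma Initial mutation noise standard deviation.
#' @param factorb,factorc,factorm,factors Multiplicative adaptation factors
#'   (`factorb >= 1`; the others in (0, 1\]).
#' @param maxb,minc,minm,mins Clamping bounds for the adapted controls.
#' @param iterb,iterc,iterm,iters,iterr Individual stagnation thresholds.
#' @param max_iter Generation cap.
#' @param min_improve Minimum decrease of the elite objective that counts as
#'   improvement.
#' @param min_dev Objective value at or below which a run counts as solved.
#' @param reintroduce `"elite"` or `"identity"`: chromosome reintroduced
#'   after `iterr` stagnant generations.
#' @return A list of class `"ga_control"` with all hyperparameters.
#' @examples
#' ga_control()                              # recommended defaults
#' ga_control(prob_sigma = "high", iter = 1000)
#' ga_control(sigma = 0.3)                   # override one value
#' @export
ga_control <- function(chromosomes = 21,
                       prob_sigma = "medium",
                       min_max = "moderate",
                       mult_factor = "moderate",
                       iter = 200,
                       probb = NULL, probc = NULL, probm = NULL, sigma = NULL,
                       maxb = NULL, minc = NULL, minm = NULL, mins = NULL,
                       factorb = NULL, factorc = NULL, factorm = NULL,
                       factors = NULL,
                       iterb = NULL, iterc = NULL, iterm = NULL,
                       iters = NULL, iterr = NULL,
                       max_iter = 100000, min_improve = 0, min_dev = 0,
                       reintroduce = c("elite", "identity")) {
  ps <- .prob_sigma_levels[[match.arg(prob_sigma,
                                      names(.prob_sigma_levels))]]
  mm <- .min_max_levels[[match.arg(min_max, names(.min_max_levels))]]
  mf <- .mult_factor_levels[[match.arg(mult_factor,
                                       names(.mult_factor_levels))]]
  hp <- list(
    chromosomes = chromosomes,
    probb = probb %||% ps$probb, probc = probc %||% ps$probc,
    probm = probm %||% ps$probm, sigma = sigma %||% ps$sigma,
    maxb = maxb %||% mm$maxb, minc = minc %||% mm$minc,
    minm = minm %||% mm$minm, mins = mins %||% mm$mins,
    factorb = factorb %||% mf$factorb, factorc = factorc %||% mf$factorc,
    factorm = factorm %||% mf$factorm, factors = factors %||% mf$factors,
    iterb = iterb %||% iter, iterc = iterc %||% iter,
    iterm = iterm %||% iter, iters = iters %||% iter,
    iterr = iterr %||% iter,
    max_iter = max_iter, min_improve = min_improve, min_dev = min_dev,
    reintroduce = match.arg(reintroduce)
  )
  validate_ga_control(hp)
  structure(hp, class = "ga_control")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_ga_control <- function(hp) {
  stopifnot_msg(hp$chromosomes >= 3 && hp$chromosomes %% 2 == 1,
                "`chromosomes` must be an odd integer >= 3")
  for (p in c("probb", "probc", "probm"))
    stopifnot_msg(hp[[p]] >= 0 && hp[[p]] <= 1,
                  sprintf("`%s` must lie in [0, 1]", p))
  stopifnot_msg(hp$sigma > 0, "`sigma` must be > 0")
  stopifnot_msg(hp$factorb >= 1, "`factorb` must be >= 1 (blending grows)")
  for (p in c("factorc", "factorm", "factors"))
    stopifnot_msg(hp[[p]] > 0 && hp[[p]] <= 1,
                  sprintf("`%s` must lie in (0, 1]", p))
  stopifnot_msg(hp$maxb >= hp$probb, "`maxb` must be >= `probb`")
  stopifnot_msg(hp$minc <= hp$probc, "`minc` must be <= `probc`")
  stopifnot_msg(hp$minm <= hp$probm, "`minm` must be <= `probm`")
  stopifnot_msg(hp$mins <= hp$sigma, "`mins` must be <= `sigma`")
  for (p in c("iterb", "iterc", "iterm", "iters", "iterr"))
    stopifnot_msg(hp[[p]] >= 1, sprintf("`%s` must be >= 1", p))
  stopifnot_msg(hp$max_iter >= 1, "`max_iter` must be >= 1")
  stopifnot_msg(hp$min_improve >= 0, "`min_improve` must be >= 0")
  stopifnot_msg(hp$min_dev >= 0, "`min_dev` must be >= 0")
  invisible(hp)
}

stopifnot_msg <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

#' @export
print.ga_control <- function(x, ...) {
  cat("<ga_control>\n")
  cat("  population:", x$chromosomes, "chromosomes;",
      "reintroduce", x$reintroduce, "\n")
  cat(sprintf("  initial controls: p_b=%g p_c=%g p_m=%g sigma=%g\n",
              x$probb, x$probc, x$probm, x$sigma))
  cat(sprintf("  bounds: maxb=%g minc=%g minm=%g mins=%g\n",
              x$maxb, x$minc, x$minm, x$mins))
  cat(sprintf("  factors: b=%g c=%g m=%g s=%g\n",
              x$factorb, x$factorc, x$factorm, x$factors))
  cat(sprintf("  stagnation thresholds: b=%d c=%d m=%d s=%d r=%d\n",
              x$iterb, x$iterc, x$iterm, x$iters, x$iterr))
  cat(sprintf("  stopping: max_iter=%d min_improve=%g min_dev=%g\n",
              x$max_iter, x$min_improve, x$min_dev))
  invisible(x)
}

#' Read a hyperparameter configuration from JSON
#'
#' Reads a flat key-value JSON file whose keys are the hyperparameter names
#' accepted by [ga_control()] (`chromosomes`, `probb`, `factorb`, `maxb`,
#' `iterb`, ..., `reintroduce`, `iterr`), plus the optional grouped preset
#' keys `prob_sigma` (low/medium/high), `min_max` (minimal/moderate/extreme),
#' `mult_factor` (slow/moderate/rapid) and `iter`. Individual keys override
#' preset expansions, as in [ga_control()].
#'
#' @param path Path to a JSON file.
#' @return A `"ga_control"` object.
#' @export
read_ga_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(ga_control))
  extra <- setdiff(names(cfg), known)
  if (length(extra) > 0)
    stop("unknown configuration keys: ", paste(extra, collapse = ", "),
         call. = FALSE)
  do.call(ga_control, cfg)
}
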