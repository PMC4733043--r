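#' Rate constants of the stochastic organelle-production model
#'
#' Bundles the four non-negative rate constants that define a model instance.
#' Time units are arbitrary; only ratios of the rates matter for the limiting
#' distribution, so rates are often quoted in multiples of the decay rate
#' \code{gamma}.
#'
#' @param k_de_novo De novo synthesis rate (events per unit time, independent
#'   of the current organelle count).
#' @param k_fission Fission rate per organelle per unit time.
#' @param gamma First-order decay rate per organelle per unit time.
#' @param k_fusion Fusion rate per ordered pair of organelles per unit time
#'   (propensity \code{k_fusion * n * (n - 1)}).
#'
#' @return An object of class \code{"model_rates"}: a named list of the four
#'   rates.
#' @examples
#' model_rates(k_de_novo = 2, k_fission = 0.9, gamma = 1, k_fusion = 0.02)
#' @export
model_rates <- function(k_de_novo = 0, k_fission = 0, gamma = 0, k_fusion = 0) {
  r <- list(k_de_novo = k_de_novo, k_fission = k_fission,
            gamma = gamma, k_fusion = k_fusion)
  for (nm in names(r)) {
    v <- r[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop(sprintf("'%s' must be a single non-negative number", nm),
           call. = FALSE)
    r[[nm]] <- as.numeric(v)
  }
  if (all(unlist(r) == 0))
    stop("degenerate model: at least one rate must be positive", call. = FALSE)
  structure(r, class = "model_rates")
}

#' @export
print.model_rates <- function(x, ...) {
  cat("Organelle production model rates\n")
  cat(sprintf("  k_de_novo = %g  (de novo synthesis, per unit time)\n", x$k_de_novo))
  cat(sprintf("  k_fission = %g  (per organelle per unit time)\n", x$k_fission))
  cat(sprintf("  gamma     = %g  (decay, per organelle per unit time)\n", x$gamma))
  cat(sprintf("  k_fusion  = %g  (per ordered organelle pair per unit time)\n", x$k_fusion))
  invisible(x)
}

as_model_rates <- function(rates) {
  if (inherits(rates, "model_rates")) return(rates)
  if (is.numeric(rates) && length(rates) == 4L && is.null(names(rates)))
    return(model_rates(rates[1], rates[2], rates[3], rates[4]))
  do.call(model_rates, as.list(rates))
}

#' Per-cell event probabilities over a short time window
#'
#' First-order probabilities that each of the four processes fires within a
#' window \code{dt} in a cell currently holding \code{n} organelles:
#' \code{k_de_novo*dt}, \code{k_fission*n*dt}, \code{gamma*n*dt} and
#' \code{k_fusion*n*(n-1)*dt}. These are valid only for \code{dt} small enough
#' that their sum is well below 1; a warning is issued when the sum exceeds
#' 0.1 and an error when it exceeds 1 (the caller owns the step-size choice,
#' no clamping is applied).
#'
#' @param rates A \code{\link{model_rates}} object.
#' @param n Current organelle count (non-negative integer).
#' @param dt Length of the time window (positive).
#'
#' @return A named list with components \code{de_novo}, \code{fission},
#'   \code{decay}, \code{fusion}.
#' @examples
#' # a cell with n = 2 and k_fission = 0.02 has probability 0.004 of a
#' # fission event within 0.1 time units
#' event_probabilities(model_rates(k_fission = 0.02, gamma = 1), n = 2,
#'                     dt = 0.1)$fission
#' @export
event_probabilities <- function(rates, n, dt) {
  rates <- as_model_rates(rates)
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 0 || n != floor(n))
    stop("'n' must be a single non-negative integer", call. = FALSE)
  if (!is.numeric(dt) || length(dt) != 1L || is.na(dt) || dt <= 0)
    stop("'dt' must be a single positive number", call. = FALSE)
  p <- list(de_novo = rates$k_de_novo * dt,
            fission = rates$k_fission * n * dt,
            decay   = rates$gamma * n * dt,
            fusion  = rates$k_fusion * n * (n - 1) * dt)
  tot <- sum(unlist(p))
  if (tot > 1)
    stop(sprintf("summed event probability %.3g exceeds 1; reduce dt", tot),
         call. = FALSE)
  if (tot > 0.1)
    warning(sprintf("summed event probability %.3g exceeds 0.1; first-order-in-dt probabilities are inaccurate at this step size", tot),
            call. = FALSE)
  p
}

#' Population rate of a process in a sample of cells
#'
#' Instantaneous rate, in cells per unit time, at which cells holding
#' \code{n} organelles undergo the named process in a population of \code{N}
#' cells of which a fraction \code{f_n} currently holds \code{n} organelles.
#'
#' @param rates A \code{\link{model_rates}} object.
#' @param n Organelle count of the source class.
#' @param f_n Fraction of cells holding \code{n} organelles (in \code{[0, 1]}).
#' @param N Number of cells in the sample.
#' @param process One of \code{"de_novo"}, \code{"fission"}, \code{"decay"},
#'   \code{"fusion"}.
#'
#' @return The process rate in cells per unit time.
#' @examples
#' # 1000 cells, 23% with n = 2, k_fission = 0.02: cells move from n = 2 to
#' # n = 3 by fission at 9.2 cells per time unit
#' population_process_rate(model_rates(k_fission = 0.02, gamma = 1),
#'                         n = 2, f_n = 0.23, N = 1000, process = "fission")
#' @export
population_process_rate <- function(rates, n, f_n, N,
                                    process = c("de_novo", "fission",
                                                "decay", "fusion")) {
  rates <- as_model_rates(rates)
  process <- match.arg(process)
  if (!is.numeric(f_n) || length(f_n) != 1L || is.na(f_n) || f_n < 0 || f_n > 1)
    stop("'f_n' must be a fraction in [0, 1]", call. = FALSE)
  if (!is.numeric(N) || length(N) != 1L || is.na(N) || N < 0)
    stop("'N' must be a non-negative cell count", call. = FALSE)
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 0 || n != floor(n))
    stop("'n' must be a single non-negative integer", call. = FALSE)
  per_cell <- switch(process,
                     de_novo = rates$k_de_novo,
                     fission = rates$k_fission * n,
                     decay   = rates$gamma * n,
                     fusion  = rates$k_fusion * n * (n - 1))
  per_cell * f_n * N
}

#' Classify whether a model admits a limiting distribution
#'
#' With no fusion, the per-organelle fission gain must stay below the
#' per-organelle decay loss (\code{k_fission < gamma}) or the organelle count
#' grows without bound and no limiting distribution exists. The boundary case
#' \code{k_fission = gamma} is also classified as divergent: the mean and
#' Fano factor diverge there and the recurrence is non-normalisable. A
#' positive fusion rate regularises growth through its quadratic loss term.
#' When de novo synthesis is absent, state 0 is either absorbing (decay
#' present: the limiting law is the point mass at 0) or unreachable from
#' \eqn{n \ge 1} (no decay: the chain lives on \eqn{n \ge 1}).
#'
#' @param rates A \code{\link{model_rates}} object.
#'
#' @return An object of class \code{"regime_classification"}: a list with
#'   \code{has_limiting_distribution} (logical), \code{support_min} (0 or 1)
#'   and \code{reason} (one of \code{"STANDARD"},
#'   \code{"FISSION_EXCEEDS_DECAY"}, \code{"NO_LOSS_PROCESS"},
#'   \code{"ABSORBED_AT_ZERO"}, \code{"FUSION_REGULARISED"}).
#' @examples
#' classify_regime(model_rates(2, 0.9, 1, 0.02))   # limiting law exists
#' classify_regime(model_rates(2, 1.1, 1, 0))      # diverges
#' @export
classify_regime <- function(rates) {
  rates <- as_model_rates(rates)
  has_lim <- TRUE
  support_min <- 0L
  reason <- "STANDARD"
  if (rates$k_fusion == 0 && rates$k_fission > 0 &&
      rates$k_fission >= rates$gamma) {
    has_lim <- FALSE
    reason <- "FISSION_EXCEEDS_DECAY"
  } else if (rates$k_fusion == 0 && rates$gamma == 0 && rates$k_de_novo > 0) {
    # production with no loss process at all: n grows without bound
    has_lim <- FALSE
    reason <- "NO_LOSS_PROCESS"
  } else if (rates$k_de_novo == 0 && rates$gamma == 0) {
    # state 0 unreachable from n >= 1; fusion's quadratic loss bounds growth
    support_min <- 1L
    reason <- "FUSION_REGULARISED"
  } else if (rates$k_de_novo == 0 && rates$gamma > 0) {
    # state 0 absorbing: the only stationary law is the point mass at 0
    reason <- "ABSORBED_AT_ZERO"
  }
  structure(list(has_limiting_distribution = has_lim,
                 support_min = support_min,
                 reason = reason),
            class = "regime_classification")
}

#' @export
print.regime_classification <- function(x, ...) {
  cat(sprintf("Regime: %s (limiting distribution: %s; support starts at n = %d)\n",
              x$reason,
              if (x$has_limiting_distribution) "exists" else "does not exist",
              x$support_min))
  invisible(x)
}
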