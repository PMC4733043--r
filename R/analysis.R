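#' Decompose organelle production into de novo and fission fractions
#'
#' In the \{de novo, fission; decay\} model at equilibrium, total production
#' splits into a de novo part (\eqn{k_{denovo}}) and a fission part
#' (\eqn{k_{fission}\langle n\rangle}), and the Fano factor
#' \eqn{F = 1 + k_{fission}\langle n\rangle / k_{denovo}} fixes their
#' proportions without knowing the rates themselves: the de novo fraction is
#' \eqn{1/F} and the fission fraction \eqn{(F-1)/F}. A Fano factor of 1 means
#' purely de novo production; equal contributions require \eqn{F = 2}, and
#' the fission fraction grows only slowly beyond that.
#'
#' @param fano Observed Fano factor (must be at least 1 in this model; values
#'   below 1 indicate fusion or a non-equilibrium population).
#' @param tolerance Sampling-noise allowance: a \code{fano} in
#'   \code{[1 - tolerance, 1)} is clamped to 1 with a warning instead of
#'   erroring. Default 0 (strict).
#'
#' @return An object of class \code{"production_decomposition"}: a list with
#'   \code{fano}, \code{de_novo_fraction}, \code{fission_fraction}, and the
#'   whole-percent renderings \code{de_novo_percent}, \code{fission_percent}.
#' @examples
#' decompose_production(2.4)   # 42% de novo, 58% fission
#' @export
decompose_production <- function(fano, tolerance = 0) {
  if (!is.numeric(fano) || length(fano) != 1L || is.na(fano))
    stop("'fano' must be a single number", call. = FALSE)
  if (fano < 1) {
    if (fano >= 1 - tolerance) {
      warning(sprintf("fano = %g < 1 clamped to 1 (within tolerance %g); treat as purely de novo",
                      fano, tolerance), call. = FALSE)
      fano <- 1
    } else {
      stop(sprintf(paste0("fano = %g is below 1, outside the ",
                          "{de novo, fission; decay} model: suggests fusion ",
                          "or a non-equilibrium population"), fano),
           call. = FALSE)
    }
  }
  de_novo <- 1 / fano
  structure(list(fano = fano,
                 de_novo_fraction = de_novo,
                 fission_fraction = 1 - de_novo,
                 de_novo_percent = round(100 * de_novo),
                 fission_percent = round(100 * (1 - de_novo))),
            class = "production_decomposition")
}

#' @export
print.production_decomposition <- function(x, ...) {
  cat(sprintf("Production decomposition at Fano = %g:\n", x$fano))
  cat(sprintf("  de novo %d%%  |  fission %d%%\n",
              x$de_novo_percent, x$fission_percent))
  invisible(x)
}

#' Invert observed mean and Fano factor to rate constants
#'
#' Solves the exact equilibrium moment formulas of the
#' \{de novo, fission; decay\} model for the rates, in units of the decay
#' rate \eqn{\gamma}:
#' \deqn{k_{fission}/\gamma = 1 - 1/F, \qquad k_{denovo}/\gamma = \langle n\rangle / F.}
#' Applying the forward formulas to the result recovers the observed
#' (mean, Fano) pair exactly. Fusion-inclusive inversion is refused: the
#' moment formulas hold only with \code{k_fusion = 0}.
#'
#' @param mean Observed mean organelle count (positive).
#' @param fano Observed Fano factor (at least 1; see
#'   \code{\link{decompose_production}} for the \code{tolerance} treatment of
#'   values slightly below 1).
#' @param tolerance As in \code{\link{decompose_production}}.
#'
#' @return An object of class \code{"inferred_rates"}: a list with
#'   \code{k_de_novo_over_gamma} and \code{k_fission_over_gamma}.
#' @examples
#' invert_rates(mean = 3, fano = 1.1)   # about 2.7 and 0.1
#' @export
invert_rates <- function(mean, fano, tolerance = 0) {
  if (!is.numeric(mean) || length(mean) != 1L || is.na(mean) || mean <= 0)
    stop("'mean' must be a single positive number", call. = FALSE)
  dec <- decompose_production(fano, tolerance = tolerance)
  structure(list(k_de_novo_over_gamma = mean / dec$fano,
                 k_fission_over_gamma = 1 - 1 / dec$fano),
            class = "inferred_rates")
}

#' @export
print.inferred_rates <- function(x, ...) {
  cat(sprintf("Inferred rates: k_de_novo = %.4g*gamma, k_fission = %.4g*gamma\n",
              x$k_de_novo_over_gamma, x$k_fission_over_gamma))
  invisible(x)
}

#' Predicted drop in mean organelle count on fission knockout
#'
#' Predicts, from inferred rates, the relative drop in the equilibrium mean
#' when the fission pathway is deleted (\code{k_fission} set to 0): the mean
#' falls from \eqn{k_{denovo}/(\gamma - k_{fission})} to
#' \eqn{k_{denovo}/\gamma}, a drop of \eqn{100\, k_{fission}/\gamma}
#' percent.
#'
#' @param inferred An \code{"inferred_rates"} object (or a list with
#'   \code{k_de_novo_over_gamma} and \code{k_fission_over_gamma}).
#'
#' @return Percent drop in the equilibrium mean.
#' @examples
#' knockout_prediction(invert_rates(mean = 3, fano = 1.1))  # 10 (percent)
#' @export
knockout_prediction <- function(inferred) {
  kdn <- inferred$k_de_novo_over_gamma
  kf <- inferred$k_fission_over_gamma
  if (is.null(kdn) || is.null(kf))
    stop("'inferred' must carry k_de_novo_over_gamma and k_fission_over_gamma",
         call. = FALSE)
  if (kf < 0 || kf >= 1)
    stop("k_fission_over_gamma must lie in [0, 1) for a valid equilibrium",
         call. = FALSE)
  full <- peroxisome_mean(model_rates(k_de_novo = kdn, k_fission = kf,
                                      gamma = 1))
  ko <- peroxisome_mean(model_rates(k_de_novo = kdn, k_fission = 0,
                                    gamma = 1))
  100 * (full - ko) / full
}

#' Sample moments of an observed count histogram
#'
#' Sample mean, unbiased sample variance (denominator \code{n_cells - 1})
#' and Fano factor of per-cell organelle counts, with optional percentile
#' bootstrap confidence intervals obtained by resampling cells.
#'
#' @param counts Either a vector of per-cell counts, or a two-column data
#'   frame / matrix of (count, cells) histogram rows, or an
#'   \code{"ensemble_snapshot"}.
#' @param bootstrap_reps Number of bootstrap resamples (0 = no intervals).
#' @param seed RNG seed for the bootstrap (required when
#'   \code{bootstrap_reps > 0}).
#' @param conf Confidence level for the percentile intervals (default 0.95).
#'
#' @return An object of class \code{"observed_moments"}: a list with
#'   \code{mean}, \code{variance}, \code{fano}, \code{fano_defined},
#'   \code{n_cells}, and (when bootstrapped) \code{ci} — a matrix with rows
#'   \code{mean}, \code{variance}, \code{fano} and columns \code{lower},
#'   \code{upper} — plus \code{se}, the bootstrap standard errors.
#' @examples
#' observed_moments(c(2, 3, 3, 4, 5, 1, 0, 2))
#' @export
observed_moments <- function(counts, bootstrap_reps = 0, seed = NULL,
                             conf = 0.95) {
  x <- as_cell_counts(counts)
  if (length(x) < 2L)
    stop("at least two cells are required", call. = FALSE)
  if (any(x < 0) || any(x != floor(x)))
    stop("counts must be non-negative integers", call. = FALSE)
  moments <- function(v) {
    m <- mean(v); s2 <- var(v)
    c(mean = m, variance = s2, fano = if (m > 0) s2 / m else NaN)
  }
  est <- moments(x)
  out <- list(mean = unname(est["mean"]), variance = unname(est["variance"]),
              fano = unname(est["fano"]),
              fano_defined = est["mean"] > 0, n_cells = length(x))
  if (bootstrap_reps > 0) {
    if (is.null(seed))
      stop("'seed' is required when bootstrapping", call. = FALSE)
    boot <- withr_seed(seed, {
      replicate(bootstrap_reps, moments(sample(x, replace = TRUE)))
    })
    alpha <- (1 - conf) / 2
    ci <- t(apply(boot, 1, quantile, probs = c(alpha, 1 - alpha),
                  na.rm = TRUE))
    colnames(ci) <- c("lower", "upper")
    out$ci <- ci
    out$se <- apply(boot, 1, function(v) sqrt(var(v[is.finite(v)])))
    out$bootstrap_reps <- bootstrap_reps
  }
  structure(out, class = "observed_moments")
}

# evaluate expr under a private RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

as_cell_counts <- function(counts) {
  if (inherits(counts, "ensemble_snapshot")) return(counts$counts)
  if (is.data.frame(counts) || is.matrix(counts)) {
    if (ncol(counts) != 2L)
      stop("histogram input must have two columns: count, cells",
           call. = FALSE)
    counts <- as.data.frame(counts)
    return(rep(as.numeric(counts[[1]]), times = as.numeric(counts[[2]])))
  }
  as.numeric(counts)
}

#' @export
print.observed_moments <- function(x, ...) {
  cat(sprintf("Observed moments over %d cells:\n", x$n_cells))
  cat(sprintf("  mean %.4g, variance %.4g, Fano %s\n", x$mean, x$variance,
              if (x$fano_defined) sprintf("%.4g", x$fano) else "undefined"))
  if (!is.null(x$ci)) {
    cat(sprintf("  bootstrap %d reps: mean [%.4g, %.4g], fano [%.4g, %.4g]\n",
                x$bootstrap_reps, x$ci["mean", 1], x$ci["mean", 2],
                x$ci["fano", 1], x$ci["fano", 2]))
  }
  invisible(x)
}
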