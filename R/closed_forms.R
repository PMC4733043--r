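#' Closed-form limiting laws of the classic sub-models
#'
#' Three sub-models of the four-process scheme have limiting distributions in
#' standard families, identified directly from the detailed-balance term
#' ratio:
#' \itemize{
#'   \item \code{POISSON}: the \{de novo; decay\} (immigration--death) model,
#'     with \eqn{\lambda = k_{denovo}/\gamma};
#'   \item \code{TRUNCATED_POISSON}: the \{fission; fusion\} model, a Poisson
#'     law conditioned on \eqn{n \ge 1}, with
#'     \eqn{\lambda = k_{fission}/k_{fusion}};
#'   \item \code{NEGATIVE_BINOMIAL}: the \{de novo, fission; decay\} model,
#'     with size \eqn{r = k_{denovo}/k_{fission}} and success probability
#'     \eqn{p = k_{fission}/\gamma} (pmf \eqn{\propto
#'     \Gamma(r+n)/(\Gamma(r)\,n!)\, p^n}).
#' }
#' A fourth family, \code{SHIFTED_POISSON} (\eqn{n - 1} Poisson distributed,
#' support \eqn{n \ge 1}), is not a limiting law of any sub-model; it is kept
#' for comparison because it has been used in place of the truncated Poisson
#' for the fission--fusion model and its Fano--mean curve differs markedly.
#'
#' @param family One of \code{"POISSON"}, \code{"TRUNCATED_POISSON"},
#'   \code{"SHIFTED_POISSON"}, \code{"NEGATIVE_BINOMIAL"}.
#' @param lambda Shape parameter for the three Poisson-type families.
#' @param r,p Size and success probability for the negative binomial
#'   (\code{r > 0}, \code{0 < p < 1}).
#' @param rates Alternatively, a \code{\link{model_rates}} object from which
#'   the family's shape parameters are derived as above.
#'
#' @return An object of class \code{"closed_form_spec"}.
#' @examples
#' closed_form_spec("POISSON", lambda = 2)
#' closed_form_spec("NEGATIVE_BINOMIAL", rates = model_rates(2, 0.9, 1, 0))
#' @export
closed_form_spec <- function(family = c("POISSON", "TRUNCATED_POISSON",
                                        "SHIFTED_POISSON",
                                        "NEGATIVE_BINOMIAL"),
                             lambda = NULL, r = NULL, p = NULL,
                             rates = NULL) {
  family <- match.arg(family)
  if (!is.null(rates)) {
    rates <- as_model_rates(rates)
    if (family == "POISSON") {
      if (rates$gamma <= 0) stop("POISSON needs gamma > 0", call. = FALSE)
      lambda <- rates$k_de_novo / rates$gamma
    } else if (family == "TRUNCATED_POISSON") {
      if (rates$k_fusion <= 0)
        stop("TRUNCATED_POISSON needs k_fusion > 0", call. = FALSE)
      lambda <- rates$k_fission / rates$k_fusion
    } else if (family == "NEGATIVE_BINOMIAL") {
      if (rates$k_fission <= 0 || rates$gamma <= 0)
        stop("NEGATIVE_BINOMIAL needs k_fission > 0 and gamma > 0",
             call. = FALSE)
      r <- rates$k_de_novo / rates$k_fission
      p <- rates$k_fission / rates$gamma
    } else {
      stop("SHIFTED_POISSON is not the limiting law of any sub-model; give lambda directly",
           call. = FALSE)
    }
  }
  if (family == "NEGATIVE_BINOMIAL") {
    if (is.null(r) || is.null(p) || r <= 0 || p <= 0 || p >= 1)
      stop("NEGATIVE_BINOMIAL requires r > 0 and 0 < p < 1", call. = FALSE)
    spec <- list(family = family, r = r, p = p)
  } else {
    if (is.null(lambda) || lambda <= 0)
      stop(sprintf("%s requires lambda > 0", family), call. = FALSE)
    spec <- list(family = family, lambda = lambda)
  }
  structure(spec, class = "closed_form_spec")
}

#' @export
print.closed_form_spec <- function(x, ...) {
  if (x$family == "NEGATIVE_BINOMIAL")
    cat(sprintf("Closed form: NEGATIVE_BINOMIAL(r = %g, p = %g)\n", x$r, x$p))
  else
    cat(sprintf("Closed form: %s(lambda = %g)\n", x$family, x$lambda))
  invisible(x)
}

#' Probability mass function of a closed-form family
#'
#' Vectorised over \code{n}; counts below the family's support minimum
#' (\eqn{n \ge 1} for the truncated and shifted Poisson) return 0.
#'
#' @param spec A \code{\link{closed_form_spec}}.
#' @param n Organelle counts (non-negative integers).
#'
#' @return Probabilities of the same length as \code{n}.
#' @examples
#' closed_form_pmf(closed_form_spec("POISSON", lambda = 2), 0:5)
#' @export
closed_form_pmf <- function(spec, n) {
  if (!inherits(spec, "closed_form_spec"))
    stop("'spec' must be a closed_form_spec", call. = FALSE)
  stopifnot(is.numeric(n), all(n == floor(n)))
  out <- numeric(length(n))
  ok <- n >= 0
  switch(spec$family,
         POISSON = {
           out[ok] <- dpois(n[ok], spec$lambda)
         },
         TRUNCATED_POISSON = {
           sup <- n >= 1
           # Poisson conditioned on n >= 1; -expm1(-lambda) = 1 - e^-lambda
           out[sup] <- dpois(n[sup], spec$lambda) / (-expm1(-spec$lambda))
         },
         SHIFTED_POISSON = {
           sup <- n >= 1
           out[sup] <- dpois(n[sup] - 1, spec$lambda)
         },
         NEGATIVE_BINOMIAL = {
           out[ok] <- dnbinom(n[ok], size = spec$r, prob = 1 - spec$p)
         })
  out
}

#' Exact moments of a closed-form family
#'
#' @param spec A \code{\link{closed_form_spec}}.
#' @return A list with \code{mean}, \code{variance} and \code{fano}.
#' @export
closed_form_moments <- function(spec) {
  if (!inherits(spec, "closed_form_spec"))
    stop("'spec' must be a closed_form_spec", call. = FALSE)
  switch(spec$family,
         POISSON = {
           list(mean = spec$lambda, variance = spec$lambda, fano = 1)
         },
         TRUNCATED_POISSON = {
           lam <- spec$lambda
           mu <- lam / (-expm1(-lam))
           v <- mu * (1 + lam - mu)
           list(mean = mu, variance = v, fano = 1 + lam - mu)
         },
         SHIFTED_POISSON = {
           lam <- spec$lambda
           list(mean = 1 + lam, variance = lam, fano = lam / (1 + lam))
         },
         NEGATIVE_BINOMIAL = {
           mu <- spec$r * spec$p / (1 - spec$p)
           list(mean = mu, variance = mu / (1 - spec$p),
                fano = 1 / (1 - spec$p))
         })
}

#' Exact equilibrium mean of the \{de novo, fission; decay\} model
#'
#' \deqn{\langle n\rangle = \frac{k_{denovo}}{\gamma - k_{fission}}}
#' valid for \code{k_fusion = 0} and \code{k_fission < gamma}; the mean
#' diverges as \code{k_fission} approaches \code{gamma}.
#'
#' @param rates A \code{\link{model_rates}} object with \code{k_fusion = 0}.
#' @return The equilibrium mean organelle count.
#' @examples
#' peroxisome_mean(model_rates(k_de_novo = 2.7, k_fission = 0.1, gamma = 1))
#' @export
peroxisome_mean <- function(rates) {
  rates <- as_model_rates(rates)
  check_peroxisome_rates(rates)
  rates$k_de_novo / (rates$gamma - rates$k_fission)
}

#' Exact equilibrium Fano factor of the \{de novo, fission; decay\} model
#'
#' \deqn{\sigma^2/\langle n\rangle = \frac{\gamma}{\gamma - k_{fission}}}
#' exact for all parameter values with \code{k_fusion = 0} and
#' \code{k_fission < gamma} (the negative-binomial limit); equals 1 in the
#' pure immigration--death (Poisson) case and diverges as \code{k_fission}
#' approaches \code{gamma}.
#'
#' @inheritParams peroxisome_mean
#' @return The equilibrium Fano factor.
#' @examples
#' peroxisome_fano(model_rates(k_de_novo = 2.7, k_fission = 0.1, gamma = 1))
#' @export
peroxisome_fano <- function(rates) {
  rates <- as_model_rates(rates)
  check_peroxisome_rates(rates)
  rates$gamma / (rates$gamma - rates$k_fission)
}

check_peroxisome_rates <- function(rates) {
  if (rates$k_fusion != 0)
    stop("closed-form moments require k_fusion = 0", call. = FALSE)
  if (rates$gamma <= 0)
    stop("closed-form moments require gamma > 0", call. = FALSE)
  if (rates$k_fission >= rates$gamma)
    stop("mean and Fano factor diverge for k_fission >= gamma",
         call. = FALSE)
  invisible(rates)
}

#' Fano factor from the production contributions
#'
#' Alternative exact form of the equilibrium Fano factor of the
#' \{de novo, fission; decay\} model in terms of the mean:
#' \deqn{\sigma^2/\langle n\rangle = 1 + \frac{k_{fission}\langle n\rangle}{k_{denovo}}.}
#' At the equilibrium mean it coincides with \code{\link{peroxisome_fano}}.
#'
#' @param mean Mean organelle count.
#' @param rates A \code{\link{model_rates}} object with
#'   \code{k_de_novo > 0}.
#' @return The Fano factor implied by the contributions.
#' @export
fano_from_contributions <- function(mean, rates) {
  rates <- as_model_rates(rates)
  if (rates$k_de_novo <= 0)
    stop("'k_de_novo' must be positive", call. = FALSE)
  if (!is.numeric(mean) || any(mean < 0))
    stop("'mean' must be non-negative", call. = FALSE)
  1 + rates$k_fission * mean / rates$k_de_novo
}

#' Fano-factor versus mean curve of a closed-form family
#'
#' Sweeps the family's shape parameter and reports the exact (mean, Fano)
#' pair at each value — the machine-readable form of the theoretical curves
#' used to compare candidate limiting laws against observed count moments.
#' By default the sweep is log-spaced so both the small- and large-mean
#' limits are covered.
#'
#' @param family Family name, as in \code{\link{closed_form_spec}}.
#' @param sweep Increasing vector of shape-parameter values (\code{lambda},
#'   or \code{p} for the negative binomial). Defaults to a 200-point log grid
#'   on \code{[1e-2, 1e2]} (Poisson-type) or \code{p} in
#'   \code{[1e-3, 1 - 1e-3]} (negative binomial).
#' @param r Negative-binomial size parameter, fixed along the sweep.
#'
#' @return A data frame of class \code{"fano_mean_curve"} with columns
#'   \code{sweep_value}, \code{mean}, \code{fano} and attribute
#'   \code{family}; means are strictly increasing along the sweep.
#' @examples
#' head(fano_mean_curve("TRUNCATED_POISSON"))
#' @export
fano_mean_curve <- function(family = c("POISSON", "TRUNCATED_POISSON",
                                       "SHIFTED_POISSON",
                                       "NEGATIVE_BINOMIAL"),
                            sweep = NULL, r = 1) {
  family <- match.arg(family)
  if (is.null(sweep)) {
    sweep <- if (family == "NEGATIVE_BINOMIAL") {
      1 - exp(seq(log(1 - 1e-3), log(1 - (1 - 1e-3)), length.out = 200))
    } else {
      exp(seq(log(1e-2), log(1e2), length.out = 200))
    }
  }
  if (length(sweep) == 0L)
    stop("empty sweep", call. = FALSE)
  if (is.unsorted(sweep, strictly = TRUE))
    stop("'sweep' must be strictly increasing", call. = FALSE)
  rows <- lapply(sweep, function(s) {
    spec <- if (family == "NEGATIVE_BINOMIAL")
      closed_form_spec(family, r = r, p = s)
    else
      closed_form_spec(family, lambda = s)
    m <- closed_form_moments(spec)
    data.frame(sweep_value = s, mean = m$mean, fano = m$fano)
  })
  out <- do.call(rbind, rows)
  attr(out, "family") <- family
  class(out) <- c("fano_mean_curve", "data.frame")
  out
}
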