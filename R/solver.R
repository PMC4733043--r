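#' Exact limiting distribution by the detailed-balance recurrence
#'
#' At equilibrium the probability flux from state \eqn{n} to \eqn{n+1}
#' balances the reverse flux, giving the term ratio
#' \deqn{f_{n+1} = \frac{k_{denovo} + k_{fission} n}{(\gamma + k_{fusion} n)(n+1)} f_n.}
#' Starting from an arbitrary seed value at the bottom of the support, the
#' recurrence is run forward and the result normalised; the seed choice
#' cancels in the normalisation. Terms are accumulated in log space so that
#' large-mean models neither overflow nor underflow.
#'
#' The support is extended until the current (pre-normalisation) term is
#' below \code{tail_tolerance * 1e-3} of the running sum, the term ratio has
#' dropped below 1 (past the mode, so the remaining tail is bounded by a
#' geometric series), and that geometric tail bound itself is below
#' \code{tail_tolerance}. The retained probabilities are normalised so that
#' their sum plus the reported \code{tail_bound} equals 1.
#'
#' @param rates A \code{\link{model_rates}} object.
#' @param tail_tolerance Maximum probability mass allowed beyond the retained
#'   support (default \code{1e-12}).
#' @param n_cap Hard cap on the largest organelle count retained (default
#'   \code{1e5}); if the tail criterion is not met by \code{n_cap} a
#'   truncation error reports the accumulated mass.
#'
#' @return An object of class \code{"count_distribution"}: a list with
#'   \code{support_min}, \code{n} (the support), \code{probabilities},
#'   \code{tail_bound} and \code{rates}.
#' @examples
#' d <- stationary_distribution(model_rates(2, 0.9, 1, 0.02))
#' distribution_stats(d)$mean   # about 7.1
#' @export
stationary_distribution <- function(rates, tail_tolerance = 1e-12,
                                    n_cap = 100000L) {
  rates <- as_model_rates(rates)
  reg <- classify_regime(rates)
  if (!reg$has_limiting_distribution)
    stop(sprintf(paste0("no limiting distribution exists for these rates ",
                        "(%s): the recurrence is non-normalisable"),
                 reg$reason),
         call. = FALSE)
  if (!is.numeric(tail_tolerance) || tail_tolerance <= 0 || tail_tolerance >= 1)
    stop("'tail_tolerance' must be in (0, 1)", call. = FALSE)
  smin <- reg$support_min

  # log of the unnormalised terms, seeded at log f_{smin} = 0
  lt <- numeric(1024L)
  n_terms <- 0L
  lt_n <- 0
  log_sum <- -Inf
  n <- smin
  repeat {
    if (n_terms == length(lt)) lt <- c(lt, numeric(length(lt)))
    n_terms <- n_terms + 1L
    lt[n_terms] <- lt_n
    log_sum <- logspace_add(log_sum, lt_n)
    num <- rates$k_de_novo + rates$k_fission * n
    den <- (rates$gamma + rates$k_fusion * n) * (n + 1)
    ratio <- if (num == 0) 0 else num / den
    term_rel <- exp(lt_n - log_sum)
    if (ratio < 1 &&
        term_rel < tail_tolerance * 1e-3 &&
        term_rel * ratio / (1 - ratio) < tail_tolerance)
      break
    if (n - smin + 1L >= n_cap) {
      stop(sprintf(paste0("support cap n_cap = %d reached before the tail ",
                          "criterion was met (last term ratio %.4g, relative ",
                          "term %.4g); raise n_cap or tail_tolerance"),
                   n_cap, ratio, term_rel), call. = FALSE)
    }
    if (ratio == 0) break  # chain cannot leave the current state upward
    lt_n <- lt_n + log(num) - log(den)
    n <- n + 1L
  }

  lt <- lt[seq_len(n_terms)]
  n_last <- n
  num <- rates$k_de_novo + rates$k_fission * n_last
  den <- (rates$gamma + rates$k_fusion * n_last) * (n_last + 1)
  r_last <- if (num == 0) 0 else num / den
  # geometric bound on mass beyond n_last (ratio is decreasing past the mode)
  log_tail <- if (r_last == 0) -Inf else
    lt[n_terms] + log(r_last) - log1p(-r_last)
  log_total <- logspace_add(log_sum, log_tail)
  probs <- exp(lt - log_total)
  tail_bound <- exp(log_tail - log_total)

  structure(list(support_min = smin,
                 n = seq.int(smin, n_last),
                 probabilities = probs,
                 tail_bound = tail_bound,
                 rates = rates),
            class = "count_distribution")
}

logspace_add <- function(lx, ly) {
  if (lx == -Inf) return(ly)
  if (ly == -Inf) return(lx)
  m <- max(lx, ly)
  m + log1p(exp(min(lx, ly) - m))
}

count_distribution <- function(n, probabilities, tail_bound = 0,
                               rates = NULL) {
  stopifnot(length(n) == length(probabilities), all(probabilities >= 0),
            all(diff(n) == 1))
  structure(list(support_min = n[1], n = n, probabilities = probabilities,
                 tail_bound = tail_bound, rates = rates),
            class = "count_distribution")
}

#' @export
print.count_distribution <- function(x, ...) {
  st <- distribution_stats(x)
  cat(sprintf("Organelle count distribution on n = %d..%d (tail bound %.2e)\n",
              x$n[1], x$n[length(x$n)], x$tail_bound))
  cat(sprintf("  mean %.4g, variance %.4g, Fano %s\n", st$mean, st$variance,
              if (st$fano_defined) sprintf("%.4g", st$fano) else "undefined"))
  invisible(x)
}

#' Mean, variance and Fano factor of a count distribution
#'
#' Moments of the distribution over organelle number: mean
#' \eqn{\langle n\rangle = \sum_n n f_n}, variance
#' \eqn{\sigma^2 = \sum_n n^2 f_n - \langle n\rangle^2} and Fano factor
#' \eqn{\sigma^2/\langle n\rangle}. The Fano factor has no value when the
#' mean is zero; it is then returned as \code{NaN} with
#' \code{fano_defined = FALSE} rather than silently set to 0.
#'
#' @param dist A \code{"count_distribution"} (from
#'   \code{\link{stationary_distribution}} or \code{\link{read_distribution}}).
#'
#' @return A list with \code{mean}, \code{variance}, \code{fano} and
#'   \code{fano_defined}.
#' @export
distribution_stats <- function(dist) {
  if (!inherits(dist, "count_distribution"))
    stop("'dist' must be a count_distribution", call. = FALSE)
  p <- dist$probabilities
  if (length(p) == 0L || sum(p) == 0)
    stop("empty distribution", call. = FALSE)
  w <- p / sum(p)
  m <- sum(dist$n * w)
  v <- sum(dist$n^2 * w) - m^2
  v <- max(v, 0)  # guard tiny negative rounding
  if (m > 0) {
    list(mean = m, variance = v, fano = v / m, fano_defined = TRUE)
  } else {
    list(mean = m, variance = v, fano = NaN, fano_defined = FALSE)
  }
}

#' Maximum detailed-balance flux imbalance of a distribution
#'
#' For each adjacent state pair the up-flux
#' \eqn{(k_{denovo} + k_{fission} n) f_n} is compared with the down-flux
#' \eqn{(\gamma + k_{fusion} n)(n+1) f_{n+1}}; the maximum absolute imbalance
#' is returned (probability per unit time). A distribution produced by
#' \code{\link{stationary_distribution}} satisfies the balance to floating
#' precision by construction; an empirical histogram's residual measures its
#' distance from stationarity and shrinks with sample size.
#'
#' @param dist A \code{"count_distribution"}; probabilities are renormalised
#'   internally so empirical histograms can be passed after conversion.
#' @param rates A \code{\link{model_rates}} object.
#'
#' @return Maximum absolute flux imbalance over adjacent state pairs.
#' @export
stationarity_residual <- function(dist, rates) {
  if (!inherits(dist, "count_distribution"))
    stop("'dist' must be a count_distribution", call. = FALSE)
  rates <- as_model_rates(rates)
  p <- dist$probabilities / sum(dist$probabilities)
  n <- dist$n
  k <- length(n)
  # pad one state above the support: f there is 0
  up <- (rates$k_de_novo + rates$k_fission * n) * p
  dn <- (rates$gamma + rates$k_fusion * n[-k]) * (n[-k] + 1) * p[-1]
  max(abs(up[-k] - dn), abs(up[k]) * (dist$tail_bound == 0))
}

#' Convert an observed count histogram to a count_distribution
#'
#' Normalises a histogram of per-cell organelle counts into a
#' \code{"count_distribution"} on a contiguous support, e.g. for computing
#' its \code{\link{stationarity_residual}} against a candidate model.
#'
#' @param n Integer vector of organelle counts (histogram bin labels).
#' @param cells Number of cells observed at each count.
#'
#' @return A \code{"count_distribution"}.
#' @export
empirical_distribution <- function(n, cells) {
  stopifnot(length(n) == length(cells), all(cells >= 0), sum(cells) > 0,
            all(n >= 0), all(n == floor(n)))
  full_n <- seq.int(min(n), max(n))
  p <- numeric(length(full_n))
  p[match(n, full_n)] <- cells
  count_distribution(full_n, p / sum(p), tail_bound = 0)
}
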