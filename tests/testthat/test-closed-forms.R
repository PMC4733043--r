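test_that("closed-form pmfs have the right support and normalisation", {
  # e^-2 at n = 0 for Poisson(2); series sums to 1
  pois <- closed_form_spec("POISSON", lambda = 2)
  expect_equal(closed_form_pmf(pois, 0), exp(-2), tolerance = 1e-14)
  expect_equal(sum(closed_form_pmf(pois, 0:60)), 1, tolerance = 1e-14)

  ztp <- closed_form_spec("TRUNCATED_POISSON", lambda = 3)
  expect_identical(closed_form_pmf(ztp, 0), 0)
  expect_equal(sum(closed_form_pmf(ztp, 1:80)), 1, tolerance = 1e-14)

  sp <- closed_form_spec("SHIFTED_POISSON", lambda = 3)
  expect_identical(closed_form_pmf(sp, 0), 0)
  expect_equal(closed_form_pmf(sp, 1:10), dpois(0:9, 3), tolerance = 1e-15)

  nb <- closed_form_spec("NEGATIVE_BINOMIAL", r = 2.5, p = 0.4)
  expect_equal(sum(closed_form_pmf(nb, 0:200)), 1, tolerance = 1e-12)
})

test_that("shape parameters derive correctly from model rates", {
  expect_equal(closed_form_spec("POISSON", rates = model_rates(2, 0, 1, 0))$lambda, 2)
  expect_equal(closed_form_spec("TRUNCATED_POISSON",
                                rates = model_rates(0, 3, 0, 0.5))$lambda, 6)
  nb <- closed_form_spec("NEGATIVE_BINOMIAL", rates = model_rates(2, 0.9, 1, 0))
  expect_equal(nb$r, 2 / 0.9)
  expect_equal(nb$p, 0.9)
  expect_error(closed_form_spec("NEGATIVE_BINOMIAL", r = 1, p = 1.2), "0 < p < 1")
})

test_that("recurrence solutions coincide with the closed-form laws", {
  families <- c(POISSON = 101, TRUNCATED_POISSON = 202,
                NEGATIVE_BINOMIAL = 303)
  for (fam in names(families)) {
    for (r in random_family_rates(fam, 21, seed = families[[fam]])) {
      d <- stationary_distribution(r)
      spec <- closed_form_spec(fam, rates = r)
      expect_lt(tv_between(d, spec), 1e-10)
    }
  }
})

test_that("the negative binomial tends to the Poisson as fission vanishes", {
  pois <- closed_form_spec("POISSON", lambda = 2)
  n <- 0:30
  for (kf in c(1e-3, 1e-5)) {
    nb <- closed_form_spec("NEGATIVE_BINOMIAL",
                           rates = model_rates(2, kf, 1, 0))
    expect_equal(closed_form_pmf(nb, n), closed_form_pmf(pois, n),
                 tolerance = 50 * kf)
  }
})

test_that("family moment formulas agree with moment sums over the pmf", {
  specs <- list(closed_form_spec("POISSON", lambda = 0.3),
                closed_form_spec("POISSON", lambda = 12),
                closed_form_spec("TRUNCATED_POISSON", lambda = 0.2),
                closed_form_spec("TRUNCATED_POISSON", lambda = 7),
                closed_form_spec("SHIFTED_POISSON", lambda = 1),
                closed_form_spec("SHIFTED_POISSON", lambda = 9),
                closed_form_spec("NEGATIVE_BINOMIAL", r = 0.7, p = 0.3),
                closed_form_spec("NEGATIVE_BINOMIAL", r = 4, p = 0.8))
  for (spec in specs) {
    n <- 0:5000  # support long enough that the omitted tail is < 1e-14
    p <- closed_form_pmf(spec, n)
    m <- sum(n * p)
    v <- sum(n^2 * p) - m^2
    mom <- closed_form_moments(spec)
    expect_equal(mom$mean, m, tolerance = 1e-8)
    expect_equal(mom$variance, v, tolerance = 1e-8)
    expect_equal(mom$fano, v / m, tolerance = 1e-8)
  }
})

test_that("the exact mean and Fano formulas match the recurrence moments", {
  # hand arithmetic: 2.7/(1 - 0.1) = 3; 1/(1 - 0.1) = 1.111...
  glucose <- model_rates(2.7, 0.1, 1, 0)
  expect_equal(peroxisome_mean(glucose), 3)
  expect_equal(peroxisome_fano(glucose), 1 / 0.9)
  # immigration-death limit
  expect_equal(peroxisome_mean(model_rates(2, 0, 1, 0)), 2)
  expect_equal(peroxisome_fano(model_rates(2, 0, 0.7, 0)), 1)
  # hand arithmetic plus cross-check against the solver
  r <- model_rates(5, 0.5, 1, 0)
  expect_equal(peroxisome_mean(r), 10)
  expect_equal(peroxisome_fano(r), 2)
  st <- distribution_stats(stationary_distribution(r))
  expect_equal(st$mean, peroxisome_mean(r), tolerance = 1e-10)
  expect_equal(st$fano, peroxisome_fano(r), tolerance = 1e-10)

  expect_error(peroxisome_mean(model_rates(2, 1.2, 1, 0)), "diverge")
  expect_error(peroxisome_fano(model_rates(2, 1, 1, 0)), "diverge")
  expect_error(peroxisome_mean(model_rates(2, 0.5, 1, 0.1)), "k_fusion")
})

test_that("the contribution form of the Fano factor is exactly consistent", {
  set.seed(19)
  for (i in 1:50) {
    g <- runif(1, 0.3, 3)
    r <- model_rates(runif(1, 0.1, 8), runif(1, 0, 0.95) * g, g, 0)
    expect_equal(fano_from_contributions(peroxisome_mean(r), r),
                 peroxisome_fano(r), tolerance = 1e-14)
  }
  expect_equal(fano_from_contributions(3, model_rates(2.7, 0.1, 1, 0)),
               1 / 0.9)
  expect_equal(fano_from_contributions(123, model_rates(2, 0, 1, 0)), 1)
  expect_equal(fano_from_contributions(10, model_rates(5, 0.5, 1, 0)), 2)
  expect_error(fano_from_contributions(3, model_rates(0, 0.1, 1, 0)),
               "k_de_novo")
})

test_that("mean and Fano factor diverge as fission approaches decay", {
  kfs <- c(0.9, 0.99, 0.999, 0.9999)
  means <- vapply(kfs, function(kf) peroxisome_mean(model_rates(2, kf, 1, 0)),
                  numeric(1))
  fanos <- vapply(kfs, function(kf) peroxisome_fano(model_rates(2, kf, 1, 0)),
                  numeric(1))
  expect_true(all(diff(means) > 0) && all(diff(fanos) > 0))
  expect_gt(means[length(means)], 1e4)
  expect_gt(fanos[length(fanos)], 1e3)
})

test_that("Fano-mean curves sweep correctly and order the two n >= 1 laws", {
  # shifted Poisson at mean 2: variance lambda = 1, so Fano = 0.5
  sp <- fano_mean_curve("SHIFTED_POISSON", sweep = 1)
  expect_equal(sp$mean, 2)
  expect_equal(sp$fano, 0.5)

  # truncated Poisson approaches Fano 1 from below as lambda grows, with the
  # gap closing like lambda * exp(-lambda)
  tp <- fano_mean_curve("TRUNCATED_POISSON", sweep = c(2, 5, 10, 20))
  expect_true(all(tp$fano < 1))
  expect_true(all(diff(tp$fano) > 0))
  expect_gt(tp$fano[4], 1 - 1e-7)
  gap <- 1 - tp$fano
  lam <- tp$sweep_value
  expect_equal(gap, lam * exp(-lam) / (1 - exp(-lam)), tolerance = 1e-6)

  # at equal mean the truncated-Poisson Fano exceeds the shifted-Poisson Fano
  grid <- exp(seq(log(0.2), log(10), length.out = 120))
  tpc <- fano_mean_curve("TRUNCATED_POISSON", sweep = grid)
  spc <- fano_mean_curve("SHIFTED_POISSON", sweep = grid)
  for (m in seq(1.5, 5, by = 0.25)) {
    f_tp <- approx(tpc$mean, tpc$fano, xout = m)$y
    f_sp <- approx(spc$mean, spc$fano, xout = m)$y
    expect_gt(f_tp, f_sp)
  }

  # means strictly increase along every family's sweep
  for (fam in c("POISSON", "TRUNCATED_POISSON", "SHIFTED_POISSON",
                "NEGATIVE_BINOMIAL")) {
    cur <- fano_mean_curve(fam)
    expect_true(all(diff(cur$mean) > 0))
  }
  expect_error(fano_mean_curve("POISSON", sweep = numeric(0)), "empty")
})
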