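# total-variation distance between a solver distribution and a closed-form
# pmf, accounting for the truncation tails of both
tv_between <- function(dist, spec) {
  pmf <- closed_form_pmf(spec, dist$n)
  cf_tail <- max(0, 1 - sum(pmf))
  0.5 * (sum(abs(dist$probabilities - pmf)) + dist$tail_bound + cf_tail)
}

# random valid rate sets per closed-form family, reproducible
random_family_rates <- function(family, n_sets, seed) {
  set.seed(seed)
  lapply(seq_len(n_sets), function(i) {
    switch(family,
      POISSON = model_rates(k_de_novo = runif(1, 0.1, 20),
                            gamma = runif(1, 0.2, 3)),
      TRUNCATED_POISSON = model_rates(k_fission = runif(1, 0.1, 10),
                                      k_fusion = runif(1, 0.05, 2)),
      NEGATIVE_BINOMIAL = {
        g <- runif(1, 0.5, 2)
        model_rates(k_de_novo = runif(1, 0.1, 10),
                    k_fission = runif(1, 0.05, 0.9) * g,
                    gamma = g)
      })
  })
}
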