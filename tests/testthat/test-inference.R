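test_that("trial log-likelihood reaches the uniform and greedy limits", {
  blk <- blocks_default[["2"]]
  # an uncapped trial: DTD-1 samples plus one declaration
  steps <- tibble::tibble(
    step = 1:5, fish_color = c("g", "b", "g", "g", "g"),
    action = c("S", "S", "S", "S", "DG")
  )
  # infinite temperature: every step uniform over the three actions
  expect_equal(trial_loglik(steps, 1, 1e7, blk, cfg_default),
               5 * log(1 / 3), tolerance = 1e-4)

  # a greedy-policy record at near-zero temperature has log-probability ~ 0
  sq <- generate_sequences(cfg_default, 4, exact_ratio = TRUE, seed = 13)
  sim <- simulate_agent(5, 1e-3, blocks_default[["3"]], sq, cfg_default, seed = 2)
  for (tr in unique(sim$trial)) {
    ll <- trial_loglik(sim[sim$trial == tr, ], 5, 1e-3,
                       blocks_default[["3"]], cfg_default)
    expect_gt(ll, -1e-3)
  }

  # a sample recorded at the draw cap is structurally impossible
  bad <- tibble::tibble(step = 20L, fish_color = "g", action = "S")
  expect_error(trial_loglik(bad, 1, 1, blk, cfg_default), "draw cap")
})

test_that("the grid covers the quadrature identities it is used for", {
  g <- param_grid(40, 40, c(1e-3, 60), c(0.05, 40))
  # trapezoid weights integrate a gamma density to ~ 1 over the grid span
  m <- gamma_moments(3, 5)
  ss <- gamma_shape_scale(m)
  mass_inside <- stats::pgamma(60, ss$shape, scale = ss$scale) -
    stats::pgamma(1e-3, ss$shape, scale = ss$scale)
  approx_mass <- sum(dgamma_mv(g$nodes$cs, m) *
                       dgamma_mv(g$nodes$temperature, gamma_moments(3, 5)) *
                       exp(g$lw))
  expect_equal(approx_mass,
               mass_inside * (stats::pgamma(40, ss$shape, scale = ss$scale) -
                                stats::pgamma(0.05, ss$shape, scale = ss$scale)),
               tolerance = 0.02)
  expect_error(param_grid(1, 10), "n_cs")
})

test_that("EM increases the marginal likelihood and recovers a planted cohort", {
  spec <- cohort_spec(
    groups = list(g = list(n_subjects = 12L,
                           cs = gamma_moments(3, 4),
                           temperature = gamma_moments(2.5, 2))),
    config = cfg_default, blocks = blocks_default[2], sequence_seed = 31L
  )
  coh <- simulate_dataset(spec, seed = 17)
  fit <- suppressWarnings(
    em_fit(coh, blocks_default[2], cfg_default, "combined", grid_small,
           step_logp = list(cached_logp(blocks_default[["2"]])))
  )
  tr <- fit$groups[[1]]$trace
  expect_true(all(diff(tr) >= -1e-6 * (1 + abs(tr[-length(tr)]))))
  # group means land near the realized cohort means
  expect_equal(fit$groups[[1]]$cs$mean, mean(coh$subjects$cs), tolerance = 0.35)
  expect_equal(fit$groups[[1]]$temperature$mean,
               mean(coh$subjects$temperature), tolerance = 0.35)
})

test_that("degenerate and boundary cohorts are handled", {
  # all subjects share one parameter pair at low noise: fitted variances shrink
  spec <- cohort_spec(
    groups = list(g = list(n_subjects = 8L,
                           cs = gamma_moments(4, 1e-10),
                           temperature = gamma_moments(0.5, 1e-10))),
    config = cfg_default, blocks = blocks_default[3], sequence_seed = 5L
  )
  coh <- simulate_dataset(spec, seed = 23)
  fit <- suppressWarnings(
    em_fit(coh, blocks_default[3], cfg_default, "combined", grid_small,
           step_logp = list(cached_logp(blocks_default[["3"]])))
  )
  f <- fit$groups[[1]]
  expect_lt(sqrt(f$cs$variance) / f$cs$mean, 0.5)

  # a one-subject dataset runs and returns prior-dominated posteriors
  solo <- coh$steps[coh$steps$subject_id == coh$steps$subject_id[1], ]
  fit1 <- suppressWarnings(
    em_fit(solo, blocks_default[3], cfg_default, "combined", grid_small,
           step_logp = list(cached_logp(blocks_default[["3"]])))
  )
  expect_equal(nrow(fit1$groups[[1]]$subject_summaries), 1)
  expect_true(is.finite(fit1$loglik))
})

test_that("individual estimates rank planted outliers and ignore row order", {
  spec <- two_group_spec(n = 8L, blocks = blocks_default[2], sequence_seed = 41L)
  coh <- simulate_dataset(spec, seed = 29)
  logp <- list(cached_logp(blocks_default[["2"]]))
  fit <- suppressWarnings(
    em_fit(coh, blocks_default[2], cfg_default, "combined", grid_small,
           step_logp = logp)
  )
  est <- individual_estimates(fit)
  # the subject with the largest true cost sits in the top quartile of estimates
  top_true <- coh$subjects$subject_id[which.max(coh$subjects$cs)]
  est_rank <- rank(est$cs_mean)[est$subject_id == top_true]
  expect_gte(est_rank, 0.75 * nrow(est))

  # permuting dataset rows leaves the estimates unchanged
  shuffled <- coh$steps[rev(seq_len(nrow(coh$steps))), ]
  fit2 <- suppressWarnings(
    em_fit(shuffled, blocks_default[2], cfg_default, "combined", grid_small,
           step_logp = logp)
  )
  expect_equal(individual_estimates(fit2), est)
})

test_that("recovered estimates track a correlated symptom covariate", {
  # inject a covariate rank-correlated with the true cost and check the
  # association survives estimation
  spec <- cohort_spec(
    groups = list(psy = list(n_subjects = 31L,
                             cs = gamma_moments(3, 10),
                             temperature = gamma_moments(2.5, 2))),
    config = cfg_default, blocks = blocks_default[2], sequence_seed = 61L
  )
  coh <- simulate_dataset(spec, seed = 37)
  truth <- coh$subjects
  symptoms <- withr::with_seed(53L, rank(truth$cs) + stats::rnorm(31, sd = 4))
  fit <- suppressWarnings(
    em_fit(coh, blocks_default[2], cfg_default, "combined", grid_small,
           step_logp = list(cached_logp(blocks_default[["2"]])))
  )
  est <- individual_estimates(fit)
  est <- est[match(truth$subject_id, est$subject_id), ]
  ct <- stats::cor.test(est$cs_mean, symptoms, method = "spearman", exact = FALSE)
  expect_gt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.05)
})

test_that("iBIC arithmetic and dataset guards are correct", {
  spec <- two_group_spec(n = 4L, blocks = blocks_default[2], sequence_seed = 3L)
  coh <- simulate_dataset(spec, seed = 11)
  logp <- list(cached_logp(blocks_default[["2"]]))
  fitC <- suppressWarnings(em_fit(coh, blocks_default[2], cfg_default,
                                  "combined", grid_small, step_logp = logp))
  fitS <- suppressWarnings(em_fit(coh, blocks_default[2], cfg_default,
                                  "by_group", grid_small, step_logp = logp))
  rep_ <- ibic(fitC, fitS)
  # penalty terms: k ln(N) with k = 4 vs 8 and N = total decision steps
  n_steps <- nrow(coh$steps)
  expect_equal(rep_$n_steps, n_steps)
  expect_equal(rep_$k_combined, 4)
  expect_equal(rep_$k_separate, 8)
  int_ll_c <- -(rep_$ibic_combined - 4 * log(n_steps)) / 2
  int_ll_s <- -(rep_$ibic_separate - 8 * log(n_steps)) / 2
  expect_true(is.finite(int_ll_c) && is.finite(int_ll_s))
  expect_equal(rep_$difference, rep_$ibic_combined - rep_$ibic_separate)
  expect_equal(rep_$preferred, if (rep_$difference > 0) "separate" else "combined")

  # fits on different datasets are rejected
  coh2 <- simulate_dataset(two_group_spec(n = 3L, blocks = blocks_default[2]),
                           seed = 12)
  fitC2 <- suppressWarnings(em_fit(coh2, blocks_default[2], cfg_default,
                                   "combined", grid_small, step_logp = logp))
  expect_error(ibic(fitC2, fitS), "same dataset")
})

test_that("fitted group means are stable under grid refinement", {
  spec <- cohort_spec(
    groups = list(g = list(n_subjects = 10L,
                           cs = gamma_moments(3, 4),
                           temperature = gamma_moments(2.5, 2))),
    config = cfg_default, blocks = blocks_default[2], sequence_seed = 19L
  )
  coh <- simulate_dataset(spec, seed = 43)
  coarse <- param_grid(32, 32, c(1e-4, 100), c(0.05, 50))
  fine <- param_grid(64, 64, c(1e-4, 100), c(0.05, 50))
  fit_a <- suppressWarnings(em_fit(coh, blocks_default[2], cfg_default,
                                   "combined", coarse))
  fit_b <- suppressWarnings(em_fit(coh, blocks_default[2], cfg_default,
                                   "combined", fine))
  expect_equal(fit_a$groups[[1]]$cs$mean, fit_b$groups[[1]]$cs$mean,
               tolerance = 0.05)
  expect_equal(fit_a$groups[[1]]$temperature$mean,
               fit_b$groups[[1]]$temperature$mean, tolerance = 0.05)
})
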