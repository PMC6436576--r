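make_steps <- function(subject_id, group, block, trial, colors, actions) {
  tibble::tibble(
    subject_id = subject_id, group = group, block = block, trial = trial,
    step = seq_along(colors), fish_color = colors, action = actions
  )
}

test_that("behavioural summaries compute DTD, Bayesian accuracy and JTC", {
  steps <- dplyr::bind_rows(
    # declares gold after one gold fish: accuracy 0.6, a JTC trial
    make_steps("s1", "a", 2L, 1L, "g", "DG"),
    # declares after 3 fish, 2 gold: posterior 0.6 for gold
    make_steps("s1", "a", 2L, 2L, c("g", "b", "g"), c("S", "S", "DG")),
    # declares black after 2 black fish
    make_steps("s2", "a", 2L, 1L, c("b", "b"), c("S", "DB")),
    make_steps("s2", "a", 2L, 2L, c("b", "g", "b", "b"), c("S", "S", "S", "DB"))
  )
  summ <- summarize_behavior(steps, blocks_default, cfg_default)
  s1 <- summ[summ$subject_id == "s1", ]
  expect_equal(s1$mean_dtd, 2)
  expect_equal(s1$mean_accuracy, 0.6, tolerance = 1e-12)
  expect_true(s1$jtc)           # median DTD = 2
  expect_equal(s1$n_jtc_trials, 1)
  s2 <- summ[summ$subject_id == "s2", ]
  expect_equal(s2$mean_accuracy,
               mean(c(1 - posterior_gold(2, 0), 1 - posterior_gold(4, 1))),
               tolerance = 1e-12)

  expect_equal(jtc_flag(c(1, 2, 3)), c(TRUE, TRUE, FALSE))
  # JTC and non-JTC subject counts partition the block
  expect_equal(sum(summ$jtc) + sum(!summ$jtc), nrow(summ))

  # unknown block id is rejected
  steps_bad <- make_steps("s1", "a", 9L, 1L, "g", "DG")
  expect_error(summarize_behavior(steps_bad, blocks_default, cfg_default),
               "unknown block")
})

test_that("summaries are invariant to input row order and match the ideal agent", {
  sq <- generate_sequences(cfg_default, 10, exact_ratio = TRUE, seed = 15)
  vt <- solve_value_table(blocks_default[["2"]], cfg_default, "max")
  runs <- run_ideal_policy(vt, sq)
  # express the ideal runs as a step-level dataset
  steps <- purrr::pmap_dfr(runs[c("trial", "dtd", "declared")], function(trial, dtd, declared) {
    colors <- sq$colors[[trial]][1:dtd]
    acts <- c(rep("S", dtd - 1), if (declared == "G") "DG" else "DB")
    tibble::tibble(
      subject_id = "ideal", group = "ideal", block = 2L, trial = trial,
      step = 1:dtd, fish_color = colors, action = acts
    )
  })
  summ <- summarize_behavior(steps, blocks_default, cfg_default)
  expect_equal(summ$mean_dtd, 20)
  expect_equal(summ$mean_accuracy, 0.835, tolerance = 5e-4)

  shuffled <- steps[withr::with_seed(1L, sample(nrow(steps))), ]
  expect_equal(summarize_behavior(shuffled, blocks_default, cfg_default), summ)
})

test_that("accuracy of posterior-mode declarations stays in [0.5, 1]", {
  spec <- two_group_spec(n = 4L, blocks = blocks_default[3], sequence_seed = 9L)
  coh <- simulate_dataset(spec, seed = 19)
  trials <- nest_trials(coh$steps, cfg_default)
  p_gold <- posterior_gold(trials$dtd, trials$n_g, cfg_default)
  mode_acc <- pmax(p_gold, 1 - p_gold)
  expect_true(all(mode_acc >= 0.5 & mode_acc <= 1))
})

test_that("group comparisons reproduce rank-test identities", {
  d <- tibble::tibble(group = rep(c("a", "b"), each = 3),
                      m = c(1, 2, 3, 4, 5, 6))
  res <- group_compare(d, "m")
  expect_equal(res$test$statistic, 0)  # complete separation

  # relabelled identical groups: U = n1*n2/2, p ~ 1
  d2 <- tibble::tibble(group = rep(c("a", "b"), times = 4),
                       m = rep(c(1, 2, 5, 9), each = 2))
  res2 <- group_compare(d2, "m")
  expect_equal(res2$test$statistic, 4 * 4 / 2)
  expect_gt(res2$test$p_value, 0.95)

  # Welch t on a symmetric metric reports its method
  res3 <- group_compare(d, "m", test = "t")
  expect_match(res3$test$method, "Welch")

  # covariate equal to the metric: Spearman rho = 1 within each group
  d$cov <- d$m
  res4 <- group_compare(d, "m", covariate = "cov")
  expect_equal(res4$spearman$a$rho, 1)
  expect_equal(res4$spearman$b$rho, 1)

  expect_error(group_compare(d[1:4, ], "m"), "at least 2")
})

test_that("ICC(3,1) identifies perfect, null and degenerate consistency", {
  # subjects repeat their own DTD exactly, subjects differ: ICC = 1
  steps <- dplyr::bind_rows(lapply(1:4, function(s) {
    dplyr::bind_rows(lapply(1:5, function(tr) {
      dtd <- s  # subject s always stops after s fish
      make_steps(paste0("s", s), "a", 2L, as.integer(tr),
                 rep("g", dtd), c(rep("S", dtd - 1), "DG"))
    }))
  }))
  res <- icc_consistency(steps, cfg_default)
  expect_equal(res$icc, 1)
  expect_match(res$icc_type, "ICC\\(3,1\\)")

  # i.i.d. DTD across subjects and trials: ICC near 0 on average
  iccs <- vapply(1:6, function(seed) {
    dtds <- withr::with_seed(seed, matrix(sample(1:20, 6 * 8, TRUE), 6, 8))
    steps <- dplyr::bind_rows(lapply(1:6, function(s) {
      dplyr::bind_rows(lapply(1:8, function(tr) {
        dtd <- dtds[s, tr]
        acts <- if (dtd < 20) c(rep("S", dtd - 1), "DG") else c(rep("S", 19), "DG")
        make_steps(paste0("s", s), "a", 2L, as.integer(tr),
                   rep("g", length(acts)), acts)
      }))
    }))
    icc_consistency(steps, cfg_default)$icc
  }, numeric(1))
  expect_lt(abs(mean(iccs)), 0.2)

  # identical deterministic agents: degenerate, reported as NA with a note
  steps_same <- dplyr::bind_rows(lapply(1:3, function(s) {
    dplyr::bind_rows(lapply(1:4, function(tr) {
      make_steps(paste0("s", s), "a", 2L, as.integer(tr),
                 c("g", "g"), c("S", "DG"))
    }))
  }))
  res_same <- icc_consistency(steps_same, cfg_default)
  expect_true(is.na(res_same$icc))
  expect_match(res_same$note, "degenerate")

  # single-trial blocks are rejected
  steps_single <- make_steps("s1", "a", 2L, 1L, "g", "DG")
  expect_error(icc_consistency(steps_single, cfg_default), "2 trials")
})
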