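#' Gamma distributions parameterized by mean and variance
#'
#' Group-level distributions of the cost-of-sampling and temperature
#' parameters are gamma distributions, described throughout by their mean and
#' variance (the clinically interpretable centre/spread) rather than shape and
#' scale. `gamma_moments()` validates a (mean, variance) pair;
#' `gamma_shape_scale()` converts to the shape/scale parameterization
#' (`shape = mean^2/variance`, `scale = variance/mean`); `rgamma_mv()` and
#' `dgamma_mv()` draw from / evaluate the density of the distribution. A tiny
#' variance floor of 1e-12 guards against degenerate densities.
#'
#' @param mean,variance Positive reals.
#' @return `gamma_moments()`: a list with class `gamma_moments`.
#' @export
gamma_moments <- function(mean, variance) {
  if (!is.numeric(mean) || mean <= 0 || !is.numeric(variance) || variance <= 0) {
    stop("gamma mean and variance must be positive", call. = FALSE)
  }
  variance <- max(variance, 1e-12)
  structure(list(mean = mean, variance = variance), class = "gamma_moments")
}

#' @rdname gamma_moments
#' @param m A `gamma_moments` object.
#' @export
gamma_shape_scale <- function(m) {
  list(shape = m$mean^2 / m$variance, scale = m$variance / m$mean)
}

#' @rdname gamma_moments
#' @param n Number of draws.
#' @export
rgamma_mv <- function(n, m) {
  ss <- gamma_shape_scale(m)
  stats::rgamma(n, shape = ss$shape, scale = ss$scale)
}

#' @rdname gamma_moments
#' @param x Quantiles.
#' @param log Return log density?
#' @export
dgamma_mv <- function(x, m, log = FALSE) {
  ss <- gamma_shape_scale(m)
  stats::dgamma(x, shape = ss$shape, scale = ss$scale, log = log)
}

#' @export
print.gamma_moments <- function(x, ...) {
  ss <- gamma_shape_scale(x)
  cat("<gamma_moments> mean ", signif(x$mean, 4), ", variance ",
      signif(x$variance, 4), " (shape ", signif(ss$shape, 4), ", scale ",
      signif(ss$scale, 4), ")\n", sep = "")
  invisible(x)
}

#' Specification of a synthetic cohort
#'
#' Describes the generative model the hierarchical fit assumes: each group has
#' gamma population distributions over the subjective cost of sampling (CS,
#' points per draw) and the decision temperature (T, points), every subject
#' draws an independent (CS, T) pair from their group's distributions, and all
#' subjects see the same pseudo-random fish sequences. Defaults mirror the
#' study design: two groups of 31 subjects, 10 trials per block, with the
#' group moments from the no-cost-block population fits (control CS near zero,
#' psychosis CS mean 1.7 and variance 13; temperatures of a few points).
#'
#' @param groups Named list: one entry per group, each a list with elements
#'   `n_subjects`, `cs` ([gamma_moments()]) and `temperature`
#'   ([gamma_moments()]).
#' @param config A [task_config()].
#' @param blocks Blocks to simulate (list of [block_spec()]).
#' @param sequence_seed Seed for the shared fish sequences.
#' @param exact_ratio Constrain sequences to the exact 60:40 ratio?
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(groups = list(
                          control = list(n_subjects = 31L,
                                         cs = gamma_moments(1.9e-3, 2.0e-6),
                                         temperature = gamma_moments(3.4, 13)),
                          psychosis = list(n_subjects = 31L,
                                           cs = gamma_moments(1.7, 13),
                                           temperature = gamma_moments(4.2, 13))
                        ),
                        config = task_config(),
                        blocks = default_blocks(config),
                        sequence_seed = 20180601L,
                        exact_ratio = TRUE) {
  stopifnot(length(groups) >= 1, !is.null(names(groups)))
  for (g in groups) {
    stopifnot(g$n_subjects >= 1, inherits(g$cs, "gamma_moments"),
              inherits(g$temperature, "gamma_moments"))
  }
  structure(
    list(groups = groups, config = config, blocks = blocks,
         sequence_seed = as.integer(sequence_seed), exact_ratio = exact_ratio),
    class = "cohort_spec"
  )
}

#' Draw subject-level parameters for a cohort
#'
#' Samples one (CS, T) pair per subject from the group gamma distributions.
#' A fixed master seed spawns an independent stream per subject, so adding
#' subjects to a group does not perturb the draws of existing ones.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer master seed.
#' @return A tibble: `subject_id`, `group`, `cs`, `temperature`.
#' @export
sample_cohort <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  out <- list()
  i <- 0L
  for (gname in names(spec$groups)) {
    g <- spec$groups[[gname]]
    for (s in seq_len(g$n_subjects)) {
      i <- i + 1L
      sseed <- subject_seed(seed, i)
      pars <- with_local_seed(sseed, {
        c(rgamma_mv(1, g$cs), rgamma_mv(1, g$temperature))
      })
      out[[i]] <- tibble::tibble(
        subject_id = sprintf("%s_%02d", gname, s),
        group = gname, cs = pars[1], temperature = pars[2]
      )
    }
  }
  dplyr::bind_rows(out)
}

# deterministic per-subject stream seed, kept inside 32-bit integer range
subject_seed <- function(master, i) {
  as.integer((as.numeric(master) * 1000003 + 7919 * as.numeric(i)) %% 2147483647)
}

#' Simulate a complete synthetic dataset
#'
#' Composes [sample_cohort()] with [simulate_agent()]: every subject plays
#' every trial of every block in the spec, all subjects seeing the same
#' sequences (fresh sequences per block, shared across subjects, as in the
#' task's fixed pseudo-random stimulus lists). Temperatures below `min_temp`
#' are floored to keep the softmax defined.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer master seed for parameter draws and choice noise.
#' @param min_temp Lower floor on sampled temperatures.
#' @return A list with class `cohort_dataset`: `steps` (trial-CSV layout
#'   tibble), `subjects` (ground-truth parameter tibble from
#'   [sample_cohort()]), and `sequences` (one tibble per block, with the
#'   block id column added).
#' @export
simulate_dataset <- function(spec, seed = 1L, min_temp = 1e-3) {
  stopifnot(inherits(spec, "cohort_spec"))
  truth <- sample_cohort(spec, seed)
  truth$temperature <- pmax(truth$temperature, min_temp)
  n_tr <- spec$config$n_trials_per_block
  seqs <- purrr::imap(spec$blocks, function(blk, key) {
    sq <- generate_sequences(spec$config, n_tr, exact_ratio = spec$exact_ratio,
                             seed = subject_seed(spec$sequence_seed, blk$block_id))
    sq$block <- blk$block_id
    sq
  })
  steps <- purrr::pmap_dfr(truth, function(subject_id, group, cs, temperature) {
    i <- match(subject_id, truth$subject_id)
    purrr::imap_dfr(spec$blocks, function(blk, key) {
      simulate_agent(cs, temperature, blk, seqs[[key]], spec$config,
                     seed = subject_seed(seed + 1L, i * 101L + blk$block_id),
                     subject_id = subject_id, group = group)
    })
  })
  structure(list(steps = steps, subjects = truth, sequences = seqs),
            class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat("<cohort_dataset> ", nrow(x$subjects), " subjects, ",
      length(unique(x$steps$block)), " block(s), ",
      nrow(x$steps), " decision steps\n", sep = "")
  invisible(x)
}
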