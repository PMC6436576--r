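#' Per-subject, per-block behavioural summaries
#'
#' Computes the task's behavioural outcomes from a step-level dataset, per
#' subject and block: mean draws to decision (DTD) over trials; mean Bayesian
#' accuracy, i.e. the posterior probability of the chosen lake given the
#' number and colours of fish seen; total points under the block's payoff and
#' objective cost schedule; the number of jumping-to-conclusions trials
#' (declaration after one or two fish); and a subject-level JTC flag, true
#' when the subject's median trial DTD in the block is at most 2. When a
#' sequence table with the true lakes is supplied (e.g. from
#' [simulate_dataset()]), the empirical fraction of correct declarations is
#' added; the posterior-based accuracy remains the headline metric.
#'
#' @param dataset A step-level tibble or `cohort_dataset`.
#' @param blocks Named list of [block_spec()]s covering the block ids present.
#' @param config A [task_config()].
#' @param sequences Optional tibble with columns `block`, `trial`,
#'   `true_lake` (or the `sequences` element of a `cohort_dataset`, which is
#'   used automatically).
#' @return A tibble, one row per subject x block.
#' @export
summarize_behavior <- function(dataset, blocks = default_blocks(config),
                               config = task_config(), sequences = NULL) {
  if (inherits(dataset, "cohort_dataset")) {
    if (is.null(sequences)) sequences <- dplyr::bind_rows(dataset$sequences)
    dataset <- dataset$steps
  }
  if (is.list(sequences) && !is.data.frame(sequences)) {
    sequences <- dplyr::bind_rows(sequences)
  }
  trials <- nest_trials(dataset, config)
  block_ids <- vapply(blocks, `[[`, integer(1), "block_id")
  unknown <- setdiff(unique(trials$block), block_ids)
  if (length(unknown)) {
    stop("unknown block id(s) in dataset: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }

  trials$p_declared <- {
    p_gold <- posterior_gold(trials$dtd, trials$n_g, config)
    ifelse(trials$declared == config$lake_labels[1], p_gold, 1 - p_gold)
  }
  if (!is.null(sequences)) {
    trials <- dplyr::left_join(
      trials, sequences[c("block", "trial", "true_lake")],
      by = c("block", "trial")
    )
    trials$correct <- trials$declared == trials$true_lake
  } else {
    trials$correct <- NA
  }
  trials$points <- purrr::pmap_dbl(
    trials[c("block", "dtd", "p_declared", "correct")],
    function(block, dtd, p_declared, correct) {
      blk <- blocks[[match(block, block_ids)]]
      cost_paid <- sum(blk$cost_schedule[seq_len(dtd)])
      payoff <- if (!is.na(correct)) {
        # realized payoff when the true lake is known
        if (correct) blk$reward_correct else -blk$cost_wrong
      } else {
        # expected payoff under the declaration posterior
        p_declared * blk$reward_correct - (1 - p_declared) * blk$cost_wrong
      }
      payoff - cost_paid
    }
  )

  trials |>
    dplyr::group_by(.data$subject_id, .data$group, .data$block) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      mean_dtd = mean(.data$dtd),
      median_dtd = stats::median(.data$dtd),
      mean_accuracy = mean(.data$p_declared),
      frac_correct = mean(.data$correct),
      total_points = sum(.data$points),
      n_jtc_trials = sum(.data$dtd <= 2),
      jtc = stats::median(.data$dtd) <= 2,
      .groups = "drop"
    )
}

#' Trial-level jumping-to-conclusions flags
#'
#' The dichotomous JTC classification: a trial exhibits jumping to
#' conclusions when the decision was made after one or two pieces of
#' information.
#'
#' @param dtd Vector of draws-to-decision values.
#' @return Logical vector.
#' @export
#' @examples
#' jtc_flag(c(1, 2, 3))  # TRUE TRUE FALSE
jtc_flag <- function(dtd) dtd <= 2

#' Two-group comparison of a behavioural metric or parameter estimate
#'
#' Runs the field's conventional tests: a two-sided Mann-Whitney (Wilcoxon
#' rank-sum) test for skewed metrics such as DTD or the cost parameter, a
#' Welch two-sample t test for approximately symmetric ones such as the
#' temperature, and (when a covariate is supplied) a Spearman rank
#' correlation of the metric with the covariate within each group. The method
#' actually used is recorded in the output.
#'
#' @param data A data frame with a `group` column and the metric column.
#' @param metric Name of the metric column (string).
#' @param test `"mann-whitney"` or `"t"`.
#' @param covariate Optional name of a covariate column for the Spearman
#'   correlation.
#' @return A list of class `group_test` with the test statistic(s),
#'   p value(s) and method names.
#' @export
group_compare <- function(data, metric, test = c("mann-whitney", "t"),
                          covariate = NULL) {
  test <- match.arg(test)
  stopifnot(metric %in% names(data), "group" %in% names(data))
  groups <- sort(unique(data$group))
  if (length(groups) != 2) stop("exactly two groups required", call. = FALSE)
  x <- data[[metric]][data$group == groups[1]]
  y <- data[[metric]][data$group == groups[2]]
  if (length(x) < 2 || length(y) < 2) {
    stop("each group needs at least 2 subjects", call. = FALSE)
  }
  main <- if (test == "mann-whitney") {
    ht <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
    list(method = "Mann-Whitney U (two-sided, normal approximation)",
         statistic = unname(ht$statistic), p_value = ht$p.value)
  } else {
    ht <- stats::t.test(x, y)
    list(method = "Welch two-sample t (two-sided)",
         statistic = unname(ht$statistic), df = unname(ht$parameter),
         p_value = ht$p.value)
  }
  out <- list(metric = metric, groups = groups,
              n = c(length(x), length(y)), test = main)
  if (!is.null(covariate)) {
    stopifnot(covariate %in% names(data))
    out$spearman <- lapply(stats::setNames(groups, groups), function(g) {
      d <- data[data$group == g, ]
      ct <- suppressWarnings(
        stats::cor.test(d[[metric]], d[[covariate]], method = "spearman")
      )
      list(method = "Spearman rank correlation",
           rho = unname(ct$estimate), p_value = ct$p.value)
    })
  }
  structure(out, class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  cat("<group_test> ", x$metric, ": ", x$groups[1], " (n=", x$n[1], ") vs ",
      x$groups[2], " (n=", x$n[2], ")\n  ", x$test$method, ": statistic = ",
      signif(x$test$statistic, 4), ", p = ", signif(x$test$p_value, 3),
      "\n", sep = "")
  if (!is.null(x$spearman)) {
    for (g in names(x$spearman)) {
      s <- x$spearman[[g]]
      cat("  Spearman (", g, "): rho = ", signif(s$rho, 3), ", p = ",
          signif(s$p_value, 3), "\n", sep = "")
    }
  }
  invisible(x)
}

#' Within-block consistency of DTD (intraclass correlation)
#'
#' Quantifies how consistent each subject's draws-to-decision are across the
#' trials of a block, per group: the two-way mixed-effects, single-measure,
#' consistency-type intraclass correlation ICC(3,1) over the subject x trial
#' DTD matrix, computed from the mean squares of the two-way decomposition:
#' `(MS_subjects - MS_error) / (MS_subjects + (k - 1) MS_error)` with `k`
#' trials. Degenerate matrices (no between-subject variance, e.g. a cohort of
#' identical deterministic agents) yield `NA` with the reason recorded.
#'
#' @param dataset A step-level tibble or `cohort_dataset`.
#' @param config A [task_config()].
#' @return A tibble: `group`, `block`, `n_subjects`, `n_trials`, `icc`,
#'   `icc_type`, `note`.
#' @export
icc_consistency <- function(dataset, config = task_config()) {
  if (inherits(dataset, "cohort_dataset")) dataset <- dataset$steps
  trials <- nest_trials(dataset, config)
  combos <- dplyr::distinct(trials, .data$group, .data$block)
  purrr::pmap_dfr(combos, function(group, block) {
    d <- trials[trials$group == group & trials$block == block, ]
    m <- stats::xtabs(dtd ~ subject_id + trial, data = d)
    n <- nrow(m); k <- ncol(m)
    if (k < 2) stop("ICC needs at least 2 trials per block", call. = FALSE)
    row_m <- rowMeans(m); col_m <- colMeans(m); grand <- mean(m)
    ss_subj <- k * sum((row_m - grand)^2)
    ss_trial <- n * sum((col_m - grand)^2)
    ss_err <- sum((m - outer(row_m, rep(1, k)) -
                     outer(rep(1, n), col_m) + grand)^2)
    ms_subj <- ss_subj / (n - 1)
    ms_err <- ss_err / ((n - 1) * (k - 1))
    denom <- ms_subj + (k - 1) * ms_err
    if (denom <= 0 || (ms_subj == 0 && ms_err == 0)) {
      icc <- NA_real_
      note <- "degenerate: no variance in DTD"
    } else {
      icc <- (ms_subj - ms_err) / denom
      note <- ""
    }
    tibble::tibble(group = group, block = block, n_subjects = n, n_trials = k,
                   icc = icc, icc_type = "ICC(3,1) consistency", note = note)
  })
}
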