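#' Task configuration for the fish sampling task
#'
#' The task presents fish drawn one at a time from one of two lakes whose
#' colour ratios are mirror images of each other: the gold lake "G" contains
#' gold fish in proportion `majority_prob` (and black fish otherwise), the
#' black lake "B" the reverse. The subject sees the first fish unconditionally
#' and may then, at every step, sample another fish or declare a lake, up to a
#' hard cap of `draw_cap` fish.
#'
#' @param majority_prob Probability that a fish matches its lake's majority
#'   colour, i.e. P(gold | G) = P(black | B). Must lie strictly between 0.5
#'   and 1. Default 0.6 (the 60:40 ratio).
#' @param draw_cap Maximum number of fish that can be seen in a trial.
#' @param n_trials_per_block Number of trials per block.
#' @param lake_labels Length-2 character vector naming the gold-majority and
#'   black-majority lakes.
#' @return An object of class `task_config`.
#' @export
#' @examples
#' cfg <- task_config()
#' cfg$majority_prob
task_config <- function(majority_prob = 0.6, draw_cap = 20L,
                        n_trials_per_block = 10L,
                        lake_labels = c("G", "B")) {
  stopifnot(is.numeric(majority_prob), length(majority_prob) == 1)
  if (!(majority_prob > 0.5 && majority_prob < 1)) {
    stop("`majority_prob` must lie strictly between 0.5 and 1", call. = FALSE)
  }
  draw_cap <- as.integer(draw_cap)
  if (is.na(draw_cap) || draw_cap < 1) stop("`draw_cap` must be >= 1", call. = FALSE)
  stopifnot(length(lake_labels) == 2, !anyDuplicated(lake_labels))
  structure(
    list(
      majority_prob = majority_prob,
      draw_cap = draw_cap,
      n_trials_per_block = as.integer(n_trials_per_block),
      lake_labels = as.character(lake_labels)
    ),
    class = "task_config"
  )
}

#' @export
print.task_config <- function(x, ...) {
  cat("<task_config> ratio ", round(100 * x$majority_prob), ":",
      round(100 * (1 - x$majority_prob)), ", draw cap ", x$draw_cap,
      ", lakes ", x$lake_labels[1], "/", x$lake_labels[2], "\n", sep = "")
  invisible(x)
}

#' Specification of one task block
#'
#' A block fixes the payoff for declaring (`reward_correct` points for the
#' right lake, `cost_wrong` points lost for the wrong one) and the price of
#' information: `cost_schedule[k]` is the number of points charged for seeing
#' the k-th fish. The first fish is always shown, so `cost_schedule[1]` never
#' enters any decision; it is kept for bookkeeping.
#'
#' @param block_id Integer block index.
#' @param reward_correct Points won for declaring the true lake.
#' @param cost_wrong Points lost for declaring the wrong lake.
#' @param cost_schedule Numeric vector of length `draw_cap`: points charged
#'   per successive draw. A scalar is recycled to all draws.
#' @param draw_cap Draw cap the schedule must cover.
#' @param label Optional human-readable block label.
#' @return An object of class `block_spec`.
#' @export
block_spec <- function(block_id, reward_correct, cost_wrong, cost_schedule,
                       draw_cap = 20L, label = NULL) {
  stopifnot(reward_correct >= 0, cost_wrong >= 0)
  draw_cap <- as.integer(draw_cap)
  if (length(cost_schedule) == 1) cost_schedule <- rep(cost_schedule, draw_cap)
  if (length(cost_schedule) != draw_cap) {
    stop("`cost_schedule` must have one entry per draw (", draw_cap, ")", call. = FALSE)
  }
  structure(
    list(
      block_id = as.integer(block_id),
      reward_correct = reward_correct,
      cost_wrong = cost_wrong,
      cost_schedule = as.numeric(cost_schedule),
      draw_cap = draw_cap,
      label = label %||% paste("Block", block_id)
    ),
    class = "block_spec"
  )
}

#' @export
print.block_spec <- function(x, ...) {
  cs <- x$cost_schedule
  sched <- if (all(cs == cs[1])) {
    paste0("flat ", cs[1])
  } else if (length(unique(diff(cs))) == 1) {
    paste0(cs[1], ", ", cs[2], ", ", cs[3], ", ... (escalating)")
  } else "custom"
  cat("<block_spec> ", x$label, ": +", x$reward_correct, "/-", x$cost_wrong,
      ", draw cost ", sched, "\n", sep = "")
  invisible(x)
}

#' The four standard blocks of the task
#'
#' Block 1 gives correct/incorrect feedback only; for modelling it carries the
#' same nominal +/-100 payoff as the later blocks, since the cost and
#' temperature parameters are only interpretable relative to the declaration
#' stake. Block 2 pays +/-100 with free sampling. Block 3 adds a flat 5-point
#' charge for every fish after the first. Block 4 escalates the charge: the
#' k-th fish costs 5*(k-1) points.
#'
#' @param config A [task_config()].
#' @return A named list of four [block_spec()] objects (`"1"` ... `"4"`).
#' @export
#' @examples
#' blocks <- default_blocks(task_config())
#' blocks[["3"]]$cost_schedule[1:3]  # 0 5 5
default_blocks <- function(config = task_config()) {
  cap <- config$draw_cap
  blocks <- list(
    block_spec(1L, 100, 100, rep(0, cap), cap, label = "Block 1 (feedback only)"),
    block_spec(2L, 100, 100, rep(0, cap), cap, label = "Block 2 (win/lose 100)"),
    block_spec(3L, 100, 100, c(0, rep(5, cap - 1L)), cap,
               label = "Block 3 (flat 5-point draw cost)"),
    block_spec(4L, 100, 100, 5 * (seq_len(cap) - 1), cap,
               label = "Block 4 (escalating draw cost)")
  )
  names(blocks) <- as.character(1:4)
  blocks
}

#' Generate fish sequences
#'
#' Generates `n` full-length colour sequences, half (rounding down) drawn from
#' each lake, with the lake order shuffled. Colours are either i.i.d. with the
#' lake's majority probability, or — when `exact_ratio` is set — a seeded
#' permutation of the exact majority/minority multiset (12 majority and 8
#' minority fish at the default 60:40 ratio over 20 draws), emulating
#' constrained pseudo-random stimulus sequences that are identical for every
#' subject.
#'
#' @param config A [task_config()].
#' @param n Number of sequences.
#' @param exact_ratio Logical; constrain every sequence to the exact ratio.
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments.
#' @return A tibble with columns `trial`, `true_lake`, `colors` (list column
#'   of single-character vectors, length `draw_cap`), `exact_ratio`.
#' @export
generate_sequences <- function(config = task_config(), n, exact_ratio = FALSE,
                               seed = 1L) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed) || seed != round(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  stopifnot(n >= 1)
  n <- as.integer(n)
  cap <- config$draw_cap
  q <- config$majority_prob
  gold_lab <- config$lake_labels[1]
  black_lab <- config$lake_labels[2]

  with_local_seed(seed, {
    n_g <- n %/% 2L
    lakes <- c(rep(gold_lab, n - n_g), rep(black_lab, n_g))
    lakes <- sample(lakes)
    n_major <- round(q * cap)
    colors <- lapply(lakes, function(lake) {
      major <- if (lake == gold_lab) "g" else "b"
      minor <- if (lake == gold_lab) "b" else "g"
      if (exact_ratio) {
        sample(c(rep(major, n_major), rep(minor, cap - n_major)))
      } else {
        ifelse(stats::runif(cap) < q, major, minor)
      }
    })
    tibble::tibble(
      trial = seq_len(n),
      true_lake = lakes,
      colors = colors,
      exact_ratio = exact_ratio
    )
  })
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

trial_csv_cols <- c("subject_id", "group", "block", "trial", "step",
                    "fish_color", "action")

#' Read and write trial-level data
#'
#' The on-disk format is a UTF-8 comma-separated file with a mandatory header
#' and one row per decision step: `subject_id, group, block, trial, step,
#' fish_color, action`, with `action` one of `S` (sample another fish), `DG`
#' (declare gold-majority lake), `DB` (declare black-majority lake) and
#' `fish_color` the colour shown at that step (`g`/`b`). Within a trial steps
#' run 1..DTD; every step before the last is `S` and the last is a
#' declaration.
#'
#' @param path File path.
#' @param config A [task_config()] used for validation (draw cap).
#' @return `read_trials()` returns a step-level tibble (the package's
#'   `Dataset` representation); `write_trials()` returns `path` invisibly.
#' @export
read_trials <- function(path, config = task_config()) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  missing <- setdiff(trial_csv_cols, names(df))
  if (length(missing)) {
    stop("trial file is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("block", "trial", "step")) df[[col]] <- as.integer(df[[col]])
  validate_dataset(df, config)
  df
}

#' @rdname read_trials
#' @param dataset A step-level tibble as returned by [read_trials()] or
#'   [simulate_dataset()].
#' @export
write_trials <- function(dataset, path, config = task_config()) {
  validate_dataset(dataset, config)
  readr::write_csv(dataset[trial_csv_cols], path, progress = FALSE)
  invisible(path)
}

#' Validate a step-level dataset
#'
#' Checks the trial-record invariants: actions are `S`/`DG`/`DB`, fish colours
#' are `g`/`b`, steps within a trial are contiguous from 1, nothing follows a
#' declaration, every trial ends with a declaration, and no trial exceeds the
#' draw cap. Violations raise an error naming the offending row (in file/frame
#' order, header excluded).
#'
#' @inheritParams write_trials
#' @return The dataset, invisibly.
#' @export
validate_dataset <- function(dataset, config = task_config()) {
  missing <- setdiff(trial_csv_cols, names(dataset))
  if (length(missing)) {
    stop("dataset is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(dataset) == 0) return(invisible(dataset))
  bad <- which(!dataset$action %in% c("S", "DG", "DB"))
  if (length(bad)) stop("row ", bad[1], ": unknown action '", dataset$action[bad[1]], "'",
                        call. = FALSE)
  bad <- which(!dataset$fish_color %in% c("g", "b"))
  if (length(bad)) stop("row ", bad[1], ": unknown fish colour '",
                        dataset$fish_color[bad[1]], "'", call. = FALSE)
  bad <- which(dataset$step > config$draw_cap)
  if (length(bad)) stop("row ", bad[1], ": step ", dataset$step[bad[1]],
                        " exceeds the draw cap (", config$draw_cap, ")", call. = FALSE)

  key <- paste(dataset$subject_id, dataset$block, dataset$trial, sep = "\r")
  row_id <- seq_len(nrow(dataset))
  for (idx in split(row_id, key)) {
    idx <- idx[order(dataset$step[idx])]
    steps <- dataset$step[idx]
    if (!identical(steps, seq_along(steps))) {
      stop("row ", idx[which(steps != seq_along(steps))[1]],
           ": steps within a trial must be contiguous from 1", call. = FALSE)
    }
    acts <- dataset$action[idx]
    ndecl <- length(acts)
    first_decl <- which(acts != "S")[1]
    if (is.na(first_decl)) {
      stop("row ", idx[ndecl], ": trial never ends with a declaration", call. = FALSE)
    }
    if (first_decl < ndecl) {
      stop("row ", idx[first_decl + 1L],
           ": action recorded after a declaration at step ", first_decl, call. = FALSE)
    }
  }
  invisible(dataset)
}

#' Read and write task/block configuration documents
#'
#' Serializes a [task_config()] together with its [block_spec()]s as a JSON
#' or YAML document (chosen by file extension), so a run's task definition
#' can live beside its data. Round-trips exactly.
#'
#' @param config A [task_config()].
#' @param blocks A list of [block_spec()]s.
#' @param path Destination (`.json`, `.yaml` or `.yml`).
#' @return `write_task_config()` returns `path` invisibly;
#'   `read_task_config()` returns a list with elements `config` and
#'   `blocks`.
#' @export
write_task_config <- function(config, blocks, path) {
  doc <- list(
    task = list(
      majority_prob = config$majority_prob,
      draw_cap = config$draw_cap,
      n_trials_per_block = config$n_trials_per_block,
      lake_labels = config$lake_labels
    ),
    blocks = lapply(blocks, function(b) list(
      block_id = b$block_id,
      reward_correct = b$reward_correct,
      cost_wrong = b$cost_wrong,
      cost_schedule = b$cost_schedule,
      label = b$label
    ))
  )
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(doc, path)
  } else {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_task_config
#' @export
read_task_config <- function(path) {
  doc <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (is.null(doc$task) || is.null(doc$blocks)) {
    stop("configuration document needs `task` and `blocks` entries",
         call. = FALSE)
  }
  config <- task_config(
    majority_prob = doc$task$majority_prob,
    draw_cap = doc$task$draw_cap,
    n_trials_per_block = doc$task$n_trials_per_block,
    lake_labels = unlist(doc$task$lake_labels)
  )
  blocks <- lapply(if (is.data.frame(doc$blocks)) {
    split(doc$blocks, seq_len(nrow(doc$blocks)))
  } else doc$blocks, function(b) {
    block_spec(b$block_id, b$reward_correct, b$cost_wrong,
               unlist(b$cost_schedule), draw_cap = config$draw_cap,
               label = unlist(b$label))
  })
  names(blocks) <- vapply(blocks, function(b) as.character(b$block_id), "")
  list(config = config, blocks = blocks)
}

#' Nest a step-level dataset into trial records
#'
#' Collapses the one-row-per-step representation into one row per trial with
#' the derived quantities used throughout the package: draws to decision
#' (`dtd`), the number of gold fish seen (`n_g`), the declared lake and the
#' posterior-based fields added by downstream summaries.
#'
#' @inheritParams write_trials
#' @return A tibble with one row per subject x block x trial: `subject_id`,
#'   `group`, `block`, `trial`, `dtd`, `n_g`, `declared` (lake label or `NA`),
#'   `colors` (list column of the colours seen).
#' @export
nest_trials <- function(dataset, config = task_config()) {
  validate_dataset(dataset, config)
  dataset |>
    dplyr::arrange(.data$subject_id, .data$block, .data$trial, .data$step) |>
    dplyr::group_by(.data$subject_id, .data$group, .data$block, .data$trial) |>
    dplyr::summarise(
      dtd = dplyr::n(),
      n_g = sum(.data$fish_color == "g"),
      declared = dplyr::case_match(dplyr::last(.data$action),
                                   "DG" ~ "G", "DB" ~ "B",
                                   .default = NA_character_),
      colors = list(.data$fish_color),
      .groups = "drop"
    )
}
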