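#' Posterior probability of the gold-majority lake
#'
#' Given `n_d` fish seen of which `n_g` were gold, and equal prior probability
#' on the two lakes, Bayes' theorem gives
#' \deqn{P(G \mid n_d, n_g) = \frac{q^{n_g}(1-q)^{n_d-n_g}}
#'   {q^{n_g}(1-q)^{n_d-n_g} + (1-q)^{n_g} q^{n_d-n_g}}
#'   = \frac{1}{1 + r^{\,n_d - 2 n_g}}, \quad r = \frac{q}{1-q},}
#' where `q` is the majority probability. Only the excess of one colour over
#' the other matters. Vectorised over `n_d`/`n_g`.
#'
#' @param n_d Draws seen (0 allowed: the prior state).
#' @param n_g Gold fish among them.
#' @param config A [task_config()].
#' @return Posterior probability (or vector) of the gold-majority lake.
#' @export
#' @examples
#' posterior_gold(20, 12)        # 0.835
#' posterior_gold(1, 1)          # 0.6
posterior_gold <- function(n_d, n_g, config = task_config()) {
  if (any(n_g > n_d) || any(n_g < 0) || any(n_d < 0)) {
    stop("need 0 <= n_g <= n_d", call. = FALSE)
  }
  q <- config$majority_prob
  log_r <- log(q) - log1p(-q)
  stats::plogis(-(n_d - 2 * n_g) * log_r)
}

#' Action values of declaring each lake
#'
#' Declaring lake G is worth the stake on being right minus the stake on being
#' wrong: `Q(DG) = R_C * P(G|s) - C_W * P(B|s)`, and symmetrically for DB.
#' With the task's symmetric stakes (`R_C = C_W`) this reduces to
#' `R_C * (2 P(G|s) - 1)`.
#'
#' @inheritParams posterior_gold
#' @param block A [block_spec()].
#' @return A list with numeric components `Q_DG` and `Q_DB` (vectorised).
#' @export
declare_values <- function(n_d, n_g, block, config = task_config()) {
  p <- posterior_gold(n_d, n_g, config)
  list(
    Q_DG = block$reward_correct * p - block$cost_wrong * (1 - p),
    Q_DB = block$reward_correct * (1 - p) - block$cost_wrong * p
  )
}

#' Softmax action probabilities
#'
#' Converts action values to choice probabilities, `p(a)` proportional to
#' `exp(q_a / T)`, with a max-shifted exponential so large stakes cannot
#' overflow. At the draw cap sampling is not an option and the softmax is
#' taken over the two declarations only: pass a length-2 `q`.
#'
#' @param q Numeric vector of action values (or a matrix, one state per row).
#' @param temperature Decision temperature `T > 0`. As `T` grows choices tend
#'   to uniform; as `T` shrinks to 0 the maximiser is chosen almost surely.
#' @return Probabilities of the same shape as `q`, summing to 1 per state.
#' @export
action_probabilities <- function(q, temperature) {
  if (!is.numeric(temperature) || length(temperature) != 1 || temperature <= 0) {
    stop("`temperature` must be a single positive number", call. = FALSE)
  }
  if (any(!is.finite(q))) stop("action values must be finite", call. = FALSE)
  if (is.matrix(q)) {
    z <- q / temperature
    z <- z - apply(z, 1, max)
    e <- exp(z)
    e / rowSums(e)
  } else {
    z <- q / temperature
    e <- exp(z - max(z))
    e / sum(e)
  }
}

# log softmax probabilities, matrix rows = states
log_softmax <- function(qmat, temperature) {
  z <- qmat / temperature
  m <- apply(z, 1, max)
  z <- z - m
  z - log(rowSums(exp(z)))
}

#' Solve the value table for a block by backward induction
#'
#' Fills action values `Q(DG)`, `Q(DB)`, `Q(DS)` and state values `V` for
#' every reachable belief state `(n_d, n_g)`, `1 <= n_d <= draw_cap`,
#' `0 <= n_g <= n_d`. The sampling value is the predictive expectation of the
#' next state's value minus the cost of the next draw:
#' `Q(DS; s) = -C_S + P(g|s) V(n_d+1, n_g+1) + P(b|s) V(n_d+1, n_g)`, where
#' the predictive colour probability mixes the two lakes through the current
#' posterior. At `n_d = draw_cap` sampling is unavailable and `Q(DS)` is `NA`.
#'
#' Two backup modes are supported: `"max"` (the ideal, deterministically
#' maximising agent, `V = max(q)`) and `"softmax"` (a noisy agent,
#' `V = sum_a q_a p(a|q)` with softmax probabilities at temperature `T`).
#'
#' @param block A [block_spec()] providing payoff and objective cost
#'   schedule.
#' @param config A [task_config()].
#' @param mode `"max"` or `"softmax"`.
#' @param temperature Decision temperature, required for `"softmax"`.
#' @param cost Optional constant subjective cost per draw; when supplied it
#'   replaces the block's objective schedule for every draw after the first
#'   (the first fish is always shown free of charge). This is how a subject's
#'   cost-of-sampling parameter enters the model.
#' @return An object of class `value_table`: a list of `draw_cap x
#'   (draw_cap+1)` matrices `Q_DG`, `Q_DB`, `Q_DS`, `V` (rows `n_d`, columns
#'   `n_g = 0..draw_cap`; `NA` where `n_g > n_d`), plus the solver metadata.
#' @export
solve_value_table <- function(block, config = task_config(),
                              mode = c("max", "softmax"),
                              temperature = NULL, cost = NULL) {
  mode <- match.arg(mode)
  if (mode == "softmax") {
    if (is.null(temperature) || temperature <= 0) {
      stop("softmax mode needs `temperature` > 0", call. = FALSE)
    }
  }
  cap <- config$draw_cap
  q_prob <- config$majority_prob
  sched <- if (is.null(cost)) block$cost_schedule else {
    if (cost < 0) stop("`cost` must be non-negative", call. = FALSE)
    rep(cost, cap)
  }

  Q_DG <- Q_DB <- Q_DS <- V <- matrix(NA_real_, cap, cap + 1L,
                                      dimnames = list(n_d = 1:cap, n_g = 0:cap))
  for (nd in cap:1) {
    ng <- 0:nd
    dv <- declare_values(nd, ng, block, config)
    qg <- dv$Q_DG; qb <- dv$Q_DB
    Q_DG[nd, ng + 1L] <- qg
    Q_DB[nd, ng + 1L] <- qb
    if (nd < cap) {
      p <- posterior_gold(nd, ng, config)
      p_gold_next <- p * q_prob + (1 - p) * (1 - q_prob)
      qs <- -sched[nd + 1L] +
        p_gold_next * V[nd + 1L, ng + 2L] +
        (1 - p_gold_next) * V[nd + 1L, ng + 1L]
      Q_DS[nd, ng + 1L] <- qs
      qmat <- cbind(qg, qb, qs)
    } else {
      qmat <- cbind(qg, qb)
    }
    V[nd, ng + 1L] <- if (mode == "max") {
      apply(qmat, 1, max)
    } else {
      pr <- action_probabilities(qmat, temperature)
      rowSums(qmat * pr)
    }
  }
  structure(
    list(Q_DG = Q_DG, Q_DB = Q_DB, Q_DS = Q_DS, V = V,
         mode = mode, temperature = temperature,
         cost = cost, block = block, config = config),
    class = "value_table"
  )
}

#' @export
print.value_table <- function(x, ...) {
  cat("<value_table> ", x$block$label, ", mode ", x$mode,
      if (x$mode == "softmax") paste0(" (T = ", signif(x$temperature, 3), ")"),
      if (!is.null(x$cost)) paste0(", subjective cost ", signif(x$cost, 3)),
      ", states n_d = 1..", x$config$draw_cap, "\n", sep = "")
  invisible(x)
}

# Greedy action at a state from a (deterministic-mode) table.
# Ties: sampling is preferred over declaring (so a zero-cost ideal agent keeps
# sampling); between equal declarations "G" is returned but accuracy is scored
# by the 0.5 posterior, never by the arbitrary label.
greedy_action <- function(vt, n_d, n_g) {
  qg <- vt$Q_DG[n_d, n_g + 1L]
  qb <- vt$Q_DB[n_d, n_g + 1L]
  qs <- if (n_d < vt$config$draw_cap) vt$Q_DS[n_d, n_g + 1L] else -Inf
  best_decl <- max(qg, qb)
  # exact ties are structural at zero cost (the posterior is a martingale, so
  # E[V(next)] can equal the declare value); compare with a tolerance so
  # rounding in the backup cannot flip a tie into an early declaration
  tol <- 1e-9 * (1 + abs(best_decl))
  if (qs >= best_decl - tol) "S" else if (qg >= qb) "DG" else "DB"
}

#' Smallest colour difference at which declaring beats sampling
#'
#' For a deterministic-mode value table, finds the smallest absolute
#' black-minus-gold difference `|n_b - n_g|` such that, at every state with
#' that difference not adjacent to the draw cap (`n_d <= draw_cap - 2`), the
#' better declaration's value strictly exceeds the sampling value. States near
#' the cap are excluded because the truncated horizon makes declaring
#' artificially attractive there.
#'
#' @param vt A deterministic-mode [solve_value_table()] result.
#' @return The threshold difference (integer), or `NA` if declaring never
#'   dominates away from the cap.
#' @export
declare_threshold <- function(vt) {
  stopifnot(inherits(vt, "value_table"))
  cap <- vt$config$draw_cap
  for (d in 0:(cap - 2L)) {
    dominated <- TRUE
    seen <- FALSE
    for (nd in 1:(cap - 2L)) {
      # states with |n_d - 2 n_g| = d: n_g = (n_d - d)/2 or (n_d + d)/2
      for (ng in unique(c((nd - d) / 2, (nd + d) / 2))) {
        if (ng < 0 || ng > nd || ng != round(ng)) next
        seen <- TRUE
        best_decl <- max(vt$Q_DG[nd, ng + 1L], vt$Q_DB[nd, ng + 1L])
        if (!(best_decl > vt$Q_DS[nd, ng + 1L])) dominated <- FALSE
      }
    }
    if (seen && dominated) return(d)
  }
  NA_integer_
}

#' Run the deterministic (ideal-agent) policy over fish sequences
#'
#' Walks each sequence under the greedy policy of a deterministic-mode value
#' table and reports, per trial: draws to decision, the declared lake, the
#' posterior probability of the declared lake at declaration (the Bayesian
#' accuracy; 0.5 when the forced final declaration is indifferent), whether
#' the declaration was correct, and the points won under the block's payoff
#' and objective cost schedule.
#'
#' @param vt A deterministic-mode [solve_value_table()].
#' @param sequences A tibble from [generate_sequences()].
#' @return A tibble, one row per sequence.
#' @export
run_ideal_policy <- function(vt, sequences) {
  stopifnot(inherits(vt, "value_table"), vt$mode == "max")
  cfg <- vt$config
  blk <- vt$block
  cap <- cfg$draw_cap
  gold_lab <- cfg$lake_labels[1]
  purrr::pmap_dfr(
    sequences[c("trial", "true_lake", "colors")],
    function(trial, true_lake, colors) {
      if (length(colors) < cap) stop("sequence shorter than the draw cap", call. = FALSE)
      ng <- 0L
      cost_paid <- 0
      for (nd in 1:cap) {
        if (colors[nd] == "g") ng <- ng + 1L
        cost_paid <- cost_paid + blk$cost_schedule[nd]
        act <- greedy_action(vt, nd, ng)
        if (act != "S") break
      }
      p_gold <- posterior_gold(nd, ng, cfg)
      declared <- if (act == "S") {
        # can only happen at the cap through the tie-break; forced declaration
        if (p_gold >= 0.5) "DG" else "DB"
      } else act
      decl_lake <- if (declared == "DG") gold_lab else cfg$lake_labels[2]
      p_decl <- if (declared == "DG") p_gold else 1 - p_gold
      correct <- decl_lake == true_lake
      points <- (if (correct) blk$reward_correct else -blk$cost_wrong) - cost_paid
      tibble::tibble(
        trial = trial, true_lake = true_lake, dtd = nd, n_g = ng,
        declared = decl_lake, p_declared = p_decl,
        correct = correct, points = points
      )
    }
  )
}

#' Exact policy statistics under i.i.d. sequences
#'
#' Computes, by forward dynamic programming over belief states rather than
#' Monte Carlo, the exact expected draws to decision and probability of a
#' correct declaration for the greedy policy of a deterministic value table,
#' when fish are drawn i.i.d. from a lake with the configured majority
#' probability and the two lakes are equally likely. States where the forced
#' final declaration is indifferent contribute 0.5 to the accuracy. This is
#' the absorbing-random-walk enumeration: for the flat-cost block the policy
#' stops when the colour difference reaches 2 and the closed form ignoring
#' the cap is (1-(2/3)^2)/(1-(2/3)^4) = 9/13.
#'
#' @param vt A deterministic-mode [solve_value_table()].
#' @return A list with `expected_dtd`, `p_correct`, `expected_points`.
#' @export
ideal_policy_exact <- function(vt) {
  stopifnot(inherits(vt, "value_table"), vt$mode == "max")
  cfg <- vt$config
  blk <- vt$block
  cap <- cfg$draw_cap
  q <- cfg$majority_prob
  gold_lab <- cfg$lake_labels[1]

  total_dtd <- 0; total_correct <- 0
  for (lake in cfg$lake_labels) {
    p_g_draw <- if (lake == gold_lab) q else 1 - q   # P(gold fish | lake)
    # reach[ng+1] = P(reach state (nd, ng) with the policy still sampling)
    reach <- c(1 - p_g_draw, p_g_draw)               # after the first (free) fish
    dtd <- 0; correct <- 0
    for (nd in 1:cap) {
      ng <- 0:nd
      stopped <- if (nd == cap) rep(TRUE, nd + 1L) else vapply(ng, function(g) {
        reach[g + 1L] > 0 && greedy_action(vt, nd, g) != "S"
      }, logical(1))
      w <- reach * stopped
      if (any(w > 0)) {
        p_gold <- posterior_gold(nd, ng, cfg)
        # declared lake = posterior mode; forced indifference scores half
        declared_gold <- p_gold > 0.5
        p_corr_state <- ifelse(p_gold == 0.5, 0.5,
                               as.numeric(declared_gold == (lake == gold_lab)))
        dtd <- dtd + sum(w * nd)
        correct <- correct + sum(w * p_corr_state)
      }
      if (nd == cap) break
      cont <- reach * !stopped
      nxt <- numeric(nd + 2L)
      # under the true lake the next colour is gold w.p. p_g_draw; the belief
      # only routes which state is reached
      nxt[ng + 1L] <- nxt[ng + 1L] + cont * (1 - p_g_draw)
      nxt[ng + 2L] <- nxt[ng + 2L] + cont * p_g_draw
      reach <- nxt
    }
    total_dtd <- total_dtd + 0.5 * dtd
    total_correct <- total_correct + 0.5 * correct
  }
  exp_cost <- expected_sampling_cost(vt)
  list(expected_dtd = total_dtd, p_correct = total_correct,
       expected_points = total_correct * blk$reward_correct -
         (1 - total_correct) * blk$cost_wrong - exp_cost)
}

# Expected total objective sampling cost of the greedy policy under i.i.d.
# sequences: E[sum_{k<=DTD} C_S(k)].
expected_sampling_cost <- function(vt) {
  cfg <- vt$config; blk <- vt$block; cap <- cfg$draw_cap; q <- cfg$majority_prob
  total <- 0
  for (lake in cfg$lake_labels) {
    p_g_draw <- if (lake == cfg$lake_labels[1]) q else 1 - q
    reach <- c(1 - p_g_draw, p_g_draw)
    cost <- blk$cost_schedule[1]            # the first fish is always shown
    for (nd in 1:(cap - 1L)) {
      ng <- 0:nd
      sampling <- vapply(ng, function(g) {
        reach[g + 1L] > 0 && greedy_action(vt, nd, g) == "S"
      }, logical(1))
      cont <- reach * sampling
      cost <- cost + sum(cont) * blk$cost_schedule[nd + 1L]
      nxt <- numeric(nd + 2L)
      nxt[ng + 1L] <- nxt[ng + 1L] + cont * (1 - p_g_draw)
      nxt[ng + 2L] <- nxt[ng + 2L] + cont * p_g_draw
      reach <- nxt
    }
    total <- total + 0.5 * cost
  }
  total
}

#' Ideal-agent statistics for a set of blocks
#'
#' Convenience wrapper: solves each block in deterministic mode and reports
#' the realised policy statistics on the supplied sequences together with the
#' exact (enumeration-based) expectations under i.i.d. sequences.
#'
#' @param blocks A list of [block_spec()]s (e.g. [default_blocks()]).
#' @param sequences A tibble from [generate_sequences()].
#' @param config A [task_config()].
#' @return A tibble, one row per block: realised mean DTD, mean posterior of
#'   the declared lake, fraction correct and total points on the sequences,
#'   plus exact expected DTD and accuracy under i.i.d. draws.
#' @export
ideal_policy_stats <- function(blocks, sequences, config = task_config()) {
  purrr::map_dfr(blocks, function(blk) {
    vt <- solve_value_table(blk, config, mode = "max")
    runs <- run_ideal_policy(vt, sequences)
    exact <- ideal_policy_exact(vt)
    tibble::tibble(
      block = blk$block_id,
      mean_dtd = mean(runs$dtd),
      mean_p_declared = mean(runs$p_declared),
      frac_correct = mean(runs$correct),
      total_points = sum(runs$points),
      exact_dtd = exact$expected_dtd,
      exact_p_correct = exact$p_correct
    )
  })
}

#' Simulate a noisy (softmax) agent on fish sequences
#'
#' Solves the block's value table in softmax mode with the subject's
#' subjective constant cost of sampling substituted for the objective
#' schedule, then walks each sequence sampling an action from the softmax
#' probabilities at every step; at the draw cap the choice is a forced binary
#' declaration. Reproducible for a given seed.
#'
#' @param cs Subjective cost of sampling per draw (points), `>= 0`.
#' @param temperature Decision temperature, `> 0`.
#' @param block A [block_spec()].
#' @param sequences A tibble from [generate_sequences()].
#' @param config A [task_config()].
#' @param seed Integer seed.
#' @param subject_id,group Labels stamped on the output rows.
#' @return A step-level tibble in the trial-CSV layout.
#' @export
simulate_agent <- function(cs, temperature, block, sequences,
                           config = task_config(), seed = 1L,
                           subject_id = "s1", group = "sim") {
  stopifnot(cs >= 0, temperature > 0)
  vt <- solve_value_table(block, config, mode = "softmax",
                          temperature = temperature, cost = cs)
  cap <- config$draw_cap
  with_local_seed(seed, {
    purrr::pmap_dfr(
      sequences[c("trial", "colors")],
      function(trial, colors) {
        ng <- 0L
        rows <- vector("list", cap)
        for (nd in 1:cap) {
          if (colors[nd] == "g") ng <- ng + 1L
          if (nd < cap) {
            qv <- c(vt$Q_DG[nd, ng + 1L], vt$Q_DB[nd, ng + 1L], vt$Q_DS[nd, ng + 1L])
            act <- sample(c("DG", "DB", "S"), 1,
                          prob = action_probabilities(qv, temperature))
          } else {
            qv <- c(vt$Q_DG[nd, ng + 1L], vt$Q_DB[nd, ng + 1L])
            act <- sample(c("DG", "DB"), 1,
                          prob = action_probabilities(qv, temperature))
          }
          rows[[nd]] <- tibble::tibble(
            subject_id = subject_id, group = group,
            block = block$block_id, trial = trial, step = nd,
            fish_color = colors[nd], action = act
          )
          if (act != "S") break
        }
        dplyr::bind_rows(rows[!vapply(rows, is.null, logical(1))])
      }
    )
  })
}
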