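# Independent oracle for the belief-state model on tiny tasks: everything is
# computed by plain recursion straight from the defining formulas (posterior
# odds, declare values, predictive expectation for sampling, softmax or max
# backup), with no tables, vectorization or caching shared with the package
# implementation.

oracle_posterior <- function(nd, ng, q) {
  pg <- q^ng * (1 - q)^(nd - ng)
  pb <- (1 - q)^ng * q^(nd - ng)
  pg / (pg + pb)
}

# action values at a state; cost_fn(k) = points charged for the k-th draw
oracle_q <- function(nd, ng, cap, q, R, C, cost_fn, mode, temp = NULL) {
  p <- oracle_posterior(nd, ng, q)
  qg <- R * p - C * (1 - p)
  qb <- R * (1 - p) - C * p
  if (nd == cap) return(c(DG = qg, DB = qb))
  p_gold_next <- p * q + (1 - p) * (1 - q)
  v_up <- oracle_v(nd + 1, ng + 1, cap, q, R, C, cost_fn, mode, temp)
  v_dn <- oracle_v(nd + 1, ng, cap, q, R, C, cost_fn, mode, temp)
  qs <- -cost_fn(nd + 1) + p_gold_next * v_up + (1 - p_gold_next) * v_dn
  c(DG = qg, DB = qb, S = qs)
}

oracle_softmax <- function(qv, temp) {
  e <- exp(qv / temp - max(qv / temp))
  e / sum(e)
}

oracle_v <- function(nd, ng, cap, q, R, C, cost_fn, mode, temp = NULL) {
  qv <- oracle_q(nd, ng, cap, q, R, C, cost_fn, mode, temp)
  if (mode == "max") max(qv) else sum(qv * oracle_softmax(qv, temp))
}

# log-likelihood of an observed action sequence for one trial, evaluated
# step by step from the recursion above
oracle_trial_loglik <- function(colors, actions, cap, q, R, C, cost_fn, temp) {
  ng <- 0
  ll <- 0
  for (i in seq_along(actions)) {
    if (colors[i] == "g") ng <- ng + 1
    qv <- oracle_q(i, ng, cap, q, R, C, cost_fn, "softmax", temp)
    pr <- oracle_softmax(qv, temp)
    ll <- ll + log(pr[[actions[i]]])
  }
  ll
}

# exact accuracy/DTD of the deterministic policy by enumerating every colour
# sequence of length cap under each lake (ties at the forced final
# declaration score 0.5; sampling preferred on value ties)
oracle_policy_enumeration <- function(cap, q, R, C, cost_fn) {
  grids <- rep(list(c("g", "b")), cap)
  seqs <- do.call(expand.grid, c(grids, stringsAsFactors = FALSE))
  acc <- 0; dtd <- 0
  for (lake in c("G", "B")) {
    p_g <- if (lake == "G") q else 1 - q
    for (r in seq_len(nrow(seqs))) {
      colors <- unlist(seqs[r, ])
      w <- prod(ifelse(colors == "g", p_g, 1 - p_g))
      ng <- 0
      for (nd in 1:cap) {
        if (colors[nd] == "g") ng <- ng + 1
        qv <- oracle_q(nd, ng, cap, q, R, C, cost_fn, "max")
        if (nd == cap || max(qv[1:2]) > qv[["S"]] + 1e-9) break
      }
      p_post <- oracle_posterior(nd, ng, q)
      corr <- if (p_post == 0.5) 0.5 else as.numeric((p_post > 0.5) == (lake == "G"))
      acc <- acc + 0.5 * w * corr
      dtd <- dtd + 0.5 * w * nd
    }
  }
  list(p_correct = acc, expected_dtd = dtd)
}
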