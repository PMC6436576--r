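cfg_default <- task_config()
blocks_default <- default_blocks(cfg_default)

cfg_toy <- task_config(draw_cap = 4L, n_trials_per_block = 4L)
blocks_toy <- default_blocks(cfg_toy)

# small log-spaced grid used by the fitting tests; the step log-probability
# matrices are cached per block so repeated fits do not re-solve the grid
grid_small <- param_grid(24, 24, c(1e-4, 100), c(0.05, 50))
.logp_cache <- new.env(parent = emptyenv())
cached_logp <- function(block, config = cfg_default, grid = grid_small) {
  key <- paste0("b", block$block_id, "_n", length(grid$cs_nodes))
  if (is.null(.logp_cache[[key]])) {
    .logp_cache[[key]] <- grid_step_logp(grid, block, config)
  }
  .logp_cache[[key]]
}

# two-group cohort spec with Table-5-style no-cost-block generators
two_group_spec <- function(n = 31L, blocks = blocks_default[2],
                           control_cs = gamma_moments(1.9e-3, 2.0e-6),
                           control_t = gamma_moments(3.4, 13),
                           psych_cs = gamma_moments(1.7, 13),
                           psych_t = gamma_moments(4.2, 13),
                           sequence_seed = 2018L) {
  cohort_spec(
    groups = list(
      control = list(n_subjects = n, cs = control_cs, temperature = control_t),
      psychosis = list(n_subjects = n, cs = psych_cs, temperature = psych_t)
    ),
    config = cfg_default, blocks = blocks, sequence_seed = sequence_seed
  )
}
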