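# shared fixtures for the test suite: everything is generated in code

# light MCMC settings for bulk simulation tests; the model is 1-D and mixes
# fast, so short chains give ample effective sample sizes
quick_mcmc <- function(chains = 2, tune = 400, draws = 800) {
  mcmc_settings(chains = chains, tune = tune, draws = draws)
}

# one participant's comparisons with stimuli drawn uniformly on x_range
sim_participant <- function(true_jnd, n = 99, x_range = c(-40, 60),
                            lapse = 0.02, A = NULL) {
  x <- stats::runif(n, x_range[1], x_range[2])
  if (is.null(A)) A <- stats::runif(n, 1.5, 6.6)
  data.frame(participant = 1, block = 1, pair = seq_len(n),
             A_w_kg = A, B_w_kg = A * (1 + x / 100),
             x_percent = x, response = simulate_response(x, true_jnd, lapse))
}

# cohort of participants, stimuli uniform on x_range, references on 1.5-6.6
sim_cohort <- function(true_jnds, n = 99, x_range = c(-40, 60)) {
  do.call(rbind, lapply(seq_along(true_jnds), function(p) {
    cmp <- sim_participant(true_jnds[p], n = n, x_range = x_range)
    cmp$participant <- p
    cmp
  }))
}

# trials table for build_comparisons tests (net rates given directly)
make_trials <- function(net_by_block, responses_by_block) {
  out <- list()
  for (b in seq_along(net_by_block)) {
    net <- net_by_block[[b]]
    resp <- c(NA_integer_, responses_by_block[[b]])
    out[[b]] <- data.frame(participant = 1, block = b,
                           trial = seq_along(net), net_w_kg = net,
                           response = resp)
  }
  do.call(rbind, out)
}
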