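# Shared fixtures, all generated in code.

# Small clean dataset reused across tests (white background, no noise).
tiny_clean_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_dataset(3, 6, 48, 48, master_seed = 101,
                                 background_kind = "white", noise_sigma = 0)
    }
    cache
  }
})

# Random one-hot / probability-pair generator on C classes.
random_prob_pair <- function(C) {
  p1 <- stats::runif(C); p1 <- p1 / sum(p1)
  p2 <- stats::runif(C); p2 <- p2 / sum(p2)
  t <- rep(0, C); t[sample.int(C, 1)] <- 1
  list(t = t, p1 = p1, p2 = p2)
}

# Jitter every parameter of a model slightly; avoids finite-difference
# checks landing exactly on ReLU kinks that zero-initialized biases plus
# exactly-zero activations can create.
jitter_params <- function(model, sd = 1e-3) {
  for (s in leafnet:::nn_param_slots(model)) {
    s$env$params[[s$name]] <- s$env$params[[s$name]] +
      stats::rnorm(length(s$env$params[[s$name]]), sd = sd)
  }
  invisible(model)
}

# Central finite difference of `lossfn()` w.r.t. randomly sampled
# parameter entries, compared against the accumulated analytic grads.
max_fd_rel_error <- function(model, lossfn, n_checks = 20, h = 1e-5) {
  slots <- leafnet:::nn_param_slots(model)
  errs <- numeric(n_checks)
  for (r in seq_len(n_checks)) {
    s <- slots[[sample.int(length(slots), 1)]]
    i <- sample.int(length(s$env$params[[s$name]]), 1)
    orig <- s$env$params[[s$name]][i]
    s$env$params[[s$name]][i] <- orig + h
    lp <- lossfn()
    s$env$params[[s$name]][i] <- orig - h
    lm <- lossfn()
    s$env$params[[s$name]][i] <- orig
    fd <- (lp - lm) / (2 * h)
    an <- s$env$grads[[s$name]][i]
    errs[r] <- abs(fd - an) / max(1e-7, abs(fd) + abs(an))
  }
  max(errs)
}
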