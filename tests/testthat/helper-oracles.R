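# Brute-force oracles for the two-state HMM: enumerate all 2^T state paths.

enumerate_paths <- function(T) {
  as.matrix(expand.grid(rep(list(1:2), T)))
}

# log-likelihood by exhaustive summation
brute_force_loglik <- function(obs, mu, sigma, A, init) {
  T <- length(obs)
  paths <- enumerate_paths(T)
  total <- 0
  for (r in seq_len(nrow(paths))) {
    s <- paths[r, ]
    p <- init[s[1]] * stats::dnorm(obs[1], mu[s[1]], sigma[s[1]])
    for (t in 2:T)
      p <- p * A[s[t - 1], s[t]] * stats::dnorm(obs[t], mu[s[t]], sigma[s[t]])
    total <- total + p
  }
  log(total)
}

# most probable path by exhaustive argmax
brute_force_viterbi <- function(obs, mu, sigma, A, init) {
  T <- length(obs)
  paths <- enumerate_paths(T)
  best <- -Inf
  best_path <- NULL
  for (r in seq_len(nrow(paths))) {
    s <- paths[r, ]
    lp <- log(init[s[1]]) + stats::dnorm(obs[1], mu[s[1]], sigma[s[1]], log = TRUE)
    for (t in 2:T)
      lp <- lp + log(A[s[t - 1], s[t]]) +
        stats::dnorm(obs[t], mu[s[t]], sigma[s[t]], log = TRUE)
    if (lp > best) { best <- lp; best_path <- s }
  }
  best_path
}

# a hand-built state path for deterministic tests
manual_path <- function(states, times, duration = max(times),
                        dt = NA_real_) {
  seg <- data.frame(state = states,
                    t_start = utils::head(times, -1),
                    t_end = utils::tail(times, -1),
                    stringsAsFactors = FALSE)
  structure(seg, duration = duration, bleach_channel = NA_character_,
            cleaved = any(states == "CLEAVED"), dt = dt,
            class = c("state_path", "data.frame"))
}
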