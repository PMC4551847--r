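# Fixtures built in code: no data files.

# balanced design: n_subj subjects at the standard six study weeks
std_times <- c(0, 0.5, 1, 2, 3, 4)

make_design <- function(n_subj = 10, times = std_times,
                        group_sizes = NULL) {
  subj <- rep(paste0("s", seq_len(n_subj)), each = length(times))
  tt <- rep(times, n_subj)
  group <- if (!is.null(group_sizes))
    rep(rep(paste0("g", seq_along(group_sizes)), group_sizes),
        each = length(times))
  list(subject = subj, time = tt, group = group)
}

# experiment of pure-noise profiles plus optionally some with a linear
# time trend prepended
make_noise_experiment <- function(n_mol = 50, n_subj = 10,
                                  times = std_times, sd = 1,
                                  n_trend = 0, slope = 1,
                                  group_sizes = NULL, seed = 1) {
  set.seed(seed)
  d <- make_design(n_subj, times, group_sizes)
  n_col <- length(d$subject)
  vals <- matrix(rnorm(n_mol * n_col, sd = sd), n_mol, n_col)
  if (n_trend > 0)
    vals[seq_len(n_trend), ] <- vals[seq_len(n_trend), , drop = FALSE] +
      rep(slope * d$time, each = n_trend)
  rownames(vals) <- sprintf("m%03d", seq_len(n_mol))
  tc_experiment(vals, subject = d$subject, time = d$time,
                group = d$group)
}

make_profile <- function(y, n_subj = 10, times = std_times) {
  d <- make_design(n_subj, times)
  data.frame(subject = d$subject, time = d$time, value = y)
}

# independent step-up FDR oracle (sorted-ascending right-to-left minima)
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  pmin(1, adj)[order(o)]
}

# exact hypergeometric upper tail P(X >= x) by direct summation
hyper_tail_oracle <- function(x, N, K, n) {
  js <- x:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}
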