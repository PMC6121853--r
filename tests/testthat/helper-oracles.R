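# Independent oracles and small fixture builders. Everything here is coded
# separately from the package internals so that tests compare two routes.

flat_spec <- function(value, kind = "reflectance", grid = default_grid()) {
  spectrum(grid, rep(value, length(grid)), kind)
}

# literal transcription of the A1 nomogram equations, written directly from
# the published constants (independent of pigment_template's vectorization)
nomogram_oracle <- function(lambda_max, grid) {
  s <- numeric(length(grid))
  for (i in seq_along(grid)) {
    lam <- grid[i]
    x <- lambda_max / lam
    a_const <- 0.8795 + 0.0459 * exp(-((lambda_max - 300)^2) / 11940)
    alpha <- 1 / (exp(69.7 * (a_const - x)) +
                    exp(28 * (0.922 - x)) +
                    exp(-14.9 * (1.104 - x)) + 0.674)
    lmb <- 189 + 0.315 * lambda_max
    bwid <- -40.5 + 0.195 * lambda_max
    beta <- 0.26 * exp(-(((lam - lmb) / bwid)^2))
    s[i] <- alpha + beta
  }
  s / max(s)
}

# independent piecewise-linear evaluation by manual bracketing
piecewise_linear_oracle <- function(x, y, xout) {
  vapply(xout, function(x0) {
    j <- findInterval(x0, x, rightmost.closed = TRUE)
    if (x[j] == x0) return(y[j])
    y[j] + (y[j + 1] - y[j]) * (x0 - x[j]) / (x[j + 1] - x[j])
  }, numeric(1))
}

# receptor-noise-limited distance as a numeric minimization over the
# achromatic direction: dS^2 = min_c sum_i ((df_i - c)/omega_i)^2
rnl_minimization_oracle <- function(df, w) {
  f <- function(cc) sum(((df - cc) / w)^2)
  opt <- stats::optimize(f, interval = range(df) + c(-10, 10), tol = 1e-12)
  sqrt(opt$objective)
}

# build a quantum catch vector directly (bypasses integration on purpose)
qcv <- function(q, ql = 1) {
  structure(list(adapted_catches = q, luminance_catch = ql,
                 illuminant_id = "test"),
            class = "quantum_catch_vector")
}

# toy visual system with explicit Weber fractions and Gaussian sensitivities
toy_system <- function(omegas, peaks = NULL, luminance_weber = 0.05,
                       grid = seq(400, 700, 5)) {
  n <- length(omegas)
  if (is.null(peaks)) peaks <- seq(450, 600, length.out = n)
  recs <- lapply(seq_len(n), function(i) {
    s <- exp(-((grid - peaks[i]) / 40)^2)
    receptor_class(paste0("r", i), spectrum(grid, s / max(s), "sensitivity"),
                   relative_density = 1, weber_fraction = omegas[i])
  })
  visual_system(recs, luminance_weber = luminance_weber)
}

# Mann-Whitney U as a direct pair count, plus its exact two-sided p-value by
# enumeration of all group assignments of the pooled sample
mann_whitney_enum <- function(x, y) {
  u_stat <- function(a, b) {
    sum(vapply(a, function(ai) sum(ai > b) + 0.5 * sum(ai == b), numeric(1)))
  }
  u_obs <- u_stat(x, y)
  pooled <- c(x, y)
  idx <- utils::combn(length(pooled), length(x))
  us <- apply(idx, 2, function(i) u_stat(pooled[i], pooled[-i]))
  m <- length(x) * length(y)
  # two-sided: distance of U from its mean
  p <- mean(abs(us - m / 2) >= abs(u_obs - m / 2) - 1e-12)
  list(U = u_obs, p = p)
}

# Wilcoxon signed-rank V and exact p by enumerating all 2^n sign patterns
signed_rank_enum <- function(d) {
  d <- d[d != 0]
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- signs %*% r
  ev <- sum(r) / 2
  p <- mean(abs(vs - ev) >= abs(v_obs - ev) - 1e-12)
  list(V = v_obs, p = p)
}

# Benjamini-Hochberg step-up, literal formula
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# sequential sum-of-squares by explicit nested projections
seq_ss_oracle <- function(y, terms_list) {
  n <- length(y)
  X <- matrix(1, n, 1)
  ss <- numeric(length(terms_list))
  fit0 <- stats::lm.fit(X, y)
  rss_prev <- sum(fit0$residuals^2)
  for (k in seq_along(terms_list)) {
    X <- cbind(X, terms_list[[k]])
    rss <- sum(stats::lm.fit(X, y)$residuals^2)
    ss[k] <- rss_prev - rss
    rss_prev <- rss
  }
  ss
}

# aggregated per-fish contrast table simulator with known adjacency effect
simulate_aggregated <- function(n_fish, effect, fish_sd = 0.5,
                                resid_sd = 0.5, mu = 5) {
  fish <- sprintf("f%02d", seq_len(n_fish))
  u <- stats::rnorm(n_fish, 0, fish_sd)
  rows <- expand.grid(fish_id = fish, adjacent = c(TRUE, FALSE),
                      stringsAsFactors = FALSE)
  y <- mu + effect * rows$adjacent + u[match(rows$fish_id, fish)] +
    stats::rnorm(nrow(rows), 0, resid_sd)
  data.frame(fish_id = rows$fish_id, state = "dominant",
             adjacent = rows$adjacent, mean_delta_S = y, mean_delta_L = y,
             n_pairs = 5L)
}
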