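# Independent oracles used by the unit and acceptance tests.  These are
# deliberately written against base dnorm/pnorm directly (not the package's
# likelihood functions), so they check the implementation along a separate
# path.

# Exhaustive grid-search MLE over (mu, sigma).  Exact observations enter
# through their sufficient statistics so the full grid stays cheap.
grid_mle <- function(x, mu_grid = seq(-6, 8, by = 0.01),
                     sigma_grid = seq(0.02, 6, by = 0.01)) {
  o <- x$observations
  ex <- o$kind == "exact"
  n_ex <- sum(o$weight[ex])
  s1 <- sum(o$weight[ex] * o$value[ex])
  s2 <- sum(o$weight[ex] * o$value[ex]^2)
  lc <- o[o$kind == "left_censored", , drop = FALSE]
  iv <- o[o$kind == "interval", , drop = FALSE]
  best_ll <- -Inf
  best <- c(NA_real_, NA_real_)
  for (s in sigma_grid) {
    ll <- rep(-n_ex * log(sqrt(2 * pi) * s), length(mu_grid))
    if (n_ex > 0)
      ll <- ll - (s2 - 2 * s1 * mu_grid + n_ex * mu_grid^2) / (2 * s^2)
    for (i in seq_len(nrow(lc)))
      ll <- ll + lc$weight[i] *
        pnorm((lc$upper[i] - mu_grid) / s, log.p = TRUE)
    for (i in seq_len(nrow(iv))) {
      p <- pnorm((iv$upper[i] - mu_grid) / s) -
        pnorm((iv$lower[i] - mu_grid) / s)
      ll <- ll + iv$weight[i] * log(pmax(p, 1e-300))
    }
    j <- which.max(ll)
    if (ll[j] > best_ll) {
      best_ll <- ll[j]
      best <- c(mu_grid[j], s)
    }
  }
  c(mu = best[1], sigma = best[2], loglik = best_ll)
}

# Literal product-of-probabilities likelihood (no logs); only usable on
# datasets small enough not to underflow.
product_likelihood <- function(x, mu, sigma) {
  o <- x$observations
  p <- 1
  for (i in seq_len(nrow(o))) {
    pi <- switch(o$kind[i],
      exact = dnorm(o$value[i], mu, sigma),
      left_censored = pnorm(o$upper[i], mu, sigma),
      interval = pnorm(o$upper[i], mu, sigma) -
        pnorm(o$lower[i], mu, sigma))
    p <- p * pi^o$weight[i]
  }
  p
}

# Table-1-style case datasets, built in code from the printed counts.
case_datasets <- function() {
  list(
    case1 = enum_intervals(10^(1:5), 10^(2:6), c(258, 368, 234, 44, 2),
                           nd = 214, loq = 10, label = "total coliforms"),
    case2 = enum_intervals(10^(1:5), 10^(2:6), c(49, 48, 12, 2, 1),
                           nd = 1008, loq = 10, label = "B. cereus"),
    case3 = enum_intervals(10^(1:5), 10^(2:6), c(19, 34, 22, 8, 1),
                           nd = 16, loq = 10, label = "total coliforms"),
    case4 = enum_intervals(10^(1:3), 10^(2:4), c(16, 2, 1),
                           nd = 81, loq = 10, label = "E. coli"))
}

# Deterministic small random datasets with bounded censoring, for the
# grid-oracle comparisons.
random_small_dataset <- function(seed, n_max = 30, max_censoring = 0.5) {
  for (k in 0:100) {
    s <- seed + 1000L * k
    mu <- with_seed_val(s, runif(1, 1.2, 3.2))
    sg <- with_seed_val(s + 1L, runif(1, 0.4, 1.8))
    n <- with_seed_val(s + 2L, sample(10:n_max, 1))
    d <- simulate_enum(mu, sg, n, loq = 10, seed = s + 3L)
    if (n_detected(d) >= 2 && censored_fraction(d) <= max_censoring)
      return(d)
  }
  stop("could not generate a dataset within the censoring bound")
}

with_seed_val <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
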