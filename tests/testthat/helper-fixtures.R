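# Shared fixtures, built in code.

# a small, fast study configuration used across tests
light_config <- function(seed = 1, ...) {
  sim_config(n_species = 30, plot_cols = 4, plot_rows = 5, mean_stems = 25,
             null = null_spec(n_iterations = 99, seed = seed), seed = seed, ...)
}

# random symmetric species distance matrix with zero diagonal
random_dist <- function(n, seed = 1, labels = sprintf("sp%02d", seq_len(n))) {
  set.seed(seed)
  m <- matrix(runif(n * n, 0.1, 2), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  dimnames(m) <- list(labels, labels)
  m
}

# random regression frame with k predictors
random_frame <- function(n, k, seed = 1, betas = NULL, noise = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * k), n, k, dimnames = list(NULL, paste0("x", seq_len(k))))
  if (is.null(betas)) betas <- rnorm(k)
  y <- drop(X %*% betas) + rnorm(n, 0, noise)
  tibble::as_tibble(cbind(y = y, X))
}

# --- independent oracles (deliberately separate from the package code) ---

# raw MPD/MNTD by naive double loops
oracle_mpd <- function(sp, D) {
  pairs <- utils::combn(sp, 2)
  mean(apply(pairs, 2, function(p) D[p[1], p[2]]))
}
oracle_mntd <- function(sp, D) {
  mean(vapply(sp, function(a) min(D[a, setdiff(sp, a)]), numeric(1)))
}

# exact SES by enumerating every same-richness subset of the pool; the null
# standard deviation is the population sd over the equally likely subsets,
# which is what resampled null draws converge to
oracle_ses_exact <- function(sp, D, metric = c("MPD", "MNTD")) {
  metric <- match.arg(metric)
  f <- if (metric == "MPD") oracle_mpd else oracle_mntd
  pool <- rownames(D)
  subsets <- utils::combn(pool, length(sp), simplify = FALSE)
  vals <- vapply(subsets, f, numeric(1), D = D)
  (f(sp, D) - mean(vals)) / sqrt(mean((vals - mean(vals))^2))
}

# Gaussian AIC as used throughout
oracle_aic <- function(fit) {
  n <- length(stats::residuals(fit))
  rss <- sum(stats::residuals(fit)^2)
  k <- length(stats::coef(fit)) - 1
  n * log(rss / n) + 2 * (k + 2)
}

# hierarchical partitioning by averaging R2 increments over all k! orderings
oracle_hp_orderings <- function(data, response, predictors) {
  r2_of <- function(terms) {
    if (length(terms) == 0) return(0)
    summary(stats::lm(stats::reformulate(terms, response), data = data))$r.squared
  }
  perms <- combinat_perms(length(predictors))
  acc <- stats::setNames(numeric(length(predictors)), predictors)
  for (p in perms) {
    prev <- 0
    for (i in seq_along(p)) {
      cur <- r2_of(predictors[p[seq_len(i)]])
      acc[predictors[p[i]]] <- acc[predictors[p[i]]] + cur - prev
      prev <- cur
    }
  }
  acc / length(perms)
}

# all permutations of 1..k, by inserting k into permutations of 1..(k-1)
combinat_perms <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (sub in combinat_perms(k - 1)) {
    for (pos in 0:(k - 1)) {
      out[[length(out) + 1]] <- append(sub, k, after = pos)
    }
  }
  out
}
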