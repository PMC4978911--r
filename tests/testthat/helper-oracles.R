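# Independent oracles used across the suite: closed-form normal equations,
# GLS with a Brownian covariance, brute-force pairwise diversity, and a
# brute-force interval matcher. These deliberately avoid the package's own
# code paths.

ols_closed_form <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  res <- y - intercept - slope * x
  s2 <- sum(res^2) / (n - 2)
  list(
    slope = slope, intercept = intercept,
    se_slope = sqrt(s2 / sxx),
    se_intercept = sqrt(s2 * (1 / n + mean(x)^2 / sxx)),
    r2 = 1 - sum(res^2) / sum((y - mean(y))^2)
  )
}

origin_closed_form <- function(x, y) {
  slope <- sum(x * y) / sum(x^2)
  res <- y - slope * x
  s2 <- sum(res^2) / (length(x) - 1)
  list(slope = slope, se_slope = sqrt(s2 / sum(x^2)),
       r2 = 1 - sum(res^2) / sum(y^2))
}

# Phylogenetic GLS slope of y on x (intercept included) under the Brownian
# covariance of the tree; algebraically identical to the through-origin
# regression of independent contrasts.
gls_brownian_slope <- function(tree, x, y) {
  V <- ape::vcv(tree)
  ord <- rownames(V)
  Vi <- solve(V)
  X <- cbind(1, x[ord])
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y[ord])
  unname(beta[2, 1])
}

# Average pairwise difference per site over all allele pairs.
pi_brute_force <- function(sample) {
  g <- sample$genotypes
  n <- nrow(g)
  tot <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) tot <- tot + sum(g[i, ] != g[j, ])
  }
  tot / choose(n, 2) / sample$L
}

# Brute-force one-to-one event matching within a positional slop.
match_events_brute <- function(a, b, slop) {
  used <- rep(FALSE, nrow(b))
  keep <- logical(nrow(a))
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (used[j]) next
      if (b$kind[j] == a$kind[i] &&
          abs(b$position[j] - a$position[i]) <= slop &&
          (a$length[i] > 9 || b$length[j] == a$length[i])) {
        used[j] <- TRUE
        keep[i] <- TRUE
        break
      }
    }
  }
  keep
}

# Canonical sortable view of an event set (drops auxiliary attributes so
# called and planted events compare value-for-value).
event_key <- function(d, cols = c("line_id", "position", "kind", "length")) {
  d <- tibble::as_tibble(d)
  out <- tibble::as_tibble(lapply(stats::setNames(cols, cols),
                                  function(c) d[[c]]))
  dplyr::arrange(out, !!!rlang::syms(cols))
}

# Random count configuration rows for consensus tests.
random_counts <- function(n, mean_cov = 30, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rpois(8 * n, mean_cov / 8), n, 8)
    out <- as.data.frame(m)
    names(out) <- c("A", "a", "C", "c", "G", "g", "T", "t")
    out
  })
}
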