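# Independent oracles used across the suite.

# brute-force enumeration of nonempty up-sets of the K x J product order by
# scanning all 2^(K*J) membership masks
brute_force_upsets <- function(K, J) {
  n <- K * J
  masks <- list()
  for (mask in seq_len(2^n - 1)) {
    bits <- as.integer(intToBits(mask))[seq_len(n)]
    m <- matrix(bits == 1L, K, J)
    ok <- TRUE
    for (k in seq_len(K)) {
      for (j in seq_len(J)) {
        if (m[k, j]) {
          if (k < K && !m[k + 1L, j]) ok <- FALSE
          if (j < J && !m[k, j + 1L]) ok <- FALSE
        }
      }
    }
    if (ok) masks[[length(masks) + 1L]] <- m
  }
  masks
}

# exact JSD between two normal densities by adaptive quadrature on the true
# densities (no samples, no KDE)
jsd_normals_exact <- function(m1, s1, m2, s2) {
  f <- function(x) stats::dnorm(x, m1, s1)
  g <- function(x) stats::dnorm(x, m2, s2)
  kl_term <- function(p, lo, hi) {
    stats::integrate(function(x) {
      px <- p(x); mx <- (f(x) + g(x)) / 2
      out <- ifelse(px > 0, px * log(pmax(px, 1e-300) / pmax(mx, 1e-300)), 0)
      out
    }, lo, hi, rel.tol = 1e-9)$value
  }
  lo <- min(m1 - 10 * s1, m2 - 10 * s2)
  hi <- max(m1 + 10 * s1, m2 + 10 * s2)
  0.5 * kl_term(f, lo, hi) + 0.5 * kl_term(g, lo, hi)
}

# trial data with exact per-subgroup sample mean and sd (n >= 2)
exact_moment_data <- function(grid, mean_mat, sd_mat, n) {
  base <- scale(seq_len(n))[, 1]              # mean 0, sd 1
  obs <- do.call(rbind, lapply(seq_len(grid$K), function(k) {
    do.call(rbind, lapply(seq_len(grid$J), function(j) {
      data.frame(k = k, j = j, y = mean_mat[k, j] + sd_mat[k, j] * base)
    }))
  }))
  trial_data(grid, obs)
}

random_status_grid <- function(K, J) {
  matrix(sample(c("effective", "promising", "ineffective"), K * J, replace = TRUE),
         K, J)
}

is_up_set_mat <- function(m) {
  K <- nrow(m); J <- ncol(m)
  if (K > 1 && any(m[-K, ] & !m[-1, ])) return(FALSE)
  if (J > 1 && any(m[, -J] & !m[, -1])) return(FALSE)
  TRUE
}
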