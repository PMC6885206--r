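# Independent oracles used to pin expected values; these never call the
# code paths they check.

# Exhaustive-partition oracle for univariate K = 2 mixtures: evaluates
# the observed-data log-likelihood at the hard-partition MLE of every
# bipartition and returns the best. Degenerate partitions (zero
# within-group variance under the family) are excluded.
oracle_partition_loglik <- function(x, family = c("E", "V")) {
  family <- match.arg(family)
  n <- length(x)
  best <- -Inf
  for (code in seq_len(2^(n - 1) - 1)) {
    g <- as.integer(intToBits(code))[seq_len(n)]
    n1 <- sum(g == 1); n0 <- n - n1
    if (n1 == 0 || n0 == 0) next
    mu <- c(mean(x[g == 0]), mean(x[g == 1]))
    ss <- c(sum((x[g == 0] - mu[1])^2), sum((x[g == 1] - mu[2])^2))
    if (family == "E") {
      s2 <- rep(sum(ss) / n, 2)
    } else {
      s2 <- c(ss[1] / n0, ss[2] / n1)
    }
    if (any(s2 < 1e-12)) next
    pro <- c(n0, n1) / n
    ll <- sum(log(pro[1] * stats::dnorm(x, mu[1], sqrt(s2[1])) +
                  pro[2] * stats::dnorm(x, mu[2], sqrt(s2[2]))))
    if (ll > best) best <- ll
  }
  best
}

# Breslow partial-likelihood score at beta for right-censored data
# without tied event times (equals Efron's there).
cox_score <- function(beta, time, event, x) {
  x <- as.matrix(x)
  eta <- drop(x %*% beta)
  w <- exp(eta)
  U <- numeric(ncol(x))
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    U <- U + x[i, ] - colSums(x[risk, , drop = FALSE] * w[risk]) / sum(w[risk])
  }
  U
}

# Step-up BH adjustment written from the definition, as a cross-check.
bh_by_hand <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(m * p[o] / seq_len(m))))
  pmin(q_sorted, 1)[order(o)]
}

# Draws from a 2-component VEI truth in d dimensions.
gen_vei_data <- function(seed, n = 2000, lambda = c(1, 4),
                         shape = c(2, 0.5, 1), sep = 4, prob = 0.5) {
  set.seed(seed)
  d <- length(shape)
  shape <- shape / exp(mean(log(shape)))      # det 1
  k <- stats::rbinom(n, 1, prob) + 1L
  mu <- cbind(rep(0, d), rep(sep, d))
  x <- matrix(0, n, d)
  for (i in seq_len(n))
    x[i, ] <- stats::rnorm(d, mu[, k[i]], sqrt(lambda[k[i]] * shape))
  list(x = x, component = k)
}

# Small aligned expression + survival pair with planted minority genes.
make_small_cohort <- function(seed, n_genes = 300, n = 450, shift = 2.5) {
  generate_cohort(synthetic_config(n_samples = n, n_genes = n_genes,
                                   shift = shift, seed = seed))
}
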