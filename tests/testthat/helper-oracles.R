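# Independent oracles used across the suite.

# Linear-weighted Cohen's kappa, coded directly from the textbook
# definition (proportion matrices and marginal products), independent of
# the package's observed/expected/weight machinery.
cohen_kappa_linear <- function(a, b, N = 5) {
  n <- length(a)
  P <- matrix(0, N, N)
  for (i in seq_len(n)) P[a[i], b[i]] <- P[a[i], b[i]] + 1 / n
  pa <- rowSums(P)
  pb <- colSums(P)
  wt <- 1 - abs(outer(1:N, 1:N, "-")) / (N - 1)   # agreement weights
  po <- sum(wt * P)
  pe <- sum(wt * outer(pa, pb))
  (po - pe) / (1 - pe)
}

# Central finite-difference gradient of scalar f at x.
numeric_gradient <- function(f, x, eps = 1e-5) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xm <- x
    xp[i] <- x[i] + eps
    xm[i] <- x[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

random_scores <- function(n, N = 5) sample.int(N, n, replace = TRUE)

make_record <- function(id = "s1", g = rep(3L, 6), o = rep(3L, 7),
                        task = "cut", valid = TRUE) {
  rating_record(id,
                stats::setNames(g, gears_subcategories()),
                stats::setNames(o, osats_subcategories()),
                task, valid = valid)
}
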