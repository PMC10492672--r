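test_that("penalty weight matrix follows the ordinal-distance formula", {
  w <- weight_matrix(5, 1)
  expect_equal(w[1, 5], 1)
  expect_equal(w[2, 2], 0)
  expect_equal(w[1, 3], 0.5)
  expect_true(isSymmetric(w))
  expect_true(all(diag(w) == 0))
  expect_equal(max(w), 1)
  expect_error(weight_matrix(1), "N")
})

test_that("observed matrix cross-tabulates hard scores", {
  O <- observed_matrix(c(1, 2), c(1, 2))
  expect_equal(sum(O != 0), 2)
  expect_equal(O[1, 1], 1)
  expect_equal(O[2, 2], 1)
  O2 <- observed_matrix(c(1, 1, 2), c(1, 2, 2))
  expect_equal(c(O2[1, 1], O2[1, 2], O2[2, 2]), c(1, 1, 1))
  expect_equal(sum(O2), 3)
  expect_error(observed_matrix(c(0, 1), c(1, 1)), "1..5")
})

test_that("soft observed matrix reduces to hard counts at one-hot limit", {
  y_a <- c(1L, 1L, 2L)
  y_b <- c(1L, 2L, 2L)
  P <- matrix(0, 3, 5)
  P[cbind(1:3, y_b)] <- 1
  expect_equal(soft_observed(P, y_a), observed_matrix(y_a, y_b),
               ignore_attr = TRUE)
  Pr <- t(apply(matrix(runif(15), 3), 1, function(r) r / sum(r)))
  Os <- soft_observed(Pr, y_a)
  expect_equal(sum(Os), 3)
  expect_true(all(Os >= 0))
})

test_that("expected matrix is the marginal outer product with conserved mass", {
  O <- observed_matrix(c(1, 1, 2), c(1, 2, 2), N = 2)
  E <- expected_matrix(O)
  expect_equal(E[1, 1], 2 / 3)
  expect_equal(E[1, 2], 4 / 3)
  expect_equal(E[2, 1], 1 / 3)
  expect_equal(E[2, 2], 2 / 3)
  expect_equal(sum(E), sum(O))
  # invariance under simultaneous row/column permutation
  set.seed(11)
  O5 <- observed_matrix(random_scores(40), random_scores(40))
  pm <- sample(5)
  expect_equal(expected_matrix(O5[pm, pm]), expected_matrix(O5)[pm, pm])
  expect_error(expected_matrix(matrix(0, 5, 5)), "positive")
})

test_that("worked weighted-kappa example evaluates to 0.4", {
  O <- observed_matrix(c(1, 1, 2), c(1, 2, 2))
  w <- weight_matrix(5, 1)
  expect_equal(sum(w * O), 0.25)
  expect_equal(sum(w * expected_matrix(O)), 5 / 12)
  expect_equal(weighted_kappa_loss(O)$kappa, 0.4)
})

test_that("kappa boundary cases: perfect agreement and chance agreement", {
  a <- rep(1:5, 4)
  O <- observed_matrix(a, a)
  r <- weighted_kappa_loss(O, epsilon = 1e-6)
  expect_equal(r$kappa, 1)
  expect_equal(r$loss, log(1e-6))
  # O equal to its own expected matrix (rank-1 observed): kappa = 0
  O2 <- outer(c(4, 3, 2, 1, 0), c(1, 2, 3, 4, 0))
  expect_equal(expected_matrix(O2), O2)
  r2 <- weighted_kappa_loss(O2)
  expect_equal(r2$kappa, 0)
  expect_equal(r2$loss, log(1 + 1e-6))
  expect_error(weighted_kappa_loss(diag(c(1, 0, 0, 0, 0))), "degenerate")
})

test_that("kappa matches an independent Cohen's kappa on random pairs", {
  set.seed(101)
  for (i in 1:1000) {
    a <- random_scores(30)
    b <- random_scores(30)
    O <- observed_matrix(a, b)
    if (sum(weight_matrix(5, 1) * expected_matrix(O)) == 0) next
    expect_equal(weighted_kappa_loss(O)$kappa, cohen_kappa_linear(a, b),
                 tolerance = 1e-10)
  }
})

test_that("kappa is invariant under joint sample permutation and loss is monotone", {
  set.seed(7)
  a <- random_scores(40)
  b <- random_scores(40)
  k1 <- weighted_kappa_loss(observed_matrix(a, b))$kappa
  pm <- sample(40)
  expect_equal(weighted_kappa_loss(observed_matrix(a[pm], b[pm]))$kappa, k1)
  # loss strictly decreasing in kappa
  ks <- seq(-0.5, 0.99, by = 0.1)
  ls <- log(1 - ks + 1e-6)
  expect_true(all(diff(ls) < 0))
})

test_that("batch weighted-kappa loss gradient matches finite differences", {
  set.seed(5)
  n <- 10
  z <- matrix(rnorm(n * 5), n, 5)
  y <- random_scores(n)
  P <- exp(z) / rowSums(exp(z))
  r <- wk_batch_loss(P, y)
  f <- function(zv) {
    P2 <- exp(matrix(zv, n, 5))
    P2 <- P2 / rowSums(P2)
    wk_batch_loss(P2, y)$loss
  }
  dz <- P * (r$dP - rowSums(P * r$dP))
  expect_equal(as.vector(dz), numeric_gradient(f, as.vector(z)),
               tolerance = 1e-6)
})
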