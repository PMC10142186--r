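test_that("replicate summaries pool within-species variance by hand arithmetic", {
  rows <- data.frame(species = c("a", "a", "b", "b"),
                     x = c(1.0, 1.0, 2.0, 2.0),
                     y = c(1, 3, 4, 8))
  sm <- summarize_replicates(rows)
  expect_equal(sm$y_mean, c(2, 6))
  # ((1-2)^2+(3-2)^2 + (4-6)^2+(8-6)^2) / (1 + 1) = (2 + 8) / 2
  expect_equal(sm$pooled_within_var_y, 5)
  expect_equal(sm$sampling_var_y, c(2.5, 2.5))
  expect_equal(sm$sampling_var_x, c(0, 0))
})

test_that("replicate summaries handle degenerate variance cases", {
  sm <- summarize_replicates(data.frame(
    species = c("a", "a", "b", "b"), x = c(1, 1, 2, 2), y = c(5, 5, 7, 7)))
  expect_equal(sm$pooled_within_var_y, 0)
  expect_warning(
    sm1 <- summarize_replicates(data.frame(species = c("a", "b", "c"),
                                           x = 1:3, y = 4:6)),
    "single record")
  expect_equal(sm1$pooled_within_var_y, 0)
  expect_error(summarize_replicates(data.frame(
    species = c("a", "a"), x = c(1, 2), y = c(1, 2))), "conflicting x")
})

test_that("likelihood matches an independent dense gaussian oracle", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(2:6, 1)
    tr <- ape::rcoal(n, tip.label = paste0("t", seq_len(n)))
    C <- bm_covariance(tr)
    s2x <- runif(1, 0.2, 2); s2y <- runif(1, 0.2, 2)
    rho <- runif(1, -0.9, 0.9)
    sxy <- rho * sqrt(s2x * s2y)
    dx <- runif(n, 0, 0.3); dy <- runif(n, 0, 0.3)
    ax <- rnorm(1); ay <- rnorm(1)
    x <- rnorm(n, ax, 0.5); y <- rnorm(n, ay, 0.5)
    sm <- make_summary(C$taxa, x, y, svy = dy)
    sm$sampling_var_x <- dx
    got <- ives_loglik(list(a_x = ax, a_y = ay, sigma2_x = s2x,
                            sigma2_y = s2y, sigma_xy = sxy), sm, C)
    V <- oracle_joint_V(s2x, s2y, sxy, C$C, dx, dy)
    want <- oracle_mvn_loglik(c(x, y), c(rep(ax, n), rep(ay, n)), V)
    expect_equal(got, want, tolerance = 1e-8)
  }
})

test_that("zero cross-rate factorizes into two univariate pGLS likelihoods", {
  set.seed(32)
  n <- 8
  tr <- ape::rcoal(n, tip.label = paste0("t", 1:n))
  C <- bm_covariance(tr)
  x <- rnorm(n, 1, 0.5); y <- rnorm(n, 2, 0.5)
  dy <- runif(n, 0, 0.2)
  sm <- make_summary(C$taxa, x, y, svy = dy)
  got <- ives_loglik(list(a_x = 0.8, a_y = 2.1, sigma2_x = 0.7,
                          sigma2_y = 1.3, sigma_xy = 0), sm, C)
  want <- oracle_pgls_loglik(x, C$C, 0.7, rep(0, n), 0.8) +
    oracle_pgls_loglik(y, C$C, 1.3, dy, 2.1)
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("at the mean the likelihood reduces to the normalizing constant", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  C <- bm_covariance(tr)
  sm <- make_summary(C$taxa, rep(1.5, 3), rep(-0.5, 3))
  ll <- ives_loglik(list(a_x = 1.5, a_y = -0.5, sigma2_x = 1, sigma2_y = 1,
                         sigma_xy = 0.5), sm, C)
  V <- oracle_joint_V(1, 1, 0.5, C$C, rep(0, 3), rep(0, 3))
  expect_equal(ll, -0.5 * (6 * log(2 * pi) +
                             as.numeric(determinant(V)$modulus)))
})

test_that("likelihood is independent of taxon ordering", {
  set.seed(33)
  tr <- ape::rcoal(6, tip.label = paste0("t", 1:6))
  C <- bm_covariance(tr)
  x <- rnorm(6); y <- rnorm(6)
  sm <- make_summary(C$taxa, x, y, svy = runif(6, 0, 0.2))
  params <- list(a_x = 0, a_y = 0, sigma2_x = 1, sigma2_y = 1, sigma_xy = 0.4)
  base <- ives_loglik(params, sm, C)
  perm <- sample(6)
  sm2 <- sm
  sm2$species <- sm$species[perm]; sm2$x_mean <- sm$x_mean[perm]
  sm2$y_mean <- sm$y_mean[perm]; sm2$m <- sm$m[perm]
  sm2$sampling_var_y <- sm$sampling_var_y[perm]
  sm2$sampling_var_x <- sm$sampling_var_x[perm]
  expect_equal(ives_loglik(params, sm2, C), base, tolerance = 1e-12)
})

test_that("non-positive-definite covariance yields -Inf, not an error", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  C <- bm_covariance(tr)
  sm <- make_summary(C$taxa, c(1, 2, 3), c(2, 3, 4))
  ll <- ives_loglik(list(a_x = 0, a_y = 0, sigma2_x = 1, sigma2_y = 1,
                         sigma_xy = 1.5), sm, C)  # |rho| > 1
  expect_identical(ll, -Inf)
})

test_that("star-tree fits reduce to ordinary least squares", {
  set.seed(34)
  st <- ape::stree(12, "star"); st$edge.length <- rep(1, 12)
  st$tip.label <- paste0("t", 1:12)
  C <- bm_covariance(st)
  x <- rnorm(12, 1, 0.8); y <- 0.4 + 0.6 * x + rnorm(12, 0, 0.3)
  sm <- make_summary(C$taxa, x, y)
  f <- suppressWarnings(fit_ives(sm, C, n_starts = 3, seed = 1))
  ols <- stats::coef(stats::lm(y ~ x))
  expect_equal(f$b1, unname(ols[2]), tolerance = 1e-4)
  expect_equal(f$b0, unname(ols[1]), tolerance = 1e-4)
})

test_that("the constrained fit has slope exactly zero and b0 = a_y", {
  set.seed(35)
  tr <- ape::rcoal(8, tip.label = paste0("t", 1:8))
  C <- bm_covariance(tr)
  sm <- make_summary(C$taxa, rnorm(8), rnorm(8))
  f <- suppressWarnings(fit_ives(sm, C, constrain_slope = TRUE,
                                 n_starts = 2, seed = 2))
  expect_identical(f$b1, 0)
  expect_identical(f$b0, f$params$a_y)
  expect_true(f$converged)
})

test_that("full fit never falls below the nested constrained fit", {
  set.seed(36)
  tr <- ape::rcoal(10, tip.label = paste0("t", 1:10))
  C <- bm_covariance(tr)
  sm <- make_summary(C$taxa, rnorm(10), rnorm(10))
  full <- suppressWarnings(fit_ives(sm, C, FALSE, n_starts = 4, seed = 3))
  null <- suppressWarnings(fit_ives(sm, C, TRUE, n_starts = 4, seed = 4))
  expect_gte(full$loglik, null$loglik - 1e-6)
})

test_that("estimates are scale- and translation-equivariant", {
  set.seed(37)
  tr <- ape::rcoal(12, tip.label = paste0("t", 1:12))
  C <- bm_covariance(tr)
  x <- rnorm(12, 1, 0.5); y <- 0.5 + 0.8 * x + rnorm(12, 0, 0.2)
  sm <- make_summary(C$taxa, x, y)
  f0 <- suppressWarnings(fit_ives(sm, C, n_starts = 3, seed = 5))
  # y -> 3 y: slope and intercept scale by 3
  smy <- make_summary(C$taxa, x, 3 * y)
  fy <- suppressWarnings(fit_ives(smy, C, n_starts = 3, seed = 5))
  expect_equal(fy$b1, 3 * f0$b1, tolerance = 1e-3)
  expect_equal(fy$b0, 3 * f0$b0, tolerance = 1e-3)
  # x -> x + 2: slope unchanged, intercept shifts by -2 b1
  smx <- make_summary(C$taxa, x + 2, y)
  fx <- suppressWarnings(fit_ives(smx, C, n_starts = 3, seed = 5))
  expect_equal(fx$b1, f0$b1, tolerance = 1e-3)
  expect_equal(fx$b0, f0$b0 - 2 * f0$b1, tolerance = 1e-3)
})

test_that("fits require matching species sets and at least 3 species", {
  tr <- ape::rcoal(4, tip.label = paste0("t", 1:4))
  C <- bm_covariance(tr)
  sm <- make_summary(paste0("u", 1:4), rnorm(4), rnorm(4))
  expect_error(fit_ives(sm, C), "differ")
  tr2 <- ape::read.tree(text = "(A:1,B:1);")
  expect_error(fit_ives(make_summary(c("A", "B"), 1:2, 1:2),
                        bm_covariance(tr2)), "at least 3")
})
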