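# Bivariate Brownian phylogenetic regression with within-species
# (among-record) variation, fitted by maximum likelihood.
#
# Model: species-level traits (x, y) evolve by correlated Brownian motion on
# the phylogeny with rate matrix [[sigma2_x, sigma_xy], [sigma_xy, sigma2_y]]
# around phylogenetic means (a_x, a_y). Observed species means carry
# additional independent sampling variance (within-species variance divided
# by the number of records). Stacking z = (x_means, y_means):
#
#   z ~ N( (a_x 1, a_y 1),  V ),
#   V = [[sigma2_x C + D_x, sigma_xy C], [sigma_xy C, sigma2_y C + D_y]]
#
# with C the BM covariance of the tree and D_x, D_y diagonal sampling
# variances. The evolutionary regression of y on x has slope
# b1 = sigma_xy / sigma2_x and intercept b0 = a_y - b1 a_x.

#' Summarize replicated records into species-level means
#'
#' Collapses per-record observations to species means and derives sampling
#' variances from a pooled within-species variance: species with m records
#' get sampling variance `pooled/m`. Pooling stabilizes the estimate when
#' most species have only a handful of records; species with a single record
#' receive the pooled value. The predictor x must be constant within species
#' (it is a species-level quantity such as diet diversity), so its sampling
#' variance is 0 by default.
#'
#' @param rows data.frame with columns `species`, `x`, `y`; species repeat
#'   across rows (one row per venomic record).
#' @return Object of class `species_summary`: `species`, `x_mean`, `y_mean`,
#'   `m` (records per species), `pooled_within_var_y`, `sampling_var_y`,
#'   `sampling_var_x` (zeros).
#' @export
summarize_replicates <- function(rows) {
  stopifnot(all(c("species", "x", "y") %in% names(rows)))
  rows <- rows[!is.na(rows$x) & !is.na(rows$y), , drop = FALSE]
  if (nrow(rows) == 0L) stop("no complete (x, y) rows")
  idx <- split(seq_len(nrow(rows)), rows$species)
  idx <- idx[order(vapply(idx, min, 1L))]
  species <- vapply(idx, function(i) rows$species[i[1]], "")
  xr <- vapply(idx, function(i) {
    xs <- rows$x[i]
    if (diff(range(xs)) > 1e-9)
      stop("species ", rows$species[i[1]], " has conflicting x values")
    xs[1]
  }, 1.0)
  m <- vapply(idx, length, 1L)
  y_mean <- vapply(idx, function(i) mean(rows$y[i]), 1.0)
  ss <- sum(vapply(idx, function(i) sum((rows$y[i] - mean(rows$y[i]))^2), 1.0))
  df <- sum(pmax(m - 1L, 0L))
  if (df > 0) {
    pooled <- ss / df
  } else {
    pooled <- 0
    warning("all species have a single record; within-species variance set to 0")
  }
  structure(
    list(species = unname(species),
         x_mean = unname(xr),
         y_mean = unname(y_mean),
         m = unname(m),
         pooled_within_var_y = pooled,
         sampling_var_y = unname(pooled / m),
         sampling_var_x = rep(0, length(m))),
    class = "species_summary")
}

#' @export
print.species_summary <- function(x, ...) {
  cat(sprintf("<species_summary> %d species, %d records, pooled within-var(y) %.4g\n",
              length(x$species), sum(x$m), x$pooled_within_var_y))
  invisible(x)
}

# Align a species_summary to the taxon order of a phylo_covariance.
.align_summary <- function(data, C) {
  taxa <- C$taxa
  if (length(taxa) != length(data$species) ||
      !setequal(taxa, data$species))
    stop("species in data and covariance matrix differ: ",
         paste(c(setdiff(data$species, taxa), setdiff(taxa, data$species)),
               collapse = ", "))
  ord <- match(taxa, data$species)
  data$species <- data$species[ord]
  data$x_mean <- data$x_mean[ord]
  data$y_mean <- data$y_mean[ord]
  data$m <- data$m[ord]
  data$sampling_var_y <- data$sampling_var_y[ord]
  data$sampling_var_x <- data$sampling_var_x[ord]
  data
}

.data_fingerprint <- function(data, C) {
  paste(c(data$species, signif(data$x_mean, 12), signif(data$y_mean, 12),
          data$m, signif(data$sampling_var_y, 12), signif(C$C, 12)),
        collapse = "|")
}

# Joint covariance of the stacked (x, y) species means.
.ives_V <- function(s2x, s2y, sxy, C, dx, dy) {
  n <- nrow(C)
  V <- matrix(0, 2 * n, 2 * n)
  V[1:n, 1:n] <- s2x * C + diag(dx, n)
  V[(n + 1):(2 * n), (n + 1):(2 * n)] <- s2y * C + diag(dy, n)
  V[1:n, (n + 1):(2 * n)] <- sxy * C
  V[(n + 1):(2 * n), 1:n] <- sxy * C
  V
}

# Log-likelihood with explicit means; -Inf when V is not positive definite.
.loglik_given_V <- function(V, z, mu) {
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) return(-Inf)
  logdet <- 2 * sum(log(diag(R)))
  w <- backsolve(R, z - mu, transpose = TRUE)
  -0.5 * (length(z) * log(2 * pi) + logdet + sum(w^2))
}

#' Log-likelihood of the bivariate phylogenetic measurement-error model
#'
#' Evaluates the exact Gaussian log-likelihood of stacked species means
#' under correlated Brownian motion plus diagonal sampling variance (see the
#' model description above). Returns `-Inf` (not an error) when the implied
#' joint covariance is not positive definite, so optimizers can recover.
#'
#' @param params Named list or vector with `a_x`, `a_y`, `sigma2_x`,
#'   `sigma2_y`, `sigma_xy`.
#' @param data A [summarize_replicates()] `species_summary`.
#' @param C A [bm_covariance()] `phylo_covariance` whose taxa match
#'   `data$species` (any order).
#' @return Scalar log-likelihood.
#' @export
ives_loglik <- function(params, data, C) {
  params <- as.list(params)
  data <- .align_summary(data, C)
  n <- length(data$species)
  V <- .ives_V(params$sigma2_x, params$sigma2_y, params$sigma_xy, C$C,
               data$sampling_var_x, data$sampling_var_y)
  z <- c(data$x_mean, data$y_mean)
  mu <- c(rep(params$a_x, n), rep(params$a_y, n))
  .loglik_given_V(V, z, mu)
}

# Profiled objective: given covariance parameters, the ML phylogenetic means
# solve a 2-parameter GLS; returns the profiled log-likelihood and the means.
.profiled_loglik <- function(s2x, s2y, sxy, data, Cmat) {
  n <- nrow(Cmat)
  V <- .ives_V(s2x, s2y, sxy, Cmat, data$sampling_var_x, data$sampling_var_y)
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) return(list(loglik = -Inf))
  z <- c(data$x_mean, data$y_mean)
  X <- cbind(c(rep(1, n), rep(0, n)), c(rep(0, n), rep(1, n)))
  Wz <- backsolve(R, z, transpose = TRUE)
  WX <- backsolve(R, X, transpose = TRUE)
  XtX <- crossprod(WX)
  a <- tryCatch(solve(XtX, crossprod(WX, Wz)), error = function(e) NULL)
  if (is.null(a)) return(list(loglik = -Inf))
  resid <- Wz - WX %*% a
  logdet <- 2 * sum(log(diag(R)))
  ll <- -0.5 * (2 * n * log(2 * pi) + logdet + sum(resid^2))
  list(loglik = ll, a_x = a[1], a_y = a[2])
}

# Empirical univariate GLS rate used for starting values.
.gls_rate <- function(v, Cmat) {
  n <- length(v)
  Ci <- solve(Cmat)
  one <- rep(1, n)
  a <- sum(Ci %*% v) / sum(Ci)
  r <- v - a
  max(drop(t(r) %*% Ci %*% r) / n, 1e-8)
}

#' Fit the phylogenetic regression with intraspecific variation
#'
#' Maximizes [ives_loglik()] by multi-start optimization (a derivative-free
#' Nelder-Mead pass followed by a BFGS polish at each start). The
#' covariance parameters are searched on an unconstrained scale
#' (log variances, atanh of the Brownian correlation) so the 2x2 rate matrix
#' stays positive definite by construction; the phylogenetic means are
#' profiled out analytically at each step (the profiled maximum is the joint
#' ML optimum). The constrained fit fixes `sigma_xy = 0`, giving the
#' "intercept-only" null model with slope exactly 0.
#'
#' @param data A `species_summary`.
#' @param C A `phylo_covariance` on the same species.
#' @param constrain_slope If TRUE fix `sigma_xy = 0` (null model).
#' @param n_starts Number of randomized starts; each draws log-variances
#'   uniformly within +/-1 of the empirical GLS rates and atanh(rho) uniform
#'   on (-1, 1). A deterministic start at the empirical GLS center is always
#'   tried in addition (it consumes no random numbers).
#' @param seed Integer seed for start randomization.
#' @return Object of class `ives_fit`: `params` (a_x, a_y, sigma2_x,
#'   sigma2_y, sigma_xy), `b1`, `b0`, `loglik`, `constrained`, `n_species`,
#'   `converged`, `n_starts_used`, `start_seed`.
#' @export
fit_ives <- function(data, C, constrain_slope = FALSE, n_starts = 5,
                     seed = NULL) {
  data <- .align_summary(data, C)
  n <- length(data$species)
  if (n < 3) stop("need at least 3 species")
  Cmat <- C$C
  if (!is.null(seed)) set.seed(seed)

  ls2x0 <- log(.gls_rate(data$x_mean, Cmat))
  ls2y0 <- log(.gls_rate(data$y_mean, Cmat))

  negll <- function(theta) {
    s2x <- exp(min(max(theta[1], -30), 30))
    s2y <- exp(min(max(theta[2], -30), 30))
    rho <- if (constrain_slope) 0 else tanh(theta[3])
    sxy <- rho * sqrt(s2x * s2y)
    ll <- .profiled_loglik(s2x, s2y, sxy, data, Cmat)$loglik
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  # start list: the empirical GLS center, then (for the full model) the
  # constrained optimum — warm-starting from the nested null guarantees the
  # full fit cannot end below it — then the randomized restarts
  starts <- list(if (constrain_slope) c(ls2x0, ls2y0) else c(ls2x0, ls2y0, 0))
  if (!constrain_slope) {
    null_fit <- fit_ives(data, C, constrain_slope = TRUE, n_starts = n_starts,
                         seed = NULL)
    if (null_fit$converged)
      starts <- c(starts, list(c(log(null_fit$params$sigma2_x),
                                 log(null_fit$params$sigma2_y), 0)))
  }
  for (k in seq_len(n_starts)) {
    # every restart is a random draw around the empirical GLS rates
    theta0 <- c(ls2x0, ls2y0) + stats::runif(2, -1, 1)
    if (!constrain_slope) theta0 <- c(theta0, stats::runif(1, -1, 1))
    starts <- c(starts, list(theta0))
  }

  best <- NULL
  n_ok <- 0L
  for (theta0 in starts) {
    # derivative-free pass first (robust to the -Inf cliff of non-PD
    # covariances), then a quasi-Newton polish from its optimum
    opt <- tryCatch({
      nm <- stats::optim(theta0, negll, method = "Nelder-Mead",
                         control = list(maxit = 2000, reltol = 1e-10))
      bf <- tryCatch(
        stats::optim(nm$par, negll, method = "BFGS",
                     control = list(maxit = 500, reltol = 1e-12)),
        error = function(e) NULL)
      if (!is.null(bf) && is.finite(bf$value) && bf$value <= nm$value) bf
      else nm
    }, error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$value) || opt$value >= 1e9) next
    n_ok <- n_ok + 1L
    if (is.null(best) || opt$value < best$value) best <- opt
  }

  if (is.null(best)) {
    return(structure(
      list(params = NULL, b1 = NA_real_, b0 = NA_real_, loglik = -Inf,
           constrained = constrain_slope, n_species = n, converged = FALSE,
           n_starts_used = n_starts, start_seed = seed,
           fingerprint = .data_fingerprint(data, C)),
      class = "ives_fit"))
  }

  th <- best$par
  s2x <- exp(th[1]); s2y <- exp(th[2])
  rho <- if (constrain_slope) 0 else tanh(th[3])
  sxy <- rho * sqrt(s2x * s2y)
  prof <- .profiled_loglik(s2x, s2y, sxy, data, Cmat)
  b1 <- if (constrain_slope) 0 else sxy / s2x
  b0 <- if (constrain_slope) prof$a_y else prof$a_y - b1 * prof$a_x
  structure(
    list(params = list(a_x = prof$a_x, a_y = prof$a_y, sigma2_x = s2x,
                       sigma2_y = s2y, sigma_xy = sxy),
         b1 = b1, b0 = b0, loglik = prof$loglik,
         constrained = constrain_slope, n_species = n,
         converged = best$convergence == 0 && is.finite(prof$loglik),
         n_starts_used = n_ok, start_seed = seed,
         fingerprint = .data_fingerprint(data, C)),
    class = "ives_fit")
}

#' @export
print.ives_fit <- function(x, ...) {
  cat(sprintf(
    "<ives_fit>%s n = %d, logLik = %.4f\n  slope = %.4f, intercept = %.4f\n",
    if (x$constrained) " [intercept-only]" else "", x$n_species, x$loglik,
    x$b1, x$b0))
  invisible(x)
}
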