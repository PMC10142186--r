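#' Shannon diversity index
#'
#' Computes the Shannon index \eqn{H = -\sum_i p_i \ln p_i} of a composition,
#' in nats. Abundances are renormalized internally to sum to one; zero
#' components contribute nothing (the limit \eqn{p \ln p \to 0}).
#'
#' @param p Numeric vector of nonnegative abundances (need not sum to 1).
#' @return Shannon index in nats, a value in \eqn{[0, \ln R]} where R is the
#'   number of components.
#' @examples
#' shannon_index(rep(0.25, 4))   # log(4)
#' shannon_index(c(0.5, 0.25, 0.25))
#' @seealso [simpson_index()]
#' @export
shannon_index <- function(p) {
  p <- .validate_abundances(p)
  pos <- p[p > 0]
  -sum(pos * log(pos))
}

#' Gini-Simpson diversity index
#'
#' Computes the Gini-Simpson index \eqn{D = 1 - \sum_i p_i^2}: the probability
#' that two components drawn at random (with replacement) differ. Emphasizes
#' evenness; dominated compositions score low.
#'
#' @inheritParams shannon_index
#' @return Value in \eqn{[0, 1 - 1/R]}.
#' @examples
#' simpson_index(rep(0.25, 4))   # 0.75
#' @export
simpson_index <- function(p) {
  p <- .validate_abundances(p)
  1 - sum(p^2)
}

#' @param index "shannon" or "simpson"
#' @noRd
.diversity_fun <- function(index) {
  switch(match.arg(index, c("shannon", "simpson")),
         shannon = shannon_index,
         simpson = simpson_index)
}

.validate_abundances <- function(p) {
  if (!is.numeric(p) || length(p) == 0L)
    stop("abundance vector must be a nonempty numeric vector")
  if (anyNA(p)) stop("abundance vector contains NA")
  if (any(p < 0)) stop("negative abundance in vector")
  s <- sum(p)
  if (s <= 0) stop("all-zero abundance vector: diversity undefined")
  p / s
}
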