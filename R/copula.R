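#' Archimedean copula specifications
#'
#' An Archimedean copula is generated by a strictly decreasing continuous
#' function \eqn{\vartheta : (0,1] \to [0,\infty)} with \eqn{\vartheta(1)=0}
#' through \eqn{C(x,y) = \vartheta^{[-1]}(\vartheta(x)+\vartheta(y))}, where
#' \eqn{\vartheta^{[-1]}} is the pseudo-inverse (the true inverse on
#' \eqn{[0, \vartheta(0)]}, 0 beyond). Five classical one-parameter families
#' are supported:
#'
#' \describe{
#'   \item{1 (Gumbel)}{\eqn{\vartheta(x) = (-\ln x)^\lambda}, \eqn{\lambda \ge 1};
#'     the product copula at \eqn{\lambda = 1}.}
#'   \item{2 (Clayton)}{\eqn{\vartheta(x) = (x^{-\lambda}-1)/\max(\lambda,
#'     \mathrm{sign}(\lambda))}, \eqn{\lambda \ge -1, \lambda \ne 0}; for
#'     \eqn{\lambda > 0} the unscaled form \eqn{x^{-\lambda}-1} is used (a
#'     positive rescaling of the generator leaves the copula unchanged),
#'     for \eqn{\lambda < 0} the \eqn{1/\lambda} scaling is required to keep
#'     the generator decreasing. Tends to the product copula as
#'     \eqn{\lambda \to 0^+}.}
#'   \item{3 (Frank)}{\eqn{\vartheta(x) = -\ln\left(\frac{e^{-\lambda x}-1}
#'     {e^{-\lambda}-1}\right)}, \eqn{\lambda \ne 0}; evaluated as the
#'     independence limit \eqn{-\ln x} below \eqn{|\lambda| < 10^{-5}} for
#'     numerical stability.}
#'   \item{4 (Ali-Mikhail-Haq)}{\eqn{\vartheta(x) = \ln\frac{1-\lambda(1-x)}{x}},
#'     \eqn{\lambda \in [-1, 1)}.}
#'   \item{5 (Joe)}{\eqn{\vartheta(x) = -\ln(1-(1-x)^\lambda)},
#'     \eqn{\lambda \ge 1}.}
#' }
#'
#' On construction the generator is spot-checked numerically: it must be
#' strictly decreasing on a grid of (0,1] and vanish at 1.
#'
#' @param family integer in 1..5 selecting the generator family.
#' @param lam the real copula parameter \eqn{\lambda}; its admissible domain
#'   depends on the family (see Details).
#' @return an object of class `"ldf_copula"`.
#' @examples
#' sp <- ldf_copula(2, 1)               # Clayton, lambda = 1
#' archimedean_copula(sp, 0.5, 0.5)     # 1/3
#' co_copula(ldf_copula(1, 1), 0.5, 0.4) # 0.7 (probabilistic sum)
#' @export
ldf_copula <- function(family = 2L, lam = 1) {
  if (length(family) != 1L || !family %in% 1:5)
    stop("'family' must be an integer in 1..5", call. = FALSE)
  family <- as.integer(family)
  if (length(lam) != 1L || !is.finite(lam))
    stop("'lam' must be a single finite number", call. = FALSE)
  ok <- switch(family,
               lam >= 1,
               lam >= -1 && lam != 0,
               lam != 0,
               lam >= -1 && lam < 1,
               lam >= 1)
  if (!ok)
    stop(sprintf("lambda = %g is outside the domain of family %d",
                 lam, family), call. = FALSE)
  spec <- structure(list(family = family, lam = lam), class = "ldf_copula")
  # numeric sanity check of the generator axioms
  grid <- seq(0.05, 1, by = 0.05)
  g <- copula_generator(spec, grid)
  if (abs(g[length(g)]) > 1e-12 || any(diff(g) >= 0))
    stop("internal error: generator is not strictly decreasing to 0 at 1",
         call. = FALSE)
  spec
}

#' @export
print.ldf_copula <- function(x, ...) {
  fam <- c("Gumbel", "Clayton", "Frank", "Ali-Mikhail-Haq", "Joe")[x$family]
  cat(sprintf("Archimedean copula: family %d (%s), lambda = %g\n",
              x$family, fam, x$lam))
  invisible(x)
}

.check_copula <- function(spec) {
  if (!inherits(spec, "ldf_copula"))
    stop("'spec' must be an 'ldf_copula' object (see ldf_copula())",
         call. = FALSE)
  spec
}

# Frank below this |lambda| is evaluated as the independence limit
.frank_eps <- 1e-5

#' Copula generator and its pseudo-inverse
#'
#' `copula_generator()` evaluates the family's additive generator
#' \eqn{\vartheta(x)}; `copula_generator_inverse()` evaluates the
#' pseudo-inverse, i.e. \eqn{\vartheta^{-1}(s)} for
#' \eqn{s \le \vartheta(0)} and 0 beyond. Families whose generator diverges
#' at 0 return `Inf` there; the pseudo-inverse maps `Inf` (and any value
#' past \eqn{\vartheta(0)}) to 0, which makes crisp components absorbing in
#' the weighted aggregation sums.
#'
#' @param spec an [ldf_copula()] specification.
#' @param x numeric vector in \[0, 1\].
#' @param s numeric vector, \eqn{s \ge 0} (values within `1e-12` of 0 are
#'   clamped).
#' @return numeric vector; generator values in \eqn{[0, \infty]}, inverse
#'   values in \[0, 1\].
#' @export
copula_generator <- function(spec, x) {
  .check_copula(spec)
  if (any(x < -1e-12 | x > 1 + 1e-12, na.rm = TRUE))
    stop("generator argument must lie in [0, 1]", call. = FALSE)
  x <- pmin(pmax(x, 0), 1)
  lam <- spec$lam
  g <- switch(spec$family,
    (-log(x))^lam,
    if (lam > 0) x^(-lam) - 1 else (x^(-lam) - 1) / lam,
    if (abs(lam) < .frank_eps) -log(x)
      else -log(expm1(-lam * x) / expm1(-lam)),
    log((1 - lam * (1 - x)) / x),
    -log1p(-(1 - x)^lam))
  # exact endpoints: theta(1) = 0, theta(0) = the family's limit
  g[x >= 1] <- 0
  g[x <= 0] <- .generator_at_zero(spec)
  g
}

.generator_at_zero <- function(spec) {
  if (spec$family == 2L && spec$lam < 0) -1 / spec$lam else Inf
}

#' @rdname copula_generator
#' @export
copula_generator_inverse <- function(spec, s) {
  .check_copula(spec)
  if (any(s < -1e-12, na.rm = TRUE))
    stop("pseudo-inverse argument must be non-negative", call. = FALSE)
  s <- pmax(s, 0)
  lam <- spec$lam
  out <- switch(spec$family,
    exp(-s^(1 / lam)),
    if (lam > 0) (s + 1)^(-1 / lam)
      else (pmax(lam * s + 1, 0))^(-1 / lam),
    if (abs(lam) < .frank_eps) exp(-s)
      else -log1p(exp(-s) * expm1(-lam)) / lam,
    (1 - lam) / (exp(s) - lam),
    1 - (-expm1(-s))^(1 / lam))
  # pseudo-inverse clamp: anything past theta(0) maps to 0
  out[s >= .generator_at_zero(spec)] <- 0
  out[s == 0] <- 1
  pmin(pmax(out, 0), 1)
}

#' Extended copula and co-copula
#'
#' The copula value \eqn{C(x,y) = \vartheta^{-1}(\vartheta(x)+\vartheta(y))}
#' acts as the t-norm of the operational laws (non-membership side); the
#' co-copula \eqn{C^*(x,y) = 1 - C(1-x, 1-y)} is its dual t-conorm
#' (membership side). Both satisfy the boundary axioms
#' \eqn{C(x,1) = x}, \eqn{C(x,0) = 0}, \eqn{C^*(x,0) = x}, and the
#' Frechet bound \eqn{C(x,y) \le \min(x,y)}.
#'
#' @param spec an [ldf_copula()] specification.
#' @param x,y numeric vectors in \[0, 1\] (recycled).
#' @return numeric vector in \[0, 1\].
#' @export
archimedean_copula <- function(spec, x, y) {
  gx <- copula_generator(spec, x)
  gy <- copula_generator(spec, y)
  s <- gx + gy
  s[is.infinite(gx) | is.infinite(gy)] <- Inf  # avoid Inf - Inf style NaN
  copula_generator_inverse(spec, s)
}

#' @rdname archimedean_copula
#' @export
co_copula <- function(spec, x, y) {
  1 - archimedean_copula(spec, 1 - x, 1 - y)
}
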