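# Extended copula operational laws on LDFNs and the weighted copula
# aggregation operators built from them.

# weighted sum of generator values; weight-0 terms are dropped so that a
# crisp component (generator = Inf) is absorbing only when actually weighted
.gen_wsum <- function(w, g) {
  keep <- w > 0
  if (!any(keep)) return(0)
  g <- g[keep]; w <- w[keep]
  if (any(is.infinite(g))) return(Inf)
  sum(w * g)
}

.check_weights <- function(w, n = NULL, name = "weights") {
  if (!is.numeric(w) || length(w) < 1L)
    stop(sprintf("'%s' must be a non-empty numeric vector", name),
         call. = FALSE)
  if (!is.null(n) && length(w) != n)
    stop(sprintf("'%s' has length %d but %d values are being aggregated",
                 name, length(w), n), call. = FALSE)
  if (any(w < -.ldf_tol))
    stop(sprintf("'%s' must be non-negative", name), call. = FALSE)
  if (abs(sum(w) - 1) > .ldf_tol)
    stop(sprintf("'%s' must sum to 1 (got %.10g); normalize explicitly",
                 name, sum(w)), call. = FALSE)
  pmax(w, 0)
}

#' Copula operational laws on LDFNs
#'
#' The extended operational laws replace the product t-norm of the
#' classical LDF algebra with an arbitrary Archimedean copula \eqn{C} and
#' its co-copula \eqn{C^*}:
#' \deqn{L_1 \oplus L_2 = \left((C^*(\varphi_1,\varphi_2),\,
#'   C(\psi_1,\psi_2)),\ (C^*(\varrho_1,\varrho_2),\,
#'   C(\sigma_1,\sigma_2))\right),}
#' with `cop_mult` the dual (\eqn{C} and \eqn{C^*} swapped). The scalar
#' multiple and power follow from the generator form,
#' \deqn{\alpha L = \left(1-\vartheta^{-1}(\alpha\,\vartheta(1-\varphi)),\
#'   \vartheta^{-1}(\alpha\,\vartheta(\psi)),\ \ldots\right), \quad \alpha > 0,}
#' which for integer \eqn{\alpha = n} coincides with the n-fold
#' \eqn{\oplus}-chain. Under the product copula (family 1,
#' \eqn{\lambda = 1}) all four operations reduce to [alg_add()] /
#' [alg_mult()] / [alg_scalar()] / [alg_power()].
#'
#' @param a,b `"ldfn"` vectors sharing q (recycled elementwise).
#' @param alpha a single positive real.
#' @param x an `"ldfn"` vector.
#' @param spec an [ldf_copula()] specification.
#' @return an `"ldfn"` vector.
#' @examples
#' prod_cop <- ldf_copula(1, 1)
#' cop_add(ldfn(0.6, 0.3, 0.5, 0.4), ldfn(0.5, 0.4, 0.3, 0.6), prod_cop)
#' @export
cop_add <- function(a, b, spec) {
  q <- .check_same_q(.check_ldfn(a), .check_ldfn(b))
  .check_copula(spec)
  ldfn(co_copula(spec, a$mem, b$mem),
       archimedean_copula(spec, a$non, b$non),
       co_copula(spec, a$rmem, b$rmem),
       archimedean_copula(spec, a$rnon, b$rnon), q = q)
}

#' @rdname cop_add
#' @export
cop_mult <- function(a, b, spec) {
  q <- .check_same_q(.check_ldfn(a), .check_ldfn(b))
  .check_copula(spec)
  ldfn(archimedean_copula(spec, a$mem, b$mem),
       co_copula(spec, a$non, b$non),
       archimedean_copula(spec, a$rmem, b$rmem),
       co_copula(spec, a$rnon, b$rnon), q = q)
}

# scalar transform t -> theta_inv(alpha * theta(t)); alpha * Inf stays Inf
.scaled_gen <- function(spec, alpha, t) {
  g <- copula_generator(spec, t)
  copula_generator_inverse(spec, alpha * g)
}

#' @rdname cop_add
#' @export
cop_scalar <- function(alpha, x, spec) {
  .check_ldfn(x); .check_copula(spec)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0)
    stop("'alpha' must be a single positive number", call. = FALSE)
  ldfn(1 - .scaled_gen(spec, alpha, 1 - x$mem),
       .scaled_gen(spec, alpha, x$non),
       1 - .scaled_gen(spec, alpha, 1 - x$rmem),
       .scaled_gen(spec, alpha, x$rnon), q = attr(x, "q"))
}

#' @rdname cop_add
#' @export
cop_power <- function(x, alpha, spec) {
  .check_ldfn(x); .check_copula(spec)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0)
    stop("'alpha' must be a single positive number", call. = FALSE)
  ldfn(.scaled_gen(spec, alpha, x$mem),
       1 - .scaled_gen(spec, alpha, 1 - x$non),
       .scaled_gen(spec, alpha, x$rmem),
       1 - .scaled_gen(spec, alpha, 1 - x$rnon), q = attr(x, "q"))
}

#' Weighted copula aggregation of LDFNs
#'
#' `ldfwca()` is the linear Diophantine fuzzy weighted copula aggregation
#' operator: for values \eqn{L_1,\dots,L_n} and weights \eqn{\omega} summing
#' to 1,
#' \deqn{\mathrm{LDFWCA}(L_1,\dots,L_n) = \left(
#'   1-\vartheta^{-1}\!\left(\textstyle\sum_i \omega_i\,
#'     \vartheta(1-\varphi_i)\right),\
#'   \vartheta^{-1}\!\left(\textstyle\sum_i \omega_i\,
#'     \vartheta(\psi_i)\right),\ \ldots\right),}
#' with the reference parameters aggregated the same way. It is idempotent,
#' and under the product copula reduces to the classical LDFWA closed form
#' \eqn{(1-\prod_i(1-\varphi_i)^{\omega_i},\ \prod_i \psi_i^{\omega_i},
#' \ldots)}.
#'
#' `ldfwoca()` is the ordered variant: the values are first sorted in
#' descending score order (ties broken by accuracy, then lexicographically)
#' and the weights applied by position, making the operator invariant under
#' permutation of its inputs. `ldfwhca()` is the hybrid: each value is first
#' rescaled by `cop_scalar(n * weights[i], .)` and the ordered operator is
#' then applied with the position weights `order_weights`; with uniform
#' `weights` the rescaling is the identity and the hybrid collapses to the
#' ordered operator.
#'
#' @param x an `"ldfn"` vector, the collection to aggregate.
#' @param weights numeric weights, non-negative, summing to 1, one per
#'   element of `x`.
#' @param order_weights position weights for the hybrid operator, same
#'   constraints as `weights`.
#' @param spec an [ldf_copula()] specification.
#' @return a length-1 `"ldfn"`.
#' @examples
#' cl <- ldf_copula(2, 1)
#' v <- from_pair(c(0.2, 0.8), c(0.5, 0.5))
#' ldfwca(v, c(0.5, 0.5), cl)   # membership 0.68
#' @export
ldfwca <- function(x, weights, spec) {
  .check_ldfn(x); .check_copula(spec)
  n <- length(x)
  if (n < 1L) stop("cannot aggregate an empty collection", call. = FALSE)
  w <- .check_weights(weights, n)
  inv <- function(s) copula_generator_inverse(spec, s)
  gen <- function(t) copula_generator(spec, t)
  ldfn(1 - inv(.gen_wsum(w, gen(1 - x$mem))),
       inv(.gen_wsum(w, gen(x$non))),
       1 - inv(.gen_wsum(w, gen(1 - x$rmem))),
       inv(.gen_wsum(w, gen(x$rnon))), q = attr(x, "q"))
}

#' @rdname ldfwca
#' @export
ldfwoca <- function(x, weights, spec) {
  .check_ldfn(x)
  w <- .check_weights(weights, length(x))
  ldfwca(x[.ldf_order(x, decreasing = TRUE)], w, spec)
}

#' @rdname ldfwca
#' @export
ldfwhca <- function(x, weights, order_weights, spec) {
  .check_ldfn(x); .check_copula(spec)
  n <- length(x)
  w <- .check_weights(weights, n)
  ow <- .check_weights(order_weights, n, "order_weights")
  scaled <- lapply(seq_len(n), function(i) {
    # a zero importance weight scales the value down to the neutral element
    if (w[i] == 0) ldfn(0, 1, 0, 1, q = attr(x, "q"))
    else cop_scalar(n * w[i], x[i], spec)
  })
  ldfwoca(do.call(c, scaled), ow, spec)
}
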