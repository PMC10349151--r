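#' @title Linear Diophantine fuzzy numbers
#'
#' @description
#' A linear Diophantine fuzzy number (LDFN) couples a membership grade
#' \eqn{\varphi} and a non-membership grade \eqn{\psi} with a pair of
#' reference parameters \eqn{(\varrho, \sigma)} and an exponent \eqn{q \ge 1}.
#' The reference parameters weight the grades in the validity constraints
#' \deqn{\varrho^q + \sigma^q \le 1, \qquad
#'       \varphi\,\varrho^q + \psi\,\sigma^q \le 1,}
#' which relax the classical intuitionistic constraint
#' \eqn{\varphi + \psi \le 1} and make the LDFN family strictly larger than
#' intuitionistic, Pythagorean and q-rung orthopair fuzzy numbers (each of
#' those is an LDFN for a particular choice of reference parameters).
#'
#' `ldfn()` builds a validated vector of LDFNs; all four components are
#' recycled to a common length. Values within `1e-9` of the unit interval
#' boundary are clamped; anything further outside, or violating either
#' constraint by more than the tolerance, is rejected with an error that
#' names the inequality and its slack.
#'
#' @param mem,nonmem numeric vectors of membership / non-membership grades
#'   in \[0, 1\].
#' @param ref_mem,ref_nonmem numeric vectors of reference parameters in
#'   \[0, 1\].
#' @param q a single integer exponent, \eqn{q \ge 1}.
#' @return an object of class `"ldfn"`: a vectorized record of the four
#'   components with the common exponent attached as attribute `"q"`.
#' @examples
#' ldfn(0.8, 0.9, 0.3, 0.6)            # valid: 0.8*0.3 + 0.9*0.6 = 0.78
#' ldfn(1, 0, 1, 0)                    # crisp full membership
#' try(ldfn(0.9, 0.9, 0.8, 0.8))       # rejected: 0.8 + 0.8 > 1
#' @seealso [from_pair()], [ldf_complement()], [ldf_score()]
#' @export
ldfn <- function(mem, nonmem, ref_mem, ref_nonmem, q = 1L) {
  if (length(q) != 1L || !is.numeric(q) || q < 1 || q != round(q))
    stop("'q' must be a single integer >= 1", call. = FALSE)
  q <- as.integer(q)
  n <- max(length(mem), length(nonmem), length(ref_mem), length(ref_nonmem))
  comp <- list(mem = rep_len(as.numeric(mem), n),
               non = rep_len(as.numeric(nonmem), n),
               rmem = rep_len(as.numeric(ref_mem), n),
               rnon = rep_len(as.numeric(ref_nonmem), n))
  comp <- lapply(comp, .clamp01)
  with(comp, {
    ref <- rmem^q + rnon^q
    bad <- which(ref > 1 + .ldf_tol)
    if (length(bad))
      stop(sprintf(
        "reference constraint violated at element %d: rho^q + sigma^q = %.6g > 1 (slack %.3g)",
        bad[1L], ref[bad[1L]], ref[bad[1L]] - 1), call. = FALSE)
    mix <- mem * rmem^q + non * rnon^q
    bad <- which(mix > 1 + .ldf_tol)
    if (length(bad))
      stop(sprintf(
        "mixed constraint violated at element %d: phi*rho^q + psi*sigma^q = %.6g > 1 (slack %.3g)",
        bad[1L], mix[bad[1L]], mix[bad[1L]] - 1), call. = FALSE)
  })
  structure(comp, q = q, class = "ldfn")
}

.ldf_tol <- 1e-9

# clamp values within tol of [0,1]; reject anything further out
.clamp01 <- function(x) {
  if (anyNA(x)) stop("LDFN components must not be NA", call. = FALSE)
  out <- which(x < -.ldf_tol | x > 1 + .ldf_tol)
  if (length(out))
    stop(sprintf("component %.6g at element %d lies outside [0, 1]",
                 x[out[1L]], out[1L]), call. = FALSE)
  pmin(pmax(x, 0), 1)
}

#' Lift a membership/non-membership pair to a full LDFN
#'
#' Expert panels are often elicited as bare grade pairs; the reference
#' parameters are then supplied once, as a panel-wide default. This helper
#' attaches the default reference pair to every grade pair and validates the
#' result as [ldfn()] would.
#'
#' @param mem,nonmem numeric vectors of grades.
#' @param refs length-2 numeric, the default reference pair
#'   \eqn{(\varrho_0, \sigma_0)} with \eqn{\varrho_0^q + \sigma_0^q \le 1}.
#' @param q integer exponent.
#' @return an `"ldfn"` vector.
#' @examples
#' from_pair(c(0.8, 0.2), c(0.9, 0.1))
#' @export
from_pair <- function(mem, nonmem, refs = c(0.5, 0.5), q = 1L) {
  if (length(refs) != 2L)
    stop("'refs' must be a numeric pair (rho0, sigma0)", call. = FALSE)
  if (refs[1L]^q + refs[2L]^q > 1 + .ldf_tol)
    stop(sprintf("default references violate rho0^q + sigma0^q <= 1 (got %.6g)",
                 refs[1L]^q + refs[2L]^q), call. = FALSE)
  ldfn(mem, nonmem, refs[1L], refs[2L], q = q)
}

#' @export
length.ldfn <- function(x) length(x$mem)

#' @export
`[.ldfn` <- function(x, i) {
  structure(lapply(unclass(x), `[`, i), q = attr(x, "q"), class = "ldfn")
}

#' @export
c.ldfn <- function(...) {
  xs <- list(...)
  qs <- vapply(xs, attr, integer(1), "q")
  if (length(unique(qs)) != 1L)
    stop("cannot combine LDFNs with different exponents q", call. = FALSE)
  structure(list(mem = unlist(lapply(xs, `[[`, "mem")),
                 non = unlist(lapply(xs, `[[`, "non")),
                 rmem = unlist(lapply(xs, `[[`, "rmem")),
                 rnon = unlist(lapply(xs, `[[`, "rnon"))),
            q = qs[1L], class = "ldfn")
}

#' @export
format.ldfn <- function(x, digits = 3L, ...) {
  sprintf("<(%s, %s), (%s, %s)>",
          format(x$mem, digits = digits), format(x$non, digits = digits),
          format(x$rmem, digits = digits), format(x$rnon, digits = digits))
}

#' @export
print.ldfn <- function(x, ...) {
  cat(sprintf("LDFN vector of length %d (q = %d)\n", length(x), attr(x, "q")))
  print(format(x, ...), quote = FALSE)
  invisible(x)
}

#' @export
as.data.frame.ldfn <- function(x, ...) {
  data.frame(mem = x$mem, nonmem = x$non,
             ref_mem = x$rmem, ref_nonmem = x$rnon)
}

#' Exponent of an LDFN vector
#' @param x an `"ldfn"` object.
#' @return the integer exponent q shared by all elements.
#' @export
ldf_q <- function(x) attr(x, "q")

.check_ldfn <- function(x, arg = deparse(substitute(x))) {
  if (!inherits(x, "ldfn"))
    stop(sprintf("'%s' must be an 'ldfn' object", arg), call. = FALSE)
  x
}

.check_same_q <- function(a, b) {
  if (attr(a, "q") != attr(b, "q"))
    stop("mixed-q arithmetic is not defined; both operands must share q",
         call. = FALSE)
  attr(a, "q")
}

#' Complement of an LDFN
#'
#' Swaps the grade pair and the reference pair:
#' \eqn{(\varphi,\psi,\varrho,\sigma)^c = (\psi,\varphi,\sigma,\varrho)}.
#' This is an involution, preserves both validity constraints, and maps the
#' crisp value \eqn{(1,0,1,0)} to its anti-crisp dual \eqn{(0,1,0,1)}.
#'
#' @param x an `"ldfn"` vector.
#' @return the elementwise complement, an `"ldfn"` vector.
#' @export
ldf_complement <- function(x) {
  .check_ldfn(x)
  structure(list(mem = x$non, non = x$mem, rmem = x$rnon, rnon = x$rmem),
            q = attr(x, "q"), class = "ldfn")
}

#' Score, accuracy and comparison of LDFNs
#'
#' The score function ranks LDFNs on \[-1, 1\]:
#' \deqn{S(L) = \tfrac12\left[(\varphi - \psi) + (\varrho^q - \sigma^q)\right],}
#' and the accuracy on \[0, 1\]:
#' \deqn{A(L) = \tfrac12\left[(\varphi + \psi) + (\varrho^q + \sigma^q)\right].}
#' `ldf_compare()` induces a total order: first by score, then by accuracy,
#' then lexicographically on the four components, so that argmax/argmin
#' selections in the decision pipeline are deterministic.
#'
#' @param x,a,b `"ldfn"` vectors (`a` and `b` are recycled to a common
#'   length and must share q).
#' @return `ldf_score`/`ldf_accuracy`: numeric vectors. `ldf_compare`: an
#'   integer vector in \{-1, 0, 1\} (sign of `a` relative to `b`).
#' @examples
#' ldf_score(ldfn(1, 0, 1, 0))    #  1
#' ldf_score(ldfn(0, 1, 0, 1))    # -1
#' @export
ldf_score <- function(x) {
  .check_ldfn(x)
  q <- attr(x, "q")
  ((x$mem - x$non) + (x$rmem^q - x$rnon^q)) / 2
}

#' @rdname ldf_score
#' @export
ldf_accuracy <- function(x) {
  .check_ldfn(x)
  q <- attr(x, "q")
  ((x$mem + x$non) + (x$rmem^q + x$rnon^q)) / 2
}

#' @rdname ldf_score
#' @export
ldf_compare <- function(a, b) {
  .check_ldfn(a); .check_ldfn(b)
  .check_same_q(a, b)
  n <- max(length(a), length(b))
  a <- a[rep_len(seq_len(length(a)), n)]
  b <- b[rep_len(seq_len(length(b)), n)]
  keys <- list(ldf_score(a) - ldf_score(b),
               ldf_accuracy(a) - ldf_accuracy(b),
               a$mem - b$mem, a$non - b$non,
               a$rmem - b$rmem, a$rnon - b$rnon)
  out <- integer(n)
  for (k in keys) {
    idx <- out == 0L & abs(k) > .ldf_tol
    out[idx] <- sign(k[idx])
  }
  out
}

# ordering permutation by the total order (descending by default); used by
# the ordered aggregation operators and the ideal-solution selections
.ldf_order <- function(x, decreasing = TRUE) {
  q <- attr(x, "q")
  o <- order(ldf_score(x), ldf_accuracy(x), x$mem, x$non, x$rmem, x$rnon,
             decreasing = decreasing)
  o
}

# ---- classical (product t-norm) algebra --------------------------------

#' Classical algebraic operations on LDFNs
#'
#' The product t-norm algebra on LDF numbers: probabilistic sum on the
#' membership side, product on the non-membership side, applied to grades
#' and reference parameters alike,
#' \deqn{L_1 \oplus L_2 = (\varphi_1 + \varphi_2 - \varphi_1\varphi_2,\;
#'   \psi_1\psi_2,\; \varrho_1 + \varrho_2 - \varrho_1\varrho_2,\;
#'   \sigma_1\sigma_2),}
#' with `alg_mult` the dual, and the scalar/power forms
#' \eqn{\gamma L = (1-(1-\varphi)^\gamma, \psi^\gamma, \ldots)} and
#' \eqn{L^\gamma = (\varphi^\gamma, 1-(1-\psi)^\gamma, \ldots)}.
#' These coincide with the copula operations of [cop_add()] under the
#' product copula, and serve as the independent closed form for the
#' reduction tests of the copula engine.
#'
#' @param a,b `"ldfn"` vectors sharing q (recycled elementwise).
#' @param gamma a positive scalar.
#' @param x an `"ldfn"` vector.
#' @return an `"ldfn"` vector.
#' @examples
#' alg_add(ldfn(0.6, 0.3, 0.5, 0.4), ldfn(0.5, 0.4, 0.3, 0.6))
#' # <(0.8, 0.12), (0.65, 0.24)>
#' @export
alg_add <- function(a, b) {
  q <- .check_same_q(.check_ldfn(a), .check_ldfn(b))
  ldfn(a$mem + b$mem - a$mem * b$mem, a$non * b$non,
       a$rmem + b$rmem - a$rmem * b$rmem, a$rnon * b$rnon, q = q)
}

#' @rdname alg_add
#' @export
alg_mult <- function(a, b) {
  q <- .check_same_q(.check_ldfn(a), .check_ldfn(b))
  ldfn(a$mem * b$mem, a$non + b$non - a$non * b$non,
       a$rmem * b$rmem, a$rnon + b$rnon - a$rnon * b$rnon, q = q)
}

#' @rdname alg_add
#' @export
alg_scalar <- function(gamma, x) {
  .check_ldfn(x)
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0)
    stop("'gamma' must be a single positive number", call. = FALSE)
  ldfn(1 - (1 - x$mem)^gamma, x$non^gamma,
       1 - (1 - x$rmem)^gamma, x$rnon^gamma, q = attr(x, "q"))
}

#' @rdname alg_add
#' @export
alg_power <- function(x, gamma) {
  .check_ldfn(x)
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0)
    stop("'gamma' must be a single positive number", call. = FALSE)
  ldfn(x$mem^gamma, 1 - (1 - x$non)^gamma,
       x$rmem^gamma, 1 - (1 - x$rnon)^gamma, q = attr(x, "q"))
}
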