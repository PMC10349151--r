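# Generalized distance and entropy measures on LDF collections.

#' Generalized distance between LDF collections
#'
#' The generalized distance of order \eqn{\Upsilon > 0} between two
#' equal-length collections of LDFNs averages the component-wise
#' \eqn{\Upsilon}-power differences over all four components:
#' \deqn{d^g(A, B) = \left(\frac{1}{4n}\sum_{i=1}^n
#'   |\Delta\varphi_i|^\Upsilon + |\Delta\psi_i|^\Upsilon +
#'   |\Delta\varrho_i|^\Upsilon + |\Delta\sigma_i|^\Upsilon
#'   \right)^{1/\Upsilon}.}
#' \eqn{\Upsilon = 1} gives the Hamming distance, \eqn{\Upsilon = 2} the
#' Euclidean distance, and `upsilon = Inf` the Chebyshev distance (the
#' maximum component difference). The weighted form multiplies each term by
#' \eqn{w_i}; with `strict = TRUE` (the default) the \eqn{1/(4n)} prefactor
#' is kept alongside the weights, with `strict = FALSE` the prefactor is
#' \eqn{1/4} only, so that uniform weights reproduce the plain distance
#' exactly.
#'
#' @param a,b `"ldfn"` vectors of equal length sharing q.
#' @param upsilon the distance order \eqn{\Upsilon > 0}; `Inf` selects the
#'   Chebyshev limit.
#' @param weights optional non-negative weights summing to 1, one per
#'   element; `NULL` gives the plain (unweighted) distance.
#' @param strict logical; for the weighted form, keep the \eqn{1/(4n)}
#'   prefactor (`TRUE`) or use the conventional \eqn{1/4}-only
#'   normalization (`FALSE`). Ignored when `weights` is `NULL`.
#' @return a single number in \[0, 1\].
#' @examples
#' ldf_distance(ldfn(1, 0, 1, 0), ldfn(0, 1, 0, 1))  # 1
#' @export
ldf_distance <- function(a, b, upsilon = 1, weights = NULL, strict = TRUE) {
  .check_ldfn(a); .check_ldfn(b)
  .check_same_q(a, b)
  n <- length(a)
  if (length(b) != n)
    stop("'a' and 'b' must have the same length", call. = FALSE)
  if (!(is.numeric(upsilon) && length(upsilon) == 1L && upsilon > 0))
    stop("'upsilon' must be a single positive number (Inf allowed)",
         call. = FALSE)
  d <- cbind(abs(a$mem - b$mem), abs(a$non - b$non),
             abs(a$rmem - b$rmem), abs(a$rnon - b$rnon))
  if (is.null(weights)) {
    if (is.infinite(upsilon)) return(max(d))
    return(min((sum(d^upsilon) / (4 * n))^(1 / upsilon), 1))
  }
  w <- .check_weights(weights, n)
  if (is.infinite(upsilon)) {
    keep <- w > 0
    if (!any(keep)) return(0)
    return(max(d[keep, , drop = FALSE]))
  }
  pref <- if (strict) 1 / (4 * n) else 1 / 4
  min((pref * sum(w * rowSums(d^upsilon)))^(1 / upsilon), 1)
}

#' Hesitancy of an LDFN
#'
#' The hesitancy margin \eqn{\pi = 1 - (\varphi\varrho^q + \psi\sigma^q)}:
#' the slack of the mixed validity constraint, guaranteed to lie in
#' \[0, 1\] for every valid LDFN and invariant under complementation.
#'
#' @param x an `"ldfn"` vector.
#' @return a numeric vector in \[0, 1\].
#' @export
ldf_hesitancy <- function(x) {
  .check_ldfn(x)
  q <- attr(x, "q")
  pmax(1 - (x$mem * x$rmem^q + x$non * x$rnon^q), 0)
}

#' Entropy of an LDF collection
#'
#' Measures how fuzzy (close to its own complement, and hesitant) a
#' collection is:
#' \deqn{E(\mathfrak{I}) = \frac{1}{n}\sum_{i=1}^n
#'   \left\{1 - d(\mathfrak{I}_i, \mathfrak{I}_i^c)\right\}
#'   \frac{1 + \pi_i}{2},}
#' where \eqn{d} is the single-element Hamming distance ([ldf_distance()]
#' with \eqn{\Upsilon = 1}) between an element and its complement and
#' \eqn{\pi_i} its hesitancy. The entropy is 0 exactly on crisp
#' collections (every element \eqn{(1,0,1,0)} or \eqn{(0,1,0,1)}), takes
#' the value 0.75 on the maximally fuzzy element
#' \eqn{(0.5, 0.5, 0.5, 0.5)}, and is invariant under complementation of
#' the collection.
#'
#' @param x a non-empty `"ldfn"` vector.
#' @param collapse logical; return the mean over elements (`TRUE`, the
#'   entropy of the collection) or the per-element values.
#' @return a number in \[0, 1\], or a vector of them if `collapse = FALSE`.
#' @examples
#' ldf_entropy(ldfn(1, 0, 1, 0))               # 0
#' ldf_entropy(ldfn(0.5, 0.5, 0.5, 0.5))       # 0.75
#' @export
ldf_entropy <- function(x, collapse = TRUE) {
  .check_ldfn(x)
  if (length(x) == 0L)
    stop("entropy of an empty collection is undefined", call. = FALSE)
  xc <- ldf_complement(x)
  # per-element Hamming distance to the complement
  d <- (abs(x$mem - xc$mem) + abs(x$non - xc$non) +
        abs(x$rmem - xc$rmem) + abs(x$rnon - xc$rnon)) / 4
  e <- (1 - d) * (1 + ldf_hesitancy(x)) / 2
  if (collapse) mean(e) else e
}
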