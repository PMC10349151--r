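# Built-in panels: the EEG classifier-selection worked example and a
# seeded random panel generator for property testing and simulation.

#' EEG classifier selection panel
#'
#' The embedded worked example: three decision experts evaluate five EEG
#' classifiers for depression screening --- P1 k-nearest neighbours (k-NN),
#' P2 Gaussian mixture model (GMM), P3 decision tree (DT), P4 naive Bayes
#' (NBC), P5 probabilistic neural network (PNN) --- against five
#' entropy-feature criteria: C1 sample entropy (SampEn), C2 spectral
#' entropy, C3 bispectrum entropy (Ph), C4 approximate entropy (ApEn),
#' C5 Renyi entropy. All criteria are benefit-sense. The experts elicit
#' membership/non-membership pairs; the reference parameters are attached
#' panel-wide via `refs` (no per-cell reference values were elicited).
#'
#' No EEG signal processing happens here: the entropies are criterion
#' labels only, and the cells are expert judgements.
#'
#' @param refs default reference pair attached to every cell (see
#'   [from_pair()]).
#' @param q the exponent of the panel's LDFNs.
#' @return an `"ldf_panel"` with 3 experts, 5 alternatives, 5 criteria.
#' @examples
#' panel <- eeg_classifier_panel()
#' panel$matrices[[1]]
#' @export
eeg_classifier_panel <- function(refs = c(0.5, 0.5), q = 1L) {
  alts <- c("P1", "P2", "P3", "P4", "P5")
  crit <- c("C1", "C2", "C3", "C4", "C5")
  # one row per alternative, (mem, nonmem) pairs left to right C1..C5
  e1 <- rbind(
    c(0.8, 0.9, 0.8, 0.9, 0.1, 0.1, 0.9, 0.1, 0.9, 0.1),
    c(0.3, 0.9, 0.3, 0.2, 0.9, 0.5, 0.7, 0.9, 0.9, 0.1),
    c(0.2, 0.1, 0.2, 0.9, 0.3, 0.7, 0.4, 0.2, 0.2, 0.9),
    c(0.7, 0.6, 0.8, 0.3, 0.5, 0.8, 0.4, 0.4, 0.8, 0.9),
    c(0.6, 0.7, 0.1, 0.3, 0.6, 0.1, 0.8, 0.7, 0.9, 0.1))
  e2 <- rbind(
    c(0.7, 0.7, 0.9, 0.1, 0.9, 0.8, 0.9, 0.1, 0.8, 0.9),
    c(0.5, 0.6, 0.2, 0.9, 0.3, 0.1, 0.2, 0.9, 0.4, 0.9),
    c(0.2, 0.9, 0.5, 0.3, 0.5, 0.2, 0.3, 0.3, 0.5, 0.6),
    c(0.1, 0.5, 0.8, 0.9, 0.9, 0.8, 0.9, 0.9, 0.7, 0.8),
    c(0.3, 0.6, 0.9, 1.0, 0.9, 0.8, 0.6, 0.9, 0.2, 0.9))
  e3 <- rbind(
    c(0.2, 0.8, 0.3, 0.8, 0.2, 0.5, 0.8, 0.8, 0.7, 0.9),
    c(0.7, 0.8, 0.4, 0.9, 0.1, 0.5, 0.9, 0.9, 0.2, 0.1),
    c(0.3, 0.6, 0.6, 0.4, 0.3, 0.6, 0.4, 0.9, 0.8, 0.3),
    c(0.2, 0.9, 0.7, 0.8, 0.8, 0.9, 0.9, 0.4, 0.7, 0.6),
    c(0.5, 0.4, 0.2, 0.9, 0.8, 0.9, 0.9, 0.4, 0.6, 0.7))
  as_matrix <- function(tab) {
    mem <- tab[, seq(1, 9, by = 2)]
    non <- tab[, seq(2, 10, by = 2)]
    decision_matrix(from_pair(as.vector(mem), as.vector(non), refs, q),
                    alts, crit, rep("benefit", 5))
  }
  expert_panel(list(as_matrix(e1), as_matrix(e2), as_matrix(e3)))
}

#' Random valid expert panel
#'
#' Draws a reproducible panel of valid LDFNs. Per cell, the reference pair
#' is drawn uniformly from the region \eqn{\varrho^q + \sigma^q \le 1}
#' (rejection sampling from the unit square) and the grades uniformly from
#' \[0, 1\] (the mixed constraint
#' \eqn{\varphi\varrho^q + \psi\sigma^q \le \varrho^q + \sigma^q \le 1} is
#' then automatic). Criterion senses are drawn at random.
#'
#' @param n number of alternatives (\eqn{\ge 2}).
#' @param m number of criteria (\eqn{\ge 1}).
#' @param e number of experts (\eqn{\ge 1}).
#' @param q the LDFN exponent.
#' @param seed optional integer seed; identical seeds give identical
#'   panels without disturbing the caller's RNG state.
#' @return an `"ldf_panel"`.
#' @examples
#' identical(random_panel(seed = 7), random_panel(seed = 7))
#' @export
random_panel <- function(n = 5L, m = 5L, e = 3L, q = 1L, seed = NULL) {
  stopifnot(n >= 2L, m >= 1L, e >= 1L)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(as.integer(seed))
  }
  ncell <- n * m
  draw_refs <- function(k) {
    rmem <- rnon <- numeric(0)
    while (length(rmem) < k) {
      a <- stats::runif(2 * k); b <- stats::runif(2 * k)
      ok <- a^q + b^q <= 1
      rmem <- c(rmem, a[ok]); rnon <- c(rnon, b[ok])
    }
    list(rmem = rmem[seq_len(k)], rnon = rnon[seq_len(k)])
  }
  senses <- sample(c("benefit", "cost"), m, replace = TRUE)
  alts <- paste0("A", seq_len(n)); crit <- paste0("C", seq_len(m))
  mats <- lapply(seq_len(e), function(k) {
    r <- draw_refs(ncell)
    cells <- ldfn(stats::runif(ncell), stats::runif(ncell),
                  r$rmem, r$rnon, q = q)
    decision_matrix(cells, alts, crit, senses)
  })
  expert_panel(mats)
}
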