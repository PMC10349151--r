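# The three-phase extended TOPSIS group decision algorithm under LDF
# information: expert weights from closeness to group ideal solutions,
# criterion weights from entropy, per-expert relative closeness, and the
# final expert-weighted ranking.

#' Decision matrices and expert panels of LDFNs
#'
#' A decision matrix holds one expert's evaluation of `n` alternatives
#' against `m` criteria, each cell an LDFN; every criterion carries a sense
#' (`"benefit"`: larger grades preferable, or `"cost"`: smaller preferable;
#' cost cells are complemented during normalization). An expert panel is a
#' list of shape-congruent decision matrices, one per expert, plus the
#' within-panel aggregation weights used when fusing experts into the group
#' ideal solution (uniform by default).
#'
#' @param cells an `"ldfn"` vector of length `n * m` in column-major order
#'   (alternative index varies fastest).
#' @param alternatives character vector of `n >= 2` alternative labels.
#' @param criteria character vector of `m >= 1` criterion labels.
#' @param senses character vector of length `m`, each `"benefit"` or
#'   `"cost"`.
#' @param matrices a list of `"ldf_matrix"` objects with identical labels,
#'   senses and exponent q.
#' @param agg_weights optional aggregation weights over experts
#'   (non-negative, summing to 1); uniform if `NULL`.
#' @return `decision_matrix()`: an object of class `"ldf_matrix"`;
#'   `expert_panel()`: an object of class `"ldf_panel"`.
#' @export
decision_matrix <- function(cells, alternatives, criteria, senses) {
  .check_ldfn(cells)
  n <- length(alternatives); m <- length(criteria)
  if (n < 2L) stop("need at least 2 alternatives", call. = FALSE)
  if (m < 1L) stop("need at least 1 criterion", call. = FALSE)
  if (length(cells) != n * m)
    stop(sprintf("expected %d cells (%d x %d), got %d",
                 n * m, n, m, length(cells)), call. = FALSE)
  senses <- match.arg(senses, c("benefit", "cost"), several.ok = TRUE)
  if (length(senses) == 1L) senses <- rep(senses, m)
  if (length(senses) != m)
    stop("'senses' must have one entry per criterion", call. = FALSE)
  structure(list(cells = cells, alternatives = as.character(alternatives),
                 criteria = as.character(criteria), senses = senses,
                 n = n, m = m),
            class = "ldf_matrix")
}

#' @export
print.ldf_matrix <- function(x, digits = 3L, ...) {
  cat(sprintf("LDF decision matrix: %d alternatives x %d criteria (q = %d)\n",
              x$n, x$m, ldf_q(x$cells)))
  grid <- matrix(sprintf("(%s,%s)",
                         format(round(x$cells$mem, digits)),
                         format(round(x$cells$non, digits))),
                 x$n, x$m, dimnames = list(x$alternatives, x$criteria))
  print(grid, quote = FALSE)
  cat("senses:", paste(x$senses, collapse = ", "), "\n")
  invisible(x)
}

# cell/row/column extraction (column-major layout)
.dm_cell <- function(dm, i, j) dm$cells[(j - 1L) * dm$n + i]
.dm_row  <- function(dm, i) dm$cells[(seq_len(dm$m) - 1L) * dm$n + i]
.dm_col  <- function(dm, j) dm$cells[(j - 1L) * dm$n + seq_len(dm$n)]

#' @rdname decision_matrix
#' @export
expert_panel <- function(matrices, agg_weights = NULL) {
  if (!is.list(matrices) || length(matrices) < 1L ||
      !all(vapply(matrices, inherits, logical(1), "ldf_matrix")))
    stop("'matrices' must be a non-empty list of 'ldf_matrix' objects",
         call. = FALSE)
  ref <- matrices[[1L]]
  for (k in seq_along(matrices)[-1L]) {
    mk <- matrices[[k]]
    if (!identical(mk$alternatives, ref$alternatives) ||
        !identical(mk$criteria, ref$criteria) ||
        !identical(mk$senses, ref$senses))
      stop(sprintf("expert %d matrix is not congruent with expert 1", k),
           call. = FALSE)
    if (ldf_q(mk$cells) != ldf_q(ref$cells))
      stop("all experts must share the exponent q", call. = FALSE)
  }
  e <- length(matrices)
  if (is.null(agg_weights)) agg_weights <- rep(1 / e, e)
  agg_weights <- .check_weights(agg_weights, e, "agg_weights")
  structure(list(matrices = matrices, agg_weights = agg_weights,
                 e = e, n = ref$n, m = ref$m,
                 alternatives = ref$alternatives, criteria = ref$criteria,
                 senses = ref$senses),
            class = "ldf_panel")
}

#' @export
print.ldf_panel <- function(x, ...) {
  cat(sprintf(
    "LDF expert panel: %d experts, %d alternatives, %d criteria (q = %d)\n",
    x$e, x$n, x$m, ldf_q(x$matrices[[1L]]$cells)))
  cat("criteria:",
      paste(sprintf("%s (%s)", x$criteria, x$senses), collapse = ", "), "\n")
  invisible(x)
}

#' Normalize an expert panel
#'
#' Benefit cells are kept as given; cost cells are replaced elementwise by
#' their [ldf_complement()]. After normalization all criteria are treated
#' as benefit. Applying the function twice to an all-cost panel returns the
#' original grades (the complement is an involution).
#'
#' @param panel an `"ldf_panel"`.
#' @return the normalized panel, all senses `"benefit"`.
#' @export
normalize_panel <- function(panel) {
  stopifnot(inherits(panel, "ldf_panel"))
  cost <- which(panel$senses == "cost")
  if (length(cost)) {
    for (k in seq_len(panel$e)) {
      dm <- panel$matrices[[k]]
      idx <- as.vector(outer(seq_len(dm$n), cost - 1L,
                             function(i, j0) j0 * dm$n + i))
      comp <- ldf_complement(dm$cells[idx])
      for (f in c("mem", "non", "rmem", "rnon"))
        dm$cells[[f]][idx] <- comp[[f]]
      dm$senses <- rep("benefit", dm$m)
      panel$matrices[[k]] <- dm
    }
    panel$senses <- rep("benefit", panel$m)
  }
  panel
}

#' Group ideal solutions of a normalized panel
#'
#' Computes three `n x m` reference matrices against which each expert is
#' scored:
#' \itemize{
#'   \item GDIS, the group decision ideal solution: the cellwise
#'     [ldfwca()] aggregate of the expert matrices under the panel's
#'     aggregation weights;
#'   \item GRIS, the group right ideal solution: per cell, the expert value
#'     with maximal score (ties broken by the total order of
#'     [ldf_compare()]);
#'   \item GLIS, the group left ideal solution: the score-minimal cell.
#' }
#'
#' @param panel a normalized `"ldf_panel"`.
#' @param spec an [ldf_copula()] specification.
#' @return a list with `"ldf_matrix"` components `gdis`, `gris`, `glis`.
#' @export
group_ideals <- function(panel, spec) {
  stopifnot(inherits(panel, "ldf_panel"))
  .check_copula(spec)
  cells_of <- function(pick) {
    out <- vector("list", panel$n * panel$m)
    for (j in seq_len(panel$m)) for (i in seq_len(panel$n)) {
      cand <- do.call(c, lapply(panel$matrices, .dm_cell, i, j))
      out[[(j - 1L) * panel$n + i]] <- pick(cand)
    }
    do.call(c, out)
  }
  gdis <- cells_of(function(cand) ldfwca(cand, panel$agg_weights, spec))
  gris <- cells_of(function(cand) cand[.ldf_order(cand)[1L]])
  glis <- cells_of(function(cand) {
    o <- .ldf_order(cand, decreasing = FALSE); cand[o[1L]]
  })
  mk <- function(cells) decision_matrix(cells, panel$alternatives,
                                        panel$criteria, panel$senses)
  list(gdis = mk(gdis), gris = mk(gris), glis = mk(glis))
}

#' Expert weights from closeness to the group ideals
#'
#' For every expert the rowwise generalized distance of their matrix to
#' GDIS, GRIS and GLIS is computed; the closeness index of expert `k`
#' aggregates the alternative sums,
#' \deqn{CI^k = \frac{\sum_i DGRIS_i + \sum_i DGLIS_i}
#'                  {\sum_i DGDIS_i + \sum_i DGRIS_i + \sum_i DGLIS_i},}
#' and the expert weights are the normalized closeness indices
#' \eqn{w_k = CI^k / \sum_k CI^k}. An expert whose matrix coincides with
#' all three ideals (zero denominator) receives the neutral index 0.5; a
#' fully degenerate panel in which all experts coincide therefore yields
#' uniform weights.
#'
#' @param panel a normalized `"ldf_panel"`.
#' @param ideals the result of [group_ideals()].
#' @param upsilon the distance order passed to [ldf_distance()].
#' @return a list with per-expert distance matrices (`dgdis`, `dgris`,
#'   `dglis`; experts in rows, alternatives in columns), the closeness
#'   indices `ci` and the weights `w`.
#' @export
expert_weights <- function(panel, ideals, upsilon = 1) {
  stopifnot(inherits(panel, "ldf_panel"))
  e <- panel$e; n <- panel$n
  dd <- dr <- dl <- matrix(0, e, n,
                           dimnames = list(paste0("DM", seq_len(e)),
                                           panel$alternatives))
  for (k in seq_len(e)) for (i in seq_len(n)) {
    row <- .dm_row(panel$matrices[[k]], i)
    dd[k, i] <- ldf_distance(row, .dm_row(ideals$gdis, i), upsilon)
    dr[k, i] <- ldf_distance(row, .dm_row(ideals$gris, i), upsilon)
    dl[k, i] <- ldf_distance(row, .dm_row(ideals$glis, i), upsilon)
  }
  denom <- rowSums(dd) + rowSums(dr) + rowSums(dl)
  # an expert numerically indistinguishable from all three ideals gets the
  # neutral index 0.5 (covers single-expert and all-identical panels)
  ci <- ifelse(denom > .ldf_tol, (rowSums(dr) + rowSums(dl)) / denom, 0.5)
  if (sum(ci) <= 0)
    stop("all closeness indices are zero; expert weights are undefined",
         call. = FALSE)
  list(dgdis = dd, dgris = dr, dglis = dl,
       ci = as.vector(ci), w = as.vector(ci / sum(ci)))
}

#' Criterion weights from the entropy of the revised group matrix
#'
#' The revised group decision matrix (RGDIS) re-aggregates the expert
#' matrices cellwise with the derived expert weights. Each criterion's
#' entropy is the mean per-cell [ldf_entropy()] down its column, and the
#' criterion weights follow the entropy weight method,
#' \deqn{\gamma_j = \frac{1 - E(C_j)}{m - \sum_j E(C_j)},}
#' so that sharper (lower-entropy) criteria receive more weight and
#' \eqn{\sum_j \gamma_j = 1}.
#'
#' @param panel a normalized `"ldf_panel"`.
#' @param w expert weights from [expert_weights()].
#' @param spec an [ldf_copula()] specification.
#' @return a list with the `"ldf_matrix"` `rgdis`, the per-criterion
#'   `entropy` and the weights `gamma`.
#' @export
criteria_weights <- function(panel, w, spec) {
  stopifnot(inherits(panel, "ldf_panel"))
  w <- .check_weights(w, panel$e, "w")
  cells <- vector("list", panel$n * panel$m)
  for (j in seq_len(panel$m)) for (i in seq_len(panel$n)) {
    cand <- do.call(c, lapply(panel$matrices, .dm_cell, i, j))
    cells[[(j - 1L) * panel$n + i]] <- ldfwca(cand, w, spec)
  }
  rgdis <- decision_matrix(do.call(c, cells), panel$alternatives,
                           panel$criteria, panel$senses)
  ent <- vapply(seq_len(panel$m),
                function(j) ldf_entropy(.dm_col(rgdis, j)), numeric(1))
  names(ent) <- panel$criteria
  denom <- panel$m - sum(ent)
  if (denom <= .ldf_tol)
    stop("all criteria have entropy 1; criterion weights are undefined",
         call. = FALSE)
  gamma <- (1 - ent) / denom
  list(rgdis = rgdis, entropy = ent, gamma = gamma)
}

#' Relative closeness from ideal-solution distances
#'
#' \eqn{RCI = DIS^- / (DIS^+ + DIS^-)}: 1 when an alternative sits on the
#' positive ideal, 0 on the negative ideal. An alternative at zero distance
#' from both ideals is indistinguishable and receives 0.5 with a warning.
#'
#' @param dpos,dneg numeric vectors of distances to the positive and
#'   negative ideal solutions.
#' @return a numeric vector in \[0, 1\].
#' @export
relative_closeness <- function(dpos, dneg) {
  denom <- dpos + dneg
  zero <- denom <= 0
  if (any(zero)) {
    warning("alternative indistinguishable from both ideals; RCI set to 0.5")
    denom[zero] <- 1
    dneg[zero] <- 0.5
  }
  dneg / denom
}

#' Per-expert weighted closeness to the positive and negative ideals
#'
#' For each expert the normalized matrix is column-rescaled by
#' `cop_scalar(gamma_j, .)`; the positive (negative) ideal solution of a
#' column is its score-maximal (minimal) cell; and each alternative's
#' distances \eqn{DIS^+} and \eqn{DIS^-} to the ideal rows are the
#' \eqn{\gamma}-weighted generalized distances, from which the relative
#' closeness indices follow.
#'
#' @param panel a normalized `"ldf_panel"`.
#' @param gamma criterion weights (length `m`, summing to 1).
#' @param spec an [ldf_copula()] specification.
#' @param upsilon the distance order.
#' @param strict passed to [ldf_distance()] (keep the \eqn{1/(4m)}
#'   prefactor alongside the weights).
#' @return a list with the per-expert weighted matrices, `pis`/`nis` rows,
#'   distance matrices `dpos`/`dneg` and closeness matrix `rci` (experts in
#'   rows, alternatives in columns).
#' @export
per_expert_closeness <- function(panel, gamma, spec, upsilon = 1,
                                 strict = TRUE) {
  stopifnot(inherits(panel, "ldf_panel"))
  gamma <- .check_weights(gamma, panel$m, "gamma")
  .check_copula(spec)
  e <- panel$e; n <- panel$n; m <- panel$m
  weighted <- vector("list", e)
  pis <- nis <- vector("list", e)
  dpos <- dneg <- matrix(0, e, n,
                         dimnames = list(paste0("DM", seq_len(e)),
                                         panel$alternatives))
  for (k in seq_len(e)) {
    dm <- panel$matrices[[k]]
    wcols <- lapply(seq_len(m), function(j) {
      if (gamma[j] == 0)
        ldfn(rep(0, n), rep(1, n), rep(0, n), rep(1, n), q = ldf_q(dm$cells))
      else cop_scalar(gamma[j], .dm_col(dm, j), spec)
    })
    wm <- decision_matrix(do.call(c, wcols), panel$alternatives,
                          panel$criteria, panel$senses)
    weighted[[k]] <- wm
    pk <- nk <- vector("list", m)
    for (j in seq_len(m)) {
      col <- .dm_col(wm, j)
      pk[[j]] <- col[.ldf_order(col)[1L]]
      nk[[j]] <- col[.ldf_order(col, decreasing = FALSE)[1L]]
    }
    pis[[k]] <- do.call(c, pk)
    nis[[k]] <- do.call(c, nk)
    for (i in seq_len(n)) {
      row <- .dm_row(wm, i)
      dpos[k, i] <- ldf_distance(row, pis[[k]], upsilon, gamma, strict)
      dneg[k, i] <- ldf_distance(row, nis[[k]], upsilon, gamma, strict)
    }
  }
  rci <- matrix(relative_closeness(as.vector(dpos), as.vector(dneg)),
                e, n, dimnames = dimnames(dpos))
  list(weighted = weighted, pis = pis, nis = nis,
       dpos = dpos, dneg = dneg, rci = rci)
}

#' Final closeness and ranking
#'
#' The final closeness of an alternative is the expert-weighted average of
#' its per-expert relative closeness indices,
#' \eqn{FC(A_i) = \sum_k w_k\, RCI_k(A_i)}; alternatives are ranked by
#' descending FC, ties broken by label order with a warning.
#'
#' @param rci a matrix of relative closeness indices, experts in rows,
#'   alternatives in columns.
#' @param w expert weights (length `nrow(rci)`, summing to 1).
#' @return a list with the named vector `fc` and the character vector
#'   `ranking` (labels in decreasing preference).
#' @export
final_closeness <- function(rci, w) {
  if (!is.matrix(rci)) rci <- matrix(rci, nrow = length(w))
  w <- .check_weights(w, nrow(rci), "w")
  fc <- as.vector(t(rci) %*% w)
  names(fc) <- colnames(rci)
  if (anyDuplicated(round(fc / .ldf_tol)))
    warning("tied final closeness values; ranking ties broken by label order")
  ord <- order(-fc, names(fc))
  list(fc = fc, ranking = names(fc)[ord])
}

#' Extended TOPSIS under linear Diophantine fuzzy information
#'
#' Runs the full three-phase group decision algorithm on an expert panel:
#' \enumerate{
#'   \item normalize the panel (complement cost columns), build the group
#'     decision / right / left ideal solutions, and derive the expert
#'     weights from each expert's closeness to the ideals;
#'   \item re-aggregate the panel with the expert weights and derive the
#'     criterion weights from the column entropies (entropy weight method);
#'   \item rescale each expert's matrix by the criterion weights, score
#'     every alternative's distance to the per-column positive and negative
#'     ideal cells, and fuse the per-expert relative closeness indices into
#'     the final closeness and ranking.
#' }
#' All intermediate artifacts are retained in the returned object.
#'
#' @param panel an `"ldf_panel"` (see [expert_panel()]).
#' @param copula the [ldf_copula()] used by every aggregation; the default
#'   is the Clayton family (2) with \eqn{\lambda = 1}.
#' @param upsilon the distance order \eqn{\Upsilon} for every distance in
#'   the pipeline (1 = Hamming, the default).
#' @param strict_weighting keep the literal \eqn{1/(4m)} prefactor in the
#'   weighted ideal distances (see [ldf_distance()]).
#' @param collective_phase3 if `TRUE`, phase 3 operates on a single
#'   collective matrix (the expert-weight aggregate) instead of per expert;
#'   the final closeness is then the collective relative closeness.
#' @return an object of class `"ldf_topsis"` with components `fc`,
#'   `ranking`, `expert_weights`, `criteria_weights`, `entropy`, `ci`,
#'   `rci`, `dpos`, `dneg`, the ideal matrices and every intermediate
#'   artifact; see also [summary.ldf_topsis()] and [plot.ldf_topsis()].
#' @examples
#' fit <- ldf_topsis(eeg_classifier_panel())
#' fit
#' coef(fit)
#' @export
ldf_topsis <- function(panel, copula = ldf_copula(2, 1), upsilon = 1,
                       strict_weighting = TRUE, collective_phase3 = FALSE) {
  stopifnot(inherits(panel, "ldf_panel"))
  .check_copula(copula)
  norm <- normalize_panel(panel)
  ideals <- group_ideals(norm, copula)
  ew <- expert_weights(norm, ideals, upsilon)
  cw <- criteria_weights(norm, ew$w, copula)
  phase3_panel <- norm
  if (collective_phase3) {
    cells <- vector("list", norm$n * norm$m)
    for (j in seq_len(norm$m)) for (i in seq_len(norm$n)) {
      cand <- do.call(c, lapply(norm$matrices, .dm_cell, i, j))
      cells[[(j - 1L) * norm$n + i]] <- ldfwca(cand, ew$w, copula)
    }
    coll <- decision_matrix(do.call(c, cells), norm$alternatives,
                            norm$criteria, norm$senses)
    phase3_panel <- expert_panel(list(coll))
  }
  cls <- per_expert_closeness(phase3_panel, cw$gamma, copula, upsilon,
                              strict_weighting)
  fin <- final_closeness(cls$rci,
                         if (collective_phase3) 1 else ew$w)
  structure(list(call = match.call(),
                 copula = copula, upsilon = upsilon,
                 strict_weighting = strict_weighting,
                 collective_phase3 = collective_phase3,
                 panel = panel, normalized = norm,
                 gdis = ideals$gdis, gris = ideals$gris, glis = ideals$glis,
                 dgdis = ew$dgdis, dgris = ew$dgris, dglis = ew$dglis,
                 ci = ew$ci, expert_weights = ew$w,
                 rgdis = cw$rgdis, entropy = cw$entropy,
                 criteria_weights = cw$gamma,
                 weighted = cls$weighted, pis = cls$pis, nis = cls$nis,
                 dpos = cls$dpos, dneg = cls$dneg, rci = cls$rci,
                 fc = fin$fc, ranking = fin$ranking),
            class = "ldf_topsis")
}

#' @export
print.ldf_topsis <- function(x, digits = 3L, ...) {
  cat("Extended LDF-TOPSIS group decision\n")
  cat(sprintf("  %d experts, %d alternatives, %d criteria; %s\n",
              x$panel$e, x$panel$n, x$panel$m,
              sub("\n$", "", format(x$copula))))
  cat("Final closeness:\n")
  print(round(x$fc, digits))
  cat("Ranking:", paste(x$ranking, collapse = " > "), "\n")
  invisible(x)
}

#' @export
format.ldf_copula <- function(x, ...) {
  fam <- c("Gumbel", "Clayton", "Frank", "Ali-Mikhail-Haq", "Joe")[x$family]
  sprintf("copula family %d (%s), lambda = %g", x$family, fam, x$lam)
}

#' Summarize an extended LDF-TOPSIS fit
#'
#' @param object an `"ldf_topsis"` fit.
#' @param ... unused.
#' @return an object of class `"summary.ldf_topsis"` printing the expert
#'   weights, criterion entropies and weights, the per-expert relative
#'   closeness matrix, and the final ranking.
#' @export
summary.ldf_topsis <- function(object, ...) {
  structure(list(copula = object$copula, upsilon = object$upsilon,
                 ci = object$ci, expert_weights = object$expert_weights,
                 entropy = object$entropy,
                 criteria_weights = object$criteria_weights,
                 rci = object$rci, fc = object$fc,
                 ranking = object$ranking),
            class = "summary.ldf_topsis")
}

#' @export
print.summary.ldf_topsis <- function(x, digits = 4L, ...) {
  cat("Extended LDF-TOPSIS summary (",
      format(x$copula), ", upsilon = ", x$upsilon, ")\n", sep = "")
  cat("\nExpert closeness indices and weights:\n")
  print(round(rbind(CI = x$ci, weight = x$expert_weights), digits))
  cat("\nCriterion entropies and weights:\n")
  print(round(rbind(entropy = x$entropy, weight = x$criteria_weights),
              digits))
  cat("\nRelative closeness (experts x alternatives):\n")
  print(round(x$rci, digits))
  cat("\nFinal closeness:\n")
  print(round(x$fc, digits))
  cat("Ranking:", paste(x$ranking, collapse = " > "), "\n")
  invisible(x)
}

#' Extract derived weights from an LDF-TOPSIS fit
#'
#' @param object an `"ldf_topsis"` fit.
#' @param which which derived quantity to return: the entropy-based
#'   criterion weights, the closeness-based expert weights, or the final
#'   closeness values.
#' @param ... unused.
#' @return a named numeric vector.
#' @export
coef.ldf_topsis <- function(object,
                            which = c("criteria", "experts", "closeness"),
                            ...) {
  switch(match.arg(which),
         criteria = object$criteria_weights,
         experts = stats::setNames(object$expert_weights,
                                   paste0("DM", seq_along(object$expert_weights))),
         closeness = object$fc)
}

#' Plot the final closeness of an LDF-TOPSIS fit
#'
#' Bar chart of the final closeness indices in ranked order.
#'
#' @param x an `"ldf_topsis"` fit.
#' @param ... passed on to [graphics::barplot()].
#' @return the bar midpoints, invisibly.
#' @export
plot.ldf_topsis <- function(x, ...) {
  fc <- x$fc[x$ranking]
  graphics::barplot(fc, ylab = "final closeness", ylim = c(0, 1),
                    main = "LDF-TOPSIS ranking", ...)
}
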