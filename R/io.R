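# Panel and trace interchange. JSON is the canonical format; CSV is a
# convenience dialect with "phi,psi" or "phi,psi|rho,sigma" cell strings.

.ldfn_to_cells <- function(x) {
  lapply(seq_len(length(x)), function(i)
    c(x$mem[i], x$non[i], x$rmem[i], x$rnon[i]))
}

#' Read and write LDF expert panels
#'
#' The JSON panel document has fields `alternatives` (labels), `criteria`
#' (objects with `label` and `sense`), `q`, `agg_weights` (optional) and
#' `experts`: one cell grid per expert, rows in alternative order, each
#' cell either a pair `[phi, psi]` (lifted with the default references) or
#' a quadruple `[phi, psi, rho, sigma]`. Writing always emits quadruples at
#' full precision, so a read/write round trip is lossless. Schema and
#' constraint violations are reported with the offending expert/row/column
#' coordinates.
#'
#' @param path file path.
#' @param refs default reference pair used to lift pair-only cells.
#' @param q exponent used when the document does not carry one.
#' @param panel an `"ldf_panel"` to write.
#' @return `read_panel()` returns an `"ldf_panel"`; the writers return
#'   `path` invisibly.
#' @export
read_panel <- function(path, refs = c(0.5, 0.5), q = 1L) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (f in c("alternatives", "criteria", "experts"))
    if (is.null(doc[[f]]))
      stop(sprintf("panel document lacks required field '%s'", f),
           call. = FALSE)
  alts <- vapply(doc$alternatives, as.character, character(1))
  crit <- vapply(doc$criteria, function(cj) as.character(cj$label),
                 character(1))
  senses <- vapply(doc$criteria, function(cj) as.character(cj$sense),
                   character(1))
  if (!all(senses %in% c("benefit", "cost")))
    stop("criterion senses must be 'benefit' or 'cost'", call. = FALSE)
  if (!is.null(doc$q)) q <- as.integer(doc$q)
  n <- length(alts); m <- length(crit)
  mats <- lapply(seq_along(doc$experts), function(k) {
    grid <- doc$experts[[k]]
    if (length(grid) != n)
      stop(sprintf("expert %d: expected %d rows, found %d",
                   k, n, length(grid)), call. = FALSE)
    comp <- matrix(NA_real_, n * m, 4)
    for (i in seq_len(n)) {
      row <- grid[[i]]
      if (length(row) != m)
        stop(sprintf("expert %d row %d: expected %d cells, found %d",
                     k, i, m, length(row)), call. = FALSE)
      for (j in seq_len(m)) {
        cell <- as.numeric(unlist(row[[j]]))
        if (!length(cell) %in% c(2L, 4L))
          stop(sprintf(
            "expert %d cell (%d,%d): a cell is [phi,psi] or [phi,psi,rho,sigma]",
            k, i, j), call. = FALSE)
        if (length(cell) == 2L) cell <- c(cell, refs)
        comp[(j - 1L) * n + i, ] <- cell
      }
    }
    cells <- tryCatch(ldfn(comp[, 1], comp[, 2], comp[, 3], comp[, 4], q = q),
                      error = function(err) stop(sprintf(
                        "expert %d: %s", k, conditionMessage(err)),
                        call. = FALSE))
    decision_matrix(cells, alts, crit, senses)
  })
  expert_panel(mats, if (!is.null(doc$agg_weights))
    as.numeric(unlist(doc$agg_weights)) else NULL)
}

#' @rdname read_panel
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "ldf_panel"))
  doc <- list(
    alternatives = panel$alternatives,
    criteria = lapply(seq_len(panel$m), function(j)
      list(label = panel$criteria[j], sense = panel$senses[j])),
    q = ldf_q(panel$matrices[[1L]]$cells),
    agg_weights = panel$agg_weights,
    experts = lapply(panel$matrices, function(dm)
      lapply(seq_len(dm$n), function(i) .ldfn_to_cells(.dm_row(dm, i)))))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# "phi,psi" or "phi,psi|rho,sigma" cell strings
.parse_cell_string <- function(s, refs, where) {
  parts <- strsplit(s, "|", fixed = TRUE)[[1L]]
  grades <- suppressWarnings(as.numeric(strsplit(parts[1L], ",")[[1L]]))
  if (length(grades) != 2L || anyNA(grades))
    stop(sprintf("%s: malformed cell '%s'", where, s), call. = FALSE)
  if (length(parts) == 1L) return(c(grades, refs))
  rp <- suppressWarnings(as.numeric(strsplit(parts[2L], ",")[[1L]]))
  if (length(rp) != 2L || anyNA(rp))
    stop(sprintf("%s: malformed reference pair in '%s'", where, s),
         call. = FALSE)
  c(grades, rp)
}

#' Read and write the CSV panel dialect
#'
#' One CSV file per expert: first column the alternative labels, remaining
#' columns one per criterion, cells quoted strings `"phi,psi"` or
#' `"phi,psi|rho,sigma"`. Criterion senses are not part of the CSV and are
#' supplied by the caller.
#'
#' @param paths character vector of per-expert file paths.
#' @param senses criterion senses (length = number of criteria, or a
#'   single value recycled).
#' @param refs,q as in [read_panel()].
#' @param panel an `"ldf_panel"` to write.
#' @return `read_panel_csv()`: an `"ldf_panel"`; `write_panel_csv()`
#'   returns the written paths invisibly.
#' @export
read_panel_csv <- function(paths, senses = "benefit", refs = c(0.5, 0.5),
                           q = 1L) {
  mats <- lapply(seq_along(paths), function(k) {
    tab <- utils::read.csv(paths[k], check.names = FALSE,
                           colClasses = "character")
    alts <- tab[[1L]]
    crit <- colnames(tab)[-1L]
    n <- length(alts); m <- length(crit)
    comp <- matrix(NA_real_, n * m, 4)
    for (i in seq_len(n)) for (j in seq_len(m))
      comp[(j - 1L) * n + i, ] <-
        .parse_cell_string(tab[i, j + 1L], refs,
                           sprintf("expert %d cell (%d,%d)", k, i, j))
    s <- if (length(senses) == 1L) rep(senses, m) else senses
    cells <- tryCatch(ldfn(comp[, 1], comp[, 2], comp[, 3], comp[, 4], q = q),
                      error = function(err) stop(sprintf(
                        "expert %d: %s", k, conditionMessage(err)),
                        call. = FALSE))
    decision_matrix(cells, alts, crit, s)
  })
  expert_panel(mats)
}

#' @rdname read_panel_csv
#' @export
write_panel_csv <- function(panel, paths) {
  stopifnot(inherits(panel, "ldf_panel"), length(paths) == panel$e)
  for (k in seq_len(panel$e)) {
    dm <- panel$matrices[[k]]
    grid <- matrix("", dm$n, dm$m)
    for (i in seq_len(dm$n)) for (j in seq_len(dm$m)) {
      cl <- .dm_cell(dm, i, j)
      grid[i, j] <- sprintf("%.17g,%.17g|%.17g,%.17g",
                            cl$mem, cl$non, cl$rmem, cl$rnon)
    }
    tab <- data.frame(alternative = dm$alternatives, grid,
                      check.names = FALSE)
    colnames(tab) <- c("alternative", dm$criteria)
    utils::write.csv(tab, paths[k], row.names = FALSE)
  }
  invisible(paths)
}

.matrix_to_json <- function(dm) {
  lapply(seq_len(dm$n), function(i) .ldfn_to_cells(.dm_row(dm, i)))
}

#' Serialize an LDF-TOPSIS trace to JSON
#'
#' Writes every intermediate artifact of a fit --- ideal matrices, distance
#' and closeness tables, derived weights, weighted matrices, PIS/NIS rows,
#' final closeness and ranking --- as a named JSON document.
#'
#' @param fit an `"ldf_topsis"` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trace <- function(fit, path) {
  stopifnot(inherits(fit, "ldf_topsis"))
  doc <- list(
    config = list(family = fit$copula$family, lambda = fit$copula$lam,
                  upsilon = fit$upsilon,
                  strict_weighting = fit$strict_weighting,
                  collective_phase3 = fit$collective_phase3),
    alternatives = fit$panel$alternatives,
    criteria = fit$panel$criteria,
    gdis = .matrix_to_json(fit$gdis),
    gris = .matrix_to_json(fit$gris),
    glis = .matrix_to_json(fit$glis),
    dgdis = fit$dgdis, dgris = fit$dgris, dglis = fit$dglis,
    ci = fit$ci, expert_weights = fit$expert_weights,
    rgdis = .matrix_to_json(fit$rgdis),
    entropy = fit$entropy, criteria_weights = fit$criteria_weights,
    weighted = lapply(fit$weighted, .matrix_to_json),
    pis = lapply(fit$pis, .ldfn_to_cells),
    nis = lapply(fit$nis, .ldfn_to_cells),
    dpos = fit$dpos, dneg = fit$dneg, rci = fit$rci,
    fc = as.list(fit$fc), ranking = fit$ranking)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}
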