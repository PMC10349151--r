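make_toy_panel <- function(seed = 1, n = 3, m = 3, e = 2,
                           senses = "benefit") {
  set.seed(seed)
  mats <- lapply(seq_len(e), function(k)
    decision_matrix(random_ldfn(n * m), paste0("A", 1:n), paste0("C", 1:m),
                    rep(senses, length.out = m)))
  expert_panel(mats)
}

test_that("panel construction validates shape congruence and weights", {
  p <- make_toy_panel()
  expect_s3_class(p, "ldf_panel")
  bad <- make_toy_panel(n = 4)
  expect_error(expert_panel(list(p$matrices[[1]], bad$matrices[[1]])),
               "congruent")
  expect_error(expert_panel(p$matrices, agg_weights = c(0.7, 0.7)),
               "sum to 1")
  expect_error(decision_matrix(random_ldfn(4), "A1", c("C1", "C2", "C3"),
                               "benefit"),
               "at least 2")
})

test_that("normalization complements cost columns and is involutive", {
  pb <- make_toy_panel(seed = 2)
  expect_equal(normalize_panel(pb), pb)   # all-benefit: unchanged
  pc <- make_toy_panel(seed = 3, senses = "cost")
  nc <- normalize_panel(pc)
  expect_ldfn_equal(nc$matrices[[1]]$cells,
                    ldf_complement(pc$matrices[[1]]$cells))
  expect_true(all(nc$senses == "benefit"))
  # complementing twice returns the original grades
  renc <- normalize_panel(structure(modifyList(nc, list(
    senses = rep("cost", nc$m),
    matrices = lapply(nc$matrices, function(dm) {
      dm$senses <- rep("cost", dm$m); dm
    })), keep.null = TRUE), class = "ldf_panel"))
  expect_ldfn_equal(renc$matrices[[1]]$cells, pc$matrices[[1]]$cells)
})

test_that("group ideals degenerate correctly and match the worked-example picks", {
  sp <- ldf_copula(2, 1)
  # identical experts: all three ideals equal the common matrix
  p1 <- make_toy_panel(seed = 4, e = 1)
  p3 <- expert_panel(rep(p1$matrices, 3))
  ids <- group_ideals(p3, sp)
  for (nm in c("gdis", "gris", "glis"))
    expect_ldfn_equal(ids[[nm]]$cells, p1$matrices[[1]]$cells, tol = 1e-9)
  # EEG panel, cell (P1, C1): candidates (0.8,0.9), (0.7,0.7), (0.2,0.8)
  eeg <- group_ideals(normalize_panel(eeg_classifier_panel()), sp)
  gris11 <- eeg$gris$cells[1]
  glis11 <- eeg$glis$cells[1]
  expect_equal(c(gris11$mem, gris11$non), c(0.7, 0.7))
  expect_equal(c(glis11$mem, glis11$non), c(0.2, 0.8))
  # two-expert toy: Clayton lambda 1 equal weights on memberships 0.2 / 0.8
  cells <- function(mem) decision_matrix(from_pair(rep(mem, 4), 0.5),
                                         c("A1", "A2"), c("C1", "C2"),
                                         "benefit")
  toy <- expert_panel(list(cells(0.2), cells(0.8)))
  expect_equal(group_ideals(toy, sp)$gdis$cells$mem, rep(0.68, 4))
})

test_that("expert weights normalize and degenerate panels fall back to uniform", {
  sp <- ldf_copula(2, 1)
  p <- make_toy_panel(seed = 5, e = 3)
  ids <- group_ideals(p, sp)
  ew <- expert_weights(p, ids)
  expect_equal(sum(ew$w), 1, tolerance = 1e-12)
  expect_true(all(ew$w >= 0))
  # CI recomputes from the returned distance matrices
  ci <- (rowSums(ew$dgris) + rowSums(ew$dglis)) /
    (rowSums(ew$dgdis) + rowSums(ew$dgris) + rowSums(ew$dglis))
  expect_equal(ew$ci, unname(ci))
  # single expert
  p1 <- make_toy_panel(seed = 6, e = 1)
  expect_equal(expert_weights(p1, group_ideals(p1, sp))$w, 1)
  # all experts identical -> uniform weights
  same <- expert_panel(rep(p1$matrices, 4))
  expect_equal(expert_weights(same, group_ideals(same, sp))$w, rep(0.25, 4))
})

test_that("criterion weights favour sharp columns and sum to one", {
  sp <- ldf_copula(2, 1)
  p <- make_toy_panel(seed = 7, e = 3, m = 4)
  cw <- criteria_weights(p, rep(1 / 3, 3), sp)
  expect_equal(sum(cw$gamma), 1, tolerance = 1e-12)
  expect_true(all(cw$entropy >= 0 & cw$entropy <= 1))
  # identical columns share the weight equally
  one_col <- random_ldfn(3)
  dm <- decision_matrix(one_col[rep(1:3, 3)], paste0("A", 1:3),
                        paste0("C", 1:3), "benefit")
  cw2 <- criteria_weights(expert_panel(list(dm)), 1, sp)
  expect_equal(unname(cw2$gamma), rep(1 / 3, 3), tolerance = 1e-12)
  # a crisp column (entropy 0) gets the largest weight
  crisp <- ldfn(c(1, 0, 1), c(0, 1, 0), c(1, 0, 1), c(0, 1, 0))
  dm3 <- decision_matrix(c(crisp, random_ldfn(6)), paste0("A", 1:3),
                         paste0("C", 1:3), "benefit")
  cw3 <- criteria_weights(expert_panel(list(dm3)), 1, sp)
  expect_equal(unname(which.max(cw3$gamma)), 1L)
  expect_equal(unname(cw3$entropy[1]), 0)
})

test_that("relative closeness handles the ideal, anti-ideal and degenerate cases", {
  expect_equal(relative_closeness(0, 0.3), 1)
  expect_equal(relative_closeness(0.3, 0), 0)
  expect_equal(relative_closeness(0.1018, 0.2343), 0.697, tolerance = 5e-4)
  expect_warning(rc <- relative_closeness(0, 0), "indistinguishable")
  expect_equal(rc, 0.5)
})

test_that("per-expert closeness gives RCI = 1 for a dominant alternative", {
  sp <- ldf_copula(2, 1)
  # row A1 dominates every column, row A2 is dominated
  hi <- from_pair(rep(0.9, 3), 0.1); lo <- from_pair(rep(0.2, 3), 0.8)
  cells <- do.call(c, lapply(1:3, function(j) c(hi[j], lo[j])))
  dm <- decision_matrix(cells, c("A1", "A2"), paste0("C", 1:3), "benefit")
  res <- per_expert_closeness(expert_panel(list(dm)), rep(1 / 3, 3), sp)
  expect_equal(unname(res$rci[1, ]), c(1, 0))
  expect_equal(unname(res$dpos[1, "A1"]), 0)
})

test_that("final closeness reproduces the published fusion arithmetic", {
  w <- c(0.2995, 0.3553, 0.3452)
  rci <- rbind(c(0.697, 0.664), c(0.695, 0.469), c(0.308, 0.651))
  colnames(rci) <- c("P1", "P5")
  fin <- final_closeness(rci, w / sum(w))
  expect_equal(unname(round(fin$fc, 3)), c(0.562, 0.590))
  # single expert: FC is that expert's RCI row
  fin1 <- final_closeness(matrix(c(0.3, 0.7), 1, 2,
                                 dimnames = list(NULL, c("A1", "A2"))), 1)
  expect_equal(unname(fin1$fc), c(0.3, 0.7))
  expect_equal(fin1$ranking, c("A2", "A1"))
})

test_that("the full pipeline satisfies its invariants on the EEG panel", {
  fit <- ldf_topsis(eeg_classifier_panel())
  expect_s3_class(fit, "ldf_topsis")
  expect_equal(sum(fit$expert_weights), 1, tolerance = 1e-9)
  expect_equal(sum(fit$criteria_weights), 1, tolerance = 1e-9)
  expect_true(all(fit$rci >= 0 & fit$rci <= 1))
  expect_true(all(fit$fc >= 0 & fit$fc <= 1))
  expect_setequal(fit$ranking, fit$panel$alternatives)
  # methods
  expect_output(print(fit), "Ranking")
  expect_output(print(summary(fit)), "Criterion entropies")
  expect_equal(coef(fit), fit$criteria_weights)
  expect_equal(sum(coef(fit, "experts")), 1)
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("the collective phase-3 variant runs and ranks all alternatives", {
  fit <- ldf_topsis(eeg_classifier_panel(), collective_phase3 = TRUE)
  expect_equal(nrow(fit$rci), 1L)
  expect_setequal(fit$ranking, fit$panel$alternatives)
  expect_true(all(fit$fc >= 0 & fit$fc <= 1))
})

test_that("rankings are equivariant under relabeling of alternatives", {
  p <- make_toy_panel(seed = 8, n = 4, m = 3, e = 3)
  fit <- ldf_topsis(p)
  perm <- c(3, 1, 4, 2)
  permute_dm <- function(dm) {
    idx <- as.vector(outer(perm, (seq_len(dm$m) - 1L) * dm$n, `+`))
    decision_matrix(dm$cells[idx], dm$alternatives, dm$criteria, dm$senses)
  }
  pp <- expert_panel(lapply(p$matrices, permute_dm))
  pfit <- ldf_topsis(pp)
  # row i of the permuted panel is row perm[i] of the original
  expect_equal(unname(pfit$fc), unname(fit$fc[perm]), tolerance = 1e-12)
})

test_that("raising one alternative across the board cannot lower its closeness", {
  sp <- ldf_copula(1, 1)
  p <- make_toy_panel(seed = 9, n = 4, m = 3, e = 2)
  fit <- ldf_topsis(p, copula = sp)
  boost <- function(dm) {
    idx <- (seq_len(dm$m) - 1L) * dm$n + 2L   # alternative A2 everywhere
    dm$cells$mem[idx] <- pmin(1, dm$cells$mem[idx] + 0.15)
    dm
  }
  bfit <- ldf_topsis(expert_panel(lapply(p$matrices, boost)), copula = sp)
  expect_gte(bfit$fc[["A2"]], fit$fc[["A2"]] - 1e-9)
})
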