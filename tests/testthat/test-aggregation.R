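test_that("copula sum/product reduce to the classical algebra under the product copula", {
  sp <- ldf_copula(1, 1)
  a <- ldfn(0.6, 0.3, 0.5, 0.4); b <- ldfn(0.5, 0.4, 0.3, 0.6)
  expect_ldfn_equal(cop_add(a, b, sp), ldfn(0.8, 0.12, 0.65, 0.24))
  set.seed(41)
  x <- random_ldfn(500); y <- random_ldfn(500)
  expect_ldfn_equal(cop_add(x, y, sp), alg_add(x, y), tol = 1e-12)
  expect_ldfn_equal(cop_mult(x, y, sp), alg_mult(x, y), tol = 1e-12)
})

test_that("the crisp extremes are neutral elements for every family", {
  zero <- ldfn(0, 1, 0, 1); one <- ldfn(1, 0, 1, 0)
  set.seed(43)
  x <- random_ldfn(50)
  for (sp in one_spec_per_family()) {
    expect_ldfn_equal(cop_add(x, zero[rep(1, 50)], sp), x, tol = 1e-9)
    expect_ldfn_equal(cop_mult(one[rep(1, 50)], x, sp), x, tol = 1e-9)
  }
})

test_that("scalar multiplication agrees with repeated copula addition", {
  set.seed(47)
  x <- random_ldfn(300)
  for (sp in one_spec_per_family()) {
    expect_ldfn_equal(cop_scalar(1, x, sp), x, tol = 1e-9)
    expect_lt(max_ldfn_dev(cop_scalar(2, x, sp), cop_add(x, x, sp)), 1e-8)
    # Definition-style induction at larger n
    chain <- x
    for (n in 2:5) {
      chain <- cop_add(chain, x, sp)
      expect_lt(max_ldfn_dev(cop_scalar(n, x, sp), chain), 1e-8)
    }
    # additivity in the scalar: (a+b)L = aL + bL
    ab <- runif(2, 0.2, 3)
    expect_lt(max_ldfn_dev(cop_scalar(sum(ab), x, sp),
                           cop_add(cop_scalar(ab[1], x, sp),
                                   cop_scalar(ab[2], x, sp), sp)), 1e-8)
    # dual statement for powers
    expect_lt(max_ldfn_dev(cop_power(x, sum(ab), sp),
                           cop_mult(cop_power(x, ab[1], sp),
                                    cop_power(x, ab[2], sp), sp)), 1e-8)
  }
  expect_error(cop_scalar(-1, x, ldf_copula(1, 1)), "positive")
})

test_that("product-copula scalar has the classical closed form", {
  sp <- ldf_copula(1, 1)
  x <- ldfn(0.5, 0.3, 0.4, 0.2)
  y <- cop_scalar(2, x, sp)
  expect_equal(y$mem, 1 - (1 - 0.5)^2)   # 0.75
  expect_ldfn_equal(y, alg_scalar(2, x), tol = 1e-12)
  expect_ldfn_equal(cop_power(x, 2, sp), alg_power(x, 2), tol = 1e-12)
})

test_that("LDFWCA is idempotent and matches its Clayton hand computation", {
  set.seed(53)
  for (sp in one_spec_per_family()) {
    x <- random_ldfn(1)
    rep5 <- x[rep(1, 5)]
    expect_ldfn_equal(ldfwca(rep5, rep(0.2, 5), sp), x, tol = 1e-9)
  }
  # two memberships 0.2 / 0.8, equal weights, Clayton lambda = 1:
  # generator mean of (0.8^-1 - 1) and (0.2^-1 - 1) is 2.125 -> 1 - 1/3.125
  v <- from_pair(c(0.2, 0.8), c(0.5, 0.5))
  agg <- ldfwca(v, c(0.5, 0.5), ldf_copula(2, 1))
  expect_equal(agg$mem, 0.68, tolerance = 1e-12)
  expect_error(ldfwca(v, c(0.6, 0.6), ldf_copula(2, 1)), "sum to 1")
  expect_error(ldfwca(v, 1, ldf_copula(2, 1)), "length")
})

test_that("LDFWCA under the product copula equals the classical LDFWA closed form", {
  ldfwa <- function(x, w) {
    ldfn(1 - prod((1 - x$mem)^w), prod(x$non^w),
         1 - prod((1 - x$rmem)^w), prod(x$rnon^w))
  }
  set.seed(59)
  for (rep in 1:50) {
    x <- random_ldfn(4)
    w <- runif(4); w <- w / sum(w)
    expect_lt(max_ldfn_dev(ldfwca(x, w, ldf_copula(1, 1)), ldfwa(x, w)), 1e-9)
    expect_lt(max_ldfn_dev(ldfwca(x, w, ldf_copula(2, 1e-6)), ldfwa(x, w)),
              1e-6)
  }
})

test_that("aggregates are bounded and monotone under the product copula", {
  set.seed(61)
  sp <- ldf_copula(1, 1)
  for (rep in 1:40) {
    x <- random_ldfn(5)
    w <- runif(5); w <- w / sum(w)
    agg <- ldfwca(x, w, sp)
    # bounded between the componentwise envelopes in the score order
    lower <- ldfn(min(x$mem), max(x$non), min(x$rmem), max(x$rnon))
    upper <- ldfn(max(x$mem), min(x$non), max(x$rmem), min(x$rnon))
    expect_gte(ldf_score(agg), ldf_score(lower) - 1e-9)
    expect_lte(ldf_score(agg), ldf_score(upper) + 1e-9)
    # raising one membership cannot lower the aggregated membership
    bumped <- x
    bumped$mem[2] <- min(1, bumped$mem[2] + 0.1)
    expect_gte(ldfwca(bumped, w, sp)$mem, agg$mem - 1e-12)
  }
})

test_that("ordered aggregation is permutation invariant; hybrid reduces to it", {
  set.seed(67)
  sp <- ldf_copula(2, 1)
  x <- random_ldfn(5)
  w <- c(0.4, 0.25, 0.15, 0.12, 0.08)
  base <- ldfwoca(x, w, sp)
  for (rep in 1:10) {
    p <- sample(5)
    expect_ldfn_equal(ldfwoca(x[p], w, sp), base, tol = 1e-12)
  }
  # identical inputs make the ordering vacuous
  r <- x[rep(2, 5)]
  expect_ldfn_equal(ldfwoca(r, w, sp), ldfwca(r, w, sp), tol = 1e-12)
  # uniform importance weights make the hybrid rescaling the identity
  u <- rep(0.2, 5)
  expect_ldfn_equal(ldfwhca(x, u, w, sp), ldfwoca(x, w, sp), tol = 1e-9)
})

test_that("crisp components are absorbing in weighted generator sums", {
  sp <- ldf_copula(2, 1)
  x <- c(ldfn(1, 0, 1, 0), ldfn(0.5, 0.4, 0.3, 0.3))
  agg <- ldfwca(x, c(0.5, 0.5), sp)
  expect_equal(agg$mem, 1)   # membership 1 with positive weight absorbs
  expect_equal(agg$non, 0)
  # ...but not when its weight is zero
  agg0 <- ldfwca(x, c(0, 1), sp)
  expect_ldfn_equal(agg0, x[2], tol = 1e-12)
})
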