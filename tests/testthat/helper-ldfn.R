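# shared fixtures: random valid LDFNs and a lambda grid over the five
# copula families

random_ldfn <- function(n, q = 1L) {
  rm <- rn <- numeric(0)
  while (length(rm) < n) {
    a <- runif(2L * n); b <- runif(2L * n)
    ok <- a^q + b^q <= 1
    rm <- c(rm, a[ok]); rn <- c(rn, b[ok])
  }
  ldfn(runif(n), runif(n), rm[seq_len(n)], rn[seq_len(n)], q = q)
}

# representative parameter values inside each family's domain
copula_grid <- function() {
  specs <- list()
  for (lam in c(1, 1.5, 2, 5))        specs <- c(specs, list(ldf_copula(1, lam)))
  for (lam in c(-0.8, -0.5, 0.5, 1, 2, 5)) specs <- c(specs, list(ldf_copula(2, lam)))
  for (lam in c(-5, -1, 1e-7, 0.5, 1, 5))  specs <- c(specs, list(ldf_copula(3, lam)))
  for (lam in c(-1, -0.5, 0, 0.5, 0.9))    specs <- c(specs, list(ldf_copula(4, lam)))
  for (lam in c(1, 2, 5))             specs <- c(specs, list(ldf_copula(5, lam)))
  specs
}

# one spec per family, mid-domain
one_spec_per_family <- function() {
  list(ldf_copula(1, 2), ldf_copula(2, 1), ldf_copula(3, 2),
       ldf_copula(4, 0.5), ldf_copula(5, 2))
}

expect_ldfn_equal <- function(a, b, tol = 1e-9) {
  expect_equal(a$mem, b$mem, tolerance = tol)
  expect_equal(a$non, b$non, tolerance = tol)
  expect_equal(a$rmem, b$rmem, tolerance = tol)
  expect_equal(a$rnon, b$rnon, tolerance = tol)
}

max_ldfn_dev <- function(a, b) {
  max(abs(a$mem - b$mem), abs(a$non - b$non),
      abs(a$rmem - b$rmem), abs(a$rnon - b$rnon))
}
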