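# POD reduced-order machinery: snapshot stacking, SVD basis, projection,
# reduced solves and lifting.

test_that("snapshot matrices stack field-major columns in input order", {
  mz <- make_mapped_snapshots()
  one <- build_snapshots(mz$snaps[1])
  expect_equal(ncol(one$X), 1)
  expect_equal(one$X[, 1], mz$snaps[[1]]$coeffs)
  X <- build_snapshots(mz$snaps)
  expect_equal(nrow(X$X), 2 * mz$snaps[[1]]$space$D)
  expect_equal(ncol(X$X), length(mz$snaps))
  # permuting inputs permutes columns; singular values are invariant
  perm <- c(3, 1, 5, 2, 4)
  Xp <- build_snapshots(mz$snaps[perm])
  expect_equal(Xp$X, X$X[, perm])
  expect_equal(svd(Xp$X, nu = 0, nv = 0)$d, svd(X$X, nu = 0, nv = 0)$d,
               tolerance = 1e-10)
  # mixed spaces are rejected
  cx <- fix_cohort6()
  other <- cx$sols_a[[1]]
  expect_error(build_snapshots(c(mz$snaps[1], list(other))), "share")
})

test_that("rank-one snapshot matrices have the expected decomposition", {
  set.seed(7)
  c0 <- rnorm(40)
  X <- matrix(rep(c0, 5), ncol = 5)
  b <- pod(X, 1)
  expect_equal(b$sigma[1], sqrt(sum(c0^2)) * sqrt(5), tolerance = 1e-10)
  expect_lt(max(b$sigma[-1]), 1e-10 * b$sigma[1])
  expect_equal(abs(sum(b$U[, 1] * c0)) / sqrt(sum(c0^2)), 1, tolerance = 1e-10)
})

test_that("Eckart-Young squared-Frobenius identity holds for all d", {
  set.seed(8)
  mats <- list(random = matrix(rnorm(500), 50, 10),
               real = make_mapped_snapshots()$snaps |> build_snapshots() |>
                 (\(s) s$X)())
  for (X in mats) {
    sv <- svd(X, nu = 0, nv = 0)$d
    S <- min(dim(X))
    for (d in seq_len(S)) {
      b <- pod(X, d)
      rec <- sum((X - b$U %*% crossprod(b$U, X))^2)
      tail2 <- if (d < S) sum(sv[(d + 1):S]^2) else 0
      expect_lt(abs(rec - tail2), 1e-8 * max(sum(sv^2), 1))
      expect_lt(max(abs(crossprod(b$U) - diag(d))), 1e-10)
    }
    # full-rank reconstruction is exact
    bS <- pod(X, S)
    expect_lt(sum((X - bS$U %*% crossprod(bS$U, X))^2), 1e-8)
  }
})

test_that("POD sign convention is deterministic", {
  set.seed(9)
  X <- matrix(rnorm(300), 30, 10)
  b1 <- pod(X, 4); b2 <- pod(X, 4)
  expect_identical(b1$U, b2$U)
  for (j in 1:4) expect_gt(b1$U[which.max(abs(b1$U[, j])), j], 0)
})

test_that("projection satisfies the Galerkin identities", {
  mz <- make_mapped_snapshots()
  snaps <- build_snapshots(mz$snaps)
  b <- pod(snaps, 4)
  rs <- project_system(mz$system, b)
  expect_lt(max(abs(rs$A_rb - t(rs$A_rb))), 1e-10 * max(abs(rs$A_rb)))
  set.seed(10)
  x <- rnorm(4)
  lhs <- as.numeric(t(x) %*% rs$A_rb %*% x)
  Ux <- as.numeric(b$U %*% x)
  rhs <- sum(Ux * as.numeric(mz$system$A %*% Ux))
  expect_lt(abs(lhs - rhs), 1e-10 * abs(rhs))
  # canonical-basis projection densifies A
  D <- nrow(mz$system$A)
  can <- b
  can$U <- diag(D)[, 1:4]
  can$d <- 4L
  rs2 <- project_system(mz$system, can)
  expect_equal(rs2$A_rb, as.matrix(mz$system$A[1:4, 1:4]),
               ignore_attr = TRUE, tolerance = 1e-12)
  # dimension mismatch is caught
  expect_error(project_system(mz$system, pod(matrix(rnorm(40), 10, 4), 2)),
               "does not match")
})

test_that("reduced solves meet the residual contract", {
  mz <- make_mapped_snapshots()
  snaps <- build_snapshots(mz$snaps)
  for (d in c(1, 3, 5)) {
    rs <- project_system(mz$system, pod(snaps, d))
    u <- solve_reduced(rs)
    expect_lt(attr(u, "residual"), 1e-12)
  }
  # d = 1 reduces to scalar division
  rs1 <- project_system(mz$system, pod(snaps, 1))
  expect_equal(as.numeric(solve_reduced(rs1)), rs1$F_rb / rs1$A_rb[1, 1],
               tolerance = 1e-14)
})

test_that("lifting inverts projection on the basis span", {
  mz <- make_mapped_snapshots()
  snaps <- build_snapshots(mz$snaps)
  b <- pod(snaps, 3)
  e1 <- c(1, 0, 0)
  expect_equal(lift(b, e1)$coeffs, as.numeric(b$U[, 1]))
  expect_equal(lift(b, c(0, 0, 0))$coeffs, rep(0, nrow(b$U)))
  # project-then-lift reproduces any field already in span(U)
  set.seed(11)
  w <- rnorm(3)
  fld <- lift(b, w)
  w2 <- as.numeric(crossprod(b$U, fld$coeffs))
  expect_equal(lift(b, w2)$coeffs, fld$coeffs, tolerance = 1e-10)
})

test_that("snapshot inclusion makes the reduced solution exact", {
  mz <- make_mapped_snapshots()
  with_target <- c(mz$snaps, list(mz$reference))
  snaps <- build_snapshots(with_target)
  rg <- run_grom(mz$system, snaps, d = length(with_target),
                 reference = mz$reference)
  expect_lt(max(rg$errors), 1e-8)
})

test_that("energy-norm reduced error is nonincreasing in the basis size", {
  mz <- make_mapped_snapshots()
  snaps <- build_snapshots(mz$snaps)
  A <- mz$system$A
  errs <- vapply(1:5, function(d) {
    rg <- run_grom(mz$system, snaps, d)
    e <- rg$field$coeffs - mz$reference$coeffs
    sqrt(sum(e * as.numeric(A %*% e)))
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-9 * errs[1]))
})

test_that("run_grom smoke: d = 1 runs, d = 0 is rejected", {
  mz <- make_mapped_snapshots()
  snaps <- build_snapshots(mz$snaps)
  expect_error(run_grom(mz$system, snaps, 0), "d must be")
  rg <- run_grom(mz$system, snaps, 1, reference = mz$reference)
  expect_true(all(is.finite(rg$errors)))
})

test_that("span nesting: larger snapshot sets project no worse", {
  mz <- make_mapped_snapshots()
  u <- mz$reference$coeffs
  proj_err <- function(flds) {
    X <- build_snapshots(flds)$X
    q <- qr(X)
    r <- u - qr.fitted(q, u)
    sqrt(sum(r^2))
  }
  full <- proj_err(mz$snaps)
  subset <- proj_err(mz$snaps[1:3])
  expect_lte(full, subset + 1e-12)
})
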