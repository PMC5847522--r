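test_that("Kabsch recovers planted rigid motions", {
  set.seed(11)
  for (k in 1:10) {
    n <- sample(3:12, 1)
    fixed <- matrix(rnorm(3 * n, sd = 5), n, 3)
    rot <- random_rotation()
    trans <- rnorm(3, sd = 10)
    moving <- sweep(fixed %*% t(rot), 2, -trans) # rotate then translate
    # recover the inverse motion
    fit <- kabsch_superpose(moving, fixed)
    expect_lt(fit$rmsd, 1e-9)
    expect_equal(apply_transform(fit$transform, moving), fixed,
      tolerance = 1e-8)
    expect_equal(det(fit$transform$rotation), 1, tolerance = 1e-9)
  }
  # the simple 90-degree case
  fixed <- matrix(c(1, 0, 0, 0, 1, 0, 0, 0, 1, 1, 1, 1), 4, 3, byrow = TRUE)
  moving <- sweep(fixed %*% t(rotz90), 2, -c(1, 2, 3))
  expect_lt(kabsch_superpose(moving, fixed)$rmsd, 1e-9)
})

test_that("single-point displacement gives the closed-form RMSD", {
  # 4 points; one displaced by 1 A along x.  The optimal fit re-centers and
  # re-orients, so the closed form sqrt(1/4) = 0.5 is an upper bound reached
  # only without re-fitting; verify the fitted optimum against a dense
  # rotation grid oracle instead.
  base <- matrix(c(0, 0, 0, 4, 0, 0, 0, 4, 0, 0, 0, 4), 4, 3, byrow = TRUE)
  pert <- base
  pert[1, 1] <- pert[1, 1] + 1
  expect_equal(rmsd_paired(base, pert, superpose = FALSE), 0.5)
  fit <- kabsch_superpose(base, pert)
  # oracle: exhaustive search over a 2-degree rotation grid (z-y-x Euler),
  # each candidate with the optimal translation (centroid match)
  grid <- seq(-pi, pi, by = 2 * pi / 180)
  cb <- colMeans(base)
  cp <- colMeans(pert)
  b0 <- sweep(base, 2, cb)
  p0 <- sweep(pert, 2, cp)
  best <- Inf
  rot1 <- function(a, axis) {
    c_ <- cos(a); s <- sin(a)
    switch(axis,
      z = matrix(c(c_, -s, 0, s, c_, 0, 0, 0, 1), 3, 3, byrow = TRUE),
      y = matrix(c(c_, 0, s, 0, 1, 0, -s, 0, c_), 3, 3, byrow = TRUE),
      x = matrix(c(1, 0, 0, 0, c_, -s, 0, s, c_), 3, 3, byrow = TRUE)
    )
  }
  small <- seq(-0.2, 0.2, by = 2 * pi / 180) # refine near identity
  for (az in small) {
    for (ay in small) {
      for (ax in small) {
        r <- rot1(az, "z") %*% rot1(ay, "y") %*% rot1(ax, "x")
        best <- min(best, sqrt(mean(rowSums((b0 %*% t(r) - p0)^2))))
      }
    }
  }
  expect_lte(fit$rmsd, best + 1e-3)
  expect_equal(fit$rmsd, best, tolerance = 1e-2)
})

test_that("rmsd_paired handles translation with and without superposition", {
  a <- matrix(rnorm(15), 5, 3)
  b <- sweep(a, 2, -c(3, 4, 0)) # shifted by magnitude 5
  expect_equal(rmsd_paired(a, a), 0)
  expect_equal(rmsd_paired(a, b, superpose = FALSE), 5)
  expect_lt(rmsd_paired(a, b, superpose = TRUE), 1e-9)
  expect_error(rmsd_paired(a, b[1:3, ]), "differ")
})

test_that("TM-score is 1 for identity, low for unrelated chains, monotone in distance", {
  set.seed(21)
  ref <- matrix(rnorm(300, sd = 10), 100, 3)
  expect_equal(tm_score(ref, ref), 1, tolerance = 1e-6)
  # random unrelated chains score below 0.3
  scores <- replicate(5, {
    tm_score(matrix(rnorm(300, sd = 10), 100, 3), ref)
  })
  expect_lt(mean(scores), 0.3)
  # doubling all deviations lowers the score: compare a small versus larger
  # uniform perturbation of the same structure
  d1 <- ref + matrix(rnorm(300, sd = 1), 100, 3)
  s1 <- tm_score(d1, ref)
  s2 <- tm_score(ref + 2 * (d1 - ref), ref)
  expect_gt(s1, s2)
  expect_error(tm_score(ref[1:20, ], ref[1:20, ], norm_length = 15), "norm_length")
})

test_that("TM-score and GDT are invariant under rigid motion of the model", {
  set.seed(22)
  ref <- matrix(rnorm(120, sd = 8), 40, 3)
  model <- ref + matrix(rnorm(120, sd = 1.5), 40, 3)
  rot <- random_rotation()
  moved <- sweep(model %*% t(rot), 2, -c(11, -4, 7))
  expect_equal(tm_score(model, ref), tm_score(moved, ref), tolerance = 1e-6)
  expect_equal(gdt_ts(model, ref), gdt_ts(moved, ref), tolerance = 1e-9)
})

test_that("GDT partitions displacement regimes as direct counting predicts", {
  set.seed(23)
  ref <- matrix(rnorm(90, sd = 10), 30, 3)
  expect_equal(gdt_ts(ref, ref), 1)
  # icosahedron vertices at radius 10, radially inflated so every residue
  # sits exactly 3 A from its reference position under the global best fit:
  # all pass 4 and 8, none passes 1 under any partial fit (vertex spacing
  # 10.5 A makes subsets non-congruent), so GDT lands in [0.5, 0.75]
  phi <- (1 + sqrt(5)) / 2
  ico <- rbind(
    c(0, 1, phi), c(0, -1, phi), c(0, 1, -phi), c(0, -1, -phi),
    c(1, phi, 0), c(-1, phi, 0), c(1, -phi, 0), c(-1, -phi, 0),
    c(phi, 0, 1), c(-phi, 0, 1), c(phi, 0, -1), c(-phi, 0, -1)
  )
  ico <- ico / sqrt(sum(ico[1, ]^2)) * 10
  inflated <- ico * 1.3 # every point moves 3 A radially
  expect_equal(unname(sqrt(rowSums((inflated - ico)^2))), rep(3, 12))
  g <- gdt_ts(inflated, ico)
  expect_gte(g, 0.5)
  expect_lte(g, 0.75)
  # direct counting at thresholds the global fit satisfies for all residues
  expect_equal(gdt_ts(inflated, ico, thresholds = c(4, 8)), 1)
  # all pairs far beyond 8 A: zero
  expect_equal(gdt_ts(ico * 4, ico, thresholds = c(8)), 0)
})

test_that("MCC matches the hand-evaluated confusion matrix and is symmetric", {
  universe <- sprintf("r%02d", 1:20)
  actual <- universe[1:8]
  predicted <- universe[c(1:6, 9, 10)] # TP 6, FP 2, FN 2, TN 10
  expect_equal(mcc_sets(predicted, actual, universe),
    (6 * 10 - 2 * 2) / sqrt(8 * 8 * 12 * 12))
  expect_equal(mcc_sets(predicted, actual, universe),
    mcc_sets(actual, predicted, universe))
  expect_equal(mcc_sets(actual, actual, universe), 1)
  expect_equal(mcc_sets(setdiff(universe, actual), actual, universe), -1)
  expect_equal(mcc_sets(character(), actual, universe), 0)
  expect_error(mcc_sets("zzz", actual, universe), "subsets")
})

test_that("Kabsch RMSD equals the dense rotation-grid minimum on small sets", {
  set.seed(31)
  for (k in 1:3) {
    n <- sample(4:6, 1)
    a <- matrix(rnorm(3 * n, sd = 3), n, 3)
    b <- a + matrix(rnorm(3 * n, sd = 0.5), n, 3)
    fit <- kabsch_superpose(a, b)
    # the grid oracle can only do worse than the analytic optimum
    a0 <- sweep(a, 2, colMeans(a))
    b0 <- sweep(b, 2, colMeans(b))
    angles <- seq(-pi, pi, length.out = 40)
    best <- Inf
    for (az in angles) {
      rz <- matrix(c(cos(az), -sin(az), 0, sin(az), cos(az), 0, 0, 0, 1),
        3, 3, byrow = TRUE)
      for (ay in angles) {
        ry <- matrix(c(cos(ay), 0, sin(ay), 0, 1, 0, -sin(ay), 0, cos(ay)),
          3, 3, byrow = TRUE)
        best <- min(best, sqrt(mean(rowSums((a0 %*% t(ry %*% rz) - b0)^2))))
      }
    }
    expect_lte(fit$rmsd, best + 1e-9)
  }
})
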