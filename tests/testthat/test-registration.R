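test_that("pairwise ratios reflect uniform scaling and flag contamination", {
  lm_id <- make_landmarks(scale = 1)
  expect_equal(pairwise_scale_ratios(lm_id), rep(1, choose(8, 2)),
               tolerance = 1e-12, ignore_attr = TRUE)
  lm2 <- make_landmarks(scale = 2)
  expect_equal(pairwise_scale_ratios(lm2), rep(2, choose(8, 2)),
               tolerance = 1e-12, ignore_attr = TRUE)

  # 6 landmarks, one MSI point displaced: exactly the 5 ratios involving
  # it are contaminated (brute-force enumeration over the pair index)
  lm6 <- make_landmarks(scale = 1.5, n = 6)
  bad <- 4L
  lm6$msi[bad, ] <- lm6$msi[bad, ] + c(400, -300)
  r <- pairwise_scale_ratios(lm6)
  pairs <- attr(r, "pairs")
  touches_bad <- pairs[, 1] == bad | pairs[, 2] == bad
  expect_equal(sum(touches_bad), 5L)
  expect_equal(r[!touches_bad], rep(1.5, 10), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_true(all(abs(r[touches_bad] - 1.5) > 1e-3))

  # filtered mean equals the clean-pair mean
  est <- estimate_scale(r)
  expect_equal(est$scale, mean(r[!touches_bad]), tolerance = 1e-12)
  expect_equal(est$kept, !touches_bad, ignore_attr = TRUE)
})

test_that("coincident MSI landmarks raise a degenerate-pair error", {
  lm <- make_landmarks(n = 6)
  lm$msi[2, ] <- lm$msi[1, ]
  expect_error(pairwise_scale_ratios(lm), "degenerate")
})

test_that("MAD rule rejects the {1,1,1,10} outlier; IQR rule available", {
  est <- estimate_scale(c(1, 1, 1, 10), rule = "mad")
  expect_equal(est$scale, 1)
  expect_equal(est$kept, c(TRUE, TRUE, TRUE, FALSE))
  # with zero MAD the band degenerates to the median: discrepant ratios go
  est2 <- estimate_scale(c(1, 1, 1.5), rule = "mad")
  expect_equal(est2$scale, 1)
  expect_equal(est2$kept, c(TRUE, TRUE, FALSE))
  # a dispersed clean set is kept wholesale
  est4 <- estimate_scale(c(1.0, 1.1, 0.9, 1.05, 0.95), rule = "mad")
  expect_true(all(est4$kept))
  expect_equal(est4$scale, 1)
  expect_error(estimate_scale(c(1, 1)), "at least 3")
  est3 <- estimate_scale(rep(1.5, 5), rule = "iqr")
  expect_equal(est3$scale, 1.5)
})

test_that("pairwise angles carry the MSI-to-ST correction sign", {
  # MSI frame = ST frame rotated by +30 degrees about the centroid, so
  # the correction that maps MSI back onto ST is -30 degrees
  st <- st_layout(8)
  c0 <- colMeans(st)
  th <- 30 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  msi <- sweep(sweep(st, 2, c0) %*% t(R), 2, c0, `+`)
  lm <- landmark_set(st, msi)
  ang <- pairwise_rotation_angles(lm)
  expect_equal(ang, rep(-30, choose(8, 2)), tolerance = 1e-9)
  fit <- fit_transform(lm)
  expect_equal(fit$transform$rotation_deg, -30, tolerance = 1e-9)

  # identity correspondence: all angles zero
  lm0 <- make_landmarks()
  expect_equal(pairwise_rotation_angles(lm0), rep(0, choose(8, 2)),
               tolerance = 1e-9)
})

test_that("rotation estimation is circular, not arithmetic", {
  # angles straddling the wrap average to 180, not 0
  est <- estimate_rotation(c(178, -178, 180), spread_ceiling = 15)
  expect_equal(est$rotation, 180, tolerance = 1e-9)
  # constant input and the strict 5-degree boundary
  est30 <- estimate_rotation(rep(30, 4))
  expect_equal(est30$rotation, 30)
  expect_true(est30$exceeds_5deg)
  est5 <- estimate_rotation(c(4, 5, 6))
  expect_equal(est5$rotation, 5, tolerance = 1e-9)
  expect_equal(est5$angle_spread, 0.8163, tolerance = 1e-3)
  expect_false(est5$exceeds_5deg)   # 5 is not > 5
  est0 <- estimate_rotation(rep(0, 5))
  expect_equal(est0$rotation, 0)
  expect_false(est0$exceeds_5deg)
  expect_error(estimate_rotation(c(0, 60, 120)), "inconsistent")
})

test_that("fit_transform recovers noise-free parameters exactly", {
  fit <- fit_transform(make_landmarks(1.3, 25, c(400, -150)))
  expect_equal(fit$transform$scale, 1.3, tolerance = 1e-9)
  expect_equal(fit$transform$rotation_deg, 25, tolerance = 1e-9)
  expect_lt(fit$diagnostics$landmark_rmse, 1e-6)
  expect_lt(transform_max_rel_err(fit$transform, 1.3, 25, c(400, -150)),
            1e-9)
  expect_true(fit$diagnostics$exceeds_5deg)

  # identity landmarks give the identity transform with zero residual
  fit0 <- fit_transform(make_landmarks())
  expect_equal(fit0$transform$scale, 1, tolerance = 1e-12)
  expect_equal(fit0$transform$rotation_deg, 0, tolerance = 1e-12)
  expect_equal(fit0$diagnostics$landmark_rmse, 0, tolerance = 1e-9)
  pts <- physical_points(c("p1", "p2"), c(10, 700), c(-20, 300),
                         frame = "MSI_unified")
  out <- apply_transform(pts, fit0$transform)
  expect_equal(out$x, pts$x, tolerance = 1e-9)
  expect_equal(out$y, pts$y, tolerance = 1e-9)
})

test_that("estimators are invariant to landmark ordering", {
  lm <- make_landmarks(1.7, -40, c(-200, 90), jitter = 5, seed = 11)
  perm <- c(5, 1, 8, 3, 7, 2, 6, 4)
  lmp <- landmark_set(lm$st[perm, ], lm$msi[perm, ],
                      barcodes = lm$barcodes[perm])
  f1 <- fit_transform(lm); f2 <- fit_transform(lmp)
  expect_equal(f1$transform$scale, f2$transform$scale, tolerance = 1e-12)
  expect_equal(f1$transform$rotation_deg, f2$transform$rotation_deg,
               tolerance = 1e-12)
  expect_equal(f1$diagnostics$landmark_rmse, f2$diagnostics$landmark_rmse,
               tolerance = 1e-12)
})

test_that("rotation recovery is exact across the +/-180 wrap", {
  for (rot in c(-170, -30, 5, 90, 179)) {
    fit <- fit_transform(make_landmarks(1, rot, c(30, -70)))
    expect_equal(fit$transform$rotation_deg, rot, tolerance = 1e-9)
  }
})

test_that("threshold rotation mode drops only sub-5-degree rotations", {
  lm3 <- make_landmarks(1, 3, c(100, 50))
  fit_thr <- fit_transform(lm3, rotation_mode = "threshold")
  expect_equal(fit_thr$diagnostics$rotation_applied, 0)
  expect_equal(fit_thr$diagnostics$rotation_estimate, 3, tolerance = 1e-9)
  fit_alw <- fit_transform(lm3, rotation_mode = "always")
  expect_equal(fit_alw$transform$rotation_deg, 3, tolerance = 1e-9)
  # above the threshold both modes apply the rotation
  lm9 <- make_landmarks(1, 9, c(100, 50))
  fit9 <- fit_transform(lm9, rotation_mode = "threshold")
  expect_equal(fit9$transform$rotation_deg, 9, tolerance = 1e-9)
})

test_that("transforms invert and round-trip to 1e-9", {
  tr <- similarity_transform(1.3, 25, c(120, -40), c(400, -150))
  inv <- invert_transform(tr)
  pts <- cbind(runif(20, -500, 2000), runif(20, -500, 2000))
  fwd <- apply_transform(pts, tr)
  back <- apply_transform(
    structure(data.frame(id = fwd$id, x = fwd$x, y = fwd$y),
              frame = "MSI_unified",
              class = c("physical_points", "data.frame")), inv)
  expect_equal(cbind(back$x, back$y), unname(pts), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("procrustes oracle agrees on clean data, never loses on jitter", {
  lm <- make_landmarks(1.3, 25, c(400, -150))
  po <- procrustes_oracle(lm)
  expect_equal(po$transform$scale, 1.3, tolerance = 1e-9)
  expect_equal(po$transform$rotation_deg, 25, tolerance = 1e-9)
  fit <- fit_transform(lm)
  expect_equal(po$transform$scale, fit$transform$scale, tolerance = 1e-9)
  expect_equal(po$transform$rotation_deg, fit$transform$rotation_deg,
               tolerance = 1e-9)
  # least-squares optimality on jittered data
  for (s in 1:20) {
    lmj <- make_landmarks(1.2, 15, c(100, 200), jitter = 10, seed = s)
    expect_lte(procrustes_oracle(lmj)$landmark_rmse,
               fit_transform(lmj)$diagnostics$landmark_rmse + 1e-9)
  }
})

test_that("oracle matches vegan's procrustes solution where available", {
  skip_if_not_installed("vegan")
  lm <- make_landmarks(1.4, 35, c(250, -80), jitter = 8, seed = 3)
  po <- procrustes_oracle(lm)
  vp <- vegan::procrustes(lm$st, lm$msi, symmetric = FALSE)
  expect_equal(po$transform$scale, vp$scale, tolerance = 1e-9)
  got <- apply_transform(lm$msi, po$transform)
  expect_equal(cbind(got$x, got$y), unname(predict(vp, lm$msi)),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("jittered fits land within the expected residual band", {
  sigma <- 10   # landmark marking noise at unit scale
  rmses <- vapply(1:50, function(s) {
    fit <- fit_transform(make_landmarks(1, 25, c(400, -150),
                                        jitter = sigma, seed = s))
    fit$diagnostics$landmark_rmse
  }, numeric(1))
  expect_true(all(rmses >= sigma / 2 & rmses <= 2 * sigma))
})

test_that("mirrored landmark sets are refused unless reflection enabled", {
  lm <- make_landmarks(1, 0, c(0, 0))
  lm$msi[, 1] <- -lm$msi[, 1]
  expect_error(fit_transform(lm), "mirror")
  fit <- fit_transform(lm, reflection = "detect")
  expect_true(fit$transform$reflection)
  expect_lt(fit$diagnostics$landmark_rmse, 1e-6)
})

test_that("landmark validation enforces count and spread", {
  st <- st_layout(5)
  expect_error(landmark_set(st, st), "six")
  line <- cbind(1:8 * 100, 1:8 * 50)
  expect_error(landmark_set(line, line), "collinear")
})
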