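test_that("linker vectors use the 5-bp-in / 10-bp-out registers", {
  ## distinct integer coordinates let us identify which rows were read
  n <- 200L
  pts <- cbind(seq_len(n), 0, 0)
  tr <- bp_track(pts, core_start = 31L, core_len = 147L)
  en <- linker_vector(tr, "entry")
  ex <- linker_vector(tr, "exit")
  expect_equal(en$p4, c(35, 0, 0))   # 5th core bp
  expect_equal(en$p5, c(21, 0, 0))   # 10th linker bp outward
  expect_equal(ex$p4, c(173, 0, 0))
  expect_equal(ex$p5, c(187, 0, 0))
  expect_equal(en$direction, c(-1, 0, 0))
  expect_equal(ex$direction, c(1, 0, 0))
  ## configurable registers shift accordingly
  en2 <- linker_vector(tr, "entry", into_offset = 6L, outside_offset = 8L)
  expect_equal(en2$p4, c(36, 0, 0))
  expect_equal(en2$p5, c(23, 0, 0))
})

test_that("sides with fewer than 10 linker bp are undefined, not errors", {
  core <- build_core()$track
  C <- core$centroids
  fr <- build_frame(core)
  ex8 <- nucgeom:::linker_points(C, fr, "exit", 40, 10, 8L)
  tr <- bp_track(rbind(C, ex8), core_start = 1L, core_len = 147L)
  lv <- linker_vector(tr, "exit")
  expect_false(lv$defined)
  ang <- trajectory_angles(tr)
  expect_true(is.na(ang$alpha[ang$side == "exit"]))
  expect_true(is.na(ang$beta[ang$side == "exit"]))
  expect_true(is.na(ang$alpha[ang$side == "entry"]))  # no entry linker
})

test_that("projected angles reproduce rotations about the plane normals", {
  fr <- build_frame(build_core()$track)
  expect_equal(projected_angle(fr, fr$u, "disc"), 0, tolerance = 1e-9)
  expect_equal(projected_angle(fr, fr$u, "perp"), 0, tolerance = 1e-9)
  expect_equal(projected_angle(fr, fr$disc_basis[, 2], "disc"), 90,
               tolerance = 1e-9)
  expect_equal(projected_angle(fr, fr$perp_basis[, 2], "perp"), 90,
               tolerance = 1e-9)
  ## rotating u by theta within each plane must read back theta,
  ## +theta toward the plane's second basis vector
  for (theta in seq(-179, 179, by = 23)) {
    vd2 <- cos(theta * pi / 180) * fr$disc_basis[, 1] +
      sin(theta * pi / 180) * fr$disc_basis[, 2]
    expect_equal(projected_angle(fr, vd2, "disc"), theta,
                 tolerance = 1e-9)
    vp2 <- cos(theta * pi / 180) * fr$perp_basis[, 1] +
      sin(theta * pi / 180) * fr$perp_basis[, 2]
    expect_equal(projected_angle(fr, vp2, "perp"), theta,
                 tolerance = 1e-9)
  }
  ## a vector along the plane normal has no defined projection
  ## (exact normals: u x w for the disc plane, w for the perp plane)
  expect_true(is.na(projected_angle(fr, fr$w * 2, "perp")))
  expect_true(is.na(projected_angle(fr, fr$perp_basis[, 2], "disc")))
  ## projection idempotence: projecting a projected vector changes nothing
  v <- c(0.3, -0.8, 0.52)
  pr <- fr$disc_basis %*% crossprod(fr$disc_basis, v)
  expect_equal(projected_angle(fr, as.numeric(pr), "disc"),
               projected_angle(fr, v, "disc"), tolerance = 1e-9)
})

test_that("generator angles are recovered exactly at zero noise", {
  for (ab in list(c(0, 0), c(25, -10), c(-40, 40), c(68, 15))) {
    tr <- mono_track(exit = ab)
    ang <- trajectory_angles(tr)
    expect_equal(ang$alpha[ang$side == "exit"], ab[1], tolerance = 1e-6)
    expect_equal(ang$beta[ang$side == "exit"], ab[2], tolerance = 1e-6)
  }
})

test_that("mirroring the structure flips alpha and preserves beta", {
  tr <- mono_track(entry = c(-50, -25), exit = c(40, 20))
  fr <- build_frame(tr)
  a0 <- trajectory_angles(tr)
  n <- fr$perp_basis[, 2]  # disc-plane normal (orthonormalized v)
  M <- diag(3) - 2 * outer(n, n)
  mirrored <- sweep(sweep(tr$centroids, 2, fr$p1) %*% M, 2, fr$p1,
                    FUN = "+")
  a1 <- trajectory_angles(bp_track(mirrored, tr$core_start, tr$core_len))
  expect_equal(a1$alpha, -a0$alpha, tolerance = 1e-6)
  expect_equal(a1$beta, a0$beta, tolerance = 1e-6)
})

test_that("angles and deviations are invariant under common rigid motion", {
  target <- mono_track(entry = c(-60, -5), exit = c(55, 28))
  ref <- synthetic_reference()
  a0 <- trajectory_angles(target)
  d0 <- delta_angles(target, ref$track)
  for (s in 1:3) {
    R <- random_rotation(seed = 30 + s)
    t <- stats::rnorm(3, sd = 100)
    tgt2 <- move_track(target, R, t)
    a1 <- trajectory_angles(tgt2)
    d1 <- delta_angles(tgt2, ref$track)
    expect_equal(a1$alpha, a0$alpha, tolerance = 1e-6)
    expect_equal(a1$beta, a0$beta, tolerance = 1e-6)
    expect_equal(d1$per_side$delta_beta, d0$per_side$delta_beta,
                 tolerance = 1e-6)
    expect_equal(d1$per_side$delta_alpha, d0$per_side$delta_alpha,
                 tolerance = 1e-6)
  }
})

test_that("delta of a track against itself is zero", {
  tr <- mono_track()
  d <- delta_angles(tr, tr, "self")
  expect_lt(max(abs(d$per_side$delta_alpha)), 1e-9)
  expect_lt(max(abs(d$per_side$delta_beta)), 1e-9)
  expect_lt(d$rmsd, 1e-9)
})

test_that("a controlled 5-degree out-of-plane bend reads back as delta-beta 5", {
  ra <- reference_angles()
  ref <- mono_track()
  bent <- mono_track(exit = ra$exit + c(0, -5))
  d <- delta_angles(bent, ref, "unbent")
  expect_equal(d$per_side$delta_beta[d$per_side$side == "exit"], 5,
               tolerance = 0.1)
  expect_lt(d$per_side$delta_beta[d$per_side$side == "entry"], 0.1)
  expect_lt(d$per_side$delta_alpha[d$per_side$side == "exit"], 0.1)
})

test_that("projection-angle delta equals |difference of signed angles|", {
  ra <- reference_angles()
  ref <- synthetic_reference()
  ref_beta <- trajectory_angles(ref$track)$beta
  for (db in c(-20, -6, 3, 14, 31)) {
    tgt <- mono_track(entry = ra$entry + c(0, db),
                      exit = ra$exit + c(0, -db))
    d <- delta_angles(tgt, ref$track, ref$id)
    tgt_beta <- trajectory_angles(tgt)$beta
    expect_equal(d$per_side$delta_beta,
                 abs(nucgeom:::wrap180(tgt_beta - ref_beta)),
                 tolerance = 1e-9)
  }
})

test_that("measured delta-beta increases strictly with the injected bend", {
  ra <- reference_angles()
  ref <- synthetic_reference()
  deltas <- vapply(seq(1, 30, by = 4), function(db) {
    tgt <- mono_track(entry = ra$entry + c(0, db))
    delta_angles(tgt, ref$track)$per_side$delta_beta[1]
  }, numeric(1))
  expect_true(all(diff(deltas) > 0))
  expect_equal(deltas, seq(1, 30, by = 4), tolerance = 0.01)
})

test_that("averages lie between per-side extremes and skip undefined sides", {
  ra <- reference_angles()
  ref <- synthetic_reference()
  tgt <- mono_track(entry = ra$entry + c(2, 10), exit = ra$exit - c(1, 4))
  d <- delta_angles(tgt, ref$track)
  expect_gte(d$avg_delta_beta, min(d$per_side$delta_beta))
  expect_lte(d$avg_delta_beta, max(d$per_side$delta_beta))
  ## exit-only nucleosome: average equals the single defined side
  solo <- mono_track(entry = NULL, exit = ra$exit - c(0, 12))
  d2 <- delta_angles(solo, ref$track)
  expect_equal(d2$avg_delta_beta,
               d2$per_side$delta_beta[d2$per_side$side == "exit"])
  ## reference must have both linkers
  expect_error(delta_angles(tgt, solo, "bad-ref"), "both linker sides")
})

test_that("noisy measurements stay near truth at sigma = 0.5 A", {
  ## seeded Monte-Carlo: pooled angle errors within 3 degrees >= 95%
  set.seed(1)
  errs <- replicate(100, {
    ab <- stats::runif(2, -40, 40)
    tr <- mono_track(entry = NULL, exit = ab)
    noisy <- bp_track(tr$centroids +
                        matrix(stats::rnorm(length(tr$centroids),
                                            sd = 0.5), ncol = 3),
                      tr$core_start, tr$core_len)
    ang <- trajectory_angles(noisy)
    c(abs(nucgeom:::wrap180(ang$alpha[2] - ab[1])),
      abs(nucgeom:::wrap180(ang$beta[2] - ab[2])))
  })
  expect_gte(mean(errs <= 3), 0.95)
  expect_lt(max(errs), 8)
})
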