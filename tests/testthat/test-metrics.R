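# Trabecular morphometry operations against phantoms with analytic truth.

test_that("Otsu threshold separates bimodal data and matches the exhaustive scan", {
  set.seed(2)
  arr <- array(sample(c(40, 200), 8^3, replace = TRUE), rep(8L, 3L))
  v <- voxel_volume(arr, 20)
  thr <- optimise_threshold(v)
  expect_gt(thr, 40); expect_lt(thr, 200)
  expect_equal(attr(thr, "method"), "otsu")

  mix <- c(rnorm(4000 * 0.4, 50, 10), rnorm(4000 * 0.6, 180, 10))
  mix <- pmin(255, pmax(0, round(mix)))
  arr2 <- array(mix[seq_len(4096)], rep(16L, 3L))
  arr2[is.na(arr2)] <- 180
  thr2 <- optimise_threshold(voxel_volume(arr2, 20))
  expect_lt(abs(thr2 - naive_otsu(arr2)), 3)

  expect_error(optimise_threshold(voxel_volume(array(5, rep(4L, 3L)), 20)),
               "constant")
  expect_equal(as.numeric(optimise_threshold(v, "fixed:100")), 100)
})

test_that("purify removes islands, fills cavities, and is idempotent", {
  x <- array(FALSE, rep(20L, 3L))
  x[5:15, 5:15, 5:15] <- TRUE        # main block
  x[10, 10, 10] <- FALSE             # enclosed cavity
  x[2, 2, 2] <- TRUE; x[2, 2, 3] <- TRUE; x[2, 3, 2] <- TRUE  # floating island
  p <- purify(voxel_volume(x, 20, binary = TRUE))
  expect_false(p$data[2, 2, 2])
  expect_true(p$data[10, 10, 10])
  p2 <- purify(p)
  expect_identical(p2$data, p$data)
  expect_error(purify(voxel_volume(array(FALSE, rep(4L, 3L)), 20, binary = TRUE)),
               "empty foreground")
})

test_that("bone volume fraction matches closed forms for solid, plate and rod phantoms", {
  solid <- voxel_volume(array(TRUE, rep(100L, 3L)), 20, binary = TRUE)
  bv <- bone_volume_fraction(solid)
  expect_equal(bv$BVTV, 1)
  expect_equal(bv$TV, 8)   # (100 * 0.02 mm)^3

  pl <- make_phantom("plate_stack", size = 60, spacing = 20, period = 10, thickness = 4)
  expect_equal(bone_volume_fraction(pl$vol)$BVTV, 0.400)
  rl <- make_phantom("rod_lattice", size = 60, spacing = 20, period = 10, width = 2)
  expect_equal(bone_volume_fraction(rl$vol)$BVTV, 0.104)
  # conservation: BV + background volume = TV
  bvr <- bone_volume_fraction(rl$vol)
  bg <- sum(!rl$vol$data) * (20 / 1000)^3
  expect_equal(bvr$BV + bg, bvr$TV)
})

test_that("Crofton surface area is within 3% on ball and box and scales with spacing", {
  ball <- make_phantom("ball", size = 89, spacing = 10, radius = 40)
  set.seed(1)
  bs <- bone_surface(ball$vol, n_directions = 200)
  truth <- 4 * pi * 0.4^2
  expect_lt(abs(bs - truth) / truth, 0.03)

  box <- array(FALSE, c(40L, 50L, 60L)); box[6:35, 6:45, 6:55] <- TRUE
  set.seed(2)
  bsb <- bone_surface(voxel_volume(box, 10, binary = TRUE), n_directions = 200)
  tb <- 2 * (0.3 * 0.4 + 0.4 * 0.5 + 0.3 * 0.5)
  expect_lt(abs(bsb - tb) / tb, 0.03)

  set.seed(3); a1 <- bone_surface(voxel_volume(box, 10, binary = TRUE), n_directions = 100)
  set.seed(3); a2 <- bone_surface(voxel_volume(box, 20, binary = TRUE), n_directions = 100)
  expect_equal(a2 / a1, 4, tolerance = 1e-10)  # doubling spacing quadruples area
})

test_that("local thickness recovers sphere diameter and plate thickness/separation", {
  ball <- make_phantom("ball", size = 41, spacing = 20, radius = 8)
  th <- local_thickness(ball$vol, "foreground")
  expect_lt(abs(th - 0.32), 0.02)     # within one voxel of the diameter

  pl <- make_phantom("plate_stack", size = 60, spacing = 20, period = 10, thickness = 4)
  expect_lte(abs(local_thickness(pl$vol, "foreground") - 0.08), 0.02 + 1e-9)
  expect_lte(abs(local_thickness(pl$vol, "background") - 0.12), 0.02 + 1e-9)

  # thickness is linear in spacing at a fixed grid
  pl2 <- pl$vol; pl2$spacing <- 40
  expect_equal(local_thickness(pl2, "foreground"),
               2 * local_thickness(pl$vol, "foreground"))
  expect_error(local_thickness(voxel_volume(array(TRUE, rep(8L, 3L)), 20, binary = TRUE),
                               "background"), "empty")
})

test_that("connectivity distinguishes ball, closed loop, and wireframe cube", {
  ball <- make_phantom("ball", size = 33, spacing = 20, radius = 10)
  cn <- connectivity(ball$vol)
  expect_equal(cn$chi, 1)
  expect_equal(cn$Conn, 0)

  loop <- array(FALSE, rep(12L, 3L))
  loop[3:9, 3, 3] <- TRUE; loop[3:9, 9, 3] <- TRUE
  loop[3, 3:9, 3] <- TRUE; loop[9, 3:9, 3] <- TRUE
  expect_equal(connectivity(voxel_volume(loop, 20, binary = TRUE))$Conn, 1)

  wf <- make_phantom("wireframe_cube", size = 32)
  expect_equal(connectivity(wf$vol)$Conn, 5)
})

test_that("Euler characteristic equals the independent integral-geometry oracle", {
  skip_if_not(has_python_skimage(), "python scikit-image oracle unavailable")
  set.seed(42)
  for (i in 1:5) {
    raw <- array(rnorm(16^3), rep(16L, 3L))
    sm <- musteloTrab:::gaussian_smooth3(raw, c(1.5, 1.5, 1.5))
    vol <- sm > quantile(sm, 0.6)
    chi <- connectivity(voxel_volume(vol, 20, binary = TRUE))$chi
    expect_equal(chi, python_euler(vol))
  }
})

test_that("MIL fabric recovers phantom orientations and isotropy", {
  pl <- make_phantom("plate_stack", size = 64, spacing = 20, period = 10,
                     thickness = 4, axis = 1)
  fb <- mil_fabric(pl$vol, n_directions = 300, line_spacing = 2, step = 1, seed = 1)
  # smallest-MIL eigendirection within 5 degrees of the plate normal (z)
  ang <- acos(abs(fb$eigenvectors["z", 3L])) * 180 / pi
  expect_lt(ang, 5)
  expect_gt(degree_of_anisotropy(fb), 0.8)

  rd <- make_phantom("aligned_rods", size = 64, spacing = 20, period = 16,
                     width = 4, axis = 1)
  fr <- mil_fabric(rd$vol, n_directions = 300, line_spacing = 2, step = 1, seed = 1)
  expect_lt(acos(abs(fr$eigenvectors["z", 1L])) * 180 / pi, 5)

  iso <- make_phantom("grf", size = 64, sigma = c(3, 3, 3), bvtv = 0.35, seed = 5)
  fi <- mil_fabric(purify(iso$vol), n_directions = 300, line_spacing = 2,
                   step = 1, seed = 2)
  expect_gte(fi$eigenvalues[3L] / fi$eigenvalues[1L], 0.85)

  # orthonormal eigenvectors, eigenvalues sorted, upper-hemisphere convention
  V <- fr$eigenvectors
  expect_equal(crossprod(V), diag(3), tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(diff(fr$eigenvalues) <= 0))
  expect_true(all(V["z", ] >= 0))
})

test_that("DA increases monotonically with GRF anisotropy stretch", {
  das <- vapply(c(1, 2, 4), function(s) {
    g <- make_phantom("grf", size = 48, sigma = c(2 * s, 2, 2), bvtv = 0.35, seed = 11)
    degree_of_anisotropy(mil_fabric(purify(g$vol), n_directions = 200,
                                    line_spacing = 2, step = 1, seed = 3))
  }, numeric(1))
  expect_true(all(diff(das) > 0))
})

test_that("degree of anisotropy and MDT follow their conventions", {
  fab <- structure(list(eigenvalues = c(2, 1, 1),
                        eigenvectors = diag(3),
                        n_capped = 0L), class = "fabric_tensor")
  rownames(fab$eigenvectors) <- c("x", "y", "z")
  expect_equal(degree_of_anisotropy(fab), 0.5)
  fab$eigenvalues <- c(1, 1, 1)
  expect_equal(degree_of_anisotropy(fab), 0)

  mk <- function(v) {
    f <- fab; f$eigenvectors[, 1L] <- v / sqrt(sum(v^2)); f
  }
  expect_equal(main_direction(mk(c(0, 0, 1))), c(theta = 0, phi = 0))
  expect_equal(main_direction(mk(c(1, 0, 0))), c(theta = 90, phi = 0))
  expect_equal(main_direction(mk(c(1, 1, sqrt(2)) / 2)), c(theta = 45, phi = 45))
})

test_that("relative resolution check applies the 5 pixels/trabecula rule", {
  r1 <- relative_resolution_check(0.17, 34)
  expect_equal(r1$ratio, 5); expect_true(r1$pass)
  r2 <- relative_resolution_check(0.12, 30)
  expect_equal(r2$ratio, 4); expect_false(r2$pass)
  r3 <- relative_resolution_check(0.17, 17)
  expect_equal(r3$ratio, 10); expect_true(r3$pass)
})

test_that("repeatability CV matches hand computation and flags zero means", {
  reps <- data.frame(a = c(9, 10, 11), b = c(5, 5, 5), c = c(-1, 0, 1))
  cv <- repeatability_cv(reps)
  expect_equal(unname(cv$cv["a"]), 10)
  expect_equal(unname(cv$cv["b"]), 0)
  expect_true(is.na(cv$cv["c"]))
  expect_equal(repeatability_cv(reps[c(1, 1), ])$mean_cv, 0)
  expect_error(repeatability_cv(reps[1, , drop = FALSE]), "two repeats")
})

test_that("re-extraction with jittered centres keeps mean CV under 5%", {
  g <- make_phantom("grf", size = 72, sigma = c(2.5, 2.5, 2.5), bvtv = 0.4,
                    seed = 21, spacing = 20)
  vol <- purify(g$vol)
  set.seed(9)
  rows <- lapply(1:8, function(i) {
    c0 <- c(36L, 36L, 36L) + sample(-1:1, 3L, replace = TRUE)
    voi <- extract_cubic_voi(vol, c0, edge = 49L)$voi
    voi <- purify(voi)
    data.frame(BVTV = bone_volume_fraction(voi)$BVTV,
               TbTh = local_thickness(voi, "foreground"),
               TbSp = local_thickness(voi, "background"))
  })
  cv <- repeatability_cv(do.call(rbind, rows))
  expect_lt(cv$mean_cv, 5)
})

test_that("deterministic metrics are invariant under 90-degree rotation and mirroring", {
  g <- make_phantom("grf", size = 40, sigma = c(2, 2, 2), bvtv = 0.4, seed = 31,
                    spacing = 20)
  vol <- purify(g$vol)
  rot <- voxel_volume(rot90_3d(vol$data, 1L), 20, binary = TRUE)
  expect_equal(bone_volume_fraction(rot)$BVTV, bone_volume_fraction(vol)$BVTV)
  expect_equal(local_thickness(rot, "foreground"), local_thickness(vol, "foreground"))
  expect_equal(connectivity(rot)$Conn, connectivity(vol)$Conn)

  vol$side <- "left"
  mir <- mirror_left_bone(vol)
  expect_equal(bone_volume_fraction(mir)$BVTV, bone_volume_fraction(vol)$BVTV)
  expect_equal(local_thickness(mir, "foreground"), local_thickness(vol, "foreground"))
  expect_equal(connectivity(mir)$Conn, connectivity(vol)$Conn)
  da1 <- degree_of_anisotropy(mil_fabric(vol, 200, 2, 1, seed = 4))
  da2 <- degree_of_anisotropy(mil_fabric(mir, 200, 2, 1, seed = 4))
  expect_lt(abs(da1 - da2), 0.05)
})

test_that("the full metric battery is deterministic for a fixed seed", {
  g <- make_phantom("grf", size = 33, sigma = c(2, 2, 2), bvtv = 0.4, seed = 13,
                    spacing = 20)
  vol <- purify(g$vol)
  m1 <- trabecular_metrics(vol, n_directions = 100, line_spacing = 2, step = 1, seed = 5)
  m2 <- trabecular_metrics(vol, n_directions = 100, line_spacing = 2, step = 1, seed = 5)
  expect_identical(m1, m2)
  expect_equal(m1$BVTV, m1$BV / m1$TV)
  expect_true(m1$DA >= 0 && m1$DA <= 1)
})
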