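# Volume I/O, mirroring and landmark-driven VOI extraction.

test_that("TIFF and raw round-trips are bit-exact and constant stacks read back", {
  arr <- array(7L, c(8L, 6L, 5L))
  vol <- voxel_volume(arr, spacing = 20, side = "right")
  tf <- tempfile(fileext = ".tif")
  write_volume(vol, tf)
  expect_error(read_volume(tf), "spacing")
  back <- read_volume(tf, spacing_override = 20)
  expect_equal(dim(back$data), c(8L, 6L, 5L))
  expect_true(all(back$data == 7L))
  expect_equal(back$spacing, 20)

  set.seed(1)
  arr2 <- array(sample.int(65535L, 4 * 5 * 6, replace = TRUE), c(4L, 5L, 6L))
  v2 <- voxel_volume(arr2, spacing = 17.5)
  jf <- tempfile(fileext = ".json")
  write_volume(v2, jf)
  b2 <- read_volume(jf)
  expect_identical(as.integer(b2$data), as.integer(arr2))
  expect_equal(b2$spacing, 17.5)

  tf2 <- tempfile(fileext = ".tif")
  write_volume(v2, tf2)
  b3 <- read_volume(tf2, spacing_override = 17.5)
  expect_identical(as.integer(b3$data), as.integer(arr2))
})

test_that("slice directories demand contiguous numbering and report gaps", {
  dirp <- tempfile(); dir.create(dirp)
  for (i in c(1:3, 5:6))
    tiff::writeTIFF(matrix(0.5, 4, 4), file.path(dirp, sprintf("slice_%03d.tif", i)))
  expect_error(read_volume(dirp, spacing_override = 20), "missing slice.*4")
  tiff::writeTIFF(matrix(0.5, 4, 4), file.path(dirp, "slice_004.tif"))
  v <- read_volume(dirp, spacing_override = 20)
  expect_equal(dim(v$data)[1L], 6L)
})

test_that("unsupported and malformed inputs are rejected", {
  expect_error(read_volume(tempfile(fileext = ".dcm")), "no such file")
  f <- tempfile(fileext = ".dcm"); writeLines("x", f)
  expect_error(read_volume(f), "DICOM")
  hdr <- tempfile(fileext = ".json")
  jsonlite::write_json(list(shape = c(2, 2, 2), spacing_um = c(10, 10, 20),
                            dtype = "uint8", data_file = "x.raw"),
                       hdr, auto_unbox = TRUE)
  expect_error(read_volume(hdr), "anisotropic")
})

test_that("mirroring is an involution, moves markers on axis 3, and refuses right bones", {
  arr <- array(0L, c(4L, 5L, 6L))
  arr[2L, 3L, 1L] <- 9L   # marker at low index of the horizontal axis
  v <- voxel_volume(arr, 20, side = "left")
  m <- mirror_left_bone(v)
  expect_equal(m$side, "right")
  expect_equal(m$data[2L, 3L, 6L], 9L)
  expect_error(mirror_left_bone(m), "already right-sided")
  m$side <- "left"                      # reset flag to test involution
  mm <- mirror_left_bone(m)
  expect_identical(mm$data, arr)
})

test_that("VOI centre is the floored midpoint of the landmark bounding box", {
  lm <- anatomical_landmarks("humeral_head", list(
    proximal_most = c(10, 40, 20), distal_most = c(30, 60, 80),
    anterolateral_corner = c(20, 40, 20), medial_most = c(20, 60, 80),
    posterior_most = c(20, 50, 50)))
  expect_equal(unname(locate_voi_centre(lm)), c(20, 50, 50))

  # translation equivariance of the centre
  sh <- c(3, 7, 11)
  lm2 <- anatomical_landmarks("humeral_head",
    lapply(lm$landmarks, function(p) p + sh))
  expect_equal(unname(locate_voi_centre(lm2)), c(20, 50, 50) + sh)

  # .5 midpoints round down
  lm3 <- anatomical_landmarks("humeral_head", list(
    proximal_most = c(10, 40, 20), distal_most = c(31, 60, 80),
    anterolateral_corner = c(20, 40, 20), medial_most = c(20, 60, 80),
    posterior_most = c(20, 50, 50)))
  expect_equal(unname(locate_voi_centre(lm3))[1L], 20)
})

test_that("missing or degenerate landmarks raise named errors", {
  expect_error(anatomical_landmarks("humeral_head", list(
    proximal_most = c(1, 2, 3), distal_most = c(5, 2, 3),
    anterolateral_corner = c(3, 1, 1), medial_most = c(3, 4, 4))),
    "posterior_most")
  lm <- anatomical_landmarks("humeral_head", list(
    proximal_most = c(10, 40, 20), distal_most = c(10, 60, 80),
    anterolateral_corner = c(10, 40, 20), medial_most = c(10, 60, 80),
    posterior_most = c(10, 50, 50)))
  expect_error(locate_voi_centre(lm), "single slice")
  expect_error(required_landmarks("patella"), "unknown structure")
})

test_that("landmark JSON files round-trip through read_landmarks", {
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(list(structure = "humeral_head", side = "right",
                            landmarks = list(proximal_most = c(1, 2, 3),
                                             distal_most = c(9, 2, 3),
                                             anterolateral_corner = c(5, 0, 0),
                                             medial_most = c(5, 9, 9),
                                             posterior_most = c(5, 5, 5))),
                       f, auto_unbox = TRUE)
  lm <- read_landmarks(f)
  expect_s3_class(lm, "anatomical_landmarks")
  expect_equal(lm$landmarks$distal_most, c(9, 2, 3))
})

test_that("cubic VOI growth matches the brute-force largest cube in a spherical mask", {
  n <- 111L
  c0 <- 55L
  idx <- (0:(n - 1L)) - c0
  d2 <- outer(outer(idx^2, idx^2, `+`), idx^2, `+`)
  mask <- array(d2 <= 50^2, rep(n, 3L))
  vol <- voxel_volume(array(1L, rep(n, 3L)), 20)
  res <- extract_cubic_voi(vol, centre = rep(c0, 3L), mask = mask)
  expect_equal(res$selection$edge, naive_max_cube(mask, rep(c0, 3L)))
  expect_equal(res$selection$edge, 57L)   # largest odd edge <= 2*50/sqrt(3)
  # no VOI voxel may fall outside the mask
  h <- (res$selection$edge - 1L) %/% 2L
  blk <- mask[(c0 - h):(c0 + h) + 1L, (c0 - h):(c0 + h) + 1L, (c0 - h):(c0 + h) + 1L]
  expect_true(all(blk))
})

test_that("unconstrained growth fills the volume and tight masks stop at the shell", {
  vol <- voxel_volume(array(1L, rep(101L, 3L)), 20)
  res <- extract_cubic_voi(vol, centre = rep(50L, 3L),
                           mask = array(TRUE, rep(101L, 3L)), min_edge = 16L)
  expect_equal(res$selection$edge, 101L)

  mask <- array(TRUE, rep(41L, 3L))
  mask[, , 26:41] <- FALSE               # boundary 3 voxels from the centre
  res2 <- extract_cubic_voi(vol = voxel_volume(array(1L, rep(41L, 3L)), 20),
                            centre = c(20L, 20L, 21L), mask = mask, min_edge = 3L)
  expect_equal(res2$selection$edge, 7L)
  expect_error(extract_cubic_voi(voxel_volume(array(1L, rep(41L, 3L)), 20),
                                 centre = c(20L, 20L, 21L), mask = mask),
               "unusable")
})
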