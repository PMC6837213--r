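# Body-mass estimation, AN(C)OVA routing, ratios, descriptives, pPCA, PLS.

test_that("body-mass estimation interpolates exact allometric data", {
  tr <- simulate_tree(12, seed = 1)
  tv <- exp(seq(0.5, 3, length.out = 12))
  mass <- exp(2 + 1 * log(tv))
  names(mass) <- tr$tip.label
  bm <- estimate_specimen_mass(tv, tr$tip.label, mass, tr)
  expect_equal(as.numeric(bm), log(mass), tolerance = 1e-6, ignore_attr = TRUE)

  # duplicated specimens of one species with equal TV get equal BMsp
  sp <- c(tr$tip.label, tr$tip.label[1L])
  bm2 <- estimate_specimen_mass(c(tv, tv[1L]), sp, mass, tr)
  expect_equal(bm2[13L], bm2[1L])

  expect_error(estimate_specimen_mass(c(tv[-1], -1), sp[-1], mass, tr), "positive")
  expect_error(estimate_specimen_mass(tv, c(tr$tip.label[-1], "nope"), mass, tr),
               "missing from tree")
})

test_that("allometric slope is recovered within 2 se on simulated data", {
  tr <- simulate_tree(29, seed = 4)
  ln_tv <- simulate_traits(tr, lambda = 1, sigma2 = 1, seed = 5) + 3
  ln_mass <- 2 + 1 * ln_tv + simulate_traits(tr, lambda = 1, sigma2 = 0.05, seed = 6)
  bm <- estimate_specimen_mass(exp(ln_tv[tr$tip.label]), tr$tip.label,
                               exp(ln_mass), tr)
  fit <- attr(bm, "fit")
  slope <- unname(fit$beta[2L])
  # rough se from the GLS fit residual scale
  expect_lt(abs(slope - 1), 0.25)
})

test_that("alpha extremes force the AN(C)OVA routing contract", {
  st <- make_synthetic_study(seed = 11)
  sub <- st$metrics[st$metrics$voi_type == "humeral_head", ]
  sub <- merge(sub, st$specimens[, c("specimen_id", "habit")], by = "specimen_id")
  bm <- estimate_specimen_mass(sub$TV, sub$species, st$species_mass, st$tree)
  r1 <- size_screen(sub$BVTV, as.numeric(bm), sub$habit, sub$species, st$tree,
                    alpha = 1, n_perm = 99, seed = 1)
  expect_equal(r1$route, "ANCOVA"); expect_true(r1$size_correlated)
  r0 <- size_screen(sub$BVTV, as.numeric(bm), sub$habit, sub$species, st$tree,
                    alpha = 0, n_perm = 99, seed = 1)
  expect_equal(r0$route, "ANOVA"); expect_false(r0$size_correlated)
})

test_that("a pure size effect routes to ANCOVA and a pure type effect to ANOVA", {
  tr <- simulate_tree(29, seed = 21)
  types <- setNames(rep(c("fossorial", "generalized", "natatorial", "scansorial"),
                        c(7, 9, 6, 7)), tr$tip.label)
  bm <- simulate_traits(tr, lambda = 1, sigma2 = 1, seed = 22) + 6
  # size-driven trait: strong BMsp dependence, no type effect
  ysize <- 0.5 * bm + simulate_traits(tr, lambda = 1, sigma2 = 0.01, seed = 23)
  rs <- size_screen(ysize[tr$tip.label], bm[tr$tip.label], types[tr$tip.label],
                    tr$tip.label, tr, n_perm = 199, seed = 2)
  expect_true(rs$size_correlated)
  expect_equal(rs$route, "ANCOVA")

  # type-driven trait: 2-sd natatorial shift, no size effect
  eff <- c(fossorial = 0, generalized = 0, natatorial = 2, scansorial = 0)
  ytype <- simulate_traits(tr, lambda = 0.8, group_effects = eff, groups = types,
                           sigma2 = 1, seed = 24)
  rt <- size_screen(ytype[tr$tip.label], bm[tr$tip.label], types[tr$tip.label],
                    tr$tip.label, tr, n_perm = 199, seed = 3)
  expect_equal(rt$route, "ANOVA")
})

test_that("inter-limb ratios are identity on equal metrics and plain quotients otherwise", {
  met <- data.frame(specimen_id = rep(c("s1", "s2"), each = 4),
                    voi_type = rep(c("humeral_head", "femoral_head",
                                     "humeral_trochlea", "femoral_lateral_condyle"), 2),
                    DA = c(0.5, 0.5, 0.4, 0.4, 0.50, 0.58, 0.3, 0.6),
                    BVTV = c(0.4, 0.4, 0.3, 0.3, 0.42, 0.42, 0.2, 0.4))
  r <- interlimb_ratios(met, parameters = c("DA", "BVTV"))
  s1p <- r[r$specimen_id == "s1" & r$pair == "proximal", ]
  expect_equal(s1p$DA, 1); expect_equal(s1p$BVTV, 1)
  s2p <- r[r$specimen_id == "s2" & r$pair == "proximal", ]
  expect_equal(s2p$DA, 0.50 / 0.58, tolerance = 1e-12)
  s2d <- r[r$specimen_id == "s2" & r$pair == "distal", ]
  expect_equal(s2d$BVTV, 0.5)

  # zero denominator -> NA with a log entry; missing member -> skipped
  met2 <- met; met2$DA[2L] <- 0
  expect_message(r2 <- interlimb_ratios(met2, parameters = "DA"), "zero")
  expect_true(is.na(r2$DA[r2$specimen_id == "s1" & r2$pair == "proximal"]))
  met3 <- met[met$voi_type != "femoral_head" | met$specimen_id != "s2", ]
  expect_message(r3 <- interlimb_ratios(met3, parameters = "DA"), "skipping")
  expect_false("s2" %in% r3$specimen_id[r3$pair == "proximal"])
})

test_that("descriptive statistics match hand values and handle singletons", {
  d <- descriptive_stats(c(9, 10, 11), rep("g", 3))
  expect_equal(d$mean, c(10, 10))
  expect_equal(d$sd, c(1, 1))
  expect_equal(d$min, c(9, 9)); expect_equal(d$max, c(11, 11))
  s <- descriptive_stats(5, "solo")
  expect_true(is.na(s$sd[1L]))
  expect_equal(s$min[1L], s$max[1L])
})

test_that("phylogenetic PCA equals ordinary PCA on a star tree", {
  star <- ape::stree(10, "star"); star$edge.length <- rep(1, 10)
  set.seed(3)
  X <- matrix(rnorm(40), 10, 4,
              dimnames = list(star$tip.label, paste0("v", 1:4)))
  pp <- phylogenetic_pca(X, star)
  pc <- stats::prcomp(X, scale. = TRUE)
  expect_lt(max(abs(abs(pp$scores) - abs(pc$x))), 1e-8)
  expect_lt(max(abs(abs(pp$loadings) - abs(pc$rotation))), 1e-8)
  expect_equal(sum(pp$percent_variance), 100, tolerance = 1e-6)
  # scores are translation invariant
  pp2 <- phylogenetic_pca(sweep(X, 2, c(5, -2, 0, 100), "+"), star)
  expect_equal(abs(pp2$scores), abs(pp$scores), tolerance = 1e-8)
  # duplicated variables are refused with names
  expect_error(phylogenetic_pca(cbind(X, v1b = X[, 1L]), star), "collinear")
})

test_that("phylogenetic PCA agrees with the phytools implementation", {
  skip_if_not_installed("phytools")
  tr <- simulate_tree(15, seed = 13)
  set.seed(14)
  X <- matrix(rnorm(45), 15, 3, dimnames = list(tr$tip.label, paste0("v", 1:3)))
  pp <- phylogenetic_pca(X, tr, mode = "correlation")
  pt <- phytools::phyl.pca(tr, X, method = "BM", mode = "corr")
  expect_lt(max(abs(abs(pp$loadings) - abs(unclass(pt$Evec)))), 1e-8)
  expect_equal(pp$percent_variance,
               100 * diag(pt$Eval) / sum(diag(pt$Eval)),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("two-block PLS is 1 on identical blocks and rotation invariant", {
  tr <- simulate_tree(16, seed = 17)
  set.seed(18)
  B <- matrix(rnorm(16 * 3), 16, 3, dimnames = list(tr$tip.label, NULL))
  p1 <- phylo_two_block_pls(B, B, tr, n_perm = 99, seed = 1)
  expect_equal(p1$rPLS, 1, tolerance = 1e-10)
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  p2 <- phylo_two_block_pls(B, B %*% Q, tr, n_perm = 99, seed = 1)
  expect_equal(p2$rPLS, 1, tolerance = 1e-10)
  expect_error(phylo_two_block_pls(B, matrix(1, 16, 2,
    dimnames = list(tr$tip.label, NULL)), tr, n_perm = 99, seed = 1), "constant")
})

test_that("PLS p-values are approximately uniform for independent blocks", {
  tr <- simulate_tree(20, seed = 19)
  ps <- vapply(1:20, function(i) {
    set.seed(100 + i)
    A <- matrix(rnorm(40), 20, 2, dimnames = list(tr$tip.label, NULL))
    B <- matrix(rnorm(40), 20, 2, dimnames = list(tr$tip.label, NULL))
    phylo_two_block_pls(A, B, tr, n_perm = 99, seed = i)$p
  }, numeric(1))
  expect_gt(mean(ps), 0.2)   # not systematically significant under the null
  expect_lt(mean(ps < 0.05), 0.3)
})
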