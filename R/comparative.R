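# The comparative inference chain: specimen body-mass estimation from VOI
# total volume, size-correlation screening with AN(C)OVA routing, inter-limb
# ratios, descriptive group summaries, phylogenetic PCA and two-block PLS.
#
# Multiple conspecific specimens are averaged to species values before any
# phylogenetic fit; specimen-level values are kept for descriptive tables.

#' Estimate specimen body mass from VOI total volume
#'
#' Fits `ln(species mean mass) ~ ln(species mean TV)` with a
#' lambda-optimised phylogenetic GLS (lambda clamped to `[0, 1]`), then
#' predicts each specimen from its own TV.  The returned unit is the natural
#' logarithm of mass in grams (BMsp).
#'
#' @param tv per-specimen total VOI volume (mm^3), positive.
#' @param species species of each specimen (must be tree tips).
#' @param species_mass named vector of species mean body masses (g).
#' @param tree timetree (`phylo`).
#' @param method lambda estimation method, `"ML"` or `"REML"`.
#' @return Numeric vector of BMsp (ln g) per specimen, with the
#'   `lambda_fit` attached as attribute `fit`.
#' @export
estimate_specimen_mass <- function(tv, species, species_mass, tree, method = "ML") {
  if (any(tv <= 0)) stop("TV must be positive for all specimens")
  species <- as.character(species)
  miss <- setdiff(unique(species), tree$tip.label)
  if (length(miss)) stop("species missing from tree: ", paste(miss, collapse = ", "))
  missm <- setdiff(unique(species), names(species_mass))
  if (length(missm)) stop("species missing a mass entry: ", paste(missm, collapse = ", "))

  sp_tv <- tapply(tv, species, mean)
  used <- tree$tip.label[tree$tip.label %in% names(sp_tv)]
  tr <- if (length(used) < length(tree$tip.label))
    ape::drop.tip(tree, setdiff(tree$tip.label, used)) else tree
  x <- log(sp_tv[tr$tip.label])
  y <- log(species_mass[tr$tip.label])
  X <- cbind(`(Intercept)` = 1, lnTV = as.numeric(x))
  fit <- fit_lambda_gls(setNames(as.numeric(y), tr$tip.label), X, tr, method = method)
  bmsp <- unname(fit$beta[1L] + fit$beta[2L] * log(tv))
  attr(bmsp, "fit") <- fit
  bmsp
}

species_means <- function(values, species) {
  tapply(values, as.character(species), mean)
}

#' Size screen and AN(C)OVA routing for one parameter
#'
#' Step 1: an RRPP regression of the (species-averaged) parameter on BMsp
#' under the lambda-rescaled covariance decides whether the parameter is
#' size-correlated (`p < alpha`).  Step 2: the omnibus locomotor-type test
#' is an RRPP ANCOVA (`param ~ BMsp + type`) when size-correlated, else an
#' RRPP ANOVA (`param ~ type`).  Step 3: pairwise contrasts under the same
#' permutation schedule.  Residuals of the size regression are returned for
#' plotting ("sc" convention).
#'
#' @param values per-specimen parameter values.
#' @param bmsp per-specimen BMsp (ln g).
#' @param types locomotor type per specimen.
#' @param species species per specimen (tree tips).
#' @param tree timetree.
#' @param alpha size-screen significance level (default 0.05).
#' @param n_perm permutations (default 999).
#' @param seed permutation seed.
#' @param method lambda estimation method.
#' @return Object of class `ancova_result`: `size_correlated`, `route`,
#'   `lambda_used`, omnibus `F`, `R2`, `p`, `pairwise` table, `size_p`,
#'   and `sc_residuals` (species-level residuals of the size regression).
#' @export
size_screen <- function(values, bmsp, types, species, tree, alpha = 0.05,
                        n_perm = 999L, seed = 1L, method = "ML") {
  keep <- complete.cases(values, bmsp, types, species)
  if (!all(keep)) message("dropping ", sum(!keep), " incomplete case(s)")
  values <- values[keep]; bmsp <- bmsp[keep]
  types <- as.character(types)[keep]; species <- as.character(species)[keep]

  sp <- sort(unique(species))
  y <- as.numeric(species_means(values, species)[sp])
  x <- as.numeric(species_means(bmsp, species)[sp])
  ty <- vapply(sp, function(s) unique(types[species == s])[1L], character(1))
  if (length(unique(ty)) < 2L) stop("need at least two locomotor types")
  tr <- ape::drop.tip(tree, setdiff(tree$tip.label, sp))
  miss_lv <- setdiff(unique(as.character(types)), ty)
  if (length(miss_lv)) stop("locomotor type absent after species averaging")

  o <- match(tr$tip.label, sp)
  y <- y[o]; x <- x[o]; ty <- factor(ty[o])

  # lambda for the size model, clamped; covariance used for all RRPP fits
  Xsize <- cbind(1, x)
  lam <- fit_lambda_gls(setNames(y, tr$tip.label), Xsize, tr, method = method)
  C <- lam$C_lambda
  n <- length(y)

  X1 <- matrix(1, n, 1L)
  fit_size <- rrpp_fit(y, Xsize, X1, C, n_perm = n_perm, seed = seed)
  size_correlated <- is.finite(alpha) && fit_size$p < alpha
  if (alpha >= 1) size_correlated <- TRUE   # routing contract: alpha = 1 forces ANCOVA
  if (alpha <= 0) size_correlated <- FALSE  # alpha = 0 forces ANOVA

  G <- stats::model.matrix(~ ty)[, -1L, drop = FALSE]
  if (size_correlated) {
    Xr <- Xsize; Xf <- cbind(Xsize, G); route <- "ANCOVA"
  } else {
    Xr <- X1; Xf <- cbind(X1, G); route <- "ANOVA"
  }
  omni <- rrpp_fit(y, Xf, Xr, C, n_perm = n_perm, seed = seed)
  pw <- rrpp_pairwise(omni, ty)

  sc_res <- drop(y - Xsize %*% qr.coef(qr(fit_size$Tm %*% Xsize), fit_size$ty))
  structure(list(size_correlated = size_correlated, route = route,
                 lambda_used = lam$lambda_used, lambda_raw = lam$lambda_raw,
                 F = omni$F, R2 = omni$R2, p = omni$p, size_p = fit_size$p,
                 pairwise = pw, species = tr$tip.label, types = ty,
                 sc_residuals = setNames(sc_res, tr$tip.label)),
            class = "ancova_result")
}

#' @export
print.ancova_result <- function(x, ...) {
  cat(sprintf("%s (size-correlated: %s, lambda = %.3g): F = %.4g, R2 = %.4g, p = %.4g\n",
              x$route, x$size_correlated, x$lambda_used, x$F, x$R2, x$p))
  invisible(x)
}

#' Inter-limb ratios of trabecular parameters
#'
#' Proximal ratio: humeral head / femoral head; distal ratio: humeral
#' trochlea / femoral lateral condyle, element-wise per parameter per
#' specimen.  Specimens missing one member of a pair are skipped; zero
#' denominators yield missing values (both logged via `message()`).
#'
#' @param metrics data frame with columns `specimen_id`, `voi_type`, and
#'   parameter columns.
#' @param parameters parameter columns to ratio (default the standard six).
#' @return Data frame with `specimen_id`, `pair` (`"proximal"`/`"distal"`)
#'   and one ratio column per parameter.
#' @export
interlimb_ratios <- function(metrics,
                             parameters = c("DA", "ConnD", "BVTV", "TbTh", "TbSp", "BS")) {
  pairs <- list(proximal = c("humeral_head", "femoral_head"),
                distal = c("humeral_trochlea", "femoral_lateral_condyle"))
  out <- list()
  for (pn in names(pairs)) {
    num_t <- pairs[[pn]][1L]; den_t <- pairs[[pn]][2L]
    ids <- intersect(metrics$specimen_id[metrics$voi_type == num_t],
                     metrics$specimen_id[metrics$voi_type == den_t])
    skipped <- setdiff(unique(metrics$specimen_id), ids)
    if (length(skipped))
      message(pn, " ratio: skipping specimen(s) missing a member: ",
              paste(skipped, collapse = ", "))
    for (id in ids) {
      a <- metrics[metrics$specimen_id == id & metrics$voi_type == num_t, , drop = FALSE][1L, ]
      b <- metrics[metrics$specimen_id == id & metrics$voi_type == den_t, , drop = FALSE][1L, ]
      r <- vapply(parameters, function(p) {
        den <- as.numeric(b[[p]])
        if (is.na(den) || den == 0) {
          message("zero/missing denominator for ", p, " in specimen ", id)
          return(NA_real_)
        }
        as.numeric(a[[p]]) / den
      }, numeric(1))
      row <- data.frame(specimen_id = id, pair = pn, stringsAsFactors = FALSE)
      out[[length(out) + 1L]] <- cbind(row, as.data.frame(as.list(r)))
    }
  }
  if (!length(out)) return(data.frame())
  do.call(rbind, out)
}

#' Descriptive statistics per group
#'
#' Mean, sample sd, min and max per group plus a pooled row; values are
#' rounded only at output time by the caller.
#'
#' @param values numeric vector.
#' @param groups group labels.
#' @return Data frame with `group, n, mean, sd, min, max` (last row pooled).
#' @export
descriptive_stats <- function(values, groups) {
  groups <- as.character(groups)
  one <- function(v, g) {
    data.frame(group = g, n = length(v), mean = mean(v),
               sd = if (length(v) > 1L) sd(v) else NA_real_,
               min = min(v), max = max(v), stringsAsFactors = FALSE)
  }
  rows <- lapply(sort(unique(groups)), function(g) one(values[groups == g], g))
  rows[[length(rows) + 1L]] <- one(values, "all")
  do.call(rbind, rows)
}

#' Phylogenetic principal component analysis
#'
#' Removes the GLS phylogenetic mean, forms the evolutionary covariance
#' `R = t(Xc) C^-1 Xc / (n - 1)`, eigen-decomposes it (correlation mode by
#' default, since the variables carry heterogeneous units) and projects the
#' centred data onto the eigenvectors.
#'
#' @param X species-by-variables matrix (rows named by tree tips).
#' @param tree timetree.
#' @param mode `"correlation"` (default) or `"covariance"`.
#' @return Object of class `ppca_result`: `scores`, `loadings`,
#'   `percent_variance`, `evals`.
#' @export
phylogenetic_pca <- function(X, tree, mode = c("correlation", "covariance")) {
  mode <- match.arg(mode)
  X <- as.matrix(X)
  pc <- phylo_covariance(tree)
  if (is.null(rownames(X))) {
    if (nrow(X) != length(pc$tips)) stop("rows of X must match the tips")
    rownames(X) <- pc$tips
  }
  miss <- setdiff(pc$tips, rownames(X))
  if (length(miss)) stop("X missing species: ", paste(miss, collapse = ", "))
  X <- X[pc$tips, , drop = FALSE]
  C <- pc$C
  n <- nrow(X)
  Ci <- solve(C)
  one <- matrix(1, n, 1L)
  a <- solve(t(one) %*% Ci %*% one, t(one) %*% Ci %*% X)   # GLS mean, 1 x p
  Xc <- X - one %*% a
  R <- t(Xc) %*% Ci %*% Xc / (n - 1)
  if (qr(R)$rank < ncol(R)) {
    d <- diag(R)
    cors <- abs(stats::cov2cor(R)); diag(cors) <- 0
    bad <- colnames(R)[apply(cors > 0.9999, 2L, any) | d < 1e-12]
    stop("evolutionary covariance is rank deficient; collinear variable(s): ",
         paste(unique(bad), collapse = ", "))
  }
  if (mode == "correlation") {
    sds <- sqrt(diag(R))
    R <- stats::cov2cor(R)
    Xc <- sweep(Xc, 2L, sds, "/")
  }
  e <- eigen(R, symmetric = TRUE)
  loadings <- e$vectors
  # deterministic sign convention: largest-magnitude loading positive
  for (j in seq_len(ncol(loadings))) {
    jmax <- which.max(abs(loadings[, j]))
    if (loadings[jmax, j] < 0) loadings[, j] <- -loadings[, j]
  }
  dimnames(loadings) <- list(colnames(X), paste0("pPC", seq_len(ncol(X))))
  scores <- Xc %*% loadings
  structure(list(scores = scores, loadings = loadings,
                 evals = e$values,
                 percent_variance = 100 * e$values / sum(e$values),
                 mode = mode),
            class = "ppca_result")
}

#' Phylogenetic two-block partial least squares
#'
#' Two-block PLS between a trait/grouping block and a phylogeny block.  The
#' Brownian-motion model enters through the phylogeny representation (see
#' [phylo_block()]: the matrix square root of the BM covariance, so species
#' are placed by their expected BM covariance profile).  Both blocks are
#' column-centred; the first singular pair of the cross-covariance gives
#' rPLS (the correlation of the paired singular scores); the p-value comes
#' from seeded row permutations of the second block.  The blocks are
#' deliberately not whitened by `C^{-1/2}`: whitening turns the phylogeny
#' block into an orthogonal basis of the whole tip space and forces
#' rPLS = 1 for any first block.
#'
#' @param block1,block2 matrices with rows named by tree tips (e.g.
#'   dummy-coded locomotor types and a phylogeny representation).
#' @param tree timetree.
#' @param n_perm permutations (default 999).
#' @param seed integer seed.
#' @return Object of class `pls_result`: `rPLS`, `p`, `left`, `right`
#'   singular vectors.
#' @export
phylo_two_block_pls <- function(block1, block2, tree, n_perm = 999L, seed = 1L) {
  pc <- phylo_covariance(tree)
  prep <- function(B) {
    B <- as.matrix(B)
    if (is.null(rownames(B))) rownames(B) <- pc$tips
    B[pc$tips, , drop = FALSE]
  }
  B1 <- prep(block1); B2 <- prep(block2)
  if (all(apply(B1, 2L, sd) == 0) || all(apply(B2, 2L, sd) == 0))
    stop("constant block")
  n <- nrow(B1)
  centre <- function(B) sweep(B, 2L, colMeans(B))
  Z1 <- centre(B1)
  Z2 <- centre(B2)
  rpls_of <- function(Z2x) {
    s <- svd(crossprod(Z1, Z2x) / (n - 1))
    s1 <- Z1 %*% s$u[, 1L]; s2 <- Z2x %*% s$v[, 1L]
    if (sd(s1) < 1e-14 || sd(s2) < 1e-14) return(0)
    abs(as.numeric(cor(s1, s2)))
  }
  r_obs <- rpls_of(Z2)
  set.seed(seed)
  ge <- 0L
  for (i in seq_len(n_perm)) {
    if (rpls_of(Z2[sample.int(n), , drop = FALSE]) >= r_obs) ge <- ge + 1L
  }
  s <- svd(crossprod(Z1, Z2) / (n - 1))
  structure(list(rPLS = r_obs, p = (1 + ge) / (n_perm + 1),
                 left = s$u[, 1L], right = s$v[, 1L],
                 n_perm = n_perm, seed = seed),
            class = "pls_result")
}

#' Dummy-code a factor for PLS blocks
#' @param x factor or character vector.
#' @return Indicator matrix (one column per level).
#' @export
dummy_code <- function(x) {
  x <- factor(x)
  m <- stats::model.matrix(~ x - 1)
  colnames(m) <- levels(x)
  rownames(m) <- names(x)
  m
}

#' Phylogeny representation for PLS (rows of the matrix square root of C)
#' @param tree timetree.
#' @return Full-rank numeric representation of tip positions on the tree.
#' @export
phylo_block <- function(tree) {
  pc <- phylo_covariance(tree)
  e <- eigen(pc$C, symmetric = TRUE)
  B <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(pc$C))
  rownames(B) <- pc$tips
  B
}
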