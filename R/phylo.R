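# Phylogenetic machinery: Newick I/O, Brownian covariance, Pagel's lambda
# transform and ML/REML estimation under GLS, and residual-randomisation
# (RRPP) permutation linear models with pairwise contrasts.

#' Read a Newick tree with validation
#'
#' @param path Newick file.
#' @return An `ape` `phylo` object (rooted, with branch lengths).
#' @export
read_newick <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse Newick file: ", path)
  validate_tree(tr)
  tr
}

validate_tree <- function(tr) {
  if (is.null(tr$edge.length)) stop("tree has no branch lengths")
  if (anyNA(tr$edge.length) || any(tr$edge.length < 0))
    stop("branch lengths must be non-negative and complete")
  if (anyDuplicated(tr$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  invisible(tr)
}

#' Brownian-motion covariance of a tree
#'
#' `C[i, j]` is the shared root-to-MRCA path length of tips i and j; the
#' diagonal holds root-to-tip distances.
#'
#' @param tree a `phylo` object.
#' @return List with `C` (named matrix), `tips`, and `ultrametric` (checked
#'   to a tolerance of 1e-6 of the tree height).
#' @export
phylo_covariance <- function(tree) {
  validate_tree(tree)
  C <- ape::vcv.phylo(tree)
  h <- max(diag(C))
  ultra <- diff(range(diag(C))) <= 1e-6 * h
  list(C = C, tips = rownames(C), ultrametric = ultra)
}

#' Pagel's lambda transform of a phylogenetic covariance
#'
#' Multiplies the off-diagonal entries by `lambda`, leaving the diagonal
#' unchanged (for ultrametric trees this equals rescaling internal branches).
#' Clamping out-of-range estimates happens in [fit_lambda_gls()], not here.
#'
#' @param C covariance matrix (or the list from [phylo_covariance()]).
#' @param lambda value in `[0, 1]`.
#' @return Transformed covariance matrix.
#' @export
lambda_transform <- function(C, lambda) {
  if (is.list(C)) C <- C$C
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0 || lambda > 1)
    stop("lambda must lie in [0, 1]")
  Cl <- C * lambda
  diag(Cl) <- diag(C)
  Cl
}

# GLS log-likelihood for y ~ X with covariance sigma2 * V; profile over
# sigma2.  Returns -Inf when V is not positive definite.
gls_loglik <- function(y, X, V, method = "ML") {
  n <- length(y)
  p <- qr(X)$rank
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(list(ll = -Inf))
  logdetV <- 2 * sum(log(diag(ch)))
  Li <- backsolve(ch, diag(n), transpose = TRUE)   # t(ch)^{-1}
  ty <- Li %*% y
  tX <- Li %*% X
  fit <- lm.fit(tX, ty)
  beta <- fit$coefficients
  r <- fit$residuals
  rss <- sum(r^2)
  if (method == "ML") {
    s2 <- rss / n
    ll <- -0.5 * (n * log(2 * pi * s2) + logdetV + n)
  } else {
    s2 <- rss / (n - p)
    XtViX <- crossprod(tX)
    ll <- -0.5 * ((n - p) * log(2 * pi * s2) + logdetV +
                    determinant(XtViX, logarithm = TRUE)$modulus + (n - p))
  }
  list(ll = as.numeric(ll), beta = beta, sigma2 = s2, rss = rss)
}

#' Maximum-likelihood Pagel's lambda under GLS
#'
#' Profiles the multivariate-normal log-likelihood of the GLS fit of
#' `y ~ X` over an unconstrained lambda (bounded search on
#' `[lower, upper]`, default `[-0.5, 1.5]`, tolerance 1e-6), then clamps
#' the optimum to `[0, 1]`: negative estimates are forced to 0 and
#' estimates above 1 to 1.
#'
#' @param y trait vector named by (or ordered as) the tree tips.
#' @param X design matrix (default intercept-only).
#' @param tree a `phylo` object.
#' @param method `"ML"` (default) or `"REML"`.
#' @param lower,upper search bounds for the unconstrained optimum.
#' @param tol convergence tolerance of the line search.
#' @return Object of class `lambda_fit`: `lambda_raw`, `lambda_used`,
#'   `logLik`, `beta`, `sigma2`, and the optimizer `trace`.
#' @export
fit_lambda_gls <- function(y, X = NULL, tree, method = c("ML", "REML"),
                           lower = -0.5, upper = 1.5, tol = 1e-6) {
  method <- match.arg(method)
  pc <- phylo_covariance(tree)
  y <- align_to_tips(y, pc$tips)
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  if (nrow(X) != n) stop("rows of X must match the tips")
  if (qr(X)$rank < ncol(X)) stop("singular design matrix")
  if (n < ncol(X) + 2L) stop("too few tips for the design (need n >= p + 2)")
  C <- pc$C

  trace_env <- new.env()
  trace_env$tab <- list()
  obj <- function(lam) {
    Cl <- C * lam
    diag(Cl) <- diag(C)
    ll <- gls_loglik(y, X, Cl, method)$ll
    trace_env$tab[[length(trace_env$tab) + 1L]] <- c(lambda = lam, logLik = ll)
    if (!is.finite(ll)) return(1e12)   # non-PD covariance (e.g. lambda > 1)
    -ll
  }
  opt <- optimize(obj, c(lower, upper), tol = tol)
  # guard against boundary optima the golden section can miss
  cand <- c(opt$minimum, lower, upper, 0, 1)
  vals <- vapply(cand, obj, numeric(1))
  lambda_raw <- cand[which.min(vals)]
  lambda_used <- min(1, max(0, lambda_raw))
  logLik_raw <- -vals[which.min(vals)]
  Cl <- lambda_transform(C, lambda_used)
  fit <- gls_loglik(y, X, Cl, method)
  structure(list(lambda_raw = lambda_raw, lambda_used = lambda_used,
                 logLik = fit$ll, logLik_raw = logLik_raw,
                 beta = fit$beta, sigma2 = fit$sigma2,
                 method = method, C_lambda = Cl, tips = pc$tips,
                 trace = do.call(rbind, trace_env$tab)),
            class = "lambda_fit")
}

#' Clamp a raw lambda estimate to [0, 1]
#'
#' Negative values are forced to 0 and values above 1 to 1.
#' @param lambda_raw unconstrained estimate.
#' @return Clamped value.
#' @export
clamp_lambda <- function(lambda_raw) min(1, max(0, lambda_raw))

align_to_tips <- function(y, tips) {
  if (!is.null(names(y))) {
    miss <- setdiff(tips, names(y))
    if (length(miss)) stop("trait vector missing tip(s): ", paste(miss, collapse = ", "))
    y <- y[tips]
  } else if (length(y) != length(tips)) {
    stop("trait length does not match number of tips")
  }
  as.numeric(y)
}

#' Inverse square root of a covariance matrix
#'
#' Eigen-decomposition based; eigenvalues below `1e-10 * max` indicate a
#' numerically singular covariance and raise an error rather than being
#' pseudo-inverted.
#'
#' @param C symmetric positive-definite matrix.
#' @return Matrix `T` with `T %*% C %*% t(T) = I`.
#' @export
inv_sqrt_matrix <- function(C) {
  e <- eigen(C, symmetric = TRUE)
  if (any(e$values < 1e-10 * max(e$values)))
    stop("covariance is numerically singular (eigenvalue below 1e-10 of max)")
  e$vectors %*% diag(1 / sqrt(e$values), nrow(C)) %*% t(e$vectors)
}

#' Residual-randomisation permutation (RRPP) linear model
#'
#' Data are phylogenetically transformed by the inverse square root of
#' `C`; OLS fits of the full and reduced models on the transformed data
#' give the observed F and R-squared; the reduced-model residuals are
#' permuted (seeded) and re-added to the reduced-model fitted values
#' `n_perm` times, and the p-value is the proportion of permuted F
#' statistics at least as large as the observed one, counting the observed
#' case.
#'
#' @param y response vector.
#' @param X_full,X_reduced design matrices (reduced nested in full).
#' @param C phylogenetic covariance (or `NULL` for iid).
#' @param n_perm number of permutations (>= 99; default 999).
#' @param seed integer seed for the permutation schedule.
#' @return Object of class `rrpp_fit` with `F`, `R2`, `p`, `coefficients`,
#'   `F_perm`, plus the transformed data for pairwise contrasts.
#' @export
rrpp_fit <- function(y, X_full, X_reduced, C = NULL, n_perm = 999L, seed = 1L) {
  y <- as.numeric(y)
  n <- length(y)
  X_full <- as.matrix(X_full); X_reduced <- as.matrix(X_reduced)
  if (nrow(X_full) != n || nrow(X_reduced) != n) stop("design rows must match y")
  if (n_perm < 99L) stop("n_perm must be at least 99")
  Tm <- if (is.null(C)) diag(n) else inv_sqrt_matrix(C)
  ty <- drop(Tm %*% y)
  if (sd(ty) < 1e-12) stop("response is constant after phylogenetic transformation")
  tXf <- Tm %*% X_full
  tXr <- Tm %*% X_reduced
  tXi <- Tm %*% matrix(1, n, 1L)   # transformed intercept, for SS_total

  qf <- qr(tXf); qr_ <- qr(tXr); qi <- qr(tXi)
  dff <- qf$rank - qr_$rank
  if (dff < 1L) stop("full model does not extend the reduced model")
  rdf <- n - qf$rank

  rss <- function(qrobj, v) sum(qr.resid(qrobj, v)^2)
  rss_f <- rss(qf, ty); rss_r <- rss(qr_, ty); tss <- rss(qi, ty)
  F_obs <- ((rss_r - rss_f) / dff) / (rss_f / rdf)
  R2 <- (rss_r - rss_f) / tss

  fit_r <- qr.fitted(qr_, ty)
  e_r <- qr.resid(qr_, ty)
  set.seed(seed)
  F_perm <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    ystar <- fit_r + e_r[sample.int(n)]
    rf <- rss(qf, ystar); rr <- rss(qr_, ystar)
    F_perm[i] <- ((rr - rf) / dff) / (rf / rdf)
  }
  p <- (1 + sum(F_perm >= F_obs)) / (n_perm + 1)

  beta <- qr.coef(qf, ty)
  structure(list(F = F_obs, R2 = R2, p = p, coefficients = beta,
                 F_perm = F_perm, n_perm = n_perm, seed = seed,
                 df = c(effect = dff, residual = rdf),
                 ty = ty, tXf = tXf, tXr = tXr, qf = qf, qr_red = qr_,
                 X_full = X_full, X_reduced = X_reduced, Tm = Tm),
            class = "rrpp_fit")
}

#' @export
print.rrpp_fit <- function(x, ...) {
  cat(sprintf("RRPP fit: F = %.4g, R2 = %.4g, p = %.4g (%d permutations)\n",
              x$F, x$R2, x$p, x$n_perm))
  invisible(x)
}

#' Pairwise contrasts between group least-squares means under RRPP
#'
#' One row per unordered pair of groups: the absolute distance between
#' least-squares means (covariate columns of the reduced design held at
#' their means) and a permutation p-value from the same residual-
#' randomisation schedule as the omnibus test.  Groups with fewer than two
#' members are flagged and their p-values reported missing.
#'
#' @param fit an [rrpp_fit()] whose full design is
#'   `cbind(X_reduced, group dummies)`.
#' @param groups factor of group membership (length = observations).
#' @return Data frame with columns `group1, group2, distance, p, flagged`.
#' @export
rrpp_pairwise <- function(fit, groups) {
  stopifnot(inherits(fit, "rrpp_fit"))
  groups <- factor(groups)
  n <- length(fit$ty)
  if (length(groups) != n) stop("groups length must match observations")
  lev <- levels(groups)
  if (length(lev) < 2L) stop("need at least two groups")

  # LS-mean design rows on the untransformed scale: reduced-design columns at
  # their column means, group columns from the full design averaged per group
  Xf <- fit$X_full
  pr <- ncol(fit$X_reduced)
  lsrow <- function(g) {
    rows <- Xf[groups == g, , drop = FALSE]
    v <- colMeans(rows)
    if (pr >= 1L) {
      cm <- colMeans(fit$X_reduced)
      # keep intercept-like constant columns, average covariates globally
      v[seq_len(pr)] <- cm
    }
    v
  }
  L <- do.call(rbind, lapply(lev, lsrow))

  beta_of <- function(v) {
    b <- qr.coef(fit$qf, v)
    b[is.na(b)] <- 0
    b
  }
  dist_vec <- function(v) {
    mu <- drop(L %*% beta_of(v))
    d <- outer(mu, mu, `-`)
    abs(d[lower.tri(d)])
  }
  d_obs <- dist_vec(fit$ty)

  fit_r <- qr.fitted(fit$qr_red, fit$ty)
  e_r <- qr.resid(fit$qr_red, fit$ty)
  set.seed(fit$seed)
  ge <- rep(0L, length(d_obs))
  for (i in seq_len(fit$n_perm)) {
    ystar <- fit_r + e_r[sample.int(n)]
    ge <- ge + (dist_vec(ystar) >= d_obs)
  }
  p <- (1 + ge) / (fit$n_perm + 1)

  pairs <- which(lower.tri(diag(length(lev))), arr.ind = TRUE)
  small <- table(groups) < 2L
  flagged <- small[lev[pairs[, "col"]]] | small[lev[pairs[, "row"]]]
  out <- data.frame(group1 = lev[pairs[, "col"]], group2 = lev[pairs[, "row"]],
                    distance = d_obs, p = ifelse(flagged, NA_real_, p),
                    flagged = as.logical(flagged), stringsAsFactors = FALSE)
  out[order(out$group1, out$group2), , drop = FALSE]
}
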