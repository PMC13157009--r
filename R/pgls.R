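#' Pagel's lambda transform of a phylogenetic covariance matrix
#'
#' Multiplies the off-diagonal entries of the Brownian-motion covariance
#' matrix by lambda while leaving the diagonal untouched. lambda = 1
#' keeps the full phylogenetic covariance; lambda = 0 removes all shared
#' history, reducing generalized least squares to ordinary least squares.
#'
#' @param C symmetric positive semi-definite covariance matrix from
#'   [phylo_cov()].
#' @param lambda scalar in \[0, 1\].
#' @return Transformed matrix of the same dimensions.
#' @export
lambda_transform <- function(C, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1 ||
      lambda < 0 || lambda > 1) {
    stop("lambda must be a single value in [0, 1]", call. = FALSE)
  }
  V <- lambda * C
  diag(V) <- diag(C)
  V
}

#' Generalized least squares fit at a fixed covariance
#'
#' Solves `beta = (X' V^-1 X)^-1 X' V^-1 y` with the maximum-likelihood
#' residual variance scale `sigma2 = r' V^-1 r / n` and the corresponding
#' multivariate-normal log-likelihood. Coefficient standard errors use
#' the small-sample scale `sigma2 * n / (n - p)` with t-tests on `n - p`
#' degrees of freedom.
#'
#' @param y response vector, aligned to the taxa order of `V`.
#' @param X design matrix (include the intercept column explicitly).
#' @param V positive definite covariance structure.
#' @param lambda optional lambda recorded in the result (bookkeeping
#'   only; the transform must already be applied to `V`).
#' @return Object of class `pgls_fit`: `beta`, `se`, `t`, `p`, `sigma2`,
#'   `loglik`, `n`, `lambda`.
#' @export
gls_fit <- function(y, X, V, lambda = NA_real_) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y)
  if (nrow(X) != n || nrow(V) != n || ncol(V) != n) {
    stop("y, X and V dimensions disagree", call. = FALSE)
  }
  L <- tryCatch(chol(V), error = function(e) {
    stop("covariance matrix V is singular or not positive definite",
         call. = FALSE)
  })
  # whiten: solve L' z = v  <=>  z = L'^-1 v, so z'z = v' V^-1 v
  Xw <- backsolve(L, X, transpose = TRUE)
  yw <- backsolve(L, y, transpose = TRUE)
  XtX <- crossprod(Xw)
  qrX <- qr(XtX)
  if (qrX$rank < ncol(X)) {
    stop("design matrix X is singular", call. = FALSE)
  }
  XtX_inv <- solve(qrX)
  beta <- drop(XtX_inv %*% crossprod(Xw, yw))
  names(beta) <- colnames(X)
  resid_w <- yw - Xw %*% beta
  rss <- drop(crossprod(resid_w))
  sigma2 <- rss / n                      # ML convention
  logdetV <- 2 * sum(log(diag(L)))
  loglik <- if (sigma2 <= 0) {
    # exact fit: density degenerates; report +Inf-free sentinel
    Inf
  } else {
    -0.5 * (n * log(2 * pi) + n * log(sigma2) + logdetV + n)
  }
  p <- ncol(X)
  se <- if (n > p && sigma2 > 0) {
    sqrt(diag(XtX_inv) * sigma2 * n / (n - p))
  } else {
    rep(NA_real_, p)
  }
  t_stat <- beta / se
  p_val <- 2 * stats::pt(-abs(t_stat), df = max(n - p, 1))
  structure(list(beta = beta, se = se, t = t_stat, p = p_val,
                 sigma2 = sigma2, loglik = loglik, n = n,
                 lambda = lambda),
            class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat(sprintf("PGLS fit (n = %d%s): sigma2 = %.4g, logLik = %.4f\n",
              x$n,
              if (is.na(x$lambda)) "" else sprintf(", lambda = %.3f",
                                                   x$lambda),
              x$sigma2, x$loglik))
  tab <- data.frame(estimate = x$beta, se = x$se, t = x$t, p = x$p)
  print(tab, digits = 4)
  invisible(x)
}

#' Phylogenetic GLS with maximum-likelihood Pagel's lambda
#'
#' Profiles the log-likelihood over a lambda grid on \[0, 1\], then
#' refines around the grid argmax by golden-section search. Grid ties
#' and refinements that do not improve the likelihood resolve toward the
#' smaller lambda, so a flat profile (e.g. a star phylogeny, whose
#' off-diagonal covariance is already zero) returns lambda = 0.
#'
#' @param y response vector aligned to the taxa order of `C`.
#' @param X design matrix with intercept column.
#' @param C phylogenetic covariance from [phylo_cov()].
#' @param grid_step lambda grid spacing (default 0.01).
#' @param refine_tol golden-section interval tolerance (default 1e-8).
#' @return A `pgls_fit` at the optimal lambda, with a `profile` element:
#'   data frame of `lambda`, `loglik`, `slope_p` (p-value of the last
#'   non-intercept coefficient, NA for an intercept-only design) over
#'   the grid.
#' @export
optimize_lambda <- function(y, X, C, grid_step = 0.01, refine_tol = 1e-8) {
  X <- as.matrix(X)
  grid <- seq(0, 1, by = grid_step)
  if (abs(grid[length(grid)] - 1) > 1e-12) grid <- c(grid, 1)
  fit_at <- function(l) gls_fit(y, X, lambda_transform(C, l), lambda = l)
  fits <- lapply(grid, fit_at)
  ll <- vapply(fits, `[[`, numeric(1), "loglik")
  if (any(!is.finite(ll))) {
    stop("non-finite log-likelihood on the lambda grid", call. = FALSE)
  }
  slope_p <- vapply(fits, function(f) {
    if (length(f$beta) > 1) unname(f$p[length(f$p)]) else NA_real_
  }, numeric(1))
  profile <- data.frame(lambda = grid, loglik = ll, slope_p = slope_p)

  k <- which.max(ll)  # first maximum -> ties resolve to smaller lambda
  best <- fits[[k]]
  lo <- grid[max(k - 1, 1)]
  hi <- grid[min(k + 1, length(grid))]
  gold <- golden_section_max(function(l) fit_at(l)$loglik, lo, hi,
                             tol = refine_tol)
  # accept refinement only on strict improvement, keeping the
  # tie-toward-zero convention and loglik(hat) >= every grid point
  if (gold$fmax > best$loglik + 1e-9) best <- fit_at(gold$xmax)
  best$profile <- profile
  best
}

# golden-section search for the maximum of f on [lo, hi]
golden_section_max <- function(f, lo, hi, tol = 1e-8) {
  phi <- (sqrt(5) - 1) / 2
  a <- lo
  b <- hi
  x1 <- b - phi * (b - a)
  x2 <- a + phi * (b - a)
  f1 <- f(x1)
  f2 <- f(x2)
  while (b - a > tol) {
    if (f1 >= f2) {
      b <- x2
      x2 <- x1
      f2 <- f1
      x1 <- b - phi * (b - a)
      f1 <- f(x1)
    } else {
      a <- x1
      x1 <- x2
      f1 <- f2
      x2 <- a + phi * (b - a)
      f2 <- f(x2)
    }
  }
  xmax <- if (f1 >= f2) x1 else x2
  list(xmax = xmax, fmax = max(f1, f2))
}
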