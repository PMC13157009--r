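#' Spearman rank correlation with the t-approximation p-value
#'
#' Computes Spearman's rho as the Pearson correlation of average-tie
#' ranks. The default p-value is the two-sided t-approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom,
#' the convention of the common scientific-computing routines for this
#' statistic and the one under which the six-species diversity data give
#' p = 0.019 at rho = 0.886. An exact permutation p-value (all `n!` rank
#' permutations, two-sided by doubling the one-sided tail, capped at 1)
#' is available for n <= 8.
#'
#' @param x,y numeric vectors of equal length, n >= 3, no NAs, neither
#'   constant.
#' @param p_method `"t_approx"` (default) or `"exact_perm"`.
#' @return Object of class `correlation_result`: list with `rho`,
#'   `p_value`, `n`, `p_method`.
#' @examples
#' panel <- six_species_panel()
#' spearman_cor(panel$rbp_family_count, panel$neuron_count)
#' @export
spearman_cor <- function(x, y, p_method = c("t_approx", "exact_perm")) {
  p_method <- match.arg(p_method)
  if (length(x) != length(y)) stop("x and y differ in length",
                                   call. = FALSE)
  n <- length(x)
  if (n < 3) stop("need n >= 3 observations", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("NA values not allowed", call. = FALSE)
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    stop("degenerate input: constant vector, rho undefined", call. = FALSE)
  }
  rx <- rank(x)
  ry <- rank(y)
  rho <- stats::cor(rx, ry)

  if (p_method == "t_approx") {
    if (abs(rho) >= 1 - 1e-15) {
      p <- 0  # limit of the t tail as |rho| -> 1
    } else {
      t_stat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(t_stat), df = n - 2)
    }
  } else {
    if (n > 8) stop("exact_perm supports n <= 8 only", call. = FALSE)
    perms <- .permutations(n)
    # distribution of rho over all permutations of one margin
    perm_rho <- apply(perms, 1, function(p_i) stats::cor(rx, ry[p_i]))
    tail1 <- if (rho >= 0) mean(perm_rho >= rho - 1e-12)
             else mean(perm_rho <= rho + 1e-12)
    p <- min(1, 2 * tail1)
  }
  structure(list(rho = rho, p_value = p, n = n, p_method = p_method),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman rho = %.3f, p = %.3g (n = %d, %s)\n",
              x$rho, x$p_value, x$n, x$p_method))
  invisible(x)
}

# all permutations of 1..n as a matrix (n! rows); n <= 8 keeps this small
.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    block <- matrix(rest[sub], nrow(sub), n - 1L)
    out[row:(row + nrow(sub) - 1L), ] <- cbind(k, block)
    row <- row + nrow(sub)
  }
  out
}

#' Bootstrap resampling of a rank correlation
#'
#' Resamples the n observation pairs with replacement B times and
#' recomputes Spearman's rho for each resample (ranks recomputed within
#' the resample, average ranks for ties). Resamples in which either
#' coordinate is constant leave rho undefined; they are redrawn and
#' counted, so the result always reflects B effective iterations. The
#' resample distribution is discrete for small n; the summary statistics
#' are percentile-based.
#'
#' @param x,y numeric vectors (>= 3 pairs).
#' @param B number of bootstrap iterations (default 10000).
#' @param seed integer seed; mandatory, the run is fully reproducible.
#' @param ci_level two-sided percentile interval coverage (default 0.95).
#' @return Object of class `bootstrap_result`: `median_rho`, `ci_low`,
#'   `ci_high`, `frac_negative`, `n_degenerate`, `B`, `seed`, `rhos`
#'   (the B resample correlations).
#' @export
bootstrap_correlation <- function(x, y, B = 10000, seed, ci_level = 0.95) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("need >= 3 aligned pairs", call. = FALSE)
  }
  if (missing(seed)) stop("seed is required", call. = FALSE)
  stopifnot(B >= 1, ci_level > 0, ci_level < 1)
  n <- length(x)
  set.seed(as.integer(seed))
  rhos <- numeric(B)
  n_degenerate <- 0L
  consecutive <- 0L
  for (b in seq_len(B)) {
    repeat {
      i <- sample.int(n, n, replace = TRUE)
      xb <- x[i]
      yb <- y[i]
      if (length(unique(xb)) > 1 && length(unique(yb)) > 1) {
        consecutive <- 0L
        break
      }
      n_degenerate <- n_degenerate + 1L
      consecutive <- consecutive + 1L
      if (consecutive >= 10L * B) {
        stop("pathological input: ", consecutive,
             " consecutive degenerate resamples", call. = FALSE)
      }
    }
    rhos[b] <- stats::cor(rank(xb), rank(yb))
  }
  alpha <- (1 - ci_level) / 2
  ci <- unname(stats::quantile(rhos, c(alpha, 1 - alpha)))
  structure(list(median_rho = stats::median(rhos),
                 ci_low = ci[1], ci_high = ci[2],
                 frac_negative = mean(rhos < 0),
                 n_degenerate = n_degenerate,
                 B = B, seed = as.integer(seed),
                 ci_level = ci_level, rhos = rhos),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf(paste0("Bootstrap (B = %d, seed = %d): median rho = %.3f, ",
                     "%d%% CI [%.3f, %.3f], %.1f%% negative, ",
                     "%d degenerate redraws\n"),
              x$B, x$seed, x$median_rho, round(100 * x$ci_level),
              x$ci_low, x$ci_high, 100 * x$frac_negative,
              x$n_degenerate))
  invisible(x)
}

#' Leave-one-out rank-correlation validation
#'
#' Recomputes Spearman's rho with each observation excluded in turn,
#' quantifying how much the correlation depends on any single species.
#' Exclusions that leave a constant coordinate yield NA.
#'
#' @param x,y numeric vectors (>= 4 pairs).
#' @param ids optional labels for the exclusions (defaults to indices).
#' @return Named numeric vector: rho with that element excluded.
#' @export
leave_one_out_rho <- function(x, y, ids = NULL) {
  n <- length(x)
  if (length(y) != n || n < 4) stop("need >= 4 aligned pairs",
                                    call. = FALSE)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  out <- vapply(seq_len(n), function(i) {
    xs <- x[-i]
    ys <- y[-i]
    if (length(unique(xs)) < 2 || length(unique(ys)) < 2) {
      return(NA_real_)  # undefined: constant subset
    }
    stats::cor(rank(xs), rank(ys))
  }, numeric(1))
  stats::setNames(out, ids)
}

#' Cohen's d between two correlations via the Fisher z-transform
#'
#' Effect size for the difference of two correlation coefficients
#' estimated on the same n: `d = |atanh(rho_1) - atanh(rho_2)| / se`
#' with `se = sqrt(2 / (n - 3))`. atanh is the variance-stabilizing
#' Fisher z-transform; the statistic is symmetric in its two rho
#' arguments.
#'
#' @param rho_1,rho_2 correlations, strictly inside (-1, 1).
#' @param n common sample size, >= 4.
#' @return Object of class `effect_size`: `d`, `rho_1`, `rho_2`, `n`,
#'   `se`.
#' @examples
#' cohens_d_fisher(0.886, 0.429, 6)  # d = 1.157
#' @export
cohens_d_fisher <- function(rho_1, rho_2, n) {
  if (n < 4) stop("need n >= 4 (se undefined below)", call. = FALSE)
  if (abs(rho_1) >= 1 || abs(rho_2) >= 1) {
    stop("|rho| = 1: Fisher z is infinite", call. = FALSE)
  }
  se <- sqrt(2 / (n - 3))
  d <- abs(atanh(rho_1) - atanh(rho_2)) / se
  structure(list(d = d, rho_1 = rho_1, rho_2 = rho_2, n = n, se = se),
            class = "effect_size")
}

#' @export
print.effect_size <- function(x, ...) {
  cat(sprintf("Cohen's d = %.3f (rho %.3f vs %.3f, n = %d, se = %.3f)\n",
              x$d, x$rho_1, x$rho_2, x$n, x$se))
  invisible(x)
}

#' Per-clade summary of a species-level metric
#'
#' Used e.g. to detect saturation: a clade whose members all share the
#' same value (such as transcription factor families fixed at 72 across
#' vertebrates) has `all_equal = TRUE`.
#'
#' @param values named numeric vector, one value per species.
#' @param clades named character vector mapping every species in
#'   `values` to its clade.
#' @return Data frame with one row per non-empty clade: `clade`, `n`,
#'   `min`, `max`, `mean`, `all_equal`.
#' @export
clade_summary <- function(values, clades) {
  miss <- setdiff(names(values), names(clades))
  if (length(miss) > 0) {
    stop("species without clade label: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  cl <- clades[names(values)]
  out <- do.call(rbind, lapply(sort(unique(cl)), function(k) {
    v <- values[cl == k]
    data.frame(clade = k, n = length(v), min = min(v), max = max(v),
               mean = mean(v), all_equal = min(v) == max(v),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
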