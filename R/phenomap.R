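# Phenotype-map statistics: LOESS-style local linear regression of tumble
# bias over (log10 N_R, log10 N_B), residual-SD surfaces, the global
# log-linear fit and contour-orientation diagnostics.

# nearest-neighbor tricube local degree-1 WLS at query points.
# points: matrix (n x 2) standardized coords; y: response;
# queries: matrix (m x 2) standardized coords.
local_linear_smooth <- function(points, y, queries, k, min_support = 10L) {
  m <- nrow(queries)
  fit <- rep(NA_real_, m)
  support <- logical(m)
  flagged <- logical(m)
  for (q in seq_len(m)) {
    d <- sqrt((points[, 1] - queries[q, 1])^2 +
                (points[, 2] - queries[q, 2])^2)
    nn <- order(d)[seq_len(k)]
    dmax <- d[nn[k]]
    if (k < min_support) next
    w <- if (dmax > 0) (1 - pmin(d[nn] / dmax, 1)^3)^3 else rep(1, k)
    w[w <= 0] <- 1e-12
    X <- cbind(1, points[nn, 1] - queries[q, 1],
               points[nn, 2] - queries[q, 2])
    XtW <- t(X * w)
    fitq <- tryCatch({
      beta <- solve(XtW %*% X, XtW %*% y[nn])
      beta[1]
    }, error = function(e) NA_real_)
    if (is.na(fitq)) {        # collinear neighborhood: local weighted mean
      fitq <- sum(w * y[nn]) / sum(w)
      flagged[q] <- TRUE
    }
    fit[q] <- fitq
    support[q] <- TRUE
  }
  list(fit = fit, support = support, flagged = flagged)
}

standardize_points <- function(logR, logB, center = NULL, scale = NULL) {
  if (is.null(center)) center <- c(mean(logR), mean(logB))
  if (is.null(scale)) {
    scale <- c(stats::sd(logR), stats::sd(logB))
    scale[scale == 0] <- 1
  }
  list(X = cbind((logR - center[1]) / scale[1],
                 (logB - center[2]) / scale[2]),
       center = center, scale = scale)
}

#' Local linear regression surface of tumble bias
#'
#' Classical LOESS smooth (tricube weights over the nearest
#' `bandwidth`-fraction of points, local degree 1) of `TB` over
#' `(log10 N_R, log10 N_B)` on a regular grid spanning the data's bounding
#' box. Distances are Euclidean after standardizing each axis by its SD.
#'
#' @param points A data.frame with columns `N_R`, `N_B`, `tumble_bias` (or
#'   `logR`, `logB` already in log10 units).
#' @param bandwidth Nearest-neighbor fraction (default 0.20).
#' @param grid_n Grid resolution per axis (default 50).
#' @param min_support Minimum neighborhood size for a grid point to be in
#'   the support.
#' @return An object of class `phenotype_map`: `grid_R`, `grid_B` (log10
#'   axes), `value` (matrix, `grid_R` rows x `grid_B` columns),
#'   `support_mask`, `bandwidth`, `n_points`, plus the standardization
#'   record.
#' @export
local_linear_mean <- function(points, bandwidth = 0.20, grid_n = 50,
                              min_support = 10L) {
  pts <- map_points(points)
  n <- nrow(pts)
  if (n < 30) stop("need at least 30 points")
  k <- max(2L, ceiling(bandwidth * n))
  if (k < min_support)
    stop("bandwidth * n must be at least ", min_support, " points")
  std <- standardize_points(pts$logR, pts$logB)
  grid_R <- seq(min(pts$logR), max(pts$logR), length.out = grid_n)
  grid_B <- seq(min(pts$logB), max(pts$logB), length.out = grid_n)
  gq <- as.matrix(expand.grid(logR = grid_R, logB = grid_B))
  Q <- standardize_points(gq[, 1], gq[, 2], std$center, std$scale)$X
  sm <- local_linear_smooth(std$X, pts$y, Q, k, min_support)
  structure(list(grid_R = grid_R, grid_B = grid_B,
                 value = matrix(sm$fit, grid_n, grid_n),
                 support_mask = matrix(sm$support, grid_n, grid_n),
                 n_flagged = sum(sm$flagged),
                 bandwidth = bandwidth, n_points = n,
                 center = std$center, scale = std$scale,
                 kind = "mean"),
            class = "phenotype_map")
}

map_points <- function(points) {
  if (all(c("logR", "logB") %in% names(points))) {
    logR <- points$logR; logB <- points$logB
  } else {
    stopifnot(all(c("N_R", "N_B") %in% names(points)))
    logR <- log10(points$N_R); logB <- log10(points$N_B)
  }
  ycol <- intersect(c("tumble_bias", "tb", "y"), names(points))[1]
  if (is.na(ycol)) stop("no response column (tumble_bias/tb/y)")
  keep <- is.finite(logR) & is.finite(logB) & is.finite(points[[ycol]])
  data.frame(logR = logR[keep], logB = logB[keep], y = points[[ycol]][keep])
}

#' @export
print.phenotype_map <- function(x, ...) {
  cat(sprintf(paste0("<phenotype_map> %s surface, %dx%d grid, bandwidth ",
                     "%.2f, %d points, support %.0f%%\n"),
              x$kind, length(x$grid_R), length(x$grid_B), x$bandwidth,
              x$n_points, 100 * mean(x$support_mask)))
  invisible(x)
}

#' Query a phenotype map by bilinear interpolation
#'
#' @param object A `phenotype_map`.
#' @param N_R,N_B Copy numbers (natural units, not logs).
#' @param ... Unused.
#' @return Interpolated surface values; NA outside the grid/support.
#' @export
predict.phenotype_map <- function(object, N_R, N_B, ...) {
  xq <- log10(N_R); yq <- log10(N_B)
  gx <- object$grid_R; gy <- object$grid_B
  ix <- findInterval(xq, gx, rightmost.closed = TRUE)
  iy <- findInterval(yq, gy, rightmost.closed = TRUE)
  out <- rep(NA_real_, length(xq))
  ok <- ix >= 1 & ix < length(gx) & iy >= 1 & iy < length(gy)
  if (!any(ok)) return(out)
  i <- ix[ok]; j <- iy[ok]
  tx <- (xq[ok] - gx[i]) / (gx[i + 1] - gx[i])
  ty <- (yq[ok] - gy[j]) / (gy[j + 1] - gy[j])
  V <- object$value
  v <- (1 - tx) * (1 - ty) * V[cbind(i, j)] +
    tx * (1 - ty) * V[cbind(i + 1, j)] +
    (1 - tx) * ty * V[cbind(i, j + 1)] +
    tx * ty * V[cbind(i + 1, j + 1)]
  out[ok] <- v
  out
}

#' Residual-SD surface around a mean map
#'
#' Computes residuals `r_i = TB_i - mean_map(point_i)` (the local regression
#' evaluated at each data point), smooths the squared residuals with the
#' same local-linear machinery, and returns `sqrt(max(0, fit))`. Negative
#' fitted variances are clipped to 0 and counted.
#'
#' @inheritParams local_linear_mean
#' @param mean_map The [local_linear_mean()] surface on the same data.
#' @return A `phenotype_map` with `kind = "resid_sd"` and an `n_clipped`
#'   field.
#' @export
local_residual_sd <- function(points, mean_map, bandwidth = 0.20,
                              grid_n = 50, min_support = 10L) {
  pts <- map_points(points)
  n <- nrow(pts)
  k <- max(2L, ceiling(bandwidth * n))
  std <- standardize_points(pts$logR, pts$logB, mean_map$center,
                            mean_map$scale)
  # fitted mean at the data points themselves (same local regression)
  fit_at_pts <- local_linear_smooth(std$X, pts$y, std$X, k, min_support)$fit
  r2 <- (pts$y - fit_at_pts)^2
  gq <- as.matrix(expand.grid(logR = mean_map$grid_R,
                              logB = mean_map$grid_B))
  Q <- standardize_points(gq[, 1], gq[, 2], mean_map$center,
                          mean_map$scale)$X
  sm <- local_linear_smooth(std$X, r2, Q, k, min_support)
  n_clipped <- sum(sm$fit < 0, na.rm = TRUE)
  gn_R <- length(mean_map$grid_R); gn_B <- length(mean_map$grid_B)
  structure(list(grid_R = mean_map$grid_R, grid_B = mean_map$grid_B,
                 value = matrix(sqrt(pmax(sm$fit, 0)), gn_R, gn_B),
                 support_mask = matrix(sm$support, gn_R, gn_B),
                 n_flagged = sum(sm$flagged), n_clipped = n_clipped,
                 bandwidth = bandwidth, n_points = n,
                 center = mean_map$center, scale = mean_map$scale,
                 kind = "resid_sd"),
            class = "phenotype_map")
}

#' Global log-linear fit of tumble bias to protein numbers
#'
#' Nonlinear least squares of
#' `TB = a + b * (log10 N_R - c * log10 N_B)`, i.e.
#' `TB = a + b * log10(N_R / N_B^c)`, with confidence intervals by
#' nonparametric bootstrap over cells.
#'
#' @param points Data.frame with `N_R`, `N_B`, `tumble_bias`.
#' @param n_boot Bootstrap resamples (default 2000).
#' @param level CI level.
#' @param seed Bootstrap seed.
#' @return A list of class `loglinear_fit`: `a`, `b`, `c`, `ci` (matrix),
#'   `n_cells`.
#' @export
fit_loglinear <- function(points, n_boot = 2000, level = 0.95, seed = 1L) {
  pts <- map_points(points)
  if (stats::sd(pts$logB) < 1e-8)
    stop("c is not identifiable: N_B has no spread")
  fit1 <- function(d) {
    # profile out (a, b) by OLS at fixed c; 1-D optimize over c
    sse <- function(cc) {
      x <- d$logR - cc * d$logB
      r <- stats::lm.fit(cbind(1, x), d$y)$residuals
      sum(r^2)
    }
    copt <- stats::optimize(sse, c(-5, 10), tol = 1e-9)$minimum
    x <- d$logR - copt * d$logB
    cf <- stats::lm.fit(cbind(1, x), d$y)$coefficients
    c(a = unname(cf[1]), b = unname(cf[2]), c = copt)
  }
  est <- fit1(pts)
  ci <- NULL
  if (n_boot > 0) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old))
      assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    bs <- matrix(NA_real_, n_boot, 3)
    n <- nrow(pts)
    for (b in seq_len(n_boot))
      bs[b, ] <- fit1(pts[sample.int(n, n, replace = TRUE), ])
    alpha <- (1 - level) / 2
    ci <- t(apply(bs, 2, stats::quantile, c(alpha, 1 - alpha), na.rm = TRUE))
    rownames(ci) <- c("a", "b", "c")
  }
  structure(list(a = est[["a"]], b = est[["b"]], c = est[["c"]], ci = ci,
                 n_cells = nrow(pts), n_boot = n_boot),
            class = "loglinear_fit")
}

#' @export
print.loglinear_fit <- function(x, ...) {
  cat(sprintf("<loglinear_fit> TB = %.4f + %.4f * log10(N_R / N_B^%.3f)\n",
              x$a, x$b, x$c))
  if (!is.null(x$ci)) {
    cat("  95% bootstrap CIs:\n")
    for (pm in rownames(x$ci))
      cat(sprintf("    %s: [%.4f, %.4f]\n", pm, x$ci[pm, 1], x$ci[pm, 2]))
  }
  invisible(x)
}

#' Contour orientation of a phenotype map
#'
#' Finite-difference gradient angles over the support, summarized as an
#' axial circular mean (angles mod 180 degrees, doubled-angle averaging)
#' with a dispersion measure (mean resultant length).
#'
#' @param map A `phenotype_map`.
#' @return A list of class `map_orientation`: `mean_angle_deg` (gradient
#'   direction in (-90, 90], measured from the +log10 N_R axis),
#'   `dispersion` (1 = perfectly aligned), `n_used`.
#' @export
contour_orientation <- function(map) {
  V <- map$value
  M <- map$support_mask
  nx <- length(map$grid_R); ny <- length(map$grid_B)
  hx <- diff(map$grid_R[1:2]); hy <- diff(map$grid_B[1:2])
  ang <- c()
  for (i in 2:(nx - 1)) for (j in 2:(ny - 1)) {
    if (!all(M[(i - 1):(i + 1), j]) || !all(M[i, (j - 1):(j + 1)])) next
    gx <- (V[i + 1, j] - V[i - 1, j]) / (2 * hx)
    gy <- (V[i, j + 1] - V[i, j - 1]) / (2 * hy)
    if (gx == 0 && gy == 0) next
    ang <- c(ang, atan2(gy, gx))
  }
  if (!length(ang)) stop("empty support: no gradient angles")
  s <- mean(sin(2 * ang)); cmean <- mean(cos(2 * ang))
  mean2 <- atan2(s, cmean)
  structure(list(mean_angle_deg = mean2 / 2 * 180 / pi,
                 dispersion = sqrt(s^2 + cmean^2), n_used = length(ang)),
            class = "map_orientation")
}

#' Angular separation between two map orientations (degrees, 0-90)
#'
#' @param o1,o2 [contour_orientation()] results (or `phenotype_map`s).
#' @return Axial angular separation in degrees.
#' @export
orientation_separation <- function(o1, o2) {
  if (inherits(o1, "phenotype_map")) o1 <- contour_orientation(o1)
  if (inherits(o2, "phenotype_map")) o2 <- contour_orientation(o2)
  d <- abs(o1$mean_angle_deg - o2$mean_angle_deg) %% 180
  min(d, 180 - d)
}
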