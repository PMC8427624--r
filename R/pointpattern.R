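#' Planar point pattern with an observation window
#'
#' Coordinates are assumed locally projected (metres). The window may be a
#' rectangle `c(xmin, xmax, ymin, ymax)` or a polygon given as a two-column
#' matrix of vertices (closed implicitly). Marks, when present, are per-point
#' mussel densities (ind/m^2) and must be nonnegative.
#'
#' @param x,y point coordinates (m).
#' @param marks optional nonnegative per-point marks.
#' @param window rectangle `c(xmin, xmax, ymin, ymax)` or polygon vertex
#'   matrix; defaults to the bounding box of the points.
#' @return object of class `river_ppp`.
#' @export
point_pattern <- function(x, y, marks = NULL, window = NULL) {
  if (length(x) != length(y)) stop_invalid("x and y lengths differ")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop_invalid("non-finite coordinates")
  if (!is.null(marks)) {
    if (length(marks) != length(x)) stop_invalid("marks must match points")
    if (any(!is.finite(marks)) || any(marks < 0)) stop_invalid("marks must be >= 0")
  }
  if (is.null(window)) window <- c(range(x), range(y))
  win <- as_window(window)
  if (!all(window_contains(win, x, y)))
    stop_invalid("all points must lie inside the window")
  structure(list(x = as.numeric(x), y = as.numeric(y), marks = marks,
                 window = win), class = "river_ppp")
}

#' @export
print.river_ppp <- function(x, ...) {
  cat("Planar point pattern: ", length(x$x), " points",
      if (!is.null(x$marks)) " (marked)", "\n", sep = "")
  cat("  window area ", signif(x$window$area, 5), " m^2\n", sep = "")
  invisible(x)
}

as_window <- function(window) {
  if (is.matrix(window)) {
    if (ncol(window) != 2 || nrow(window) < 3)
      stop_invalid("polygon window needs a 2-column matrix of >= 3 vertices")
    a <- polygon_area(window[, 1], window[, 2])
    if (a <= 0) stop_invalid("window area must be > 0")
    list(type = "polygon", vertices = window, area = a,
         bbox = c(range(window[, 1]), range(window[, 2])))
  } else {
    if (length(window) != 4 || window[2] <= window[1] || window[4] <= window[3])
      stop_invalid("rectangle window must be c(xmin, xmax, ymin, ymax) with positive extent")
    list(type = "rectangle", bbox = as.numeric(window),
         area = (window[2] - window[1]) * (window[4] - window[3]))
  }
}

polygon_area <- function(px, py) {
  n <- length(px)
  j <- c(n, seq_len(n - 1))
  abs(sum(px[j] * py - px * py[j])) / 2
}

window_contains <- function(win, x, y) {
  b <- win$bbox
  inside <- x >= b[1] & x <= b[2] & y >= b[3] & y <= b[4]
  if (win$type == "polygon") {
    vx <- win$vertices[, 1]; vy <- win$vertices[, 2]
    n <- length(vx); j <- c(n, seq_len(n - 1))
    for (i in which(inside)) {
      crossings <- (vy > y[i]) != (vy[j] > y[i]) &
        (x[i] < (vx[j] - vx) * (y[i] - vy) / (vy[j] - vy) + vx)
      # points exactly on an edge count as inside via <= tolerance fallback
      inside[i] <- sum(crossings) %% 2 == 1 ||
        any(abs((vx - x[i])^2 + (vy - y[i])^2) < 1e-18)
    }
  }
  inside
}

window_sample <- function(win, n) {
  b <- win$bbox
  if (win$type == "rectangle") {
    return(cbind(runif(n, b[1], b[2]), runif(n, b[3], b[4])))
  }
  out <- matrix(NA_real_, 0, 2)
  while (nrow(out) < n) {
    m <- max(2 * (n - nrow(out)), 16)
    cand <- cbind(runif(m, b[1], b[2]), runif(m, b[3], b[4]))
    keep <- window_contains(win, cand[, 1], cand[, 2])
    out <- rbind(out, cand[keep, , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

#' Kernel-smoothed intensity surface
#'
#' Isotropic Gaussian kernel sum over the points (mark-weighted when marks are
#' present) evaluated on a regular grid, with uniform (Diggle) edge
#' correction: each cell's value is divided by the kernel mass lying inside
#' the window when the kernel is centred at that cell. With edge correction
#' the surface integrates to the number of points (or total mark sum) up to
#' discretization error. Cells outside a polygon window are `NA`.
#'
#' @param pattern a [point_pattern()].
#' @param sigma Gaussian bandwidth (m), positive.
#' @param dimyx grid cells per axis (single integer or `c(ny, nx)`).
#' @param edge apply the edge correction (default TRUE).
#' @return object of class `intensity_surface`: list with `xcol`, `yrow`
#'   (cell-centre coordinates), `values` (ny x nx matrix), `sigma`,
#'   `cell_area`.
#' @export
kernel_intensity <- function(pattern, sigma, dimyx = 128, edge = TRUE) {
  stopifnot(inherits(pattern, "river_ppp"))
  if (!is.finite(sigma) || sigma <= 0) stop_invalid("sigma must be > 0")
  if (length(dimyx) == 1) dimyx <- c(dimyx, dimyx)
  b <- pattern$window$bbox
  nx <- dimyx[2]; ny <- dimyx[1]
  dx <- (b[2] - b[1]) / nx; dy <- (b[4] - b[3]) / ny
  xcol <- b[1] + (seq_len(nx) - 0.5) * dx
  yrow <- b[3] + (seq_len(ny) - 0.5) * dy
  cx <- rep(xcol, each = ny); cy <- rep(yrow, times = nx)
  w <- if (is.null(pattern$marks)) rep(1, length(pattern$x)) else pattern$marks
  vals <- gauss_sum(cx, cy, pattern$x, pattern$y, w, sigma)
  if (edge) {
    if (pattern$window$type == "rectangle") {
      ex <- (pnorm(b[2], cx, sigma) - pnorm(b[1], cx, sigma))
      ey <- (pnorm(b[4], cy, sigma) - pnorm(b[3], cy, sigma))
      vals <- vals / (ex * ey)
    } else {
      # discrete kernel mass inside the polygon, cell-to-cell
      inside <- window_contains(pattern$window, cx, cy)
      mass <- gauss_cross_mass(cx, cy, cx[inside], cy[inside], sigma) *
        (dx * dy)
      vals <- vals / pmax(mass, 1e-12)
      vals[!inside] <- NA_real_
    }
  } else if (pattern$window$type == "polygon") {
    vals[!window_contains(pattern$window, cx, cy)] <- NA_real_
  }
  structure(list(xcol = xcol, yrow = yrow,
                 values = matrix(vals, nrow = ny, ncol = nx),
                 sigma = sigma, cell_area = dx * dy,
                 window = pattern$window),
            class = "intensity_surface")
}

# kernel mass at (cx, cy) integrated over target cells (tx, ty): one Gaussian
# evaluation per (centre, target) pair
gauss_cross_mass <- function(cx, cy, tx, ty, sigma) {
  vapply(seq_along(cx), function(i) {
    sum(exp(-((cx[i] - tx)^2 + (cy[i] - ty)^2) / (2 * sigma^2))) /
      (2 * pi * sigma^2)
  }, numeric(1))
}

#' Integral of an intensity surface over its window
#' @param surface an [kernel_intensity()] result.
#' @return total mass (points or mark sum, when edge-corrected).
#' @export
surface_integral <- function(surface) {
  sum(surface$values, na.rm = TRUE) * surface$cell_area
}

#' Bandwidth selection by the Berman-Diggle mean-squared-error criterion
#'
#' Evaluates, on a grid of candidate bandwidths, the mean-squared-error
#' criterion for the Gaussian kernel intensity estimator of a stationary
#' (Cox) process,
#' \deqn{M(\sigma) = \hat\lambda/(4\pi\sigma^2) +
#'   a^{-1} \sum_{i \ne j} [ k_{\sigma\sqrt2}(d_{ij}) - 2 k_\sigma(d_{ij}) ]}
#' where \eqn{k_s(d) = \exp(-d^2/(2s^2))/(2\pi s^2)}, \eqn{a} is the window
#' area and \eqn{\hat\lambda = n/a}. The first term is the integrated squared
#' kernel (estimation variance); the pair sum estimates the smoothing-bias
#' terms through the pair-correlation structure. No edge correction is
#' applied to the pair distances (documented limitation). Ties are broken by
#' the smallest bandwidth.
#'
#' @param pattern a [point_pattern()] with at least 2 points.
#' @param sigmas positive candidate bandwidths (m).
#' @return list with `sigma` (the argmin), `criterion` (data frame of
#'   `sigma`, `M`).
#' @export
bandwidth_cv <- function(pattern, sigmas) {
  stopifnot(inherits(pattern, "river_ppp"))
  if (length(pattern$x) < 2) stop_invalid("criterion undefined for < 2 points")
  if (!length(sigmas) || any(!is.finite(sigmas)) || any(sigmas <= 0))
    stop_invalid("sigma grid must be nonempty and positive")
  sigmas <- sort(sigmas)
  a <- pattern$window$area
  n <- length(pattern$x)
  M <- (n / a) / (4 * pi * sigmas^2) +
    pair_kernel_contrast(pattern$x, pattern$y, sigmas) / a
  list(sigma = sigmas[which.min(M)],
       criterion = data.frame(sigma = sigmas, M = M))
}

#' Hopkins-Skellam clustering test
#'
#' Statistic `A = sum(event nearest-neighbour distance^2) / sum(empty-space
#' distance^2)`, where the empty-space distances run from `n` uniform random
#' test locations in the window to their nearest event. `A < 1` indicates
#' clustering and `A > 1` regularity. The p-value is two-sided: by
#' Monte-Carlo rank of `A` against `nsim` simulations of complete spatial
#' randomness (CSR) with the same `n` and window (default), or from the
#' F(2n, 2n) reference distribution (`method = "analytic"`; fragile in small
#' windows because edge effects distort the reference).
#'
#' @param pattern a [point_pattern()] with >= 2 points.
#' @param seed integer seed (test locations and CSR simulations).
#' @param nsim CSR simulations for the Monte-Carlo p-value (>= 19).
#' @param method `"monte_carlo"` (default) or `"analytic"`.
#' @return list of class `hopkins_skellam` with `A`, `p_value`, `n_points`,
#'   `method`, `seed`.
#' @export
hopkins_skellam <- function(pattern, seed = 1, nsim = 999,
                            method = c("monte_carlo", "analytic")) {
  stopifnot(inherits(pattern, "river_ppp"))
  method <- match.arg(method)
  n <- length(pattern$x)
  if (n < 2) stop_invalid("need >= 2 points")
  if (method == "monte_carlo" && nsim < 19)
    stop_invalid("nsim must be >= 19 for a usable Monte-Carlo p-value")
  set.seed(derive_seed(seed, "hopskel"))
  A <- hs_statistic(pattern$x, pattern$y, pattern$window)
  if (method == "analytic") {
    p <- 2 * min(pf(A, 2 * n, 2 * n), 1 - pf(A, 2 * n, 2 * n))
  } else {
    Asim <- vapply(seq_len(nsim), function(s) {
      pts <- window_sample(pattern$window, n)
      hs_statistic(pts[, 1], pts[, 2], pattern$window)
    }, numeric(1))
    p_lo <- (1 + sum(Asim <= A)) / (nsim + 1)
    p_hi <- (1 + sum(Asim >= A)) / (nsim + 1)
    p <- min(1, 2 * min(p_lo, p_hi))
  }
  structure(list(A = A, p_value = p, n_points = n, method = method,
                 seed = seed),
            class = "hopkins_skellam")
}

hs_statistic <- function(x, y, win) {
  n <- length(x)
  nn <- nn_dist(x, y)
  rnd <- window_sample(win, n)
  es <- cross_min_dist(rnd[, 1], rnd[, 2], x, y)
  sum(nn^2) / sum(es^2)
}

#' @export
print.hopkins_skellam <- function(x, ...) {
  cat("Hopkins-Skellam test: A = ", signif(x$A, 4),
      ", p = ", signif(x$p_value, 3), " (", x$method, ", n = ", x$n_points,
      ")\n", sep = "")
  cat("  A < 1 suggests clustering, A > 1 regularity\n")
  invisible(x)
}

#' Simulate complete spatial randomness
#' @param n number of points.
#' @param window rectangle or polygon as in [point_pattern()].
#' @param seed optional integer seed.
#' @return a [point_pattern()].
#' @export
simulate_csr <- function(n, window, seed = NULL) {
  if (!is.null(seed)) set.seed(derive_seed(seed, "csr"))
  win <- as_window(window)
  pts <- window_sample(win, n)
  point_pattern(pts[, 1], pts[, 2], window = window)
}

#' Simulate a Thomas cluster process
#'
#' Poisson(kappa * area) parents uniform in the window; each parent gets a
#' Poisson(mu) number of offspring displaced by isotropic Gaussian(scale)
#' jitter; offspring falling outside the window are discarded.
#'
#' @param kappa parent intensity (per m^2).
#' @param mu mean offspring per parent.
#' @param scale offspring dispersion (m).
#' @param window rectangle or polygon.
#' @param seed optional integer seed.
#' @return a [point_pattern()] (may have few points if kappa*mu*area is small).
#' @export
simulate_thomas <- function(kappa, mu, scale, window, seed = NULL) {
  if (!is.null(seed)) set.seed(derive_seed(seed, "thomas"))
  win <- as_window(window)
  nparents <- rpois(1, kappa * win$area)
  parents <- window_sample(win, max(nparents, 1))[seq_len(max(nparents, 0)), , drop = FALSE]
  xs <- ys <- numeric(0)
  for (i in seq_len(nrow(parents))) {
    k <- rpois(1, mu)
    if (k > 0) {
      xs <- c(xs, parents[i, 1] + rnorm(k, 0, scale))
      ys <- c(ys, parents[i, 2] + rnorm(k, 0, scale))
    }
  }
  keep <- window_contains(win, xs, ys)
  point_pattern(xs[keep], ys[keep], window = window)
}

#' Write an intensity surface as an ESRI ASCII grid
#' @param surface a [kernel_intensity()] result.
#' @param path output file.
#' @export
write_surface_asc <- function(surface, path) {
  v <- surface$values
  v[is.na(v)] <- -9999
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", ncol(v)),
               paste("nrows", nrow(v)),
               paste("xllcorner", surface$xcol[1] - diff(surface$xcol[1:2]) / 2),
               paste("yllcorner", surface$yrow[1] - diff(surface$yrow[1:2]) / 2),
               paste("cellsize", signif(diff(surface$xcol[1:2]), 12)),
               "NODATA_value -9999"), con)
  # ESRI grids are written top row first
  for (i in rev(seq_len(nrow(v))))
    writeLines(paste(signif(v[i, ], 8), collapse = " "), con)
}
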