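# 1-D Akima interpolation: local cubic Hermite with Akima's slope rule.
# Linear data reproduce exactly (the slope rule degenerates to the
# common difference) and overshoot near outliers is suppressed, which
# is why this scheme suits response surfaces sampled on coarse grids.

akima_slopes <- function(x, y) {
  n <- length(x)
  d <- diff(y) / diff(x)
  # linear extrapolation of the divided differences past both ends
  d_ext <- numeric(n + 3)
  d_ext[3:(n + 1)] <- d
  d_ext[2] <- 2 * d[1] - d[2]
  d_ext[1] <- 2 * d_ext[2] - d[1]
  d_ext[n + 2] <- 2 * d[n - 1] - d[n - 2]
  d_ext[n + 3] <- 2 * d_ext[n + 2] - d[n - 1]
  m <- numeric(n)
  for (i in seq_len(n)) {
    dm2 <- d_ext[i]; dm1 <- d_ext[i + 1]
    dp1 <- d_ext[i + 2]; dp2 <- d_ext[i + 3]
    w1 <- abs(dp2 - dp1)
    w2 <- abs(dm1 - dm2)
    m[i] <- if (w1 + w2 > 0) (w1 * dm1 + w2 * dp1) / (w1 + w2)
    else (dm1 + dp1) / 2
  }
  m
}

akima_eval <- function(x, y, m, xout) {
  i <- findInterval(xout, x, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), length(x) - 1L)
  h <- x[i + 1] - x[i]
  t <- (xout - x[i]) / h
  h00 <- (1 + 2 * t) * (1 - t)^2
  h10 <- t * (1 - t)^2
  h01 <- t^2 * (3 - 2 * t)
  h11 <- t^2 * (t - 1)
  h00 * y[i] + h10 * h * m[i] + h01 * y[i + 1] + h11 * h * m[i + 1]
}

akima_interp1 <- function(x, y, xout) {
  if (length(x) == 2) {
    return(y[1] + (xout - x[1]) * (y[2] - y[1]) / (x[2] - x[1]))
  }
  akima_eval(x, y, akima_slopes(x, y), xout)
}

spline_interp1 <- function(x, y, xout) {
  stats::splinefun(x, y, method = "natural")(xout)
}

#' Interpolate a response surface
#'
#' Builds a continuous interpolant `f(x, y)` of a response surface
#' sampled on a rectilinear grid, by a tensor product of 1-D Akima
#' local splines (overshoot-resistant, continuous first derivatives in
#' the interior, exact at the grid nodes, exact for planar data).
#' `method = "spline"` switches to tensor natural cubic splines.
#'
#' @param surface Either a long tibble with columns `scale_v`,
#'   `scale_j` and a value column, or a numeric matrix with `x` and `y`
#'   supplied separately.
#' @param value Name of the value column when `surface` is a tibble
#'   (default `"relchange"`).
#' @param x,y Grid coordinates when `surface` is a matrix
#'   (`surface[i, j]` is the value at `(x[i], y[j])`).
#' @param method `"akima"` (default) or `"spline"`.
#' @return A function `f(x, y)` returning the interpolated value;
#'   evaluation outside the grid hull is an error. The grid ranges are
#'   attached as attribute `"hull"`.
#' @examples
#' z <- outer(1:5, 1:5, function(a, b) a + 2 * b)
#' f <- interpolate_surface(z, x = 1:5, y = 1:5)
#' f(2.5, 3.25)  # 9 (planar data reproduce exactly)
#' @export
interpolate_surface <- function(surface, value = "relchange",
                                x = NULL, y = NULL,
                                method = c("akima", "spline")) {
  method <- match.arg(method)
  if (is.matrix(surface)) {
    stopifnot(!is.null(x), !is.null(y))
    z <- surface
  } else {
    df <- as.data.frame(surface)
    stopifnot(all(c("scale_v", "scale_j", value) %in% names(df)))
    x <- sort(unique(df$scale_v))
    y <- sort(unique(df$scale_j))
    z <- matrix(NA_real_, length(x), length(y))
    z[cbind(match(df$scale_v, x), match(df$scale_j, y))] <- df[[value]]
    if (anyNA(z)) stop("surface grid is incomplete", call. = FALSE)
  }
  if (length(x) < 2 || length(y) < 2) {
    stop("surface needs at least a 2x2 grid", call. = FALSE)
  }
  interp1 <- if (method == "akima") akima_interp1 else spline_interp1
  hull <- list(x = range(x), y = range(y))
  f <- function(px, py) {
    if (px < hull$x[1] - 1e-12 || px > hull$x[2] + 1e-12 ||
        py < hull$y[1] - 1e-12 || py > hull$y[2] + 1e-12) {
      stop(sprintf("evaluation point (%g, %g) outside the surface hull",
                   px, py), call. = FALSE)
    }
    col_vals <- vapply(seq_along(y), function(jj) {
      interp1(x, z[, jj], px)
    }, numeric(1))
    interp1(y, col_vals, py)
  }
  attr(f, "hull") <- hull
  f
}

#' Central-difference gradient of a surface function
#'
#' Symmetric finite differences
#' `(f(x + h, y) - f(x - h, y)) / (2h)` and likewise in `y`; exact for
#' linear `f` and O(h^2) accurate on smooth functions.
#'
#' @param f A function `f(x, y)`, e.g. from [interpolate_surface()].
#' @param x,y Evaluation point; `(x - h, x + h)` (and same for `y`)
#'   must lie inside the hull.
#' @param h Finite-difference step.
#' @return Numeric `c(dfdx, dfdy)`.
#' @export
gradient <- function(f, x, y, h = 0.01) {
  c((f(x + h, y) - f(x - h, y)) / (2 * h),
    (f(x, y + h) - f(x, y - h)) / (2 * h))
}

#' Steepest gradient path on a response surface
#'
#' Iterates `X[n+1] = X[n] +/- alpha * grad f(X[n])` (plus for ascent,
#' minus for descent) from a start point, recording the visited points
#' until the gradient norm drops below `stop_tol`, the path would leave
#' the interpolation hull, or `max_steps` is reached.
#'
#' @param f Surface function from [interpolate_surface()] (its
#'   `"hull"` attribute bounds the path).
#' @param start Numeric `c(x, y)` inside the hull.
#' @param alpha Step-size factor.
#' @param direction `"ascend"` or `"descend"`.
#' @param max_steps Iteration cap.
#' @param stop_tol Gradient-norm stopping threshold.
#' @param h Finite-difference step for [gradient()].
#' @return An object of class `gradient_path`: list with `points` (a
#'   tibble `step`, `x`, `y`, `value`), `alpha`, `h`, `direction` and
#'   `termination` (`"gradient_below_tol"`, `"hull_exit"` or
#'   `"max_steps"`).
#' @export
steepest_path <- function(f, start, alpha = 0.001,
                          direction = c("ascend", "descend"),
                          max_steps = 2000, stop_tol = 1e-3, h = 0.01) {
  direction <- match.arg(direction)
  hull <- attr(f, "hull")
  if (is.null(hull)) stop("`f` lacks a hull attribute", call. = FALSE)
  inside <- function(p, margin = 0) {
    p[1] >= hull$x[1] + margin && p[1] <= hull$x[2] - margin &&
      p[2] >= hull$y[1] + margin && p[2] <= hull$y[2] - margin
  }
  if (!inside(start)) stop("start point outside the hull", call. = FALSE)
  sgn <- if (direction == "ascend") 1 else -1
  pts <- matrix(NA_real_, max_steps + 1, 3)
  p <- start
  pts[1, ] <- c(p, f(p[1], p[2]))
  termination <- "max_steps"
  n_pts <- 1
  for (s in seq_len(max_steps)) {
    if (!inside(p, margin = h)) {
      termination <- "hull_exit"
      break
    }
    g <- gradient(f, p[1], p[2], h)
    if (sqrt(sum(g^2)) < stop_tol) {
      termination <- "gradient_below_tol"
      break
    }
    p_new <- p + sgn * alpha * g
    if (!inside(p_new)) {
      termination <- "hull_exit"
      break
    }
    p <- p_new
    n_pts <- n_pts + 1
    pts[n_pts, ] <- c(p, f(p[1], p[2]))
  }
  structure(list(
    points = tibble::tibble(step = seq_len(n_pts) - 1L,
                            x = pts[seq_len(n_pts), 1],
                            y = pts[seq_len(n_pts), 2],
                            value = pts[seq_len(n_pts), 3]),
    alpha = alpha, h = h, direction = direction, termination = termination
  ), class = "gradient_path")
}

#' @export
print.gradient_path <- function(x, ...) {
  p <- x$points
  cat(sprintf(paste0("<gradient_path> %s, %d step(s), alpha %g, ",
                     "terminated: %s\n  from (%.3f, %.3f) value %.3f ",
                     "to (%.3f, %.3f) value %.3f\n"),
              x$direction, nrow(p) - 1, x$alpha, x$termination,
              p$x[1], p$y[1], p$value[1],
              p$x[nrow(p)], p$y[nrow(p)], p$value[nrow(p)]))
  invisible(x)
}
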