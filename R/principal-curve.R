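# Principal-curve fitting (Hastie-Stuetzle projection/smoothing iteration).
#
# The curve is represented as a polyline through the smoothed sample points
# ordered by arc length.  Each iteration alternates (i) orthogonal projection
# of every data point onto the current polyline, yielding an arc-length
# parameter per point, and (ii) scatterplot smoothing of every coordinate
# against arc length.  The iteration starts from the first principal
# component and stops when the mean squared projection distance stabilises.

#' Fit a principal curve to a point cloud
#'
#' @param points numeric matrix, one row per observation (n >= 5), no missing
#'   values.
#' @param max_iter maximum projection/smoothing iterations; `0` returns the
#'   first-principal-component initialisation (arc length affine in the PC1
#'   score).
#' @param tol convergence tolerance on the change in mean squared projection
#'   distance between iterations.
#' @param span smoother span as a fraction of points (passed to
#'   [stats::lowess()]).
#' @return object of class `principal_curve_fit` with elements
#'   `s` (ordered curve points), `lambda` (per-observation arc length, input
#'   order), `order` (observation order along the curve), `dist2`
#'   (per-observation squared projection distance), `length` (total curve
#'   length), `converged`, `iterations`.
#' @export
fit_principal_curve <- function(points, max_iter = 50, tol = 1e-4, span = 0.3) {
  points <- as.matrix(points)
  if (nrow(points) < 5) stop("insufficient points: need at least 5", call. = FALSE)
  if (anyNA(points)) stop("points contain missing values", call. = FALSE)
  if (all(abs(sweep(points, 2, points[1, ], `-`)) < .Machine$double.eps^0.5)) {
    stop("zero variance: all points identical", call. = FALSE)
  }
  n <- nrow(points)
  d <- ncol(points)

  ctr <- colMeans(points)
  x <- sweep(points, 2, ctr, `-`)
  sv <- svd(x, nu = 0, nv = 1)
  lambda <- drop(x %*% sv$v[, 1])

  make_curve <- function(lambda) {
    ord <- order(lambda, seq_len(n))
    lam_s <- lambda[ord]
    s <- matrix(0, n, d)
    for (j in seq_len(d)) {
      s[, j] <- stats::lowess(lam_s, x[ord, j], f = span, iter = 0)$y
    }
    list(s = s, ord = ord)
  }

  # Initial curve: orthogonal projections onto the PC1 line, ordered by score.
  ord <- order(lambda, seq_len(n))
  s <- (lambda %*% t(sv$v[, 1]))[ord, , drop = FALSE]
  proj <- project_to_polyline(x, s)
  lambda <- proj$lambda
  dist2 <- proj$dist2
  d_prev <- mean(dist2)
  converged <- max_iter == 0
  iter <- 0L

  while (iter < max_iter) {
    iter <- iter + 1L
    cur <- make_curve(lambda)
    proj <- project_to_polyline(x, cur$s)
    lambda <- proj$lambda
    dist2 <- proj$dist2
    s <- cur$s
    ord <- cur$ord
    d_cur <- mean(dist2)
    if (abs(d_prev - d_cur) < tol) {
      converged <- TRUE
      break
    }
    d_prev <- d_cur
  }

  structure(
    list(
      s = sweep(s, 2, ctr, `+`),
      lambda = lambda,
      order = ord,
      dist2 = dist2,
      length = polyline_length(s),
      converged = converged,
      iterations = iter
    ),
    class = "principal_curve_fit"
  )
}

#' Project points onto a polyline
#'
#' Orthogonal projection of each row of `x` onto the nearest point of the
#' polyline through the rows of `vertices` (in order).  Vectorised over
#' segments; used both by the fitter and as the dense-grid oracle in tests.
#'
#' @param x numeric matrix of points (n x d).
#' @param vertices numeric matrix of polyline vertices (m x d, m >= 2 after
#'   duplicate removal; a degenerate single-vertex polyline maps everything
#'   to that vertex).
#' @return list with `lambda` (arc length of the projection foot per point)
#'   and `dist2` (squared distance to the polyline).
#' @export
project_to_polyline <- function(x, vertices) {
  x <- as.matrix(x)
  v <- as.matrix(vertices)
  keep <- c(TRUE, rowSums((v[-1, , drop = FALSE] - v[-nrow(v), , drop = FALSE])^2) > 0)
  v <- v[keep, , drop = FALSE]
  n <- nrow(x)
  m <- nrow(v)
  if (m == 1L) {
    return(list(
      lambda = rep(0, n),
      dist2 = rowSums(sweep(x, 2, v[1, ], `-`)^2)
    ))
  }
  a <- v[-m, , drop = FALSE]
  b <- v[-1, , drop = FALSE]
  dif <- b - a
  seg_l2 <- rowSums(dif^2)
  seg_len <- sqrt(seg_l2)
  cum0 <- c(0, cumsum(seg_len))[seq_len(m - 1L)]

  # t (n x m-1): position of the orthogonal foot along each segment, clamped
  tmat <- (x %*% t(dif) - matrix(rowSums(a * dif), n, m - 1L, byrow = TRUE)) /
    matrix(seg_l2, n, m - 1L, byrow = TRUE)
  tmat[tmat < 0] <- 0
  tmat[tmat > 1] <- 1

  # squared distance to the clamped foot on each segment
  xx <- rowSums(x^2)
  d2 <- xx - 2 * (x %*% t(a)) - 2 * tmat * (x %*% t(dif)) +
    matrix(rowSums(a^2), n, m - 1L, byrow = TRUE) +
    2 * tmat * matrix(rowSums(a * dif), n, m - 1L, byrow = TRUE) +
    tmat^2 * matrix(seg_l2, n, m - 1L, byrow = TRUE)
  d2[d2 < 0] <- 0

  best <- max.col(-d2, ties.method = "first")
  idx <- cbind(seq_len(n), best)
  list(
    lambda = cum0[best] + tmat[idx] * seg_len[best],
    dist2 = d2[idx]
  )
}

polyline_length <- function(v) {
  if (nrow(v) < 2) return(0)
  sum(sqrt(rowSums((v[-1, , drop = FALSE] - v[-nrow(v), , drop = FALSE])^2)))
}
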