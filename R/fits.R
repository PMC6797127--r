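# Least-squares geometric fits used across the pipeline.

normalize3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalize zero vector", call. = FALSE)
  v / n
}

#' Least-squares plane fit
#' @param points n x 3 matrix, n >= 3.
#' @return list with `point` (centroid) and unit `normal` (smallest principal
#'   direction).
#' @export
fit_plane <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3) stop("plane fit needs >= 3 points", call. = FALSE)
  cen <- colMeans(points)
  sv <- svd(sweep(points, 2, cen))
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1))
    stop("plane fit degenerate: points are collinear", call. = FALSE)
  list(point = cen, normal = sv$v[, 3])
}

#' Linear least-squares sphere fit
#'
#' Solves the algebraic sphere equation `|p|^2 = 2 c.p + k` by linear least
#' squares; exact (residual ~ machine precision) on noiseless data.
#' @param points n x 3 matrix of surface samples, n >= 4, non-coplanar.
#' @return list with `center`, `radius`, `rms` residual.
#' @export
fit_sphere <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 4) stop("sphere fit needs >= 4 points", call. = FALSE)
  A <- cbind(2 * points, 1)
  b <- rowSums(points^2)
  qa <- qr(A)
  if (qa$rank < 4)
    stop("sphere fit degenerate: points are coplanar", call. = FALSE)
  th <- qr.coef(qa, b)
  center <- th[1:3]
  radius <- sqrt(th[4] + sum(center^2))
  r <- sqrt(rowSums(sweep(points, 2, center)^2)) - radius
  list(center = unname(center), radius = unname(radius),
       rms = sqrt(mean(r^2)))
}

# Trimmed sphere fit for mixed point sets (e.g. all vertices of a cup mesh,
# where only the articulating spherical patch should drive the fit).
fit_sphere_trimmed <- function(points, iterations = 3, keep = 0.7) {
  pts <- as.matrix(points)
  fit <- fit_sphere(pts)
  for (i in seq_len(iterations)) {
    r <- abs(sqrt(rowSums(sweep(pts, 2, fit$center)^2)) - fit$radius)
    cut <- stats::quantile(r, keep)
    sel <- r <= cut
    if (sum(sel) < 10) break
    fit <- fit_sphere(pts[sel, , drop = FALSE])
  }
  fit
}

#' 2D circle fit (Kasa linear least squares)
#' @param xy n x 2 matrix.
#' @return list with `center` (length 2) and `radius`.
#' @export
fit_circle2d <- function(xy) {
  xy <- as.matrix(xy)
  A <- cbind(2 * xy, 1)
  th <- qr.coef(qr(A), rowSums(xy^2))
  center <- th[1:2]
  list(center = unname(center),
       radius = sqrt(th[3] + sum(center^2)))
}

#' Direct least-squares ellipse fit (Halir-Flusser)
#'
#' Numerically stable variant of the Fitzgibbon direct conic fit with the
#' ellipse constraint `4AC - B^2 = 1`.
#' @param xy n x 2 matrix of points, n >= 6, not collinear.
#' @return list with `center`, `axes` (semi-axes, major first), `angle`
#'   (radians, major axis), `conic` (A, B, C, D, E, F).
#' @export
fit_ellipse <- function(xy) {
  xy <- as.matrix(xy)
  if (nrow(xy) < 6) stop("ellipse fit needs >= 6 points", call. = FALSE)
  # center/scale for conditioning
  mx <- colMeans(xy)
  sc <- max(apply(abs(sweep(xy, 2, mx)), 2, max), 1e-12)
  x <- (xy[, 1] - mx[1]) / sc
  y <- (xy[, 2] - mx[2]) / sc
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  if (rcond(S3) < 1e-12)
    stop("ellipse fit degenerate: points are collinear", call. = FALSE)
  T2 <- -solve(S3, t(S2))
  M <- S1 + S2 %*% T2
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  vecs <- Re(ev$vectors)
  cond <- 4 * vecs[1, ] * vecs[3, ] - vecs[2, ]^2
  sel <- which(cond > 0)
  if (length(sel) == 0) stop("no ellipse fits these points", call. = FALSE)
  a1 <- vecs[, sel[1]]
  coefs <- c(a1, T2 %*% a1)
  if (coefs[1] < 0) coefs <- -coefs  # canonical sign: A > 0
  # un-scale conic: substitute x -> (x - mx)/sc
  A <- coefs[1] / sc^2
  B <- coefs[2] / sc^2
  C <- coefs[3] / sc^2
  D <- coefs[4] / sc - 2 * A * mx[1] - B * mx[2]
  E <- coefs[5] / sc - 2 * C * mx[2] - B * mx[1]
  Fc <- coefs[6] + A * mx[1]^2 + B * mx[1] * mx[2] + C * mx[2]^2 -
    coefs[4] * mx[1] / sc - coefs[5] * mx[2] / sc
  Mq <- matrix(c(A, B / 2, B / 2, C), 2, 2)
  center <- drop(solve(2 * Mq, -c(D, E)))
  val <- A * center[1]^2 + B * center[1] * center[2] + C * center[2]^2 +
    D * center[1] + E * center[2] + Fc
  eg <- eigen(Mq, symmetric = TRUE)
  s <- -val
  if (s <= 0 || any(eg$values * s <= 0))
    stop("fitted conic is not a real ellipse", call. = FALSE)
  semis <- sqrt(s / eg$values)  # eigen() sorts descending -> semis ascending
  ord <- order(semis, decreasing = TRUE)
  major_vec <- eg$vectors[, ord[1]]
  list(center = center, axes = semis[ord],
       angle = atan2(major_vec[2], major_vec[1]),
       conic = c(A = A, B = B, C = C, D = D, E = E, F = Fc))
}
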