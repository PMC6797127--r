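#' Axis-aligned box mesh
#' @param center box center (mm).
#' @param size edge lengths (mm), length 1 or 3.
#' @param name label.
#' @export
box_mesh <- function(center = c(0, 0, 0), size = 10, name = "box") {
  h <- rep(size, length.out = 3) / 2
  s <- expand.grid(x = c(-1, 1), y = c(-1, 1), z = c(-1, 1))
  V <- sweep(as.matrix(s) * rep(h, each = 8), 2, -center)
  # vertex order: (---, +--, -+-, ++-, --+, +-+, -++, +++) -> indices 1..8
  F <- rbind(c(1, 3, 4), c(1, 4, 2),   # z-
             c(5, 6, 8), c(5, 8, 7),   # z+
             c(1, 2, 6), c(1, 6, 5),   # y-
             c(3, 7, 8), c(3, 8, 4),   # y+
             c(1, 5, 7), c(1, 7, 3),   # x-
             c(2, 4, 8), c(2, 8, 6))   # x+
  solid_mesh(V, F, name = name, clean = FALSE)
}

#' Icosphere mesh
#'
#' Subdivided icosahedron with vertices projected to the sphere; volume
#' converges to the sphere volume from below.
#' @param radius sphere radius (mm).
#' @param subdivisions number of 4-to-1 triangle subdivisions.
#' @param center sphere center.
#' @param name label.
#' @export
icosphere <- function(radius = 1, subdivisions = 3, center = c(0, 0, 0),
                      name = "icosphere") {
  phi <- (1 + sqrt(5)) / 2
  V <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  F <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    nv <- nrow(V)
    edges <- unique(rbind(
      cbind(pmin(F[, 1], F[, 2]), pmax(F[, 1], F[, 2])),
      cbind(pmin(F[, 2], F[, 3]), pmax(F[, 2], F[, 3])),
      cbind(pmin(F[, 1], F[, 3]), pmax(F[, 1], F[, 3]))))
    ek <- paste(edges[, 1], edges[, 2])
    mid <- (V[edges[, 1], , drop = FALSE] + V[edges[, 2], , drop = FALSE]) / 2
    V <- rbind(V, mid)
    midx <- function(a, b) nv + match(paste(pmin(a, b), pmax(a, b)), ek)
    m12 <- midx(F[, 1], F[, 2])
    m23 <- midx(F[, 2], F[, 3])
    m13 <- midx(F[, 1], F[, 3])
    F <- rbind(cbind(F[, 1], m12, m13), cbind(F[, 2], m23, m12),
               cbind(F[, 3], m13, m23), cbind(m12, m23, m13))
  }
  V <- V / sqrt(rowSums(V^2)) * radius
  V <- sweep(V, 2, -center)
  solid_mesh(V, F, name = name, clean = FALSE)
}

#' Closed cylinder mesh
#' @param radius,height cylinder radius and height (mm); axis along z.
#' @param center cylinder center.
#' @param n number of circumferential segments.
#' @param name label.
#' @export
cylinder_mesh <- function(radius = 5, height = 10, center = c(0, 0, 0),
                          n = 48, name = "cylinder") {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  ring <- cbind(radius * cos(th), radius * sin(th))
  V <- rbind(cbind(ring, -height / 2), cbind(ring, height / 2),
             c(0, 0, -height / 2), c(0, 0, height / 2))
  lo <- seq_len(n)
  hi <- lo + n
  nx <- c(lo[-1], lo[1])
  nxh <- nx + n
  cb <- 2 * n + 1
  ct <- 2 * n + 2
  F <- rbind(cbind(lo, nx, nxh), cbind(lo, nxh, hi),     # side
             cbind(cb, nx, lo),                          # bottom cap
             cbind(ct, hi, nxh))                         # top cap
  solid_mesh(sweep(V, 2, -center), F, name = name, clean = FALSE)
}
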