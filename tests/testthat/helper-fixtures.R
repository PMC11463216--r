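# Programmatic mesh fixtures: all built in code, no stored data.

# Rectangular flat patch in the z = 0 plane, diagonal-split triangulation,
# faces wound CCW seen from +z. nx, ny = number of vertices per side.
flat_patch <- function(nx = 5L, ny = 5L, spacing = 1) {
  g <- expand.grid(x = 0:(nx - 1L), y = 0:(ny - 1L))
  V <- cbind(g$x * spacing, g$y * spacing, 0)
  idx <- function(i, j) (j - 1L) * nx + i
  faces <- list()
  for (j in seq_len(ny - 1L)) {
    for (i in seq_len(nx - 1L)) {
      v00 <- idx(i, j); v10 <- idx(i + 1L, j)
      v01 <- idx(i, j + 1L); v11 <- idx(i + 1L, j + 1L)
      faces[[length(faces) + 1L]] <- c(v00, v10, v11)
      faces[[length(faces) + 1L]] <- c(v00, v11, v01)
    }
  }
  colony_mesh(V, do.call(rbind, faces))
}

# Equilateral triangular-lattice patch (rows offset by a/2), z = 0, CCW from
# +z. Interior vertices have exactly 6 neighbours.
tri_lattice_patch <- function(n_rows = 5L, n_cols = 6L, a = 1) {
  V <- NULL
  index <- matrix(NA_integer_, n_rows, n_cols)
  k <- 0L
  for (j in seq_len(n_rows)) {
    for (i in seq_len(n_cols)) {
      k <- k + 1L
      index[j, i] <- k
      V <- rbind(V, c((i - 1L) * a + (j %% 2L) * a / 2, (j - 1L) * a * sqrt(3) / 2, 0))
    }
  }
  faces <- list()
  for (j in seq_len(n_rows - 1L)) {
    for (i in seq_len(n_cols - 1L)) {
      v00 <- index[j, i]; v10 <- index[j, i + 1L]
      v01 <- index[j + 1L, i]; v11 <- index[j + 1L, i + 1L]
      if (j %% 2L == 1L) {
        faces[[length(faces) + 1L]] <- c(v00, v10, v11)
        faces[[length(faces) + 1L]] <- c(v00, v11, v01)
      } else {
        faces[[length(faces) + 1L]] <- c(v00, v10, v01)
        faces[[length(faces) + 1L]] <- c(v10, v11, v01)
      }
    }
  }
  colony_mesh(V, do.call(rbind, faces))
}

# Open triangulated cylinder of radius r and height h, axis = z, outward CCW
# winding. Boundary rings at both ends.
cylinder_mesh <- function(r = 10, h = 60, n_around = 24L, n_axial = 13L) {
  zs <- seq(0, h, length.out = n_axial)
  ang <- (0:(n_around - 1L)) * 2 * pi / n_around
  V <- NULL
  for (z in zs) V <- rbind(V, cbind(r * cos(ang), r * sin(ang), z))
  idx <- function(ring, i) (ring - 1L) * n_around + ((i - 1L) %% n_around) + 1L
  faces <- list()
  for (ring in seq_len(n_axial - 1L)) {
    for (i in seq_len(n_around)) {
      a <- idx(ring, i); b <- idx(ring, i + 1L)
      c2 <- idx(ring + 1L, i); d <- idx(ring + 1L, i + 1L)
      faces[[length(faces) + 1L]] <- c(a, b, d)
      faces[[length(faces) + 1L]] <- c(a, d, c2)
    }
  }
  colony_mesh(V, do.call(rbind, faces))
}

# Open cone: base radius r0 at z = 0 tapering to r1 at z = h.
cone_mesh <- function(r0 = 20, r1 = 5, h = 60, n_around = 24L, n_axial = 13L) {
  zs <- seq(0, h, length.out = n_axial)
  rs <- r0 + (r1 - r0) * zs / h
  ang <- (0:(n_around - 1L)) * 2 * pi / n_around
  V <- NULL
  for (k in seq_along(zs)) {
    V <- rbind(V, cbind(rs[k] * cos(ang), rs[k] * sin(ang), zs[k]))
  }
  idx <- function(ring, i) (ring - 1L) * n_around + ((i - 1L) %% n_around) + 1L
  faces <- list()
  for (ring in seq_along(zs)[-length(zs)]) {
    for (i in seq_len(n_around)) {
      a <- idx(ring, i); b <- idx(ring, i + 1L)
      c2 <- idx(ring + 1L, i); d <- idx(ring + 1L, i + 1L)
      faces[[length(faces) + 1L]] <- c(a, b, d)
      faces[[length(faces) + 1L]] <- c(a, d, c2)
    }
  }
  colony_mesh(V, do.call(rbind, faces))
}

# Five-vertex fixture violating the link condition for edge (1,2): vertex 5 is
# a common neighbour of 1 and 2 without (1,2,5) being a face, so collapsing
# 1-2 would create a non-manifold fin.
link_violation_fixture <- function() {
  V <- rbind(c(0, 0, 0), c(2, 0, 0), c(1, 1.5, 0.2),
             c(1, -1.5, 0.2), c(1, -0.5, 1.5))
  F <- rbind(c(1L, 2L, 3L), c(2L, 1L, 4L),
             c(1L, 4L, 5L), c(2L, 5L, 4L))
  colony_mesh(V, F)
}

# Euler characteristic V - E + F (1 for a disk)
euler_char <- function(mesh) {
  nrow(mesh$V) - nrow(mesh_edges(mesh)) + nrow(mesh$F)
}

# independent de Casteljau evaluation of a cubic Bezier
decasteljau <- function(P0, P1, P2, P3, t) {
  lerp <- function(a, b) (1 - t) * a + t * b
  a <- lerp(P0, P1); b <- lerp(P1, P2); c2 <- lerp(P2, P3)
  d <- lerp(a, b); e <- lerp(b, c2)
  lerp(d, e)
}
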