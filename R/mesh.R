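# Triangular-mesh data model: vertices are individual polyps, faces the tissue
# surface (coenosarc). Faces are wound counter-clockwise seen from outside the
# colony; the substrate rim is the open boundary of the mesh (the base disk is
# never meshed). All lengths are millimetres, substrate plane at z = 0.

# key base for packing an undirected edge (a,b), a < b, into one double;
# exact for meshes below ~6.7e7 vertices
.KEYBASE <- 2^26

.row_norms <- function(m) sqrt(rowSums(m * m))

.normalize_rows <- function(m) {
  n <- .row_norms(m)
  n[n == 0] <- NA_real_
  m / n
}

#' Construct a colony mesh
#'
#' A `colony_mesh` is a manifold triangular mesh with attribute-carrying
#' vertices. Each vertex is one polyp and holds a stable integer id (never
#' reused after a fusion removes a vertex), a substrate flag (`is_base`,
#' vertices pinned to the z = 0 plane) and an apical flag (`is_leader`,
#' branch-leading polyps).
#'
#' @param vertices numeric n x 3 matrix of polyp positions, mm.
#' @param faces integer m x 3 matrix of vertex row indices, wound
#'   counter-clockwise seen from outside the colony.
#' @param is_base logical vector: substrate-bound vertices (must lie on z = 0).
#' @param is_leader logical vector: branch-leading (apical) polyps.
#' @param id stable integer vertex identifiers.
#' @return an object of class `colony_mesh`.
#' @seealso [validate_mesh()], [split_edge()], [collapse_edge()]
#' @export
colony_mesh <- function(vertices, faces,
                        is_base = rep(FALSE, nrow(vertices)),
                        is_leader = rep(FALSE, nrow(vertices)),
                        id = seq_len(nrow(vertices))) {
  vertices <- matrix(as.numeric(vertices), ncol = 3L,
                     dimnames = NULL)
  if (length(faces) == 0L) faces <- matrix(integer(), 0L, 3L)
  faces <- matrix(as.integer(faces), ncol = 3L, dimnames = NULL)
  n <- nrow(vertices)
  stopifnot(length(is_base) == n, length(is_leader) == n, length(id) == n)
  if (anyDuplicated(id)) stop("vertex ids must be unique")
  if (nrow(faces) > 0L && (min(faces) < 1L || max(faces) > n)) {
    stop("face indices out of range")
  }
  structure(list(
    V = vertices,
    F = faces,
    id = as.integer(id),
    is_base = as.logical(is_base),
    is_leader = as.logical(is_leader),
    next_id = if (n > 0L) max(id) + 1L else 1L
  ), class = "colony_mesh")
}

#' @export
print.colony_mesh <- function(x, ...) {
  et <- .edge_table(x$F)
  cat(sprintf(
    "<colony_mesh> %d polyps, %d faces, %d edges (%d base, %d leader)\n",
    nrow(x$V), nrow(x$F), length(et$a), sum(x$is_base), sum(x$is_leader)))
  invisible(x)
}

#' Number of polyps / faces in a mesh
#' @param mesh a `colony_mesh`.
#' @return integer count.
#' @export
n_polyps <- function(mesh) nrow(mesh$V)

#' @rdname n_polyps
#' @export
n_faces <- function(mesh) nrow(mesh$F)

# row index of a vertex id, with error on unknown ids
.rows_of <- function(mesh, v) {
  r <- match(as.integer(v), mesh$id)
  if (anyNA(r)) stop("unknown vertex id(s): ", paste(v[is.na(r)], collapse = ", "))
  r
}

# Undirected edge table derived from the face matrix. Returns parallel vectors:
# a, b (row indices, a < b), n_faces per edge, f1/f2 the (up to two) incident
# faces, and `opposed`: whether a 2-face edge is traversed in opposite
# directions by its faces (orientation consistency).
.edge_table <- function(F) {
  m <- nrow(F)
  if (m == 0L) {
    return(list(a = integer(), b = integer(), n_faces = integer(),
                f1 = integer(), f2 = integer(), opposed = logical()))
  }
  a0 <- c(F[, 1L], F[, 2L], F[, 3L])
  b0 <- c(F[, 2L], F[, 3L], F[, 1L])
  fi <- rep.int(seq_len(m), 3L)
  swap <- a0 > b0
  a <- ifelse(swap, b0, a0)
  b <- ifelse(swap, a0, b0)
  key <- a * .KEYBASE + b
  o <- order(key)
  ks <- key[o]
  newg <- c(TRUE, ks[-1L] != ks[-length(ks)])
  first <- which(newg)
  cnt <- diff(c(first, length(ks) + 1L))
  fo <- fi[o]
  so <- swap[o]
  has2 <- cnt >= 2L
  f2 <- rep(NA_integer_, length(first))
  f2[has2] <- fo[first[has2] + 1L]
  opposed <- rep(NA, length(first))
  opposed[has2] <- so[first[has2]] != so[first[has2] + 1L]
  list(a = a[o][first], b = b[o][first], n_faces = cnt,
       f1 = fo[first], f2 = f2, opposed = opposed)
}

#' Edge list of a colony mesh
#'
#' @param mesh a `colony_mesh`.
#' @return data frame with one row per undirected edge: vertex ids `v1`, `v2`,
#'   Euclidean `length` (mm), `n_faces` incident faces (1 = substrate-rim
#'   boundary edge, 2 = interior edge).
#' @export
mesh_edges <- function(mesh) {
  et <- .edge_table(mesh$F)
  d <- mesh$V[et$a, , drop = FALSE] - mesh$V[et$b, , drop = FALSE]
  data.frame(v1 = mesh$id[et$a], v2 = mesh$id[et$b],
             length = .row_norms(d), n_faces = et$n_faces)
}

# Unnormalized face normals (cross products; norm = 2 * face area).
.face_cross <- function(V, F) {
  u <- V[F[, 2L], , drop = FALSE] - V[F[, 1L], , drop = FALSE]
  w <- V[F[, 3L], , drop = FALSE] - V[F[, 1L], , drop = FALSE]
  cbind(u[, 2L] * w[, 3L] - u[, 3L] * w[, 2L],
        u[, 3L] * w[, 1L] - u[, 1L] * w[, 3L],
        u[, 1L] * w[, 2L] - u[, 2L] * w[, 1L])
}

# Area-weighted unit vertex normals for all vertices; rows of vertices with no
# incident face are NA.
.vertex_normals <- function(mesh) {
  n <- nrow(mesh$V)
  acc <- matrix(0, n, 3L)
  if (nrow(mesh$F) > 0L) {
    fc <- .face_cross(mesh$V, mesh$F)
    g <- c(mesh$F[, 1L], mesh$F[, 2L], mesh$F[, 3L])
    s <- rowsum(rbind(fc, fc, fc), g)
    acc[as.integer(rownames(s)), ] <- s
  }
  touched <- tabulate(mesh$F, nbins = n) > 0L
  out <- .normalize_rows(acc)
  out[!touched, ] <- NA_real_
  out
}

#' Area-weighted vertex normal
#'
#' The polyp's surface normal: the area-weighted average of the normals of its
#' incident faces, normalized to unit length. This is the direction a polyp
#' accretes along in the surface-growth step.
#'
#' @param mesh a `colony_mesh`.
#' @param v a vertex id.
#' @return unit 3-vector.
#' @export
vertex_normal <- function(mesh, v) {
  r <- .rows_of(mesh, v)
  stopifnot(length(r) == 1L)
  F <- mesh$F
  fs <- which(F[, 1L] == r | F[, 2L] == r | F[, 3L] == r)
  if (length(fs) == 0L) {
    stop("vertex ", v, " has no incident face (corrupted topology)")
  }
  fc <- .face_cross(mesh$V, F[fs, , drop = FALSE])
  s <- colSums(fc)
  ns <- sqrt(sum(s^2))
  if (ns == 0) stop("degenerate normal at vertex ", v)
  s / ns
}

# Split several edges at once. `edges_rows` is a k x 2 matrix of vertex ROW
# indices; no two edges may share a face (caller guarantees this). `inc` is an
# optional k x 2 matrix of incident face indices (NA for missing second face).
.split_edges_rows <- function(mesh, edges_rows, positions, inc = NULL) {
  F <- mesh$F
  k <- nrow(edges_rows)
  nv <- nrow(mesh$V)
  positions <- matrix(as.numeric(positions), ncol = 3L)
  base_new <- mesh$is_base[edges_rows[, 1L]] & mesh$is_base[edges_rows[, 2L]]
  positions[base_new, 3L] <- 0
  new_rows <- nv + seq_len(k)
  drop <- logical(nrow(F))
  add <- vector("list", 2L * k)
  nadd <- 0L
  for (e in seq_len(k)) {
    a <- edges_rows[e, 1L]
    b <- edges_rows[e, 2L]
    mr <- new_rows[e]
    if (is.null(inc)) {
      fs <- which((F[, 1L] == a | F[, 2L] == a | F[, 3L] == a) &
                  (F[, 1L] == b | F[, 2L] == b | F[, 3L] == b))
    } else {
      fs <- inc[e, ]
      fs <- fs[!is.na(fs)]
    }
    if (length(fs) == 0L) stop("edge not found in any face")
    for (fidx in fs) {
      f <- F[fidx, ]
      ia <- which(f == a)
      f <- f[((ia - 1L + 0:2) %% 3L) + 1L]  # rotate so f[1] == a
      if (f[2L] == b) {
        nf <- rbind(c(a, mr, f[3L]), c(mr, b, f[3L]))
      } else {
        # f == (a, c, b): directed edge is b -> a
        nf <- rbind(c(mr, a, f[2L]), c(b, mr, f[2L]))
      }
      drop[fidx] <- TRUE
      nadd <- nadd + 1L
      add[[nadd]] <- nf
    }
  }
  ids <- mesh$next_id + seq_len(k) - 1L
  mesh$V <- rbind(mesh$V, positions)
  mesh$F <- rbind(F[!drop, , drop = FALSE], do.call(rbind, add[seq_len(nadd)]))
  mesh$id <- c(mesh$id, ids)
  mesh$is_base <- c(mesh$is_base, base_new)
  mesh$is_leader <- c(mesh$is_leader, rep(FALSE, k))
  mesh$next_id <- mesh$next_id + k
  list(mesh = mesh, ids = ids)
}

#' Split an edge, inserting a new polyp
#'
#' Inserts one vertex at `new_position`; each face incident to the edge (one
#' for a substrate-rim boundary edge, two for an interior edge) is replaced by
#' two faces with the original winding preserved. The new polyp inherits the
#' substrate flag only when both endpoints are base vertices (its z is then
#' forced to 0); the apical flag is never inherited.
#'
#' @param mesh a `colony_mesh`.
#' @param edge length-2 vector of vertex ids.
#' @param new_position 3-vector, mm.
#' @return list with elements `mesh` (updated mesh) and `vertex` (the new
#'   vertex id).
#' @export
split_edge <- function(mesh, edge, new_position) {
  stopifnot(length(edge) == 2L, length(new_position) == 3L,
            all(is.finite(new_position)))
  r <- .rows_of(mesh, edge)
  res <- .split_edges_rows(mesh, matrix(r, 1L, 2L),
                           matrix(new_position, 1L, 3L))
  list(mesh = res$mesh, vertex = res$ids[1L])
}

#' Collapse an edge, fusing two polyps
#'
#' The two endpoints are replaced by one surviving vertex. The collapse is
#' refused (returned with `collapsed = FALSE`, mesh unchanged) when it would
#' break manifoldness: the link condition requires the endpoints' common
#' neighbours to be exactly the vertices opposite the edge; additionally an
#' interior edge between two boundary vertices is refused (boundary pinch), a
#' collapse that would isolate an opposite vertex is refused, and two apical
#' leaders never fuse.
#'
#' Position and flag rules: both endpoints base -> midpoint with z = 0, base;
#' exactly one base -> the base vertex survives in place (keeps the substrate
#' rim intact); exactly one leader -> the leader survives in place (fusion
#' never removes an apical polyp); otherwise the first endpoint survives at the
#' edge midpoint.
#'
#' @param mesh a `colony_mesh`.
#' @param edge length-2 vector of vertex ids.
#' @return list with `mesh`, `vertex` (surviving vertex id) and `collapsed`
#'   (logical; `FALSE` means the collapse was refused and the mesh unchanged).
#' @export
collapse_edge <- function(mesh, edge) {
  stopifnot(length(edge) == 2L)
  r <- .rows_of(mesh, edge)
  ra <- r[1L]; rb <- r[2L]
  F <- mesh$F
  in_a <- F[, 1L] == ra | F[, 2L] == ra | F[, 3L] == ra
  in_b <- F[, 1L] == rb | F[, 2L] == rb | F[, 3L] == rb
  fa <- which(in_a)
  fb <- which(in_b)
  fs <- which(in_a & in_b)
  if (length(fs) == 0L) stop("edge not found: ", edge[1L], "-", edge[2L])

  refuse <- function() list(mesh = mesh, vertex = NA_integer_, collapsed = FALSE)

  opp <- setdiff(as.vector(F[fs, , drop = FALSE]), c(ra, rb))
  na_ <- setdiff(as.vector(F[fa, , drop = FALSE]), c(ra, rb))
  nb_ <- setdiff(as.vector(F[fb, , drop = FALSE]), c(ra, rb))
  common <- intersect(na_, nb_)
  if (!setequal(common, opp)) return(refuse())

  # boundary pinch: interior edge whose endpoints both sit on the mesh
  # boundary (a manifold boundary vertex has one face fewer than neighbours)
  if (length(fs) == 2L) {
    if (length(fa) < length(na_) + 1L && length(fb) < length(nb_) + 1L) {
      return(refuse())
    }
  }
  # never isolate an opposite vertex
  for (vo in opp) {
    fo <- which(F[, 1L] == vo | F[, 2L] == vo | F[, 3L] == vo)
    if (all(fo %in% fs)) return(refuse())
  }

  ba <- mesh$is_base[ra]; bb <- mesh$is_base[rb]
  la <- mesh$is_leader[ra]; lb <- mesh$is_leader[rb]
  if (la && lb) return(refuse())
  if ((la && bb) || (lb && ba)) return(refuse())  # leader/base mix: keep both

  if (la || lb) {
    surv <- if (la) ra else rb
    pos <- mesh$V[surv, ]
  } else if (ba && bb) {
    surv <- ra
    pos <- (mesh$V[ra, ] + mesh$V[rb, ]) / 2
    pos[3L] <- 0
  } else if (ba || bb) {
    surv <- if (ba) ra else rb
    pos <- mesh$V[surv, ]
  } else {
    surv <- ra
    pos <- (mesh$V[ra, ] + mesh$V[rb, ]) / 2
  }
  gone <- if (surv == ra) rb else ra

  mesh$V[surv, ] <- pos
  surv_id <- mesh$id[surv]
  F[F == gone] <- surv
  degen <- F[, 1L] == F[, 2L] | F[, 2L] == F[, 3L] | F[, 1L] == F[, 3L]
  F <- F[!degen, , drop = FALSE]
  F[F > gone] <- F[F > gone] - 1L
  keep <- -gone
  mesh$V <- mesh$V[keep, , drop = FALSE]
  mesh$id <- mesh$id[keep]
  mesh$is_base <- mesh$is_base[keep]
  mesh$is_leader <- mesh$is_leader[keep]
  mesh$F <- F
  list(mesh = mesh, vertex = surv_id, collapsed = TRUE)
}

#' Validate a colony mesh
#'
#' Diagnostic check of all structural invariants: face indices in range, no
#' degenerate or duplicate faces, every edge shared by at most two faces,
#' consistent (orientable, outward) winding, substrate vertices on the z = 0
#' plane, and no isolated vertices.
#'
#' @param mesh a `colony_mesh`.
#' @return list with `ok` (logical) and `violations` (character vector).
#' @export
validate_mesh <- function(mesh) {
  v <- character()
  n <- nrow(mesh$V)
  F <- mesh$F
  if (nrow(F) > 0L && (min(F) < 1L || max(F) > n)) {
    v <- c(v, "face index out of range")
    return(list(ok = FALSE, violations = v))
  }
  if (nrow(F) > 0L) {
    degen <- F[, 1L] == F[, 2L] | F[, 2L] == F[, 3L] | F[, 1L] == F[, 3L]
    if (any(degen)) v <- c(v, sprintf("%d degenerate face(s)", sum(degen)))
    key <- apply(F, 1L, function(f) paste(sort(f), collapse = "-"))
    if (anyDuplicated(key)) v <- c(v, "duplicate face(s)")
  }
  et <- .edge_table(F)
  if (any(et$n_faces > 2L)) {
    v <- c(v, sprintf("%d non-manifold edge(s) (>2 incident faces)",
                      sum(et$n_faces > 2L)))
  }
  two <- et$n_faces == 2L
  if (any(two) && !all(et$opposed[two])) {
    v <- c(v, sprintf("%d edge(s) with inconsistent face orientation",
                      sum(!et$opposed[two])))
  }
  off <- mesh$is_base & abs(mesh$V[, 3L]) > 1e-9
  if (any(off)) v <- c(v, sprintf("%d base vertex(es) off the substrate plane",
                                  sum(off)))
  if (nrow(F) > 0L) {
    touched <- tabulate(F, nbins = n) > 0L
    if (any(!touched)) v <- c(v, sprintf("%d isolated vertex(es)", sum(!touched)))
    fc <- .face_cross(mesh$V, F)
    if (sum(fc[, 3L]) <= 0) v <- c(v, "mean face normal not pointing upward")
  }
  list(ok = length(v) == 0L, violations = v)
}
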