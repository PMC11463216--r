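# Polyp cloning (asexual budding) and fusion. Edges longer than delta_sub are
# split at the midpoint of a cubic Bezier interpolant of the surface (so new
# polyps land on a smooth bulge, not the chord); edges shorter than
# delta_fuse = 0.2 * delta_sub are collapsed, smoothing the tiling and
# mimicking polyp death/reabsorption.

#' Cloning parameters
#'
#' @param delta_sub maximal inter-polyp distance, mm; an edge longer than this
#'   triggers a cloning (subdivision) event.
#' @return object of class `clone_params` with derived fusion distance
#'   `delta_fuse = 0.2 * delta_sub`.
#' @export
clone_params <- function(delta_sub) {
  stopifnot(is.numeric(delta_sub), length(delta_sub) == 1L, delta_sub > 0)
  structure(list(delta_sub = delta_sub, delta_fuse = 0.2 * delta_sub),
            class = "clone_params")
}

# Vectorized Bezier midpoints for edges A->B with endpoint unit normals.
# Control points: P0 = A, P3 = B, P1 = A + (L/3) tA, P2 = B + (L/3) tB with
# tA/tB the unit tangent-plane projections of the chord; the de Casteljau
# midpoint collapses to (A+B)/2 + (L/8)(tA + tB). Degenerate projections drop
# their handle (control point falls back to the endpoint).
.bezier_mid_rows <- function(A, NA_, B, NB) {
  d <- B - A
  L <- .row_norms(d)
  u <- d / L
  pa <- u - rowSums(u * NA_) * NA_
  pb <- -u - rowSums(-u * NB) * NB
  ha <- .row_norms(pa)
  hb <- .row_norms(pb)
  dega <- ha < 1e-9
  degb <- hb < 1e-9
  ha[dega] <- 1; pa[dega, ] <- 0
  hb[degb] <- 1; pb[degb, ] <- 0
  (A + B) / 2 + (L / 8) * (pa / ha + pb / hb)
}

#' Bezier surface-interpolated midpoint between two polyps
#'
#' Evaluates at t = 0.5 (de Casteljau) the cubic Bezier with control points
#' `P0 = A`, `P3 = B`, `P1 = A + (L/3) tA`, `P2 = B + (L/3) tB`, where `L` is
#' the chord length and `tA`, `tB` are the unit projections of the chord onto
#' the tangent planes of the endpoint normals. On a flat region both handles
#' cancel and the result is the Euclidean midpoint; on a curved region the new
#' polyp bulges outward, following the surface.
#'
#' @param A,B endpoint positions, mm (must differ).
#' @param nA,nB unit surface normals at the endpoints.
#' @return 3-vector: the interpolated midpoint.
#' @export
bezier_midpoint <- function(A, nA, B, nB) {
  stopifnot(length(A) == 3L, length(B) == 3L, length(nA) == 3L,
            length(nB) == 3L)
  if (sqrt(sum((B - A)^2)) < 1e-12) stop("coincident endpoints")
  drop(.bezier_mid_rows(matrix(A, 1L), matrix(nA, 1L),
                        matrix(B, 1L), matrix(nB, 1L)))
}

#' Cloning step: adaptive subdivision of over-long edges
#'
#' Repeatedly collects all edges longer than `delta_sub` (longest first),
#' splits each at its Bezier surface midpoint — skipping edges sharing a face
#' with an earlier split in the same pass — and iterates until no edge exceeds
#' `delta_sub`. Endpoint normals are taken from the pass-start geometry.
#'
#' @param mesh a `colony_mesh`.
#' @param params a [clone_params()].
#' @param max_passes safety cap on subdivision passes (default 20); reaching it
#'   with over-long edges left is an error signalling runaway geometry.
#' @return list with `mesh` (updated) and `added` (number of new polyps).
#' @export
cloning_step <- function(mesh, params, max_passes = 20L) {
  stopifnot(inherits(params, "clone_params"))
  dsub <- params$delta_sub
  added <- 0L
  for (pass in seq_len(max_passes)) {
    et <- .edge_table(mesh$F)
    len <- .row_norms(mesh$V[et$a, , drop = FALSE] -
                      mesh$V[et$b, , drop = FALSE])
    over <- which(len > dsub)
    if (length(over) == 0L) return(list(mesh = mesh, added = added))
    over <- over[order(len[over], decreasing = TRUE)]
    used <- logical(nrow(mesh$F))
    sel <- integer(0)
    for (e in over) {
      fs <- c(et$f1[e], et$f2[e])
      fs <- fs[!is.na(fs)]
      if (any(used[fs])) next
      used[fs] <- TRUE
      sel <- c(sel, e)
    }
    normals <- .vertex_normals(mesh)
    a <- et$a[sel]; b <- et$b[sel]
    pos <- .bezier_mid_rows(mesh$V[a, , drop = FALSE],
                            normals[a, , drop = FALSE],
                            mesh$V[b, , drop = FALSE],
                            normals[b, , drop = FALSE])
    res <- .split_edges_rows(mesh, cbind(a, b), pos,
                             inc = cbind(et$f1[sel], et$f2[sel]))
    mesh <- res$mesh
    added <- added + length(sel)
  }
  et <- .edge_table(mesh$F)
  len <- .row_norms(mesh$V[et$a, , drop = FALSE] - mesh$V[et$b, , drop = FALSE])
  if (any(len > dsub)) {
    stop("cloning did not converge after ", max_passes,
         " passes (runaway geometry)")
  }
  list(mesh = mesh, added = added)
}

#' Fusion step: collapse of under-short edges
#'
#' Collects all edges shorter than `delta_fuse` at entry (shortest first) and
#' collapses each, skipping edges invalidated by earlier collapses or refused
#' by the manifoldness link condition. One pass per time step: fusion is a
#' smoothing process, while cloning must guarantee the density bound. Apical
#' leader polyps are never removed (the other endpoint is absorbed into the
#' leader).
#'
#' @param mesh a `colony_mesh`.
#' @param params a [clone_params()].
#' @return list with `mesh` (updated) and `removed` (number of polyps fused
#'   away).
#' @export
fusion_step <- function(mesh, params) {
  stopifnot(inherits(params, "clone_params"))
  et <- .edge_table(mesh$F)
  len <- .row_norms(mesh$V[et$a, , drop = FALSE] - mesh$V[et$b, , drop = FALSE])
  short <- which(len < params$delta_fuse)
  if (length(short) == 0L) return(list(mesh = mesh, removed = 0L))
  short <- short[order(len[short])]
  pairs <- cbind(mesh$id[et$a[short]], mesh$id[et$b[short]])
  removed <- 0L
  for (k in seq_len(nrow(pairs))) {
    e1 <- pairs[k, 1L]; e2 <- pairs[k, 2L]
    r <- match(c(e1, e2), mesh$id)
    if (anyNA(r)) next  # an endpoint was absorbed earlier this pass
    F <- mesh$F
    still <- any((F[, 1L] == r[1L] | F[, 2L] == r[1L] | F[, 3L] == r[1L]) &
                 (F[, 1L] == r[2L] | F[, 2L] == r[2L] | F[, 3L] == r[2L]))
    if (!still) next
    res <- collapse_edge(mesh, c(e1, e2))
    if (res$collapsed) {
      mesh <- res$mesh
      removed <- removed + 1L
    }
  }
  list(mesh = mesh, removed = removed)
}
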