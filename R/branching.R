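# Self-regulated branching (apical dominance, as in Acropora): candidate
# polyps in a spherical band at distance l_br +/- eps from existing branching
# nodes are promoted to branch leaders at a rate nu / (l_br * Nbr), kicked a
# distance 4 * alpha along the branch axis, and thereafter elongate
# persistently along that axis at rate nu, bypassing the growth-mode gate.

#' Branching parameters
#'
#' @param l_br mean inter-branching (internode) distance, mm.
#' @param theta branching angle from the parent branch axis, degrees in
#'   \[0, 90\].
#' @param epsilon selection band half-width, mm; defaults to the 25 percent
#'   measurement-error band `0.25 * l_br`.
#' @param kick initial displacement multiplier (new leaders are displaced
#'   `kick * alpha` along the branch axis; fixed at 4).
#' @return object of class `branch_params`.
#' @export
branch_params <- function(l_br, theta, epsilon = 0.25 * l_br, kick = 4) {
  stopifnot(is.numeric(l_br), l_br > 0, is.numeric(theta),
            theta >= 0, theta <= 90, epsilon > 0, kick > 0)
  structure(list(l_br = l_br, theta = theta, epsilon = epsilon, kick = kick),
            class = "branch_params")
}

#' Branch registry
#'
#' Bookkeeping of branching nodes: where each branch was initiated (`origin`),
#' its axis (`axis`, the unit direction the leader elongates along), the
#' leading polyp (`leader` vertex id) and the parent branch index (`NA` for
#' the trunk). The trunk (seed apex, axis vertically up) is branch 1, so the
#' branch count `Nbr` is at least 1 in any branching-enabled colony.
#'
#' @return empty object of class `branch_registry`.
#' @export
branch_registry <- function() {
  structure(list(branches = list()), class = "branch_registry")
}

#' @export
print.branch_registry <- function(x, ...) {
  cat(sprintf("<branch_registry> %d branch(es)\n", n_branches(x)))
  invisible(x)
}

#' @rdname branch_registry
#' @param registry a `branch_registry`.
#' @export
n_branches <- function(registry) length(registry$branches)

#' @rdname branch_registry
#' @param origin 3-vector: position where the branch was initiated (the
#'   leader's pre-kick position), mm.
#' @param axis unit 3-vector: branch direction.
#' @param leader vertex id of the leading polyp.
#' @param parent parent branch index (`NA` for the trunk).
#' @export
add_branch <- function(registry, origin, axis, leader, parent = NA_integer_) {
  stopifnot(inherits(registry, "branch_registry"), length(origin) == 3L,
            abs(sqrt(sum(axis^2)) - 1) < 1e-9)
  registry$branches[[n_branches(registry) + 1L]] <-
    list(origin = as.numeric(origin), axis = as.numeric(axis),
         leader = as.integer(leader), parent = as.integer(parent))
  registry
}

# k x 3 matrix of node origins
.branch_origins <- function(registry) {
  do.call(rbind, lapply(registry$branches, `[[`, "origin"))
}

#' Branching rate
#'
#' The self-regulating rate at which candidate polyps are promoted to branch
#' leaders: `nu / (l_br * Nbr)` (per year). The `1/Nbr` damping keeps the
#' total branching activity bounded as the colony ramifies. The per-step
#' selection probability applied to each candidate is `min(1, rate * dt)`.
#'
#' @param params a [branch_params()].
#' @param growth a [growth_params()].
#' @param n_br number of existing branches (>= 1; the trunk counts).
#' @return rate, 1/yr.
#' @export
branch_rate <- function(params, growth, n_br) {
  stopifnot(inherits(params, "branch_params"), inherits(growth, "growth_params"))
  if (n_br < 1L) stop("branch count must be >= 1 (the trunk must be registered)")
  growth$nu / (params$l_br * n_br)
}

#' Candidate polyps for new branches
#'
#' Vertices that are neither leaders nor base polyps and whose Euclidean
#' distance to the nearest branching-node origin lies in the closed band
#' `[l_br - epsilon, l_br + epsilon]`; no candidate may sit closer than
#' `l_br - epsilon` to any node (exclusion zone).
#'
#' @param mesh a `colony_mesh`.
#' @param registry a `branch_registry` (non-empty).
#' @param params a [branch_params()].
#' @return integer vector of candidate vertex ids, ascending (possibly empty).
#' @export
candidate_vertices <- function(mesh, registry, params) {
  stopifnot(inherits(registry, "branch_registry"), n_branches(registry) >= 1L)
  orig <- .branch_origins(registry)
  dmin <- rep(Inf, nrow(mesh$V))
  for (k in seq_len(nrow(orig))) {
    d <- .row_norms(mesh$V - matrix(orig[k, ], nrow(mesh$V), 3L, byrow = TRUE))
    dmin <- pmin(dmin, d)
  }
  lo <- params$l_br - params$epsilon
  hi <- params$l_br + params$epsilon
  ok <- !mesh$is_leader & !mesh$is_base & dmin >= lo & dmin <= hi
  sort(mesh$id[ok])
}

#' Direction of a new branch
#'
#' The unit vector making the branching angle `theta` with the parent branch
#' axis, tilted towards the polyp's own normal: `cos(theta) * axis +
#' sin(theta) * u` where `u` is the normalized projection of the vertex normal
#' onto the plane perpendicular to the axis. For a vertical parent axis this
#' is exactly "sharing the horizontal direction with the normal while the
#' vertical component forms an angle theta with the z-axis". If the normal is
#' parallel to the axis the perpendicular direction is drawn uniformly at
#' random (seeded RNG).
#'
#' @param vertex_normal unit 3-vector.
#' @param parent_axis unit 3-vector.
#' @param theta branching angle, degrees.
#' @return unit 3-vector.
#' @export
branch_direction <- function(vertex_normal, parent_axis, theta) {
  stopifnot(length(vertex_normal) == 3L, length(parent_axis) == 3L)
  th <- theta * pi / 180
  ax <- parent_axis / sqrt(sum(parent_axis^2))
  p <- vertex_normal - sum(vertex_normal * ax) * ax
  np <- sqrt(sum(p^2))
  if (np < 1e-9) {
    # degenerate: draw a direction uniformly in the plane perpendicular to ax
    ref <- if (abs(ax[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- ref - sum(ref * ax) * ax
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(ax[2L] * e1[3L] - ax[3L] * e1[2L],
            ax[3L] * e1[1L] - ax[1L] * e1[3L],
            ax[1L] * e1[2L] - ax[2L] * e1[1L])
    phi <- stats::runif(1L, 0, 2 * pi)
    u <- cos(phi) * e1 + sin(phi) * e2
  } else {
    u <- p / np
  }
  cos(th) * ax + sin(th) * u
}

#' Branching step: promote candidates to branch leaders
#'
#' Each candidate (visited in ascending vertex-id order) independently becomes
#' a new leader with probability `min(1, branch_rate * dt)`. On selection the
#' branching node nearest at step entry becomes its parent (selection and
#' parenting both read the step-entry registry, so every internode distance
#' inherits the selection band), its branch axis is
#' [branch_direction()] of its own normal about the parent axis, it is flagged
#' as leader and immediately displaced `kick * alpha` along the axis, and a
#' new node (origin at its pre-kick position) is appended to the registry.
#'
#' @param mesh a `colony_mesh`.
#' @param registry a `branch_registry`.
#' @param params a [branch_params()].
#' @param growth a [growth_params()].
#' @return list with `mesh`, `registry` and `created` (number of new branches).
#' @export
branching_step <- function(mesh, registry, params, growth) {
  p <- min(1, branch_rate(params, growth, n_branches(registry)) * growth$dt)
  cand <- candidate_vertices(mesh, registry, params)
  created <- 0L
  if (length(cand) == 0L) {
    return(list(mesh = mesh, registry = registry, created = 0L))
  }
  # candidates are selected independently against the step-entry registry:
  # parenting uses the same snapshot, so every internode distance inherits
  # the selection band [l_br - eps, l_br + eps] by construction
  orig <- .branch_origins(registry)
  axes <- lapply(registry$branches, `[[`, "axis")
  for (v in cand) {
    if (stats::runif(1L) >= p) next
    r <- .rows_of(mesh, v)
    d <- .row_norms(orig - matrix(mesh$V[r, ], nrow(orig), 3L, byrow = TRUE))
    parent <- which.min(d)
    axis <- branch_direction(vertex_normal(mesh, v),
                             axes[[parent]], params$theta)
    pre_kick <- mesh$V[r, ]
    mesh$is_leader[r] <- TRUE
    mesh$V[r, ] <- pre_kick + params$kick * growth$alpha * axis
    registry <- add_branch(registry, pre_kick, axis, v, parent)
    created <- created + 1L
  }
  list(mesh = mesh, registry = registry, created = created)
}

#' Leader growth step: persistent apical elongation
#'
#' Every branch-leading polyp advances `alpha = nu * dt` along its branch
#' axis, bypassing the growth-mode gate, so each branch elongates linearly at
#' rate `nu`.
#'
#' @param mesh a `colony_mesh`.
#' @param registry a `branch_registry`.
#' @param growth a [growth_params()].
#' @return list with `mesh` and `moved` (leader count).
#' @export
leader_growth_step <- function(mesh, registry, growth) {
  moved <- 0L
  for (b in registry$branches) {
    r <- match(b$leader, mesh$id)
    if (is.na(r)) stop("dangling branch leader (vertex ", b$leader,
                       " was removed from the mesh)")
    mesh$V[r, ] <- mesh$V[r, ] + growth$alpha * b$axis
    moved <- moved + 1L
  }
  list(mesh = mesh, moved = moved)
}
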