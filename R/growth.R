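# Surface accretion: each polyp relocates by alpha = nu * dt along its surface
# normal, gated by the growth mode s = [smin, smax] acting on the normalized
# elevation xi of the normal. Base polyps grow only horizontally (vertical
# component of their normal suppressed), which anchors the colony.

#' Growth mode (the gate on the normal's elevation)
#'
#' The growth mode `s = [smin, smax]` is the closed interval of permitted
#' values of the normalized elevation `xi` of a polyp's surface normal. It is
#' the principal shape-selecting parameter: `[0, 1]` gives massive
#' (hemispherical) colonies, `[0.01, 1]` cauliflower, `[0.375, 1]` columnar,
#' `[0, 0]` encrusting sheets.
#'
#' @param smin,smax dimensionless bounds, `0 <= smin <= smax <= 1`.
#' @return object of class `growth_mode`.
#' @export
growth_mode <- function(smin, smax) {
  stopifnot(is.numeric(smin), is.numeric(smax), length(smin) == 1L,
            length(smax) == 1L)
  if (!(smin >= 0 && smin <= smax && smax <= 1)) {
    stop("growth mode requires 0 <= smin <= smax <= 1 (got [",
         smin, ", ", smax, "])")
  }
  structure(list(smin = smin, smax = smax), class = "growth_mode")
}

#' @export
print.growth_mode <- function(x, ...) {
  cat(sprintf("<growth_mode> s = [%g, %g]\n", x$smin, x$smax))
  invisible(x)
}

#' Piecewise-in-time growth-mode schedule
#'
#' Tabular colonies use two regimes: an initial vertically biased mode that is
#' switched to a horizontal mode at a fixed time, producing the stem-then-disc
#' shape of table corals.
#'
#' @param t_start numeric vector of regime start times (yr), strictly
#'   increasing, first element 0.
#' @param modes list of [growth_mode()] objects, same length.
#' @return object of class `growth_schedule`.
#' @export
growth_schedule <- function(t_start, modes) {
  if (inherits(modes, "growth_mode")) modes <- list(modes)
  stopifnot(length(t_start) == length(modes), length(t_start) >= 1L)
  if (t_start[1L] != 0) stop("first schedule entry must start at t = 0")
  if (length(t_start) > 1L && any(diff(t_start) <= 0)) {
    stop("schedule start times must be strictly increasing")
  }
  for (m in modes) stopifnot(inherits(m, "growth_mode"))
  structure(list(t_start = as.numeric(t_start), modes = modes),
            class = "growth_schedule")
}

#' Growth mode in force at a given time
#'
#' @param schedule a [growth_schedule()].
#' @param t time, yr (the switch is inclusive at each regime's start time).
#' @return the active [growth_mode()].
#' @export
mode_at <- function(schedule, t) {
  stopifnot(inherits(schedule, "growth_schedule"), t >= 0)
  i <- max(which(schedule$t_start <= t + 1e-12))
  schedule$modes[[i]]
}

#' Growth parameters
#'
#' @param nu linear elongation rate, mm/yr (radial expansion rate for massive
#'   colonies; linear branch extension rate for columnar/branching ones).
#' @param dt time step, yr (0.1 yr throughout).
#' @return object of class `growth_params` with derived per-step displacement
#'   `alpha = nu * dt` (mm).
#' @export
growth_params <- function(nu, dt = 0.1) {
  stopifnot(is.numeric(nu), is.numeric(dt), nu > 0, dt > 0)
  structure(list(nu = nu, dt = dt, alpha = nu * dt), class = "growth_params")
}

# internal, vectorized over rows of a k x 3 matrix; no unit check
.xi_rows <- function(n, variant = "elevation") {
  h <- sqrt(n[, 1L]^2 + n[, 2L]^2)
  if (variant == "elevation") {
    (2 / pi) * atan2(n[, 3L], h)
  } else {  # alternative variant, kept for comparison only
    out <- (2 / pi) * atan((1 - n[, 3L]) / h)
    deg <- h < 1e-12
    out[deg] <- ifelse(n[deg, 3L] >= 1 - 1e-12, 0, 1)
    out
  }
}

#' Normalized elevation of a unit normal
#'
#' `xi` maps a polyp's unit surface normal to the dimensionless range
#' \eqn{[-1, 1]}: `xi = (2/pi) * atan(nz / sqrt(nx^2 + ny^2))`, so that a
#' vertically-up normal gives 1, a horizontal normal 0, and vertically-down
#' gives -1. A polyp accretes only when its `xi` falls inside the growth-mode
#' gate. The `"as_printed"` variant, `(2/pi) * atan((1 - nz)/h)`, is retained
#' for comparison only; it does not reproduce the vertical/horizontal limits
#' above and no preset uses it.
#'
#' @param n unit 3-vector (or k x 3 matrix of unit rows). A non-unit input is
#'   an error; no silent renormalization.
#' @param variant `"elevation"` (default) or `"as_printed"`.
#' @return dimensionless value(s) in \eqn{[-1, 1]}.
#' @export
xi <- function(n, variant = c("elevation", "as_printed")) {
  variant <- match.arg(variant)
  if (is.null(dim(n))) {
    stopifnot(length(n) == 3L)
    n <- matrix(n, 1L, 3L)
    single <- TRUE
  } else {
    single <- FALSE
  }
  nn <- .row_norms(n)
  if (any(abs(nn - 1) > 1e-9)) {
    stop("xi() requires unit normals (|n| - 1 within 1e-9)")
  }
  out <- .xi_rows(n, variant)
  if (single) out[[1L]] else out
}

#' Is growth permitted under a growth mode?
#'
#' Closed-interval gate: `TRUE` iff `smin <= xi_value <= smax`.
#'
#' @param xi_value numeric vector of normalized elevations.
#' @param mode a [growth_mode()].
#' @return logical vector.
#' @export
is_growth_permitted <- function(xi_value, mode) {
  stopifnot(inherits(mode, "growth_mode"))
  xi_value >= mode$smin & xi_value <= mode$smax
}

# Horizontal growth directions for base rows given their full normals; falls
# back to the outward radial direction when the horizontal part is degenerate.
.base_directions <- function(mesh, normals, rows) {
  d <- normals[rows, , drop = FALSE]
  d[, 3L] <- 0
  h <- .row_norms(d)
  deg <- h < 1e-9
  if (any(deg)) {
    p <- mesh$V[rows[deg], , drop = FALSE]
    p[, 3L] <- 0
    hp <- .row_norms(p)
    p[hp < 1e-12, 1L] <- 1  # vertex on the z-axis: arbitrary fixed direction
    hp[hp < 1e-12] <- 1
    d[deg, ] <- p / hp
    h[deg] <- 1
  }
  d / h
}

#' Growth direction of a substrate-bound polyp
#'
#' The vertex normal with its vertical component suppressed and renormalized;
#' base polyps therefore always carry `xi = 0` and expand horizontally, which
#' pins the colony base to the substrate. If the horizontal part of the normal
#' is degenerate the outward radial direction from the colony's z-axis is used.
#'
#' @param mesh a `colony_mesh`.
#' @param v a base vertex id.
#' @return unit 3-vector with zero z-component.
#' @export
base_direction <- function(mesh, v) {
  r <- .rows_of(mesh, v)
  if (!mesh$is_base[r]) stop("vertex ", v, " is not a base vertex")
  d <- vertex_normal(mesh, v)
  d[3L] <- 0
  h <- sqrt(sum(d^2))
  if (h < 1e-9) {
    p <- c(mesh$V[r, 1:2], 0)
    hp <- sqrt(sum(p^2))
    if (hp < 1e-12) return(c(1, 0, 0))  # on the z-axis: fixed tie-break
    return(p / hp)
  }
  d / h
}

#' One synchronous surface-accretion step
#'
#' Every non-leader polyp computes its growth direction (the area-weighted
#' vertex normal, or its horizontal projection for base polyps) from the
#' pre-step geometry, evaluates `xi` of that direction, and, if the growth mode
#' permits, relocates by `alpha = nu * dt` along it. The update is synchronous:
#' all normals are frozen at step start, so the result is independent of vertex
#' ordering.
#'
#' @param mesh a `colony_mesh`.
#' @param mode a [growth_mode()].
#' @param params a [growth_params()].
#' @param xi_variant passed to the elevation functional (see [xi()]).
#' @return list with `mesh` (updated) and `moved` (number of polyps displaced).
#' @export
growth_step <- function(mesh, mode, params, xi_variant = "elevation") {
  stopifnot(inherits(mode, "growth_mode"), inherits(params, "growth_params"))
  normals <- .vertex_normals(mesh)
  if (anyNA(normals)) stop("mesh has isolated vertices; cannot grow")
  dirs <- normals
  brows <- which(mesh$is_base)
  if (length(brows) > 0L) {
    dirs[brows, ] <- .base_directions(mesh, normals, brows)
  }
  xiv <- .xi_rows(dirs, xi_variant)
  move <- is_growth_permitted(xiv, mode) & !mesh$is_leader
  if (any(move)) {
    mesh$V[move, ] <- mesh$V[move, , drop = FALSE] +
      params$alpha * dirs[move, , drop = FALSE]
  }
  list(mesh = mesh, moved = sum(move))
}
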