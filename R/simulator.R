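# Top-level time loop: per time step dt the colony (a) accretes surface along
# gated normals, (b) advances its branch leaders, (c) clones over-spaced
# polyps, (d) fuses over-crowded ones, and (e) may initiate new branches.
# A single seeded RNG stream drives the (only) stochastic component,
# branching; non-branching morphotypes are fully deterministic.

#' Simulation configuration
#'
#' @param schedule a [growth_schedule()] (or a single [growth_mode()], wrapped
#'   into a one-regime schedule).
#' @param growth a [growth_params()].
#' @param clone a [clone_params()].
#' @param branch a [branch_params()] or `NULL` to disable branching.
#' @param t_end total simulated time, yr.
#' @param seed RNG seed (integer).
#' @param snapshot_every snapshot interval, yr.
#' @param xi_variant elevation functional variant (see [xi()]).
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(schedule, growth, clone, branch = NULL,
                              t_end, seed = 1L, snapshot_every = 2,
                              xi_variant = c("elevation", "as_printed")) {
  if (inherits(schedule, "growth_mode")) {
    schedule <- growth_schedule(0, list(schedule))
  }
  stopifnot(inherits(schedule, "growth_schedule"),
            inherits(growth, "growth_params"),
            inherits(clone, "clone_params"),
            is.null(branch) || inherits(branch, "branch_params"),
            t_end > 0, snapshot_every > 0)
  structure(list(schedule = schedule, growth = growth, clone = clone,
                 branch = branch, t_end = t_end, seed = as.integer(seed),
                 snapshot_every = snapshot_every,
                 xi_variant = match.arg(xi_variant)),
            class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  m <- x$schedule$modes[[1L]]
  cat(sprintf(
    "<simulation_config> s=[%g,%g]%s nu=%g mm/yr dt=%g yr delta_sub=%g mm%s t_end=%g yr seed=%d\n",
    m$smin, m$smax,
    if (length(x$schedule$modes) > 1L) " (+schedule)" else "",
    x$growth$nu, x$growth$dt, x$clone$delta_sub,
    if (!is.null(x$branch)) sprintf(" l_br=%g mm theta=%g deg", x$branch$l_br,
                                    x$branch$theta) else "",
    x$t_end, x$seed))
  invisible(x)
}

#' Hexacone seed colony
#'
#' The initial condition: a hexagonal pyramid whose apex is the founder polyp
#' (sexually produced) and whose six base vertices are its first clone
#' generation. The regular hexagonal base has side length `delta_sub`
#' (circumradius = side), the apex height is `delta_sub / 2`, base vertices
#' are substrate-bound, and the base disk is open (the substrate is not
#' meshed). With branching enabled the apex is registered as the trunk leader
#' with a vertical axis.
#'
#' @param delta_sub subdivision distance, mm (sets the seed scale).
#' @param branching register the apex as trunk leader (logical).
#' @return object of class `colony_state` with elements `mesh`, `registry`
#'   (`NULL` when branching is off) and time `t = 0`.
#' @export
make_hexacone_seed <- function(delta_sub, branching = FALSE) {
  stopifnot(delta_sub > 0)
  ang <- (0:5) * pi / 3
  V <- rbind(c(0, 0, delta_sub / 2),
             cbind(delta_sub * cos(ang), delta_sub * sin(ang), 0))
  nxt <- c(2:6, 1) + 1L
  F <- cbind(1L, 2:7, nxt)  # (apex, b_i, b_{i+1}): outward CCW winding
  mesh <- colony_mesh(V, F,
                      is_base = c(FALSE, rep(TRUE, 6L)),
                      is_leader = c(branching, rep(FALSE, 6L)))
  registry <- NULL
  if (branching) {
    registry <- add_branch(branch_registry(), origin = V[1L, ],
                           axis = c(0, 0, 1), leader = 1L)
  }
  structure(list(mesh = mesh, registry = registry, t = 0),
            class = "colony_state")
}

#' @export
print.colony_state <- function(x, ...) {
  cat(sprintf("<colony_state> t = %.1f yr, %d polyps, %d branch(es)\n",
              x$t, nrow(x$mesh$V),
              if (is.null(x$registry)) 0L else n_branches(x$registry)))
  invisible(x)
}

#' One full simulation time step
#'
#' Applies, in order: (1) gated surface accretion with the growth mode in
#' force at the current time; (2) leader elongation (if branching); (3)
#' cloning; (4) fusion; (5) branching (if branching). Advances time by `dt`.
#' The sub-step order guarantees that a fresh branch kick is consolidated by
#' subdivision before the next step and that fusion never precedes the
#' density restoration of cloning.
#'
#' @param state a `colony_state`.
#' @param config a [simulation_config()]. Branching consumes the R RNG
#'   stream; seed it (or use [run_colony()], which does) for reproducibility.
#' @return updated `colony_state`; `state$counts` holds the per-step event
#'   counts (moved, leaders, added, removed, branched).
#' @export
step_colony <- function(state, config) {
  stopifnot(inherits(state, "colony_state"),
            inherits(config, "simulation_config"))
  mode <- mode_at(config$schedule, state$t)
  g <- growth_step(state$mesh, mode, config$growth, config$xi_variant)
  mesh <- g$mesh
  leaders <- 0L
  if (!is.null(config$branch)) {
    lg <- leader_growth_step(mesh, state$registry, config$growth)
    mesh <- lg$mesh
    leaders <- lg$moved
  }
  cl <- cloning_step(mesh, config$clone)
  mesh <- cl$mesh
  fu <- fusion_step(mesh, config$clone)
  mesh <- fu$mesh
  branched <- 0L
  if (!is.null(config$branch)) {
    br <- branching_step(mesh, state$registry, config$branch, config$growth)
    mesh <- br$mesh
    state$registry <- br$registry
    branched <- br$created
  }
  state$mesh <- mesh
  state$t <- state$t + config$growth$dt
  state$counts <- c(moved = g$moved, leaders = leaders, added = cl$added,
                    removed = fu$removed, branched = branched)
  state
}

#' Run a colony simulation
#'
#' Seeds the RNG, builds the hexacone seed and iterates [step_colony()] to
#' `t_end`, recording morphometrics and a mesh snapshot at every multiple of
#' `snapshot_every`. Bitwise-reproducible for a fixed seed; morphotypes
#' without branching consume no randomness at all.
#'
#' @param config a [simulation_config()].
#' @return object of class `colony_run`: list with `config`, `final` (the
#'   final `colony_state`), `snapshots` (list of `list(t, state, metrics)`),
#'   `metrics` (data frame, one row per snapshot) and `log` (per-step event
#'   counts).
#' @export
run_colony <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  state <- make_hexacone_seed(config$clone$delta_sub,
                              branching = !is.null(config$branch))
  nsteps <- round(config$t_end / config$growth$dt)
  snap_steps <- round(config$snapshot_every / config$growth$dt)
  snapshots <- list()
  logs <- vector("list", nsteps)
  for (i in seq_len(nsteps)) {
    state <- step_colony(state, config)
    state$t <- i * config$growth$dt  # exact multiple, no fp drift
    logs[[i]] <- c(t = state$t, n_polyps = nrow(state$mesh$V), state$counts)
    if (i %% snap_steps == 0L || i == nsteps) {
      met <- colony_metrics(state, config$clone)
      snapshots[[length(snapshots) + 1L]] <-
        list(t = state$t, state = state, metrics = met)
    }
  }
  # drop a duplicate final snapshot when t_end is itself a snapshot time
  ts <- vapply(snapshots, `[[`, numeric(1L), "t")
  snapshots <- snapshots[!duplicated(ts)]
  metrics <- do.call(rbind, lapply(snapshots, `[[`, "metrics"))
  structure(list(config = config, final = state, snapshots = snapshots,
                 metrics = metrics,
                 log = as.data.frame(do.call(rbind, logs))),
            class = "colony_run")
}

#' @export
print.colony_run <- function(x, ...) {
  cat(sprintf("<colony_run> t_end = %g yr, %d snapshot(s)\n",
              x$config$t_end, length(x$snapshots)))
  print(x$metrics, row.names = FALSE)
  invisible(x)
}
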