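# Named morphotype presets. All share nu = 10 mm/yr, delta_sub = 10 mm,
# dt = 0.1 yr; only the growth-mode gate (and, for branching, l_br and theta)
# differs:
#   massive      s = [0, 1]        t_end 6 yr   hemispherical dome
#   cauliflower  s = [0.01, 1]     t_end 6 yr   inverted cone
#   columnar     s = [0.375, 1]    t_end 6 yr   pillar
#   branching    s = [0.375, 1], l_br = 40 mm, theta = 30 deg, t_end 32 yr
#   tabular      s = [0.30, 1] until 3 yr, then s = [0, 0.24]; t_end 6 yr
#   encrusting   s = [0, 0]        t_end 6 yr   flat sheet (height frozen)

#' Morphotype preset configurations
#'
#' Builds the [simulation_config()] for one of the six named coral
#' morphotypes. Any argument overrides the preset default.
#'
#' @param name one of `"massive"`, `"cauliflower"`, `"columnar"`,
#'   `"branching"`, `"tabular"`, `"encrusting"`.
#' @param delta_sub subdivision distance, mm.
#' @param nu elongation rate, mm/yr.
#' @param dt time step, yr.
#' @param l_br inter-branching distance, mm (branching preset).
#' @param theta branching angle, degrees (branching preset).
#' @param t_end total time, yr (default 32 for branching, 6 otherwise).
#' @param seed RNG seed.
#' @param snapshot_every snapshot interval, yr.
#' @return a [simulation_config()].
#' @export
preset_config <- function(name = c("massive", "cauliflower", "columnar",
                                   "branching", "tabular", "encrusting"),
                          delta_sub = 10, nu = 10, dt = 0.1,
                          l_br = 40, theta = 30,
                          t_end = NULL, seed = 1L, snapshot_every = 2) {
  name <- match.arg(name)
  growth <- growth_params(nu, dt)
  clone <- clone_params(delta_sub)
  branch <- NULL
  schedule <- switch(name,
    massive = growth_schedule(0, list(growth_mode(0, 1))),
    cauliflower = growth_schedule(0, list(growth_mode(0.01, 1))),
    columnar = growth_schedule(0, list(growth_mode(0.375, 1))),
    branching = growth_schedule(0, list(growth_mode(0.375, 1))),
    tabular = growth_schedule(c(0, 3), list(growth_mode(0.30, 1),
                                            growth_mode(0, 0.24))),
    encrusting = growth_schedule(0, list(growth_mode(0, 0))))
  if (name == "branching") branch <- branch_params(l_br, theta)
  if (is.null(t_end)) t_end <- if (name == "branching") 32 else 6
  simulation_config(schedule = schedule, growth = growth, clone = clone,
                    branch = branch, t_end = t_end, seed = seed,
                    snapshot_every = snapshot_every)
}
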