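# Mesh serialization (OBJ / ascii PLY / ascii STL) and the flat key:value
# configuration format. All formats are plain text; PLY additionally carries
# the per-polyp attributes (base flag, leader flag, xi of the vertex normal).

#' Export a colony mesh to OBJ, PLY or STL
#'
#' OBJ carries vertices and oriented faces; ascii PLY additionally stores the
#' per-vertex attributes `is_base`, `is_leader` and `xi` (normalized
#' elevation of the vertex normal); ascii STL stores bare triangles. OBJ and
#' PLY round-trip through [read_mesh()] with coordinates preserved to 1e-6 mm.
#'
#' @param x a `colony_mesh` or `colony_state`.
#' @param path output file.
#' @param format `"obj"`, `"ply"` or `"stl"` (default: from the file
#'   extension).
#' @return `path`, invisibly.
#' @export
export_mesh <- function(x, path, format = NULL) {
  mesh <- if (inherits(x, "colony_state")) x$mesh else x
  stopifnot(inherits(mesh, "colony_mesh"))
  if (is.null(format)) {
    format <- tolower(tools::file_ext(path))
  }
  format <- match.arg(tolower(format), c("obj", "ply", "stl"))
  lines <- switch(format,
    obj = c("# coralclone colony mesh",
            sprintf("v %.9g %.9g %.9g", mesh$V[, 1L], mesh$V[, 2L], mesh$V[, 3L]),
            sprintf("f %d %d %d", mesh$F[, 1L], mesh$F[, 2L], mesh$F[, 3L])),
    ply = {
      nn <- .vertex_normals(mesh)
      xiv <- .xi_rows(nn)
      xiv[is.na(xiv)] <- 0
      c("ply", "format ascii 1.0",
        sprintf("element vertex %d", nrow(mesh$V)),
        "property float x", "property float y", "property float z",
        "property uchar is_base", "property uchar is_leader",
        "property float xi",
        sprintf("element face %d", nrow(mesh$F)),
        "property list uchar int vertex_indices",
        "end_header",
        sprintf("%.9g %.9g %.9g %d %d %.9g",
                mesh$V[, 1L], mesh$V[, 2L], mesh$V[, 3L],
                as.integer(mesh$is_base), as.integer(mesh$is_leader), xiv),
        sprintf("3 %d %d %d",
                mesh$F[, 1L] - 1L, mesh$F[, 2L] - 1L, mesh$F[, 3L] - 1L))
    },
    stl = {
      fn <- .normalize_rows(.face_cross(mesh$V, mesh$F))
      body <- character(0)
      for (i in seq_len(nrow(mesh$F))) {
        tri <- mesh$V[mesh$F[i, ], , drop = FALSE]
        body <- c(body,
                  sprintf("  facet normal %.9g %.9g %.9g",
                          fn[i, 1L], fn[i, 2L], fn[i, 3L]),
                  "    outer loop",
                  sprintf("      vertex %.9g %.9g %.9g",
                          tri[, 1L], tri[, 2L], tri[, 3L]),
                  "    endloop", "  endfacet")
      }
      c("solid colony", body, "endsolid colony")
    })
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write mesh to ", path)
  invisible(path)
}

#' Read a colony mesh from OBJ or PLY
#'
#' @param path file written by [export_mesh()] (or any triangle OBJ / ascii
#'   PLY with the same layout). PLY restores the `is_base` / `is_leader`
#'   flags.
#' @return a `colony_mesh`.
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  lines <- readLines(path)
  if (ext == "obj") {
    vl <- lines[startsWith(lines, "v ")]
    fl <- lines[startsWith(lines, "f ")]
    V <- do.call(rbind, lapply(strsplit(trimws(sub("^v", "", vl)), "\\s+"),
                               function(x) as.numeric(x[1:3])))
    F <- do.call(rbind, lapply(strsplit(trimws(sub("^f", "", fl)), "\\s+"),
                               function(x) as.integer(sub("/.*", "", x[1:3]))))
    colony_mesh(V, F)
  } else if (ext == "ply") {
    he <- which(lines == "end_header")
    nv <- as.integer(sub("element vertex ", "",
                         grep("^element vertex", lines, value = TRUE)))
    nf <- as.integer(sub("element face ", "",
                         grep("^element face", lines, value = TRUE)))
    vrows <- lines[(he + 1L):(he + nv)]
    frows <- lines[(he + nv + 1L):(he + nv + nf)]
    vm <- do.call(rbind, lapply(strsplit(vrows, "\\s+"), as.numeric))
    fm <- do.call(rbind, lapply(strsplit(frows, "\\s+"), as.integer))
    colony_mesh(vm[, 1:3, drop = FALSE], fm[, 2:4, drop = FALSE] + 1L,
                is_base = vm[, 4L] != 0, is_leader = vm[, 5L] != 0)
  } else {
    stop("unsupported mesh format: ", ext)
  }
}

# keys understood by the flat config format
.config_keys <- c("preset", "smin", "smax", "schedule", "nu", "delta_sub",
                  "l_br", "theta", "dt", "t_end", "seed", "snapshot_every",
                  "xi_variant")

#' Load a simulation configuration from a flat key:value file
#'
#' The format is a flat YAML-style `key: value` file (comments start with
#' `#`). Recognized keys: `preset`, `smin`, `smax`, `schedule`, `nu`,
#' `delta_sub`, `l_br`, `theta`, `dt`, `t_end`, `seed`, `snapshot_every`,
#' `xi_variant`. A `schedule` is written as semicolon-separated
#' `t,smin,smax` triples, e.g. `schedule: 0,0.30,1; 3,0,0.24`. Defaults:
#' `dt = 0.1`, `epsilon = 0.25 * l_br`, `delta_fuse = 0.2 * delta_sub`;
#' branching is enabled when `l_br` is given or the preset is `branching`.
#' Unknown keys and invalid values are rejected with a message listing every
#' violation.
#'
#' @param path configuration file.
#' @return a [simulation_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*:\\s*(.*)$", lines))
  bad <- lengths(kv) != 3L
  errs <- character(0)
  if (any(bad)) errs <- c(errs, paste0("unparseable line(s): ",
                                       paste(lines[bad], collapse = " | ")))
  keys <- vapply(kv[!bad], `[[`, character(1L), 2L)
  vals <- vapply(kv[!bad], `[[`, character(1L), 3L)
  unknown <- setdiff(keys, .config_keys)
  if (length(unknown) > 0L) {
    errs <- c(errs, paste0("unknown key(s): ", paste(unknown, collapse = ", ")))
  }
  if (anyDuplicated(keys)) errs <- c(errs, "duplicate key(s)")
  if (length(errs) > 0L) stop("invalid configuration:\n  - ",
                              paste(errs, collapse = "\n  - "))
  cfg <- as.list(vals)
  names(cfg) <- keys
  num <- function(k) if (k %in% keys) as.numeric(cfg[[k]]) else NULL

  # start from preset defaults when given
  preset <- cfg$preset
  smin <- num("smin"); smax <- num("smax")
  nu <- num("nu"); delta_sub <- num("delta_sub")
  l_br <- num("l_br"); theta <- num("theta")
  dt <- num("dt"); t_end <- num("t_end"); seed <- num("seed")
  snap <- num("snapshot_every")
  for (k in c("smin", "smax", "nu", "delta_sub", "l_br", "theta", "dt",
              "t_end", "seed", "snapshot_every")) {
    v <- num(k)
    if (!is.null(v) && (is.na(v) || !is.finite(v))) {
      errs <- c(errs, paste0("key '", k, "' is not a number"))
    }
  }
  if (!is.null(smin) && !is.null(smax) && length(errs) == 0L && smin > smax) {
    errs <- c(errs, "smin > smax")
  }
  if (length(errs) > 0L) stop("invalid configuration:\n  - ",
                              paste(errs, collapse = "\n  - "))

  build <- function() {
    if (!is.null(preset)) {
      args <- list(name = preset)
      if (!is.null(delta_sub)) args$delta_sub <- delta_sub
      if (!is.null(nu)) args$nu <- nu
      if (!is.null(dt)) args$dt <- dt
      if (!is.null(l_br)) args$l_br <- l_br
      if (!is.null(theta)) args$theta <- theta
      if (!is.null(t_end)) args$t_end <- t_end
      if (!is.null(seed)) args$seed <- as.integer(seed)
      if (!is.null(snap)) args$snapshot_every <- snap
      conf <- do.call(preset_config, args)
      if (!is.null(smin) || !is.null(smax)) {
        m <- conf$schedule$modes[[1L]]
        conf$schedule <- growth_schedule(0, list(growth_mode(
          if (is.null(smin)) m$smin else smin,
          if (is.null(smax)) m$smax else smax)))
      }
      return(conf)
    }
    sched <- if ("schedule" %in% keys) {
      parts <- strsplit(cfg$schedule, ";")[[1L]]
      triple <- lapply(strsplit(trimws(parts), ","), as.numeric)
      growth_schedule(vapply(triple, `[[`, numeric(1L), 1L),
                      lapply(triple, function(x) growth_mode(x[2L], x[3L])))
    } else {
      if (is.null(smin) || is.null(smax)) {
        stop("invalid configuration:\n  - smin and smax (or a preset or a ",
             "schedule) are required")
      }
      growth_schedule(0, list(growth_mode(smin, smax)))
    }
    if (is.null(nu) || is.null(delta_sub) || is.null(t_end)) {
      stop("invalid configuration:\n  - nu, delta_sub and t_end are required ",
           "when no preset is given")
    }
    branch <- if (!is.null(l_br)) {
      branch_params(l_br, if (is.null(theta)) 30 else theta)
    }
    simulation_config(
      schedule = sched,
      growth = growth_params(nu, if (is.null(dt)) 0.1 else dt),
      clone = clone_params(delta_sub), branch = branch, t_end = t_end,
      seed = if (is.null(seed)) 1L else as.integer(seed),
      snapshot_every = if (is.null(snap)) 2 else snap,
      xi_variant = if ("xi_variant" %in% keys) cfg$xi_variant else "elevation")
  }
  build()
}

#' Write a configuration in the flat key:value format
#'
#' Inverse of [load_config()]: `load_config(dump_config(cfg, f))` yields an
#' identical configuration.
#'
#' @param config a [simulation_config()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
dump_config <- function(config, path) {
  stopifnot(inherits(config, "simulation_config"))
  sch <- config$schedule
  lines <- c(
    sprintf("schedule: %s", paste(vapply(seq_along(sch$t_start), function(i) {
      sprintf("%.10g,%.10g,%.10g", sch$t_start[i], sch$modes[[i]]$smin,
              sch$modes[[i]]$smax)
    }, character(1L)), collapse = "; ")),
    sprintf("nu: %.10g", config$growth$nu),
    sprintf("dt: %.10g", config$growth$dt),
    sprintf("delta_sub: %.10g", config$clone$delta_sub),
    sprintf("t_end: %.10g", config$t_end),
    sprintf("seed: %d", config$seed),
    sprintf("snapshot_every: %.10g", config$snapshot_every),
    sprintf("xi_variant: %s", config$xi_variant))
  if (!is.null(config$branch)) {
    lines <- c(lines,
               sprintf("l_br: %.10g", config$branch$l_br),
               sprintf("theta: %.10g", config$branch$theta))
  }
  writeLines(lines, path)
  invisible(path)
}
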