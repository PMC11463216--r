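test_that("branch_rate implements the self-regulating formula", {
  g <- growth_params(10, 0.1)
  p <- branch_params(40, 30)
  expect_equal(branch_rate(p, g, 1L), 0.25)                # nu/(l_br * Nbr)
  expect_equal(branch_rate(p, g, 1L) * g$dt, 0.025)        # per-step prob
  expect_equal(branch_rate(p, g, 2L), branch_rate(p, g, 1L) / 2)
  expect_error(branch_rate(p, g, 0L), "trunk")
  # grid cross-check against the closed form
  for (nu in c(5, 10, 12)) {
    for (lbr in c(20, 40, 60)) {
      for (nbr in 1:4) {
        expect_equal(branch_rate(branch_params(lbr, 30), growth_params(nu), nbr),
                     nu / (lbr * nbr))
      }
    }
  }
})

test_that("branch_params derives the selection band and validates theta", {
  p <- branch_params(40, 30)
  expect_equal(p$epsilon, 10)   # 0.25 * l_br
  expect_equal(p$kick, 4)
  expect_error(branch_params(40, 120))
  expect_error(branch_params(-1, 30))
})

test_that("candidate_vertices selects the closed spherical band", {
  # vertical trunk: cylinder of height 60, node at the base centre
  cyl <- cylinder_mesh(r = 10, h = 60, n_around = 12L, n_axial = 25L)
  reg <- add_branch(branch_registry(), c(0, 0, 0), c(0, 0, 1),
                    leader = cyl$id[which.max(cyl$V[, 3L])])
  cyl$is_leader[which.max(cyl$V[, 3L])] <- TRUE
  p <- branch_params(40, 30)  # band [30, 50]
  cand <- candidate_vertices(cyl, reg, p)
  d <- sqrt(rowSums(cyl$V^2))
  manual <- sort(cyl$id[d >= 30 & d <= 50 & !cyl$is_leader & !cyl$is_base])
  expect_identical(cand, manual)
  expect_gt(length(cand), 0L)
  # closed band: a vertex at exactly l_br is included
  m <- colony_mesh(rbind(c(40, 0, 0), c(41, 1, 0), c(40, 0, 1)),
                   rbind(c(1L, 2L, 3L)))
  reg2 <- add_branch(branch_registry(), c(0, 0, 0), c(0, 0, 1), leader = 1L)
  expect_true(1L %in% candidate_vertices(m, reg2, p))
})

test_that("a young colony offers no candidates", {
  st <- make_hexacone_seed(10, branching = TRUE)
  p <- branch_params(40, 30)
  # everything is within ~10 mm of the apex node: below the 30 mm band floor
  expect_length(candidate_vertices(st$mesh, st$registry, p), 0L)
})

test_that("branch_direction tilts the parent axis toward the normal", {
  z <- c(0, 0, 1)
  expect_equal(branch_direction(c(0.6, 0, 0.8), z, 0), z, tolerance = 1e-12)
  n <- c(1, 0, 0.5); n <- n / sqrt(sum(n^2))
  expect_equal(branch_direction(n, z, 90), c(1, 0, 0), tolerance = 1e-12)
  expect_equal(branch_direction(c(1, 0, 1) / sqrt(2), z, 30),
               c(0.5, 0, sqrt(3) / 2), tolerance = 1e-12)
  # angle with an arbitrary parent axis is exactly theta
  ax <- c(1, 1, 1) / sqrt(3)
  d <- branch_direction(c(0.2, -0.4, 0.89), ax, 42)
  expect_equal(acos(sum(d * ax)) * 180 / pi, 42, tolerance = 1e-9)
  expect_equal(sqrt(sum(d^2)), 1, tolerance = 1e-12)
  # degenerate projection: direction drawn in the perpendicular plane
  set.seed(1)
  d2 <- branch_direction(z, z, 35)
  expect_equal(acos(sum(d2 * z)) * 180 / pi, 35, tolerance = 1e-9)
})

test_that("branching_step promotes a candidate with certainty when rate*dt >= 1", {
  # one eligible vertex at exactly l_br = 40 from the node; nu chosen so that
  # rate * dt = 400/(40*1) * 0.1 = 1 (certain selection)
  m <- colony_mesh(rbind(c(40, 0, 0), c(41, 1, 0), c(40, 0, 1)),
                   rbind(c(1L, 2L, 3L)), is_leader = c(FALSE, FALSE, TRUE))
  reg <- add_branch(branch_registry(), c(0, 0, 0), c(0, 0, 1), leader = 3L)
  g <- growth_params(nu = 400, dt = 0.1)  # alpha = 40
  p1 <- branch_params(l_br = 40, theta = 30, epsilon = 1e-6)
  expect_identical(candidate_vertices(m, reg, p1), 1L)
  pre <- m$V[1L, ]
  set.seed(99)
  res <- branching_step(m, reg, p1, g)
  expect_equal(res$created, 1L)
  expect_equal(n_branches(res$registry), 2L)
  node <- res$registry$branches[[2L]]
  expect_equal(node$leader, 1L)
  expect_equal(node$origin, pre)
  expect_equal(node$parent, 1L)
  r <- match(1L, res$mesh$id)
  expect_true(res$mesh$is_leader[r])
  # kicked exactly 4 * alpha along the branch axis
  expect_equal(res$mesh$V[r, ], pre + 4 * g$alpha * node$axis,
               tolerance = 1e-12)
  # the axis makes the branching angle with the parent axis
  expect_equal(acos(sum(node$axis * c(0, 0, 1))) * 180 / pi, 30,
               tolerance = 1e-9)
})

test_that("no candidates means no branching and an untouched registry", {
  st <- make_hexacone_seed(10, branching = TRUE)
  res <- branching_step(st$mesh, st$registry, branch_params(40, 30),
                        growth_params(10))
  expect_equal(res$created, 0L)
  expect_equal(n_branches(res$registry), 1L)
})

test_that("branching events follow the binomial expectation", {
  cyl <- cylinder_mesh(r = 10, h = 60, n_around = 12L, n_axial = 25L)
  top <- cyl$id[which.max(cyl$V[, 3L])]
  cyl$is_leader[match(top, cyl$id)] <- TRUE
  reg <- add_branch(branch_registry(), c(0, 0, 0), c(0, 0, 1), leader = top)
  g <- growth_params(10, 0.1)
  p <- branch_params(40, 30)  # per-candidate prob = 0.025 per step
  C <- length(candidate_vertices(cyl, reg, p))
  B <- 400L
  set.seed(1234)
  created <- 0L
  for (i in seq_len(B)) {
    created <- created + branching_step(cyl, reg, p, g)$created
  }
  prob <- branch_rate(p, g, 1L) * g$dt
  expected <- B * C * prob
  se <- sqrt(B * C * prob * (1 - prob))
  expect_lt(abs(created - expected), 3 * se)
})

test_that("leaders elongate persistently along their axis, bypassing the gate", {
  st <- make_hexacone_seed(10, branching = TRUE)
  g <- growth_params(10, 0.1)
  mesh <- st$mesh
  for (i in 1:10) mesh <- leader_growth_step(mesh, st$registry, g)$mesh
  expect_equal(mesh$V[1L, ], c(0, 0, 15))  # +10 mm vertically
  # a theta = 90 branch advances purely horizontally
  reg <- add_branch(st$registry, c(0, 0, 5), c(1, 0, 0), leader = 2L)
  mesh2 <- st$mesh
  mesh2$is_leader[2L] <- TRUE
  res <- leader_growth_step(mesh2, reg, g)
  expect_equal(res$moved, 2L)
  expect_equal(res$mesh$V[2L, ], c(11, 0, 0))
  # dangling leader is an error
  reg_bad <- add_branch(branch_registry(), c(0, 0, 0), c(0, 0, 1), leader = 999L)
  expect_error(leader_growth_step(st$mesh, reg_bad, g), "dangling")
})

test_that("branch elongation rate equals nu along the branch axis", {
  cfg <- preset_config("branching", t_end = 6, seed = 5)
  run <- run_colony(cfg)
  trunk <- run$final$registry$branches[[1L]]
  r <- match(trunk$leader, run$final$mesh$id)
  tip <- sum((run$final$mesh$V[r, ] - trunk$origin) * trunk$axis)
  # trunk leader advanced nu * t along z from its origin
  expect_equal(tip, 10 * 6, tolerance = 1e-9)
})
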