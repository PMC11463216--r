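test_that("clone_params derives the fusion distance", {
  p <- clone_params(10)
  expect_identical(p$delta_fuse, 2)
  expect_error(clone_params(-1))
})

test_that("bezier_midpoint degenerates to the chord midpoint on flat regions", {
  expect_equal(bezier_midpoint(c(0, 0, 0), c(0, 0, 1), c(10, 0, 0), c(0, 0, 1)),
               c(5, 0, 0))
  # property: whenever both normals are perpendicular to the edge the handles
  # cancel and the Euclidean midpoint comes out exactly
  withr::with_seed(3, {
    for (rep in 1:20) {
      A <- runif(3, -5, 5); B <- runif(3, -5, 5)
      d <- (B - A) / sqrt(sum((B - A)^2))
      r <- runif(3, -1, 1)
      n <- r - sum(r * d) * d
      n <- n / sqrt(sum(n^2))
      expect_equal(bezier_midpoint(A, n, B, n), (A + B) / 2, tolerance = 1e-9)
    }
  })
})

test_that("bezier_midpoint matches the hand-evaluated curved configuration", {
  # A=(-5,0,0), nA=(-1,0,1)/sqrt(2), B=(5,0,0), nB=(1,0,1)/sqrt(2):
  # tangent handles tilt both control points up by (10/3)/sqrt(2), giving the
  # de Casteljau midpoint (0, 0, 10*sqrt(2)/8) = (0, 0, 1.7677670)
  p <- bezier_midpoint(c(-5, 0, 0), c(-sqrt(2) / 2, 0, sqrt(2) / 2),
                       c(5, 0, 0), c(sqrt(2) / 2, 0, sqrt(2) / 2))
  expect_equal(p, c(0, 0, 1.76776695), tolerance = 1e-7)
})

test_that("bezier_midpoint agrees with an independent de Casteljau evaluation", {
  withr::with_seed(5, {
    for (rep in 1:20) {
      A <- runif(3, -5, 5); B <- runif(3, -5, 5)
      nA <- runif(3, -1, 1); nA <- nA / sqrt(sum(nA^2))
      nB <- runif(3, -1, 1); nB <- nB / sqrt(sum(nB^2))
      L <- sqrt(sum((B - A)^2))
      u <- (B - A) / L
      tA <- u - sum(u * nA) * nA; tA <- tA / sqrt(sum(tA^2))
      tB <- -u - sum(-u * nB) * nB; tB <- tB / sqrt(sum(tB^2))
      P1 <- A + (L / 3) * tA
      P2 <- B + (L / 3) * tB
      expect_equal(bezier_midpoint(A, nA, B, nB),
                   decasteljau(A, P1, P2, B, 0.5), tolerance = 1e-9)
      # and the closed form (P0 + 3P1 + 3P2 + P3)/8
      expect_equal(decasteljau(A, P1, P2, B, 0.5),
                   (A + 3 * P1 + 3 * P2 + B) / 8, tolerance = 1e-12)
    }
  })
})

test_that("bezier_midpoint is mirror-symmetric and rejects coincident points", {
  A <- c(-3, 1, 0); B <- c(4, -2, 1)
  nA <- c(0.2, -0.3, 0.93); nA <- nA / sqrt(sum(nA^2))
  nB <- c(-0.5, 0.1, 0.86); nB <- nB / sqrt(sum(nB^2))
  expect_equal(bezier_midpoint(A, nA, B, nB), bezier_midpoint(B, nB, A, nA))
  expect_error(bezier_midpoint(A, nA, A, nA), "coincident")
})

test_that("cloning_step leaves a within-bound mesh untouched", {
  tp <- tri_lattice_patch(4L, 4L, 1)
  res <- cloning_step(tp, clone_params(10))
  expect_equal(res$added, 0L)
  expect_identical(res$mesh$V, tp$V)
})

test_that("cloning_step splits a single over-long flat edge at its midpoint", {
  # two flat triangles sharing an 11 mm edge; all other edges are short
  V <- rbind(c(0, 0, 0), c(11, 0, 0), c(5.5, 3, 0), c(5.5, -3, 0))
  m <- colony_mesh(V, rbind(c(1L, 2L, 3L), c(2L, 1L, 4L)))
  res <- cloning_step(m, clone_params(10))
  expect_equal(res$added, 1L)
  r <- match(5L, res$mesh$id)
  expect_equal(res$mesh$V[r, ], c(5.5, 0, 0), tolerance = 1e-9)
  e <- mesh_edges(res$mesh)
  daughters <- e[e$v1 == 5L | e$v2 == 5L, ]
  expect_equal(sort(daughters$length)[3:4], c(5.5, 5.5), tolerance = 1e-9)
  expect_true(all(e$length <= 10))
})

test_that("a uniformly over-stretched patch splits every original edge once", {
  dsub <- 10
  # at 1.15 * dsub the daughter half-edges (0.575 dsub) AND the new
  # midpoint-to-apex edges (1.15 * sqrt(3)/2 = 0.996 dsub) are all in bound,
  # so exactly one split per original edge occurs
  tp <- tri_lattice_patch(4L, 4L, 1.15 * dsub)
  n_edges <- nrow(mesh_edges(tp))
  res <- cloning_step(tp, clone_params(dsub))
  expect_equal(res$added, n_edges)
  e <- mesh_edges(res$mesh)
  expect_true(all(e$length <= dsub))
  expect_true(validate_mesh(res$mesh)$ok)

  # at 1.5 * dsub the cross edges (1.30 dsub) must split again: every original
  # edge is still split (no original adjacency survives) and the bound holds
  tp2 <- tri_lattice_patch(4L, 4L, 1.5 * dsub)
  e0 <- mesh_edges(tp2)
  res2 <- cloning_step(tp2, clone_params(dsub))
  expect_gte(res2$added, nrow(e0))
  e2 <- mesh_edges(res2$mesh)
  key2 <- paste(pmin(e2$v1, e2$v2), pmax(e2$v1, e2$v2))
  key0 <- paste(pmin(e0$v1, e0$v2), pmax(e0$v1, e0$v2))
  expect_false(any(key0 %in% key2))
  expect_true(all(e2$length <= dsub))
})

test_that("cloning_step enforces the max-edge bound on curved colonies", {
  cfg <- preset_config("massive")
  st <- make_hexacone_seed(10)
  for (i in 1:30) {
    st <- step_colony(st, cfg)
    expect_true(all(mesh_edges(st$mesh)$length <= 10 + 1e-9))
  }
})

test_that("fusion_step collapses only under-short edges, shortest first", {
  tp <- tri_lattice_patch(5L, 5L, 1)
  expect_equal(fusion_step(tp, clone_params(1))$removed, 0L)  # all >= 0.2
  # shrink one interior edge to 1.9 mm with delta_sub = 10 (delta_fuse = 2)
  tp2 <- tri_lattice_patch(5L, 5L, 10)
  e <- mesh_edges(tp2)
  bnd <- unique(c(e$v1[e$n_faces == 1L], e$v2[e$n_faces == 1L]))
  ie <- e[!(e$v1 %in% bnd) & !(e$v2 %in% bnd), ][1L, ]
  ra <- match(ie$v1, tp2$id); rb <- match(ie$v2, tp2$id)
  dir <- tp2$V[rb, ] - tp2$V[ra, ]
  tp2$V[rb, ] <- tp2$V[ra, ] + dir / sqrt(sum(dir^2)) * 1.9
  res <- fusion_step(tp2, clone_params(10))
  expect_equal(res$removed, 1L)
  expect_false(all(c(ie$v1, ie$v2) %in% res$mesh$id))  # one absorbed
  surv <- intersect(c(ie$v1, ie$v2), res$mesh$id)
  expect_equal(res$mesh$V[match(surv, res$mesh$id), ],
               tp2$V[ra, ] + dir / sqrt(sum(dir^2)) * 0.95, tolerance = 1e-9)
})

test_that("fusion skips collapses that would break manifoldness", {
  m <- link_violation_fixture()
  m$V <- m$V * 10  # scale up so only the 1-2 edge is a fusion candidate
  m$V[2L, ] <- m$V[1L, ] + c(1.9, 0, 0)
  res <- fusion_step(m, clone_params(10))
  expect_equal(res$removed, 0L)
  expect_identical(res$mesh$F, m$F)
})

test_that("fusion absorbs into leaders and never removes them", {
  tp <- tri_lattice_patch(5L, 5L, 10)
  e <- mesh_edges(tp)
  bnd <- unique(c(e$v1[e$n_faces == 1L], e$v2[e$n_faces == 1L]))
  ie <- e[!(e$v1 %in% bnd) & !(e$v2 %in% bnd), ][1L, ]
  ra <- match(ie$v1, tp$id); rb <- match(ie$v2, tp$id)
  tp$is_leader[ra] <- TRUE
  lead_pos <- tp$V[ra, ]
  tp$V[rb, ] <- lead_pos + c(1, 0, 0)  # 1 mm < delta_fuse
  res <- fusion_step(tp, clone_params(10))
  expect_equal(res$removed, 1L)
  expect_true(ie$v1 %in% res$mesh$id)       # leader survives
  expect_false(ie$v2 %in% res$mesh$id)      # neighbour absorbed
  r <- match(ie$v1, res$mesh$id)
  expect_equal(res$mesh$V[r, ], lead_pos)   # in place
  expect_true(res$mesh$is_leader[r])
})
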