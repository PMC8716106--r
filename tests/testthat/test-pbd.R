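test_that("effective stiffness correction matches its closed form", {
  expect_equal(effective_stiffness(1, 5), 1)
  expect_equal(effective_stiffness(0, 5), 0)
  expect_equal(effective_stiffness(0.75, 2), 0.5)
  # monotone increasing in k, decreasing in n
  ks <- seq(0, 1, by = 0.1)
  expect_true(all(diff(effective_stiffness(ks, 4)) >= 0))
  expect_true(all(diff(vapply(1:8, function(n) effective_stiffness(0.6, n),
                              numeric(1))) <= 0))
})

test_that("repeated k'-projection approximates single-pass stiffness", {
  # two points, distance constraint with stiffness k applied once vs
  # k' applied n times: residual violations agree within 5%
  for (k in c(0.3, 0.6, 0.9)) {
    n <- 6
    single <- (1 - k) * 1              # violation remaining after one pass
    pos <- matrix(c(0, 0, 2, 0), 2, 2, byrow = TRUE)
    for (it in seq_len(n)) {
      pr <- project_distance(pos, 1L, 2L, rest = 1, stiffness = k, n_iter = n)
      pos[1, ] <- pos[1, ] + pr$d_i
      pos[2, ] <- pos[2, ] + pr$d_j
    }
    remaining <- abs(sqrt(sum((pos[1, ] - pos[2, ])^2)) - 1)
    expect_lt(abs(remaining - single) / single, 0.05)
  }
})

test_that("distance projection splits corrections by inverse mass", {
  pos <- matrix(c(0, 0, 2, 0), 2, 2, byrow = TRUE)
  # symmetric projection halves the violation on each side
  st <- pbd_step(list(pos = pos),
                 list(list(kind = "distance", i = 1L, j = 2L, rest = 1, k = 1)),
                 dt = 1, iterations = 1)
  expect_equal(st$pos[1, ], c(0.5, 0))
  expect_equal(st$pos[2, ], c(1.5, 0))
  # at rest length: zero correction
  pr <- project_distance(matrix(c(0, 0, 1, 0), 2, 2, byrow = TRUE),
                         1L, 2L, rest = 1)
  expect_equal(pr$d_i, matrix(0, 1, 2), ignore_attr = TRUE)
  # pinned first vertex absorbs nothing
  pr <- project_distance(pos, 1L, 2L, rest = 1, inv_mass = c(0, 1))
  expect_equal(pr$d_i, matrix(0, 1, 2), ignore_attr = TRUE)
  expect_equal(pr$d_j[1, 1], -1)   # p2 moves the full violation
  # masses 1 and 3 -> inverse masses 1 and 1/3 -> 3:1 split (analytic)
  pos2 <- matrix(c(0, 0, 1.4, 0), 2, 2, byrow = TRUE)
  pr <- project_distance(pos2, 1L, 2L, rest = 1, inv_mass = c(1, 1 / 3))
  expect_equal(pr$d_i[1, 1], 0.4 * (1 / (1 + 1 / 3)))      # = 0.3
  expect_equal(pr$d_j[1, 1], -0.4 * ((1 / 3) / (1 + 1 / 3))) # = -0.1
  expect_equal(abs(pr$d_i[1, 1] / pr$d_j[1, 1]), 3)
})

test_that("a zero-force, zero-constraint step leaves the state unchanged", {
  pos <- matrix(stats::rnorm(10), 5, 2)
  st <- pbd_step(list(pos = pos), list(), dt = 0.5, iterations = 3)
  expect_equal(st$pos, pos)
  expect_equal(st$vel, matrix(0, 5, 2))
})

test_that("constraint residual is non-increasing on a random spring network", {
  set.seed(11)
  n <- 10
  pos <- matrix(stats::rnorm(2 * n, sd = 2), n, 2)
  i <- sample(n, 18, replace = TRUE)
  j <- ((i + sample(n - 1, 18, replace = TRUE) - 1) %% n) + 1
  keep <- i != j
  i <- i[keep]; j <- j[keep]
  rest <- stats::runif(length(i), 0.5, 2)
  resid <- function(p) sum(abs(sqrt((p[i, 1] - p[j, 1])^2 +
                                      (p[i, 2] - p[j, 2])^2) - rest))
  r <- numeric(50)
  for (it in 1:50) {
    for (k in seq_along(i)) {     # Gauss-Seidel: one constraint at a time
      pr <- project_distance(pos, i[k], j[k], rest[k], stiffness = 0.8,
                             n_iter = 1)
      pos[i[k], ] <- pos[i[k], ] + pr$d_i[1, ]
      pos[j[k], ] <- pos[j[k], ] + pr$d_j[1, ]
    }
    r[it] <- resid(pos)
  }
  expect_true(all(diff(r) <= 1e-9))
})

test_that("pressure constraint drives the area to its target", {
  cc <- make_rect_cell(1, 1)
  ring <- cc$rings[[1]]
  pos <- cc$V
  target <- 1.2
  rv <- cc$ring_vertex
  # XPBD: lambda accumulates within a step and resets across steps;
  # iterate steps until the compliant fixed point is reached
  for (it in 1:200) {
    pr <- project_pressure(pos, rv, cc$ring_cell, cc$ring_prev_v,
                           cc$ring_next_v, target, compliance = 10,
                           lambda = 0)
    pos[rv, ] <- pos[rv, ] + pr$dP
  }
  expect_lt(abs(polygon_area(pos[ring, ]) - target) / target, 0.01)
  # target equal to current area: zero correction
  pr <- project_pressure(cc$V, rv, cc$ring_cell, cc$ring_prev_v,
                         cc$ring_next_v, target = 1, compliance = 10,
                         lambda = 0)
  expect_equal(max(abs(pr$dP)), 0)
})

test_that("all projections vanish at the rest configuration", {
  cc <- make_rect_cell(2, 1)
  V <- cc$V
  d <- project_distance(V, cc$wall_v1, cc$wall_v2, cc$wall_rest, 1)
  expect_equal(max(abs(rbind(d$d_i, d$d_j))), 0)
  s <- project_shape(V, cc$grp_vertex, cc$grp_cell, cc$shape_qx, cc$shape_qy, 1)
  expect_lt(max(abs(s)), 1e-12)
  b <- project_bending(V, cc$bend_a, cc$bend_b, cc$bend_c, cc$bend_rest, 1)
  expect_lt(max(abs(rbind(b$d_a, b$d_c))), 1e-12)
  st <- project_strain(V, cc$wall_v1, cc$wall_v2, cc$wall_rest,
                       afx = rep(1, cc$nw), afy = rep(0, cc$nw))
  expect_equal(max(abs(rbind(st$d_i, st$d_j))), 0)
})

test_that("strain constraint suppresses expansion along the AF", {
  p <- default_params(overpressure = 0.3)
  grow <- function(af) {
    cc <- make_rect_cell(4, 4)
    cc$cells$kE <- 0.005
    cc$cells$afx <- af[1]; cc$cells$afy <- af[2]
    for (i in 1:150) {
      cc <- mech_step(cc, p)
      cc <- plastic_update(cc, p, p$mechanics$dt)
    }
    xy <- cc$V[cc$rings[[1]], ]
    c(w = diff(range(xy[, 1])) / 4, h = diff(range(xy[, 2])) / 4)
  }
  iso <- grow(c(0, 0))
  anis <- grow(c(1, 0))   # |af| = 1 along x: x-expansion suppressed
  expect_lt(anis["w"] / anis["h"], 1)
  expect_lt(anis["w"], iso["w"])
})

test_that("wall strain measurement and plastic yield follow closed forms", {
  cc <- make_rect_cell(1, 1)
  expect_equal(measure_strain(cc), rep(0, 4))
  cc$wall_rest <- cc$wall_rest / 1.1
  expect_equal(measure_strain(cc), rep(0.1, 4), tolerance = 1e-12)
  # plastic relaxation of (L - rest) is exactly exponential for a fully
  # extensible wall (plastic flow scales with 1 - kE)
  p <- default_params()
  cc$cells$kE <- 0
  r <- p$mechanics$plastic_rate
  d0 <- 1 - cc$wall_rest[1]
  nstep <- 40
  dt <- 0.1
  for (k in seq_len(nstep)) cc <- plastic_update(cc, p, dt)
  expect_lt(abs((1 - cc$wall_rest[1]) - d0 * exp(-r * nstep * dt)), 1e-6)
})

test_that("pinned vertices never move", {
  cc <- build_synthetic_root_template(root_template_config(cells_per_file = 2))
  pinned <- which(cc$pinned)
  before <- cc$V[pinned, ]
  p <- default_params()
  cc$cells$kE <- rep(0.01, length(cc$rings))
  for (i in 1:30) {
    cc <- mech_step(cc, p)
    cc <- plastic_update(cc, p, p$mechanics$dt)
  }
  expect_identical(cc$V[pinned, ], before)
})

test_that("stiff constraints restore a perturbed toy mesh to low residual", {
  cc <- make_column(3)
  p <- default_params(overpressure = 0, plastic_rate = 0)
  p$mechanics$iterations <- 20L
  cc$cells$kE <- rep(1, 3)
  set.seed(5)
  free <- setdiff(seq_len(nrow(cc$V)), cc$cells$center)
  cc$V[free, ] <- cc$V[free, ] + matrix(stats::rnorm(2 * length(free), sd = 0.05),
                                        ncol = 2)
  r0 <- sum(abs(measure_strain(cc)))
  for (i in 1:300) cc <- mech_step(cc, p)
  expect_lt(sum(abs(measure_strain(cc) * cc$wall_rest)), 1e-6)
  expect_lt(sum(abs(measure_strain(cc))), r0 / 1e3)
})
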