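p0 <- default_params()

test_that("PIN sensitivity is a per-cell softmax with the columella exception", {
  cc <- make_rect_cell(4, 4, type = "Vascular")
  z <- numeric(4)
  s <- pin_sensitivity(cc, IP = z, IAF = z, IG = z, params = p0)
  expect_equal(s, rep(0.25, 4))
  # raws [1,0,0,0] -> softmax
  s <- pin_sensitivity(cc, IP = c(1, 0, 0, 0) / p0$polarity$kP * p0$polarity$kP,
                       IAF = z, IG = z,
                       params = default_params(kP = 1, kAFP = 0, kG = 0))
  expect_equal(s, c(exp(1), 1, 1, 1) / (exp(1) + 3), tolerance = 1e-12)
  # columella-lineage cells get uniform sensitivities whatever the raws
  cc2 <- make_rect_cell(4, 4, type = "Columella")
  s2 <- pin_sensitivity(cc2, IP = c(5, 0, 2, 0), IAF = z, IG = z, params = p0)
  expect_equal(s2, rep(0.25, 4))
})

test_that("softmax normalization holds for random sensitivities", {
  set.seed(9)
  cc <- build_synthetic_root_template(root_template_config(cells_per_file = 3))
  IP <- stats::runif(cc$ns); IAF <- stats::runif(cc$ns); IG <- stats::runif(cc$ns)
  s <- pin_sensitivity(cc, IP, IAF, IG, p0)
  sums <- tapply(s, cc$side_cell, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_true(all(s > 0 & s < 1))
})

test_that("the flux vector points from the influx face toward the efflux face", {
  cc <- make_rect_cell(2, 2)
  g <- cc_geometry(cc)
  # net influx +1 through the left section only: auxin enters on the left
  # and will exit right, so the flux vector points right (+x)
  left <- which(g$side_nx < -0.9)
  I <- numeric(4); I[left] <- 1
  FLUX <- flux_vector(cc, list(I = I, E = numeric(4)), g)
  expect_equal(FLUX[1, ], c(1, 0), tolerance = 1e-12)
  # I = E everywhere: zero vector
  FLUX0 <- flux_vector(cc, list(I = rep(2, 4), E = rep(2, 4)), g)
  expect_equal(FLUX0[1, ], c(0, 0))
})

test_that("flux vector equals a brute-force summation on a hexagon", {
  xy <- make_convex_polygon(6, seed = 12)
  cc <- new_cell_complex(xy, list(1:6), "Cortex")
  g <- cc_geometry(cc)
  set.seed(4)
  I <- stats::runif(6); E <- stats::runif(6)
  FLUX <- flux_vector(cc, list(I = I, E = E), g)
  cen <- c(g$cell_cx[1], g$cell_cy[1])
  acc <- c(0, 0)
  for (k in 1:6) {
    v <- c(g$side_mx[k], g$side_my[k]) - cen
    acc <- acc + v / sqrt(sum(v^2)) * (E[k] - I[k])
  }
  expect_equal(FLUX[1, ], acc, tolerance = 1e-12)
})

test_that("flux contribution is a quartic switch on the projected flux", {
  cc <- make_rect_cell(2, 2)
  g <- cc_geometry(cc)
  right <- which(g$side_nx > 0.9)
  Kf <- p0$polarity$Kflux
  L <- g$side_L[right]
  # F_mem = Kflux at the right face -> IP = 0.5 there
  FLUX <- matrix(c(Kf / L, 0), 1)
  IP <- flux_contribution(cc, FLUX, p0, g)
  expect_equal(IP[right], 0.5, tolerance = 1e-12)
  # F ten times the half-max saturates
  IP10 <- flux_contribution(cc, FLUX * 10, p0, g)
  expect_gt(IP10[right], 0.9999)
  # flux orthogonal to the normal contributes nothing
  top <- which(g$side_ny > 0.9)
  expect_equal(IP[top], 0)
  # inward-aligned flux is clamped to zero by default
  left <- which(g$side_nx < -0.9)
  expect_equal(IP[left], 0)
})

test_that("the gradient metric localizes net influx and scales linearly", {
  cc <- make_rect_cell(2, 2)
  g <- cc_geometry(cc)
  fl0 <- list(I = rep(1, 4), E = rep(1, 4))
  expect_equal(grad_mem(cc, fl0, p0, g), rep(0, 4))
  left <- which(g$side_nx < -0.9)
  I <- numeric(4); I[left] <- 1
  gr1 <- grad_mem(cc, list(I = I, E = numeric(4)), p0, g)
  gr2 <- grad_mem(cc, list(I = 3 * I, E = numeric(4)), p0, g)
  expect_equal(gr2, 3 * gr1, tolerance = 1e-12)
  expect_gt(gr1[left], 0)
  expect_identical(which.max(gr1), left)
  # documented form: (net/A + sum(net/A)/dist) * amplification / A
  A <- g$cell_A[1]
  expected <- (1 / A) * p0$polarity$grad_amplification / A
  expect_equal(gr1[left], expected, tolerance = 1e-12)
})

test_that("polarizer displacement drains toward the low-regulator side", {
  # two-cell strip: focus on one cell's 4-section ring with trafficking,
  # production and decay silenced; only diffusion + displacement act
  p <- default_params(b_REG = 0, b_POL = 0, d_REG = 0, d_POL = 0,
                      Kreg_tr = 0, Kpol_tr = 0, D_reg = 0, D_pol = 0)
  cc <- make_rect_cell(4, 4)
  cc$side_REG <- c(1, 0.5, 0, 0.5)     # gradient around the ring
  cc$side_POL <- c(1, 0, 0, 0)
  g <- cc_geometry(cc)
  set.seed(1)
  tot0 <- sum(cc$side_POL)
  for (i in 1:400) {
    up <- step_regulator_polarizer(cc, grad = numeric(4), params = p,
                                   dt = 0.02, geom = g)
    cc$side_REG <- up$REG_mem
    cc$side_POL <- up$POL_mem
    expect_lt(abs(sum(cc$side_POL) - tot0), 1e-9)   # exact conservation
  }
  # polarizer ends opposite the regulator maximum
  expect_identical(which.max(cc$side_POL), 3L)
  expect_gt(cc$side_POL[3], 0.95)
})

test_that("uniform regulator blocks displacement entirely", {
  p <- default_params(b_REG = 0, b_POL = 0, d_REG = 0, d_POL = 0,
                      Kreg_tr = 0, Kpol_tr = 0, D_reg = 0, D_pol = 0)
  cc <- make_rect_cell(4, 4)
  cc$side_REG <- rep(2, 4)
  cc$side_POL <- c(1, 2, 3, 4)
  set.seed(2)
  up <- step_regulator_polarizer(cc, grad = numeric(4), params = p, dt = 0.02)
  expect_equal(up$POL_mem, c(1, 2, 3, 4))   # strict inequality never met
})

test_that("polarizer contribution is a Hill switch", {
  expect_equal(polarizer_contribution(0, p0), 0)
  expect_equal(polarizer_contribution(p0$polarity$Kpol_IP, p0), 0.5)
  x <- seq(0, 1, by = 0.05)
  expect_true(all(diff(polarizer_contribution(x, p0)) > 0))
})

test_that("AF and geometry contributions follow their closed forms", {
  cc <- make_rect_cell(2, 2)
  g <- cc_geometry(cc)
  # af parallel to the right face normal
  cc$cells$afx <- 1; cc$cells$afy <- 0
  IAF <- af_contribution(cc, p0, g)
  right <- which(g$side_nx > 0.9); top <- which(g$side_ny > 0.9)
  expect_equal(IAF[right], 1 / (1 + 0.5^4), tolerance = 1e-12)  # ~0.9412
  expect_equal(IAF[top], 0)
  # zero-length af contributes nothing anywhere
  cc$cells$afx <- 0
  expect_equal(af_contribution(cc, p0, g), rep(0, 4))
  # isotropic cell: geometry contribution vanishes
  expect_lt(max(geometry_contribution(cc, p0, g)), 1e-9)
  # needle cell: faces at the long-axis ends approach the Hill limit
  ndl <- make_rect_cell(10, 0.5)
  gn <- cc_geometry(ndl)
  IG <- geometry_contribution(ndl, p0, gn)
  ends <- which(abs(gn$side_nx) > 0.9)
  r <- gn$ax_ratio[1]
  expect_equal(IG[ends], rep((1 - r)^4 / ((1 - r)^4 + 0.5^4), 2),
               tolerance = 1e-9)
  expect_gt(min(IG[ends]), 0.9)
  # faces orthogonal to the long axis get nothing
  lat <- which(abs(gn$side_ny) > 0.9)
  expect_lt(max(IG[lat]), 1e-9)
})
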