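p0 <- default_params()

test_that("wall stiffness is biphasic in auxin", {
  expect_equal(wall_stiffness(0, p0), 1)
  expect_equal(wall_stiffness(1e9, p0), 1, tolerance = 1e-9)
  # direct evaluation at IAA = 0.5 with the reference constants
  I4 <- 0.5^4; K1 <- 0.05; K2 <- 3
  expect_equal(wall_stiffness(0.5, p0),
               K1^4 / (I4 + K1^4) + I4 / (I4 + K2^4))
  expect_lt(wall_stiffness(0.5, p0), 1e-3)   # maximally relaxed regime
  # global minimum lies strictly between K_1auxin and K_2auxin
  grid <- 10^seq(-4, 2, length.out = 2000)
  imin <- grid[which.min(wall_stiffness(grid, p0))]
  expect_gt(imin, p0$growth$K_1auxin)
  expect_lt(imin, p0$growth$K_2auxin)
})

test_that("QC and columella never divide", {
  for (ty in c("QC", "Columella")) {
    cc <- make_rect_cell(50, 50, type = ty)
    cc$cells$A_max <- 1   # far above any threshold
    expect_null(check_and_divide(cc, 1))
  }
})

test_that("CEID divides periclinally into endodermis and cortex", {
  cc <- make_rect_cell(6, 8, type = "CEID", x0 = 2)   # inner side toward x=0
  cc$cells$A_max <- 10
  ev <- check_and_divide(cc, 1)
  expect_setequal(ev$types, c("Endodermis", "Cortex"))
  expect_equal(abs(ev$u), c(0, 1))   # division line along the organ axis
  a0 <- cc_geometry(cc)$cell_A[1]
  res <- apply_division(cc, ev)
  expect_true(res$ok)
  g <- cc_geometry(res$cc)
  expect_lt(abs(sum(g$cell_A) - a0) / a0, 0.01)
  # the inner daughter differentiates into endodermis
  inner <- which.min(abs(g$cell_cx))
  expect_identical(res$cc$cells$type[inner], "Endodermis")
  expect_identical(res$cc$cells$type[-inner], "Cortex")
})

test_that("epidermis/LRC initials alternate division orientation and fate", {
  cc <- make_rect_cell(6, 8, type = "EpidermisLRCInitial", x0 = 2)
  cc$cells$A_max <- 10
  cc$cells$afx <- 1   # AF radial: parallel division line = horizontal
  ev1 <- check_and_divide(cc, 1)           # parity 0: orthogonal -> LRC
  expect_true("LRC" %in% ev1$types)
  res1 <- apply_division(cc, ev1)
  expect_true(res1$ok)
  expect_setequal(res1$cc$cells$type, c("EpidermisLRCInitial", "LRC"))
  init <- which(res1$cc$cells$type == "EpidermisLRCInitial")
  cc2 <- res1$cc
  cc2$cells$A_max[init] <- 1               # force the second division
  ev2 <- check_and_divide(cc2, init)       # parity 1: parallel -> Epidermis
  expect_true("Epidermis" %in% ev2$types)
})

test_that("division conserves auxin mass and seeds an empty new wall", {
  p <- default_params()
  cc <- make_rect_cell(6, 8)
  cc$cells$IAA <- 2.5
  cc$wall_IAA[] <- c(1, 2, 3, 4)
  cc$side_PIN <- c(5, 6, 7, 8)
  g0 <- cc_geometry(cc)
  mass0 <- sum(cc$cells$IAA * g0$cell_A) +
    sum(cc$wall_IAA * g0$wall_L * p$transport$wall_thickness)
  ev <- list(cell = 1, p0 = c(3, 4), u = c(1, 0),
             types = c("Vascular", "Vascular"), parity_used = FALSE)
  res <- apply_division(cc, ev)
  expect_true(res$ok)
  cc2 <- res$cc
  g1 <- cc_geometry(cc2)
  mass1 <- sum(cc2$cells$IAA * g1$cell_A) +
    sum(cc2$wall_IAA * g1$wall_L * p$transport$wall_thickness)
  expect_lt(abs(mass1 - mass0) / mass0, 1e-9)
  # equal daughters inherit equal concentrations
  expect_equal(cc2$cells$IAA, rep(2.5, 2))
  expect_equal(g1$cell_A[1], g1$cell_A[2], tolerance = 1e-9)
  # the new cross wall starts with no PIN and no apoplastic auxin
  new_wall <- which(!is.na(cc2$wall_cb) &
                      ((cc2$wall_ca == 1 & cc2$wall_cb == 2) |
                         (cc2$wall_ca == 2 & cc2$wall_cb == 1)))
  expect_identical(length(new_wall), 1L)
  expect_equal(cc2$wall_IAA[new_wall], 0)
  expect_equal(cc2$side_PIN[cc2$side_wall == new_wall], c(0, 0))
  # AF inherited verbatim, parity toggled
  expect_equal(cc2$cells$afx, rep(cc$cells$afx, 2))
  expect_identical(cc2$cells$parity, rep(1L, 2))
  expect_silent(validate_complex(cc2))
})

test_that("divisions in tissue keep the mesh valid and the count non-decreasing", {
  p <- default_params()
  cc <- build_synthetic_root_template(root_template_config(cells_per_file = 3))
  # push several cells over threshold by shrinking their A_max
  set.seed(8)
  g <- cc_geometry(cc)
  idx <- which(cc$cells$type %in% c("Cortex", "Endodermis", "Epidermis"))
  idx <- sample(idx, 6)
  cc$cells$A_max[idx] <- g$cell_A[idx] * 0.9
  n0 <- length(cc$rings)
  ndiv <- 0L
  for (ci in sort(idx, decreasing = TRUE)) {
    ev <- check_and_divide(cc, ci, cc_geometry(cc))
    if (is.null(ev)) next
    res <- apply_division(cc, ev)
    if (res$ok) { cc <- res$cc; ndiv <- ndiv + 1L }
  }
  expect_gt(ndiv, 3)
  expect_identical(length(cc$rings), n0 + ndiv)
  expect_silent(validate_complex(cc))
  # neighbours of divided cells still share conforming walls
  for (w in seq_len(cc$nw)) {
    if (is.na(cc$wall_cb[w])) next
    ra <- cc$rings[[cc$wall_ca[w]]]
    rb <- cc$rings[[cc$wall_cb[w]]]
    expect_true(all(c(cc$wall_v1[w], cc$wall_v2[w]) %in% intersect(ra, rb)))
  }
})
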