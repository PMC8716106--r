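test_that("default template has the embryonic niche layout", {
  cc <- build_synthetic_root_template()
  expect_identical(sum(cc$cells$type == "QC"), 2L)
  expect_true(all(c("ColumellaInitial", "Columella", "CEI", "CEID",
                    "EpidermisLRCInitial", "LRC", "Source", "Sink") %in%
                    cc$cells$type))
  # columella initials sit below the QC, LRC sheathes the tip
  g <- cc_geometry(cc)
  qc_y <- mean(g$cell_cy[cc$cells$type == "QC"])
  expect_true(min(g$cell_cy[cc$cells$type == "ColumellaInitial"]) < qc_y)
  expect_true(min(g$cell_cy[cc$cells$type == "LRC"]) < qc_y)
  # sources central, sinks flanking, all on the top row
  expect_true(all(abs(g$cell_cx[cc$cells$type == "Source"]) <
                    min(abs(g$cell_cx[cc$cells$type == "Sink"]))))
  # non-polar start
  expect_true(all(cc$cells$afx == 0 & cc$cells$afy == 0))
  expect_silent(validate_complex(cc))
})

test_that("template cell count matches the closed form of the layout", {
  for (nf in c(3L, 5L)) for (cpf in c(4L, 8L)) {
    cc <- build_synthetic_root_template(
      root_template_config(n_files = nf, cells_per_file = cpf))
    # exhaustive enumeration of generated cells vs closed form
    expect_identical(length(cc$rings), 2L * nf * (cpf + 5L))
    expect_identical(length(cc$cells$type), length(cc$rings))
  }
  expect_error(root_template_config(n_files = 0), "configuration error")
})

test_that("template generation is deterministic", {
  a <- build_synthetic_root_template()
  b <- build_synthetic_root_template()
  expect_identical(a$V, b$V)
  expect_identical(a$rings, b$rings)
  expect_identical(a$cells$type, b$cells$type)
})

test_that("wall adjacency is a symmetric involution", {
  cc <- build_synthetic_root_template(root_template_config(cells_per_file = 4))
  for (w in seq_len(cc$nw)) {
    cells <- stats::na.omit(c(cc$wall_ca[w], cc$wall_cb[w]))
    expect_true(length(cells) %in% 1:2)
    for (ci in cells) {
      # the cell's side list contains this wall exactly once
      expect_identical(sum(cc$side_wall == w & cc$side_cell == ci), 1L)
    }
  }
})

test_that("fan triangulation tiles every cell polygon", {
  cc <- build_synthetic_root_template(root_template_config(cells_per_file = 4))
  g <- cc_geometry(cc)
  for (ci in seq_along(cc$rings)) {
    r <- cc$rings[[ci]]
    nx <- c(r[-1], r[1])
    cen <- cc$V[cc$cells$center[ci], ]
    tri <- 0.5 * abs((cc$V[r, 1] - cen[1]) * (cc$V[nx, 2] - cen[2]) -
                       (cc$V[nx, 1] - cen[1]) * (cc$V[r, 2] - cen[2]))
    expect_lt(abs(sum(tri) - g$cell_A[ci]), 1e-9 * g$cell_A[ci])
  }
})

test_that("cell_geometry matches elementary shapes", {
  sq <- make_rect_cell(1, 1)
  geo <- cell_geometry(sq, 1)
  expect_equal(geo$area, 1)
  expect_equal(sqrt(sum(geo$axisMax^2)) / sqrt(sum(geo$axisMin^2)), 1,
               tolerance = 1e-9)
  expect_identical(nrow(geo$sections), 4L)
  expect_equal(geo$sections$L_mem, rep(1, 4))
  # outward normals: dot of normal with (midpoint - centroid) positive
  out <- (geo$sections$mx - geo$centroid[1]) * geo$sections$nx +
    (geo$sections$my - geo$centroid[2]) * geo$sections$ny
  expect_true(all(out > 0))

  rect <- make_rect_cell(2, 1)
  geo2 <- cell_geometry(rect, 1)
  expect_equal(sqrt(sum(geo2$axisMax^2)) / sqrt(sum(geo2$axisMin^2)), 2,
               tolerance = 1e-9)
  # long axis along x
  expect_gt(abs(geo2$axisMax[1]), 10 * abs(geo2$axisMax[2]))
})

test_that("polygon area agrees with a Monte-Carlo point-in-polygon oracle", {
  xy <- make_convex_polygon(6, seed = 42)
  cc <- new_cell_complex(xy, list(1:6), "Cortex")
  a <- cell_geometry(cc, 1)$area
  set.seed(7)
  n <- 1e6
  lim <- apply(xy, 2, range)
  px <- stats::runif(n, lim[1, 1], lim[2, 1])
  py <- stats::runif(n, lim[1, 2], lim[2, 2])
  # point in convex polygon: left of every CCW edge
  inside <- rep(TRUE, n)
  nxt <- c(2:6, 1)
  for (e in 1:6) {
    inside <- inside &
      ((xy[nxt[e], 1] - xy[e, 1]) * (py - xy[e, 2]) -
         (xy[nxt[e], 2] - xy[e, 2]) * (px - xy[e, 1]) >= 0)
  }
  a_mc <- mean(inside) * prod(lim[2, ] - lim[1, ])
  expect_lt(abs(a - a_mc) / a, 0.01)
})

test_that("mesh JSON round-trip preserves geometry and state", {
  cc <- build_synthetic_root_template(root_template_config(cells_per_file = 4))
  set.seed(3)
  cc$cells$IAA <- stats::runif(length(cc$rings), 0, 5)
  cc$cells$afx <- stats::runif(length(cc$rings), -0.5, 0.5)
  cc$side_PIN <- stats::runif(cc$ns, 0, 10)
  cc$wall_IAA <- stats::runif(cc$nw, 0, 3)
  path <- withr::local_tempfile(fileext = ".json")
  save_mesh(cc, path)
  cc2 <- load_mesh(path)
  used <- sort(unique(unlist(cc$rings)))
  expect_identical(cc2$V[seq_along(used), ], unname(cc$V[used, ]))
  expect_identical(cc2$cells$type, cc$cells$type)
  expect_identical(cc2$cells$IAA, cc$cells$IAA)
  expect_identical(cc2$cells$afx, cc$cells$afx)
  # per-side state keyed by (cell, wall vertices) must survive
  vmap <- integer(nrow(cc$V)); vmap[used] <- seq_along(used)
  key1 <- paste(cc$side_cell, pmin(vmap[cc$side_from], vmap[cc$side_to]),
                pmax(vmap[cc$side_from], vmap[cc$side_to]))
  key2 <- paste(cc2$side_cell, pmin(cc2$side_from, cc2$side_to),
                pmax(cc2$side_from, cc2$side_to))
  m <- match(key1, key2)
  expect_false(anyNA(m))
  expect_identical(cc$side_PIN, cc2$side_PIN[m])
  expect_silent(validate_complex(cc2))
})

test_that("mesh schema violations are reported with the offending record", {
  cc <- make_rect_cell()
  path <- withr::local_tempfile(fileext = ".json")
  save_mesh(cc, path)
  obj <- jsonlite::read_json(path)
  obj$cells[[1]]$type <- NULL
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  expect_error(load_mesh(path), "cell 1.*missing cell_type")
  # a wall claiming three cells is rejected
  save_mesh(cc, path)
  obj <- jsonlite::read_json(path)
  obj$walls[[1]]$cells <- list(1, 2, 3)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  expect_error(load_mesh(path), "shared by 3 cells")
})

test_that("an edge claimed by three rings is rejected at construction", {
  V <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1, 2, 0, 2, 1), 6, 2, byrow = TRUE)
  rings <- list(c(1, 2, 3, 4), c(2, 5, 6, 3), c(1, 2, 3, 4))
  # third ring reuses edges already shared by the first two
  expect_error(new_cell_complex(V, rings, rep("Cortex", 3)),
               "more than 2 cells")
})
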