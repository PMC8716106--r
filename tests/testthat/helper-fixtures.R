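# In-code fixtures: tiny cell complexes with known geometry, and a cache
# for the heavier study runs shared between test files.

# one rectangular cell, CCW ring
make_rect_cell <- function(w = 1, h = 1, type = "Vascular", x0 = 0, y0 = 0) {
  V <- matrix(c(x0, y0, x0 + w, y0, x0 + w, y0 + h, x0, y0 + h),
              4, 2, byrow = TRUE)
  new_cell_complex(V, list(1:4), type)
}

# a vertical column of n stacked rectangular cells sharing walls
# vertices: (0,0)=1 (w,0)=2 (w,h)=3 (0,h)=4 (w,2h)=5 (0,2h)=6 ...
make_column <- function(n = 2, w = 5, h = 5, types = rep("Vascular", n)) {
  V <- matrix(0, 2 * n + 2, 2)
  V[1, ] <- c(0, 0); V[2, ] <- c(w, 0)
  for (k in seq_len(n)) {
    V[2 * k + 1, ] <- c(w, k * h)
    V[2 * k + 2, ] <- c(0, k * h)
  }
  rings <- lapply(seq_len(n), function(k) {
    if (k == 1) c(1L, 2L, 3L, 4L)
    else c(2L * k, 2L * k - 1L, 2L * k + 1L, 2L * k + 2L)
  })
  new_cell_complex(V, rings, types)
}

# random convex polygon (CCW convex hull of random points)
make_convex_polygon <- function(nv = 6, seed = 42) {
  set.seed(seed)
  repeat {
    pts <- matrix(stats::runif(24, -3, 3), ncol = 2)
    h <- rev(grDevices::chull(pts))   # chull returns clockwise
    if (length(h) >= nv) return(pts[h[seq_len(nv)], ])
  }
}

# ---- cached study runs (computed once per test session) ----------------

.run_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.run_cache[[name]])) .run_cache[[name]] <- force(expr)
  .run_cache[[name]]
}

get_wt <- function(mechanism = "flux") {
  cached(paste0("wt_", mechanism),
         run_simulation(wildtype_config(mechanism = mechanism, steps = 1500L,
                                        seed = 1L)))
}

get_mech_only <- function(kind = c("uniform", "differential", "switch")) {
  kind <- match.arg(kind)
  tmpl <- root_template_config(cells_per_file = 2)
  cached(paste0("mech_", kind), switch(kind,
    uniform = mechanics_only(tmpl, steps = 300L, differential = 1, rsi_rows = 2),
    differential = mechanics_only(tmpl, steps = 300L, differential = 4, rsi_rows = 2),
    switch = mechanics_only(tmpl, steps = 300L, differential = 4, rsi_rows = 2,
                            switch_step = 150L)))
}

get_reflux <- function() cached("reflux", reflux_experiment(seed = 1L))

get_pulse <- function() cached("pulse", pulse_experiment(seed = 1L))

get_panel <- function() cached("panel", perturbation_panel(seed = 1L))

get_pin_reloc <- function() cached("pin_reloc",
  pin_relocalization_experiment(prep_steps = 800L, seed = 1L))
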