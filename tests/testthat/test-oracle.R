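test_that("uniform-tube resistance matches the Hagen-Poiseuille closed form", {
  mu <- 0.0035
  L <- 0.03
  R <- 0.0015
  tube <- make_tube_tree(length = L, radius = R)
  rh <- segment_resistance(tube$segments[1, ], fluid_properties(viscosity = mu))
  expect_equal(rh, 8 * mu * L / (pi * R^4), tolerance = 1e-12)
  expect_equal(rh * 1e-6, 52.81, tolerance = 1e-3) # dP at Q = 1e-6 m^3/s

  # zero-rate stenosis changes nothing
  st0 <- tibble::tibble(rate = 0, center = 0.5, extent = 0.004)
  tube0 <- make_tube_tree(length = L, radius = R, stenoses = st0)
  expect_equal(segment_resistance(tube0$segments[1, ], fluid_properties()),
               8 * 0.0035 * L / (pi * R^4), tolerance = 1e-12)

  # R^-4 scaling
  half <- make_tube_tree(length = L, radius = R / 2)
  expect_equal(
    segment_resistance(half$segments[1, ], fluid_properties()) /
      segment_resistance(tube$segments[1, ], fluid_properties()),
    16, tolerance = 1e-12
  )
})

test_that("resistance increases strictly with stenosis severity", {
  res <- vapply(c(0.60, 0.70, 0.80, 0.90), function(s) {
    st <- tibble::tibble(rate = s, center = 0.5, extent = 0.004)
    segment_resistance(make_tube_tree(stenoses = st)$segments[1, ],
                       fluid_properties())
  }, 0)
  expect_true(all(diff(res) > 0))
})

test_that("network solve honors conservation and the Ohm analogy", {
  tube <- make_tube_tree(length = 0.03, radius = 0.0015)
  bc <- boundary_conditions(inlet_velocity = 0.2)
  sol <- solve_network(tube, bc)
  q_in <- 0.2 * pi * 0.0015^2
  rh <- segment_resistance(tube$segments[1, ], fluid_properties())
  expect_equal(unname(sol$segment_flows["tube"]), q_in, tolerance = 1e-12)
  expect_equal(unname(sol$node_pressures["inlet"]), q_in * rh, tolerance = 1e-12)
  expect_equal(unname(sol$node_pressures["out"]), 0)

  # parallel paths: conductances add (the graft loop is the in-vivo case)
  pre <- make_base_tree(0, 3)
  post <- add_graft(pre)
  solp <- solve_network(post)
  segs <- post$segments
  g_id <- segs$id[segs$role == "graft"]
  lp_id <- segs$id[segs$role == "lad_proximal"]
  dp_graft <- sum(solp$node_pressures[segs$start_node[segs$id == g_id]] -
                    solp$node_pressures[segs$end_node[segs$id == g_id]])
  expect_equal(unname(solp$segment_flows[g_id]),
               unname(dp_graft / solp$resistances[g_id]), tolerance = 1e-10)
  # flows into the anastomosis node equal the distal outflow
  dd <- segs$id[segs$role == "lad_distal"]
  expect_equal(
    unname(solp$segment_flows[g_id] + solp$segment_flows[lp_id]),
    unname(solp$segment_flows[dd]), tolerance = 1e-10
  )
})

test_that("mass conservation holds on randomized trees", {
  base_trees <- lapply(0:2, function(tpl) make_base_tree(tpl, 10 + tpl))
  worst <- 0
  for (b in base_trees) {
    for (v in expand_model(b, geometry_ranges(), count = 12, seed = 21)) {
      worst <- max(worst, solve_network(v)$max_imbalance_rel)
      worst <- max(worst, solve_network(add_graft(v))$max_imbalance_rel)
    }
  }
  expect_lt(worst, 1e-10)
})

test_that("parabolic velocity closure evaluates exactly", {
  R <- 0.0015
  tube <- make_tube_tree(length = 0.03, radius = R)
  sol <- solve_network(tube, boundary_conditions(inlet_velocity = 1e-6 / (pi * R^2)))
  expect_equal(unname(sol$segment_flows["tube"]), 1e-6, tolerance = 1e-12)
  pts <- tibble::tibble(segment_id = "tube",
                        axial_fraction = c(0.5, 0.5, 0.5),
                        radial_fraction = c(0, 0.5, 0.999999))
  v <- velocity_at(tube, sol, pts)
  expect_equal(v[1, 3], 2 * 1e-6 / (pi * R^2), tolerance = 1e-12) # ~0.2829 m/s
  expect_equal(v[1, 3], 0.2829, tolerance = 1e-3)
  expect_equal(v[2, 3] / v[1, 3], 0.75, tolerance = 1e-12)
  expect_lt(abs(v[3, 3]), 1e-5 * v[1, 3] + 1e-9) # no-slip wall limit
  expect_equal(v[, 1:2], matrix(0, 3, 2)) # axial flow only

  expect_error(
    velocity_at(tube, sol, tibble::tibble(segment_id = "tube",
                                          axial_fraction = 0.5,
                                          radial_fraction = 1.0)),
    "outside lumen"
  )
})

test_that("pressure is continuous and linear along uniform segments", {
  tree <- make_base_tree(1, 5)
  sol <- solve_network(tree)
  seg <- tree$segments[tree$segments$id == "asc2", ]
  pts <- tibble::tibble(segment_id = "asc2", axial_fraction = c(0, 0.5, 1),
                        radial_fraction = 0.3)
  p <- pressure_at(tree, sol, pts)
  p_up <- unname(sol$node_pressures[seg$start_node])
  p_dn <- unname(sol$node_pressures[seg$end_node])
  expect_equal(p[1], p_up, tolerance = 1e-9)
  expect_equal(p[3], p_dn, tolerance = 1e-9)
  expect_equal(p[2], (p_up + p_dn) / 2, tolerance = 1e-9)
})

test_that("bypass grafting strictly increases distal LAD flow", {
  for (s in c(0.60, 0.75, 0.90)) {
    pre <- make_sweep_tree(s)
    post <- add_graft(pre)
    dd <- pre$segments$id[pre$segments$role == "lad_distal"]
    q_pre <- solve_network(pre)$segment_flows[dd]
    q_post <- solve_network(post)$segment_flows[dd]
    expect_gt(unname(q_post), unname(q_pre))
  }
})

test_that("samples bundle clouds with consistent targets", {
  tree <- make_base_tree(0, 2)
  sp <- make_sample(tree, n_query = 512, surface_density = 0.02,
                    field_kind = "pressure", seed = 4)
  expect_identical(nrow(sp$query), 512L)
  expect_equal(sp$query$tx, sp$query$ty)
  expect_equal(sp$query$ty, sp$query$tz)

  tube <- make_tube_tree(length = 0.05, radius = 0.002)
  sv <- make_sample(tube, n_query = 256, surface_density = 0.05,
                    field_kind = "velocity", seed = 5)
  # straight tube along +z: all velocity vectors parallel to the axis
  expect_equal(sv$query$tx, rep(0, 256))
  expect_equal(sv$query$ty, rep(0, 256))
  expect_true(all(sv$query$tz > 0))
})
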