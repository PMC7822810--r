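test_that("base trees are structurally valid and deterministic", {
  t0 <- make_base_tree(0, 1)
  expect_s3_class(t0, "vessel_tree")
  expect_gte(nrow(t0$segments), 5)
  expect_identical(t0$op_state, "preoperative")
  expect_false("graft" %in% t0$segments$role)
  expect_identical(make_base_tree(0, 1), make_base_tree(0, 1))
  expect_false(identical(make_base_tree(0, 1), make_base_tree(0, 2)))

  t1 <- make_base_tree(1, 2)
  expect_identical(sum(t1$segments$role %in% c("lad_proximal", "lad_distal")), 2L)

  expect_error(make_base_tree(9, 1), "unknown template")
})

test_that("model expansion draws every parameter inside its range", {
  base <- make_base_tree(0, 1)
  variants <- expand_model(base, geometry_ranges(), count = 9, seed = 3)
  expect_length(variants, 9)

  # deterministic re-draw
  expect_identical(variants, expand_model(base, geometry_ranges(), count = 9, seed = 3))

  many <- expand_model(base, geometry_ranges(), count = 400, seed = 5)
  rates <- unlist(lapply(many, function(v) {
    unlist(lapply(v$segments$stenoses, function(s) s$rate))
  }))
  expect_gt(length(rates), 400) # 1-2 stenoses per variant
  expect_gte(min(rates), 0.60)
  expect_lte(max(rates), 0.90)

  asc <- vapply(many, function(v) v$segments$radius[v$segments$id == "asc1"], 0)
  expect_gte(min(asc) * 2000, 20)
  expect_lte(max(asc) * 2000, 30)
  nsb <- vapply(many, function(v) sum(v$segments$role == "side_branch"), 0)
  expect_setequal(unique(nsb), 0:3)
})

test_that("collapsed ranges give geometrically identical variants", {
  base <- make_base_tree(0, 1)
  pt <- geometry_ranges(
    stenosis_rate = c(0.75, 0.75), n_stenoses = c(1, 1),
    bifurcation_angle_deg = c(60, 60), n_side_branches = c(2, 2),
    ascending_aorta_diameter_mm = c(25, 25),
    descending_aorta_diameter_mm = c(18, 18),
    arch_angle_deg = c(110, 110), stenosis_center = c(0.5, 0.5)
  )
  vs <- expand_model(base, pt, count = 4, seed = 9)
  for (v in vs[-1]) {
    expect_equal(v$nodes, vs[[1]]$nodes)
    expect_equal(v$segments, vs[[1]]$segments)
  }
})

test_that("degenerate ranges are rejected as configuration errors", {
  expect_error(geometry_ranges(stenosis_rate = c(0.9, 0.6)), "degenerate")
  expect_error(geometry_ranges(arch_angle_deg = c(140, 80)), "degenerate")
})

test_that("grafting creates exactly one loop distal to the culprit stenosis", {
  pre <- make_base_tree(0, 4)
  post <- add_graft(pre)
  expect_identical(post$op_state, "postoperative")
  gseg <- post$segments[post$segments$role == "graft", ]
  expect_identical(nrow(gseg), 1L)
  expect_equal(gseg$radius, 0.001)

  # downstream endpoint sits on the distal LAD run
  dist <- post$segments[post$segments$role == "lad_distal", ]
  expect_identical(gseg$end_node, dist$start_node[1])

  # exactly one cycle; removing the graft restores a tree
  n_cycles <- nrow(post$segments) - nrow(post$nodes) + 1L
  expect_identical(n_cycles, 1L)
  expect_identical(nrow(post$segments) - 1L, nrow(pre$segments))
  expect_equal(post$segments[post$segments$role != "graft", ], pre$segments)

  expect_error(add_graft(post), "already postoperative")

  no_sten <- pre
  i <- which(no_sten$segments$role == "lad_proximal")
  no_sten$segments$stenoses[[i]] <- coroflow:::empty_stenoses()
  expect_error(add_graft(no_sten), "no stenosed LAD")
})

test_that("surface points sit exactly on the stenosed wall profile", {
  st <- tibble::tibble(rate = 0.8, center = 0.5, extent = 0.004)
  tube <- make_tube_tree(length = 0.03, radius = 0.0015, stenoses = st)
  pts <- surface_points(tube, points_per_mm2 = 3, seed = 2)
  seg <- tube$segments[1, ]
  # tube axis is +z: axial position is z, wall distance is sqrt(x^2 + y^2)
  r_expected <- radius_profile(seg, pts$z)
  expect_lt(max(abs(sqrt(pts$x^2 + pts$y^2) - r_expected)), 1e-9)

  expect_identical(pts, surface_points(tube, points_per_mm2 = 3, seed = 2))

  n1 <- nrow(surface_points(tube, points_per_mm2 = 4, seed = 5))
  n2 <- nrow(surface_points(tube, points_per_mm2 = 8, seed = 6))
  expect_gt(n2 / n1, 1.8)
  expect_lt(n2 / n1, 2.2)
})

test_that("interior points fill the lumen uniformly", {
  tree <- make_base_tree(0, 1)
  q <- interior_points(tree, n_points = 4096, seed = 3)
  expect_identical(nrow(q), 4096L)
  expect_true(all(q$radial_fraction < 1))
  expect_true(all(q$axial_fraction >= 0 & q$axial_fraction <= 1))
  expect_true(all(q$region %in% flow_regions()))

  # uniform-over-disk radial law: rho^2 ~ U(0, 1)
  tube <- make_tube_tree(length = 0.05, radius = 0.002)
  q2 <- interior_points(tube, n_points = 10000, seed = 11)
  ks <- suppressWarnings(stats::ks.test(q2$radial_fraction^2, "punif"))
  expect_gt(ks$p.value, 0.01)

  expect_identical(q, interior_points(tree, n_points = 4096, seed = 3))
})

test_that("tree YAML and STL exports round-trip / emit valid files", {
  tree <- add_graft(make_base_tree(2, 6))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_vessel_tree(tree, path)
  back <- read_vessel_tree(path)
  expect_equal(back$nodes, tree$nodes)
  expect_equal(back$segments, tree$segments, tolerance = 1e-12)
  expect_identical(back$op_state, "postoperative")

  stl <- withr::local_tempfile(fileext = ".stl")
  write_stl(tree, stl, n_axial = 6, n_circ = 8)
  lines <- readLines(stl)
  expect_identical(lines[1], "solid vessel_tree")
  expect_identical(tail(lines, 1), "endsolid vessel_tree")
  expect_gt(sum(grepl("^facet normal", lines)), 100)

  ply <- withr::local_tempfile(fileext = ".ply")
  write_ply(surface_points(tree, 0.01, 1), ply)
  expect_identical(readLines(ply, n = 1), "ply")
})
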