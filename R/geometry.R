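# Idealized stenosed coronary-aortic vessel trees.
#
# A tree is a classed list: a node table (id, x, y, z in meters), a segment
# table (id, start/end node, nominal radius, anatomical role, stenoses as a
# list-column), the inlet node, the outlet nodes, and the operative state.
# Cross-sections are circular; centerlines are straight runs between nodes.

SEGMENT_ROLES <- c(
  "aorta", "lad_proximal", "lad_distal", "lcx", "ra", "side_branch", "graft"
)

#' Anatomical regions used in error reports
#'
#' The aorta and its supra-aortic side branches are pooled into a single
#' region; the LAD is split at the stenosis into proximal and distal runs.
#'
#' @return Character vector of region names.
#' @export
flow_regions <- function() {
  c("lad_proximal", "lad_distal", "lcx", "ra", "graft", "aorta_and_branches")
}

region_of_role <- function(role) {
  ifelse(role %in% c("aorta", "side_branch"), "aorta_and_branches", role)
}

#' Parameter ranges for geometric model expansion
#'
#' Closed intervals from which expansion draws one value per variant, covering
#' stenosis severity and count, coronary bifurcation angle, number of
#' supra-aortic side branches, aortic diameters and arch angulation. The graft
#' diameter is fixed at 2 mm (a LIMA conduit). Stenosis axial placement
#' (`stenosis_center`, fraction of the proximal LAD run) and extent
#' (`stenosis_extent_mm`) are template conventions, not literature-derived.
#'
#' @param stenosis_rate Diameter-reduction fraction interval.
#' @param n_stenoses Integer interval, stenoses per LAD.
#' @param bifurcation_angle_deg LAD-LCX angle interval, degrees.
#' @param n_side_branches Integer interval, supra-aortic branches.
#' @param ascending_aorta_diameter_mm,descending_aorta_diameter_mm Diameter
#'   intervals, millimeters.
#' @param arch_angle_deg Aortic arch angulation interval, degrees.
#' @param graft_diameter_mm Fixed graft diameter, millimeters.
#' @param stenosis_center Interval for the stenosis center as a fraction of
#'   the proximal LAD length.
#' @param stenosis_extent_mm Fixed axial extent of each stenosis bump.
#' @return A `geometry_ranges` object.
#' @export
geometry_ranges <- function(stenosis_rate = c(0.60, 0.90),
                            n_stenoses = c(1L, 2L),
                            bifurcation_angle_deg = c(30, 90),
                            n_side_branches = c(0L, 3L),
                            ascending_aorta_diameter_mm = c(20, 30),
                            descending_aorta_diameter_mm = c(15, 20),
                            arch_angle_deg = c(80, 140),
                            graft_diameter_mm = 2.0,
                            stenosis_center = c(0.25, 0.75),
                            stenosis_extent_mm = 4.0) {
  r <- list(
    stenosis_rate = as.numeric(stenosis_rate),
    n_stenoses = as.integer(n_stenoses),
    bifurcation_angle_deg = as.numeric(bifurcation_angle_deg),
    n_side_branches = as.integer(n_side_branches),
    ascending_aorta_diameter_mm = as.numeric(ascending_aorta_diameter_mm),
    descending_aorta_diameter_mm = as.numeric(descending_aorta_diameter_mm),
    arch_angle_deg = as.numeric(arch_angle_deg),
    graft_diameter_mm = as.numeric(graft_diameter_mm),
    stenosis_center = as.numeric(stenosis_center),
    stenosis_extent_mm = as.numeric(stenosis_extent_mm)
  )
  for (nm in setdiff(names(r), c("graft_diameter_mm", "stenosis_extent_mm"))) {
    iv <- r[[nm]]
    if (length(iv) != 2 || any(!is.finite(iv))) {
      abort(sprintf("range '%s' must be a finite length-2 interval", nm))
    }
    if (iv[1] > iv[2]) abort(sprintf("degenerate range '%s': low > high", nm))
  }
  if (r$graft_diameter_mm <= 0 || r$stenosis_extent_mm <= 0) {
    abort("graft diameter and stenosis extent must be positive")
  }
  if (r$stenosis_rate[1] < 0 || r$stenosis_rate[2] >= 1) {
    abort("stenosis_rate must lie in [0, 1)")
  }
  structure(r, class = "geometry_ranges")
}

new_vessel_tree <- function(nodes, segments, inlet_node, outlet_nodes,
                            op_state = c("preoperative", "postoperative"),
                            params = NULL) {
  op_state <- match.arg(op_state)
  tree <- structure(
    list(
      nodes = nodes, segments = segments,
      inlet_node = inlet_node, outlet_nodes = outlet_nodes,
      op_state = op_state
    ),
    params = params,
    class = "vessel_tree"
  )
  validate_vessel_tree(tree)
  tree
}

#' @export
print.vessel_tree <- function(x, ...) {
  cat(sprintf(
    "<vessel_tree> %s: %d nodes, %d segments (%s), inlet '%s', %d outlets\n",
    x$op_state, nrow(x$nodes), nrow(x$segments),
    paste(sort(unique(x$segments$role)), collapse = ", "),
    x$inlet_node, length(x$outlet_nodes)
  ))
  invisible(x)
}

node_coord <- function(tree, id) {
  i <- match(id, tree$nodes$id)
  c(tree$nodes$x[i], tree$nodes$y[i], tree$nodes$z[i])
}

segment_row <- function(tree, seg_id) {
  i <- match(seg_id, tree$segments$id)
  if (is.na(i)) abort(sprintf("unknown segment '%s'", seg_id))
  tree$segments[i, ]
}

# Straight-run geometry of one segment: start point, unit direction, length,
# and a deterministic cross-sectional basis.
segment_frame <- function(tree, seg) {
  if (is.character(seg)) seg <- segment_row(tree, seg)
  a <- node_coord(tree, seg$start_node)
  b <- node_coord(tree, seg$end_node)
  d <- b - a
  len <- vnorm(d)
  dhat <- d / len
  c(list(start = a, end = b, dir = dhat, length = len), perp_basis(dhat))
}

#' Local lumen radius along a segment
#'
#' The wall follows the nominal radius except inside stenosis windows, where a
#' smooth cosine bump narrows the lumen: within `|x - xc| < extent/2` the
#' radius is `R - (R s / 2)(1 + cos(2 pi (x - xc) / extent))`, giving a throat
#' radius `R (1 - s)` at the center and a C1 join at the window edges. This
#' single profile is shared by the surface sampler and the flow solver.
#'
#' @param segment One row of a tree's segment table (or a segment id with
#'   `tree` supplied).
#' @param x Axial positions in meters from the segment start.
#' @param tree Optional tree, when `segment` is an id.
#' @return Numeric vector of radii (meters).
#' @export
radius_profile <- function(segment, x, tree = NULL) {
  if (is.character(segment)) segment <- segment_row(tree, segment)
  R <- segment$radius
  r <- rep(R, length(x))
  st <- segment$stenoses[[1]]
  if (!is.null(st) && nrow(st) > 0) {
    for (k in seq_len(nrow(st))) {
      xc <- st$center[k] * segment$length
      ext <- st$extent[k]
      w <- abs(x - xc) < ext / 2
      r[w] <- r[w] - (R * st$rate[k] / 2) * (1 + cos(2 * pi * (x[w] - xc) / ext))
    }
  }
  r
}

empty_stenoses <- function() {
  tibble(rate = numeric(), center = numeric(), extent = numeric())
}

validate_vessel_tree <- function(tree) {
  nodes <- tree$nodes
  segs <- tree$segments
  if (anyDuplicated(nodes$id)) abort("duplicate node ids")
  if (anyDuplicated(segs$id)) abort("duplicate segment ids")
  if (!all(c(segs$start_node, segs$end_node) %in% nodes$id)) {
    abort("segment endpoint references unknown node")
  }
  if (!all(segs$role %in% SEGMENT_ROLES)) abort("unknown segment role")
  if (any(segs$radius <= 0) || any(segs$length <= 0)) {
    abort("segment radii and lengths must be positive")
  }
  for (i in seq_len(nrow(segs))) {
    st <- segs$stenoses[[i]]
    if (is.null(st) || nrow(st) == 0) next
    if (any(st$rate < 0 | st$rate >= 1)) abort("stenosis rate must be in [0, 1)")
    if (any(st$center <= 0 | st$center >= 1)) abort("stenosis center must be in (0, 1)")
    if (any(st$extent <= 0 | st$extent >= segs$length[i])) {
      abort("stenosis extent must be positive and shorter than the segment")
    }
    if (any(segs$radius[i] * (1 - st$rate) <= 0)) abort("stenotic throat closed")
    if (nrow(st) > 1) {
      o <- order(st$center)
      gaps <- diff(st$center[o]) * segs$length[i]
      if (any(gaps < (head(st$extent[o], -1) + tail(st$extent[o], -1)) / 2)) {
        abort("stenosis windows overlap")
      }
    }
  }
  if (tree$inlet_node %in% tree$outlet_nodes) abort("inlet coincides with an outlet")
  # Connectivity and cycle count on the undirected graph.
  ids <- nodes$id
  adj <- lapply(setNames(vector("list", length(ids)), ids), function(x) character())
  for (i in seq_len(nrow(segs))) {
    adj[[segs$start_node[i]]] <- c(adj[[segs$start_node[i]]], segs$end_node[i])
    adj[[segs$end_node[i]]] <- c(adj[[segs$end_node[i]]], segs$start_node[i])
  }
  seen <- setNames(rep(FALSE, length(ids)), ids)
  queue <- tree$inlet_node
  seen[queue] <- TRUE
  while (length(queue)) {
    cur <- queue[[1]]; queue <- queue[-1]
    for (nb in adj[[cur]]) {
      if (!seen[[nb]]) { seen[[nb]] <- TRUE; queue <- c(queue, nb) }
    }
  }
  if (!all(seen)) abort("vessel tree is not connected")
  n_cycles <- nrow(segs) - nrow(nodes) + 1L
  n_grafts <- sum(segs$role == "graft")
  if (tree$op_state == "preoperative") {
    if (n_grafts != 0) abort("preoperative tree must not contain a graft")
    if (n_cycles != 0) abort("preoperative tree must be acyclic")
  } else {
    if (n_grafts != 1) abort("postoperative tree must contain exactly one graft")
    if (n_cycles != 1) abort("postoperative tree must contain exactly one cycle (the graft loop)")
  }
  invisible(tree)
}

# Template parameter sets. Coronary calibers and branch lengths are idealized
# conventions (not literature-fitted); aortic calibers sit at range midpoints.
tree_templates <- function() {
  base <- list(
    asc_diameter_mm = 25, desc_diameter_mm = 17.5,
    arch_angle_deg = 110, bifurcation_angle_deg = 60,
    n_side_branches = 2L,
    asc_length = 0.080, desc_length = 0.100,
    lad_prox_length = 0.030, lad_dist_length = 0.040,
    lcx_length = 0.045, ra_length = 0.050,
    lad_radius = 0.0015, lcx_radius = 0.0014, ra_radius = 0.0015,
    side_length = 0.040, side_radius = 0.004,
    stenoses = tibble(rate = 0.75, center = 0.5, extent = 0.004)
  )
  t1 <- base
  t1$arch_angle_deg <- 95; t1$bifurcation_angle_deg <- 45
  t1$n_side_branches <- 0L; t1$asc_length <- 0.070
  for (nm in c("lad_prox_length", "lad_dist_length", "lcx_length", "ra_length")) {
    t1[[nm]] <- base[[nm]] * 0.9
  }
  t2 <- base
  t2$arch_angle_deg <- 130; t2$bifurcation_angle_deg <- 75
  t2$n_side_branches <- 3L; t2$desc_length <- 0.110
  for (nm in c("lad_prox_length", "lad_dist_length", "lcx_length", "ra_length")) {
    t2[[nm]] <- base[[nm]] * 1.15
  }
  list(`0` = base, `1` = t1, `2` = t2)
}

build_tree_from_params <- function(p) {
  asc_r <- p$asc_diameter_mm / 2000
  desc_r <- p$desc_diameter_mm / 2000
  dir_lad <- unit(c(-0.75, 0.45, -0.50))
  dir_ra <- unit(c(0.85, 0.35, -0.40))
  a_arch <- p$arch_angle_deg * pi / 180
  dir_desc <- c(sin(a_arch), 0, cos(a_arch))
  bif_axis <- unit(c(
    dir_lad[2] * 1 - dir_lad[3] * 0,
    dir_lad[3] * 0 - dir_lad[1] * 1,
    dir_lad[1] * 0 - dir_lad[2] * 0
  ))
  dir_lcx <- rotate_about(dir_lad, bif_axis, p$bifurcation_angle_deg * pi / 180)

  n <- list(inlet = c(0, 0, 0))
  n$ra_ost <- c(0, 0, 0.25 * p$asc_length)
  n$lm_ost <- c(0, 0, 0.50 * p$asc_length)
  n$arch <- c(0, 0, p$asc_length)
  n$desc_out <- n$arch + p$desc_length * dir_desc
  n$ra_out <- n$ra_ost + p$ra_length * dir_ra
  n$lad_mid <- n$lm_ost + p$lad_prox_length * dir_lad
  n$lad_out <- n$lad_mid + p$lad_dist_length * dir_lad
  n$lcx_out <- n$lm_ost + p$lcx_length * dir_lcx

  seg <- list(
    list("asc1", "inlet", "ra_ost", asc_r, "aorta", NULL),
    list("asc2", "ra_ost", "lm_ost", asc_r, "aorta", NULL),
    list("asc3", "lm_ost", "arch", asc_r, "aorta", NULL),
    list("desc", "arch", "desc_out", desc_r, "aorta", NULL),
    list("ra", "ra_ost", "ra_out", p$ra_radius, "ra", NULL),
    list("lad_prox", "lm_ost", "lad_mid", p$lad_radius, "lad_proximal", p$stenoses),
    list("lad_dist", "lad_mid", "lad_out", p$lad_radius, "lad_distal", NULL),
    list("lcx", "lm_ost", "lcx_out", p$lcx_radius, "lcx", NULL)
  )
  outlets <- c("desc_out", "ra_out", "lad_out", "lcx_out")
  nsb <- p$n_side_branches
  if (nsb > 0) {
    for (k in seq_len(nsb)) {
      phi <- 0.4 + (k - 1) * 2 * pi / 3
      dir_sb <- unit(c(0.30 * cos(phi), 0.30 * sin(phi), 0.95))
      nid <- sprintf("sb%d_out", k)
      n[[nid]] <- n$arch + p$side_length * dir_sb
      seg <- c(seg, list(list(sprintf("sb%d", k), "arch", nid, p$side_radius,
                              "side_branch", NULL)))
      outlets <- c(outlets, nid)
    }
  }
  coords <- unname(do.call(rbind, n))
  nodes <- tibble(
    id = names(n), x = coords[, 1], y = coords[, 2], z = coords[, 3]
  )
  segments <- tibble(
    id = vapply(seg, `[[`, "", 1),
    start_node = vapply(seg, `[[`, "", 2),
    end_node = vapply(seg, `[[`, "", 3),
    radius = vapply(seg, `[[`, 0, 4),
    role = vapply(seg, `[[`, "", 5),
    stenoses = lapply(seg, function(s) if (is.null(s[[6]])) empty_stenoses() else s[[6]])
  )
  len <- vapply(seq_len(nrow(segments)), function(i) {
    vnorm(node_coord(list(nodes = nodes), segments$end_node[i]) -
            node_coord(list(nodes = nodes), segments$start_node[i]))
  }, 0)
  segments$length <- len
  segments <- segments[, c("id", "start_node", "end_node", "length", "radius",
                           "role", "stenoses")]
  new_vessel_tree(nodes, segments, "inlet", outlets, "preoperative", params = p)
}

#' Build a base vessel tree from a built-in template
#'
#' Three idealized coronary-aortic topologies are built in: an ascending
#' aorta / arch / descending trunk, LAD split into proximal and distal runs at
#' the stenosis site, LCX, RA, and 0-3 supra-aortic side branches. Templates
#' differ in arch angulation, bifurcation angle, branch counts and lengths.
#' `scale_seed` applies a small (+-5%) deterministic jitter to branch lengths
#' so different bases are not congruent.
#'
#' @param template_id Template index: 0, 1 or 2.
#' @param scale_seed Integer seed for the length jitter.
#' @return A preoperative `vessel_tree`.
#' @export
make_base_tree <- function(template_id, scale_seed = 1L) {
  tpl <- tree_templates()[[as.character(template_id)]]
  if (is.null(tpl)) {
    abort(sprintf("unknown template '%s' (built-ins: 0, 1, 2)", template_id))
  }
  local_seed(scale_seed, {
    for (nm in c("asc_length", "desc_length", "lad_prox_length",
                 "lad_dist_length", "lcx_length", "ra_length", "side_length")) {
      tpl[[nm]] <- tpl[[nm]] * runif(1, 0.95, 1.05)
    }
  })
  build_tree_from_params(tpl)
}

draw_interval <- function(iv) runif(1, iv[1], iv[2])
draw_int_interval <- function(iv) {
  if (iv[1] == iv[2]) return(as.integer(iv[1]))
  sample(seq.int(iv[1], iv[2]), 1)
}

#' Expand a base tree into randomized geometric variants
#'
#' Mirrors population-level geometric variation: each variant redraws every
#' applicable parameter uniformly from its range (stenosis rate and count,
#' stenosis placement, bifurcation angle, side-branch count, aortic diameters,
#' arch angulation) and rebuilds the tree. Deterministic for a fixed seed; the
#' i-th variant uses child seed `derive_seed(seed, i)`.
#'
#' @param base A preoperative `vessel_tree` from [make_base_tree()].
#' @param ranges A [geometry_ranges()] object.
#' @param count Number of variants.
#' @param seed Integer seed.
#' @return List of `count` preoperative trees.
#' @export
expand_model <- function(base, ranges = geometry_ranges(), count = 9L, seed = 1L) {
  stopifnot(inherits(base, "vessel_tree"), count >= 1)
  if (!inherits(ranges, "geometry_ranges")) {
    ranges <- do.call(geometry_ranges, as.list(ranges))
  }
  p0 <- attr(base, "params")
  if (is.null(p0)) abort("base tree carries no template parameters")
  lapply(seq_len(count), function(i) {
    local_seed(derive_seed(seed, i), {
      p <- p0
      p$asc_diameter_mm <- draw_interval(ranges$ascending_aorta_diameter_mm)
      p$desc_diameter_mm <- draw_interval(ranges$descending_aorta_diameter_mm)
      p$arch_angle_deg <- draw_interval(ranges$arch_angle_deg)
      p$bifurcation_angle_deg <- draw_interval(ranges$bifurcation_angle_deg)
      p$n_side_branches <- draw_int_interval(ranges$n_side_branches)
      ns <- draw_int_interval(ranges$n_stenoses)
      ext <- ranges$stenosis_extent_mm / 1000
      centers <- draw_stenosis_centers(ns, ranges$stenosis_center, ext,
                                       p$lad_prox_length)
      p$stenoses <- tibble(
        rate = runif(ns, ranges$stenosis_rate[1], ranges$stenosis_rate[2]),
        center = centers,
        extent = rep(ext, ns)
      )
      build_tree_from_params(p)
    })
  })
}

draw_stenosis_centers <- function(n, center_iv, extent, seg_length) {
  if (n == 1) return(draw_interval(center_iv))
  min_gap <- extent / seg_length # centers must be >= one extent apart
  for (try in 1:200) {
    c_ <- sort(runif(n, center_iv[1], center_iv[2]))
    if (all(diff(c_) >= min_gap)) return(c_)
  }
  abort("cannot place non-overlapping stenoses in the given center range")
}

#' Deploy a bypass graft (virtual CABG)
#'
#' Adds a 2 mm-diameter conduit from the aortic arch (the LIMA-origin analog)
#' to the LAD immediately distal to the highest-grade stenosis, turning a
#' preoperative tree into a postoperative one with exactly one graft loop.
#' All pre-existing segments are left unchanged.
#'
#' @param tree A preoperative `vessel_tree` with a stenosed LAD.
#' @param seed Unused; accepted for call-site symmetry with the other
#'   generators (grafting is deterministic).
#' @param graft_diameter_mm Conduit diameter, default 2 mm.
#' @return A postoperative `vessel_tree`.
#' @export
add_graft <- function(tree, seed = NULL, graft_diameter_mm = 2.0) {
  stopifnot(inherits(tree, "vessel_tree"))
  if (tree$op_state != "preoperative") {
    abort("tree is already postoperative (graft present)")
  }
  segs <- tree$segments
  lad <- which(segs$role %in% c("lad_proximal", "lad_distal") &
                 vapply(segs$stenoses, nrow, 0L) > 0)
  if (length(lad) == 0) abort("no stenosed LAD segment: nothing to bypass")
  rates <- vapply(lad, function(i) max(segs$stenoses[[i]]$rate), 0)
  culprit <- lad[which.max(rates)]
  # Anastomose at the proximal/distal junction: the distal end of the culprit
  # segment, which is the start of the distal LAD run.
  target_node <- segs$end_node[culprit]
  origin_node <- "arch"
  glen <- vnorm(node_coord(tree, target_node) - node_coord(tree, origin_node))
  graft <- tibble(
    id = "graft", start_node = origin_node, end_node = target_node,
    length = glen, radius = graft_diameter_mm / 2000, role = "graft",
    stenoses = list(empty_stenoses())
  )
  new_vessel_tree(
    tree$nodes, dplyr::bind_rows(segs, graft),
    tree$inlet_node, tree$outlet_nodes, "postoperative",
    params = attr(tree, "params")
  )
}

segment_wall_area <- function(tree, seg, n_grid = 401) {
  fr <- segment_frame(tree, seg)
  x <- seq(0, fr$length, length.out = n_grid)
  r <- radius_profile(seg, x)
  sum(2 * pi * (r[-1] + r[-n_grid]) / 2) * (fr$length / (n_grid - 1))
}

segment_volume <- function(tree, seg, n_grid = 401) {
  fr <- segment_frame(tree, seg)
  x <- seq(0, fr$length, length.out = n_grid)
  r <- radius_profile(seg, x)
  sum(pi * (r[-1]^2 + r[-n_grid]^2) / 2) * (fr$length / (n_grid - 1))
}

#' Sample the wall surface of a vessel tree
#'
#' Draws points on the tubular wall of every segment: per segment the count is
#' Poisson with mean `area x density`, axial position and azimuth are uniform,
#' and each point sits exactly at the local stenosed radius from the
#' centerline (the same [radius_profile()] the flow solver integrates).
#' This is the "model point cloud": wall coordinates only.
#'
#' @param tree A `vessel_tree`.
#' @param points_per_mm2 Mean sampling density on the wall, points per square
#'   millimeter.
#' @param seed Integer seed.
#' @return Tibble with columns `x`, `y`, `z` (meters).
#' @export
surface_points <- function(tree, points_per_mm2 = 0.1, seed = 1L) {
  stopifnot(inherits(tree, "vessel_tree"), points_per_mm2 > 0)
  local_seed(seed, {
    parts <- lapply(seq_len(nrow(tree$segments)), function(i) {
      seg <- tree$segments[i, ]
      fr <- segment_frame(tree, seg)
      area_mm2 <- segment_wall_area(tree, seg) * 1e6
      m <- stats::rpois(1, area_mm2 * points_per_mm2)
      if (m == 0) return(NULL)
      ax <- runif(m, 0, fr$length)
      th <- runif(m, 0, 2 * pi)
      r <- radius_profile(seg, ax)
      ctr <- outer(ax, fr$dir)
      pts <- sweep(ctr, 2, fr$start, "+") +
        r * cos(th) * matrix(fr$e1, m, 3, byrow = TRUE) +
        r * sin(th) * matrix(fr$e2, m, 3, byrow = TRUE)
      tibble(x = pts[, 1], y = pts[, 2], z = pts[, 3])
    })
    out <- dplyr::bind_rows(parts)
    if (nrow(out) == 0) abort("density too low: no surface points drawn")
    out
  })
}

#' Sample interior (query) points of a vessel tree
#'
#' Draws exactly `n_points` points uniformly over the lumen volume: segments
#' are chosen proportionally to their volume, axial positions by rejection
#' against the local cross-sectional area, radial position as
#' `sqrt(U)` (uniform over the disk), azimuth uniform. Each point keeps its
#' segment id, axial fraction and radial fraction so analytic fields can be
#' evaluated on it directly, plus its anatomical region label.
#'
#' @param tree A `vessel_tree`.
#' @param n_points Number of points.
#' @param seed Integer seed.
#' @return Tibble `x, y, z, segment_id, axial_fraction, radial_fraction,
#'   region`.
#' @export
interior_points <- function(tree, n_points = 2048L, seed = 1L) {
  stopifnot(inherits(tree, "vessel_tree"), n_points >= 1)
  local_seed(seed, {
    segs <- tree$segments
    vols <- vapply(seq_len(nrow(segs)), function(i) segment_volume(tree, segs[i, ]), 0)
    pick <- sample.int(nrow(segs), n_points, replace = TRUE, prob = vols)
    parts <- lapply(seq_len(nrow(segs)), function(i) {
      m <- sum(pick == i)
      if (m == 0) return(NULL)
      seg <- segs[i, ]
      fr <- segment_frame(tree, seg)
      rmax <- seg$radius
      ax <- numeric(0)
      while (length(ax) < m) { # rejection: axial density proportional to r(x)^2
        cand <- runif(2 * (m - length(ax)) + 8, 0, fr$length)
        keep <- runif(length(cand)) < (radius_profile(seg, cand) / rmax)^2
        ax <- c(ax, cand[keep])
      }
      ax <- ax[seq_len(m)]
      rho <- sqrt(runif(m))
      th <- runif(m, 0, 2 * pi)
      r <- radius_profile(seg, ax) * rho
      pts <- sweep(outer(ax, fr$dir), 2, fr$start, "+") +
        r * cos(th) * matrix(fr$e1, m, 3, byrow = TRUE) +
        r * sin(th) * matrix(fr$e2, m, 3, byrow = TRUE)
      tibble(
        x = pts[, 1], y = pts[, 2], z = pts[, 3],
        segment_id = seg$id, axial_fraction = ax / fr$length,
        radial_fraction = rho, region = region_of_role(seg$role)
      )
    })
    out <- dplyr::bind_rows(parts)
    out[sample.int(nrow(out)), ] # shuffle so point order carries no structure
  })
}
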