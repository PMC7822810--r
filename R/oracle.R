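# Reduced-order steady-flow solver: Hagen-Poiseuille hydraulic network with
# analytic parabolic in-segment profiles. Plays the role of a 3D CFD stage at
# desk scale: linear, exactly solvable, conservation assertable.

#' Blood properties for the steady-flow solver
#'
#' @param density kg/m^3, default 1050.
#' @param viscosity Pa.s, default 0.0035 (Newtonian approximation of blood).
#' @return A `fluid_properties` object.
#' @export
fluid_properties <- function(density = 1050, viscosity = 0.0035) {
  if (density <= 0 || viscosity <= 0) abort("density and viscosity must be positive")
  structure(list(density = density, viscosity = viscosity),
            class = "fluid_properties")
}

#' Boundary conditions for the steady-flow solver
#'
#' A uniform inlet velocity (peak-systole convention) and zero gauge pressure
#' at every outlet; walls are no-slip through the parabolic profile closure.
#'
#' @param inlet_velocity m/s, default 1.125.
#' @param outlet_pressure Pa, fixed 0 by convention.
#' @return A `boundary_conditions` object.
#' @export
boundary_conditions <- function(inlet_velocity = 1.125, outlet_pressure = 0) {
  if (inlet_velocity <= 0) abort("inlet velocity must be positive")
  structure(list(inlet_velocity = inlet_velocity, outlet_pressure = outlet_pressure),
            class = "boundary_conditions")
}

# Composite Simpson on [a, b] with n (odd) points.
simpson <- function(f, a, b, n = 1001) {
  if (b <= a) return(0)
  if (n %% 2 == 0) n <- n + 1
  x <- seq(a, b, length.out = n)
  w <- rep(c(2, 4), length.out = n)
  w[1] <- 1
  w[n] <- 1
  sum(w * f(x)) * (b - a) / (n - 1) / 3
}

#' Hydraulic resistance of a vessel segment
#'
#' `R_h = integral of 8 mu / (pi r(x)^4) dx` along the segment. The uniform
#' part is closed-form `8 mu L / (pi R^4)`; each stenosis window adds a
#' correction integrated by 1001-point composite Simpson over its extent.
#'
#' @param seg One row of a tree's segment table.
#' @param fluid A [fluid_properties()] object.
#' @return Resistance in Pa.s/m^3.
#' @export
segment_resistance <- function(seg, fluid = fluid_properties()) {
  R <- seg$radius
  st <- seg$stenoses[[1]]
  if (!is.null(st) && nrow(st) > 0 && any(R * (1 - st$rate) <= 0)) {
    abort("stenotic throat radius must be positive")
  }
  base <- 8 * fluid$viscosity * seg$length / (pi * R^4)
  corr <- 0
  if (!is.null(st) && nrow(st) > 0) {
    for (k in seq_len(nrow(st))) {
      xc <- st$center[k] * seg$length
      ext <- st$extent[k]
      corr <- corr + simpson(
        function(x) 8 * fluid$viscosity / pi * (radius_profile(seg, x)^-4 - R^-4),
        xc - ext / 2, xc + ext / 2
      )
    }
  }
  base + corr
}

# Resistance from the segment start up to axial position x (vectorized).
partial_resistance <- function(seg, fluid, x) {
  R <- seg$radius
  base <- 8 * fluid$viscosity * x / (pi * R^4)
  st <- seg$stenoses[[1]]
  if (is.null(st) || nrow(st) == 0) return(base)
  corr <- numeric(length(x))
  for (k in seq_len(nrow(st))) {
    w1 <- st$center[k] * seg$length - st$extent[k] / 2
    w2 <- st$center[k] * seg$length + st$extent[k] / 2
    hit <- which(x > w1)
    for (i in hit) {
      corr[i] <- corr[i] + simpson(
        function(t) 8 * fluid$viscosity / pi * (radius_profile(seg, t)^-4 - R^-4),
        w1, min(x[i], w2)
      )
    }
  }
  base + corr
}

#' Solve steady flow on a vessel tree
#'
#' Kirchhoff nodal analysis of the hydraulic network: the inlet carries flow
#' `inlet_velocity x pi R_inlet^2`, every outlet is held at the outlet
#' pressure, interior nodes conserve mass. The linear nodal-pressure system is
#' solved directly; a graft in parallel with a stenosed path simply adds
#' conductance. Mass conservation is asserted on every solve.
#'
#' @param tree A `vessel_tree`.
#' @param bc A [boundary_conditions()] object.
#' @param fluid A [fluid_properties()] object.
#' @return A `network_solution` with signed `segment_flows` (m^3/s, positive
#'   along start to end), `node_pressures` (Pa), per-segment resistances, the
#'   inlet flow, and the worst relative nodal imbalance.
#' @export
solve_network <- function(tree, bc = boundary_conditions(),
                          fluid = fluid_properties()) {
  stopifnot(inherits(tree, "vessel_tree"))
  segs <- tree$segments
  res <- vapply(seq_len(nrow(segs)), function(i) {
    segment_resistance(segs[i, ], fluid)
  }, 0)
  names(res) <- segs$id
  g <- 1 / res

  inlet_segs <- which(segs$start_node == tree$inlet_node |
                        segs$end_node == tree$inlet_node)
  r_inlet <- segs$radius[inlet_segs[1]]
  q_in <- bc$inlet_velocity * pi * r_inlet^2

  unknown <- setdiff(tree$nodes$id, tree$outlet_nodes)
  idx <- setNames(seq_along(unknown), unknown)
  A <- matrix(0, length(unknown), length(unknown))
  b <- numeric(length(unknown))
  b[idx[[tree$inlet_node]]] <- q_in
  for (i in seq_len(nrow(segs))) {
    u <- segs$start_node[i]
    v <- segs$end_node[i]
    for (pair in list(c(u, v), c(v, u))) {
      a <- pair[1]; z <- pair[2]
      if (a %in% unknown) {
        ia <- idx[[a]]
        A[ia, ia] <- A[ia, ia] + g[i]
        if (z %in% unknown) {
          A[ia, idx[[z]]] <- A[ia, idx[[z]]] - g[i]
        } else {
          b[ia] <- b[ia] + g[i] * bc$outlet_pressure
        }
      }
    }
  }
  p_unknown <- tryCatch(
    drop(solve(A, b)),
    error = function(e) abort(paste0("singular hydraulic system: ", conditionMessage(e)))
  )
  p <- setNames(numeric(nrow(tree$nodes)), tree$nodes$id)
  p[unknown] <- p_unknown
  p[tree$outlet_nodes] <- bc$outlet_pressure

  q <- (p[segs$start_node] - p[segs$end_node]) * g
  names(q) <- segs$id

  # Conservation audit at interior nodes.
  imb <- 0
  for (nd in setdiff(tree$nodes$id, c(tree$inlet_node, tree$outlet_nodes))) {
    net <- sum(q[segs$end_node == nd]) - sum(q[segs$start_node == nd])
    imb <- max(imb, abs(net) / q_in)
  }
  if (imb >= 1e-10) {
    abort(sprintf("mass conservation violated: relative imbalance %.3e", imb))
  }
  structure(
    list(segment_flows = q, node_pressures = p, resistances = res,
         q_inlet = q_in, max_imbalance_rel = imb, fluid = fluid),
    class = "network_solution"
  )
}

check_lumen_points <- function(points) {
  need <- c("segment_id", "axial_fraction", "radial_fraction")
  if (!all(need %in% names(points))) {
    abort("points must carry segment_id, axial_fraction, radial_fraction")
  }
  if (any(points$radial_fraction >= 1)) abort("point outside lumen (radial_fraction >= 1)")
  if (any(points$axial_fraction < 0 | points$axial_fraction > 1)) {
    abort("axial_fraction must lie in [0, 1]")
  }
  invisible(points)
}

#' Velocity vectors at interior points
#'
#' Parabolic (Poiseuille) profile closure: at axial position `x` with local
#' radius `r(x)` and signed flow `Q`, the section-mean velocity is
#' `Q / (pi r(x)^2)` and the point velocity is `2 ubar (1 - rho^2)` along the
#' segment axis, with `rho` the radial fraction. No transverse components;
#' the wall limit is no-slip.
#'
#' @param tree A `vessel_tree`.
#' @param sol A `network_solution` for that tree.
#' @param points Tibble with `segment_id`, `axial_fraction`, `radial_fraction`
#'   (as produced by [interior_points()]).
#' @return N x 3 numeric matrix (m/s).
#' @export
velocity_at <- function(tree, sol, points) {
  check_lumen_points(points)
  out <- matrix(0, nrow(points), 3)
  for (sid in unique(points$segment_id)) {
    seg <- segment_row(tree, sid)
    fr <- segment_frame(tree, seg)
    w <- which(points$segment_id == sid)
    x <- points$axial_fraction[w] * seg$length
    r <- radius_profile(seg, x)
    ubar <- sol$segment_flows[[sid]] / (pi * r^2)
    mag <- 2 * ubar * (1 - points$radial_fraction[w]^2)
    out[w, ] <- outer(mag, fr$dir)
  }
  out
}

#' Pressures at interior points
#'
#' The upstream node pressure minus the flow times the partial hydraulic
#' resistance integrated up to the point's axial position. Pressure is uniform
#' over each cross-section (lubrication closure) and continuous across nodes.
#'
#' @inheritParams velocity_at
#' @return Numeric vector of pressures (Pa).
#' @export
pressure_at <- function(tree, sol, points) {
  check_lumen_points(points)
  out <- numeric(nrow(points))
  for (sid in unique(points$segment_id)) {
    seg <- segment_row(tree, sid)
    w <- which(points$segment_id == sid)
    x <- points$axial_fraction[w] * seg$length
    pr <- partial_resistance(seg, sol$fluid, x)
    out[w] <- sol$node_pressures[[seg$start_node]] - sol$segment_flows[[sid]] * pr
  }
  out
}

#' Bundle one model into a paired point-cloud sample
#'
#' Solves the tree, samples a wall ("model") cloud and an interior ("query")
#' cloud, and attaches per-point targets: the velocity vector, or the scalar
#' pressure replicated into three identical components so both field kinds
#' share one N x 3 target layout.
#'
#' @param tree A `vessel_tree`.
#' @param bc,fluid Solver conditions.
#' @param n_query Interior points.
#' @param surface_density Wall points per mm^2.
#' @param field_kind `"velocity"` or `"pressure"`.
#' @param seed Integer seed (surface and interior clouds use derived children).
#' @param model_id,base_model_id Identifiers kept for split hygiene.
#' @return A `hemo_sample`: `surface` tibble, `query` tibble with `tx, ty, tz`
#'   targets and region labels, the tree, and metadata.
#' @export
make_sample <- function(tree, bc = boundary_conditions(),
                        fluid = fluid_properties(),
                        n_query = 2048L, surface_density = 0.1,
                        field_kind = c("velocity", "pressure"),
                        seed = 1L, model_id = "model", base_model_id = model_id) {
  field_kind <- match.arg(field_kind)
  sol <- solve_network(tree, bc, fluid)
  surface <- surface_points(tree, surface_density, derive_seed(seed, 1))
  query <- interior_points(tree, n_query, derive_seed(seed, 2))
  targets <- if (field_kind == "velocity") {
    velocity_at(tree, sol, query)
  } else {
    pressure_to_components(pressure_at(tree, sol, query))
  }
  query$tx <- targets[, 1]
  query$ty <- targets[, 2]
  query$tz <- targets[, 3]
  structure(
    list(surface = surface, query = query, tree = tree, solution = sol,
         op_state = tree$op_state, field_kind = field_kind,
         model_id = model_id, base_model_id = base_model_id, seed = seed),
    class = "hemo_sample"
  )
}

#' @export
print.hemo_sample <- function(x, ...) {
  cat(sprintf(
    "<hemo_sample> %s %s field: %d surface + %d query points (model %s, base %s)\n",
    x$op_state, x$field_kind, nrow(x$surface), nrow(x$query),
    x$model_id, x$base_model_id
  ))
  invisible(x)
}
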