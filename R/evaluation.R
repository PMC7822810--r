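# Error functions, regional reports, clinical indices, method agreement and
# vortex/error-attribution analysis.

target_matrix <- function(x) {
  if (is.null(dim(x))) matrix(x, ncol = 1) else as.matrix(x)
}

check_pair <- function(truth, pred) {
  truth <- target_matrix(truth)
  pred <- target_matrix(pred)
  if (!all(dim(truth) == dim(pred))) abort("truth and prediction shapes differ")
  if (nrow(truth) < 1) abort("need at least one point")
  list(truth = truth, pred = pred)
}

#' Normalized mean absolute error (percent)
#'
#' `NMAE = (1/N) sum |P_i - Phat_i| / (max|P| - min|P|) x 100`, where `|.|`
#' is the per-point magnitude: the Euclidean norm of the component difference
#' for vector fields, the absolute value for scalars, and the normalizing
#' range is taken over the truth magnitudes of the selected points.
#'
#' @param truth,pred N x k matrices (or vectors) of true and predicted values.
#' @return NMAE as a percentage.
#' @export
nmae <- function(truth, pred) {
  p <- check_pair(truth, pred)
  mag <- row_norms(p$truth)
  rng <- max(mag) - min(mag)
  if (rng == 0) {
    abort("NMAE undefined: all truth magnitudes are equal (zero range)")
  }
  mean(row_norms(p$truth - p$pred)) / rng * 100
}

#' Per-point relative errors (percent)
#'
#' `||P_i - Phat_i|| / ||P_i|| x 100` per point; points whose truth magnitude
#' falls below `floor_frac` times the largest truth magnitude are returned as
#' `NA` (excluded from [mre()] averaging) to keep near-zero denominators out.
#'
#' @inheritParams nmae
#' @param floor_frac Relative exclusion floor for the truth magnitude.
#' @return Numeric vector of percentages with `NA` at excluded points.
#' @export
mre_points <- function(truth, pred, floor_frac = 1e-9) {
  p <- check_pair(truth, pred)
  mag <- row_norms(p$truth)
  out <- rep(NA_real_, length(mag))
  keep <- mag >= floor_frac * max(mag) & mag > 0
  out[keep] <- row_norms(p$truth[keep, , drop = FALSE] -
                           p$pred[keep, , drop = FALSE]) / mag[keep] * 100
  out
}

#' Mean relative error (percent)
#'
#' Mean of [mre_points()] over the included points. The number of excluded
#' near-zero points is attached as attribute `n_excluded`.
#'
#' @inheritParams mre_points
#' @return MRE as a percentage.
#' @export
mre <- function(truth, pred, floor_frac = 1e-9) {
  pts <- mre_points(truth, pred, floor_frac)
  if (all(is.na(pts))) abort("MRE undefined: every point excluded by the magnitude floor")
  structure(mean(pts, na.rm = TRUE), n_excluded = sum(is.na(pts)))
}

sample_truth <- function(sample) {
  cbind(sample$query$tx, sample$query$ty, sample$query$tz)
}

sample_pred <- function(sample) {
  if (!all(c("px", "py", "pz") %in% names(sample$query))) {
    abort(sprintf("sample '%s' carries no predictions; see add_predictions()",
                  sample$model_id))
  }
  cbind(sample$query$px, sample$query$py, sample$query$pz)
}

#' Attach network predictions to a sample
#'
#' @param sample A `hemo_sample`.
#' @param fit A `hemo_fit` or `hemo_net`.
#' @return The sample with `px, py, pz` columns added to its query cloud.
#' @export
add_predictions <- function(sample, fit) {
  model <- if (inherits(fit, "hemo_fit")) fit$model else fit
  pr <- net_predict(model, sample$surface, sample$query)
  sample$query$px <- pr$px
  sample$query$py <- pr$py
  sample$query$pz <- pr$pz
  sample
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Regional error report over a set of predicted models
#'
#' Computes NMAE and MRE per anatomical region per model (normalizing ranges
#' are region-local, per model), then aggregates mean and population standard
#' deviation across models. A region absent from a model (e.g. the graft in a
#' preoperative corpus) is skipped with a warning unless it is absent from
#' every model, in which case it is simply omitted.
#'
#' @param samples List of `hemo_sample`s carrying predictions
#'   (see [add_predictions()]).
#' @return An `error_report` tibble: `region`, `metric`, `mean`, `sd`,
#'   `n_models`.
#' @export
regional_report <- function(samples) {
  if (inherits(samples, "hemo_sample")) samples <- list(samples)
  rows <- list()
  all_regions <- flow_regions()
  present_any <- unique(unlist(lapply(samples, function(s) unique(s$query$region))))
  for (s in samples) {
    for (reg in intersect(all_regions, present_any)) {
      w <- which(s$query$region == reg)
      if (length(w) == 0) {
        warn(sprintf("model '%s' has no points in region '%s'; skipped",
                     s$model_id, reg))
        next
      }
      truth <- sample_truth(s)[w, , drop = FALSE]
      pred <- sample_pred(s)[w, , drop = FALSE]
      rows[[length(rows) + 1]] <- tibble(
        model_id = s$model_id, region = reg,
        nmae = tryCatch(nmae(truth, pred), error = function(e) NA_real_),
        mre = as.numeric(tryCatch(mre(truth, pred), error = function(e) NA_real_))
      )
    }
  }
  per_model <- dplyr::bind_rows(rows)
  out <- per_model |>
    tidyr::pivot_longer(c("nmae", "mre"), names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$region, .data$metric) |>
    dplyr::summarise(
      mean = mean(.data$value, na.rm = TRUE),
      sd = pop_sd(.data$value[!is.na(.data$value)]),
      n_models = sum(!is.na(.data$value)), .groups = "drop"
    ) |>
    dplyr::mutate(
      region = factor(.data$region, levels = all_regions),
      metric = toupper(.data$metric)
    ) |>
    dplyr::arrange(.data$metric, .data$region)
  structure(out, per_model = per_model,
            class = c("error_report", class(out)))
}

#' @export
autoplot.error_report <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$region, y = .data$mean)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(.data$mean - .data$sd, 0), ymax = .data$mean + .data$sd),
      width = 0.3
    ) +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = NULL, y = "error (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 40, hjust = 1))
}

# Deterministic sunflower pattern over a cross-sectional disk: radial
# fractions sqrt((k - 1/2)/n) make the disk-average of a parabolic profile
# equal the section mean exactly.
slab_points <- function(tree, seg_id, axial_fraction, n = 64L) {
  seg <- segment_row(tree, seg_id)
  fr <- segment_frame(tree, seg)
  k <- seq_len(n)
  rho <- sqrt((k - 0.5) / n)
  th <- k * pi * (3 - sqrt(5))
  x <- axial_fraction * seg$length
  r <- radius_profile(seg, x) * rho
  ctr <- fr$start + x * fr$dir
  pts <- matrix(ctr, n, 3, byrow = TRUE) +
    r * cos(th) * matrix(fr$e1, n, 3, byrow = TRUE) +
    r * sin(th) * matrix(fr$e2, n, 3, byrow = TRUE)
  tibble(
    x = pts[, 1], y = pts[, 2], z = pts[, 3],
    segment_id = seg$id, axial_fraction = axial_fraction, radial_fraction = rho,
    region = region_of_role(seg$role)
  )
}

#' Field accessors for clinical-index computation
#'
#' Clinical indices are computed identically for the reduced-order truth and
#' for network predictions by abstracting the field behind an accessor
#' function. Oracle accessors evaluate the analytic solution on the lumen
#' parameterization; network accessors run [net_predict()] on the point
#' coordinates (pressure = mean of the three replicated components).
#'
#' @param tree A `vessel_tree`.
#' @param sol A `network_solution`.
#' @param fit A `hemo_fit`/`hemo_net` trained on the matching field kind.
#' @param surface The wall cloud conditioning the network.
#' @return A function mapping a slab-point tibble to pressures (scalar) or
#'   velocities (N x 3).
#' @export
pressure_accessor_oracle <- function(tree, sol) {
  function(points) pressure_at(tree, sol, points)
}

#' @rdname pressure_accessor_oracle
#' @export
velocity_accessor_oracle <- function(tree, sol) {
  function(points) velocity_at(tree, sol, points)
}

#' @rdname pressure_accessor_oracle
#' @export
pressure_accessor_network <- function(fit, surface) {
  model <- if (inherits(fit, "hemo_fit")) fit$model else fit
  function(points) {
    pr <- net_predict(model, surface, points)
    (pr$px + pr$py + pr$pz) / 3
  }
}

#' @rdname pressure_accessor_oracle
#' @export
velocity_accessor_network <- function(fit, surface) {
  model <- if (inherits(fit, "hemo_fit")) fit$model else fit
  function(points) {
    pr <- net_predict(model, surface, points)
    cbind(pr$px, pr$py, pr$pz)
  }
}

lad_culprit <- function(tree) {
  segs <- tree$segments
  lad <- which(segs$role %in% c("lad_proximal", "lad_distal") &
                 vapply(segs$stenoses, nrow, 0L) > 0)
  if (length(lad) == 0) abort("no stenosed LAD segment")
  rates <- vapply(lad, function(i) max(segs$stenoses[[i]]$rate), 0)
  i <- lad[which.max(rates)]
  st <- segs$stenoses[[i]]
  k <- which.max(st$rate)
  list(seg = segs[i, ], rate = st$rate[k], center = st$center[k],
       extent = st$extent[k])
}

#' Fractional flow reserve of the stenosed LAD
#'
#' The ratio of mean pressure over a thin cross-section a fixed distance
#' (default 3 cm) downstream of the highest-grade stenosis to the mean
#' pressure at the LAD entry. Because the solver works in gauge pressure with
#' zero-pressure outlets, a fixed aortic reference pressure (default
#' 100 mmHg = 13332 Pa) is added to numerator and denominator; this is a
#' reporting convention of the package, applied identically to both methods
#' being compared, and is returned with the result. Offsets that run past the
#' distal LAD are clamped to 80% of its length with a warning.
#'
#' @param tree A `vessel_tree` with a stenosed LAD.
#' @param pressure_accessor A function from slab points to pressures (see
#'   [pressure_accessor_oracle()]).
#' @param distal_offset Meters downstream of the stenosis, default 0.03.
#' @param reference_pa Additive reference pressure, Pa.
#' @param n_slab Points per measurement slab.
#' @return List with `ffr`, the slab mean pressures, and the stations used.
#' @export
compute_ffr <- function(tree, pressure_accessor, distal_offset = 0.03,
                        reference_pa = 13332, n_slab = 64L) {
  culprit <- lad_culprit(tree)
  segs <- tree$segments
  prox <- segs[segs$role == "lad_proximal", ][1, ]
  dist <- segs[segs$role == "lad_distal", ][1, ]
  entry <- slab_points(tree, prox$id, 0.02, n_slab)

  sten_end <- culprit$center * culprit$seg$length + culprit$extent / 2
  remain <- culprit$seg$length - sten_end
  if (distal_offset <= remain && culprit$seg$id == prox$id) {
    distal <- slab_points(tree, prox$id, (sten_end + distal_offset) / prox$length,
                          n_slab)
  } else {
    into_dist <- distal_offset - remain
    if (into_dist > 0.8 * dist$length) {
      warn(sprintf(
        "distal offset %.3g m exceeds the distal LAD; clamped to 80%% of its length",
        distal_offset
      ))
      into_dist <- 0.8 * dist$length
    }
    distal <- slab_points(tree, dist$id, into_dist / dist$length, n_slab)
  }
  p_entry <- mean(pressure_accessor(entry))
  p_distal <- mean(pressure_accessor(distal))
  list(
    ffr = (p_distal + reference_pa) / (p_entry + reference_pa),
    p_entry = p_entry, p_distal = p_distal, reference_pa = reference_pa,
    entry_station = entry, distal_station = distal
  )
}

#' Graft inflow (improved blood flow)
#'
#' Mean axial velocity over a thin slab at the graft inlet times the graft
#' cross-sectional area `pi d^2 / 4`.
#'
#' @param tree A postoperative `vessel_tree`.
#' @param velocity_accessor Function from slab points to N x 3 velocities.
#' @param n_slab Points in the inlet slab.
#' @return Volumetric flow in m^3/s.
#' @export
graft_flow <- function(tree, velocity_accessor, n_slab = 64L) {
  segs <- tree$segments
  gi <- which(segs$role == "graft")
  if (length(gi) == 0) abort("tree has no graft (preoperative?)")
  seg <- segs[gi[1], ]
  fr <- segment_frame(tree, seg)
  slab <- slab_points(tree, seg$id, 0.05, n_slab)
  v <- velocity_accessor(slab)
  mean_axial <- mean(v %*% fr$dir)
  mean_axial * pi * seg$radius^2
}

#' Pearson correlation and Bland-Altman agreement of two methods
#'
#' Pearson r with its p-value, the mean paired difference, the population
#' standard deviation of the differences, limits of agreement at mean
#' +- 1.96 SD, and the count of pairs inside the limits.
#'
#' @param values_a,values_b Paired measurements from the two methods
#'   (length >= 3).
#' @return An `agreement_stats` object.
#' @export
agreement <- function(values_a, values_b) {
  a <- as.numeric(values_a)
  b <- as.numeric(values_b)
  if (length(a) != length(b)) abort("paired vectors must have equal length")
  if (length(a) < 3) abort("need at least 3 pairs")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    abort("correlation undefined: one method has zero variance")
  }
  ct <- stats::cor.test(a, b, method = "pearson")
  d <- a - b
  md <- mean(d)
  sdd <- pop_sd(d)
  lo <- md - 1.96 * sdd
  hi <- md + 1.96 * sdd
  structure(
    list(
      pearson_r = unname(ct$estimate), p_value = ct$p.value,
      mean_diff = md, sd_diff = sdd, loa_lower = lo, loa_upper = hi,
      n = length(a), n_within_limits = sum(d >= lo & d <= hi),
      data = tibble(a = a, b = b, mean = (a + b) / 2, diff = d)
    ),
    class = "agreement_stats"
  )
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf(
    "<agreement_stats> n=%d: r=%.4f (p=%.3g); Bland-Altman %.4g [%.4g, %.4g], %d/%d within limits\n",
    x$n, x$pearson_r, x$p_value, x$mean_diff, x$loa_lower, x$loa_upper,
    x$n_within_limits, x$n
  ))
  invisible(x)
}

#' @export
tidy.agreement_stats <- function(x, ...) x$data

#' @export
glance.agreement_stats <- function(x, ...) {
  tibble(
    pearson_r = x$pearson_r, p_value = x$p_value, mean_diff = x$mean_diff,
    sd_diff = x$sd_diff, loa_lower = x$loa_lower, loa_upper = x$loa_upper,
    n = x$n, n_within_limits = x$n_within_limits
  )
}

#' @export
autoplot.agreement_stats <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = object$mean_diff, linetype = "solid") +
    ggplot2::geom_hline(yintercept = c(object$loa_lower, object$loa_upper),
                        linetype = "dashed") +
    ggplot2::labs(x = "mean of methods", y = "difference",
                  title = "Bland-Altman agreement") +
    ggplot2::theme_minimal()
}

#' Vorticity magnitude on a scattered velocity field
#'
#' Estimates the velocity-gradient tensor at each point by weighted least
#' squares over its k nearest neighbors (Gaussian distance weights), takes
#' the curl, and thresholds its magnitude into a binary vortex mask. Points
#' with rank-deficient neighborhoods are flagged and excluded from the mask.
#' The default threshold is the 90th percentile of the estimated magnitudes.
#'
#' @param coords N x 3 coordinates (or data frame with x, y, z).
#' @param velocities N x 3 velocities.
#' @param k_neighbors Neighborhood size (>= 10).
#' @param threshold Vortex threshold in 1/s; `NULL` for the 90th percentile.
#' @return A tibble `vorticity, flagged, in_vortex` with the threshold as
#'   attribute `threshold`.
#' @export
vorticity_field <- function(coords, velocities, k_neighbors = 16L,
                            threshold = NULL) {
  X <- as_coord_matrix(coords, "coordinates")
  U <- as_coord_matrix(velocities, "velocities")
  n <- nrow(X)
  if (nrow(U) != n) abort("coordinates and velocities must align")
  if (k_neighbors < 10) abort("k_neighbors must be at least 10")
  if (n <= k_neighbors) abort("need more points than neighbors")

  sq <- rowSums(X^2)
  omega <- rep(NA_real_, n)
  flagged <- logical(n)
  chunk <- 512L
  for (lo in seq(1, n, by = chunk)) {
    hi <- min(lo + chunk - 1, n)
    d2 <- outer(sq[lo:hi], sq, "+") - 2 * X[lo:hi, , drop = FALSE] %*% t(X)
    for (i in lo:hi) {
      row <- d2[i - lo + 1, ]
      nb <- order(row)[2:(k_neighbors + 1)]
      dx <- X[nb, , drop = FALSE] - matrix(X[i, ], k_neighbors, 3, byrow = TRUE)
      du <- U[nb, , drop = FALSE] - matrix(U[i, ], k_neighbors, 3, byrow = TRUE)
      h2 <- max(row[nb])
      w <- exp(-rowSums(dx^2) / h2)
      Xw <- dx * w
      M <- crossprod(Xw, dx)
      if (rcond(M) < 1e-12) {
        flagged[i] <- TRUE
        next
      }
      B <- solve(M, crossprod(Xw, du)) # B[j, c] = d u_c / d x_j
      cw <- c(B[2, 3] - B[3, 2], B[3, 1] - B[1, 3], B[1, 2] - B[2, 1])
      omega[i] <- sqrt(sum(cw^2))
    }
  }
  if (is.null(threshold)) {
    threshold <- unname(quantile(omega, 0.9, na.rm = TRUE))
  }
  out <- tibble(
    vorticity = omega, flagged = flagged,
    in_vortex = !is.na(omega) & omega > threshold
  )
  attr(out, "threshold") <- threshold
  out
}

#' Overlap between high-error points and the vortex region
#'
#' @param point_mre Per-point relative errors in percent
#'   (see [mre_points()]).
#' @param vortex_mask Logical vortex membership per point.
#' @param error_threshold Percent; points above it count as high-error.
#' @param region Optional per-point region labels for a breakdown.
#' @return One-row tibble: `n_high`, `frac_high_in_vortex` (NA when no point
#'   exceeds the threshold), `vortex_fraction`, `n`. Per-region rows are in
#'   attribute `per_region` when regions are supplied.
#' @export
high_error_overlap <- function(point_mre, vortex_mask, error_threshold = 10,
                               region = NULL) {
  if (length(point_mre) != length(vortex_mask)) abort("arrays must align")
  high <- !is.na(point_mre) & point_mre > error_threshold
  summarize_one <- function(h, m) {
    tibble(
      n = length(h), n_high = sum(h),
      frac_high_in_vortex = if (sum(h) == 0) NA_real_ else mean(m[h]),
      vortex_fraction = mean(m)
    )
  }
  out <- summarize_one(high, vortex_mask)
  if (!is.null(region)) {
    per <- dplyr::bind_rows(lapply(split(seq_along(high), region), function(w) {
      summarize_one(high[w], vortex_mask[w])
    }), .id = "region")
    attr(out, "per_region") <- per
  }
  out
}

#' Mean test-set MRE over one region
#'
#' Predicts every test sample and averages the per-model MRE of the selected
#' region.
#'
#' @param fit A `hemo_fit`.
#' @param corpus A `corpus_split`.
#' @param region Region name (see [flow_regions()]).
#' @return Mean MRE in percent.
#' @export
test_region_mre <- function(fit, corpus, region = "aorta_and_branches") {
  vals <- vapply(corpus$test, function(s) {
    s <- add_predictions(s, fit)
    w <- which(s$query$region == region)
    if (length(w) == 0) return(NA_real_)
    as.numeric(mre(sample_truth(s)[w, , drop = FALSE],
                   sample_pred(s)[w, , drop = FALSE]))
  }, 0)
  mean(vals, na.rm = TRUE)
}

#' Training-set-size sweep
#'
#' Retrains the network from scratch on growing fractions of the training
#' split (fixed test split), recording the test-region MRE per fraction; the
#' Spearman rank correlation of MRE against fraction is attached as attribute
#' `spearman_rho`.
#'
#' @param corpus A `corpus_split`.
#' @param fractions Fractions of the training split to use.
#' @param region Evaluation region.
#' @param config Base [net_config()]; each fraction gets a derived seed.
#' @param seed Sweep master seed.
#' @param epochs Override epochs per run (defaults to the config's).
#' @return A tibble `fraction, n_train, mre_pct`.
#' @export
training_size_sweep <- function(corpus, fractions = seq(0.1, 1, by = 0.1),
                                region = "aorta_and_branches",
                                config = net_config(), seed = 1L,
                                epochs = NULL) {
  rows <- list()
  for (i in seq_along(fractions)) {
    f <- fractions[i]
    n <- round(f * length(corpus$train))
    if (n < 1) {
      warn(sprintf("fraction %.2f yields no training models; skipped", f))
      next
    }
    cfg <- config
    cfg$seed <- derive_seed(seed, i)
    sub <- corpus
    sub$train <- corpus$train[seq_len(n)]
    fit <- net_train(net_build(cfg), sub, epochs = epochs)
    rows[[length(rows) + 1]] <- tibble(
      fraction = f, n_train = n,
      mre_pct = test_region_mre(fit, corpus, region)
    )
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) >= 3 && stats::sd(out$mre_pct) > 0) {
    attr(out, "spearman_rho") <- stats::cor(out$fraction, out$mre_pct,
                                            method = "spearman")
  }
  out
}
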