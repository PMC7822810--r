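test_that("error functions reproduce hand-computed values", {
  # scalar truth (1, 2) vs (1.1, 1.8)
  expect_equal(nmae(c(1, 2), c(1.1, 1.8)), 15, tolerance = 1e-12)
  expect_equal(as.numeric(mre(c(1, 2), c(1.1, 1.8))), 10, tolerance = 1e-12)
  # orthogonal unit vectors: relative error sqrt(2)
  expect_equal(
    as.numeric(mre(matrix(c(1, 0, 0), 1), matrix(c(0, 1, 0), 1))),
    sqrt(2) * 100, tolerance = 1e-9
  )
  expect_equal(as.numeric(mre(matrix(c(0, 1, 0), 1), matrix(c(0, 1, 0), 1))), 0)
  truth <- matrix(rnorm(30), 10, 3)
  expect_equal(nmae(truth, truth), 0)
  expect_error(nmae(c(2, 2, 2), c(1, 2, 3)), "zero range")
  expect_error(mre(c(0, 0), c(1, 1)), "every point excluded")
  expect_error(nmae(c(1, 2), c(1, 2, 3)), "shapes differ")
})

test_that("metrics match an independent brute-force implementation", {
  set.seed(42)
  for (i in 1:25) {
    n <- sample(2:500, 1)
    k <- sample(c(1, 3), 1)
    truth <- matrix(rnorm(n * k, sd = 2), n, k)
    pred <- truth + matrix(rnorm(n * k, sd = 0.3), n, k)
    expect_equal(nmae(truth, pred), bf_nmae(truth, pred), tolerance = 1e-12)
    expect_equal(as.numeric(mre(truth, pred)), bf_mre(truth, pred),
                 tolerance = 1e-12)
  }
})

test_that("metrics are rotation- and scale-invariant", {
  set.seed(7)
  truth <- matrix(rnorm(60), 20, 3)
  pred <- truth + matrix(rnorm(60, sd = 0.2), 20, 3)
  # random rotation via QR
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Rot <- qr.Q(qr_)
  if (det(Rot) < 0) Rot[, 1] <- -Rot[, 1]
  expect_equal(nmae(truth %*% Rot, pred %*% Rot), nmae(truth, pred),
               tolerance = 1e-9)
  expect_equal(as.numeric(mre(truth %*% Rot, pred %*% Rot)),
               as.numeric(mre(truth, pred)), tolerance = 1e-9)
  for (c_ in c(0.01, 5)) {
    expect_equal(nmae(c_ * truth, c_ * pred), nmae(truth, pred), tolerance = 1e-9)
    expect_equal(as.numeric(mre(c_ * truth, c_ * pred)),
                 as.numeric(mre(truth, pred)), tolerance = 1e-9)
  }
})

fake_sample <- function(model_id, region, truth, pred) {
  query <- tibble::tibble(
    x = 0, y = 0, z = 0, region = region,
    tx = truth[, 1], ty = truth[, 2], tz = truth[, 3],
    px = pred[, 1], py = pred[, 2], pz = pred[, 3]
  )
  structure(list(query = query, model_id = model_id, op_state = "preoperative",
                 field_kind = "velocity"),
            class = "hemo_sample")
}

test_that("regional report aggregates with a population SD across models", {
  set.seed(1)
  truth <- matrix(rnorm(90, mean = 3), 30, 3)
  # model A: 10% relative error on every point; model B: 20%
  sA <- fake_sample("A", "lcx", truth, truth * 1.1)
  sB <- fake_sample("B", "lcx", truth, truth * 1.2)
  rep <- regional_report(list(sA, sB))
  mre_row <- rep[rep$region == "lcx" & rep$metric == "MRE", ]
  expect_equal(mre_row$mean, 15, tolerance = 1e-9)
  expect_equal(mre_row$sd, 5, tolerance = 1e-9)
  expect_identical(mre_row$n_models, 2L)

  # perfect predictions: all zero, zero spread
  perfect <- regional_report(list(fake_sample("A", "ra", truth, truth)))
  expect_equal(perfect$mean, rep(0, nrow(perfect)))
  expect_equal(perfect$sd, rep(0, nrow(perfect)))

  # graft rows only exist when the region is sampled (postoperative corpora)
  expect_false("graft" %in% as.character(rep$region))
})

test_that("FFR approaches 1 without stenosis and decreases with severity", {
  zero <- make_sweep_tree(0)
  sol <- solve_network(zero)
  f0 <- compute_ffr(zero, pressure_accessor_oracle(zero, sol))
  expect_gt(f0$ffr, 0.99)
  expect_lte(f0$ffr, 1)

  ffrs <- vapply(c(0.60, 0.70, 0.80, 0.90), function(s) {
    tr <- make_sweep_tree(s)
    compute_ffr(tr, pressure_accessor_oracle(tr, solve_network(tr)))$ffr
  }, 0)
  expect_true(all(diff(ffrs) < 0))
  expect_true(all(ffrs > 0 & ffrs <= 1))
})

test_that("graft flow recovers the closed-form and the solver segment flow", {
  post <- add_graft(make_base_tree(0, 3))
  gseg <- post$segments[post$segments$role == "graft", ]
  fr <- coroflow:::segment_frame(post, gseg)
  # uniform 0.5 m/s axial plug flow through a 2 mm conduit
  plug <- function(points) matrix(fr$dir, nrow(points), 3, byrow = TRUE) * 0.5
  expect_equal(graft_flow(post, plug), 0.5 * pi * 0.002^2 / 4, tolerance = 1e-9)
  expect_equal(graft_flow(post, plug), 1.5708e-6, tolerance = 1e-4)
  expect_equal(graft_flow(post, function(p) matrix(0, nrow(p), 3)), 0)

  sol <- solve_network(post)
  q_slab <- graft_flow(post, velocity_accessor_oracle(post, sol))
  q_seg <- unname(sol$segment_flows[gseg$id])
  expect_lt(abs(q_slab - q_seg) / q_seg, 0.02)

  expect_error(graft_flow(make_base_tree(0, 3), plug), "no graft")
})

test_that("agreement reproduces hand Bland-Altman limits and degenerate r", {
  a <- c(1, 2, 3, 4)
  ag <- agreement(a + c(0.01, -0.01, 0.01, -0.01), a)
  expect_equal(ag$mean_diff, 0, tolerance = 1e-12)
  expect_equal(ag$sd_diff, 0.01, tolerance = 1e-12)
  expect_equal(ag$loa_lower, -0.0196, tolerance = 1e-12)
  expect_equal(ag$loa_upper, 0.0196, tolerance = 1e-12)

  same <- agreement(a, a + 1e-9 * c(1, -1, 1, -1) + 0)
  expect_equal(same$pearson_r, 1, tolerance = 1e-6)

  anti <- agreement(c(1, 2, 3), c(5, 3, 1))
  expect_equal(anti$pearson_r, -1, tolerance = 1e-12)

  expect_error(agreement(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(agreement(c(1, 2), c(1, 2)), "at least 3")

  set.seed(5)
  x <- rnorm(40)
  y <- x + rnorm(40, sd = 0.1)
  bf <- bf_bland_altman(x, y)
  ag2 <- agreement(x, y)
  expect_equal(ag2$mean_diff, bf$mean_diff, tolerance = 1e-12)
  expect_equal(ag2$loa_lower, bf$lower, tolerance = 1e-12)
  expect_equal(ag2$loa_upper, bf$upper, tolerance = 1e-12)
  expect_equal(ag2$pearson_r, unname(cor(x, y)), tolerance = 1e-12)
})

test_that("vorticity estimation recovers analytic fields", {
  set.seed(3)
  n <- 3000
  X <- cbind(runif(n, -1, 1), runif(n, -1, 1), runif(n, -0.3, 0.3))
  # rigid rotation about z at 1 rad/s: curl = (0, 0, 2)
  U <- cbind(-X[, 2], X[, 1], 0)
  vf <- vorticity_field(X, U, k_neighbors = 14)
  expect_lt(abs(mean(vf$vorticity, na.rm = TRUE) - 2), 0.05)

  # uniform translation: zero curl
  U0 <- matrix(rep(c(0.3, -0.1, 0.2), each = n), n, 3)
  vf0 <- vorticity_field(X, U0, k_neighbors = 14)
  expect_lt(max(vf0$vorticity, na.rm = TRUE), 0.01)
})

test_that("vorticity matches the Poiseuille closed form at mid-radius", {
  set.seed(9)
  n <- 6000
  r_tube <- 0.0015
  ubar <- 0.1
  rho <- sqrt(runif(n))
  th <- runif(n, 0, 2 * pi)
  X <- cbind(rho * r_tube * cos(th), rho * r_tube * sin(th), runif(n, 0, 0.01))
  U <- cbind(0, 0, 2 * ubar * (1 - rho^2))
  vf <- vorticity_field(X, U, k_neighbors = 16)
  mid <- which(abs(rho - 0.5) < 0.05)
  est <- mean(vf$vorticity[mid], na.rm = TRUE)
  expect_lt(abs(est - 4 * ubar * 0.5 / r_tube), 5) # 133.33 1/s analytic
})

test_that("high-error overlap behaves at its edges and under independence", {
  m <- c(20, 30, 5, 1)
  expect_equal(high_error_overlap(m, c(TRUE, TRUE, FALSE, FALSE))$frac_high_in_vortex, 1)
  expect_equal(high_error_overlap(m, c(FALSE, FALSE, TRUE, TRUE))$frac_high_in_vortex, 0)
  none <- high_error_overlap(c(1, 2, 3), c(TRUE, FALSE, TRUE))
  expect_identical(none$n_high, 0L)
  expect_true(is.na(none$frac_high_in_vortex))

  set.seed(11)
  n <- 10000
  q <- 0.2
  mask <- runif(n) < q
  errs <- ifelse(runif(n) < 0.3, 50, 1) # independent of the mask
  ov <- high_error_overlap(errs, mask)
  sigma <- sqrt(q * (1 - q) / ov$n_high)
  expect_lt(abs(ov$frac_high_in_vortex - q), 3 * sigma)
})

test_that("training-size sweep is consistent and deterministic", {
  corpus <- tiny_corpus(n_train = 3, n_query = 96)
  cfg <- tiny_config(epochs = 2)
  curve <- training_size_sweep(corpus, fractions = 1.0, config = cfg, seed = 5)
  expect_identical(nrow(curve), 1L)
  expect_identical(curve$n_train, 3)
  # a fraction-1.0 sweep point equals a standard run under the derived seed
  cfg1 <- cfg
  cfg1$seed <- derive_seed(5, 1)
  fit <- net_train(net_build(cfg1), corpus)
  expect_equal(curve$mre_pct, test_region_mre(fit, corpus), tolerance = 1e-9)

  curve2 <- training_size_sweep(corpus, fractions = 1.0, config = cfg, seed = 5)
  expect_identical(curve, curve2)

  expect_warning(
    training_size_sweep(corpus, fractions = c(0.01, 1), config = cfg, seed = 5),
    "skipped"
  )
})
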