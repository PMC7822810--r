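# Independent brute-force reference implementations used to cross-check the
# package's metric and agreement code. Deliberately written as plain loops,
# sharing no code with the implementations under test.

bf_nmae <- function(truth, pred) {
  truth <- as.matrix(truth)
  pred <- as.matrix(pred)
  n <- nrow(truth)
  mags <- numeric(n)
  diffs <- numeric(n)
  for (i in seq_len(n)) {
    mags[i] <- sqrt(sum(truth[i, ]^2))
    diffs[i] <- sqrt(sum((truth[i, ] - pred[i, ])^2))
  }
  acc <- 0
  for (i in seq_len(n)) acc <- acc + diffs[i]
  (acc / n) / (max(mags) - min(mags)) * 100
}

bf_mre <- function(truth, pred, floor_frac = 1e-9) {
  truth <- as.matrix(truth)
  pred <- as.matrix(pred)
  n <- nrow(truth)
  mags <- numeric(n)
  for (i in seq_len(n)) mags[i] <- sqrt(sum(truth[i, ]^2))
  floor <- floor_frac * max(mags)
  acc <- 0
  kept <- 0
  for (i in seq_len(n)) {
    if (mags[i] >= floor && mags[i] > 0) {
      acc <- acc + sqrt(sum((truth[i, ] - pred[i, ])^2)) / mags[i]
      kept <- kept + 1
    }
  }
  acc / kept * 100
}

bf_bland_altman <- function(a, b) {
  n <- length(a)
  d <- numeric(n)
  for (i in seq_len(n)) d[i] <- a[i] - b[i]
  md <- sum(d) / n
  ssq <- 0
  for (i in seq_len(n)) ssq <- ssq + (d[i] - md)^2
  sdd <- sqrt(ssq / n)
  list(mean_diff = md, lower = md - 1.96 * sdd, upper = md + 1.96 * sdd)
}

# Minimal straight-tube tree (single segment along +z), optionally stenosed.
make_tube_tree <- function(length = 0.03, radius = 0.0015, stenoses = NULL,
                           role = "lad_proximal") {
  nodes <- tibble::tibble(
    id = c("inlet", "out"), x = c(0, 0), y = c(0, 0), z = c(0, length)
  )
  segments <- tibble::tibble(
    id = "tube", start_node = "inlet", end_node = "out",
    length = length, radius = radius, role = role,
    stenoses = list(if (is.null(stenoses)) coroflow:::empty_stenoses() else stenoses)
  )
  coroflow:::new_vessel_tree(nodes, segments, "inlet", "out", "preoperative")
}

# A base tree whose LAD stenosis severity is fixed at `rate`.
make_sweep_tree <- function(rate, template = 0, scale_seed = 11) {
  tree <- make_base_tree(template, scale_seed)
  i <- which(tree$segments$role == "lad_proximal")
  st <- tree$segments$stenoses[[i]]
  st$rate <- rate
  tree$segments$stenoses[[i]] <- st
  tree
}

tiny_corpus <- function(n_train = 2, n_test = 1, n_query = 256,
                        field_kind = "velocity", op_state = "preoperative",
                        seed = 7) {
  build_corpus(
    n_base_train = n_train, n_base_test = n_test, expansions_per_base = 1,
    op_state = op_state, field_kind = field_kind,
    n_query = n_query, surface_density = 0.01, master_seed = seed
  )
}

tiny_config <- function(...) {
  net_config(fc1_width = 16, fc2_width = 16, fc3_width = 32, fc4_width = 16,
             fc5_width = 16, ...)
}
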