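# Dual-input, dual-sampling-channel point-cloud regression network.
#
# Channel A takes the wall ("model") cloud, channel B the interior ("query")
# cloud. Both run a per-point trunk FC1 -> FC2 (weights shared across channels
# by default). The wall branch continues FC3 -> max-pool over points (the
# symmetric function that removes point-order dependence) -> one 512-wide
# global feature, tiled to every query point; the query branch continues
# FC4 -> per-point 128-wide local features. Concatenation gives N x 640,
# finished by FC5 -> FC6 -> N x 3. All layers are per-point affine maps, so
# the whole forward pass is dense matrix algebra.

#' Network architecture and training hyperparameters
#'
#' Defaults follow the dual-channel design: a shared 64/64 per-point trunk,
#' a 512-wide global (wall) path and a 128-wide local (query) path whose
#' concatenation is 640 wide, a 64-wide head, 3 outputs, rectifier
#' activations, mean-absolute-error loss, and Adam (lr 0.001, beta1 0.9,
#' beta2 0.999, eps 1e-8). `single_channel = TRUE` gives the classic
#' one-input baseline where global and local features are pooled from the
#' same cloud; `share_weights = FALSE` unties the trunk across channels.
#'
#' @param fc1_width,fc2_width Trunk widths.
#' @param fc3_width Global-feature width (512).
#' @param fc4_width Local-feature width (128).
#' @param fc5_width Head width.
#' @param fc6_out Output components (3).
#' @param share_weights Share the FC1/FC2 trunk across channels.
#' @param single_channel Use one input cloud for both feature paths.
#' @param learning_rate,beta1,beta2,adam_eps Adam hyperparameters.
#' @param epochs Training epochs.
#' @param points_per_step Query points per optimization step. The default
#'   (`Inf`) trains one whole model — its full wall and query clouds — per
#'   step. A finite value splits each model's query cloud into randomized
#'   chunks of at most this many points (each epoch still visits every cloud
#'   once), trading more Adam steps per epoch against a higher per-epoch
#'   cost.
#' @param seed Integer seed for initialization and model shuffling.
#' @return A `net_config` object.
#' @export
net_config <- function(fc1_width = 64L, fc2_width = 64L, fc3_width = 512L,
                       fc4_width = 128L, fc5_width = 64L, fc6_out = 3L,
                       share_weights = TRUE, single_channel = FALSE,
                       learning_rate = 0.001, beta1 = 0.9, beta2 = 0.999,
                       adam_eps = 1e-8, epochs = 50L, points_per_step = Inf,
                       seed = 1L) {
  cfg <- list(
    fc1_width = as.integer(fc1_width), fc2_width = as.integer(fc2_width),
    fc3_width = as.integer(fc3_width), fc4_width = as.integer(fc4_width),
    fc5_width = as.integer(fc5_width), fc6_out = as.integer(fc6_out),
    share_weights = isTRUE(share_weights),
    single_channel = isTRUE(single_channel),
    learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
    adam_eps = adam_eps, epochs = as.integer(epochs),
    points_per_step = points_per_step, seed = as.integer(seed)
  )
  widths <- unlist(cfg[c("fc1_width", "fc2_width", "fc3_width", "fc4_width",
                         "fc5_width", "fc6_out")])
  if (any(widths <= 0)) abort("all layer widths must be positive")
  if (cfg$fc6_out != 3L) abort("the network predicts 3-component fields; fc6_out must be 3")
  if (!(length(cfg$points_per_step) == 1 &&
          (is.infinite(cfg$points_per_step) || cfg$points_per_step >= 1))) {
    abort("points_per_step must be a positive count or Inf")
  }
  structure(cfg, class = "net_config")
}

concat_width <- function(cfg) cfg$fc3_width + cfg$fc4_width

init_affine <- function(n_in, n_out) {
  lim <- 1 / sqrt(n_in) # uniform fan-in initialization
  list(W = matrix(runif(n_in * n_out, -lim, lim), n_in, n_out),
       b = numeric(n_out))
}

layer_plan <- function(cfg) {
  plan <- list(
    trunk1 = c(3L, cfg$fc1_width),
    trunk2 = c(cfg$fc1_width, cfg$fc2_width)
  )
  if (!cfg$share_weights && !cfg$single_channel) {
    plan$trunk1q <- c(3L, cfg$fc1_width)
    plan$trunk2q <- c(cfg$fc1_width, cfg$fc2_width)
  }
  c(plan, list(
    fc3 = c(cfg$fc2_width, cfg$fc3_width),
    fc4 = c(cfg$fc2_width, cfg$fc4_width),
    fc5 = c(concat_width(cfg), cfg$fc5_width),
    fc6 = c(cfg$fc5_width, cfg$fc6_out)
  ))
}

#' Build an untrained network
#'
#' @param config A [net_config()].
#' @return A `hemo_net` model handle with freshly initialized weights.
#' @export
net_build <- function(config = net_config()) {
  stopifnot(inherits(config, "net_config"))
  plan <- layer_plan(config)
  weights <- local_seed(config$seed, {
    lapply(plan, function(d) init_affine(d[1], d[2]))
  })
  structure(
    list(config = config, weights = weights,
         adam = NULL, step = 0L),
    class = "hemo_net"
  )
}

#' Total number of trainable parameters
#'
#' @param model A `hemo_net`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$weights, function(l) length(l$W) + length(l$b), 0))
}

#' @export
print.hemo_net <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<hemo_net> %s, trunk %s: %d/%d -> global %d + local %d = %d -> %d -> %d (%d parameters)\n",
    if (cfg$single_channel) "single-channel" else "dual-channel",
    if (cfg$share_weights || cfg$single_channel) "shared" else "unshared",
    cfg$fc1_width, cfg$fc2_width, cfg$fc3_width, cfg$fc4_width,
    concat_width(cfg), cfg$fc5_width, cfg$fc6_out, n_parameters(x)
  ))
  invisible(x)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

affine <- function(x, l) sweep(x %*% l$W, 2, l$b, "+")

# Forward pass keeping intermediates for backprop. S: wall cloud (M x 3) or
# NULL in single-channel mode; Q: query coordinates (N x 3).
net_forward <- function(model, S, Q) {
  cfg <- model$config
  w <- model$weights
  trunk_q <- if (cfg$share_weights || cfg$single_channel) {
    list(l1 = w$trunk1, l2 = w$trunk2)
  } else {
    list(l1 = w$trunk1q, l2 = w$trunk2q)
  }
  A1q <- relu(affine(Q, trunk_q$l1))
  A2q <- relu(affine(A1q, trunk_q$l2))
  if (cfg$single_channel) {
    A1s <- A1q; A2s <- A2q; Sin <- Q
  } else {
    Sin <- S
    A1s <- relu(affine(S, w$trunk1))
    A2s <- relu(affine(A1s, w$trunk2))
  }
  H <- relu(affine(A2s, w$fc3)) # M x fc3
  imax <- max.col(t(H), ties.method = "first") # per-feature argmax point
  g <- H[cbind(imax, seq_len(ncol(H)))] # pooled global feature
  L <- relu(affine(A2q, w$fc4)) # N x fc4
  Z <- cbind(matrix(g, nrow(Q), length(g), byrow = TRUE), L)
  A5 <- relu(affine(Z, w$fc5))
  out <- affine(A5, w$fc6)
  list(out = out, A5 = A5, Z = Z, L = L, H = H, imax = imax, g = g,
       A1q = A1q, A2q = A2q, A1s = A1s, A2s = A2s, Sin = Sin, Q = Q)
}

# Gradients of mean-absolute-error loss wrt every weight tensor.
net_backward <- function(model, fwd, targets) {
  cfg <- model$config
  w <- model$weights
  N <- nrow(fwd$Q)
  err <- fwd$out - targets
  dOut <- sign(err) / length(err)

  gr <- list()
  gr$fc6 <- list(W = crossprod(fwd$A5, dOut), b = colSums(dOut))
  dA5 <- tcrossprod(dOut, w$fc6$W)
  dZ5 <- dA5 * (fwd$A5 > 0)
  gr$fc5 <- list(W = crossprod(fwd$Z, dZ5), b = colSums(dZ5))
  dZ <- tcrossprod(dZ5, w$fc5$W)
  k3 <- cfg$fc3_width
  dG <- colSums(dZ[, seq_len(k3), drop = FALSE]) # tiled -> pooled feature
  dL <- dZ[, (k3 + 1):ncol(dZ), drop = FALSE]

  # Global path: route pooled gradient to the argmax points.
  dH <- matrix(0, nrow(fwd$H), ncol(fwd$H))
  dH[cbind(fwd$imax, seq_len(ncol(fwd$H)))] <- dG
  dZ3 <- dH * (fwd$H > 0)
  gr$fc3 <- list(W = crossprod(fwd$A2s, dZ3), b = colSums(dZ3))
  dA2s <- tcrossprod(dZ3, w$fc3$W)

  # Local path.
  dZ4 <- dL * (fwd$L > 0)
  gr$fc4 <- list(W = crossprod(fwd$A2q, dZ4), b = colSums(dZ4))
  dA2q <- tcrossprod(dZ4, w$fc4$W)

  trunk_grad <- function(dA2, A2, A1, X, l2) {
    dZ2 <- dA2 * (A2 > 0)
    gW2 <- crossprod(A1, dZ2)
    dA1 <- tcrossprod(dZ2, l2$W)
    dZ1 <- dA1 * (A1 > 0)
    list(l1 = list(W = crossprod(X, dZ1), b = colSums(dZ1)),
         l2 = list(W = gW2, b = colSums(dZ2)))
  }

  if (cfg$single_channel) {
    tg <- trunk_grad(dA2s + dA2q, fwd$A2q, fwd$A1q, fwd$Q, w$trunk2)
    gr$trunk1 <- tg$l1; gr$trunk2 <- tg$l2
  } else if (cfg$share_weights) {
    tgs <- trunk_grad(dA2s, fwd$A2s, fwd$A1s, fwd$Sin, w$trunk2)
    tgq <- trunk_grad(dA2q, fwd$A2q, fwd$A1q, fwd$Q, w$trunk2)
    gr$trunk1 <- list(W = tgs$l1$W + tgq$l1$W, b = tgs$l1$b + tgq$l1$b)
    gr$trunk2 <- list(W = tgs$l2$W + tgq$l2$W, b = tgs$l2$b + tgq$l2$b)
  } else {
    tgs <- trunk_grad(dA2s, fwd$A2s, fwd$A1s, fwd$Sin, w$trunk2)
    tgq <- trunk_grad(dA2q, fwd$A2q, fwd$A1q, fwd$Q, w$trunk2q)
    gr$trunk1 <- tgs$l1; gr$trunk2 <- tgs$l2
    gr$trunk1q <- tgq$l1; gr$trunk2q <- tgq$l2
  }
  list(grads = gr, loss = mean(abs(err)))
}

adam_init <- function(weights) {
  lapply(weights, function(l) {
    list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0)
  })
}

adam_step <- function(model, grads) {
  cfg <- model$config
  if (is.null(model$adam)) model$adam <- adam_init(model$weights)
  model$step <- model$step + 1L
  t <- model$step
  b1 <- cfg$beta1; b2 <- cfg$beta2
  corr1 <- 1 - b1^t
  corr2 <- 1 - b2^t
  for (nm in names(grads)) {
    st <- model$adam[[nm]]
    gW <- grads[[nm]]$W; gb <- grads[[nm]]$b
    st$mW <- b1 * st$mW + (1 - b1) * gW
    st$vW <- b2 * st$vW + (1 - b2) * gW^2
    st$mb <- b1 * st$mb + (1 - b1) * gb
    st$vb <- b2 * st$vb + (1 - b2) * gb^2
    model$weights[[nm]]$W <- model$weights[[nm]]$W -
      cfg$learning_rate * (st$mW / corr1) / (sqrt(st$vW / corr2) + cfg$adam_eps)
    model$weights[[nm]]$b <- model$weights[[nm]]$b -
      cfg$learning_rate * (st$mb / corr1) / (sqrt(st$vb / corr2) + cfg$adam_eps)
    model$adam[[nm]] <- st
  }
  model
}

sample_matrices <- function(sample) {
  list(
    S = as_coord_matrix(sample$surface, "surface cloud"),
    Q = as_coord_matrix(sample$query, "query cloud"),
    T = cbind(sample$query$tx, sample$query$ty, sample$query$tz)
  )
}

#' Predict hemodynamic fields at query coordinates
#'
#' Only spatial coordinates go in: the wall cloud fixes the pooled global
#' feature, and each query point's prediction depends on its own coordinate
#' plus that global feature only — so wall-point order is irrelevant and
#' query points do not influence one another.
#'
#' @param model A `hemo_net` (trained or untrained).
#' @param surface Wall cloud (data frame with x, y, z or M x 3 matrix).
#' @param query Query coordinates (data frame or N x 3 matrix).
#' @return Tibble with columns `px`, `py`, `pz`.
#' @export
net_predict <- function(model, surface, query) {
  stopifnot(inherits(model, "hemo_net"))
  Q <- as_coord_matrix(query, "query cloud")
  if (nrow(Q) == 0) abort("empty query cloud")
  S <- NULL
  if (!model$config$single_channel) {
    S <- as_coord_matrix(surface, "surface cloud")
    if (nrow(S) == 0) abort("empty surface cloud")
  }
  out <- net_forward(model, S, Q)$out
  tibble(px = out[, 1], py = out[, 2], pz = out[, 3])
}

#' @export
predict.hemo_net <- function(object, surface, query, ...) {
  net_predict(object, surface, query)
}

#' Train the network on a corpus
#'
#' One model (its full wall + query cloud) per optimization step, models
#' shuffled every epoch under the run seed, mean-absolute-error loss over all
#' points and components, Adam updates. The per-epoch loss history records
#' the mean step loss (computed before each update).
#'
#' @param model A `hemo_net` from [net_build()].
#' @param corpus A `corpus_split`; training uses `corpus$train`.
#' @param epochs Number of epochs (defaults to the model's config).
#' @param quiet Suppress per-epoch messages.
#' @return A `hemo_fit`: the trained model, `loss_history`, config, seed and
#'   wall time.
#' @export
net_train <- function(model, corpus, epochs = NULL, quiet = TRUE) {
  stopifnot(inherits(model, "hemo_net"), inherits(corpus, "corpus_split"))
  samples <- corpus$train
  if (length(samples) == 0) abort("empty training split")
  kinds <- unique(vapply(samples, `[[`, "", "field_kind"))
  ops <- unique(vapply(samples, `[[`, "", "op_state"))
  if (length(kinds) != 1 || length(ops) != 1) {
    abort("training corpus must have a single field_kind and op_state")
  }
  cfg <- model$config
  if (is.null(epochs)) epochs <- cfg$epochs
  mats <- lapply(samples, sample_matrices)
  pps <- cfg$points_per_step
  if (is.finite(pps)) {
    steps <- list()
    for (i in seq_along(mats)) {
      m <- mats[[i]]
      n <- nrow(m$Q)
      if (n <= pps) {
        steps[[length(steps) + 1]] <- m
        next
      }
      perm <- local_seed(derive_seed(cfg$seed, 1000L + i), sample.int(n))
      for (ch in split(perm, ceiling(seq_along(perm) / pps))) {
        steps[[length(steps) + 1]] <- list(
          S = m$S, Q = m$Q[ch, , drop = FALSE], T = m$T[ch, , drop = FALSE]
        )
      }
    }
    mats <- steps
  }
  t0 <- proc.time()[["elapsed"]]
  loss_history <- numeric(0)
  if (epochs > 0) {
    orders <- local_seed(derive_seed(cfg$seed, 7L), {
      m <- matrix(0L, epochs, length(mats))
      for (ep in seq_len(epochs)) m[ep, ] <- sample.int(length(mats))
      m
    })
    res <- .cf_train_cpp(model$weights, mats, cfg, orders)
    model$weights <- lapply(res$weights, function(l) {
      list(W = l$W, b = as.numeric(l$b))
    })[names(model$weights)]
    model$step <- as.integer(res$step)
    loss_history <- as.numeric(res$loss_history)
    if (!quiet) {
      for (ep in seq_len(epochs)) {
        message(sprintf("epoch %3d  mae %.6g", ep, loss_history[ep]))
      }
    }
  }
  if (any(!is.finite(loss_history))) abort("training diverged: non-finite loss")
  structure(
    list(model = model, loss_history = loss_history, config = cfg,
         seed = cfg$seed, field_kind = kinds, op_state = ops,
         wall_time = proc.time()[["elapsed"]] - t0),
    class = "hemo_fit"
  )
}

#' @export
print.hemo_fit <- function(x, ...) {
  cat(sprintf(
    "<hemo_fit> %s %s: %d epochs, train MAE %.4g -> %.4g (%.1f s)\n",
    x$op_state, x$field_kind, length(x$loss_history),
    if (length(x$loss_history)) x$loss_history[1] else NA,
    if (length(x$loss_history)) tail(x$loss_history, 1) else NA,
    x$wall_time
  ))
  invisible(x)
}

#' @export
predict.hemo_fit <- function(object, surface, query, ...) {
  net_predict(object$model, surface, query)
}

#' @rdname tidy.hemo_fit
#' @export
glance.hemo_fit <- function(x, ...) {
  tibble(
    epochs = length(x$loss_history),
    initial_mae = if (length(x$loss_history)) x$loss_history[1] else NA_real_,
    final_mae = if (length(x$loss_history)) tail(x$loss_history, 1) else NA_real_,
    n_parameters = n_parameters(x$model),
    field_kind = x$field_kind, op_state = x$op_state,
    wall_time = x$wall_time, seed = x$seed
  )
}

#' Tidiers for fitted networks
#'
#' `tidy()` returns the per-epoch loss history; `glance()` a one-row summary.
#'
#' @param x A `hemo_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.hemo_fit <- function(x, ...) {
  tibble(epoch = seq_along(x$loss_history), mae = x$loss_history)
}

#' @export
autoplot.hemo_fit <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$epoch, y = .data$mae)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "training MAE",
                  title = sprintf("%s %s field", object$op_state, object$field_kind)) +
    ggplot2::theme_minimal()
}

WEIGHTS_FORMAT <- "coroflow-weights"
WEIGHTS_VERSION <- 1L

#' Persist / restore network weights
#'
#' Weights travel in a versioned container (R serialization) embedding the
#' architecture config; loading validates the format tag, version, and every
#' tensor shape against the embedded config, and maps unreadable files to a
#' corruption error.
#'
#' @param model A `hemo_net` or `hemo_fit`.
#' @param path File path.
#' @return `load_weights` returns a `hemo_net`.
#' @export
save_weights <- function(model, path) {
  meta <- NULL
  if (inherits(model, "hemo_fit")) {
    meta <- list(field_kind = model$field_kind, op_state = model$op_state)
    model <- model$model
  }
  stopifnot(inherits(model, "hemo_net"))
  saveRDS(list(format = WEIGHTS_FORMAT, version = WEIGHTS_VERSION,
               config = model$config, weights = model$weights, meta = meta),
          path)
  invisible(path)
}

#' @rdname save_weights
#' @export
load_weights <- function(path) {
  obj <- tryCatch(
    readRDS(path),
    error = function(e) abort(sprintf("corrupt weights file '%s': %s",
                                      path, conditionMessage(e)))
  )
  if (!is.list(obj) || !identical(obj$format, WEIGHTS_FORMAT)) {
    abort(sprintf("'%s' is not a weights file", path))
  }
  if (!identical(obj$version, WEIGHTS_VERSION)) {
    abort(sprintf("unsupported weights version %s", obj$version))
  }
  cfg <- structure(obj$config, class = "net_config")
  plan <- layer_plan(cfg)
  if (!setequal(names(plan), names(obj$weights))) {
    abort("weights file layer set does not match its config")
  }
  for (nm in names(plan)) {
    d <- dim(obj$weights[[nm]]$W)
    if (!identical(as.integer(d), as.integer(plan[[nm]]))) {
      abort(sprintf("shape mismatch for layer '%s': stored %s, config wants %s",
                    nm, paste(d, collapse = "x"),
                    paste(plan[[nm]], collapse = "x")))
    }
  }
  structure(list(config = cfg, weights = obj$weights, adam = NULL, step = 0L),
            meta = obj$meta, class = "hemo_net")
}
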