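# Corpus assembly: four independent corpora (pre/post-op x velocity/pressure),
# each split into train/test with base-model-disjoint splits.

#' Replicate scalar pressures into three identical components
#'
#' Pressure samples share the velocity target layout: each scalar becomes a
#' row `(p, p, p)`.
#'
#' @param p Finite numeric vector of pressures.
#' @return N x 3 matrix.
#' @export
pressure_to_components <- function(p) {
  if (!is.numeric(p) || !all(is.finite(p))) abort("pressures must be finite numeric")
  matrix(rep(p, 3), ncol = 3)
}

#' Build a train/test corpus of hemodynamic point-cloud samples
#'
#' The desk-scale analog of a base-models-times-expansions corpus: base trees
#' are built by cycling the built-in templates, each is expanded into
#' `expansions_per_base` randomized variants, each variant is solved and
#' sampled into a paired surface/query cloud. Train and test draw from
#' disjoint base models (split hygiene), so test geometries descend from bases
#' the training set never saw. Fully reproducible from `master_seed`.
#'
#' @param n_base_train,n_base_test Base models per split.
#' @param expansions_per_base Variants per base.
#' @param op_state `"preoperative"` or `"postoperative"` (adds the graft).
#' @param field_kind `"velocity"` or `"pressure"`.
#' @param ranges A [geometry_ranges()] object.
#' @param bc,fluid Solver conditions.
#' @param n_query,surface_density Cloud sizes per model.
#' @param master_seed Integer master seed.
#' @return A `corpus_split` with `train` and `test` lists of `hemo_sample`s.
#' @export
build_corpus <- function(n_base_train = 10L, n_base_test = 1L,
                         expansions_per_base = 9L,
                         op_state = c("preoperative", "postoperative"),
                         field_kind = c("velocity", "pressure"),
                         ranges = geometry_ranges(),
                         bc = boundary_conditions(), fluid = fluid_properties(),
                         n_query = 2048L, surface_density = 0.1,
                         master_seed = 1L) {
  op_state <- match.arg(op_state)
  field_kind <- match.arg(field_kind)
  stopifnot(n_base_train >= 1, n_base_test >= 1, expansions_per_base >= 1)
  build_split <- function(n_base, split, seed_offset) {
    out <- list()
    for (b in seq_len(n_base)) {
      base_seed <- derive_seed(master_seed, seed_offset + b)
      base_id <- sprintf("%s_base%03d", split, b)
      base <- make_base_tree((b - 1L) %% 3L, scale_seed = base_seed)
      variants <- expand_model(base, ranges, expansions_per_base,
                               seed = derive_seed(base_seed, 1))
      for (v in seq_along(variants)) {
        tree <- variants[[v]]
        if (op_state == "postoperative") tree <- add_graft(tree)
        out[[length(out) + 1]] <- make_sample(
          tree, bc, fluid, n_query, surface_density, field_kind,
          seed = derive_seed(base_seed, 1 + v),
          model_id = sprintf("%s_v%02d", base_id, v),
          base_model_id = base_id
        )
      }
    }
    out
  }
  corpus <- structure(
    list(
      train = build_split(n_base_train, "train", 0L),
      test = build_split(n_base_test, "test", 100000L),
      op_state = op_state, field_kind = field_kind, master_seed = master_seed
    ),
    class = "corpus_split"
  )
  validate_corpus_split(corpus)
  corpus
}

validate_corpus_split <- function(corpus) {
  bases <- function(split) unique(vapply(split, `[[`, "", "base_model_id"))
  overlap <- intersect(bases(corpus$train), bases(corpus$test))
  if (length(overlap)) {
    abort(paste0("split hygiene violated: base models shared across splits: ",
                 paste(overlap, collapse = ", ")))
  }
  kinds <- unique(vapply(c(corpus$train, corpus$test), `[[`, "", "field_kind"))
  if (length(kinds) != 1) abort("corpus mixes field kinds")
  invisible(corpus)
}

#' @export
print.corpus_split <- function(x, ...) {
  cat(sprintf(
    "<corpus_split> %s %s: %d train / %d test samples (seed %d)\n",
    x$op_state, x$field_kind, length(x$train), length(x$test), x$master_seed
  ))
  invisible(x)
}
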