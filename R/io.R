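# On-disk interchange: CSV point tables (canonical), YAML tree/manifest
# documents, ASCII STL and PLY convenience exports.

SURFACE_COLS <- c("x", "y", "z")
QUERY_REQ_COLS <- c("x", "y", "z", "tx", "ty", "tz", "region")
QUERY_OPT_COLS <- c("segment_id", "axial_fraction", "radial_fraction")

tree_to_list <- function(tree) {
  segs <- tree$segments
  list(
    op_state = tree$op_state,
    inlet_node = tree$inlet_node,
    outlet_nodes = as.list(tree$outlet_nodes),
    nodes = lapply(seq_len(nrow(tree$nodes)), function(i) {
      list(id = tree$nodes$id[i],
           coord = c(tree$nodes$x[i], tree$nodes$y[i], tree$nodes$z[i]))
    }),
    segments = lapply(seq_len(nrow(segs)), function(i) {
      st <- segs$stenoses[[i]]
      list(
        id = segs$id[i], start_node = segs$start_node[i],
        end_node = segs$end_node[i], length = segs$length[i],
        radius = segs$radius[i], role = segs$role[i],
        stenoses = lapply(seq_len(nrow(st)), function(k) {
          list(rate = st$rate[k], center = st$center[k], extent = st$extent[k])
        })
      )
    })
  )
}

tree_from_list <- function(doc) {
  x <- doc
  coords <- t(vapply(x$nodes, function(n) as.numeric(n$coord), numeric(3)))
  nodes <- tibble(
    id = vapply(x$nodes, `[[`, "", "id"),
    x = coords[, 1], y = coords[, 2], z = coords[, 3]
  )
  sten_col <- lapply(x$segments, function(s) {
    if (length(s$stenoses) == 0) return(empty_stenoses())
    tibble(
      rate = vapply(s$stenoses, `[[`, 0, "rate"),
      center = vapply(s$stenoses, `[[`, 0, "center"),
      extent = vapply(s$stenoses, `[[`, 0, "extent")
    )
  })
  segments <- tibble(
    id = vapply(x$segments, `[[`, "", "id"),
    start_node = vapply(x$segments, `[[`, "", "start_node"),
    end_node = vapply(x$segments, `[[`, "", "end_node"),
    length = vapply(x$segments, `[[`, 0, "length"),
    radius = vapply(x$segments, `[[`, 0, "radius"),
    role = vapply(x$segments, `[[`, "", "role"),
    stenoses = sten_col
  )
  new_vessel_tree(nodes, segments, x$inlet_node,
                  unlist(x$outlet_nodes), x$op_state)
}

#' Serialize / restore a vessel tree as a YAML document
#'
#' @param tree A `vessel_tree`.
#' @param path File path.
#' @return `read_vessel_tree` returns the restored tree.
#' @export
write_vessel_tree <- function(tree, path) {
  yaml::write_yaml(tree_to_list(tree), path, precision = 17)
  invisible(path)
}

#' @rdname write_vessel_tree
#' @export
read_vessel_tree <- function(path) {
  tree_from_list(yaml::read_yaml(path))
}

check_point_table <- function(df, kind, path) {
  req <- if (kind == "surface") SURFACE_COLS else QUERY_REQ_COLS
  allowed <- if (kind == "surface") SURFACE_COLS else c(QUERY_REQ_COLS, QUERY_OPT_COLS)
  missing <- setdiff(req, names(df))
  if (length(missing)) {
    abort(sprintf("%s: %s cloud is missing column(s): %s",
                  path, kind, paste(missing, collapse = ", ")))
  }
  extra <- setdiff(names(df), allowed)
  if (length(extra)) {
    abort(sprintf("%s: unexpected column(s) for a %s cloud: %s",
                  path, kind, paste(extra, collapse = ", ")))
  }
  num_cols <- setdiff(intersect(allowed, names(df)), c("region", "segment_id"))
  for (cc in num_cols) {
    vals <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(!is.finite(vals))
    if (length(bad)) {
      abort(sprintf("%s: non-numeric or missing value in column '%s' at line %d",
                    path, cc, bad[1] + 1L)) # +1 for the header row
    }
    df[[cc]] <- vals
  }
  df
}

read_point_csv <- function(path, kind) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = readr::col_guess()))
  pb <- readr::problems(df)
  if (nrow(pb) > 0) {
    abort(sprintf("%s: malformed value at line %d: %s",
                  path, pb$row[1] + 1L, pb$expected[1]))
  }
  check_point_table(as_tibble(df), kind, path)
}

sample_paths <- function(dir, model_id) {
  list(
    surface = file.path(dir, paste0(model_id, "_surface.csv")),
    query = file.path(dir, paste0(model_id, "_query.csv")),
    meta = file.path(dir, paste0(model_id, "_meta.yaml"))
  )
}

#' Write / read one hemodynamic sample
#'
#' The canonical interchange is plain CSV: the surface cloud as `x,y,z`, the
#' query cloud as `x,y,z,tx,ty,tz,region` plus the lumen parameterization
#' columns, with full-roundtrip numeric precision. Metadata and the vessel
#' tree travel in a YAML sidecar, so a sample re-read from disk supports the
#' full clinical-index pipeline.
#'
#' @param sample A `hemo_sample`.
#' @param dir Directory to write into (created if needed).
#' @param model_id Model identifier to read.
#' @return `read_sample` returns the restored `hemo_sample` (without the
#'   cached network solution, which is recomputed on demand).
#' @export
write_sample <- function(sample, dir) {
  stopifnot(inherits(sample, "hemo_sample"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- sample_paths(dir, sample$model_id)
  readr::write_csv(sample$surface[SURFACE_COLS], p$surface, progress = FALSE)
  readr::write_csv(sample$query[c(QUERY_REQ_COLS, QUERY_OPT_COLS)], p$query,
                   progress = FALSE)
  yaml::write_yaml(
    list(model_id = sample$model_id, base_model_id = sample$base_model_id,
         op_state = sample$op_state, field_kind = sample$field_kind,
         seed = sample$seed, tree = tree_to_list(sample$tree)),
    p$meta, precision = 17
  )
  invisible(p)
}

#' @rdname write_sample
#' @export
read_sample <- function(dir, model_id) {
  p <- sample_paths(dir, model_id)
  if (!file.exists(p$meta)) abort(sprintf("no metadata for model '%s' in %s", model_id, dir))
  meta <- yaml::read_yaml(p$meta)
  surface <- read_point_csv(p$surface, "surface")
  query <- read_point_csv(p$query, "query")
  structure(
    list(surface = surface, query = query, tree = tree_from_list(meta$tree),
         solution = NULL, op_state = meta$op_state, field_kind = meta$field_kind,
         model_id = meta$model_id, base_model_id = meta$base_model_id,
         seed = meta$seed),
    class = "hemo_sample"
  )
}

#' Persist / restore a full corpus with its manifest
#'
#' Writes every sample plus a `manifest.yaml` recording split membership,
#' seeds, corpus configuration and a content hash of the configuration.
#' Reading validates the manifest and re-enforces split hygiene: a manifest
#' whose train and test splits share a base model is rejected.
#'
#' @param corpus A `corpus_split`.
#' @param dir Target directory.
#' @return `read_corpus` returns the restored `corpus_split`.
#' @export
write_corpus <- function(corpus, dir) {
  stopifnot(inherits(corpus, "corpus_split"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entry <- function(s, split) {
    list(model_id = s$model_id, base_model_id = s$base_model_id, split = split)
  }
  manifest <- list(
    op_state = corpus$op_state, field_kind = corpus$field_kind,
    master_seed = corpus$master_seed,
    config_hash = rlang::hash(list(corpus$op_state, corpus$field_kind,
                                   corpus$master_seed,
                                   length(corpus$train), length(corpus$test))),
    samples = c(lapply(corpus$train, entry, split = "train"),
                lapply(corpus$test, entry, split = "test"))
  )
  for (s in c(corpus$train, corpus$test)) write_sample(s, dir)
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(dir) {
  mf_path <- file.path(dir, "manifest.yaml")
  if (!file.exists(mf_path)) abort(sprintf("no manifest.yaml in %s", dir))
  mf <- yaml::read_yaml(mf_path)
  train <- list(); test <- list()
  for (e in mf$samples) {
    s <- read_sample(dir, e$model_id)
    if (e$split == "train") train[[length(train) + 1]] <- s
    else test[[length(test) + 1]] <- s
  }
  corpus <- structure(
    list(train = train, test = test, op_state = mf$op_state,
         field_kind = mf$field_kind, master_seed = mf$master_seed),
    class = "corpus_split"
  )
  validate_corpus_split(corpus)
  corpus
}

#' Export the triangulated vessel wall as ASCII STL
#'
#' Each segment's wall is meshed as axial rings of `n_circ` vertices following
#' the stenosed radius profile; for visualization only.
#'
#' @param tree A `vessel_tree`.
#' @param path Output file.
#' @param n_axial,n_circ Mesh resolution per segment.
#' @export
write_stl <- function(tree, path, n_axial = 48L, n_circ = 20L) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid vessel_tree", con)
  for (i in seq_len(nrow(tree$segments))) {
    seg <- tree$segments[i, ]
    fr <- segment_frame(tree, seg)
    ax <- seq(0, fr$length, length.out = n_axial)
    r <- radius_profile(seg, ax)
    th <- seq(0, 2 * pi, length.out = n_circ + 1)[-(n_circ + 1)]
    ring <- function(j) {
      ctr <- fr$start + ax[j] * fr$dir
      t(vapply(th, function(a) {
        ctr + r[j] * (cos(a) * fr$e1 + sin(a) * fr$e2)
      }, numeric(3)))
    }
    prev <- ring(1)
    for (j in 2:n_axial) {
      cur <- ring(j)
      for (k in seq_len(n_circ)) {
        k2 <- k %% n_circ + 1
        tri <- function(a, b, c_) {
          nrm <- c(
            (b - a)[2] * (c_ - a)[3] - (b - a)[3] * (c_ - a)[2],
            (b - a)[3] * (c_ - a)[1] - (b - a)[1] * (c_ - a)[3],
            (b - a)[1] * (c_ - a)[2] - (b - a)[2] * (c_ - a)[1]
          )
          nn <- vnorm(nrm)
          if (nn > 0) nrm <- nrm / nn
          c(sprintf("facet normal %.9e %.9e %.9e", nrm[1], nrm[2], nrm[3]),
            "  outer loop",
            sprintf("    vertex %.9e %.9e %.9e", a[1], a[2], a[3]),
            sprintf("    vertex %.9e %.9e %.9e", b[1], b[2], b[3]),
            sprintf("    vertex %.9e %.9e %.9e", c_[1], c_[2], c_[3]),
            "  endloop", "endfacet")
        }
        writeLines(tri(prev[k, ], prev[k2, ], cur[k, ]), con)
        writeLines(tri(cur[k, ], prev[k2, ], cur[k2, ]), con)
      }
      prev <- cur
    }
  }
  writeLines("endsolid vessel_tree", con)
  invisible(path)
}

#' Export a point cloud as ASCII PLY (vertex-only)
#'
#' @param points Data frame with `x`, `y`, `z`.
#' @param path Output file.
#' @export
write_ply <- function(points, path) {
  m <- as_coord_matrix(points, "point cloud")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "ply", "format ascii 1.0",
    sprintf("element vertex %d", nrow(m)),
    "property float x", "property float y", "property float z",
    "end_header"
  ), con)
  writeLines(sprintf("%.9e %.9e %.9e", m[, 1], m[, 2], m[, 3]), con)
  invisible(path)
}
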