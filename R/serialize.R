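# Versioned JSON persistence for fitted ensembles. All splitters are plain
# numeric objects, so the archive is a faithful reconstruction: splitter
# weights, feature subsets, branch labels and leaf class distributions.

LANDMARK_ARCHIVE_VERSION <- "1.0"

ser_mat <- function(m) list(dim = dim(m), data = as.numeric(m))
unser_mat <- function(s) matrix(unlist(s$data), unlist(s$dim)[1], unlist(s$dim)[2])

ser_splitter <- function(sp) {
  if (is.null(sp)) return(NULL)
  base <- list(family = sp$family, kind = sp$kind,
               branch_labels = sp$branch_labels,
               feature_idx = sp$feature_idx,
               achieved_gain = sp$achieved_gain)
  if (sp$kind == "linear") {
    c(base, list(W = ser_mat(as.matrix(sp$W)), b = as.numeric(sp$b)))
  } else if (sp$kind == "oracle") {
    c(base, list(midpoint = as.numeric(sp$midpoint),
                 normal = as.numeric(sp$normal)))
  } else {
    c(base, list(
      layers_a = lapply(sp$layers_a, function(l) list(W = ser_mat(l$W), b = l$b)),
      layers_b = lapply(sp$layers_b, function(l) list(W = ser_mat(l$W), b = l$b)),
      out_layer = list(W = ser_mat(sp$out_layer$W), b = sp$out_layer$b),
      Omega = ser_mat(sp$Omega), beta = as.numeric(sp$beta),
      rff_dim = sp$rff_dim))
  }
}

unser_splitter <- function(s) {
  if (is.null(s)) return(NULL)
  out <- list(family = s$family, kind = s$kind,
              branch_labels = unlist(s$branch_labels),
              feature_idx = unlist(s$feature_idx),
              params = list(),
              achieved_gain = s$achieved_gain)
  if (s$kind == "linear") {
    out$W <- unser_mat(s$W)
    out$b <- unlist(s$b)
  } else if (s$kind == "oracle") {
    out$midpoint <- unlist(s$midpoint)
    out$normal <- unlist(s$normal)
  } else {
    out$layers_a <- lapply(s$layers_a, function(l)
      list(W = unser_mat(l$W), b = unlist(l$b)))
    out$layers_b <- lapply(s$layers_b, function(l)
      list(W = unser_mat(l$W), b = unlist(l$b)))
    out$out_layer <- list(W = unser_mat(s$out_layer$W),
                          b = unlist(s$out_layer$b))
    out$Omega <- unser_mat(s$Omega)
    out$beta <- unlist(s$beta)
    out$rff_dim <- s$rff_dim
  }
  class(out) <- "landmark_splitter"
  out
}

ser_node <- function(node) {
  list(id = node$id, depth = node$depth, n_train = node$n_train,
       class_distribution = as.list(node$class_distribution),
       majority_child = node$majority_child,
       splitter = ser_splitter(node$splitter),
       children = if (is.null(node$children)) NULL else
         lapply(node$children, ser_node))
}

unser_node <- function(s) {
  list(id = s$id, depth = s$depth, n_train = s$n_train,
       class_distribution = unlist(s$class_distribution),
       majority_child = s$majority_child,
       splitter = unser_splitter(s$splitter),
       children = if (is.null(s$children)) NULL else
         lapply(s$children, unser_node))
}

#' Save a fitted ensemble as a versioned JSON archive
#'
#' @param ensemble a `landmark_ensemble`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
landmark_save <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "landmark_ensemble"))
  ctl <- unclass(ensemble$control)
  if (!is.finite(ctl$max_depth)) ctl$max_depth <- NULL  # JSON has no Inf
  doc <- list(
    format = "landmark_ensemble",
    version = LANDMARK_ARCHIVE_VERSION,
    classes = ensemble$classes,
    n_features = ensemble$n_features,
    feature_ids = ensemble$feature_ids,
    control = ctl,
    seed = ensemble$seed,
    trees = lapply(ensemble$trees, function(tr) {
      list(classes = tr$classes, n_features = tr$n_features,
           root = ser_node(tr$root))
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Load an ensemble from a JSON archive
#'
#' @param path file written by [landmark_save()].
#' @return a `landmark_ensemble`.
#' @export
landmark_load <- function(path) {
  doc <- jsonlite::read_json(path)
  if (!identical(doc$format, "landmark_ensemble")) {
    stop("not a landmark ensemble archive")
  }
  ctl <- doc$control
  ctl$max_depth <- if (is.null(ctl$max_depth)) Inf else as.numeric(ctl$max_depth)
  ctl <- structure(lapply(ctl, function(v) if (is.list(v)) unlist(v) else v),
                   class = "landmark_control")
  trees <- lapply(doc$trees, function(tr) {
    structure(list(root = unser_node(tr$root),
                   classes = unlist(tr$classes),
                   n_features = tr$n_features,
                   control = ctl),
              class = "landmark_tree")
  })
  structure(
    list(trees = trees, classes = unlist(doc$classes),
         n_features = doc$n_features,
         feature_ids = if (is.null(doc$feature_ids)) NULL else unlist(doc$feature_ids),
         control = ctl, oob = NULL, seed = doc$seed),
    class = "landmark_ensemble"
  )
}
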