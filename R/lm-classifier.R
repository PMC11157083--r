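# Two-class random-forest pixel classifier: 100 trees with 2 decisions per
# tree (depth 2), trained on sparse per-voxel annotations (typically 100
# voxels per class per image) over the convolutional feature bank.

#' Sparse voxel annotations
#'
#' @param image Image identifier (recycled).
#' @param z,y,x 1-based voxel coordinates.
#' @param class Character `"signal"` or `"background"`.
#' @return Data.frame of class `sparse_annotation`.
#' @export
sparse_annotation <- function(image, z, y, x, class) {
  class <- match.arg(class, c("signal", "background"), several.ok = TRUE)
  stopifnot(length(z) == length(y), length(y) == length(x))
  structure(data.frame(image = rep_len(image, length(z)),
                       z = as.integer(z), y = as.integer(y),
                       x = as.integer(x),
                       class = rep_len(class, length(z)),
                       stringsAsFactors = FALSE),
            class = c("sparse_annotation", "data.frame"))
}

# JSON nulls may come back as list elements; flatten to NA-bearing vectors
unlist_na <- function(x) {
  if (is.list(x)) x <- vapply(x, function(e)
    if (is.null(e)) NA_real_ else as.numeric(e), numeric(1))
  x
}

# -- internal depth-limited CART with gini splits ---------------------------

best_split <- function(X, y, feat_idx) {
  n <- length(y)
  best <- list(gain = 0, feature = NA_integer_, threshold = NA_real_)
  n1 <- sum(y); gini_parent <- 1 - (n1 / n)^2 - ((n - n1) / n)^2
  for (f in feat_idx) {
    v <- X[, f]
    o <- order(v)
    vs <- v[o]; ys <- y[o]
    distinct <- which(diff(vs) > 0)
    if (length(distinct) == 0L) next
    cum1 <- cumsum(ys)
    nl <- distinct
    l1 <- cum1[distinct]
    r1 <- n1 - l1
    nr <- n - nl
    gl <- 1 - (l1 / nl)^2 - ((nl - l1) / nl)^2
    gr <- 1 - (r1 / nr)^2 - ((nr - r1) / nr)^2
    gain <- gini_parent - (nl * gl + nr * gr) / n
    i <- which.max(gain)
    if (gain[i] > best$gain + 1e-12) {
      best <- list(gain = gain[i], feature = f,
                   threshold = (vs[distinct[i]] + vs[distinct[i] + 1L]) / 2)
    }
  }
  best
}

# grows a tree of at most `depth` decisions; returns data.frame of nodes:
# id, feature (NA at leaf), threshold, left, right, pred (1 = signal)
fit_tree <- function(X, y, mtry, depth) {
  nodes <- list()
  new_node <- function(idx, d) {
    id <- length(nodes) + 1L
    nodes[[id]] <<- list(id = id, feature = NA_integer_,
                         threshold = NA_real_, left = NA_integer_,
                         right = NA_integer_,
                         # majority vote; exact tie -> background
                         pred = as.integer(sum(y[idx]) * 2L > length(idx)))
    if (d < depth && length(idx) >= 2L && length(unique(y[idx])) > 1L) {
      feat_idx <- sample.int(ncol(X), mtry)
      sp <- best_split(X[idx, , drop = FALSE], y[idx], feat_idx)
      if (!is.na(sp$feature)) {
        go_left <- X[idx, sp$feature] <= sp$threshold
        lid <- new_node(idx[go_left], d + 1L)
        rid <- new_node(idx[!go_left], d + 1L)
        node <- nodes[[id]]
        node$feature <- sp$feature
        node$threshold <- sp$threshold
        node$left <- lid
        node$right <- rid
        nodes[[id]] <<- node
      }
    }
    id
  }
  new_node(seq_along(y), 0L)
  do.call(rbind, lapply(nodes, as.data.frame))
}

predict_tree <- function(tree, X) {
  node <- rep(1L, nrow(X))
  repeat {
    f <- tree$feature[node]
    inner <- !is.na(f)
    if (!any(inner)) break
    idx <- which(inner)
    go_left <- X[cbind(idx, f[idx])] <= tree$threshold[node[idx]]
    node[idx] <- ifelse(go_left, tree$left[node[idx]], tree$right[node[idx]])
  }
  tree$pred[node]
}

#' Train the random-forest pixel classifier
#'
#' Computes the feature bank on each (preprocessed) training stack, gathers
#' the feature vectors of the annotated voxels and fits a forest of
#' `n_trees` bootstrap trees with at most `max_depth` decisions each
#' (gini splits, sqrt-mtry feature subsampling). Duplicate annotation
#' coordinates are deduplicated with a warning. Reproducible given `seed`.
#'
#' @param stacks Named list of [image_stack()] objects (names are image ids).
#' @param annotations A [sparse_annotation()] data.frame whose `image` column
#'   matches `names(stacks)`.
#' @param bank A [feature_bank()].
#' @param n_trees,max_depth Forest size (default 100) and decisions per tree
#'   (default 2).
#' @param seed Integer RNG seed.
#' @return List of class `pos_classifier`.
#' @export
train_pos_classifier <- function(stacks, annotations, bank = feature_bank(),
                                 n_trees = 100L, max_depth = 2L, seed = 1L) {
  stopifnot(is.list(stacks), length(stacks) >= 1L)
  if (is.null(names(stacks))) names(stacks) <- paste0("img", seq_along(stacks))
  ann <- as.data.frame(annotations)
  if (!all(c("image", "z", "y", "x", "class") %in% names(ann)))
    stop("annotations need columns image, z, y, x, class")
  dup <- duplicated(ann[c("image", "z", "y", "x")])
  if (any(dup)) {
    warning(sum(dup), " duplicate annotation coordinate(s) removed")
    ann <- ann[!dup, , drop = FALSE]
  }
  if (length(unique(ann$class)) < 2L)
    stop("annotations must contain both classes")
  Xs <- list(); ys <- list()
  for (id in unique(ann$image)) {
    if (!id %in% names(stacks)) stop("no stack named '", id, "'")
    st <- as_image_stack(stacks[[id]])
    d <- dim(st$voxels)
    a <- ann[ann$image == id, , drop = FALSE]
    if (any(a$z < 1 | a$z > d[1] | a$y < 1 | a$y > d[2] |
            a$x < 1 | a$x > d[3]))
      stop("annotation out of bounds for image '", id, "'")
    feats <- compute_features(st, bank)
    lin <- a$z + (a$y - 1L) * d[1] + (a$x - 1L) * d[1] * d[2]
    Xs[[id]] <- feats[lin, , drop = FALSE]
    ys[[id]] <- as.integer(a$class == "signal")
  }
  X <- do.call(rbind, Xs)
  y <- unlist(ys, use.names = FALSE)
  mtry <- max(1L, floor(sqrt(ncol(X))))
  set.seed(seed)
  trees <- vector("list", n_trees)
  for (t in seq_len(n_trees)) {
    boot <- sample.int(length(y), replace = TRUE)
    trees[[t]] <- fit_tree(X[boot, , drop = FALSE], y[boot], mtry,
                           as.integer(max_depth))
  }
  structure(list(trees = trees, n_trees = as.integer(n_trees),
                 max_depth = as.integer(max_depth), bank = bank,
                 feature_names = colnames(X), seed = as.integer(seed),
                 image_ids = unique(ann$image), format_version = 1L),
            class = "pos_classifier")
}

#' Predict a binary POS mask for a stack
#'
#' Applies the model's feature bank to the stack (which must have been
#' preprocessed identically to training) and classifies every voxel by
#' majority vote over the trees; an exact tie counts as background.
#'
#' @param model A `pos_classifier`.
#' @param stack An [image_stack()] or 3D array.
#' @return Logical 3D array, `TRUE` = signal.
#' @export
predict_pos <- function(model, stack) {
  stopifnot(inherits(model, "pos_classifier"))
  stack <- as_image_stack(stack)
  X <- compute_features(stack, model$bank)
  if (!identical(colnames(X), model$feature_names))
    stop("feature bank mismatch between model and request")
  votes <- numeric(nrow(X))
  for (tree in model$trees) votes <- votes + predict_tree(tree, X)
  array(votes * 2 > model$n_trees, dim(stack$voxels))
}

#' @export
print.pos_classifier <- function(x, ...) {
  cat(sprintf("<pos_classifier> %d trees, depth %d, %d features, seed %d\n",
              x$n_trees, x$max_depth, length(x$feature_names), x$seed))
  invisible(x)
}

#' Serialize / restore a classifier as portable JSON
#'
#' The text format stores trees, feature-bank spec, seed and a format
#' version; reading it back reproduces the model losslessly (all thresholds
#' kept at full precision).
#'
#' @param model A `pos_classifier`.
#' @param path File path (conventionally `*.posquant.json`).
#' @return `read_pos_classifier` returns the `pos_classifier`.
#' @export
write_pos_classifier <- function(model, path) {
  stopifnot(inherits(model, "pos_classifier"))
  obj <- list(format = "posquant-forest", format_version = model$format_version,
              n_trees = model$n_trees, max_depth = model$max_depth,
              seed = model$seed, image_ids = model$image_ids,
              feature_names = model$feature_names,
              bank = list(filters = model$bank$filter,
                          sigmas = model$bank$sigma),
              trees = lapply(model$trees, function(tr)
                lapply(tr, function(col) unname(col))))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                              na = "null"), path)
  invisible(path)
}

#' @rdname write_pos_classifier
#' @export
read_pos_classifier <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  if (!identical(obj$format, "posquant-forest"))
    stop("not a posquant forest file")
  trees <- lapply(obj$trees, function(tr) {
    out <- data.frame(id = as.integer(unlist_na(tr$id)),
                      feature = as.integer(unlist_na(tr$feature)),
                      threshold = as.numeric(unlist_na(tr$threshold)),
                      left = as.integer(unlist_na(tr$left)),
                      right = as.integer(unlist_na(tr$right)),
                      pred = as.integer(unlist_na(tr$pred)))
    out
  })
  structure(list(trees = trees, n_trees = as.integer(obj$n_trees),
                 max_depth = as.integer(obj$max_depth),
                 bank = feature_bank(obj$bank$filters, obj$bank$sigmas),
                 feature_names = obj$feature_names,
                 seed = as.integer(obj$seed), image_ids = obj$image_ids,
                 format_version = as.integer(obj$format_version)),
            class = "pos_classifier")
}
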