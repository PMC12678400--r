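# From-scratch binary CART with the Gini criterion.
#
# This is the core of the method: a greedy recursive partitioner over
# numeric/ordinal features whose leaves are later read off as candidate
# subtype rules. Determinism is part of the contract — among splits with
# equal impurity decrease the lowest feature index wins, then the smallest
# threshold — so refitting on the same data always yields the same rules.

#' Gini impurity of a two-class count vector
#'
#' `1 - sum(p^2)` over the class proportions; 0 for a pure node, 0.5 for a
#' balanced binary node.
#'
#' @param class_counts nonnegative counts, one per class
#' @return impurity in [0, 0.5] for two classes
#' @export
gini_impurity <- function(class_counts) {
  stopifnot(all(class_counts >= 0))
  total <- sum(class_counts)
  if (total == 0) stop("cannot compute impurity of an empty node")
  1 - sum((class_counts / total)^2)
}

# Exhaustive best split for one node. Candidate thresholds are midpoints of
# consecutive distinct sorted values of each feature; the split maximising
# the decrease in count-weighted Gini wins. Returns NULL when no split
# leaves both children with at least min_leaf rows or none strictly
# decreases impurity.
best_split <- function(x, y, min_leaf) {
  n <- length(y)
  c1 <- sum(y)
  c0 <- n - c1
  parent_gini <- gini_impurity(c(c0, c1))
  best <- NULL
  best_dec <- 1e-12
  for (j in seq_len(ncol(x))) {
    ord <- order(x[, j])
    xo <- x[ord, j]
    yo <- y[ord]
    cut <- which(xo[-n] != xo[-1])
    cut <- cut[cut >= min_leaf & (n - cut) >= min_leaf]
    if (length(cut) == 0L) next
    c1cum <- cumsum(yo)
    nl <- cut
    nr <- n - cut
    c1l <- c1cum[cut]
    c0l <- nl - c1l
    c1r <- c1 - c1l
    c0r <- c0 - c0l
    gl <- 1 - (c0l / nl)^2 - (c1l / nl)^2
    gr <- 1 - (c0r / nr)^2 - (c1r / nr)^2
    dec <- parent_gini - (nl / n) * gl - (nr / n) * gr
    k <- which.max(dec)  # ascending scan: first max = smallest threshold
    if (dec[k] > best_dec) {
      best_dec <- dec[k]
      best <- list(
        feature = j,
        threshold = (xo[cut[k]] + xo[cut[k] + 1L]) / 2,
        decrease = dec[k]
      )
    }
  }
  best
}

unique_class_counts <- function(ids, y) {
  c(length(unique(ids[y == 0L])), length(unique(ids[y == 1L])))
}

#' Fit a binary CART classifier
#'
#' Greedy recursive partitioning with the Gini criterion. At each node every
#' feature and every midpoint between consecutive distinct sorted values is
#' evaluated; growth stops when a node is pure, the depth limit is reached,
#' or no split leaves both children with at least `min_samples_leaf` rows.
#' Leaf labels are the majority class, with exact ties labelled late onset
#' (class 1, the dataset-majority class) and logged in `tie_leaves`.
#'
#' @param x numeric feature matrix or data frame (ordinal items coded 0-4
#'   are treated as numeric)
#' @param y binary integer labels (0 = early onset, 1 = late onset)
#' @param max_depth maximum tree depth (root at depth 0)
#' @param min_samples_leaf minimum rows per leaf, counted over rows
#'   including oversampling duplicates
#' @param ids optional patient ids per row; enables per-node unique-patient
#'   counts used downstream by the subtype-size criterion
#' @return an `onset_tree` object
#' @export
fit_tree <- function(x, y, max_depth = 8L, min_samples_leaf = 10L,
                     ids = NULL) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (nrow(x) == 0L) stop("cannot fit a tree on empty input")
  stopifnot(is.numeric(x), nrow(x) == length(y), all(y %in% c(0L, 1L)))
  y <- as.integer(y)
  ids <- ids %||% as.character(seq_along(y))
  features <- colnames(x) %||% paste0("x", seq_len(ncol(x)))

  env <- new.env()
  env$next_id <- 1L
  env$tie_leaves <- integer(0)

  grow <- function(rows, depth) {
    id <- env$next_id
    env$next_id <- env$next_id + 1L
    yr <- y[rows]
    counts <- c(sum(yr == 0L), sum(yr == 1L))
    node <- list(
      id = id, depth = depth, n = length(rows),
      counts = counts,
      unique_counts = unique_class_counts(ids[rows], yr),
      gini = gini_impurity(counts),
      is_leaf = TRUE, label = NA_integer_, p1 = counts[2] / sum(counts),
      feature = NA_character_, threshold = NA_real_,
      left = NULL, right = NULL
    )
    split <- NULL
    if (node$gini > 0 && depth < max_depth) {
      split <- best_split(x[rows, , drop = FALSE], yr, min_samples_leaf)
    }
    if (is.null(split)) {
      if (counts[1] == counts[2]) {
        node$label <- 1L  # tie: dataset-majority (late onset) class
        env$tie_leaves <- c(env$tie_leaves, id)
      } else {
        node$label <- as.integer(counts[2] > counts[1])
      }
      return(node)
    }
    node$is_leaf <- FALSE
    node$feature <- features[split$feature]
    node$threshold <- split$threshold
    go_left <- x[rows, split$feature] <= split$threshold
    node$left <- grow(rows[go_left], depth + 1L)
    node$right <- grow(rows[!go_left], depth + 1L)
    node
  }

  root <- grow(seq_along(y), 0L)
  structure(
    list(root = root, features = features, n = length(y),
         max_depth = max_depth, min_samples_leaf = min_samples_leaf,
         tie_leaves = env$tie_leaves),
    class = "onset_tree"
  )
}

# Depth-first left-to-right leaf collection.
tree_leaves <- function(tree) {
  out <- list()
  walk <- function(node) {
    if (node$is_leaf) {
      out[[length(out) + 1L]] <<- node
    } else {
      walk(node$left)
      walk(node$right)
    }
  }
  walk(tree$root)
  out
}

#' Predict with a fitted tree
#'
#' @param object an `onset_tree`
#' @param newdata data frame or matrix carrying the training feature columns
#' @param type `"label"` for hard 0/1 predictions, `"prob"` for the leaf
#'   class-1 training fraction, `"leaf"` for leaf node ids
#' @param ... unused
#' @return numeric or integer vector, one element per row
#' @export
predict.onset_tree <- function(object, newdata,
                               type = c("label", "prob", "leaf"), ...) {
  type <- match.arg(type)
  if (is.data.frame(newdata)) {
    missing_feats <- setdiff(object$features, names(newdata))
    if (length(missing_feats) > 0L) {
      stop("newdata lacks feature(s): ", paste(missing_feats, collapse = ", "))
    }
    newdata <- as.matrix(newdata[, object$features, drop = FALSE])
  } else if (is.null(colnames(newdata))) {
    if (ncol(newdata) != length(object$features)) {
      stop("unnamed matrix must have one column per training feature")
    }
    colnames(newdata) <- object$features
  }
  out <- numeric(nrow(newdata))
  route <- function(node, rows) {
    if (length(rows) == 0L) return(invisible(NULL))
    if (node$is_leaf) {
      out[rows] <<- switch(type,
        label = node$label, prob = node$p1, leaf = node$id
      )
      return(invisible(NULL))
    }
    go_left <- newdata[rows, node$feature] <= node$threshold
    route(node$left, rows[go_left])
    route(node$right, rows[!go_left])
  }
  route(object$root, seq_len(nrow(newdata)))
  if (type %in% c("label", "leaf")) out <- as.integer(out)
  out
}

#' @export
print.onset_tree <- function(x, ...) {
  leaves <- tree_leaves(x)
  cat(sprintf(
    "<onset_tree> %d training rows, %d leaves, max depth %d, min leaf %d\n",
    x$n, length(leaves), x$max_depth, x$min_samples_leaf
  ))
  invisible(x)
}

#' Normalized Gini feature importance
#'
#' For each feature, the sum over its internal nodes of the node's training
#' count fraction times the impurity decrease of its split, normalized to
#' sum to one. Features never used to split score zero. A tree with no
#' splits returns an all-zero vector flagged with `attr(, "no_splits")`.
#'
#' @param tree an `onset_tree`
#' @return named numeric vector over the training features
#' @export
gini_feature_importance <- function(tree) {
  imp <- stats::setNames(numeric(length(tree$features)), tree$features)
  n_root <- tree$root$n
  any_split <- FALSE
  walk <- function(node) {
    if (node$is_leaf) return(invisible(NULL))
    any_split <<- TRUE
    dec <- node$gini -
      (node$left$n / node$n) * node$left$gini -
      (node$right$n / node$n) * node$right$gini
    imp[[node$feature]] <<- imp[[node$feature]] + (node$n / n_root) * dec
    walk(node$left)
    walk(node$right)
  }
  walk(tree$root)
  if (!any_split) {
    attr(imp, "no_splits") <- TRUE
    return(imp)
  }
  imp / sum(imp)
}

# --- serialization -------------------------------------------------------

node_to_list <- function(node) {
  out <- node[c("id", "depth", "n", "counts", "unique_counts", "gini",
                "is_leaf", "p1")]
  if (node$is_leaf) {
    out$label <- node$label
  } else {
    out$feature <- node$feature
    out$threshold <- node$threshold
    out$left <- node_to_list(node$left)
    out$right <- node_to_list(node$right)
  }
  out
}

#' Serialize a fitted tree to JSON
#' @param tree an `onset_tree`
#' @param path output path
#' @export
tree_to_json <- function(tree, path) {
  obj <- list(
    features = tree$features, n = tree$n, max_depth = tree$max_depth,
    min_samples_leaf = tree$min_samples_leaf, tie_leaves = tree$tie_leaves,
    root = node_to_list(tree$root)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

list_to_node <- function(lst) {
  node <- lst
  node$counts <- as.numeric(unlist(lst$counts))
  node$unique_counts <- as.numeric(unlist(lst$unique_counts))
  node$label <- if (is.null(lst$label)) NA_integer_ else as.integer(lst$label)
  node$feature <- if (is.null(lst$feature)) NA_character_ else lst$feature
  node$threshold <- if (is.null(lst$threshold)) NA_real_ else lst$threshold
  if (!lst$is_leaf) {
    node$left <- list_to_node(lst$left)
    node$right <- list_to_node(lst$right)
  } else {
    node$left <- NULL
    node$right <- NULL
  }
  node
}

#' Read a tree serialized by [tree_to_json()]
#' @param path JSON path
#' @return an `onset_tree`
#' @export
tree_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  structure(
    list(root = list_to_node(obj$root),
         features = unlist(obj$features), n = obj$n,
         max_depth = obj$max_depth,
         min_samples_leaf = obj$min_samples_leaf,
         tie_leaves = as.integer(unlist(obj$tie_leaves))),
    class = "onset_tree"
  )
}
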