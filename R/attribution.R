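#' Per-feature attribution of forest predictions
#'
#' Tree mode performs exact path decomposition (the Saabas method): every
#' node of every tree is assigned its in-bag mean outcome; walking a sample
#' down a tree, the change in node value across each split is credited to
#' the split feature, and credits are averaged over trees. By construction
#' the attribution is locally accurate: `base_value` (mean root value) plus
#' the sum of a sample's contributions equals the forest's prediction for
#' that sample. On a depth-1 tree the decomposition coincides with the
#' exact Shapley value. Permutation mode returns global importances only
#' (mean absolute prediction change when one column is permuted).
#'
#' @param model A `screening_model` from [fit_screening_model()].
#' @param features Feature matrix/data.frame in the training column order.
#' @param mode `"tree"` (default) or `"permutation"`.
#' @param seed Seed for the permutation mode shuffles.
#' @return For tree mode, an `attribution_report`: `base_value`,
#'   `contributions` (n x p matrix), `prediction` (base + row sums) and
#'   `ranking` (features by mean absolute contribution). For permutation
#'   mode: `ranking` only.
#' @export
feature_attributions <- function(model, features,
                                 mode = c("tree", "permutation"),
                                 seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "screening_model"))
  x <- feature_matrix(features)
  if (!identical(colnames(x), model$feature_names))
    stop("feature columns do not match the training order")
  if (mode == "permutation")
    return(permutation_importances(model, x, seed))
  p <- length(model$feature_names)
  n <- nrow(x)
  contrib <- matrix(0, n, p, dimnames = list(NULL, model$feature_names))
  base <- 0
  ntree <- model$fit$num.trees
  y_num <- if (model$spec$task == "detect") as.numeric(model$train_y) else
    as.numeric(model$train_y)
  for (t in seq_len(ntree)) {
    ti <- ranger::treeInfo(model$fit, t)
    vals <- node_values(ti, model$train_x, y_num,
                        model$fit$inbag.counts[[t]])
    base <- base + vals[1L] / ntree
    for (i in seq_len(n)) {
      node <- 1L
      while (!ti$terminal[node]) {
        nxt <- if (x[i, ti$splitvarID[node] + 1L] <= ti$splitval[node])
          ti$leftChild[node] + 1L else ti$rightChild[node] + 1L
        j <- ti$splitvarID[node] + 1L
        contrib[i, j] <- contrib[i, j] + (vals[nxt] - vals[node]) / ntree
        node <- nxt
      }
    }
  }
  mean_abs <- colMeans(abs(contrib))
  ranking <- data.frame(feature = names(sort(mean_abs, decreasing = TRUE)),
                        mean_abs_contribution = as.numeric(sort(mean_abs,
                                                decreasing = TRUE)),
                        row.names = NULL)
  structure(list(base_value = base, contributions = contrib,
                 prediction = base + rowSums(contrib),
                 ranking = ranking, mode = "tree"),
            class = "attribution_report")
}

# in-bag mean outcome at every node of one tree, by routing the in-bag
# training samples down the split structure
node_values <- function(ti, train_x, y_num, inbag) {
  n_nodes <- nrow(ti)
  sw <- numeric(n_nodes)
  swy <- numeric(n_nodes)
  use <- which(inbag > 0)
  for (i in use) {
    w <- inbag[i]
    node <- 1L
    repeat {
      sw[node] <- sw[node] + w
      swy[node] <- swy[node] + w * y_num[i]
      if (ti$terminal[node]) break
      node <- if (train_x[i, ti$splitvarID[node] + 1L] <= ti$splitval[node])
        ti$leftChild[node] + 1L else ti$rightChild[node] + 1L
    }
  }
  vals <- swy / sw
  vals[sw == 0] <- 0   # unreachable nodes (pruned by in-bag routing)
  vals
}

permutation_importances <- function(model, x, seed) {
  set.seed(seed)
  ref <- predict_screening(model, x)
  imp <- vapply(seq_len(ncol(x)), function(j) {
    xp <- x
    xp[, j] <- xp[sample(nrow(xp)), j]
    mean(abs(predict_screening(model, xp) - ref))
  }, 0)
  names(imp) <- colnames(x)
  ranking <- data.frame(feature = names(sort(imp, decreasing = TRUE)),
                        mean_abs_contribution = as.numeric(sort(imp,
                                                decreasing = TRUE)),
                        row.names = NULL)
  structure(list(ranking = ranking, mode = "permutation"),
            class = "attribution_report")
}

#' @export
print.attribution_report <- function(x, ...) {
  cat(sprintf("<attribution report (%s mode)>\n", x$mode))
  print(utils::head(x$ranking, 10))
  invisible(x)
}
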