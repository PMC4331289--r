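# CART classifier with Gini splitting, grown from scratch.
#
# Split selection is exact: for a candidate split the weighted child
# impurity is an affine function of f = S_L/n_L + S_R/n_R, where S is the
# sum of squared class counts in a child.  f is a rational number with a
# small integer numerator and denominator, so candidate splits are ranked
# by integer cross-multiplication — two splits that are tied at the level
# of class counts compare as exactly equal, independent of floating-point
# evaluation order.  Ties are broken deterministically: more balanced
# children first (smaller |n_L - n_R|), then earlier variable in column
# order, then smaller threshold.  All quantities stay exact for node
# sizes up to a few thousand rows (the integer products fit in a double).

#' CART growth parameters
#'
#' @param max_depth maximum number of splits along any root-to-leaf path
#'   (root depth 0); default 5.
#' @param min_parent minimum node size eligible for splitting; default 8.
#' @param min_child minimum size of either child; default 4.
#' @param cv_folds folds for cross-validated risk; default 10.
#' @param seed RNG seed for fold assignment.
#' @return a list of class `tree_params`.
#' @export
tree_params <- function(max_depth = 5, min_parent = 8, min_child = 4,
                        cv_folds = 10, seed = 1L) {
  stopifnot(max_depth >= 0, min_child >= 1, min_parent >= 2, cv_folds >= 2)
  structure(list(max_depth = as.integer(max_depth),
                 min_parent = as.integer(min_parent),
                 min_child = as.integer(min_child),
                 cv_folds = as.integer(cv_folds),
                 seed = seed),
            class = "tree_params")
}

#' Gini impurity of a node
#'
#' `sum_i p_i (1 - p_i)` over the class proportions `p_i`; zero iff the
#' node is pure, at most `1 - 1/k` for `k` classes.
#'
#' @param class_counts non-negative counts with positive sum.
#' @return impurity in `[0, 1 - 1/k]`.
#' @export
#' @examples
#' gini(c(5, 5))    # 0.5
#' gini(c(2, 1, 1)) # 0.625
gini <- function(class_counts) {
  if (any(class_counts < 0)) stop("class counts must be non-negative")
  n <- sum(class_counts)
  if (n <= 0) stop("class counts must have positive sum")
  p <- class_counts / n
  sum(p * (1 - p))
}

# Exact comparison of two candidate splits.
# Returns TRUE when candidate 1 (score a1/d1, balance b1, normalized
# margin g1, variable v1, threshold t1) beats candidate 2.
# a = S_L*n_R + S_R*n_L, d = n_L*n_R (small exact integers).
better_split <- function(a1, d1, b1, g1, v1, t1, a2, d2, b2, g2, v2, t2) {
  lhs <- a1 * d2; rhs <- a2 * d1
  if (lhs != rhs) return(lhs > rhs)
  if (b1 != b2) return(b1 < b2)
  if (g1 != g2) return(g1 > g2)
  if (v1 != v2) return(v1 < v2)
  t1 < t2
}

#' Best binary split of a node
#'
#' Scans every (variable, threshold) pair with thresholds at midpoints of
#' consecutive distinct sorted values, keeping only splits whose children
#' both hold at least `min_child` rows, and returns the pair maximizing
#' the Gini improvement `gini(parent) - (n_L/n) gini(L) - (n_R/n) gini(R)`.
#' Exact count-level ties (common under balanced class frequencies, where
#' every class-clean partition yields the same improvement) are broken
#' deterministically: more balanced children first, then the widest
#' margin (gap between the values flanking the threshold, normalized by
#' the variable's scale), then earlier variable in column order, then
#' smaller threshold.
#'
#' @param features data frame (or matrix) of numeric predictor columns.
#' @param labels vector of class labels, one per row.
#' @param params a [tree_params()]; only `min_child` is used here.
#' @param scales optional named vector of per-variable scales for margin
#'   normalization; [grow_tree()] passes each variable's root-node range
#'   so margins are comparable across nodes.  Defaults to the within-node
#'   range.
#' @return `NULL` when no admissible split improves impurity, else a list
#'   with `variable`, `threshold`, `improvement`, `n_left`, `n_right`.
#' @export
best_split <- function(features, labels, params = tree_params(),
                       scales = NULL) {
  features <- as.data.frame(features)
  y <- as.integer(factor(labels, levels = sort(unique(as.character(labels)))))
  n <- length(y)
  k <- max(y)
  tot <- tabulate(y, k)
  S_p <- sum(tot^2)
  g_parent <- 1 - S_p / n^2
  mc <- params$min_child
  best <- NULL
  ba <- bd <- bb <- bg <- bv <- bt <- NULL
  for (v in seq_along(features)) {
    x <- as.numeric(features[[v]])
    scale_v <- if (!is.null(scales)) scales[[names(features)[v]]] else {
      diff(range(x))
    }
    ord <- order(x)
    xs <- x[ord]
    ys <- y[ord]
    # cumulative class counts after each sorted row
    Y <- matrix(0L, n, k)
    Y[cbind(seq_len(n), ys)] <- 1L
    C <- apply(Y, 2, cumsum)
    if (k == 1) C <- matrix(C, ncol = 1)
    S_L <- rowSums(C^2)
    S_R <- rowSums((matrix(tot, n, k, byrow = TRUE) - C)^2)
    i <- seq_len(n - 1)
    n_L <- i; n_R <- n - i
    a <- S_L[i] * n_R + S_R[i] * n_L   # exact small integers in doubles
    d <- n_L * n_R
    valid <- (xs[i + 1] > xs[i]) & n_L >= mc & n_R >= mc & (n * a > S_p * d)
    if (!any(valid)) next
    # float pre-ranking, then exact rational comparison among near-ties
    f <- a / d
    fmax <- max(f[valid])
    cand <- which(valid & f >= fmax - max(1e-12 * fmax, 1e-300))
    for (ci in cand) {
      thr <- (xs[ci] + xs[ci + 1]) / 2
      bal <- abs(n_L[ci] - n_R[ci])
      gap <- if (scale_v > 0) (xs[ci + 1] - xs[ci]) / scale_v else 0
      if (is.null(best) ||
          better_split(a[ci], d[ci], bal, gap, v, thr,
                       ba, bd, bb, bg, bv, bt)) {
        ba <- a[ci]; bd <- d[ci]; bb <- bal; bg <- gap; bv <- v; bt <- thr
        g_children <- (n_L[ci] / n) * (1 - S_L[ci] / n_L[ci]^2) +
          (n_R[ci] / n) * (1 - S_R[ci] / n_R[ci]^2)
        best <- list(variable = names(features)[v], threshold = thr,
                     improvement = g_parent - g_children,
                     n_left = n_L[ci], n_right = n_R[ci])
      }
    }
  }
  best
}

#' Grow a CART tree
#'
#' Recursive binary partitioning of the feature matrix.  A node becomes
#' terminal when it is pure, smaller than `min_parent`, at `max_depth`, or
#' when no admissible split reduces impurity.  Every node records its
#' class counts, Gini impurity, predicted class (majority, ties to the
#' alphabetically first label) and the majority frequency as probability.
#'
#' @param matrix a `cropclass_matrix` (see [build_matrix()]) or any data
#'   frame with numeric feature columns and a label column.
#' @param params a [tree_params()].
#' @param label_col name of the label column (default `"land_use"`).
#' @return an object of class `crop_tree`.
#' @export
grow_tree <- function(matrix, params = tree_params(), label_col = "land_use") {
  df <- as.data.frame(matrix)
  if (!label_col %in% names(df)) stop("no label column '", label_col, "'")
  vars <- setdiff(names(df), c("parcel_id", label_col))
  vars <- vars[vapply(df[vars], is.numeric, logical(1))]
  if (!length(vars)) stop("no numeric feature columns")
  y <- as.character(df[[label_col]])
  if (length(y) < 2) stop("need at least 2 labeled rows")
  classes <- sort(unique(y))
  feats <- df[vars]
  # margin normalization scales fixed at the root so split margins are
  # comparable across nodes and depths
  scales <- vapply(feats, function(x) diff(range(as.numeric(x))), numeric(1))
  nodes <- list()
  new_node <- function(rows, depth) {
    id <- length(nodes) + 1L
    counts <- table(factor(y[rows], levels = classes))
    counts <- stats::setNames(as.integer(counts), classes)
    node <- list(id = id, depth = depth, n = length(rows),
                 class_counts = counts, gini = gini(counts),
                 terminal_class = classes[which.max(counts)],
                 probability = max(counts) / length(rows),
                 split = NULL, left = NA_integer_, right = NA_integer_)
    nodes[[id]] <<- node
    pure <- max(counts) == length(rows)
    if (!pure && length(rows) >= params$min_parent &&
        depth < params$max_depth) {
      sp <- best_split(feats[rows, , drop = FALSE], y[rows], params,
                       scales = scales)
      if (!is.null(sp)) {
        go_left <- feats[rows, sp$variable] <= sp$threshold
        nodes[[id]]$split <<- sp[c("variable", "threshold", "improvement")]
        nodes[[id]]$left <<- new_node(rows[go_left], depth + 1L)
        nodes[[id]]$right <<- new_node(rows[!go_left], depth + 1L)
      }
    }
    id
  }
  new_node(seq_along(y), 0L)
  structure(list(nodes = nodes, classes = classes, var_names = vars,
                 n = length(y), params = params, label_col = label_col),
            class = "crop_tree")
}

#' @export
print.crop_tree <- function(x, ...) {
  leaves <- sum(vapply(x$nodes, function(nd) is.null(nd$split), logical(1)))
  cat(sprintf("<crop_tree: %d rows, %d classes, %d nodes (%d leaves), depth %d>\n",
              x$n, length(x$classes), length(x$nodes), leaves,
              max(vapply(x$nodes, function(nd) nd$depth, integer(1)))))
  invisible(x)
}

# Descend from the root for one named feature vector; returns the leaf.
descend <- function(tree, rec) {
  nd <- tree$nodes[[1]]
  while (!is.null(nd$split)) {
    v <- nd$split$variable
    val <- rec[[v]]
    if (is.null(val) || is.na(val)) {
      stop("record lacks variable '", v, "' tested by the tree")
    }
    nd <- tree$nodes[[if (val <= nd$split$threshold) nd$left else nd$right]]
  }
  nd
}

#' Predict with a CART tree
#'
#' Deterministic root-to-leaf descent; a value equal to a threshold takes
#' the left (`<=`) branch.
#'
#' @param object a `crop_tree`.
#' @param newdata data frame (or single named vector/list) containing
#'   every variable the tree tests.
#' @param ... unused.
#' @return data frame with columns `class` and `probability`, one row per
#'   input row.
#' @export
predict.crop_tree <- function(object, newdata, ...) {
  if (!is.data.frame(newdata)) newdata <- as.data.frame(as.list(newdata))
  out <- lapply(seq_len(nrow(newdata)), function(i) {
    nd <- descend(object, newdata[i, , drop = FALSE])
    data.frame(class = nd$terminal_class, probability = nd$probability,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Resubstitution risk of a tree
#'
#' @param tree a `crop_tree`.
#' @param matrix the data to re-classify (defaults semantics: training
#'   matrix gives the resubstitution estimate).
#' @return a `risk_estimate`: list with `risk`, `se`, `method`, `n`.
#' @export
resubstitution_risk <- function(tree, matrix) {
  pred <- predict(tree, as.data.frame(matrix)[tree$var_names])
  y <- as.character(as.data.frame(matrix)[[tree$label_col]])
  risk_estimate(mean(pred$class != y), length(y), "resubstitution")
}

#' Risk estimate with binomial standard error
#'
#' @param risk misclassification proportion in `[0, 1]`.
#' @param n number of evaluated cases.
#' @param method `"resubstitution"` or `"cross_validation"`.
#' @return list of class `risk_estimate` with `risk`,
#'   `se = sqrt(risk (1 - risk) / n)`, `method`, `n`.
#' @export
risk_estimate <- function(risk, n, method) {
  structure(list(risk = risk, se = sqrt(risk * (1 - risk) / n),
                 method = method, n = n),
            class = "risk_estimate")
}

#' @export
print.risk_estimate <- function(x, ...) {
  cat(sprintf("Risk (%s): %.3f +/- %.3f (n = %d)\n",
              x$method, x$risk, x$se, x$n))
  invisible(x)
}

# Stratified fold assignment: within each class, shuffled rows are dealt
# round-robin over folds.
stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  with_seed(seed, {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Cross-validated risk of a CART analysis
#'
#' Stratified k-fold cross-validation (default 10-fold): each fold is
#' held out, a tree grown on the remainder, and the pooled held-out
#' misclassification proportion reported with its binomial standard error
#' `sqrt(r (1 - r) / N)`.  Priors are the empirical class frequencies, so
#' the prior-adjusted risk reduces to the plain misclassification
#' proportion.
#'
#' @param matrix a `cropclass_matrix` with labels.
#' @param params a [tree_params()]; `cv_folds` and `seed` control the
#'   fold assignment.  When the rarest class has fewer members than
#'   `cv_folds`, the fold count is reduced to that size with a warning.
#' @param label_col label column name.
#' @return a `risk_estimate` with `method = "cross_validation"`.
#' @export
cross_validate <- function(matrix, params = tree_params(),
                           label_col = "land_use") {
  df <- as.data.frame(matrix)
  y <- as.character(df[[label_col]])
  n <- length(y)
  if (n < 2) stop("need at least 2 rows for cross-validation")
  k <- params$cv_folds
  smallest <- min(table(y))
  if (smallest < k) {
    k <- max(2L, as.integer(smallest))
    warning("rarest class has ", smallest, " members; folds reduced to ", k)
  }
  fold <- stratified_folds(y, k, params$seed)
  wrong <- 0L
  for (f in seq_len(k)) {
    hold <- fold == f
    tr <- grow_tree(df[!hold, , drop = FALSE], params, label_col)
    pred <- predict(tr, df[hold, tr$var_names, drop = FALSE])
    wrong <- wrong + sum(pred$class != y[hold])
  }
  est <- risk_estimate(wrong / n, n, "cross_validation")
  est$folds <- k
  est
}

#' Normalized variable importance
#'
#' Raw importance of a variable is the sum over the internal nodes that
#' split on it of `(node size / root size) * improvement`; values are
#' normalized so the largest equals 100 (primary splits only — no
#' surrogate splits are grown).
#'
#' @param tree a `crop_tree`.
#' @return data frame with columns `variable`, `importance` (descending);
#'   zero rows for a splitless tree.
#' @export
variable_importance <- function(tree) {
  raw <- numeric(0)
  for (nd in tree$nodes) {
    if (is.null(nd$split)) next
    v <- nd$split$variable
    raw[v] <- (if (is.na(raw[v])) 0 else raw[v]) +
      (nd$n / tree$n) * nd$split$improvement
  }
  if (!length(raw)) {
    return(data.frame(variable = character(), importance = numeric(),
                      stringsAsFactors = FALSE))
  }
  imp <- 100 * raw / max(raw)
  ord <- order(-imp, names(imp))
  data.frame(variable = names(imp)[ord], importance = as.numeric(imp[ord]),
             stringsAsFactors = FALSE)
}

#' Serialize a tree to JSON for audit
#'
#' Writes nodes, class counts, splits and probabilities.  The interchange
#' format for classification is the SQL rule file (see [write_sql()]);
#' the JSON is a human-auditable record of the full tree.
#'
#' @param tree a `crop_tree`.
#' @param path output `.json` file.
#' @return `path`, invisibly.
#' @export
write_tree_json <- function(tree, path) {
  nodes <- lapply(tree$nodes, function(nd) {
    list(id = nd$id, depth = nd$depth, n = nd$n,
         class_counts = as.list(nd$class_counts), gini = nd$gini,
         split = nd$split, left = nd$left, right = nd$right,
         terminal_class = nd$terminal_class, probability = nd$probability)
  })
  jsonlite::write_json(
    list(classes = tree$classes, n = tree$n, var_names = tree$var_names,
         params = unclass(tree$params), nodes = nodes),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}
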