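# Gini splitting, tree growth, prediction, CV risk, importance.

test_that("gini impurity: purity, symmetry, direct values and bounds", {
  expect_equal(gini(c(8, 0, 0)), 0)
  expect_equal(gini(c(5, 5)), 0.5)
  expect_equal(gini(c(2, 1, 1)), 0.625)
  expect_error(gini(c(0, 0)), "positive sum")
  expect_error(gini(c(-1, 2)), "non-negative")
  set.seed(4)
  for (i in 1:50) {
    k <- sample(2:6, 1)
    counts <- rpois(k, 5) + (seq_len(k) == 1)  # ensure positive sum
    g <- gini(counts)
    expect_gte(g, 0)
    expect_lte(g, 1 - 1 / k + 1e-12)
    if (sum(counts > 0) == 1) expect_equal(g, 0)
  }
})

test_that("best_split recovers the obvious separation with improvement 0.5", {
  sp <- best_split(data.frame(x = c(1, 2, 3, 4)), c("A", "A", "B", "B"),
                   tree_params(min_child = 1))
  expect_identical(sp$variable, "x")
  expect_equal(sp$threshold, 2.5)
  expect_equal(sp$improvement, 0.5)
  # a pure node has no admissible split
  expect_null(best_split(data.frame(x = 1:6), rep("A", 6),
                         tree_params(min_child = 1)))
  # min_child excludes otherwise optimal cuts
  sp2 <- best_split(data.frame(x = c(1, 2, 3, 4, 5, 6)),
                    c("A", "B", "B", "B", "B", "B"),
                    tree_params(min_child = 2))
  expect_gte(sp2$n_left, 2)
  expect_gte(sp2$n_right, 2)
})

test_that("best_split agrees with the exhaustive enumeration oracle", {
  set.seed(31)
  for (i in 1:60) {
    n <- sample(5:30, 1)
    nv <- sample(1:3, 1)
    feats <- as.data.frame(stats::setNames(
      lapply(seq_len(nv), function(j) round(runif(n, 0, 10), 1)),
      paste0("v", seq_len(nv))))
    labels <- sample(LETTERS[1:sample(2:4, 1)], n, replace = TRUE)
    mine <- best_split(feats, labels, tree_params(min_child = 1))
    oracle <- oracle_best_split(feats, labels, min_child = 1)
    if (is.null(oracle)) {
      expect_null(mine)
    } else {
      expect_identical(mine$variable, oracle$variable)
      expect_equal(mine$threshold, oracle$thr)
      expect_equal(mine$improvement, oracle$improvement, tolerance = 1e-12)
    }
  }
})

test_that("tree growth respects purity, depth and node-size stopping rules", {
  # linearly separable two-class data -> depth-1 tree, zero risk
  m <- toy_matrix(n_per = 10, k = 2)
  tr <- grow_tree(m)
  expect_equal(length(tr$nodes), 3L)
  expect_equal(resubstitution_risk(tr, m)$risk, 0)

  # max_depth 0 -> root-only majority tree
  tr0 <- grow_tree(m, tree_params(max_depth = 0))
  expect_equal(length(tr0$nodes), 1L)
  p <- predict(tr0, m[tr0$var_names])
  expect_true(all(p$class == tr0$nodes[[1]]$terminal_class))
  expect_equal(unique(p$probability), 0.5)

  # single-class input stays a depth-0 tree
  m1 <- m; m1$land_use <- "A"
  expect_equal(length(grow_tree(m1)$nodes), 1L)

  # min_parent/min_child honored everywhere
  st <- default_study()
  big <- grow_tree(st$train)
  for (nd in big$nodes) {
    if (!is.null(nd$split)) {
      expect_gte(nd$n, big$params$min_parent)
      expect_gte(big$nodes[[nd$left]]$n, big$params$min_child)
      expect_gte(big$nodes[[nd$right]]$n, big$params$min_child)
      expect_gte(nd$split$improvement, 0)
      expect_equal(big$nodes[[nd$left]]$n + big$nodes[[nd$right]]$n, nd$n)
    }
    expect_equal(sum(nd$class_counts), nd$n)
  }
  depths <- vapply(big$nodes, function(nd) nd$depth, integer(1))
  expect_lte(max(depths), big$params$max_depth)
})

test_that("prediction descends deterministically with <= taking the left branch", {
  m <- toy_matrix(n_per = 10, k = 2)
  tr <- grow_tree(m)
  thr <- tr$nodes[[1]]$split$threshold
  v <- tr$nodes[[1]]$split$variable
  rec <- m[1, tr$var_names]
  rec[[v]] <- thr  # exactly at the threshold
  p <- predict(tr, rec)
  expect_identical(p$class, tr$nodes[[tr$nodes[[1]]$left]]$terminal_class)
  # every training row lands in the leaf that produced its label share
  st <- default_study()
  big <- grow_tree(st$train)
  pred <- predict(big, st$train[big$var_names])
  cm <- confusion(st$train$land_use, pred$class, classes = big$classes)
  expect_equal(100 - accuracy_stats(cm)$OA,
               100 * resubstitution_risk(big, st$train)$risk)
  # missing tested variable is a named error
  rootvar <- big$nodes[[1]]$split$variable
  rec2 <- st$train[1, setdiff(big$var_names, rootvar)]
  expect_error(predict(big, rec2), rootvar)
})

test_that("resubstitution risk is non-increasing in max_depth", {
  st <- default_study()
  risks <- vapply(0:5, function(d) {
    resubstitution_risk(grow_tree(st$train, tree_params(max_depth = d)),
                        st$train)$risk
  }, numeric(1))
  expect_true(all(diff(risks) <= 1e-12))
})

test_that("cross-validation: se closed form, separable data, permuted labels", {
  expect_equal(round_half_up(risk_estimate(0.4, 156, "cross_validation")$se, 2),
               0.04)
  m <- toy_matrix(n_per = 20, k = 3)
  cv <- cross_validate(m, tree_params(seed = 5))
  expect_lte(cv$risk, 0.05)          # perfectly separable classes
  expect_identical(cv$method, "cross_validation")
  expect_equal(cv$se, sqrt(cv$risk * (1 - cv$risk) / nrow(m)))

  # labels shuffled uniformly over k classes -> risk near 1 - 1/k
  set.seed(77)
  ms <- toy_matrix(n_per = 40, k = 3, sd = 6)  # heavy overlap
  ms$land_use <- sample(ms$land_use)
  cvs <- cross_validate(ms, tree_params(seed = 5))
  expect_gt(cvs$risk, 2 / 3 - 0.12)
  # folds reduced with warning when the rarest class is small
  msmall <- toy_matrix(n_per = 4, k = 2)
  expect_warning(cv2 <- cross_validate(msmall, tree_params(seed = 1)),
                 "folds reduced")
  expect_equal(cv2$folds, 4L)
})

test_that("CV fold assignment is stratified and seeded", {
  y <- rep(c("A", "B", "C"), times = c(30, 20, 10))
  f1 <- cropclassr:::stratified_folds(y, 10, seed = 3)
  f2 <- cropclassr:::stratified_folds(y, 10, seed = 3)
  f3 <- cropclassr:::stratified_folds(y, 10, seed = 4)
  expect_identical(f1, f2)
  expect_false(identical(f1, f3))
  expect_equal(max(tabulate(f1[y == "A"], 10)), 3)
  expect_equal(max(tabulate(f1[y == "C"], 10)), 1)
})

test_that("variable importance is normalized to max 100 over primary splits", {
  m <- toy_matrix(n_per = 10, k = 2)
  tr <- grow_tree(m)
  imp <- variable_importance(tr)
  expect_equal(nrow(imp), 1L)
  expect_equal(imp$importance, 100)
  expect_identical(imp$variable, tr$nodes[[1]]$split$variable)
  # splitless tree -> empty list
  expect_equal(nrow(variable_importance(grow_tree(m, tree_params(max_depth = 0)))), 0L)
  st <- default_study()
  impb <- variable_importance(grow_tree(st$train))
  expect_true(all(impb$importance > 0 & impb$importance <= 100))
  expect_equal(max(impb$importance), 100)
})

test_that("tree accuracy matches an independent CART implementation on separable data", {
  skip_if_not_installed("rpart")
  m <- toy_matrix(n_per = 15, k = 4, seed = 9)
  tr <- grow_tree(m)
  df <- as.data.frame(m)[c(feature_columns(m), "land_use")]
  df$land_use <- factor(df$land_use)
  rp <- rpart::rpart(land_use ~ ., data = df, method = "class",
                     control = rpart::rpart.control(minsplit = 8, minbucket = 4,
                                                    maxdepth = 5, cp = 0,
                                                    xval = 0))
  acc_rp <- mean(predict(rp, df, type = "class") == df$land_use)
  acc_me <- 1 - resubstitution_risk(tr, m)$risk
  expect_equal(acc_me, acc_rp)
})

test_that("tree JSON audit file is written and structurally sound", {
  m <- toy_matrix(n_per = 10, k = 2)
  tr <- grow_tree(m)
  f <- file.path(withr::local_tempdir(), "tree.json")
  write_tree_json(tr, f)
  back <- jsonlite::fromJSON(f, simplifyVector = FALSE)
  expect_equal(length(back$nodes), length(tr$nodes))
  expect_equal(back$nodes[[1]]$split$threshold, tr$nodes[[1]]$split$threshold)
  expect_identical(unlist(back$classes), tr$classes)
})
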