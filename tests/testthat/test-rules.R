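# SQL rule extraction, serialization and phase-II classification.

test_that("leaf rules collapse path bounds to tightest intervals", {
  # root-only tree -> single always-true rule
  m <- toy_matrix(n_per = 10, k = 2)
  rs0 <- tree_to_rules(grow_tree(m, tree_params(max_depth = 0)), "m0")
  expect_length(rs0$rules, 1)
  expect_length(rs0$rules[[1]]$predicates, 0)

  # depth-1 tree -> the two complementary half-spaces
  tr <- grow_tree(m)
  rs <- tree_to_rules(tr, "m1")
  expect_length(rs$rules, 2)
  v <- tr$nodes[[1]]$split$variable
  thr <- tr$nodes[[1]]$split$threshold
  expect_identical(rs$rules[[1]]$predicates[[1]],
                   list(variable = v, op = "<=", threshold = thr))
  expect_identical(rs$rules[[2]]$predicates[[1]],
                   list(variable = v, op = ">", threshold = thr))
  expect_identical(rs$rules[[1]]$class_label,
                   tr$nodes[[tr$nodes[[1]]$left]]$terminal_class)

  # repeated splits on one variable collapse: at most one bound per op
  st <- default_study()
  big <- tree_to_rules(grow_tree(st$train), "crops")
  for (rule in big$rules) {
    key <- vapply(rule$predicates, function(p) paste(p$variable, p$op),
                  character(1))
    expect_false(anyDuplicated(key) > 0)
  }
})

test_that("sqlmodel files round-trip losslessly, with JSON sidecar", {
  st <- default_study()
  rs <- tree_to_rules(grow_tree(st$train), "crops", "Crop")
  d <- withr::local_tempdir()
  f <- file.path(d, "crops.sqlmodel")
  write_sql(rs, f)
  expect_true(file.exists(paste0(f, ".json")))
  back <- parse_sql(f)
  strip <- function(x) lapply(x$rules, function(r)
    r[c("predicates", "class_label", "probability")])
  expect_identical(strip(back), strip(rs))
  expect_identical(back$model_name, "crops")
  expect_identical(back$model_type, "Crop")
  expect_identical(back$times_used, rs$times_used)
})

test_that("hand-written WHERE rules parse, bad files are rejected", {
  d <- withr::local_tempdir()
  f <- file.path(d, "hand.sqlmodel")
  writeLines(c("-- model_name: hand", "-- model_type: Crop",
               "-- times_used: T3",
               "WHERE T3Stu > 1.2 AND T3Stu <= 2.0 THEN 'WHT' PROB 0.89"), f)
  rs <- parse_sql(f)
  expect_length(rs$rules, 1)
  expect_length(rs$rules[[1]]$predicates, 2)
  expect_identical(vapply(rs$rules[[1]]$predicates, `[[`, "", "op"),
                   c(">", "<="))
  expect_equal(rs$rules[[1]]$probability, 0.89)

  writeLines(c("-- model_name: bad", "-- model_type: Crop",
               "-- times_used: T3",
               "WHEN T3Bogus > 1 THEN 'WHT' PROB 0.5"), f)
  expect_error(parse_sql(f), "T3Bogus")
  writeLines(c("-- model_name: bad", "-- model_type: Crop",
               "-- times_used: T3",
               "WHEN T3Stu > 2 AND T3Stu <= 1 THEN 'WHT' PROB 0.5"), f)
  expect_error(parse_sql(f), "empty interval")
  writeLines(c("-- model_name: bad", "-- model_type: Crop",
               "-- times_used: T3",
               "WHEN TRUE THEN 'A' PROB 1", "WHEN TRUE THEN 'B' PROB 1"), f)
  expect_error(parse_sql(f), "always-true")
  writeLines(c("-- model_name: bad", "-- model_type: Crop",
               "-- times_used: T3", "nonsense line"), f)
  expect_error(parse_sql(f), "syntax error")
  # alias tokens canonicalize on parse
  writeLines(c("-- model_name: alias", "-- model_type: Crop",
               "-- times_used: T3",
               "WHEN T3B/G <= 0.5 AND T3Green > 10 THEN 'WHT' PROB 1"), f)
  rs2 <- parse_sql(f)
  expect_setequal(vapply(rs2$rules[[1]]$predicates, `[[`, "", "variable"),
                  c("T3BG", "T3Gree"))
})

test_that("rule application reproduces tree prediction exactly", {
  st <- default_study()
  tr <- grow_tree(st$train)
  rs <- tree_to_rules(tr, "Crop", "Crop")
  out <- classify(rs, st$records[st$train$parcel_id])
  pred <- predict(tr, st$train[tr$var_names])
  expect_identical(out$Crop_class, pred$class)
  expect_identical(out$Crop_prob, pred$probability)
  # several rule sets side by side, one column pair each, input order kept
  hier <- default_hierarchy()
  msys <- st$train; msys$land_use <- relabel(msys$land_use, hier, "system")
  rs2 <- tree_to_rules(grow_tree(msys), "CropSys", "CropSys")
  out2 <- classify(list(rs, rs2), st$records[st$train$parcel_id])
  expect_identical(names(out2),
                   c("parcel", "Crop_class", "Crop_prob",
                     "CropSys_class", "CropSys_prob"))
  expect_identical(out2$parcel, st$train$parcel_id)
  # empty record list -> empty output
  expect_equal(nrow(classify(rs, list())), 0)
})

test_that("rule sets partition the feature space", {
  st <- default_study()
  tr <- grow_tree(st$train)
  rs <- tree_to_rules(tr, "Crop", "Crop")
  rng <- apply(st$train[tr$var_names], 2, range)
  set.seed(13)
  for (i in 1:1000) {
    rec <- stats::setNames(as.list(runif(ncol(rng), rng[1, ], rng[2, ])),
                           colnames(rng))
    hits <- sum(vapply(rs$rules, function(rule) {
      cropclassr:::rule_matches(rule, rec)
    }, logical(1)))
    expect_equal(hits, 1L)
  }
})

test_that("a rule set refuses records from other acquisition times", {
  st <- default_study()
  tr <- grow_tree(st$train)
  rs <- tree_to_rules(tr, "Crop", "Crop",
                      times_used = paste0("T", 1:7))
  short <- lapply(st$records[1:3], function(r) r[1:3, ])
  for (i in seq_along(short)) {
    attr(short[[i]], "parcel_id") <- attr(st$records[[i]], "parcel_id")
    class(short[[i]]) <- class(st$records[[i]])
  }
  expect_error(classify(rs, short), "same times")
})

test_that("random trees: rule application equals prediction on all rows", {
  set.seed(55)
  for (i in 1:25) {
    m <- toy_matrix(n_per = sample(6:12, 1), k = sample(2:4, 1),
                    seed = i, sd = runif(1, 0.3, 4))
    tr <- grow_tree(m, tree_params(min_parent = 4, min_child = 2))
    rs <- tree_to_rules(tr, "m", "Crop")
    pred <- predict(tr, m[tr$var_names])
    feats <- m[c("parcel_id", feature_columns(m))]
    out <- classify(rs, feats)
    expect_identical(out$m_class, pred$class)
    expect_identical(out$m_prob, pred$probability)
  }
})
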