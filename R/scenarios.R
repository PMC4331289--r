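# Image-number / image-timing sensitivity study: train and evaluate trees
# on subsets of the acquisition times.

#' Default acquisition-time scenarios
#'
#' For a seven-image series the canonical scenario set is: the full
#' series; the triplets `{T1,T3,T5}` and `{T2,T4,T6}`; the pairs
#' `{T2,T5}` and `{T3,T6}`; and each single image `T1 ... T7` — twelve
#' scenarios.  For other series lengths the analogous construction is
#' used: the full set; two evenly spaced "triplet" subsets (offset by one
#' position, requiring at least 5 images); two evenly spaced pairs
#' (at least 4 images); and every singleton.  Degenerate or duplicate
#' subsets are removed.
#'
#' @param times ordered acquisition time tags (at least one).
#' @return named list of character vectors (subsets of `times`).
#' @export
default_scenarios <- function(times) {
  n <- length(times)
  if (!n) stop("times must be non-empty")
  scen <- list(times)
  if (n >= 5) {
    p <- round(seq(1, n - 2, length.out = 3))
    if (!anyDuplicated(p)) {
      scen <- c(scen, list(times[p], times[p + 1]))
    }
  }
  if (n >= 4) {
    p <- round(seq(2, n - 2, length.out = 2))
    if (!anyDuplicated(p)) {
      scen <- c(scen, list(times[p], times[p + 1]))
    }
  }
  scen <- c(scen, lapply(times, identity))
  keys <- vapply(scen, paste, character(1), collapse = ",")
  scen <- scen[!duplicated(keys)]
  names(scen) <- vapply(scen, function(s) {
    if (length(s) == length(times) && length(s) > 1) {
      paste0(s[1], "-", s[length(s)])
    } else paste(s, collapse = ",")
  }, character(1))
  scen
}

#' Run the image-timing scenario study
#'
#' For every scenario the feature columns are restricted to the scenario's
#' times, a tree is grown with the standard parameters, and the
#' resubstitution per-class percent-correct (UA on the observed row), the
#' overall accuracy and the stratified cross-validated risk are recorded.
#' Deterministic given `params$seed`.
#'
#' @param matrix a labeled `cropclass_matrix`.
#' @param scenarios list of time subsets (default
#'   `default_scenarios(attr(matrix, "times"))`).
#' @param params a [tree_params()].
#' @return list of `scenario_result` entries (`scenario`, `times`,
#'   `per_class` percent-correct, `OA`, `risk`), one per scenario.
#' @export
run_scenarios <- function(matrix, scenarios = NULL, params = tree_params()) {
  if (is.null(scenarios)) scenarios <- default_scenarios(attr(matrix, "times"))
  if (!length(scenarios)) stop("no scenarios given")
  if (is.null(names(scenarios))) {
    names(scenarios) <- vapply(scenarios, paste, character(1), collapse = ",")
  }
  lapply(stats::setNames(names(scenarios), names(scenarios)), function(lbl) {
    times <- scenarios[[lbl]]
    sub <- subset_times(matrix, times)
    tree <- grow_tree(sub, params)
    pred <- predict(tree, sub[tree$var_names])
    cm <- confusion(sub$land_use, pred$class, classes = tree$classes)
    st <- accuracy_stats(cm)
    structure(list(scenario = lbl, times = times, per_class = st$UA,
                   OA = st$OA, risk = cross_validate(sub, params)),
              class = "scenario_result")
  })
}

#' Tabulate scenario results
#'
#' @param results list from [run_scenarios()].
#' @return data frame shaped classes x scenarios: one row per class
#'   (percent correctly classified) plus `OA`, `risk` and `risk_se` rows.
#' @export
scenario_table <- function(results) {
  classes <- names(results[[1]]$per_class)
  tab <- vapply(results, function(r) {
    c(r$per_class[classes], OA = r$OA, risk = r$risk$risk,
      risk_se = r$risk$se)
  }, numeric(length(classes) + 3))
  out <- data.frame(measure = c(classes, "OA", "risk", "risk_se"), tab,
                    check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
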