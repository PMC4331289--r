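# Terminal nodes as SQL predicate rules: export, parse, and phase-II
# classification of unlabeled parcels.
#
# Dialect (one rule per line, UTF-8, '.' decimal, thresholds printed with
# 17 significant digits so parsing reproduces the doubles exactly):
#
#   -- cropclassr sql model
#   -- model_name: crops
#   -- model_type: Crop
#   -- times_used: T1,T2,T3,T4,T5,T6,T7
#   WHEN T3Stu > 1.2 AND T3Stu <= 2 THEN 'WHT' PROB 0.89
#
# `WHERE` is accepted as a synonym of `WHEN` on parse; a root-only tree
# yields the single always-true rule `WHEN TRUE THEN ... PROB ...`.
# A machine-readable JSON sidecar (<path>.json) is written alongside.

MODEL_TYPES <- c("NonVeg-Veg", "CropSys", "Crop")

VAR_PATTERN <- "^T[0-9]+(Blue|Gree|Green|Red|NIR|NDVI|Stu|STU|BG|B/G)$"

new_ruleset <- function(model_name, model_type, times_used, rules) {
  if (!model_type %in% MODEL_TYPES) {
    stop("model_type must be one of ", paste(MODEL_TYPES, collapse = ", "))
  }
  structure(list(model_name = model_name, model_type = model_type,
                 times_used = times_used, rules = rules),
            class = "crop_ruleset")
}

#' @export
print.crop_ruleset <- function(x, ...) {
  cat(sprintf("<crop_ruleset '%s' (%s): %d rules over %s>\n",
              x$model_name, x$model_type, length(x$rules),
              paste(x$times_used, collapse = ",")))
  invisible(x)
}

#' Convert a grown tree to an SQL rule set
#'
#' Emits one rule per terminal node: the conjunction of the split
#' conditions on the root-to-leaf path, with repeated bounds on the same
#' variable collapsed to the tightest interval (a lower `>` bound and/or
#' an upper `<=` bound per variable).  The leaf's class and within-node
#' frequency become the rule's class and probability.  Because the leaves
#' of one tree partition the feature space, the rules are mutually
#' exclusive and exhaustive.
#'
#' @param tree a `crop_tree`.
#' @param model_name short identifier written to the rule file header.
#' @param model_type one of `"NonVeg-Veg"`, `"CropSys"`, `"Crop"`.
#' @param times_used acquisition time tags the training matrix was built
#'   from; a rule set only applies to features extracted at these times.
#' @return an object of class `crop_ruleset`.
#' @export
tree_to_rules <- function(tree, model_name = "model",
                          model_type = "Crop",
                          times_used = NULL) {
  stopifnot(inherits(tree, "crop_tree"))
  if (is.null(times_used)) {
    times_used <- unique(sub("^(T[0-9]+).*$", "\\1", tree$var_names))
  }
  rules <- list()
  walk <- function(id, lower, upper) {
    nd <- tree$nodes[[id]]
    if (is.null(nd$split)) {
      preds <- list()
      for (v in tree$var_names) {
        if (!is.null(lower[[v]])) {
          preds[[length(preds) + 1]] <- list(variable = v, op = ">",
                                             threshold = lower[[v]])
        }
        if (!is.null(upper[[v]])) {
          preds[[length(preds) + 1]] <- list(variable = v, op = "<=",
                                             threshold = upper[[v]])
        }
      }
      rules[[length(rules) + 1]] <<- list(
        predicates = preds, class_label = nd$terminal_class,
        probability = nd$probability, node_id = nd$id)
      return(invisible())
    }
    v <- nd$split$variable; t <- nd$split$threshold
    ul <- upper; ul[[v]] <- min(t, ul[[v]] %||% Inf)
    walk(nd$left, lower, ul)
    ll <- lower; ll[[v]] <- max(t, ll[[v]] %||% -Inf)
    walk(nd$right, ll, upper)
  }
  walk(1L, list(), list())
  new_ruleset(model_name, model_type, times_used, rules)
}

format_rule <- function(rule) {
  conj <- if (!length(rule$predicates)) "TRUE" else {
    paste(vapply(rule$predicates, function(p) {
      paste(p$variable, p$op, num17(p$threshold))
    }, character(1)), collapse = " AND ")
  }
  sprintf("WHEN %s THEN '%s' PROB %s", conj, rule$class_label,
          num17(rule$probability))
}

#' Write a rule set as an `.sqlmodel` file
#'
#' Writes the text dialect described in the package overview plus a JSON
#' sidecar `<path>.json`.  The write -> [parse_sql()] round trip
#' reproduces the rule set exactly.
#'
#' @param ruleset a `crop_ruleset`.
#' @param path output file (conventionally `*.sqlmodel`).
#' @return `path`, invisibly.
#' @export
write_sql <- function(ruleset, path) {
  stopifnot(inherits(ruleset, "crop_ruleset"))
  lines <- c("-- cropclassr sql model",
             paste0("-- model_name: ", ruleset$model_name),
             paste0("-- model_type: ", ruleset$model_type),
             paste0("-- times_used: ", paste(ruleset$times_used, collapse = ",")),
             vapply(ruleset$rules, format_rule, character(1)))
  writeLines(lines, path, useBytes = TRUE)
  jsonlite::write_json(
    list(model_name = ruleset$model_name, model_type = ruleset$model_type,
         times_used = ruleset$times_used,
         rules = lapply(ruleset$rules, function(r) {
           list(predicates = r$predicates, class_label = r$class_label,
                probability = r$probability)
         })),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Parse an `.sqlmodel` file
#'
#' Accepts `WHEN` or `WHERE` clauses, `<=` / `>` operators joined by
#' `AND`, and the literal `TRUE` for an unconditional rule.  Variable
#' tokens must name a band or index at an acquisition time
#' (`T<k><Blue|Gree|Red|NIR|NDVI|Stu|BG>`; aliases `Green`, `STU`, `B/G`
#' are canonicalized).
#'
#' @param path an `.sqlmodel` file.
#' @return a `crop_ruleset`.
#' @export
parse_sql <- function(path) {
  if (!file.exists(path)) stop("rule file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  header <- function(key) {
    pat <- paste0("^--\\s*", key, ":\\s*(.*)\\s*$")
    hit <- grep(pat, lines, value = TRUE)
    if (!length(hit)) stop("missing '-- ", key, ":' header in '", path, "'")
    sub(pat, "\\1", hit[1])
  }
  model_name <- header("model_name")
  model_type <- header("model_type")
  times_used <- strsplit(header("times_used"), ",\\s*")[[1]]
  body <- grep("^\\s*(--.*)?$", lines, invert = TRUE, value = TRUE)
  rules <- list()
  for (li in seq_along(body)) {
    line <- trimws(body[li])
    m <- regexec("^(?:WHEN|WHERE)\\s+(.*?)\\s+THEN\\s+'([^']+)'\\s+PROB\\s+([0-9.eE+-]+)\\s*$",
                 line)
    g <- regmatches(line, m)[[1]]
    if (!length(g)) {
      stop("syntax error at rule line ", li, " in '", path, "': ", line)
    }
    conj <- g[2]; cls <- g[3]; prob <- as.numeric(g[4])
    if (is.na(prob) || prob <= 0 || prob > 1) {
      stop("invalid probability at rule line ", li, " in '", path, "'")
    }
    preds <- list()
    if (toupper(conj) != "TRUE") {
      terms <- strsplit(conj, "\\s+AND\\s+")[[1]]
      for (term in terms) {
        tm <- regmatches(term, regexec("^(\\S+)\\s*(<=|>)\\s*([0-9.eE+-]+)$", term))[[1]]
        if (!length(tm)) {
          stop("syntax error in predicate '", term, "' at rule line ", li,
               " in '", path, "'")
        }
        var <- tm[2]
        if (!grepl(VAR_PATTERN, var)) {
          stop("unknown variable name '", var, "' at rule line ", li,
               " in '", path, "'")
        }
        var <- paste0(sub("^(T[0-9]+).*$", "\\1", var),
                      canonicalize_var(sub("^T[0-9]+", "", var)))
        thr <- as.numeric(tm[4])
        if (is.na(thr)) {
          stop("non-numeric threshold in '", term, "' at rule line ", li,
               " in '", path, "'")
        }
        preds[[length(preds) + 1]] <- list(variable = var, op = tm[3],
                                           threshold = thr)
      }
    }
    rules[[length(rules) + 1]] <- list(predicates = preds, class_label = cls,
                                       probability = prob)
  }
  # consistency: each variable's interval must be non-empty
  for (i in seq_along(rules)) {
    lo <- list(); hi <- list()
    for (p in rules[[i]]$predicates) {
      if (p$op == ">") lo[[p$variable]] <- max(p$threshold, lo[[p$variable]] %||% -Inf)
      else hi[[p$variable]] <- min(p$threshold, hi[[p$variable]] %||% Inf)
    }
    for (v in names(lo)) {
      if (!is.null(hi[[v]]) && lo[[v]] >= hi[[v]]) {
        stop("inconsistent predicates on '", v, "' in rule ", i,
             " of '", path, "' (empty interval)")
      }
    }
  }
  if (sum(vapply(rules, function(r) length(r$predicates) == 0, logical(1))) > 1) {
    stop("multiple always-true rules in '", path, "' (overlapping rules)")
  }
  new_ruleset(model_name, model_type, times_used, rules)
}

rule_matches <- function(rule, feats) {
  for (p in rule$predicates) {
    val <- feats[[p$variable]]
    if (is.null(val) || is.na(val)) {
      stop("record lacks variable '", p$variable, "' referenced by a rule")
    }
    ok <- if (p$op == "<=") val <= p$threshold else val > p$threshold
    if (!ok) return(FALSE)
  }
  TRUE
}

#' Classify feature records with SQL rule models
#'
#' Phase-II application: every record is evaluated independently against
#' each rule set; the (by mutual exclusivity unique) matching rule
#' supplies the predicted class and its probability.  Each rule set must
#' have been trained on acquisition times available in the records.
#'
#' @param rulesets a `crop_ruleset` or list of them.
#' @param records list of `sbvi_record`s (see [extract_sbvi()]) or a
#'   `cropclass_matrix` / data frame of feature rows with a `parcel_id`
#'   column.
#' @return data frame in input order: `parcel`, then for each rule set a
#'   `<model_name>_class` and `<model_name>_prob` column.  A record
#'   matching no rule raises an error (a rule file from one tree always
#'   partitions the feature space, so this indicates corruption).
#' @export
classify <- function(rulesets, records) {
  if (inherits(rulesets, "crop_ruleset")) rulesets <- list(rulesets)
  if (is.data.frame(records)) {
    ids <- if ("parcel_id" %in% names(records)) records$parcel_id
           else rownames(records)
    featlist <- lapply(seq_len(nrow(records)), function(i) {
      as.list(records[i, setdiff(names(records), c("parcel_id", "land_use")),
                      drop = FALSE])
    })
    have_times <- attr(records, "times")
  } else {
    ids <- vapply(records, function(r) attr(r, "parcel_id"), character(1))
    featlist <- lapply(records, function(r) as.list(sbvi_features(r)))
    have_times <- if (length(records)) records[[1]]$time else character()
  }
  if (!is.null(have_times) && length(featlist)) {
    for (rs in rulesets) {
      miss <- setdiff(rs$times_used, have_times)
      if (length(miss)) {
        stop("rule set '", rs$model_name, "' was trained on times ",
             paste(rs$times_used, collapse = ","),
             " but the records only cover ",
             paste(have_times, collapse = ","),
             "; models only apply to matrices built from the same times")
      }
    }
  }
  out <- data.frame(parcel = ids, stringsAsFactors = FALSE)
  for (rs in rulesets) {
    cls <- character(length(featlist)); prb <- numeric(length(featlist))
    for (i in seq_along(featlist)) {
      hit <- NULL
      for (rule in rs$rules) {
        if (rule_matches(rule, featlist[[i]])) { hit <- rule; break }
      }
      if (is.null(hit)) {
        stop("record '", ids[i], "' matches no rule of model '",
             rs$model_name, "' (corrupted rule file?)")
      }
      cls[i] <- hit$class_label; prb[i] <- hit$probability
    }
    out[[paste0(rs$model_name, "_class")]] <- cls
    out[[paste0(rs$model_name, "_prob")]] <- prb
  }
  out
}

#' Write a classification output table
#'
#' Tab-delimited table mirroring the phase-II output layout: parcel name,
#' then predicted class and probability per applied model.
#'
#' @param output data frame from [classify()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_classification <- function(output, path) {
  tab <- output
  for (v in names(tab)) if (is.numeric(tab[[v]])) tab[[v]] <- num17(tab[[v]])
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
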