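# Land-use label hierarchy: crop -> cropping system -> Veg/NonVeg.

#' Default label hierarchy
#'
#' The crop codes and their agronomic groupings used throughout the
#' package: adult tree orchards (ATO: CIT, MFO, OLV, POP), summer crops
#' (SUC: COT, CRN, POT, SUN), winter crops (WIC: BNS, CKP, OAT, WHT),
#' young tree orchards (YTO) and the non-vegetative land uses civil works
#' (CIV) and water surfaces (WAT).
#'
#' @return an object of class `label_hierarchy`: a data frame with columns
#'   `crop`, `system`, `veg`.
#' @export
default_hierarchy <- function() {
  h <- data.frame(
    crop = c("CIT", "MFO", "OLV", "POP",
             "COT", "CRN", "POT", "SUN",
             "BNS", "CKP", "OAT", "WHT",
             "YTO", "CIV", "WAT"),
    system = c(rep("ATO", 4), rep("SUC", 4), rep("WIC", 4),
               "YTO", "CiWo", "WTS"),
    veg = c(rep("Veg", 13), "NonVeg", "NonVeg"),
    stringsAsFactors = FALSE
  )
  label_hierarchy(h)
}

#' Construct a label hierarchy
#'
#' @param mapping data frame with character columns `crop`, `system`,
#'   `veg`; every crop maps to exactly one system and every system to
#'   exactly one of `Veg`/`NonVeg`.
#' @return an object of class `label_hierarchy`.
#' @export
label_hierarchy <- function(mapping) {
  stopifnot(is.data.frame(mapping),
            all(c("crop", "system", "veg") %in% names(mapping)))
  mapping <- mapping[c("crop", "system", "veg")]
  for (cl in names(mapping)) mapping[[cl]] <- as.character(mapping[[cl]])
  if (anyDuplicated(mapping$crop)) {
    stop("crop(s) mapped more than once: ",
         paste(unique(mapping$crop[duplicated(mapping$crop)]), collapse = ", "))
  }
  if (!all(mapping$veg %in% c("Veg", "NonVeg"))) {
    stop("veg column must be 'Veg' or 'NonVeg'")
  }
  amb <- tapply(mapping$veg, mapping$system, function(v) length(unique(v)))
  if (any(amb > 1)) {
    stop("system(s) mapped to both Veg and NonVeg: ",
         paste(names(amb)[amb > 1], collapse = ", "))
  }
  structure(mapping, class = c("label_hierarchy", "data.frame"))
}

#' Read a label hierarchy from a TSV file
#'
#' Expects a header `crop<TAB>system<TAB>veg`.
#'
#' @param path tab-delimited file.
#' @return a [label_hierarchy()].
#' @export
read_hierarchy <- function(path) {
  label_hierarchy(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Map crop labels to a coarser hierarchy level
#'
#' @param labels character vector of crop codes.
#' @param hierarchy a [label_hierarchy()] (default [default_hierarchy()]).
#' @param level `"crop"` (identity, validated), `"system"` or `"veg"`.
#' @return character vector of mapped labels; `NA` inputs pass through.
#' @export
relabel <- function(labels, hierarchy = default_hierarchy(),
                    level = c("crop", "system", "veg")) {
  level <- match.arg(level)
  known <- !is.na(labels)
  unknown <- setdiff(unique(labels[known]), hierarchy$crop)
  if (length(unknown)) {
    stop("label(s) outside the hierarchy: ", paste(unknown, collapse = ", "))
  }
  if (level == "crop") return(labels)
  out <- labels
  idx <- match(labels[known], hierarchy$crop)
  out[known] <- hierarchy[[level]][idx]
  out
}
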