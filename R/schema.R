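#' Attribute schema of a CTG feature table
#'
#' The 22 cardiotocography attributes extracted by SisPorto-style processing
#' of fetal heart rate (FHR) and uterine contraction (UC) tracings, in their
#' canonical column order, plus a short description of each. The class label
#' column `NSP` (1 = normal, 2 = suspect, 3 = pathologic) is not part of the
#' schema; it is carried separately as the `nsp` column of a CTG table.
#'
#' @return A tibble with columns `index` (1..22), `name`, and `description`.
#' @examples
#' ctg_attributes()
#' @export
ctg_attributes <- function() {
  tibble::tibble(
    index = 1:22,
    name = c(
      "LB", "AC", "FM", "UC", "ASTV", "mSTV", "ALTV", "mLTV",
      "DL", "DS", "DP", "DR", "Width", "Min", "Max", "Nmax",
      "Nzeros", "Mode", "Mean", "Median", "Variance", "Tendency"
    ),
    description = c(
      "FHR baseline (bpm)",
      "Accelerations (count)",
      "Fetal movements (count)",
      "Uterine contractions (count)",
      "Percent time with abnormal short-term variability",
      "Mean short-term variability",
      "Percent time with abnormal long-term variability",
      "Mean long-term variability",
      "Light decelerations (count)",
      "Severe decelerations (count)",
      "Prolonged decelerations (count)",
      "Repetitive decelerations (count)",
      "FHR histogram width",
      "FHR histogram minimum",
      "FHR histogram maximum",
      "Number of histogram peaks",
      "Number of histogram zeros",
      "Histogram mode",
      "Histogram mean",
      "Histogram median",
      "Histogram variance",
      "Histogram tendency (-1 left-asymmetric, 0 symmetric, 1 right-asymmetric)"
    )
  )
}

#' Names of the NSP classes
#'
#' @param code Integer vector of NSP codes (1, 2, or 3).
#' @return Character vector of class names.
#' @examples
#' nsp_class_name(c(1, 2, 3))
#' @export
nsp_class_name <- function(code) {
  c("normal", "suspect", "pathologic")[code]
}

# Resolve attribute references given as indices or names to integer indices.
# Errors on anything outside the schema.
resolve_attributes <- function(x) {
  schema <- ctg_attributes()
  if (is.numeric(x)) {
    idx <- as.integer(x)
    bad <- setdiff(idx, schema$index)
    if (length(bad) > 0) {
      stop("unknown attribute index: ", paste(bad, collapse = ", "), call. = FALSE)
    }
    return(idx)
  }
  pos <- match(tolower(x), tolower(schema$name))
  if (anyNA(pos)) {
    stop("unknown attribute name: ", paste(x[is.na(pos)], collapse = ", "),
         call. = FALSE)
  }
  schema$index[pos]
}
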