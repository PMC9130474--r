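#' Read a CTG feature table from a delimited file
#'
#' Reads a CSV (comma- or semicolon-delimited, autodetected) holding the
#' 22-attribute CTG schema plus the `NSP` label column. Columns are matched
#' by name, case-insensitively and in any order; the returned table always
#' uses the canonical schema order of [ctg_attributes()] with the label in a
#' final `nsp` column. Rows containing unparseable or missing values are
#' dropped with a warning giving their count.
#'
#' The public UCI Cardiotocography export (2,126 records) ships as a
#' spreadsheet; export its "Raw Data" sheet to CSV to use it here.
#'
#' @param path Path to the delimited file. A header row is required.
#' @param delim Field delimiter; `NULL` (default) autodetects `","` vs `";"`.
#' @return A validated CTG table: a tibble with the 22 feature columns and an
#'   integer `nsp` column with values in {1, 2, 3}.
#' @seealso [validate_ctg_table()], [write_ctg_table()]
#' @examples
#' # a small synthetic example table shipped with the package
#' path <- system.file("extdata", "ctg_synthetic_example.csv",
#'                     package = "ctgfusion")
#' tab <- read_ctg_table(path)
#' validate_ctg_table(tab)
#' @export
read_ctg_table <- function(path, delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(delim)) {
    first <- readLines(path, n = 1L, warn = FALSE)
    delim <- if (lengths(regmatches(first, gregexpr(";", first))) >
                 lengths(regmatches(first, gregexpr(",", first)))) ";" else ","
  }
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE, trim_ws = TRUE)
  as_ctg_table(raw)
}

#' Coerce a data frame to a validated CTG table
#'
#' @param x A data frame with the 22 CTG attribute columns (any order,
#'   case-insensitive names) and an `NSP`/`nsp` label column.
#' @return A tibble in canonical column order; see [read_ctg_table()].
#' @export
as_ctg_table <- function(x) {
  schema <- ctg_attributes()
  nm <- tolower(names(x))
  missing_cols <- schema$name[!tolower(schema$name) %in% nm]
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!"nsp" %in% nm) stop("missing required column(s): NSP", call. = FALSE)

  out <- x[match(tolower(c(schema$name, "NSP")), nm)]
  names(out) <- c(schema$name, "nsp")
  out <- tibble::as_tibble(lapply(out, function(col) {
    if (is.character(col)) suppressWarnings(as.numeric(col)) else as.numeric(col)
  }))

  bad_label <- !is.na(out$nsp) & !out$nsp %in% c(1, 2, 3)
  if (any(bad_label)) {
    stop("label outside {1,2,3} at row(s): ",
         paste(utils::head(which(bad_label), 5), collapse = ", "),
         call. = FALSE)
  }
  incomplete <- !stats::complete.cases(out) |
    !apply(is.finite(as.matrix(out)), 1, all)
  if (any(incomplete)) {
    warning(sum(incomplete), " row(s) with unparseable or missing values rejected",
            call. = FALSE)
    out <- out[!incomplete, , drop = FALSE]
  }
  out$nsp <- as.integer(out$nsp)
  out
}

#' Validate a CTG table and report findings
#'
#' Pure reporting: flags constant columns, duplicated rows, and tallies the
#' label distribution. Never modifies the table; repeated calls on the same
#' table return identical findings.
#'
#' @param table A CTG table as returned by [read_ctg_table()].
#' @return A tibble of findings with columns `finding` and `detail`.
#' @export
validate_ctg_table <- function(table) {
  findings <- list()
  if (nrow(table) == 0) {
    return(tibble::tibble(finding = "no records", detail = ""))
  }
  feats <- ctg_feature_names(table)
  for (f in feats) {
    v <- table[[f]]
    if (length(unique(v)) == 1L) {
      findings[[length(findings) + 1L]] <-
        tibble::tibble(finding = "constant column", detail = f)
    }
  }
  ndup <- sum(duplicated(table))
  if (ndup > 0) {
    findings[[length(findings) + 1L]] <-
      tibble::tibble(finding = "duplicate rows", detail = as.character(ndup))
  }
  counts <- table(factor(table$nsp, levels = 1:3))
  findings[[length(findings) + 1L]] <- tibble::tibble(
    finding = "label counts",
    detail = paste(sprintf("%s:%d", names(counts), as.integer(counts)),
                   collapse = " ")
  )
  dplyr::bind_rows(findings)
}

#' Write a CTG table to CSV
#'
#' @param table A CTG table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ctg_table <- function(table, path) {
  readr::write_csv(dplyr::rename(table, NSP = "nsp"), path, progress = FALSE)
  invisible(path)
}

# Feature column names of a CTG table (everything except the label).
ctg_feature_names <- function(table) setdiff(names(table), "nsp")

#' Construct a feature subset
#'
#' A feature subset is a set of attribute indices (1..22) together with a
#' provenance tag recording which stage produced it.
#'
#' @param attributes Attribute indices or names.
#' @param provenance One of `"prefilter"`, `"apriori_health"`,
#'   `"apriori_suspect"`, `"apriori_pathologic"`, `"fused"`, `"manual"`.
#' @return An object of class `feature_subset`.
#' @examples
#' feature_subset(c("LB", "AC", "ASTV"), "manual")
#' @export
feature_subset <- function(attributes, provenance = "manual") {
  provenance <- match.arg(provenance, c("prefilter", "apriori_health",
                                        "apriori_suspect", "apriori_pathologic",
                                        "fused", "manual"))
  idx <- sort(unique(resolve_attributes(attributes)))
  if (provenance == "fused" && length(idx) == 0) {
    stop("a fused feature subset must be non-empty", call. = FALSE)
  }
  structure(list(attributes = idx, provenance = provenance),
            class = "feature_subset")
}

#' @export
print.feature_subset <- function(x, ...) {
  schema <- ctg_attributes()
  cat("<feature_subset> provenance:", x$provenance, "\n")
  if (length(x$attributes) == 0) {
    cat("  (empty)\n")
  } else {
    cat(" ", paste(sprintf("%d=%s", x$attributes,
                           schema$name[x$attributes]), collapse = " "), "\n")
  }
  invisible(x)
}

#' @export
format.feature_subset <- function(x, ...) {
  paste0(x$provenance, ": {", paste(x$attributes, collapse = ","), "}")
}

#' Names of the attributes in a feature subset
#'
#' @param subset A `feature_subset`.
#' @return Character vector of attribute names in schema order.
#' @export
subset_names <- function(subset) {
  ctg_attributes()$name[subset$attributes]
}

#' Write / read a feature subset as plain text
#'
#' One attribute per line as `index<TAB>name`; lines starting with `#` are
#' comments. The provenance is stored in a `# provenance:` header comment.
#' `read_feature_subset(write_feature_subset(s))` is the identity.
#'
#' @param subset A `feature_subset`.
#' @param path File path.
#' @return `write_feature_subset()` returns `path` invisibly;
#'   `read_feature_subset()` returns a `feature_subset`.
#' @export
write_feature_subset <- function(subset, path) {
  schema <- ctg_attributes()
  lines <- c(
    paste0("# provenance: ", subset$provenance),
    sprintf("%d\t%s", subset$attributes, schema$name[subset$attributes])
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_feature_subset
#' @export
read_feature_subset <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  prov_line <- grep("^#\\s*provenance:", lines, value = TRUE)
  provenance <- if (length(prov_line) > 0) {
    trimws(sub("^#\\s*provenance:", "", prov_line[1]))
  } else "manual"
  body <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(body) == 0) return(feature_subset(integer(0), provenance))
  idx <- suppressWarnings(as.integer(sub("\\s.*$", "", body)))
  if (anyNA(idx)) stop("malformed feature-subset file: ", path, call. = FALSE)
  feature_subset(idx, provenance)
}
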