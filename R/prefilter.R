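#' Equal-frequency discretization of a numeric vector
#'
#' Bins a vector at its empirical quantiles into at most `bins` levels.
#' Tied quantiles collapse, so heavily tied (e.g. zero-inflated) vectors get
#' fewer, wider bins; a constant vector collapses to a single bin. Bin
#' indices are zero-based.
#'
#' @param x Numeric vector.
#' @param bins Maximum number of bins (>= 2).
#' @return Integer vector of bin indices in `0..(k-1)`, `k <= bins`.
#' @export
equal_frequency_bin <- function(x, bins = 10) {
  stopifnot(bins >= 2, is.numeric(x))
  breaks <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1),
                                   names = FALSE, type = 7))
  if (length(breaks) < 2) return(rep(0L, length(x)))
  as.integer(cut(x, breaks = breaks, include.lowest = TRUE, labels = FALSE)) - 1L
}

#' Kruskal-Wallis screen of every attribute against the class label
#'
#' Per-attribute Kruskal-Wallis rank test of the feature across the NSP
#' classes. Attributes whose p-value reaches `alpha_remove` are marked for
#' removal; a constant attribute carries no rank information, its p-value is
#' reported as 1 and it is always removed. The default `alpha_remove` of
#' 0.999 captures exactly the "p = 1" case (constant or class-independent by
#' rank), which removes the identically-zero repetitive-deceleration column
#' (DR) of the public dataset.
#'
#' @param table A CTG table with at least two classes present.
#' @param alpha_remove Remove attributes with `p >= alpha_remove`.
#' @param method `"kruskal"` (default) for the Kruskal-Wallis rank test, or
#'   `"chisq"` for a chi-squared test of equal-frequency-binned counts
#'   against the label. Both give p = 1 on constant columns.
#' @param bins Bins for the `"chisq"` variant.
#' @return A tibble with columns `index`, `name`, `statistic`, `p_value`,
#'   `removed`.
#' @export
rank_screen <- function(table, alpha_remove = 0.999,
                        method = c("kruskal", "chisq"), bins = 10) {
  method <- match.arg(method)
  if (length(unique(table$nsp)) < 2) {
    stop("rank screen needs at least two classes present", call. = FALSE)
  }
  g <- factor(table$nsp)
  schema <- ctg_attributes()
  res <- purrr::map_dfr(schema$index, function(i) {
    x <- table[[schema$name[i]]]
    if (length(unique(x)) == 1L) {
      tibble::tibble(index = i, name = schema$name[i],
                     statistic = 0, p_value = 1)
    } else if (method == "kruskal") {
      kw <- stats::kruskal.test(x, g)
      tibble::tibble(index = i, name = schema$name[i],
                     statistic = unname(kw$statistic),
                     p_value = unname(kw$p.value))
    } else {
      ct <- suppressWarnings(
        stats::chisq.test(table(equal_frequency_bin(x, bins), g)))
      tibble::tibble(index = i, name = schema$name[i],
                     statistic = unname(ct$statistic),
                     p_value = unname(ct$p.value))
    }
  })
  res$removed <- res$p_value >= alpha_remove
  res
}

#' Plug-in mutual information between a feature and the class label
#'
#' The feature is discretized by equal-frequency binning; the mutual
#' information of the binned feature and the label is the plug-in estimate
#' \eqn{\sum_{x,y} \hat p(x,y) \log[\hat p(x,y) / (\hat p(x)\hat p(y))]},
#' non-negative and symmetric in its two discrete arguments.
#'
#' @param feature Numeric vector.
#' @param labels Vector of class labels, same length.
#' @param bins Maximum number of equal-frequency bins (default 10).
#' @param base Logarithm base; `exp(1)` (nats) by default.
#' @return Mutual information (non-negative scalar).
#' @export
mutual_information <- function(feature, labels, bins = 10, base = exp(1)) {
  if (length(feature) != length(labels)) {
    stop("feature and labels must have equal length", call. = FALSE)
  }
  discrete_mi(equal_frequency_bin(feature, bins), labels, base = base)
}

# MI of two discrete vectors from their joint contingency table.
discrete_mi <- function(x, y, base = exp(1)) {
  joint <- table(x, y) / length(x)
  px <- rowSums(joint); py <- colSums(joint)
  terms <- joint * log(joint / outer(px, py))
  max(0, sum(terms[joint > 0]) / log(base))
}

#' Mutual-information filter
#'
#' Scores every attribute by [mutual_information()] against the label and
#' removes those below `threshold`. At the default threshold of 0.01 this
#' eliminates attributes carrying essentially no label information (on the
#' public dataset: the constant DS column and the weakly-informative Nzeros).
#' The filter is idempotent: re-filtering its own output removes nothing.
#'
#' @param table A CTG table.
#' @param threshold Minimum MI to retain (>= 0); default 0.01.
#' @param bins,base Passed to [mutual_information()].
#' @return A list with `subset` (a `feature_subset`, provenance
#'   `"prefilter"`) and `report` (tibble: `index`, `name`, `mi`, `removed`).
#' @export
mi_filter <- function(table, threshold = 0.01, bins = 10, base = exp(1)) {
  stopifnot(threshold >= 0)
  schema <- ctg_attributes()
  mi <- vapply(schema$name, function(nm) {
    mutual_information(table[[nm]], table$nsp, bins = bins, base = base)
  }, numeric(1))
  report <- tibble::tibble(index = schema$index, name = schema$name,
                           mi = unname(mi), removed = unname(mi) < threshold)
  list(subset = feature_subset(report$index[!report$removed], "prefilter"),
       report = report)
}

#' Combined feature screen
#'
#' Applies the rank screen and the mutual-information filter and retains the
#' attributes surviving both, reporting every per-attribute statistic.
#'
#' @inheritParams rank_screen
#' @inheritParams mi_filter
#' @return A list with `subset` (provenance `"prefilter"`) and `report`
#'   (tibble: `index`, `name`, `statistic`, `p_value`, `mi`,
#'   `removed_by_screen`, `removed_by_mi`, `retained`).
#' @export
screen_features <- function(table, alpha_remove = 0.999, threshold = 0.01,
                            bins = 10, base = exp(1)) {
  rs <- rank_screen(table, alpha_remove)
  mf <- mi_filter(table, threshold, bins, base)
  report <- dplyr::select(rs, "index", "name", "statistic", "p_value") |>
    dplyr::mutate(mi = mf$report$mi,
                  removed_by_screen = rs$removed,
                  removed_by_mi = mf$report$removed,
                  retained = !rs$removed & !mf$report$removed)
  list(subset = feature_subset(report$index[report$retained], "prefilter"),
       report = report)
}
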