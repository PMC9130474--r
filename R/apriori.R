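#' Encode a CTG table as transactions of (attribute, bin) items
#'
#' Each retained attribute is discretized by equal-frequency binning into at
#' most `bins` levels (tied quantiles collapse, so zero-inflated attributes
#' get fewer levels); each record then becomes the set of its
#' (attribute, bin) items — exactly one item per retained attribute.
#'
#' @param table A CTG table with at least one record.
#' @param subset A `feature_subset` of attributes to encode (non-empty).
#' @param bins Maximum bins per attribute (default 4).
#' @return An object of class `transaction_set`: a list with `mat` (n x m
#'   logical incidence matrix, one column per item), `items` (tibble: `item`
#'   column id, `attribute`, `bin`, `label`), and `n` (number of
#'   transactions).
#' @export
encode_transactions <- function(table, subset, bins = 4) {
  stopifnot(inherits(subset, "feature_subset"), bins >= 2)
  if (nrow(table) == 0) stop("cannot encode an empty table", call. = FALSE)
  if (length(subset$attributes) == 0) {
    stop("cannot encode an empty feature subset", call. = FALSE)
  }
  schema <- ctg_attributes()
  n <- nrow(table)
  cols <- list(); meta <- list()
  for (a in subset$attributes) {
    b <- equal_frequency_bin(table[[schema$name[a]]], bins)
    for (lev in sort(unique(b))) {
      cols[[length(cols) + 1L]] <- b == lev
      meta[[length(meta) + 1L]] <- tibble::tibble(
        attribute = a, bin = lev,
        label = sprintf("%s:%d", schema$name[a], lev))
    }
  }
  mat <- do.call(cbind, cols)
  items <- dplyr::bind_rows(meta)
  items$item <- seq_len(nrow(items))
  structure(list(mat = mat, items = items[c("item", "attribute", "bin", "label")],
                 n = n),
            class = "transaction_set")
}

#' @export
print.transaction_set <- function(x, ...) {
  cat("<transaction_set>", x$n, "transactions,", nrow(x$items), "items over",
      length(unique(x$items$attribute)), "attributes\n")
  invisible(x)
}

#' Support of an itemset
#'
#' The fraction of transactions containing every item of the itemset:
#' `number(X)/num(AllSamples)`. The empty itemset has support 1 (vacuous
#' containment).
#'
#' @param itemset Integer vector of item ids (columns of the transaction
#'   set).
#' @param transactions A `transaction_set`.
#' @return Support in `[0, 1]`.
#' @export
itemset_support <- function(itemset, transactions) {
  stopifnot(inherits(transactions, "transaction_set"), transactions$n > 0)
  if (length(itemset) == 0) return(1)
  m <- transactions$mat[, itemset, drop = FALSE]
  sum(rowSums(m) == length(itemset)) / transactions$n
}

#' Level-wise Apriori frequent-itemset mining
#'
#' Finds exactly the non-empty itemsets with support >= `minsupport` by
#' level-wise candidate generation with the downward-closure prune: a
#' candidate of size k is counted only if all of its (k-1)-subsets were
#' frequent, which is sound because support is anti-monotone (every subset
#' of a frequent itemset is frequent).
#'
#' @param transactions A `transaction_set`.
#' @param minsupport Support threshold in `(0, 1]`.
#' @return An object of class `frequent_itemsets`: a tibble with columns
#'   `items` (list of integer item-id vectors), `itemset` (human-readable
#'   `;`-joined labels), `size`, `support`; attributes `minsupport` and
#'   `class_label`.
#' @export
apriori <- function(transactions, minsupport) {
  stopifnot(inherits(transactions, "transaction_set"))
  if (!is.numeric(minsupport) || minsupport <= 0) {
    stop("minsupport must be positive (a threshold of 0 would admit items ",
         "absent from every transaction)", call. = FALSE)
  }
  mat <- transactions$mat
  n <- transactions$n

  out_items <- list(); out_support <- numeric(0)

  sup1 <- colSums(mat) / n
  frequent <- lapply(which(sup1 >= minsupport), function(i) i)
  supports <- sup1[sup1 >= minsupport]
  out_items <- c(out_items, frequent)
  out_support <- c(out_support, supports)

  prev <- frequent
  while (length(prev) > 1) {
    prev_key <- vapply(prev, paste, "", collapse = ",")
    cands <- generate_candidates(prev, prev_key)
    if (length(cands) == 0) break
    sup <- vapply(cands, function(s) {
      sum(rowSums(mat[, s, drop = FALSE]) == length(s)) / n
    }, numeric(1))
    keep <- sup >= minsupport
    if (!any(keep)) break
    prev <- cands[keep]
    out_items <- c(out_items, prev)
    out_support <- c(out_support, sup[keep])
  }

  res <- tibble::tibble(
    items = out_items,
    itemset = vapply(out_items, function(s) {
      paste(transactions$items$label[s], collapse = ";")
    }, ""),
    size = lengths(out_items),
    support = out_support
  )
  res <- res[order(res$size, -res$support, res$itemset), ]
  structure(res, class = c("frequent_itemsets", class(tibble::tibble()))) |>
    `attr<-`("minsupport", minsupport) |>
    `attr<-`("items_meta", transactions$items)
}

# Join step + downward-closure prune. `prev` is the list of frequent
# (k-1)-itemsets as sorted integer vectors; candidates of size k are unions
# of two members sharing their first k-2 items, kept only if every
# (k-1)-subset is in `prev`.
generate_candidates <- function(prev, prev_key) {
  k1 <- length(prev[[1]])
  prefix <- vapply(prev, function(s) paste(s[-k1], collapse = ","), "")
  cands <- list()
  for (grp in split(seq_along(prev), prefix)) {
    if (length(grp) < 2) next
    last <- vapply(grp, function(i) as.numeric(prev[[i]][k1]), numeric(1))
    ord <- grp[order(last)]
    for (a in seq_len(length(ord) - 1)) {
      for (b in seq(a + 1, length(ord))) {
        cand <- c(prev[[ord[a]]], prev[[ord[b]]][k1])
        ok <- TRUE
        for (drop in seq_len(k1 + 1)) {
          if (!paste(cand[-drop], collapse = ",") %in% prev_key) {
            ok <- FALSE
            break
          }
        }
        if (ok) cands[[length(cands) + 1L]] <- cand
      }
    }
  }
  cands
}

#' Frequent attribute columns of one class
#'
#' Restricts the table to records of `class_label`, encodes them as
#' transactions, mines frequent itemsets, and returns the attributes that
#' participate in frequent itemsets of size >= `min_size` (default 2:
#' attributes that co-occur frequently with another attribute's bin, i.e.
#' association rather than mere marginal frequency).
#'
#' @param table A CTG table containing records of `class_label`.
#' @param class_label NSP code (1, 2 or 3).
#' @param minsupport Support threshold in `(0, 1]`.
#' @param bins Bins per attribute for encoding (default 4).
#' @param subset Attributes to consider (default: all 22).
#' @param min_size Minimum itemset size for an attribute to count (default 2;
#'   1 reduces the criterion to marginal frequency).
#' @return A `feature_subset` with provenance `"apriori_<class>"`.
#' @export
class_frequent_attributes <- function(table, class_label, minsupport = 0.1,
                                      bins = 4,
                                      subset = feature_subset(1:22, "manual"),
                                      min_size = 2) {
  slice <- table[table$nsp == class_label, , drop = FALSE]
  if (nrow(slice) == 0) {
    stop("class ", class_label, " absent from table", call. = FALSE)
  }
  tset <- encode_transactions(slice, subset, bins)
  fi <- apriori(tset, minsupport)
  big <- fi$items[fi$size >= min_size]
  attrs <- sort(unique(tset$items$attribute[unlist(big)]))
  provenance <- switch(as.character(class_label),
                       "1" = "apriori_health",
                       "2" = "apriori_suspect",
                       "3" = "apriori_pathologic",
                       "manual")
  feature_subset(attrs, provenance)
}

#' Fuse per-class attribute sets
#'
#' The union of the attribute sets — the set calculation that merges the
#' per-class frequent attribute columns into the final feature set.
#' Commutative, associative, and idempotent.
#'
#' @param sets A list of `feature_subset` objects (at least one).
#' @return A `feature_subset` with provenance `"fused"`.
#' @examples
#' fuse_attribute_sets(list(
#'   feature_subset(c(3, 4, 6, 9, 19, 14, 5, 2), "manual"),
#'   feature_subset(c(2, 4, 6, 19, 14, 5, 2, 8, 18), "manual"),
#'   feature_subset(c(3, 4, 6, 9, 19, 14, 5, 2, 8, 18, 10, 12, 1), "manual")
#' ))
#' @export
fuse_attribute_sets <- function(sets) {
  stopifnot(length(sets) >= 1,
            all(vapply(sets, inherits, logical(1), "feature_subset")))
  feature_subset(sort(unique(unlist(lapply(sets, `[[`, "attributes")))),
                 "fused")
}

#' Sweep the minimum-support threshold
#'
#' Mines per-class frequent attributes at every grid value and reports the
#' attribute counts, which are non-increasing in minsupport because support
#' is anti-monotone. The selected threshold is the largest grid value at
#' which the pathologic attribute set contains the union of the health and
#' suspect sets (so restricting attention to the pathologic-frequent
#' attributes loses nothing from the other classes); if no grid value
#' satisfies containment, `selected` is `NA` and `selection_ok` is `FALSE`.
#'
#' @param table A CTG table with all three classes present.
#' @param grid Ascending minsupport values in `(0, 1]`.
#' @param bins,subset,min_size Passed to [class_frequent_attributes()].
#' @return An object of class `support_sweep`: a list with `counts` (tibble:
#'   `minsupport`, `class`, `n_attributes`), `sets` (per grid value, the
#'   three `feature_subset`s), `selected`, `selection_ok`.
#' @export
support_sweep <- function(table, grid = c(0.05, 0.08, 0.1, 0.15, 0.2, 0.3),
                          bins = 4, subset = feature_subset(1:22, "manual"),
                          min_size = 2) {
  if (length(grid) == 0) stop("empty minsupport grid", call. = FALSE)
  stopifnot(all(grid > 0), all(grid <= 1), !is.unsorted(grid))
  rows <- list(); sets <- list(); contained <- logical(length(grid))
  for (i in seq_along(grid)) {
    ms <- grid[i]
    cls_sets <- lapply(c(1L, 2L, 3L), function(cl) {
      class_frequent_attributes(table, cl, minsupport = ms, bins = bins,
                                subset = subset, min_size = min_size)
    })
    names(cls_sets) <- c("health", "suspect", "pathologic")
    sets[[as.character(ms)]] <- cls_sets
    rows[[i]] <- tibble::tibble(
      minsupport = ms,
      class = c("health", "suspect", "pathologic"),
      n_attributes = vapply(cls_sets, function(s) length(s$attributes),
                            integer(1))
    )
    other <- union(cls_sets$health$attributes, cls_sets$suspect$attributes)
    contained[i] <- all(other %in% cls_sets$pathologic$attributes) &&
      length(cls_sets$pathologic$attributes) > 0
  }
  selected <- if (any(contained)) max(grid[contained]) else NA_real_
  structure(list(counts = dplyr::bind_rows(rows), sets = sets,
                 selected = selected, selection_ok = !is.na(selected)),
            class = "support_sweep")
}

#' @export
print.support_sweep <- function(x, ...) {
  cat("<support_sweep>\n")
  print(tidyr::pivot_wider(x$counts, names_from = "class",
                           values_from = "n_attributes"))
  if (x$selection_ok) {
    cat("selected minsupport:", x$selected,
        "(largest value where the pathologic set contains the others)\n")
  } else {
    cat("selection failed: no grid value satisfies the containment criterion\n")
  }
  invisible(x)
}

#' Export frequent itemsets as a plain tibble
#'
#' @param x A `frequent_itemsets` object.
#' @param ... Unused.
#' @return A tibble with columns `itemset`, `size`, `support`.
#' @exportS3Method generics::tidy
tidy.frequent_itemsets <- function(x, ...) {
  tibble::tibble(itemset = x$itemset, size = x$size, support = x$support)
}
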