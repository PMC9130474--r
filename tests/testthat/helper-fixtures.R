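# Shared fixtures and independent oracles, all built in code.

# A CTG table from a features matrix (n x 22) and a label vector.
ctg_from_matrix <- function(X, nsp) {
  colnames(X) <- ctg_attributes()$name
  tab <- tibble::as_tibble(as.data.frame(X))
  tab$nsp <- as.integer(nsp)
  tab
}

# A small CTG table whose 22 columns are deterministic filler except the
# ones explicitly overridden; labels default to balanced 1/2/3.
toy_ctg <- function(n, overrides = list(), nsp = rep(1:3, length.out = n)) {
  X <- matrix(((seq_len(n * 22) * 7) %% 53) + seq_len(n * 22) / 1000, n, 22)
  tab <- ctg_from_matrix(X, nsp)
  for (nm in names(overrides)) tab[[nm]] <- overrides[[nm]]
  tab
}

# A transaction_set built directly from a logical incidence matrix, for
# miner tests that do not need the one-item-per-attribute encoding.
tset_from_matrix <- function(mat) {
  m <- ncol(mat)
  structure(list(
    mat = mat,
    items = tibble::tibble(item = seq_len(m), attribute = seq_len(m),
                           bin = 0L, label = paste0("i", seq_len(m))),
    n = nrow(mat)
  ), class = "transaction_set")
}

# Brute-force frequent-itemset oracle: enumerates the full power set of the
# item universe with bitmasks and filters by the support definition.
brute_force_itemsets <- function(tset, minsupport) {
  m <- ncol(tset$mat)
  stopifnot(m <= 16)
  tmask <- as.integer(tset$mat %*% (2^(seq_len(m) - 1)))
  smask <- seq_len(2^m - 1)
  sup <- vapply(smask, function(s) {
    mean(bitwAnd(tmask, s) == s)
  }, numeric(1))
  keep <- sup >= minsupport
  keys <- vapply(smask[keep], function(s) {
    paste(which(bitwAnd(s, 2^(seq_len(m) - 1)) > 0), collapse = ",")
  }, "")
  tibble::tibble(key = keys, support = sup[keep])
}

# Canonical key form of an apriori() result for oracle comparison.
apriori_keys <- function(fi) {
  tibble::tibble(
    key = vapply(fi$items, function(s) paste(sort(s), collapse = ","), ""),
    support = fi$support
  )
}

# Brute-force AUC: fraction of concordant positive-negative pairs, ties
# counting one half.
brute_force_auc <- function(scores, truth) {
  truth <- as.logical(truth)
  pos <- scores[truth]; neg <- scores[!truth]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Engineered table whose support sweep selects minsupport 0.1: attributes
# 1-2 share bin combinations in the pathologic slice at support 0.10-0.15
# (alive at 0.1, dead at 0.2), attributes 3-4 co-occur in the health slice
# at support 0.08 (alive at 0.08, dead at 0.1), and every other pairwise
# joint stays below the relevant thresholds.
sweep_fixture <- function() {
  pairs_from <- function(M) {
    out <- NULL
    for (a in 1:4) for (b in 1:4) if (M[a, b] > 0) {
      out <- rbind(out, matrix(rep(c(a, b), M[a, b]), ncol = 2, byrow = TRUE))
    }
    out
  }
  make_slice <- function(M_ab, M_cd, stride = 7) {
    ab <- pairs_from(M_ab); cd <- pairs_from(M_cd)
    n <- nrow(ab)
    ord <- (seq_len(n) * stride) %% n + 1
    cbind(ab, cd[ord, ])
  }
  Mp1 <- matrix(c(3,2,0,0, 0,3,2,0, 0,0,3,2, 2,0,0,3), 4, byrow = TRUE)
  Mp2 <- matrix(c(2,1,1,1, 1,2,1,1, 1,1,2,1, 1,1,1,2), 4, byrow = TRUE)
  Mh1 <- matrix(c(7,6,6,6, 6,7,6,6, 6,6,7,6, 6,6,6,7), 4, byrow = TRUE)
  Mh2 <- matrix(c(8,7,5,5, 5,8,7,5, 5,5,8,7, 7,5,5,8), 4, byrow = TRUE)
  four <- rbind(make_slice(Mh1, Mh2), make_slice(Mh1, Mh1),
                make_slice(Mp1, Mp2))
  n <- nrow(four)
  filler <- matrix(seq_len(n * 18) %% 97 + seq_len(n * 18) / 1000, n, 18)
  ctg_from_matrix(cbind(four, filler), rep(c(1L, 2L, 3L), c(100, 100, 20)))
}

# Small synthetic dataset for fast end-to-end tests.
syn_small <- function(seed = 7, n = c(150, 40, 30), ...) {
  generate_ctg(synthetic_ctg_spec(n_per_class = n, seed = seed, ...))
}
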