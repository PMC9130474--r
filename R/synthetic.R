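#' Specification of a synthetic CTG table
#'
#' Defines the generating distribution of a synthetic CTG dataset: per-class,
#' per-attribute Gaussian locations and scales, a set of informative
#' attributes whose locations separate the normal and pathologic classes, a
#' set of constant attributes (emulating DS/DR, which are identically zero in
#' the public CTG export), noise attributes identical in distribution across
#' classes, and a latent mixture for the suspect class: each suspect record
#' is drawn from the normal or pathologic generating distribution according
#' to `suspect_mixture_weight`, and that latent class is recorded as ground
#' truth. Count-like attributes are rounded and truncated at zero, which
#' reproduces the zero-inflation of the real features (and hence gives the
#' itemset miner high-support items to find).
#'
#' Defaults mimic the shape of the public dataset: 22 attributes, unbalanced
#' class counts (1655, 295, 176) totalling 2,126, constant DS and DR, and
#' informative attributes mirroring the fused attribute set that the feature
#' selection recovers on the real data.
#'
#' @param n_per_class Integer vector of record counts for classes 1, 2, 3.
#' @param separation Multiplier on the normal-vs-pathologic location
#'   differences of informative attributes; 1 gives strong (several-SD)
#'   separation, 0 makes every attribute uninformative.
#' @param informative_features Attributes with class-separated locations.
#' @param constant_features Attributes generated as a single constant value.
#' @param suspect_mixture_weight Probability that a suspect record's latent
#'   truth is normal (class 1); the complement is pathologic (class 3).
#' @param heavy_tails If `TRUE`, draws use a scaled t(3) instead of a
#'   Gaussian, keeping the same location/scale.
#' @param seed Integer seed; generation is a pure function of the spec.
#' @return An object of class `synthetic_ctg_spec`.
#' @seealso [generate_ctg()]
#' @export
synthetic_ctg_spec <- function(n_per_class = c(1655L, 295L, 176L),
                               separation = 1,
                               informative_features = c(1:6, 8, 9, 14, 18, 19),
                               constant_features = c(10, 12),
                               suspect_mixture_weight = 0.7,
                               heavy_tails = FALSE,
                               seed = 1L) {
  stopifnot(length(n_per_class) == 3, all(n_per_class >= 0),
            suspect_mixture_weight >= 0, suspect_mixture_weight <= 1,
            separation >= 0)
  informative_features <- resolve_attributes(informative_features)
  constant_features <- resolve_attributes(constant_features)
  if (length(intersect(informative_features, constant_features)) > 0) {
    stop("informative and constant feature sets must be disjoint", call. = FALSE)
  }

  # Per-attribute generating parameters. `normal` / `pathologic` are the class
  # locations (the pathologic shift is scaled by `separation` for informative
  # attributes and ignored otherwise); `sd` the common scale; `count` marks
  # attributes rounded and truncated at zero.
  params <- tibble::tibble(
    index      = 1:22,
    name       = ctg_attributes()$name,
    normal     = c(132, 4, 8, 5, 40, 1.6, 10, 9, 1, 0, 0.2, 0, 70, 100, 164,
                   4, 0.3, 140, 135, 138, 19, 0.3),
    pathologic = c(148, 0, 60, 1, 75, 0.4, 45, 3, 4, 0, 0.2, 0, 70, 60, 164,
                   4, 0.3, 110, 105, 138, 19, 0.3),
    sd         = c(10, 3, 15, 2.5, 13, 0.6, 16, 4, 1.5, 0, 0.5, 0, 35, 22, 18,
                   2.5, 0.7, 13, 13, 14, 25, 0.6),
    count      = c(FALSE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, TRUE,
                   FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, FALSE,
                   FALSE, FALSE, FALSE, FALSE)
  )
  mid <- (params$normal + params$pathologic) / 2
  inf <- params$index %in% informative_features
  params$mean1 <- ifelse(inf, mid + (params$normal - mid) * separation,
                         params$normal)
  params$mean3 <- ifelse(inf, mid + (params$pathologic - mid) * separation,
                         params$normal)
  const <- params$index %in% constant_features
  params$sd[const] <- 0
  params$mean1[const] <- params$normal[const]
  params$mean3[const] <- params$normal[const]

  structure(
    list(n_per_class = as.integer(n_per_class),
         separation = separation,
         informative_features = informative_features,
         constant_features = constant_features,
         noise_features = setdiff(1:22, c(informative_features,
                                          constant_features)),
         suspect_mixture_weight = suspect_mixture_weight,
         heavy_tails = heavy_tails,
         seed = as.integer(seed),
         params = params),
    class = "synthetic_ctg_spec"
  )
}

#' @export
print.synthetic_ctg_spec <- function(x, ...) {
  cat("<synthetic_ctg_spec>\n")
  cat("  n per class:", paste(x$n_per_class, collapse = "/"),
      " separation:", x$separation,
      " suspect mixture weight:", x$suspect_mixture_weight, "\n")
  cat("  informative:", paste(x$informative_features, collapse = ","), "\n")
  cat("  constant:", paste(x$constant_features, collapse = ","),
      " seed:", x$seed, "\n")
  invisible(x)
}

#' Generate a synthetic CTG table with latent suspect ground truth
#'
#' Draws a CTG table from a [synthetic_ctg_spec()]. Suspect records (label 2)
#' are drawn from the class-1 or class-3 generating distribution according to
#' the spec's mixture weight; which one is recorded in `latent_truth`. The
#' same spec (including its seed) always yields an identical table.
#'
#' @param spec A `synthetic_ctg_spec`.
#' @return An object of class `synthetic_ctg`: a list with `table` (a CTG
#'   table) and `latent_truth` (integer vector in {1, 3}, one entry per
#'   suspect record, in row order of the suspect records).
#' @export
generate_ctg <- function(spec) {
  stopifnot(inherits(spec, "synthetic_ctg_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)

  n1 <- spec$n_per_class[1]; n2 <- spec$n_per_class[2]; n3 <- spec$n_per_class[3]
  latent <- if (n2 > 0) {
    ifelse(stats::runif(n2) < spec$suspect_mixture_weight, 1L, 3L)
  } else integer(0)

  # generating class of every record: 1/3 for the labelled classes, the
  # latent class for suspects
  gen_class <- c(rep(1L, n1), latent, rep(3L, n3))
  labels <- c(rep(1L, n1), rep(2L, n2), rep(3L, n3))
  n <- length(gen_class)

  draw <- function(n) {
    if (spec$heavy_tails) stats::rt(n, df = 3) / sqrt(3) else stats::rnorm(n)
  }

  p <- spec$params
  cols <- lapply(seq_len(22), function(j) {
    mu <- ifelse(gen_class == 1L, p$mean1[j], p$mean3[j])
    v <- mu + p$sd[j] * draw(n)
    if (p$count[j]) v <- pmax(0, round(v))
    v
  })
  names(cols) <- p$name
  table <- tibble::as_tibble(cols)
  table$nsp <- labels
  structure(list(table = table, latent_truth = latent),
            class = "synthetic_ctg")
}

#' @export
print.synthetic_ctg <- function(x, ...) {
  cat("<synthetic_ctg> ", nrow(x$table), "records; label counts:",
      paste(table(x$table$nsp), collapse = "/"), "\n")
  invisible(x)
}

#' Estimate per-class generating moments from a CTG table
#'
#' Sample mean and standard deviation of every attribute within each label
#' class; a test utility for checking parameter recovery of the generator.
#'
#' @param table A CTG table (or a `synthetic_ctg`, whose table is used).
#' @return A tibble with columns `nsp`, `name`, `mean`, `sd`.
#' @export
estimate_generating_params <- function(table) {
  if (inherits(table, "synthetic_ctg")) table <- table$table
  counts <- table(table$nsp)
  if (any(counts < 2)) {
    stop("need at least 2 records in every class present", call. = FALSE)
  }
  table |>
    tidyr::pivot_longer(-"nsp", names_to = "name", values_to = "value") |>
    dplyr::group_by(.data$nsp, .data$name) |>
    dplyr::summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
                     .groups = "drop")
}

# Save/restore the global RNG state so generation is side-effect free.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
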