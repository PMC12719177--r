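# Kernel-weighted k-nearest-neighbors classification (Hechenbichler & Schliep
# weighting: neighbor distances standardized by the (k+1)-th neighbor).

ECD_KERNELS <- c("rectangular", "triangular", "epanechnikov", "biweight",
                 "triweight", "cos", "inv", "gaussian", "rank", "optimal")

# weight cap for the inverse-distance kernel at d = 0
INV_KERNEL_CAP <- 1e6

#' Minkowski distance
#'
#' `(sum |x_i - y_i|^p)^(1/p)` for `p >= 1`.
#'
#' @param x,y Equal-length numeric vectors.
#' @param p Minkowski exponent (`>= 1`; 1 = Manhattan, 2 = Euclidean).
#' @return A single distance.
#' @export
minkowski_distance <- function(x, y, p) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal lengths.")
  if (p < 1) abort("`p` must be >= 1.")
  sum(abs(x - y)^p)^(1 / p)
}

# rows of X to rows of Y: |X| x |Y| distance matrix
minkowski_matrix <- function(X, Y, p) {
  out <- matrix(0, nrow(X), nrow(Y))
  for (j in seq_len(ncol(X))) {
    out <- out + abs(outer(X[, j], Y[, j], "-"))^p
  }
  out^(1 / p)
}

# asymptotically optimal rank weights for k neighbors in d dimensions
optimal_rank_weights <- function(k, d = 1) {
  i <- seq_len(k)
  (1 / k) * (1 + d / 2 - d / (2 * k^(2 / d)) * (i^(1 + 2 / d) - (i - 1)^(1 + 2 / d)))
}

#' Kernel weight of a standardized neighbor distance
#'
#' The ten kernels of the weighted-KNN tuning grid, evaluated on distances
#' standardized by the (k+1)-th neighbor distance (so the k-th neighbor sits
#' near `d = 1`). Distance kernels: rectangular `1/2 * 1(d<=1)`; triangular
#' `(1-d) * 1(d<=1)`; epanechnikov `3/4 (1-d^2) * 1`; biweight
#' `15/16 (1-d^2)^2 * 1`; triweight `35/32 (1-d^2)^3 * 1`; cos
#' `pi/4 cos(pi d / 2) * 1`; inv `1/d` (capped at 1e6 at zero distance);
#' gaussian `dnorm(d * q)` with `q = |qnorm(1 / (2(k+1)))|` so the (k+1)-th
#' neighbor lands in the far tail. Rank kernels ignore the distance value:
#' rank gives weight `k + 1 - rank`, optimal the asymptotically optimal rank
#' weights for `dim` feature dimensions.
#'
#' @param d Standardized distances (`>= 0`), sorted or not.
#' @param kernel One of rectangular, triangular, epanechnikov, biweight,
#'   triweight, cos, inv, gaussian, rank, optimal.
#' @param k Neighbor count the standardization refers to.
#' @param ranks Neighbor ranks matching `d` (needed by the rank/optimal
#'   kernels; defaults to `seq_along(d)`, i.e. `d` sorted ascending).
#' @param dim Feature dimension (optimal kernel only).
#' @return Non-negative weights, one per element of `d`.
#' @export
kernel_weight <- function(d, kernel, k, ranks = seq_along(d), dim = 1) {
  kernel <- match.arg(kernel, ECD_KERNELS)
  if (any(d < 0)) abort("Standardized distances must be >= 0.")
  ind <- as.numeric(d <= 1)
  switch(kernel,
    rectangular = 0.5 * ind,
    triangular = (1 - d) * ind,
    epanechnikov = 0.75 * (1 - d^2) * ind,
    biweight = 15 / 16 * (1 - d^2)^2 * ind,
    triweight = 35 / 32 * (1 - d^2)^3 * ind,
    cos = pi / 4 * cos(pi * d / 2) * ind,
    inv = pmin(1 / pmax(d, 1 / INV_KERNEL_CAP), INV_KERNEL_CAP),
    gaussian = dnorm(d * abs(qnorm(1 / (2 * (k + 1))))),
    rank = pmax(k + 1 - ranks, 0),
    optimal = optimal_rank_weights(k, dim)[pmin(ranks, k)] * (ranks <= k)
  )
}

#' Fit a kernel-weighted KNN classifier
#'
#' Stores the training features (raw kOhm by default — the classifier is
#' applied to unscaled Rp features; optional min-max scaling is available)
#' and the hyperparameters: neighbor count `k` (2-6), `kernel` (one of ten),
#' and Minkowski `distance_power` (1-5).
#'
#' @param data A data frame with feature columns and a binary label column.
#' @param k Neighbor count.
#' @param kernel Kernel name (see [kernel_weight()]).
#' @param distance_power Minkowski exponent.
#' @param label Name of the label column (factor or character with levels
#'   no/yes; "yes" is the positive, lesion class).
#' @param features Feature column names (default: all `rp_*` columns).
#' @param scale Min-max scale features to `[0, 1]` using training ranges?
#' @return An object of class `ecd_wknn`.
#' @examples
#' \donttest{
#' ds <- generate_dataset(dataset_spec("9cm", "phantom"), seed = 1)
#' fit <- fit_wknn(ds, k = 3, kernel = "triangular", distance_power = 2)
#' predict(fit, ds[1:3, ])
#' }
#' @export
fit_wknn <- function(data, k = 2L, kernel = "rectangular", distance_power = 1,
                     label = "lesion", features = NULL, scale = FALSE) {
  kernel <- match.arg(kernel, ECD_KERNELS)
  if (!k %in% 2:6) abort("`k` must be in 2..6.")
  if (!distance_power %in% 1:5) abort("`distance_power` must be in 1..5.")
  features <- features %||% grep("^rp_\\d+$", names(data), value = TRUE)
  if (length(features) == 0L) abort("No feature columns found (expected rp_* columns).")
  X <- as.matrix(data[, features, drop = FALSE])
  y <- factor(as.character(data[[label]]), levels = c("no", "yes"))
  if (anyNA(y)) abort('Labels must be "no"/"yes".')
  if (nlevels(droplevels(y)) < 2L) abort("Both classes must be present in training data.")
  if (nrow(X) < k + 1L) abort(sprintf("Need at least k + 1 = %d training rows.", k + 1L))
  scl <- NULL
  if (scale) {
    lo <- apply(X, 2, min); hi <- apply(X, 2, max)
    rng <- pmax(hi - lo, .Machine$double.eps)
    X <- sweep(sweep(X, 2, lo), 2, rng, "/")
    scl <- list(lo = lo, range = rng)
  }
  structure(
    list(X = X, y = y, k = as.integer(k), kernel = kernel,
         distance_power = distance_power, features = features, label = label,
         scaling = scl),
    class = "ecd_wknn"
  )
}

#' @export
print.ecd_wknn <- function(x, ...) {
  cat(sprintf("<ecd_wknn> k = %d, kernel = %s, distance power = %g; %d training rows, %d features\n",
              x$k, x$kernel, x$distance_power, nrow(x$X), length(x$features)))
  invisible(x)
}

# core prediction from a precomputed query-to-train distance matrix
wknn_prob_from_dist <- function(D, y, k, kernel, dim) {
  unname(apply(D, 1, function(d) {
    ord <- order(d)  # stable: first-encountered training row wins distance ties
    dk1 <- d[ord[k + 1L]]
    nb <- ord[seq_len(k)]
    if (dk1 <= 0) {
      w <- rep(0.5, k)  # all candidate neighbors coincide with the query
    } else {
      w <- kernel_weight(d[nb] / dk1, kernel, k, ranks = seq_len(k), dim = dim)
      if (sum(w) <= 0) w <- rep(0.5, k)  # documented rectangular fallback
    }
    sum(w[y[nb] == "yes"]) / sum(w)
  }))
}

#' Predict with a kernel-weighted KNN model
#'
#' Finds the k nearest training rows under the Minkowski distance,
#' standardizes their distances by the (k+1)-th neighbor distance, applies
#' the kernel, and votes: `prob_yes = sum(weights of lesion neighbors) /
#' sum(weights)`; the predicted class is `"yes"` iff `prob_yes >= 0.5`.
#' Degenerate all-zero weights fall back to rectangular voting.
#'
#' @param object An `ecd_wknn` fit.
#' @param newdata A data frame with the model's feature columns.
#' @param ... Unused.
#' @return A tibble with `.prob_yes` and `.class` per row of `newdata`.
#' @export
predict.ecd_wknn <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, object$features, drop = FALSE])
  if (!is.null(object$scaling)) {
    X <- sweep(sweep(X, 2, object$scaling$lo), 2, object$scaling$range, "/")
  }
  D <- minkowski_matrix(X, object$X, object$distance_power)
  prob <- wknn_prob_from_dist(D, object$y, object$k, object$kernel,
                              dim = length(object$features))
  tibble::tibble(
    .prob_yes = prob,
    .class = factor(ifelse(prob >= 0.5, "yes", "no"), levels = c("no", "yes"))
  )
}

#' @exportS3Method generics::tidy
tidy.ecd_wknn <- function(x, ...) {
  tibble::tibble(
    term = c("k", "kernel", "distance_power"),
    value = list(x$k, x$kernel, x$distance_power)
  )
}

#' @exportS3Method generics::glance
glance.ecd_wknn <- function(x, ...) {
  tibble::tibble(
    n_train = nrow(x$X), n_features = length(x$features),
    k = x$k, kernel = x$kernel, distance_power = x$distance_power,
    scaled = !is.null(x$scaling)
  )
}
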