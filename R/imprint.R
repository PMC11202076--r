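#' Build the typical-weight reference multiset
#'
#' Flattens the original `n_original x M` weight block, sorts all
#' `n_original * M` elements in descending order, partitions them into `M`
#' consecutive rank groups of `n_original` elements, and returns the median
#' of each group. The result is an `M`-element multiset of "typical" weight
#' values, in non-increasing order, used as the target distribution for
#' quantile normalization: its top element is the median of the largest
#' `n_original` weights, its bottom element the median of the smallest.
#'
#' @param head a [classifier_head()]; only rows `1..n_original` are used,
#'   so previously imprinted rows never contaminate the reference.
#' @return an object of class `reference_distribution`: a numeric vector of
#'   length `m_features`, sorted descending, with attribute `source_shape`.
#' @examples
#' h <- classifier_head(matrix(c(3, 1, 2, 0), 2, 2, byrow = TRUE))
#' build_reference(h)  # medians of rank groups {3,2} and {1,0}: 2.5, 0.5
#' @export
build_reference <- function(head) {
  validate_head(head)
  n <- head$n_original
  w_ori <- head$weights[seq_len(n), , drop = FALSE]
  flat <- sort(as.vector(w_ori), decreasing = TRUE)
  ref <- apply(matrix(flat, nrow = n), 2, stats::median)
  structure(ref, class = "reference_distribution",
            source_shape = c(n, ncol(head$weights)))
}

#' @export
print.reference_distribution <- function(x, ...) {
  shp <- attr(x, "source_shape")
  cat(sprintf("Typical-weight reference multiset: %d values from a %d x %d head\n",
              length(x), shp[1], shp[2]))
  cat(sprintf("  range [%.4g, %.4g], median %.4g\n",
              min(x), max(x), stats::median(unclass(x))))
  invisible(x)
}

#' Quantile-normalize an activation vector against a reference multiset
#'
#' Rank-maps `x` onto `ref`: the most active element of `x` receives the
#' largest reference value, the second most active the second largest, and
#' so on. The output is a permutation of `ref` (its multiset of values —
#' hence every statistical property of its distribution — equals the
#' reference exactly) while the ranking of the elements of `x` is
#' preserved. Ties in `x` are broken by ascending index, which makes the
#' map deterministic and idempotent.
#'
#' @param x numeric activation vector.
#' @param ref a [build_reference()] result (or any descending-sorted
#'   numeric vector) of the same length.
#' @return numeric vector of `length(x)` holding the reference values.
#' @export
quantile_normalize <- function(x, ref) {
  x <- as.double(x)
  ref <- as.double(ref)
  if (length(x) != length(ref))
    stop(sprintf("length mismatch: activation %d vs reference %d",
                 length(x), length(ref)))
  out <- numeric(length(x))
  # stable radix sort: descending ties keep ascending original index
  out[order(x, decreasing = TRUE)] <- ref
  out
}

#' Match an activation vector's moments to the original weights
#'
#' Affine alternatives to full quantile normalization. With `mu_W` and
#' `sigma_W` the mean and population standard deviation of the flattened
#' original weight block:
#' \describe{
#'   \item{`mean`}{shift only: `x - mean(x) + mu_W` (1st central moment
#'     matched).}
#'   \item{`var`}{scale about the activation's own mean:
#'     `mean(x) + (x - mean(x)) * sigma_W / sigma_x` (2nd central moment
#'     matched, average left as-is — the same normalization gap as a pure
#'     cosine head).}
#'   \item{`mean_var`}{full affine map
#'     `mu_W + (x - mean(x)) * sigma_W / sigma_x` (both moments matched).}
#' }
#' Population (divide-by-n) variance is used throughout.
#'
#' @param x numeric activation vector of length `m_features`.
#' @param head a [classifier_head()] supplying the original weight moments.
#' @param mode one of `"mean"`, `"var"`, `"mean_var"`.
#' @return numeric vector of length `m_features`.
#' @export
moment_normalize <- function(x, head, mode = c("mean", "var", "mean_var")) {
  mode <- match.arg(mode)
  x <- as.double(x)
  if (length(x) != ncol(head$weights))
    stop(sprintf("activation length %d does not match m_features %d",
                 length(x), ncol(head$weights)))
  w_ori <- as.vector(head$weights[seq_len(head$n_original), , drop = FALSE])
  mu_w <- mean(w_ori)
  if (mode == "mean") return(x - mean(x) + mu_w)
  sd_w <- sqrt(mean((w_ori - mu_w)^2))
  sd_x <- sqrt(mean((x - mean(x))^2))
  if (sd_x == 0)
    stop("activation vector has zero variance; cannot match scale")
  scaled <- (x - mean(x)) * sd_w / sd_x
  if (mode == "var") mean(x) + scaled else mu_w + scaled
}

#' Average K training activations into one K-shot vector
#'
#' Element-wise arithmetic mean of the raw (un-normalized) activation
#' vectors; all imprinting methods consume this mean.
#'
#' @param xs a numeric matrix (one activation per row), a list of numeric
#'   vectors, or a single vector.
#' @return numeric vector, the element-wise mean.
#' @export
average_activations <- function(xs) {
  xs <- as_activation_matrix(xs)
  if (nrow(xs) == 0) stop("empty activation sequence")
  colMeans(xs)
}

as_activation_matrix <- function(xs) {
  if (is.list(xs) && !is.data.frame(xs)) {
    len <- vapply(xs, length, integer(1))
    if (length(unique(len)) > 1)
      stop("activation vectors have inconsistent lengths")
    xs <- do.call(rbind, lapply(xs, as.double))
  }
  if (is.null(dim(xs))) xs <- matrix(as.double(xs), nrow = 1)
  storage.mode(xs) <- "double"
  as.matrix(xs)
}

#' Median of the original biases
#'
#' The bias assigned to every imprinted class: the median of the biases of
#' the original rows only (the even-length case takes the midpoint of the
#' two central values). For a head with an all-zero bias vector this is 0.
#'
#' @param head a [classifier_head()].
#' @return numeric scalar.
#' @export
median_bias <- function(head) {
  stats::median(head$biases[seq_len(head$n_original)])
}

#' Imprint new classes onto a classifier head
#'
#' The main fitting function: extends a trained head with one weight row
#' and bias per new class, computed directly from training activations with
#' no gradient optimization — a single fast Hebbian-like write.
#'
#' For each new label the K training activations are averaged element-wise,
#' then transformed into a weight row:
#' \describe{
#'   \item{`done1`}{mean of the new row matched to the original weights
#'     ([moment_normalize()] mode `mean`).}
#'   \item{`done2`}{variance matched, mean untouched (mode `var`).}
#'   \item{`done3`}{mean and variance matched (mode `mean_var`).}
#'   \item{`done4`}{full distribution matched by [quantile_normalize()]
#'     against the [build_reference()] multiset (the default and the
#'     recommended method).}
#'   \item{`qi`}{cosine-head imprinting: the averaged activation is
#'     L2-normalized and used as the row; additionally every original row
#'     is rescaled to unit norm and all biases are set to zero, and queries
#'     must be L2-normalized at prediction time (handled automatically by
#'     [predict.classifier_head()] and [evaluate_classification()]).}
#' }
#' The `done*` methods leave the original rows and biases bit-identical and
#' assign each new class the [median_bias()] of the original head; `qi`
#' preserves only the original row directions. The reference distribution,
#' moments and bias median are always computed from the original rows only,
#' so the order in which classes are added never changes the result.
#'
#' @param head a [classifier_head()].
#' @param training_xs named list: one entry per new class label, each a
#'   matrix of K training activations (rows) or a single numeric vector.
#' @param method one of `"done4"`, `"done3"`, `"done2"`, `"done1"`, `"qi"`.
#' @return a new `classifier_head` with the imprinted rows appended and
#'   attribute `method` set; the input head is not modified.
#' @examples
#' h <- classifier_head(matrix(c(3, 1, 2, 0), 2, 2, byrow = TRUE),
#'                      biases = c(0, 0.4))
#' h2 <- imprint(h, list(cat = c(10, -5)), method = "done4")
#' coef(h2)["cat", ]  # the reference multiset values, rank-mapped
#' @export
imprint <- function(head, training_xs,
                    method = c("done4", "done3", "done2", "done1", "qi")) {
  method <- match.arg(method)
  validate_head(head)
  if (is.null(names(training_xs)) || any(names(training_xs) == ""))
    stop("training_xs must be a named list (one entry per new class)")
  if (method == "qi") return(imprint_qi(head, training_xs))
  imprint_done(head, training_xs, method)
}

imprint_done <- function(head, training_xs, variant) {
  ref <- if (variant == "done4") build_reference(head)
  mode <- c(done1 = "mean", done2 = "var", done3 = "mean_var")[variant]
  b_new <- median_bias(head)
  out <- head
  for (label in names(training_xs)) {
    xbar <- average_activations(training_xs[[label]])
    w_new <- if (variant == "done4") quantile_normalize(xbar, ref)
             else moment_normalize(xbar, head, mode)
    out <- append_class(out, w_new, b_new, label)
  }
  attr(out, "method") <- variant
  out
}

imprint_qi <- function(head, training_xs) {
  w <- head$weights
  nrm <- sqrt(rowSums(w^2))
  if (any(nrm == 0))
    stop(sprintf("weight row %d has zero norm; cannot unit-normalize",
                 which(nrm == 0)[1]))
  out <- classifier_head(w / nrm, numeric(nrow(w)), head$labels,
                         n_original = head$n_original, method = "qi")
  for (label in names(training_xs)) {
    xbar <- average_activations(training_xs[[label]])
    xn <- sqrt(sum(xbar^2))
    if (xn == 0)
      stop(sprintf("averaged activation for '%s' has zero norm", label))
    out <- append_class(out, xbar / xn, 0, label)
  }
  out
}
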