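#' Construct a classifier head
#'
#' A classifier head is the final dense layer of a classification network:
#' an `N x M` weight matrix `W` (one row per class, one column per feature),
#' a length-`N` bias vector `b`, and `N` class labels. The first `n_original`
#' rows are the original (trained) classes; any rows beyond them were added
#' by weight imprinting. For an activation vector `x` the class scores are
#' the raw logits `y_i = x . w_i + b_i`; no softmax is applied because only
#' the arg-max matters for top-1 classification.
#'
#' @param weights numeric matrix, `N x M` (classes by features).
#' @param biases numeric vector of length `N`. Defaults to all zeros.
#' @param labels character vector of `N` distinct class identifiers.
#'   Defaults to `"class_1" ... "class_N"`.
#' @param n_original integer, number of original (non-imprinted) classes;
#'   rows `1..n_original` are the original head. Defaults to `N`.
#' @param method optional string recording the imprinting method that
#'   produced this head (`"qi"` heads require L2-normalized queries).
#'
#' @return An object of class `classifier_head`: a list with elements
#'   `weights`, `biases`, `labels`, `n_original` and attribute `method`.
#' @examples
#' h <- classifier_head(matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE),
#'                      biases = c(0.5, -0.5), labels = c("a", "b"))
#' compute_logits(h, c(1, 0))
#' @export
classifier_head <- function(weights, biases = NULL, labels = NULL,
                            n_original = NULL, method = "none") {
  weights <- as.matrix(weights)
  storage.mode(weights) <- "double"
  n <- nrow(weights)
  if (is.null(biases)) biases <- numeric(n)
  if (is.null(labels)) labels <- paste0("class_", seq_len(n))
  if (is.null(n_original)) n_original <- n
  head <- structure(
    list(weights = weights, biases = as.double(biases),
         labels = as.character(labels), n_original = as.integer(n_original)),
    class = "classifier_head", method = method)
  validate_head(head)
}

#' Validate a classifier head
#'
#' Checks the structural invariants of a [classifier_head()]: matching
#' dimensions, finite entries, distinct labels, and `1 <= n_original <= N`.
#'
#' @param head a `classifier_head`.
#' @return `head`, unchanged, if valid; otherwise an error naming the
#'   offending field (and the row/column of any non-finite entry).
#' @export
validate_head <- function(head) {
  if (!inherits(head, "classifier_head"))
    stop("not a classifier_head object")
  w <- head$weights
  n <- nrow(w)
  if (length(head$biases) != n)
    stop(sprintf("dimension mismatch: weights have %d rows but biases have length %d",
                 n, length(head$biases)))
  if (length(head$labels) != n)
    stop(sprintf("dimension mismatch: weights have %d rows but labels have length %d",
                 n, length(head$labels)))
  if (anyDuplicated(head$labels))
    stop(sprintf("duplicate label: '%s'",
                 head$labels[anyDuplicated(head$labels)]))
  if (!all(is.finite(w))) {
    bad <- which(!is.finite(w), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite weight at row %d, column %d", bad[1], bad[2]))
  }
  if (!all(is.finite(head$biases)))
    stop(sprintf("non-finite bias at index %d", which(!is.finite(head$biases))[1]))
  if (head$n_original < 1L || head$n_original > n)
    stop(sprintf("n_original must be in [1, %d], got %d", n, head$n_original))
  head
}

#' Number of classes and features of a head
#' @param head a `classifier_head`.
#' @return named integer vector `c(n_classes, m_features)`.
#' @export
head_dim <- function(head) {
  c(n_classes = nrow(head$weights), m_features = ncol(head$weights))
}

#' Compute class logits for an activation vector
#'
#' Scores every class as `y_i = x . w_i + b_i`, the dot product of the
#' activation vector with the class's weight row plus its bias. This equals
#' `||x|| ||w_i|| cos(theta) + b_i`, so with unit-norm rows and queries (a
#' Qi-imprinted head) the logit is the cosine similarity.
#'
#' @param head a `classifier_head`.
#' @param x numeric activation vector of length `m_features`.
#' @return numeric vector of `n_classes` logits, named by class label.
#' @export
compute_logits <- function(head, x) {
  x <- as.double(x)
  if (length(x) != ncol(head$weights))
    stop(sprintf("activation length %d does not match m_features %d",
                 length(x), ncol(head$weights)))
  if (!all(is.finite(x))) stop("non-finite activation value")
  y <- drop(head$weights %*% x) + head$biases
  names(y) <- head$labels
  y
}

#' Top-1 prediction for an activation vector
#'
#' Returns the label of the class with the largest logit. Ties are broken
#' deterministically by the lowest row index.
#'
#' @inheritParams compute_logits
#' @return a single class label (character).
#' @export
top1_predict <- function(head, x) {
  y <- compute_logits(head, x)
  head$labels[which.max(y)]
}

#' Append a class row to a head
#'
#' Returns a new head with one extra row; the existing rows, biases and
#' `n_original` are untouched (the input head is never modified), so the
#' stored knowledge of the original classes is preserved exactly.
#'
#' @param head a `classifier_head`.
#' @param w_new numeric weight row of length `m_features`.
#' @param b_new numeric bias scalar.
#' @param label new class identifier; must not already be present.
#' @return a `classifier_head` with `n_classes + 1` rows.
#' @export
append_class <- function(head, w_new, b_new, label) {
  w_new <- as.double(w_new)
  if (length(w_new) != ncol(head$weights))
    stop(sprintf("new row length %d does not match m_features %d",
                 length(w_new), ncol(head$weights)))
  if (label %in% head$labels)
    stop(sprintf("duplicate label: '%s' already present", label))
  classifier_head(rbind(head$weights, w_new, deparse.level = 0),
                  c(head$biases, as.double(b_new)),
                  c(head$labels, as.character(label)),
                  n_original = head$n_original,
                  method = attr(head, "method"))
}

#' @export
print.classifier_head <- function(x, ...) {
  d <- head_dim(x)
  n_new <- d[["n_classes"]] - x$n_original
  cat(sprintf("Classifier head: %d classes x %d features\n",
              d[["n_classes"]], d[["m_features"]]))
  cat(sprintf("  original classes: %d   imprinted classes: %d\n",
              x$n_original, n_new))
  if (!identical(attr(x, "method"), "none"))
    cat(sprintf("  imprinting method: %s\n", attr(x, "method")))
  if (n_new > 0)
    cat("  imprinted labels:", paste(x$labels[-seq_len(x$n_original)],
                                     collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.classifier_head <- function(object, ...) {
  w_ori <- object$weights[seq_len(object$n_original), , drop = FALSE]
  out <- list(
    dim = head_dim(object),
    n_original = object$n_original,
    method = attr(object, "method"),
    weight_mean = mean(w_ori),
    weight_sd = stats::sd(as.vector(w_ori)),
    bias_median = stats::median(object$biases[seq_len(object$n_original)]))
  class(out) <- "summary.classifier_head"
  out
}

#' @export
print.summary.classifier_head <- function(x, ...) {
  cat(sprintf("Classifier head: %d classes x %d features (%d original)\n",
              x$dim[["n_classes"]], x$dim[["m_features"]], x$n_original))
  cat(sprintf("  original weights: mean %.4g, sd %.4g; median bias %.4g\n",
              x$weight_mean, x$weight_sd, x$bias_median))
  cat(sprintf("  method: %s\n", x$method))
  invisible(x)
}

#' @export
coef.classifier_head <- function(object, ...) {
  w <- object$weights
  rownames(w) <- object$labels
  w
}

#' Predict classes for activation vectors
#'
#' @param object a `classifier_head`.
#' @param newdata numeric vector (one activation) or matrix with one
#'   activation per row.
#' @param type `"class"` for top-1 labels, `"logits"` for the score matrix.
#' @param l2_query L2-normalize each query before scoring; defaults to
#'   `TRUE` for heads produced by Qi imprinting, `FALSE` otherwise.
#' @param ... unused.
#' @return character vector of labels, or a logit matrix (rows = queries).
#' @export
predict.classifier_head <- function(object, newdata,
                                    type = c("class", "logits"),
                                    l2_query = NULL, ...) {
  type <- match.arg(type)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(object$weights))
    stop(sprintf("activation length %d does not match m_features %d",
                 ncol(newdata), ncol(object$weights)))
  if (is.null(l2_query)) l2_query <- identical(attr(object, "method"), "qi")
  if (l2_query) {
    nrm <- sqrt(rowSums(newdata^2))
    if (any(nrm == 0)) stop("cannot L2-normalize a zero activation vector")
    newdata <- newdata / nrm
  }
  logits <- newdata %*% t(object$weights) +
    rep(object$biases, each = nrow(newdata))
  colnames(logits) <- object$labels
  if (type == "logits") return(logits)
  object$labels[max.col(logits, ties.method = "first")]
}
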