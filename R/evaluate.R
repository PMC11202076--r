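#' Evaluate a head on a labeled activation set
#'
#' Computes the three quantities that summarize a class-addition
#' experiment:
#' \describe{
#'   \item{per-new-class top-1}{for each imprinted class, the fraction of
#'     its evaluation items whose top-1 prediction is that class.}
#'   \item{original top-1}{the fraction of original-class items predicted
#'     as their true class.}
#'   \item{interference fraction}{the fraction of original-class items
#'     whose top-1 prediction falls on ANY imprinted class — the cost the
#'     new classes impose on stored knowledge.}
#' }
#' Every fraction is backed by its raw counts in the returned object.
#'
#' @param head a [classifier_head()].
#' @param eval_set an [activation_set()].
#' @param l2_query L2-normalize queries before scoring; defaults to `TRUE`
#'   for Qi-imprinted heads (which are pure cosine classifiers) and
#'   `FALSE` otherwise. A warning is raised if a Qi head is evaluated with
#'   the flag explicitly disabled.
#' @return an object of class `evaluation_report`.
#' @export
evaluate_classification <- function(head, eval_set, l2_query = NULL) {
  stopifnot(inherits(eval_set, "activation_set"))
  is_qi <- identical(attr(head, "method"), "qi")
  if (is.null(l2_query)) {
    l2_query <- is_qi
  } else if (is_qi && !l2_query) {
    warning("head was imprinted with Qi's method; enabling query L2 normalization")
    l2_query <- TRUE
  }
  pred <- predict(head, eval_set$x, type = "class", l2_query = l2_query)
  new_labels <- if (head$n_original < length(head$labels))
    head$labels[(head$n_original + 1):length(head$labels)] else character()

  ori <- eval_set$is_original
  n_ori <- sum(ori)
  ori_correct <- sum(pred[ori] == eval_set$labels[ori])
  interfered <- sum(pred[ori] %in% new_labels)

  per_new <- lapply(new_labels[new_labels %in% eval_set$labels], function(lb) {
    idx <- eval_set$labels == lb
    c(correct = sum(pred[idx] == lb), total = sum(idx))
  })
  names(per_new) <- new_labels[new_labels %in% eval_set$labels]

  structure(list(
    per_new_class_top1 = vapply(per_new, function(ct) ct["correct"] / ct["total"],
                                numeric(1)),
    original_top1 = if (n_ori > 0) ori_correct / n_ori else NA_real_,
    interference_fraction = if (n_ori > 0) interfered / n_ori else NA_real_,
    counts = list(original_total = n_ori, original_correct = ori_correct,
                  interfered = interfered, per_new_class = per_new)),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Evaluation report\n")
  if (!is.na(x$original_top1))
    cat(sprintf("  original-class top-1:   %.4f (%d/%d)\n", x$original_top1,
                x$counts$original_correct, x$counts$original_total))
  if (!is.na(x$interference_fraction))
    cat(sprintf("  interference fraction:  %.4f (%d/%d)\n",
                x$interference_fraction, x$counts$interfered,
                x$counts$original_total))
  if (length(x$per_new_class_top1)) {
    cat(sprintf("  mean new-class top-1:   %.4f\n", mean(x$per_new_class_top1)))
    for (lb in names(x$per_new_class_top1))
      cat(sprintf("    %-12s %.4f\n", lb, x$per_new_class_top1[[lb]]))
  }
  invisible(x)
}

#' Flatten an evaluation report to a data frame
#' @param x an `evaluation_report`.
#' @param ... unused.
#' @return data frame with columns `metric`, `value`, `numerator`,
#'   `denominator`.
#' @export
as.data.frame.evaluation_report <- function(x, ...) {
  rows <- list(
    data.frame(metric = "original_top1", value = x$original_top1,
               numerator = x$counts$original_correct,
               denominator = x$counts$original_total),
    data.frame(metric = "interference_fraction",
               value = x$interference_fraction,
               numerator = x$counts$interfered,
               denominator = x$counts$original_total))
  for (lb in names(x$per_new_class_top1)) {
    ct <- x$counts$per_new_class[[lb]]
    rows <- c(rows, list(data.frame(
      metric = paste0("top1_", lb), value = x$per_new_class_top1[[lb]],
      numerator = ct[["correct"]], denominator = ct[["total"]])))
  }
  do.call(rbind, rows)
}

#' Principal-component scores of weight rows
#'
#' Centers by the mean of the ORIGINAL rows only and computes the principal
#' axes from the original rows only; imprinted or probe rows supplied in
#' `extra_rows` are projected passively onto those axes, so they are placed
#' relative to the original weight cloud without influencing it. Each axis
#' is oriented so that its largest-magnitude loading is positive.
#'
#' @param head a [classifier_head()].
#' @param extra_rows optional matrix of additional weight rows to project.
#' @param k number of principal axes (`1 <= k <= min(rows, m_features)`).
#' @return numeric score matrix, one row per input row (originals first,
#'   then any imprinted rows of the head, then `extra_rows`), `k` columns.
#' @export
pca_weight_scores <- function(head, extra_rows = NULL, k = 2) {
  validate_head(head)
  w_ori <- head$weights[seq_len(head$n_original), , drop = FALSE]
  all_rows <- head$weights
  if (!is.null(extra_rows)) {
    extra_rows <- as.matrix(extra_rows)
    if (ncol(extra_rows) != ncol(all_rows))
      stop("extra_rows feature dimension does not match the head")
    all_rows <- rbind(all_rows, extra_rows)
  }
  if (k < 1 || k > min(nrow(all_rows), ncol(all_rows)))
    stop(sprintf("k must be in [1, %d]", min(nrow(all_rows), ncol(all_rows))))
  ctr <- colMeans(w_ori)
  cov_ori <- stats::cov(w_ori)
  ev <- eigen(cov_ori, symmetric = TRUE)
  axes <- ev$vectors[, seq_len(k), drop = FALSE]
  # orient each axis so its largest-|loading| element is positive
  for (j in seq_len(k)) {
    lead <- which.max(abs(axes[, j]))
    if (axes[lead, j] < 0) axes[, j] <- -axes[, j]
  }
  scores <- sweep(all_rows, 2, ctr) %*% axes
  colnames(scores) <- paste0("PC", seq_len(k))
  rownames(scores) <- c(head$labels,
                        if (!is.null(extra_rows))
                          rownames(extra_rows, do.NULL = FALSE,
                                   prefix = "probe_"))
  scores
}

#' Minimum-volume enclosing ellipsoid (Khachiyan's algorithm)
#'
#' Fits the smallest ellipsoid `{z : (z - c)' A (z - c) <= 1}` containing
#' all the points, by Khachiyan's barycentric-coordinate ascent iterated to
#' a relative tolerance on the weight update.
#'
#' @param points numeric matrix, one point per row (n points, d columns);
#'   requires `n >= d + 1` affinely independent points.
#' @param tol relative convergence tolerance.
#' @param max_iter iteration cap.
#' @return list with `center` (length d), `shape` (d x d matrix `A`), and
#'   `u` (the barycentric weights).
#' @export
mvee <- function(points, tol = 1e-6, max_iter = 10000) {
  p <- as.matrix(points)
  n <- nrow(p)
  d <- ncol(p)
  if (n < d + 1) stop("need at least d + 1 points for a d-dimensional ellipsoid")
  if (qr(sweep(p, 2, colMeans(p)))$rank < d)
    stop("degenerate point set: points are rank-deficient (affinely dependent)")
  q <- t(cbind(p, 1))                     # (d+1) x n lifted points
  u <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    xmat <- q %*% (u * t(q))
    m <- colSums(q * solve(xmat, q))      # lifted Mahalanobis scores
    j <- which.max(m)
    # membership value of point p is (m_p - 1) / d, so this stopping rule
    # bounds every point's membership by 1 + tol/2
    if (m[j] - d - 1 <= 0.5 * d * tol) break
    step <- (m[j] - d - 1) / ((d + 1) * (m[j] - 1))
    u_new <- (1 - step) * u
    u_new[j] <- u_new[j] + step
    u <- u_new
  }
  center <- drop(crossprod(p, u))
  shape <- solve(crossprod(p, u * p) - tcrossprod(center)) / d
  # rescale so the farthest defining point lies exactly on the boundary:
  # guarantees enclosure of all points even when the ascent stops at the
  # iteration cap short of the requested tolerance
  ctr <- sweep(p, 2, center)
  v_max <- max(rowSums((ctr %*% shape) * ctr))
  shape <- shape / v_max
  list(center = center, shape = shape, u = u)
}

#' Test whether a point lies inside a minimum-volume enclosing ellipsoid
#'
#' Fits the MVEE of `points` (unless a prefitted ellipsoid is supplied) and
#' tests `(q - c)' A (q - c) <= 1 + tol`, so boundary/support points count
#' as inside. This is the "inside the original weight cloud" criterion used
#' to judge whether an imprinted weight row is in-distribution in PC space.
#'
#' @param points numeric matrix of defining points (one per row).
#' @param query numeric vector, the point to test.
#' @param tol tolerance for both the fit and the membership slack.
#' @param fit optional prefitted [mvee()] result (skips refitting).
#' @return logical.
#' @export
mvee_contains <- function(points, query, tol = 1e-6, fit = NULL) {
  if (is.null(fit)) fit <- mvee(points, tol = tol)
  dq <- as.double(query) - fit$center
  drop(t(dq) %*% fit$shape %*% dq) <= 1 + tol
}

#' Run a full synthetic class-addition experiment
#'
#' End-to-end harness: builds a synthetic backbone, draws `shots` training
#' activations for each of `n_new_classes` held-out prototypes, imprints
#' them with `method`, then evaluates on freshly drawn activations for
#' every original and new class. Fully determined by `seed`.
#'
#' @param spec a [synthetic_spec()]; its `seed` field is overridden by
#'   `seed` when that is supplied.
#' @param method imprinting method passed to [imprint()].
#' @param n_new_classes number of classes to add (>= 1).
#' @param shots training activations per new class (K-shot).
#' @param eval_per_class evaluation items per class.
#' @param seed optional integer overriding `spec$seed`.
#' @return an `evaluation_report` (invisible extras: the imprinted head and
#'   backbone as attributes `head` and `backbone`).
#' @export
run_experiment <- function(spec, method = "done4", n_new_classes = 8,
                           shots = 1, eval_per_class = 25, seed = NULL) {
  stopifnot(n_new_classes >= 1, shots >= 1)
  if (!is.null(seed)) spec$seed <- as.integer(seed)
  backbone <- make_backbone(spec, n_reserve = n_new_classes)
  new_idx <- spec$n_classes + seq_len(n_new_classes)
  training <- lapply(new_idx, function(ci)
    sample_activations(backbone, ci, shots, stream = "train")$x)
  names(training) <- backbone$labels[new_idx]
  fitted <- imprint(backbone$head, training, method = method)
  eval_set <- make_eval_set(backbone, seq_len(spec$n_classes), new_idx,
                            per_class = eval_per_class)
  rep <- evaluate_classification(fitted, eval_set)
  attr(rep, "head") <- fitted
  attr(rep, "backbone") <- backbone
  rep
}
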