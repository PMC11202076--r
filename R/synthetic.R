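#' Specification of a synthetic backbone
#'
#' Generative parameters for a prototype-structured classifier head with the
#' activation statistics seen in real vision backbones: transformer-like
#' final-dense-layer inputs are approximately symmetric ("bell") with mean
#' near zero, while CNN-like inputs are non-negative and right-skewed
#' ("right_tailed"). Weight elements are bell-shaped around `weight_mean`
#' in either case.
#'
#' @param n_classes number of original classes (>= 2).
#' @param m_features feature dimension of the head (>= 2).
#' @param activation_shape `"bell"` or `"right_tailed"`.
#' @param weight_mean,weight_sd mean and standard deviation (per row,
#'   exact) of the weight elements; `weight_sd > 0`.
#' @param noise_sd within-class activation noise around the class
#'   prototype (>= 0).
#' @param bias_sd standard deviation of the original biases (>= 0).
#' @param seed integer master seed; all draws are pure functions of it.
#' @return an object of class `synthetic_spec` (a named list).
#' @export
synthetic_spec <- function(n_classes = 50, m_features = 64,
                           activation_shape = c("bell", "right_tailed"),
                           weight_mean = 0, weight_sd = 1,
                           noise_sd = 0.5, bias_sd = 0.1, seed = 1) {
  activation_shape <- match.arg(activation_shape)
  stopifnot(n_classes >= 2, m_features >= 2, weight_sd > 0,
            noise_sd >= 0, bias_sd >= 0)
  structure(list(n_classes = as.integer(n_classes),
                 m_features = as.integer(m_features),
                 activation_shape = activation_shape,
                 weight_mean = weight_mean, weight_sd = weight_sd,
                 noise_sd = noise_sd, bias_sd = bias_sd,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Named counter-based substreams: a deterministic integer seed in
# [0, 2^31 - 2] derived from (master seed, purpose, index). Each (class,
# purpose) pair gets its own stream, so adding classes or resampling one
# stream never perturbs another's draws. Products stay < 2^53, so the
# arithmetic is exact in doubles.
substream_seed <- function(seed, purpose, index = 0L) {
  pid <- match(purpose, c("prototypes", "biases", "train", "eval"))
  if (is.na(pid)) stop("unknown rng purpose: ", purpose)
  h <- as.double(seed) %% 2147483647
  for (comp in c(pid, as.double(index))) {
    h <- (h * 69069 + comp + 1) %% 2147483647
  }
  as.integer(h)
}

#' Generate a synthetic backbone
#'
#' Draws `n_classes + n_reserve` latent class prototypes from a standard
#' normal in `m_features` dimensions. The head's weight row for original
#' class `i` is `weight_mean + weight_sd * standardize(prototype_i)`, where
#' standardization subtracts the row's own mean and divides by its
#' population standard deviation — so every row has exactly the requested
#' mean and spread, and the pooled weight elements are bell-shaped. Because
#' rows are (standardized) prototypes, the head classifies its own
#' prototypes correctly without any training loop. Reserve prototypes are
#' held out as ground truth for future imprinted classes.
#'
#' @param spec a [synthetic_spec()].
#' @param n_reserve number of held-out prototypes for new classes (>= 0).
#' @return an object of class `synthetic_backbone`: list with `head` (a
#'   [classifier_head()] of the original classes), `prototypes`
#'   (`(n_classes + n_reserve) x m_features`), `labels` for all prototypes,
#'   and the `spec`.
#' @export
make_backbone <- function(spec, n_reserve = 0L) {
  stopifnot(inherits(spec, "synthetic_spec"), n_reserve >= 0)
  n_total <- spec$n_classes + n_reserve
  protos <- with_seed(substream_seed(spec$seed, "prototypes"), {
    matrix(stats::rnorm(n_total * spec$m_features),
           nrow = n_total, ncol = spec$m_features)
  })
  w <- protos[seq_len(spec$n_classes), , drop = FALSE]
  ctr <- w - rowMeans(w)
  pop_sd <- sqrt(rowMeans(ctr^2))
  w <- spec$weight_mean + spec$weight_sd * ctr / pop_sd
  biases <- with_seed(substream_seed(spec$seed, "biases"), {
    stats::rnorm(spec$n_classes, 0, spec$bias_sd)
  })
  labels <- c(sprintf("orig_%03d", seq_len(spec$n_classes)),
              if (n_reserve > 0) sprintf("new_%03d", seq_len(n_reserve)))
  head <- classifier_head(w, biases, labels[seq_len(spec$n_classes)],
                          n_original = spec$n_classes)
  structure(list(head = head, prototypes = protos, labels = labels,
                 spec = spec),
            class = "synthetic_backbone")
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

#' @export
print.synthetic_backbone <- function(x, ...) {
  s <- x$spec
  cat(sprintf("Synthetic backbone: %d original classes, %d reserve, %d features\n",
              s$n_classes, nrow(x$prototypes) - s$n_classes, s$m_features))
  cat(sprintf("  activations: %s, noise sd %.3g; weights mean %.3g sd %.3g\n",
              s$activation_shape, s$noise_sd, s$weight_mean, s$weight_sd))
  invisible(x)
}

#' Sample activation vectors for one class
#'
#' Each draw is the class prototype plus i.i.d. Gaussian noise of standard
#' deviation `noise_sd`. In `bell` mode the latent draw is returned as-is;
#' in `right_tailed` mode it is rectified element-wise at zero, giving
#' non-negative, positively skewed activations — the CNN-like statistic
#' whose mismatch with bell-shaped weights drives imprinting interference.
#'
#' @param backbone a [make_backbone()] result.
#' @param class_index prototype index (1-based; indices above `n_classes`
#'   address the reserve prototypes).
#' @param count number of vectors to draw.
#' @param stream rng substream name, `"train"` or `"eval"`; together with
#'   `class_index` it selects an independent deterministic stream.
#' @return an [activation_set()] with `count` rows labeled by the class.
#' @export
sample_activations <- function(backbone, class_index, count,
                               stream = c("train", "eval")) {
  stream <- match.arg(stream)
  stopifnot(inherits(backbone, "synthetic_backbone"))
  if (class_index < 1 || class_index > nrow(backbone$prototypes))
    stop(sprintf("class_index %d out of range [1, %d]",
                 class_index, nrow(backbone$prototypes)))
  spec <- backbone$spec
  proto <- backbone$prototypes[class_index, ]
  x <- with_seed(substream_seed(spec$seed, stream, class_index), {
    matrix(stats::rnorm(count * spec$m_features, 0, spec$noise_sd),
           nrow = count, byrow = TRUE)
  })
  x <- sweep(x, 2, proto, "+")
  if (spec$activation_shape == "right_tailed") x <- pmax(x, 0)
  activation_set(x, rep(backbone$labels[class_index], count),
                 is_original = rep(class_index <= spec$n_classes, count))
}

#' Labeled activation set
#'
#' Container for evaluation or training activations: a matrix of vectors
#' (one per row), their true class labels, and a flag marking whether each
#' item belongs to an original or an imprinted class.
#'
#' @param x numeric matrix, one activation vector per row.
#' @param labels character vector of true class labels, one per row.
#' @param is_original logical vector, one per row.
#' @return an object of class `activation_set`.
#' @export
activation_set <- function(x, labels, is_original) {
  x <- as_activation_matrix(x)
  stopifnot(nrow(x) == length(labels), nrow(x) == length(is_original))
  if (nrow(x) == 0) stop("activation set must be non-empty")
  structure(list(x = x, labels = as.character(labels),
                 is_original = as.logical(is_original)),
            class = "activation_set")
}

#' @export
print.activation_set <- function(x, ...) {
  cat(sprintf("Activation set: %d items x %d features (%d original-class, %d new-class)\n",
              nrow(x$x), ncol(x$x), sum(x$is_original), sum(!x$is_original)))
  invisible(x)
}

#' Combine activation sets
#' @param ... `activation_set` objects.
#' @return a single `activation_set`.
#' @export
c.activation_set <- function(...) {
  sets <- list(...)
  activation_set(do.call(rbind, lapply(sets, `[[`, "x")),
                 unlist(lapply(sets, `[[`, "labels")),
                 unlist(lapply(sets, `[[`, "is_original")))
}

#' Build an evaluation set over original and new classes
#'
#' Draws `per_class` evaluation activations for every listed class from the
#' `"eval"` rng substream (disjoint per class, so adding classes never
#' perturbs other classes' draws) and concatenates them with partition
#' flags set.
#'
#' @param backbone a [make_backbone()] result.
#' @param original_classes,new_classes prototype indices (1-based).
#' @param per_class evaluation items per class (>= 1).
#' @return an [activation_set()].
#' @export
make_eval_set <- function(backbone, original_classes, new_classes = integer(),
                          per_class = 25) {
  stopifnot(per_class >= 1)
  sets <- lapply(c(original_classes, new_classes), function(ci)
    sample_activations(backbone, ci, per_class, stream = "eval"))
  do.call(c, sets)
}
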