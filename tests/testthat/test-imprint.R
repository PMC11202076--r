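test_that("reference multiset is the per-rank-group median of W_ori", {
  h <- classifier_head(matrix(c(3, 1, 2, 0), 2, 2, byrow = TRUE))
  expect_equal(unclass(build_reference(h))[1:2], c(2.5, 0.5))

  h1 <- classifier_head(matrix(c(5, -2, 0), 1, 3))
  expect_equal(unclass(build_reference(h1))[1:3], c(5, 0, -2))

  h3 <- classifier_head(matrix(c(6, 5, 4, 3, 2, 1), 3, 2, byrow = TRUE))
  expect_equal(unclass(build_reference(h3))[1:2], c(5, 2))

  # imprinted rows never enter the reference
  h_imp <- append_class(h, c(100, 100), 0, "new")
  expect_equal(unclass(build_reference(h_imp)), unclass(build_reference(h)),
               ignore_attr = TRUE)

  r <- build_reference(random_head(20, 10, seed = 5))
  expect_length(unclass(r), 10)
  expect_true(all(diff(unclass(r)) <= 0))  # non-increasing
})

test_that("quantile normalization rank-maps x onto the reference", {
  expect_equal(quantile_normalize(c(0.5, 2.0, 1.0), c(3, 0, -1)), c(-1, 3, 0))
  # ties broken by ascending index
  expect_equal(quantile_normalize(c(1, 1, 0), c(3, 0, -1)), c(3, 0, -1))
  # fixed point: x already a permutation of ref
  expect_equal(quantile_normalize(c(0, 3, -1), c(3, 0, -1)), c(0, 3, -1))
  expect_error(quantile_normalize(c(1, 2), c(3, 0, -1)), "length mismatch")
})

test_that("quantile normalization: multiset equality, monotonicity, idempotence", {
  set.seed(11)
  for (i in 1:100) {
    m <- sample(c(10, 50), 1)
    x <- if (i %% 3 == 0) sample(round(rnorm(m), 1)) else rnorm(m)  # ties
    ref <- sort(rnorm(m), decreasing = TRUE)
    out <- quantile_normalize(x, ref)
    # output multiset equals the reference exactly
    expect_identical(sort(out, decreasing = TRUE), ref)
    # rank preservation / monotonicity
    ord <- order(x)
    expect_true(all(diff(out[ord]) >= 0 | diff(x[ord]) == 0))
    gt <- outer(x, x, ">")
    expect_true(all(out[row(gt)[gt]] >= out[col(gt)[gt]]))
    # idempotence under the stable tie rule
    expect_identical(quantile_normalize(out, ref), out)
  }
})

test_that("moment normalization matches the original-weight moments", {
  h_mean <- classifier_head(matrix(c(1, -1, 1, -1), 2, 2, byrow = TRUE))
  expect_equal(moment_normalize(c(0, 2), h_mean, "mean"), c(-1, 1))

  h_var <- classifier_head(matrix(c(2, -2, 2, -2), 2, 2, byrow = TRUE))
  expect_equal(moment_normalize(c(0, 2), h_var, "var"), c(-1, 3))
  expect_equal(moment_normalize(c(0, 2), h_var, "mean_var"), c(-2, 2))

  expect_error(moment_normalize(c(1, 1), h_var, "var"), "zero variance")
  expect_error(moment_normalize(c(1, 1), h_var, "mean_var"), "zero variance")
  expect_equal(moment_normalize(c(1, 1), h_var, "mean"), c(0, 0))

  set.seed(12)
  for (i in 1:50) {
    h <- random_head(8, 6, seed = 3000 + i)
    x <- rnorm(6, sd = 4) + 2
    w_flat <- as.vector(h$weights)
    out <- moment_normalize(x, h, "mean_var")
    scale <- max(1, abs(mean(w_flat)), pop_var(w_flat))
    expect_lt(abs(mean(out) - mean(w_flat)), 1e-10 * scale)
    expect_lt(abs(pop_var(out) - pop_var(w_flat)), 1e-10 * scale)
    expect_lt(abs(cor(out, x) - 1), 1e-12)  # affine with positive slope
    # var mode preserves the activation's own mean
    expect_equal(mean(moment_normalize(x, h, "var")), mean(x))
  }
})

test_that("K-shot averaging is the raw element-wise mean", {
  expect_equal(average_activations(rbind(c(0, 2), c(2, 0))), c(1, 1))
  expect_equal(average_activations(c(3, 7)), c(3, 7))
  expect_equal(average_activations(list(c(1, 1), c(1, 1), c(4, 4))), c(2, 2))
  expect_error(average_activations(list(c(1, 2), c(1, 2, 3))),
               "inconsistent lengths")
  expect_error(average_activations(matrix(numeric(0), 0, 2)), "empty")
})

test_that("median_bias uses original biases only, midpoint for even counts", {
  mk <- function(b) classifier_head(matrix(rnorm(length(b) * 2), length(b), 2),
                                    biases = b)
  expect_equal(median_bias(mk(c(0.1, -0.3, 0.5))), 0.1)
  expect_equal(median_bias(mk(c(0, 1))), 0.5)
  expect_equal(median_bias(mk(-1)), -1)
  expect_equal(median_bias(mk(c(0, 0, 0))), 0)  # bias-free heads give 0
  # imprinted biases excluded
  h <- append_class(mk(c(0, 1)), c(9, 9), 100, "new")
  expect_equal(median_bias(h), 0.5)
})

test_that("DONE imprinting composes transform, bias, and append", {
  h <- classifier_head(matrix(c(3, 1, 2, 0), 2, 2, byrow = TRUE),
                       biases = c(0.0, 0.4), labels = c("a", "b"))
  fit <- imprint(h, list(cat = c(10, -5)), method = "done4")
  expect_equal(unname(fit$weights[3, ]), c(2.5, 0.5))
  expect_equal(fit$biases[3], 0.2)
  expect_identical(fit$weights[1:2, ], h$weights)
  expect_identical(fit$biases[1:2], h$biases)
  expect_identical(fit$n_original, 2L)
  expect_identical(attr(fit, "method"), "done4")

  h2 <- classifier_head(matrix(c(1, -1, 1, -1), 2, 2, byrow = TRUE),
                        biases = c(0, 0))
  fit1 <- imprint(h2, list(cat = c(0, 2)), method = "done1")
  expect_equal(unname(fit1$weights[3, ]), c(-1, 1))
  expect_equal(fit1$biases[3], 0)

  # two labels in one call share the original-only reference
  fit2 <- imprint(h, list(cat = c(10, -5), dog = c(-5, 10)), method = "done4")
  expect_equal(nrow(fit2$weights), 4)
  expect_equal(unname(fit2$weights[3, ]), c(2.5, 0.5))
  expect_equal(unname(fit2$weights[4, ]), c(0.5, 2.5))

  # K-shot: mean of raw activations feeds the transform
  fitk <- imprint(h, list(cat = rbind(c(20, -10), c(0, 0))), method = "done4")
  expect_equal(unname(fitk$weights[3, ]), c(2.5, 0.5))

  expect_error(imprint(h, list(c(1, 2))), "named list")
  expect_error(imprint(h, list(a = c(1, 2))), "duplicate label")
})

test_that("Qi imprinting unit-normalizes rows, zeroes biases, keeps directions", {
  h <- classifier_head(matrix(c(3, 1, 2, 0), 2, 2, byrow = TRUE),
                       biases = c(0.3, -0.2), labels = c("a", "b"))
  fit <- imprint(h, list(cat = c(3, 4)), method = "qi")
  expect_equal(unname(fit$weights[3, ]), c(0.6, 0.8))
  expect_equal(unname(fit$weights[1, ]), c(3, 1) / sqrt(10))
  expect_equal(fit$biases, c(0, 0, 0))
  expect_identical(attr(fit, "method"), "qi")

  # original directions preserved: cosine(old, new) == 1 within 1e-12
  for (i in 1:2) {
    cosang <- sum(h$weights[i, ] * fit$weights[i, ]) /
      (sqrt(sum(h$weights[i, ]^2)) * sqrt(sum(fit$weights[i, ]^2)))
    expect_lt(abs(cosang - 1), 1e-12)
  }

  # self-logit: the L2-normalized training activation scores 1 on its class
  lg <- predict(fit, c(3, 4), type = "logits")
  expect_identical(unname(lg[1, "cat"]), 1)
  expect_identical(colnames(lg)[which.max(lg)], "cat")

  expect_error(imprint(h, list(z = c(0, 0)), method = "qi"), "zero norm")
  h0 <- classifier_head(matrix(c(0, 0, 1, 1), 2, 2, byrow = TRUE))
  expect_error(imprint(h0, list(z = c(1, 1)), method = "qi"), "zero norm")
})
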