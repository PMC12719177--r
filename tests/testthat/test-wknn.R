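test_that("Minkowski distance matches closed forms and a log-domain brute force", {
  expect_equal(minkowski_distance(c(1, 2, 3), c(1, 2, 3), 3), 0)
  expect_equal(minkowski_distance(c(0, 0), c(3, 4), 1), 7)
  expect_equal(minkowski_distance(c(0, 0), c(3, 4), 2), 5)
  set.seed(12)
  for (i in 1:20) {
    x <- rnorm(9); y <- rnorm(9)
    brute <- exp(log(sum(exp(5 * log(abs(x - y))))) / 5)
    expect_equal(minkowski_distance(x, y, 5), brute, tolerance = 1e-12)
  }
  expect_error(minkowski_distance(1:3, 1:4, 2))
  expect_error(minkowski_distance(1:3, 3:1, 0.5))
})

test_that("kernels take their textbook values at 0, 1/2 and the support edge", {
  expect_equal(kernel_weight(c(0.3, 1, 1.7), "rectangular", 3), c(0.5, 0.5, 0))
  expect_equal(kernel_weight(0.5, "triangular", 3), 0.5)
  expect_equal(kernel_weight(0.5, "epanechnikov", 3), 0.75 * 0.75)
  expect_equal(kernel_weight(0.5, "biweight", 3), 15 / 16 * 0.5625)
  expect_equal(kernel_weight(0.5, "triweight", 3), 35 / 32 * 0.75^3)
  expect_equal(kernel_weight(0.5, "cos", 3), pi / 4 * cos(pi / 4))
  # compact kernels vanish at the boundary d = 1
  for (kn in c("triangular", "epanechnikov", "biweight", "triweight", "cos")) {
    expect_equal(kernel_weight(1, kn, 3), 0)
  }
  # inv is capped at zero distance; gaussian stays positive past d = 1
  expect_equal(kernel_weight(0, "inv", 3), 1e6)
  expect_equal(kernel_weight(2, "inv", 3), 0.5)
  expect_gt(kernel_weight(1.2, "gaussian", 3), 0)
  # rank kernels depend on the rank only
  expect_equal(kernel_weight(c(0.1, 0.5, 0.9), "rank", 3), c(3, 2, 1))
  expect_equal(kernel_weight(c(0.9, 0.5, 0.1), "rank", 3, ranks = 1:3), c(3, 2, 1))
  w_opt <- kernel_weight(c(0.2, 0.4, 0.8), "optimal", 3, dim = 9)
  expect_equal(sum(w_opt), 1, tolerance = 1e-12)
  expect_true(all(diff(w_opt) < 0))
})

test_that("the worked one-dimensional prediction follows the weighting scheme", {
  train <- tibble::tibble(rp_01 = c(0, 1, 10),
                          lesion = factor(c("no", "no", "yes"), c("no", "yes")))
  fit <- fit_wknn(train, k = 2, kernel = "triangular", distance_power = 1)
  p <- predict(fit, tibble::tibble(rp_01 = 9))
  # neighbors at distances 1 (yes) and 8 (no); standardizer d3 = 9
  expect_equal(p$.prob_yes, (1 - 1 / 9) / ((1 - 1 / 9) + (1 - 8 / 9)))
  expect_equal(as.character(p$.class), "yes")
})

test_that("rectangular weighting equals the brute-force majority vote", {
  set.seed(33)
  for (rep in 1:12) {
    n <- sample(10:50, 1)
    k <- sample(2:6, 1)
    p <- sample(1:5, 1)
    train <- tibble::tibble(
      rp_01 = rnorm(n), rp_02 = rnorm(n),
      lesion = factor(sample(c("no", "yes"), n, replace = TRUE), c("no", "yes"))
    )
    while (length(unique(train$lesion)) < 2) {
      train$lesion <- factor(sample(c("no", "yes"), n, replace = TRUE), c("no", "yes"))
    }
    query <- tibble::tibble(rp_01 = rnorm(5), rp_02 = rnorm(5))
    fit <- fit_wknn(train, k = k, kernel = "rectangular", distance_power = p)
    got <- predict(fit, query)
    for (i in 1:5) {
      d <- apply(train[, 1:2], 1, function(r) {
        minkowski_distance(as.numeric(query[i, ]), as.numeric(r), p)
      })
      nb <- order(d)[seq_len(k)]
      expect_equal(got$.prob_yes[i], mean(train$lesion[nb] == "yes"))
    }
  }
})

test_that("probabilities are bounded and invariant to training-row permutations", {
  set.seed(8)
  train <- tibble::tibble(
    rp_01 = rnorm(30), rp_02 = rnorm(30),
    lesion = factor(rep(c("no", "yes"), 15), c("no", "yes"))
  )
  q <- tibble::tibble(rp_01 = rnorm(10), rp_02 = rnorm(10))
  fit <- fit_wknn(train, k = 4, kernel = "biweight", distance_power = 2)
  p1 <- predict(fit, q)
  expect_true(all(p1$.prob_yes >= 0 & p1$.prob_yes <= 1))
  perm <- sample(30)
  fit2 <- fit_wknn(train[perm, ], k = 4, kernel = "biweight", distance_power = 2)
  expect_equal(predict(fit2, q)$.prob_yes, p1$.prob_yes)
})

test_that("rank-kernel predictions survive strictly increasing feature-scale maps", {
  # a common positive rescaling is monotone in every pairwise distance
  set.seed(9)
  train <- tibble::tibble(
    rp_01 = rnorm(20), rp_02 = rnorm(20),
    lesion = factor(rep(c("no", "yes"), 10), c("no", "yes"))
  )
  q <- tibble::tibble(rp_01 = rnorm(6), rp_02 = rnorm(6))
  f1 <- fit_wknn(train, k = 3, kernel = "rank", distance_power = 2)
  scaled <- dplyr::mutate(train, rp_01 = 100 * rp_01, rp_02 = 100 * rp_02)
  f2 <- fit_wknn(scaled, k = 3, kernel = "rank", distance_power = 2)
  expect_equal(predict(f1, q)$.prob_yes,
               predict(f2, dplyr::mutate(q, rp_01 = 100 * rp_01,
                                         rp_02 = 100 * rp_02))$.prob_yes)
})

test_that("fitting validates hyperparameters, labels and training size", {
  train <- tibble::tibble(rp_01 = rnorm(10),
                          lesion = factor(rep(c("no", "yes"), 5), c("no", "yes")))
  expect_error(fit_wknn(train, k = 7), "k")
  expect_error(fit_wknn(train, kernel = "box"))
  expect_error(fit_wknn(train, distance_power = 9), "distance_power")
  expect_error(fit_wknn(train[1:2, ], k = 2), "k \\+ 1")
  one_class <- dplyr::mutate(train, lesion = factor("no", c("no", "yes")))
  expect_error(fit_wknn(one_class), "Both classes")
  g <- glance(fit_wknn(train, k = 3, kernel = "cos", distance_power = 2))
  expect_equal(g$k, 3L)
  expect_equal(g$kernel, "cos")
})
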