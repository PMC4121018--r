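test_that("naive Bayes posteriors match closed-form Gaussian likelihood ratios", {
  # class A pixels {-1, 1}: ML fit N(0, 1); class B {1, 3}: N(2, 1)
  tab <- data.frame(label = c("granulation", "granulation", "slough", "slough"),
                    x = c(-1, 1, 1, 3))
  m <- fitBayes(tab)
  expect_equal(predict(m, data.frame(x = 1), type = "posterior")[1, ],
               c(granulation = 0.5, slough = 0.5))
  p <- predict(m, data.frame(x = 0), type = "posterior")
  expect_equal(unname(p[1, "granulation"]), 1 / (1 + exp(-2)),
               tolerance = 1e-9)
  expect_equal(predict(m, data.frame(x = 0)), "granulation")
})

test_that("posteriors normalize and match a brute-force density product", {
  set.seed(5)
  n <- 45
  tab <- data.frame(label = rep(c("granulation", "slough", "necrotic"),
                                times = c(20, 15, 10)),
                    a = rnorm(n, rep(c(0, 2, 5), times = c(20, 15, 10))),
                    b = rnorm(n, rep(c(1, -1, 0), times = c(20, 15, 10)), 2))
  m <- fitBayes(tab)
  q <- data.frame(a = rnorm(100, 2, 2), b = rnorm(100, 0, 2))
  post <- predict(m, q, type = "posterior")
  expect_equal(rowSums(post), rep(1, 100), tolerance = 1e-12)

  # oracle: standardize with the model parameters, multiply marginal
  # normal densities and priors directly
  xs <- sweep(sweep(as.matrix(q), 2, m@center), 2, m@scale, "/")
  for (r in c(1, 17, 58, 100)) {
    lik <- sapply(seq_along(m@classes), function(ci)
      m@priors[ci] * prod(dnorm(xs[r, ], m@means[ci, ], sqrt(m@vars[ci, ]))))
    expect_equal(post[r, ], lik / sum(lik), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
  # predictions invariant to uniform scaling of likelihoods (normalization)
  expect_identical(predict(m, q), m@classes[apply(post, 1, which.max)])
})

test_that("Bayes handles balanced identical classes and rejects bad input", {
  tab <- data.frame(label = rep(c("granulation", "slough"), each = 3),
                    x = rep(c(1, 2, 3), 2))
  m <- fitBayes(tab)
  p <- predict(m, data.frame(x = 2), type = "posterior")
  expect_equal(p[1, ], c(granulation = 0.5, slough = 0.5))
  expect_error(predict(m, data.frame(x = NaN)), "non-finite")
  expect_error(fitBayes(data.frame(label = rep("slough", 4), x = 1:4)),
               "2 classes")
})

test_that("SVMs separate linearly separable toys with every kernel", {
  toy <- data.frame(label = rep(c("granulation", "slough"), each = 2),
                    x = c(0, 0, 4, 4), y = c(0, 1, 0, 1))
  for (k in c("linear", "poly2", "poly3", "rbf")) {
    m <- fitSVM(toy, kernel = k, C = 100)
    expect_identical(predict(m, toy), toy$label)
  }
  # linear decision boundary crosses x in (0, 4): probe the midline
  m <- fitSVM(toy, kernel = "linear", C = 100)
  expect_identical(predict(m, data.frame(x = c(-1, 5), y = c(0.5, 0.5))),
                   c("granulation", "slough"))
})

test_that("XOR needs a nonlinear kernel", {
  xor <- data.frame(label = c("granulation", "granulation", "slough", "slough"),
                    x = c(0, 1, 0, 1), y = c(0, 1, 1, 0))
  accLin <- mean(predict(fitSVM(xor, kernel = "linear", C = 100), xor) == xor$label)
  expect_lte(accLin, 0.75)
  accPoly <- mean(predict(fitSVM(xor, kernel = "poly2", C = 100), xor) == xor$label)
  expect_equal(accPoly, 1)
})

test_that("one-vs-one decisions agree with the training backend", {
  set.seed(3)
  n <- 60
  tab <- data.frame(label = rep(c("granulation", "slough", "necrotic"),
                                each = n / 3),
                    a = rnorm(n) + rep(c(0, 2, 4), each = n / 3),
                    b = rnorm(n) + rep(c(0, -2, 1), each = n / 3))
  q <- data.frame(a = rnorm(50, 1.5, 2), b = rnorm(50, -1, 2))
  for (k in c("linear", "poly2", "poly3", "rbf")) {
    m <- fitSVM(tab, kernel = k)
    xs <- scale(as.matrix(tab[, c("a", "b")]))
    fit <- e1071::svm(
      x = xs, y = factor(tab$label, tissueClasses()), scale = FALSE, cost = 1,
      kernel = switch(k, linear = "linear", rbf = "radial", "polynomial"),
      degree = switch(k, poly2 = 2, poly3 = 3, 1),
      gamma = m@kernel$gamma, coef0 = 1)
    qs <- scale(as.matrix(q), attr(xs, "scaled:center"),
                attr(xs, "scaled:scale"))
    expect_identical(predict(m, q), as.character(predict(fit, qs)),
                     info = k)
  }
})

test_that("SVM decisions match an independent quadratic-programming solve", {
  set.seed(12)
  n <- 20
  x <- rbind(matrix(rnorm(n, 0, 0.8), n / 2),
             matrix(rnorm(n, 3, 0.8), n / 2))
  colnames(x) <- c("a", "b")
  y <- rep(c(1, -1), each = n / 2)
  tab <- data.frame(label = ifelse(y > 0, "granulation", "slough"),
                    a = x[, 1], b = x[, 2])
  m <- fitSVM(tab, kernel = "rbf", C = 10)

  # solve the dual max sum(alpha) - 1/2 alpha' Q alpha by QP on the
  # standardized data with the same kernel
  xs <- scale(x)
  g <- m@kernel$gamma
  K <- exp(-g * as.matrix(dist(xs))^2)
  Q <- (y %o% y) * K
  sol <- kernlab::ipop(c = matrix(-1, n), H = Q, A = matrix(y, 1), b = 0,
                       l = matrix(0, n), u = matrix(10, n), r = 0)
  alpha <- kernlab::primal(sol)
  wsv <- alpha > 1e-5
  bvals <- y[wsv] - colSums(alpha * y * K[, wsv, drop = FALSE])
  bias <- mean(bvals[alpha[wsv] < 10 - 1e-5])
  dec <- colSums(alpha * y * K) + bias
  qpPred <- ifelse(dec > 0, "granulation", "slough")
  expect_identical(predict(m, tab), unname(qpPred))
  expect_identical(predict(m, tab), tab$label)   # separable toy
})

test_that("prediction is invariant to standardization being baked in", {
  set.seed(7)
  tab <- data.frame(label = rep(c("granulation", "slough"), each = 10),
                    a = rnorm(20, rep(c(0, 500), each = 10), 40),
                    b = rnorm(20, rep(c(0, 0.03), each = 10), 0.005))
  m <- fitSVM(tab, kernel = "rbf")
  # raw-scale queries go through the stored standardizer: training points
  # classify back to their labels despite wildly mixed feature scales
  expect_identical(predict(m, tab), tab$label)
  mB <- fitBayes(tab)
  expect_identical(predict(mB, tab), tab$label)
})

test_that("models round-trip through JSON with identical predictions", {
  set.seed(9)
  tab <- data.frame(label = rep(c("granulation", "slough", "necrotic"),
                                each = 8),
                    a = rnorm(24) + rep(c(0, 3, 6), each = 8),
                    b = rnorm(24) + rep(c(2, 0, -2), each = 8))
  q <- data.frame(a = rnorm(30, 3, 3), b = rnorm(30, 0, 2))
  for (mk in list(fitBayes(tab), fitSVM(tab, kernel = "poly3"))) {
    tf <- tempfile(fileext = ".json")
    writeModelJSON(mk, tf)
    back <- readModelJSON(tf)
    expect_identical(predict(back, q), predict(mk, q))
  }
})

test_that("well-separated Gaussian clusters are classified almost perfectly", {
  set.seed(33)
  gen <- function(n) {
    mu <- rbind(c(0, 0), c(4, 0), c(0, 4))   # >= 4 sigma apart, sigma = 1
    lab <- rep(tissueClasses(), each = n)
    data.frame(label = lab,
               a = rnorm(3 * n) + mu[rep(1:3, each = n), 1],
               b = rnorm(3 * n) + mu[rep(1:3, each = n), 2])
  }
  train <- gen(40); test <- gen(25)
  models <- c(list(fitBayes(train)),
              lapply(c("linear", "poly2", "poly3", "rbf"),
                     function(k) fitSVM(train, kernel = k)))
  for (m in models)
    expect_gte(mean(predict(m, test) == test$label), 0.95)
})
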