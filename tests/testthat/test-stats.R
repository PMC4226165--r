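# construct a two-column dataset whose sample correlation is exactly r
make_pair_with_r <- function(n, r, seed = 1) {
  set.seed(seed)
  x <- scale(rnorm(n))[, 1]
  e <- stats::residuals(lm(rnorm(n) ~ x)) # exactly orthogonal to x
  tibble::tibble(x = x, y = r * x + sqrt(1 - r^2) * e / sd(e))
}

test_that("pearson_matrix reproduces cor.test and flags degenerate input", {
  set.seed(2)
  d <- tibble::tibble(a = rnorm(16), b = rnorm(16), c = rnorm(16))
  cm <- pearson_matrix(d)
  ct <- stats::cor.test(d$a, d$b)
  expect_equal(cm$r["a", "b"], unname(ct$estimate), tolerance = 1e-12)
  expect_equal(cm$p["a", "b"], ct$p.value, tolerance = 1e-12)
  expect_equal(diag(cm$r), c(a = 1, b = 1, c = 1))
  expect_identical(cm$r, t(cm$r))
  # y = x exactly
  cm <- pearson_matrix(tibble::tibble(x = 1:5, y = 1:5))
  expect_equal(cm$r["x", "y"], 1)
  # |r| = 0.63 at n = 16 is significant below 0.01
  d <- make_pair_with_r(16, 0.63, seed = 3)
  cm <- pearson_matrix(d)
  expect_equal(cm$r["x", "y"], 0.63, tolerance = 1e-9)
  expect_lt(cm$p["x", "y"], 0.01)
  expect_error(pearson_matrix(tibble::tibble(x = rep(1, 5), y = 1:5)),
               "zero variance")
  expect_error(pearson_matrix(d[1:2, ]), "at least 3")
})

test_that("correlations are invariant under affine rescaling", {
  set.seed(4)
  d <- tibble::tibble(a = rnorm(20), b = rnorm(20))
  d2 <- dplyr::mutate(d, a = 100 * a - 7, b = b / 3 + 2)
  expect_equal(pearson_matrix(d)$r, pearson_matrix(d2)$r,
               tolerance = 1e-12)
})

test_that("standardized OLS from correlations equals least squares on z-scores", {
  # single predictor: beta collapses to r
  fit <- standardized_ols_from_correlations(0.4, matrix(1), n = 20)
  expect_equal(unname(fit$beta), 0.4)
  # random well-conditioned problems against an lm oracle
  set.seed(8)
  for (i in 1:100) {
    n <- sample(10:40, 1)
    k <- sample(2:4, 1)
    X <- matrix(rnorm(n * k), n)
    y <- X %*% rnorm(k) + rnorm(n)
    Z <- scale(cbind(y, X))
    colnames(Z) <- c("y", paste0("x", 1:k))
    cm <- cor(Z)
    fit <- standardized_ols_from_correlations(cm[1, -1], cm[-1, -1], n = n)
    oracle <- lm(y ~ . - 1, data = as.data.frame(Z))
    expect_equal(unname(fit$beta), unname(coef(oracle)), tolerance = 1e-10)
    r2 <- 1 - sum(stats::residuals(oracle)^2) / (n - 1)
    expect_equal(fit$r_squared, r2, tolerance = 1e-10)
  }
  expect_error(
    standardized_ols_from_correlations(c(0.5, 0.5),
                                       matrix(c(1, 1, 1, 1), 2), n = 16),
    "singular")
})

test_that("the two-predictor normal equations reproduce published-style betas", {
  fit <- standardized_ols_from_correlations(
    c(0.63, -0.31), matrix(c(1, 0.07, 0.07, 1), 2), n = 16,
    labels = c("ne", "lf_hf"))
  expect_equal(round(unname(fit$beta[["ne"]]), 2), 0.65)
  expect_equal(fit$r_squared, 0.5229, tolerance = 1e-3)
  expect_equal(fit$adj_r_squared, 0.4495, tolerance = 1e-3)
  expect_equal(fit$df1, 2)
  expect_equal(fit$df2, 13)
  expect_lt(fit$p_coef[["ne"]], 0.05)
  g <- glance(fit)
  expect_lt(g$p.value, 0.01)
})

test_that("stepwise selection finds true predictors and controls false entry", {
  hits <- logical(200)
  only_x1 <- logical(200)
  for (s in 1:200) {
    set.seed(s)
    d <- tibble::tibble(x1 = rnorm(200), x2 = rnorm(200))
    d$y <- 0.8 * d$x1 + rnorm(200)
    sw <- stepwise_regression(d, "y")
    hits[s] <- "x1" %in% sw$selected
    only_x1[s] <- identical(sw$selected, "x1")
  }
  expect_true(all(hits))
  expect_gte(mean(only_x1), 0.90)

  empty <- logical(200)
  for (s in 1:200) {
    set.seed(s + 500)
    d <- tibble::tibble(x1 = rnorm(200), x2 = rnorm(200), y = rnorm(200))
    sw <- stepwise_regression(d, "y")
    empty[s] <- length(sw$selected) == 0
  }
  # two independent null candidates at p_enter = 0.05: ~0.95^2 empty
  expect_gt(mean(empty), 0.82)
  expect_lt(mean(empty), 0.98)
})

test_that("stepwise trace records entries and removals", {
  set.seed(12)
  d <- tibble::tibble(x1 = rnorm(100))
  d$x2 <- d$x1 + rnorm(100, sd = 0.1) # near-duplicate of x1
  d$y <- d$x1 + rnorm(100, sd = 0.5)
  sw <- stepwise_regression(d, "y")
  expect_true(all(c("step", "action", "variable", "p_value") %in%
                    names(sw$trace)))
  expect_true(nrow(sw$trace) >= 1)
  expect_true(all(sw$trace$action %in% c("enter", "remove")))
  expect_equal(nrow(tidy(sw)), length(sw$selected))
})

test_that("repeated-measures ANOVA matches the aov oracle on a 2 x 3 design", {
  d <- make_rm_data(8, c(2, 3), seed = 41)
  fit <- tidy(rm_anova(d, dv = "value", within = c("f1", "f2")))
  oracle <- summary(stats::aov(
    value ~ f1 * f2 + Error(factor(subject_id) / (f1 * f2)), data = d))
  of <- c(oracle[["Error: factor(subject_id):f1"]][[1]]["f1", "F value"],
          oracle[["Error: factor(subject_id):f2"]][[1]]["f2", "F value"],
          oracle[["Error: factor(subject_id):f1:f2"]][[1]]["f1:f2",
                                                           "F value"])
  expect_equal(fit$statistic, unname(of), tolerance = 1e-8)
  # 2-level effect: epsilon exactly 1
  expect_equal(fit$gg_epsilon[fit$effect == "f1"], 1)
  # epsilon within its theoretical bounds
  expect_true(all(fit$gg_epsilon > 1 / pmax(fit$df1, 1) - 1e-12 &
                    fit$gg_epsilon <= 1 + 1e-12))
  # partial eta squared consistent with its definition
  expect_equal(fit$partial_eta_sq,
               fit$ss_effect / (fit$ss_effect + fit$ss_error))
})

test_that("three-way within-subject ANOVA matches the aov oracle", {
  d <- make_rm_data(8, c(2, 2, 3), seed = 42)
  fit <- tidy(rm_anova(d, dv = "value", within = c("f1", "f2", "f3")))
  oracle <- summary(stats::aov(
    value ~ f1 * f2 * f3 + Error(factor(subject_id) / (f1 * f2 * f3)),
    data = d))
  for (eff in c("f1", "f2", "f3", "f1:f2", "f1:f3", "f2:f3", "f1:f2:f3")) {
    stratum <- oracle[[paste0("Error: factor(subject_id):", eff)]][[1]]
    expect_equal(fit$statistic[fit$effect == eff],
                 stratum[trimws(rownames(stratum)) == eff, "F value"],
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("degenerate and malformed ANOVA inputs are handled", {
  d <- make_rm_data(6, c(2, 3), seed = 43)
  d$value <- 1 # identical data everywhere
  fit <- tidy(rm_anova(d, dv = "value", within = c("f1", "f2")))
  expect_true(all(fit$statistic == 0))
  d <- make_rm_data(6, c(2, 3), seed = 44)
  expect_error(rm_anova(d[-1, ], dv = "value", within = c("f1", "f2")),
               "missing cell")
  d2 <- dplyr::bind_rows(d, d[1, ])
  expect_error(rm_anova(d2, dv = "value", within = c("f1", "f2")),
               "duplicate")
})
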