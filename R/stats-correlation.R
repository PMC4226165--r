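#' Pearson correlation matrix with two-sided p-values
#'
#' Pairwise Pearson correlations over the numeric columns of a
#' subjects-by-variables table, with two-sided p-values from the
#' t-transform `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` degrees of
#' freedom. No multiple-testing correction is applied.
#'
#' @param data Data frame with one row per subject; non-numeric columns
#'   (identifiers) are dropped unless `vars` is given.
#' @param vars Optional character vector naming the columns to use.
#' @return An object of class `expl_cormat` with elements `r`, `p`
#'   (matrices), `n` and `labels`. Use [tidy()] for a long tibble.
#' @examples
#' d <- tibble::tibble(x = rnorm(16), y = rnorm(16))
#' tidy(pearson_matrix(d))
#' @export
pearson_matrix <- function(data, vars = NULL) {
  stopifnot(is.data.frame(data))
  if (is.null(vars)) {
    vars <- names(data)[vapply(data, is.numeric, logical(1))]
  }
  m <- as.matrix(data[vars])
  n <- nrow(m)
  if (n < 3) abort("need at least 3 subjects for a correlation")
  if (anyNA(m)) abort("missing values are not allowed")
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) {
    abort(sprintf("column '%s' has zero variance: correlation undefined",
                  vars[sds == 0][1]))
  }
  r <- cor(m)
  tstat <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  diag(p) <- NA_real_
  structure(list(r = r, p = p, n = n, labels = vars),
            class = "expl_cormat")
}

#' @export
print.expl_cormat <- function(x, digits = 2, ...) {
  cat(sprintf("<Pearson correlation matrix: %d variables, n = %d>\n",
              length(x$labels), x$n))
  print(round(x$r, digits))
  invisible(x)
}

#' @rdname pearson_matrix
#' @param x An `expl_cormat`.
#' @param ... Unused.
#' @export
tidy.expl_cormat <- function(x, ...) {
  idx <- which(upper.tri(x$r), arr.ind = TRUE)
  tibble(
    var1 = x$labels[idx[, 1]],
    var2 = x$labels[idx[, 2]],
    r = x$r[idx],
    p = x$p[idx],
    n = x$n
  )
}

#' Standardized regression solved from a correlation matrix
#'
#' Solves the standardized normal equations `beta = R_xx^{-1} r_yx` for the
#' standardized coefficients of a multiple regression, given only the
#' predictor intercorrelation matrix `R_xx` and the predictor-response
#' correlations `r_yx` — the computation that reconstructs a published
#' standardized model from a printed correlation table. `R^2 = r_yx' beta`,
#' adjusted `R^2 = 1 - (1 - R^2)(n - 1)/(n - k - 1)`, the model F has
#' `(k, n - k - 1)` degrees of freedom, and coefficient t-tests use
#' `Var(beta_j) = (1 - R^2) [R_xx^{-1}]_jj / (n - k - 1)`. Results are
#' identical to ordinary least squares on z-scored raw data having exactly
#' these sample correlations.
#'
#' @param r_yx Numeric vector of correlations between the response and each
#'   predictor.
#' @param R_xx Predictor correlation matrix (`k x k`); a scalar 1 is
#'   accepted for a single predictor.
#' @param n Number of subjects.
#' @param labels Optional predictor names.
#' @return An object of class `expl_std_ols`; see [tidy()] and [glance()].
#' @examples
#' # two predictors correlated 0.07, with response correlations 0.63, -0.31
#' fit <- standardized_ols_from_correlations(
#'   c(0.63, -0.31), matrix(c(1, 0.07, 0.07, 1), 2), n = 16)
#' round(fit$beta, 2)
#' @export
standardized_ols_from_correlations <- function(r_yx, R_xx, n, labels = NULL) {
  r_yx <- as.numeric(r_yx)
  R_xx <- as.matrix(R_xx)
  k <- length(r_yx)
  stopifnot(nrow(R_xx) == k, ncol(R_xx) == k, n > k + 1)
  labels <- labels %||% rownames(R_xx) %||% paste0("x", seq_len(k))
  Rinv <- tryCatch(solve(R_xx), error = function(e) {
    abort("predictor correlation matrix is singular (collinear predictors)")
  })
  beta <- drop(Rinv %*% r_yx)
  r2 <- sum(r_yx * beta)
  df2 <- n - k - 1
  adj_r2 <- 1 - (1 - r2) * (n - 1) / df2
  fstat <- (r2 / k) / ((1 - r2) / df2)
  se <- sqrt((1 - r2) * diag(Rinv) / df2)
  tstat <- beta / se
  p_coef <- 2 * pt(abs(tstat), df = df2, lower.tail = FALSE)
  structure(list(
    predictors = labels, beta = setNames(beta, labels),
    se = setNames(se, labels), t = setNames(tstat, labels),
    p_coef = setNames(p_coef, labels),
    r_squared = r2, adj_r_squared = adj_r2,
    f_statistic = fstat, df1 = k, df2 = df2,
    p_model = pf(fstat, k, df2, lower.tail = FALSE), n = n
  ), class = "expl_std_ols")
}

#' @export
print.expl_std_ols <- function(x, ...) {
  cat(sprintf(
    "<standardized OLS: R2 = %.3f, adj R2 = %.3f, F(%d,%d) = %.2f, p = %.3g>\n",
    x$r_squared, x$adj_r_squared, x$df1, x$df2, x$f_statistic, x$p_model))
  print(tidy(x))
  invisible(x)
}

#' @rdname standardized_ols_from_correlations
#' @param x An `expl_std_ols`.
#' @param ... Unused.
#' @export
tidy.expl_std_ols <- function(x, ...) {
  tibble(term = x$predictors, estimate = unname(x$beta),
         std.error = unname(x$se), statistic = unname(x$t),
         p.value = unname(x$p_coef))
}

#' @rdname standardized_ols_from_correlations
#' @export
glance.expl_std_ols <- function(x, ...) {
  tibble(r.squared = x$r_squared, adj.r.squared = x$adj_r_squared,
         statistic = x$f_statistic, df = x$df1, df.residual = x$df2,
         p.value = x$p_model, nobs = x$n)
}

#' Stepwise regression by forward selection with removal
#'
#' Forward selection: at each step the candidate with the smallest partial
#' p-value enters if it is below `p_enter`; after each entry, any included
#' variable whose p-value has risen above `p_remove` leaves. Stops when no
#' candidate can enter. If nothing ever meets `p_enter` the empty
#' (intercept-only) model is returned — not an error. A trace records every
#' entry and removal.
#'
#' @param data Data frame containing the response and candidate predictors.
#' @param response Name of the response column.
#' @param predictors Candidate predictor names (default: every other
#'   numeric column).
#' @param p_enter,p_remove Entry / removal thresholds (defaults 0.05,
#'   0.10).
#' @return An object of class `expl_stepwise` with the selected variables,
#'   the final [lm] fit (`NULL` if empty), standardized coefficients of the
#'   final model, and a `trace` tibble.
#' @export
stepwise_regression <- function(data, response, predictors = NULL,
                                p_enter = 0.05, p_remove = 0.10) {
  stopifnot(is.data.frame(data), response %in% names(data))
  if (is.null(predictors)) {
    predictors <- setdiff(
      names(data)[vapply(data, is.numeric, logical(1))], response)
  }
  y <- data[[response]]
  selected <- character(0)
  trace <- list()
  step <- 0L
  coef_p <- function(vars) {
    if (length(vars) == 0) return(numeric(0))
    fit <- lm(stats::reformulate(vars, response), data = data)
    summary(fit)$coefficients[-1, 4]
  }
  repeat {
    candidates <- setdiff(predictors, selected)
    if (length(candidates) == 0) break
    entry_p <- vapply(candidates, function(v) {
      ps <- coef_p(c(selected, v))
      unname(ps[length(ps)])
    }, numeric(1))
    best <- which.min(entry_p)
    if (length(best) == 0 || entry_p[best] >= p_enter) break
    step <- step + 1L
    selected <- c(selected, candidates[best])
    trace[[length(trace) + 1]] <- tibble(
      step = step, action = "enter", variable = candidates[best],
      p_value = unname(entry_p[best]))
    repeat {
      ps <- coef_p(selected)
      if (length(ps) == 0) break
      worst <- which.max(ps)
      if (ps[worst] <= p_remove) break
      step <- step + 1L
      trace[[length(trace) + 1]] <- tibble(
        step = step, action = "remove", variable = selected[worst],
        p_value = unname(ps[worst]))
      selected <- selected[-worst]
    }
  }
  fit <- if (length(selected)) {
    lm(stats::reformulate(selected, response), data = data)
  } else NULL
  std_beta <- if (length(selected)) {
    zd <- as.data.frame(scale(data[c(response, selected)]))
    coef(lm(stats::reformulate(selected, response), data = zd))[-1]
  } else numeric(0)
  structure(list(
    response = response, selected = selected, fit = fit,
    std_beta = std_beta,
    trace = if (length(trace)) dplyr::bind_rows(trace) else
      tibble(step = integer(), action = character(),
             variable = character(), p_value = numeric()),
    p_enter = p_enter, p_remove = p_remove, n = nrow(data)
  ), class = "expl_stepwise")
}

#' @export
print.expl_stepwise <- function(x, ...) {
  if (length(x$selected) == 0) {
    cat(sprintf("<stepwise model of %s: empty (no predictor met p_enter = %g)>\n",
                x$response, x$p_enter))
  } else {
    cat(sprintf("<stepwise model of %s: %s>\n", x$response,
                paste(x$selected, collapse = " + ")))
    print(glance(x))
  }
  invisible(x)
}

#' @rdname stepwise_regression
#' @param x An `expl_stepwise`.
#' @param ... Unused.
#' @export
tidy.expl_stepwise <- function(x, ...) {
  if (is.null(x$fit)) {
    return(tibble(term = character(), estimate = numeric(),
                  std_estimate = numeric(), statistic = numeric(),
                  p.value = numeric()))
  }
  sm <- summary(x$fit)$coefficients
  tibble(term = rownames(sm)[-1], estimate = sm[-1, 1],
         std_estimate = unname(x$std_beta),
         statistic = sm[-1, 3], p.value = sm[-1, 4])
}

#' @rdname stepwise_regression
#' @export
glance.expl_stepwise <- function(x, ...) {
  if (is.null(x$fit)) {
    return(tibble(r.squared = 0, adj.r.squared = NA_real_,
                  statistic = NA_real_, df = 0L,
                  df.residual = x$n - 1L, p.value = NA_real_, nobs = x$n))
  }
  sm <- summary(x$fit)
  tibble(r.squared = sm$r.squared, adj.r.squared = sm$adj.r.squared,
         statistic = unname(sm$fstatistic[1]),
         df = as.integer(sm$fstatistic[2]),
         df.residual = as.integer(sm$fstatistic[3]),
         p.value = pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                      lower.tail = FALSE),
         nobs = x$n)
}
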