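#' Repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Fully within-subject ANOVA for balanced designs with one observation
#' per subject and cell (any number of within factors; the designs used
#' here are Condition x Block and Condition x Period x Block). Each effect
#' is tested against its own subject-by-effect error term via orthonormal
#' contrast scores: for effect *E* with orthonormal contrast matrix *W*,
#' `SS_effect = n * ||colMeans(Y W)||^2` and
#' `SS_error = (n - 1) * tr(cov(Y W))`. The Greenhouse-Geisser epsilon is
#' computed from the covariance of the contrast scores,
#' `eps = tr(S)^2 / (df * tr(S^2))`, and equals 1 exactly for
#' single-degree-of-freedom effects (2-level factors), where sphericity
#' holds trivially. Partial eta squared is
#' `SS_effect / (SS_effect + SS_error)`.
#'
#' @param data Long data frame with one row per subject and cell.
#' @param dv Name of the dependent-variable column.
#' @param within Character vector of within-subject factor column names.
#' @param subject Name of the subject identifier column (default
#'   `"subject_id"`).
#' @return An object of class `expl_rmanova`; [tidy()] returns the effect
#'   table with columns `effect`, `df1`, `df2`, `ss_effect`, `ss_error`,
#'   `statistic` (F), `p.value`, `gg_epsilon`, `p.value.gg`,
#'   `partial_eta_sq`.
#' @export
rm_anova <- function(data, dv, within, subject = "subject_id") {
  stopifnot(is.data.frame(data), dv %in% names(data),
            all(within %in% names(data)), subject %in% names(data))
  levs <- lapply(within, function(f) sort(unique(as.character(data[[f]]))))
  names(levs) <- within
  nlev <- vapply(levs, length, integer(1))
  subjects <- sort(unique(as.character(data[[subject]])))
  n <- length(subjects)
  if (n < 2) abort("need at least 2 subjects")

  # cell grid in a fixed order: last factor varies fastest
  grid <- rev(expand.grid(rev(levs), stringsAsFactors = FALSE))
  cell_key <- do.call(paste, c(grid, sep = "\r"))
  data_key <- do.call(paste, c(lapply(within, function(f)
    as.character(data[[f]])), sep = "\r"))
  Y <- matrix(NA_real_, n, nrow(grid),
              dimnames = list(subjects, cell_key))
  for (i in seq_len(nrow(data))) {
    s <- as.character(data[[subject]][i])
    jcol <- match(data_key[i], cell_key)
    if (!is.na(Y[s, jcol])) {
      abort(sprintf("duplicate observation for subject %s in cell (%s)",
                    s, gsub("\r", ", ", data_key[i])))
    }
    Y[s, jcol] <- data[[dv]][i]
  }
  if (anyNA(Y)) {
    miss <- which(is.na(Y), arr.ind = TRUE)[1, ]
    abort(sprintf("missing cell for subject %s: (%s)",
                  subjects[miss[1]],
                  gsub("\r", ", ", cell_key[miss[2]])))
  }

  orth_contrast <- function(L) {
    # orthonormal columns spanning the deviation-from-mean space
    qr.Q(qr(cbind(1, stats::contr.helmert(L))))[, -1, drop = FALSE]
  }
  unit <- function(L) matrix(1 / sqrt(L), L, 1)

  effects <- unlist(lapply(seq_along(within), function(k) {
    utils::combn(within, k, simplify = FALSE)
  }), recursive = FALSE)

  rows <- purrr::map(effects, function(eff) {
    W <- Reduce(function(a, b) kronecker(a, b),
                lapply(within, function(f) {
                  if (f %in% eff) orth_contrast(nlev[[f]])
                  else unit(nlev[[f]])
                }))
    scores <- Y %*% W
    df1 <- ncol(scores)
    mu <- colMeans(scores)
    ss_eff <- n * sum(mu^2)
    S <- stats::cov(scores)
    ss_err <- (n - 1) * sum(diag(S))
    df2 <- df1 * (n - 1)
    fstat <- if (ss_err > 0) (ss_eff / df1) / (ss_err / df2) else 0
    eps <- if (df1 == 1) 1 else sum(diag(S))^2 / (df1 * sum(S * S))
    tibble(
      effect = paste(eff, collapse = ":"),
      df1 = df1, df2 = df2, ss_effect = ss_eff, ss_error = ss_err,
      statistic = fstat,
      p.value = pf(fstat, df1, df2, lower.tail = FALSE),
      gg_epsilon = eps,
      p.value.gg = pf(fstat, eps * df1, eps * df2, lower.tail = FALSE),
      partial_eta_sq = if (ss_eff + ss_err > 0) ss_eff / (ss_eff + ss_err)
                       else 0
    )
  })
  structure(list(table = dplyr::bind_rows(rows), dv = dv, within = within,
                 n = n), class = "expl_rmanova")
}

#' @export
print.expl_rmanova <- function(x, ...) {
  cat(sprintf("<repeated-measures ANOVA of %s (%s), n = %d>\n",
              x$dv, paste(x$within, collapse = " x "), x$n))
  print(as.data.frame(x$table), digits = 4)
  invisible(x)
}

#' @rdname rm_anova
#' @param x An `expl_rmanova`.
#' @param ... Unused.
#' @export
tidy.expl_rmanova <- function(x, ...) x$table
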