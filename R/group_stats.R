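#' Group summary of a scalar metric
#'
#' Mean, SD, SEM and the 90% confidence-interval half-width
#' (`t[0.95, n-1] * SEM`, the error-bar convention used for organoid group
#' plots). The t distribution, not the normal, is used throughout because
#' group sizes are small (typically 6-10 organoids).
#'
#' @param values numeric vector, length >= 2.
#' @param name group label.
#' @return a `group_summary` with fields `name, n, mean, sd, sem,
#'   ci90_halfwidth`.
#' @export
summarize_group <- function(values, name = "group") {
  values <- as.numeric(values)
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2L) stop("need at least 2 finite values to summarize a group")
  s <- sd(values)
  sem <- s / sqrt(n)
  structure(list(name = name, n = n, mean = mean(values), sd = s, sem = sem,
                 ci90_halfwidth = qt(0.95, n - 1L) * sem),
            class = "group_summary")
}

#' Build a group summary from a published mean, error bar and n
#'
#' Figures in this literature mix two error-bar conventions: SEM and 90% CI
#' half-width. This converter makes the reading explicit: with
#' `interpretation = "ci90"`, `sem = halfwidth / t[0.95, n-1]`.
#'
#' @param mean,halfwidth printed mean and error-bar half-width.
#' @param n group size.
#' @param interpretation `"sem"` or `"ci90"`.
#' @param name group label.
#' @return a `group_summary` (with `sd` back-computed as `sem * sqrt(n)`).
#' @export
summary_from_errorbar <- function(mean, halfwidth, n,
                                  interpretation = c("sem", "ci90"),
                                  name = "group") {
  interpretation <- match.arg(interpretation)
  if (halfwidth < 0) stop("'halfwidth' must be >= 0")
  if (n < 2L) stop("'n' must be >= 2")
  sem <- switch(interpretation, sem = halfwidth,
                ci90 = halfwidth / qt(0.95, n - 1L))
  structure(list(name = name, n = as.integer(n), mean = mean,
                 sd = sem * sqrt(n), sem = sem,
                 ci90_halfwidth = qt(0.95, n - 1L) * sem),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("%s: mean %.4g +/- %.3g (SEM), 90%% CI half-width %.3g, n=%d\n",
              x$name, x$mean, x$sem, x$ci90_halfwidth, x$n))
  invisible(x)
}

#' Two-sample t-test from group summaries
#'
#' Classical pooled-variance Student test (`df = n_a + n_b - 2`, the
#' default) or Welch with Satterthwaite degrees of freedom; two-sided p
#' from the t distribution. Both methods operate on summary statistics so
#' published group means can be tested directly.
#'
#' @param a,b `group_summary` objects.
#' @param method `"pooled"` or `"welch"`.
#' @return a `t_test_result` with `t, df, p, method, degenerate, inputs`.
#'   If both dispersions are zero and the means differ, `p` is reported as
#'   0 with `degenerate = TRUE`.
#' @export
t_test_from_summary <- function(a, b, method = c("pooled", "welch")) {
  method <- match.arg(method)
  stopifnot(inherits(a, "group_summary"), inherits(b, "group_summary"))
  if (a$n < 2L || b$n < 2L) stop("both groups need n >= 2")
  va <- a$sd^2; vb <- b$sd^2
  diff <- a$mean - b$mean
  degenerate <- FALSE
  if (va == 0 && vb == 0) {
    if (diff == 0) {
      res <- list(t = 0, df = a$n + b$n - 2, p = 1)
    } else {
      degenerate <- TRUE
      res <- list(t = sign(diff) * Inf, df = a$n + b$n - 2, p = 0)
    }
  } else if (method == "pooled") {
    sp2 <- ((a$n - 1) * va + (b$n - 1) * vb) / (a$n + b$n - 2)
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
    tt <- diff / se
    df <- a$n + b$n - 2
    res <- list(t = tt, df = df, p = 2 * pt(-abs(tt), df))
  } else {
    se2a <- va / a$n; se2b <- vb / b$n
    se <- sqrt(se2a + se2b)
    tt <- diff / se
    df <- (se2a + se2b)^2 /
      (se2a^2 / (a$n - 1) + se2b^2 / (b$n - 1))
    res <- list(t = tt, df = df, p = 2 * pt(-abs(tt), df))
  }
  structure(c(res, list(method = method, degenerate = degenerate,
                        inputs = list(a = a, b = b))),
            class = "t_test_result")
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf("two-sample t (%s): t = %.4g, df = %.4g, p = %.4g%s\n",
              x$method, x$t, x$df, x$p,
              if (x$degenerate) "  [degenerate: zero dispersion]" else ""))
  invisible(x)
}

#' Two-sample t-test from raw values
#'
#' @param x,y numeric vectors.
#' @inheritParams t_test_from_summary
#' @param names labels for the two groups.
#' @return a `t_test_result`.
#' @export
t_test_values <- function(x, y, method = c("pooled", "welch"),
                          names = c("a", "b")) {
  t_test_from_summary(summarize_group(x, names[1]),
                      summarize_group(y, names[2]), method = method)
}

#' Summaries and pairwise tests for named groups of values
#'
#' @param groups named list of numeric vectors (>= 2 values each).
#' @param method t-test flavour, as in [t_test_from_summary()].
#' @return list with `summaries` (one `group_summary` per group) and
#'   `tests` (a data.frame of all pairwise comparisons: t, df, p for both
#'   pooled and Welch).
#' @export
compare_groups <- function(groups, method = c("pooled", "welch")) {
  stopifnot(is.list(groups), length(groups) >= 1L, !is.null(names(groups)))
  summaries <- lapply(names(groups), function(nm)
    summarize_group(groups[[nm]], nm))
  names(summaries) <- names(groups)
  tests <- NULL
  nms <- names(groups)
  if (length(nms) >= 2L) {
    pairs <- utils::combn(nms, 2L)
    rows <- lapply(seq_len(ncol(pairs)), function(i) {
      a <- summaries[[pairs[1, i]]]; b <- summaries[[pairs[2, i]]]
      tp <- t_test_from_summary(a, b, "pooled")
      tw <- t_test_from_summary(a, b, "welch")
      data.frame(group_a = a$name, group_b = b$name,
                 t_pooled = tp$t, df_pooled = tp$df, p_pooled = tp$p,
                 t_welch = tw$t, df_welch = tw$df, p_welch = tw$p)
    })
    tests <- do.call(rbind, rows)
  }
  list(summaries = summaries, tests = tests)
}

summary_to_row <- function(s) {
  data.frame(name = s$name, n = s$n, mean = s$mean, sd = s$sd, sem = s$sem,
             ci90_halfwidth = s$ci90_halfwidth)
}
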