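#' Two-tailed Student's t-test (pooled variance)
#'
#' Implemented from the closed form: the pooled-variance t statistic with
#' df = n_a + n_b - 2, and the two-sided p-value from the regularized
#' incomplete beta function, P(|T| > t) = I_{df/(df + t^2)}(df/2, 1/2).
#' Welch's unequal-variance form is available behind `var_equal = FALSE`.
#'
#' @param a,b Numeric vectors, each with at least 2 finite values.
#' @param alpha Significance cutoff (default 0.05).
#' @param var_equal Pool the variances (default `TRUE`, Student's test).
#' @return A `stat_result`: statistic, df, p_value, test_name, alpha,
#'   significant.
#' @export
students_t_test <- function(a, b, alpha = 0.05, var_equal = TRUE) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L || anyNA(a) || anyNA(b) ||
      !all(is.finite(c(a, b))))
    abort_field("a/b", "both groups need >= 2 finite values")
  check_number(alpha, "alpha", lower = 0, upper = 1, strict_lower = TRUE)
  na <- length(a)
  nb <- length(b)
  va <- var(a)
  vb <- var(b)
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    if (sp2 == 0)
      stop("pooled variance is zero; t statistic undefined", call. = FALSE)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
    name <- "Student t (two-tailed, pooled)"
  } else {
    if (va == 0 && vb == 0)
      stop("both variances are zero; t statistic undefined", call. = FALSE)
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    name <- "Welch t (two-tailed)"
  }
  t_stat <- (mean(a) - mean(b)) / se
  p <- pbeta(df / (df + t_stat^2), df / 2, 0.5)
  stat_result(t_stat, df, p, name, alpha)
}

#' One-way ANOVA
#'
#' F statistic from between/within sums of squares with df (k-1, N-k); the
#' p-value comes from the F distribution through the regularized incomplete
#' beta function, P(F > f) = I_{df2/(df2 + df1 f)}(df2/2, df1/2).
#'
#' @param groups List of >= 2 numeric vectors, each with >= 2 values.
#' @param alpha Significance cutoff.
#' @return A `stat_result`; `df` is the pair `c(df1, df2)`.
#' @export
one_way_anova <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2L)
    abort_field("groups", "must be a list of >= 2 groups")
  groups <- lapply(groups, as.numeric)
  if (any(vapply(groups, length, integer(1)) < 2L) ||
      any(!vapply(groups, function(g) all(is.finite(g)), logical(1))))
    abort_field("groups", "every group needs >= 2 finite values")
  check_number(alpha, "alpha", lower = 0, upper = 1, strict_lower = TRUE)
  k <- length(groups)
  ns <- vapply(groups, length, integer(1))
  N <- sum(ns)
  means <- vapply(groups, mean, numeric(1))
  grand <- sum(ns * means) / N
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  if (ssw == 0)
    stop("zero within-group variance everywhere; F statistic undefined",
         call. = FALSE)
  df1 <- k - 1
  df2 <- N - k
  f_stat <- (ssb / df1) / (ssw / df2)
  p <- pbeta(df2 / (df2 + df1 * f_stat), df2 / 2, df1 / 2)
  stat_result(f_stat, c(df1, df2), p, "one-way ANOVA", alpha)
}

stat_result <- function(statistic, df, p_value, test_name, alpha) {
  structure(list(statistic = statistic, df = df,
                 p_value = min(max(p_value, 0), 1),
                 test_name = test_name, alpha = alpha,
                 significant = p_value < alpha),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4f, df = %s, p = %.4g%s\n", x$test_name,
              x$statistic, paste(format(x$df, digits = 4), collapse = ", "),
              x$p_value,
              if (x$significant) sprintf(" (significant at %g)", x$alpha)
              else ""))
  invisible(x)
}

#' Fold change relative to a reference group
#'
#' Each value is divided by the mean of the reference group, so the reference
#' group itself maps to mean 1.  The transform is a common rescaling of both
#' groups and therefore leaves t-test p-values unchanged.
#'
#' @param values Numeric vector to express as fold change.
#' @param reference Numeric reference-group values with non-zero mean.
#' @return Numeric vector of fold changes.
#' @export
fold_change <- function(values, reference) {
  values <- as.numeric(values)
  reference <- as.numeric(reference)
  if (length(reference) < 1L || !all(is.finite(reference)))
    abort_field("reference", "must be non-empty and finite")
  m <- mean(reference)
  if (m == 0) stop("reference mean is zero; fold change undefined",
                   call. = FALSE)
  values / m
}

numeric_parameters <- function(df, exclude = c("group_label", "field_id",
                                               "run_id")) {
  nm <- setdiff(names(df), exclude)
  nm[vapply(df[nm], is.numeric, logical(1))]
}

#' Build a group-comparison report
#'
#' Produces, for each requested comparison, a table of per-parameter group
#' means +/- SEM with the chosen test (two-tailed Student's t for two groups,
#' one-way ANOVA otherwise), the p-value and a significance marker at
#' `alpha`.  Parameter and comparison ordering is deterministic (input
#' order).
#'
#' @param records Optional data frame of morphometry records (post filtering
#'   and normalization), keyed by `group_label`.
#' @param rates Optional data frame of per-run state rates
#'   ([rates_table()]), keyed by `group_label`.
#' @param comparisons List of comparisons; each is a list with `data`
#'   ("morphometry" or "respirometry"), `groups` (character vector of group
#'   labels), optional `test` ("t" or "anova"; default "t" for two groups),
#'   and optional `parameters` (default: all numeric columns).
#' @param alpha Significance cutoff applied throughout.
#' @return An object of class `analysis_report`: list with `summaries` (per
#'   dataset long mean/SEM tables) and `comparisons` (one row per parameter
#'   per comparison).
#' @export
build_report <- function(records = NULL, rates = NULL, comparisons = list(),
                         alpha = 0.05) {
  datasets <- list(morphometry = records, respirometry = rates)
  datasets <- datasets[!vapply(datasets, is.null, logical(1))]
  if (length(datasets) == 0L)
    abort_field("records/rates", "at least one dataset is required")

  summaries <- lapply(datasets, function(df) {
    params <- numeric_parameters(df)
    rows <- list()
    for (grp in unique(df$group_label)) {
      for (p in params) {
        v <- df[[p]][df$group_label == grp]
        v <- v[!is.na(v)]
        rows[[length(rows) + 1L]] <- data.frame(
          group_label = grp, parameter = p, n = length(v),
          mean = if (length(v) > 0L) mean(v) else NA_real_,
          sem = if (length(v) > 1L) sd(v) / sqrt(length(v)) else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })

  cmp_rows <- list()
  for (ci in seq_along(comparisons)) {
    cmp <- comparisons[[ci]]
    dat_name <- cmp$data %||% "morphometry"
    if (!dat_name %in% names(datasets))
      abort_field("comparisons",
                  sprintf("comparison %d needs dataset '%s' which was not supplied",
                          ci, dat_name))
    df <- datasets[[dat_name]]
    unmatched <- setdiff(cmp$groups, unique(df$group_label))
    if (length(unmatched) > 0L)
      stop(sprintf("comparison %d: unmatched group labels: %s", ci,
                   paste(unmatched, collapse = ", ")), call. = FALSE)
    test <- cmp$test %||% if (length(cmp$groups) == 2L) "t" else "anova"
    params <- cmp$parameters %||% numeric_parameters(df)
    for (p in params) {
      vals <- lapply(cmp$groups, function(g) {
        v <- df[[p]][df$group_label == g]
        v[!is.na(v)]
      })
      res <- if (test == "t") {
        students_t_test(vals[[1L]], vals[[2L]], alpha = alpha)
      } else {
        one_way_anova(vals, alpha = alpha)
      }
      row <- data.frame(
        comparison = ci, data = dat_name, parameter = p,
        groups = paste(cmp$groups, collapse = " vs "),
        test_name = res$test_name, statistic = res$statistic,
        p_value = res$p_value, significant = res$significant,
        marker = if (res$significant) "*" else "",
        stringsAsFactors = FALSE)
      for (gi in seq_along(cmp$groups)) {
        v <- vals[[gi]]
        row[[paste0("mean_", cmp$groups[gi])]] <- mean(v)
        row[[paste0("sem_", cmp$groups[gi])]] <-
          if (length(v) > 1L) sd(v) / sqrt(length(v)) else NA_real_
      }
      cmp_rows[[length(cmp_rows) + 1L]] <- row
    }
  }
  cmp_df <- if (length(cmp_rows) > 0L) {
    nms <- unique(unlist(lapply(cmp_rows, names)))
    do.call(rbind, lapply(cmp_rows, function(r) {
      for (nm in setdiff(nms, names(r))) r[[nm]] <- NA
      r[nms]
    }))
  } else {
    NULL
  }
  structure(list(summaries = summaries, comparisons = cmp_df, alpha = alpha),
            class = "analysis_report")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.analysis_report <- function(x, ...) {
  for (nm in names(x$summaries)) {
    cat(sprintf("== %s: group mean +/- SEM ==\n", nm))
    print(x$summaries[[nm]], row.names = FALSE)
    cat("\n")
  }
  if (!is.null(x$comparisons)) {
    cat(sprintf("== comparisons (alpha = %g; * = significant) ==\n", x$alpha))
    print(x$comparisons, row.names = FALSE)
  } else {
    cat("(no comparisons requested)\n")
  }
  invisible(x)
}
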