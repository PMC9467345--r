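#' Summary statistic triple
#'
#' Group summaries in the mean +/- SD convention of clinical tables; accepted
#' by [ttest_two_sample()] in place of raw values, so printed tables can be
#' re-tested without individual-level data.
#'
#' @param n Group size, >= 2.
#' @param mean Group mean.
#' @param sd Group standard deviation, >= 0.
#' @return An object of class `summary_stat`.
#' @export
summary_stat <- function(n, mean, sd) {
  if (n < 2) stop("`n` must be >= 2")
  if (sd < 0) stop("`sd` must be >= 0")
  structure(list(n = as.integer(n), mean = as.numeric(mean),
                 sd = as.numeric(sd)),
            class = "summary_stat")
}

as_summary_stat <- function(x) {
  if (inherits(x, "summary_stat")) return(x)
  if (is.numeric(x)) {
    if (length(x) < 2) stop("need at least 2 values per group")
    return(summary_stat(length(x), mean(x), stats::sd(x)))
  }
  stop("expected a numeric vector or a summary_stat")
}

#' Unpaired two-sample t-test (raw values or summary statistics)
#'
#' Student's pooled-variance test by default, Welch-Satterthwaite on request.
#' Each group may be given either as a vector of raw values or as a
#' `summary_stat` (n, mean, sd); the two paths agree exactly when the
#' summaries are computed from the raw values, so the test is applicable to
#' published group summaries.
#'
#' @param a,b Numeric vectors or `summary_stat` objects.
#' @param variant `"student"` (default) or `"welch"`.
#' @return List with `t`, `df`, `p` (two-sided), `mean_diff`, `variant`.
#' @export
ttest_two_sample <- function(a, b, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  a <- as_summary_stat(a); b <- as_summary_stat(b)
  if (a$sd == 0 && b$sd == 0 && a$mean == b$mean)
    stop("zero variance in both groups with equal means: t undefined")
  md <- a$mean - b$mean
  if (variant == "student") {
    df <- a$n + b$n - 2
    sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
  } else {
    va <- a$sd^2 / a$n; vb <- b$sd^2 / b$n
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  }
  if (se == 0) stop("zero standard error: t undefined")
  t <- md / se
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df),
       mean_diff = md, variant = variant)
}

#' Pearson chi-square test on a 2 x 2 table
#'
#' Without Yates continuity correction by default (the convention under
#' which the published sex-ratio comparison reproduces); correction
#' available by flag.
#'
#' @param table 2 x 2 matrix of non-negative counts with no zero margin.
#' @param yates Apply the continuity correction (default FALSE).
#' @return List with `chisq`, `df` (= 1), `p`.
#' @export
chisq_2x2 <- function(table, yates = FALSE) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2)) || any(table < 0))
    stop("`table` must be a 2 x 2 matrix of non-negative counts")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero margin: chi-square undefined")
  # asymptotic Pearson test by design; suppress the small-count advisory
  ht <- suppressWarnings(stats::chisq.test(table, correct = yates))
  list(chisq = unname(ht$statistic), df = 1, p = unname(ht$p.value))
}

#' Pearson product-moment correlation
#'
#' Two-sided p-value via the t transform with n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length >= 3, finite values.
#' @return List with `r`, `df`, `p`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("values must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  ht <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ht$estimate), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Partial correlation controlling for covariates
#'
#' Correlation between the residuals of `x` and `y` after least-squares
#' projection on the covariates (plus intercept); this is the adjustment
#' used for the age- and sex-adjusted p-values in the cohort tables, with
#' sex encoded 0/1. With an empty covariate set it reduces exactly to
#' [pearson_r()]. Degrees of freedom are n - 2 - (number of covariates).
#'
#' @param x,y Numeric vectors.
#' @param covariates Numeric matrix / data.frame with one row per
#'   observation, or NULL for none.
#' @return List with `r`, `df`, `p`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  n <- length(x)
  if (is.null(covariates) || NCOL(covariates) == 0 || NROW(covariates) == 0)
    return(pearson_r(x, y))
  Z <- as.matrix(covariates)
  storage.mode(Z) <- "double"
  if (nrow(Z) != n) stop("covariates must have one row per observation")
  k <- ncol(Z)
  if (n <= k + 2) stop("need n > number of covariates + 2")
  X <- cbind(1, Z)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X))
    stop("collinear covariates: design matrix is rank-deficient")
  rx <- stats::resid(stats::lm.fit(X, x))
  ry <- stats::resid(stats::lm.fit(X, y))
  if (sqrt(mean(rx^2)) < 1e-10 * max(1, stats::sd(x)) ||
      sqrt(mean(ry^2)) < 1e-10 * max(1, stats::sd(y)))
    stop("a variable is collinear with the covariates: residual is zero, ",
         "partial correlation undefined")
  r <- stats::cor(rx, ry)
  df <- n - 2 - k
  t <- r * sqrt(df / (1 - r^2))
  list(r = r, df = df, p = 2 * stats::pt(-abs(t), df))
}

fmt_msd <- function(x, digits = 2) {
  sprintf(paste0("%.", digits, "f ± %.", digits, "f (%.", digits,
                 "f–%.", digits, "f)"),
          mean(x), stats::sd(x), min(x), max(x))
}

#' Group-comparison report over a cohort table
#'
#' Reproduces the structure of the clinical tables: per-group mean +/- SD
#' (range) for every metric, the unadjusted between-group p-value (Student's
#' t-test for continuous metrics, chi-square for the sex ratio) and the age-
#' and sex-adjusted p-value (partial correlation between the 0/1 group
#' indicator and the metric, controlling age and sex). Three tables are
#' produced: participant characteristics, flow-void metrics (PPE vs
#' control), and flow-void metrics within PPE split by pachyvessel presence
#' in the 3 x 3 mm field.
#'
#' @param cohort Cohort data.frame (schema of [generate_cohort()]) or a path
#'   to such a CSV.
#' @param ttest_variant `"student"` (default) or `"welch"`.
#' @return List of class `cohort_report` with data.frames `characteristics`,
#'   `flow_voids`, `pachyvessel_split`. With a single group the p columns
#'   are NA and a notice is emitted.
#' @export
run_table_reports <- function(cohort, ttest_variant = c("student", "welch")) {
  ttest_variant <- match.arg(ttest_variant)
  if (is.character(cohort)) cohort <- read_cohort_csv(cohort)
  need <- c("eye_id", "group", "age", "sex", "axial_length_mm", "sfct_um",
            "pachyvessel_in_3mm", "n_voids", "total_void_area_mm2",
            "mean_void_size_um2", "rpe_vein_distance_um")
  missing <- setdiff(need, names(cohort))
  if (length(missing) > 0)
    stop("cohort is missing column(s): ", paste(missing, collapse = ", "))

  two_group_rows <- function(dat, split, metrics, labels) {
    split <- factor(as.character(split), levels = unique(as.character(split)))
    gs <- base::split(seq_len(nrow(dat)), split)
    if (length(gs) < 2) {
      message("only one group present: p columns left empty")
      one <- dat[gs[[1]], , drop = FALSE]
      return(data.frame(metric = labels,
                        group1 = vapply(metrics, function(m) fmt_msd(one[[m]]),
                                        character(1)),
                        group2 = NA_character_, p = NA_real_,
                        p_adjusted = NA_real_, stringsAsFactors = FALSE))
    }
    g1 <- dat[gs[[1]], , drop = FALSE]
    g2 <- dat[gs[[2]], , drop = FALSE]
    ind <- as.numeric(split[unlist(gs)] == names(gs)[1])
    orddat <- dat[unlist(gs), , drop = FALSE]
    cov <- cbind(age = orddat$age, sex = as.numeric(orddat$sex == "M"))
    rows <- lapply(seq_along(metrics), function(i) {
      m <- metrics[i]
      p <- tryCatch(ttest_two_sample(g1[[m]], g2[[m]], ttest_variant)$p,
                    error = function(e) NA_real_)
      padj <- if (m %in% c("age")) NA_real_ else
        tryCatch(partial_correlation(ind, orddat[[m]], cov)$p,
                 error = function(e) NA_real_)
      data.frame(metric = labels[i], group1 = fmt_msd(g1[[m]]),
                 group2 = fmt_msd(g2[[m]]), p = p, p_adjusted = padj,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }

  groups <- unique(cohort$group)
  two <- length(groups) >= 2
  char_metrics <- c("age", "axial_length_mm", "sfct_um")
  char_labels <- c("Age (yr)", "Axial length (mm)", "SFCT (um)")
  characteristics <- two_group_rows(cohort, cohort$group, char_metrics,
                                    char_labels)
  # sex row by chi-square
  sex_row <- if (two) {
    tab <- table(factor(cohort$group, levels = groups),
                 factor(cohort$sex, levels = c("M", "F")))
    psex <- tryCatch(chisq_2x2(tab)$p, error = function(e) NA_real_)
    fmt_mf <- function(g) {
      s <- cohort$sex[cohort$group == g]
      sprintf("%d/%d", sum(s == "M"), sum(s == "F"))
    }
    data.frame(metric = "Sex (M/F)", group1 = fmt_mf(groups[1]),
               group2 = fmt_mf(groups[2]), p = psex, p_adjusted = NA_real_,
               stringsAsFactors = FALSE)
  } else {
    s <- cohort$sex
    data.frame(metric = "Sex (M/F)",
               group1 = sprintf("%d/%d", sum(s == "M"), sum(s == "F")),
               group2 = NA_character_, p = NA_real_, p_adjusted = NA_real_,
               stringsAsFactors = FALSE)
  }
  characteristics <- rbind(characteristics[1, , drop = FALSE], sex_row,
                           characteristics[-1, , drop = FALSE])
  rownames(characteristics) <- NULL

  fv_metrics <- c("n_voids", "total_void_area_mm2", "mean_void_size_um2")
  fv_labels <- c("Number of flow voids", "Total flow void area (mm2)",
                 "Average size of the flow voids (um2)")
  flow_voids <- two_group_rows(cohort, cohort$group, fv_metrics, fv_labels)

  ppe <- cohort[cohort$group == "PPE", , drop = FALSE]
  pachyvessel_split <- if (nrow(ppe) > 0 &&
                           length(unique(ppe$pachyvessel_in_3mm)) == 2) {
    split_lab <- factor(ifelse(ppe$pachyvessel_in_3mm, "pachyvessel",
                               "no_pachyvessel"),
                        levels = c("pachyvessel", "no_pachyvessel"))
    two_group_rows(ppe, split_lab,
                   c("age", fv_metrics, "sfct_um", "rpe_vein_distance_um"),
                   c("Age", fv_labels, "SFCT (um)",
                     "Distance between RPE and choroidal vein (um)"))
  } else NULL

  structure(list(characteristics = characteristics, flow_voids = flow_voids,
                 pachyvessel_split = pachyvessel_split,
                 groups = groups, ttest_variant = ttest_variant),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("Cohort report (groups:", paste(x$groups, collapse = " vs "), ")\n\n")
  cat("Characteristics:\n"); print(x$characteristics, row.names = FALSE)
  cat("\nFlow voids:\n"); print(x$flow_voids, row.names = FALSE)
  if (!is.null(x$pachyvessel_split)) {
    cat("\nPPE split by pachyvessel in 3 x 3 mm:\n")
    print(x$pachyvessel_split, row.names = FALSE)
  }
  invisible(x)
}

#' Write a cohort report to Markdown and JSON
#'
#' @param report A `cohort_report`.
#' @param md_path,json_path Output file paths (NULL to skip one).
#' @return Invisibly, the report.
#' @export
write_report <- function(report, md_path = NULL, json_path = NULL) {
  stopifnot(inherits(report, "cohort_report"))
  if (!is.null(md_path)) {
    fmt_tab <- function(df, title) {
      df <- df[, c("metric", "group1", "group2", "p", "p_adjusted")]
      c(paste("##", title), "",
        "| Metric | Group 1 | Group 2 | p | p (adjusted) |",
        "|---|---|---|---|---|",
        apply(df, 1, function(r) {
          fmtp <- function(p) {
            p <- suppressWarnings(as.numeric(p))
            if (is.na(p)) "-" else if (p < 0.001) "< 0.001" else sprintf("%.3f", p)
          }
          sprintf("| %s | %s | %s | %s | %s |", r[1], r[2],
                  ifelse(is.na(r[3]), "-", r[3]), fmtp(r[4]), fmtp(r[5]))
        }), "")
    }
    lines <- c("# Cohort report", "",
               fmt_tab(report$characteristics, "Participant characteristics"),
               fmt_tab(report$flow_voids, "Flow-void metrics"))
    if (!is.null(report$pachyvessel_split))
      lines <- c(lines, fmt_tab(report$pachyvessel_split,
                                "PPE eyes by pachyvessel presence (3 x 3 mm)"))
    writeLines(lines, md_path)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(characteristics = report$characteristics,
           flow_voids = report$flow_voids,
           pachyvessel_split = report$pachyvessel_split),
      json_path, dataframe = "rows", auto_unbox = TRUE, digits = NA,
      na = "null")
  }
  invisible(report)
}
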