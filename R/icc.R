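#' Intraclass correlation ICC(2,1): two-way random, single measures,
#' absolute agreement
#'
#' Computes the absolute-agreement single-measures intraclass correlation
#' from a complete subjects x raters table via the two-way ANOVA mean
#' squares:
#' \deqn{ICC = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))}
#' where `MSR` is the between-subjects, `MSC` the between-raters and `MSE`
#' the residual mean square, `n` the number of subjects and `k` the number
#' of raters. The 95% confidence interval is the F-based construction for
#' ICC(A,1) of the McGraw-Wong convention (two-sided, 2.5% in each tail).
#' Negative estimates are legitimate (agreement worse than chance) and are
#' returned as-is.
#'
#' A table with zero total variance (all cells equal) is perfect agreement;
#' it returns ICC 1 with the degenerate interval \[1, 1\] and a warning.
#'
#' @param table numeric n x k matrix, rows = subjects (n >= 3), columns =
#'   raters/methods (k >= 2), no missing cells.
#' @param conf_level confidence level (default 0.95).
#' @return An object of class `icc_result`: `icc`, `ci_low`, `ci_high`,
#'   `n`, `k`, `mean_squares` (MSR, MSC, MSE), `classification`.
#' @export
icc_2_1 <- function(table, conf_level = 0.95) {
  x <- as.matrix(table)
  if (anyNA(x)) stop("ICC requires a complete table (no missing cells)",
                     call. = FALSE)
  n <- nrow(x); k <- ncol(x)
  if (n < 3L) stop("ICC requires at least 3 subjects", call. = FALSE)
  if (k < 2L) stop("ICC requires at least 2 raters", call. = FALSE)

  grand <- mean(x)
  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  SSR <- k * sum((row_m - grand)^2)              # between subjects
  SSC <- n * sum((col_m - grand)^2)              # between raters
  SST <- sum((x - grand)^2)
  SSE <- SST - SSR - SSC                          # residual
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))

  if (SST < 1e-24) {
    warning("zero total variance: all cells equal; ICC defined as 1",
            call. = FALSE)
    return(structure(list(icc = 1, ci_low = 1, ci_high = 1, n = n, k = k,
                          mean_squares = c(MSR = 0, MSC = 0, MSE = 0),
                          classification = classify_icc(1)),
                     class = "icc_result"))
  }

  icc <- (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))

  # F-based CI for ICC(A,1) (Satterthwaite df for the rater term)
  alpha <- 1 - conf_level
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * MSC + b * MSE)^2 /
    ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
  FL <- qf(1 - alpha / 2, n - 1, v)
  FU <- qf(1 - alpha / 2, v, n - 1)
  ci_low <- n * (MSR - FL * MSE) /
    (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
  ci_high <- n * (FU * MSR - MSE) /
    (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
  # icc = 1 exactly (MSE = MSC = 0) degenerates the F construction
  if (!is.finite(ci_low)) ci_low <- icc
  if (!is.finite(ci_high)) ci_high <- icc

  structure(list(icc = icc, ci_low = ci_low, ci_high = ci_high, n = n, k = k,
                 mean_squares = c(MSR = MSR, MSC = MSC, MSE = MSE),
                 classification = classify_icc(icc)),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(2,1) = %.3f [%.3f, %.3f] (n = %d, k = %d): %s\n",
              x$icc, x$ci_low, x$ci_high, x$n, x$k, x$classification))
  invisible(x)
}

#' Qualitative ICC classification
#'
#' The conventional bands: `> 0.75` excellent, `0.40`-`0.75` (inclusive)
#' fair to good, `< 0.40` poor. Negative values are poor.
#'
#' @param icc numeric ICC value(s).
#' @return character vector: `"excellent"`, `"fair_to_good"` or `"poor"`.
#' @export
classify_icc <- function(icc) {
  ifelse(icc > 0.75, "excellent",
         ifelse(icc >= 0.40, "fair_to_good", "poor"))
}

#' Mean and SD of signed differences against a reference
#'
#' Signed differences `measured - truth` with their mean and sample standard
#' deviation (n - 1 denominator), the summary reported alongside the ICC.
#'
#' @param measured numeric vector of measurements (mm).
#' @param truth numeric vector of reference values (mm), same length >= 2.
#' @return list with `mean_diff_mm`, `sd_diff_mm`, `differences_mm`.
#' @export
difference_summary <- function(measured, truth) {
  if (length(measured) != length(truth)) {
    stop("measured and truth must have the same length", call. = FALSE)
  }
  if (length(measured) < 2L) {
    stop("difference summary needs at least 2 pairs", call. = FALSE)
  }
  d <- measured - truth
  list(mean_diff_mm = mean(d), sd_diff_mm = sd(d), differences_mm = d)
}

#' Per-method agreement report against the drill size
#'
#' For every measurement method in `measurements`, forms the two-column
#' subjects x (drill size, method) rating table, computes the
#' absolute-agreement ICC(2,1) with its 95% CI and classification, and the
#' mean +/- SD signed difference to the drill size. When repeat measurements
#' are supplied, a second table of per-method intra-rater ICCs
#' (first vs second measurement) is added.
#'
#' @param measurements `data.frame` with columns `id`, `method`,
#'   `diameter_mm` (long format, e.g. rows of [measure_all()]).
#' @param truths `data.frame` with columns `id`, `true_diameter_mm`.
#' @param repeat_measurements optional `data.frame` like `measurements` with
#'   the second measurement session.
#' @return list with `agreement` (one row per method: `method`, `n`, `icc`,
#'   `ci_low`, `ci_high`, `classification`, `mean_diff_mm`, `sd_diff_mm`)
#'   and, when repeats are given, `intra_rater` (same columns minus the
#'   differences).
#' @export
agreement_report <- function(measurements, truths, repeat_measurements = NULL) {
  req <- c("id", "method", "diameter_mm")
  if (!all(req %in% names(measurements))) {
    stop("measurements must have columns id, method, diameter_mm", call. = FALSE)
  }
  methods <- unique(measurements$method)
  rows <- lapply(methods, function(m) {
    sub <- measurements[measurements$method == m &
                          !is.na(measurements$diameter_mm),
                        c("id", "method", "diameter_mm"), drop = FALSE]
    sub <- merge(sub, truths[, c("id", "true_diameter_mm")], by = "id")
    if (nrow(sub) < 3L) {
      return(data.frame(method = m, n = nrow(sub), icc = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        classification = NA_character_,
                        mean_diff_mm = NA_real_, sd_diff_mm = NA_real_,
                        stringsAsFactors = FALSE))
    }
    res <- icc_2_1(cbind(drill = sub$true_diameter_mm,
                         measured = sub$diameter_mm))
    ds <- difference_summary(sub$diameter_mm, sub$true_diameter_mm)
    data.frame(method = m, n = nrow(sub), icc = res$icc,
               ci_low = res$ci_low, ci_high = res$ci_high,
               classification = res$classification,
               mean_diff_mm = ds$mean_diff_mm, sd_diff_mm = ds$sd_diff_mm,
               stringsAsFactors = FALSE)
  })
  out <- list(agreement = do.call(rbind, rows))

  if (!is.null(repeat_measurements)) {
    rrows <- lapply(methods, function(m) {
      a <- measurements[measurements$method == m, c("id", "diameter_mm")]
      b <- repeat_measurements[repeat_measurements$method == m,
                               c("id", "diameter_mm")]
      ab <- merge(a, b, by = "id", suffixes = c("_1", "_2"))
      ab <- ab[stats::complete.cases(ab), , drop = FALSE]
      if (nrow(ab) < 3L) {
        return(data.frame(method = m, n = nrow(ab), icc = NA_real_,
                          ci_low = NA_real_, ci_high = NA_real_,
                          classification = NA_character_,
                          stringsAsFactors = FALSE))
      }
      res <- icc_2_1(cbind(ab$diameter_mm_1, ab$diameter_mm_2))
      data.frame(method = m, n = nrow(ab), icc = res$icc,
                 ci_low = res$ci_low, ci_high = res$ci_high,
                 classification = res$classification,
                 stringsAsFactors = FALSE)
    })
    out$intra_rater <- do.call(rbind, rrows)
  }
  out
}

#' Write an agreement report to CSV and JSON
#'
#' @param report result of [agreement_report()].
#' @param stem output path without extension.
#' @return written paths, invisibly.
#' @export
write_agreement_report <- function(report, stem) {
  csv <- paste0(stem, ".csv")
  js <- paste0(stem, ".json")
  write.csv(report$agreement, csv, row.names = FALSE)
  jsonlite::write_json(report, js, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(c(csv = csv, json = js))
}
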