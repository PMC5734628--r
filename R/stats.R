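#' Summary statistics for a replicate series
#'
#' Mean, sample standard deviation (n - 1 denominator), coefficient of
#' variation, median and range - the quantities summarised by the
#' box-plot convention used throughout the analysis (box = SD, whiskers =
#' range, line = median).
#'
#' @param values numeric vector of replicate values (length >= 2).
#' @export
replicate_summary <- function(values) {
  if (length(values) < 2) stop("at least two replicates are required")
  if (any(!is.finite(values))) stop("replicate values must be finite")
  m <- mean(values)
  s <- stats::sd(values)
  list(n = length(values), mean = m, sd = s,
       cv = if (m != 0) s / m else NA_real_,
       median = stats::median(values), min = min(values), max = max(values))
}

#' Two-sample variance F-test
#'
#' Tests equality of variances between two replicate series with
#' `F = var(a) / var(b)` on `(n_a - 1, n_b - 1)` degrees of freedom and a
#' two-sided p-value `2 min(P(F' <= F), P(F' >= F))` capped at 1.
#' Degenerate inputs are handled by convention: both series constant
#' gives `F = 1, p = 1`; one constant series gives `p = 0` and a
#' degeneracy flag.
#'
#' @param a,b numeric vectors (each length >= 2). By convention `a` is
#'   the repositioned series and `b` the stationary one, so the variance
#'   ratio reads repositioned over stationary.
#' @param alpha significance level for the `significant` flag.
#' @return An object of class `ftest_result`.
#' @export
variance_f_test <- function(a, b, alpha = 0.05) {
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least two values")
  df1 <- length(a) - 1L
  df2 <- length(b) - 1L
  va <- stats::var(a)
  vb <- stats::var(b)
  degenerate <- NA_character_
  if (va == 0 && vb == 0) {
    f <- 1; p <- 1; degenerate <- "both constant"
  } else if (vb == 0) {
    f <- Inf; p <- 0; degenerate <- "zero variance in denominator"
  } else if (va == 0) {
    f <- 0; p <- 0; degenerate <- "zero variance in numerator"
  } else {
    f <- va / vb
    p <- min(1, 2 * min(stats::pf(f, df1, df2), stats::pf(f, df1, df2, lower.tail = FALSE)))
  }
  structure(list(F = f, df = c(df1, df2), p = p, variance_ratio = f,
                 alpha = alpha, significant = is.finite(p) && p < alpha,
                 degenerate = degenerate),
            class = "ftest_result")
}

#' @export
print.ftest_result <- function(x, ...) {
  cat(sprintf("<ftest_result> F(%d, %d) = %.4g, two-sided p = %.4g%s\n",
              x$df[1], x$df[2], x$F, x$p,
              if (!is.na(x$degenerate)) paste0(" [", x$degenerate, "]") else ""))
  invisible(x)
}

#' Variance inflation from repositioning
#'
#' Ratio of sample variances, repositioned over stationary; values above
#' one mean repositioning degraded precision. A zero stationary variance
#' is flagged as infinite.
#'
#' @param repositioned,stationary numeric vectors (length >= 2).
#' @export
variance_inflation <- function(repositioned, stationary) {
  if (length(repositioned) < 2 || length(stationary) < 2)
    stop("each series needs at least two values")
  vs <- stats::var(stationary)
  if (vs == 0) {
    warning("stationary variance is zero; inflation ratio is infinite")
    return(Inf)
  }
  stats::var(repositioned) / vs
}

#' Precision comparison table
#'
#' Runs the repositioned-versus-stationary variance F-test for every
#' (target, reconstruction, metric) cell of a measurement table and
#' arranges the p-values like the study's summary tables: one row per
#' target, one column per reconstruction-by-metric combination. Cells
#' missing a condition are reported as NA and flagged, not dropped.
#'
#' @param records data.frame with columns `target`, `metric`, `recon`,
#'   `condition` ("stationary" / "repositioned") and `value`.
#' @param alpha significance level.
#' @param holm also compute Holm-adjusted p-values (off by default; the
#'   headline tables are uncorrected).
#' @return list with `tests` (tidy data.frame: one row per cell with F,
#'   df, p, variance ratio), `wide` (numeric p-value matrix rows =
#'   targets) and `display` (character matrix with non-significant cells
#'   shown as "-").
#' @export
precision_table <- function(records, alpha = 0.05, holm = FALSE) {
  needed <- c("target", "metric", "recon", "condition", "value")
  if (!all(needed %in% names(records)))
    stop("records must have columns: ", paste(needed, collapse = ", "))
  cells <- unique(records[, c("target", "recon", "metric")])
  cells <- cells[order(cells$target, cells$recon, cells$metric), ]
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    sel <- records$target == cells$target[i] & records$recon == cells$recon[i] &
      records$metric == cells$metric[i]
    a <- records$value[sel & records$condition == "repositioned"]
    b <- records$value[sel & records$condition == "stationary"]
    row <- data.frame(target = cells$target[i], recon = cells$recon[i],
                      metric = cells$metric[i], n_repositioned = length(a),
                      n_stationary = length(b), F = NA_real_, df1 = NA_integer_,
                      df2 = NA_integer_, p = NA_real_,
                      variance_ratio = NA_real_, significant = NA,
                      missing_condition = FALSE)
    if (length(a) >= 2 && length(b) >= 2) {
      ft <- variance_f_test(a, b, alpha = alpha)
      row$F <- ft$F; row$df1 <- ft$df[1]; row$df2 <- ft$df[2]
      row$p <- ft$p; row$variance_ratio <- ft$variance_ratio
      row$significant <- ft$significant
    } else row$missing_condition <- TRUE
    out[[i]] <- row
  }
  tests <- do.call(rbind, out)
  if (holm) tests$p_holm <- stats::p.adjust(tests$p, method = "holm")
  targets <- unique(tests$target)
  cols <- unique(paste(tests$recon, tests$metric, sep = " "))
  wide <- matrix(NA_real_, nrow = length(targets), ncol = length(cols),
                 dimnames = list(as.character(targets), cols))
  for (i in seq_len(nrow(tests)))
    wide[as.character(tests$target[i]),
         paste(tests$recon[i], tests$metric[i], sep = " ")] <- tests$p[i]
  display <- matrix("-", nrow = nrow(wide), ncol = ncol(wide),
                    dimnames = dimnames(wide))
  sig <- !is.na(wide) & wide < alpha
  display[sig] <- formatC(wide[sig], digits = 3, format = "g")
  display[is.na(wide)] <- "missing"
  list(tests = tests, wide = wide, display = display, alpha = alpha)
}

#' Export box-plot summary statistics
#'
#' Per (target, metric, recon, condition) group: median, mean, SD box and
#' range, as JSON-ready records mirroring the box-plot convention of the
#' figures.
#'
#' @param records measurement data.frame as in [precision_table()].
#' @param path optional JSON output path.
#' @export
boxplot_summaries <- function(records, path = NULL) {
  keys <- unique(records[, c("target", "metric", "recon", "condition")])
  out <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    sel <- records$target == keys$target[i] & records$metric == keys$metric[i] &
      records$recon == keys$recon[i] & records$condition == keys$condition[i]
    s <- replicate_summary(records$value[sel])
    out[[i]] <- c(as.list(keys[i, ]), s)
  }
  if (!is.null(path)) {
    writeLines(jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA), path)
    return(invisible(path))
  }
  out
}
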