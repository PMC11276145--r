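#' Per-replicate deviation series
#'
#' The replicate-agreement statistic used throughout the reporting: each
#' value minus its group mean (`random_error`) and the same as a
#' percentage of the group mean (`random_error_pct`). The errors sum to
#' zero by construction; the group SD is returned for the chart's
#' reference lines.
#'
#' @param values numeric vector of replicate measurements (>= 2).
#' @param pct also compute the percentage form (requires nonzero mean).
#' @return an object of class `deviation_series`: `values`,
#'   `random_error`, `random_error_pct`, `mean`, `sd`.
#' @export
deviation_series <- function(values, pct = TRUE) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("at least 2 values required")
  m <- mean(values)
  err <- values - m
  if (pct && m == 0) stop("mean is zero; percentage deviation undefined")
  structure(list(values = values, random_error = err,
                 random_error_pct = if (pct) 100 * err / m else NULL,
                 mean = m, sd = stats::sd(values)),
            class = "deviation_series")
}

#' Pooled mean and SD from two group summaries
#'
#' Exact mean and SD of the concatenation of two samples reconstructed
#' from their summary statistics:
#' pooled mean = (n1 m1 + n2 m2) / (n1 + n2);
#' pooled variance = ((n1-1) s1^2 + (n2-1) s2^2 +
#'   n1 n2 (m1 - m2)^2 / (n1 + n2)) / (n1 + n2 - 1).
#'
#' @param mean1,sd1,n1 first group summary.
#' @param mean2,sd2,n2 second group summary.
#' @return list with `mean`, `sd`, `n`.
#' @export
pooled_group_stats <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2L || n2 < 2L) stop("group sizes must be >= 2")
  if (sd1 < 0 || sd2 < 0) stop("SDs must be nonnegative")
  n <- n1 + n2
  m <- (n1 * mean1 + n2 * mean2) / n
  v <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2 +
        n1 * n2 * (mean1 - mean2)^2 / n) / (n - 1)
  list(mean = m, sd = sqrt(v), n = n)
}

#' Mann-Whitney-Wilcoxon two-sample test
#'
#' Two-sided rank-sum test. The exact null distribution is used whenever
#' the combined sample size is at most 20 and there are no ties;
#' otherwise the tie-corrected normal approximation (without continuity
#' correction) is used.
#'
#' @param x,y numeric samples.
#' @return a `test_result` list: `statistic` (the U statistic for `x`),
#'   `p_value`, `method`, `exact`.
#' @export
mann_whitney <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("empty sample")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- !ties && (length(x) + length(y)) <= 20L
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = FALSE))
  structure(list(statistic = unname(wt$statistic), p_value = wt$p.value,
                 method = "Mann-Whitney-Wilcoxon", exact = exact),
            class = "test_result")
}

#' Mean +/- 3 SD outlier screen
#'
#' Single-pass screen: values outside `[mean - 3 sd, mean + 3 sd]` of the
#' full sample are flagged for removal; the bounds are not re-estimated
#' after removal. With zero SD nothing is removed.
#'
#' @param values numeric vector (>= 2).
#' @return an `outlier_filter` list: `mu`, `sigma`, `retained`, `removed`
#'   (index vectors), `values_clean`.
#' @export
screen_outliers <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("at least 2 values required")
  mu <- mean(values)
  sigma <- stats::sd(values)
  keep <- values >= mu - 3 * sigma & values <= mu + 3 * sigma
  structure(list(mu = mu, sigma = sigma,
                 retained = which(keep), removed = which(!keep),
                 values_clean = values[keep]),
            class = "outlier_filter")
}

#' Kruskal-Wallis test with Dunn-Bonferroni post hoc
#'
#' Tie-corrected Kruskal-Wallis H with chi-square p (k-1 df), followed by
#' Dunn's pairwise rank comparisons with Bonferroni multiplication by the
#' number of pairs k(k-1)/2, capped at 1.
#'
#' @param groups list of k >= 2 non-empty numeric samples.
#' @return a `test_result` list: `statistic` (H), `p_value`, `df`,
#'   `posthoc` data.frame (`group1`, `group2`, `z`, `p_raw`, `p_adj`).
#' @export
kruskal_wallis_posthoc <- function(groups) {
  if (length(groups) < 2L) stop("at least 2 groups required")
  if (any(vapply(groups, length, 1L) == 0L)) stop("empty group")
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  kw <- stats::kruskal.test(groups)
  all_v <- unlist(groups)
  N <- length(all_v)
  r <- rank(all_v)
  gidx <- rep(seq_along(groups), vapply(groups, length, 1L))
  rbar <- tapply(r, gidx, mean)
  n <- vapply(groups, length, 1L)
  tie <- table(all_v)
  tiecorr <- sum(tie^3 - tie) / (12 * (N - 1))
  pairs <- utils::combn(seq_along(groups), 2L)
  z <- apply(pairs, 2L, function(pr) {
    se <- sqrt((N * (N + 1) / 12 - tiecorr) * (1 / n[pr[1]] + 1 / n[pr[2]]))
    (rbar[pr[1]] - rbar[pr[2]]) / se
  })
  p_raw <- 2 * stats::pnorm(-abs(z))
  p_adj <- pmin(1, p_raw * ncol(pairs))
  structure(list(
    statistic = unname(kw$statistic), p_value = kw$p.value,
    df = unname(kw$parameter),
    posthoc = data.frame(group1 = names(groups)[pairs[1L, ]],
                         group2 = names(groups)[pairs[2L, ]],
                         z = as.numeric(z), p_raw = as.numeric(p_raw),
                         p_adj = as.numeric(p_adj),
                         stringsAsFactors = FALSE),
    method = "Kruskal-Wallis + Dunn-Bonferroni"),
    class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g\n", x$method,
              x$statistic, x$p_value))
  if (!is.null(x$posthoc)) {
    cat("post hoc (Bonferroni-adjusted):\n")
    print(x$posthoc, digits = 4)
  }
  invisible(x)
}

#' Method-comparison deviations against a gold-standard mean
#'
#' Each test-method (MRI) replicate is compared to the mean of the
#' gold-standard (CBCT) replicates: deviations in absolute units and as a
#' percentage of the gold-standard mean, with the mean offset and SD for
#' the chart's reference lines. A classical Bland-Altman variant
#' (difference vs pairwise average, limits = bias +/- 1.96 SD) is
#' available via `classical = TRUE` for equal-length samples.
#'
#' @param test_values numeric MRI-method measurements.
#' @param reference_values numeric CBCT gold-standard measurements.
#' @param classical also compute classical difference-vs-average limits.
#' @return list: `deviation`, `deviation_pct`, `reference_mean`,
#'   `mean_offset`, `sd`, optionally `classical`.
#' @export
bland_altman_method_compare <- function(test_values, reference_values,
                                        classical = FALSE) {
  if (length(reference_values) == 0L) stop("empty reference sample")
  ref_mean <- mean(reference_values)
  dev <- test_values - ref_mean
  out <- list(deviation = dev, deviation_pct = 100 * dev / ref_mean,
              reference_mean = ref_mean, mean_offset = mean(dev),
              sd = stats::sd(dev))
  if (classical) {
    if (length(test_values) != length(reference_values))
      stop("classical mode needs paired samples")
    diffs <- test_values - reference_values
    avgs <- (test_values + reference_values) / 2
    bias <- mean(diffs); s <- stats::sd(diffs)
    out$classical <- list(difference = diffs, average = avgs, bias = bias,
                          limits = bias + c(-1.96, 1.96) * s)
  }
  out
}

# --- full report ------------------------------------------------------------

#' Validate a measurement table
#'
#' The complete replicate design: 2 operators x 2 modalities x 2 sides x
#' 3 replicates = 24 rows with columns operator, modality, side,
#' replicate, S_mm2, V_mm3.
#'
#' @param table data.frame.
#' @return the table, invisibly; error listing missing cells otherwise.
#' @export
validate_measurement_table <- function(table) {
  need <- c("operator", "modality", "side", "replicate", "S_mm2", "V_mm3")
  miss <- setdiff(need, names(table))
  if (length(miss) > 0)
    stop("missing columns: ", paste(miss, collapse = ", "))
  full <- expand.grid(operator = unique(table$operator),
                      modality = unique(table$modality),
                      side = unique(table$side),
                      replicate = sort(unique(table$replicate)),
                      stringsAsFactors = FALSE)
  key <- function(d) paste(d$operator, d$modality, d$side, d$replicate)
  absent <- setdiff(key(full), key(table))
  if (length(absent) > 0)
    stop("incomplete design; missing cells: ",
         paste(absent, collapse = "; "))
  invisible(table)
}

#' Build the replicate-agreement report
#'
#' Produces the full statistical summary of a replicate study: per-group
#' means and SDs, operator-pooled comparisons with
#' Mann-Whitney p, per-modality deviation series, the
#' MRI-vs-CBCT method comparison, and (when distance fields are supplied)
#' Kruskal-Wallis + Dunn-Bonferroni tables on the outlier-screened
#' distance distributions.
#'
#' @param table a complete measurement table
#'   (see [validate_measurement_table()]).
#' @param distance_fields optional named list of `distance_field` objects
#'   (or numeric vectors) to compare.
#' @return an object of class `condyle_report`.
#' @export
build_report <- function(table, distance_fields = NULL) {
  validate_measurement_table(table)
  ops <- sort(unique(table$operator))
  mods <- sort(unique(table$modality))
  # per-group summaries (operator x modality, n = sides x reps)
  groups <- do.call(rbind, lapply(ops, function(op)
    do.call(rbind, lapply(mods, function(mo) {
      sub <- table[table$operator == op & table$modality == mo, ]
      data.frame(operator = op, modality = mo, n = nrow(sub),
                 S_mean = mean(sub$S_mm2), S_sd = stats::sd(sub$S_mm2),
                 V_mean = mean(sub$V_mm3), V_sd = stats::sd(sub$V_mm3),
                 stringsAsFactors = FALSE)
    }))))
  # pooled (across modality) comparison between operators
  pooled <- do.call(rbind, lapply(c("S_mm2", "V_mm3"), function(col) {
    vals <- lapply(ops, function(op) table[table$operator == op, col])
    mw <- if (length(ops) == 2L) mann_whitney(vals[[1]], vals[[2]])
          else NULL
    do.call(rbind, lapply(seq_along(ops), function(i)
      data.frame(quantity = sub("_mm.$", "", col), operator = ops[i],
                 n = length(vals[[i]]), mean = mean(vals[[i]]),
                 sd = stats::sd(vals[[i]]),
                 p_value = if (is.null(mw)) NA_real_ else mw$p_value,
                 stringsAsFactors = FALSE)))
  }))
  # per operator x modality x side deviation series
  dev <- list()
  for (op in ops) for (mo in mods)
    for (sd_ in sort(unique(table$side))) {
      sub <- table[table$operator == op & table$modality == mo &
                   table$side == sd_, ]
      sub <- sub[order(sub$replicate), ]
      dev[[paste(op, mo, sd_, sep = ".")]] <-
        list(S = deviation_series(sub$S_mm2),
             V = deviation_series(sub$V_mm3))
    }
  # method comparison: MRI replicates against the CBCT mean, per side
  method_cmp <- NULL
  if (all(c("CBCT", "MRI") %in% mods)) {
    method_cmp <- list()
    for (sd_ in sort(unique(table$side))) {
      cb <- table[table$modality == "CBCT" & table$side == sd_, ]
      mr <- table[table$modality == "MRI" & table$side == sd_, ]
      method_cmp[[sd_]] <- list(
        S = bland_altman_method_compare(mr$S_mm2, cb$S_mm2),
        V = bland_altman_method_compare(mr$V_mm3, cb$V_mm3))
    }
  }
  distance_tests <- NULL
  if (!is.null(distance_fields)) {
    vals <- lapply(distance_fields, function(f)
      if (inherits(f, "distance_field")) f$distances else as.numeric(f))
    cleaned <- lapply(vals, function(v) screen_outliers(v)$values_clean)
    distance_tests <- kruskal_wallis_posthoc(cleaned)
  }
  structure(list(table = table, groups = groups, pooled = pooled,
                 deviations = dev, method_comparison = method_cmp,
                 distance_tests = distance_tests),
            class = "condyle_report")
}

#' @export
print.condyle_report <- function(x, digits = 2, ...) {
  cat("Replicate study report\n\nGroup summaries (operator x modality):\n")
  print(format_num_df(x$groups, digits))
  cat("\nPooled operator comparison (Mann-Whitney p):\n")
  print(format_num_df(x$pooled, digits = digits))
  if (!is.null(x$method_comparison)) {
    cat("\nMRI vs CBCT gold standard (mean offset +/- SD):\n")
    for (sd_ in names(x$method_comparison)) {
      mc <- x$method_comparison[[sd_]]
      cat(sprintf(
        "  side %s: dS = %.2f +/- %.2f mm2 (%.2f%%), dV = %.2f +/- %.2f mm3 (%.2f%%)\n",
        sd_, mc$S$mean_offset, mc$S$sd,
        100 * mc$S$mean_offset / mc$S$reference_mean,
        mc$V$mean_offset, mc$V$sd,
        100 * mc$V$mean_offset / mc$V$reference_mean))
    }
  }
  if (!is.null(x$distance_tests)) {
    cat("\nDistance distributions: ")
    print(x$distance_tests)
  }
  invisible(x)
}

format_num_df <- function(d, digits = 2) {
  num <- vapply(d, is.numeric, TRUE)
  d[num] <- lapply(d[num], round, digits = digits)
  d
}

#' Write report tables as CSV
#'
#' @param report a `condyle_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$table, file.path(dir, "measurements.csv"),
                   row.names = FALSE)
  utils::write.csv(report$groups, file.path(dir, "group_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(report$pooled, file.path(dir, "pooled_comparison.csv"),
                   row.names = FALSE)
  devrows <- do.call(rbind, lapply(names(report$deviations), function(k) {
    dv <- report$deviations[[k]]
    parts <- strsplit(k, ".", fixed = TRUE)[[1]]
    data.frame(operator = parts[1], modality = parts[2], side = parts[3],
               replicate = seq_along(dv$S$random_error),
               S_random_error = dv$S$random_error,
               S_random_error_pct = dv$S$random_error_pct,
               V_random_error = dv$V$random_error,
               V_random_error_pct = dv$V$random_error_pct,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(devrows, file.path(dir, "deviations.csv"),
                   row.names = FALSE)
  if (!is.null(report$distance_tests))
    utils::write.csv(report$distance_tests$posthoc,
                     file.path(dir, "distance_posthoc.csv"),
                     row.names = FALSE)
  invisible(dir)
}

#' Read a measurement table from CSV
#'
#' @param path CSV with columns operator, modality, side, replicate,
#'   `S_mm2`, `V_mm3`.
#' @return a validated data.frame.
#' @export
read_measurement_table <- function(path) {
  validate_measurement_table(
    utils::read.csv(path, stringsAsFactors = FALSE))
}
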