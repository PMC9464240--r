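assay_at_timepoint <- function(data, label, at_min) {
  rows <- data[data$group == label & data$timepoint_min == at_min, , drop = FALSE]
  if (nrow(rows) == 0 && !any(data$group == label)) {
    stop("group not present in the data: ", label)
  }
  if (nrow(rows) == 0) {
    stop("timepoint ", at_min, " min not in the measurement grid for group ", label)
  }
  rows$reading
}

welch_p <- function(x, y, var_equal = FALSE) {
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    # degenerate: constant replicates in both groups
    return(if (mean(x) == mean(y)) 1 else 0)
  }
  stats::t.test(x, y, var.equal = var_equal)$p.value
}

#' Call detection of one group against the negative control
#'
#' Two-sample t-test (Welch, unequal variance, by default) on replicate
#' fluorescence readings at a single timepoint. A group is "detected" when
#' the two-sided p-value is below `alpha` *and* the group mean exceeds the
#' control mean — the direction guard makes the call one-sided in the only
#' biologically meaningful direction (collateral cleavage can only raise the
#' signal above background).
#'
#' @param data Long tibble of readings with columns `group`, `replicate`,
#'   `timepoint_min`, `reading` (see [read_assay_tsv()],
#'   [generate_assay_series()]).
#' @param group Label of the group to test.
#' @param control Label of the negative control (default `"CK"`).
#' @param at_min Timepoint (minutes) at which to test; default 25, where the
#'   Cas12a reporter signal typically plateaus.
#' @param alpha Significance threshold (default 0.01).
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @return One-row tibble: `group`, `n_group`, `n_control`, `mean_group`,
#'   `mean_control`, `test_timepoint_min`, `p_value`, `alpha`, `detected`.
#' @export
detection_call <- function(data, group, control = "CK", at_min = 25,
                           alpha = 0.01, var_equal = FALSE) {
  x <- assay_at_timepoint(data, group, at_min)
  y <- assay_at_timepoint(data, control, at_min)
  if (length(x) < 2 || length(y) < 2) {
    stop("need >= 2 replicates per group at the tested timepoint")
  }
  if (any(c(x, y) < 0)) stop("fluorescence readings must be non-negative")
  p <- welch_p(x, y, var_equal)
  tibble::tibble(
    group = group,
    n_group = length(x), n_control = length(y),
    mean_group = mean(x), mean_control = mean(y),
    test_timepoint_min = at_min,
    p_value = p, alpha = alpha,
    detected = p < alpha && mean(x) > mean(y)
  )
}

#' Determine the limit of detection over a dilution series
#'
#' Runs [detection_call()] for every non-control group and reports the
#' smallest concentration called detected (LOD). Groups are ordered by
#' concentration, taken from a numeric `concentration` column if present and
#' otherwise parsed from the group labels (e.g. `"0.01 ng/uL"`). A
#' monotonicity flag reports whether any undetected concentration lies above
#' a detected one, which would make the LOD call suspect.
#'
#' @inheritParams detection_call
#' @return An `lod_result`; [tidy()] gives the per-concentration calls,
#'   [glance()] the LOD row (`lod` is `NA` when no group is detected).
#' @export
lod_scan <- function(data, control = "CK", at_min = 25, alpha = 0.01,
                     var_equal = FALSE) {
  groups <- setdiff(unique(data$group), control)
  if (length(groups) == 0) stop("no non-control groups in the data")
  conc <- if ("concentration" %in% names(data)) {
    vapply(groups, function(g) data$concentration[data$group == g][1],
           numeric(1), USE.NAMES = FALSE)
  } else {
    suppressWarnings(as.numeric(gsub("[^0-9.eE+-]", "", groups)))
  }
  if (anyNA(conc)) {
    stop("cannot parse a concentration for group(s): ",
         paste(groups[is.na(conc)], collapse = ", "))
  }
  if (anyDuplicated(conc)) stop("concentrations must be distinct")
  ord <- order(conc, decreasing = TRUE)
  calls <- dplyr::bind_rows(lapply(groups[ord], detection_call, data = data,
                                   control = control, at_min = at_min,
                                   alpha = alpha, var_equal = var_equal))
  calls$concentration <- conc[ord]
  detected <- calls$concentration[calls$detected]
  lod <- if (length(detected)) min(detected) else NA_real_
  # monotone if everything above the LOD is detected and below is not
  monotonic <- identical(calls$detected, calls$concentration >= lod) ||
    (is.na(lod) && !any(calls$detected))
  structure(list(calls = calls, lod = lod, lod_reached = !is.na(lod),
                 monotonic = monotonic, alpha = alpha, at_min = at_min),
            class = "lod_result")
}

#' @export
print.lod_result <- function(x, ...) {
  cat("<lod_result> tested at", x$at_min, "min, alpha =", x$alpha, "\n")
  print(x$calls[, c("group", "concentration", "mean_group", "mean_control",
                    "p_value", "detected")])
  cat("LOD:", if (x$lod_reached) x$lod else "not reached",
      if (!x$monotonic) "(warning: non-monotonic detection pattern)" else "",
      "\n")
  invisible(x)
}

#' Tidy an LOD result into per-concentration calls
#'
#' @param x An `lod_result`.
#' @param ... Unused.
#' @return The per-concentration detection-call tibble.
#' @method tidy lod_result
#' @export
tidy.lod_result <- function(x, ...) x$calls

#' One-row summary of an LOD result
#'
#' @param x An `lod_result`.
#' @param ... Unused.
#' @return One-row tibble: `lod`, `lod_reached`, `monotonic`, `alpha`,
#'   `at_min`, `n_groups`.
#' @method glance lod_result
#' @export
glance.lod_result <- function(x, ...) {
  tibble::tibble(lod = x$lod, lod_reached = x$lod_reached,
                 monotonic = x$monotonic, alpha = x$alpha,
                 at_min = x$at_min, n_groups = nrow(x$calls))
}

#' Read replicate fluorescence readings from TSV
#'
#' Expects columns `group`, `replicate`, `timepoint_min`, `reading` (an
#' optional `concentration` column is kept); the header line may be plain or
#' `#`-commented.
#'
#' @param path TSV path.
#' @return A long tibble of readings.
#' @export
read_assay_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  df <- if (startsWith(first, "#")) read_tsv_commented(path) else {
    tibble::as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                                        stringsAsFactors = FALSE))
  }
  need <- c("group", "replicate", "timepoint_min", "reading")
  if (!all(need %in% names(df))) {
    stop("assay TSV must have columns: ", paste(need, collapse = ", "))
  }
  df
}
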