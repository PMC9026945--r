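#' Read a table of paired volume measurements
#'
#' Long-format CSV with header `lesion_id, rater, session, volume_mm3`; one
#' row per measurement. Each `(lesion, rater, session)` combination may
#' appear at most once and volumes must be non-negative.
#'
#' @param path CSV file path.
#' @return A validated `data.frame` of class `rater_table`.
#' @export
read_rater_table <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("table not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  rater_table(df)
}

#' @rdname read_rater_table
#' @param df A data frame with columns `lesion_id`, `rater`, `session`,
#'   `volume_mm3`.
#' @export
rater_table <- function(df) {
  need <- c("lesion_id", "rater", "session", "volume_mm3")
  if (!all(need %in% names(df)))
    stop_contract(sprintf("rater table needs columns: %s",
                          paste(need, collapse = ", ")))
  if (any(!is.finite(df$volume_mm3)) || any(df$volume_mm3 < 0))
    stop_data("volume_mm3 must be finite and >= 0")
  key <- interaction(df$lesion_id, df$rater, df$session, drop = TRUE)
  if (anyDuplicated(key))
    stop_contract("duplicate (lesion, rater, session) rows in rater table")
  class(df) <- c("rater_table", "data.frame")
  df
}

#' Extract a paired measurement matrix from a rater table
#'
#' Pivots the long table to an n-lesion by 2 matrix for the requested pair
#' of raters (inter-rater, at a fixed session) or sessions (intra-rater, for
#' a fixed rater). Missing cells are a contract error: agreement statistics
#' require a complete design.
#'
#' @param table A [rater_table()].
#' @param pair Character or numeric length-2: the two raters or sessions.
#' @param by `"rater"` or `"session"`.
#' @param fixed Value of the other factor to condition on; may be omitted
#'   when that factor has a single level.
#' @return Numeric matrix, rows = lesions (named), columns = the pair.
#' @export
rater_matrix <- function(table, pair, by = c("rater", "session"),
                         fixed = NULL) {
  by <- match.arg(by)
  table <- rater_table(as.data.frame(table))
  other <- if (by == "rater") "session" else "rater"
  if (length(pair) != 2L) stop_contract("pair must name exactly two columns")
  if (is.null(fixed)) {
    lv <- unique(table[[other]])
    if (length(lv) > 1L)
      stop_contract(sprintf("multiple %ss present; supply `fixed`", other))
    fixed <- lv
  }
  sub <- table[table[[other]] == fixed & table[[by]] %in% pair, ]
  lesions <- sort(unique(sub$lesion_id))
  m <- matrix(NA_real_, length(lesions), 2,
              dimnames = list(as.character(lesions), as.character(pair)))
  for (c2 in 1:2) {
    s <- sub[sub[[by]] == pair[c2], ]
    m[match(as.character(s$lesion_id), rownames(m)), c2] <- s$volume_mm3
  }
  if (anyNA(m))
    stop_contract("incomplete design: every lesion needs both measurements")
  if (nrow(m) < 3L) stop_contract("at least 3 lesions are required")
  m
}

#' Intraclass correlation ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measures intraclass
#' correlation — the standard form for inter-rater or test-retest
#' reliability of single measurements — with the F-based 95% confidence
#' interval of McGraw and Wong. Interpretation guideline: below 0.5 poor,
#' 0.5-0.75 moderate, 0.75-0.9 good, above 0.9 excellent reliability.
#'
#' With zero residual *and* zero column variance (e.g. two identical
#' columns) agreement is perfect: the value is 1 and the CI degenerates
#' (`degenerate = TRUE`).
#'
#' @param ratings n x k numeric matrix, rows = subjects (lesions), columns =
#'   raters/sessions; complete, `n >= 3`, `k >= 2`.
#' @param conf_level Confidence level (default 0.95).
#' @return List with `value`, `ci` (length-2), `df` (n, k), `ms` (the mean
#'   squares), and `degenerate`.
#' @export
icc21 <- function(ratings, conf_level = 0.95) {
  m <- as.matrix(ratings)
  if (anyNA(m)) stop_contract("icc21: ratings must be complete (no NA)")
  n <- nrow(m); k <- ncol(m)
  if (n < 3L || k < 2L) stop_contract("icc21: need >= 3 subjects and >= 2 columns")
  grand <- mean(m)
  rowm <- rowMeans(m); colm <- colMeans(m)
  MSR <- k * sum((rowm - grand)^2) / (n - 1)
  MSC <- n * sum((colm - grand)^2) / (k - 1)
  SSE <- sum((m - outer(rowm, rep(1, k)) - outer(rep(1, n), colm) + grand)^2)
  MSE <- SSE / ((n - 1) * (k - 1))

  denom <- MSR + (k - 1) * MSE + (k / n) * (MSC - MSE)
  if (denom <= .Machine$double.eps * max(1, abs(MSR))) {
    return(list(value = 1, ci = c(NA_real_, NA_real_), df = c(n = n, k = k),
                ms = c(MSR = MSR, MSC = MSC, MSE = MSE), degenerate = TRUE))
  }
  icc <- (MSR - MSE) / denom

  alpha <- 1 - conf_level
  ci <- c(NA_real_, NA_real_); degenerate <- FALSE
  if (MSE > 0 && icc < 1) {
    a <- (k * icc) / (n * (1 - icc))
    b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    v <- (a * MSC + b * MSE)^2 /
      ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
    FL <- stats::qf(1 - alpha / 2, n - 1, v)
    FU <- stats::qf(1 - alpha / 2, v, n - 1)
    ci <- c(
      n * (MSR - FL * MSE) /
        (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR),
      n * (FU * MSR - MSE) /
        (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
    )
  } else {
    degenerate <- TRUE
  }
  list(value = icc, ci = ci, df = c(n = n, k = k),
       ms = c(MSR = MSR, MSC = MSC, MSE = MSE), degenerate = degenerate)
}

#' Bland-Altman bias and 95% limits of agreement
#'
#' Absolute mode works on raw differences `d = a - b`; percent mode on
#' `d = 100 (a - b) / pairmean`, as used when agreement is displayed
#' relative to lesion size. Bias is `mean(d)`; the limits of agreement are
#' `bias +/- 1.96 sd(d)` with the sample (n-1) standard deviation, the
#' interval expected to contain 95% of the differences.
#'
#' @param a,b Numeric vectors of equal length `>= 3`.
#' @param mode `"absolute"` (default) or `"percent"`.
#' @return List with `bias`, `loa_low`, `loa_high`, `sd`, `n`, `mode`.
#' @export
bland_altman <- function(a, b, mode = c("absolute", "percent")) {
  mode <- match.arg(mode)
  if (length(a) != length(b)) stop_contract("bland_altman: unequal lengths")
  if (length(a) < 3L) stop_contract("bland_altman: need at least 3 pairs")
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop_data("bland_altman: non-finite values")
  d <- if (mode == "absolute") {
    a - b
  } else {
    pm <- (a + b) / 2
    if (any(pm == 0)) stop_contract("percent mode undefined for a zero pair mean")
    100 * (a - b) / pm
  }
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
       sd = s, n = length(d), mode = mode)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (ties get average ranks). Undefined for
#' a constant series, which is rejected rather than returned as NA.
#'
#' @param a,b Numeric vectors of equal length `>= 3`.
#' @return Correlation in `[-1, 1]`.
#' @export
spearman_rho <- function(a, b) {
  if (length(a) != length(b)) stop_contract("spearman_rho: unequal lengths")
  if (length(a) < 3L) stop_contract("spearman_rho: need at least 3 pairs")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop_contract("spearman_rho: undefined for a constant series")
  stats::cor(a, b, method = "spearman")
}

#' Full agreement report for a measurement pair
#'
#' Bundles [icc21()], [bland_altman()] and [spearman_rho()] for one pair of
#' raters or sessions, mirroring a reproducibility analysis of lesion
#' volumes.
#'
#' @param m n x 2 matrix from [rater_matrix()], or any 2-column matrix of
#'   paired measurements.
#' @param mode Bland-Altman mode, `"absolute"` or `"percent"`.
#' @return A list of class `agreement_report` with `icc_value`,
#'   `icc_ci_low`, `icc_ci_high`, `bias`, `loa_low`, `loa_high`,
#'   `spearman_rho`, `n` and `mode`.
#' @export
agreement_report <- function(m, mode = c("absolute", "percent")) {
  mode <- match.arg(mode)
  m <- as.matrix(m)
  if (ncol(m) != 2L) stop_contract("agreement_report: need exactly 2 columns")
  ic <- icc21(m)
  ba <- bland_altman(m[, 1], m[, 2], mode)
  rho <- spearman_rho(m[, 1], m[, 2])
  structure(list(icc_value = ic$value, icc_ci_low = ic$ci[1],
                 icc_ci_high = ic$ci[2], icc_degenerate = ic$degenerate,
                 bias = ba$bias, loa_low = ba$loa_low, loa_high = ba$loa_high,
                 spearman_rho = rho, n = nrow(m), mode = mode),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("Agreement report (n = %d lesions, %s differences)\n",
              x$n, x$mode))
  ci <- if (is.na(x$icc_ci_low)) "degenerate CI"
        else sprintf("95%% CI %.3f-%.3f", x$icc_ci_low, x$icc_ci_high)
  cat(sprintf("  ICC(2,1)      : %.3f (%s)\n", x$icc_value, ci))
  cat(sprintf("  bias          : %.4g (95%% LoA %.4g, %.4g)\n",
              x$bias, x$loa_low, x$loa_high))
  cat(sprintf("  Spearman rho  : %.3f\n", x$spearman_rho))
  invisible(x)
}
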