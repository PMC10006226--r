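#' Mann-Whitney U test (two-sided)
#'
#' Computes the U statistic of the first sample and a two-sided p-value.
#' When both samples have at most `exact_max` observations the null
#' distribution of U is enumerated exactly over all assignments of the
#' pooled (mid-)ranks to the two groups — valid under ties — via a
#' dynamic-programming count over rank subsets. Otherwise the normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param x,y Numeric samples (first and second group).
#' @param exact Force (`TRUE`) or forbid (`FALSE`) exact enumeration;
#'   default `NULL` chooses exact iff both sample sizes are <= `exact_max`.
#' @param exact_max Size threshold for the exact path (default 12).
#' @return List with `U` (for sample `x`), `p`, `method`, `n1`, `n2`.
#' @export
mann_whitney_u <- function(x, y, exact = NULL, exact_max = 12L) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1L || n2 < 1L) stop("both samples must be non-empty",
                               call. = FALSE)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (is.null(exact)) exact <- (n1 <= exact_max && n2 <= exact_max)
  if (exact) {
    p <- exact_u_pvalue(r, n1)
    method <- "exact"
  } else {
    N <- n1 + n2
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(U - n1 * n2 / 2) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    }
    method <- "normal"
  }
  list(U = U, p = p, method = method, n1 = n1, n2 = n2)
}

# Exact two-sided p-value of U by counting, for every achievable doubled
# rank sum s, the number of n1-subsets of the pooled ranks with that sum
# (knapsack DP; doubling makes midranks integral).
exact_u_pvalue <- function(r, n1) {
  r2 <- as.integer(round(2 * r))
  S <- sum(r2)
  dp <- matrix(0, n1 + 1L, S + 1L)
  dp[1L, 1L] <- 1
  for (v in r2) {
    kmax <- n1
    for (k in kmax:1) {
      dp[k + 1L, (v + 1L):(S + 1L)] <-
        dp[k + 1L, (v + 1L):(S + 1L)] + dp[k, 1:(S + 1L - v)]
    }
  }
  counts <- dp[n1 + 1L, ]
  total <- sum(counts)
  s_obs <- sum(r2[seq_len(n1)])
  # rank-sum and U differ by a constant, so tail probabilities transfer
  p_le <- sum(counts[1:(s_obs + 1L)]) / total
  p_ge <- sum(counts[(s_obs + 1L):(S + 1L)]) / total
  min(1, 2 * min(p_le, p_ge))
}

#' Per-feature group summary with Mann-Whitney testing
#'
#' For each texture feature, reports mean and SD (n-1 denominator) per
#' group, the Mann-Whitney U (computed for the control sample) with its
#' two-sided p-value, and a Holm-adjusted p-value across the features.
#' Undefined feature values (e.g. COR on a constant ROI) are excluded from
#' that feature's statistics and counted in `n_excluded`, with a warning.
#'
#' @param features Feature data.frame from [extract_features()] with a
#'   `group` column (0 = control, 1 = AKI).
#' @param feature_names Columns to summarize (default the nine texture
#'   features present in the table).
#' @return A data.frame of class `group_summary` with columns
#'   `feature, mean_ctrl, sd_ctrl, mean_aki, sd_aki, U, p, p_holm,
#'   n_ctrl, n_aki, n_excluded`.
#' @export
summarize_groups <- function(features,
                             feature_names = intersect(FEATURE_NAMES,
                                                       names(features))) {
  stopifnot("group" %in% names(features),
            all(features$group %in% c(0L, 1L)))
  if (length(feature_names) == 0L) stop("no feature columns found",
                                        call. = FALSE)
  rows <- lapply(feature_names, function(f) {
    v <- features[[f]]
    excl <- sum(is.na(v))
    if (excl > 0L) {
      warning(excl, " undefined value(s) of ", f,
              " excluded from group statistics", call. = FALSE)
    }
    ctrl <- v[features$group == 0L & !is.na(v)]
    aki <- v[features$group == 1L & !is.na(v)]
    if (length(ctrl) < 2L || length(aki) < 2L) {
      stop("fewer than 2 usable observations in a group for feature ", f,
           call. = FALSE)
    }
    mw <- mann_whitney_u(ctrl, aki)
    data.frame(feature = f,
               mean_ctrl = mean(ctrl), sd_ctrl = stats::sd(ctrl),
               mean_aki = mean(aki), sd_aki = stats::sd(aki),
               U = mw$U, p = mw$p, p_holm = NA_real_,
               n_ctrl = length(ctrl), n_aki = length(aki),
               n_excluded = excl, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_holm <- stats::p.adjust(out$p, method = "holm")
  class(out) <- c("group_summary", "data.frame")
  out
}

#' @export
print.group_summary <- function(x, digits = 4, ...) {
  cat("Group comparison (control vs AKI), Mann-Whitney U, two-sided\n\n")
  df <- as.data.frame(x)
  df$`mean+/-sd (ctrl)` <- sprintf("%.*g +/- %.*g", digits, df$mean_ctrl,
                                   digits, df$sd_ctrl)
  df$`mean+/-sd (AKI)` <- sprintf("%.*g +/- %.*g", digits, df$mean_aki,
                                  digits, df$sd_aki)
  print(df[, c("feature", "mean+/-sd (ctrl)", "mean+/-sd (AKI)",
               "U", "p", "p_holm")], row.names = FALSE)
  invisible(x)
}

#' Write the group summary CSV
#'
#' Header:
#' `feature,mean_ctrl,sd_ctrl,mean_aki,sd_aki,U,p,p_holm,n_ctrl,n_aki,n_excluded`.
#'
#' @param summary A `group_summary` from [summarize_groups()].
#' @param path Output CSV path.
#' @export
write_group_summary <- function(summary, path) {
  utils::write.csv(as.data.frame(summary), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
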