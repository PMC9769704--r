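#' Wilcoxon matched-pairs signed-rank test (exact by enumeration)
#'
#' Differences `d = x - y` are computed; zero differences are dropped
#' (classical treatment; `zero_method = "pratt"` ranks them first and then
#' drops their ranks). Absolute differences are ranked with midranks for
#' ties; `W+` is the sum of ranks of positive differences. For
#' `n <= exact_limit` the exact two-sided p-value is computed from the full
#' conditional distribution of `W+` over all `2^n` sign assignments of the
#' observed `|d|` multiset (evaluated by dynamic-programming convolution,
#' which is exact under ties); above that a normal approximation with tie
#' correction and continuity correction is used. The reported statistic is
#' `min(W+, W-)`.
#'
#' @param x,y paired numeric vectors of equal length.
#' @param mode `"auto"` (exact up to `exact_limit`), `"exact"`, or
#'   `"approx"`.
#' @param zero_method `"wilcox"` (drop zeros) or `"pratt"`.
#' @param exact_limit largest `n` for the exact distribution in `"auto"`
#'   mode (default 15).
#' @param comparison label carried into the result.
#' @return list of class `ecog_test`: `method`, `statistic`, `p_two_sided`,
#'   `n_effective`, `comparison`.
#' @export
wilcoxon_signed_rank <- function(x, y, mode = c("auto", "exact", "approx"),
                                 zero_method = c("wilcox", "pratt"),
                                 exact_limit = 15, comparison = "") {
  mode <- match.arg(mode)
  zero_method <- match.arg(zero_method)
  if (length(x) != length(y)) stop("x and y must have equal length")
  d <- x - y
  d <- d[!is.na(d)]
  if (!length(d) || all(d == 0))
    stop("all paired differences are zero; test undefined")
  if (zero_method == "wilcox") {
    d <- d[d != 0]
    r <- rank(abs(d))
  } else {
    r_all <- rank(abs(d))
    keep <- d != 0
    r <- r_all[keep]
    d <- d[keep]
  }
  n <- length(d)
  if (n < 2) stop("need n >= 2 nonzero differences")
  wp <- sum(r[d > 0])
  wm <- sum(r[d < 0])
  use_exact <- mode == "exact" || (mode == "auto" && n <= exact_limit)
  if (use_exact) {
    p <- .wsr_exact_p(r, min(wp, wm))
    method <- "wilcoxon_exact"
  } else {
    mu <- sum(r) / 2
    sigma <- sqrt(sum(r^2) / 4)
    z <- (wp - mu - sign(wp - mu) * 0.5) / sigma
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "wilcoxon_normal_approx"
  }
  structure(list(method = method, statistic = min(wp, wm),
                 p_two_sided = p, n_effective = n, comparison = comparison),
            class = "ecog_test")
}

# exact two-sided p for observed min(W+, W-) given the rank multiset:
# distribution of 2*W+ (integer support with midranks) by DP convolution
.wsr_exact_p <- function(r, wmin) {
  r2 <- as.integer(round(2 * r))
  total <- sum(r2)
  f <- numeric(total + 1)
  f[1] <- 1
  for (ri in r2) {
    g <- f / 2
    g[(ri + 1):(total + 1)] <- g[(ri + 1):(total + 1)] +
      f[1:(total + 1 - ri)] / 2
    f <- g
  }
  w2 <- as.integer(round(2 * wmin))
  lower <- sum(f[seq_len(w2 + 1)])
  upper <- sum(f[seq((total - w2) + 1, total + 1)])
  min(1, lower + upper)
}

#' @export
print.ecog_test <- function(x, ...) {
  cat(sprintf("<ecog_test> %s%s: statistic = %g, p = %.6g, n = %d\n",
              x$method,
              if (nzchar(x$comparison)) paste0(" [", x$comparison, "]") else "",
              x$statistic, x$p_two_sided, x$n_effective))
  invisible(x)
}

#' Friedman rank test for repeated measures
#'
#' Within-unit midranks across `k` conditions; the tie-corrected statistic
#' is \deqn{Q = \frac{12 \sum_j R_j^2 / (n k (k+1)) - 3 n (k+1)}{C},}
#' with `C = 1 - sum(t^3 - t) / (n k (k^2 - 1))` over tie groups. The
#' p-value comes from the chi-square distribution with `k - 1` df, or from a
#' within-row permutation null (`p_method = "permutation"`, seeded by the
#' caller).
#'
#' @param mat numeric matrix, units in rows, conditions in columns.
#' @param p_method `"chisq"` or `"permutation"`.
#' @param n_perm number of random within-row permutations (default 20000).
#' @param comparison label carried into the result.
#' @return list of class `ecog_test` with `method = "friedman"`.
#' @export
friedman_rank_test <- function(mat, p_method = c("chisq", "permutation"),
                               n_perm = 20000, comparison = "") {
  p_method <- match.arg(p_method)
  mat <- as.matrix(mat)
  n <- nrow(mat); k <- ncol(mat)
  if (n < 2 || k < 2) stop("need >= 2 units and >= 2 conditions")
  stat <- .friedman_q(mat)
  if (p_method == "chisq") {
    p <- if (is.na(stat)) 1 else stats::pchisq(stat, df = k - 1,
                                               lower.tail = FALSE)
    if (is.na(stat)) stat <- 0
  } else {
    obs <- if (is.na(stat)) 0 else stat
    cnt <- 0L
    for (b in seq_len(n_perm)) {
      pm <- t(apply(mat, 1, sample))
      q <- .friedman_q(pm)
      if (is.na(q)) q <- 0
      if (q >= obs - 1e-12) cnt <- cnt + 1L
    }
    p <- (cnt + 1) / (n_perm + 1)
    stat <- obs
  }
  structure(list(method = "friedman", statistic = stat, p_two_sided = p,
                 n_effective = n, comparison = comparison),
            class = "ecog_test")
}

.friedman_q <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  R <- t(apply(mat, 1, rank))
  Rj <- colSums(R)
  q_raw <- 12 / (n * k * (k + 1)) * sum(Rj^2) - 3 * n * (k + 1)
  ties <- apply(mat, 1, function(row) {
    t <- table(row); sum(t^3 - t)
  })
  C <- 1 - sum(ties) / (n * k * (k^2 - 1))
  if (C <= 0) return(NA_real_)      # fully tied everywhere
  q_raw / C
}

#' Design A: baseline vs post-occlusion timepoints across animals
#'
#' For each (electrode, band), the baseline epoch values across animals are
#' paired with each post-occlusion timepoint (0 h, 4 h, 8 h, 12 h) and
#' compared with the exact Wilcoxon signed-rank test. Pairing is
#' animal-wise and pairwise-complete; the effective `n` is reported. An
#' all-zero-difference cell is surfaced as an untestable entry (`NA`
#' p-value) rather than an error.
#'
#' @param bp band-power data.frame with columns `animal`, `channel`,
#'   `epoch`, `band`, `mean_power`.
#' @param alpha significance level (default 0.05).
#' @param timepoints post-occlusion epoch labels.
#' @param adjust p-adjustment method passed to [stats::p.adjust()]
#'   (default `"none"`, matching per-test reporting; `"holm"` available).
#' @return data.frame
#'   `electrode,band,contrast,method,n,statistic,p,significant`.
#' @export
compare_timepoints <- function(bp, alpha = 0.05,
                               timepoints = c("0h", "4h", "8h", "12h"),
                               adjust = "none") {
  stopifnot(all(c("animal", "channel", "epoch", "band", "mean_power")
                %in% names(bp)))
  rows <- list()
  for (el in unique(bp$channel)) {
    for (bd in unique(bp$band)) {
      cell <- bp[bp$channel == el & bp$band == bd, ]
      base <- cell[cell$epoch == "baseline", c("animal", "mean_power")]
      for (tp in timepoints) {
        post <- cell[cell$epoch == tp, c("animal", "mean_power")]
        m <- merge(base, post, by = "animal", suffixes = c("_base", "_tp"))
        m <- m[stats::complete.cases(m), ]
        lab <- paste0("baseline_vs_", tp)
        if (nrow(m) < 2 || all(m$mean_power_base == m$mean_power_tp)) {
          rows[[length(rows) + 1]] <- data.frame(
            electrode = el, band = bd, contrast = lab,
            method = NA_character_, n = nrow(m), statistic = NA_real_,
            p = NA_real_, significant = NA, stringsAsFactors = FALSE)
          next
        }
        ts <- wilcoxon_signed_rank(m$mean_power_base, m$mean_power_tp,
                                   comparison = lab)
        rows[[length(rows) + 1]] <- data.frame(
          electrode = el, band = bd, contrast = lab, method = ts$method,
          n = ts$n_effective, statistic = ts$statistic, p = ts$p_two_sided,
          significant = NA, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$p <- ifelse(is.na(out$p), NA, stats::p.adjust(out$p, method = adjust))
  out$significant <- ifelse(is.na(out$p), NA, out$p <= alpha)
  rownames(out) <- NULL
  out
}

#' Design B: preSD vs SD and preSD vs postSD across 3-h lapses
#'
#' For each (electrode, band), the per-lapse mean band powers
#' ([lapse_means()]) are paired across lapses: preSD vs SD and preSD vs
#' postSD, exact Wilcoxon signed-rank. Electrodes with no included events
#' are skipped with a message (the isoelectric-core case).
#'
#' @param lm aggregated data.frame from [lapse_means()].
#' @param alpha significance level (default 0.05).
#' @param include_friedman also report a Friedman omnibus across the three
#'   phases per (electrode, band) (default FALSE).
#' @return data.frame
#'   `electrode,band,contrast,method,n,statistic,p,significant`.
#' @export
compare_sd_phases <- function(lm, alpha = 0.05, include_friedman = FALSE) {
  rows <- list()
  for (el in unique(lm$electrode)) {
    sub <- lm[lm$electrode == el, ]
    if (!nrow(sub)) next
    for (bd in unique(sub$band)) {
      cell <- sub[sub$band == bd, ]
      wide <- stats::reshape(
        cell[, c("lapse", "phase", "mean_power")],
        direction = "wide", idvar = "lapse", timevar = "phase")
      names(wide) <- sub("^mean_power\\.", "", names(wide))
      wide <- wide[stats::complete.cases(wide), ]
      if (nrow(wide) < 2) next
      for (con in c("SD", "postSD")) {
        lab <- paste0("preSD_vs_", con)
        ts <- tryCatch(
          wilcoxon_signed_rank(wide$preSD, wide[[con]], comparison = lab),
          error = function(e) NULL)
        rows[[length(rows) + 1]] <- data.frame(
          electrode = el, band = bd, contrast = lab,
          method = if (is.null(ts)) NA_character_ else ts$method,
          n = nrow(wide),
          statistic = if (is.null(ts)) NA_real_ else ts$statistic,
          p = if (is.null(ts)) NA_real_ else ts$p_two_sided,
          significant = NA, stringsAsFactors = FALSE)
      }
      if (include_friedman) {
        ts <- friedman_rank_test(as.matrix(wide[, c("preSD", "SD", "postSD")]),
                                 comparison = "phase_omnibus")
        rows[[length(rows) + 1]] <- data.frame(
          electrode = el, band = bd, contrast = "phase_omnibus",
          method = ts$method, n = ts$n_effective, statistic = ts$statistic,
          p = ts$p_two_sided, significant = NA, stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(electrode = character(0), band = character(0),
               contrast = character(0), method = character(0),
               n = integer(0), statistic = numeric(0), p = numeric(0),
               significant = logical(0))
  out$significant <- ifelse(is.na(out$p), NA, out$p <= alpha)
  rownames(out) <- NULL
  out
}

#' Write a statistics results table
#'
#' Fixed header `electrode,band,contrast,method,n,statistic,p,significant`.
#'
#' @param results data.frame from [compare_timepoints()] /
#'   [compare_sd_phases()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_stats_csv <- function(results, path) {
  cols <- c("electrode", "band", "contrast", "method", "n", "statistic",
            "p", "significant")
  utils::write.csv(as.data.frame(results)[cols], path, row.names = FALSE)
  invisible(path)
}
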