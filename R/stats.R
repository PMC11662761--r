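# Clinical-score aggregation and the exact one-tailed Mann-Whitney U test.

#' Cumulative clinical score over a DPI window
#'
#' Sums each animal's daily ordinal clinical scores over the inclusive window
#' `[start_dpi, end_dpi]` (DPI 16-44 by default: treatment onset at peak
#' disease through the end of the study). Every day in the window must be
#' present for every animal unless `interpolate = TRUE`, in which case
#' isolated missing days are filled by linear interpolation between
#' neighbouring days.
#'
#' @param scores data frame with columns `animal_id`, `group`, `dpi`,
#'   `score` (ordinal 0-5 scale in 0.5 steps).
#' @param start_dpi,end_dpi inclusive window bounds (defaults 16 and 44).
#' @param interpolate fill missing days by linear interpolation instead of
#'   failing (default `FALSE`).
#' @return Data frame `animal_id`, `group`, `cumulative_score`.
#' @export
cumulative_clinical_score <- function(scores, start_dpi = 16, end_dpi = 44,
                                      interpolate = FALSE) {
  need <- c("animal_id", "group", "dpi", "score")
  miss <- setdiff(need, names(scores))
  if (length(miss) > 0L)
    stop("scores is missing columns: ", paste(miss, collapse = ", "))
  if (start_dpi > end_dpi) stop("start_dpi must be <= end_dpi")
  window <- seq(start_dpi, end_dpi)
  rows <- lapply(split(scores, scores$animal_id), function(d) {
    have <- d$dpi[!is.na(d$score)]
    missing_days <- setdiff(window, have)
    if (length(missing_days) > 0L && !interpolate)
      stop(sprintf("animal '%s' is missing scores for DPI %s",
                   d$animal_id[1L], paste(missing_days, collapse = ", ")))
    s <- if (length(missing_days) > 0L) {
      ok <- !is.na(d$score)
      if (sum(ok) < 2L)
        stop(sprintf("animal '%s' has too few scores to interpolate",
                     d$animal_id[1L]))
      stats::approx(d$dpi[ok], d$score[ok], xout = window, rule = 2)$y
    } else {
      d$score[match(window, d$dpi)]
    }
    data.frame(animal_id = d$animal_id[1L], group = d$group[1L],
               cumulative_score = sum(s))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Number of n-subsets of the doubled midranks `dranks` whose sum is s, for
# s = 0..S, computed by dynamic programming over items. Counting subsets of
# the observed pooled midranks is exactly the complete enumeration of all
# choose(n + m, n) group assignments, conditional on the observed values.
ranksum_subset_counts <- function(dranks, n) {
  stopifnot(n >= 1L, n < length(dranks))
  S <- sum(sort(dranks, decreasing = TRUE)[seq_len(n)])
  f <- matrix(0, nrow = n + 1L, ncol = S + 1L)
  f[1L, 1L] <- 1
  for (d in dranks) {
    for (k in n:1L) {
      cols <- (d + 1L):(S + 1L)
      f[k + 1L, cols] <- f[k + 1L, cols] + f[k, cols - d]
    }
  }
  f[n + 1L, ] # counts for sums 0..S
}

#' Exact one-tailed Mann-Whitney U test
#'
#' The U statistic is computed from midrank-summed ranks (ties share
#' midranks). For pooled sample sizes n + m <= 20 the one-tailed p-value is
#' exact: the conditional permutation distribution of the rank sum given the
#' observed (tie-laden) values is obtained by counting all choose(n + m, n)
#' assignments of the pooled values to the first group. Half-point clinical
#' scores make ties pervasive, where the normal approximation is unreliable
#' and exactness matters. For larger samples the normal approximation with
#' tie and continuity corrections is used; the `method` field records which
#' route was taken.
#'
#' @param a,b numeric score vectors for the two groups (non-empty).
#' @param alternative `"a_less"` (group a stochastically smaller) or
#'   `"a_greater"`.
#' @return A `mwu_test` list: `U` (for group a), `p_one_tailed`,
#'   `alternative`, `method` (`"exact"` or `"normal-approximation"`), `n`,
#'   `m`.
#' @export
mann_whitney_u_one_tailed <- function(a, b,
                                      alternative = c("a_less", "a_greater")) {
  alternative <- match.arg(alternative)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0L || length(b) == 0L) stop("both groups must be non-empty")
  if (any(!is.finite(c(a, b)))) stop("scores must be finite")
  n <- length(a); m <- length(b); N <- n + m
  r <- rank(c(a, b))
  Ra <- sum(r[seq_len(n)])
  U <- Ra - n * (n + 1) / 2

  if (N <= 20L) {
    dranks <- as.integer(round(2 * r)) # doubled midranks are exact integers
    counts <- ranksum_subset_counts(dranks, n)
    obs2 <- as.integer(round(2 * Ra))
    total <- choose(N, n)
    p <- if (alternative == "a_less") {
      sum(counts[seq_len(obs2 + 1L)]) / total
    } else {
      sum(counts[(obs2 + 1L):length(counts)]) / total
    }
    method <- "exact"
  } else {
    mu <- n * m / 2
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma <- sqrt(n * m / 12 * ((N + 1) - tie_term))
    p <- if (alternative == "a_less") {
      stats::pnorm((U + 0.5 - mu) / sigma)
    } else {
      stats::pnorm((U - 0.5 - mu) / sigma, lower.tail = FALSE)
    }
    method <- "normal-approximation"
  }
  structure(list(U = U, p_one_tailed = min(max(p, .Machine$double.xmin), 1),
                 alternative = alternative, method = method, n = n, m = m),
            class = "mwu_test")
}

#' @export
print.mwu_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g (n = %d, m = %d), one-tailed p = %.4g [%s, %s]\n",
              x$U, x$n, x$m, x$p_one_tailed, x$alternative, x$method))
  invisible(x)
}
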