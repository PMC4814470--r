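#' Good's coverage
#'
#' `C = 1 - F1/N`: one minus the fraction of individuals belonging to
#' classes observed exactly once. Estimates the probability that the next
#' sampled individual belongs to an already-observed class.
#'
#' @param counts Vector of positive integer class abundances.
#' @return Coverage in `[0, 1]`.
#' @export
#' @examples
#' good_coverage(c(5, 3, 1, 1))  # 0.8
good_coverage <- function(counts) {
  counts <- .check_counts(counts)
  1 - sum(counts == 1L) / sum(counts)
}

.check_counts <- function(counts) {
  if (length(counts) == 0L) stop("empty abundance vector")
  if (any(counts < 1) || any(counts != round(counts)))
    stop("abundances must be positive integers")
  as.integer(counts)
}

#' Chao1 richness estimator
#'
#' Classic Chao1, `S_obs + F1^2 / (2 F2)`, with the bias-corrected form
#' `S_obs + F1 (F1 - 1) / 2` when no doubletons are present. The standard
#' error follows the standard variance formulas for the respective branch,
#' and a log-normal 95% confidence interval on the estimated number of
#' unseen classes is returned.
#'
#' @param counts Vector of positive integer class abundances.
#' @return List: `estimate`, `se`, `ci` (length-2 95% interval), `s_obs`,
#'   `f1`, `f2`.
#' @export
#' @examples
#' chao1(c(1, 1, 2, 2, 5))$estimate  # 6
chao1 <- function(counts) {
  counts <- .check_counts(counts)
  s_obs <- length(counts)
  f1 <- sum(counts == 1L)
  f2 <- sum(counts == 2L)
  if (f2 > 0L) {
    est <- s_obs + f1^2 / (2 * f2)
    r <- f1 / f2
    v <- f2 * (r^2 / 2 + r^3 + r^4 / 4)
  } else {
    est <- s_obs + f1 * (f1 - 1) / 2
    v <- if (f1 > 0L)
      f1 * (f1 - 1) / 2 + f1 * (2 * f1 - 1)^2 / 4 - f1^4 / (4 * est)
    else 0
  }
  se <- sqrt(max(v, 0))
  # log-normal CI on the unseen-class count (Chao 1987)
  t_unseen <- est - s_obs
  ci <- if (t_unseen > 0 && se > 0) {
    k <- exp(1.96 * sqrt(log(1 + v / t_unseen^2)))
    c(s_obs + t_unseen / k, s_obs + t_unseen * k)
  } else c(est, est)
  list(estimate = est, se = se, ci = ci, s_obs = s_obs, f1 = f1, f2 = f2)
}

#' ACE richness estimator
#'
#' Abundance-based coverage estimator:
#' `S_abund + S_rare / C_ace + (F1 / C_ace) * gamma^2` with
#' `C_ace = 1 - F1 / N_rare` and `gamma^2` the rare-class coefficient of
#' variation (floored at 0); classes with abundance `> rare_cutoff` are
#' "abundant". When every rare individual is a singleton (`N_rare = F1`)
#' the sample coverage is zero and the estimator is undefined; the function
#' then falls back to `S_obs` with a warning. The standard error is
#' obtained by the delta method over the rare frequency counts (numeric
#' gradient, multinomial-style covariance), matching the approach of
#' standard implementations.
#'
#' @param counts Vector of positive integer class abundances.
#' @param rare_cutoff Largest abundance counted as "rare" (default 10).
#' @return List: `estimate`, `se`, `s_obs`, plus `c_ace` and `gamma2`
#'   (NA on the fallback branch).
#' @export
ace <- function(counts, rare_cutoff = 10L) {
  counts <- .check_counts(counts)
  s_obs <- length(counts)
  rare <- counts[counts <= rare_cutoff]
  s_abund <- sum(counts > rare_cutoff)
  if (length(rare) == 0L)
    return(list(estimate = as.numeric(s_obs), se = 0, s_obs = s_obs,
                c_ace = NA_real_, gamma2 = NA_real_))
  f <- tabulate(rare, nbins = rare_cutoff)   # f[i] = # classes with count i
  est_fun <- function(f) {
    n_rare <- sum(seq_along(f) * f)
    s_rare <- sum(f)
    f1 <- f[1L]
    c_ace <- 1 - f1 / n_rare
    if (c_ace <= 0) return(NA_real_)
    g2 <- max(s_rare / c_ace *
                sum(seq_along(f) * (seq_along(f) - 1) * f) /
                (n_rare * (n_rare - 1)) - 1, 0)
    s_abund + s_rare / c_ace + f1 / c_ace * g2
  }
  est <- est_fun(f)
  if (is.na(est)) {
    warning("ACE undefined (all rare classes are singletons); falling back to S_obs")
    return(list(estimate = as.numeric(s_obs), se = NA_real_, s_obs = s_obs,
                c_ace = 0, gamma2 = NA_real_))
  }
  n_rare <- sum(seq_along(f) * f)
  c_ace <- 1 - f[1L] / n_rare
  g2 <- max(sum(f) / c_ace * sum(seq_along(f) * (seq_along(f) - 1) * f) /
              (n_rare * (n_rare - 1)) - 1, 0)
  # delta method: numeric gradient over the frequency counts
  grad <- vapply(seq_along(f), function(i) {
    h <- 1e-4
    fp <- f; fp[i] <- fp[i] + h
    fm <- f; fm[i] <- max(fm[i] - h, 0)
    (est_fun(fp) - est_fun(fm)) / (fp[i] - fm[i])
  }, numeric(1))
  cov_f <- -outer(f, f) / est
  diag(cov_f) <- f * (1 - f / est)
  v <- drop(t(grad) %*% cov_f %*% grad)
  list(estimate = est, se = sqrt(max(v, 0)), s_obs = s_obs,
       c_ace = c_ace, gamma2 = g2)
}

#' Shannon and Simpson diversity
#'
#' Shannon entropy `H = -sum p_i ln p_i` and the unbiased Simpson
#' concentration `D = sum n_i (n_i - 1) / (N (N - 1))`.
#'
#' @param counts Vector of positive integer class abundances (total must
#'   exceed 1 for Simpson).
#' @return List with `shannon` and `simpson`.
#' @export
shannon_simpson <- function(counts) {
  counts <- .check_counts(counts)
  n <- sum(counts)
  if (n < 2L) stop("Simpson's index is undefined for a single individual")
  p <- counts / n
  list(shannon = -sum(p * log(p)),
       simpson = sum(counts * (counts - 1)) / (n * (n - 1)))
}

#' Estimated library coverage percentage
#'
#' `round(100 * s_obs / s_est)` with ties rounded half-up: the observed
#' richness as a percentage of the estimated true richness.
#'
#' @param s_obs Observed number of classes.
#' @param s_est Estimated richness (must be `>= s_obs`).
#' @return Integer percentage.
#' @export
#' @examples
#' estimated_coverage_percent(3822, 6271)  # 61
estimated_coverage_percent <- function(s_obs, s_est) {
  if (s_obs <= 0) stop("s_obs must be positive")
  if (s_est < s_obs) stop("estimated richness below observed richness")
  as.integer(round_half_up(100 * s_obs / s_est))
}

#' Full richness and diversity report for one abundance vector
#'
#' @param counts Vector of positive integer class abundances.
#' @param rare_cutoff ACE rare-class cutoff (default 10).
#' @return List of class `richness_estimate`: `s_obs`, `n`, `s_chao1`,
#'   `se_chao1`, `ci_chao1`, `s_ace`, `se_ace`, `shannon`, `simpson`,
#'   `good_coverage`, `coverage_percent` (from Chao1).
#' @export
richness_estimate <- function(counts, rare_cutoff = 10L) {
  counts <- .check_counts(counts)
  ch <- chao1(counts)
  ac <- ace(counts, rare_cutoff)
  dv <- if (sum(counts) >= 2L) shannon_simpson(counts)
        else list(shannon = 0, simpson = NA_real_)
  structure(list(s_obs = length(counts), n = sum(counts),
                 s_chao1 = ch$estimate, se_chao1 = ch$se, ci_chao1 = ch$ci,
                 s_ace = ac$estimate, se_ace = ac$se,
                 shannon = dv$shannon, simpson = dv$simpson,
                 good_coverage = good_coverage(counts),
                 coverage_percent =
                   estimated_coverage_percent(length(counts), ch$estimate)),
            class = "richness_estimate")
}

#' Richness/diversity table over sites
#'
#' One row per site, mirroring a sequencing-statistics table: observed
#' clusters, Chao1 and ACE with standard errors, Good's coverage, and the
#' estimated library coverage percentage (observed / Chao1).
#'
#' @param counts_by_site Named list of abundance vectors (or list of
#'   `spacer_clusters`, whose `abundance` columns are used).
#' @param rare_cutoff ACE rare-class cutoff (default 10).
#' @return Data frame with columns `site`, `n`, `s_obs`, `s_chao1`,
#'   `se_chao1`, `s_ace`, `se_ace`, `shannon`, `simpson`, `good_coverage`,
#'   `coverage_percent`.
#' @export
diversity_table <- function(counts_by_site, rare_cutoff = 10L) {
  rows <- lapply(names(counts_by_site), function(s) {
    x <- counts_by_site[[s]]
    if (is.data.frame(x)) x <- x$abundance
    r <- richness_estimate(x, rare_cutoff)
    data.frame(site = s, n = r$n, s_obs = r$s_obs,
               s_chao1 = r$s_chao1, se_chao1 = r$se_chao1,
               s_ace = r$s_ace, se_ace = r$se_ace,
               shannon = r$shannon, simpson = r$simpson,
               good_coverage = r$good_coverage,
               coverage_percent = r$coverage_percent,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
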