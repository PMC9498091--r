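#' Assign the low/high risk label
#'
#' Low risk requires overall survival beyond 548 days (18 months) AND a
#' treatment response (CR, PR or SD); every other patient is high risk.
#'
#' @param os_days Overall survival in days (> 0). Vectorized.
#' @param response Response category, one of CR/PR/SD/PD. Vectorized.
#' @param cutoff_days OS cutoff (default 548).
#' @return Character vector with values `"low"` / `"high"`.
#' @export
assign_risk <- function(os_days, response, cutoff_days = 548) {
  if (any(!is.finite(os_days)) || any(os_days <= 0))
    stop("os_days must be positive")
  if (any(!response %in% RESPONSE_LEVELS))
    stop("unknown response category")
  ifelse(os_days > cutoff_days & response %in% c("CR", "PR", "SD"),
         "low", "high")
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator via [survival::survfit]. The median survival
#' follows the convention: smallest event time with `S(t) <= 0.5`,
#' undefined (`NA`) when the curve never reaches 0.5.
#'
#' @param times Positive follow-up times (days).
#' @param events Logical/0-1; `TRUE` = death observed, `FALSE` = censored.
#' @return A list of class `mel_km` with `time`, `surv`, `n_risk`,
#'   `n_event` (all at the distinct observed times) and `median`.
#' @export
km_curve <- function(times, events) {
  if (length(times) == 0) stop("empty survival input")
  if (any(!is.finite(times)) || any(times <= 0)) stop("times must be positive")
  events <- as.logical(events)
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "none")
  s <- summary(fit, censored = TRUE)
  med <- {
    ev <- s$time[s$n.event > 0 & s$surv <= 0.5 + 1e-12]
    if (length(ev)) min(ev) else NA_real_
  }
  structure(list(time = s$time, surv = s$surv, n_risk = s$n.risk,
                 n_event = s$n.event, median = med),
            class = "mel_km")
}

#' @export
print.mel_km <- function(x, ...) {
  cat(sprintf("<mel_km> %d time points, median %s days\n", length(x$time),
              ifelse(is.na(x$median), "not reached", format(x$median))))
  invisible(x)
}

#' Dichotomize a continuous marker by constrained 1-D clustering
#'
#' Among all cut points between consecutive sorted values that leave at
#' least `min_group` patients on each side, picks the cut maximizing the
#' between-group sum of squares. For two groups in one dimension this is
#' the Ward's-criterion split under the size constraint, computed by
#' exhaustive enumeration (deterministic). Ties are broken toward the
#' more balanced split.
#'
#' @param values Numeric marker values (no NA).
#' @param min_group Minimum patients per group (default 10).
#' @return A list with `threshold` (group 2 is `values > threshold`),
#'   `group` (integer 1/2 per input), `n1`, `n2`, `bss`.
#' @export
dichotomize_marker <- function(values, min_group = 10) {
  n <- length(values)
  if (any(!is.finite(values))) stop("marker values must be finite")
  if (n < 2 * min_group)
    stop("need at least ", 2 * min_group, " patients to dichotomize")
  s <- sort(values)
  cands <- which(diff(s) > 0)                       # cut after position i
  cands <- cands[cands >= min_group & (n - cands) >= min_group]
  if (length(cands) == 0)
    stop("no admissible cut point satisfies the group-size constraint")
  gm <- mean(values)
  best <- NULL
  for (i in cands) {
    m1 <- mean(s[1:i]); m2 <- mean(s[(i + 1):n])
    bss <- i * (m1 - gm)^2 + (n - i) * (m2 - gm)^2
    balance <- -abs(i - (n - i))
    key <- c(bss, balance)
    if (is.null(best) || key[1] > best$key[1] + 1e-12 ||
        (abs(key[1] - best$key[1]) <= 1e-12 && key[2] > best$key[2])) {
      best <- list(i = i, key = key,
                   threshold = (s[i] + s[i + 1]) / 2, bss = bss)
    }
  }
  grp <- ifelse(values > best$threshold, 2L, 1L)
  list(threshold = best$threshold, group = grp,
       n1 = sum(grp == 1L), n2 = sum(grp == 2L), bss = best$bss)
}

## vectorized permutation p-value for the Gehan statistic: group labels
## are shuffled B times; the standardized statistics of all permutations
## come from two (event-time x n) by (n x B) matrix products
gehan_perm_p <- function(times, events, group2, B, seed) {
  n <- length(times)
  ut <- sort(unique(times[events]))
  if (length(ut) == 0) return(NA_real_)
  at_risk <- outer(ut, times, "<=")                 # ut x n
  dmat <- outer(ut, times, "==") * rep(events, each = length(ut))
  Y <- rowSums(at_risk)
  d <- rowSums(dmat)
  w <- Y
  stat_of <- function(Y2, d2) {
    U <- colSums(w * (d2 - d * Y2 / Y))
    vcoef <- ifelse(Y > 1, w^2 * d * (Y - d) / (Y - 1), 0)
    V <- colSums(vcoef * (Y2 / Y) * (1 - Y2 / Y))
    abs(U) / sqrt(pmax(V, 1e-300))
  }
  obs <- stat_of(cbind(rowSums(at_risk[, group2, drop = FALSE])),
                 cbind(rowSums(dmat[, group2, drop = FALSE])))
  G <- withr::with_seed(seed, {
    vapply(seq_len(B), function(b) {
      g <- logical(n); g[sample.int(n, sum(group2))] <- TRUE; g
    }, logical(n))
  })
  zb <- stat_of(at_risk %*% G, dmat %*% G)
  (sum(zb >= obs - 1e-12) + 1) / (B + 1)
}

gehan_stat <- function(times, events, group2) {
  ## Gehan-Breslow-Wilcoxon weighted log-rank: weight = total n at risk.
  ot <- order(times)
  t_s <- times[ot]; e_s <- events[ot]; g_s <- group2[ot]
  n <- length(t_s)
  ut <- unique(t_s[e_s])
  if (length(ut) == 0) return(c(stat = 0, var = 0))
  U <- 0; V <- 0
  for (tt in ut) {
    at_risk <- t_s >= tt
    Y <- sum(at_risk)
    Y2 <- sum(at_risk & g_s)
    d <- sum(e_s & t_s == tt)
    d2 <- sum(e_s & t_s == tt & g_s)
    w <- Y
    U <- U + w * (d2 - d * Y2 / Y)
    if (Y > 1)
      V <- V + w^2 * d * (Y2 / Y) * (1 - Y2 / Y) * (Y - d) / (Y - 1)
  }
  c(stat = U, var = V)
}

#' Gehan-Breslow-Wilcoxon two-group survival test
#'
#' Weighted log-rank statistic with weight equal to the total number at
#' risk, emphasizing early survival differences. The p-value comes from
#' the chi-square approximation with 1 df; `permutations > 0` adds an
#' assumption-free permutation p-value (group labels shuffled, seeded).
#'
#' @param times1,events1 Follow-up times and event flags of group 1.
#' @param times2,events2 Same for group 2.
#' @param permutations Number of label permutations (0 = none).
#' @param seed Seed for the permutation draw.
#' @return A list with `statistic` (chi-square), `p` (chi-square p),
#'   `p_perm` (or `NA`), and `no_events` flag.
#' @export
gehan_wilcoxon_test <- function(times1, events1, times2, events2,
                                permutations = 0, seed = 1) {
  if (length(times1) == 0 || length(times2) == 0)
    stop("both groups must be nonempty")
  times <- c(times1, times2)
  events <- as.logical(c(events1, events2))
  group2 <- c(rep(FALSE, length(times1)), rep(TRUE, length(times2)))
  if (!any(events))
    return(list(statistic = 0, p = 1, p_perm = NA_real_, no_events = TRUE))
  uv <- gehan_stat(times, events, group2)
  chisq <- if (uv["var"] > 0) unname(uv["stat"]^2 / uv["var"]) else 0
  p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  p_perm <- if (permutations > 0)
    gehan_perm_p(times, events, group2, permutations, seed)
  else NA_real_
  list(statistic = chisq, p = p, p_perm = p_perm, no_events = FALSE)
}

#' Welch two-sample t-test (unequal variances)
#'
#' @param x1,x2 Numeric samples with at least two values each.
#' @return A list with `statistic`, `df`, `p`, and `degenerate` flag
#'   (both samples constant).
#' @export
welch_t_test <- function(x1, x2) {
  if (length(x1) < 2 || length(x2) < 2)
    stop("both samples need at least two values")
  if (stats::var(x1) == 0 && stats::var(x2) == 0) {
    eq <- isTRUE(all.equal(mean(x1), mean(x2)))
    return(list(statistic = if (eq) 0 else Inf, df = NA_real_,
                p = if (eq) 1 else 0, degenerate = TRUE))
  }
  tt <- stats::t.test(x1, x2, var.equal = FALSE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, degenerate = FALSE)
}

#' Holm-Bonferroni step-down correction
#'
#' Sorts the p-values ascending and rejects while
#' `p_(i) <= alpha / (m - i + 1)`, stopping at the first failure;
#' decisions are mapped back to the input order.
#'
#' @param pvals Numeric p-values in \[0, 1\].
#' @param alpha Family-wise error level (default 0.05).
#' @return Logical vector of rejections, same order as `pvals`.
#' @export
holm_bonferroni <- function(pvals, alpha = 0.05) {
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(pvals)
  ord <- order(pvals)
  reject <- logical(m)
  for (i in seq_len(m)) {
    if (pvals[ord[i]] <= alpha / (m - i + 1)) reject[ord[i]] <- TRUE
    else break
  }
  reject
}

marker_is_indicator <- function(x) all(x %in% c(0, 1, TRUE, FALSE))

#' Screen survival markers across the cohort
#'
#' For each marker: continuous markers are dichotomized by
#' [dichotomize_marker()] (indicator markers use their own two levels and
#' are skipped when either level holds fewer than `min_indicator`
#' patients); overall survival is compared between the marker groups with
#' the Gehan-Breslow-Wilcoxon test; the marker is compared between
#' responders and nonresponders with a Welch t-test. Holm-Bonferroni is
#' applied separately to the OS family and the response family.
#'
#' @param features `data.frame` of patient-level features (one row per
#'   patient, same order as `outcomes`).
#' @param outcomes `data.frame` with columns `os_days`, `died`, `response`.
#' @param markers Character vector of feature columns to screen; defaults
#'   to the study battery present in `features`.
#' @param min_group Minimum group size for clustering-based cuts.
#' @param min_indicator Minimum patients per level for indicator markers.
#' @param alpha Family-wise level for Holm.
#' @param os_permutations Label permutations behind each OS p-value
#'   (exact small-sample inference; the chi-square approximation of the
#'   Gehan test is mildly anticonservative at cohort sizes of a few
#'   dozen). 0 falls back to the chi-square p.
#' @param seed Seed for the permutation draws.
#' @return A `data.frame` with one row per tested marker: `marker`,
#'   `threshold`, `n1`, `n2`, `os_stat`, `os_p`, `os_reject`,
#'   `resp_stat`, `resp_p`, `resp_reject`. Skipped markers are reported
#'   in `attr(, "skipped")`.
#' @export
marker_screen <- function(features, outcomes, markers = NULL,
                          min_group = 10, min_indicator = 2, alpha = 0.05,
                          os_permutations = 2000, seed = 1) {
  stopifnot(nrow(features) == nrow(outcomes))
  if (is.null(markers)) {
    battery <- c("tmtv_ml", "tlg_total", "n_lesions", "n_organ_regions",
                 paste0("organ_", gsub(" ", "_", ORGAN_REGIONS)),
                 "dm_max", "sul_min", "adc_range", "slr_elevated", "blr")
    markers <- intersect(battery, names(features))
  }
  responder <- outcomes$response %in% c("CR", "PR", "SD")
  rows <- list(); skipped <- character(0)
  for (mk in markers) {
    x <- features[[mk]]
    if (all(is.na(x))) { skipped <- c(skipped, mk); next }
    if (marker_is_indicator(x[!is.na(x)])) {
      x <- as.numeric(x)
      if (any(is.na(x)) || min(sum(x == 1), sum(x == 0)) < min_indicator) {
        skipped <- c(skipped, mk); next
      }
      grp <- x + 1L
      thr <- 0.5
    } else {
      if (any(is.na(x))) { skipped <- c(skipped, mk); next }
      cut <- tryCatch(dichotomize_marker(x, min_group = min_group),
                      error = function(e) NULL)
      if (is.null(cut)) { skipped <- c(skipped, mk); next }
      grp <- cut$group
      thr <- cut$threshold
    }
    g2 <- grp == 2L
    os <- gehan_wilcoxon_test(outcomes$os_days[!g2], outcomes$died[!g2],
                              outcomes$os_days[g2], outcomes$died[g2],
                              permutations = os_permutations,
                              seed = seed + sum(utf8ToInt(mk)))
    if (os_permutations > 0 && is.finite(os$p_perm)) os$p <- os$p_perm
    rt <- if (sum(responder) >= 2 && sum(!responder) >= 2)
      welch_t_test(x[responder], x[!responder])
    else list(statistic = NA_real_, p = NA_real_)
    rows[[mk]] <- data.frame(marker = mk, threshold = thr,
                             n1 = sum(!g2), n2 = sum(g2),
                             os_stat = os$statistic, os_p = os$p,
                             resp_stat = rt$statistic, resp_p = rt$p,
                             stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    stop("no marker could be tested")
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res$os_reject <- holm_bonferroni(res$os_p, alpha = alpha)
  res$resp_reject <- NA
  ok <- is.finite(res$resp_p)
  if (any(ok)) res$resp_reject[ok] <- holm_bonferroni(res$resp_p[ok],
                                                      alpha = alpha)
  attr(res, "skipped") <- skipped
  res
}
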