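PERCENTILES <- c(p25 = 0.25, p50 = 0.50, p75 = 0.75, p90 = 0.90)

#' Quantile features of an AI distribution
#'
#' The 25th, 50th (median), 75th and 90th percentiles of a per-minute AI
#' distribution, using linear interpolation between order statistics
#' (`stats::quantile` type 7). The 90th percentile targets the
#' high-intensity end of the movement distribution.
#'
#' @param values numeric vector of (valid) per-minute AI values.
#' @return named numeric vector `p25`, `p50`, `p75`, `p90`.
#' @export
percentile_features <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values))
    stop("empty AI distribution: interval not analyzable")
  stats::setNames(as.numeric(quantile(values, PERCENTILES, type = 7)),
                  names(PERCENTILES))
}

#' Per-percentile delta between attack and matched distributions
#'
#' `delta_q = CH_q - nonCH_q` for q in \{25, 50, 75, 90\}: a negative delta
#' means lower activity during the attack than on matched attack-free
#' intervals.
#'
#' @param ch,non_ch named vectors from [percentile_features()].
#' @return named numeric vector of deltas.
#' @export
delta_features <- function(ch, non_ch) {
  ch[names(PERCENTILES)] - non_ch[names(PERCENTILES)]
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-tailed signed-rank test on a vector of paired differences. Exact
#' p-values (from the signed-rank null distribution) are used for n <= 25
#' untied differences; otherwise a normal approximation with midranks, tie
#' correction and continuity correction. Zero differences are dropped by
#' default (classic rule) or retained in the ranking with Pratt's method.
#'
#' @param deltas numeric vector of paired differences.
#' @param zero_method `"wilcox"` (drop zeros, default) or `"pratt"`.
#' @param exact force (`TRUE`)/suppress (`FALSE`) the exact distribution;
#'   default `NULL` chooses it for n <= 25 with no ties and no zeros.
#' @return list with `statistic` (W+, sum of positive ranks), `p_value`
#'   (two-tailed), `n` (differences used in ranking), `exact` (logical).
#' @export
wilcoxon_signed_rank <- function(deltas, zero_method = c("wilcox", "pratt"),
                                 exact = NULL) {
  zero_method <- match.arg(zero_method)
  deltas <- deltas[!is.na(deltas)]
  if (!length(deltas)) stop("no differences to test")
  if (all(deltas == 0)) {
    warning("all differences are zero: the test carries no information")
    return(list(statistic = 0, p_value = 1, n = 0L, exact = TRUE))
  }
  zeros <- sum(deltas == 0)
  if (zero_method == "wilcox") {
    d <- deltas[deltas != 0]
    n <- length(d)
    rk <- rank(abs(d))
    W <- sum(rk[d > 0])
    ties <- any(duplicated(abs(d)))
    if (is.null(exact)) exact <- n <= 25L && !ties
    if (exact && ties)
      stop("exact p-values are not defined with tied |differences|")
    if (exact) {
      W <- round(W)
      p_le <- psignrank(W, n)
      p_ge <- psignrank(n * (n + 1) / 2 - W, n)  # symmetry of the null
      p <- min(1, 2 * min(p_le, p_ge))
    } else {
      mu <- n * (n + 1) / 4
      tie_tab <- table(rk)
      sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
        sum(tie_tab^3 - tie_tab) / 48
      z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    list(statistic = W, p_value = p, n = n, exact = exact)
  } else {
    # Pratt: rank |d| with zeros included, discard the zero ranks from W,
    # shift the null moments accordingly; normal approximation only
    n <- length(deltas)
    rk <- rank(abs(deltas))
    W <- sum(rk[deltas > 0])
    z0 <- zeros
    mu <- (n * (n + 1) - z0 * (z0 + 1)) / 4
    tie_tab <- table(rk[deltas != 0])
    sigma2 <- (n * (n + 1) * (2 * n + 1) - z0 * (z0 + 1) * (2 * z0 + 1)) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    list(statistic = W, p_value = p, n = n - z0, exact = FALSE)
  }
}

#' Bonferroni adjustment with explicit family size
#'
#' `p_adj = min(1, m * p)`. The family size `m` defaults to the number of
#' p-values but may be set larger (never smaller) when the analysis family
#' extends beyond the supplied vector.
#'
#' @param p numeric vector of raw p-values.
#' @param m family size, at least `length(p)`.
#' @return adjusted p-values.
#' @export
bonferroni <- function(p, m = length(p)) {
  if (m < length(p))
    stop("family size m must be at least the number of tests")
  pmin(1, m * p)
}

#' Whole-attack delta analysis
#'
#' For every eligible attack, computes the percentile features of its
#' per-minute AI distribution and of the pooled matched non-attack
#' distribution, their deltas, and one paired Wilcoxon signed-rank test per
#' percentile across attacks (family size 4 under Bonferroni by default).
#' Optionally restricts to attacks carrying a given treatment label.
#'
#' @param elig an `eligibility` object from [attack_eligibility()].
#' @param ai an `ai_series` from [compute_ai()].
#' @param log the [event_log()] (treatment labels are read from it).
#' @param m Bonferroni family size (default 4, one test per percentile).
#' @param treatment optional label: restrict the test to attacks treated
#'   with it (the delta table always covers all eligible attacks).
#' @return list with `delta_table` (one row per attack x percentile) and
#'   `stat_report` (one row per percentile: `n`, `statistic`, `p_raw`,
#'   `p_adj`, `m`); both empty (with an `explanation` attribute) when no
#'   attack is eligible.
#' @export
analyze_whole_attacks <- function(elig, ai, log, m = 4L, treatment = NULL) {
  keep <- which(elig$ledger$status == "eligible")
  if (!length(keep)) {
    out <- list(delta_table = empty_delta_table(),
                stat_report = empty_stat_report())
    attr(out, "explanation") <- "no eligible attacks"
    return(out)
  }
  rows <- list()
  for (i in keep) {
    a <- log$events[[i]]
    ch_vals <- minute_values(ai, a$onset, a$end)
    if (!length(ch_vals)) next
    non_vals <- pool_non_ch(elig$candidates[[i]], ai)
    if (!length(non_vals)) next
    ch_f <- percentile_features(ch_vals)
    non_f <- percentile_features(non_vals)
    d <- delta_features(ch_f, non_f)
    rows[[length(rows) + 1L]] <- data.frame(
      attack_id = i, bin_id = "whole", percentile = names(PERCENTILES),
      ch_value = as.numeric(ch_f), non_ch_value = as.numeric(non_f),
      delta = as.numeric(d),
      treatment = paste(a$treatments, collapse = ";"),
      n_ch_minutes = length(ch_vals), n_non_ch_minutes = length(non_vals),
      row.names = NULL)
  }
  delta_table <- if (length(rows)) do.call(rbind, rows) else empty_delta_table()
  test_table <- delta_table
  if (!is.null(treatment) && nrow(test_table))
    test_table <- test_table[vapply(strsplit(test_table$treatment, ";"),
                                    function(x) treatment %in% x, logical(1)), ]
  rep_rows <- lapply(names(PERCENTILES), function(q) {
    d <- test_table$delta[test_table$percentile == q]
    if (!length(d)) return(NULL)
    wt <- wilcoxon_signed_rank(d)
    data.frame(analysis = "whole_attack", bin_id = "whole", percentile = q,
               n = length(d), statistic = wt$statistic, p_raw = wt$p_value,
               m = m, row.names = NULL)
  })
  stat_report <- do.call(rbind, rep_rows[!vapply(rep_rows, is.null, logical(1))])
  if (is.null(stat_report)) stat_report <- empty_stat_report()
  if (nrow(stat_report)) stat_report$p_adj <- bonferroni(stat_report$p_raw, m)
  list(delta_table = delta_table, stat_report = stat_report)
}

#' Onset-relative delta analysis
#'
#' For each eligible attack, builds the seven onset-relative bins, pairs
#' each bin with matched intervals on the bin's own wall-clock range, and
#' keeps a bin only when both the attack side and the pooled matched side
#' reach the data-ratio threshold (and, in strict mode, the bin does not
#' overlap the nighttime window). One paired Wilcoxon test is run per
#' (bin, percentile) with at least two contributing attacks; the Bonferroni
#' family defaults to the number of tests actually performed.
#'
#' @param elig an `eligibility` object from [attack_eligibility()].
#' @param ai an `ai_series` from [compute_ai()].
#' @param rec the [acc_recording()] (for data ratios).
#' @param log the [event_log()].
#' @param cal a [calendar_config()].
#' @param strict_bin_daytime drop bins overlapping nighttime (default
#'   `TRUE`); `FALSE` keeps them subject only to the data-ratio rule.
#' @param m Bonferroni family size; `NULL` (default) = tests performed.
#' @param min_ratio data-ratio threshold (default 0.75).
#' @return list with `delta_table`, `stat_report` (per bin x percentile)
#'   and `skipped_bins` (attack x bin with the reason it was dropped).
#' @export
analyze_onset_relative <- function(elig, ai, rec, log, cal = calendar_config(),
                                   strict_bin_daytime = TRUE, m = NULL,
                                   min_ratio = 0.75) {
  keep <- which(elig$ledger$status == "eligible")
  rows <- list(); skipped <- list()
  skip <- function(i, bin, why)
    data.frame(attack_id = i, bin_id = bin, reason = why)
  for (i in keep) {
    a <- log$events[[i]]
    bins <- onset_relative_bins(a)
    for (b in seq_len(nrow(bins))) {
      bs <- bins$start[b]; be <- bins$end[b]; bid <- bins$bin_id[b]
      if (secs_between(rec$start_time, bs) < 0 ||
          secs_between(be, rec_end_time(rec)) < 0) {
        skipped[[length(skipped) + 1L]] <- skip(i, bid, "outside_recording")
        next
      }
      if (strict_bin_daytime && overlaps_nighttime(bs, be, cal)) {
        skipped[[length(skipped) + 1L]] <- skip(i, bid, "nighttime_overlap")
        next
      }
      if (data_ratio(rec, bs, be) < min_ratio) {
        skipped[[length(skipped) + 1L]] <- skip(i, bid, "ch_data_ratio")
        next
      }
      cand <- find_non_ch_intervals(
        a, log, rec, cal, min_ratio,
        clock_start_s = clock_secs(a$onset) +
          round(secs_between(a$onset, bs)),
        clock_end_s = clock_secs(a$onset) + round(secs_between(a$onset, be)))
      if (!nrow(cand)) {
        skipped[[length(skipped) + 1L]] <- skip(i, bid, "no_match")
        next
      }
      ch_vals <- minute_values(ai, bs, be)
      non_vals <- pool_non_ch(cand, ai)
      if (!length(ch_vals) || !length(non_vals)) {
        skipped[[length(skipped) + 1L]] <- skip(i, bid, "no_valid_minutes")
        next
      }
      ch_f <- percentile_features(ch_vals)
      non_f <- percentile_features(non_vals)
      d <- delta_features(ch_f, non_f)
      rows[[length(rows) + 1L]] <- data.frame(
        attack_id = i, bin_id = bid, percentile = names(PERCENTILES),
        ch_value = as.numeric(ch_f), non_ch_value = as.numeric(non_f),
        delta = as.numeric(d),
        treatment = paste(a$treatments, collapse = ";"),
        n_ch_minutes = length(ch_vals), n_non_ch_minutes = length(non_vals),
        row.names = NULL)
    }
  }
  delta_table <- if (length(rows)) do.call(rbind, rows) else empty_delta_table()
  combos <- unique(delta_table[, c("bin_id", "percentile")])
  rep_rows <- list()
  if (nrow(combos)) for (r in seq_len(nrow(combos))) {
    d <- delta_table$delta[delta_table$bin_id == combos$bin_id[r] &
                             delta_table$percentile == combos$percentile[r]]
    if (length(d) < 2L) next
    wt <- wilcoxon_signed_rank(d)
    rep_rows[[length(rep_rows) + 1L]] <- data.frame(
      analysis = "onset_relative", bin_id = combos$bin_id[r],
      percentile = combos$percentile[r], n = length(d),
      statistic = wt$statistic, p_raw = wt$p_value, row.names = NULL)
  }
  stat_report <- if (length(rep_rows)) do.call(rbind, rep_rows) else
    empty_stat_report()
  if (is.null(m)) m <- max(1L, nrow(stat_report))
  if (nrow(stat_report)) {
    stat_report$m <- m
    stat_report$p_adj <- bonferroni(stat_report$p_raw, m)
  }
  list(delta_table = delta_table, stat_report = stat_report,
       skipped_bins = if (length(skipped)) do.call(rbind, skipped) else
         data.frame(attack_id = integer(), bin_id = character(),
                    reason = character()))
}

empty_delta_table <- function() {
  data.frame(attack_id = integer(), bin_id = character(),
             percentile = character(), ch_value = numeric(),
             non_ch_value = numeric(), delta = numeric(),
             treatment = character(), n_ch_minutes = integer(),
             n_non_ch_minutes = integer())
}

empty_stat_report <- function() {
  data.frame(analysis = character(), bin_id = character(),
             percentile = character(), n = integer(), statistic = numeric(),
             p_raw = numeric(), m = integer(), p_adj = numeric())
}
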