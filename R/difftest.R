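#' Parameters for the regularized differential-growth test
#'
#' @param conf Prior weight (pseudo-observations) of the background variance
#'   in the regularized variance; larger values trust the neighbors more.
#' @param window Odd number of intensity-ranked neighbor strains over which
#'   the background variance is averaged.
#' @param alpha Significance threshold for a day to qualify.
#' @param min_days Number of qualifying days (with consistent direction)
#'   required to call a strain a hit.
#' @param use_adjusted If `TRUE` (default) the threshold applies to
#'   BH-adjusted p-values, else to raw p-values.
#' @param df_mode `"regularized"` (default): `df = n_c + n_d + 2 conf - 4`,
#'   each group's posterior variance carrying `n + conf - 2` effective df;
#'   `"classic"`: `n_c + n_d - 2`.
#' @return List of class `test_params`.
#' @export
test_params <- function(conf = 15, window = 101L, alpha = 0.01,
                        min_days = 2L, use_adjusted = TRUE,
                        df_mode = c("regularized", "classic")) {
  if (conf < 0) stop("conf must be non-negative")
  if (window < 3L || window %% 2L == 0L) stop("window must be odd and >= 3")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (min_days < 1L) stop("min_days must be at least 1")
  structure(list(conf = conf, window = as.integer(window), alpha = alpha,
                 min_days = as.integer(min_days),
                 use_adjusted = use_adjusted,
                 df_mode = match.arg(df_mode)),
            class = "test_params")
}

#' Background variance from a ranked window of neighbor strains
#'
#' Strains are ranked by their mean normalized density; the background
#' variance of a strain is the mean of the sample variances of the `window`
#' strains centered on it in that ranking (truncated at the ends).
#'
#' @param means Per-strain mean normalized densities.
#' @param variances Per-strain sample variances.
#' @param window Odd window size; clamped (with a warning) if it exceeds the
#'   number of strains.
#' @return Per-strain background variances, in the input order.
#' @export
window_background_variance <- function(means, variances, window = 101L) {
  n <- length(means)
  stopifnot(length(variances) == n)
  if (window > n) {
    warning("window exceeds number of strains; clamped to ", n)
    window <- n
  }
  h <- (window - 1L) %/% 2L
  ord <- order(means)
  v <- variances[ord]
  cs <- cumsum(c(0, v))
  i <- seq_len(n)
  lo <- pmax(1L, i - h)
  hi <- pmin(n, i + h)
  bg <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  out <- numeric(n)
  out[ord] <- bg
  out
}

#' Regularized (empirical-Bayes) two-sample t statistics
#'
#' Per group the sample variance is shrunk toward a background variance
#' estimated from ranked neighbor strains:
#' `v = (conf * s0^2 + (n - 1) * s^2) / (conf + n - 2)`.
#' The t statistic is `(mean_d - mean_c) / sqrt(v_c / n_c + v_d / n_d)` with
#' degrees of freedom per `df_mode`, and a two-sided p-value from the t
#' distribution. All arguments are vectorized over strains.
#'
#' @param mean_c,mean_d Group means.
#' @param s2_c,s2_d Group sample variances.
#' @param n_c,n_d Group sizes (>= 2).
#' @param bg_c,bg_d Background variances per group.
#' @param conf Prior weight of the background variance.
#' @param df_mode See [test_params()].
#' @return Data frame with delta, var_c, var_d (regularized), t, df, p.
#' @export
regularized_t <- function(mean_c, mean_d, s2_c, s2_d, n_c, n_d,
                          bg_c, bg_d, conf = 15,
                          df_mode = c("regularized", "classic")) {
  df_mode <- match.arg(df_mode)
  if (any(n_c < 2 | n_d < 2)) stop("at least 2 replicates per group")
  v_c <- (conf * bg_c + (n_c - 1) * s2_c) / (conf + n_c - 2)
  v_d <- (conf * bg_d + (n_d - 1) * s2_d) / (conf + n_d - 2)
  delta <- mean_d - mean_c
  se <- sqrt(v_c / n_c + v_d / n_d)
  df <- if (df_mode == "regularized") n_c + n_d + 2 * conf - 4 else
    n_c + n_d - 2
  t <- ifelse(se > 0, delta / se, ifelse(delta == 0, 0, sign(delta) * Inf))
  p <- ifelse(is.finite(t), 2 * stats::pt(-abs(t), df),
              ifelse(t == 0, 1, 0))
  p[se == 0 & delta == 0] <- 1
  data.frame(delta = delta, var_c = v_c, var_d = v_d, t = t,
             df = rep_len(df, length(t)), p = p)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR-adjusted p-values (via `stats::p.adjust`), after
#' validating the input range.
#'
#' @param p Raw p-values in `[0, 1]` (`NA` allowed).
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

row_var <- function(m) {
  n <- rowSums(!is.na(m))
  mu <- rowMeans(m, na.rm = TRUE)
  rowSums((m - mu)^2, na.rm = TRUE) / (n - 1)
}

#' Test one day of a normalized screen
#'
#' Control vs drug regularized t-test for every strain on one imaging day,
#' with the background variance of each condition taken from that
#' condition's own ranked window, followed by BH adjustment across strains.
#' Strains missing more than one replicate in either condition are excluded
#' from the day's test (p-values `NA`).
#'
#' @param table Normalized (stage `loess` or `quantile`) density table.
#' @param day The day to test.
#' @param params A [test_params()].
#' @return Data frame with one row per strain: strain_id, day, mean_control,
#'   mean_drug, delta, s2_control, s2_drug, bg_var_control, bg_var_drug,
#'   reg_var_control, reg_var_drug, t, df, p_raw, p_adj, direction.
#' @export
test_day <- function(table, day, params = test_params()) {
  sub <- table[table$day == day, , drop = FALSE]
  mc <- table_matrix(sub[sub$condition == "control", ],
                     as.character(sub$replicate[sub$condition == "control"]))
  md <- table_matrix(sub[sub$condition == "drug", ],
                     as.character(sub$replicate[sub$condition == "drug"]))
  strains <- rownames(mc)
  if (!identical(strains, rownames(md)))
    stop("inconsistent strain sets across conditions on day ", day)
  n_c <- rowSums(!is.na(mc)); n_d <- rowSums(!is.na(md))
  ok <- n_c >= ncol(mc) - 1L & n_d >= ncol(md) - 1L & n_c >= 2L & n_d >= 2L
  mean_c <- rowMeans(mc, na.rm = TRUE); mean_d <- rowMeans(md, na.rm = TRUE)
  s2_c <- row_var(mc); s2_d <- row_var(md)
  bg_c <- bg_d <- rep(NA_real_, length(strains))
  bg_c[ok] <- window_background_variance(mean_c[ok], s2_c[ok], params$window)
  bg_d[ok] <- window_background_variance(mean_d[ok], s2_d[ok], params$window)
  res <- data.frame(strain_id = strains, day = day,
                    mean_control = mean_c, mean_drug = mean_d,
                    delta = mean_d - mean_c,
                    s2_control = s2_c, s2_drug = s2_d,
                    bg_var_control = bg_c, bg_var_drug = bg_d,
                    reg_var_control = NA_real_, reg_var_drug = NA_real_,
                    t = NA_real_, df = NA_real_, p_raw = NA_real_,
                    p_adj = NA_real_, row.names = NULL,
                    stringsAsFactors = FALSE)
  if (any(ok)) {
    rt <- regularized_t(mean_c[ok], mean_d[ok], s2_c[ok], s2_d[ok],
                        n_c[ok], n_d[ok], bg_c[ok], bg_d[ok],
                        conf = params$conf, df_mode = params$df_mode)
    res$reg_var_control[ok] <- rt$var_c
    res$reg_var_drug[ok] <- rt$var_d
    res$t[ok] <- rt$t
    res$df[ok] <- rt$df
    res$p_raw[ok] <- rt$p
    res$p_adj[ok] <- bh_adjust(rt$p)
  }
  res$direction <- ifelse(res$delta > 0, "increased",
                          ifelse(res$delta < 0, "decreased", "none"))
  res
}

#' Test every day of a normalized screen
#'
#' @param table Normalized density table.
#' @param params A [test_params()].
#' @return Data frame stacking [test_day()] results over all days.
#' @export
test_screen <- function(table, params = test_params()) {
  days <- sort(unique(table$day))
  out <- do.call(rbind, lapply(days, function(d) test_day(table, d, params)))
  rownames(out) <- NULL
  out
}

#' Combine per-day tests into multi-day hit calls
#'
#' A day qualifies for a strain when its (adjusted, by default) p-value is
#' below `alpha`. A strain is a hit when at least `min_days` qualifying days
#' agree in direction; the shared sign assigns the strain to the increased-
#' on-drug or decreased-on-drug hit set (the two sets are disjoint; a strain
#' with `min_days` qualifying days in each direction is not called).
#'
#' @param day_results Stacked per-day results from [test_screen()].
#' @param params A [test_params()].
#' @return Data frame, one row per strain: strain_id, n_days_increased,
#'   n_days_decreased, n_days_significant, is_hit, direction, days
#'   (comma-separated qualifying days).
#' @export
call_hits <- function(day_results, params = test_params()) {
  p <- if (params$use_adjusted) day_results$p_adj else day_results$p_raw
  qual <- !is.na(p) & p < params$alpha & day_results$direction != "none"
  qd <- day_results[qual, c("strain_id", "day", "direction")]
  strains <- sort(unique(day_results$strain_id))
  n_up <- n_dn <- integer(length(strains))
  daystr <- character(length(strains))
  if (nrow(qd) > 0) {
    tab_up <- table(factor(qd$strain_id[qd$direction == "increased"],
                           levels = strains))
    tab_dn <- table(factor(qd$strain_id[qd$direction == "decreased"],
                           levels = strains))
    n_up <- as.integer(tab_up)
    n_dn <- as.integer(tab_dn)
    dl <- split(qd$day, factor(qd$strain_id, levels = strains))
    daystr <- vapply(dl, function(d) paste(sort(d), collapse = ","), "")
  }
  both <- n_up >= params$min_days & n_dn >= params$min_days
  is_hit <- (n_up >= params$min_days | n_dn >= params$min_days) & !both
  direction <- rep("none", length(strains))
  direction[is_hit & n_up > n_dn] <- "increased"
  direction[is_hit & n_dn > n_up] <- "decreased"
  data.frame(strain_id = strains, n_days_increased = n_up,
             n_days_decreased = n_dn,
             n_days_significant = n_up + n_dn,
             is_hit = is_hit, direction = direction, days = daystr,
             row.names = NULL, stringsAsFactors = FALSE)
}
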