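#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Computes the two-sided p-value by the probability-ordering convention:
#' with the table's margins fixed, the hypergeometric probability of every
#' admissible table is computed in log space, and p is the sum of
#' probabilities of all tables whose probability does not exceed that of the
#' observed table (relative tolerance 1e-12 guards floating-point ties).
#' This is the convention of mainstream implementations of the two-sided
#' exact test.
#'
#' The table is
#' \preformatted{   a  b
#'    c  d }
#' with row margins a+b and c+d fixed (e.g. responsive / non-responsive units
#' in two groups).
#'
#' @param a,b,c,d nonnegative integer cell counts; at least one margin must
#'   be positive.
#' @param relTol relative tolerance for the probability comparison.
#' @return the two-sided p-value, in (0, 1].
#' @export
#' @examples
#' fisherExact2x2(5, 0, 0, 5)   # 2 / choose(10, 5)
#' fisherExact2x2(3, 7, 3, 7)   # identical proportions -> 1
fisherExact2x2 <- function(a, b, c, d, relTol = 1e-12) {
  cells <- c(a, b, c, d)
  stopIfNot(all(cells >= 0) && all(cells == round(cells)),
            "cell counts must be nonnegative integers")
  stopIfNot(sum(cells) > 0, "all-zero table has no defined test")
  m <- a + b          # row 1 margin
  n <- c + d          # row 2 margin
  k <- a + c          # column 1 margin
  # support of the (1,1) cell given fixed margins
  lo <- max(0, k - n)
  hi <- min(k, m)
  x <- lo:hi
  # log hypergeometric pmf from first principles (no dhyper):
  # P(X = x) = C(m, x) C(n, k - x) / C(m + n, k)
  logp <- lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k)
  obs <- logp[x == a]
  keep <- logp <= obs + log1p(relTol)
  p <- sum(exp(logp[keep]))
  min(p, 1)
}

#' Paired t test from baseline/post value pairs
#'
#' Computes the paired t statistic on the within-unit differences
#' \code{post - baseline}: t = mean(d) / (sd(d) / sqrt(n)) with n - 1
#' degrees of freedom and a two-sided p-value from the t distribution. Pairs
#' with zero-variance differences are degenerate: the test is flagged and no
#' p-value is emitted.
#'
#' @param baseline,post equal-length numeric vectors, one pair per unit
#'   (e.g. mean baseline-bin z vs mean response-bin z); n >= 2.
#' @return list with \code{t}, \code{df}, \code{p}, \code{mean_diff},
#'   \code{n}, \code{degenerate}; \code{t} and \code{p} are NA when
#'   degenerate.
#' @export
#' @examples
#' pairedT(baseline = c(0, 1, 2), post = c(2, 5, 8))
pairedT <- function(baseline, post) {
  stopIfNot(length(baseline) == length(post),
            "baseline and post must pair up")
  n <- length(baseline)
  stopIfNot(n >= 2, "need at least 2 pairs")
  d <- post - baseline
  sdd <- sd(d)
  if (!is.finite(sdd) || sdd == 0)
    return(list(t = NA_real_, df = n - 1L, p = NA_real_,
                mean_diff = mean(d), n = n, degenerate = TRUE))
  tstat <- mean(d) / (sdd / sqrt(n))
  list(t = tstat, df = n - 1L, p = 2 * pt(-abs(tstat), df = n - 1L),
       mean_diff = mean(d), n = n, degenerate = FALSE)
}

#' Summarize responsive-unit proportions and compare groups
#'
#' Tabulates, per group and event label, the number of responsive units out
#' of all classified (non-excluded) units, with the percentage
#' 100 x n_responsive / n_total, and runs the two-sided exact test on every
#' pairwise group comparison within each event label. Raw p-values are
#' reported; an optional multiplicity correction over the pairwise tests per
#' label is available but off by default.
#'
#' @param calls classification data.frame from [classifyAll()].
#' @param groupMap data.frame mapping \code{unit_id} to \code{group}.
#' @param correction p-adjustment method passed to [stats::p.adjust()];
#'   \code{"none"} (default) reports raw exact p-values.
#' @return list with \code{summary} (group, event_label, n_responsive,
#'   n_total, percent) and \code{comparisons} (group_a, group_b,
#'   event_label, a, b, c, d, p_two_sided[, p_adjusted]); the a,b,c,d cells
#'   are responsive/non-responsive counts for the two groups.
#' @export
#' @examples
#' calls <- data.frame(unit_id = sprintf("u%d", 1:20),
#'                     event_label = "CS_ON",
#'                     responsive = rep(c(TRUE, FALSE), 10),
#'                     excluded = FALSE)
#' gm <- data.frame(unit_id = sprintf("u%d", 1:20),
#'                  group = rep(c("ctrl", "inh"), each = 10))
#' summarizeGroups(calls, gm)
summarizeGroups <- function(calls, groupMap, correction = "none") {
  stopIfNot(all(c("unit_id", "event_label", "responsive") %in% names(calls)),
            "calls must come from classifyAll()")
  stopIfNot(all(c("unit_id", "group") %in% names(groupMap)),
            "groupMap needs unit_id and group columns")
  df <- merge(calls, groupMap, by = "unit_id")
  if ("excluded" %in% names(df)) df <- df[!df$excluded, , drop = FALSE]
  df <- df[!is.na(df$responsive), , drop = FALSE]
  stopIfNot(nrow(df) > 0, "no classified units after exclusions")
  groups <- unique(groupMap$group)
  labels <- unique(df$event_label)
  summ <- expand.grid(group = groups, event_label = labels,
                      stringsAsFactors = FALSE)
  summ$n_responsive <- mapply(function(g, l)
    sum(df$responsive[df$group == g & df$event_label == l]),
    summ$group, summ$event_label)
  summ$n_total <- mapply(function(g, l)
    sum(df$group == g & df$event_label == l), summ$group, summ$event_label)
  stopIfNot(all(summ$n_total > 0), "every group must have classified units")
  summ$percent <- 100 * summ$n_responsive / summ$n_total
  comps <- NULL
  if (length(groups) >= 2L) {
    pairs <- combn(as.character(groups), 2L)
    rows <- list()
    for (l in labels) {
      for (j in seq_len(ncol(pairs))) {
        ga <- pairs[1L, j]; gb <- pairs[2L, j]
        sa <- summ[summ$group == ga & summ$event_label == l, ]
        sb <- summ[summ$group == gb & summ$event_label == l, ]
        a <- sa$n_responsive; b <- sa$n_total - sa$n_responsive
        c_ <- sb$n_responsive; d <- sb$n_total - sb$n_responsive
        rows[[length(rows) + 1L]] <- data.frame(
          group_a = ga, group_b = gb, event_label = l,
          a = a, b = b, c = c_, d = d,
          p_two_sided = fisherExact2x2(a, b, c_, d))
      }
    }
    comps <- do.call(rbind, rows)
    if (correction != "none")
      comps$p_adjusted <- ave(comps$p_two_sided, comps$event_label,
                              FUN = function(p) p.adjust(p, method = correction))
  }
  list(summary = summ, comparisons = comps)
}

#' Pooled baseline-vs-response comparison for responsive units
#'
#' For the units called responsive to one event label, pairs each unit's
#' mean z over the baseline bins with its mean z over the response bins and
#' runs the paired t test — the group-level check that responsive units show
#' a genuine change in baseline-normalised activity.
#'
#' @param profiles list of [ZScoreProfile-class] for the responsive units.
#' @return the [pairedT()] result, plus the per-unit pairs in
#'   \code{$pairs}.
#' @export
baselineVsResponse <- function(profiles) {
  stopIfNot(length(profiles) >= 2, "need at least 2 responsive units")
  pairs <- t(vapply(profiles, function(p) {
    stopIfNot(!p@degenerate, "degenerate profile in pooled comparison")
    c(baseline = mean(p@z[p@baselineBins]),
      response = mean(p@z[p@responseBins]))
  }, numeric(2)))
  res <- pairedT(pairs[, "baseline"], pairs[, "response"])
  res$pairs <- as.data.frame(pairs)
  res
}
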