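.as_group_list <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need at least 2 groups", call. = FALSE)
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("g", seq_along(groups))
  groups <- lapply(groups, function(v) as.numeric(v[!is.na(v)]))
  if (any(vapply(groups, length, 1L) < 2L))
    stop("each group needs at least 2 values", call. = FALSE)
  groups
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA: `F = MSB / MSW` with the p value
#' from the F distribution. If all values are identical the statistic is
#' undefined and a degenerate result (`F = NaN`, `p = NA`) is returned with
#' a warning; if the groups are internally constant but differ in mean,
#' `F = Inf` and `p = 0` are returned, also with a warning.
#'
#' @param groups Named list of numeric vectors, one per group (>= 2 groups
#'   of >= 2 values each).
#' @return List with `F`, `df1`, `df2`, `p`, and per-group `means`, `sds`,
#'   `n`.
#' @examples
#' one_way_anova(list(a = c(1, 2), b = c(3, 4)))$F  # 8
#' @export
one_way_anova <- function(groups) {
  groups <- .as_group_list(groups)
  k <- length(groups)
  n <- vapply(groups, length, 1L)
  means <- vapply(groups, mean, 1)
  ssb <- sum(n * (means - sum(n * means) / sum(n))^2)
  ssw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), 1))
  df1 <- k - 1L
  df2 <- sum(n) - k
  if (ssw == 0) {
    if (ssb == 0) {
      warning("all values identical: F statistic undefined", call. = FALSE)
      Fv <- NaN; p <- NA_real_
    } else {
      warning("zero within-group variance: F statistic infinite",
              call. = FALSE)
      Fv <- Inf; p <- 0
    }
  } else {
    df <- data.frame(y = unlist(groups, use.names = FALSE),
                     g = factor(rep(names(groups), n)))
    fit <- stats::oneway.test(y ~ g, data = df, var.equal = TRUE)
    Fv <- unname(fit$statistic)
    p <- fit$p.value
  }
  list(F = Fv, df1 = df1, df2 = df2, p = p,
       means = means, sds = vapply(groups, stats::sd, 1), n = n)
}

# Compact letter display by the standard insert-and-absorb algorithm:
# start with one set holding all groups; for each significantly different
# pair split every set containing both; drop sets contained in others.
.compact_letters <- function(levels, sig_pairs) {
  absorb <- function(sets) {
    keep <- rep(TRUE, length(sets))
    for (i in seq_along(sets)) for (j in seq_along(sets)) {
      if (i == j || !keep[i] || !keep[j]) next
      if (all(sets[[i]] %in% sets[[j]]) &&
          (length(sets[[i]]) < length(sets[[j]]) || i > j))
        keep[i] <- FALSE
    }
    sets[keep]
  }
  sets <- list(levels)
  if (nrow(sig_pairs) > 0L) {
    for (r in seq_len(nrow(sig_pairs))) {
      a <- sig_pairs[r, 1]; b <- sig_pairs[r, 2]
      new_sets <- list()
      for (s in sets) {
        if (a %in% s && b %in% s) {
          new_sets <- c(new_sets, list(setdiff(s, a)), list(setdiff(s, b)))
        } else {
          new_sets <- c(new_sets, list(s))
        }
      }
      sets <- absorb(new_sets)
    }
  }
  # order sets by the first (mean-ordered) group they contain
  first <- vapply(sets, function(s) min(match(s, levels)), 1)
  sets <- sets[order(first)]
  letters_out <- stats::setNames(rep("", length(levels)), levels)
  for (i in seq_along(sets))
    for (g in sets[[i]])
      letters_out[g] <- paste0(letters_out[g], letters[i])
  letters_out
}

#' Tukey HSD post-hoc comparisons with compact letters
#'
#' All pairwise group comparisons using the studentized range distribution
#' at the given alpha, plus a compact letter display: groups sharing a
#' letter are not significantly different. With two groups the Tukey
#' adjusted p equals the ANOVA (pooled t-test) p exactly. Letters are
#' assigned with groups ordered by decreasing mean, so the group with the
#' largest mean carries letter "a".
#'
#' @inheritParams one_way_anova
#' @param alpha Significance threshold, default 0.05.
#' @return List with `pairs` (data frame: group1, group2, diff, lwr, upr,
#'   p_adj, significant), `letters` (named character), and `alpha`.
#' @export
tukey_hsd <- function(groups, alpha = 0.05) {
  groups <- .as_group_list(groups)
  a <- one_way_anova(groups)
  msw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), 1)) / a$df2
  cmb <- utils::combn(names(groups), 2)
  pairs <- data.frame(group1 = cmb[1, ], group2 = cmb[2, ],
                      diff = NA_real_, lwr = NA_real_, upr = NA_real_,
                      p_adj = NA_real_, stringsAsFactors = FALSE)
  if (msw == 0) {
    for (r in seq_len(nrow(pairs))) {
      dif <- a$means[[pairs$group2[r]]] - a$means[[pairs$group1[r]]]
      pairs$diff[r] <- dif
      pairs$p_adj[r] <- if (dif == 0) NA_real_ else 0
    }
  } else {
    df <- data.frame(y = unlist(groups, use.names = FALSE),
                     g = factor(rep(names(groups), a$n),
                                levels = names(groups)))
    hsd <- stats::TukeyHSD(stats::aov(y ~ g, data = df),
                           conf.level = 1 - alpha)$g
    # rows are named "group2-group1"
    key <- paste(pairs$group2, pairs$group1, sep = "-")
    idx <- match(key, rownames(hsd))
    pairs$diff <- hsd[idx, "diff"]
    pairs$lwr <- hsd[idx, "lwr"]
    pairs$upr <- hsd[idx, "upr"]
    pairs$p_adj <- hsd[idx, "p adj"]
  }
  pairs$significant <- !is.na(pairs$p_adj) & pairs$p_adj < alpha
  ord <- names(sort(a$means, decreasing = TRUE))
  sig <- as.matrix(pairs[pairs$significant, c("group1", "group2"),
                         drop = FALSE])
  list(pairs = pairs, letters = .compact_letters(ord, sig)[names(groups)],
       alpha = alpha, anova = a)
}

#' Compare wheel summaries between groups
#'
#' Runs one-way ANOVA with Tukey post-hoc letters on each summary metric
#' across groups of wheels (typically young vs mature ripening stages, or
#' production batches). Metrics that are absent (all `NA`) in any group, or
#' leave fewer than two values in a group, are skipped with a warning. A
#' metric with zero variance everywhere is reported as non-significant
#' (all groups lettered "a").
#'
#' @param summaries Data frame of [summarize_wheel()] rows (one per wheel).
#' @param group_by Column to group by, default `"age_days"`.
#' @param alpha Significance threshold, default 0.05.
#' @param metrics Character vector of summary columns to compare.
#' @return A `stage_comparison` object: list of per-metric results (each
#'   with group means/sds, F, df, p, Tukey pairs, letters, and a formatted
#'   `mean +- sd^letter` row) plus a `table` data frame.
#' @export
compare_stages <- function(summaries, group_by = "age_days", alpha = 0.05,
                           metrics = c("n_eyes", "mean_eye_volume_cm3",
                                       "eye_volume_p10_cm3",
                                       "eye_volume_p90_cm3",
                                       "total_eye_volume_cm3", "ratio",
                                       "eye_percent", "mean_roundness",
                                       "roundness_p10", "roundness_p90")) {
  summaries <- as.data.frame(summaries)
  if (!group_by %in% names(summaries))
    stop("grouping column '", group_by, "' not found", call. = FALSE)
  fac <- factor(summaries[[group_by]])
  if (nlevels(fac) < 2L)
    stop("need at least 2 groups after grouping by '", group_by, "'",
         call. = FALSE)
  lev <- levels(fac)

  results <- list()
  rows <- list()
  for (m in metrics) {
    if (!m %in% names(summaries)) next
    vals <- split(summaries[[m]], fac)
    vals <- lapply(vals, function(v) v[!is.na(v)])
    if (any(vapply(vals, length, 1L) < 2L)) {
      warning("metric '", m,
              "' has fewer than 2 values in some group; skipped",
              call. = FALSE)
      next
    }
    th <- withCallingHandlers(
      tukey_hsd(vals, alpha = alpha),
      warning = function(w) invokeRestart("muffleWarning"))
    an <- th$anova
    degenerate <- !is.finite(an$F) && is.na(an$p)
    lets <- th$letters
    if (degenerate) lets[] <- "a"
    fmt <- sprintf("%.3g ± %.3g^%s", an$means, an$sds, lets)
    names(fmt) <- lev
    results[[m]] <- list(metric = m, groups = lev, means = an$means,
                         sds = an$sds, F = an$F, df = c(an$df1, an$df2),
                         p = an$p, pairs = th$pairs, letters = lets,
                         significant = !degenerate && !is.na(an$p) &&
                           an$p < alpha && any(th$pairs$significant),
                         formatted = fmt)
    rows[[m]] <- c(list(metric = m), as.list(fmt),
                   list(p_value = an$p))
  }
  tab <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE, check.names = FALSE)))
  rownames(tab) <- NULL
  structure(list(comparisons = results, table = tab, group_by = group_by,
                 alpha = alpha,
                 note = "No multiple-testing correction across metrics."),
            class = "stage_comparison")
}

#' @export
print.stage_comparison <- function(x, ...) {
  cat(sprintf("Group comparison by '%s' (one-way ANOVA + Tukey, alpha = %g)\n",
              x$group_by, x$alpha))
  if (!is.null(x$table)) print(x$table, row.names = FALSE)
  cat(x$note, "\n")
  invisible(x)
}
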