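# Group statistics: damaged-area quantification, one-way ANOVA with the
# between/within variance decomposition (R^2 = SS_between / SS_total) and
# Bonferroni-adjusted pooled-variance pairwise t tests.

#' Damaged-area fraction
#'
#' Fraction of the tumour area covered by the damaged region; the damaged
#' mask is intersected with the tumour mask first.
#'
#' @param damaged An [roi_mask()] (or logical matrix) of damaged tissue.
#' @param tumor An [roi_mask()] (or logical matrix) of the whole tumour.
#' @return A single fraction in `[0, 1]`.
#' @export
damaged_fraction <- function(damaged, tumor) {
  tm <- if (inherits(tumor, "roi_mask")) tumor$mask else tumor
  dm <- if (inherits(damaged, "roi_mask")) damaged$mask else damaged
  stopifnot(is.matrix(tm), is.matrix(dm), identical(dim(tm), dim(dm)))
  if (!any(tm)) stop("tumour mask is empty", call. = FALSE)
  sum(dm & tm) / sum(tm)
}

check_group_table <- function(table, feature) {
  stopifnot(is.data.frame(table),
            all(c("subject", "group", "feature", "value") %in%
                  names(table)))
  d <- table[table$feature == feature, ]
  if (nrow(d) == 0L) {
    stop("feature '", feature, "' not present in the table", call. = FALSE)
  }
  if (anyDuplicated(d[, c("subject", "feature")])) {
    stop("more than one value per (subject, feature)", call. = FALSE)
  }
  sizes <- table(d$group)
  if (length(sizes) < 2L) stop("need at least two groups", call. = FALSE)
  small <- names(sizes)[sizes < 2L]
  if (length(small) > 0L) {
    stop("group(s) with fewer than two subjects: ",
         paste(small, collapse = ", "), call. = FALSE)
  }
  d
}

#' One-way ANOVA for one feature of a group table
#'
#' Fits the standard one-way analysis of variance and reports the F
#' statistic, its p value, and the fraction of variance explained by the
#' group factor (`R^2 = SS_between / SS_total`). A zero-variance table
#' (all values identical) is degenerate (F = 0/0) and is reported as
#' `F = 0`, `p = 1` with a warning so feature sweeps keep running.
#'
#' @param table A long data frame with columns `subject`, `group`,
#'   `feature`, `value`.
#' @param feature Feature name to analyse.
#' @return An object of class `htx_anova` with [generics::tidy()] and
#'   [generics::glance()] methods.
#' @export
one_way_anova <- function(table, feature) {
  d <- check_group_table(table, feature)
  d$group <- factor(d$group)
  fit <- stats::lm(value ~ group, data = d)
  an <- suppressWarnings(stats::anova(fit))  # degenerate fits handled below
  ss_b <- an$`Sum Sq`[1L]; ss_w <- an$`Sum Sq`[2L]
  degenerate <- (ss_b + ss_w) < .Machine$double.eps * max(1, sum(d$value^2))
  if (degenerate) {
    warning("all values identical; reporting F = 0", call. = FALSE)
    f <- 0; p <- 1; r2 <- 0
  } else {
    f <- an$`F value`[1L]; p <- an$`Pr(>F)`[1L]
    r2 <- ss_b / (ss_b + ss_w)
  }
  structure(
    list(feature = feature, statistic = f, p_value = p, r_squared = r2,
         df_between = an$Df[1L], df_within = an$Df[2L],
         ss_between = ss_b, ss_within = ss_w,
         groups = levels(d$group), n = nrow(d), data = d),
    class = "htx_anova"
  )
}

#' @export
print.htx_anova <- function(x, ...) {
  cat(sprintf(
    "One-way ANOVA for '%s': F(%d, %d) = %.4g, p = %.3g, R^2 = %.3f\n",
    x$feature, x$df_between, x$df_within, x$statistic, x$p_value,
    x$r_squared))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname one_way_anova
#' @param x An `htx_anova` object.
#' @param ... Unused.
#' @method tidy htx_anova
#' @export
tidy.htx_anova <- function(x, ...) {
  tibble::tibble(
    feature = x$feature, term = c("group", "residuals"),
    df = c(x$df_between, x$df_within),
    sumsq = c(x$ss_between, x$ss_within),
    statistic = c(x$statistic, NA_real_),
    p.value = c(x$p_value, NA_real_))
}

#' @rdname one_way_anova
#' @method glance htx_anova
#' @export
glance.htx_anova <- function(x, ...) {
  tibble::tibble(feature = x$feature, statistic = x$statistic,
                 p.value = x$p_value, r.squared = x$r_squared,
                 df = x$df_between, df.residual = x$df_within,
                 nobs = x$n)
}

#' Bonferroni-adjusted pairwise comparisons
#'
#' Two-sample pooled-variance t tests for every pair of groups (or a
#' restricted pair list); each raw p value is multiplied by the number of
#' compared pairs and capped at 1.
#'
#' @inheritParams one_way_anova
#' @param alpha Significance level for the `significant` flag
#'   (default 0.05).
#' @param pairs Optional two-column matrix or list of length-2 vectors
#'   restricting the comparisons; default all pairs.
#' @return A tibble with columns `feature`, `group1`, `group2`,
#'   `estimate` (mean difference), `statistic`, `p_raw`, `p_bonferroni`,
#'   `significant`.
#' @export
bonferroni_pairwise <- function(table, feature, alpha = 0.05,
                                pairs = NULL) {
  d <- check_group_table(table, feature)
  gs <- sort(unique(d$group))
  if (is.null(pairs)) {
    cmb <- utils::combn(gs, 2L)
    pairs <- lapply(seq_len(ncol(cmb)), function(k) cmb[, k])
  } else if (is.matrix(pairs)) {
    pairs <- lapply(seq_len(nrow(pairs)), function(k) pairs[k, ])
  }
  m <- length(pairs)
  purrr::map_dfr(pairs, function(pr) {
    x <- d$value[d$group == pr[1L]]
    y <- d$value[d$group == pr[2L]]
    if (stats::var(x) + stats::var(y) == 0) {
      # pooled sd 0: identical groups get p = 1, differing ones p = 0
      est <- mean(x) - mean(y)
      praw <- if (est == 0) 1 else 0
      stat <- if (est == 0) 0 else Inf * sign(est)
    } else {
      tt <- stats::t.test(x, y, var.equal = TRUE)
      est <- unname(tt$estimate[1L] - tt$estimate[2L])
      praw <- tt$p.value
      stat <- unname(tt$statistic)
    }
    tibble::tibble(
      feature = feature, group1 = pr[1L], group2 = pr[2L],
      estimate = est, statistic = stat, p_raw = praw,
      p_bonferroni = min(1, praw * m),
      significant = min(1, praw * m) < alpha)
  })
}

#' Compare groups across every feature of a table
#'
#' Runs [one_way_anova()] and [bonferroni_pairwise()] for each feature.
#'
#' @inheritParams bonferroni_pairwise
#' @return A list with `anova` (one row per feature: [generics::glance()]
#'   output) and `pairwise` (stacked pairwise tibbles).
#' @export
compare_groups <- function(table, alpha = 0.05, pairs = NULL) {
  feats <- unique(table$feature)
  anova_tab <- purrr::map_dfr(feats, function(f) {
    glance(one_way_anova(table, f))
  })
  pw <- purrr::map_dfr(feats, function(f) {
    bonferroni_pairwise(table, f, alpha = alpha, pairs = pairs)
  })
  list(anova = anova_tab, pairwise = pw)
}

#' Write analysis tier tables to CSV
#'
#' Writes one CSV per analysis tier plus a significance summary, with
#' deterministic row ordering so reruns are byte-identical.
#'
#' @param tiers Named list of data frames (e.g. `whole_tumor`,
#'   `segmented`, `map_medians`, `derivatives`).
#' @param results A [compare_groups()] result (or NULL to skip).
#' @param outdir Output directory, created if needed.
#' @return Paths of the written files, invisibly.
#' @export
report <- function(tiers, results = NULL, outdir) {
  stopifnot(is.list(tiers), length(tiers) > 0L)
  if (!dir.exists(outdir)) {
    dir.create(outdir, recursive = TRUE)
  }
  paths <- character(0)
  for (nm in names(tiers)) {
    d <- as.data.frame(tiers[[nm]])
    d <- d[do.call(order, d[, intersect(c("subject", "group", "region",
                                          "family", "feature", "name"),
                                        names(d)), drop = FALSE]), ,
           drop = FALSE]
    p <- file.path(outdir, paste0(nm, ".csv"))
    utils::write.csv(d, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(results)) {
    an <- as.data.frame(results$anova)
    an <- an[order(an$feature), , drop = FALSE]
    p1 <- file.path(outdir, "anova_summary.csv")
    utils::write.csv(an, p1, row.names = FALSE)
    pw <- as.data.frame(results$pairwise)
    pw <- pw[order(pw$feature, pw$group1, pw$group2), , drop = FALSE]
    p2 <- file.path(outdir, "pairwise_summary.csv")
    utils::write.csv(pw, p2, row.names = FALSE)
    paths <- c(paths, p1, p2)
  }
  invisible(paths)
}
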