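#' Average per-frame measurements into per-subject values
#'
#' Repeated frames of one subject and site (six per site in the
#' reference acquisition protocol) are averaged arithmetically per
#' metric before any group statistics, so each subject contributes one
#' value per site and metric.
#'
#' @param measurements data.frame with columns \code{subject_id},
#'   \code{site}, \code{metric}, \code{value} (one row per frame).
#' @return data.frame with columns \code{subject_id}, \code{site},
#'   \code{metric}, \code{mean} — one row per subject x site x metric.
#' @export
aggregatePerSubject <- function(measurements) {
  need <- c("subject_id", "site", "metric", "value")
  if (!is.data.frame(measurements) || !all(need %in% names(measurements)))
    .sqError("measurements must have columns subject_id, site, metric, value",
             "sq_validation_error")
  agg <- stats::aggregate(value ~ subject_id + site + metric,
                          data = measurements, FUN = mean)
  names(agg)[names(agg) == "value"] <- "mean"
  agg[order(agg$metric, agg$site, agg$subject_id), , drop = FALSE]
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the D'Agostino skewness z-score and the Anscombe-Glynn
#' kurtosis z-score into the K^2 = Z1^2 + Z2^2 statistic, chi-squared
#' with 2 df under normality. Requires n >= 8.
#'
#' @param x numeric vector, n >= 8.
#' @return list with \code{statistic} (K^2) and \code{p.value}.
#' @export
dagostinoPearsonTest <- function(x) {
  n <- length(x)
  if (n < 8L)
    .sqError("D'Agostino-Pearson test requires n >= 8", "sq_validation_error")
  x <- as.numeric(x)
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  if (m2 == 0)
    .sqError("zero variance: normality test undefined", "sq_validation_error")
  ## skewness z (D'Agostino 1970)
  b1 <- m3 / m2^1.5
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  alpha <- sqrt(2 / (W2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))
  ## kurtosis z (Anscombe & Glynn 1983)
  b2 <- m4 / m2^2
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - eb2) / sqrt(vb2)
  sb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sb1 * (2 / sb1 + sqrt(1 + 4 / sb1^2))
  z2 <- ((1 - 2 / (9 * A)) -
           ((1 - 2 / A) / (1 + xk * sqrt(2 / (A - 4))))^(1 / 3)) /
    sqrt(2 / (9 * A))
  k2 <- z1^2 + z2^2
  list(statistic = k2, p.value = stats::pchisq(k2, df = 2, lower.tail = FALSE))
}

## Dunn's post-hoc test after Kruskal-Wallis, Bonferroni-adjusted
.dunnTest <- function(values, groups) {
  groups <- factor(groups)
  N <- length(values)
  r <- rank(values)
  tieTab <- table(r)
  tieCorr <- sum(tieTab^3 - tieTab) / (12 * (N - 1))
  rbar <- tapply(r, groups, mean)
  ns <- tapply(r, groups, length)
  lev <- levels(groups)
  k <- length(lev)
  m <- k * (k - 1) / 2
  out <- data.frame(comparison = character(m), z = numeric(m),
                    p_adj = numeric(m), stringsAsFactors = FALSE)
  row <- 0L
  for (i in seq_len(k - 1)) for (j in seq.int(i + 1, k)) {
    row <- row + 1L
    se <- sqrt((N * (N + 1) / 12 - tieCorr) * (1 / ns[i] + 1 / ns[j]))
    z <- if (se > 0) (rbar[i] - rbar[j]) / se else 0
    p <- min(1, 2 * stats::pnorm(-abs(z)) * m)
    out$comparison[row] <- paste(lev[i], lev[j], sep = " - ")
    out$z[row] <- z
    out$p_adj[row] <- p
  }
  out
}

#' Compare a metric between sites
#'
#' Runs the cohort group comparison on per-subject means: each group is
#' first screened for normality (D'Agostino-Pearson when n >= 8,
#' Shapiro-Wilk for 3 <= n < 8; groups with n < 3 or zero variance
#' force the nonparametric branch, as no normality test is defined
#' there). If every group passes (p > 0.05), a one-way ANOVA with
#' Tukey's multiple-comparison post-hoc is used; otherwise the
#' Mann-Whitney test for two groups or the Kruskal-Wallis test with
#' Dunn's Bonferroni-adjusted post-hoc for more. P-values are
#' star-coded p <= 0.05 (*), p <= 0.01 (**), p <= 0.001 (***).
#'
#' @param table per-subject table from
#'   \code{\link{aggregatePerSubject}} (column \code{mean}; a
#'   \code{value} column is also accepted).
#' @param metric metric to compare (e.g. \code{"vr"}).
#' @param groups character vector of >= 2 site names.
#' @return list with \code{method}, \code{normality} (per-group
#'   data.frame), \code{statistic}, \code{p.value}, \code{stars},
#'   \code{pairwise} (data.frame with adjusted p and stars, for > 2
#'   groups), and \code{notes} documenting gate decisions.
#' @export
compareGroups <- function(table, metric, groups) {
  valCol <- if ("mean" %in% names(table)) "mean" else "value"
  if (!all(c("site", "metric", valCol) %in% names(table)))
    .sqError("table must have columns site, metric and mean (or value)",
             "sq_validation_error")
  if (length(unique(groups)) < 2L)
    .sqError("need at least 2 groups to compare", "sq_validation_error")
  sub <- table[table$metric == metric & table$site %in% groups, , drop = FALSE]
  sub$site <- factor(sub$site, levels = groups)
  vals <- split(sub[[valCol]], sub$site)
  ns <- vapply(vals, length, integer(1))
  if (any(ns < 2L))
    .sqError(sprintf("every group needs n >= 2 (got: %s)",
                     paste(sprintf("%s=%d", names(ns), ns), collapse = ", ")),
             "sq_validation_error")
  notes <- character(0)
  norm <- data.frame(site = names(vals), n = ns, test = NA_character_,
                     p = NA_real_, normal = NA, stringsAsFactors = FALSE)
  for (i in seq_along(vals)) {
    v <- vals[[i]]
    if (length(v) < 3L) {
      norm$test[i] <- "none (n < 3)"; norm$normal[i] <- FALSE
      notes <- c(notes, sprintf("group '%s': n < 3, nonparametric forced", norm$site[i]))
    } else if (stats::var(v) == 0) {
      norm$test[i] <- "none (zero variance)"; norm$normal[i] <- FALSE
      notes <- c(notes, sprintf("group '%s': zero variance, nonparametric forced", norm$site[i]))
    } else if (length(v) >= 8L) {
      tt <- dagostinoPearsonTest(v)
      norm$test[i] <- "dagostino_pearson"; norm$p[i] <- tt$p.value
      norm$normal[i] <- tt$p.value > 0.05
    } else {
      tt <- stats::shapiro.test(v)
      norm$test[i] <- "shapiro_wilk"; norm$p[i] <- tt$p.value
      norm$normal[i] <- tt$p.value > 0.05
    }
  }
  allNormal <- all(norm$normal)
  k <- length(vals)
  if (allNormal) {
    fit <- stats::aov(sub[[valCol]] ~ sub$site)
    an <- summary(fit)[[1]]
    p <- an[["Pr(>F)"]][1]
    tuk <- stats::TukeyHSD(fit)[[1]]
    pairwise <- data.frame(comparison = rownames(tuk),
                           diff = tuk[, "diff"], p_adj = tuk[, "p adj"],
                           stars = pSignifStars(tuk[, "p adj"]),
                           row.names = NULL, stringsAsFactors = FALSE)
    method <- if (k > 2L) "one-way ANOVA + Tukey" else "one-way ANOVA"
    statistic <- an[["F value"]][1]
  } else if (k == 2L) {
    wt <- suppressWarnings(stats::wilcox.test(vals[[1]], vals[[2]]))
    p <- wt$p.value
    ## fully tied data carry no evidence of a difference
    if (is.na(p)) p <- 1
    statistic <- unname(wt$statistic)
    pairwise <- data.frame(comparison = paste(names(vals), collapse = " - "),
                           diff = NA_real_, p_adj = p, stars = pSignifStars(p),
                           stringsAsFactors = FALSE)
    method <- "Mann-Whitney"
  } else {
    kw <- suppressWarnings(stats::kruskal.test(sub[[valCol]], sub$site))
    p <- kw$p.value
    if (is.na(p)) p <- 1
    statistic <- unname(kw$statistic)
    dn <- .dunnTest(sub[[valCol]], sub$site)
    pairwise <- data.frame(comparison = dn$comparison, diff = NA_real_,
                           p_adj = dn$p_adj, stars = pSignifStars(dn$p_adj),
                           stringsAsFactors = FALSE)
    method <- "Kruskal-Wallis + Dunn (Bonferroni)"
    notes <- c(notes, "Dunn post-hoc p-values Bonferroni-adjusted")
  }
  list(method = method, normality = norm, statistic = statistic,
       p.value = p, stars = pSignifStars(p), pairwise = pairwise,
       notes = notes)
}

#' Pearson correlation between two metrics
#'
#' Pairs the per-subject values of two metrics by subject and site and
#' computes the Pearson correlation coefficient with its two-sided
#' p-value.
#'
#' @param table per-subject table (see
#'   \code{\link{aggregatePerSubject}}).
#' @param metricX,metricY the two metrics to correlate.
#' @return list with \code{r}, \code{p.value}, \code{n}.
#' @export
correlateMetrics <- function(table, metricX, metricY) {
  valCol <- if ("mean" %in% names(table)) "mean" else "value"
  a <- table[table$metric == metricX, c("subject_id", "site", valCol)]
  b <- table[table$metric == metricY, c("subject_id", "site", valCol)]
  mg <- merge(a, b, by = c("subject_id", "site"), suffixes = c(".x", ".y"))
  x <- mg[[paste0(valCol, ".x")]]
  y <- mg[[paste0(valCol, ".y")]]
  if (length(x) < 3L)
    .sqError("correlation needs at least 3 paired values", "sq_validation_error")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    .sqError("zero variance in a metric: correlation undefined",
             "sq_undefined_correlation")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p.value = ct$p.value, n = length(x))
}
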