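#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the D'Agostino (1970) skewness Z and the Anscombe-Glynn (1983)
#' kurtosis Z into the omnibus statistic K2 = Zs^2 + Zk^2, referred to a
#' chi-squared distribution with 2 df. Requires n >= 8 (the kurtosis
#' transform is undefined below that).
#'
#' @param x numeric sample, n >= 8.
#' @return list `statistic` (K2), `p.value`, `z_skew`, `z_kurt`, `n`.
#' @export
dagostino_pearson <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8) stop("D'Agostino-Pearson test requires n >= 8")
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  g1 <- m3 / m2^1.5
  g2 <- m4 / m2^2 - 3
  # skewness: D'Agostino's Z via Johnson SU approximation
  Y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (b2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  alpha <- sqrt(2 / (W2 - 1))
  Zs <- delta * log(Y / alpha + sqrt((Y / alpha)^2 + 1))
  # kurtosis: Anscombe-Glynn Z
  Eb2 <- 3 * (n - 1) / (n + 1)
  Vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  b2s <- g2 + 3                       # sample kurtosis (biased, as scipy)
  xk <- (b2s - Eb2) / sqrt(Vb2)
  beta1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / beta1 * (2 / beta1 + sqrt(1 + 4 / beta1^2))
  Zk <- ((1 - 2 / (9 * A)) -
           ((1 - 2 / A) / (1 + xk * sqrt(2 / (A - 4))))^(1 / 3)) /
    sqrt(2 / (9 * A))
  K2 <- Zs^2 + Zk^2
  list(statistic = K2,
       p.value = stats::pchisq(K2, df = 2, lower.tail = FALSE),
       z_skew = Zs, z_kurt = Zk, n = n)
}

#' Dunn's post-hoc test after Kruskal-Wallis
#'
#' Pairwise rank-sum comparisons on the joint ranking of all groups:
#' `z = (Ri - Rj) / sqrt((N(N+1)/12 - T) (1/ni + 1/nj))` with tie
#' correction `T = sum(t^3 - t) / (12 (N - 1))`. Two-sided p-values with a
#' multiplicity adjustment over all pairs (Bonferroni by default).
#'
#' @param samples named list of numeric vectors, one per group.
#' @param p.adjust.method adjustment passed to [stats::p.adjust()].
#' @return data.frame `group1, group2, z, p.value, p.adjusted`.
#' @export
dunn_test <- function(samples, p.adjust.method = "bonferroni") {
  g <- names(samples)
  if (is.null(g)) g <- paste0("g", seq_along(samples))
  x <- unlist(samples, use.names = FALSE)
  grp <- rep(g, lengths(samples))
  N <- length(x)
  rk <- rank(x)
  ties <- table(x)
  Tcorr <- sum(ties^3 - ties) / (12 * (N - 1))
  mean_rank <- tapply(rk, grp, mean)
  n <- tapply(rk, grp, length)
  pairs <- utils::combn(g, 2)
  z <- apply(pairs, 2, function(p) {
    (mean_rank[[p[1]]] - mean_rank[[p[2]]]) /
      sqrt((N * (N + 1) / 12 - Tcorr) * (1 / n[[p[1]]] + 1 / n[[p[2]]]))
  })
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = z,
             p.value = p,
             p.adjusted = stats::p.adjust(p, method = p.adjust.method),
             stringsAsFactors = FALSE)
}

#' Normality-gated group comparison
#'
#' The statistical decision procedure: per-group normality is assessed with
#' the D'Agostino-Pearson omnibus test at `alpha`. Two groups: unpaired
#' two-sided t-test when every group is consistent with normality,
#' Mann-Whitney (Wilcoxon rank-sum) otherwise. More than two groups:
#' one-way ANOVA followed by Tukey's multiple-comparison test when all
#' groups are normal, Kruskal-Wallis followed by Dunn's test otherwise.
#' Groups with n < 8 cannot be normality-tested; the nonparametric branch
#' is used and the reason recorded.
#'
#' @param samples named list of >= 2 numeric vectors, each with >= 3 values.
#' @param alpha significance level of the normality pre-test, default 0.05.
#' @param paired use a paired t-test / Wilcoxon signed-rank for two groups.
#' @param p.adjust.method adjustment for Dunn's test.
#' @return list of class `group_comparison`: `test` (name), `statistic`,
#'   `p.value`, `normality` (data.frame `group, n, p.value, normal`),
#'   `posthoc` (pairwise data.frame or NULL), `note`.
#' @export
compare_groups <- function(samples, alpha = 0.05, paired = FALSE,
                           p.adjust.method = "bonferroni") {
  if (length(samples) < 2) stop("need at least 2 groups")
  if (is.null(names(samples)))
    names(samples) <- paste0("group", seq_along(samples))
  ns <- lengths(samples)
  if (any(ns < 3)) stop("every group needs >= 3 values")
  norm <- do.call(rbind, lapply(names(samples), function(g) {
    x <- samples[[g]]
    if (length(x) >= 8) {
      t_ <- dagostino_pearson(x)
      data.frame(group = g, n = length(x), p.value = t_$p.value,
                 normal = t_$p.value >= alpha, testable = TRUE,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(group = g, n = length(x), p.value = NA_real_,
                 normal = FALSE, testable = FALSE, stringsAsFactors = FALSE)
    }
  }))
  note <- if (any(!norm$testable))
    "group(s) with n < 8: normality untestable, nonparametric branch used"
  else NULL
  all_normal <- all(norm$normal)
  posthoc <- NULL
  if (length(samples) == 2) {
    if (all_normal) {
      ht <- stats::t.test(samples[[1]], samples[[2]], paired = paired,
                          var.equal = FALSE)
      test <- if (paired) "paired t-test" else "unpaired t-test"
    } else {
      ht <- stats::wilcox.test(samples[[1]], samples[[2]], paired = paired,
                               exact = FALSE)
      test <- if (paired) "Wilcoxon signed-rank" else "Mann-Whitney"
    }
    statistic <- unname(ht$statistic); p <- ht$p.value
  } else {
    grp <- factor(rep(names(samples), ns), levels = names(samples))
    val <- unlist(samples, use.names = FALSE)
    if (all_normal) {
      fit <- stats::aov(val ~ grp)
      s <- summary(fit)[[1]]
      statistic <- s[["F value"]][1]; p <- s[["Pr(>F)"]][1]
      test <- "one-way ANOVA + Tukey"
      tk <- stats::TukeyHSD(fit)$grp
      posthoc <- data.frame(
        comparison = rownames(tk), diff = tk[, "diff"],
        p.adjusted = tk[, "p adj"], row.names = NULL,
        stringsAsFactors = FALSE)
    } else {
      ht <- stats::kruskal.test(val, grp)
      statistic <- unname(ht$statistic); p <- ht$p.value
      test <- "Kruskal-Wallis + Dunn"
      posthoc <- dunn_test(samples, p.adjust.method = p.adjust.method)
    }
  }
  structure(list(test = test, statistic = statistic, p.value = p,
                 normality = norm, posthoc = posthoc, note = note,
                 alpha = alpha),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Group comparison:", x$test, "\n")
  cat(sprintf("  statistic = %.4g, p = %.4g\n", x$statistic, x$p.value))
  cat("  normality (D'Agostino-Pearson, alpha =", x$alpha, "):\n")
  print(x$normality, row.names = FALSE)
  if (!is.null(x$posthoc)) {
    cat("  post-hoc:\n")
    print(x$posthoc, row.names = FALSE)
  }
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}
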