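#' Decide between the parametric and non-parametric branch
#'
#' The parametric branch (t-test for 2 groups, one-way ANOVA for 3 or
#' more) is chosen only when every group passes a Shapiro-Wilk
#' normality check and Levene's test (median-centered) finds no
#' evidence of variance heterogeneity, both at `alpha_assume`.
#' Otherwise the rank-based branch (Wilcoxon rank-sum /
#' Kruskal-Wallis) is chosen. Groups too small for the Shapiro-Wilk
#' test (n < 3) or with zero variance cannot support the normality
#' assumption and fall to the non-parametric branch with a warning.
#'
#' @param samples named list of numeric vectors, one per group (>= 2
#'   groups, each n >= 2).
#' @param alpha_assume significance level for the assumption checks.
#' @return A list with `chosen` (`"parametric"` or `"nonparametric"`),
#'   `normality_p` (per group), `levene_p`.
#' @export
choose_test <- function(samples, alpha_assume = 0.05) {
  check_groups(samples)
  normality_p <- vapply(samples, function(g) {
    if (length(g) < 3L || stats::sd(g) == 0) return(NA_real_)
    stats::shapiro.test(g)$p.value
  }, numeric(1))
  if (anyNA(normality_p)) {
    warning("group(s) with n < 3 or zero variance: normality cannot be assumed",
            call. = FALSE)
  }
  values <- unlist(samples, use.names = FALSE)
  grp <- factor(rep(names_or_index(samples), lengths(samples)))
  levene_p <- if (stats::sd(values) == 0) NA_real_ else
    car::leveneTest(values ~ grp)[1L, "Pr(>F)"]
  parametric <- !anyNA(normality_p) && !is.na(levene_p) &&
    all(normality_p > alpha_assume) && levene_p > alpha_assume
  list(chosen = if (parametric) "parametric" else "nonparametric",
       normality_p = normality_p, levene_p = levene_p)
}

names_or_index <- function(samples) {
  nm <- names(samples)
  if (is.null(nm) || any(!nzchar(nm))) nm <- paste0("group", seq_along(samples))
  nm
}

check_groups <- function(samples) {
  stopifnot(is.list(samples))
  if (length(samples) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(lengths(samples) < 2L)) {
    stop("every group needs at least 2 observations", call. = FALSE)
  }
  invisible(samples)
}

#' Compare groups with both parametric and rank-based tests
#'
#' Both branches are always computed and reported side by side (the
#' assumption-based selection rule only marks which one is `chosen`):
#' for two groups a Student t-test (equal variances, as implied by the
#' homogeneity check) and the Wilcoxon rank-sum test; for three or more
#' a one-way ANOVA and the Kruskal-Wallis rank-sum test. All tests are
#' two-sided.
#'
#' The Wilcoxon p-value uses exact enumeration when
#' `min(n, m) <= 8` and there are no ties, otherwise the normal
#' approximation with continuity correction. The Kruskal-Wallis
#' statistic uses mid-ranks with tie correction; its p-value is
#' computed by exhaustive permutation enumeration when the number of
#' distinct group-label arrangements is at most `enum_limit`, and by
#' the chi-squared approximation otherwise.
#'
#' @param samples named list of numeric vectors (>= 2 groups, each
#'   n >= 2).
#' @param alpha_assume level for the assumption checks.
#' @param enum_limit largest number of label arrangements for which the
#'   Kruskal-Wallis p-value is enumerated exactly.
#' @return A list of class `group_comparison`: `group_labels`,
#'   `n_per_group`, `parametric` and `nonparametric` (each `method`,
#'   `statistic`, `p`), `assumptions`, `chosen`.
#' @export
compare_groups <- function(samples, alpha_assume = 0.05,
                           enum_limit = 50000) {
  check_groups(samples)
  labels <- names_or_index(samples)
  decision <- suppressWarnings(choose_test(samples, alpha_assume))
  k <- length(samples)
  values <- unlist(samples, use.names = FALSE)
  grp <- factor(rep(labels, lengths(samples)), levels = labels)
  if (k == 2L) {
    par_fit <- stats::t.test(samples[[1L]], samples[[2L]], var.equal = TRUE)
    parametric <- list(method = "Two-sample t-test (pooled variance)",
                       statistic = unname(par_fit$statistic), p = par_fit$p.value)
    nonparametric <- wilcoxon_rank_sum(samples[[1L]], samples[[2L]])
  } else {
    fit <- stats::aov(values ~ grp)
    tab <- summary(fit)[[1L]]
    parametric <- list(method = "One-way ANOVA",
                       statistic = tab[1L, "F value"], p = tab[1L, "Pr(>F)"])
    nonparametric <- kruskal_wallis(samples, enum_limit = enum_limit)
  }
  structure(list(group_labels = labels, n_per_group = lengths(samples),
                 parametric = parametric, nonparametric = nonparametric,
                 assumptions = decision[c("normality_p", "levene_p")],
                 chosen = decision$chosen),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Group comparison (%s): chosen branch = %s\n",
              paste(sprintf("%s n=%d", x$group_labels, x$n_per_group),
                    collapse = ", "), x$chosen))
  cat(sprintf("  p  (%s): statistic = %.4g, p = %.4g\n",
              x$parametric$method, x$parametric$statistic, x$parametric$p))
  cat(sprintf("  np (%s): statistic = %.4g, p = %.4g\n",
              x$nonparametric$method, x$nonparametric$statistic,
              x$nonparametric$p))
  invisible(x)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration (via the exact null distribution of the rank-sum
#' statistic) when `min(n, m) <= 8` and the pooled data has no ties;
#' otherwise the normal approximation with continuity correction.
#'
#' @param x,y numeric samples.
#' @return list with `method`, `statistic` (W), `p`, `exact`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- min(length(x), length(y)) <= 8L && !ties
  ht <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  list(method = sprintf("Wilcoxon rank-sum (%s)",
                        if (exact) "exact" else "normal approx."),
       statistic = unname(ht$statistic), p = ht$p.value, exact = exact)
}

#' Kruskal-Wallis rank-sum test with exact small-sample enumeration
#'
#' The statistic is the tie-corrected Kruskal-Wallis H on mid-ranks.
#' When the number of distinct assignments of observations to groups,
#' `N! / prod(n_j!)`, does not exceed `enum_limit`, the p-value is the
#' exact permutation tail probability `P(H* >= H)` computed by full
#' enumeration; otherwise the chi-squared approximation with `k - 1`
#' degrees of freedom is used.
#'
#' @param samples list of numeric vectors.
#' @param enum_limit enumeration budget (number of arrangements).
#' @return list with `method`, `statistic` (H), `p`, `exact`.
#' @export
kruskal_wallis <- function(samples, enum_limit = 50000) {
  check_groups(samples)
  values <- unlist(samples, use.names = FALSE)
  grp <- factor(rep(seq_along(samples), lengths(samples)))
  ht <- stats::kruskal.test(values, grp)
  H <- unname(ht$statistic)
  n <- lengths(samples)
  n_arr <- exp(lgamma(sum(n) + 1) - sum(lgamma(n + 1)))
  if (n_arr <= enum_limit) {
    p <- kw_exact_p(values, n, H)
    list(method = "Kruskal-Wallis (exact enumeration)", statistic = H,
         p = p, exact = TRUE)
  } else {
    list(method = "Kruskal-Wallis (chi-squared approx.)", statistic = H,
         p = ht$p.value, exact = FALSE)
  }
}

# Exact permutation tail probability of the Kruskal-Wallis H statistic:
# enumerate every distinct assignment of the pooled mid-ranks to groups
# of the given sizes and count arrangements with H >= H_obs. Ties are
# handled by the usual correction factor, constant across arrangements.
kw_exact_p <- function(values, n, H_obs) {
  N <- sum(n)
  r <- rank(values)
  tie_tab <- table(r)
  C <- 1 - sum(tie_tab^3 - tie_tab) / (N^3 - N)
  if (C <= 0) return(1)   # all observations identical
  h_of <- function(rank_sums) {
    (12 / (N * (N + 1)) * sum(rank_sums^2 / n) - 3 * (N + 1)) / C
  }
  count <- 0L
  total <- 0L
  recurse <- function(avail, gi, sums) {
    if (gi == length(n)) {
      sums[gi] <- sum(r[avail])
      if (h_of(sums) >= H_obs - 1e-12) count <<- count + 1L
      total <<- total + 1L
      return(invisible())
    }
    picks <- utils::combn(length(avail), n[gi])
    for (j in seq_len(ncol(picks))) {
      idx <- picks[, j]
      sums[gi] <- sum(r[avail[idx]])
      recurse(avail[-idx], gi + 1L, sums)
    }
  }
  recurse(seq_len(N), 1L, numeric(length(n)))
  count / total
}

#' Pairwise group comparisons
#'
#' Runs [compare_groups()] on every pair of groups, with no
#' multiple-testing correction (pairwise comparisons are reported
#' raw).
#'
#' @inheritParams compare_groups
#' @return named list of `group_comparison` objects, one per pair.
#' @export
compare_groups_pairwise <- function(samples, alpha_assume = 0.05) {
  check_groups(samples)
  labels <- names_or_index(samples)
  names(samples) <- labels
  pairs <- utils::combn(length(samples), 2L)
  out <- lapply(seq_len(ncol(pairs)), function(j) {
    compare_groups(samples[pairs[, j]], alpha_assume = alpha_assume)
  })
  names(out) <- apply(pairs, 2L, function(ij) {
    paste(labels[ij], collapse = " vs ")
  })
  out
}
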