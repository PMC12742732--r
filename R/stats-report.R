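# Nonparametric statistical battery: Shapiro-Wilk gating, one-tailed
# Mann-Whitney, Kruskal-Wallis with epsilon-squared, Pearson correlation,
# and the Wilcoxon power analysis (ARE route plus simulation route).

#' Shapiro-Wilk normality gate per group
#'
#' @param groups named list of numeric vectors (n >= 3 each)
#' @return data frame `(group, W, p, normal)`; `normal = p > 0.05`.
#'   Degenerate (constant) samples are reported as non-normal with `NA`
#'   statistics rather than erroring.
#' @export
shapiro_gate <- function(groups) {
  if (any(vapply(groups, length, 1L) < 3))
    stop_invalid("Shapiro-Wilk needs n >= 3 per group")
  do.call(rbind, lapply(names(groups) %||% seq_along(groups), function(g) {
    v <- groups[[g]]
    res <- tryCatch(shapiro.test(v), error = function(e) NULL)
    if (is.null(res))
      data.frame(group = g, W = NA_real_, p = NA_real_, normal = FALSE)
    else
      data.frame(group = g, W = unname(res$statistic), p = res$p.value,
                 normal = res$p.value > 0.05)
  }))
}

#' One-tailed Mann-Whitney U comparison
#'
#' Exact p-value for small untied samples, normal approximation with tie
#' correction otherwise (delegated to `stats::wilcox.test`).
#'
#' @param a,b numeric samples
#' @param tail "greater" (a tends larger than b), "less", or "two.sided"
#' @param label optional comparison label
#' @return list of class `group_comparison`: test, statistic (U), p_value,
#'   tail, groups
#' @export
mann_whitney_one_tailed <- function(a, b, tail = c("greater", "less", "two.sided"),
                                    label = NULL) {
  tail <- match.arg(tail)
  if (!length(a) || !length(b)) stop_invalid("empty group")
  res <- suppressWarnings(wilcox.test(a, b, alternative = tail))
  structure(list(test = "Mann-Whitney U", statistic = unname(res$statistic),
                 p_value = res$p.value, tail = tail,
                 groups = label %||% "a vs b", effect_size = NA_real_),
            class = "group_comparison")
}

#' Kruskal-Wallis omnibus test with epsilon-squared effect size
#'
#' `epsilon^2 = H (n+1) / (n^2 - 1)` with `n` the total observation
#' count; magnitude labels use the conventional cut-offs
#' small (.01-.06), medium (.06-.14), large (>= .14).
#'
#' @param groups list (>= 2) of numeric vectors (each n >= 2)
#' @return list of class `group_comparison` with `effect_size` (epsilon^2)
#'   and `magnitude`
#' @export
kruskal_wallis_epsilon2 <- function(groups) {
  if (length(groups) < 2) stop_invalid("need at least 2 groups")
  if (any(vapply(groups, length, 1L) < 2)) stop_invalid("each group needs n >= 2")
  res <- kruskal.test(groups)
  H <- unname(res$statistic)
  n <- sum(vapply(groups, length, 1L))
  eps2 <- H * (n + 1) / (n^2 - 1)
  magnitude <- if (eps2 >= 0.14) "large" else if (eps2 >= 0.06) "medium"
    else if (eps2 >= 0.01) "small" else "negligible"
  structure(list(test = "Kruskal-Wallis", statistic = H, p_value = res$p.value,
                 tail = "two.sided", groups = paste(names(groups), collapse = ", "),
                 effect_size = eps2, magnitude = magnitude),
            class = "group_comparison")
}

#' Pearson correlation with two-sided t-based p-value
#'
#' @param x,y equal-length numeric vectors (n >= 3)
#' @param pair optional `(feature, behavior)` label
#' @return list of class `correlation_result`: r, p_value, n, pair;
#'   `r = NA` when either input has zero variance
#' @export
pearson_corr <- function(x, y, pair = NULL) {
  if (length(x) != length(y) || length(x) < 3)
    stop_invalid("need equal-length vectors with n >= 3")
  if (sd(x) == 0 || sd(y) == 0)
    return(structure(list(r = NA_real_, p_value = NA_real_, n = length(x),
                          pair = pair), class = "correlation_result"))
  res <- cor.test(x, y, method = "pearson")
  structure(list(r = unname(res$estimate), p_value = res$p.value,
                 n = length(x), pair = pair),
            class = "correlation_result")
}

#' Minimal sample size for a paired Wilcoxon signed-rank design
#'
#' Two routes: the asymptotic-relative-efficiency (ARE) correction of the
#' one-sample t-test size (`n_t / 0.955`, rounded up), and an optional
#' direct Monte-Carlo search that simulates Gaussian paired differences of
#' standardised effect `d` and finds the smallest n whose rejection rate
#' reaches the target power.
#'
#' @param d standardised effect size (> 0)
#' @param alpha significance level (default 0.05)
#' @param power target power (default 0.95)
#' @param tail "one.sided" (default) or "two.sided"
#' @param n_sims simulation replicates per candidate n (0 skips the
#'   simulation route)
#' @param seed seed for the simulation route
#' @return list with `n_are`, and when simulated `n_sim` and
#'   `power_at_n_sim`
#' @export
wilcoxon_power_n <- function(d, alpha = 0.05, power = 0.95,
                             tail = c("one.sided", "two.sided"),
                             n_sims = 0, seed = 1L) {
  tail <- match.arg(tail)
  if (d <= 0) stop_invalid("effect size d must be positive")
  if (alpha <= 0 || alpha >= 1 || power <= alpha || power >= 1)
    stop_invalid("need 0 < alpha < power < 1")
  pt <- power.t.test(delta = d, sd = 1, sig.level = alpha, power = power,
                     type = "one.sample", alternative = tail)
  n_are <- as.integer(ceiling(pt$n / 0.955))
  out <- list(n_are = n_are, d = d, alpha = alpha, power = power, tail = tail)
  if (n_sims > 0) {
    alt <- if (tail == "one.sided") "greater" else "two.sided"
    sim_power <- function(n) {
      with_local_seed(seed, {
        mean(vapply(seq_len(n_sims), function(i) {
          x <- rnorm(n, mean = d)
          suppressWarnings(wilcox.test(x, alternative = alt)$p.value) < alpha
        }, logical(1)))
      })
    }
    n <- n_are
    if (sim_power(n) >= power) {
      while (n > 3 && sim_power(n - 1) >= power) n <- n - 1
    } else {
      while (sim_power(n + 1) < power) {
        n <- n + 1
        if (n > 10 * n_are) stop("target power unreachable in simulation")
      }
      n <- n + 1
    }
    out$n_sim <- n
    out$power_at_n_sim <- sim_power(n)
  }
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s [%s] (%s): statistic = %.4g, p = %.4g", x$test, x$groups,
              x$tail, x$statistic, x$p_value))
  if (!is.na(x$effect_size))
    cat(sprintf(", epsilon^2 = %.3f (%s)", x$effect_size, x$magnitude))
  cat("\n")
  invisible(x)
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f (p = %.4g, n = %d)%s\n", x$r, x$p_value, x$n,
              if (!is.null(x$pair)) paste0(" [", paste(x$pair, collapse = " ~ "), "]") else ""))
  invisible(x)
}

#' Holm correction helper used by the pipeline report
#'
#' Correction is off by default, mirroring a pilot-study analysis; when
#' enabled the report states so.
#'
#' @param p p-values
#' @param correct logical
#' @return adjusted (or untouched) p-values
#' @export
maybe_holm <- function(p, correct = FALSE) {
  if (correct) stats::p.adjust(p, method = "holm") else p
}
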