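# Group statistics for flux experiments: WT normalization and one-way
# ANOVA with Dunnett many-to-one comparisons against a control group.

#' Normalize construct fluxes to wild type
#'
#' Percent-of-WT per construct, \code{100 x mean(construct) / mean(WT)},
#' with the standard error propagated by the delta method for a ratio of
#' independent means.
#'
#' @param construct numeric vector of per-cell (or per-experiment) fluxes
#'   for one construct, or a named list of such vectors.
#' @param wt numeric vector of WT fluxes; nonzero mean required.
#' @return data.frame with columns \code{construct}, \code{n},
#'   \code{percent_wt}, \code{sem}.
#' @export
normalize_to_wt <- function(construct, wt) {
  if (!length(wt) || mean(wt) == 0)
    stop("WT group must be non-empty with nonzero mean")
  if (!is.list(construct)) construct <- list(construct = construct)
  mw <- mean(wt)
  vw <- if (length(wt) > 1) stats::var(wt) / length(wt) else 0
  rows <- lapply(names(construct), function(nm) {
    x <- construct[[nm]]
    mx <- mean(x)
    vx <- if (length(x) > 1) stats::var(x) / length(x) else 0
    sem <- 100 * sqrt(vx / mw^2 + mx^2 * vw / mw^4)
    data.frame(construct = nm, n = length(x),
               percent_wt = 100 * mx / mw, sem = sem,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Two-sided Dunnett adjusted p-value: P(max_i |T_i| >= |t|) under the
# multivariate t distribution of the k contrasts vs control.
.dunnett_p <- function(t_obs, corr, df, abseps = 1e-5) {
  k <- nrow(corr)
  if (k == 1) return(2 * stats::pt(-abs(t_obs), df))
  p_in <- mvtnorm::pmvt(lower = rep(-abs(t_obs), k),
                        upper = rep(abs(t_obs), k),
                        df = df, corr = corr, type = "shifted",
                        algorithm = mvtnorm::GenzBretz(abseps = abseps,
                                                       maxpts = 50000))
  max(0, min(1, 1 - as.numeric(p_in)))
}

#' One-way ANOVA with Dunnett many-to-one comparisons
#'
#' Fits the one-way ANOVA F-test over all groups, then compares each
#' non-control group mean to the control with Dunnett's procedure:
#' adjusted p-values from the exact multivariate t distribution of the
#' contrast statistics (correlation induced by the shared control mean
#' and pooled variance). Significance is flagged at the conventional
#' reporting thresholds as well as \code{alpha}.
#'
#' @param values numeric response vector.
#' @param groups group labels (coerced to factor), one per value.
#' @param control label of the control group.
#' @param alpha familywise level for the \code{significant} flag,
#'   default 0.05.
#' @param thresholds extra flag thresholds, default \code{c(0.001,
#'   0.005)}.
#' @param abseps absolute error bound for the multivariate t integration.
#' @return List of class \code{dunnett_result} with \code{anova}
#'   (\code{F}, \code{df1}, \code{df2}, \code{p}) and \code{comparisons}:
#'   a data.frame with \code{group}, \code{n}, \code{diff} (group minus
#'   control), \code{t}, \code{df}, \code{p_adj}, \code{significant},
#'   plus one logical column per extra threshold.
#' @export
compare_to_control <- function(values, groups, control, alpha = 0.05,
                               thresholds = c(0.001, 0.005),
                               abseps = 1e-5) {
  groups <- factor(groups)
  if (!control %in% levels(groups)) stop("control group not found")
  n_g <- table(groups)
  if (length(n_g) < 2) stop("need >= 2 groups")
  if (any(n_g < 2)) stop("every group needs n >= 2")
  within_var <- tapply(values, groups, stats::var)
  if (all(within_var == 0))
    stop("degenerate input: all groups have zero variance")
  # pooled variance and classic one-way ANOVA
  N <- length(values)
  k_all <- length(n_g)
  df2 <- N - k_all
  means <- tapply(values, groups, mean)
  ss_within <- sum((n_g - 1) * within_var)
  s2 <- ss_within / df2
  if (s2 == 0) stop("degenerate input: zero pooled variance")
  ss_between <- sum(n_g * (means - mean(values))^2)
  f_stat <- (ss_between / (k_all - 1)) / s2
  anova_p <- stats::pf(f_stat, k_all - 1, df2, lower.tail = FALSE)
  others <- setdiff(levels(groups), control)
  n0 <- n_g[[control]]
  lam <- vapply(others, function(g)
    sqrt((1 / n0) / (1 / n_g[[g]] + 1 / n0)), 0)
  corr <- outer(lam, lam)
  diag(corr) <- 1
  comp <- do.call(rbind, lapply(seq_along(others), function(i) {
    g <- others[i]
    d <- means[[g]] - means[[control]]
    se <- sqrt(s2 * (1 / n_g[[g]] + 1 / n0))
    t_obs <- d / se
    p <- .dunnett_p(t_obs, corr, df2, abseps)
    data.frame(group = g, n = n_g[[g]], diff = d, t = t_obs, df = df2,
               p_adj = p, stringsAsFactors = FALSE)
  }))
  comp$significant <- comp$p_adj < alpha
  for (th in thresholds)
    comp[[sprintf("sig_%g", th)]] <- comp$p_adj < th
  rownames(comp) <- NULL
  structure(list(anova = list(F = f_stat, df1 = k_all - 1, df2 = df2,
                              p = anova_p),
                 control = control, alpha = alpha, comparisons = comp),
            class = "dunnett_result")
}

#' @export
print.dunnett_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.3f, p = %.3g; control = %s\n",
              x$anova$df1, x$anova$df2, x$anova$F, x$anova$p, x$control))
  print(x$comparisons, row.names = FALSE)
  invisible(x)
}
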