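# The statistical battery applied to the RR tables: balanced two-way
# fixed-effects ANOVA with Type-3 sums of squares, Tukey-Kramer HSD with a
# compact letter display, Pearson and first-order partial correlations, and
# pooled two-sample t-tests.

#' Balanced two-way fixed-effects ANOVA (no interaction, Type-3 SS)
#'
#' Fits `response ~ factor_a + factor_b` on a balanced design with exactly one
#' observation per cell. In the balanced case Type-3 (marginal) sums of squares
#' coincide with sequential sums of squares; this is asserted numerically via
#' `drop1`, not assumed.
#'
#' @param data data.frame.
#' @param response name of the numeric response column.
#' @param factor_a,factor_b names of the two factor columns.
#' @return Object of class `rr_anova`: `terms` data.frame (term, df, sum_sq,
#'   mean_sq, F, p), `residual` (df, sum_sq, mean_sq), `total_ss`, and the
#'   underlying `fit`.
#' @export
#' @examples
#' maps <- load_table2()
#' maps$rr <- maps$total_cm / maps$phys_mb
#' anova_two_way(maps, "rr", "parent_id", "chromosome")
anova_two_way <- function(data, response, factor_a, factor_b) {
  d <- data.frame(y = data[[response]],
                  a = factor(data[[factor_a]]),
                  b = factor(data[[factor_b]]))
  cells <- table(d$a, d$b)
  if (any(cells != 1)) {
    stop("design must be balanced with one observation per ",
         factor_a, " x ", factor_b, " cell")
  }
  fit <- stats::lm(y ~ a + b, data = d)
  constant_y <- sum((d$y - mean(d$y))^2) <= 1e-12
  seq_tab <- if (constant_y) {
    suppressWarnings(stats::anova(fit))  # perfect-fit F is replaced below
  } else {
    stats::anova(fit)
  }
  ss_seq <- seq_tab[c("a", "b"), "Sum Sq"]
  if (!constant_y) {
    # Type-3 = marginal SS from dropping each term from the full model;
    # asserted equal to the sequential SS (balanced design), not assumed
    d1 <- stats::drop1(fit, scope = ~ a + b, test = "F")
    ss_t3 <- d1[c("a", "b"), "Sum of Sq"]
    if (max(abs(ss_seq - ss_t3)) > 1e-8 * max(ss_seq)) {
      stop("Type-3 and sequential SS disagree; design is not balanced")
    }
  } else {
    ss_t3 <- ss_seq  # constant response: every SS is zero
  }
  res <- seq_tab["Residuals", ]
  df_term <- seq_tab[c("a", "b"), "Df"]
  # a term SS at floating-point noise level (constant response) counts as zero
  eps <- 1e-12 * (sum((d$y - mean(d$y))^2) + 1)
  f_val <- ifelse(ss_t3 <= eps, 0, ss_t3 / df_term / res[["Mean Sq"]])
  terms <- data.frame(
    term = c(factor_a, factor_b),
    df = df_term,
    sum_sq = ss_t3,
    mean_sq = ss_t3 / df_term,
    F = f_val,
    row.names = NULL)
  terms$p <- stats::pf(terms$F, terms$df, res[["Df"]], lower.tail = FALSE)
  structure(list(terms = terms,
                 residual = list(df = res[["Df"]], sum_sq = res[["Sum Sq"]],
                                 mean_sq = res[["Mean Sq"]]),
                 total_ss = sum(seq_tab[["Sum Sq"]]),
                 fit = fit),
            class = "rr_anova")
}

#' @export
print.rr_anova <- function(x, ...) {
  tab <- x$terms
  tab$p <- format.pval(tab$p, digits = 3)
  print(tab, row.names = FALSE)
  cat(sprintf("residual: df %d, MS %.4f\n", x$residual$df, x$residual$mean_sq))
  invisible(x)
}

#' Tukey-Kramer HSD pairwise comparisons with compact letter display
#'
#' Tests all pairwise differences of the level means against the studentized
#' range critical value q(1-alpha, k, df) * sqrt(MSE/2 * (1/n_i + 1/n_j)) and
#' assigns letters by insert-and-absorb: levels sharing a letter are not
#' significantly different.
#'
#' @param means named numeric vector of level means.
#' @param n replications per level (scalar or named vector).
#' @param mse residual mean square from the ANOVA.
#' @param df_resid residual degrees of freedom.
#' @param alpha significance level (default 0.05).
#' @return List with `pairs` (data.frame: level_1, level_2, diff, q_crit_diff,
#'   significant, p_adj) and `letters` (named character vector, levels in
#'   decreasing mean order).
#' @export
tukey_kramer <- function(means, n, mse, df_resid, alpha = 0.05) {
  k <- length(means)
  if (k < 2) stop("need at least 2 level means")
  if (is.null(names(means))) names(means) <- as.character(seq_len(k))
  if (length(n) == 1) n <- setNames(rep(n, k), names(means))
  q_crit <- stats::qtukey(1 - alpha, k, df_resid)
  combs <- utils::combn(names(means), 2)
  pairs <- data.frame(level_1 = combs[1, ], level_2 = combs[2, ],
                      stringsAsFactors = FALSE)
  means <- setNames(as.numeric(means), names(means))  # drop tapply's dim
  n <- setNames(as.numeric(n), names(n))
  pairs$diff <- means[pairs$level_1] - means[pairs$level_2]
  se <- sqrt(mse / 2 * (1 / n[pairs$level_1] + 1 / n[pairs$level_2]))
  pairs$q_stat <- abs(pairs$diff) / se
  pairs$significant <- pairs$q_stat > q_crit
  pairs$p_adj <- stats::ptukey(pairs$q_stat, k, df_resid, lower.tail = FALSE)
  rownames(pairs) <- NULL
  letters_out <- cld_insert_absorb(means, pairs)
  list(pairs = pairs, letters = letters_out, q_crit = q_crit)
}

# Compact letter display, insert-and-absorb: start from one column covering
# all levels; for every significant pair split each column containing both;
# absorb columns contained in another; label columns in order of the best
# (largest) mean they cover.
cld_insert_absorb <- function(means, pairs) {
  lev <- names(sort(means, decreasing = TRUE))
  cols <- list(lev)
  sig <- pairs[pairs$significant, , drop = FALSE]
  for (i in seq_len(nrow(sig))) {
    a <- sig$level_1[i]; b <- sig$level_2[i]
    new_cols <- list()
    for (col in cols) {
      if (a %in% col && b %in% col) {
        new_cols <- c(new_cols, list(setdiff(col, a)), list(setdiff(col, b)))
      } else {
        new_cols <- c(new_cols, list(col))
      }
    }
    # absorb: drop any column whose levels are a subset of another's
    keep <- rep(TRUE, length(new_cols))
    for (p in seq_along(new_cols)) {
      for (q in seq_along(new_cols)) {
        if (p != q && keep[q] &&
            all(new_cols[[p]] %in% new_cols[[q]]) &&
            !(all(new_cols[[q]] %in% new_cols[[p]]) && p < q)) {
          keep[p] <- FALSE
          break
        }
      }
    }
    cols <- unique(new_cols[keep])
  }
  # order columns by the rank of their best mean, label a, b, c, ...
  best <- vapply(cols, function(col) min(match(col, lev)), numeric(1))
  cols <- cols[order(best)]
  out <- setNames(rep("", length(lev)), lev)
  for (i in seq_along(cols)) {
    lab <- letters[(i - 1) %% 26 + 1]
    for (l in cols[[i]]) out[l] <- paste0(out[l], lab)
  }
  out
}

#' Pearson correlation with two-sided p-value
#'
#' Product-moment correlation; p from t = r * sqrt((n-2)/(1-r^2)) on n-2
#' degrees of freedom.
#'
#' @param x,y numeric vectors of equal length (n >= 3, finite).
#' @return List with `r`, `n`, `p` (and `controlled_for = NA`). `r` is `NA`
#'   with a warning when either variable has zero variance.
#' @export
pearson_corr <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3,
            all(is.finite(x)), all(is.finite(y)))
  n <- length(x)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance; correlation undefined")
    return(list(r = NA_real_, n = n, p = NA_real_, controlled_for = NA_character_))
  }
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  p <- if (abs(r) >= 1) 0 else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(abs(tstat), n - 2, lower.tail = FALSE)
  }
  list(r = r, n = n, p = p, controlled_for = NA_character_)
}

#' First-order partial correlation
#'
#' r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2)); the p-value
#' uses the t transform on n - 3 degrees of freedom. Equivalent to correlating
#' the residuals of least-squares fits of x on z and y on z.
#'
#' @param x,y,z numeric vectors of equal length (n >= 4).
#' @param control_name label stored in the result.
#' @return List with `r`, `n`, `p`, `controlled_for`.
#' @export
partial_corr <- function(x, y, z, control_name = deparse(substitute(z))) {
  stopifnot(length(x) == length(y), length(y) == length(z), length(x) >= 4)
  n <- length(x)
  rxy <- pearson_corr(x, y)$r
  rxz <- pearson_corr(x, z)$r
  ryz <- pearson_corr(y, z)$r
  if (abs(rxz) >= 1 || abs(ryz) >= 1) {
    warning("control variable collinear with x or y; partial correlation undefined")
    return(list(r = NA_real_, n = n, p = NA_real_, controlled_for = control_name))
  }
  r <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  p <- if (abs(r) >= 1) 0 else {
    tstat <- r * sqrt((n - 3) / (1 - r^2))
    2 * stats::pt(abs(tstat), n - 3, lower.tail = FALSE)
  }
  list(r = r, n = n, p = p, controlled_for = control_name)
}

#' Pooled-variance two-sample t-test
#'
#' @param group_a,group_b numeric vectors (each n >= 2).
#' @return List with `t`, `df` (= n_a + n_b - 2), `p` (two-sided); `t` is `NA`
#'   when the pooled variance is zero.
#' @export
two_sample_t <- function(group_a, group_b) {
  na <- length(group_a); nb <- length(group_b)
  stopifnot(na >= 2, nb >= 2)
  df <- na + nb - 2
  sp2 <- ((na - 1) * stats::var(group_a) + (nb - 1) * stats::var(group_b)) / df
  if (sp2 == 0) {
    if (mean(group_a) == mean(group_b)) {
      return(list(t = 0, df = df, p = 1))
    }
    return(list(t = NA_real_, df = df, p = NA_real_))
  }
  tstat <- (mean(group_a) - mean(group_b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = tstat, df = df, p = 2 * stats::pt(abs(tstat), df, lower.tail = FALSE))
}

#' Significance stars at the conventional thresholds
#'
#' `***` P < 0.001, `**` P < 0.01, `*` P < 0.05, `ns` otherwise.
#'
#' @param p numeric vector of p-values.
#' @return Character vector.
#' @export
significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}

#' Full pairwise correlation matrix with p-values and stars
#'
#' @param df data.frame of numeric columns.
#' @return List of matrices `r`, `p`, `stars` (diagonal `NA`).
#' @export
correlation_matrix <- function(df) {
  vars <- names(df)
  k <- length(vars)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    res <- pearson_corr(df[[i]], df[[j]])
    r[i, j] <- res$r
    p[i, j] <- res$p
  }
  stars <- matrix(NA_character_, k, k, dimnames = list(vars, vars))
  stars[!is.na(p)] <- significance_stars(p[!is.na(p)])
  list(r = r, p = p, stars = stars)
}
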