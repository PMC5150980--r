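#' Two-way fixed-effects ANOVA with Type-II sums of squares
#'
#' Full-factorial species x health designs in field data are unbalanced
#' (cell sizes of 2-16), so main effects are tested with Type-II sums of
#' squares: each main effect is adjusted for the other main effect, and the
#' interaction for both. On balanced designs this reduces exactly to the
#' classical decomposition. If `factor_b` has a single level the analysis
#' degenerates to a one-way ANOVA on `factor_a`.
#'
#' @param data data.frame of measurements.
#' @param value,factor_a,factor_b column names (character) holding the
#'   response and the two factors (e.g. `"species"`, `"health"`).
#' @return object of class `anova_result`: data.frame with columns
#'   `effect`, `df_num`, `df_den`, `ss`, `F`, `p`.
#' @export
two_way_anova <- function(data, value = "value", factor_a = "species",
                          factor_b = "health") {
  stopifnot(all(c(value, factor_a, factor_b) %in% names(data)))
  y <- data[[value]]
  if (!all(is.finite(y))) stop("response values must be finite")
  A <- factor(data[[factor_a]])
  B <- factor(data[[factor_b]])
  if (nlevels(A) < 2) stop(factor_a, " must have >= 2 levels")
  d <- data.frame(y = y, A = A, B = B)
  one_way <- nlevels(B) < 2
  if (!one_way) {
    tab <- table(A, B)
    if (any(tab == 0)) {
      empty <- which(tab == 0, arr.ind = TRUE)
      cells <- apply(empty, 1, function(i)
        paste0(levels(A)[i[1]], ":", levels(B)[i[2]]))
      stop("empty design cell(s): ", paste(cells, collapse = ", "))
    }
  }
  rss <- function(f) sum(stats::resid(stats::lm(f, data = d))^2)
  if (one_way) {
    rss_a <- rss(y ~ A)
    ss_a <- rss(y ~ 1) - rss_a
    df_den <- nrow(d) - nlevels(A)
    mse <- rss_a / df_den
    out <- data.frame(effect = factor_a,
                      df_num = nlevels(A) - 1, df_den = df_den,
                      ss = ss_a,
                      F = (ss_a / (nlevels(A) - 1)) / mse)
  } else {
    rss_full <- rss(y ~ A * B)
    rss_ab <- rss(y ~ A + B)
    ss_a <- rss(y ~ B) - rss_ab
    ss_b <- rss(y ~ A) - rss_ab
    ss_int <- rss_ab - rss_full
    df_den <- nrow(d) - nlevels(A) * nlevels(B)
    if (df_den < 1) stop("no residual degrees of freedom")
    mse <- rss_full / df_den
    df_num <- c(nlevels(A) - 1, nlevels(B) - 1,
                (nlevels(A) - 1) * (nlevels(B) - 1))
    ss <- c(ss_a, ss_b, ss_int)
    out <- data.frame(effect = c(factor_a, factor_b,
                                 paste0(factor_a, ":", factor_b)),
                      df_num = df_num, df_den = df_den, ss = ss,
                      F = (ss / df_num) / mse)
  }
  out$p <- stats::pf(out$F, out$df_num, out$df_den, lower.tail = FALSE)
  structure(out, class = c("anova_result", "data.frame"))
}

#' @export
print.anova_result <- function(x, ...) {
  cat("Two-way ANOVA (Type-II sums of squares)\n")
  df <- as.data.frame(x)
  df$F <- signif(df$F, 4); df$ss <- signif(df$ss, 5)
  df$p <- format.pval(df$p, digits = 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Tukey's honest significant difference (Tukey-Kramer)
#'
#' Pairwise comparisons of group means against the studentized-range
#' distribution; the Tukey-Kramer standard error
#' `sqrt(MSE/2 * (1/n_i + 1/n_j))` handles unbalanced groups.
#'
#' @param data data.frame of measurements.
#' @param value,group column names for the response and the grouping factor
#'   (>= 3 groups required).
#' @return data.frame with columns `group1`, `group2`, `diff`, `se`,
#'   `q`, `p`.
#' @export
tukey_hsd <- function(data, value = "value", group = "species") {
  stopifnot(all(c(value, group) %in% names(data)))
  y <- data[[value]]
  g <- factor(data[[group]])
  k <- nlevels(g)
  if (k < 3) stop("Tukey HSD needs >= 3 groups (got ", k, ")")
  ns <- tapply(y, g, length)
  if (any(ns < 2)) stop("every group needs >= 2 observations")
  means <- tapply(y, g, mean)
  df_err <- length(y) - k
  mse <- sum(stats::resid(stats::lm(y ~ g))^2) / df_err
  pairs <- utils::combn(levels(g), 2)
  res <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    diff <- means[[j]] - means[[i]]
    se <- sqrt(mse / 2 * (1 / ns[[i]] + 1 / ns[[j]]))
    q <- abs(diff) / se
    c(diff = diff, se = se, q = q,
      p = stats::ptukey(q, nmeans = k, df = df_err, lower.tail = FALSE))
  })
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
             t(res), row.names = NULL)
}

#' Two-sample t-test (pooled or Welch)
#'
#' @param a,b numeric samples, each with >= 2 observations.
#' @param variant `"unequal_variance"` (Welch-Satterthwaite degrees of
#'   freedom; the default, as used for cell-count comparisons) or
#'   `"pooled"` (classical Student).
#' @return list with `t`, `df`, `p` (two-sided). When both samples have
#'   zero variance and equal means the convention t = 0, p = 1 applies.
#' @export
two_sample_t <- function(a, b, variant = c("unequal_variance", "pooled")) {
  variant <- match.arg(variant)
  if (length(a) < 2 || length(b) < 2)
    stop("each sample needs >= 2 observations")
  na <- length(a); nb <- length(b)
  va <- stats::var(a); vb <- stats::var(b)
  md <- mean(a) - mean(b)
  if (va == 0 && vb == 0) {
    if (md == 0)
      return(list(t = 0, df = na + nb - 2, p = 1, variant = variant))
    stop("zero variance in both samples with unequal means: t is undefined")
  }
  if (variant == "pooled") {
    df <- na + nb - 2
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / df
    se <- sqrt(sp2 * (1 / na + 1 / nb))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  t <- md / se
  list(t = t, df = df, p = 2 * stats::pt(abs(t), df, lower.tail = FALSE),
       variant = variant)
}
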