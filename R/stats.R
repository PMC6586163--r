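# Statistical reporting: one-way ANOVA with Fisher LSD compact letter
# display, pooled two-sample t-test, and TPM expression summaries.

#' One-way ANOVA with Fisher LSD letters
#'
#' Runs a one-way ANOVA and all pairwise comparisons by Fisher's least
#' significant difference: pairwise t statistics use the pooled
#' within-group mean square and its degrees of freedom.  Group letters
#' are assigned by the insert-absorb compact-letter-display algorithm so
#' that two groups share a letter exactly when their pairwise comparison
#' is non-significant at `alpha`.  Letters run in ascending-mean order
#' starting at `"a"`.
#'
#' With `protected = TRUE` (the default) the pairwise tests are only
#' interpreted when the omnibus F-test is significant; otherwise all
#' groups share one letter.  A Shapiro-Wilk normality check per group is
#' reported but never blocks the analysis.
#'
#' @param values numeric response vector.
#' @param groups group labels (coerced to factor), `>= 2` groups with
#'   `>= 2` observations each.
#' @param alpha significance level (default 0.05).
#' @param protected logical; protect the LSD behind the omnibus test
#'   (default `TRUE`).
#' @param p_adjust p-value adjustment for the pairwise matrix, passed to
#'   [stats::p.adjust()] (default `"none"`, plain LSD; `"holm"`
#'   available for conservative users).
#' @return an object of class `"lsd_anova"`: list with `F`, `p_omnibus`,
#'   `df`, `means`, `n`, `pairwise` (symmetric p-value matrix),
#'   `letters` (named character), `protected`, `normality` (per-group
#'   Shapiro-Wilk p-values where computable).
#' @examples
#' set.seed(1)
#' g <- rep(c("ctrl", "mid", "high"), each = 3)
#' y <- rnorm(9, rep(c(0, 10, 20), each = 3), 0.1)
#' anova_fisher_lsd(y, g)$letters
#' @export
anova_fisher_lsd <- function(values, groups, alpha = 0.05, protected = TRUE,
                             p_adjust = "none") {
  groups <- factor(groups)
  stopifnot(length(values) == length(groups), all(is.finite(values)))
  n <- tapply(values, groups, length)
  if (nlevels(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(n < 2)) stop("every group needs at least 2 observations",
                       call. = FALSE)
  fit <- stats::aov(values ~ groups)
  # a perfect fit (all groups constant) triggers an aov reliability warning;
  # that case is handled explicitly below
  at <- withCallingHandlers(stats::anova(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  Fstat <- at[["F value"]][1]
  p_omni <- at[["Pr(>F)"]][1]
  if (!is.finite(p_omni)) p_omni <- 1  # no residual variance, no evidence
  mse <- at[["Mean Sq"]][2]
  df_err <- at[["Df"]][2]
  means <- tapply(values, groups, mean)

  lev <- levels(groups)
  k <- length(lev)
  pmat <- matrix(NA_real_, k, k, dimnames = list(lev, lev))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    se <- sqrt(mse * (1 / n[i] + 1 / n[j]))
    tij <- if (se == 0) {
      if (means[i] == means[j]) 0 else Inf
    } else (means[i] - means[j]) / se
    pmat[i, j] <- pmat[j, i] <- 2 * stats::pt(-abs(tij), df_err)
  }
  diag(pmat) <- 1
  if (p_adjust != "none") {
    upper <- upper.tri(pmat)
    pmat[upper] <- stats::p.adjust(pmat[upper], method = p_adjust)
    pmat[lower.tri(pmat)] <- t(pmat)[lower.tri(pmat)]
  }

  sig <- if (protected && p_omni > alpha) {
    matrix(FALSE, k, k, dimnames = dimnames(pmat))
  } else pmat < alpha

  letters <- compact_letter_display(sig, order(means))
  normality <- tapply(values, groups, function(v) {
    if (length(v) >= 3 && stats::sd(v) > 0) stats::shapiro.test(v)$p.value
    else NA_real_
  })

  structure(list(F = Fstat, p_omnibus = p_omni,
                 df = c(between = at[["Df"]][1], within = df_err),
                 means = means, n = n, mse = mse, pairwise = pmat,
                 letters = letters, alpha = alpha, protected = protected,
                 normality = normality),
            class = "lsd_anova")
}

#' @export
print.lsd_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.3f, p = %.4g%s\n",
              x$df["between"], x$df["within"], x$F, x$p_omnibus,
              if (x$protected) " (protected LSD)" else ""))
  tab <- data.frame(mean = round(as.numeric(x$means), 4),
                    n = as.integer(x$n),
                    letters = x$letters[names(x$means)])
  print(tab)
  invisible(x)
}

#' Compact letter display by insert-absorb
#'
#' Builds a letter display from a logical significance matrix: two groups
#' share a letter iff their comparison is non-significant.  Starting from
#' a single letter covering all groups, each significant pair splits every
#' letter column containing both; redundant (subset) columns are
#' absorbed.  Letters are assigned to columns in the order given by
#' `group_order` (typically ascending means).
#'
#' @param sig symmetric logical matrix (`TRUE` = significantly
#'   different), dimnames = group labels.
#' @param group_order integer permutation used to order letter
#'   assignment (default: as given).
#' @return named character vector of letter strings per group.
#' @export
compact_letter_display <- function(sig, group_order = seq_len(nrow(sig))) {
  k <- nrow(sig)
  labels <- rownames(sig)
  cols <- list(rep(TRUE, k))  # each column: logical membership over groups
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (!isTRUE(sig[i, j])) next
    for (ci in seq_along(cols)) {
      col <- cols[[ci]]
      if (col[i] && col[j]) {
        a <- col; a[i] <- FALSE
        b <- col; b[j] <- FALSE
        cols[[ci]] <- a
        cols[[length(cols) + 1]] <- b
      }
    }
    # absorb columns contained in another
    keep <- rep(TRUE, length(cols))
    for (ci in seq_along(cols)) for (cj in seq_along(cols)) {
      if (ci != cj && keep[ci] && keep[cj] &&
          all(cols[[ci]] <= cols[[cj]]) && any(cols[[ci]] < cols[[cj]]))
        keep[ci] <- FALSE
      else if (ci < cj && keep[ci] && keep[cj] &&
               all(cols[[ci]] == cols[[cj]]))
        keep[cj] <- FALSE
    }
    cols <- cols[keep]
  }
  # order columns by the first (in group_order) group they contain
  first_member <- vapply(cols, function(col)
    min(match(which(col), group_order)), numeric(1))
  cols <- cols[order(first_member)]
  out <- vapply(seq_len(k), function(g)
    paste(letters[which(vapply(cols, `[`, logical(1), g))], collapse = ""),
    character(1))
  stats::setNames(out, labels)
}

#' Pooled two-sample t-test
#'
#' Two-sided two-sample t-test with pooled variance (equal variances
#' assumed), as used to compare pressure-probe transport parameters
#' between growth conditions.  If both samples have zero variance and
#' equal means, `t = 0, p = 1` by convention.
#'
#' @param a,b numeric samples, `>= 2` values each.
#' @param alpha significance level for the verdict (default 0.05).
#' @return list with `t`, `df`, `p`, `significant` (logical verdict at
#'   `alpha`), and the group means.
#' @export
two_sample_t <- function(a, b, alpha = 0.05) {
  stopifnot(length(a) >= 2, length(b) >= 2,
            all(is.finite(a)), all(is.finite(b)))
  df <- length(a) + length(b) - 2
  sp2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) / df
  se <- sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  tt <- if (se == 0) {
    if (mean(a) == mean(b)) 0 else Inf * sign(mean(a) - mean(b))
  } else (mean(a) - mean(b)) / se
  p <- 2 * stats::pt(-abs(tt), df)
  list(t = tt, df = df, p = p, significant = p <= alpha,
       means = c(a = mean(a), b = mean(b)))
}

#' Transcripts per million
#'
#' Length-normalized within-sample expression:
#' `TPM_i = 1e6 * (c_i / l_i) / sum_j (c_j / l_j)`, so TPM sums to 1e6 in
#' every sample.
#'
#' @param counts non-negative read counts: a vector, or a matrix with
#'   genes in rows and samples in columns.
#' @param lengths transcript lengths in bp, `> 0`, one per gene.
#' @return TPM values with the shape of `counts`.
#' @export
tpm <- function(counts, lengths) {
  if (any(lengths <= 0)) stop("lengths must be positive", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  f <- function(cvec) {
    rate <- cvec / lengths
    s <- sum(rate)
    if (s == 0) stop("all-zero counts: TPM undefined", call. = FALSE)
    1e6 * rate / s
  }
  if (is.matrix(counts)) {
    stopifnot(nrow(counts) == length(lengths))
    apply(counts, 2, f)
  } else {
    stopifnot(length(counts) == length(lengths))
    f(counts)
  }
}
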