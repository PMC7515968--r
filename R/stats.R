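#' Significance stars
#'
#' The exact reporting convention: `*` for p < 0.05, `**` for p < 0.01,
#' `***` for p < 0.001, empty otherwise.
#'
#' @param p numeric vector of p-values.
#' @return character vector of star strings.
#' @export
p_stars <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    if (pi < 0.001) "***" else if (pi < 0.01) "**"
    else if (pi < 0.05) "*" else ""
  }, "")
}

#' Format a sample as `mean ± SD` to three decimals
#'
#' @param x numeric vector.
#' @param digits decimals (default 3).
#' @return character scalar, e.g. `"30.221 ± 5.524"`.
#' @export
format_mean_sd <- function(x, digits = 3) {
  sprintf(paste0("%.", digits, "f ± %.", digits, "f"),
          mean(x), stats::sd(x))
}

#' Two-group comparison (t test)
#'
#' Welch's t test by default (`welch = FALSE` gives the classic pooled
#' Student test), two-sided.  Intended to be run on animal means, the
#' design's statistical unit.  When both groups have zero within-group
#' variance the test is degenerate: equal means report `t = 0, p = 1`,
#' unequal means `t = Inf, p = 0`, both flagged.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param welch use the Welch-Satterthwaite df (default `TRUE`).
#' @param labels group labels for printing.
#' @return object of class `group_comparison`: `statistic`, `df`,
#'   `p_value`, `means`, `sds`, `formatted`, `stars`, `welch`,
#'   `degenerate`.
#' @export
two_group_test <- function(a, b, welch = TRUE,
                           labels = c("group A", "group B")) {
  stopifnot("each group needs n >= 2" = length(a) >= 2 && length(b) >= 2)
  degenerate <- FALSE
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    degenerate <- TRUE
    equal <- isTRUE(all.equal(mean(a), mean(b)))
    tt <- list(statistic = if (equal) 0 else Inf * sign(mean(a) - mean(b)),
               parameter = length(a) + length(b) - 2,
               p.value = if (equal) 1 else 0)
    warning("zero within-group variance in both groups: degenerate test")
  } else {
    tt <- stats::t.test(a, b, var.equal = !welch)
  }
  structure(list(statistic = unname(tt$statistic),
                 df = unname(tt$parameter),
                 p_value = tt$p.value,
                 means = c(mean(a), mean(b)),
                 sds = c(stats::sd(a), stats::sd(b)),
                 formatted = c(format_mean_sd(a), format_mean_sd(b)),
                 labels = labels,
                 stars = p_stars(tt$p.value),
                 welch = welch,
                 degenerate = degenerate),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: %s  vs  %s: %s\n", x$labels[1], x$formatted[1],
              x$labels[2], x$formatted[2]))
  cat(sprintf("  %s t(%.2f) = %.3f, P = %.4g %s%s\n",
              if (x$welch) "Welch" else "Student", x$df, x$statistic,
              x$p_value, x$stars,
              if (x$degenerate) " [degenerate: zero variance]" else ""))
  invisible(x)
}

#' Two-way ANOVA with Tukey-corrected pairwise comparisons
#'
#' Fits `value ~ A * B`, reports F and p for both main effects and the
#' interaction, and Tukey HSD adjusted p-values for all pairwise
#' comparisons of the A x B cell means (alongside the unadjusted p from
#' the same pooled error, for reference).  With zero between- and
#' within-cell variance (all observations identical) the F ratios are
#' degenerate and reported as `F = 0, p = 1`.
#'
#' @param values numeric response.
#' @param factor_a,factor_b factors (coerced), >= 2 levels each and >= 2
#'   observations per cell.
#' @param names names of the two factors in the output (default
#'   `"treatment"`, `"volume"`).
#' @return object of class `anova_tukey`: `effects` (data frame with
#'   `term`, `df`, `F`, `p`) and `pairwise` (data frame with `pair`,
#'   `diff`, `p_adj`, `p_unadj`).
#' @export
two_way_anova_tukey <- function(values, factor_a, factor_b,
                                names = c("treatment", "volume")) {
  A <- factor(factor_a); B <- factor(factor_b)
  stopifnot("each factor needs >= 2 levels" =
              nlevels(A) >= 2 && nlevels(B) >= 2)
  tab <- table(A, B)
  if (any(tab < 2)) {
    bad <- which(tab < 2, arr.ind = TRUE)[1, ]
    stop("cell (", levels(A)[bad[1]], ", ", levels(B)[bad[2]],
         ") has fewer than 2 observations")
  }
  d <- data.frame(y = values, A = A, B = B)
  fit <- stats::aov(y ~ A * B, data = d)
  sm <- summary(fit)[[1]]
  terms <- trimws(rownames(sm))
  keep <- terms != "Residuals"
  Fv <- sm[keep, "F value"]; pv <- sm[keep, "Pr(>F)"]
  ss <- sm[keep, "Sum Sq"]
  # all observations (numerically) identical: no signal and no noise, so
  # every F ratio is 0/0; report the no-effect limit F = 0, p = 1
  total_ss <- sum(sm[, "Sum Sq"])
  if (total_ss <= 1e-12 * max(1, mean(values)^2) * length(values)) {
    Fv[] <- 0; pv[] <- 1
  } else {
    deg <- !is.finite(Fv) & ss < 1e-12
    Fv[deg] <- 0; pv[deg] <- 1
  }
  effects <- data.frame(
    term = c(names[1], names[2], paste(names, collapse = " x ")),
    df = sm[keep, "Df"], F = Fv, p = pv)

  # pairwise comparisons of the A x B cells
  cell <- interaction(A, B, sep = ":")
  mse <- sm["Residuals", "Mean Sq"]
  df_res <- sm["Residuals", "Df"]
  mns <- tapply(values, cell, mean)
  ns <- tapply(values, cell, length)
  lv <- names(mns)
  pairs <- utils::combn(seq_along(lv), 2)
  k <- length(lv)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(q) {
    i <- pairs[1, q]; j <- pairs[2, q]
    diff <- mns[j] - mns[i]
    se <- sqrt(mse * (1 / ns[i] + 1 / ns[j]))
    if (se == 0) {
      p_adj <- if (abs(diff) < 1e-12) 1 else 0
      p_un <- p_adj
    } else {
      tstat <- diff / se
      p_un <- 2 * stats::pt(-abs(tstat), df_res)
      p_adj <- stats::ptukey(abs(tstat) * sqrt(2), k, df_res,
                             lower.tail = FALSE)
    }
    data.frame(pair = paste(lv[j], "-", lv[i]), diff = unname(diff),
               p_adj = unname(p_adj), p_unadj = unname(p_un))
  }))
  structure(list(effects = effects, pairwise = pw, mse = mse,
                 df_residual = df_res),
            class = "anova_tukey")
}

#' @export
print.anova_tukey <- function(x, ...) {
  cat("Two-way ANOVA\n")
  for (i in seq_len(nrow(x$effects)))
    cat(sprintf("  %-20s F(%d, %d) = %.3f, P = %.4g %s\n",
                x$effects$term[i], x$effects$df[i], x$df_residual,
                x$effects$F[i], x$effects$p[i], p_stars(x$effects$p[i])))
  cat("Tukey HSD pairwise comparisons (cells):\n")
  for (i in seq_len(nrow(x$pairwise)))
    cat(sprintf("  %-28s diff = %8.3f, adj. P = %.4g %s\n",
                x$pairwise$pair[i], x$pairwise$diff[i], x$pairwise$p_adj[i],
                p_stars(x$pairwise$p_adj[i])))
  invisible(x)
}

#' Write a set of group comparisons as CSV + readable report
#'
#' @param comparisons named list of [two_group_test()] results.
#' @param csv_path,txt_path output paths (`NULL` to skip either).
#' @return the summary data frame, invisibly.
#' @export
write_comparisons <- function(comparisons, csv_path = NULL,
                              txt_path = NULL) {
  df <- do.call(rbind, lapply(names(comparisons), function(nm) {
    x <- comparisons[[nm]]
    data.frame(comparison = nm,
               group_a = x$labels[1], mean_sd_a = x$formatted[1],
               group_b = x$labels[2], mean_sd_b = x$formatted[2],
               t = x$statistic, df = x$df, p = x$p_value,
               stars = x$stars, welch = x$welch)
  }))
  if (!is.null(csv_path))
    utils::write.csv(df, csv_path, row.names = FALSE)
  if (!is.null(txt_path)) {
    con <- file(txt_path, "w")
    on.exit(close(con))
    for (nm in names(comparisons)) {
      x <- comparisons[[nm]]
      writeLines(c(nm, utils::capture.output(print(x)), ""), con)
    }
  }
  invisible(df)
}
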