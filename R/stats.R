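# Statistical battery: Shapiro-Wilk normality gating, two-way ANOVA
# with Tukey HSD post hoc for gait parameters, unpaired two-sample
# rank-sum tests for home-cage parameters, Kruskal-Wallis with Dunn's
# post hoc for syllable usage, and significance-matrix reporting.
# Tests are per-parameter at p < 0.05, unadjusted across parameters
# (Benjamini-Hochberg available behind a flag in the reporting layer).

#' Star annotation for a p-value
#'
#' `***` below 0.001, `**` below 0.01, `*` below 0.05, `NS` otherwise.
#'
#' @param p P-value(s).
#' @return Character vector of annotations.
#' @export
p_stars <- function(p) {
  ifelse(p < 0.001, "***",
         ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "NS")))
}

new_stat_result <- function(test, statistic, p, posthoc = NULL,
                            direction = NA_character_,
                            normality_p = NA_real_) {
  structure(list(test = test, statistic = statistic, p = p,
                 posthoc = posthoc,
                 direction = if (!is.na(p) && p < 0.05) direction
                             else NA_character_,
                 stars = p_stars(p), normality_p = normality_p),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat("<stat_result> ", x$test, ": statistic = ",
      signif(x$statistic, 4), ", p = ", signif(x$p, 4), " (", x$stars,
      if (!is.na(x$direction)) paste0(" ", x$direction), ")\n", sep = "")
  if (!is.null(x$posthoc)) {
    cat("  post hoc:\n")
    print(x$posthoc)
  }
  invisible(x)
}

#' Shapiro-Wilk normality gate
#'
#' @param x Numeric sample (n of at least 3, non-constant).
#' @param alpha Normality threshold (default 0.05).
#' @return List with `W`, `p` and `normal` (`p >= alpha`).
#' @export
shapiro_gate <- function(x, alpha = 0.05) {
  x <- x[!is.na(x)]
  if (length(x) < 3L)
    stop("Shapiro-Wilk needs at least 3 observations")
  if (stats::sd(x) == 0)
    stop("Shapiro-Wilk is undefined for a constant sample")
  sw <- stats::shapiro.test(x)
  list(W = unname(sw$statistic), p = sw$p.value,
       normal = sw$p.value >= alpha)
}

#' Two-way ANOVA for gait parameters
#'
#' Fits `value ~ age * genotype` and reports the age, genotype and
#' interaction effects. The Tukey HSD pairwise table is computed only
#' when the interaction is significant (p < 0.05); otherwise the main
#' effects stand alone. The direction annotation compares the second
#' genotype level against the first (the reference, conventionally WT).
#'
#' @param values Numeric response.
#' @param age,genotype Factors (coerced).
#' @return A `stat_result` whose `statistic`/`p` are the interaction F
#'   and p; `$effects` holds the full ANOVA table and `$posthoc` the
#'   Tukey table when gated open.
#' @export
gait_anova <- function(values, age, genotype) {
  d <- data.frame(value = values, age = factor(age),
                  genotype = factor(genotype))
  if (nlevels(d$age) < 2L || nlevels(d$genotype) < 2L)
    stop("two-way ANOVA needs at least 2 levels per factor")
  fit <- stats::aov(value ~ age * genotype, data = d)
  tab <- summary(fit)[[1]]
  rn <- trimws(rownames(tab))
  get <- function(term, col) {
    if (!col %in% colnames(tab)) return(NA_real_)
    v <- tab[rn == term, col]
    if (length(v) != 1L || is.nan(v)) NA_real_ else v
  }
  inter_p <- get("age:genotype", "Pr(>F)")
  inter_f <- get("age:genotype", "F value")
  posthoc <- NULL
  if (!is.na(inter_p) && inter_p < 0.05) {
    tk <- stats::TukeyHSD(fit, "age:genotype")[["age:genotype"]]
    posthoc <- data.frame(contrast = rownames(tk),
                          diff = tk[, "diff"],
                          p_adj = tk[, "p adj"],
                          row.names = NULL)
  }
  gref <- levels(d$genotype)
  dirn <- if (length(gref) == 2L) {
    delta <- mean(d$value[d$genotype == gref[2]]) -
      mean(d$value[d$genotype == gref[1]])
    if (delta > 0) "up" else "down"
  } else NA_character_
  out <- new_stat_result("two-way ANOVA (age x genotype)",
                         statistic = inter_f, p = inter_p,
                         posthoc = posthoc, direction = dirn)
  terms <- rn[rn != "Residuals"]
  # with zero residual df the ANOVA table carries no F/p columns
  fcol <- if ("F value" %in% colnames(tab))
    tab[match(terms, rn), "F value"] else rep(NA_real_, length(terms))
  pcol <- if ("Pr(>F)" %in% colnames(tab))
    tab[match(terms, rn), "Pr(>F)"] else rep(NA_real_, length(terms))
  out$effects <- data.frame(term = terms, F = fcol, p = pcol,
                            row.names = NULL)
  out
}

#' Unpaired two-sample rank-sum test
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test with mid-ranks for
#' ties. The exact null distribution is used when both groups have at
#' most `exact_max` observations and no ties are present; otherwise the
#' tie-corrected normal approximation (without continuity correction on
#' the exact path's scale).
#'
#' @param a,b Numeric samples.
#' @param exact_max Largest per-group n for the exact null (default
#'   10).
#' @return A `stat_result` (statistic = rank-sum W of the first
#'   sample; direction compares `a` against `b`).
#' @export
homecage_wilcoxon <- function(a, b, exact_max = 10L) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  ties <- any(duplicated(c(a, b)))
  exact <- length(a) <= exact_max && length(b) <= exact_max && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided", exact = exact,
                       correct = !exact)
  )
  dirn <- if (stats::median(a) > stats::median(b)) "up" else "down"
  out <- new_stat_result("Wilcoxon rank-sum", unname(wt$statistic),
                         wt$p.value, direction = dirn)
  out$exact <- exact
  out
}

#' Kruskal-Wallis with Dunn's post hoc test
#'
#' Kruskal-Wallis rank test across groups; when requested (default),
#' Dunn's two-sided pairwise z tests on the joint mid-ranks with a
#' tie-corrected variance, adjusted for multiple comparisons (Holm by
#' default).
#'
#' @param values Numeric response.
#' @param groups Group labels (coerced to factor).
#' @param p_adjust Adjustment method for the Dunn table (an
#'   [stats::p.adjust()] method; default `"holm"`).
#' @return A `stat_result` with the Kruskal-Wallis H statistic and p,
#'   and the Dunn pairwise table as `$posthoc`.
#' @export
syllable_kw_dunn <- function(values, groups, p_adjust = "holm") {
  g <- factor(groups)
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  kw <- stats::kruskal.test(values, g)
  out <- new_stat_result("Kruskal-Wallis", unname(kw$statistic),
                         kw$p.value)
  out$posthoc <- dunn_test(values, g, p_adjust)
  out
}

# Dunn's pairwise z statistics on joint mid-ranks with tie correction
dunn_test <- function(values, g, p_adjust = "holm") {
  r <- rank(values)
  N <- length(values)
  tie_tab <- table(values)
  tie_term <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  lev <- levels(g)
  pairs <- utils::combn(lev, 2)
  z <- p <- numeric(ncol(pairs))
  for (i in seq_len(ncol(pairs))) {
    ga <- g == pairs[1, i]; gb <- g == pairs[2, i]
    na <- sum(ga); nb <- sum(gb)
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / na + 1 / nb))
    z[i] <- (mean(r[ga]) - mean(r[gb])) / se
    p[i] <- 2 * stats::pnorm(-abs(z[i]))
  }
  data.frame(contrast = paste(pairs[1, ], pairs[2, ], sep = " - "),
             z = z, p = p,
             p_adj = stats::p.adjust(p, method = p_adjust))
}

#' Significance matrix reporting
#'
#' Renders per-parameter, per-contrast test results as an annotated
#' matrix of `NS` / `*^` / `**v` cells (stars by p-value, arrow `^`
#' for an increase and `v` for a decrease relative to the reference
#' group), in the style of a gait-analysis significance table.
#'
#' @param results Data frame with columns `parameter`, `contrast`, `p`
#'   and `direction` (`"up"`/`"down"`).
#' @param adjust Optional multiple-testing adjustment applied across
#'   all cells before annotation (an [stats::p.adjust()] method, e.g.
#'   `"BH"`); default `"none"`, mirroring per-parameter testing at
#'   p < 0.05.
#' @return Data frame, one row per parameter, one column per contrast.
#' @export
significance_matrix <- function(results, adjust = "none") {
  stopifnot(all(c("parameter", "contrast", "p", "direction") %in%
                  names(results)))
  p <- stats::p.adjust(results$p, method = adjust)
  cell <- ifelse(p >= 0.05, "NS",
                 paste0(p_stars(p),
                        ifelse(results$direction == "up", "^", "v")))
  params <- unique(results$parameter)
  contrasts <- unique(results$contrast)
  out <- data.frame(parameter = params, stringsAsFactors = FALSE)
  for (ct in contrasts) {
    v <- rep(NA_character_, length(params))
    sel <- results$contrast == ct
    v[match(results$parameter[sel], params)] <- cell[sel]
    out[[ct]] <- v
  }
  out
}

#' Write / read a significance matrix as TSV
#'
#' @param mat A [significance_matrix()] table.
#' @param path File path.
#' @return `read_significance_matrix` returns the parsed data frame.
#' @export
write_significance_matrix <- function(mat, path) {
  utils::write.table(mat, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_significance_matrix
#' @export
read_significance_matrix <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    check.names = FALSE, stringsAsFactors = FALSE)
}
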