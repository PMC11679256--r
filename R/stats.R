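#' Per-group descriptive statistics
#'
#' Mean and sample (n-1) standard deviation of every feature column, per
#' group.
#'
#' @param table Feature table (as from [assemble_feature_table()] or
#'   [generate_feature_cohort()]).
#' @param group_col Name of the group column.
#' @return Long data.frame: `feature`, `group`, `n`, `mean`, `sd`.
#' @export
describe_by_group <- function(table, group_col = "group") {
  feats <- setdiff(names(table)[vapply(table, is.numeric, logical(1))],
                   group_col)
  groups <- unique(table[[group_col]])
  if (any(table(table[[group_col]]) < 1)) stop("empty group")
  out <- expand.grid(feature = feats, group = groups,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$n <- NA_integer_; out$mean <- NA_real_; out$sd <- NA_real_
  for (i in seq_len(nrow(out))) {
    v <- table[table[[group_col]] == out$group[i], out$feature[i]]
    out$n[i] <- length(v); out$mean[i] <- mean(v); out$sd[i] <- stats::sd(v)
  }
  out
}

#' One-way fixed-effects ANOVA
#'
#' Classical equal-variance F test for a global difference in means across
#' groups.
#'
#' @param values Numeric vector.
#' @param groups Group labels, same length.
#' @return List with `F`, `p`, `df` (numerator, denominator).
#' @export
anova_oneway <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need >= 2 groups")
  if (any(table(groups) < 2)) stop("each group needs >= 2 values")
  if (all(tapply(values, groups, stats::var) == 0))
    stop("degenerate: zero within-group variance everywhere")
  ft <- stats::oneway.test(values ~ groups, var.equal = TRUE)
  list(F = unname(ft$statistic), p = unname(ft$p.value),
       df = unname(ft$parameter))
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom,
#' two-sided. The statistic is positive when `a` has the larger mean.
#' Degenerate inputs follow a fixed convention: both variances zero with
#' equal means gives `t = 0, p = 1`; both zero with different means gives an
#' infinite statistic and `p = 0` with a warning.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return List with `t`, `p`, `df`.
#' @export
welch_ttest <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("each sample needs >= 2 values")
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, p = 1, df = NA_real_))
    warning("zero variance in both samples with different means: p -> 0")
    return(list(t = sign(mean(a) - mean(b)) * Inf, p = 0, df = NA_real_))
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(tt$statistic), p = unname(tt$p.value),
       df = unname(tt$parameter))
}

#' Pearson chi-squared test of independence
#'
#' No continuity correction; `df = (r - 1)(c - 1)`.
#'
#' @param table Integer contingency matrix (e.g. sex by group).
#' @return List with `chisq`, `p`, `df`, `expected`.
#' @export
chi_squared_independence <- function(table) {
  table <- as.matrix(table)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero marginal in contingency table")
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  if (any(ct$expected <= 0)) stop("all expected counts must be > 0")
  list(chisq = unname(ct$statistic), p = unname(ct$p.value),
       df = unname(ct$parameter), expected = ct$expected)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values with monotonicity enforcement, returned in the
#' input order.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
fdr_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must be in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

group_pairs <- function(groups) {
  # canonical comparison order: HC vs PD, HC vs PR, PD vs PR
  ord <- c("CONTROL", "PARKINSON", "PRODROMAL")
  g <- c(intersect(ord, groups), setdiff(groups, ord))
  if (length(g) < 2) stop("need >= 2 groups")
  combn(g, 2, simplify = FALSE)
}

pair_label <- function(pair) {
  abbr <- c(CONTROL = "HC", PARKINSON = "PD", PRODROMAL = "PR")
  nm <- ifelse(pair %in% names(abbr), abbr[pair], pair)
  paste(nm, collapse = "v")
}

# ANOVA + pairwise Welch battery for a set of feature columns; BH-FDR is
# applied jointly across every p-value in the table (the category is the
# adjustment family).
comparison_table <- function(table, feats, group_col = "group",
                             alpha = 0.05) {
  groups <- unique(table[[group_col]])
  pairs <- group_pairs(groups)
  rows <- lapply(feats, function(f) {
    v <- table[[f]]; g <- table[[group_col]]
    an <- anova_oneway(v, g)
    row <- data.frame(feature = f, anova_F = an$F, anova_p = an$p)
    for (pr in pairs) {
      w <- welch_ttest(v[g == pr[1]], v[g == pr[2]])
      row[[paste0(pair_label(pr), "_t")]] <- w$t
      row[[paste0(pair_label(pr), "_p")]] <- w$p
    }
    row
  })
  out <- do.call(rbind, rows)
  pcols <- c("anova_p", paste0(vapply(pairs, pair_label, ""), "_p"))
  pmat <- as.matrix(out[, pcols])
  adj <- matrix(fdr_adjust(as.vector(pmat)), nrow(pmat), ncol(pmat))
  colnames(adj) <- paste0(pcols, "_adj")
  out <- cbind(out, adj)
  for (pc in pcols)
    out[[paste0(pc, "_sig")]] <- out[[paste0(pc, "_adj")]] <= alpha
  rownames(out) <- NULL
  out
}

#' Build the four category comparison tables
#'
#' Reproduces the statistical battery's table layout: one table per data
#' category (demographics and clinical scores, normalized volumes, Euclidean
#' distances, cosine distances), each row a feature with the global ANOVA and
#' the three pairwise Welch tests (HC vs PD, HC vs PR, PD vs PR), raw and
#' BH-FDR-adjusted p-values, and significance flags at `alpha`. The FDR
#' family is all p-values within one category table. Sex is tested once by
#' chi-squared across groups and attached to the demographics table. The
#' reference structure contributes its raw volume to the volumes table but
#' has no distance rows (it is the reference point of both metrics).
#' Pairwise tests are reported regardless of ANOVA significance.
#'
#' @param table Feature table with `group`, `Sex`, `Age`, optionally
#'   `UPDRS3`, and the geometry feature columns.
#' @param registry A [structure_registry()].
#' @param alpha Significance level for the flags (default 0.05).
#' @return List of data.frames: `demographics`, `volumes`, `euclidean`,
#'   `cosine`, plus `sex_test` (the chi-squared result).
#' @export
build_category_tables <- function(table, registry = structure_registry(),
                                  alpha = 0.05) {
  if (!all(c("Sex", "Age", "group") %in% names(table)))
    stop("missing demographics columns (Sex, Age, group)")
  others <- non_reference_structures(registry)
  ref <- attr(registry, "reference")
  demo_feats <- c("Age", intersect("UPDRS3", names(table)))
  demographics <- comparison_table(table, demo_feats, alpha = alpha)
  groups <- unique(table$group)
  ord <- intersect(c("CONTROL", "PARKINSON", "PRODROMAL"), groups)
  sex_tab <- t(vapply(ord, function(g)
    c(F = sum(table$Sex[table$group == g] == 1),
      M = sum(table$Sex[table$group == g] == 0)), numeric(2)))
  sex <- chi_squared_independence(t(sex_tab))
  vol_feats <- c(paste0(ref, "_vol"), paste0(others, "_normvol"))
  list(
    demographics = demographics,
    sex_test = sex,
    volumes = comparison_table(table, vol_feats, alpha = alpha),
    euclidean = comparison_table(table, paste0(others, "_euclid"),
                                 alpha = alpha),
    cosine = comparison_table(table, paste0(others, "_cosine"), alpha = alpha))
}
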