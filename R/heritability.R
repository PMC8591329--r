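#' @importFrom stats bartlett.test var.test pt pf qnorm
NULL

#' Bartlett test of length-variance homogeneity among tactics
#'
#' Tests whether the phenotypic variance of length at maturity differs
#' among tactics, plus all pairwise two-sided variance-ratio F tests.
#' Unequal variances matter because a single parent-offspring regression
#' only estimates heritability validly when parent- and offspring-class
#' variances are equal; otherwise the Falconer standard-deviation-ratio
#' correction applies (see [heritability_from_slope()]).
#'
#' @param groups either a pedigree (grouped by tactic, rows with missing
#'   length dropped) or a named list of numeric length vectors.
#' @return List of class `variance_comparison`: `bartlett_k2`,
#'   `bartlett_df`, `bartlett_p`, and `pairwise` (data frame with
#'   `tactic_a`, `tactic_b`, `F`, `df1`, `df2`, `p`).
#' @export
bartlett_lengths <- function(groups) {
  if (inherits(groups, "pedigree") || is.data.frame(groups)) {
    d <- as.data.frame(groups)
    d <- d[!is.na(d$length_mm), , drop = FALSE]
    groups <- split(d$length_mm, d$tactic)
  }
  if (length(groups) < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(lengths(groups) < 2))
    stop("every group needs n >= 2", call. = FALSE)
  if (any(vapply(groups, stats::var, 0) <= 0))
    stop("a group has zero variance", call. = FALSE)
  bt <- stats::bartlett.test(groups)
  nm <- names(groups)
  pairs <- utils::combn(seq_along(groups), 2)
  pw <- do.call(rbind, apply(pairs, 2, function(ij) {
    vt <- variance_ratio_test(groups[[ij[1]]], groups[[ij[2]]])
    data.frame(tactic_a = nm[ij[1]], tactic_b = nm[ij[2]],
               F = vt$F, df1 = vt$df1, df2 = vt$df2, p = vt$p,
               stringsAsFactors = FALSE)
  }))
  structure(list(bartlett_k2 = unname(bt$statistic),
                 bartlett_df = unname(bt$parameter),
                 bartlett_p = bt$p.value,
                 pairwise = pw),
            class = "variance_comparison")
}

#' Two-sided variance-ratio F test
#'
#' `F = var(a)/var(b)` on `(n_a - 1, n_b - 1)` df with a two-sided p value.
#' Swapping the arguments inverts F and swaps the dfs.
#'
#' @param a,b numeric vectors (each n >= 2, positive variance).
#' @return List with `F`, `df1`, `df2`, `p`.
#' @export
variance_ratio_test <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop("both samples need n >= 2", call. = FALSE)
  if (stats::var(a) <= 0 || stats::var(b) <= 0)
    stop("zero variance", call. = FALSE)
  vt <- stats::var.test(a, b)
  list(F = unname(vt$statistic), df1 = unname(vt$parameter[1]),
       df2 = unname(vt$parameter[2]), p = vt$p.value)
}

.parent_col <- function(parent_tactic) {
  if (parent_tactic == "female") "dam_id" else "sire_id"
}

#' Single parent-offspring regression for one tactic pair
#'
#' Regresses the per-parent mean length of same-tactic offspring on the
#' parent's length: for each parent of `parent_tactic` (dams when the
#' parent tactic is female, sires otherwise) with at least one offspring of
#' `offspring_tactic`, the offspring lengths are averaged (unweighted by
#' family size) and that mean is one regression point.  Every offspring
#' thus contributes to both its dam-side and its sire-side cell.
#'
#' @param p a pedigree with both generations.
#' @param parent_tactic,offspring_tactic tactics (see [TACTICS]).
#' @return List with `b_op` (slope), `se_slope`, `n_families`, and the
#'   per-family data frame `families` (`parent_id`, `parent_length`,
#'   `mean_offspring_length`, `n_offspring`).
#' @export
parent_offspring_regression <- function(p, parent_tactic, offspring_tactic) {
  stopifnot(inherits(p, "pedigree"),
            parent_tactic %in% TACTICS, offspring_tactic %in% TACTICS)
  pcol <- .parent_col(parent_tactic)
  par <- p[p$generation == "parent" & p$tactic == parent_tactic &
             !is.na(p$length_mm), , drop = FALSE]
  off <- p[p$generation == "offspring" & p$tactic == offspring_tactic &
             !is.na(p$length_mm) & !is.na(p[[pcol]]), , drop = FALSE]
  off <- off[off[[pcol]] %in% par$id, , drop = FALSE]
  if (!nrow(off))
    stop(sprintf("no %s offspring of %s parents", offspring_tactic,
                 parent_tactic), call. = FALSE)
  mo <- tapply(off$length_mm, off[[pcol]], mean)
  fams <- data.frame(parent_id = names(mo),
                     parent_length = par$length_mm[match(names(mo), par$id)],
                     mean_offspring_length = as.numeric(mo),
                     n_offspring = as.integer(table(off[[pcol]])[names(mo)]),
                     stringsAsFactors = FALSE)
  if (nrow(fams) < 3)
    stop(sprintf(
      "insufficient data for cell %s ~ %s: %d families (need >= 3)",
      offspring_tactic, parent_tactic, nrow(fams)), call. = FALSE)
  fit <- stats::lm(mean_offspring_length ~ parent_length, data = fams)
  list(b_op = unname(coef(fit)[2]),
       se_slope = sqrt(diag(vcov(fit)))[["parent_length"]],
       n_families = nrow(fams), families = fams)
}

#' Heritability from a single parent-offspring regression slope
#'
#' Under the additive model a single parent transmits half its breeding
#' value, so h2 = 2 b_op when parent- and offspring-class phenotypic
#' variances are equal.  When they are unequal, the Falconer correction
#' multiplies by the standard-deviation ratio: h2 = 2 b_op (sigma_p /
#' sigma_o).  The 95% CI half-width uses z = 1.96 on the same scale
#' (3.92 x se x correction), and the null slope corresponding to h2 = 1 is
#' 0.5 / (sigma_p / sigma_o) (0.5 when uncorrected).
#'
#' @param b_op regression slope from [parent_offspring_regression()].
#' @param se_slope its standard error.
#' @param sigma_p,sigma_o phenotypic SDs of length in the parent and
#'   offspring tactic classes (must be positive).
#' @param corrected apply the sigma_p/sigma_o correction (use when the
#'   variance-homogeneity test rejects for this tactic pair).
#' @return List with `h2`, `ci95` (half-width), `correction`,
#'   `null_slope` (slope under h2 = 1), plus the inputs.
#' @export
heritability_from_slope <- function(b_op, se_slope, sigma_p, sigma_o,
                                    corrected = FALSE) {
  if (!is.finite(sigma_p) || !is.finite(sigma_o) ||
      sigma_p <= 0 || sigma_o <= 0)
    stop("sigma_p and sigma_o must be positive", call. = FALSE)
  corr <- if (corrected) sigma_p / sigma_o else 1
  list(h2 = 2 * b_op * corr,
       ci95 = 2 * stats::qnorm(0.975) * se_slope * corr,
       correction = corr,
       null_slope = 0.5 / corr,
       b_op = b_op, se_slope = se_slope,
       sigma_p = sigma_p, sigma_o = sigma_o, corrected = corrected)
}

#' Test a parent-offspring regression slope against a null value
#'
#' Two tests are used on the same slope: a t test of slope = 0 (h2 = 0)
#' with `t = b_op / se` on `n - 2` df, and an F test of slope = null
#' (h2 = 1, where the null slope is 0.5 / (sigma_p / sigma_o) under the
#' variance correction, else 0.5) with `F = ((b_op - null)/se)^2` on
#' `(1, n - 2)` df.  `method = "auto"` picks the t test for a zero null
#' and the F test otherwise.
#'
#' @param b_op,se_slope slope and SE.
#' @param n_families number of regression points (must exceed 2).
#' @param null_value null slope.
#' @param method `"auto"`, `"t"`, or `"F"`.
#' @return List with `statistic`, `df` (length 1 for t, 2 for F), `p`,
#'   `method`, `null_value`.
#' @export
test_slope <- function(b_op, se_slope, n_families, null_value = 0,
                       method = c("auto", "t", "F")) {
  method <- match.arg(method)
  if (se_slope <= 0) stop("se_slope must be positive", call. = FALSE)
  if (n_families <= 2) stop("n_families must exceed 2", call. = FALSE)
  if (method == "auto") method <- if (null_value == 0) "t" else "F"
  df2 <- n_families - 2
  if (method == "t") {
    tstat <- (b_op - null_value) / se_slope
    list(statistic = tstat, df = df2,
         p = 2 * stats::pt(abs(tstat), df2, lower.tail = FALSE),
         method = "t", null_value = null_value)
  } else {
    Fstat <- ((b_op - null_value) / se_slope)^2
    list(statistic = Fstat, df = c(1, df2),
         p = stats::pf(Fstat, 1, df2, lower.tail = FALSE),
         method = "F", null_value = null_value)
  }
}

.tactic_sd <- function(p, tactic, generation) {
  x <- p$length_mm[p$generation == generation & p$tactic == tactic &
                     !is.na(p$length_mm)]
  x
}

#' 3x3 grid of intra- and intertactical heritabilities
#'
#' One [parent_offspring_regression()] per (parent tactic x offspring
#' tactic) cell.  For each cell, sigma_p is the sample SD of length of all
#' parent-generation individuals of the parent tactic and sigma_o that of
#' all offspring-generation individuals of the offspring tactic; the
#' Falconer correction is applied exactly when the two-sided variance-ratio
#' F test between those two groups rejects at `alpha_var`.  Cells with
#' insufficient data are reported as NA rows with the reason retained.
#'
#' @param p a pedigree with both generations.
#' @param alpha_var significance level of the variance-homogeneity trigger
#'   (default 0.05).
#' @return Data frame with one row per cell: `parent_tactic`,
#'   `offspring_tactic`, `n_families`, `b_op`, `se_slope`, `t_zero`,
#'   `p_zero`, `null_slope`, `F_one`, `p_one`, `sigma_p`, `sigma_o`,
#'   `corrected`, `correction`, `h2`, `ci95`, `reason`.
#' @export
heritability_grid <- function(p, alpha_var = 0.05) {
  stopifnot(inherits(p, "pedigree"))
  rows <- list()
  for (pt in TACTICS) for (ot in TACTICS) {
    lp <- .tactic_sd(p, pt, "parent")
    lo <- .tactic_sd(p, ot, "offspring")
    row <- tryCatch({
      reg <- parent_offspring_regression(p, pt, ot)
      if (length(lp) < 2 || length(lo) < 2)
        stop("too few individuals to estimate class SDs")
      vt <- variance_ratio_test(lp, lo)
      corrected <- vt$p < alpha_var
      h <- heritability_from_slope(reg$b_op, reg$se_slope,
                                   sigma_p = stats::sd(lp),
                                   sigma_o = stats::sd(lo),
                                   corrected = corrected)
      tz <- test_slope(reg$b_op, reg$se_slope, reg$n_families, 0)
      fo <- test_slope(reg$b_op, reg$se_slope, reg$n_families,
                       h$null_slope, method = "F")
      data.frame(parent_tactic = pt, offspring_tactic = ot,
                 n_families = reg$n_families,
                 b_op = reg$b_op, se_slope = reg$se_slope,
                 t_zero = tz$statistic, p_zero = tz$p,
                 null_slope = h$null_slope,
                 F_one = fo$statistic, p_one = fo$p,
                 sigma_p = h$sigma_p, sigma_o = h$sigma_o,
                 corrected = corrected, correction = h$correction,
                 h2 = h$h2, ci95 = h$ci95, reason = "",
                 stringsAsFactors = FALSE)
    }, error = function(e)
      data.frame(parent_tactic = pt, offspring_tactic = ot,
                 n_families = NA_integer_, b_op = NA_real_,
                 se_slope = NA_real_, t_zero = NA_real_, p_zero = NA_real_,
                 null_slope = NA_real_, F_one = NA_real_, p_one = NA_real_,
                 sigma_p = NA_real_, sigma_o = NA_real_, corrected = NA,
                 correction = NA_real_, h2 = NA_real_, ci95 = NA_real_,
                 reason = conditionMessage(e), stringsAsFactors = FALSE))
    rows[[length(rows) + 1]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Offspring-length interaction model
#'
#' OLS fit of individual offspring length on dam length, sire length,
#' offspring tactic, and the two parent-length x offspring-tactic
#' interactions:
#' `length_o ~ dam_length + sire_length + tactic + dam_length:tactic +
#' sire_length:tactic`.
#' A significant interaction indicates that parent-offspring resemblance —
#' and hence heritability — differs by offspring tactic, motivating the
#' tactic-by-tactic grid.  Per-term F tests use sequential (type I) sums of
#' squares in the order the terms are written above.
#'
#' @param p a pedigree; only offspring with both parents known and lengths
#'   on offspring and both parents enter the fit.
#' @return List of class `offspring_interaction_fit`: `coefficients`,
#'   `anova` (sequential F table), `n`, `residual_df`, and the `lm`
#'   object as `fit`.
#' @export
offspring_interaction_model <- function(p) {
  stopifnot(inherits(p, "pedigree"))
  len <- setNames(p$length_mm, p$id)
  off <- p[p$generation == "offspring" & !is.na(p$dam_id) &
             !is.na(p$sire_id) & !is.na(p$length_mm), , drop = FALSE]
  d <- data.frame(length_o = off$length_mm,
                  dam_length = unname(len[off$dam_id]),
                  sire_length = unname(len[off$sire_id]),
                  tactic = factor(off$tactic, levels = TACTICS),
                  stringsAsFactors = FALSE)
  d <- d[stats::complete.cases(d), , drop = FALSE]
  d$tactic <- droplevels(d$tactic)
  if (nlevels(d$tactic) < 2)
    stop("offspring interaction model needs >= 2 offspring tactics",
         call. = FALSE)
  fit <- stats::lm(length_o ~ dam_length + sire_length + tactic +
                     dam_length:tactic + sire_length:tactic, data = d)
  if (any(is.na(coef(fit))))
    stop("rank-deficient offspring interaction design", call. = FALSE)
  structure(list(coefficients = coef(fit),
                 anova = stats::anova(fit),
                 n = nrow(d),
                 residual_df = fit$df.residual,
                 fit = fit),
            class = "offspring_interaction_fit")
}
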