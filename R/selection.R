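#' @importFrom stats lm glm poisson coef vcov logLik pchisq anova as.formula
NULL

#' Standardize length and compute relative fitness within a subset
#'
#' Length is standardized to the subset mean in units of (sample) standard
#' deviations; relative fitness is each individual's reproductive success
#' divided by the subset mean reproductive success.  Means and SDs are
#' always computed on the subset actually passed in — for pooled analyses,
#' pass the pooled subset (never average per-subset values).
#'
#' @param p a pedigree (or data frame with `id`, `tactic`, `year`,
#'   `length_mm`, `rs`), typically a [subset_pedigree()] result.
#' @return Data frame with `id`, `tactic`, `year`, `rs`, `std_length`,
#'   `rel_fitness`.  Within the subset, `mean(std_length) == 0`,
#'   `sd(std_length) == 1`, and `mean(rel_fitness) == 1` to floating
#'   tolerance.
#' @export
standardize <- function(p) {
  d <- as.data.frame(p)
  d <- d[!is.na(d$length_mm) & !is.na(d$rs), , drop = FALSE]
  if (!nrow(d)) stop("cannot standardize an empty subset", call. = FALSE)
  s <- stats::sd(d$length_mm)
  if (!is.finite(s) || s <= 0)
    stop("degenerate subset: length SD is zero (all lengths equal)",
         call. = FALSE)
  mrs <- mean(d$rs)
  if (mrs <= 0)
    stop("relative fitness undefined: mean reproductive success is zero",
         call. = FALSE)
  data.frame(id = d$id, tactic = d$tactic, year = d$year, rs = d$rs,
             std_length = (d$length_mm - mean(d$length_mm)) / s,
             rel_fitness = d$rs / mrs, stringsAsFactors = FALSE)
}

#' Linear (directional) selection gradient
#'
#' OLS regression of relative fitness on standardized length; the slope is
#' the linear selection gradient beta, reported with its standard error.
#'
#' @param records output of [standardize()].
#' @return List of class `selection_gradients` with `beta`, `se_beta`, `n`.
#' @export
linear_gradient <- function(records) {
  x <- records$std_length
  w <- records$rel_fitness
  if (length(x) < 3) stop("need at least 3 records", call. = FALSE)
  if (stats::sd(x) == 0) stop("degenerate predictor", call. = FALSE)
  fit <- stats::lm(w ~ x)
  structure(list(beta = unname(coef(fit)[2]),
                 se_beta = sqrt(diag(vcov(fit)))[["x"]],
                 n = length(x)),
            class = "selection_gradients")
}

#' Quadratic (stabilizing/disruptive) selection gradient
#'
#' OLS regression of relative fitness on standardized length and its
#' square, with the linear term retained.  Following the standard doubling
#' convention, gamma is twice the quadratic regression coefficient and its
#' SE is twice that coefficient's SE; the jointly estimated linear slope is
#' also returned.
#'
#' @param records output of [standardize()].
#' @return List of class `selection_gradients` with `gamma`, `se_gamma`,
#'   `beta_joint`, `se_beta_joint`, `n`.
#' @export
quadratic_gradient <- function(records) {
  x <- records$std_length
  w <- records$rel_fitness
  if (length(x) < 4) stop("need at least 4 records", call. = FALSE)
  X <- cbind(1, x, x^2)
  if (qr(X)$rank < 3) stop("rank-deficient quadratic design", call. = FALSE)
  fit <- stats::lm(w ~ x + I(x^2))
  se <- sqrt(diag(vcov(fit)))
  structure(list(gamma = 2 * unname(coef(fit)[3]),
                 se_gamma = 2 * unname(se[3]),
                 beta_joint = unname(coef(fit)[2]),
                 se_beta_joint = unname(se[2]),
                 n = length(x)),
            class = "selection_gradients")
}

.check_separation <- function(fit) {
  if (any(!is.finite(coef(fit))) || any(abs(coef(fit)) > 30))
    stop("Poisson GLM appears separated (unbounded likelihood)",
         call. = FALSE)
}

#' Fit a Poisson log-link GLM of reproductive success
#'
#' Maximum-likelihood fit of absolute reproductive success (counts) on the
#' supplied model terms, Poisson family, log link.  Convergence is flagged,
#' never silently ignored; a separated fit (coefficients diverging) is an
#' error.
#'
#' @param records data frame holding `rs` plus the variables named in
#'   `terms` (e.g. from [standardize()]).
#' @param terms character vector of right-hand-side model terms, e.g.
#'   `c("std_length", "I(std_length^2)", "tactic", "year")`; `"1"` fits an
#'   intercept-only model.
#' @param maxit iteration cap (default 100).
#' @return List of class `poisson_fit`: `coefficients`, `deviance`,
#'   `logLik`, `converged`, `df_model` (number of estimated coefficients),
#'   `n`, `terms`, and the underlying `glm` object as `fit`.
#' @export
fit_poisson_glm <- function(records, terms = "std_length", maxit = 100) {
  d <- as.data.frame(records)
  if (any(d$rs < 0) || any(d$rs != round(d$rs)))
    stop("rs must be nonnegative integers", call. = FALSE)
  if ("tactic" %in% names(d)) d$tactic <- factor(d$tactic)
  if ("year" %in% names(d)) d$year <- factor(d$year)
  rhs <- if (!length(terms)) "1" else paste(terms, collapse = " + ")
  f <- stats::as.formula(paste("rs ~", rhs))
  fit <- stats::glm(f, family = stats::poisson(link = "log"), data = d,
                    control = list(epsilon = 1e-10, maxit = maxit))
  .check_separation(fit)
  structure(list(coefficients = coef(fit),
                 deviance = fit$deviance,
                 logLik = as.numeric(logLik(fit)),
                 converged = isTRUE(fit$converged),
                 df_model = length(coef(fit)),
                 n = nrow(d), terms = terms, fit = fit),
            class = "poisson_fit")
}

#' Analysis-of-deviance test between nested Poisson fits
#'
#' Likelihood-ratio (analysis of deviance) chi-square test: the deviance
#' difference between the reduced and full model referred to a chi-square
#' with df equal to the difference in coefficient count.
#'
#' @param full,reduced [fit_poisson_glm()] results on the same records;
#'   `reduced`'s terms must be a subset of `full`'s.
#' @param label optional term label for reporting.
#' @return List of class `deviance_test`: `term`, `chi_sq`, `df`, `p`, `n`.
#' @export
deviance_term_test <- function(full, reduced, label = NULL) {
  stopifnot(inherits(full, "poisson_fit"), inherits(reduced, "poisson_fit"))
  if (full$n != reduced$n)
    stop("models were fitted to different records", call. = FALSE)
  if (!all(reduced$terms %in% c("1", full$terms)))
    stop("models are not nested: reduced terms ",
         paste(setdiff(reduced$terms, full$terms), collapse = ", "),
         " absent from the full model", call. = FALSE)
  df <- full$df_model - reduced$df_model
  if (df < 0) stop("models are not nested (reduced has more parameters)",
                   call. = FALSE)
  chi <- max(0, reduced$deviance - full$deviance)
  p <- if (df == 0) 1 else stats::pchisq(chi, df, lower.tail = FALSE)
  if (is.null(label))
    label <- paste(setdiff(full$terms, reduced$terms), collapse = " + ")
  structure(list(term = label, chi_sq = chi, df = df, p = p, n = full$n),
            class = "deviance_test")
}

.SCAN_TERMS <- list(
  x   = "std_length",
  x2  = "I(std_length^2)",
  xT  = "std_length:tactic",
  x2T = "I(std_length^2):tactic",
  xY  = "std_length:year",
  x2Y = "I(std_length^2):year",
  TY  = "tactic:year",
  xTY = "std_length:tactic:year",
  x2TY = "I(std_length^2):tactic:year")

#' Backward interaction scan for year/tactic heterogeneity of selection
#'
#' Fits the full Poisson fitness model
#' `rs ~ x + x^2 + tactic + year + all length interactions + tactic:year`
#' (x = length standardized to the pooled mean/SD) and runs the documented
#' backward testing sequence:
#' \enumerate{
#'   \item both three-way interactions tested against the full model;
#'   \item the quadratic three-way term is dropped and the linear
#'     three-way term retested against that reduced model;
#'   \item both three-way terms dropped; each two-way interaction
#'     involving length (`x:tactic`, `x^2:tactic`, `x:year`, `x^2:year`)
#'     tested by a drop-one analysis of deviance against the no-three-way
#'     model.
#' }
#' The output rows appear in exactly that order.
#'
#' @param p a pedigree with at least two years and two tactics among rows
#'   with complete length/rs.
#' @return Data frame with `step`, `term`, `chi_sq`, `df`, `p`, `n`.
#' @export
interaction_scan <- function(p) {
  recs <- standardize(p)
  if (length(unique(recs$tactic)) < 2)
    stop("interaction scan needs >= 2 tactics; found only ",
         paste(unique(recs$tactic), collapse = ", "), call. = FALSE)
  if (length(unique(recs$year)) < 2)
    stop("interaction scan needs >= 2 years; found only ",
         paste(unique(recs$year), collapse = ", "), call. = FALSE)
  tm <- .SCAN_TERMS
  base <- c(tm$x, tm$x2, "tactic", "year", tm$xT, tm$x2T, tm$xY, tm$x2Y,
            tm$TY)
  full <- fit_poisson_glm(recs, c(base, tm$xTY, tm$x2TY))
  m_no_x2TY <- fit_poisson_glm(recs, c(base, tm$xTY))
  m_no_xTY <- fit_poisson_glm(recs, c(base, tm$x2TY))
  m_no_3way <- fit_poisson_glm(recs, base)

  tests <- list(
    c(step = "three-way vs full",
      list(deviance_term_test(full, m_no_x2TY, "x2:tactic:year"))),
    c(step = "three-way vs full",
      list(deviance_term_test(full, m_no_xTY, "x:tactic:year"))),
    c(step = "after dropping x2:tactic:year",
      list(deviance_term_test(m_no_x2TY, m_no_3way, "x:tactic:year"))))

  two_way <- c(xT = tm$xT, x2T = tm$x2T, xY = tm$xY, x2Y = tm$x2Y)
  lab <- c(xT = "x:tactic", x2T = "x2:tactic", xY = "x:year",
           x2Y = "x2:year")
  for (k in names(two_way)) {
    red <- fit_poisson_glm(recs, setdiff(base, two_way[[k]]))
    tests <- c(tests, list(c(step = "two-way drop-one",
                             list(deviance_term_test(m_no_3way, red,
                                                     lab[[k]])))))
  }
  do.call(rbind, lapply(tests, function(t) {
    dt <- t[[2]]
    data.frame(step = t$step, term = dt$term, chi_sq = dt$chi_sq,
               df = dt$df, p = dt$p, n = dt$n, stringsAsFactors = FALSE)
  }))
}

.na_selection_row <- function(year, tactic, n, reason) {
  data.frame(year = year, tactic = tactic, n = n,
             beta = NA_real_, se_beta = NA_real_, chisq_beta = NA_real_,
             df_beta = NA_integer_, p_beta = NA_real_,
             gamma = NA_real_, se_gamma = NA_real_,
             chisq_gamma = NA_real_, df_gamma = NA_integer_,
             p_gamma = NA_real_, beta_joint = NA_real_,
             se_beta_joint = NA_real_, reason = reason,
             stringsAsFactors = FALSE)
}

#' Selection-gradient table across year and tactic subsets
#'
#' For every subset in (pooled + each year) x (pooled + each tactic),
#' standardizes on that subset, estimates the linear gradient (beta, from
#' the linear-only OLS model), the quadratic gradient (gamma, doubled
#' coefficient from the joint model, with the jointly estimated linear
#' slope reported as `beta_joint`), and tests each term by Poisson
#' analysis of deviance (linear: `rs ~ x` vs intercept; quadratic:
#' `rs ~ x + x^2` vs `rs ~ x`).  Subsets failing the preconditions
#' (too few records, degenerate length SD, zero mean rs) become NA rows
#' with the reason logged in the `reason` column.
#'
#' @param p a pedigree.
#' @param min_n minimum subset size to attempt estimation (default 5).
#' @return Data frame, one row per subset; `year`/`tactic` equal
#'   `"pooled"` for the pooled margins.
#' @export
selection_table <- function(p, min_n = 5) {
  d <- as.data.frame(p)
  d <- d[!is.na(d$length_mm) & !is.na(d$rs), , drop = FALSE]
  years <- c("pooled", as.character(sort(unique(d$year))))
  tactics <- c("pooled", TACTICS[TACTICS %in% unique(d$tactic)])
  rows <- list()
  for (yr in years) for (tc in tactics) {
    sub <- d
    if (yr != "pooled") sub <- sub[sub$year == as.integer(yr), , drop = FALSE]
    if (tc != "pooled") sub <- sub[sub$tactic == tc, , drop = FALSE]
    n <- nrow(sub)
    row <- tryCatch({
      if (n < min_n) stop(sprintf("n = %d below minimum %d", n, min_n))
      recs <- standardize(sub)
      lin <- linear_gradient(recs)
      quad <- quadratic_gradient(recs)
      m0 <- fit_poisson_glm(recs, "1")
      m1 <- fit_poisson_glm(recs, "std_length")
      m2 <- fit_poisson_glm(recs, c("std_length", "I(std_length^2)"))
      t_lin <- deviance_term_test(m1, m0, "std_length")
      t_quad <- deviance_term_test(m2, m1, "std_length^2")
      data.frame(year = yr, tactic = tc, n = n,
                 beta = lin$beta, se_beta = lin$se_beta,
                 chisq_beta = t_lin$chi_sq, df_beta = t_lin$df,
                 p_beta = t_lin$p,
                 gamma = quad$gamma, se_gamma = quad$se_gamma,
                 chisq_gamma = t_quad$chi_sq, df_gamma = t_quad$df,
                 p_gamma = t_quad$p,
                 beta_joint = quad$beta_joint,
                 se_beta_joint = quad$se_beta_joint,
                 reason = "", stringsAsFactors = FALSE)
    }, error = function(e) .na_selection_row(yr, tc, n, conditionMessage(e)))
    rows[[length(rows) + 1]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
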