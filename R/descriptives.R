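#' @importFrom stats aov TukeyHSD
NULL

#' One-way ANOVA of length at maturity among tactics, with Tukey HSD
#'
#' Fixed-effects one-way ANOVA of length on tactic followed by Tukey's
#' honestly-significant-difference test on all tactic pairs
#' (Tukey-Kramer for unbalanced group sizes, as implemented by
#' [stats::TukeyHSD()]).
#'
#' @param p a pedigree (rows with missing length are dropped).
#' @return List of class `anova_result`: `F`, `df_between`, `df_within`,
#'   `p`, `means` (data frame: tactic, n, mean, se), `tukey` (data frame:
#'   pair, diff, p_adj).
#' @export
length_anova <- function(p) {
  d <- as.data.frame(p)
  d <- d[!is.na(d$length_mm), , drop = FALSE]
  d$tactic <- factor(d$tactic)
  if (nlevels(d$tactic) < 2)
    stop("need >= 2 tactics", call. = FALSE)
  if (any(table(d$tactic) < 2))
    stop("every tactic needs n >= 2", call. = FALSE)
  fit <- stats::aov(length_mm ~ tactic, data = d)
  tab <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$tactic
  means <- do.call(rbind, lapply(split(d$length_mm, d$tactic), function(x)
    data.frame(n = length(x), mean = mean(x),
               se = stats::sd(x) / sqrt(length(x)))))
  means <- cbind(tactic = rownames(means), means)
  rownames(means) <- NULL
  structure(list(F = tab[1, "F value"],
                 df_between = tab[1, "Df"],
                 df_within = tab[2, "Df"],
                 p = tab[1, "Pr(>F)"],
                 means = means,
                 tukey = data.frame(pair = rownames(tk),
                                    diff = tk[, "diff"],
                                    p_adj = tk[, "p adj"],
                                    row.names = NULL)),
            class = "anova_result")
}

#' Count GLM of reproductive success on tactic
#'
#' Maximum-likelihood fit of reproductive success (offspring surviving to
#' maturity) on tactic with a log link, under either a negative-binomial
#' family (dispersion parameter estimated by ML, the default — fitness
#' counts are typically overdispersed) or a Poisson family.  Reports the
#' likelihood-ratio chi-square test of the tactic term against the
#' intercept-only model of the same family.
#'
#' @param p a pedigree (rows with missing rs are dropped).
#' @param family `"negative_binomial"` or `"poisson"`.
#' @return List of class `count_glm_result`: `family`, `theta` (NB size
#'   parameter, `NA` for Poisson), `chi_sq`, `df`, `p`, `logLik`,
#'   `logLik_null`, `n`, `means` (mean rs per tactic), `converged`.
#' @export
rs_count_glm <- function(p, family = c("negative_binomial", "poisson")) {
  family <- match.arg(family)
  d <- as.data.frame(p)
  d <- d[!is.na(d$rs), , drop = FALSE]
  if (any(d$rs < 0 | d$rs != round(d$rs)))
    stop("rs must be nonnegative integers", call. = FALSE)
  d$tactic <- factor(d$tactic)
  if (nlevels(d$tactic) < 2) stop("need >= 2 tactics", call. = FALSE)
  if (family == "poisson") {
    full <- stats::glm(rs ~ tactic, family = stats::poisson(), data = d)
    null <- stats::glm(rs ~ 1, family = stats::poisson(), data = d)
    theta <- NA_real_
    converged <- full$converged && null$converged
  } else {
    full <- MASS::glm.nb(rs ~ tactic, data = d)
    null <- MASS::glm.nb(rs ~ 1, data = d)
    theta <- full$theta
    converged <- isTRUE(full$converged) && isTRUE(null$converged)
  }
  ll_full <- as.numeric(stats::logLik(full))
  ll_null <- as.numeric(stats::logLik(null))
  chi <- max(0, 2 * (ll_full - ll_null))
  df <- nlevels(d$tactic) - 1
  structure(list(family = family, theta = theta, chi_sq = chi, df = df,
                 p = stats::pchisq(chi, df, lower.tail = FALSE),
                 logLik = ll_full, logLik_null = ll_null, n = nrow(d),
                 means = tapply(d$rs, d$tactic, mean),
                 converged = converged),
            class = "count_glm_result")
}

#' Per-tactic descriptive summary
#'
#' Ranges, means and standard errors of length and reproductive success for
#' each tactic, the ANOVA/Tukey comparison of length, and the
#' negative-binomial test of reproductive-success differences.
#'
#' @param p a pedigree.
#' @return List with `table` (per-tactic summary data frame),
#'   `length_anova` ([length_anova()] result) and `rs_glm`
#'   ([rs_count_glm()] result).
#' @export
tactic_descriptives <- function(p) {
  d <- as.data.frame(p)
  tabs <- lapply(split(d, d$tactic), function(g) {
    len <- g$length_mm[!is.na(g$length_mm)]
    rs <- g$rs[!is.na(g$rs)]
    data.frame(tactic = g$tactic[1], n = nrow(g),
               length_min = min(len), length_max = max(len),
               length_mean = mean(len),
               length_se = stats::sd(len) / sqrt(length(len)),
               rs_min = min(rs), rs_max = max(rs), rs_mean = mean(rs),
               rs_se = stats::sd(rs) / sqrt(length(rs)),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, tabs)
  rownames(tab) <- NULL
  list(table = tab, length_anova = length_anova(p),
       rs_glm = rs_count_glm(p))
}
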