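test_that("standardization yields unit-scale length and mean relative fitness 1", {
  r <- records_from(c(700, 730, 760), c(1L, 2L, 3L))
  expect_equal(r$std_length, c(-1, 0, 1)) # SD = 30, symmetric
  expect_equal(r$rel_fitness, c(0.5, 1.0, 1.5))
  # invariants on arbitrary subsets
  set.seed(41)
  for (i in 1:20) {
    n <- sample(5:80, 1)
    r <- records_from(rnorm(n, 700, 50), rpois(n, 2) + 1L)
    expect_equal(mean(r$std_length), 0, tolerance = 1e-10)
    expect_equal(sd(r$std_length), 1, tolerance = 1e-10)
    expect_equal(mean(r$rel_fitness), 1, tolerance = 1e-10)
  }
  expect_error(records_from(c(700, 700, 700), c(1L, 2L, 3L)), "SD")
  expect_error(records_from(c(700, 720, 740), c(0L, 0L, 0L)),
               "mean reproductive success")
})

test_that("standardize matches an explicit-sums recomputation", {
  p <- quick_sim(3)
  sub <- subset_pedigree(p, years = 2005, tactics = "female")
  r <- standardize(sub)
  len <- sub$length_mm
  s <- sqrt(sum((len - sum(len) / length(len))^2) / (length(len) - 1))
  expect_equal(r$std_length, (len - mean(len)) / s, tolerance = 1e-12)
  expect_equal(r$rel_fitness, sub$rs / (sum(sub$rs) / length(sub$rs)),
               tolerance = 1e-12)
})

test_that("linear gradient equals the OLS slope, with exact special cases", {
  x <- c(-1.2, -0.4, 0.1, 0.6, 0.9)
  flat <- data.frame(std_length = x, rel_fitness = rep(1, 5))
  expect_equal(linear_gradient(flat)$beta, 0, tolerance = 1e-12)
  exact <- data.frame(std_length = x, rel_fitness = 1 + 0.25 * x)
  lg <- linear_gradient(exact)
  expect_equal(lg$beta, 0.25, tolerance = 1e-10)
  expect_equal(lg$se_beta, 0, tolerance = 1e-10)
  # oracle match on a simulated subset
  r <- standardize(subset_pedigree(quick_sim(11), tactics = "hooknose"))
  o <- ols_oracle(cbind(1, r$std_length), r$rel_fitness)
  lg <- linear_gradient(r)
  expect_equal(lg$beta, o$coef[2], tolerance = 1e-10)
  expect_equal(lg$se_beta, o$se[2], tolerance = 1e-10)
  expect_error(linear_gradient(flat[1:2, ]), "3")
  expect_error(linear_gradient(data.frame(std_length = rep(0, 5),
                                          rel_fitness = 1:5)),
               "degenerate")
})

test_that("quadratic gradient doubles the quadratic OLS coefficient", {
  x <- c(-1.5, -0.7, 0, 0.4, 1.1, 1.7)
  pure <- data.frame(std_length = x, rel_fitness = 1 + 0.1 * x^2)
  expect_equal(quadratic_gradient(pure)$gamma, 0.2, tolerance = 1e-10)
  flat <- data.frame(std_length = x, rel_fitness = rep(1, 6))
  expect_equal(quadratic_gradient(flat)$gamma, 0, tolerance = 1e-12)
  # joint model matches the 3-column normal-equations oracle
  r <- standardize(subset_pedigree(quick_sim(5), tactics = "female"))
  o <- ols_oracle(cbind(1, r$std_length, r$std_length^2), r$rel_fitness)
  qg <- quadratic_gradient(r)
  expect_equal(qg$gamma, 2 * o$coef[3], tolerance = 1e-10)
  expect_equal(qg$se_gamma, 2 * o$se[3], tolerance = 1e-10)
  expect_equal(qg$beta_joint, o$coef[2], tolerance = 1e-10)
  expect_error(quadratic_gradient(
    data.frame(std_length = c(-1, -1, 1, 1), rel_fitness = 1:4)),
    "rank")
})

test_that("Poisson GLM matches direct likelihood maximization", {
  r <- records_from(c(700, 720, 740, 760), c(2L, 1L, 3L, 4L))
  m0 <- fit_poisson_glm(r, "1")
  expect_equal(unname(m0$coefficients), log(mean(r$rs)), tolerance = 1e-8)
  set.seed(7)
  x <- rnorm(50)
  d <- data.frame(std_length = x, rs = rpois(50, exp(0.5 + 0.3 * x)))
  m1 <- fit_poisson_glm(d, "std_length")
  o <- poisson_ml_oracle(cbind(1, x), d$rs)
  expect_equal(unname(m1$coefficients), unname(o$coef), tolerance = 1e-6)
  expect_equal(m1$logLik, o$logLik, tolerance = 1e-6)
  expect_true(m1$converged)
  # adding a term never decreases log-likelihood
  m2 <- fit_poisson_glm(d, c("std_length", "I(std_length^2)"))
  expect_gte(m2$logLik, m1$logLik - 1e-10)
  expect_gte(m1$logLik, fit_poisson_glm(d, "1")$logLik - 1e-10)
  expect_error(fit_poisson_glm(data.frame(rs = c(-1L, 2L))), "nonnegative")
})

test_that("analysis of deviance compares nested fits correctly", {
  set.seed(8)
  x <- rnorm(80)
  d <- data.frame(std_length = x, rs = rpois(80, exp(0.4 + 0.2 * x)))
  m1 <- fit_poisson_glm(d, "std_length")
  same <- deviance_term_test(m1, m1)
  expect_equal(same$chi_sq, 0)
  expect_equal(same$p, 1)
  m0 <- fit_poisson_glm(d, "1")
  dt <- deviance_term_test(m1, m0)
  expect_equal(dt$chi_sq, m0$deviance - m1$deviance, tolerance = 1e-10)
  expect_equal(dt$chi_sq, 2 * (m1$logLik - m0$logLik), tolerance = 1e-8)
  expect_equal(dt$df, 1)
  expect_equal(dt$p, pchisq(dt$chi_sq, 1, lower.tail = FALSE))
  m2 <- fit_poisson_glm(d, "I(std_length^2)")
  expect_error(deviance_term_test(m1, m2), "not nested")
})

test_that("deviance tests are invariant to categorical reference coding", {
  p <- quick_sim(13)
  r <- standardize(p)
  chi_for <- function(recs) {
    full <- fit_poisson_glm(recs, c("std_length", "tactic",
                                    "std_length:tactic"))
    red <- fit_poisson_glm(recs, c("std_length", "tactic"))
    deviance_term_test(full, red)$chi_sq
  }
  r2 <- r
  r2$tactic <- factor(r2$tactic, levels = c("jack", "female", "hooknose"))
  expect_equal(chi_for(r), chi_for(r2), tolerance = 1e-8)
})

test_that("interaction scan follows the documented backward sequence", {
  p <- quick_sim(21)
  scan <- interaction_scan(p)
  expect_equal(scan$term,
               c("x2:tactic:year", "x:tactic:year", "x:tactic:year",
                 "x:tactic", "x2:tactic", "x:year", "x2:year"))
  expect_equal(scan$step[1:3],
               c("three-way vs full", "three-way vs full",
                 "after dropping x2:tactic:year"))
  expect_true(all(scan$chi_sq >= 0))
  expect_true(all(scan$p >= 0 & scan$p <= 1))
  expect_true(all(scan$n == nrow(standardize(p))))
  # degenerate factors are named in the error
  one_year <- subset_pedigree(p, years = 2005)
  expect_error(interaction_scan(one_year), "years")
  one_tactic <- subset_pedigree(p, tactics = "female")
  expect_error(interaction_scan(one_tactic), "tactics")
})

test_that("selection table covers pooled and per-subset rows, NA for empty", {
  p <- quick_sim(2)
  tab <- selection_table(p)
  years <- sort(unique(p$year))
  expect_equal(nrow(tab), (1 + length(years)) * 4)
  pooled <- tab[tab$year == "pooled" & tab$tactic == "pooled", ]
  expect_equal(pooled$n, nrow(p))
  # pooled row equals running the gradient ops on the pooled subset
  r <- standardize(p)
  expect_equal(pooled$beta, linear_gradient(r)$beta, tolerance = 1e-12)
  expect_equal(pooled$gamma, quadratic_gradient(r)$gamma, tolerance = 1e-12)
  # a tactic-year cell with no individuals becomes an NA row with a reason
  d <- as.data.frame(p)
  d <- d[!(d$tactic == "jack" & d$generation == "offspring" &
             d$year != 2004), ]
  tab2 <- selection_table(as_pedigree(d))
  gap <- tab2[tab2$year == "2005" & tab2$tactic == "jack", ]
  expect_true(is.na(gap$beta))
  expect_match(gap$reason, "below minimum")
})
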