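test_that("Bartlett test matches the textbook formula and edge cases", {
  equalvar <- list(a = c(1, 2, 3), b = c(11, 12, 13), c = c(21, 22, 23))
  bt <- bartlett_lengths(equalvar)
  expect_equal(bt$bartlett_k2, 0, tolerance = 1e-12)
  expect_equal(bt$bartlett_p, 1, tolerance = 1e-12)
  set.seed(14)
  groups <- list(female = rnorm(40, 733, 48), hooknose = rnorm(35, 735, 74),
                 jack = rnorm(20, 423, 45))
  bt <- bartlett_lengths(groups)
  o <- bartlett_oracle(groups)
  expect_equal(bt$bartlett_k2, o$K2, tolerance = 1e-10)
  expect_equal(bt$bartlett_df, o$df)
  expect_equal(bt$bartlett_p, o$p, tolerance = 1e-10)
  expect_equal(nrow(bt$pairwise), 3)
  expect_error(bartlett_lengths(list(a = c(1, 1, 1), b = c(1, 2, 3))),
               "zero variance")
  expect_error(bartlett_lengths(list(a = c(1, 2))), "2 groups")
})

test_that("Bartlett rejects unequal variances with high power", {
  set.seed(15)
  rej <- mean(replicate(200, {
    bartlett_lengths(list(a = rnorm(100, 0, 1),
                          b = rnorm(100, 0, 2)))$bartlett_p < 0.05
  }))
  expect_gt(rej, 0.95)
})

test_that("variance-ratio F test is the ratio of sample variances", {
  set.seed(16)
  a <- rnorm(30, 700, 50)
  b <- rnorm(25, 700, 30)
  vt <- variance_ratio_test(a, b)
  expect_equal(vt$F, var(a) / var(b), tolerance = 1e-12)
  expect_equal(c(vt$df1, vt$df2), c(29, 24))
  # reciprocity: swapping the samples inverts F and swaps dfs
  vt2 <- variance_ratio_test(b, a)
  expect_equal(vt2$F, 1 / vt$F, tolerance = 1e-12)
  expect_equal(c(vt2$df1, vt2$df2), c(24, 29))
  expect_equal(vt2$p, vt$p, tolerance = 1e-12)
  expect_equal(variance_ratio_test(a, a)$F, 1)
})

test_that("parent-offspring regression uses per-parent offspring means", {
  p <- clone_pedigree()
  reg <- parent_offspring_regression(p, "female", "female")
  expect_equal(reg$b_op, 1, tolerance = 1e-10) # perfect resemblance
  expect_equal(reg$n_families, 10)
  expect_equal(reg$families$n_offspring, rep(3L, 10))
  expect_equal(reg$families$mean_offspring_length,
               reg$families$parent_length, tolerance = 1e-12)
  # slope and SE agree with the explicit normal-equations oracle
  ped <- quick_sim(31)
  reg2 <- parent_offspring_regression(ped, "hooknose", "female")
  o <- ols_oracle(cbind(1, reg2$families$parent_length),
                  reg2$families$mean_offspring_length)
  expect_equal(reg2$b_op, o$coef[2], tolerance = 1e-10)
  expect_equal(reg2$se_slope, o$se[2], tolerance = 1e-10)
  expect_error(parent_offspring_regression(toy_pedigree(), "jack", "jack"),
               "insufficient data")
})

test_that("heritability algebra holds exactly for corrected and uncorrected cells", {
  plain <- heritability_from_slope(0.25, 0.05, 50, 50, corrected = FALSE)
  expect_equal(plain$h2, 0.5)
  expect_equal(plain$correction, 1)
  expect_equal(plain$null_slope, 0.5)
  expect_equal(plain$ci95, 2 * qnorm(0.975) * 0.05)
  expect_equal(heritability_from_slope(0, 0.1, 40, 60, TRUE)$h2, 0)
  corr <- heritability_from_slope(-0.12, 0.08, 40, 60, corrected = TRUE)
  expect_equal(corr$correction, 40 / 60)
  expect_equal(corr$h2, 2 * -0.12 * 40 / 60)
  expect_equal(corr$null_slope, 0.5 / (40 / 60))
  expect_equal(corr$ci95, 2 * qnorm(0.975) * 0.08 * 40 / 60)
  # a more variable offspring class shrinks |h2| below |2 b_op|
  expect_lt(abs(corr$h2), abs(2 * -0.12))
  expect_error(heritability_from_slope(0.1, 0.05, -1, 50, TRUE), "positive")
})

test_that("slope tests against 0 and the h2=1 null behave as t and F", {
  null0 <- test_slope(0.5, 0.1, 20, 0.5, method = "F")
  expect_equal(null0$statistic, 0)
  expect_equal(null0$p, 1)
  tt <- test_slope(0.3, 0.1, 20, 0)
  expect_equal(tt$method, "t")
  expect_equal(tt$statistic, 3)
  expect_equal(tt$df, 18)
  expect_equal(tt$p, 2 * pt(3, 18, lower.tail = FALSE))
  # F equals t^2 for the same null
  ff <- test_slope(0.3, 0.1, 20, 0, method = "F")
  expect_equal(ff$statistic, tt$statistic^2, tolerance = 1e-12)
  expect_equal(ff$p, tt$p, tolerance = 1e-12)
  expect_error(test_slope(0.3, 0, 20), "positive")
  expect_error(test_slope(0.3, 0.1, 2), "exceed 2")
})

test_that("heritability grid populates 9 asymmetric cells with exact algebra", {
  p <- quick_sim(8)
  g <- heritability_grid(p)
  expect_equal(nrow(g), 9)
  expect_setequal(paste(g$parent_tactic, g$offspring_tactic),
                  as.vector(outer(TACTICS, TACTICS, paste)))
  ok <- g[g$reason == "", ]
  expect_gt(nrow(ok), 5)
  expect_equal(ok$h2, 2 * ok$b_op * ok$correction, tolerance = 1e-12)
  expect_equal(ok$ci95, 2 * qnorm(0.975) * ok$se_slope * ok$correction,
               tolerance = 1e-12)
  expect_equal(ok$null_slope, 0.5 / ok$correction, tolerance = 1e-12)
  expect_equal(ok$correction[!ok$corrected],
               rep(1, sum(!ok$corrected)))
  # dam->jack and jack->daughter come from different families
  dj <- parent_offspring_regression(p, "female", "jack")
  jd <- parent_offspring_regression(p, "jack", "female")
  expect_false(identical(dj$families$parent_id, jd$families$parent_id))
  expect_false(isTRUE(all.equal(dj$b_op, jd$b_op)))
  # the female<->hooknose pair triggers the variance correction
  fh <- g[g$parent_tactic == "female" & g$offspring_tactic == "hooknose", ]
  expect_true(fh$corrected)
  expect_equal(fh$correction, fh$sigma_p / fh$sigma_o, tolerance = 1e-12)
})

test_that("offspring interaction model matches the normal-equations oracle", {
  p <- quick_sim(17)
  fit <- offspring_interaction_model(p)
  expect_equal(fit$residual_df, fit$n - length(fit$coefficients))
  mm <- model.matrix(fit$fit)
  o <- ols_oracle(mm, fit$fit$model$length_o)
  expect_equal(unname(fit$coefficients), unname(o$coef), tolerance = 1e-10)
  # sequential F table carries the documented term order
  expect_equal(rownames(fit$anova)[1:5],
               c("dam_length", "sire_length", "tactic",
                 "dam_length:tactic", "sire_length:tactic"))
  # a single offspring tactic is degenerate
  expect_error(offspring_interaction_model(
    as_pedigree(as.data.frame(p)[p$tactic == "female" |
                                   p$generation == "parent", ])),
    "2 offspring tactics")
})

test_that("sire-length x tactic interaction is detected when slopes differ", {
  # dams/sires random; hooknose sons inherit steeply from sires, daughters not
  set.seed(18)
  n <- 400
  dams <- data.frame(id = sprintf("D%d", 1:n), sex = "female",
                     tactic = "female", year = 2002L,
                     length_mm = rnorm(n, 730, 45), rs = 1L,
                     dam_id = NA, sire_id = NA, stringsAsFactors = FALSE)
  sires <- data.frame(id = sprintf("S%d", 1:n), sex = "male",
                      tactic = "hooknose", year = 2002L,
                      length_mm = rnorm(n, 735, 70), rs = 1L,
                      dam_id = NA, sire_id = NA, stringsAsFactors = FALSE)
  son <- rbinom(n, 1, 0.5) == 1
  slope <- ifelse(son, 0.4, 0.1)
  off <- data.frame(id = sprintf("O%d", 1:n),
                    sex = ifelse(son, "male", "female"),
                    tactic = ifelse(son, "hooknose", "female"),
                    year = 2004L,
                    length_mm = 500 + slope * sires$length_mm +
                      rnorm(n, 0, 30),
                    rs = 0L, dam_id = dams$id, sire_id = sires$id,
                    stringsAsFactors = FALSE)
  fit <- offspring_interaction_model(as_pedigree(rbind(dams, sires, off)))
  expect_lt(fit$anova["sire_length:tactic", "Pr(>F)"], 0.01)
})
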