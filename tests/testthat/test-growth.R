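# Nested polynomial model comparison, flowering-time Dunnett analysis and
# flower-defect contingency statistics.

test_that("default polynomial orders match the analysis configuration", {
  expect_equal(default_order("Area"), 3)
  expect_equal(default_order("perimeter"), 3)
  expect_equal(default_order("Compactness"), 4)
  expect_equal(default_order("Roundness"), 5)
  expect_equal(default_order("Roundness 2"), 5)
  expect_equal(default_order("Isotropy"), 6)
  expect_equal(default_order("eccentricity"), 6)
  expect_equal(default_order("RMS"), 6)
  expect_equal(default_order("SOL"), 3)
  expect_error(default_order("leafiness"))
})

test_that("polynomial fits recover noiseless curves exactly", {
  days <- 10:20
  d <- data.frame(plant_id = "p1", genotype = "Col-0", day = days,
                  parameter = "area", value = days^2)
  fit <- fit_growth_model(d, "area", order = 2)
  expect_lt(sqrt(mean(stats::resid(fit$fit)^2)), 1e-8)
  expect_equal(unname(stats::predict(fit$fit,
                                     newdata = data.frame(x = phenoscreen:::scale_day(15, c(10, 20))))),
               225, tolerance = 1e-8)
  expect_error(fit_growth_model(d[d$day < 13, ], "area", order = 2),
               "distinct days")
})

test_that("identical genotypes give a null comparison; planted offsets are recovered", {
  # mutant curves literally duplicate the control curves: every genotype
  # coefficient is 0, the deviance is 0 and p = 1
  sim <- simulate_longitudinal(seed = 11, noise_sd = 1)
  d <- sim$data
  ctrl <- d[d$genotype == "Col-0", ]
  dup <- ctrl
  dup$genotype <- "mutant"
  dup$plant_id <- sub("Col-0", "mutant", dup$plant_id)
  d <- rbind(ctrl, dup)
  m0 <- fit_growth_model(d, "area", order = 3)
  m1 <- fit_growth_model(d, "area", order = 3, with_genotype = TRUE)
  cmp <- compare_nested(m0, m1)
  expect_equal(cmp$chisq_stat, 0, tolerance = 1e-6)
  expect_equal(cmp$df, 4)
  expect_equal(cmp$p_value, 1, tolerance = 1e-6)
  expect_lt(max(abs(stats::coef(m1$fit)[grep("genotype", names(stats::coef(m1$fit)))])),
            1e-8)

  # identical model vs itself: zero deviance, p = 1
  self <- compare_nested(m0, m0)
  expect_equal(self$chisq_stat, 0)
  expect_equal(self$p_value, 1)
  expect_error(compare_nested(m1, m0), "nested")

  # genotype intercept effect recovered without bias: 500 replicates
  delta <- 2
  est <- vapply(1:500, function(i) {
    s <- simulate_longitudinal(seed = i, n_plants = 20,
                               effects = list(mutant = c(intercept = delta, slope = 0)))
    f <- fit_growth_model(s$data, "area", order = 2, with_genotype = TRUE)
    unname(stats::coef(f$fit)["genotypemutant"])
  }, numeric(1))
  expect_lt(abs(mean(est) - delta) / delta, 0.05)
})

test_that("likelihood-ratio statistic is invariant to response rescaling and day shifts", {
  sim <- simulate_longitudinal(seed = 5,
                               effects = list(mutant = c(intercept = 1, slope = 0.2)))
  stat_of <- function(d) {
    m0 <- fit_growth_model(d, "area", order = 3)
    m1 <- fit_growth_model(d, "area", order = 3, with_genotype = TRUE)
    compare_nested(m0, m1)$chisq_stat
  }
  base <- stat_of(sim$data)
  scaled <- sim$data; scaled$value <- 3.7 * scaled$value - 12
  expect_equal(stat_of(scaled), base, tolerance = 1e-8)
  shifted <- sim$data; shifted$day <- shifted$day + 100
  expect_equal(stat_of(shifted), base, tolerance = 1e-8)
})

test_that("block bootstrap p-value tracks the chi-square p under the null", {
  sim <- simulate_longitudinal(seed = 23, n_plants = 10, days = 10:16)
  m0 <- fit_growth_model(sim$data, "area", order = 2)
  m1 <- fit_growth_model(sim$data, "area", order = 2, with_genotype = TRUE)
  cmp <- compare_nested(m0, m1, boot = 199, boot_seed = 7)
  expect_true(cmp$p_boot > 0 && cmp$p_boot <= 1)
  expect_lt(abs(cmp$p_boot - cmp$p_value), 0.25)
})

test_that("flowering comparison reduces to a t-test for a single contrast and detects shifts", {
  set.seed(31)
  tab <- data.frame(plant_id = 1:40,
                    genotype = rep(c("Col-0", "mut"), each = 20),
                    LAB = round(c(rnorm(20, 14, 1.5), rnorm(20, 13, 1.5))),
                    DTB = c(rnorm(20, 26, 1.2), rnorm(20, 25.5, 1.2)))
  res <- flowering_comparison(tab)
  tt <- t.test(LAB ~ genotype, data = tab, var.equal = TRUE)
  expect_equal(res$p_adj[res$trait == "LAB" & res$genotype == "mut"],
               tt$p.value, tolerance = 1e-4)

  # planted -4 leaf shift, sd 1.5, n = 20: clearly significant; a genotype
  # duplicating the control values exactly is not
  set.seed(32)
  ctrl_lab <- rnorm(20, 14, 1.5)
  tab2 <- data.frame(plant_id = 1:60,
                     genotype = rep(c("Col-0", "early", "same"), each = 20),
                     LAB = c(ctrl_lab, rnorm(20, 10, 1.5), ctrl_lab),
                     DTB = rnorm(60, 26, 1))
  res2 <- flowering_comparison(tab2)
  expect_true(res2$significant[res2$genotype == "early" & res2$trait == "LAB"])
  expect_false(res2$significant[res2$genotype == "same" & res2$trait == "LAB"])
  expect_error(flowering_comparison(tab2[tab2$genotype != "Col-0", ]), "control")
})

test_that("Dunnett adjustment never reports smaller p than the unadjusted t-test", {
  for (seed in 1:20) {
    set.seed(seed)
    tab <- data.frame(plant_id = 1:60,
                      genotype = rep(c("Col-0", "m1", "m2"), each = 20),
                      LAB = rnorm(60, 14, 1.5), DTB = rnorm(60, 26, 1.2))
    res <- flowering_comparison(tab, traits = "LAB")
    fit <- stats::aov(LAB ~ stats::relevel(factor(genotype), "Col-0"), data = tab)
    sigma <- sqrt(sum(stats::resid(fit)^2) / fit$df.residual)
    for (g in c("m1", "m2")) {
      est <- mean(tab$LAB[tab$genotype == g]) - mean(tab$LAB[tab$genotype == "Col-0"])
      tstat <- est / (sigma * sqrt(2 / 20))
      p_raw <- 2 * stats::pt(-abs(tstat), fit$df.residual)
      expect_gte(res$p_adj[res$genotype == g] + 1e-9, p_raw)
    }
  }
})

test_that("flowering null simulations keep the family-wise error near alpha", {
  hits <- vapply(1:300, function(seed) {
    set.seed(seed + 4000)
    tab <- data.frame(plant_id = 1:60,
                      genotype = rep(c("Col-0", "m1", "m2"), each = 20),
                      LAB = rnorm(60, 14, 1.5), DTB = rnorm(60, 26, 1))
    any(flowering_comparison(tab, traits = "LAB", seed = seed)$significant)
  }, logical(1))
  expect_lt(mean(hits), 0.10)   # nominal 0.05 family-wise over two contrasts
  expect_gt(mean(hits), 0.005)
})

test_that("defect proportions reproduce the reported flower counts and edge cases", {
  res <- defect_proportions(data.frame(genotype = c("sinal7-2", "Col-0"),
                                       n_affected = c(43, 6), n_total = c(80, 50)))
  expect_equal(res$proportions$percent, c(54, 12))
  expect_lt(res$fisher_p, 0.001)
  expect_gt(res$odds_ratio, 1)

  zero <- defect_proportions(data.frame(genotype = c("a", "b"),
                                        n_affected = c(0, 10), n_total = c(30, 30)))
  expect_equal(zero$proportions$percent[1], 0)
  expect_equal(zero$odds_ratio, 0)
  expect_error(defect_proportions(data.frame(genotype = "a", n_affected = 5,
                                             n_total = 0)))
})
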