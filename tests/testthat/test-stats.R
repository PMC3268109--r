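test_that("paired t matches closed forms and the reference implementation", {
  x <- c(1, 2, 3, 4)
  r <- paired_t(x, x)
  expect_equal(r$t, 0); expect_equal(r$p, 1)

  # d = (1, 2, 3): t = 2 / (1/sqrt(3)) = 3.464, p = 0.0742 on 2 df
  r2 <- paired_t(c(2, 4, 6), c(1, 2, 3))
  expect_equal(r2$t, 3.4641, tolerance = 1e-4)
  expect_equal(r2$p, 0.0742, tolerance = 1e-3)

  # zero-variance nonzero differences
  r3 <- paired_t(c(2, 3, 4), c(1, 2, 3))
  expect_equal(r3$p, 0)

  set.seed(7)
  for (i in 1:50) {
    n <- sample(4:20, 1)
    a <- rnorm(n); b <- rnorm(n)
    ours <- paired_t(a, b)
    ref <- t.test(a, b, paired = TRUE)
    expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-8)
  }
})

test_that("baseline-to-early dyssynchrony difference is detectable at the study's size", {
  # power by sampling oracle at the preset effect size: per-cohort SD16
  # values simulated directly from the generator's TTP model
  pre <- make_preset("pre_mi"); early <- make_preset("early_post_mi")
  sim_sd16 <- function(p, n = 6) {
    m16 <- p$region_ttp[p$segment_region, "mean"]
    vapply(seq_len(n), function(i)
      sd(m16 + rnorm(16, 0, p$ttp_within_sd)), numeric(1))
  }
  set.seed(99)
  rej <- vapply(1:200, function(i) {
    paired_t(sim_sd16(early), sim_sd16(pre))$p < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.80)
})

test_that("repeated-measures ANOVA reproduces a hand decomposition and aov", {
  # 3 subjects x 2 regions x 2 times, worked example
  d <- expand.grid(subject = 1:3, region = c("a", "b"), time = c("t1", "t2"))
  d$y <- c(10, 12, 14, 20, 21, 25, 11, 13, 16, 24, 26, 28)
  ours <- rm_anova(d$y, d$subject, d$region, d$time)
  ref <- summary(stats::aov(y ~ region * time +
                              Error(factor(subject) / (region * time)),
                            data = d))
  refF <- c(ref[["Error: factor(subject):region"]][[1]]["region", "F value"],
            ref[["Error: factor(subject):time"]][[1]]["time", "F value"],
            ref[["Error: factor(subject):region:time"]][[1]]["region:time",
                                                             "F value"])
  expect_equal(ours$F, unname(refF), tolerance = 1e-8)

  # collapsing one factor reduces to one-way repeated measures
  d2 <- d[d$time == "t1", ]
  one <- summary(stats::aov(y ~ region + Error(factor(subject) / region),
                            data = d2))
  oneF <- one[["Error: factor(subject):region"]][[1]]["region", "F value"]
  # two-way with a duplicated-time design must give the same region F
  d3 <- rbind(d2, transform(d2, time = "t2"))
  ours3 <- rm_anova(d3$y, d3$subject, d3$region, d3$time)
  expect_equal(ours3$F[1], unname(oneF), tolerance = 1e-8)

  expect_error(rm_anova(d$y[-1], d$subject[-1], d$region[-1], d$time[-1]),
               "unbalanced|incomplete")
  expect_error(rm_anova(rep(1, 12), d$subject, d$region, d$time),
               "constant")
  expect_error(rm_anova(d$y, d$subject, rep("a", 12), d$time), "levels")
})

test_that("rm-ANOVA holds its nominal type-I error under the null", {
  set.seed(123)
  d <- expand.grid(subject = 1:6, region = c("n", "p", "m"),
                   time = c("t1", "t2", "t3"))
  rej <- logical(1000)
  for (i in 1:1000) {
    y <- rnorm(6)[d$subject] + rnorm(nrow(d))
    rej[i] <- rm_anova(y, d$subject, d$region, d$time)$p[1] < 0.05
  }
  expect_gte(mean(rej), 0.035)
  expect_lte(mean(rej), 0.065)
})

test_that("OLS R-squared and slope inference match closed forms", {
  x <- 1:6
  expect_equal(linreg_r2(x, 2 * x)$r2, 1)
  # 5-point worked example against lm
  x5 <- c(1, 2, 4, 5, 9); y5 <- c(2.1, 3.9, 8.4, 9.6, 17.2)
  ours <- linreg_r2(x5, y5)
  fit <- summary(lm(y5 ~ x5))
  expect_equal(ours$r2, fit$r.squared, tolerance = 1e-12)
  expect_equal(ours$p, fit$coefficients["x5", 4], tolerance = 1e-10)
  expect_error(linreg_r2(rep(2, 5), rnorm(5)), "variance")

  # independent peak-strain / TTP pairs: no spurious relationship
  set.seed(5)
  r2s <- vapply(1:100, function(i)
    linreg_r2(rnorm(33, -18, 3), rnorm(33, 350, 50))$r2, numeric(1))
  expect_lt(mean(r2s), 0.05)
})

test_that("inter-observer agreement summaries", {
  a <- c(300, 320, 280, 340)
  expect_equal(interobserver_cov(a, a)$cov_pct, 0)
  b <- c(310, 310, 290, 330)
  r <- interobserver_cov(a, b)
  expect_equal(r$mean_diff, mean(a - b))
  expect_equal(r$cov_pct, 100 * sd(a - b) / mean(c(a, b)))
  expect_error(interobserver_cov(c(-1, 1), c(1, -1)), "grand mean")

  # two observers reading the same TTP with independent ~9 ms jitter:
  # CoV approximately 9 * sqrt(2) / 308
  set.seed(11)
  truth <- rnorm(63, 308, 45)
  o1 <- truth + rnorm(63, 0, 9); o2 <- truth + rnorm(63, 0, 9)
  cv <- interobserver_cov(o1, o2)$cov_pct
  expect_gt(cv, 2); expect_lt(cv, 6)
})
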