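test_that("cox_fit is null on identical groups and validates inputs", {
  d <- data.frame(months = rep(c(3, 6, 9, 12, 15), 2),
                  event = rep(1L, 10),
                  grp = rep(c(0, 1), each = 5))
  fit <- cox_fit(d, "grp")
  expect_equal(fit$HR, 1, tolerance = 1e-6)
  expect_gt(fit$p, 0.95)
  expect_error(cox_fit(data.frame(months = c(1, 2), event = c(1, 0),
                                  x = c(0, 1)), "x"), "2 events")
  d$const <- 1
  expect_error(cox_fit(d, "const"), "constant covariate")
})

test_that("cox_fit matches the hand-coded partial-likelihood oracle", {
  for (seed in 1:4) {
    d <- tiny_surv(n = 6 + seed %% 3, seed = seed)
    fit <- cox_fit(d, "x")
    oracle <- stats::optimize(function(b) {
      cox_nll_oracle(b, d$months, d$event, d$x)
    }, c(-10, 10), tol = 1e-10)$minimum
    expect_equal(fit$beta, oracle, tolerance = 1e-6)
  }
})

test_that("perfect separation is reported, not silently fitted", {
  d <- data.frame(months = c(1, 2, 3, 10, 11, 12),
                  event = rep(1L, 6), x = c(1, 1, 1, 0, 0, 0))
  expect_error(cox_fit(d, "x"), "separation")
})

test_that("Cox coefficients are shift-invariant and scale-inverse", {
  co <- generate_cohort(cohort_spec(400, beta = log(1.02), seed = 8))
  co$x <- co$marker * 1000
  b <- cox_fit(co, "x")$beta
  co$x_shift <- co$x + 500
  co$x_scale <- co$x * 4
  expect_equal(cox_fit(co, "x_shift")$beta, b, tolerance = 1e-7)
  expect_equal(cox_fit(co, "x_scale")$beta, b / 4, tolerance = 1e-7)
})

test_that("bonferroni caps, preserves order and validates m", {
  p <- c(0.2, 0.001, 0.04)
  out <- bonferroni(p, 10)
  expect_equal(out, c(1, 0.01, 0.4))
  expect_true(all(out >= p))
  expect_equal(order(out), order(pmin(1, p * 10)))
  expect_equal(bonferroni(0.5, 1), 0.5)
  expect_error(bonferroni(0.5, 0), "m must be")
})

test_that("Schoenfeld diagnostics hold their size and detect violations", {
  # type-I error under proportional hazards
  rej <- vapply(1:500, function(i) {
    set.seed(i)
    n <- 60
    x <- rnorm(n)
    d <- data.frame(months = rexp(n, 0.05 * exp(0.3 * x)),
                    event = 1L, x = x)
    fit <- cox_fit(d, "x")
    ph_test(fit)$ph_p[1] < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.02)
  expect_lte(mean(rej), 0.09)

  # effect that reverses sign over time is flagged in most replicates
  power <- vapply(1:60, function(i) {
    set.seed(i + 1000)
    n <- 150
    x <- rep(c(0, 1), n / 2)
    early <- rexp(n, 0.2 * exp(2 * x))
    d <- data.frame(
      months = ifelse(early < 3, early, 3 + rexp(n, 0.2 * exp(-2 * x))),
      event = 1L, x = x)
    fit <- cox_fit(d, "x")
    ph_test(fit)$ph_p[1] < 0.05
  }, logical(1))
  expect_gt(mean(power), 0.5)

  d2 <- data.frame(months = c(1, 2), event = c(1, 1), x = c(0, 1))
  fit2 <- suppressWarnings(
    survival::coxph(survival::Surv(months, event) ~ x, d2))
  expect_error(ph_test(fit2), "3 events")
})

test_that("log-rank matches a hand-tabulated risk-set computation", {
  # worked example: groups A = {2+, 4, 6}, B = {1, 3, 5+} (+ = censored)
  months <- c(2, 4, 6, 1, 3, 5)
  event <- c(0, 1, 1, 1, 1, 0)
  group <- c("A", "A", "A", "B", "B", "B")
  # risk sets at event times 1, 3, 4, 6:
  # t=1: nA=3 nB=3, dB=1 -> eA = 0.5
  # t=3: nA=2 nB=2, dB=1 -> eA = 0.5
  # t=4: nA=2 nB=1, dA=1 -> eA = 2/3
  # t=6: nA=1 nB=0, dA=1 -> eA = 1
  oa <- 2; ea <- 0.5 + 0.5 + 2 / 3 + 1
  va <- (3 * 3) / 36 + (2 * 2) / 16 + (2 * 1) / 9 + 0
  lr <- logrank(months, event, group)
  expect_equal(lr$observed[1], oa)
  expect_equal(unname(lr$expected[1]), ea, tolerance = 1e-10)
  expect_equal(lr$chisq, (oa - ea)^2 / va, tolerance = 1e-10)
  expect_equal(lr$df, 1)

  # identical groups: statistic 0, p 1
  lr0 <- logrank(rep(c(1, 2, 3), 2), rep(1L, 6), rep(c("a", "b"), each = 3))
  expect_equal(lr0$chisq, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1, tolerance = 1e-9)

  expect_error(logrank(c(1, 2), c(1, 1), c("a", "a")), "2 non-empty")
  expect_error(logrank(c(1, 2), c(0, 0), c("a", "b")), "1 event")
})

test_that("Mann-Whitney uses exact enumeration on small tie-free samples", {
  sep <- mann_whitney(c(1, 2, 3), c(10, 20, 30))
  expect_true(sep$U %in% c(0, 9))
  expect_equal(sep$p, 0.1) # 2/20 of the C(6,3) labelings
  expect_true(sep$exact)

  same <- mann_whitney(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_gt(same$p, 0.9)

  # rank statistic: invariant under a common monotone transform
  set.seed(2)
  x <- runif(12); y <- runif(15)
  a <- mann_whitney(x, y)
  b <- mann_whitney(exp(3 * x), exp(3 * y))
  expect_equal(a$U, b$U)
  expect_equal(a$p, b$p)
})

test_that("Spearman correlation matches a full permutation oracle at n = 5", {
  expect_equal(spearman_cor(1:6, c(2, 4, 6, 8, 10, 12))$rho, 1)
  expect_equal(spearman_cor(1:6, 6:1)$rho, -1)

  x <- c(0.3, 1.2, 0.7, 2.5, 1.9)
  y <- c(10, 3, 8, 1, 9)
  got <- spearman_cor(x, y)
  perms <- combinat_perms <- NULL
  # enumerate all 120 rank assignments of y against fixed x ranks
  allp <- expand.grid(rep(list(1:5), 5))
  allp <- allp[apply(allp, 1, function(r) length(unique(r)) == 5), ]
  rho_obs <- stats::cor(rank(x), rank(y))
  rho_all <- apply(allp, 1, function(r) stats::cor(rank(x), r))
  p_perm <- mean(abs(rho_all) >= abs(rho_obs) - 1e-12)
  expect_equal(got$rho, rho_obs)
  expect_equal(got$p, p_perm, tolerance = 1e-10)

  expect_warning(z <- spearman_cor(rep(1, 5), 1:5), "zero variance")
  expect_true(is.na(z$rho))
})

test_that("run_screen corrects over the family and joins tables correctly", {
  set.seed(3)
  co <- generate_cohort(cohort_spec(80, beta = log(1.02), seed = 3))
  tab <- data.frame(patient_id = co$patient_id,
                    PDGFRB_meso = co$marker,
                    FAP_stroma = rbeta(80, 2, 18))
  attr(tab, "scale") <- "raw"
  expect_error(run_screen(tab, co), "raw scale")
  sc <- scale_for_cox(tab)
  one <- run_screen(sc[c("patient_id", "PDGFRB_meso")], co)
  expect_equal(one$univariate$p_corrected, one$univariate$p)
  full <- run_screen(sc, co, multivariable_sets = list("PDGFRB_meso"))
  expect_equal(full$m, 2)
  expect_true(all(full$univariate$p_corrected >= full$univariate$p))
  expect_true("multivariable_1" %in% full$report$model_id)
  mv <- full$multivariable
  expect_true(any(grepl("histology", mv$variable)))
  expect_error(run_screen(sc, co[1:5, ]), "< 10 complete")
})
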