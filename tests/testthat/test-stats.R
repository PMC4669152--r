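test_that("two-way ANOVA matches the brute-force cell-means oracle", {
  d <- data.frame(
    A = rep(c("a1", "a2"), each = 6),
    B = rep(rep(c("b1", "b2"), each = 3), 2),
    value = c(1, 2, 3, 4, 5, 6, 2, 4, 6, 5, 7, 9))
  tab <- two_way_anova(factorial_sample(d$value, d$A, d$B))
  oracle <- brute_force_anova(d)
  expect_equal(tab$SS[tab$term == "A"], oracle$A, tolerance = 1e-9)
  expect_equal(tab$SS[tab$term == "B"], oracle$B, tolerance = 1e-9)
  expect_equal(tab$SS[tab$term == "A:B"], oracle$AB, tolerance = 1e-9)
  expect_equal(tab$SS[tab$term == "Residuals"], oracle$res, tolerance = 1e-9)
  expect_equal(sum(tab$SS), oracle$total, tolerance = 1e-9)

  # and agrees with the reference linear-model implementation
  a <- summary(stats::aov(value ~ A * B, d))[[1]]
  expect_equal(tab$F[1:3], a[["F value"]][1:3], tolerance = 1e-9)
  expect_equal(tab$p[1:3], a[["Pr(>F)"]][1:3], tolerance = 1e-9)
})

test_that("additive noiseless data have exactly zero interaction SS", {
  d <- expand.grid(A = c("a1", "a2", "a3"), B = c("b1", "b2"), rep = 1:2)
  d$value <- as.integer(d$A) * 2 + as.integer(d$B) * 5
  tab <- two_way_anova(factorial_sample(d$value, d$A, d$B))
  expect_equal(tab$SS[tab$term == "A:B"], 0, tolerance = 1e-12)
})

test_that("type-II sums of squares agree with car on unbalanced data", {
  skip_if_not_installed("car")
  set.seed(9)
  d <- data.frame(A = sample(c("x", "y"), 40, TRUE),
                  B = sample(c("p", "q", "r"), 40, TRUE))
  d$value <- rnorm(40) + (d$A == "y") * 0.8
  tab <- two_way_anova(factorial_sample(d$value, d$A, d$B))
  ref <- car::Anova(stats::lm(value ~ A * B, d), type = 2)
  expect_equal(tab$SS[tab$term == "A"], ref["A", "Sum Sq"], tolerance = 1e-9)
  expect_equal(tab$SS[tab$term == "B"], ref["B", "Sum Sq"], tolerance = 1e-9)
  expect_equal(tab$SS[tab$term == "A:B"], ref["A:B", "Sum Sq"],
               tolerance = 1e-9)
})

test_that("empty design cells are reported by name", {
  d <- data.frame(A = c("a", "a", "b", "b", "a", "a"),
                  B = c("x", "x", "x", "x", "y", "y"),
                  value = rnorm(6))
  expect_error(two_way_anova(factorial_sample(d$value, d$A, d$B)),
               "A=b, B=y")
})

test_that("tukey_hsd reproduces the reference studentized-range procedure", {
  set.seed(4)
  d <- expand.grid(A = c("a", "b"), B = c("x", "y", "z"), rep = 1:4)
  noise <- rnorm(8)  # same within-cell noise for every B level: x-y null
  d <- d[order(d$B, d$A, d$rep), ]
  d$value <- rep(noise, 3) + (d$B == "z") * 3
  fs <- factorial_sample(d$value, d$A, d$B)
  mine <- tukey_hsd(fs, factor = "B")
  ref <- stats::TukeyHSD(stats::aov(value ~ A * B, d), "B")$B
  key <- paste(mine$level_1, mine$level_2, sep = "-")
  expect_equal(mine$diff, unname(ref[key, "diff"]), tolerance = 1e-9)
  expect_equal(mine$lwr, unname(ref[key, "lwr"]), tolerance = 1e-9)
  expect_equal(mine$p_adj, unname(ref[key, "p adj"]), tolerance = 1e-9)

  # the far-shifted level is detected, the null pair is not
  expect_lt(mine$p_adj[key == "z-x"], 0.001)
  expect_gt(mine$p_adj[key == "y-x"], 0.5)
})

test_that("tukey_hsd of two identical groups gives p near 1", {
  set.seed(6)
  v <- rnorm(8)
  d <- data.frame(A = rep(c("g1", "g2"), each = 8), B = rep(c("u", "v"), 8),
                  value = c(v, v))
  out <- tukey_hsd(factorial_sample(d$value, d$A, d$B), factor = "A")
  expect_gt(out$p_adj, 0.999)
})

test_that("Welch t-tests match the closed form and the reference", {
  out <- multiple_t_tests(list(toy = list(x = c(1, 2, 3), y = c(4, 5, 6))))
  expect_equal(out$t, -3.674235, tolerance = 1e-6)
  expect_equal(out$df, 4, tolerance = 1e-9)
  expect_equal(out$p, 0.02131164, tolerance = 1e-6)
  ref <- stats::t.test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(out$t, unname(ref$statistic), tolerance = 1e-9)
  expect_equal(out$p, ref$p.value, tolerance = 1e-9)

  set.seed(2)
  x <- rnorm(10)
  same <- multiple_t_tests(list(id = list(x = x, y = x)))
  expect_equal(same$p, 1, tolerance = 1e-9)

  mixed <- multiple_t_tests(list(
    good = list(x = rnorm(5), y = rnorm(5)),
    degenerate = list(x = 1, y = rnorm(5)),
    flat = list(x = c(2, 2), y = c(2, 2))))
  expect_true(is.na(mixed$p[2]) && mixed$note[2] != "")
  expect_true(is.na(mixed$p[3]) && mixed$note[3] != "")
  expect_false(is.na(mixed$p[1]))
  # Holm adjustment over the valid pairs only
  expect_equal(mixed$p_holm[1], mixed$p[1])
})

test_that("penetrance intervals are exact Clopper-Pearson", {
  none <- penetrance_ci(0, 10)
  expect_equal(none$fraction, 0)
  expect_equal(none$ci_lo, 0)
  expect_equal(none$ci_hi, 1 - 0.025^(1 / 10), tolerance = 1e-12)
  expect_equal(round(none$ci_hi, 3), 0.308)

  all_p <- penetrance_ci(10, 10)
  expect_equal(all_p$fraction, 1)
  expect_equal(all_p$ci_hi, 1)

  mid <- penetrance_ci(7, 30)
  ref <- stats::binom.test(7, 30)$conf.int
  expect_equal(c(mid$ci_lo, mid$ci_hi), as.numeric(ref), tolerance = 1e-9)
  expect_error(penetrance_ci(0, 0), "empty")
})

test_that("the complexity-threshold penetrance rule scores mixed cohorts", {
  ref <- do.call(rbind, lapply(
    simulate_cohort(builtin_profiles("wild_type"), 20, 501)$arbors,
    quantify_arbor))
  wt <- do.call(rbind, lapply(
    simulate_cohort(builtin_profiles("wild_type"), 14, 502)$arbors,
    quantify_arbor))
  mut <- do.call(rbind, lapply(
    simulate_cohort(builtin_profiles("rab_10"), 6, 503)$arbors,
    quantify_arbor))
  mut$animal_id <- paste0("m_", mut$animal_id)
  res <- penetrance(rbind(wt, mut), reference = ref)
  # 30% mutant mixture: estimate within binomial error of the mixture
  expect_lt(abs(res$fraction - 0.3), 2 * sqrt(0.3 * 0.7 / 20) + 0.05)
  expect_true(res$ci_lo <= res$fraction && res$fraction <= res$ci_hi)
  expect_error(penetrance(wt[0, ], reference = ref), "empty")
})
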