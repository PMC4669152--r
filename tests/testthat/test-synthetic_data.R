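test_that("the profile registry covers the study genotypes with stated totals", {
  profs <- builtin_profiles()
  expect_gte(length(profs), 8L)
  expect_true(all(c("wild_type", "rab_10", "dma_1", "exoc_8", "sec_5",
                    "unc_116", "dhc_1", "unc_116_rab_10", "dhc_1_rab_10")
                  %in% names(profs)))

  wt <- profs$wild_type
  expect_equal(sum(wt$lambda2), 42)
  expect_equal(2 * sum(wt$lambda2 * wt$p3) * wt$mu4, 114, tolerance = 1e-9)
  # anterior +3 is the sparsest region in wild type
  expect_equal(which.min(wt$lambda2), c("+3" = 4))

  rb <- profs$rab_10
  expect_equal(sum(rb$lambda2), 28)
  expect_equal(2 * sum(rb$lambda2 * rb$p3) * rb$mu4, 17, tolerance = 1e-9)
  # anterior-shifted: densest region is distal anterior
  expect_equal(which.max(rb$lambda2), c("+3" = 4))

  # menorah-less receptor mutant
  expect_true(all(profs$dma_1$p3 == 0))
  expect_equal(profs$dma_1$mu4, 0)

  expect_error(builtin_profiles("nonesuch"), "available")
})

test_that("arbor simulation is deterministic and seed-sensitive", {
  p <- builtin_profiles("wild_type")
  a1 <- simulate_arbor(p, 5)
  a2 <- simulate_arbor(p, 5)
  expect_identical(a1$arbor$nodes, a2$arbor$nodes)
  f1 <- tempfile(); f2 <- tempfile()
  write_swc(a1$arbor, f1); write_swc(a2$arbor, f2)
  expect_identical(readLines(f1), readLines(f2))

  a3 <- simulate_arbor(p, 6)
  expect_false(identical(a1$arbor$nodes, a3$arbor$nodes))
})

test_that("zero secondary rates give a bare primary", {
  zero <- stats::setNames(rep(0, 4), c("-1", "+1", "+2", "+3"))
  p <- genotype_profile("bare", lambda2 = zero, p3 = zero)
  sim <- simulate_arbor(p, 1)
  expect_equal(sort(sim$arbor$nodes$id), sort(sim$truth$primary_ids))
  expect_true(all(sim$truth$counts$n2 == 0))
})

test_that("cohorts are reproducible and seed-distinct", {
  p <- builtin_profiles("rab_10")
  c1 <- simulate_cohort(p, 5, seed = 9)
  c2 <- simulate_cohort(p, 5, seed = 9)
  expect_identical(lapply(c1$arbors, `[[`, "nodes"),
                   lapply(c2$arbors, `[[`, "nodes"))
  expect_equal(length(unique(vapply(c1$arbors,
                                    function(a) a$metadata$animal_id,
                                    character(1)))), 5L)
  c3 <- simulate_cohort(p, 5, seed = 10)
  expect_false(identical(c1$arbors[[1]]$nodes, c3$arbors[[1]]$nodes))
})

test_that("per-region secondary means track the profile rates", {
  p <- builtin_profiles("wild_type")
  n <- 100
  coh <- simulate_cohort(p, n, seed = 71)
  n2 <- sapply(coh$truth, function(t) t$counts$n2)  # 4 x n
  for (r in 1:4) {
    se <- stats::sd(n2[r, ]) / sqrt(n)
    expect_lt(abs(mean(n2[r, ]) - p$lambda2[r]), 3 * se + 1e-9)
  }
})

test_that("tertiary arms of same-side menorahs tile without overlap", {
  for (seed in c(12, 13, 14)) {
    sim <- simulate_arbor(builtin_profiles("wild_type"), seed)
    sec <- sim$truth$secondaries
    for (s in c(-1, 1)) {
      men <- sec[sec$has3 & sec$side == s, ]
      if (nrow(men) < 2L) next
      men <- men[order(men$arm_lo), ]
      expect_true(all(men$arm_hi[-nrow(men)] <= men$arm_lo[-1] + 1e-9))
      expect_true(all(men$arm_lo < men$arm_hi))
    }
  }
})

test_that("kymograph scenes honour mixtures and degenerate rates", {
  p <- genotype_profile("allout", lambda2 = builtin_profiles("wild_type")$lambda2,
                        p3 = builtin_profiles("wild_type")$p3,
                        polarity = c("-1" = 1, "+1" = 1, "+2" = 1, "+3" = 1,
                                     axon = 1))
  s <- simulate_kymograph(p, "-1", seed = 2, n_comets = 5)
  expect_true(all(s$truth$velocity > 0))

  s0 <- simulate_kymograph(p, "-1", seed = 3, n_comets = 0)
  expect_true(all(s0$kymo$img == 0))
  expect_equal(nrow(s0$truth), 0L)

  expect_error(simulate_kymograph(p, "nowhere", seed = 1), "polarity")
})

test_that("noiseless FRAP traces equal the model exactly", {
  wt <- builtin_profiles("wild_type")
  p <- genotype_profile("clean", lambda2 = wt$lambda2, p3 = wt$p3,
                        frap = list(f0 = 0.25, f_inf = 0.75, tau = 50,
                                    noise_sd = 0))
  s <- simulate_frap(p, 2, seed = 4)
  tr <- s$traces[s$traces$animal_id == s$traces$animal_id[1], ]
  tt <- tr$t[tr$t >= 0]
  expect_equal(tr$intensity[tr$t >= 0],
               0.25 + 0.5 * (1 - exp(-tt / 50)), tolerance = 1e-12)
  expect_equal(tr$intensity[tr$t < 0], rep(1, 5))
})
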