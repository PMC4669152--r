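test_that("primary path of a straight soma-centered skeleton is symmetric", {
  fix <- make_primary_skeleton(La = 10, Lp = 10, step = 10)
  pp <- extract_primary(fix$skeleton())
  expect_equal(unname(pp$arc_length), c(-10, 0, 10))
  expect_equal(pp$L_a, 10)
  expect_equal(pp$L_p, 10)
})

test_that("the longer of two posterior arms is chosen as the primary arm", {
  nodes <- data.frame(
    id = 1:6, structure = c(1L, rep(3L, 5)),
    x = c(0, 50, -15, -30, -10, 25), y = c(0, 0, 0, 0, 4, 0), z = 0,
    radius = 0.5, parent = c(-1L, 6L, 1L, 3L, 1L, 1L))
  pp <- extract_primary(arbor_skeleton(nodes, soma_id = 1L))
  expect_true(4L %in% pp$node_ids)   # tip of the 30 um arm
  expect_false(5L %in% pp$node_ids)  # 10 um arm excluded
  expect_equal(pp$L_p, 30)
})

test_that("an arbor with no posterior arm raises a degenerate-path error", {
  nodes <- data.frame(id = 1:3, structure = c(1L, 3L, 3L), x = c(0, 10, 20),
                      y = c(0, 0, 5), z = 0, radius = 0.5,
                      parent = c(-1L, 1L, 1L))
  err <- tryCatch(extract_primary(arbor_skeleton(nodes, soma_id = 1L)),
                  error = identity)
  expect_s3_class(err, "degenerate_path_error")
  expect_true(length(err$partial) > 0)
})

test_that("extracted primary equals the generator's ground-truth path", {
  for (seed in c(2, 31)) {
    sim <- simulate_arbor(builtin_profiles("wild_type"), seed)
    pp <- extract_primary(sim$arbor)
    expect_identical(pp$node_ids, sim$truth$primary_ids)
  }
})

test_that("a bare primary classifies to zero branches", {
  fix <- make_primary_skeleton()
  cls <- classify_branch_orders(fix$skeleton(), extract_primary(fix$skeleton()))
  expect_equal(nrow(cls$branches), 0L)
  cnt <- count_by_region(cls, segment_regions(cls$primary))
  expect_true(all(cnt$n2 == 0 & cnt$n4 == 0))
})

test_that("any protrusion from the primary is a secondary, however short", {
  fix <- make_primary_skeleton()
  base <- fix$id_at(30)
  fix$add(30, 2, base)  # 2 um filopodium
  arb <- fix$skeleton()
  cls <- classify_branch_orders(arb, extract_primary(arb))
  expect_equal(cls$branches$order, 2L)
  cnt <- count_by_region(cls, segment_regions(cls$primary))
  expect_equal(sum(cnt$n2), 1L)
})

test_that("a toy menorah yields n2=1, n2_with3=1, n3=2, n4=4", {
  fix <- make_primary_skeleton(La = 90, Lp = 30, step = 15)
  add_menorah(fix, base_x = 45, arm_len = 20, n_quat = 2)
  arb <- fix$skeleton()
  cls <- classify_branch_orders(arb, extract_primary(arb))
  expect_equal(sum(cls$branches$order == 2), 1L)
  expect_equal(sum(cls$branches$order == 3 & cls$branches$oriented), 2L)
  expect_equal(sum(cls$branches$order == 4 & cls$branches$oriented), 4L)
  cnt <- count_by_region(cls, segment_regions(cls$primary))
  expect_equal(as.integer(unlist(cnt[cnt$region == "+2", c("n2", "n2_with3", "n3", "n4")])),
               c(1L, 1L, 2L, 4L))
  # menorah assignment: arms cross into +3 (45 + 20 > 60) but all counts
  # stay in the region of the secondary base
  expect_true(all(cnt[cnt$region == "+3", c("n2", "n3", "n4")] == 0))
})

test_that("misoriented children are labelled but excluded from oriented counts", {
  fix <- make_primary_skeleton(La = 90, Lp = 30, step = 15)
  base <- fix$id_at(30)
  tip <- fix$add(30, 20, base)    # secondary stem
  fix$add(40, 34, tip)            # 54-degree child of the 2°: not a tertiary
  ok <- fix$add(42, 21, tip)      # A-P child: tertiary
  fix$add(42, 15, ok)             # orthogonal child of the 3°: quaternary
  fix$add(50, 28, ok)             # 41-degree child of the 3°: misoriented 4°
  arb <- fix$skeleton()
  cls <- classify_branch_orders(arb, extract_primary(arb))
  br <- cls$branches
  expect_equal(sum(br$order == 3 & !br$oriented), 1L)
  expect_equal(sum(br$order == 3 & br$oriented), 1L)
  expect_equal(sum(br$order == 4 & br$oriented), 1L)
  expect_equal(sum(br$order == 4 & !br$oriented), 1L)
  cnt <- count_by_region(cls, segment_regions(cls$primary))
  expect_equal(sum(cnt$n3), 1L)
  expect_equal(sum(cnt$n4), 1L)
})

test_that("region partition splits the anterior extent into equal thirds", {
  fix <- make_primary_skeleton(La = 90, Lp = 30, step = 15)
  part <- segment_regions(extract_primary(fix$skeleton()))
  expect_equal(part$lo, c(-30, 0, 30, 60))
  expect_equal(part$hi, c(0, 30, 60, 90))

  fix2 <- make_primary_skeleton(La = 1, Lp = 1, step = 1)
  part2 <- segment_regions(extract_primary(fix2$skeleton()))
  expect_equal(part2$lo[3:4], c(1 / 3, 2 / 3))
})

test_that("boundary positions are assigned to the more anterior region", {
  fix <- make_primary_skeleton(La = 90, Lp = 30, step = 15)
  part <- segment_regions(extract_primary(fix$skeleton()))
  expect_equal(as.character(region_of(part, c(-30, -1e-9, 0, 30, 60, 90))),
               c("-1", "-1", "+1", "+2", "+3", "+3"))
})

test_that("shifting a base across a boundary moves exactly one count", {
  eps <- 1e-6
  counts_at <- function(x) {
    fix <- make_primary_skeleton(La = 90, Lp = 30, step = 15, extra_x = x)
    fix$add(x, 5, fix$id_at(x))
    arb <- fix$skeleton()
    cls <- classify_branch_orders(arb, extract_primary(arb))
    count_by_region(cls, segment_regions(cls$primary))$n2
  }
  below <- counts_at(30 - eps)
  above <- counts_at(30 + eps)
  expect_equal(below - above, c(0L, 1L, -1L, 0L))
})

test_that("branch complexity identities hold", {
  ideal <- data.frame(region = "+1", n2 = 14L, n2_with3 = 14L, n3 = 28L,
                      n4 = 140L)
  ci <- branch_complexity(ideal, n2_star = 14, q_star = 5)
  expect_identical(ci$bci, 1)

  empty <- data.frame(region = "+1", n2 = 0L, n2_with3 = 0L, n3 = 0L, n4 = 0L)
  expect_identical(branch_complexity(empty, 14, 5)$bci, 0)

  worked <- data.frame(region = "+1", n2 = 7L, n2_with3 = 4L, n3 = 4L,
                       n4 = 10L)
  expect_equal(branch_complexity(worked, n2_star = 14, q_star = 5)$bci,
               (0.5 + 4 / 7 + 0.5) / 3, tolerance = 1e-12)

  expect_error(branch_complexity(ideal, n2_star = 0, q_star = 5), "positive")
  expect_error(branch_complexity(ideal, n2_star = 14, q_star = -1), "positive")
})

test_that("complexity is monotone in each count component", {
  base <- data.frame(region = "+1", n2 = 8L, n2_with3 = 4L, n3 = 8L, n4 = 10L)
  bci0 <- branch_complexity(base, 14, 5)$bci
  up2 <- base; up2$n2 <- 12L
  upw <- base; upw$n2_with3 <- 6L
  up4 <- base; up4$n4 <- 20L
  expect_gt(branch_complexity(up2, 14, 5)$bci, bci0)
  expect_gt(branch_complexity(upw, 14, 5)$bci, bci0)
  expect_gt(branch_complexity(up4, 14, 5)$bci, bci0)
})

test_that("count_filopodia totals secondaries and rejects L4", {
  xs <- c(-20, 10, 25, 50, 70)
  fix <- make_primary_skeleton(La = 90, Lp = 30, step = 15, extra_x = xs)
  for (x in xs) fix$add(x, 4, fix$id_at(x))
  arb <- fix$skeleton()
  cls <- classify_branch_orders(arb, extract_primary(arb))
  expect_equal(count_filopodia(cls, "L2"), 5L)
  expect_equal(count_filopodia(cls, "L3"), 5L)
  expect_error(count_filopodia(cls, "L4"), "count_by_region")
})

test_that("per-region counts conserve whole-arbor totals on noisy arbors", {
  for (seed in c(3, 17)) {
    sim <- simulate_arbor(builtin_profiles("rab_10"), seed)
    pp <- extract_primary(sim$arbor)
    cls <- classify_branch_orders(sim$arbor, pp)
    cnt <- count_by_region(cls, segment_regions(pp))
    br <- cls$branches
    expect_equal(sum(cnt$n2), sum(br$order == 2))
    expect_equal(sum(cnt$n3), sum(br$order == 3 & br$oriented))
    expect_equal(sum(cnt$n4),
                 sum(br$order == 4 & br$oriented & br$flag != "beyond_depth"))
  }
})

test_that("every non-primary node belongs to exactly one branch", {
  sim <- simulate_arbor(builtin_profiles("wild_type"), 23)
  pp <- extract_primary(sim$arbor)
  cls <- classify_branch_orders(sim$arbor, pp)
  branch_ids <- unlist(cls$branch_nodes)
  expect_equal(sort(c(pp$node_ids, branch_ids)), sort(sim$arbor$nodes$id))
  expect_false(any(duplicated(branch_ids)))
})
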