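# In-code fixtures: small hand-built skeletons with known branch structure.

# straight primary along x from -Lp to +La with nodes every `step` um,
# soma at the origin; returns the skeleton and a lookup from x to node id
make_primary_skeleton <- function(La = 90, Lp = 30, step = 15,
                                  extra_x = numeric(0)) {
  xs <- sort(unique(c(seq(-Lp, La, by = step), 0, extra_x)))
  nodes <- data.frame(id = integer(0), structure = integer(0), x = numeric(0),
                      y = numeric(0), z = numeric(0), radius = numeric(0),
                      parent = integer(0))
  add <- function(x, y, parent, structure = 3L) {
    id <- nrow(nodes) + 1L
    nodes <<- rbind(nodes, data.frame(id = id, structure = structure, x = x,
                                      y = y, z = 0, radius = 0.5,
                                      parent = parent))
    id
  }
  soma <- add(0, 0, -1L, structure = 1L)
  prev <- soma
  for (x in xs[xs > 0]) prev <- add(x, 0, prev)
  prev <- soma
  for (x in rev(xs[xs < 0])) prev <- add(x, 0, prev)
  list(nodes = nodes, add = add,
       skeleton = function() arbor_skeleton(nodes, soma_id = soma),
       id_at = function(x) nodes$id[match(x, nodes$x)])
}

# one complete menorah: a secondary stem at base_x, two A-P tertiary arms
# each bearing n_quat orthogonal quaternary twigs
add_menorah <- function(fix, base_x, stem_len = 20, arm_len = 12,
                        n_quat = 2, side = 1) {
  base <- fix$id_at(base_x)
  tip <- fix$add(base_x, side * stem_len, base)
  for (dir in c(-1, 1)) {
    prev <- tip
    qx <- base_x + dir * arm_len * seq_len(n_quat) / (n_quat + 1)
    for (x in qx) {
      att <- fix$add(x, side * stem_len, prev)
      fix$add(x, side * (stem_len + 5), att)   # quaternary twig
      prev <- att
    }
    fix$add(base_x + dir * arm_len, side * stem_len, prev)  # arm end
  }
  invisible(fix)
}

# write SWC text lines to a temp file and return the path
swc_file <- function(lines) {
  f <- tempfile(fileext = ".swc")
  writeLines(lines, f)
  f
}

# profile with all orientation noise removed (for exact counting oracles)
zero_noise_profile <- function(label = "wild_type") {
  p <- builtin_profiles(label)
  genotype_profile(paste0(label, "_zero_noise"),
                   L_a = p$L_a, L_p = p$L_p, lambda2 = p$lambda2, p3 = p$p3,
                   defective_frac = p$defective_frac,
                   orient_sd = 0, orient_sd_defective = 0, tert_orient_sd = 0,
                   mu4 = p$mu4, polarity = p$polarity, frap = p$frap)
}

# match detected kymograph tracks to ground-truth comets: a truth comet is
# matched when some track overlaps it in time by >= 0.5 s, stays within
# `tol_um` of the true trajectory on average, and has the same velocity sign
match_comets <- function(truth, tracks, kymo, tol_um = 1.5) {
  if (nrow(truth) == 0L) return(logical(0))
  away <- if (kymo$soma_side == "left") 1 else -1
  vapply(seq_len(nrow(truth)), function(i) {
    tc <- truth[i, ]
    v_px_s <- tc$velocity * away / kymo$pixel_size
    any(vapply(seq_len(nrow(tracks)), function(j) {
      tr <- tracks[j, ]
      lo <- max(tc$t_birth, tr$t0); hi <- min(tc$t_death, tr$t1)
      if (hi - lo < 0.5) return(FALSE)
      tt <- seq(lo, hi, length.out = 5)
      x_true <- ((tc$x0_px + v_px_s * (tt - tc$t_birth)) - 1) * kymo$pixel_size
      slope <- tr$velocity * away
      x_fit <- tr$x0 + slope * (tt - tr$t0)
      mean(abs(x_true - x_fit)) < tol_um &&
        sign(tr$velocity) == sign(tc$velocity)
    }, logical(1)))
  }, logical(1))
}

# brute-force balanced two-way ANOVA decomposition from cell/grand means
brute_force_anova <- function(d) {
  g <- mean(d$value)
  ma <- tapply(d$value, d$A, mean)
  mb <- tapply(d$value, d$B, mean)
  mab <- tapply(d$value, list(d$A, d$B), mean)
  na <- tapply(d$value, d$A, length)
  nb <- tapply(d$value, d$B, length)
  nab <- tapply(d$value, list(d$A, d$B), length)
  ss_a <- sum(na * (ma - g)^2)
  ss_b <- sum(nb * (mb - g)^2)
  ss_ab <- 0
  ss_res <- 0
  for (a in rownames(mab)) for (b in colnames(mab)) {
    ss_ab <- ss_ab + nab[a, b] * (mab[a, b] - ma[a] - mb[b] + g)^2
    cell <- d$value[d$A == a & d$B == b]
    ss_res <- ss_res + sum((cell - mab[a, b])^2)
  }
  list(A = unname(ss_a), B = unname(ss_b), AB = unname(ss_ab),
       res = unname(ss_res), total = sum((d$value - g)^2))
}
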