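# Seed scoping: run expr with a fixed RNG seed, restoring global RNG state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# deterministic per-animal seed derivation from a master seed (documented
# scheme: affine map modulo the largest 32-bit prime)
.derive_seed <- function(master, i) {
  as.integer((as.numeric(master) * 48271 + i) %% 2147483647)
}

.REGIONS <- c("-1", "+1", "+2", "+3")

#' Construct a genotype profile
#'
#' A genotype profile holds the per-region generative parameters that define
#' a genotype's branching statistics, microtubule polarity mixtures, and
#' FRAP kinetics for the simulator. Expected branch totals are
#' `sum(lambda2)` secondaries and `2 * sum(lambda2 * p3) * mu4` correctly
#' oriented quaternaries (each menorah carries two tertiary arms).
#'
#' @param label genotype label.
#' @param L_a,L_p anterior/posterior primary dendrite extents (micrometres).
#' @param lambda2 named numeric, expected secondary count per region
#'   (`-1`, `+1`, `+2`, `+3`).
#' @param p3 named numeric, per-region probability that a secondary reaches
#'   the tertiary line and forms tertiary arms.
#' @param defective_frac fraction of non-menorah secondaries that are short,
#'   misoriented filopodia (the classic trafficking-mutant defect).
#' @param sec_len_mean,sec_len_sd secondary stem length distribution (um).
#' @param sec_len_short_mean,sec_len_short_sd defective-secondary lengths.
#' @param orient_sd orientation noise of stems and quaternaries, degrees
#'   from orthogonal; `orient_sd_defective` for defective secondaries.
#' @param tert_len_mean,tert_len_sd tertiary arm length distribution (um);
#'   `tert_orient_sd` arm deviation from the A-P axis (degrees).
#' @param mu4 expected quaternary count per tertiary arm.
#' @param polarity named numeric, plus-end-out comet fraction per region
#'   (regions plus `"axon"`).
#' @param frap list with `f0`, `f_inf`, `tau` (s), `noise_sd` for the
#'   single-exponential recovery model.
#' @param kymo list of kymograph scene parameters: `comet_rate` (expected
#'   comets per scene), `speed_range` (um/s), `duration_s`, `length_px`,
#'   `pixel_size_um`, `dt_s`, `amplitude`, `background`, `psf_sd_px`,
#'   `lifetime_s`.
#' @return list of class `genotype_profile`.
#' @export
genotype_profile <- function(label, L_a = 300, L_p = 100,
                             lambda2, p3,
                             defective_frac = 0.05,
                             sec_len_mean = 22, sec_len_sd = 2,
                             sec_len_short_mean = 6, sec_len_short_sd = 2,
                             orient_sd = 8, orient_sd_defective = 30,
                             tert_len_mean = 12, tert_len_sd = 3,
                             tert_orient_sd = 4,
                             mu4 = 1.5,
                             polarity = c("-1" = 0.9, "+1" = 0.1, "+2" = 0.1,
                                          "+3" = 0.1, axon = 0.95),
                             frap = list(f0 = 0.2, f_inf = 0.8, tau = 30,
                                         noise_sd = 0.02),
                             kymo = list()) {
  lambda2 <- unlist(lambda2)[.REGIONS]
  p3 <- unlist(p3)[.REGIONS]
  polarity <- unlist(polarity)
  if (anyNA(lambda2) || anyNA(p3)) {
    stop("lambda2 and p3 must name all regions ", paste(.REGIONS, collapse = " "))
  }
  stopifnot(L_a > 0, L_p > 0, all(lambda2 >= 0), all(p3 >= 0 & p3 <= 1),
            defective_frac >= 0, defective_frac <= 1, mu4 >= 0,
            all(polarity >= 0 & polarity <= 1))
  kymo_defaults <- list(comet_rate = 10, speed_range = c(0.1, 0.3),
                        duration_s = 30, length_px = 100,
                        pixel_size_um = 0.2, dt_s = 0.125,
                        amplitude = 30, background = 0, psf_sd_px = 1.2,
                        lifetime_s = 15)
  kymo <- utils::modifyList(kymo_defaults, kymo)
  structure(
    list(label = label, L_a = L_a, L_p = L_p, lambda2 = lambda2, p3 = p3,
         defective_frac = defective_frac,
         sec_len_mean = sec_len_mean, sec_len_sd = sec_len_sd,
         sec_len_short_mean = sec_len_short_mean,
         sec_len_short_sd = sec_len_short_sd,
         orient_sd = orient_sd, orient_sd_defective = orient_sd_defective,
         tert_len_mean = tert_len_mean, tert_len_sd = tert_len_sd,
         tert_orient_sd = tert_orient_sd, mu4 = mu4,
         polarity = polarity, frap = frap, kymo = kymo),
    class = "genotype_profile"
  )
}

#' @export
print.genotype_profile <- function(x, ...) {
  cat(sprintf(
    "genotype_profile '%s': E[n2] = %.1f, E[n4] = %.1f (L_a %.0f um, L_p %.0f um)\n",
    x$label, sum(x$lambda2), 2 * sum(x$lambda2 * x$p3) * x$mu4, x$L_a, x$L_p))
  invisible(x)
}

#' Built-in genotype profiles
#'
#' Loads the registry of genotype profiles shipped with the package
#' (`inst/extdata/genotype_profiles.yaml`). Whole-arbor expected totals for
#' the wild-type and rab-10 loss-of-function profiles are calibrated to the
#' reported L4 means (wild type: 42 secondaries, 114 quaternaries; mutant:
#' 28 and 17); per-region parameters for all genotypes are estimates chosen
#' to match each genotype's described regional phenotype.
#'
#' @param label optional: return the single named profile instead of the
#'   whole registry. Unknown labels raise an error listing the registry.
#' @param path optional path to an alternative YAML profile file.
#' @return a named list of [genotype_profile()] objects, or one profile.
#' @export
builtin_profiles <- function(label = NULL, path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "genotype_profiles.yaml",
                        package = "pvdarbor", mustWork = TRUE)
  }
  raw <- yaml::read_yaml(path)
  profs <- lapply(names(raw), function(nm) {
    spec <- raw[[nm]]
    spec$label <- nm
    do.call(genotype_profile, spec)
  })
  names(profs) <- names(raw)
  if (is.null(label)) return(profs)
  if (!label %in% names(profs)) {
    stop("unknown profile '", label, "'; available: ",
         paste(names(profs), collapse = ", "))
  }
  profs[[label]]
}

# truncated normal draw (simple resampling floor)
.rnorm_min <- function(n, mean, sd, min) {
  pmax(stats::rnorm(n, mean, sd), min)
}

#' Simulate one PVD-like arbor with ground truth
#'
#' Generates a menorah-structured skeleton: the primary dendrite is laid
#' along the A-P (x) axis with the soma at the origin; secondaries are
#' placed by per-region Poisson counts at uniform positions and grow
#' orthogonally (dorsoventral, alternating sides at random) with Gaussian
#' orientation noise; with probability `p3` a secondary reaches the tertiary
#' line and spawns two tertiary arms running along the A-P axis, trimmed so
#' that arms of neighbouring menorahs on the same side never overlap in A-P
#' extent (self-avoidance) and never extend beyond the primary span;
#' quaternary twigs are placed on each arm at Poisson(`mu4`) and rise
#' orthogonally away from the primary. Non-menorah secondaries are either
#' full-length stems that failed to branch or (with probability
#' `defective_frac`) short, misoriented filopodia.
#'
#' At the L2/L3 stages only secondary filopodia are generated (no menorahs).
#'
#' @param profile a [genotype_profile()].
#' @param seed integer seed; identical (profile, seed) gives byte-identical
#'   output.
#' @param stage larval stage, `"L4"` (default), `"L2"` or `"L3"`.
#' @return list with elements `arbor` (an [arbor_skeleton()]) and `truth`,
#'   a list holding `counts` (true per-region n2/n2_with3/n3/n4),
#'   `primary_ids` (node ids posterior tip to anterior tip), and
#'   `secondaries` (per-secondary table incl. tertiary arm extents).
#' @export
simulate_arbor <- function(profile, seed, stage = "L4") {
  stopifnot(inherits(profile, "genotype_profile"), stage %in% c("L2", "L3", "L4"))
  .with_seed(seed, .simulate_arbor_impl(profile, seed, stage))
}

.simulate_arbor_impl <- function(profile, seed, stage) {
  La <- profile$L_a; Lp <- profile$L_p
  third <- La / 3
  region_lo <- c("-1" = -Lp, "+1" = 0, "+2" = third, "+3" = 2 * third)
  region_hi <- c("-1" = 0, "+1" = third, "+2" = 2 * third, "+3" = La)

  # --- draw secondaries ------------------------------------------------------
  sec <- do.call(rbind, lapply(.REGIONS, function(r) {
    n <- stats::rpois(1, profile$lambda2[[r]])
    if (n == 0L) return(NULL)
    data.frame(region = r,
               x = stats::runif(n, region_lo[[r]], region_hi[[r]]),
               stringsAsFactors = FALSE)
  }))
  menorah <- stage == "L4"
  if (!is.null(sec)) {
    n <- nrow(sec)
    sec$side <- sample(c(-1, 1), n, replace = TRUE)
    sec$has3 <- menorah &
      stats::rbinom(n, 1, profile$p3[match(sec$region, .REGIONS)]) == 1L
    sec$defective <- !sec$has3 &
      (!menorah | stats::rbinom(n, 1, profile$defective_frac) == 1L)
    sec$len <- ifelse(
      sec$defective,
      .rnorm_min(n, profile$sec_len_short_mean, profile$sec_len_short_sd, 2),
      .rnorm_min(n, profile$sec_len_mean, profile$sec_len_sd, 8))
    sec$tilt <- stats::rnorm(n, 0, ifelse(sec$defective,
                                          profile$orient_sd_defective,
                                          profile$orient_sd)) * pi / 180
    sec <- sec[order(sec$x), , drop = FALSE]
    rownames(sec) <- NULL
  } else {
    sec <- data.frame(region = character(0), x = numeric(0), side = numeric(0),
                      has3 = logical(0), defective = logical(0),
                      len = numeric(0), tilt = numeric(0))
  }

  # stem tips, kept strictly inside the primary span so the primary tips
  # remain the unique A-P extremes
  sec$tip_x <- pmin(pmax(sec$x + sec$len * sin(sec$tilt), -Lp + 0.5),
                    La - 0.5)
  sec$tip_y <- sec$side * sec$len * cos(sec$tilt)

  # --- tertiary arms with self-avoidance -------------------------------------
  # each menorah on a side owns the interval between the midpoints to its
  # neighbouring menorah bases (virtual neighbours at the primary tips),
  # shrunk by a clearance; stems are bent into their corridor, so arm
  # extents of different menorahs on the same side never overlap
  margin <- 1.0
  sec$arm_lo <- rep(NA_real_, nrow(sec)); sec$arm_hi <- rep(NA_real_, nrow(sec))
  for (s in c(-1, 1)) {
    men <- which(sec$has3 & sec$side == s)
    if (length(men) == 0L) next
    bx <- sec$x[men]  # already sorted ascending
    aug <- c(-Lp, bx, La)
    lo_raw <- (aug[seq_along(men)] + bx) / 2
    hi_raw <- (bx + aug[seq_along(men) + 2L]) / 2
    delta <- pmin(margin / 2, (hi_raw - lo_raw) / 8)
    lo_lim <- lo_raw + delta
    hi_lim <- hi_raw - delta
    for (k in seq_along(men)) {
      i <- men[k]
      w <- hi_lim[k] - lo_lim[k]
      tipx <- min(max(sec$tip_x[i], lo_lim[k] + w / 4), hi_lim[k] - w / 4)
      sec$tip_x[i] <- tipx
      want <- .rnorm_min(2, profile$tert_len_mean, profile$tert_len_sd, 2)
      sec$arm_lo[i] <- max(tipx - want[1L], lo_lim[k])
      sec$arm_hi[i] <- min(tipx + want[2L], hi_lim[k])
    }
  }

  # --- quaternaries -----------------------------------------------------------
  quats <- list()   # per menorah-arm: data.frame(sec, arm, pos_x, len, tilt)
  if (any(sec$has3)) {
    for (i in which(sec$has3)) {
      for (arm in c("lo", "hi")) {
        nq <- stats::rpois(1, profile$mu4)
        if (nq == 0L) next
        a0 <- sec$tip_x[i]
        a1 <- if (arm == "lo") sec$arm_lo[i] else sec$arm_hi[i]
        fr <- sort(stats::runif(nq, 0.08, 0.92))
        quats[[length(quats) + 1L]] <- data.frame(
          sec = i, arm = arm,
          pos_x = a0 + fr * (a1 - a0),
          len = .rnorm_min(nq, 4, 1, 1.5),
          tilt = stats::rnorm(nq, 0, profile$orient_sd) * pi / 180,
          stringsAsFactors = FALSE)
      }
    }
  }
  quats <- if (length(quats) > 0L) do.call(rbind, quats) else
    data.frame(sec = integer(0), arm = character(0), pos_x = numeric(0),
               len = numeric(0), tilt = numeric(0))

  # --- assemble nodes ---------------------------------------------------------
  nodes <- new.env()
  nodes$tab <- vector("list", 4096)
  nodes$n <- 0L
  add_node <- function(x, y, parent, structure = 3L, radius = 0.3) {
    nodes$n <- nodes$n + 1L
    nodes$tab[[nodes$n]] <- c(id = nodes$n, structure = structure,
                              x = x, y = y, z = 0, radius = radius,
                              parent = parent)
    nodes$n
  }

  soma <- add_node(0, 0, -1L, structure = 1L, radius = 1.5)
  grid <- sort(unique(c(seq(-Lp, La, by = 5), 0, La, -Lp, sec$x)))
  ant_x <- grid[grid > 0]
  post_x <- rev(grid[grid < 0])
  ant_ids <- integer(length(ant_x))
  prev <- soma
  for (k in seq_along(ant_x)) {
    prev <- add_node(ant_x[k], 0, prev, radius = 0.6)
    ant_ids[k] <- prev
  }
  post_ids <- integer(length(post_x))
  prev <- soma
  for (k in seq_along(post_x)) {
    prev <- add_node(post_x[k], 0, prev, radius = 0.6)
    post_ids[k] <- prev
  }
  primary_ids <- c(rev(post_ids), soma, ant_ids)
  primary_x <- c(rev(post_x), 0, ant_x)
  node_at_x <- function(x) primary_ids[match(x, primary_x)]

  if (nrow(sec) > 0L) {
    for (i in seq_len(nrow(sec))) {
      base <- node_at_x(sec$x[i])
      tip <- add_node(sec$tip_x[i], sec$tip_y[i], base)
      if (!sec$has3[i]) next
      for (arm in c("lo", "hi")) {
        a1 <- if (arm == "lo") sec$arm_lo[i] else sec$arm_hi[i]
        qa <- quats[quats$sec == i & quats$arm == arm, , drop = FALSE]
        # arm nodes ordered from the stem tip outward
        ord <- order(abs(qa$pos_x - sec$tip_x[i]))
        qa <- qa[ord, , drop = FALSE]
        prev_arm <- tip
        arm_tilt <- stats::rnorm(1, 0, profile$tert_orient_sd) * pi / 180
        arm_y <- function(x) sec$tip_y[i] + (x - sec$tip_x[i]) * tan(arm_tilt)
        if (nrow(qa) > 0L) {
          for (qk in seq_len(nrow(qa))) {
            att <- add_node(qa$pos_x[qk], arm_y(qa$pos_x[qk]), prev_arm)
            qtip_x <- min(max(qa$pos_x[qk] + qa$len[qk] * sin(qa$tilt[qk]),
                              -Lp + 0.25), La - 0.25)
            qtip_y <- arm_y(qa$pos_x[qk]) +
              sec$side[i] * qa$len[qk] * cos(qa$tilt[qk])
            add_node(qtip_x, qtip_y, att)
            prev_arm <- att
          }
        }
        add_node(a1, arm_y(a1), prev_arm)
      }
    }
  }

  m <- do.call(rbind, nodes$tab[seq_len(nodes$n)])
  ntab <- data.frame(id = as.integer(m[, "id"]),
                     structure = as.integer(m[, "structure"]),
                     x = m[, "x"], y = m[, "y"], z = m[, "z"],
                     radius = m[, "radius"],
                     parent = as.integer(m[, "parent"]))
  arbor <- arbor_skeleton(
    ntab, soma_id = soma,
    metadata = list(genotype = profile$label, stage = stage,
                    seed = as.character(seed))
  )

  # --- ground truth -----------------------------------------------------------
  nq_by_sec <- if (nrow(quats) > 0L) {
    tapply(rep(1L, nrow(quats)), quats$sec, sum)
  } else integer(0)
  sec$n4 <- rep(0L, nrow(sec))
  if (length(nq_by_sec) > 0L) {
    sec$n4[as.integer(names(nq_by_sec))] <- as.integer(nq_by_sec)
  }
  counts <- do.call(rbind, lapply(.REGIONS, function(r) {
    in_r <- sec$region == r
    data.frame(region = r,
               n2 = sum(in_r),
               n2_with3 = sum(in_r & sec$has3),
               n3 = 2L * sum(in_r & sec$has3),
               n4 = sum(sec$n4[in_r]))
  }))
  counts$region <- factor(counts$region, levels = .REGIONS)

  list(arbor = arbor,
       truth = list(counts = counts, primary_ids = primary_ids,
                    secondaries = sec))
}

#' Simulate a cohort of arbors
#'
#' @param profile a [genotype_profile()].
#' @param n number of animals.
#' @param seed master seed; per-animal seeds are derived deterministically
#'   (see [simulate_arbor()] for the per-arbor model).
#' @param stage larval stage label passed through.
#' @return list with `arbors` (list of skeletons, metadata `animal_id` set)
#'   and `truth` (list of per-arbor ground truths).
#' @export
simulate_cohort <- function(profile, n, seed, stage = "L4") {
  stopifnot(n >= 1)
  sims <- lapply(seq_len(n), function(i) {
    s <- simulate_arbor(profile, .derive_seed(seed, i), stage = stage)
    s$arbor$metadata$animal_id <- sprintf("%s_%03d", profile$label, i)
    s
  })
  list(arbors = lapply(sims, `[[`, "arbor"),
       truth = lapply(sims, `[[`, "truth"))
}

#' Simulate an EB-comet kymograph with ground truth
#'
#' Renders a time-by-position kymograph of EB comets: comets are born at
#' uniform times and positions, move at constant velocity with direction
#' drawn from the region's plus-end-out mixture, and are rendered as
#' Gaussian-profile streaks (amplitude `amplitude`, width `psf_sd_px`) over
#' a Poisson background (`background` counts/pixel; 0 gives a noiseless
#' scene). Rows are time at `dt_s` per frame (default 0.125 s, i.e. 8
#' frames per second), columns are position.
#'
#' @param profile a [genotype_profile()] whose `polarity` entry covers
#'   `region`.
#' @param region region label (`-1`, `+1`, `+2`, `+3`, `axon`).
#' @param seed integer seed.
#' @param soma_side which column edge points toward the soma (`"left"` or
#'   `"right"`).
#' @param n_comets override the Poisson comet count (e.g. for fixed scenes).
#' @param avoid_crossings if `TRUE`, comets are confined to disjoint
#'   position lanes so trajectories never cross or overlap — used for exact
#'   detector-oracle scenes.
#' @param overrides named list overriding the profile's `kymo` parameters.
#' @return list with `kymo` (a [kymograph()]) and `truth`, a data.frame of
#'   comets (`t_birth`, `t_death`, `x0_px`, `velocity` in um/s signed
#'   positive away from the soma, `direction`).
#' @export
simulate_kymograph <- function(profile, region, seed, soma_side = "left",
                               n_comets = NULL, avoid_crossings = FALSE,
                               overrides = list()) {
  stopifnot(inherits(profile, "genotype_profile"))
  if (!region %in% names(profile$polarity)) {
    stop("region '", region, "' has no polarity mixture in this profile")
  }
  kp <- utils::modifyList(profile$kymo, overrides)
  p_out <- profile$polarity[[region]]
  .with_seed(seed, {
    nt <- as.integer(round(kp$duration_s / kp$dt_s))
    nx <- as.integer(kp$length_px)
    n <- if (is.null(n_comets)) stats::rpois(1, kp$comet_rate) else n_comets
    away <- if (soma_side == "left") 1 else -1

    truth <- NULL
    if (n > 0L) {
      dirs <- ifelse(stats::runif(n) < p_out, 1, -1)  # +1 = away from soma
      speed <- stats::runif(n, kp$speed_range[1L], kp$speed_range[2L])
      v_px <- dirs * away * speed * kp$dt_s / kp$pixel_size_um  # px per frame
      if (avoid_crossings) {
        lane_w <- nx / n
        lane_lo <- (seq_len(n) - 1) * lane_w + 4
        lane_hi <- seq_len(n) * lane_w - 4
        if (any(lane_hi - lane_lo < 2)) {
          stop("too many comets for crossing-free lanes")
        }
        t0 <- stats::runif(n, 0, kp$duration_s * 0.3)
        x0 <- ifelse(v_px > 0, lane_lo, lane_hi)
        life <- pmin(kp$lifetime_s,
                     (lane_hi - lane_lo) * kp$pixel_size_um / speed * 0.95)
      } else {
        t0 <- stats::runif(n, 0, kp$duration_s * 0.7)
        x0 <- stats::runif(n, 5, nx - 5)
        life <- pmin(stats::rexp(n, 1 / kp$lifetime_s) + 2, kp$duration_s)
      }
      t1 <- pmin(t0 + life, kp$duration_s)
      truth <- data.frame(t_birth = t0, t_death = t1, x0_px = x0,
                          velocity = dirs * speed, direction = dirs)
    }

    img <- matrix(0, nrow = nt, ncol = nx)
    cols <- seq_len(nx)
    if (n > 0L) {
      for (i in seq_len(n)) {
        fr0 <- max(1L, as.integer(ceiling(truth$t_birth[i] / kp$dt_s)) + 1L)
        fr1 <- min(nt, as.integer(floor(truth$t_death[i] / kp$dt_s)) + 1L)
        if (fr1 < fr0) next
        for (fr in fr0:fr1) {
          tt <- (fr - 1L) * kp$dt_s
          cx <- truth$x0_px[i] + v_px[i] * (tt - truth$t_birth[i]) / kp$dt_s
          if (cx < 1 || cx > nx) next
          img[fr, ] <- img[fr, ] +
            kp$amplitude * exp(-(cols - cx)^2 / (2 * kp$psf_sd_px^2))
        }
      }
    }
    if (kp$background > 0) {
      img <- img + matrix(stats::rpois(nt * nx, kp$background), nt, nx)
    }

    list(kymo = kymograph(img, dt = kp$dt_s, pixel_size = kp$pixel_size_um,
                          region = region, soma_side = soma_side),
         truth = if (is.null(truth)) {
           data.frame(t_birth = numeric(0), t_death = numeric(0),
                      x0_px = numeric(0), velocity = numeric(0),
                      direction = numeric(0))
         } else truth)
  })
}

#' Simulate FRAP traces with ground truth
#'
#' Traces follow the bleach-recovery protocol: pre-bleach frames at
#' normalized intensity 1 (t < 0), a bleach drop to `f0` at t = 0, then
#' single-exponential recovery `f0 + (f_inf - f0)(1 - exp(-t/tau))` sampled
#' every second for `duration_s` seconds, with additive Gaussian noise.
#'
#' @param profile a [genotype_profile()] with a `frap` parameter list.
#' @param n_traces number of animals/traces.
#' @param seed master seed (per-trace seeds derived deterministically).
#' @param n_pre pre-bleach frames (default 5, at t = -n_pre..-1 s).
#' @param duration_s post-bleach duration (default 300 s, sampled at 1 s).
#' @return list with `traces` (long data.frame: `t`, `intensity`,
#'   `animal_id`, `genotype`) and `truth` (per-trace f0, f_inf, tau).
#' @export
simulate_frap <- function(profile, n_traces, seed, n_pre = 5,
                          duration_s = 300) {
  fp <- profile$frap
  stopifnot(fp$tau > 0, fp$f0 >= 0, fp$f_inf >= fp$f0)
  tt <- c(seq(-n_pre, -1), seq(0, duration_s))
  model <- ifelse(tt < 0, 1,
                  fp$f0 + (fp$f_inf - fp$f0) * (1 - exp(-tt / fp$tau)))
  traces <- lapply(seq_len(n_traces), function(i) {
    .with_seed(.derive_seed(seed, i), {
      data.frame(t = tt,
                 intensity = model + stats::rnorm(length(tt), 0, fp$noise_sd),
                 animal_id = sprintf("%s_%03d", profile$label, i),
                 genotype = profile$label,
                 stringsAsFactors = FALSE)
    })
  })
  list(traces = do.call(rbind, traces),
       truth = data.frame(animal_id = sprintf("%s_%03d", profile$label,
                                              seq_len(n_traces)),
                          f0 = fp$f0, f_inf = fp$f_inf, tau = fp$tau))
}
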