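#' Normalize a FRAP trace to its pre-bleach mean
#'
#' Traces follow the bleach protocol: pre-bleach frames at t < 0, bleach at
#' t = 0, post-bleach sampling every second. Intensities are divided by the
#' mean pre-bleach intensity, so the pre-bleach level maps to 1 and the
#' normalization is idempotent and absorbs any affine gain of the detector.
#'
#' @param trace data.frame with columns `t` (seconds, negative = pre-bleach)
#'   and `intensity`; other columns are preserved.
#' @return the trace with `intensity` normalized.
#' @export
normalize_trace <- function(trace) {
  stopifnot(all(c("t", "intensity") %in% names(trace)))
  pre <- trace$intensity[trace$t < 0]
  if (length(pre) == 0L) stop("no pre-bleach frames (t < 0)")
  m <- mean(pre)
  if (!is.finite(m) || m <= 0) stop("pre-bleach mean must be positive")
  trace$intensity <- trace$intensity / m
  trace
}

#' Fit single-exponential FRAP recovery
#'
#' Least-squares fit of `F(t) = f0 + (f_inf - f0) * (1 - exp(-t / tau))`
#' over the post-bleach frames of a normalized trace. `f0` is the
#' immediate post-bleach floor, `f_inf` the recovery plateau, and `tau` the
#' recovery time constant; the mobile fraction is
#' `(min(f_inf, 1) - f0) / (1 - f0)` (the plateau is clamped to the
#' pre-bleach level, since noise can push it above 1). Starting values are
#' `f0` = first post-bleach intensity, `f_inf` = mean of the last decile,
#' and `tau` = time to half recovery.
#'
#' @param trace a [normalize_trace()]d trace with >= 10 post-bleach frames.
#' @return list of class `frap_fit`: `f0`, `f_inf`, `tau` (s),
#'   `mobile_fraction`, `rss`, `n_post`. A flat trace returns `f_inf = f0`,
#'   `tau = Inf` and mobile fraction 0. Non-convergence raises an error
#'   carrying the starting values and initial residual in the condition.
#' @export
fit_recovery <- function(trace) {
  post <- trace[trace$t >= 0, , drop = FALSE]
  post <- post[order(post$t), , drop = FALSE]
  if (nrow(post) < 10L) stop("need at least 10 post-bleach frames")
  tt <- post$t
  yy <- post$intensity

  f0_init <- yy[1L]
  tail_n <- max(1L, ceiling(length(yy) / 10))
  finf_init <- mean(yy[(length(yy) - tail_n + 1L):length(yy)])

  if (abs(finf_init - f0_init) < 1e-10 && stats::sd(yy) < 1e-10) {
    # no recovery at all: degenerate but well-defined fit
    return(structure(list(f0 = mean(yy), f_inf = mean(yy), tau = Inf,
                          mobile_fraction = 0, rss = sum((yy - mean(yy))^2),
                          n_post = length(yy)),
                     class = "frap_fit"))
  }

  half <- f0_init + (finf_init - f0_init) / 2
  idx_half <- which(yy >= half)
  tau_init <- if (length(idx_half) > 0L && tt[idx_half[1L]] > 0) {
    tt[idx_half[1L]]
  } else {
    max(tt) / 4
  }

  start <- list(f0 = f0_init, f_inf = finf_init, tau = tau_init)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      yy ~ f0 + (f_inf - f0) * (1 - exp(-tt / tau)),
      start = start,
      lower = c(f0 = -Inf, f_inf = -Inf, tau = 1e-9),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) {
      model0 <- start$f0 + (start$f_inf - start$f0) * (1 - exp(-tt / start$tau))
      stop(errorCondition(
        paste0("FRAP fit did not converge: ", conditionMessage(e)),
        class = c("frap_fit_error", "error", "condition"),
        start = start, initial_rss = sum((yy - model0)^2)
      ))
    }
  )
  cf <- stats::coef(fit)
  f0 <- unname(cf["f0"]); f_inf <- unname(cf["f_inf"]); tau <- unname(cf["tau"])
  plateau <- min(f_inf, 1)
  mf <- if (f0 >= 1) 0 else (plateau - f0) / (1 - f0)
  structure(list(f0 = f0, f_inf = f_inf, tau = tau,
                 mobile_fraction = max(0, min(1, mf)),
                 rss = sum(stats::residuals(fit)^2), n_post = length(yy)),
            class = "frap_fit")
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf("frap_fit: f0 = %.3f, f_inf = %.3f, tau = %.1f s, mobile fraction = %.2f\n",
              x$f0, x$f_inf, x$tau, x$mobile_fraction))
  invisible(x)
}

#' Compare FRAP recovery between two groups
#'
#' Normalizes every trace, interpolates all post-bleach intensities onto the
#' common time grid, and compares the groups with a two-way ANOVA (factors:
#' genotype and time), the standard analysis for recovery curves. Also
#' returns per-timepoint group means and SEM.
#'
#' @param groupA,groupB long data.frames of traces (`t`, `intensity`,
#'   `animal_id`), each with at least 2 animals.
#' @param labels group labels (length 2).
#' @param t_step grid spacing in seconds for the common post-bleach grid.
#' @return list with `anova` (an [two_way_anova()] table with A = genotype,
#'   B = time), `means` (per group x timepoint mean and SEM), and `fits`
#'   (per-animal [fit_recovery()] parameters).
#' @export
compare_recovery <- function(groupA, groupB, labels = c("A", "B"),
                             t_step = 10) {
  prep <- function(g, lab) {
    ids <- unique(g$animal_id)
    if (length(ids) < 2L) {
      stop(sprintf("group %s has %d animal(s); need at least 2", lab,
                   length(ids)))
    }
    lapply(ids, function(a) {
      tr <- normalize_trace(g[g$animal_id == a, , drop = FALSE])
      tr[tr$t >= 0, , drop = FALSE]
    })
  }
  trA <- prep(groupA, labels[1L])
  trB <- prep(groupB, labels[2L])

  tmax <- min(vapply(c(trA, trB), function(tr) max(tr$t), numeric(1)))
  grid <- seq(0, tmax, by = t_step)

  sample_rows <- function(traces, lab) {
    do.call(rbind, lapply(seq_along(traces), function(i) {
      tr <- traces[[i]]
      data.frame(value = stats::approx(tr$t, tr$intensity, xout = grid)$y,
                 A = lab, B = grid,
                 replicate = paste0(lab, "_", i), stringsAsFactors = FALSE)
    }))
  }
  d <- rbind(sample_rows(trA, labels[1L]), sample_rows(trB, labels[2L]))
  fs <- factorial_sample(d$value, d$A, d$B, d$replicate)
  aov_tab <- two_way_anova(fs)  # animals replicate within genotype x time

  agg <- stats::aggregate(value ~ A + B, d, function(v) {
    c(mean = mean(v), sem = stats::sd(v) / sqrt(length(v)))
  })
  means <- data.frame(group = agg$A, t = agg$B,
                      mean = agg$value[, "mean"], sem = agg$value[, "sem"])

  fits <- lapply(c(trA, trB), function(tr) {
    tryCatch(fit_recovery(tr), error = function(e) NULL)
  })
  list(anova = aov_tab, means = means, fits = fits)
}
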