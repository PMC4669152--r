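# Factorial designs ----------------------------------------------------------

#' Construct a two-factor sample
#'
#' Container for observations indexed by two crossed factors (e.g. genotype
#' and dendritic region, or genotype and time), as used by the two-way ANOVA
#' and Tukey procedures.
#'
#' @param value numeric vector of observations.
#' @param A,B factor (or coercible) vectors of the two factor levels, same
#'   length as `value`.
#' @param replicate optional replicate identifiers (animal ids).
#' @return data.frame of class `factorial_sample` with columns `value`,
#'   `A`, `B`, `replicate`.
#' @export
factorial_sample <- function(value, A, B, replicate = seq_along(value)) {
  stopifnot(length(A) == length(value), length(B) == length(value))
  if (!is.numeric(value) || anyNA(value)) stop("value must be numeric, no NAs")
  A <- factor(A)
  B <- factor(B)
  if (nlevels(A) < 2L || nlevels(B) < 2L) {
    stop("each factor needs at least 2 levels")
  }
  structure(
    data.frame(value = value, A = A, B = B,
               replicate = as.character(replicate),
               stringsAsFactors = FALSE),
    class = c("factorial_sample", "data.frame")
  )
}

# residual sum of squares of a least-squares fit of value on a model matrix,
# plus the matrix rank (QR-based, tolerant of rank deficiency)
.rss_fit <- function(X, y) {
  fit <- stats::lm.fit(X, y)
  list(rss = sum(fit$residuals^2), rank = fit$rank)
}

#' Two-way ANOVA (type-II sums of squares)
#'
#' Crossed two-factor analysis of variance computed from nested linear-model
#' fits: the type-II sum of squares for each main effect is the reduction in
#' residual sum of squares when that effect is added to the model already
#' containing the other main effect; the interaction is the further
#' reduction from adding the crossed term. On balanced designs this equals
#' the classical (type-I/III) decomposition and `SS_total = sum(SS)`
#' exactly; on unbalanced cohorts (animal numbers vary by genotype) type-II
#' is the conventional choice.
#'
#' @param sample a [factorial_sample()] (or data.frame with columns `value`,
#'   `A`, `B`).
#' @param interaction include the A:B interaction term (default `TRUE`).
#'   With the interaction, every A x B cell must be occupied.
#' @return data.frame of class `anova_table` with rows `A`, `B`, `A:B`,
#'   `Residuals` and columns `SS`, `df`, `MS`, `F`, `p`. The residual mean
#'   square, residual df and the input data are attached as attributes for
#'   use by [tukey_hsd()].
#' @export
two_way_anova <- function(sample, interaction = TRUE) {
  d <- as.data.frame(sample)
  stopifnot(all(c("value", "A", "B") %in% names(d)))
  d$A <- factor(d$A)
  d$B <- factor(d$B)
  y <- d$value

  if (interaction) {
    cells <- table(d$A, d$B)
    if (any(cells == 0L)) {
      empty <- which(cells == 0L, arr.ind = TRUE)[1L, ]
      stop(sprintf("empty design cell A=%s, B=%s: cannot fit the interaction",
                   rownames(cells)[empty[1L]], colnames(cells)[empty[2L]]))
    }
  }

  X0 <- stats::model.matrix(~ 1, d)
  XA <- stats::model.matrix(~ A, d)
  XB <- stats::model.matrix(~ B, d)
  XAB <- stats::model.matrix(~ A + B, d)
  Xfull <- if (interaction) stats::model.matrix(~ A * B, d) else XAB

  fA <- .rss_fit(XA, y)
  fB <- .rss_fit(XB, y)
  fAB <- .rss_fit(XAB, y)
  ffull <- .rss_fit(Xfull, y)

  ss_a <- fB$rss - fAB$rss          # A adjusted for B (type II)
  ss_b <- fA$rss - fAB$rss
  df_a <- fAB$rank - fB$rank
  df_b <- fAB$rank - fA$rank
  ss_res <- ffull$rss
  df_res <- length(y) - ffull$rank
  if (df_res < 2L) stop("fewer than 2 residual degrees of freedom")

  rows <- list(
    A = c(SS = max(ss_a, 0), df = df_a),
    B = c(SS = max(ss_b, 0), df = df_b)
  )
  if (interaction) {
    rows[["A:B"]] <- c(SS = max(fAB$rss - ffull$rss, 0),
                       df = ffull$rank - fAB$rank)
  }
  rows[["Residuals"]] <- c(SS = ss_res, df = df_res)

  tab <- do.call(rbind, rows)
  tab <- data.frame(term = rownames(tab), SS = tab[, "SS"], df = tab[, "df"],
                    row.names = NULL, stringsAsFactors = FALSE)
  tab$MS <- tab$SS / tab$df
  ms_res <- tab$MS[tab$term == "Residuals"]
  tab$F <- ifelse(tab$term == "Residuals", NA,
                  tab$MS / ms_res)
  tab$p <- ifelse(tab$term == "Residuals", NA,
                  stats::pf(tab$F, tab$df, df_res, lower.tail = FALSE))
  structure(tab, class = c("anova_table", "data.frame"),
            ms_residual = ms_res, df_residual = df_res, data = d)
}

#' Tukey honestly-significant-difference pairwise comparisons
#'
#' All pairwise comparisons between the levels of one factor of a two-factor
#' design, using the studentized-range distribution with the residual mean
#' square of the two-way ANOVA (Tukey-Kramer standard errors for unequal
#' group sizes). Adjusted p-values are
#' `ptukey(|diff| / SE_q, k, df_res)` and simultaneous confidence intervals
#' use `qtukey(1 - alpha, k, df_res)`.
#'
#' @param sample a [factorial_sample()], or an [two_way_anova()] result
#'   (whose attached data are reused).
#' @param factor which factor to compare, `"A"` or `"B"`.
#' @param alpha simultaneous error rate for the confidence intervals.
#' @param interaction passed to [two_way_anova()] when `sample` is raw data.
#' @return data.frame with one row per level pair: `level_1`, `level_2`,
#'   `diff` (level_1 minus level_2), `lwr`, `upr`, `p_adj`.
#' @export
tukey_hsd <- function(sample, factor = c("A", "B"), alpha = 0.05,
                      interaction = TRUE) {
  factor <- match.arg(factor)
  tab <- if (inherits(sample, "anova_table")) sample
         else two_way_anova(sample, interaction = interaction)
  d <- attr(tab, "data")
  ms <- attr(tab, "ms_residual")
  df_res <- attr(tab, "df_residual")
  f <- d[[factor]]
  levs <- levels(f)
  k <- length(levs)
  if (k < 2L) stop("factor has fewer than 2 levels")
  means <- as.vector(tapply(d$value, f, mean))   # in level order
  ns <- as.vector(tapply(d$value, f, length))

  pairs <- utils::combn(k, 2)
  out <- data.frame(
    level_1 = levs[pairs[2L, ]], level_2 = levs[pairs[1L, ]],
    stringsAsFactors = FALSE
  )
  se_q <- sqrt(ms / 2 * (1 / ns[pairs[1L, ]] + 1 / ns[pairs[2L, ]]))
  out$diff <- unname(means[pairs[2L, ]] - means[pairs[1L, ]])
  qcrit <- stats::qtukey(1 - alpha, k, df_res)
  out$lwr <- out$diff - qcrit * se_q
  out$upr <- out$diff + qcrit * se_q
  out$p_adj <- stats::ptukey(abs(out$diff) / se_q, k, df_res,
                             lower.tail = FALSE)
  out
}

#' Welch t-tests over a collection of group pairs
#'
#' One Welch (unequal-variance) t-test per pair, reported unadjusted to
#' match the Prism-style "multiple t-tests" convention, with a Holm-adjusted
#' column added for transparency. Degenerate pairs (a group with fewer than
#' 2 observations, or both groups with zero variance) are flagged rather
#' than raised.
#'
#' @param pairs named list; each element is a list or data.frame with
#'   elements/columns `x` and `y`, the two groups' observations.
#' @return data.frame with one row per pair: `pair`, `mean_x`, `mean_y`,
#'   `t`, `df`, `p`, `p_holm`, `note`.
#' @export
multiple_t_tests <- function(pairs) {
  if (is.null(names(pairs))) names(pairs) <- paste0("pair", seq_along(pairs))
  one <- function(x, y) {
    nx <- length(x); ny <- length(y)
    if (nx < 2L || ny < 2L) {
      return(data.frame(mean_x = mean(x), mean_y = mean(y), t = NA, df = NA,
                        p = NA, note = "group with n < 2"))
    }
    vx <- stats::var(x); vy <- stats::var(y)
    if (vx == 0 && vy == 0) {
      return(data.frame(mean_x = mean(x), mean_y = mean(y), t = NA, df = NA,
                        p = NA, note = "zero variance in both groups"))
    }
    se2 <- vx / nx + vy / ny
    tstat <- (mean(x) - mean(y)) / sqrt(se2)
    df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
    data.frame(mean_x = mean(x), mean_y = mean(y), t = tstat, df = df,
               p = 2 * stats::pt(-abs(tstat), df), note = "")
  }
  rows <- lapply(pairs, function(p) one(p$x, p$y))
  out <- cbind(data.frame(pair = names(pairs), stringsAsFactors = FALSE),
               do.call(rbind, rows))
  rownames(out) <- NULL
  out$p_holm <- NA_real_
  valid <- !is.na(out$p)
  out$p_holm[valid] <- stats::p.adjust(out$p[valid], method = "holm")
  out[, c("pair", "mean_x", "mean_y", "t", "df", "p", "p_holm", "note")]
}

# Penetrance ------------------------------------------------------------------

#' Exact binomial (Clopper-Pearson) interval for a phenotype fraction
#'
#' @param n_phenotypic number of animals scored phenotypic.
#' @param n_total cohort size.
#' @param conf confidence level (default 0.95).
#' @return list of class `penetrance_result`: `n_total`, `n_phenotypic`,
#'   `fraction`, `ci_lo`, `ci_hi`, `conf`.
#' @export
penetrance_ci <- function(n_phenotypic, n_total, conf = 0.95) {
  if (n_total < 1L) stop("empty cohort")
  stopifnot(n_phenotypic >= 0L, n_phenotypic <= n_total)
  a <- 1 - conf
  lo <- if (n_phenotypic == 0L) 0 else
    stats::qbeta(a / 2, n_phenotypic, n_total - n_phenotypic + 1)
  hi <- if (n_phenotypic == n_total) 1 else
    stats::qbeta(1 - a / 2, n_phenotypic + 1, n_total - n_phenotypic)
  structure(
    list(n_total = n_total, n_phenotypic = n_phenotypic,
         fraction = n_phenotypic / n_total, ci_lo = lo, ci_hi = hi,
         conf = conf),
    class = "penetrance_result"
  )
}

#' @export
print.penetrance_result <- function(x, ...) {
  cat(sprintf("penetrance: %d/%d = %.3f (exact %d%% CI [%.3f, %.3f])\n",
              x$n_phenotypic, x$n_total, x$fraction, round(100 * x$conf),
              x$ci_lo, x$ci_hi))
  invisible(x)
}

#' Penetrance of a branch-complexity phenotype in a cohort
#'
#' Scores each animal in a cohort as phenotypic or not by a threshold rule
#' on its per-region branch complexity index, then returns the phenotypic
#' fraction with an exact binomial confidence interval. The default rule
#' declares an animal phenotypic when its complexity falls below a fraction
#' of the wild-type reference mean in every one of the stated regions
#' (by default the posterior-proximal regions -1 and +1, where the classic
#' loss-of-branching phenotype manifests).
#'
#' @param cohort data.frame with one row per (animal, region): columns
#'   `animal_id`, `region`, `bci` (as produced by [quantify_arbor()] /
#'   [run_quantify()]).
#' @param reference either a data.frame of the same shape for the wild-type
#'   reference cohort, or a named numeric vector of per-region reference
#'   mean complexity.
#' @param regions regions that must all fall below threshold
#'   (default `c("-1", "+1")`).
#' @param frac threshold as a fraction of the reference mean (default 0.5).
#' @param conf confidence level for the interval.
#' @return a [penetrance_ci()] result with the per-animal calls attached as
#'   attribute `calls`.
#' @export
penetrance <- function(cohort, reference, regions = c("-1", "+1"),
                       frac = 0.5, conf = 0.95) {
  stopifnot(all(c("animal_id", "region", "bci") %in% names(cohort)))
  if (nrow(cohort) == 0L) stop("empty cohort")
  if (is.data.frame(reference)) {
    ref_means <- tapply(reference$bci, as.character(reference$region), mean)
  } else {
    ref_means <- reference
  }
  if (!all(regions %in% names(ref_means))) {
    stop("reference lacks regions: ",
         paste(setdiff(regions, names(ref_means)), collapse = ", "))
  }
  animals <- unique(cohort$animal_id)
  call_one <- function(aid) {
    sub <- cohort[cohort$animal_id == aid, ]
    all(vapply(regions, function(r) {
      b <- sub$bci[as.character(sub$region) == r]
      length(b) == 1L && b < frac * ref_means[[r]]
    }, logical(1)))
  }
  calls <- vapply(animals, call_one, logical(1))
  res <- penetrance_ci(sum(calls), length(calls), conf = conf)
  attr(res, "calls") <- stats::setNames(calls, animals)
  res
}
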