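#' Construct a kymograph
#'
#' A kymograph is a single-channel time-by-position intensity image: rows
#' are frames (default 0.125 s apart, i.e. 8 frames per second), columns are
#' positions along the dendrite at a fixed pixel size.
#'
#' @param img numeric matrix, rows = time, columns = position; finite and
#'   non-negative.
#' @param dt frame interval in seconds (default 0.125).
#' @param pixel_size position sampling in micrometres per pixel.
#' @param region dendritic region label (`-1`, `+1`, `+2`, `+3`, `axon`).
#' @param soma_side which column edge points toward the soma: `"left"`
#'   (column 1) or `"right"`.
#' @return object of class `kymograph`.
#' @export
kymograph <- function(img, dt = 0.125, pixel_size = 0.2,
                      region = NA_character_, soma_side = c("left", "right")) {
  soma_side <- match.arg(soma_side)
  img <- as.matrix(img)
  if (!all(is.finite(img)) || any(img < 0)) {
    stop("kymograph intensities must be finite and non-negative")
  }
  stopifnot(dt > 0, pixel_size > 0)
  structure(list(img = img, dt = dt, pixel_size = pixel_size,
                 region = region, soma_side = soma_side),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("kymograph: %d frames x %d px (dt %.3f s, %.2f um/px, region %s, soma %s)\n",
              nrow(x$img), ncol(x$img), x$dt, x$pixel_size, x$region,
              x$soma_side))
  invisible(x)
}

#' Mirror a kymograph's position axis
#'
#' Flips the columns and the `soma_side` label. Because comet direction is
#' defined relative to the soma, detection on the mirrored kymograph yields
#' identical soma-relative velocities.
#'
#' @param kymo a [kymograph()].
#' @return the mirrored [kymograph()].
#' @export
mirror_kymograph <- function(kymo) {
  kymograph(kymo$img[, rev(seq_len(ncol(kymo$img))), drop = FALSE],
            dt = kymo$dt, pixel_size = kymo$pixel_size, region = kymo$region,
            soma_side = if (kymo$soma_side == "left") "right" else "left")
}

#' Write / read a kymograph as single-channel TIFF
#'
#' Intensities are stored as 32-bit float samples; `dt`, `pixel_size`,
#' `region` and `soma_side` are supplied by the caller on read (TIFF tags
#' are not used).
#'
#' @param kymo a [kymograph()].
#' @param path TIFF file path.
#' @rdname kymograph_io
#' @export
write_kymograph <- function(kymo, path) {
  tiff::writeTIFF(kymo$img, path, bits.per.sample = 32L)
  invisible(path)
}

#' @param dt,pixel_size,region,soma_side acquisition metadata, as for
#'   [kymograph()].
#' @rdname kymograph_io
#' @export
read_kymograph <- function(path, dt = 0.125, pixel_size = 0.2,
                           region = NA_character_, soma_side = "left") {
  img <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  kymograph(img, dt = dt, pixel_size = pixel_size, region = region,
            soma_side = soma_side)
}

#' Comet detection parameters
#'
#' @param k_mad robust threshold: peaks must exceed
#'   `median + k_mad * MAD` of the whole image.
#' @param min_run minimum track length in frames.
#' @param max_disp maximum per-frame displacement for linking, pixels.
#' @param max_gap frames a track may go undetected before being closed.
#' @param v_min minimum |velocity| (um/s) for a track to count as a directed
#'   movement in polarity classification; slower tracks are stalled comets.
#' @return list of class `detection_params`.
#' @export
detection_params <- function(k_mad = 3, min_run = 5, max_disp = 3,
                             max_gap = 2, v_min = 0.02) {
  stopifnot(k_mad > 0, min_run >= 2, max_disp > 0, max_gap >= 0, v_min >= 0)
  structure(list(k_mad = k_mad, min_run = min_run, max_disp = max_disp,
                 max_gap = max_gap, v_min = v_min),
            class = "detection_params")
}

# sub-pixel peak centre by log-parabolic interpolation: exact for an
# isolated Gaussian profile
.subpixel <- function(row, j) {
  l <- row[j - 1L]; c <- row[j]; r <- row[j + 1L]
  if (l <= 0 || r <= 0 || c <= 0) return(j)
  ll <- log(l); lc <- log(c); lr <- log(r)
  den <- ll - 2 * lc + lr
  if (!is.finite(den) || abs(den) < 1e-12) return(j)
  d <- 0.5 * (ll - lr) / den
  j + max(-1, min(1, d))
}

#' Detect EB-comet tracks in a kymograph
#'
#' Per-frame bright peaks (local maxima above a robust `median + k * MAD`
#' threshold, refined to sub-pixel by log-parabolic interpolation) are
#' linked frame-to-frame by nearest neighbour within a displacement gate,
#' and each run of linked peaks at least `min_run` frames long is fitted
#' with a least-squares line whose slope gives the comet velocity. Velocity
#' is signed soma-relative: positive = anterograde (away from the soma).
#'
#' @param kymo a [kymograph()].
#' @param params a [detection_params()] list.
#' @return data.frame of class `comet_tracks`, one row per track: `track_id`,
#'   `t0`, `x0`, `t1`, `x1` (s and um), `n_frames`, `velocity` (um/s,
#'   positive away from soma). Attributes `region` and `soma_side` carry the
#'   kymograph's labels. A blank image yields zero rows.
#' @export
detect_comets <- function(kymo, params = detection_params()) {
  img <- kymo$img
  nt <- nrow(img); nx <- ncol(img)
  if (nt < params$min_run) stop("kymograph shorter than min_run frames")
  thr <- stats::median(img) + params$k_mad * stats::mad(img)

  # per-frame peak lists (sub-pixel column positions)
  peaks <- vector("list", nt)
  for (fr in seq_len(nt)) {
    row <- img[fr, ]
    if (nx >= 3L) {
      j <- 2L:(nx - 1L)
      is_peak <- row[j] > thr & row[j] >= row[j - 1L] & row[j] > row[j + 1L]
      pk <- j[is_peak]
      peaks[[fr]] <- vapply(pk, function(jj) .subpixel(row, jj), numeric(1))
    } else {
      peaks[[fr]] <- numeric(0)
    }
  }

  # greedy nearest-neighbour linking with gap tolerance
  active <- list()   # each: list(frames, xs, last_frame)
  done <- list()
  for (fr in seq_len(nt)) {
    px <- peaks[[fr]]
    taken <- rep(FALSE, length(px))
    keep <- logical(length(active))
    if (length(active) > 0L) {
      # match tracks in order of recency
      ord <- order(vapply(active, function(t) as.numeric(t$last_frame),
                          numeric(1)), decreasing = TRUE)
      for (ti in ord) {
        tr <- active[[ti]]
        gap <- fr - tr$last_frame
        if (gap > params$max_gap + 1L) next
        if (length(px) > 0L && any(!taken)) {
          cand <- which(!taken)
          d <- abs(px[cand] - tr$xs[length(tr$xs)])
          best <- which.min(d)
          if (d[best] <= params$max_disp * gap) {
            jj <- cand[best]
            tr$frames <- c(tr$frames, fr)
            tr$xs <- c(tr$xs, px[jj])
            tr$last_frame <- fr
            active[[ti]] <- tr
            taken[jj] <- TRUE
            keep[ti] <- TRUE
            next
          }
        }
        keep[ti] <- gap <= params$max_gap  # stays active through a gap
      }
      done <- c(done, active[!keep])
      active <- active[keep]
    }
    for (jj in which(!taken)) {
      active[[length(active) + 1L]] <- list(frames = fr, xs = px[jj],
                                            last_frame = fr)
    }
  }
  done <- c(done, active)

  away <- if (kymo$soma_side == "left") 1 else -1
  rows <- list()
  for (tr in done) {
    if (length(tr$frames) < params$min_run) next
    tt <- (tr$frames - 1) * kymo$dt
    xx <- (tr$xs - 1) * kymo$pixel_size
    slope <- stats::cov(tt, xx) / stats::var(tt)
    v <- away * slope
    if (!is.finite(v) || v == 0) next
    rows[[length(rows) + 1L]] <- data.frame(
      t0 = tt[1L], x0 = xx[1L], t1 = tt[length(tt)], x1 = xx[length(xx)],
      n_frames = length(tr$frames), velocity = v
    )
  }
  out <- if (length(rows) > 0L) {
    cbind(track_id = seq_along(rows), do.call(rbind, rows))
  } else {
    data.frame(track_id = integer(0), t0 = numeric(0), x0 = numeric(0),
               t1 = numeric(0), x1 = numeric(0), n_frames = integer(0),
               velocity = numeric(0))
  }
  structure(out, class = c("comet_tracks", "data.frame"),
            region = kymo$region, soma_side = kymo$soma_side,
            v_min = params$v_min)
}

#' Classify microtubule polarity from comet tracks
#'
#' EB comets mark growing microtubule plus ends, so a comet moving away from
#' the soma reports a plus-end-out microtubule at that location. Tracks
#' slower than `v_min` are stalled comets and excluded from the directed
#' counts.
#'
#' @param tracks a [detect_comets()] table (or any data.frame with a
#'   `velocity` column signed positive away from the soma).
#' @param region region label (defaults to the tracks' attribute).
#' @param v_min stalled-comet threshold, um/s.
#' @return list of class `polarity_result`: `region`, `n_anterograde`,
#'   `n_retrograde`, `plus_end_out_fraction` (NA and `defined = FALSE` when
#'   there are no directed tracks).
#' @export
classify_polarity <- function(tracks, region = attr(tracks, "region"),
                              v_min = attr(tracks, "v_min")) {
  if (is.null(v_min)) v_min <- 0.02
  v <- tracks$velocity
  v <- v[is.finite(v) & abs(v) >= v_min]
  n_a <- sum(v > 0)
  n_r <- sum(v < 0)
  structure(
    list(region = region, n_anterograde = n_a, n_retrograde = n_r,
         plus_end_out_fraction = if (n_a + n_r > 0) n_a / (n_a + n_r) else NA_real_,
         defined = n_a + n_r > 0),
    class = "polarity_result"
  )
}

#' @export
print.polarity_result <- function(x, ...) {
  if (x$defined) {
    cat(sprintf("polarity [%s]: %d anterograde / %d retrograde, plus-end-out %.2f\n",
                x$region, x$n_anterograde, x$n_retrograde,
                x$plus_end_out_fraction))
  } else {
    cat(sprintf("polarity [%s]: no directed tracks (undefined)\n", x$region))
  }
  invisible(x)
}

#' Summarize polarity across genotypes and regions
#'
#' Pools comet counts per (genotype, region) group and tests the pooled
#' plus-end-out fraction against 0.5 with a two-sided exact binomial test.
#' Groups with no defined results are omitted with a warning.
#'
#' @param results list of [classify_polarity()] results.
#' @param genotype character vector, one label per result.
#' @return data.frame: `genotype`, `region`, `n_anterograde`,
#'   `n_retrograde`, `plus_end_out_fraction`, `p_binomial`.
#' @export
polarity_summary <- function(results, genotype) {
  stopifnot(length(results) == length(genotype))
  keys <- paste(genotype, vapply(results, `[[`, character(1), "region"),
                sep = "\r")
  rows <- list()
  for (k in unique(keys)) {
    grp <- results[keys == k]
    grp <- grp[vapply(grp, `[[`, logical(1), "defined")]
    parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
    if (length(grp) == 0L) {
      warning(sprintf("group %s / %s has no directed tracks; omitted",
                      parts[1L], parts[2L]))
      next
    }
    n_a <- sum(vapply(grp, function(g) as.numeric(g$n_anterograde), numeric(1)))
    n_r <- sum(vapply(grp, function(g) as.numeric(g$n_retrograde), numeric(1)))
    rows[[length(rows) + 1L]] <- data.frame(
      genotype = parts[1L], region = parts[2L],
      n_anterograde = n_a, n_retrograde = n_r,
      plus_end_out_fraction = n_a / (n_a + n_r),
      p_binomial = stats::binom.test(n_a, n_a + n_r, p = 0.5)$p.value,
      stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0L) {
    return(data.frame(genotype = character(0), region = character(0),
                      n_anterograde = integer(0), n_retrograde = integer(0),
                      plus_end_out_fraction = numeric(0),
                      p_binomial = numeric(0)))
  }
  do.call(rbind, rows)
}
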