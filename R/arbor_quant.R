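# Internal tree helpers ------------------------------------------------------

# child indices per node, as a list parallel to nodes rows
.children_index <- function(nodes) {
  n <- nrow(nodes)
  kids <- vector("list", n)
  pidx <- match(nodes$parent, nodes$id)
  for (i in seq_len(n)) {
    p <- pidx[i]
    if (!is.na(p)) kids[[p]] <- c(kids[[p]], i)
  }
  kids
}

# Euclidean length of the edge from each node to its parent (NA at root)
.edge_lengths <- function(nodes) {
  pidx <- match(nodes$parent, nodes$id)
  dx <- nodes$x - nodes$x[pidx]
  dy <- nodes$y - nodes$y[pidx]
  dz <- nodes$z - nodes$z[pidx]
  sqrt(dx^2 + dy^2 + dz^2)
}

# index chain from node i up to the root (inclusive)
.chain_to_root <- function(pidx, i) {
  out <- i
  while (!is.na(pidx[i])) {
    i <- pidx[i]
    out <- c(out, i)
  }
  out
}

# node-index path between a and b in the tree (via their common ancestor)
.tree_path <- function(pidx, a, b) {
  ca <- .chain_to_root(pidx, a)
  cb <- .chain_to_root(pidx, b)
  common <- intersect(ca, cb)
  anc <- common[1L]  # chains are ordered leaf -> root, first shared is LCA
  up <- ca[seq_len(match(anc, ca))]
  down <- cb[seq_len(match(anc, cb) - 1L)]
  c(up, rev(down))
}

# Primary path extraction -----------------------------------------------------

#' Extract the primary dendrite path
#'
#' The PVD primary dendrite runs along the animal's anterior-posterior (A-P)
#' axis, with one arm anterior of the soma and one posterior. This finds the
#' path through the soma spanning the greatest anterior and posterior
#' extents along the A-P axis (ties broken by total arc length), and
#' parameterizes it by signed arc length (soma = 0, anterior positive).
#' Extent rather than raw arc length identifies the arms because a menorah
#' path near a primary tip accumulates more arc length than the remaining
#' primary while spanning less of the axis. Coordinates are assumed
#' registered so +x is anterior.
#'
#' @param arbor an [arbor_skeleton()].
#' @return An object of class `primary_path`: list with `node_ids` (ordered
#'   posterior tip to anterior tip), `arc_length` (signed, named by node id),
#'   `soma_id`, and anterior/posterior extents `L_a`, `L_p` in micrometres.
#'   If no posterior arm exists, an error of class `degenerate_path_error`
#'   is raised whose condition carries the anterior-only partial path in
#'   `$partial`.
#' @export
extract_primary <- function(arbor) {
  nodes <- arbor$nodes
  pidx <- match(nodes$parent, nodes$id)
  kids <- .children_index(nodes)
  elen <- .edge_lengths(nodes)
  soma <- match(arbor$soma_id, nodes$id)
  tips <- which(vapply(kids, length, integer(1)) == 0L)
  if (length(tips) < 2L && !(length(tips) == 1L && tips[1L] != soma)) {
    stop("skeleton needs at least 2 tips to define a primary path")
  }

  # arc length and subtree (first node after the soma) of each soma->tip path
  tip_info <- lapply(tips, function(t) {
    path <- .tree_path(pidx, soma, t)
    steps <- path[-1L]
    # edge between consecutive path nodes is stored on whichever is the child
    len <- 0
    for (k in seq_along(steps)) {
      a <- path[k]; b <- path[k + 1L]
      len <- len + if (identical(pidx[b], a)) elen[b] else elen[a]
    }
    list(tip = t, path = path, len = len,
         first = if (length(path) > 1L) path[2L] else NA_integer_,
         trend = nodes$x[t] - nodes$x[soma])
  })
  lens <- vapply(tip_info, `[[`, numeric(1), "len")
  trends <- vapply(tip_info, `[[`, numeric(1), "trend")
  firsts <- vapply(tip_info, `[[`, integer(1), "first")

  ant <- which(trends >= 0)
  post <- which(trends < 0)
  if (length(ant) == 0L) stop("no anterior arm: all tips posterior of soma")
  if (length(post) == 0L) {
    best_a <- ant[which.max(lens[ant])]
    stop(errorCondition(
      "no posterior arm: all tips anterior of soma",
      class = c("degenerate_path_error", "error", "condition"),
      partial = tip_info[[best_a]]$path
    ))
  }

  # best anterior/posterior pair leaving the soma through different children;
  # rank by A-P extent, arc length as tie-break
  score <- abs(trends) + lens * 1e-9
  best <- NULL
  ord_a <- ant[order(score[ant], decreasing = TRUE)]
  ord_p <- post[order(score[post], decreasing = TRUE)]
  for (a in ord_a[seq_len(min(6L, length(ord_a)))]) {
    for (p in ord_p[seq_len(min(6L, length(ord_p)))]) {
      if (identical(firsts[a], firsts[p])) next
      if (is.null(best) || score[a] + score[p] > best$total) {
        best <- list(a = a, p = p, total = score[a] + score[p])
      }
    }
  }
  if (is.null(best)) {
    stop("anterior and posterior arms share the soma's only branch")
  }

  path_a <- tip_info[[best$a]]$path   # soma .. anterior tip
  path_p <- tip_info[[best$p]]$path   # soma .. posterior tip
  full <- c(rev(path_p), path_a[-1L])  # posterior tip .. soma .. anterior tip

  # signed cumulative arc length, soma = 0
  arc <- numeric(length(full))
  soma_pos <- match(soma, full)
  seg <- function(a, b) {
    if (identical(pidx[b], a)) elen[b] else elen[a]
  }
  if (soma_pos < length(full)) {
    for (k in (soma_pos + 1L):length(full)) {
      arc[k] <- arc[k - 1L] + seg(full[k - 1L], full[k])
    }
  }
  if (soma_pos > 1L) {
    for (k in (soma_pos - 1L):1L) {
      arc[k] <- arc[k + 1L] - seg(full[k + 1L], full[k])
    }
  }

  structure(
    list(node_ids = nodes$id[full],
         arc_length = stats::setNames(arc, nodes$id[full]),
         soma_id = arbor$soma_id,
         L_a = arc[length(arc)],
         L_p = -arc[1L]),
    class = "primary_path"
  )
}

#' @export
print.primary_path <- function(x, ...) {
  cat(sprintf("primary_path: %d nodes, anterior %.1f um, posterior %.1f um\n",
              length(x$node_ids), x$L_a, x$L_p))
  invisible(x)
}

# Branch-order classification -------------------------------------------------

#' Classification parameters
#'
#' @param theta_t maximum deviation (degrees) of a tertiary branch from the
#'   A-P axis. Children of secondaries within `theta_t` of the axis are
#'   classified tertiary; others are flagged misoriented.
#' @param theta_q minimum deviation (degrees) from the A-P axis for a child
#'   of a tertiary to count as a correctly-oriented quaternary (quaternaries
#'   trend dorsoventral, i.e. orthogonal to the axis).
#' @param theta_c continuation threshold (degrees): at an internal branch
#'   point, the child edge most collinear with the running branch continues
#'   the same branch when it deviates by no more than `theta_c`; all other
#'   children start child branches. This keeps a tertiary arm one branch
#'   across its quaternary attachment points, while a secondary stem still
#'   terminates at the orthogonal T-junction with its two arms.
#' @return list of class `classification_params`.
#' @export
classification_params <- function(theta_t = 45, theta_q = 45, theta_c = 30) {
  stopifnot(theta_t > 0, theta_t < 90, theta_q > 0, theta_q < 90,
            theta_c > 0, theta_c < 90)
  structure(list(theta_t = theta_t, theta_q = theta_q, theta_c = theta_c),
            class = "classification_params")
}

# angle (degrees, in [0, 180]) between two direction vectors
.angle_between <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(180)
  acos(max(-1, min(1, sum(u * v) / (nu * nv)))) * 180 / pi
}

# angle (degrees, in [0, 90]) between a chord vector and the A-P (x) axis
.angle_to_ap <- function(v) {
  nv <- sqrt(sum(v^2))
  if (nv == 0) return(90)
  acos(min(1, abs(v[1]) / nv)) * 180 / pi
}

#' Classify branch orders of an arbor
#'
#' Decomposes the non-primary part of the skeleton into branches and assigns
#' each an order following the menorah scheme: any protrusion from the
#' primary dendrite is a secondary (2°) regardless of length or orientation;
#' a child of a secondary whose chord lies within `theta_t` of the A-P axis
#' is a tertiary (3°); a child of a tertiary deviating from the A-P axis by
#' more than `theta_q` is a correctly-oriented quaternary (4°). Misoriented
#' children of secondaries/tertiaries keep the order label but are flagged
#' (`oriented = FALSE`) and excluded from the oriented counts; branches
#' beyond depth 4 are labelled order 4 and flagged `beyond_depth` with a
#' warning.
#'
#' @param arbor an [arbor_skeleton()].
#' @param primary the [extract_primary()] path of the same arbor.
#' @param params a [classification_params()] list.
#' @return An object of class `classified_arbor`: the skeleton, the primary
#'   path, and `branches`, a data.frame with one row per branch (`branch_id`,
#'   `order`, `parent_branch`, `base_node`, `base_position`,
#'   `base_secondary_position`, `length`, `angle_ap`, `oriented`, `flag`),
#'   plus `branch_nodes`, the node ids of each branch.
#' @export
classify_branch_orders <- function(arbor, primary,
                                   params = classification_params()) {
  nodes <- arbor$nodes
  pidx <- match(nodes$parent, nodes$id)
  kids <- .children_index(nodes)
  elen <- .edge_lengths(nodes)
  prim_idx <- match(primary$node_ids, nodes$id)
  on_primary <- logical(nrow(nodes))
  on_primary[prim_idx] <- TRUE

  branches <- list()
  branch_nodes <- list()
  beyond <- 0L
  pos3 <- function(i) c(nodes$x[i], nodes$y[i], nodes$z[i])

  # walk one branch starting at `start` (child of `base_node`): the chain
  # passes through degree-1 nodes, and at internal branch points continues
  # into the most collinear child when within theta_c; all bypassed children
  # are collected as (attach node, child) pairs to start child branches
  walk <- function(start, base_node) {
    chain <- start
    spawn <- list()
    prev <- base_node
    repeat {
      last <- chain[length(chain)]
      ch <- kids[[last]]
      if (length(ch) == 0L) break
      if (length(ch) == 1L) {
        chain <- c(chain, ch)
        prev <- last
        next
      }
      run_dir <- pos3(last) - pos3(prev)
      angs <- vapply(ch, function(c2) {
        .angle_between(pos3(c2) - pos3(last), run_dir)
      }, numeric(1))
      best <- which.min(angs)
      if (angs[best] <= params$theta_c) {
        for (c2 in ch[-best]) {
          spawn[[length(spawn) + 1L]] <- c(attach = last, child = c2)
        }
        chain <- c(chain, ch[best])
        prev <- last
      } else {
        for (c2 in ch) {
          spawn[[length(spawn) + 1L]] <- c(attach = last, child = c2)
        }
        break
      }
    }
    list(chain = chain, spawn = spawn)
  }

  add_branch <- function(start, parent_order, parent_branch, base_sec_pos,
                         base_node) {
    w <- walk(start, base_node)
    chain <- w$chain
    blen <- sum(elen[chain])   # every chain node's parent edge points inward
    chord <- pos3(chain[length(chain)]) - pos3(base_node)
    ang <- .angle_to_ap(chord)
    flag <- ""
    if (parent_order == 1L) {
      ord <- 2L; oriented <- TRUE
      base_pos <- unname(primary$arc_length[as.character(nodes$id[base_node])])
      base_sec_pos <- base_pos
    } else if (parent_order == 2L) {
      ord <- 3L
      oriented <- ang <= params$theta_t
      if (!oriented) flag <- "misoriented"
      base_pos <- base_sec_pos
    } else if (parent_order == 3L) {
      ord <- 4L
      oriented <- ang > params$theta_q
      if (!oriented) flag <- "misoriented"
      base_pos <- base_sec_pos
    } else {
      ord <- 4L
      oriented <- FALSE
      flag <- "beyond_depth"
      beyond <<- beyond + 1L
      base_pos <- base_sec_pos
    }
    bid <- length(branches) + 1L
    branches[[bid]] <<- data.frame(
      branch_id = bid, order = ord, parent_branch = parent_branch,
      base_node = nodes$id[base_node],
      base_position = base_pos, base_secondary_position = base_sec_pos,
      length = blen, angle_ap = ang, oriented = oriented, flag = flag,
      stringsAsFactors = FALSE
    )
    branch_nodes[[bid]] <<- nodes$id[chain]
    for (sp in w$spawn) {
      add_branch(sp[["child"]], ord, bid, base_sec_pos, sp[["attach"]])
    }
    bid
  }

  for (p in prim_idx) {
    for (c1 in kids[[p]]) {
      if (!on_primary[c1]) add_branch(c1, 1L, NA_integer_, NA_real_, p)
    }
  }

  if (beyond > 0L) {
    warning(sprintf("%d branch(es) beyond quaternary depth labelled order 4 and flagged",
                    beyond))
  }

  br <- if (length(branches) > 0L) {
    do.call(rbind, branches)
  } else {
    data.frame(branch_id = integer(0), order = integer(0),
               parent_branch = integer(0), base_node = integer(0),
               base_position = numeric(0), base_secondary_position = numeric(0),
               length = numeric(0), angle_ap = numeric(0),
               oriented = logical(0), flag = character(0),
               stringsAsFactors = FALSE)
  }
  structure(list(skeleton = arbor, primary = primary, branches = br,
                 branch_nodes = branch_nodes, params = params),
            class = "classified_arbor")
}

#' @export
print.classified_arbor <- function(x, ...) {
  tab <- table(factor(x$branches$order, levels = 2:4))
  cat(sprintf("classified_arbor: %d branches (2°: %d, 3°: %d, 4°: %d)\n",
              nrow(x$branches), tab[["2"]], tab[["3"]], tab[["4"]]))
  invisible(x)
}

# Region segmentation ---------------------------------------------------------

#' Partition the primary dendrite into A-P regions
#'
#' Splits the anterior extent `[0, L_a]` into three equal-length regions
#' (+1 proximal, +2 middle, +3 distal) and takes the whole posterior extent
#' `[-L_p, 0)` as region -1. Intervals are half-open `[lo, hi)` with the
#' distal end of +3 closed; a position exactly on a boundary belongs to the
#' more anterior region.
#'
#' @param primary a [extract_primary()] path with positive anterior extent.
#' @return object of class `region_partition`: data.frame with columns
#'   `region` (factor levels `-1, +1, +2, +3`), `lo`, `hi` (signed arc
#'   length, micrometres).
#' @export
segment_regions <- function(primary) {
  if (primary$L_a <= 0) stop("zero anterior extent: cannot segment regions")
  La <- primary$L_a
  part <- data.frame(
    region = factor(c("-1", "+1", "+2", "+3"),
                    levels = c("-1", "+1", "+2", "+3")),
    lo = c(-primary$L_p, 0, La / 3, 2 * La / 3),
    hi = c(0, La / 3, 2 * La / 3, La)
  )
  structure(part, class = c("region_partition", "data.frame"))
}

#' Map signed arc-length positions to regions
#'
#' @param partition a [segment_regions()] partition.
#' @param pos numeric vector of signed arc lengths (micrometres).
#' @return factor of region labels, levels `-1, +1, +2, +3`.
#' @export
region_of <- function(partition, pos) {
  La <- partition$hi[partition$region == "+3"]
  third <- La / 3
  idx <- pmin(pmax(floor(pos / third), 0), 2) + 1
  lab <- c("+1", "+2", "+3")[idx]
  lab[pos < 0] <- "-1"
  factor(lab, levels = levels(partition$region))
}

# Region counts ---------------------------------------------------------------

#' Count branches per region
#'
#' Secondaries are assigned to regions by the arc-length position of their
#' base on the primary dendrite. Tertiaries and quaternaries are assigned by
#' the base position of the secondary forming the base of their menorah, so
#' a whole menorah is counted in one region even when its tertiary arms
#' cross a boundary. Only correctly-oriented tertiaries/quaternaries enter
#' `n3`/`n4`; `n2_with3` counts secondaries bearing at least one oriented
#' tertiary.
#'
#' @param classified a [classify_branch_orders()] result.
#' @param partition a [segment_regions()] partition of the same arbor.
#' @return data.frame of class `region_counts`: one row per region with
#'   columns `region`, `n2`, `n2_with3`, `n3`, `n4`.
#' @export
count_by_region <- function(classified, partition) {
  br <- classified$branches
  regions <- levels(partition$region)
  zero <- stats::setNames(rep(0L, length(regions)), regions)
  tab <- function(rows, pos_col) {
    if (sum(rows) == 0L) return(zero)
    t0 <- table(region_of(partition, br[[pos_col]][rows]))
    zero + as.integer(t0[regions])
  }

  is2 <- br$order == 2L
  is3 <- br$order == 3L & br$oriented
  is4 <- br$order == 4L & br$oriented & br$flag != "beyond_depth"

  # secondaries bearing >= 1 oriented tertiary
  sec_with3 <- unique(br$parent_branch[is3])
  is2w3 <- is2 & br$branch_id %in% sec_with3

  out <- data.frame(
    region = factor(regions, levels = regions),
    n2 = as.integer(tab(is2, "base_position")),
    n2_with3 = as.integer(tab(is2w3, "base_position")),
    n3 = as.integer(tab(is3, "base_secondary_position")),
    n4 = as.integer(tab(is4, "base_secondary_position"))
  )
  structure(out, class = c("region_counts", "data.frame"))
}

# Branch complexity index -----------------------------------------------------

#' Branch complexity index per region
#'
#' The index equally weights three characteristics of a region's menorahs:
#' the number of secondary branches relative to an ideal count
#' (`c_n2 = n2 / n2_star`), the fraction of secondaries that form a tertiary
#' (`c_p3 = n2_with3 / n2`), and the mean number of quaternaries per
#' tertiary relative to an ideal (`c_q4 = (n4 / n3) / q_star`). The index is
#' the mean of the three components, so an ideal segment in which every
#' secondary bears a tertiary scores exactly 1. Components are not clipped
#' at 1: a region denser than the ideal scores above 1. Degenerate regions
#' define `c_p3 = 0` when `n2 = 0` and `c_q4 = 0` when `n3 = 0`.
#'
#' @param counts a [count_by_region()] table.
#' @param n2_star ideal secondary count per region (scalar, or vector with
#'   one value per region). Must be > 0.
#' @param q_star ideal number of quaternaries per tertiary. Must be > 0.
#' @return data.frame of class `complexity_index`: counts plus columns
#'   `c_n2`, `c_p3`, `c_q4`, `bci`.
#' @export
branch_complexity <- function(counts, n2_star, q_star) {
  if (any(n2_star <= 0) || q_star <= 0) {
    stop("ideal-segment parameters n2_star and q_star must be positive")
  }
  if (!length(n2_star) %in% c(1L, nrow(counts))) {
    stop("n2_star must be scalar or one value per region")
  }
  out <- as.data.frame(counts)
  out$c_n2 <- out$n2 / n2_star
  out$c_p3 <- ifelse(out$n2 > 0, out$n2_with3 / out$n2, 0)
  out$c_q4 <- ifelse(out$n3 > 0, (out$n4 / out$n3) / q_star, 0)
  out$bci <- (out$c_n2 + out$c_p3 + out$c_q4) / 3
  structure(out, class = c("complexity_index", "data.frame"))
}

#' Count secondary filopodia in early larval stages
#'
#' At the L2 and L3 stages the arbor has no menorahs yet and only the total
#' number of secondary protrusions over the whole arbor is tabulated, with
#' no region split.
#'
#' @param classified a [classify_branch_orders()] result.
#' @param stage larval stage label, `"L2"` or `"L3"`.
#' @return integer count of secondary branches.
#' @export
count_filopodia <- function(classified, stage) {
  if (!stage %in% c("L2", "L3")) {
    stop("stage must be L2 or L3; for L4 arbors use count_by_region()")
  }
  sum(classified$branches$order == 2L)
}

# Convenience pipeline --------------------------------------------------------

#' Quantify one arbor end to end
#'
#' Runs primary-path extraction, branch-order classification, region
#' segmentation, counting, and the branch complexity index on one skeleton.
#'
#' @param arbor an [arbor_skeleton()].
#' @param params a [classification_params()] list.
#' @param n2_star,q_star ideal-segment parameters for [branch_complexity()].
#' @return one row per region: counts plus complexity components, with the
#'   skeleton's metadata (`genotype`, `animal_id`) prepended when present.
#' @export
quantify_arbor <- function(arbor, params = classification_params(),
                           n2_star = 14, q_star = 5) {
  primary <- extract_primary(arbor)
  cls <- classify_branch_orders(arbor, primary, params)
  part <- segment_regions(primary)
  counts <- count_by_region(cls, part)
  bci <- branch_complexity(counts, n2_star = n2_star, q_star = q_star)
  meta <- arbor$metadata
  pre <- data.frame(
    genotype = if (is.null(meta$genotype)) NA_character_ else meta$genotype,
    animal_id = if (is.null(meta$animal_id)) NA_character_ else meta$animal_id,
    stringsAsFactors = FALSE
  )
  cbind(pre[rep(1L, nrow(bci)), , drop = FALSE], as.data.frame(bci),
        row.names = NULL)
}
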