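#' Assemble or load a run configuration
#'
#' The configuration drives the end-to-end quantification run. It is either
#' a YAML file or a named list with (any of) the fields:
#' \describe{
#'   \item{input}{character vector of SWC paths to quantify, and/or}
#'   \item{simulate}{list of cohorts to simulate, each with `profile`
#'     (built-in label), `n` (animals); seeds are derived from `seed`.}
#'   \item{params}{classification parameters (`theta_t`, `theta_q`,
#'     `theta_c`).}
#'   \item{ideal}{ideal-segment parameters `n2_star`, `q_star`.}
#'   \item{seed}{master seed (recorded in every output header).}
#'   \item{output_dir}{where CSVs are written.}
#'   \item{penetrance}{optional list: `reference` (genotype label used as
#'     wild-type reference), `regions`, `frac`.}
#' }
#'
#' @param config a list or the path of a YAML file.
#' @return validated config list of class `run_config`.
#' @export
run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(input = character(0), simulate = NULL,
                   params = list(), ideal = list(n2_star = 14, q_star = 5),
                   seed = 1L, output_dir = NULL, penetrance = NULL)
  config <- utils::modifyList(defaults, config)
  missing_in <- config$input[!file.exists(config$input)]
  if (length(missing_in) > 0L) {
    stop("input files not found: ", paste(missing_in, collapse = ", "))
  }
  if (length(config$input) == 0L && is.null(config$simulate)) {
    stop("config needs 'input' SWC paths and/or a 'simulate' block")
  }
  structure(config, class = c("run_config", "list"))
}

# provenance comment lines for CSV outputs
.provenance <- function(config) {
  cfg_yaml <- yaml::as.yaml(config[setdiff(names(config), "output_dir")])
  tf <- tempfile()
  writeLines(cfg_yaml, tf)
  hash <- unname(tools::md5sum(tf))
  unlink(tf)
  c(sprintf("# pvdarbor %s",
            as.character(utils::packageVersion("pvdarbor"))),
    sprintf("# seed=%s", config$seed),
    sprintf("# config_md5=%s", hash))
}

.write_csv_prov <- function(df, path, prov) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(prov, con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, qmethod = "double")
  invisible(path)
}

#' Read a CSV written with a provenance header
#'
#' @param path CSV path.
#' @return data.frame (provenance comment lines skipped).
#' @export
read_csv_prov <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Quantify a cohort of arbors end to end
#'
#' Loads and/or simulates the configured skeletons, runs the morphology
#' pipeline ([extract_primary()], [classify_branch_orders()],
#' [segment_regions()], [count_by_region()], [branch_complexity()]) on each
#' animal, and returns (and optionally writes) the per-(animal, region)
#' table. Per-animal failures are collected as warnings and skipped; the
#' run fails only if every animal fails.
#'
#' @param config a [run_config()] (or list/path coercible to one).
#' @return data.frame, one row per animal x region, with columns `genotype`,
#'   `animal_id`, `region`, `n2`, `n2_with3`, `n3`, `n4`, `c_n2`, `c_p3`,
#'   `c_q4`, `bci`. Written to `<output_dir>/region_table.csv` when an
#'   output directory is configured.
#' @export
run_quantify <- function(config) {
  config <- run_config(config)
  params <- do.call(classification_params, config$params)

  arbors <- lapply(config$input, read_swc)
  if (!is.null(config$simulate)) {
    sims <- config$simulate
    if (!is.null(sims$profile)) sims <- list(sims)  # single cohort block
    seed_off <- 0L
    for (blk in sims) {
      prof <- builtin_profiles(blk$profile)
      coh <- simulate_cohort(prof, blk$n,
                             seed = .derive_seed(config$seed, seed_off))
      arbors <- c(arbors, coh$arbors)
      seed_off <- seed_off + 1L
    }
  }

  rows <- list()
  failures <- character(0)
  for (i in seq_along(arbors)) {
    res <- tryCatch(
      quantify_arbor(arbors[[i]], params = params,
                     n2_star = config$ideal$n2_star,
                     q_star = config$ideal$q_star),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("arbor %d: %s", i, conditionMessage(res)))
      next
    }
    if (is.na(res$animal_id[1L])) res$animal_id <- sprintf("arbor_%03d", i)
    rows[[length(rows) + 1L]] <- res
  }
  if (length(failures) > 0L) {
    warning("skipped ", length(failures), " arbor(s):\n  ",
            paste(failures, collapse = "\n  "))
  }
  if (length(rows) == 0L) stop("all arbors failed quantification")
  out <- do.call(rbind, rows)

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    .write_csv_prov(out, file.path(config$output_dir, "region_table.csv"),
                    .provenance(config))
  }
  out
}

#' Genotype x region complexity report
#'
#' Summarizes a [run_quantify()] table: per-(genotype, region) mean and SEM
#' of the branch complexity index; when several genotypes are present, a
#' two-way ANOVA (genotype x region) on the index with Tukey pairwise
#' comparisons of genotypes; and a penetrance table when the config carries
#' a penetrance criterion.
#'
#' @param config a [run_config()]; `output_dir` must contain
#'   `region_table.csv`, or pass the table directly as `table`.
#' @param table optionally, the region table data.frame itself.
#' @return list with `summary`, `anova` (NULL for a single genotype),
#'   `tukey` (NULL for a single genotype), `penetrance` (NULL unless
#'   configured).
#' @export
run_report <- function(config, table = NULL) {
  config <- run_config(config)
  if (is.null(table)) {
    path <- file.path(config$output_dir, "region_table.csv")
    if (is.null(config$output_dir) || !file.exists(path)) {
      stop("no quantify output found; run run_quantify() first or pass table=")
    }
    table <- read_csv_prov(path)
  }

  agg <- stats::aggregate(bci ~ genotype + region, table, function(v) {
    c(mean = mean(v), sem = stats::sd(v) / sqrt(length(v)), n = length(v))
  })
  summary_tab <- data.frame(genotype = agg$genotype, region = agg$region,
                            mean_bci = agg$bci[, "mean"],
                            sem = agg$bci[, "sem"], n = agg$bci[, "n"])

  anova_tab <- NULL
  tukey_tab <- NULL
  if (length(unique(table$genotype)) >= 2L) {
    fs <- factorial_sample(table$bci, table$genotype, table$region,
                           table$animal_id)
    anova_tab <- two_way_anova(fs)
    tukey_tab <- tukey_hsd(anova_tab, factor = "A")
  }

  pen <- NULL
  if (!is.null(config$penetrance)) {
    pc <- config$penetrance
    ref <- table[table$genotype == pc$reference, , drop = FALSE]
    rest <- table[table$genotype != pc$reference, , drop = FALSE]
    if (nrow(ref) == 0L || nrow(rest) == 0L) {
      stop("penetrance needs the reference genotype and at least one other")
    }
    pen <- lapply(split(rest, rest$genotype), function(g) {
      penetrance(g, reference = ref,
                 regions = if (is.null(pc$regions)) c("-1", "+1") else pc$regions,
                 frac = if (is.null(pc$frac)) 0.5 else pc$frac)
    })
  }

  res <- list(summary = summary_tab, anova = anova_tab, tukey = tukey_tab,
              penetrance = pen)
  if (!is.null(config$output_dir)) {
    prov <- .provenance(config)
    .write_csv_prov(summary_tab,
                    file.path(config$output_dir, "complexity_summary.csv"),
                    prov)
    if (!is.null(tukey_tab)) {
      .write_csv_prov(tukey_tab,
                      file.path(config$output_dir, "tukey_genotype.csv"),
                      prov)
    }
  }
  res
}
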