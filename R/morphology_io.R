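#' Construct an arbor skeleton
#'
#' An `arbor_skeleton` is a rooted geometric tree of nodes (coordinates in
#' micrometres) representing a single reconstructed PVD neuron. Nodes follow
#' SWC conventions: integer ids, a structure code (1 = soma, 3 = dendrite),
#' x/y/z position, a radius, and a parent id (`-1` for the root).
#'
#' @param nodes data.frame with columns `id`, `structure`, `x`, `y`, `z`,
#'   `radius`, `parent` (one row per node, order preserved).
#' @param soma_id id of the soma node (must have structure code 1).
#' @param metadata named list of free-form annotations (e.g. `genotype`,
#'   `stage`, `animal_id`).
#' @param validate if `TRUE` (default), stop on any invariant violation.
#' @return An object of class `arbor_skeleton`.
#' @seealso [read_swc()], [write_swc()], [validate_skeleton()]
#' @export
arbor_skeleton <- function(nodes, soma_id = NULL, metadata = list(),
                           validate = TRUE) {
  required <- c("id", "structure", "x", "y", "z", "radius", "parent")
  missing_cols <- setdiff(required, names(nodes))
  if (length(missing_cols) > 0L) {
    stop("nodes is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  nodes <- as.data.frame(nodes)[, required]
  nodes$id <- as.integer(nodes$id)
  nodes$structure <- as.integer(nodes$structure)
  nodes$parent <- as.integer(nodes$parent)
  if (is.null(soma_id)) {
    soma_candidates <- nodes$id[nodes$structure == 1L]
    soma_id <- if (length(soma_candidates) > 0L) soma_candidates[1L] else NA_integer_
  }
  obj <- structure(
    list(nodes = nodes, soma_id = as.integer(soma_id), metadata = metadata),
    class = "arbor_skeleton"
  )
  if (validate) {
    report <- validate_skeleton(obj)
    errs <- report$message[report$severity == "error"]
    if (length(errs) > 0L) {
      stop("invalid skeleton:\n  ", paste(errs, collapse = "\n  "))
    }
  }
  obj
}

#' @export
print.arbor_skeleton <- function(x, ...) {
  cat("arbor_skeleton:", nrow(x$nodes), "nodes, soma id", x$soma_id, "\n")
  if (length(x$metadata) > 0L) {
    cat("  metadata:",
        paste(names(x$metadata), unlist(x$metadata), sep = "=", collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Validate a skeleton and report violations
#'
#' Checks every structural invariant of an [arbor_skeleton()]: unique ids,
#' known parents, a single root, acyclicity, connectedness, a soma node with
#' structure code 1, and finite coordinates. Violations are returned as data,
#' never raised.
#'
#' @param arbor an `arbor_skeleton` (or a bare list with the same fields,
#'   so that invalid objects can be inspected).
#' @return data.frame with columns `severity` (`"error"` or `"warning"`),
#'   `check`, and `message`; zero rows when the skeleton is valid.
#' @export
validate_skeleton <- function(arbor) {
  nodes <- arbor$nodes
  out <- list()
  add <- function(severity, check, message) {
    out[[length(out) + 1L]] <<- data.frame(
      severity = severity, check = check, message = message,
      stringsAsFactors = FALSE
    )
  }

  dup <- unique(nodes$id[duplicated(nodes$id)])
  for (d in dup) add("error", "duplicate_id", sprintf("duplicate id %d", d))

  bad_parent <- setdiff(nodes$parent, c(-1L, nodes$id))
  for (p in bad_parent) {
    add("error", "unknown_parent", sprintf("unknown parent id %d", p))
  }

  roots <- nodes$id[nodes$parent == -1L]
  if (length(roots) == 0L) add("error", "no_root", "no root node (parent -1)")
  if (length(roots) > 1L) {
    add("error", "multiple_roots",
        sprintf("%d root nodes: %s", length(roots),
                paste(roots, collapse = ", ")))
  }

  coord_bad <- !is.finite(nodes$x) | !is.finite(nodes$y) |
    !is.finite(nodes$z) | !is.finite(nodes$radius)
  for (i in which(coord_bad)) {
    add("error", "nonfinite_coordinate",
        sprintf("node %d has non-finite coordinate or radius", nodes$id[i]))
  }

  if (is.na(arbor$soma_id) || !arbor$soma_id %in% nodes$id) {
    add("error", "missing_soma", "soma_id does not reference an existing node")
  } else if (nodes$structure[match(arbor$soma_id, nodes$id)] != 1L) {
    add("error", "soma_structure",
        sprintf("soma node %d does not have structure code 1", arbor$soma_id))
  }

  unknown_code <- !nodes$structure %in% c(1L, 3L)
  for (i in which(unknown_code)) {
    add("warning", "unknown_structure_code",
        sprintf("node %d has structure code %d (expected 1 or 3)",
                nodes$id[i], nodes$structure[i]))
  }

  # cycle / connectivity check by walking parents, only meaningful if ids are
  # unique and parents resolve
  if (length(dup) == 0L && length(bad_parent) == 0L && length(roots) == 1L) {
    idx_of <- match(nodes$parent, nodes$id)  # NA at root
    n <- nrow(nodes)
    for (i in seq_len(n)) {
      j <- i
      ok <- FALSE
      for (step in seq_len(n + 1L)) {
        if (is.na(idx_of[j])) { ok <- TRUE; break }
        j <- idx_of[j]
      }
      if (!ok) {
        add("error", "cycle",
            sprintf("node %d lies on a parent cycle", nodes$id[i]))
        break
      }
    }
  }

  if (length(out) == 0L) {
    data.frame(severity = character(0), check = character(0),
               message = character(0), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, out)
  }
}

#' Read a neuron skeleton from an SWC file
#'
#' Parses the standard 7-column SWC format (`id structure x y z radius
#' parent`), keeping 1-based ids verbatim and preserving node order. Header
#' comments of the form `# key=value` are collected into the skeleton's
#' metadata.
#'
#' @param path path to an SWC file.
#' @param validate validate the skeleton after parsing (default `TRUE`).
#' @return An [arbor_skeleton()].
#' @export
read_swc <- function(path, validate = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  metadata <- list()
  rows <- list()
  for (ln in seq_along(lines)) {
    line <- trimws(lines[[ln]])
    if (nchar(line) == 0L) next
    if (startsWith(line, "#")) {
      body <- trimws(sub("^#+", "", line))
      if (grepl("^[A-Za-z0-9_.]+=", body)) {
        key <- sub("=.*$", "", body)
        metadata[[key]] <- sub("^[^=]*=", "", body)
      }
      next
    }
    fields <- strsplit(line, "[[:space:]]+")[[1]]
    if (length(fields) != 7L) {
      stop(sprintf("parse error at line %d: expected 7 fields, found %d",
                   ln, length(fields)))
    }
    vals <- suppressWarnings(as.numeric(fields))
    if (anyNA(vals)) {
      stop(sprintf("parse error at line %d: non-numeric field", ln))
    }
    rows[[length(rows) + 1L]] <- vals
  }
  if (length(rows) == 0L) stop("no data lines in ", path)
  m <- do.call(rbind, rows)
  nodes <- data.frame(
    id = as.integer(m[, 1]), structure = as.integer(m[, 2]),
    x = m[, 3], y = m[, 4], z = m[, 5], radius = m[, 6],
    parent = as.integer(m[, 7])
  )
  arbor_skeleton(nodes, metadata = metadata, validate = validate)
}

#' Write a neuron skeleton to an SWC file
#'
#' Emits standard 7-column SWC with one `# key=value` header comment per
#' metadata entry. Coordinates are written at full double precision so that
#' `read_swc(write_swc(x))` reproduces the node table exactly.
#'
#' @param arbor an [arbor_skeleton()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(arbor, path) {
  stopifnot(inherits(arbor, "arbor_skeleton"))
  nodes <- arbor$nodes
  header <- character(0)
  if (length(arbor$metadata) > 0L) {
    header <- sprintf("# %s=%s", names(arbor$metadata),
                      vapply(arbor$metadata, as.character, character(1)))
  }
  body <- sprintf("%d %d %.17g %.17g %.17g %.17g %d",
                  nodes$id, nodes$structure, nodes$x, nodes$y, nodes$z,
                  nodes$radius, nodes$parent)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}
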