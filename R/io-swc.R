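#' Read a skeleton from an SWC file
#'
#' SWC is the plain-text standard for neuron skeletons: seven whitespace
#' separated columns (id, type, x, y, z, radius, parent; parent -1 marks the
#' root). Node ids are arbitrary positive integers and need not be
#' consecutive. Coordinates and radii are multiplied by `unit_scale` into nm,
#' e.g. `unit_scale = 1000` for files written in micrometres.
#'
#' @param path Path to the SWC file.
#' @param unit_scale Multiplier taking file coordinates into nm (default 1,
#'   i.e. the file is already in nm).
#' @return A tibble with columns `node_id`, `parent_id` (`NA` at the root),
#'   `x`, `y`, `z`, `radius` (nm).
#' @export
read_swc <- function(path, unit_scale = 1) {
  assert_scalar_pos(unit_scale, "unit_scale")
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- which(keep)
  if (length(rows) == 0L) abort(sprintf("%s: no data lines", path))
  fields <- strsplit(trimws(lines[rows]), "\\s+")
  nfield <- lengths(fields)
  bad <- which(nfield != 7L)
  if (length(bad) > 0L) {
    abort(sprintf(
      "%s: line %d has %d fields (7 expected)",
      path, rows[bad[1L]], nfield[bad[1L]]
    ))
  }
  m <- matrix(as.numeric(unlist(fields)), ncol = 7L, byrow = TRUE)
  if (anyNA(m)) {
    bad <- which(apply(m, 1L, anyNA))[1L]
    abort(sprintf("%s: line %d contains a non-numeric field", path, rows[bad]))
  }
  node_id <- as.integer(m[, 1L])
  parent <- as.integer(m[, 7L])
  if (anyDuplicated(node_id)) {
    dup <- node_id[duplicated(node_id)][1L]
    line <- rows[which(node_id == dup)[2L]]
    abort(sprintf("%s: line %d duplicates node id %d", path, line, dup))
  }
  missing_parent <- which(parent != -1L & !(parent %in% node_id))
  if (length(missing_parent) > 0L) {
    i <- missing_parent[1L]
    abort(sprintf(
      "%s: line %d references missing parent %d",
      path, rows[i], parent[i]
    ))
  }
  tibble(
    node_id = node_id,
    parent_id = ifelse(parent == -1L, NA_integer_, parent),
    x = m[, 3L] * unit_scale,
    y = m[, 4L] * unit_scale,
    z = m[, 5L] * unit_scale,
    radius = m[, 6L] * unit_scale
  )
}

#' Write a skeleton node table to SWC
#'
#' Coordinates are written in nm with full double precision (`%.17g`), so a
#' write/read round trip reproduces the node table exactly.
#'
#' @param skeleton Tibble as returned by [read_swc()] (a `radius` column is
#'   optional and defaults to 0).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(skeleton, path) {
  assert_cols(skeleton, c("node_id", "parent_id", "x", "y", "z"), "skeleton")
  radius <- if ("radius" %in% names(skeleton)) skeleton$radius else rep(0, nrow(skeleton))
  parent <- ifelse(is.na(skeleton$parent_id), -1L, skeleton$parent_id)
  lines <- sprintf(
    "%d 0 %.17g %.17g %.17g %.17g %d",
    skeleton$node_id, skeleton$x, skeleton$y, skeleton$z, radius, parent
  )
  writeLines(c("# SWC export (nm)", lines), path)
  invisible(path)
}

#' Read a polyadic connector table
#'
#' One row per postsynaptic site: `connector_id`, `pre_neuron`,
#' `post_neuron`, and the site position `x`, `y`, `z` in nm. Optional
#' `pre_x`, `pre_y`, `pre_z` columns give the presynaptic site position.
#'
#' @param path CSV file path.
#' @return Tibble of connector rows.
#' @export
read_connectors <- function(path) {
  df <- read_strict_csv(path)
  assert_cols(df, c("connector_id", "pre_neuron", "post_neuron", "x", "y", "z"),
    sprintf("connector table %s", path)
  )
  df
}

#' Read a neuron annotation table
#'
#' @param path CSV file path with columns `neuron_id`, `name`, `class`,
#'   `nerve`, `bundle`, `origin`, `side` (only `neuron_id` and `class` are
#'   required).
#' @return Tibble of annotations; unknown classes raise an error.
#' @export
read_annotations <- function(path) {
  df <- read_strict_csv(path)
  assert_cols(df, c("neuron_id", "class"), sprintf("annotation table %s", path))
  bad <- setdiff(unique(df$class), neuron_classes)
  if (length(bad) > 0L) {
    abort(sprintf(
      "%s: unknown neuron class(es): %s (allowed: %s)",
      path, paste(bad, collapse = ", "), paste(neuron_classes, collapse = ", ")
    ))
  }
  df
}

# CSV reader that rejects ragged rows, reporting the first offending line
# (header = line 1).
read_strict_csv <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) abort(sprintf("%s: empty file", path))
  # Field counts outside quoted strings; fixtures never embed commas in
  # quotes, but scan() handles them correctly if they do.
  counts <- vapply(
    lines[nzchar(lines)],
    function(l) length(scan(text = l, what = "", sep = ",", quiet = TRUE, quote = "\"")),
    integer(1)
  )
  if (length(unique(counts)) > 1L) {
    first_bad <- which(counts != counts[1L])[1L]
    abort(sprintf(
      "%s: line %d has %d fields but the header has %d",
      path, first_bad, counts[first_bad], counts[1L]
    ))
  }
  readr::read_csv(I(lines), show_col_types = FALSE, progress = FALSE)
}
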