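# Plain-text readers and writers for landmark data and heatmap meshes.

#' Write landmark configurations to a wide CSV
#'
#' One row per scan: `scan_id` then columns `x1, y1, z1, x2, y2, z2, ...`.
#'
#' @param configs Named list of k x 3 matrices.
#' @param file Output path.
#' @export
write_landmarks_csv <- function(configs, file) {
  stopifnot(is.list(configs), length(configs) >= 1L)
  k <- nrow(configs[[1L]])
  mat <- t(vapply(configs, flatten_config, numeric(3L * k)))
  colnames(mat) <- paste0(rep(c("x", "y", "z"), k), rep(seq_len(k), each = 3L))
  df <- data.frame(scan_id = names(configs) %||%
                     sprintf("scan%04d", seq_along(configs)),
                   mat, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, file, row.names = FALSE)
}

#' Read landmark configurations from a wide CSV
#'
#' @param file Path written by [write_landmarks_csv()] (columns `scan_id`,
#'   `x1, y1, z1, ...`).
#' @return Named list of k x 3 matrices.
#' @export
read_landmarks_csv <- function(file) {
  df <- utils::read.csv(file, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- df$scan_id
  mat <- as.matrix(df[, setdiff(names(df), "scan_id"), drop = FALSE])
  configs <- lapply(seq_len(nrow(mat)), function(i) {
    unflatten_config(as.numeric(mat[i, ]))
  })
  stats::setNames(configs, ids)
}

#' Write a bilateral map to CSV
#'
#' Columns: `index`, `role` (`left`/`right`/`midline`), `partner` (the paired
#' index, empty for midline landmarks).
#'
#' @param map A [bilateral_map()].
#' @param file Output path.
#' @export
write_bilateral_map_csv <- function(map, file) {
  stopifnot(inherits(map, "bilateral_map"))
  df <- data.frame(index = seq_len(map$k),
                   role = "midline",
                   partner = NA_integer_)
  df$role[map$pairs[, 1L]] <- "left"
  df$role[map$pairs[, 2L]] <- "right"
  df$partner[map$pairs[, 1L]] <- map$pairs[, 2L]
  df$partner[map$pairs[, 2L]] <- map$pairs[, 1L]
  utils::write.csv(df, file, row.names = FALSE)
}

#' Read a bilateral map from CSV
#'
#' @param file Path written by [write_bilateral_map_csv()].
#' @return A [bilateral_map()].
#' @export
read_bilateral_map_csv <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  left <- df$index[df$role == "left"]
  bilateral_map(pairs = cbind(left, df$partner[df$role == "left"]),
                midline = df$index[df$role == "midline"],
                k = nrow(df))
}

# Diverging blue-white-red colors for a 0-centered scalar field.
diverging_colors <- function(values, limits = NULL) {
  lim <- limits %||% max(abs(values), 1e-12)
  t <- pmax(-1, pmin(1, values / lim))
  r <- ifelse(t >= 0, 255, round(255 * (1 + t)))
  b <- ifelse(t <= 0, 255, round(255 * (1 - t)))
  g <- round(255 * (1 - abs(t)))
  cbind(red = r, green = g, blue = b)
}

#' Write a per-vertex heatmap as ASCII PLY
#'
#' Vertex-only PLY with positions, the scalar field in the standard `quality`
#' property, and a diverging 0-centered blue-white-red vertex coloring
#' (blue = negative = more normative-like, red = positive = more
#' affected-like).
#'
#' @param points k x 3 landmark matrix.
#' @param scores Per-vertex scalar field of length k.
#' @param file Output path.
#' @param limits Optional symmetric color limit; defaults to `max(abs(scores))`.
#' @export
write_heatmap_ply <- function(points, scores, file, limits = NULL) {
  points <- as_config(points, "points")
  if (length(scores) != nrow(points)) {
    stop("scores length must match landmark count", call. = FALSE)
  }
  cols <- diverging_colors(scores, limits)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(
    "ply", "format ascii 1.0",
    sprintf("element vertex %d", nrow(points)),
    "property float x", "property float y", "property float z",
    "property float quality",
    "property uchar red", "property uchar green", "property uchar blue",
    "end_header"
  ), con)
  body <- sprintf("%.8g %.8g %.8g %.8g %d %d %d",
                  points[, 1L], points[, 2L], points[, 3L], scores,
                  cols[, 1L], cols[, 2L], cols[, 3L])
  writeLines(body, con)
  invisible(file)
}

#' Read vertices (and scalar field, if present) from an ASCII PLY
#'
#' Minimal vertex-only reader for files produced by [write_heatmap_ply()].
#'
#' @param file PLY path.
#' @return List with `points` (k x 3) and `quality` (numeric or `NULL`).
#' @export
read_ply_vertices <- function(file) {
  lines <- readLines(file)
  end <- match("end_header", lines)
  if (is.na(end)) stop("not an ASCII PLY file: no end_header", call. = FALSE)
  header <- lines[seq_len(end)]
  n <- as.integer(sub("element vertex ", "",
                      grep("^element vertex ", header, value = TRUE)[1L]))
  props <- sub("^property \\S+ ", "", grep("^property ", header, value = TRUE))
  body <- lines[end + seq_len(n)]
  vals <- do.call(rbind, lapply(strsplit(body, " "), as.numeric))
  colnames(vals) <- props
  list(points = vals[, c("x", "y", "z"), drop = FALSE],
       quality = if ("quality" %in% props) vals[, "quality"] else NULL)
}

# Serialize a shape space as a directory of CSVs plus a version-tagged
# meta.json, so every artifact stays plain text.
write_shape_space <- function(space, dir) {
  stopifnot(inherits(space, "shape_space"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(data.frame(center = space$center),
                   file.path(dir, "center.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(space$rotation),
                   file.path(dir, "components.csv"), row.names = FALSE)
  utils::write.csv(data.frame(eigenvalue = space$eigenvalues,
                              cum_var = space$variance_explained_cum),
                   file.path(dir, "eigenvalues.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(format = "morphoscore-shape-space", version = 1L,
         k = space$k, n_samples = space$n_samples,
         n_retained = space$n_retained),
    file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(dir)
}
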