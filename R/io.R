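#' Read and write item DMs as CSV
#'
#' Two plain-text forms: condensed (columns `item_a`, `item_b`,
#' `dissimilarity`, one row per pair) and square matrix (items as header row
#' and first column). Round trips are exact to the printed precision (full
#' double precision is written).
#'
#' @param dm An [item_dm()].
#' @param path Output file path.
#' @param format `"condensed"` or `"square"`.
#' @export
write_item_dm <- function(dm, path, format = c("condensed", "square")) {
  format <- match.arg(format)
  if (format == "condensed") {
    df <- condensed_pairs(dm$items)
    df$dissimilarity <- sprintf("%.17g", dm$condensed)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    m <- as.matrix(dm)
    utils::write.csv(data.frame(item = rownames(m),
                                apply(m, 2, function(x) sprintf("%.17g", x)),
                                check.names = FALSE),
                     path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_item_dm
#' @return `read_item_dm()` returns an [item_dm()].
#' @export
read_item_dm <- function(path, format = c("condensed", "square")) {
  format <- match.arg(format)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (format == "condensed") {
    items <- unique(c(df$item_a, df$item_b))
    expected <- condensed_pairs(items)
    if (!identical(expected$item_a, df$item_a) ||
        !identical(expected$item_b, df$item_b)) {
      stop("pair rows are not in condensed order", call. = FALSE)
    }
    item_dm(as.numeric(df$dissimilarity), items)
  } else {
    items <- df$item
    m <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    if (!identical(colnames(m), items)) {
      stop("square DM header does not match item column", call. = FALSE)
    }
    item_dm(t(m)[lower.tri(m)], items)
  }
}

#' Write a per-node surface map as CSV
#'
#' Plain-text surface map exchange format: `node_index` (0-based, left
#' hemisphere then right) and `value`. Used for convergence maps, gradient
#' maps and region label maps (labels written as strings).
#'
#' @param values Per-node numeric or character/factor vector.
#' @param path Output file path.
#' @export
write_node_map <- function(values, path) {
  utils::write.csv(data.frame(node_index = seq_along(values) - 1L,
                              value = as.vector(values)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_node_map
#' @export
read_node_map <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(identical(df$node_index, seq_len(nrow(df)) - 1L))
  df$value
}

#' Write mesh geometry as CSV
#'
#' Nodes (`node_index`, `x`, `y`, `z`) and faces (`v1`, `v2`, `v3`, 0-based)
#' to two files derived from `path_prefix`.
#'
#' @param mesh A `surface_mesh`.
#' @param path_prefix Prefix for `<prefix>_nodes.csv` / `<prefix>_faces.csv`.
#' @export
write_mesh_csv <- function(mesh, path_prefix) {
  utils::write.csv(data.frame(node_index = seq_len(mesh$n_nodes) - 1L,
                              x = mesh$coords[, 1], y = mesh$coords[, 2],
                              z = mesh$coords[, 3]),
                   paste0(path_prefix, "_nodes.csv"), row.names = FALSE)
  utils::write.csv(data.frame(v1 = mesh$faces[, 1] - 1L,
                              v2 = mesh$faces[, 2] - 1L,
                              v3 = mesh$faces[, 3] - 1L),
                   paste0(path_prefix, "_faces.csv"), row.names = FALSE)
  invisible(path_prefix)
}

#' Read and write grayscale images as PNG
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param path PNG file path.
#' @export
write_image_png <- function(image, path) {
  png::writePNG(t(image), path)
  invisible(path)
}

#' @rdname write_image_png
#' @export
read_image_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) {
    img <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  }
  t(img)
}

#' Write RSA tables and traces as CSV
#'
#' @param stats A [network_rsa()] data frame.
#' @param path Output CSV path.
#' @export
write_rsa_csv <- function(stats, path) {
  utils::write.csv(stats, path, row.names = FALSE)
  invisible(path)
}
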