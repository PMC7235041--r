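#' Subdivided-icosahedron cortical surface meshes
#'
#' Standard-mesh surfaces are built by linear (edge-wise) subdivision of the
#' base icosahedron: every face is divided into `L^2` congruent sub-triangles
#' (`L` = number of linear divisions) and all vertices are projected to the
#' unit sphere. This construction yields exactly `10 * L^2 + 2` nodes per
#' hemisphere, so `L = 32` gives the conventional 10,242-node hemisphere and
#' a 20,484-node whole-brain surface.
#'
#' @param linear_divisions Positive integer subdivision factor `L`.
#' @param hemisphere `"left"` or `"right"`. The right hemisphere shares the
#'   left one's topology with mirrored (`x`-negated, shifted) coordinates.
#' @return An object of class `surface_mesh`: a list with `coords` (n x 3
#'   matrix), `faces` (m x 3 integer matrix, 1-based), `edges` (2-column
#'   integer matrix), `adj` (adjacency list), `n_nodes`, `hemisphere` and
#'   `linear_divisions`. Coordinates are unitless (unit sphere, plus a
#'   hemisphere offset along x).
#' @examples
#' m <- icosa_mesh(2)
#' m$n_nodes  # 42
#' @export
icosa_mesh <- function(linear_divisions, hemisphere = c("left", "right")) {
  hemisphere <- match.arg(hemisphere)
  L <- linear_divisions
  if (length(L) != 1L || !is.finite(L) || L < 1 || L != round(L)) {
    stop("`linear_divisions` must be a single positive integer", call. = FALSE)
  }
  L <- as.integer(L)

  base <- base_icosahedron()

  # barycentric lattice over one face: points (i, j), i + j <= L
  grid <- expand.grid(i = 0:L, j = 0:L)
  grid <- grid[grid$i + grid$j <= L, , drop = FALSE]
  grid <- grid[order(grid$i, grid$j), , drop = FALSE]
  npts <- nrow(grid)                       # (L+1)(L+2)/2
  w <- cbind(L - grid$i - grid$j, grid$i, grid$j) / L

  n_faces_base <- nrow(base$faces)
  coords_all <- matrix(0, n_faces_base * npts, 3)
  for (f in seq_len(n_faces_base)) {
    tri <- base$verts[base$faces[f, ], , drop = FALSE]
    coords_all[(f - 1L) * npts + seq_len(npts), ] <- w %*% tri
  }
  # project to unit sphere, then deduplicate shared edge/corner vertices
  coords_all <- coords_all / sqrt(rowSums(coords_all^2))
  key <- paste(round(coords_all[, 1], 8), round(coords_all[, 2], 8),
               round(coords_all[, 3], 8))
  first <- !duplicated(key)
  node_id <- match(key, key[first])        # order of first appearance
  node_id <- match(node_id, sort(unique(node_id)))
  coords <- coords_all[first, , drop = FALSE]

  # sub-faces in lattice coordinates, shared across base faces
  lat_index <- matrix(NA_integer_, L + 1L, L + 1L)
  lat_index[cbind(grid$i + 1L, grid$j + 1L)] <- seq_len(npts)
  up <- expand.grid(i = 0:(L - 1L), j = 0:(L - 1L))
  up <- up[up$i + up$j <= L - 1L, , drop = FALSE]
  tri_local <- cbind(lat_index[cbind(up$i + 1L, up$j + 1L)],
                     lat_index[cbind(up$i + 2L, up$j + 1L)],
                     lat_index[cbind(up$i + 1L, up$j + 2L)])
  if (L >= 2L) {
    dn <- expand.grid(i = 0:(L - 2L), j = 0:(L - 2L))
    dn <- dn[dn$i + dn$j <= L - 2L, , drop = FALSE]
    tri_local <- rbind(tri_local,
                       cbind(lat_index[cbind(dn$i + 2L, dn$j + 1L)],
                             lat_index[cbind(dn$i + 2L, dn$j + 2L)],
                             lat_index[cbind(dn$i + 1L, dn$j + 2L)]))
  }
  faces <- do.call(rbind, lapply(seq_len(n_faces_base), function(f) {
    matrix(node_id[(f - 1L) * npts + tri_local], ncol = 3)
  }))
  storage.mode(faces) <- "integer"

  n_nodes <- nrow(coords)
  stopifnot(n_nodes == 10L * L^2 + 2L)     # closed-sphere node-count invariant

  if (hemisphere == "right") coords[, 1] <- -coords[, 1]
  coords[, 1] <- coords[, 1] + if (hemisphere == "left") -2.5 else 2.5

  edges <- edges_from_faces(faces)
  structure(list(hemisphere = hemisphere, linear_divisions = L,
                 coords = coords, faces = faces, edges = edges,
                 adj = adjacency_list(edges, n_nodes), n_nodes = n_nodes),
            class = "surface_mesh")
}

base_icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  verts <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  verts <- verts / sqrt(rowSums(verts^2))
  faces <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  storage.mode(faces) <- "integer"
  list(verts = verts, faces = faces)
}

edges_from_faces <- function(faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(1, 3)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- unique(e)
  e[order(e[, 1], e[, 2]), , drop = FALSE]
}

adjacency_list <- function(edges, n_nodes) {
  adj <- vector("list", n_nodes)
  nb <- split(c(edges[, 2], edges[, 1]), factor(c(edges[, 1], edges[, 2]),
                                                levels = seq_len(n_nodes)))
  for (v in seq_len(n_nodes)) adj[[v]] <- sort(unique(nb[[v]]))
  adj
}

#' Two-hemisphere whole-brain surface
#'
#' Combines a left and a right hemisphere mesh into one index space: right
#' hemisphere nodes are indexed after the left ones (`node_index_offset` =
#' number of left nodes). There is no adjacency across hemispheres.
#'
#' @inheritParams icosa_mesh
#' @return An object of class `whole_brain_surface` with elements `left`,
#'   `right`, `node_index_offset`, `n_nodes` and a combined adjacency list
#'   `adj`.
#' @examples
#' wb <- whole_brain_surface(4)
#' wb$n_nodes  # 2 * (10 * 16 + 2) = 324
#' @export
whole_brain_surface <- function(linear_divisions) {
  left <- icosa_mesh(linear_divisions, "left")
  right <- icosa_mesh(linear_divisions, "right")
  offset <- left$n_nodes
  adj <- c(left$adj, lapply(right$adj, function(v) v + offset))
  structure(list(left = left, right = right, node_index_offset = offset,
                 n_nodes = left$n_nodes + right$n_nodes, adj = adj,
                 linear_divisions = left$linear_divisions),
            class = "whole_brain_surface")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %s hemisphere, L = %d: %d nodes, %d edges, %d faces\n",
              x$hemisphere, x$linear_divisions, x$n_nodes, nrow(x$edges),
              nrow(x$faces)))
  invisible(x)
}

#' @export
print.whole_brain_surface <- function(x, ...) {
  cat(sprintf("<whole_brain_surface> L = %d: %d nodes (%d per hemisphere)\n",
              x$linear_divisions, x$n_nodes, x$node_index_offset))
  invisible(x)
}

mesh_adjacency <- function(mesh) {
  if (inherits(mesh, "surface_mesh") || inherits(mesh, "whole_brain_surface")) {
    return(mesh$adj)
  }
  stop("not a surface mesh object", call. = FALSE)
}

#' k-ring neighborhood of a surface node
#'
#' Breadth-first set of all nodes within `rings` edge hops of `node`
#' (the searchlight patch). `rings = 0` returns only the center.
#'
#' @param mesh A `surface_mesh` or `whole_brain_surface`.
#' @param node 1-based node index.
#' @param rings Non-negative integer hop count.
#' @return Sorted integer vector of member node indices (always contains
#'   `node`).
#' @export
node_neighborhood <- function(mesh, node, rings) {
  adj <- mesh_adjacency(mesh)
  n <- length(adj)
  if (length(node) != 1L || is.na(node) || node < 1 || node > n) {
    stop("`node` out of range", call. = FALSE)
  }
  if (rings < 0 || rings != round(rings)) {
    stop("`rings` must be a non-negative integer", call. = FALSE)
  }
  seen <- node
  frontier <- node
  r <- 0L
  while (r < rings && length(frontier)) {
    frontier <- setdiff(unique(unlist(adj[frontier])), seen)
    seen <- c(seen, frontier)
    r <- r + 1L
  }
  sort(as.integer(seen))
}

#' All k-ring neighborhoods of a mesh
#'
#' Precomputes `node_neighborhood()` for every node; used by the searchlight.
#'
#' @inheritParams node_neighborhood
#' @return List of integer vectors, one per node.
#' @export
all_neighborhoods <- function(mesh, rings) {
  adj <- mesh_adjacency(mesh)
  lapply(seq_along(adj), function(v) node_neighborhood(mesh, v, rings))
}

#' Connected components of a node subset
#'
#' Partitions `node_set` into maximal components connected by shared mesh
#' edges (the contiguity substrate for surface cluster correction).
#' Components are ordered by decreasing size, ties broken by smallest member
#' index.
#'
#' @param node_set Integer vector of node indices (possibly empty).
#' @param mesh A `surface_mesh` or `whole_brain_surface`.
#' @return List of sorted integer vectors partitioning `node_set`.
#' @export
connected_components <- function(node_set, mesh) {
  adj <- mesh_adjacency(mesh)
  node_set <- unique(as.integer(node_set))
  if (length(node_set) == 0L) return(list())
  if (any(node_set < 1L | node_set > length(adj))) {
    stop("`node_set` contains out-of-range nodes", call. = FALSE)
  }
  in_set <- logical(length(adj))
  in_set[node_set] <- TRUE
  ends1 <- rep.int(node_set, lengths(adj[node_set]))
  ends2 <- unlist(adj[node_set], use.names = FALSE)
  keep <- in_set[ends2] & ends1 < ends2
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(ends1[keep]), to = as.character(ends2[keep])),
    directed = FALSE, vertices = data.frame(name = as.character(node_set)))
  comp <- igraph::components(g)
  members <- unname(split(as.integer(igraph::V(g)$name), comp$membership))
  members <- lapply(members, function(v) sort(as.integer(v)))
  sizes <- lengths(members)
  mins <- vapply(members, min, integer(1))
  unname(members[order(-sizes, mins)])
}
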