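# 26-connectivity neighbour offsets (3^3 - 1 rows)
.offsets26 <- local({
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
})

.encode_vox <- function(coords, dims) {
  (coords[, 1L] - 1) + dims[1L] * ((coords[, 2L] - 1) + dims[2L] * (coords[, 3L] - 1))
}

# Accepts a dense 3D binary array or an n x 3 integer coordinate matrix.
.skeleton_coords <- function(x) {
  if (is.array(x) && length(dim(x)) == 3L) {
    vals <- unique(as.vector(x))
    .assert(all(vals %in% c(0, 1) | vals %in% c(TRUE, FALSE)),
            "skeleton volume must be binary", "mycouptake_invalid_parameter")
    idx <- which(x != 0, arr.ind = TRUE)
    storage.mode(idx) <- "integer"
    list(coords = idx, dims = dim(x))
  } else if (is.matrix(x) && ncol(x) == 3L) {
    coords <- x
    storage.mode(coords) <- "integer"
    .assert(all(coords >= 1L), "voxel coordinates must be 1-based positive",
            "mycouptake_invalid_parameter")
    list(coords = coords, dims = apply(coords, 2L, max) + 1L)
  } else {
    stop(errorCondition("input must be a 3D binary array or an n x 3 voxel coordinate matrix",
                        class = c("mycouptake_invalid_parameter", "mycouptake_error")))
  }
}

#' Convert a voxel skeleton to a branch graph
#'
#' Traces a 1-voxel-wide skeleton (26-connectivity) into nodes and
#' branches. Nodes sit at voxels with a neighbour count other than 2;
#' adjacent junction voxels (>= 3 neighbours) are merged into a single node
#' at their centroid, deterministically. Isolated loops (components whose
#' voxels all have exactly 2 neighbours) are broken at their
#' smallest-index voxel. Arc length is the sum of inter-voxel Euclidean
#' steps times `voxel_size`, so axis, face-diagonal and body-diagonal
#' steps contribute 1, sqrt(2) and sqrt(3) voxel lengths.
#'
#' @param x 3D binary array, or n x 3 matrix of 1-based voxel coordinates
#' @param voxel_size voxel edge length in um (isotropic)
#' @return a [SkeletonGraph-class]; an empty input yields an empty graph
#' @examples
#' run <- cbind(1:5, rep(1, 5), rep(1, 5))
#' g <- voxelSkeletonToGraph(run, voxel_size = 1.6)
#' g@branch_length   # 4 steps x 1.6 um = 6.4 um
#' @export
voxelSkeletonToGraph <- function(x, voxel_size = 1) {
  .assert(voxel_size > 0, "'voxel_size' must be > 0", "mycouptake_invalid_parameter")
  sk <- .skeleton_coords(x)
  coords <- sk$coords
  n <- nrow(coords)
  empty_nodes <- data.frame(id = integer(), x_um = numeric(), y_um = numeric(),
                            z_um = numeric(), degree = integer(),
                            cluster = integer())
  if (n == 0L) {
    return(new("SkeletonGraph", nodes = empty_nodes, branches = list(),
               branch_nodes = matrix(integer(), 0L, 2L),
               branch_length = numeric(), cluster = integer(),
               voxel_size = voxel_size))
  }
  dims <- pmax(sk$dims, apply(coords, 2L, max)) + 2L
  keys <- .encode_vox(coords, dims)
  ord <- order(keys)
  coords <- coords[ord, , drop = FALSE]
  keys <- keys[ord]

  # adjacency: for each voxel, indices of its 26-neighbours present
  nb_idx <- matrix(NA_integer_, n, 26L)
  for (o in seq_len(26L)) {
    shifted <- sweep(coords, 2L, .offsets26[o, ], "+")
    nb_idx[, o] <- match(.encode_vox(shifted, dims), keys)
  }
  degree <- rowSums(!is.na(nb_idx))
  neighbors <- lapply(seq_len(n), function(i) {
    v <- nb_idx[i, ]
    as.integer(v[!is.na(v)])
  })

  # connected components (clusters) over voxels
  edge_from <- rep.int(seq_len(n), vapply(neighbors, length, integer(1)))
  edge_to <- unlist(neighbors, use.names = FALSE)
  gg <- igraph::graph_from_edgelist(cbind(edge_from, edge_to)[edge_from < edge_to, ,
                                                              drop = FALSE],
                                    directed = FALSE)
  gg <- igraph::add_vertices(gg, max(0L, n - igraph::vcount(gg)))
  comp <- igraph::components(gg)$membership

  is_node_vox <- degree != 2L
  # break pure loops at the smallest-key voxel of each all-degree-2 component
  for (cid in unique(comp)) {
    members <- which(comp == cid)
    if (all(degree[members] == 2L)) {
      is_node_vox[members[which.min(keys[members])]] <- TRUE
    }
  }

  # merge adjacent junction voxels (degree >= 3) into one node per group
  node_group <- integer(n)          # 0 = not a node voxel
  next_id <- 0L
  junction <- degree >= 3L
  if (any(junction)) {
    jidx <- which(junction)
    jmap <- match(seq_len(n), jidx)
    jedges <- cbind(jmap[edge_from], jmap[edge_to])
    jedges <- jedges[!is.na(jedges[, 1L]) & !is.na(jedges[, 2L]) &
                       jedges[, 1L] < jedges[, 2L], , drop = FALSE]
    jg <- igraph::graph_from_edgelist(jedges, directed = FALSE)
    jg <- igraph::add_vertices(jg, max(0L, length(jidx) - igraph::vcount(jg)))
    jcomp <- igraph::components(jg)$membership
    node_group[jidx] <- jcomp
    next_id <- max(jcomp)
  }
  for (i in which(is_node_vox & !junction)) {
    next_id <- next_id + 1L
    node_group[i] <- next_id
  }
  n_nodes <- next_id
  pos_um <- coords * voxel_size
  node_pos <- matrix(0, n_nodes, 3L)
  node_cluster <- integer(n_nodes)
  for (gid in seq_len(n_nodes)) {
    members <- which(node_group == gid)
    node_pos[gid, ] <- colMeans(pos_um[members, , drop = FALSE])
    node_cluster[gid] <- comp[members[1L]]
  }

  # trace branches from every node voxel along degree-2 chains
  branches <- list(); b_nodes <- list(); b_len <- numeric(); b_cluster <- integer()
  used <- new.env(hash = TRUE, parent = emptyenv())
  edge_key <- function(i, j) paste0(min(i, j), "_", max(i, j))
  for (start in which(node_group > 0L)) {
    for (nb in neighbors[[start]]) {
      if (node_group[nb] > 0L && node_group[nb] == node_group[start]) next
      k <- edge_key(start, nb)
      if (!is.null(used[[k]])) next
      path <- c(start, nb)
      prev <- start; cur <- nb
      while (node_group[cur] == 0L) {
        nxt <- setdiff(neighbors[[cur]], prev)
        if (length(nxt) == 0L) break         # dead end (degree-1 handled as node)
        # prefer non-previous continuation; chains have exactly one
        prev <- cur; cur <- nxt[1L]
        path <- c(path, cur)
      }
      used[[k]] <- TRUE
      used[[edge_key(path[length(path) - 1L], path[length(path)])]] <- TRUE
      poly <- pos_um[path, , drop = FALSE]
      steps <- sqrt(rowSums((poly[-1L, , drop = FALSE] -
                               poly[-nrow(poly), , drop = FALSE])^2))
      branches[[length(branches) + 1L]] <- poly
      b_nodes[[length(b_nodes) + 1L]] <- c(node_group[start], node_group[cur])
      b_len <- c(b_len, sum(steps))
      b_cluster <- c(b_cluster, comp[start])
    }
  }
  bn_mat <- if (length(b_nodes)) do.call(rbind, b_nodes) else matrix(integer(), 0L, 2L)
  node_deg <- tabulate(as.integer(bn_mat), nbins = n_nodes)
  nodes <- data.frame(id = seq_len(n_nodes),
                      x_um = node_pos[, 1L], y_um = node_pos[, 2L],
                      z_um = node_pos[, 3L], degree = node_deg,
                      cluster = node_cluster)
  new("SkeletonGraph", nodes = nodes, branches = branches,
      branch_nodes = bn_mat,
      branch_length = b_len, cluster = as.integer(b_cluster),
      voxel_size = voxel_size)
}

#' Build a skeleton graph directly from polylines
#'
#' Constructs a [SkeletonGraph-class] from continuous 3D polylines (um
#' coordinates), merging endpoint nodes that coincide. Used for analytic
#' fixtures and for the exact ground truth emitted by [genSkeleton()].
#'
#' @param polylines list of n x 3 matrices (um)
#' @param voxel_size nominal voxel size attached to the graph (um)
#' @return a [SkeletonGraph-class]
#' @export
skeletonFromPolylines <- function(polylines, voxel_size = 1) {
  .assert(length(polylines) >= 1L, "need at least one polyline",
          "mycouptake_invalid_parameter")
  ends <- do.call(rbind, lapply(polylines, function(p) rbind(p[1L, ], p[nrow(p), ])))
  key <- apply(round(ends, 9), 1L, paste, collapse = "_")
  uk <- unique(key)
  node_id <- match(key, uk)
  n_nodes <- length(uk)
  node_pos <- ends[match(uk, key), , drop = FALSE]
  b_nodes <- matrix(node_id, ncol = 2L, byrow = TRUE)
  b_len <- vapply(polylines, function(p) {
    sum(sqrt(rowSums((p[-1L, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
  }, numeric(1))
  gg <- igraph::graph_from_edgelist(b_nodes, directed = FALSE)
  gg <- igraph::add_vertices(gg, max(0L, n_nodes - igraph::vcount(gg)))
  ncomp <- igraph::components(gg)$membership
  deg <- igraph::degree(gg)
  nodes <- data.frame(id = seq_len(n_nodes), x_um = node_pos[, 1L],
                      y_um = node_pos[, 2L], z_um = node_pos[, 3L],
                      degree = as.integer(deg),
                      cluster = as.integer(ncomp))
  new("SkeletonGraph", nodes = nodes, branches = polylines,
      branch_nodes = b_nodes, branch_length = b_len,
      cluster = as.integer(ncomp[b_nodes[, 1L]]), voxel_size = voxel_size)
}

#' Morphometrics of a hyphal skeleton graph
#'
#' Computes the morphometric panel: total length, length density, cluster
#' and branch counts, mean branch length, per-branch arc-chord tortuosity
#' and per-branch orientation angle. Tortuosity is arc length over the
#' Euclidean distance between branch end points (>= 1 by construction);
#' orientation is the angle between the branch end-to-end vector and the
#' compartment midline, folded to `[0, 90]` degrees (a filament has no
#' direction). Zero-chord branches (closed loops) are excluded from both
#' and counted in `n_zero_chord`.
#'
#' @param graph a [SkeletonGraph-class]
#' @param midline_vector non-zero 3-vector along the compartment midline
#' @param analysed_volume_um3 analysed volume (um^3), > 0
#' @return a [HyphalMetrics-class]
#' @export
computeMetrics <- function(graph, midline_vector = c(1, 0, 0),
                           analysed_volume_um3) {
  stopifnot(is(graph, "SkeletonGraph"))
  .assert(analysed_volume_um3 > 0, "'analysed_volume_um3' must be > 0",
          "mycouptake_invalid_parameter")
  .assert(sum(midline_vector^2) > 0, "'midline_vector' must be non-zero",
          "mycouptake_invalid_parameter")
  m_hat <- midline_vector / sqrt(sum(midline_vector^2))
  total <- sum(graph@branch_length)
  # um / um^3 -> cm / cm^3 = multiply by 1e8
  density <- total / analysed_volume_um3 * 1e8
  clusters <- unique(c(graph@nodes$cluster, graph@cluster))
  bp <- vapply(clusters, function(cl) sum(graph@cluster == cl), integer(1))
  tort <- numeric(); ang <- numeric(); zero_chord <- 0L
  for (i in seq_along(graph@branches)) {
    p <- graph@branches[[i]]
    e <- p[nrow(p), ] - p[1L, ]
    chord <- sqrt(sum(e^2))
    if (chord <= 1e-12) { zero_chord <- zero_chord + 1L; next }
    tort <- c(tort, graph@branch_length[i] / chord)
    cosang <- abs(sum(e / chord * m_hat))
    ang <- c(ang, acos(min(1, cosang)) * 180 / pi)
  }
  new("HyphalMetrics",
      total_length_um = total, length_density_cm2 = density,
      n_clusters = length(clusters),
      branches_per_cluster = bp,
      mean_branch_length_um = if (length(graph@branches)) mean(graph@branch_length)
                              else NaN,
      tortuosity = pmax(tort, 1), angle_deg = ang,
      n_zero_chord = zero_chord)
}

#' Read / write skeleton graphs as SWC-like CSV
#'
#' Serialises branch polylines as rows `id, x_um, y_um, z_um, radius,
#' parent_id` where `parent_id = -1` starts a new branch (SWC convention).
#'
#' @param graph a [SkeletonGraph-class]
#' @param path file path
#' @return the path (writer) or a [SkeletonGraph-class] (reader)
#' @export
writeSkeletonSWC <- function(graph, path) {
  stopifnot(is(graph, "SkeletonGraph"))
  rows <- list(); id <- 0L
  for (p in graph@branches) {
    for (r in seq_len(nrow(p))) {
      id <- id + 1L
      rows[[id]] <- data.frame(id = id, x_um = p[r, 1L], y_um = p[r, 2L],
                               z_um = p[r, 3L], radius = graph@voxel_size / 2,
                               parent_id = if (r == 1L) -1L else id - 1L)
    }
  }
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSkeletonSWC
#' @param voxel_size nominal voxel size to attach (um)
#' @export
readSkeletonSWC <- function(path, voxel_size = 1) {
  df <- read.csv(path)
  .assert(all(c("id", "x_um", "y_um", "z_um", "parent_id") %in% names(df)),
          "SWC CSV must have id, x_um, y_um, z_um, parent_id columns",
          "mycouptake_invalid_format")
  starts <- which(df$parent_id == -1L)
  ends <- c(starts[-1L] - 1L, nrow(df))
  polylines <- Map(function(s, e) as.matrix(df[s:e, c("x_um", "y_um", "z_um")]),
                   starts, ends)
  polylines <- lapply(polylines, unname)
  skeletonFromPolylines(polylines, voxel_size = voxel_size)
}
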