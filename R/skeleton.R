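# Skeletonization of label masks to one-voxel-wide curve skeletons and their
# 26-connected graph representation.

#' Euclidean distance field of a vessel mask
#'
#' Per-voxel Euclidean distance (mm) to the nearest background voxel; 0
#' outside the mask. High values mark lumen-central voxels, which is what
#' the minimal-path tracing rewards.
#'
#' @param mask A [vwi_mask], or a logical array (then `spacing` is required).
#' @param artery,side Optional restriction to one artery class/side.
#' @param spacing Voxel spacing when `mask` is a bare array.
#' @return List with `data` (3D array, mm) and `spacing`.
#' @export
distance_field <- function(mask, artery = NULL, side = NULL, spacing = NULL) {
  if (inherits(mask, "vwi_mask")) {
    bin <- if (is.null(artery)) mask$data > 0 else
      mask_binary(mask, artery, side)
    spacing <- mask$spacing
  } else {
    if (is.null(spacing)) stop("spacing required for array input")
    bin <- mask
  }
  d <- cpp_edt3d(array(as.logical(bin), dim(bin)), dim(bin),
                 as.numeric(spacing))
  list(data = d, spacing = as.numeric(spacing))
}

#' Skeletonize one artery of a vessel mask
#'
#' Distance-ordered homotopic thinning: voxels are removed in increasing
#' distance-field order whenever removal preserves topology, keeping curve
#' endpoints, which yields a centred, one-voxel-wide, topology-preserving
#' curve skeleton. The result is returned as a graph with 26-connected
#' adjacency.
#'
#' @param mask A [vwi_mask].
#' @param artery Artery class to skeletonize (all sides unless `side` given).
#' @param side Optional side restriction.
#' @return A `vwi_skeleton`: voxel `nodes` (n x 3, 1-based indices), `edges`
#'   (m x 2 node indices), per-node distance-field values, the source grid
#'   geometry and the artery label. Empty label gives an empty skeleton.
#' @export
skeletonize <- function(mask, artery, side = NULL) {
  stopifnot(inherits(mask, "vwi_mask"))
  bin <- mask_binary(mask, artery, side)
  dm <- dim(bin)
  if (!any(bin)) {
    return(structure(list(nodes = matrix(0, 0, 3), edges = matrix(0L, 0, 2),
                          field = numeric(0), dims = dm,
                          spacing = mask$spacing, label = artery,
                          mask_ids = mask_label_ids(mask, artery, side),
                          mask = mask),
                     class = "vwi_skeleton"))
  }
  edt <- cpp_edt3d(bin, dm, mask$spacing)
  sk <- cpp_thin3d(bin, dm, edt, mask$spacing)
  lin <- which(sk)
  nodes <- cbind((lin - 1) %% dm[1] + 1,
                 ((lin - 1) %/% dm[1]) %% dm[2] + 1,
                 (lin - 1) %/% (dm[1] * dm[2]) + 1)
  # 26-adjacency edges via half-offset shifts of the index lookup grid
  id <- array(0L, dm)
  id[lin] <- seq_along(lin)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[offs$dx != 0 | offs$dy != 0 | offs$dz != 0, ]
  offs <- offs[as.matrix(offs) %*% c(1, 3, 9) > 0, ] # half the offsets
  edges <- matrix(0L, 0, 2)
  for (r in seq_len(nrow(offs))) {
    nb <- nodes + matrix(as.integer(offs[r, ]), nrow(nodes), 3, byrow = TRUE)
    ok <- nb[, 1] >= 1 & nb[, 1] <= dm[1] & nb[, 2] >= 1 & nb[, 2] <= dm[2] &
      nb[, 3] >= 1 & nb[, 3] <= dm[3]
    tgt <- rep(0L, nrow(nodes))
    tgt[ok] <- id[nb[ok, , drop = FALSE]]
    hit <- which(tgt > 0L)
    if (length(hit))
      edges <- rbind(edges, cbind(hit, tgt[hit]))
  }
  structure(list(nodes = nodes, edges = edges, field = edt[lin], dims = dm,
                 spacing = mask$spacing, label = artery,
                 mask_ids = mask_label_ids(mask, artery, side), mask = mask),
            class = "vwi_skeleton")
}

#' @export
print.vwi_skeleton <- function(x, ...) {
  cat(sprintf("<vwi_skeleton %s  %d nodes  %d edges>\n", x$label,
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Principal centerlines from a skeleton
#'
#' Per connected component: cycles are broken at the node of minimal
#' distance-field value (with a warning), spur branches shorter than
#' `prune_len` mm hanging off junctions are removed, and the remaining graph
#' is decomposed into maximal endpoint/junction-to-endpoint/junction paths.
#' Each path becomes a [vwi_centerline] in world mm, ordered inferior to
#' superior (the endpoint with larger z comes last). Side is taken from the
#' mask labels under the component (majority vote), falling back to the
#' component's position relative to the mid-sagittal plane.
#'
#' @param skel A `vwi_skeleton`.
#' @param prune_len Spur pruning length in mm (default 3).
#' @param min_len Minimum centerline length to keep (mm).
#' @param max_cycle_breaks Cap on node-wise cycle breaking; beyond it the
#'   remaining cycles collapse onto a spanning forest (guards pathological,
#'   e.g. untrained-network, masks).
#' @return List of [vwi_centerline].
#' @export
principal_centerlines <- function(skel, prune_len = 3, min_len = 2,
                                  max_cycle_breaks = 200L) {
  n <- nrow(skel$nodes)
  if (n == 0) return(list())

  # adjacency lists (plain integer vectors; no graph library on the hot path)
  adj <- vector("list", n)
  if (nrow(skel$edges) > 0) {
    e <- skel$edges
    adj <- split(c(e[, 2], e[, 1]), factor(c(e[, 1], e[, 2]), levels = 1:n))
    adj <- lapply(adj, unique)
  } else adj <- rep(list(integer(0)), n)

  # drop staircase chords: a 26-adjacency edge that closes a triangle is a
  # discretization shortcut, not a topological cycle; remove longest first
  if (nrow(skel$edges) > 0) {
    e <- skel$edges
    elen <- sqrt(rowSums(((skel$nodes[e[, 1], , drop = FALSE] -
                           skel$nodes[e[, 2], , drop = FALSE]) *
                          rep(skel$spacing, each = nrow(e)))^2))
    for (r in order(-elen)) {
      u <- e[r, 1]; w <- e[r, 2]
      if (!(w %in% adj[[u]])) next
      if (length(intersect(adj[[u]], adj[[w]])) > 0) {
        adj[[u]] <- setdiff(adj[[u]], w)
        adj[[w]] <- setdiff(adj[[w]], u)
      }
    }
  }

  alive <- rep(TRUE, n)
  deg <- lengths(adj)

  drop_node <- function(v) {
    for (u in adj[[v]]) adj[[u]] <<- setdiff(adj[[u]], v)
    adj[[v]] <<- integer(0)
    alive[v] <<- FALSE
  }

  # components by BFS
  components <- function() {
    comp <- integer(n); cur <- 0L
    for (s0 in which(alive)) {
      if (comp[s0] > 0L) next
      cur <- cur + 1L
      queue <- s0; comp[s0] <- cur
      while (length(queue)) {
        v <- queue[[1]]; queue <- queue[-1]
        nb <- adj[[v]]
        new <- nb[comp[nb] == 0L]
        comp[new] <- cur
        queue <- c(queue, new)
      }
    }
    comp
  }

  # break genuine cycles at the weakest (most boundary-like) node
  find_cycle_edge <- function(nodes_in_comp) {
    # DFS spanning tree; a back edge reveals a cycle
    parent <- integer(n); seen <- logical(n)
    stack <- nodes_in_comp[1]; seen[stack] <- TRUE
    while (length(stack)) {
      v <- stack[[length(stack)]]; stack <- stack[-length(stack)]
      for (u in adj[[v]]) {
        if (!seen[u]) { seen[u] <- TRUE; parent[u] <- v; stack <- c(stack, u) }
        else if (u != parent[v]) {
          # walk both ancestries to recover the cycle nodes
          pa <- v; anc_v <- v
          while (pa != 0) { anc_v <- c(anc_v, pa); pa <- parent[pa] }
          path_u <- u
          pa <- parent[u]
          while (pa != 0 && !(pa %in% anc_v)) { path_u <- c(path_u, pa); pa <- parent[pa] }
          meet <- if (pa == 0) anc_v[length(anc_v)] else pa
          anc_part <- anc_v[seq_len(which(anc_v == meet))]
          return(unique(c(anc_part, path_u)))
        }
      }
    }
    NULL
  }
  breaks <- 0L
  repeat {
    comp <- components()
    ncomp <- max(comp, 0L)
    cyc_comp <- 0L
    for (cc in seq_len(ncomp)) {
      vs <- which(comp == cc)
      ne <- sum(deg_of(adj, vs)) / 2
      if (ne >= length(vs)) { cyc_comp <- cc; break }
    }
    if (cyc_comp == 0L) break
    if (breaks >= max_cycle_breaks) {
      warning("too many skeleton cycles; remaining cycles broken by spanning forest")
      # keep a BFS spanning forest only
      comp <- components()
      intree <- vector("list", n)
      seen <- logical(n)
      for (s0 in which(alive)) {
        if (seen[s0]) next
        queue <- s0; seen[s0] <- TRUE
        while (length(queue)) {
          v <- queue[[1]]; queue <- queue[-1]
          for (u in adj[[v]]) if (!seen[u]) {
            seen[u] <- TRUE
            intree[[v]] <- c(intree[[v]], u)
            intree[[u]] <- c(intree[[u]], v)
            queue <- c(queue, u)
          }
        }
      }
      adj <- intree
      adj[vapply(adj, is.null, TRUE)] <- list(integer(0))
      break
    }
    cyc <- find_cycle_edge(which(comp == cyc_comp))
    if (is.null(cyc)) break
    drop_node(cyc[which.min(skel$field[cyc])])
    breaks <- breaks + 1L
    if (breaks <= 3L)
      warning("cyclic skeleton component: cycle broken at weakest node")
  }
  deg <- lengths(adj)

  # iterative spur pruning: remove short leaf branches hanging off junctions
  seg_len <- function(path_nodes) {
    if (length(path_nodes) < 2) return(0)
    p <- sweep(skel$nodes[path_nodes, , drop = FALSE] - 1, 2, skel$spacing, "*")
    tail(polyline_arclength(p), 1)
  }
  repeat {
    deg <- lengths(adj)
    removed <- FALSE
    for (lf in which(alive & deg == 1)) {
      if (!alive[lf] || lengths(adj[lf]) != 1) next
      path <- lf; prev <- 0L; cur <- lf
      repeat {
        nb <- setdiff(adj[[cur]], prev)
        if (length(nb) != 1) break
        prev <- cur; cur <- nb
        path <- c(path, cur)
        if (length(adj[[cur]]) >= 3) break
      }
      if (length(path) >= 2 && length(adj[[tail(path, 1)]]) >= 3 &&
          seg_len(path) < prune_len) {
        for (v in head(path, -1)) drop_node(v)
        removed <- TRUE
      }
    }
    if (!removed) break
  }
  deg <- lengths(adj)

  # decompose into maximal endpoint/junction-to-endpoint/junction paths
  paths <- list()
  visited <- new.env(hash = TRUE)
  ekey <- function(a, b) paste(min(a, b), max(a, b))
  walk <- function(start, nxt) {
    path <- c(start, nxt)
    assign(ekey(start, nxt), TRUE, envir = visited)
    prev <- start; cur <- nxt
    while (deg[cur] == 2) {
      nb <- setdiff(adj[[cur]], prev)
      if (length(nb) == 0) break
      assign(ekey(cur, nb[1]), TRUE, envir = visited)
      prev <- cur; cur <- nb[1]
      path <- c(path, cur)
    }
    path
  }
  for (t0 in which(alive & (deg == 1 | deg >= 3))) {
    for (nb in adj[[t0]]) {
      if (exists(ekey(t0, nb), envir = visited)) next
      paths <- c(paths, list(walk(t0, nb)))
    }
  }

  out <- list()
  xmid <- (skel$dims[1] - 1) * skel$spacing[1] / 2
  for (pth in paths) {
    pts <- sweep(skel$nodes[pth, , drop = FALSE] - 1, 2, skel$spacing, "*")
    if (nrow(pts) < 2) next
    if (tail(polyline_arclength(pts), 1) < min_len) next
    if (pts[nrow(pts), 3] < pts[1, 3]) pts <- pts[nrow(pts):1, , drop = FALSE]
    # side: majority vote of mask label ids under the path
    ids <- skel$mask$data[skel$nodes[pth, , drop = FALSE]]
    ids <- ids[ids %in% skel$mask_ids]
    side <- if (length(ids)) {
      tab <- table(ids)
      skel$mask$labels$side[match(as.integer(names(tab)[which.max(tab)]),
                                  skel$mask$labels$id)]
    } else if (mean(pts[, 1]) >= xmid) "left" else "right"
    out <- c(out, list(vwi_centerline(pts, skel$label, side)))
  }
  out
}

deg_of <- function(adj, vs) lengths(adj[vs])
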