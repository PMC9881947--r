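# Multi-domain mesh generation from domain images.
#
# The mesher traces region boundaries along pixel edges, simplifies them
# (Douglas-Peucker, shared interface polylines simplified once so adjacent
# domains conform), resamples them at the local target element size, fills
# regions with graded interior points, and builds a constrained Delaunay
# triangulation (compiled core) followed by Laplacian smoothing of free
# vertices. Physical coordinates are y-up micrometres: pixel (r, c) owns
# the square x in [c-1, c] * pixel_size, y in [H-r, H-r+1] * pixel_size.

# integer region id per pixel: domain code (0 tissue, 1 connected,
# 2 disconnected) * 1e5 + organ label
.region_ids <- function(dom) {
  code_int <- matrix(0L, dom$height, dom$width)
  code_int[dom$codes == 1] <- 1L
  code_int[dom$codes == 0.5] <- 2L
  code_int * 100000L + dom$organ
}

# all lattice edges separating pixels of different region id, plus the
# image border; corners are indexed r * (W+1) + c + 1 with r in 0..H from
# the top and c in 0..W from the left
.boundary_edges <- function(rid) {
  H <- nrow(rid); W <- ncol(rid)
  cid <- function(r, c) r * (W + 1L) + c + 1L
  a <- integer(0); b <- integer(0)
  # vertical edges between horizontal neighbors (i,j) | (i,j+1)
  if (W > 1L) {
    d <- which(rid[, -W, drop = FALSE] != rid[, -1L, drop = FALSE], arr.ind = TRUE)
    if (nrow(d)) {
      i <- d[, 1L]; j <- d[, 2L]
      a <- c(a, cid(i - 1L, j)); b <- c(b, cid(i, j))
    }
  }
  # horizontal edges between vertical neighbors (i,j) | (i+1,j)
  if (H > 1L) {
    d <- which(rid[-H, , drop = FALSE] != rid[-1L, , drop = FALSE], arr.ind = TRUE)
    if (nrow(d)) {
      i <- d[, 1L]; j <- d[, 2L]
      a <- c(a, cid(i, j - 1L)); b <- c(b, cid(i, j))
    }
  }
  # border
  j <- seq_len(W)
  a <- c(a, cid(0L, j - 1L), cid(H, j - 1L)); b <- c(b, cid(0L, j), cid(H, j))
  i <- seq_len(H)
  a <- c(a, cid(i - 1L, 0L), cid(i - 1L, W)); b <- c(b, cid(i, 0L), cid(i, W))
  cbind(a, b, deparse.level = 0)
}

# split the boundary edge graph into chains between junction corners
# (degree != 2); isolated cycles are returned as closed chains
.boundary_chains <- function(edges, H, W) {
  nV <- (H + 1L) * (W + 1L)
  E <- nrow(edges)
  deg <- tabulate(c(edges[, 1L], edges[, 2L]), nbins = nV)
  # CSR incidence
  inc_v <- c(edges[, 1L], edges[, 2L])
  inc_e <- c(seq_len(E), seq_len(E))
  o <- order(inc_v)
  inc_v <- inc_v[o]; inc_e <- inc_e[o]
  ptr <- c(0L, cumsum(tabulate(inc_v, nbins = nV)))
  incident <- function(v) if (ptr[v] < ptr[v + 1L]) inc_e[(ptr[v] + 1L):ptr[v + 1L]] else integer(0)
  used <- logical(E)
  chains <- vector("list", 0L)
  walk <- function(v0, e0) {
    path <- v0
    v <- v0; e <- e0
    repeat {
      used[e] <<- TRUE
      v <- if (edges[e, 1L] == v) edges[e, 2L] else edges[e, 1L]
      path <- c(path, v)
      if (deg[v] != 2L || v == v0) break
      nxt <- incident(v)
      nxt <- nxt[!used[nxt]]
      if (!length(nxt)) break
      e <- nxt[1L]
    }
    path
  }
  junctions <- which(deg != 0L & deg != 2L)
  for (v0 in junctions) {
    for (e0 in incident(v0)) {
      if (!used[e0]) chains[[length(chains) + 1L]] <- walk(v0, e0)
    }
  }
  remaining <- which(!used)
  for (e0 in remaining) {
    if (!used[e0]) chains[[length(chains) + 1L]] <- walk(edges[e0, 1L], e0)
  }
  # corner ids -> y-up pixel coordinates
  lapply(chains, function(p) {
    r <- (p - 1L) %/% (W + 1L)
    c <- (p - 1L) %% (W + 1L)
    cbind(x = as.numeric(c), y = as.numeric(H - r), id = p)
  })
}

# Douglas-Peucker on an open polyline (matrix with x, y columns); returns
# row indices kept. Iterative stack version.
.dp_keep <- function(xy, tol) {
  n <- nrow(xy)
  if (n <= 2L) return(seq_len(n))
  keep <- logical(n); keep[c(1L, n)] <- TRUE
  stack <- list(c(1L, n))
  while (length(stack)) {
    seg <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    i <- seg[1L]; j <- seg[2L]
    if (j - i < 2L) next
    p <- xy[i, 1:2]; q <- xy[j, 1:2]
    d <- q - p; L <- sqrt(sum(d^2))
    idx <- (i + 1L):(j - 1L)
    if (L < .Machine$double.eps) {
      dist <- sqrt((xy[idx, 1L] - p[1L])^2 + (xy[idx, 2L] - p[2L])^2)
    } else {
      dist <- abs(d[2L] * (xy[idx, 1L] - p[1L]) - d[1L] * (xy[idx, 2L] - p[2L])) / L
    }
    k <- which.max(dist)
    if (dist[k] > tol) {
      m <- idx[k]
      keep[m] <- TRUE
      stack[[length(stack) + 1L]] <- c(i, m)
      stack[[length(stack) + 1L]] <- c(m, j)
    }
  }
  which(keep)
}

.simplify_chain <- function(ch, tol_px) {
  n <- nrow(ch)
  closed <- n > 3L && ch[1L, "id"] == ch[n, "id"]
  if (tol_px <= 0) return(ch)
  if (!closed) return(ch[.dp_keep(ch, tol_px), , drop = FALSE])
  # closed loop: anchor at start and at the farthest vertex, simplify halves
  d2 <- (ch[, 1L] - ch[1L, 1L])^2 + (ch[, 2L] - ch[1L, 2L])^2
  m <- which.max(d2)
  if (m <= 1L || m >= n) return(ch)
  k1 <- .dp_keep(ch[1:m, , drop = FALSE], tol_px)
  k2 <- .dp_keep(ch[m:n, , drop = FALSE], tol_px) + m - 1L
  ch[unique(c(k1, k2)), , drop = FALSE]
}

#' Trace and simplify domain boundaries
#'
#' Extracts the planar straight-line graph separating the domains of a
#' [domain_image()] (including the image border), as closed chains of
#' lattice-corner vertices simplified by Douglas-Peucker. Interface chains
#' are shared verbatim between the two adjacent domains, which is what
#' makes the downstream constrained triangulation conforming.
#'
#' @param dom a `domain_image`.
#' @param simplify_tol Douglas-Peucker tolerance in um (default half a
#'   pixel, i.e. sub-pixel fidelity).
#' @return list with `vertices` (V x 2, y-up pixel coordinates), `segments`
#'   (S x 2 vertex indices), and `chains` (list of simplified chains).
#' @export
extract_boundaries <- function(dom, simplify_tol = 0.5 * dom$pixel_size) {
  stopifnot(inherits(dom, "domain_image"))
  rid <- .region_ids(dom)
  edges <- .boundary_edges(rid)
  chains <- .boundary_chains(edges, dom$height, dom$width)
  tol_px <- simplify_tol / dom$pixel_size
  chains <- lapply(chains, .simplify_chain, tol_px = tol_px)
  # assemble unique vertices (shared corners keep a single index)
  ids <- unlist(lapply(chains, function(ch) ch[, "id"]))
  uid <- sort(unique(ids))
  vmap <- integer(max(uid)); vmap[uid] <- seq_along(uid)
  verts <- NULL
  seglist <- list()
  for (ch in chains) {
    idx <- vmap[ch[, "id"]]
    if (is.null(verts)) {
      verts <- matrix(NA_real_, length(uid), 2L)
    }
    verts[idx, 1L] <- ch[, "x"]
    verts[idx, 2L] <- ch[, "y"]
    n <- length(idx)
    if (n >= 2L) seglist[[length(seglist) + 1L]] <- cbind(idx[-n], idx[-1L])
  }
  segments <- do.call(rbind, seglist)
  segments <- segments[segments[, 1L] != segments[, 2L], , drop = FALSE]
  list(vertices = verts, segments = segments, chains = chains)
}

# deterministic uniform hash in [0,1) from integer lattice indices
.hash01 <- function(ix, iy) {
  h <- (ix * 73856093 + iy * 19349663) %% 2147483647
  h <- (h * 48271) %% 2147483647
  h / 2147483647
}

#' Build a conforming multi-domain triangular mesh from a domain image
#'
#' Constrained Delaunay triangulation of the simplified region boundaries
#' with graded interior point sampling: the target edge length grows from
#' `boundary_spacing` at domain boundaries by `grad_limit` per unit
#' distance, capped so element areas stay below `max_area`. Free vertices
#' are Laplacian-smoothed with Delaunay re-legalization.
#'
#' @param dom a `domain_image`.
#' @param grad_limit mesh density gradient limit (dimensionless, default
#'   0.2): bound on the growth of target element size with distance from
#'   domain boundaries.
#' @param max_area element area cap in um^2 (default `25 * pixel_size^2`).
#' @param simplify_tol boundary simplification tolerance in um.
#' @param boundary_spacing target boundary edge length in um (default
#'   `2 * pixel_size`).
#' @param smooth_iters Laplacian smoothing sweeps (default 4).
#' @param refine_quality quality threshold below which element circumcenters
#'   are inserted (Delaunay refinement); 0 disables refinement.
#' @param refine_rmin circumradius floor (px) under which elements are left
#'   alone, preventing refinement below the boundary resolution.
#' @return a `domain_mesh`: list with `nodes` (n x 2 um, y-up), `elements`
#'   (m x 3, counter-clockwise), `code` (element domain codes 0/0.5/1),
#'   `organ` (element organ labels), `areas` (um^2), `constrained` (k x 2
#'   constrained edges), `fixed` (logical per node: boundary vertex),
#'   `pixel_size`, `img_height`, `img_width`.
#' @export
build_mesh <- function(dom, grad_limit = 0.2,
                       max_area = 25 * dom$pixel_size^2,
                       simplify_tol = 0.5 * dom$pixel_size,
                       boundary_spacing = 2 * dom$pixel_size,
                       smooth_iters = 4, refine_quality = 0.65,
                       refine_rmin = 1.0) {
  stopifnot(inherits(dom, "domain_image"))
  ps <- dom$pixel_size
  H <- dom$height; W <- dom$width
  rid <- .region_ids(dom)

  # distance (px) from each pixel to the nearest region-boundary pixel
  bmask <- matrix(FALSE, H, W)
  if (W > 1L) {
    d <- rid[, -W, drop = FALSE] != rid[, -1L, drop = FALSE]
    bmask[, -W] <- bmask[, -W] | d
    bmask[, -1L] <- bmask[, -1L] | d
  }
  if (H > 1L) {
    d <- rid[-H, , drop = FALSE] != rid[-1L, , drop = FALSE]
    bmask[-H, ] <- bmask[-H, ] | d
    bmask[-1L, ] <- bmask[-1L, ] | d
  }
  dist_px <- EBImage::distmap(1 - bmask)
  dist_px <- matrix(as.numeric(dist_px), H, W)

  h_b <- boundary_spacing / ps                 # px
  h_max <- sqrt(4 * max_area / sqrt(3)) / ps   # px
  h_of <- function(d) pmin(h_max, h_b + grad_limit * d)

  tol <- simplify_tol
  for (attempt in 1:4) {
    pslg <- extract_boundaries(dom, simplify_tol = tol)
    verts <- pslg$vertices
    segs <- pslg$segments

    # resample long segments at the local target size
    sa <- verts[segs[, 1L], , drop = FALSE]
    sb <- verts[segs[, 2L], , drop = FALSE]
    len <- sqrt(rowSums((sb - sa)^2))
    mx <- (sa[, 1L] + sb[, 1L]) / 2
    my <- (sa[, 2L] + sb[, 2L]) / 2
    pc <- pmin(pmax(ceiling(mx), 1L), W)
    pr <- pmin(pmax(ceiling(H - my + 1e-9), 1L), H)
    hseg <- h_of(dist_px[cbind(pr, pc)])
    nsub <- pmax(1L, ceiling(len / hseg))
    newv <- list(); newsegs <- list()
    nv <- nrow(verts)
    for (s in seq_len(nrow(segs))) {
      k <- nsub[s]
      if (k == 1L) {
        newsegs[[s]] <- segs[s, , drop = FALSE]
      } else {
        t <- seq_len(k - 1L) / k
        px <- sa[s, 1L] + t * (sb[s, 1L] - sa[s, 1L])
        py <- sa[s, 2L] + t * (sb[s, 2L] - sa[s, 2L])
        ids <- nv + seq_len(k - 1L)
        nv <- nv + k - 1L
        newv[[length(newv) + 1L]] <- cbind(px, py)
        chain <- c(segs[s, 1L], ids, segs[s, 2L])
        newsegs[[s]] <- cbind(chain[-length(chain)], chain[-1L])
      }
    }
    verts <- rbind(verts, do.call(rbind, newv))
    segs <- do.call(rbind, newsegs)

    # graded interior points on a jittered triangular lattice, thinned by
    # a deterministic hash to the local target density
    s0 <- h_b
    ys <- seq(s0 * 0.5, H - s0 * 0.4, by = s0 * sqrt(3) / 2)
    cand <- NULL
    if (length(ys)) {
      rows <- lapply(seq_along(ys), function(i) {
        off <- if (i %% 2L == 0L) s0 / 2 else 0
        xs <- seq(s0 * 0.5 + off, W - s0 * 0.4, by = s0)
        if (!length(xs)) return(NULL)
        cbind(xs, ys[i], i, seq_along(xs))
      })
      cand <- do.call(rbind, rows)
    }
    interior <- matrix(numeric(0), 0L, 2L)
    if (!is.null(cand) && nrow(cand)) {
      jx <- (.hash01(cand[, 4L] * 7L + 1L, cand[, 3L] * 13L + 5L) - 0.5) * 0.4 * s0
      jy <- (.hash01(cand[, 4L] * 11L + 3L, cand[, 3L] * 17L + 7L) - 0.5) * 0.4 * s0
      x <- pmin(pmax(cand[, 1L] + jx, 0.25), W - 0.25)
      y <- pmin(pmax(cand[, 2L] + jy, 0.25), H - 0.25)
      pc <- pmin(pmax(ceiling(x), 1L), W)
      pr <- pmin(pmax(ceiling(H - y + 1e-9), 1L), H)
      dloc <- dist_px[cbind(pr, pc)]
      hloc <- h_of(dloc)
      u <- .hash01(cand[, 4L], cand[, 3L])
      keep <- (dloc + 0.5) > 0.75 * hloc & u < (s0 / hloc)^2
      interior <- cbind(x[keep], y[keep])
    }

    res <- cpp_triangulate(verts, segs, interior, rid, as.integer(smooth_iters),
                           refine_quality, refine_rmin)
    if (res$n_failed_segments == 0L) break
    if (attempt == 4L)
      stop("mesh generation failed: ", res$n_failed_segments,
           " boundary segments could not be recovered")
    tol <- tol / 2
  }

  nodes <- res$points * ps
  tri <- res$triangles
  region <- res$region
  # drop unreferenced vertices (duplicate insertions are skipped by the
  # triangulator) and compact the numbering
  used <- sort(unique(as.vector(tri)))
  if (length(used) < nrow(nodes)) {
    remap <- integer(nrow(nodes))
    remap[used] <- seq_along(used)
    nodes <- nodes[used, , drop = FALSE]
    tri <- matrix(remap[tri], ncol = 3L)
    res$fixed <- res$fixed[used]
    keep_ce <- res$constrained[, 1L] %in% used & res$constrained[, 2L] %in% used
    res$constrained <- matrix(remap[res$constrained[keep_ce, ]], ncol = 2L)
  }
  code_int <- region %/% 100000L
  code <- c(0, 1, 0.5)[code_int + 1L]
  organ <- region %% 100000L
  ax <- nodes[tri[, 1L], 1L]; ay <- nodes[tri[, 1L], 2L]
  bx <- nodes[tri[, 2L], 1L]; by <- nodes[tri[, 2L], 2L]
  cx <- nodes[tri[, 3L], 1L]; cy <- nodes[tri[, 3L], 2L]
  areas <- 0.5 * ((bx - ax) * (cy - ay) - (by - ay) * (cx - ax))
  if (any(areas <= 0)) {
    bad <- which(areas <= 0)
    stop("mesh contains ", length(bad), " non-positive-area elements")
  }
  structure(
    list(nodes = nodes, elements = tri, code = code, organ = organ,
         areas = areas, constrained = res$constrained, fixed = res$fixed,
         pixel_size = ps, img_height = H, img_width = W,
         options = list(grad_limit = grad_limit, max_area = max_area,
                        simplify_tol = simplify_tol,
                        boundary_spacing = boundary_spacing,
                        smooth_iters = smooth_iters,
                        refine_quality = refine_quality,
                        refine_rmin = refine_rmin)),
    class = "domain_mesh")
}

#' @export
print.domain_mesh <- function(x, ...) {
  q <- element_quality(x)
  cat(sprintf(
    "domain_mesh: %d nodes, %d elements (%d vessel, %d disconnected, %d tissue)\n",
    nrow(x$nodes), nrow(x$elements), sum(x$code == 1), sum(x$code == 0.5),
    sum(x$code == 0)))
  cat(sprintf("mean quality %.3f, min %.3f; total area %.4g um^2\n",
              mean(q), min(q), sum(x$areas)))
  invisible(x)
}

#' Triangle element quality
#'
#' Shape score `4 * sqrt(3) * A / (a^2 + b^2 + c^2)`, i.e. area over the
#' root-mean-square edge length squared scaled so an equilateral triangle
#' scores exactly 1 and a degenerate (collinear) one 0. The score is
#' invariant under uniform scaling.
#'
#' @param x a `domain_mesh` (vectorized over elements) or a 3 x 2 matrix
#'   of triangle vertex coordinates.
#' @return numeric vector of scores in `[0, 1]`.
#' @export
element_quality <- function(x) {
  if (inherits(x, "domain_mesh")) {
    p <- x$nodes; tri <- x$elements
    a2 <- rowSums((p[tri[, 2L], , drop = FALSE] - p[tri[, 1L], , drop = FALSE])^2)
    b2 <- rowSums((p[tri[, 3L], , drop = FALSE] - p[tri[, 2L], , drop = FALSE])^2)
    c2 <- rowSums((p[tri[, 1L], , drop = FALSE] - p[tri[, 3L], , drop = FALSE])^2)
    return(4 * sqrt(3) * x$areas / (a2 + b2 + c2))
  }
  p <- as.matrix(x)
  stopifnot(nrow(p) == 3L, ncol(p) == 2L)
  e <- rbind(p[2L, ] - p[1L, ], p[3L, ] - p[2L, ], p[1L, ] - p[3L, ])
  ss <- sum(e^2)
  A <- abs((p[2L, 1L] - p[1L, 1L]) * (p[3L, 2L] - p[1L, 2L]) -
           (p[2L, 2L] - p[1L, 2L]) * (p[3L, 1L] - p[1L, 1L])) / 2
  if (ss == 0) return(0)
  4 * sqrt(3) * A / ss
}

#' Mesh quality report
#'
#' @param mesh a `domain_mesh`.
#' @param bins histogram bin count over `[0, 1]`.
#' @return list with `scores`, `mean`, `min`, `hist` (counts), `breaks`,
#'   and `flag_low_quality` (TRUE when the mean is below 0.9, the accepted
#'   threshold for an accurate solution).
#' @export
mesh_quality <- function(mesh, bins = 20) {
  q <- element_quality(mesh)
  br <- seq(0, 1, length.out = bins + 1L)
  list(scores = q, mean = mean(q), min = min(q),
       hist = as.integer(table(cut(q, br, include.lowest = TRUE))),
       breaks = br, flag_low_quality = mean(q) < 0.9)
}

# all (element, edge) triples as a data-frame-free list of matrices
.element_edges <- function(mesh) {
  tri <- mesh$elements
  m <- nrow(tri)
  u <- c(tri[, 1L], tri[, 2L], tri[, 3L])
  v <- c(tri[, 2L], tri[, 3L], tri[, 1L])
  list(u = u, v = v, elem = rep.int(seq_len(m), 3L),
       key = paste(pmin(u, v), pmax(u, v)))
}

#' Classify inlet and interface nodes of a multi-domain mesh
#'
#' Inlet nodes are vessel-domain nodes within half a pixel of an inlet
#' image side. Edge (interface) nodes are shared between a connected-vessel
#' element and a non-vessel element. Interface edges carry unit normals
#' pointing outward from the vessel domain.
#'
#' @param mesh a `domain_mesh`.
#' @param inlet_sides subset of `c("left", "right")`.
#' @return a `boundary_sets` list: `inlet_nodes`, `edge_nodes`,
#'   `inlet_edges` (e x 2), `interface_edges` (e x 2), `interface_normals`
#'   (e x 2, outward from vessels), `interface_lengths` (um).
#' @export
classify_nodes <- function(mesh, inlet_sides = c("left", "right")) {
  stopifnot(inherits(mesh, "domain_mesh"))
  inlet_sides <- match.arg(inlet_sides, c("left", "right"), several.ok = TRUE)
  ps <- mesh$pixel_size
  Wum <- mesh$img_width * ps
  vess <- mesh$code == 1
  vnodes <- sort(unique(as.vector(mesh$elements[vess, , drop = FALSE])))
  onodes <- sort(unique(as.vector(mesh$elements[!vess, , drop = FALSE])))
  x <- mesh$nodes[, 1L]
  at_inlet <- rep(FALSE, nrow(mesh$nodes))
  if ("left" %in% inlet_sides) at_inlet <- at_inlet | x < 0.5 * ps
  if ("right" %in% inlet_sides) at_inlet <- at_inlet | x > Wum - 0.5 * ps
  inlet_nodes <- intersect(vnodes, which(at_inlet))
  edge_nodes <- intersect(vnodes, onodes)

  ee <- .element_edges(mesh)
  in_vess <- vess[ee$elem]
  vkeys <- unique(ee$key[in_vess])
  okeys <- unique(ee$key[!in_vess])
  ikeys <- intersect(vkeys, okeys)
  # take the directed representative from the vessel element (CCW) so the
  # right-hand normal points out of the vessel domain
  idx <- which(in_vess & ee$key %in% ikeys)
  idx <- idx[!duplicated(ee$key[idx])]
  iu <- ee$u[idx]; iv <- ee$v[idx]
  dx <- mesh$nodes[iv, 1L] - mesh$nodes[iu, 1L]
  dy <- mesh$nodes[iv, 2L] - mesh$nodes[iu, 2L]
  len <- sqrt(dx^2 + dy^2)
  normals <- cbind(dy / len, -dx / len)

  # boundary edges of the vessel submesh that lie on an inlet side
  vkey_tab <- table(ee$key[in_vess])
  bkeys <- names(vkey_tab)[vkey_tab == 1L]
  bidx <- which(in_vess & ee$key %in% bkeys)
  bu <- ee$u[bidx]; bv <- ee$v[bidx]
  on_inlet <- at_inlet[bu] & at_inlet[bv]
  inlet_edges <- cbind(bu[on_inlet], bv[on_inlet])

  structure(
    list(inlet_nodes = inlet_nodes, edge_nodes = edge_nodes,
         inlet_edges = inlet_edges,
         interface_edges = cbind(iu, iv),
         interface_normals = normals,
         interface_lengths = len,
         inlet_sides = inlet_sides),
    class = "boundary_sets")
}

#' @export
print.boundary_sets <- function(x, ...) {
  cat(sprintf("boundary_sets: %d inlet nodes (%s), %d interface nodes, %d interface edges\n",
              length(x$inlet_nodes), paste(x$inlet_sides, collapse = "+"),
              length(x$edge_nodes), nrow(x$interface_edges)))
  invisible(x)
}
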