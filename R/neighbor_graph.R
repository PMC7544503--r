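# Cell-cell contact approximation from nuclear positions.
#
# Contacts are approximated by the 1-skeleton of the 3D Delaunay
# tetrahedralization of the nuclear centroids at one frame, i.e. pairs of
# nuclei whose Voronoi cells share a facet. The tetrahedralization is
# computed with an incremental Bowyer-Watson algorithm on coordinates
# rescaled to the unit box, with the four auxiliary "super-tetrahedron"
# vertices placed 1e4 box lengths away so that the finite construction
# agrees with the true Delaunay complex on the data points. Exactness on
# generic inputs is checked in the test suite against a brute-force
# empty-circumsphere oracle.

# circumcenters and squared radii for a set of tetrahedra (k x 4 index matrix)
tet_circumspheres <- function(points, tets) {
  v1 <- points[tets[, 1], , drop = FALSE]
  a <- points[tets[, 2], , drop = FALSE] - v1
  b <- points[tets[, 3], , drop = FALSE] - v1
  c3 <- points[tets[, 4], , drop = FALSE] - v1
  cross3 <- function(u, v) {
    cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
          u[, 3] * v[, 1] - u[, 1] * v[, 3],
          u[, 1] * v[, 2] - u[, 2] * v[, 1])
  }
  bc <- cross3(b, c3); ca <- cross3(c3, a); ab <- cross3(a, b)
  den <- 2 * rowSums(a * bc)  # 12 * signed volume
  num <- rowSums(a * a) * bc + rowSums(b * b) * ca + rowSums(c3 * c3) * ab
  ctr <- v1 + num / den
  list(center = ctr, r2 = rowSums((ctr - v1)^2), den = den)
}

#' Delaunay edges of a 3D point set
#'
#' Low-level geometric routine: returns the unordered vertex pairs of the
#' Delaunay tetrahedralization (equivalently, pairs whose Voronoi cells
#' share a facet). Input must contain at least 4 affinely independent
#' points. Exactly coincident points are perturbed by a deterministic,
#' seed-free jitter of 1e-6 length units keyed to row order, with a warning.
#'
#' @param points n x 3 numeric matrix
#' @return integer matrix with two columns (row indices into `points`,
#'   first column < second), one row per Delaunay edge
#' @export
delaunay_edges <- function(points) {
  points <- as.matrix(points)
  if (!is.numeric(points) || ncol(points) != 3L) stop("points must be an n x 3 numeric matrix")
  n <- nrow(points)
  if (n < 4L) stop("geometry error: need at least 4 points for a 3D contact graph")
  dup <- duplicated(round(points, 9))
  if (any(dup)) {
    warning(sum(dup), " duplicate coordinate(s) perturbed by deterministic 1e-6 jitter")
    idx <- which(dup)
    points[idx, ] <- points[idx, ] +
      1e-6 * seq_along(idx) * matrix(c(1, 1, 1) / sqrt(3), length(idx), 3, byrow = TRUE)
  }
  ctr <- colMeans(points)
  rng <- max(apply(points, 2, function(v) diff(range(v))))
  if (rng <= 0) rng <- 1
  p <- sweep(points, 2, ctr) / rng
  # affine-independence check
  sv <- svd(scale(p, center = TRUE, scale = FALSE), nu = 0, nv = 0)$d
  if (sv[3] < 1e-9 * max(sv[1], 1)) {
    stop("geometry error: points are (nearly) coplanar; a 3D contact graph is undefined")
  }
  # exactly cospherical/degenerate configurations can defeat the incremental
  # construction; retry with a deterministic, growing symbolic perturbation
  for (attempt in 0:2) {
    pj <- if (attempt == 0) p else {
      jit <- 10^(-9 + attempt) * outer(seq_len(n), c(1, 2, 3)) / n
      p + jit
    }
    res <- tryCatch(bw_triangulate(pj, n), error = function(e) e)
    if (!inherits(res, "error")) {
      if (attempt > 0) warning("degenerate configuration resolved by deterministic jitter")
      return(res)
    }
  }
  stop(res)
}

bw_triangulate <- function(p, n, M = 1e4) {
  sup <- M * rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  allp <- rbind(p, sup)
  tets <- matrix(n + 1:4, nrow = 1)
  cs <- tet_circumspheres(allp, tets)
  cc <- cs$center; r2 <- cs$r2
  for (i in seq_len(n)) {
    d2 <- (cc[, 1] - p[i, 1])^2 + (cc[, 2] - p[i, 2])^2 + (cc[, 3] - p[i, 3])^2
    bad <- d2 <= r2 * (1 + 1e-12) + 1e-10
    if (!any(bad)) stop("internal geometry failure: point outside all circumspheres")
    cav <- tets[bad, , drop = FALSE]
    faces <- rbind(cav[, -1, drop = FALSE], cav[, -2, drop = FALSE],
                   cav[, -3, drop = FALSE], cav[, -4, drop = FALSE])
    lo <- pmin(faces[, 1], faces[, 2], faces[, 3])
    hi <- pmax(faces[, 1], faces[, 2], faces[, 3])
    mid <- faces[, 1] + faces[, 2] + faces[, 3] - lo - hi
    key <- (lo * (n + 5) + mid) * (n + 5) + hi
    dup <- key %in% key[duplicated(key)]
    bound <- cbind(lo, mid, hi)[!dup, , drop = FALSE]
    newt <- cbind(bound, i)
    cs <- tet_circumspheres(allp, newt)
    if (any(!is.finite(cs$den)) || any(abs(cs$den) < 1e-14)) {
      stop("internal geometry failure: degenerate tetrahedron (cospherical input?)")
    }
    tets <- rbind(tets[!bad, , drop = FALSE], newt)
    cc <- rbind(cc[!bad, , drop = FALSE], cs$center)
    r2 <- c(r2[!bad], cs$r2)
  }
  keep <- rowSums(tets <= n) == 4L
  tt <- tets[keep, , drop = FALSE]
  if (nrow(tt) == 0L) return(matrix(integer(0), 0, 2))
  e <- rbind(tt[, c(1, 2)], tt[, c(1, 3)], tt[, c(1, 4)],
             tt[, c(2, 3)], tt[, c(2, 4)], tt[, c(3, 4)])
  lo <- pmin(e[, 1], e[, 2]); hi <- pmax(e[, 1], e[, 2])
  uk <- !duplicated(lo * (n + 1) + hi)
  cbind(lo[uk], hi[uk])
}

#' Contact graph of an embryo at one frame
#'
#' Approximates cell-cell contacts at frame `time` as the Delaunay
#' 1-skeleton of the calibrated nuclear positions (the dual of the Voronoi
#' diagram). With `prune_factor` p > 0, edges longer than p times the median
#' edge length are removed; the default keeps the full skeleton.
#'
#' @param recording an [embryo_recording()] in micron units
#' @param time frame index
#' @param prune_factor 0 (no pruning) or a positive multiple of the median
#'   edge length above which edges are discarded
#' @return an object of class `contact_graph`: list with `time`, `cells`
#'   (names present at the frame) and `edges` (two-column character matrix
#'   of unordered adjacent pairs, with edge lengths in the `lengths`
#'   attribute)
#' @export
contact_graph <- function(recording, time, prune_factor = 0) {
  if (recording$units != "um") {
    stop("contact graphs are built on calibrated micron coordinates; ",
         "run calibrate_to_microns() first")
  }
  if (prune_factor < 0) stop("prune_factor must be >= 0")
  fr <- frame_obs(recording, time)
  if (nrow(fr) < 4L) {
    stop("geometry error: only ", nrow(fr), " nuclei at frame ", time,
         "; need at least 4")
  }
  pts <- as.matrix(fr[, c("x", "y", "z")])
  eidx <- delaunay_edges(pts)
  len <- sqrt(rowSums((pts[eidx[, 1], , drop = FALSE] -
                         pts[eidx[, 2], , drop = FALSE])^2))
  if (prune_factor > 0 && nrow(eidx)) {
    keep <- len <= prune_factor * stats::median(len)
    eidx <- eidx[keep, , drop = FALSE]
    len <- len[keep]
  }
  edges <- cbind(fr$cell[eidx[, 1]], fr$cell[eidx[, 2]])
  # canonical order within each pair, then by pair
  swap <- edges[, 1] > edges[, 2]
  edges[swap, ] <- edges[swap, c(2, 1), drop = FALSE]
  ord <- order(edges[, 1], edges[, 2])
  structure(list(time = time, cells = fr$cell,
                 edges = edges[ord, , drop = FALSE],
                 lengths = len[ord]),
            class = "contact_graph")
}

#' @export
print.contact_graph <- function(x, ...) {
  cat(sprintf("<contact_graph> t=%d: %d cells, %d edges\n",
              x$time, length(x$cells), nrow(x$edges)))
  invisible(x)
}

#' Neighbors of a cell in a contact graph
#' @param graph a [contact_graph()]
#' @param cell cell name (must be observed at the graph's frame)
#' @return character vector of adjacent cell names (possibly empty)
#' @export
neighbors_of <- function(graph, cell) {
  if (!cell %in% graph$cells) {
    stop("cell '", cell, "' is not observed at frame ", graph$time)
  }
  hit1 <- graph$edges[, 1] == cell
  hit2 <- graph$edges[, 2] == cell
  sort(unique(c(graph$edges[hit1, 2], graph$edges[hit2, 1])))
}

#' Edge list of a contact graph as a data.frame
#' @param x a [contact_graph()]
#' @param ... unused
#' @return data.frame with columns `time`, `cell_a`, `cell_b`, `length_um`
#' @export
as.data.frame.contact_graph <- function(x, ...) {
  data.frame(time = rep(x$time, nrow(x$edges)),
             cell_a = x$edges[, 1], cell_b = x$edges[, 2],
             length_um = x$lengths)
}
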