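#' Periodic simulation box
#'
#' A rectangular box with periodic boundary conditions. Lengths are in units
#' of \eqn{\sqrt{A_0}}, so a box of sides 14 x 18.6 holds 260 unit-area cells.
#'
#' @param Lx,Ly box side lengths (must be positive).
#' @return An object of class `periodic_box`: a named numeric vector.
#' @export
periodic_box <- function(Lx, Ly) {
  if (!is.numeric(Lx) || !is.numeric(Ly) || length(Lx) != 1L || length(Ly) != 1L ||
      !is.finite(Lx) || !is.finite(Ly) || Lx <= 0 || Ly <= 0)
    stop("box sides must be finite positive numbers")
  structure(c(Lx = Lx, Ly = Ly), class = "periodic_box")
}

as_box <- function(box) {
  if (inherits(box, "periodic_box")) return(box)
  if (is.numeric(box) && length(box) == 2L) return(periodic_box(box[[1L]], box[[2L]]))
  if (is.list(box) && all(c("Lx", "Ly") %in% names(box)))
    return(periodic_box(box$Lx, box$Ly))
  stop("cannot interpret 'box' as a periodic box")
}

# reduce coordinates into [0, L)
wrap_positions <- function(pos, box) {
  pos[, 1L] <- pos[, 1L] %% box[[1L]]
  pos[, 2L] <- pos[, 2L] %% box[[2L]]
  pos
}

# minimum-image displacement, componentwise
min_image <- function(d, box) {
  d[, 1L] <- d[, 1L] - box[[1L]] * round(d[, 1L] / box[[1L]])
  d[, 2L] <- d[, 2L] - box[[2L]] * round(d[, 2L] / box[[2L]])
  d
}

# Flattened cell-loop structure used by the vectorized force/area kernels.
# One entry per (cell, vertex) incidence, in counterclockwise loop order:
#   cid   cell index of the entry
#   v     vertex at the entry
#   vn    next vertex in the loop
#   pe    index of the previous entry within the same loop (cyclic)
#   starts, lens  first entry and length of each loop
build_cell_cache <- function(cells) {
  lens <- lengths(cells)
  n <- sum(lens)
  starts <- cumsum(c(1L, lens[-length(lens)]))
  v <- unlist(cells, use.names = FALSE)
  idx <- seq_len(n)
  nxt <- idx + 1L
  ends <- starts + lens - 1L
  nxt[ends] <- starts
  pe <- idx - 1L
  pe[starts] <- ends
  list(cid = rep.int(seq_along(cells), lens), v = v, vn = v[nxt],
       pe = pe, starts = starts, lens = lens)
}

new_tissue <- function(box, pos, ja, jb, l0, cells,
                       state = integer(length(ja)), timer = numeric(length(ja)),
                       gamma = numeric(length(ja))) {
  t <- structure(list(
    box = as_box(box),
    pos = wrap_positions(pos, box),
    ja = as.integer(ja), jb = as.integer(jb),
    l0 = as.numeric(l0),
    state = as.integer(state), timer = as.numeric(timer),
    gamma = as.numeric(gamma),
    cells = cells,
    cache = build_cell_cache(cells),
    stats = list(t1_count = 0L, t1_skipped = 0L)
  ), class = "tissue")
  t
}

#' @export
print.tissue <- function(x, ...) {
  cat(sprintf("Periodic tissue: %d cells, %d junctions, %d vertices, box %.3f x %.3f\n",
              length(x$cells), length(x$ja), nrow(x$pos), x$box[[1L]], x$box[[2L]]))
  fr <- state_fractions(x)
  cat(sprintf("junction states: %.3f inactive, %.3f active, %.3f refractory\n",
              fr[[1L]], fr[[2L]], fr[[3L]]))
  invisible(x)
}

n_cells <- function(tissue) length(tissue$cells)
n_junctions <- function(tissue) length(tissue$ja)
n_vertices <- function(tissue) nrow(tissue$pos)

# all junction minimum-image vectors (E x 2) and lengths
junction_vectors <- function(tissue) {
  min_image(tissue$pos[tissue$jb, , drop = FALSE] -
            tissue$pos[tissue$ja, , drop = FALSE], tissue$box)
}

junction_lengths <- function(tissue) {
  d <- junction_vectors(tissue)
  sqrt(d[, 1L]^2 + d[, 2L]^2)
}

#' Minimum-image geometry of one junction
#'
#' @param tissue a `tissue` object.
#' @param junction junction index.
#' @return A list with `vector` (the minimum-image displacement from the first
#'   endpoint to the second) and `length` (its norm, \eqn{l_{ij}}).
#' @export
junction_geometry <- function(tissue, junction) {
  j <- as.integer(junction)
  if (length(j) != 1L || is.na(j) || j < 1L || j > n_junctions(tissue))
    stop("invalid junction index")
  d <- min_image(tissue$pos[tissue$jb[j], , drop = FALSE] -
                 tissue$pos[tissue$ja[j], , drop = FALSE], tissue$box)
  list(vector = as.numeric(d), length = sqrt(sum(d^2)))
}

# vectorized areas of all cells; loops are unwrapped with minimum-image hops
# before the shoelace sum, so cells crossing the box boundary are handled
cell_areas <- function(tissue) {
  ca <- tissue$cache
  pos <- tissue$pos
  box <- tissue$box
  dx <- pos[ca$vn, 1L] - pos[ca$v, 1L]
  dy <- pos[ca$vn, 2L] - pos[ca$v, 2L]
  dx <- dx - box[[1L]] * round(dx / box[[1L]])
  dy <- dy - box[[2L]] * round(dy / box[[2L]])
  csx <- cumsum(dx); csy <- cumsum(dy)
  n <- length(dx)
  sx <- c(0, csx[-n]); sy <- c(0, csy[-n])
  bx <- rep.int(sx[ca$starts], ca$lens)
  by <- rep.int(sy[ca$starts], ca$lens)
  rx <- sx - bx; ry <- sy - by         # vertex position relative to loop anchor
  cross <- rx * (ry + dy) - (rx + dx) * ry
  as.vector(rowsum(cross, ca$cid, reorder = TRUE)) / 2
}

#' Area of a single cell
#'
#' Shoelace area of the cell's vertex loop, unwrapped to a single periodic
#' image with minimum-image hops along the loop.
#'
#' @param tissue a `tissue` object.
#' @param cell cell index.
#' @return Positive area (units \eqn{A_0}).
#' @export
cell_area <- function(tissue, cell) {
  i <- as.integer(cell)
  if (length(i) != 1L || is.na(i) || i < 1L || i > n_cells(tissue))
    stop("invalid cell index")
  a <- cell_areas(tissue)[i]
  if (!is.finite(a) || a <= 0) stop("invalid geometry: non-positive cell area")
  a
}

#' Build an ordered hexagonal tissue
#'
#' Constructs a periodic honeycomb tiling of `n_cells` regular unit-area
#' hexagons (pointy-top orientation, `ncols` columns by `nrows` rows with
#' `nrows` even). The requested box is adjusted to the nearest commensurate
#' dimensions and a message reports the adjustment. All junctions start
#' inactive with rest length equal to length (zero strain); the lattice is a
#' mechanical equilibrium of the tissue energy by symmetry.
#'
#' @param n_cells number of cells; must factor as `ncols * nrows` with `nrows`
#'   even.
#' @param box requested box (a `periodic_box` or length-2 numeric); used to
#'   choose the factorization closest in aspect.
#' @return A `tissue` object.
#' @export
make_hexagonal_tissue <- function(n_cells, box = NULL) {
  n_cells <- as.integer(n_cells)
  if (is.na(n_cells) || n_cells < 2L) stop("n_cells must be a positive integer >= 2")
  a <- (4 / 27)^(1 / 4)                 # edge of a unit-area regular hexagon
  sx <- sqrt(3) * a                     # column spacing (Lx = ncols * sx)
  sy <- 1.5 * a                         # row spacing   (Ly = nrows * sy)
  divs <- which(n_cells %% seq_len(n_cells) == 0L)
  cand <- divs[(n_cells %/% divs) %% 2L == 0L]   # nrows must be even
  if (!length(cand))
    stop(sprintf("n_cells = %d cannot be factored into ncols x nrows with even nrows", n_cells))
  if (is.null(box)) {
    score <- abs(log((cand * sx) / ((n_cells / cand) * sy)))  # closest to square
  } else {
    box <- as_box(box)
    score <- abs(cand * sx - box[[1L]]) + abs((n_cells / cand) * sy - box[[2L]])
  }
  ncols <- cand[which.min(score)]
  nrows <- n_cells %/% ncols
  Lx <- ncols * sx
  Ly <- nrows * sy
  if (!is.null(box) && (abs(Lx - box[[1L]]) > 1e-9 || abs(Ly - box[[2L]]) > 1e-9))
    message(sprintf("box adjusted to commensurate dimensions %.4f x %.4f (%d cols x %d rows)",
                    Lx, Ly, ncols, nrows))
  # integer vertex lattice: units ux = sqrt(3) a / 2 (x), uy = a / 2 (y)
  nx <- 2L * ncols
  ny <- 3L * nrows
  i <- rep(seq_len(nrows) - 1L, each = ncols)      # row of each cell
  j <- rep(seq_len(ncols) - 1L, times = nrows)     # column
  cx <- 2L * j + (i %% 2L)
  cy <- 3L * i
  offx <- c(1L, 0L, -1L, -1L, 0L, 1L)              # CCW from the 30-degree vertex
  offy <- c(1L, 2L, 1L, -1L, -2L, -1L)
  vx <- outer(cx, offx, "+") %% nx                 # n_cells x 6
  vy <- outer(cy, offy, "+") %% ny
  key <- vx + nx * vy
  ukey <- sort(unique(as.vector(key)))
  vid <- matrix(match(key, ukey), nrow = n_cells)
  pos <- cbind((ukey %% nx) * sx / 2, (ukey %/% nx) * a / 2)
  cells <- lapply(seq_len(n_cells), function(c) vid[c, ])
  tis <- loops_to_tissue(as_box(c(Lx, Ly)), pos, cells)
  tis
}

# assemble a tissue from vertex positions + CCW loops; derives the junction
# list and initializes all junctions inactive with zero strain
loops_to_tissue <- function(box, pos, cells) {
  ends <- do.call(rbind, lapply(cells, function(lp) cbind(lp, c(lp[-1L], lp[1L]))))
  pair <- cbind(pmin(ends[, 1L], ends[, 2L]), pmax(ends[, 1L], ends[, 2L]))
  upair <- unique(pair)
  tis <- new_tissue(box, pos, upair[, 1L], upair[, 2L],
                    l0 = rep(1, nrow(upair)), cells = cells)
  tis$l0 <- junction_lengths(tis)
  tis
}

#' Build a disordered tissue
#'
#' Seeded random points are relaxed with a few Lloyd iterations, tessellated
#' with a periodic Voronoi construction, and the resulting polygonal network
#' is mechanically equilibrated (all contractilities zero) under the tissue
#' energy. Rest lengths are then set to the current lengths so all junctions
#' start strain-free and inactive. Identical inputs give identical tissues.
#'
#' @param n_cells number of cells (>= 3).
#' @param box periodic box.
#' @param seed integer seed fixing all randomness.
#' @param n_lloyd Lloyd (centroidal Voronoi) iterations before equilibration.
#' @param mech mechanical parameters used for equilibration
#'   (contractilities are ignored; line tension and area elasticity apply).
#' @param tol force tolerance passed to [equilibrate()].
#' @return An equilibrated `tissue` with heterogeneous junction lengths and
#'   polygon sidedness.
#' @export
make_disordered_tissue <- function(n_cells, box, seed, n_lloyd = 4L,
                                   mech = mech_params(), tol = 1e-6) {
  n_cells <- as.integer(n_cells)
  if (is.na(n_cells) || n_cells < 3L) stop("n_cells must be >= 3")
  box <- as_box(box)
  for (attempt in 0:2) {
    pts <- withr::with_seed(seed, {
      p <- cbind(stats::runif(n_cells, 0, box[[1L]]), stats::runif(n_cells, 0, box[[2L]]))
      if (attempt > 0)  # deterministic retry jitter for degenerate tessellations
        p <- wrap_positions(p + stats::runif(2L * n_cells, -1e-3, 1e-3) * attempt, box)
      p
    })
    for (k in seq_len(n_lloyd)) pts <- voronoi_centroids(pts, box)
    polys <- periodic_voronoi(pts, box)
    tis <- try(polygons_to_tissue(polys, box), silent = TRUE)
    if (!inherits(tis, "try-error")) break
  }
  if (inherits(tis, "try-error")) stop("degenerate Voronoi tessellation: ", tis)
  tis <- equilibrate(tis, mech, tol = tol)
  tis
}

# clip a convex polygon (rows of `poly`) by the half-plane dot(x, nrm) <= c
clip_halfplane <- function(poly, nrm, cc) {
  s <- poly %*% nrm - cc
  m <- nrow(poly)
  nx <- c(2:m, 1L)
  keep_in <- s <= 0
  out <- vector("list", m)
  for (i in seq_len(m)) {
    jn <- nx[i]
    seg <- NULL
    if (keep_in[i]) seg <- poly[i, , drop = FALSE]
    if (xor(keep_in[i], keep_in[jn])) {
      t <- s[i] / (s[i] - s[jn])
      seg <- rbind(seg, poly[i, ] + t * (poly[jn, ] - poly[i, ]))
    }
    out[[i]] <- seg
  }
  do.call(rbind, out)
}

# Voronoi cell polygons (absolute coordinates, CCW) on the torus, by
# half-plane clipping against periodic images of the neighbouring points
periodic_voronoi <- function(pts, box) {
  n <- nrow(pts)
  sh <- as.matrix(expand.grid(x = c(-1, 0, 1) * box[[1L]], y = c(-1, 0, 1) * box[[2L]]))
  imgs <- do.call(rbind, lapply(seq_len(nrow(sh)),
                                function(k) sweep(pts, 2L, sh[k, ], "+")))
  h <- 3 * sqrt(box[[1L]] * box[[2L]] / n)
  square <- matrix(c(-h, -h, h, -h, h, h, -h, h), ncol = 2L, byrow = TRUE)
  lapply(seq_len(n), function(i) {
    p <- pts[i, ]
    rel <- sweep(imgs, 2L, p)
    d2 <- rel[, 1L]^2 + rel[, 2L]^2
    nb <- order(d2)
    nb <- nb[d2[nb] > 1e-18 & d2[nb] < (2.2 * h)^2]
    poly <- square
    for (q in nb) {
      poly <- clip_halfplane(poly, rel[q, ], sum(rel[q, ]^2) / 2)
      if (is.null(poly) || nrow(poly) < 3L) stop("empty Voronoi cell")
    }
    sweep(poly, 2L, p, "+")
  })
}

poly_centroid <- function(poly) {
  x <- poly[, 1L]; y <- poly[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cr <- x * yn - xn * y
  A <- sum(cr) / 2
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * A)
}

voronoi_centroids <- function(pts, box) {
  polys <- periodic_voronoi(pts, box)
  wrap_positions(do.call(rbind, lapply(polys, poly_centroid)), box)
}

# merge per-cell polygon corners into a shared vertex set (periodic
# single-linkage clustering at `tol`) and assemble the tissue
polygons_to_tissue <- function(polys, box, tol = 1e-6) {
  lens <- vapply(polys, nrow, 1L)
  allv <- wrap_positions(do.call(rbind, polys), box)
  dx <- abs(outer(allv[, 1L], allv[, 1L], "-")); dx <- pmin(dx, box[[1L]] - dx)
  dy <- abs(outer(allv[, 2L], allv[, 2L], "-")); dy <- pmin(dy, box[[2L]] - dy)
  cl <- stats::cutree(stats::hclust(stats::as.dist(sqrt(dx^2 + dy^2)), method = "single"),
                      h = tol)
  reps <- match(seq_len(max(cl)), cl)     # first member represents the cluster
  pos <- allv[reps, , drop = FALSE]
  cells <- vector("list", length(polys))
  off <- 0L
  for (i in seq_along(polys)) {
    lp <- cl[off + seq_len(lens[i])]
    lp <- lp[c(TRUE, lp[-1L] != lp[-lens[i]])]
    if (lp[length(lp)] == lp[1L]) lp <- lp[-length(lp)]
    if (length(lp) < 3L) stop("degenerate cell after vertex merging")
    cells[[i]] <- lp
    off <- off + lens[i]
  }
  tis <- loops_to_tissue(box, pos, cells)
  deg <- tabulate(c(tis$ja, tis$jb), nrow(pos))
  if (any(deg != 3L)) stop("tessellation produced a vertex of valence != 3")
  tis
}

#' Validate tissue invariants
#'
#' Checks that every junction is shared by exactly two cells, the Euler
#' relation V - E + C = 0 holds on the torus, vertices are 3-valent, cell
#' areas are positive and partition the box area, and rest lengths are
#' positive.
#'
#' @param tissue a `tissue` object.
#' @param area_tol tolerance on the area partition.
#' @return A list with `ok` (logical) and `failures` (character vector naming
#'   each violated invariant; empty when `ok`).
#' @export
validate_tissue <- function(tissue, area_tol = 1e-9) {
  fail <- character(0)
  V <- n_vertices(tissue); E <- n_junctions(tissue); C <- n_cells(tissue)
  if (V - E + C != 0L) fail <- c(fail, "Euler relation V - E + C = 0 violated")
  ends <- cbind(tissue$cache$v, tissue$cache$vn)
  key <- paste(pmin(ends[, 1L], ends[, 2L]), pmax(ends[, 1L], ends[, 2L]))
  cnt <- table(key)
  if (length(cnt) != E || any(cnt != 2L))
    fail <- c(fail, "junction not shared by exactly 2 cells")
  jkey <- paste(pmin(tissue$ja, tissue$jb), pmax(tissue$ja, tissue$jb))
  if (anyDuplicated(jkey) || !all(jkey %in% names(cnt)))
    fail <- c(fail, "junction list inconsistent with cell loops")
  deg <- tabulate(c(tissue$ja, tissue$jb), V)
  if (any(deg != 3L)) fail <- c(fail, "vertex valence != 3")
  ar <- cell_areas(tissue)
  if (any(!is.finite(ar)) || any(ar <= 0)) fail <- c(fail, "non-positive cell area")
  else if (abs(sum(ar) - tissue$box[[1L]] * tissue$box[[2L]]) > area_tol * max(1, E))
    fail <- c(fail, "cell areas do not partition the box area")
  if (any(tissue$l0 <= 0)) fail <- c(fail, "non-positive rest length")
  if (any(!tissue$state %in% 0:2)) fail <- c(fail, "invalid junction state")
  list(ok = length(fail) == 0L, failures = fail)
}

#' Polygon sidedness distribution
#'
#' @param tissue a `tissue` object.
#' @return Integer vector of side counts per cell.
#' @export
cell_sides <- function(tissue) lengths(tissue$cells)
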