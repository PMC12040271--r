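# Free-energy surfaces over the first two principal components and
# density-grid cluster analysis.
#
# The probability density over (V1, V2) is estimated by a 2-D histogram;
# the free-energy surface is dG = -kB*T [ln rho - ln rho_max], zero at the
# most populated cell by construction and reported in kB*T units unless an
# absolute unit conversion is requested.  Isolated density maxima seed
# conformational clusters; remaining populated cells join a seed by
# steepest-ascent hill climbing, and clusters are ranked by peak density so
# cluster 1 always holds the global density maximum.

KB_KCAL <- 0.0019872  # Boltzmann constant, kcal/(mol K)

#' 2-D density histogram of two principal components
#'
#' Equal-width bins per axis over the data's bounding box, padded by 1% so
#' boundary points fall strictly inside; counts are normalised to a density
#' (counts / (T * cell area)).
#'
#' @param v1,v2 numeric vectors of equal length T (frame projections).
#' @param bins number of bins per axis (>= 2).
#' @param pad fractional padding of the bounding box.
#' @return object of class `fes` with `grid_edges` (list of two length
#'   `bins+1` vectors), `counts`, `density`, `rho_max`, and (until
#'   [free_energy()] fills it) a `NULL` `delta_g`.
#' @export
fes_density <- function(v1, v2, bins = 64L, pad = 0.01) {
  stopifnot(length(v1) == length(v2), bins >= 2L)
  t_n <- length(v1)
  if (t_n == 0L) stop("no frames to histogram")
  edges <- function(v) {
    r <- range(v)
    w <- diff(r)
    if (w == 0) w <- max(abs(r[1]), 1)  # degenerate axis: unit-width box
    seq(r[1] - pad * w, r[2] + pad * w, length.out = bins + 1L)
  }
  e1 <- edges(v1); e2 <- edges(v2)
  i1 <- findInterval(v1, e1, rightmost.closed = TRUE)
  i2 <- findInterval(v2, e2, rightmost.closed = TRUE)
  counts <- matrix(0, bins, bins)
  for (f in seq_len(t_n)) counts[i1[f], i2[f]] <- counts[i1[f], i2[f]] + 1
  cell_area <- diff(e1)[1] * diff(e2)[1]
  density <- counts / (t_n * cell_area)
  structure(list(grid_edges = list(v1 = e1, v2 = e2), counts = counts,
                 density = density, rho_max = max(density), delta_g = NULL,
                 n_frames = t_n),
            class = "fes")
}

#' @export
print.fes <- function(x, ...) {
  b <- nrow(x$density)
  cat("free-energy surface:", b, "x", b, "grid,", x$n_frames, "frames,",
      sum(x$density > 0), "populated cells\n")
  if (!is.null(x$delta_g))
    cat("  dG range: 0 -", sprintf("%.2f", max(x$delta_g, na.rm = TRUE)),
        x$units, "\n")
  invisible(x)
}

#' Fill the free-energy surface of a density histogram
#'
#' `dG = -kB T [ln rho - ln rho_max]`, so dG = 0 exactly at the highest
#' density cell.  By default energies are in kB*T units (temperature-free);
#' `units = "kcal/mol"` multiplies by kB*T at the given temperature.
#' Zero-density cells are masked as `NA` (outside the sampled region).
#'
#' @param surface an [fes_density()] result.
#' @param units `"kBT"` or `"kcal/mol"`.
#' @param temperature temperature in kelvin, used only for absolute units.
#' @return the surface with `delta_g` filled.
#' @export
free_energy <- function(surface, units = c("kBT", "kcal/mol"),
                        temperature = 310) {
  stopifnot(inherits(surface, "fes"))
  units <- match.arg(units)
  rho <- surface$density
  if (all(rho == 0)) stop("all-zero density; cannot form a free-energy surface")
  dg <- -(log(rho) - log(surface$rho_max))
  dg[dg == 0] <- 0           # canonical +0 at the density maximum
  dg[rho == 0] <- NA_real_
  if (units == "kcal/mol") dg <- dg * KB_KCAL * temperature
  surface$delta_g <- dg
  surface$units <- units
  surface$temperature <- if (units == "kcal/mol") temperature else NA_real_
  surface
}

# Separable Gaussian smoothing of a matrix (reflected edges); sigma in
# cells.  Used only for cluster seeding/climbing, never for delta_g.
smooth_matrix <- function(m, sigma) {
  if (sigma <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  pad_conv <- function(v) {
    n <- length(v)
    vp <- c(rev(v[seq_len(half)]), v, rev(v[n + 1 - seq_len(half)]))
    stats::filter(vp, k, sides = 2)[(half + 1):(half + n)]
  }
  m <- apply(m, 2L, pad_conv)
  t(apply(t(m), 2L, pad_conv))
}

#' Density-grid cluster analysis of a free-energy surface
#'
#' Isolated maxima of the density grid seed conformational clusters; every
#' populated cell joins a seed basin by steepest-ascent hill climbing over
#' the 8-neighbourhood, and clusters are ranked by raw peak density so
#' cluster 1 always contains the global density maximum.
#'
#' Two regularisations make the maxima "isolated" in a statistically
#' meaningful sense on a finite-frame histogram, whose raw counts carry
#' Poisson shot noise that would otherwise fragment every basin into many
#' one-cell maxima: (i) seed detection and climbing run on a lightly
#' smoothed copy of the density (Gaussian, `smooth_sigma` cells; the
#' free-energy values themselves are never smoothed), and (ii) a basin is
#' only kept separate when its peak is prominent -- it must rise above its
#' highest saddle to a higher-peaked basin by at least
#' `prominence_fraction` of its own height, otherwise it merges into that
#' basin.  Deep, well-separated basins always survive (their saddle is
#' near zero); noise ripples on a basin shoulder never do.  Surviving
#' maxima below `min_density_fraction` of the maximum are folded into the
#' nearest seed.
#'
#' @param surface an [fes_density()]/[free_energy()] result.
#' @param min_density_fraction seed threshold as a fraction of the maximum
#'   (smoothed) density.
#' @param smooth_sigma Gaussian sigma in grid cells for seed detection;
#'   `0` disables smoothing.
#' @param prominence_fraction minimum relative prominence of a surviving
#'   basin peak (0 disables prominence merging).
#' @return object of class `cluster_map`: `cell_labels` (B x B integers,
#'   0 = unpopulated), `peaks` (data.frame of ranked cluster peaks),
#'   `n_clusters`, and the grid edges.
#' @export
find_clusters <- function(surface, min_density_fraction = 0.05,
                          smooth_sigma = 1.5, prominence_fraction = 0.5) {
  stopifnot(inherits(surface, "fes"))
  rho <- surface$density
  b1 <- nrow(rho); b2 <- ncol(rho)
  s <- smooth_matrix(rho, smooth_sigma)
  # steepest-ascent pointer on the smoothed field, over the whole grid:
  # empty cells may be traversed (a sparse histogram's basin need not be a
  # connected set of populated cells) but only populated cells get labels
  nbi <- c(-1, -1, -1, 0, 0, 1, 1, 1)
  nbj <- c(-1, 0, 1, -1, 1, -1, 0, 1)
  ptr <- matrix(0L, b1, b2)      # linear index of best uphill neighbour
  for (i in seq_len(b1)) {
    for (j in seq_len(b2)) {
      best_v <- s[i, j]; best <- 0L
      for (q in 1:8) {
        ii <- i + nbi[q]; jj <- j + nbj[q]
        if (ii < 1 || ii > b1 || jj < 1 || jj > b2) next
        if (s[ii, jj] > best_v) {
          best_v <- s[ii, jj]; best <- (jj - 1L) * b1 + ii
        }
      }
      ptr[i, j] <- best  # 0 => local maximum (ties stay put; plateau cells
    }                    #      collapse via the equal-value merge below)
  }
  # terminal cell of every cell by pointer chasing (memoised)
  term <- matrix(0L, b1, b2)
  chase <- function(lin) {
    path <- integer(0)
    while (TRUE) {
      if (term[lin] != 0L) break
      nxt <- ptr[lin]
      if (nxt == 0L) { term[lin] <<- lin; break }
      path <- c(path, lin)
      lin <- nxt
    }
    t0 <- term[lin]
    if (length(path)) term[path] <<- t0
    t0
  }
  for (lin in seq_len(b1 * b2)) chase(lin)
  # merge adjacent equal-valued terminal maxima (plateaus) by union-find
  terms <- unique(as.integer(term))
  parent <- stats::setNames(terms, terms)
  findp <- function(x) {
    while (parent[[as.character(x)]] != x) x <- parent[[as.character(x)]]
    x
  }
  for (t0 in terms) {
    i <- (t0 - 1L) %% b1 + 1L; j <- (t0 - 1L) %/% b1 + 1L
    for (q in 1:8) {
      ii <- i + nbi[q]; jj <- j + nbj[q]
      if (ii < 1 || ii > b1 || jj < 1 || jj > b2) next
      lin <- (jj - 1L) * b1 + ii
      if (term[lin] == lin && s[lin] == s[t0]) {
        ra <- findp(t0); rb <- findp(lin)
        if (ra != rb) parent[[as.character(rb)]] <- ra
      }
    }
  }
  basin <- matrix(vapply(as.integer(term), findp, numeric(1)), b1, b2)
  # saddle heights between adjacent basins: max over shared boundary of
  # min(s, s-neighbour)
  roots <- unique(as.integer(basin))
  rid <- match(basin, roots)                    # basin id per cell
  nb_count <- length(roots)
  saddle <- matrix(-Inf, nb_count, nb_count)
  for (i in seq_len(b1)) {
    for (j in seq_len(b2)) {
      a <- rid[(j - 1L) * b1 + i]
      for (q in c(2, 4, 5, 7)) {                # right/down suffice... use all 8
        ii <- i + nbi[q]; jj <- j + nbj[q]
        if (ii < 1 || ii > b1 || jj < 1 || jj > b2) next
        b <- rid[(jj - 1L) * b1 + ii]
        if (a == b) next
        h <- min(s[i, j], s[ii, jj])
        if (h > saddle[a, b]) { saddle[a, b] <- h; saddle[b, a] <- h }
      }
    }
  }
  peak_s <- vapply(roots, function(r0) s[r0], numeric(1))
  alive <- rep(TRUE, nb_count)
  merged_into <- seq_len(nb_count)
  if (prominence_fraction > 0 && nb_count > 1L) {
    repeat {
      cand <- NULL
      for (a in which(alive)) {
        hi <- which(alive & peak_s > peak_s[a] |
                      (alive & peak_s == peak_s[a] & seq_len(nb_count) < a))
        hi <- setdiff(hi, a)
        if (!length(hi)) next
        sa <- max(saddle[a, hi])
        if (!is.finite(sa)) next
        if (peak_s[a] - sa < prominence_fraction * peak_s[a]) {
          tgt <- hi[which.max(saddle[a, hi])]
          if (is.null(cand) || sa > cand$sa) cand <- list(a = a, tgt = tgt, sa = sa)
        }
      }
      if (is.null(cand)) break
      a <- cand$a; tgt <- cand$tgt
      alive[a] <- FALSE
      merged_into[merged_into == a] <- tgt
      saddle[tgt, ] <- pmax(saddle[tgt, ], saddle[a, ])
      saddle[, tgt] <- pmax(saddle[, tgt], saddle[a, ])
      saddle[tgt, tgt] <- -Inf
      peak_s[tgt] <- max(peak_s[tgt], peak_s[a])
    }
  }
  rid_final <- merged_into[rid]
  # restrict to basins that contain populated cells
  pop_cells <- which(rho > 0)
  live <- sort(unique(rid_final[pop_cells]))
  peak_live <- peak_s[live]
  is_seed <- peak_live >= min_density_fraction * max(peak_live)
  if (!any(is_seed)) is_seed[which.max(peak_live)] <- TRUE
  seed_ids <- live[is_seed]
  # sub-threshold basins join the nearest seed peak (cell coordinates)
  seed_peak_cell <- vapply(seed_ids, function(id) {
    cells <- pop_cells[rid_final[pop_cells] == id]
    cells[which.max(rho[cells])]
  }, numeric(1))
  if (any(!is_seed)) {
    sx <- (seed_peak_cell - 1) %% b1 + 1; sy <- (seed_peak_cell - 1) %/% b1 + 1
    for (id in live[!is_seed]) {
      cells <- pop_cells[rid_final[pop_cells] == id]
      pk <- cells[which.max(rho[cells])]
      i <- (pk - 1) %% b1 + 1; j <- (pk - 1) %/% b1 + 1
      near <- which.min((sx - i)^2 + (sy - j)^2)
      rid_final[rid_final == id] <- seed_ids[near]
    }
  }
  # rank clusters by raw peak density (desc); cluster 1 holds argmax rho
  seed_peak_rho <- vapply(seed_ids, function(id)
    max(rho[pop_cells[rid_final[pop_cells] == id]]), numeric(1))
  ord <- order(-seed_peak_rho, seed_ids)
  cell_labels <- matrix(0L, b1, b2)
  for (r in seq_along(ord)) {
    id <- seed_ids[ord[r]]
    cells <- pop_cells[rid_final[pop_cells] == id]
    cell_labels[cells] <- r
  }
  pk_cells <- vapply(seed_ids[ord], function(id) {
    cells <- pop_cells[rid_final[pop_cells] == id]
    cells[which.max(rho[cells])]
  }, numeric(1))
  peaks <- data.frame(
    cluster = seq_along(ord),
    cell_i = (pk_cells - 1) %% b1 + 1,
    cell_j = (pk_cells - 1) %/% b1 + 1,
    peak_density = seed_peak_rho[ord],
    n_cells = vapply(seed_ids[ord], function(id)
      sum(rid_final[pop_cells] == id), numeric(1)))
  structure(list(cell_labels = cell_labels, peaks = peaks,
                 n_clusters = length(seed_ids),
                 grid_edges = surface$grid_edges),
            class = "cluster_map")
}

#' @export
print.cluster_map <- function(x, ...) {
  cat("cluster_map:", x$n_clusters, "cluster(s)\n")
  print(utils::head(x$peaks, 5))
  invisible(x)
}

#' Assign frames to density clusters
#'
#' Labels each (v1, v2) point by the cluster of its grid cell.  Points
#' outside the grid bounds (possible only for data other than the surface's
#' own fitting frames) raise an error.
#'
#' @param cluster_map a [find_clusters()] result.
#' @param v1,v2 projections of the frames to label.
#' @return integer vector of cluster labels (0 for an unpopulated cell).
#' @export
assign_frames <- function(cluster_map, v1, v2) {
  stopifnot(inherits(cluster_map, "cluster_map"), length(v1) == length(v2))
  e1 <- cluster_map$grid_edges$v1
  e2 <- cluster_map$grid_edges$v2
  if (any(v1 < e1[1] | v1 > e1[length(e1)] |
          v2 < e2[1] | v2 > e2[length(e2)]))
    stop("point(s) outside the cluster grid bounds")
  i1 <- findInterval(v1, e1, rightmost.closed = TRUE)
  i2 <- findInterval(v2, e2, rightmost.closed = TRUE)
  cluster_map$cell_labels[cbind(i1, i2)]
}

#' Heat-map plot of a free-energy surface
#'
#' @param x an [fes] object with `delta_g` filled (see [free_energy()]).
#' @param ... passed to [graphics::image()].
#' @export
plot.fes <- function(x, ...) {
  if (is.null(x$delta_g)) x <- free_energy(x)
  mid <- function(e) (e[-1] + e[-length(e)]) / 2
  graphics::image(mid(x$grid_edges$v1), mid(x$grid_edges$v2), x$delta_g,
                  col = grDevices::hcl.colors(50, "viridis", rev = TRUE),
                  xlab = "V1", ylab = "V2",
                  main = paste0("Free-energy surface (", x$units, ")"), ...)
  invisible(x)
}
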