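# Self-organizing map on a hexagonal grid for fingerprint clustering.

# hexagonal (offset) grid coordinates; even rows are shifted half a cell,
# row pitch sqrt(3)/2, so neighboring hexagons are at unit distance.
hex_coords <- function(n_rows, n_cols) {
  g <- data.table::CJ(row = seq_len(n_rows), col = seq_len(n_cols),
                      sorted = FALSE)
  data.table::setorder(g, row, col)
  g[, `:=`(x = col + ifelse(row %% 2 == 0, 0.5, 0),
           y = row * sqrt(3) / 2)]
  g[]
}

#' Train a self-organizing map on binary fingerprints
#'
#' Standard online SOM on a hexagonal grid: per step the best-matching unit
#' of one fingerprint is found and all codebook cells within the (decaying)
#' Gaussian neighborhood of its hexagon are pulled toward the sample with a
#' decaying learning rate. The codebook is initialized from randomly drawn
#' fingerprints with small jitter; sample order and initialization are drawn
#' from `seed`, making training deterministic. Cluster ids follow the
#' `"k<row>.<col>"` convention (1-based row, then column).
#'
#' @param fingerprints 0/1 matrix (compounds x bits) or character vector of
#'   hex fingerprints.
#' @param n_rows,n_cols grid dimensions.
#' @param epochs passes over the data.
#' @param lr learning rate, decaying geometrically from `lr[1]` to `lr[2]`.
#' @param radius neighborhood radius (hex-grid units), decaying
#'   geometrically; default from `max(n_rows, n_cols)/2` down to 0.5.
#' @param seed integer seed.
#' @return List of class `som`: `codebook` (cells x bits), `n_rows`,
#'   `n_cols`, `grid` (cell coordinates and `cluster_id`), `assignments`
#'   (per-compound cluster id, factor over all cells), `unit` (per-compound
#'   cell index).
#' @export
train_som <- function(fingerprints, n_rows = 42L, n_cols = 26L,
                      epochs = 20L, lr = c(0.5, 0.02), radius = NULL,
                      seed = 1L) {
  X <- if (is.character(fingerprints)) fp_unpack(fingerprints)
       else as.matrix(fingerprints)
  storage.mode(X) <- "double"
  n <- nrow(X)
  if (n < 1L) stop("no fingerprints supplied", call. = FALSE)
  m <- as.integer(n_rows) * as.integer(n_cols)
  if (m > n * 10L)
    stop("grid has more than 10 cells per compound; shrink it", call. = FALSE)
  if (is.null(radius)) radius <- c(max(n_rows, n_cols) / 2, 0.5)

  grid <- hex_coords(n_rows, n_cols)
  grid[, cluster_id := sprintf("k%d.%d", row, col)]

  set.seed(seed)
  init <- X[sample.int(n, m, replace = m > n), , drop = FALSE] +
    matrix(runif(m * ncol(X), -0.05, 0.05), m)
  ord <- as.integer(replicate(epochs, sample.int(n)) - 1L)

  W <- som_train_cpp(X, init, grid$x, grid$y, ord,
                     lr[1], lr[2], radius[1], radius[2])
  unit <- som_bmu_cpp(X, W)
  structure(list(codebook = W, n_rows = as.integer(n_rows),
                 n_cols = as.integer(n_cols), grid = grid,
                 assignments = factor(grid$cluster_id[unit],
                                      levels = grid$cluster_id),
                 unit = unit),
            class = "som")
}

#' @export
print.som <- function(x, ...) {
  occ <- length(unique(x$unit))
  cat(sprintf("<som> %d x %d hexagonal grid (%d cells, %d occupied), %d compounds\n",
              x$n_rows, x$n_cols, x$n_rows * x$n_cols, occ,
              length(x$unit)))
  invisible(x)
}

#' Map fingerprints onto a trained SOM
#'
#' @param som a [train_som()] result.
#' @param fingerprints 0/1 matrix or hex strings.
#' @return Factor of cluster ids (levels: all grid cells).
#' @export
som_assign <- function(som, fingerprints) {
  X <- if (is.character(fingerprints)) fp_unpack(fingerprints)
       else as.matrix(fingerprints)
  storage.mode(X) <- "double"
  unit <- som_bmu_cpp(X, som$codebook)
  factor(som$grid$cluster_id[unit], levels = som$grid$cluster_id)
}

#' Pairwise hexagonal grid distance between SOM cells
#'
#' @param som a [train_som()] result.
#' @return Matrix of Euclidean distances between cell centers in hex-grid
#'   units (neighboring hexagons are at distance 1).
#' @export
som_cell_distances <- function(som) {
  as.matrix(stats::dist(cbind(som$grid$x, som$grid$y)))
}
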