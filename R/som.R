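#' Train a self-organizing map on latent vectors
#'
#' Classic online competitive learning on a rectangular neuron grid. At each
#' iteration one training vector is drawn at random, its best-matching neuron
#' (smallest Euclidean distance) is found, and every neuron is pulled toward
#' the vector with strength `lr(t) * exp(-grid_dist^2 / (2 sigma(t)^2))`.
#' Learning rate and neighborhood radius decay asymptotically,
#' `p(t) = p0 / (1 + 2t/T)`. Weights are initialized from randomly chosen
#' training vectors.
#'
#' @param x Numeric matrix, one training vector per row.
#' @param grid Integer vector `c(rows, cols)` of the output grid
#'   (default `c(30, 30)`).
#' @param iterations Number of online updates (default 15000).
#' @param lr Initial learning rate (default 0.5).
#' @param sigma Initial neighborhood radius in grid units (default half the
#'   grid width).
#' @param seed Integer seed.
#' @return An object of class `dus_som` with the weight matrix (`n_neurons x
#'   d`), grid coordinates and training settings.
#' @export
train_som <- function(x, grid = c(30L, 30L), iterations = 15000L,
                      lr = 0.5, sigma = max(grid) / 2, seed = 1L) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (nrow(x) == 0L) abort("no training vectors.")
  d <- ncol(x)
  n_neu <- prod(grid)
  gx <- rep(seq_len(grid[1]), times = grid[2])
  gy <- rep(seq_len(grid[2]), each = grid[1])

  withr::with_seed(seed, {
    w <- x[sample.int(nrow(x), n_neu, replace = TRUE), , drop = FALSE]
    for (t in seq_len(iterations)) {
      v <- x[sample.int(nrow(x), 1L), ]
      dif <- sweep(w, 2, v)  # w - v
      win <- which.min(rowSums(dif * dif))
      frac <- 1 + 2 * (t - 1) / iterations
      lr_t <- lr / frac
      sig_t <- sigma / frac
      h <- exp(-((gx - gx[win])^2 + (gy - gy[win])^2) / (2 * sig_t^2))
      act <- h > 1e-8
      w[act, ] <- w[act, , drop = FALSE] -
        (lr_t * h[act]) * dif[act, , drop = FALSE]
    }
  })

  structure(
    list(weights = w, grid = grid, gx = gx, gy = gy,
         iterations = iterations, lr = lr, sigma = sigma, seed = seed,
         d = d),
    class = "dus_som"
  )
}

#' @export
print.dus_som <- function(x, ...) {
  cat(sprintf("<dus_som> %d x %d grid, d = %d, %d iterations\n",
              x$grid[1], x$grid[2], x$d, x$iterations))
  invisible(x)
}

#' Quantization error of vectors under a trained map
#'
#' The quantization error of a vector is its Euclidean distance to the
#' best-matching (winning) neuron, i.e. the minimum over all neurons. Small
#' errors mean the vector resembles the training corpus; outliers (here:
#' low-quality segments) land far from every prototype.
#'
#' @param som A [train_som()] model.
#' @param x A single vector of length `d` or a matrix with one vector per
#'   row.
#' @return Numeric vector of nonnegative quantization errors.
#' @export
quantization_error <- function(som, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != som$d) abort("vector dimension does not match the map.")
  w <- som$weights
  w2 <- rowSums(w * w)
  # squared distances via ||w||^2 - 2 w.x + ||x||^2
  cross <- x %*% t(w)
  d2 <- sweep(-2 * cross, 2, w2, `+`) + rowSums(x * x)
  sqrt(pmax(apply(d2, 1, min), 0))
}
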