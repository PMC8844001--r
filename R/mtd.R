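#' Temporal derivatives of an ROI time series
#'
#' First step of the multiplication-of-temporal-derivatives (MTD) coupling
#' estimator: backward differences `dx(t) = x(t+1) - x(t)` per ROI, together
#' with each ROI's derivative standard deviation over the whole run
#' (population convention, i.e. denominator T-1 differences, mean removed).
#' The run-level sigma is the normaliser that makes coupling invariant to
#' per-ROI signal scale.
#'
#' @param ts a [roi_timeseries()] with at least 3 volumes.
#' @return list of class `mtd_derivatives`: `dx` ((T-1) x n_roi matrix),
#'   `sigma` (length n_roi), `roi_names`.
#' @export
temporal_derivatives <- function(ts) {
  stopifnot(inherits(ts, "roi_timeseries"))
  x <- ts$values
  if (nrow(x) < 3L) stop_invalid("MTD needs at least 3 volumes, got ", nrow(x))
  dx <- diff(x)
  n <- nrow(dx)
  mu <- colMeans(dx)
  sigma <- sqrt(colSums(sweep(dx, 2, mu)^2) / n)
  structure(list(dx = dx, sigma = as.numeric(sigma), roi_names = ts$roi_names),
            class = "mtd_derivatives")
}

#' Raw MTD coupling tensor
#'
#' For each derivative sample t and ROI pair (i, j),
#' `raw(t, i, j) = dx_i(t) * dx_j(t) / (sigma_i * sigma_j)`. The result is a
#' (T-1) x n_roi x n_roi array, symmetric in its last two dimensions. A flat
#' ROI (sigma = 0) carries no coupling information; its entries are set to 0
#' with a warning rather than propagating NaN into clustering.
#'
#' @param deriv output of [temporal_derivatives()].
#' @return numeric array (T-1) x n_roi x n_roi of class `mtd_raw`.
#' @export
mtd_coupling <- function(deriv) {
  stopifnot(inherits(deriv, "mtd_derivatives"))
  sigma <- deriv$sigma
  flat <- sigma <= 0
  if (any(flat)) {
    warning("ROI(s) with zero derivative variance: ",
            paste(deriv$roi_names[flat], collapse = ", "),
            "; their couplings are set to 0")
    sigma[flat] <- 1
  }
  z <- sweep(deriv$dx, 2, sigma, "/")
  z[, flat] <- 0
  tn <- nrow(z)
  p <- ncol(z)
  raw <- array(0, dim = c(tn, p, p),
               dimnames = list(NULL, deriv$roi_names, deriv$roi_names))
  for (t in seq_len(tn)) raw[t, , ] <- tcrossprod(z[t, ])
  structure(raw, class = "mtd_raw")
}

#' Moving-average smoothing of raw MTD coupling
#'
#' Each output coupling matrix is the unweighted mean of `w` consecutive raw
#' matrices. The edge convention drops the first `w` window positions and
#' keeps the remaining (T - 1) - w, so a 300-volume run with the recommended
#' 7-TR window yields exactly 292 coupling matrices: window j averages raw
#' samples j+1 .. j+w.
#'
#' @param raw array from [mtd_coupling()] ((T-1) x n x n).
#' @param w window size in TRs (default 7).
#' @return object of class `coupling_windows`: list with `matrices`
#'   (W x n x n array), `window_size`, `n_windows`, `roi_names`.
#' @export
smooth_windows <- function(raw, w = 7L) {
  if (!(is.array(raw) && length(dim(raw)) == 3L && dim(raw)[2] == dim(raw)[3])) {
    stop_invalid("raw must be a (T-1) x n x n array")
  }
  w <- assert_count(w, "w", min = 1L)
  tn <- dim(raw)[1]
  if (w >= tn) stop_invalid("window w = ", w, " must be smaller than T-1 = ", tn)
  p <- dim(raw)[2]
  n_win <- tn - w
  flat <- matrix(raw, nrow = tn)            # (T-1) x p^2, column-major pairs
  cs <- rbind(0, apply(flat, 2, cumsum))    # prepend zero row for differencing
  sm <- (cs[(w + 1L):(tn + 1L), , drop = FALSE] -
           cs[1L:(tn - w + 1L), , drop = FALSE]) / w
  # drop the first window position: keep positions 2..(tn - w + 1),
  # i.e. window j averages raw[(j+1):(j+w), , ]
  sm <- sm[-1L, , drop = FALSE]
  roi_names <- dimnames(raw)[[2]]
  mats <- array(t(sm), dim = c(p, p, n_win))  # temporary; reorder below
  mats <- aperm(mats, c(3, 1, 2))
  dimnames(mats) <- list(NULL, roi_names, roi_names)
  structure(list(matrices = mats, window_size = w, n_windows = n_win,
                 roi_names = roi_names),
            class = "coupling_windows")
}

#' @export
print.coupling_windows <- function(x, ...) {
  cat(sprintf("<coupling_windows> %d windows (w = %d TRs) x %d ROIs\n",
              x$n_windows, x$window_size, length(x$roi_names)))
  invisible(x)
}

#' Full MTD windowed-coupling pipeline for one run
#'
#' Convenience composition of [temporal_derivatives()], [mtd_coupling()] and
#' [smooth_windows()]. For larger ROI counts the raw tensor is never
#' materialised: window j's matrix equals `crossprod(z[(j+1):(j+w), ]) / w`
#' for the sigma-normalised derivatives `z`, which is algebraically identical
#' to averaging the raw outer products.
#'
#' @param ts a [roi_timeseries()].
#' @param w window size in TRs (default 7).
#' @return a `coupling_windows` object.
#' @export
mtd_windows <- function(ts, w = 7L) {
  deriv <- temporal_derivatives(ts)
  w <- assert_count(w, "w", min = 1L)
  tn <- nrow(deriv$dx)
  if (w >= tn) stop_invalid("window w = ", w, " must be smaller than T-1 = ", tn)
  sigma <- deriv$sigma
  flat <- sigma <= 0
  if (any(flat)) {
    warning("ROI(s) with zero derivative variance: ",
            paste(deriv$roi_names[flat], collapse = ", "),
            "; their couplings are set to 0")
    sigma[flat] <- 1
  }
  z <- sweep(deriv$dx, 2, sigma, "/")
  z[, flat] <- 0
  p <- ncol(z)
  n_win <- tn - w
  mats <- array(0, dim = c(n_win, p, p),
                dimnames = list(NULL, deriv$roi_names, deriv$roi_names))
  for (j in seq_len(n_win)) {
    mats[j, , ] <- crossprod(z[(j + 1L):(j + w), , drop = FALSE]) / w
  }
  structure(list(matrices = mats, window_size = w, n_windows = n_win,
                 roi_names = deriv$roi_names),
            class = "coupling_windows")
}

#' Vectorise the upper triangle of a symmetric coupling matrix
#'
#' Returns the n(n-1)/2 unique off-diagonal couplings in row-major
#' upper-triangle order: (1,2), (1,3), ..., (1,n), (2,3), ... For the 114-ROI
#' parcellation this is 6441 values. The diagonal is excluded.
#'
#' @param m symmetric numeric matrix.
#' @param tol asymmetry tolerance (default 1e-8).
#' @return numeric vector of length n(n-1)/2.
#' @export
vectorize_upper <- function(m, tol = 1e-8) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop_invalid("matrix must be square")
  if (max(abs(m - t(m))) > tol) {
    stop_invalid("matrix is asymmetric beyond tolerance ", tol)
  }
  # column-major lower triangle of a symmetric matrix enumerates the upper
  # triangle in row-major order
  m[lower.tri(m)]
}

#' Rebuild a symmetric matrix from its upper-triangle vector
#'
#' Inverse of [vectorize_upper()] up to the diagonal, which is filled with
#' `diag_value` (default 0; the diagonal carries no pairwise coupling).
#'
#' @param v vector of length n(n-1)/2.
#' @param diag_value value placed on the diagonal.
#' @return symmetric n x n matrix.
#' @export
devectorize_upper <- function(v, diag_value = 0) {
  p <- length(v)
  n <- (1 + sqrt(1 + 8 * p)) / 2
  if (abs(n - round(n)) > 1e-9) {
    stop_invalid("length ", p, " is not n(n-1)/2 for any integer n")
  }
  n <- as.integer(round(n))
  m <- matrix(diag_value, n, n)
  m[lower.tri(m)] <- v
  m[upper.tri(m)] <- t(m)[upper.tri(m)]
  m
}

#' Stack a run's coupling windows as clustering vectors
#'
#' @param cw a `coupling_windows` object.
#' @return numeric matrix, n_windows rows x n(n-1)/2 columns; row j is
#'   [vectorize_upper()] of window j.
#' @export
coupling_vectors <- function(cw) {
  stopifnot(inherits(cw, "coupling_windows"))
  p <- length(cw$roi_names)
  lower <- lower.tri(matrix(0, p, p))
  out <- matrix(0, cw$n_windows, sum(lower))
  for (j in seq_len(cw$n_windows)) {
    out[j, ] <- cw$matrices[j, , ][lower]
  }
  out
}
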