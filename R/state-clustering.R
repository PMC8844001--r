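# Connectivity-state detection: k-means under cityblock (Manhattan) distance
# over concatenated coupling vectors, plus centroid matching against
# reference states.

#' @useDynLib dfcstates, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

l1_distances <- function(x, centroids) {
  # x: W x p, centroids: k x p -> W x k distance matrix
  .l1_dist_cpp(x, centroids)
}

col_medians <- function(x, idx = seq_len(nrow(x))) {
  .col_medians_cpp(x, as.integer(idx))
}

#' Fit connectivity states by cityblock k-means
#'
#' Lloyd-style alternation with Manhattan (cityblock) distance and the
#' objective-consistent component-wise **median** centroid update (for the L1
#' cost the median, not the mean, minimises within-cluster distance). The
#' algorithm is restarted `n_restarts` times from different random
#' initialisations (seeds derived from `seed`) and the solution with the
#' lowest total within-cluster cityblock distance (inertia) is kept. An
#' empty cluster arising during iteration is re-seeded from the point
#' farthest from its current centroid. Iteration stops when labels are
#' unchanged or after `max_iter` sweeps; inertia is checked to be
#' non-increasing at every sweep.
#'
#' @param vectors numeric matrix, one coupling vector per row (windows
#'   concatenated across subjects and runs).
#' @param k number of states (default 5).
#' @param n_restarts random restarts (default 10).
#' @param seed integer master seed; the fit is deterministic given it.
#' @param max_iter maximum Lloyd sweeps per restart (default 300).
#' @return object of class `state_model`: `centroids` (k x p matrix),
#'   `labels` (per-row state index in 1..k), `inertia`, `k`, `seed`,
#'   `n_restarts`, `iterations`.
#' @export
fit_states <- function(vectors, k = 5L, n_restarts = 10L, seed = 1L,
                       max_iter = 300L) {
  vectors <- as.matrix(vectors)
  k <- assert_count(k, "k", min = 1L)
  n_restarts <- assert_count(n_restarts, "n_restarts", min = 1L)
  max_iter <- assert_count(max_iter, "max_iter", min = 1L)
  w <- nrow(vectors)
  if (w < k) stop_invalid("need at least k = ", k, " vectors, got ", w)
  seeds <- derive_seeds(seed, n_restarts)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- with_seed(seeds[r], kmedians_once(vectors, k, max_iter))
    if (is.null(best) || fit$inertia < best$inertia) best <- fit
  }
  structure(list(centroids = best$centroids, labels = best$labels,
                 inertia = best$inertia, k = k, seed = as.integer(seed),
                 n_restarts = n_restarts, iterations = best$iterations),
            class = "state_model")
}

kmedians_once <- function(x, k, max_iter) {
  init <- sample.int(nrow(x), k)
  fit <- .kmedians_fit_cpp(x, as.integer(init), as.integer(max_iter))
  list(centroids = fit$centroids, labels = as.integer(fit$labels),
       inertia = fit$inertia, iterations = fit$iterations)
}

#' @export
print.state_model <- function(x, ...) {
  cat(sprintf("<state_model> k = %d states over %d windows (p = %d), inertia %.4g\n",
              x$k, length(x$labels), ncol(x$centroids), x$inertia))
  invisible(x)
}

#' Assign coupling vectors to the nearest state centroid
#'
#' Out-of-sample labelling: each vector gets the state whose centroid is
#' nearest in cityblock distance; exact ties go to the lowest state index.
#'
#' @param vectors matrix of coupling vectors (rows).
#' @param centroids k x p centroid matrix, or a `state_model`.
#' @return integer vector of state labels in 1..k.
#' @export
assign_labels <- function(vectors, centroids) {
  if (inherits(centroids, "state_model")) centroids <- centroids$centroids
  vectors <- as.matrix(vectors)
  centroids <- as.matrix(centroids)
  if (ncol(vectors) != ncol(centroids)) {
    stop_invalid("vector length (", ncol(vectors),
                 ") must match centroid length (", ncol(centroids), ")")
  }
  d <- l1_distances(vectors, centroids)
  max.col(-d, ties.method = "first")
}

spearman_rho <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) return(NA_real_)
  stats::cor(rx, ry)
}

# All injective maps from 1..m into 1..n (m <= n), one map per row.
injective_maps <- function(m, n) {
  if (m == 0L) return(matrix(integer(0), 1, 0))
  if (m > n) stop_invalid("m must not exceed n")
  total <- prod((n - m + 1):n)
  if (total > 500000) {
    stop_invalid("too many states for exhaustive assignment (", total, " maps)")
  }
  grow <- function(prefix, remaining) {
    if (length(prefix) == m) return(matrix(prefix, 1))
    do.call(rbind, lapply(remaining, function(j) {
      grow(c(prefix, j), setdiff(remaining, j))
    }))
  }
  grow(integer(0), seq_len(n))
}

#' Match two centroid sets by Spearman concordance
#'
#' Computes all pairwise Spearman correlations (average ranks for ties)
#' between the centroid vectors of two sets and finds the one-to-one
#' assignment maximising total rho (equivalently, minimising total 1 - rho)
#' by exhaustive search over injective maps of the smaller set — exact for
#' the study-scale k (120 permutations at k = 5). This is how fitted states
#' receive names: by concordance with a reference (e.g. canonical TRS / HAS /
#' LAS) centroid file, never by hard-coded anatomy. Pairs whose rho falls
#' below `rho_floor`, is undefined (constant centroid), or centroids left
#' over when the sets differ in size, are reported as unmatched.
#'
#' @param set_a,set_b centroid matrices (one centroid vector per row), or
#'   `state_model` objects.
#' @param rho_floor concordance below which a pair counts as ambiguous
#'   (default 0.5).
#' @return object of class `centroid_match`: `mapping` (data.frame with
#'   columns `a`, `b`, `rho`), `rho_matrix`, `unmatched` (list with `a`,
#'   `b` index vectors).
#' @export
match_centroids <- function(set_a, set_b, rho_floor = 0.5) {
  if (inherits(set_a, "state_model")) set_a <- set_a$centroids
  if (inherits(set_b, "state_model")) set_b <- set_b$centroids
  set_a <- as.matrix(set_a)
  set_b <- as.matrix(set_b)
  if (nrow(set_a) == 0L || nrow(set_b) == 0L) stop_invalid("both centroid sets must be nonempty")
  if (ncol(set_a) != ncol(set_b)) {
    stop_invalid("centroid vector lengths differ (", ncol(set_a), " vs ", ncol(set_b), ")")
  }
  ka <- nrow(set_a)
  kb <- nrow(set_b)
  rho <- matrix(NA_real_, ka, kb)
  for (i in seq_len(ka)) {
    for (j in seq_len(kb)) rho[i, j] <- spearman_rho(set_a[i, ], set_b[j, ])
  }
  if (anyNA(rho)) {
    warning("constant centroid vector(s): some pairwise rho undefined")
  }
  score <- rho
  score[is.na(score)] <- -2  # worse than any achievable rho
  swap <- ka > kb
  s <- if (swap) t(score) else score
  maps <- injective_maps(min(ka, kb), max(ka, kb))
  totals <- apply(maps, 1, function(mp) sum(s[cbind(seq_along(mp), mp)]))
  mp <- maps[which.max(totals), ]
  if (swap) {
    mapping <- data.frame(a = mp, b = seq_len(kb))
  } else {
    mapping <- data.frame(a = seq_len(ka), b = mp)
  }
  mapping$rho <- rho[cbind(mapping$a, mapping$b)]
  mapping <- mapping[order(mapping$a), , drop = FALSE]
  rownames(mapping) <- NULL
  ambiguous <- is.na(mapping$rho) | mapping$rho < rho_floor
  unmatched <- list(
    a = sort(unique(c(setdiff(seq_len(ka), mapping$a), mapping$a[ambiguous]))),
    b = sort(unique(c(setdiff(seq_len(kb), mapping$b), mapping$b[ambiguous])))
  )
  structure(list(mapping = mapping, rho_matrix = rho, unmatched = unmatched,
                 rho_floor = rho_floor),
            class = "centroid_match")
}

#' @export
print.centroid_match <- function(x, ...) {
  cat("<centroid_match>\n")
  print(x$mapping)
  if (length(x$unmatched$a) || length(x$unmatched$b)) {
    cat("unmatched/ambiguous: a =", paste(x$unmatched$a, collapse = ","),
        " b =", paste(x$unmatched$b, collapse = ","), "\n")
  }
  invisible(x)
}

#' Optimally relabel fitted states against reference labels
#'
#' Finds the one-to-one state relabelling that maximises agreement with a
#' reference labelling (exhaustive over injective maps) and applies it.
#' Useful for measuring recovery of a known generating partition, where the
#' fitted state indices are arbitrary.
#'
#' @param labels integer labels in 1..k (fitted).
#' @param reference integer labels of the same length (ground truth).
#' @param k number of states (default: max over both).
#' @return list: `labels` (relabelled), `agreement` (fraction equal to the
#'   reference), `map` (fitted index -> reference index).
#' @export
align_labels <- function(labels, reference, k = max(labels, reference)) {
  if (length(labels) != length(reference)) {
    stop_invalid("labels and reference must have equal length")
  }
  k <- assert_count(k, "k", min = 1L)
  conf <- matrix(0, k, k)
  tab <- table(factor(labels, levels = seq_len(k)),
               factor(reference, levels = seq_len(k)))
  conf[] <- as.numeric(tab)
  maps <- injective_maps(k, k)
  totals <- apply(maps, 1, function(mp) sum(conf[cbind(seq_len(k), mp)]))
  mp <- maps[which.max(totals), ]
  relabelled <- mp[labels]
  list(labels = relabelled, agreement = mean(relabelled == reference), map = mp)
}
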