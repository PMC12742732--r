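# Topological features of delay-embedded EEG segments: Takens embedding,
# Vietoris-Rips persistence, Betti curves, persistence entropy, Wasserstein
# amplitude, and Hodge-Laplacian spectral entropy.

#' Delay selection by the first minimum of time-delayed mutual information
#'
#' @param x numeric series
#' @param max_lag largest lag to examine (default n/10, capped at 100)
#' @param bins histogram bins per axis (default 16)
#' @return lag in samples (first local minimum of MI, or `max_lag`)
#' @export
delay_mi <- function(x, max_lag = NULL, bins = 16) {
  n <- length(x)
  max_lag <- max_lag %||% max(2L, min(100L, floor(n / 10)))
  br <- quantile(x, probs = seq(0, 1, length.out = bins + 1), names = FALSE)
  br[1] <- br[1] - 1e-9; br[bins + 1] <- br[bins + 1] + 1e-9
  br <- unique(br)
  cx <- cut(x, br, labels = FALSE, include.lowest = TRUE)
  mi <- function(lag) {
    a <- cx[1:(n - lag)]; b <- cx[(1 + lag):n]
    tab <- table(a, b) / (n - lag)
    pa <- rowSums(tab); pb <- colSums(tab)
    nz <- tab > 0
    sum(tab[nz] * log(tab[nz] / outer(pa, pb)[nz]))
  }
  prev <- mi(1)
  for (lag in 2:max_lag) {
    cur <- mi(lag)
    if (cur > prev) return(lag - 1L)
    prev <- cur
  }
  as.integer(max_lag)
}

# deterministic farthest-point subsampling, seeded from the point with the
# largest distance to the centroid
farthest_point_sample <- function(points, k) {
  n <- nrow(points)
  if (k >= n) return(seq_len(n))
  ctr <- colMeans(points)
  d2c <- rowSums(sweep(points, 2, ctr)^2)
  sel <- integer(k)
  sel[1] <- which.max(d2c)
  mind <- rowSums(sweep(points, 2, points[sel[1], ])^2)
  for (i in 2:k) {
    sel[i] <- which.max(mind)
    di <- rowSums(sweep(points, 2, points[sel[i], ])^2)
    mind <- pmin(mind, di)
  }
  sort(sel)
}

#' Takens delay embedding
#'
#' Row j of the returned cloud is
#' `(x_j, x_{j+tau}, ..., x_{j+(m-1) tau})`; the cloud has
#' `n - (m-1) tau` points before optional farthest-point subsampling.
#'
#' @param x numeric series (or a [condition_segment()])
#' @param m embedding dimension (>= 2; default 3)
#' @param tau delay in samples; `NULL` picks the first minimum of
#'   time-delayed mutual information via [delay_mi()]
#' @param subsample_to optional maximum point count (farthest-point
#'   subsampling, deterministic)
#' @return matrix of class `point_cloud` with attributes `m`, `tau`
#' @export
takens_embed <- function(x, m = 3, tau = NULL, subsample_to = NULL) {
  if (inherits(x, "condition_segment")) x <- x$samples
  if (m < 2) stop_invalid("embedding dimension m must be >= 2")
  tau <- as.integer(tau %||% delay_mi(x))
  if (tau < 1) stop_invalid("tau must be >= 1")
  n <- length(x)
  N <- n - (m - 1) * tau
  if (N < m + 2)
    stop_invalid("series too short: need at least ", (m - 1) * tau + m + 2,
                 " samples for m=", m, ", tau=", tau)
  idx <- outer(seq_len(N) - 1L, (0:(m - 1)) * tau, "+") + 1L
  cloud <- matrix(x[idx], nrow = N, ncol = m)
  if (!is.null(subsample_to) && subsample_to < N)
    cloud <- cloud[farthest_point_sample(cloud, subsample_to), , drop = FALSE]
  structure(cloud, m = m, tau = tau, class = c("point_cloud", "matrix"))
}

#' Vietoris-Rips persistence diagram
#'
#' Euclidean Rips filtration capped at `max_radius` (default twice the
#' median pairwise distance); simplices enter at their diameter.  Bars
#' alive at the cap are recorded with death `Inf`.
#'
#' @param cloud a point cloud matrix (rows = points)
#' @param max_dim largest homology dimension (0..2, default 2)
#' @param max_radius filtration cap
#' @return object of class `persistence_diagram`: data frame
#'   `(dim, birth, death)` with attributes `max_radius` and simplex counts
#' @export
vr_persistence <- function(cloud, max_dim = 2, max_radius = NULL) {
  cloud <- unclass(as.matrix(cloud))
  if (nrow(cloud) < 2) stop_invalid("need at least 2 points")
  D <- as.matrix(dist(cloud))
  max_radius <- max_radius %||% (2 * median(D[upper.tri(D)]))
  res <- cpp_rips_persistence(D, as.integer(max_dim), max_radius)
  pairs <- do.call(rbind, lapply(0:max_dim, function(k) {
    m <- res[[paste0("dim", k)]]
    if (!nrow(m)) return(NULL)
    data.frame(dim = k, birth = m[, 1], death = m[, 2])
  }))
  if (is.null(pairs)) pairs <- data.frame(dim = integer(), birth = numeric(),
                                          death = numeric())
  structure(pairs, max_radius = max_radius,
            n_simplices = c(vertices = nrow(cloud), edges = res$n_edges,
                            triangles = res$n_triangles,
                            tetrahedra = res$n_tetrahedra),
            class = c("persistence_diagram", "data.frame"))
}

diagram_pairs <- function(diag, dim, finite_only = FALSE) {
  d <- diag[diag$dim == dim, , drop = FALSE]
  if (finite_only) d <- d[is.finite(d$death), , drop = FALSE]
  d
}

#' Betti curve
#'
#' Number of dimension-`dim` bars alive at each grid radius; a bar counts
#' on the half-open interval `[birth, death)`, infinite bars to the
#' filtration cap.
#'
#' @param diag a [vr_persistence()] diagram
#' @param dim homology dimension
#' @param grid ascending radii (default 100 points over `[0, max_radius]`)
#' @return data frame `(radius, value)`
#' @export
betti_curve <- function(diag, dim, grid = NULL) {
  grid <- grid %||% seq(0, attr(diag, "max_radius"), length.out = 100)
  if (is.unsorted(grid)) stop_invalid("grid must be ascending")
  d <- diagram_pairs(diag, dim)
  death <- ifelse(is.finite(d$death), d$death, Inf)
  value <- vapply(grid, function(s) sum(d$birth <= s & s < death), numeric(1))
  data.frame(radius = grid, value = value)
}

#' Persistence entropy
#'
#' Shannon entropy (natural log) of normalised finite bar lifetimes in one
#' homology dimension; infinite bars are excluded.  A diagram with no
#' finite bars has entropy 0 (with a warning).
#'
#' @param diag a [vr_persistence()] diagram
#' @param dim homology dimension
#' @return scalar entropy in nats
#' @export
persistence_entropy <- function(diag, dim) {
  d <- diagram_pairs(diag, dim, finite_only = TRUE)
  life <- d$death - d$birth
  life <- life[life > 0]
  if (!length(life)) {
    warning("no finite bars in dimension ", dim, "; entropy defined as 0")
    return(0)
  }
  p <- life / sum(life)
  -sum(p * log(p))
}

#' Wasserstein amplitude of a persistence diagram
#'
#' Wasserstein-p distance to the empty diagram: every finite bar is
#' matched to the diagonal, at L2 ground-metric cost `(death-birth)/sqrt(2)`,
#' giving `( sum ((d_i-b_i)/sqrt(2))^p )^(1/p)`.
#'
#' @param diag a [vr_persistence()] diagram
#' @param dim homology dimension
#' @param p Wasserstein order (default 2)
#' @return scalar amplitude (0 for an empty diagram)
#' @export
persistence_amplitude <- function(diag, dim, p = 2) {
  d <- diagram_pairs(diag, dim, finite_only = TRUE)
  life <- d$death - d$birth
  if (!length(life)) return(0)
  sum((life / sqrt(2))^p)^(1 / p)
}

#' Radius at which the Rips 1-skeleton becomes connected
#'
#' Equals the largest finite H0 death, i.e. the longest MST edge.
#'
#' @param cloud a point cloud matrix
#' @return scalar radius
#' @export
rips_connectivity_radius <- function(cloud) {
  cloud <- unclass(as.matrix(cloud))
  D <- as.matrix(dist(cloud))
  res <- cpp_rips_persistence(D, 0L, max(D) + 1)
  deaths <- res$dim0[, 2]
  max(deaths[is.finite(deaths)])
}

# oriented boundary matrix: rows = (k-1)-simplices, cols = k-simplices,
# vertices ascending; sign alternates over omitted vertices
boundary_matrix <- function(faces, simplices, n_vertices) {
  k <- ncol(simplices)
  n_faces <- if (k == 2) n_vertices else nrow(faces)
  if (!nrow(simplices))
    return(Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                dims = c(n_faces, 0)))
  face_key <- function(m) apply(m, 1, paste, collapse = "_")
  lookup <- if (k == 2) NULL else setNames(seq_len(nrow(faces)), face_key(faces))
  ii <- jj <- integer(0); xx <- numeric(0)
  for (drop in seq_len(k)) {
    sub <- simplices[, -drop, drop = FALSE]
    rows <- if (k == 2) as.integer(sub) else unname(lookup[face_key(sub)])
    ii <- c(ii, rows)
    jj <- c(jj, seq_len(nrow(simplices)))
    xx <- c(xx, rep((-1)^(drop - 1), nrow(simplices)))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n_faces, nrow(simplices)))
}

#' Hodge Laplacian spectrum of the Rips complex at one radius
#'
#' Builds the Rips complex at `radius` (default: the connectivity radius
#' of the 1-skeleton), assembles oriented boundary matrices and returns
#' the full eigenvalue multiset of
#' `L_[n] = B_n^T B_n + B_{n+1} B_{n+1}^T` (for n = 0 this is the graph
#' Laplacian of the 1-skeleton).
#'
#' @param cloud point cloud matrix
#' @param order homology order n (0, 1 or 2)
#' @param radius filtration scale; default [rips_connectivity_radius()]
#' @param max_simplices guard on the number of order-n simplices
#' @return object of class `hodge_spectrum`: list with `order`,
#'   `eigenvalues` (clipped at 0), `n_simplices`, `radius`
#' @export
build_hodge_laplacian <- function(cloud, order, radius = NULL,
                                  max_simplices = 6000) {
  cloud <- unclass(as.matrix(cloud))
  if (!order %in% 0:2) stop_invalid("order must be 0, 1 or 2")
  D <- as.matrix(dist(cloud))
  radius <- radius %||% rips_connectivity_radius(cloud)
  sx <- cpp_rips_simplices(D, radius, as.integer(order + 1))
  n <- nrow(cloud)
  counts <- c(n, nrow(sx$edges), nrow(sx$triangles), nrow(sx$tetrahedra))
  n_n <- counts[order + 1]
  if (n_n < 1)
    stop("no ", order, "-simplices in the complex (radius ", signif(radius, 4),
         " too small)")
  if (n_n > max_simplices)
    stop("complex has ", n_n, " order-", order, " simplices (> ",
         max_simplices, "); reduce the cloud size or radius")
  B <- function(k) {  # boundary from k-simplices onto (k-1)-simplices
    simp <- switch(k, `1` = sx$edges, `2` = sx$triangles, `3` = sx$tetrahedra)
    faces <- switch(k, `1` = NULL, `2` = sx$edges, `3` = sx$triangles)
    boundary_matrix(faces, simp, n)
  }
  L <- if (order == 0) {
    Bn1 <- B(1); Bn1 %*% Matrix::t(Bn1)
  } else {
    Bn <- B(order); Bn1 <- B(order + 1)
    Matrix::t(Bn) %*% Bn + Bn1 %*% Matrix::t(Bn1)
  }
  ev <- eigen(as.matrix(L), symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  structure(list(order = order, eigenvalues = ev, n_simplices = n_n,
                 radius = radius),
            class = "hodge_spectrum")
}

#' Hodge spectral entropy
#'
#' Gibbs entropy of the damped spectrum: with `q_i = exp(-a l_i) / Z` and
#' `Z = sum exp(-a l_i)`, returns `a <l> + log Z` (natural log), which
#' equals `-sum q_i log q_i`.  As `a -> 0` the entropy tends to
#' `log(N_n)` for any spectrum.
#'
#' @param spectrum a [build_hodge_laplacian()] result, or a numeric vector
#'   of eigenvalues
#' @param alpha damping factor (> 0; default 1)
#' @return scalar entropy in nats
#' @export
hodge_spectral_entropy <- function(spectrum, alpha = 1) {
  ev <- if (inherits(spectrum, "hodge_spectrum")) spectrum$eigenvalues else spectrum
  if (!length(ev)) stop_invalid("empty spectrum")
  if (alpha <= 0) stop_invalid("alpha must be positive")
  w <- exp(-alpha * ev)
  Z <- sum(w)
  mean_lambda <- sum(ev * w) / Z
  alpha * mean_lambda + log(Z)
}
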