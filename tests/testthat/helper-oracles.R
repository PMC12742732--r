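# Independent oracles used by the test suite.  These deliberately share no
# code with the package: persistent homology by dense GF(2) linear algebra,
# sample entropy by a double loop, Mann-Whitney by full enumeration,
# Kruskal-Wallis by direct rank arithmetic.

# ---- GF(2) linear algebra -------------------------------------------------

gf2_rank <- function(M) {
  M <- M %% 2
  if (!length(M) || !nrow(M) || !ncol(M)) return(0L)
  r <- 0L
  for (j in seq_len(ncol(M))) {
    piv <- which(M[, j] == 1)
    piv <- piv[piv > r]
    if (!length(piv)) next
    r <- r + 1L
    if (piv[1] != r) M[c(r, piv[1]), ] <- M[c(piv[1], r), ]
    hit <- setdiff(which(M[, j] == 1), r)
    if (length(hit)) M[hit, ] <- (M[hit, , drop = FALSE] + rep(M[r, ], each = length(hit))) %% 2
    if (r == nrow(M)) break
  }
  r
}

# basis of the null space of M over GF(2) (columns = basis vectors),
# found by column elimination on M stacked over an identity block
gf2_kernel <- function(M) {
  n <- ncol(M)
  m <- nrow(M)
  if (n == 0) return(matrix(0L, nrow = 0, ncol = 0))
  A <- rbind(M %% 2, diag(n))
  done <- 0L
  for (i in seq_len(m)) {
    piv <- which(A[i, ] == 1)
    piv <- piv[piv > done]
    if (!length(piv)) next
    done <- done + 1L
    if (piv[1] != done) A[, c(done, piv[1])] <- A[, c(piv[1], done)]
    hit <- setdiff(which(A[i, ] == 1), done)
    if (length(hit)) A[, hit] <- (A[, hit, drop = FALSE] + A[, done]) %% 2
  }
  zero_top <- which(colSums(A[seq_len(m), , drop = FALSE]) == 0)
  A[m + seq_len(n), zero_top, drop = FALSE]
}

# ---- brute-force Rips persistence for tiny clouds -------------------------

# all k-subsets of 1..n with the diameter of each simplex, sorted by diameter
oracle_simplices <- function(D, k) {
  n <- nrow(D)
  if (k == 1) return(list(simplices = matrix(seq_len(n), ncol = 1),
                          diam = rep(0, n)))
  combs <- t(utils::combn(n, k))
  diam <- apply(combs, 1, function(v) max(D[v, v]))
  ord <- order(diam)
  list(simplices = combs[ord, , drop = FALSE], diam = diam[ord])
}

# full GF(2) boundary matrix (rows = faces, cols = simplices)
oracle_boundary <- function(faces, simp) {
  key <- function(m) apply(m, 1, paste, collapse = "_")
  fk <- key(faces$simplices)
  M <- matrix(0L, nrow = nrow(faces$simplices), ncol = nrow(simp$simplices))
  for (j in seq_len(nrow(simp$simplices))) {
    for (drop in seq_len(ncol(simp$simplices))) {
      f <- paste(simp$simplices[j, -drop], collapse = "_")
      M[match(f, fk), j] <- 1L
    }
  }
  M
}

# persistent Betti numbers beta_k(r_i -> r_j) over all pairs of critical
# radii: beta = dim( Z_k(r_i) / (Z_k(r_i) cap B_k(r_j)) ), each dimension
# obtained from GF(2) ranks
oracle_persistent_betti <- function(points, max_dim = 2) {
  D <- as.matrix(dist(points))
  crit <- sort(unique(c(0, D[upper.tri(D)])))
  eps <- 1e-12
  simps <- lapply(1:(max_dim + 2), function(k) oracle_simplices(D, k))
  bdry <- lapply(2:(max_dim + 2), function(k)
    oracle_boundary(simps[[k - 1]], simps[[k]]))
  n_at <- lapply(simps, function(s)
    vapply(crit, function(r) sum(s$diam <= r + eps), 0L))
  out <- list()
  for (k in 0:max_dim) {
    nk <- n_at[[k + 1]]
    nk_full <- nk[length(crit)]
    dimZ <- integer(length(crit))
    kerb <- vector("list", length(crit))
    for (i in seq_along(crit)) {
      if (k == 0) {
        dimZ[i] <- nk[i]
        kerb[[i]] <- diag(nk[i])
      } else {
        sub <- bdry[[k]][, seq_len(nk[i]), drop = FALSE]
        kb <- gf2_kernel(sub)  # nk[i] rows
        dimZ[i] <- ncol(kb)
        kerb[[i]] <- kb
      }
    }
    nk1 <- n_at[[k + 2]]
    B <- matrix(0, length(crit), length(crit))
    for (j in seq_along(crit)) {
      dkj <- bdry[[k + 1]][, seq_len(nk1[j]), drop = FALSE]  # nk_full rows
      rank_B <- gf2_rank(dkj)
      for (i in seq_len(j)) {
        Z <- kerb[[i]]
        Zpad <- matrix(0L, nk_full, ncol(Z))
        if (ncol(Z)) Zpad[seq_len(nrow(Z)), ] <- Z
        dimZB <- gf2_rank(cbind(Zpad, dkj))
        dimZcapB <- dimZ[i] + rank_B - dimZB
        B[i, j] <- dimZ[i] - dimZcapB
      }
    }
    out[[paste0("dim", k)]] <- B
  }
  list(crit = crit, betti = out)
}

# persistent Betti numbers implied by a persistence diagram on the same grid
diagram_persistent_betti <- function(diag, crit, max_dim = 2) {
  eps <- 1e-12
  out <- list()
  for (k in 0:max_dim) {
    d <- diag[diag$dim == k, , drop = FALSE]
    B <- matrix(0, length(crit), length(crit))
    for (i in seq_along(crit)) for (j in i:length(crit))
      B[i, j] <- sum(d$birth <= crit[i] + eps & d$death > crit[j] + eps)
    out[[paste0("dim", k)]] <- B
  }
  out
}

expect_diagram_matches_oracle <- function(cloud, max_radius = NULL) {
  D <- as.matrix(dist(cloud))
  cap <- if (is.null(max_radius)) max(D) + 1 else max_radius
  diag <- vr_persistence(cloud, max_dim = 2, max_radius = cap)
  ora <- oracle_persistent_betti(cloud, max_dim = 2)
  imp <- diagram_persistent_betti(diag, ora$crit, max_dim = 2)
  for (k in 0:2)
    testthat::expect_equal(imp[[paste0("dim", k)]], ora$betti[[paste0("dim", k)]],
                           info = paste("persistent Betti mismatch in dim", k))
}

# ---- other oracles --------------------------------------------------------

oracle_mst_edges <- function(points) {
  D <- as.matrix(dist(points))
  g <- igraph::graph_from_adjacency_matrix(D, mode = "undirected", weighted = TRUE)
  sort(igraph::E(igraph::mst(g))$weight)
}

oracle_sampen <- function(x, m, r_tol) {
  n <- length(x)
  nt <- n - m
  A <- 0; B <- 0
  for (i in seq_len(nt - 1)) {
    for (j in (i + 1):nt) {
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r_tol) {
        B <- B + 1
        if (abs(x[i + m] - x[j + m]) <= r_tol) A <- A + 1
      }
    }
  }
  if (A == 0 || B == 0) return(NA_real_)
  -log(A / B)
}

# exact one-sided Mann-Whitney p by enumerating all group assignments
oracle_mw_exact <- function(a, b, tail) {
  pooled <- c(a, b)
  na <- length(a)
  U <- function(xa, xb) sum(outer(xa, xb, ">")) + 0.5 * sum(outer(xa, xb, "=="))
  u_obs <- U(a, b)
  combs <- utils::combn(length(pooled), na)
  us <- apply(combs, 2, function(idx) U(pooled[idx], pooled[-idx]))
  switch(tail,
         less = mean(us <= u_obs),
         greater = mean(us >= u_obs),
         two.sided = min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs))))
}

oracle_kruskal_H <- function(groups) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  r <- rank(x)
  n <- length(x)
  H <- 12 / (n * (n + 1)) * sum(tapply(r, g, sum)^2 / lengths(groups)) - 3 * (n + 1)
  ties <- table(x)
  H / (1 - sum(ties^3 - ties) / (n^3 - n))
}
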