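unit_square <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1), ncol = 2, byrow = TRUE)

test_that("Takens embedding lays out delayed coordinates", {
  cloud <- takens_embed(c(1, 2, 3, 4, 5, 6, 7), m = 2, tau = 1)
  expect_equal(unclass(cloud)[1:4, ],
               matrix(c(1, 2, 2, 3, 3, 4, 4, 5), ncol = 2, byrow = TRUE)[1:4, ],
               ignore_attr = TRUE)
  big <- takens_embed(rnorm(1600), m = 3, tau = 8)
  expect_equal(nrow(big), 1600 - 16)
  expect_error(takens_embed(rnorm(10), m = 3, tau = 8),
               class = "topobind_invalid_config")
  sub <- takens_embed(rnorm(500), m = 3, tau = 2, subsample_to = 40)
  expect_equal(nrow(sub), 40)
})

test_that("mutual-information delay lands near the quarter period of a noisy sine", {
  s <- generate_fixture("sine", 1024)
  set.seed(2)
  s <- s + rnorm(1024, sd = 0.05)
  expect_true(delay_mi(s) %in% 4:12)  # period 32 -> quarter period ~ 8
})

test_that("unit-square diagram matches hand-computed homology", {
  d <- vr_persistence(unit_square, max_dim = 2, max_radius = 3)
  h0 <- d[d$dim == 0, ]
  expect_equal(sort(h0$death[is.finite(h0$death)]), c(1, 1, 1))
  expect_equal(sum(!is.finite(h0$death)), 1)
  h1 <- d[d$dim == 1, ]
  expect_equal(nrow(h1), 1)
  expect_equal(h1$birth, 1)
  expect_equal(h1$death, sqrt(2))
  expect_equal(nrow(d[d$dim == 2, ]), 0)
  # two points at distance d
  two <- vr_persistence(matrix(c(0, 0, 3, 0), ncol = 2, byrow = TRUE),
                        max_dim = 2, max_radius = 10)
  expect_equal(sort(two$death), c(3, Inf))
  expect_equal(unique(two$dim), 0)
})

test_that("Rips diagrams equal brute-force GF(2) homology on random tiny clouds", {
  set.seed(101)
  for (i in 1:25) {
    n <- sample(4:7, 1)
    dim <- sample(2:3, 1)
    cloud <- matrix(rnorm(n * dim), ncol = dim)
    expect_diagram_matches_oracle(cloud)
  }
})

test_that("H0 finite deaths equal the MST edge lengths", {
  set.seed(55)
  for (n in c(10, 30, 50)) {
    cloud <- matrix(rnorm(n * 3), ncol = 3)
    d <- vr_persistence(cloud, max_dim = 0, max_radius = 100)
    expect_equal(sort(d$death[is.finite(d$death)]), oracle_mst_edges(cloud),
                 tolerance = 1e-10)
  }
})

test_that("Betti curves count alive bars on half-open intervals", {
  d <- vr_persistence(unit_square, max_dim = 2, max_radius = 3)
  expect_equal(betti_curve(d, 1, grid = 1.2)$value, 1)
  expect_equal(betti_curve(d, 1, grid = 2)$value, 0)
  expect_equal(betti_curve(d, 0, grid = 0)$value, 4)
  expect_error(betti_curve(d, 1, grid = c(2, 1)), class = "topobind_invalid_config")
  # integral of the dim-1 curve over a fine grid recovers the summed lifetime
  g <- seq(0, 3, length.out = 3001)
  integral <- sum(betti_curve(d, 1, grid = g)$value) * (g[2] - g[1])
  expect_equal(integral, sqrt(2) - 1, tolerance = 1e-2)
})

test_that("persistence entropy matches closed forms and is scale invariant", {
  mk <- function(life) {
    structure(data.frame(dim = 1, birth = 0, death = life),
              max_radius = max(life) + 1,
              class = c("persistence_diagram", "data.frame"))
  }
  expect_equal(persistence_entropy(mk(c(1, 1)), 1), log(2))
  expect_equal(persistence_entropy(mk(2), 1), 0)
  expect_equal(persistence_entropy(mk(c(1, 1, 2)), 1),
               -(2 * 0.25 * log(0.25) + 0.5 * log(0.5)))
  # uniform scaling of all births/deaths leaves the entropy unchanged
  set.seed(8)
  life <- runif(6, 0.2, 2)
  expect_equal(persistence_entropy(mk(life), 1),
               persistence_entropy(mk(life * 37.5), 1), tolerance = 1e-12)
  # no finite bars -> 0 with a warning
  inf_d <- structure(data.frame(dim = 1, birth = 0, death = Inf),
                     max_radius = 2, class = c("persistence_diagram", "data.frame"))
  expect_warning(expect_equal(persistence_entropy(inf_d, 1), 0))
})

test_that("Wasserstein amplitude matches the diagonal-matching closed form", {
  mk <- function(life) {
    structure(data.frame(dim = 1, birth = 0, death = life),
              max_radius = 10, class = c("persistence_diagram", "data.frame"))
  }
  empty <- structure(data.frame(dim = integer(), birth = numeric(),
                                death = numeric()),
                     max_radius = 1, class = c("persistence_diagram", "data.frame"))
  expect_equal(persistence_amplitude(empty, 1), 0)
  expect_equal(persistence_amplitude(mk(2), 1, p = 2),
               2 * persistence_amplitude(mk(1), 1, p = 2))
  # optimal matching of {3,4} to the empty diagram sends each bar to the
  # diagonal at cost (life/sqrt 2); enumerated by hand for p = 2
  expect_equal(persistence_amplitude(mk(c(3, 4)), 1, p = 2),
               sqrt((3 / sqrt(2))^2 + (4 / sqrt(2))^2))
})

test_that("Hodge Laplacians reproduce textbook spectra", {
  # path graph P3: radius admits two edges, no triangle
  p3 <- matrix(c(0, 1, 2.1), ncol = 1)
  h0 <- build_hodge_laplacian(p3, order = 0, radius = 1.5)
  expect_equal(sort(h0$eigenvalues), c(0, 1, 3), tolerance = 1e-10)
  # no edges at all: L0 is the zero matrix
  h00 <- build_hodge_laplacian(p3, order = 0, radius = 0.5)
  expect_equal(h00$eigenvalues, c(0, 0, 0))
  # filled triangle: L1 = 3 I
  tri <- matrix(c(0, 0, 1, 0, 0.5, 0.9), ncol = 2, byrow = TRUE)
  h1 <- build_hodge_laplacian(tri, order = 1, radius = 2)
  expect_equal(h1$eigenvalues, c(3, 3, 3), tolerance = 1e-10)
  expect_error(build_hodge_laplacian(p3, order = 1, radius = 0.5), "too small")
})

test_that("order-0 Hodge Laplacian equals the graph Laplacian of the 1-skeleton", {
  set.seed(12)
  cloud <- matrix(rnorm(20 * 3), ncol = 3)
  D <- as.matrix(dist(cloud))
  r <- median(D)
  h <- build_hodge_laplacian(cloud, order = 0, radius = r)
  A <- (D <= r) * 1; diag(A) <- 0
  L <- diag(rowSums(A)) - A
  expect_equal(sort(h$eigenvalues), sort(eigen(L, symmetric = TRUE)$values),
               tolerance = 1e-8)
})

test_that("Hodge spectral entropy equals the Gibbs form and its limits", {
  expect_equal(hodge_spectral_entropy(c(0, 0, 0)), log(3))
  ev <- c(0, 1)
  q <- exp(-ev) / sum(exp(-ev))
  expect_equal(hodge_spectral_entropy(ev, alpha = 1), -sum(q * log(q)))
  expect_equal(hodge_spectral_entropy(ev, alpha = 1),
               exp(-1) / (1 + exp(-1)) + log(1 + exp(-1)), tolerance = 1e-12)
  # alpha -> 0 limit is log(N) for any spectrum, and S is always in [0, log N]
  set.seed(3)
  for (i in 1:10) {
    ev <- runif(sample(2:12, 1), 0, 5)
    expect_equal(hodge_spectral_entropy(ev, alpha = 1e-9), log(length(ev)),
                 tolerance = 1e-6)
    s <- hodge_spectral_entropy(ev, alpha = runif(1, 0.1, 3))
    expect_gte(s, 0)
    expect_lte(s, log(length(ev)) + 1e-12)
  }
  expect_error(hodge_spectral_entropy(numeric(0)), class = "topobind_invalid_config")
  expect_error(hodge_spectral_entropy(c(1, 2), alpha = 0),
               class = "topobind_invalid_config")
})
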