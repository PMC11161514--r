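test_that("single path node reproduces the closed-form path-graph spectrum", {
  n <- 7
  lay <- make_path_layout(n)
  L <- layout_laplacian(lay, w = 0.5)  # w irrelevant: no bonds
  vals <- sort(eigen(as.matrix(L$Q), symmetric = TRUE)$values)
  closed <- sort(4 * sin(pi * (0:(n - 1)) / (2 * n))^2)
  expect_equal(vals, closed, tolerance = 1e-10)
  # Laplacian structure: symmetric, zero row sums
  expect_equal(max(abs(Matrix::rowSums(L$Q))), 0, tolerance = 1e-12)
  expect_true(Matrix::isSymmetric(L$Q))
  expect_error(layout_laplacian(lay, -0.1), ">= 0")
})

test_that("two path nodes with one bond: block structure and slow eigenvalue", {
  a <- 5; b <- 5
  lay <- make_path_layout(c(a, b))
  # w = 0: one zero eigenvalue per node
  v0 <- sort(eigen(as.matrix(layout_laplacian(lay, 0)$Q), symmetric = TRUE)$values)
  expect_equal(sum(abs(v0) < 1e-12), 2)
  # small w: smallest nonzero eigenvalue ~ w (1/a + 1/b), the nonzero
  # eigenvalue of the 2-node physical Laplacian
  for (w in c(1e-2, 1e-3)) {
    v <- sort(eigen(as.matrix(layout_laplacian(lay, w)$Q), symmetric = TRUE)$values)
    expect_equal(v[2] / w, 1 / a + 1 / b, tolerance = 0.05)
  }
})

test_that("combinatorial Laplacian matches closed forms", {
  G2 <- list(N = 2, edges = data.frame(i = 1, j = 2, mult = 1))
  expect_equal(as.matrix(combinatorial_laplacian(G2)),
               matrix(c(1, -1, -1, 1), 2), ignore_attr = TRUE)
  # star with N leaves: eigenvalues {0, 1 (N-1 times), N+1}
  Nl <- 8
  star <- list(N = Nl + 1, edges = data.frame(i = 1, j = 2:(Nl + 1), mult = 1))
  vals <- sort(eigen(as.matrix(combinatorial_laplacian(star)), symmetric = TRUE)$values)
  expect_equal(vals, c(0, rep(1, Nl - 1), Nl + 1), tolerance = 1e-10)
  # tree from growth: exactly one zero eigenvalue
  set.seed(1)
  G <- combinatorial_network(grow_network(growth_config(2, 8)))
  v <- sort(eigen(as.matrix(combinatorial_laplacian(G)), symmetric = TRUE)$values)
  expect_equal(sum(v < 1e-10), 1)
})

test_that("physical Laplacian normalization and zero mode", {
  G2 <- list(N = 2, edges = data.frame(i = 1, j = 2, mult = 1))
  Qg <- combinatorial_laplacian(G2)
  # volumes (a, b): nonzero eigenvalue 1/a + 1/b (2x2 eigenproblem by hand)
  ph <- physical_laplacian(Qg, c(4, 12))
  vals <- sort(eigen(as.matrix(ph$Q_phys), symmetric = TRUE)$values)
  expect_equal(vals, c(0, 1 / 4 + 1 / 12), tolerance = 1e-12)
  # all volumes 1: identity normalization
  ph1 <- physical_laplacian(Qg, c(1, 1))
  expect_equal(as.matrix(ph1$Q_phys), as.matrix(Qg), ignore_attr = TRUE)
  # homogeneity: scaling volumes by s divides eigenvalues by s
  ph_s <- physical_laplacian(Qg, 3 * c(4, 12))
  expect_equal(max(abs(as.matrix(ph_s$Q_phys) * 3 - as.matrix(ph$Q_phys))), 0,
               tolerance = 1e-12)
  expect_error(physical_laplacian(Qg, c(1, -1)), "positive")

  # zero mode sqrt(v) for a grown network
  set.seed(2)
  G <- combinatorial_network(grow_network(growth_config(2, 10)))
  php <- physical_laplacian(combinatorial_laplacian(G), G$volumes)
  z <- sqrt(G$volumes)
  expect_lt(max(abs(as.numeric(php$Q_phys %*% z))), 1e-10)
})

test_that("volume shuffling preserves the volume multiset and equal volumes are invariant", {
  set.seed(3)
  G <- combinatorial_network(grow_network(growth_config(2, 10)))
  Qg <- combinatorial_laplacian(G)
  sh <- shuffled_physical_laplacian(Qg, G$volumes)
  expect_equal(sort(G$volumes[sh$permutation]), sort(G$volumes))
  sh1 <- shuffled_physical_laplacian(Qg, rep(2, G$N))
  ph1 <- physical_laplacian(Qg, rep(2, G$N))
  expect_equal(as.matrix(sh1$Q_phys), as.matrix(ph1$Q_phys))
})

test_that("spectrum handles dense and sparse-extremal paths consistently", {
  expect_equal(spectrum(diag(c(0, 1, 2)), mode = "full")$values, c(0, 1, 2))
  # cycle graph C_n: eigenvalues 2 - 2 cos(2 pi m / n)
  n <- 12
  cyc <- list(N = n, edges = data.frame(i = 1:n, j = c(2:n, 1), mult = 1))
  sp <- spectrum(combinatorial_laplacian(cyc), mode = "full")
  expect_equal(sp$values, sort(2 - 2 * cos(2 * pi * (0:(n - 1)) / n)),
               tolerance = 1e-10)
  # dense vs ARPACK on random trees
  set.seed(4)
  for (rep in 1:3) {
    net <- generate_fixture(500, 2.5, "linear")
    Qg <- combinatorial_laplacian(net, warn_disconnected = FALSE)
    d <- spectrum(Qg, mode = "full")
    sxt <- spectrum(Qg, mode = "extremal")
    expect_equal(sxt$lambda_N, d$lambda_N, tolerance = 1e-8)
    expect_equal(sxt$lambda_2, d$lambda_2, tolerance = 1e-8)
  }
})

test_that("perturbation theory links Q_P(w)/w to the physical Laplacian", {
  # two-path toy: slow eigenvalue / w -> 1/a + 1/b = 2/5
  lay <- make_path_layout(c(5, 5))
  tab <- perturbation_check(lay, c(1e-2, 1e-3, 1e-4))
  expect_equal(tab$max_slow[3] / 1e-4, 2 / 5, tolerance = 0.01)
  # first-order gap shrinks ~10x per decade of w
  expect_lt(tab$max_rel_gap[2], tab$max_rel_gap[1] * 0.2)
  expect_lt(tab$max_rel_gap[3], tab$max_rel_gap[2] * 0.2)

  # grown network: two-group separation, slow group ~ w, fast group Theta(1)
  set.seed(5)
  layg <- grow_network(growth_config(2, 10))
  tg <- perturbation_check(layg, 10^seq(-1, -4, by = -1))
  expect_true(all(diff(tg$max_rel_gap) < 0))
  last <- nrow(tg)
  expect_lt(tg$max_rel_gap[last], 0.01)
  # fast group converges to a constant, slow group keeps decaying
  expect_equal(tg$min_fast[last], tg$min_fast[last - 1], tolerance = 0.05)
  expect_lt(tg$max_slow[last], tg$min_fast[last] / 5)
})

test_that("eigenvector distance profiles decay from the localization center", {
  # indicator eigenvector: all weight at distance zero
  path <- list(N = 5, edges = data.frame(i = 1:4, j = 2:5, mult = 1))
  ev <- c(1, 0, 0, 0, 0)
  prof <- eigvec_distance_profile(path, ev, 1)
  expect_equal(prof$mean_weight[prof$distance == 0], 1)
  expect_true(all(prof$mean_weight[prof$distance > 0] == 0))

  # star: leading eigenvector concentrated at hub, single-step decay
  Nl <- 10
  star <- list(N = Nl + 1, edges = data.frame(i = 1, j = 2:(Nl + 1), mult = 1))
  sp <- spectrum(combinatorial_laplacian(star), mode = "full")
  expect_equal(sp$i_star, 1)
  prof2 <- eigvec_distance_profile(star, sp$u_N, 1)
  expect_true(all(diff(prof2$mean_weight) < 0))
  # closed form: hub weight sqrt(Nl/(Nl+1)), leaves sqrt(1/(Nl (Nl+1)))
  expect_equal(abs(prof2$mean_weight[1]), sqrt(Nl / (Nl + 1)), tolerance = 1e-8)
  expect_equal(prof2$mean_weight[2], sqrt(1 / (Nl * (Nl + 1))), tolerance = 1e-8)

  # model network: monotone decay over at least 4 shells
  set.seed(6)
  G <- combinatorial_network(grow_network(growth_config(2, 30)))
  spg <- spectrum(combinatorial_laplacian(G), mode = "full")
  prof3 <- eigvec_distance_profile(G, spg$u_N, spg$i_star)
  expect_gte(nrow(prof3), 5)
  expect_true(all(diff(prof3$mean_weight[1:5]) < 0))
})

test_that("localization: i_G is the hub; i_phys maximizes degree/volume", {
  # equal volumes: Q_phys proportional to Q_G, same center
  set.seed(7)
  G <- combinatorial_network(grow_network(growth_config(2, 12)))
  Qg <- combinatorial_laplacian(G)
  sG <- spectrum(Qg, mode = "full")
  sE <- spectrum(physical_laplacian(Qg, rep(1, G$N))$Q_phys, mode = "full")
  locE <- localization_report(sG, sE, G$degrees, rep(1, G$N))
  expect_equal(locE$i_G, locE$i_phys)

  # model network: i_G is the largest-degree node
  expect_equal(sG$i_star, which.max(G$degrees))

  # planted fixture: a node with extreme degree/volume ratio attracts the
  # leading eigenvector of Q_phys
  hub_vol <- 500
  edges <- data.frame(i = rep(1, 30), j = 2:31, mult = 1)
  edges <- rbind(edges, data.frame(i = rep(2, 15), j = 32:46, mult = 1))
  vols <- c(hub_vol, 1, rep(5, 45))  # node 2: degree 16, volume 1
  net <- make_real_network(edges, vols)
  Q <- combinatorial_laplacian(net, warn_disconnected = FALSE)
  sg <- spectrum(Q, mode = "full")
  sp <- spectrum(physical_laplacian(Q, net$volumes)$Q_phys, mode = "full")
  loc <- localization_report(sg, sp, net$degrees, net$volumes)
  expect_equal(loc$i_G, 1)       # hub of the combinatorial network
  expect_equal(loc$i_phys, 2)    # planted high-k/v node
  expect_true(loc$i_phys_matches_argmax_kv)
  expect_equal(loc$argmax_kv, 2)
})

test_that("interlacing-style bound holds on model networks", {
  set.seed(8)
  G <- combinatorial_network(grow_network(growth_config(2, 15)))
  Qg <- combinatorial_laplacian(G)
  ph <- physical_laplacian(Qg, G$volumes)
  sG <- spectrum(Qg, mode = "full")
  sP <- spectrum(ph$Q_phys, mode = "full")
  expect_lte(sP$lambda_2, sG$lambda_2 * max(1 / G$volumes) + 1e-12)
})
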