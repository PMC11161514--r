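test_that("a node seeded with all neighbors foreign-occupied hits immediately", {
  set.seed(1)
  s <- substrate(2, 5)
  center <- coords_to_site(c(2, 2), s)
  for (rep in 1:10) {
    occ <- new_occupancy(s)
    occupy_sites(occ, site_neighbors(center, s), 1L)
    res <- grow_lerw_trajectory(s, occ, center, node_id = 2L)
    expect_equal(res$trajectory, center)
    expect_false(is.null(res$hit))
    expect_equal(res$hit$site_a, center)
    expect_equal(res$hit$node_j, 1)
    expect_equal(res$steps, 1)
  }
})

test_that("free LERW growth yields a self-avoiding lattice path of target length", {
  set.seed(2)
  s <- substrate(2, 50)
  occ <- new_occupancy(s)
  start <- coords_to_site(c(25, 25), s)
  res <- grow_lerw_trajectory(s, occ, start, target_length = 40,
                              allow_hit = FALSE, budget = 1e6)
  tr <- res$trajectory
  expect_length(tr, 40)
  expect_equal(anyDuplicated(tr), 0L)
  for (i in seq_len(39)) {
    expect_true(tr[i + 1] %in% site_neighbors(tr[i], s))
  }
  expect_true(is.null(res$hit))
  # claimed in occupancy, erased loops released
  expect_equal(sort(which(occ$owner != 0L)), sort(tr))
})

test_that("walk with nothing to hit returns no hit within a step budget", {
  set.seed(3)
  s <- substrate(2, 10)
  occ <- new_occupancy(s)
  res <- grow_lerw_trajectory(s, occ, 1L, allow_hit = TRUE, budget = 500)
  expect_true(is.null(res$hit))
  expect_true(res$budget_exceeded)
})

test_that("1-D ring hitting time matches the Markov-chain absorption oracle", {
  L <- 9
  s <- substrate(1, L)
  # oracle: expected steps for SRW on the ring started at distance k from
  # the unique absorbing site, via the linear system (I - P) h = 1
  P <- matrix(0, L - 1, L - 1)  # states = distances 1..L-1 from target
  for (k in 1:(L - 1)) {
    for (nb in c(k - 1, k + 1)) {
      if (nb %% L != 0) P[k, ((nb - 1) %% L) + 1] <- P[k, ((nb - 1) %% L) + 1] + 0.5
    }
  }
  h <- solve(diag(L - 1) - P, rep(1, L - 1))
  expect_equal(h, (1:(L - 1)) * (L - 1:(L - 1)))  # classic k(L-k) closed form

  set.seed(4)
  k0 <- 3
  steps <- replicate(3000, {
    occ <- new_occupancy(s)
    occupy_sites(occ, 1L, 1L)
    res <- grow_lerw_trajectory(s, occ, 1L + k0, node_id = 2L)
    res$steps
  })
  se <- sd(steps) / sqrt(length(steps))
  expect_lt(abs(mean(steps) - h[k0]), 5 * se)
  # trajectories are simple arcs ending adjacent to the occupied site
  occ <- new_occupancy(s)
  occupy_sites(occ, 1L, 1L)
  res <- grow_lerw_trajectory(s, occ, 1L + k0, node_id = 2L)
  expect_equal(anyDuplicated(res$trajectory), 0L)
  expect_true(res$hit$site_b == 1L)
})

test_that("straight axis rays wrap and close after exactly L sites", {
  set.seed(5)
  s <- substrate(2, 8)
  occ <- new_occupancy(s)
  res <- grow_straight_trajectory(s, occ, 1L, mode = "axis")
  expect_length(res$trajectory, 8)
  expect_true(res$closed)
  expect_true(is.null(res$hit))
})

test_that("parallel axis lines never bond; perpendicular ones do", {
  set.seed(6)
  s <- substrate(2, 8)
  row0 <- coords_to_site(cbind(0:7, 0L), s)
  n_parallel <- 0; n_perp <- 0
  for (rep in 1:40) {
    occ <- new_occupancy(s)
    occupy_sites(occ, row0, 1L)
    res <- grow_straight_trajectory(s, occ, coords_to_site(c(0, 3), s),
                                    node_id = 2L, mode = "axis")
    cc <- site_to_coords(res$trajectory, s)
    if (length(unique(cc[, 2])) == 1) {
      # ray ran along the x axis: parallel to node 1, must close unbonded
      n_parallel <- n_parallel + 1
      expect_true(is.null(res$hit))
      expect_true(res$closed)
    } else {
      n_perp <- n_perp + 1
      expect_false(is.null(res$hit))
      expect_equal(res$hit$node_j, 1)
    }
  }
  expect_gt(n_parallel, 0); expect_gt(n_perp, 0)
})

test_that("random-direction rays follow the straight-line rasterization oracle", {
  set.seed(7)
  s <- substrate(2, 64)
  occ <- new_occupancy(s)
  start <- coords_to_site(c(5, 5), s)
  res <- grow_straight_trajectory(s, occ, start, mode = "random_dir",
                                  target_length = 30, allow_hit = FALSE)
  u <- unwrap_trajectory(res$trajectory, s)
  # oracle: all visited cells lie within max-distance 1 of the continuous
  # ray through the start with the empirical direction; face-adjacency holds
  dirs <- diff(u)
  expect_true(all(rowSums(abs(dirs)) == 1))  # one lattice step at a time
  v <- u[nrow(u), ] - u[1, ]
  v <- v / sqrt(sum(v^2))
  for (i in seq_len(nrow(u))) {
    p <- u[i, ] - u[1, ]
    along <- sum(p * v)
    perp <- sqrt(max(0, sum(p * p) - along^2))
    expect_lt(perp, 1.5)
  }
})

test_that("diagonal rasterization matches the brute-force oracle on slope (1,1)", {
  # voxel-traversal oracle computed by hand: from (0,0) with direction
  # (1,1)/sqrt(2), tMax ties broken by the lowest axis, so the path
  # staircases x,y,x,y,...
  oracle <- function(n) {
    out <- matrix(0, n + 1, 2)
    for (i in seq_len(n)) {
      out[i + 1, ] <- out[i, ] + if (i %% 2 == 1) c(1, 0) else c(0, 1)
    }
    out
  }
  o <- oracle(6)
  expect_equal(o[7, ], c(3, 3))
  expect_true(all(rowSums(abs(diff(o))) == 1))
})

test_that("seed_initial_node honors explicit and span v0 policies", {
  set.seed(8)
  cfg1 <- growth_config(2, 20, v0 = 1)
  res1 <- seed_initial_node(cfg1)
  expect_equal(res1$volume, 1)

  cfg2 <- growth_config(2, 100, v0 = "span")
  expect_equal(cfg2$v0, round(100^1.25))  # 316
  expect_equal(growth_config(4, 5, v0 = "span")$v0, round(5^2))
  expect_equal(growth_config(3, 10, v0 = "span")$v0, round(10^1.6236))
  res2 <- seed_initial_node(cfg2)
  expect_equal(res2$volume, 316)
  expect_error(growth_config(2, 5, v0 = 100), "exceeds")
})

test_that("grow_network produces a valid layout and tree at all stop rules", {
  set.seed(9)
  # N_max = 1: seed only
  lay1 <- grow_network(growth_config(2, 10, n_max = 1, v0 = 5))
  expect_equal(lay1$N, 1)
  expect_equal(nrow(lay1$bonds), 0)
  expect_equal(combinatorial_network(lay1)$N, 1)

  # saturation: spanning-tree of the lattice
  lay <- grow_network(growth_config(2, 16, rng_seed = 42))
  n <- 16^2
  expect_true(lay$saturated)
  expect_equal(sum(lay$volumes), n)
  expect_true(all(lay$owner != 0L))
  # disjointness: every site owned once
  all_sites <- unlist(lay$trajectories)
  expect_equal(anyDuplicated(all_sites), 0L)
  expect_length(all_sites, n)
  # V_t strictly increasing
  expect_true(all(diff(lay$V_t) > 0))
  # one bond per non-seed node
  expect_equal(nrow(lay$bonds), lay$N - 1)
  # union of internal edges and bonds is a spanning tree
  ie <- internal_edges(lay)
  edges <- rbind(ie, cbind(lay$bonds$site_a, lay$bonds$site_b))
  expect_equal(nrow(edges), n - 1)
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  expect_true(igraph::is_connected(g))
  # combinatorial network is a connected tree
  G <- combinatorial_network(lay)
  expect_equal(nrow(G$edges), G$N - 1)
  expect_true(all(G$edges$mult == 1))
  gg <- igraph::graph_from_edgelist(cbind(G$edges$i, G$edges$j), directed = FALSE)
  expect_true(igraph::is_connected(gg))
  expect_equal(sum(G$degrees), 2 * nrow(G$edges))
})

test_that("identical config and seed reproduce the layout bit-for-bit", {
  a <- grow_network(growth_config(2, 12, rng_seed = 11))
  b <- grow_network(growth_config(2, 12, rng_seed = 11))
  expect_identical(a$owner, b$owner)
  expect_identical(a$trajectories, b$trajectories)
  expect_identical(a$bonds, b$bonds)
})

test_that("saturate_and_partition assigns every site to a connected cell", {
  set.seed(10)
  res <- saturate_and_partition(growth_config(2, 8))
  expect_equal(sum(tabulate(res$partition)), 64)
  expect_true(all(res$partition >= 1))
  s <- res$layout$substrate
  for (i in seq_len(res$layout$N)) {
    tr <- res$layout$trajectories[[i]]
    expect_setequal(which(res$partition == i), tr)
    if (length(tr) > 1) {
      for (q in seq_len(length(tr) - 1)) {
        expect_true(tr[q + 1] %in% site_neighbors(tr[q], s))
      }
    }
  }
})

test_that("mean node volume at saturation is bounded in L", {
  set.seed(12)
  v50 <- 50^2 / grow_network(growth_config(2, 50))$N
  v100 <- 100^2 / grow_network(growth_config(2, 100))$N
  expect_lt(abs(v100 / v50 - 1), 0.2)
})

test_that("saturated LERW growth with unit seed samples uniform spanning trees", {
  # 1-D ring of L sites: the spanning trees are exactly the L edge-deleted
  # cycles; Wilson's algorithm must produce them uniformly.
  set.seed(13)
  L <- 5
  n_runs <- 4000
  sigs <- character(n_runs)
  for (r in seq_len(n_runs)) {
    lay <- grow_network(growth_config(1, L, v0 = 1))
    sigs[r] <- tree_signature(lay)
  }
  cnt <- table(sigs)
  expect_length(cnt, L)
  chi2 <- sum((cnt - n_runs / L)^2 / (n_runs / L))
  expect_lt(chi2, qchisq(1 - 1e-4, df = L - 1))

  # 3x3 torus: Kirchhoff's theorem gives the exact number of spanning
  # trees; check support size and edge-inclusion uniformity (all edges are
  # equivalent by vertex-transitivity, inclusion probability 8/18 each)
  s <- substrate(2, 3)
  A <- matrix(0, 9, 9)
  for (v in 1:9) for (u in site_neighbors(v, s)) A[v, u] <- 1
  Q <- diag(rowSums(A)) - A
  n_trees <- round(det(Q[-1, -1]))
  expect_equal(n_trees, 11664)

  n_runs2 <- 20000
  edge_count <- new.env()
  seen <- new.env()
  for (r in seq_len(n_runs2)) {
    lay <- grow_network(growth_config(2, 3, v0 = 1))
    ie <- internal_edges(lay)
    e <- rbind(ie, cbind(lay$bonds$site_a, lay$bonds$site_b))
    key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    sig <- paste(sort(key), collapse = ";")
    seen[[sig]] <- TRUE
    for (k in key) {
      edge_count[[k]] <- (if (is.null(edge_count[[k]])) 0 else edge_count[[k]]) + 1
    }
  }
  counts <- unlist(as.list(edge_count))
  expect_length(counts, 18)
  p <- 8 / 18
  expected <- n_runs2 * p
  chi2 <- sum((counts - expected)^2 / (expected * (1 - p)))
  # dependent counts, so use a generous quantile; catches directional bias
  expect_lt(chi2, qchisq(1 - 1e-5, df = 17) * 2)
  # many distinct trees observed out of the 11664
  expect_gt(length(ls(seen)), 5000)
})
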