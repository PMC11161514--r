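#' Fractal dimensions of the supported growth processes
#'
#' LERW trajectories have fractal dimension 5/4 in d = 2, approximately
#' 1.6236 in d = 3 and 2 at and above the upper critical dimension d = 4
#' (where a logarithmic correction, not modeled here, applies). Straight
#' rays are one-dimensional in any d.
#'
#' @param process one of `"lerw"`, `"straight_random_dir"`, `"straight_axis"`.
#' @param d embedding dimension.
#' @return the fractal dimension d_f.
#' @export
df_lookup <- function(process, d) {
  process <- match.arg(process, c("lerw", "straight_random_dir", "straight_axis"))
  if (process != "lerw") return(1)
  if (d <= 1) return(1)
  if (d == 2) return(5 / 4)
  if (d == 3) return(1.6236)
  2
}

process_code <- function(process) {
  switch(process, lerw = 0L, straight_random_dir = 1L, straight_axis = 2L,
         stop("unknown process: ", process))
}

#' Growth run configuration
#'
#' @param d,L substrate dimension and linear size (L >= 3 for growth runs).
#' @param process `"lerw"` (default), `"straight_random_dir"` or
#'   `"straight_axis"`.
#' @param n_max number of nodes to add, or `"saturate"` to grow until every
#'   site is occupied.
#' @param v0 initial node volume: a positive integer, or `"span"` (default)
#'   for v0 = round(L^d_f) so the first node spans the available space.
#' @param d_f fractal dimension used by the `"span"` policy and derived
#'   predictions; defaults to [df_lookup()].
#' @param seed_budget_factor safety factor on the seed node's proposal
#'   budget, `factor * v0^(d/d_f)` proposals (a LERW of length m needs
#'   ~m^(d/d_f) proposals, so a budget linear in v0 would starve large
#'   seeds); growth is flagged if the budget is exhausted.
#' @param rng_seed optional integer; when non-NULL, `grow_network()` calls
#'   `set.seed()` with it so runs are reproducible bit-for-bit.
#' @return an object of class `growth_config`.
#' @export
growth_config <- function(d, L, process = "lerw", n_max = "saturate",
                          v0 = "span", d_f = NULL,
                          seed_budget_factor = 50, rng_seed = NULL) {
  process <- match.arg(process, c("lerw", "straight_random_dir", "straight_axis"))
  s <- substrate(d, L)
  if (s$L < 3L) stop("growth runs require L >= 3")
  if (is.null(d_f)) d_f <- df_lookup(process, s$d)
  if (d_f < 1 || d_f > s$d) stop("`d_f` must lie in [1, d]")
  if (identical(v0, "span")) {
    v0_val <- round(as.numeric(s$L)^d_f)
  } else {
    v0_val <- as.numeric(v0)
    if (is.na(v0_val) || v0_val < 1) stop("`v0` must be a positive integer or \"span\"")
  }
  if (v0_val > s$n_sites) stop("`v0` exceeds the number of lattice sites")
  saturate <- identical(n_max, "saturate")
  if (!saturate) {
    n_max <- as.numeric(n_max)
    if (is.na(n_max) || n_max < 1) stop("`n_max` must be >= 1 or \"saturate\"")
  }
  structure(list(substrate = s, d = s$d, L = s$L, process = process,
                 n_max = if (saturate) Inf else n_max, saturate = saturate,
                 v0 = v0_val, d_f = d_f,
                 seed_budget_factor = seed_budget_factor,
                 rng_seed = rng_seed),
            class = "growth_config")
}

#' @export
print.growth_config <- function(x, ...) {
  cat(sprintf("<growth_config> d=%d L=%d process=%s n_max=%s v0=%d d_f=%.4f\n",
              x$d, x$L, x$process,
              if (x$saturate) "saturate" else format(x$n_max),
              as.integer(x$v0), x$d_f))
  invisible(x)
}

seed_budget <- function(cfg) {
  ceiling(cfg$seed_budget_factor * cfg$v0^(cfg$d / cfg$d_f))
}

## --- single-trajectory operations -----------------------------------------

grow_single <- function(s, occ, start_site, node_id, process,
                        target = -1, allow_hit = TRUE, budget = Inf) {
  if (occ$owner[start_site] != 0L) stop("start site is occupied")
  if (is.infinite(budget)) budget <- 2e18
  res <- cpp_grow_single(s$d, s$L, occ$owner, start_site - 1L, node_id,
                         process_code(process), target, allow_hit, budget)
  occ$owner <- res$owner
  occ$n_occupied <- sum(occ$owner != 0L)
  hit <- NULL
  if (res$hit) {
    hit <- list(site_a = res$hit_a + 1L, site_b = res$hit_b + 1L,
                node_i = node_id, node_j = res$partner)
  }
  list(trajectory = res$trajectory + 1L, hit = hit, closed = res$closed,
       steps = res$steps, erased = res$erased,
       budget_exceeded = res$budget_exceeded)
}

#' Grow a loop-erased random walk trajectory
#'
#' Runs the kinetic LERW from `start_site`: a uniform neighbor of the head
#' is proposed at each step; an empty site extends the walk, a site on the
#' walk's own trajectory triggers loop erasure (the loop's sites are
#' released immediately), and a site owned by another node stops the walk
#' and forms a bond on that lattice edge. Claimed sites are recorded in
#' `occ` on return.
#'
#' @param s a [substrate()].
#' @param occ an [new_occupancy()], updated in place.
#' @param start_site an unoccupied site index.
#' @param node_id id to claim sites under.
#' @param target_length stop once the post-erasure length reaches this
#'   value (used for free seed growth); `-1` to grow until a hit.
#' @param allow_hit whether contact with another node stops the walk.
#' @param budget maximum number of proposals before giving up (flagged in
#'   the result as `budget_exceeded`).
#' @return list with `trajectory` (site indices, in order), `hit` (NULL or
#'   a bond: `site_a`, `site_b`, `node_i`, `node_j`), `steps`, `erased`,
#'   `budget_exceeded`.
#' @export
grow_lerw_trajectory <- function(s, occ, start_site, node_id = 1L,
                                 target_length = -1, allow_hit = TRUE,
                                 budget = Inf) {
  grow_single(s, occ, start_site, node_id, "lerw",
              target = target_length, allow_hit = allow_hit, budget = budget)
}

#' Grow a straight-ray trajectory
#'
#' Digitized straight line from `start_site` (face-adjacent voxel
#' traversal). `mode = "random_dir"` draws a uniform direction on the unit
#' sphere; `mode = "axis"` picks a random signed lattice axis. The ray
#' stops at first contact with another node (bond formed) or with itself
#' after periodic wrap (node closed, no bond).
#'
#' @inheritParams grow_lerw_trajectory
#' @param mode `"random_dir"` or `"axis"`.
#' @return as [grow_lerw_trajectory()], plus `closed`.
#' @export
grow_straight_trajectory <- function(s, occ, start_site, node_id = 1L,
                                     mode = c("random_dir", "axis"),
                                     target_length = -1, allow_hit = TRUE,
                                     budget = Inf) {
  mode <- match.arg(mode)
  grow_single(s, occ, start_site, node_id,
              if (mode == "random_dir") "straight_random_dir" else "straight_axis",
              target = target_length, allow_hit = allow_hit, budget = budget)
}

#' Seed the initial node
#'
#' Grows node 1 on the empty lattice by the configured process until its
#' post-erasure volume reaches the v0 target (hits are impossible on an
#' empty substrate). Under the `"span"` policy v0 = round(L^d_f).
#'
#' @param cfg a [growth_config()].
#' @param occ optionally, an empty [new_occupancy()] to fill in place.
#' @return list with `trajectory`, `volume`, `steps`, `erased` and the
#'   occupancy used.
#' @export
seed_initial_node <- function(cfg, occ = new_occupancy(cfg$substrate)) {
  if (occ$n_occupied != 0L) stop("seed_initial_node requires an empty occupancy")
  if (!is.null(cfg$rng_seed)) set.seed(cfg$rng_seed)
  start <- sample.int(cfg$substrate$n_sites, 1L)
  res <- grow_single(cfg$substrate, occ, start, 1L, cfg$process,
                     target = cfg$v0, allow_hit = FALSE,
                     budget = seed_budget(cfg))
  if (res$budget_exceeded && !res$closed)
    warning("seed node failed to reach its v0 target within the proposal budget")
  list(trajectory = res$trajectory, volume = length(res$trajectory),
       steps = res$steps, erased = res$erased, occupancy = occ)
}

## --- full growth run -------------------------------------------------------

#' Grow a physical network
#'
#' Seeds an initial node of volume v0, then iteratively seeds new nodes at
#' uniformly random unoccupied sites, each growing by the configured
#' trajectory process until it hits the existing network, at which point a
#' single bond (and one combinatorial link) is formed. Stops after `n_max`
#' nodes or at saturation (all sites occupied).
#'
#' At saturation with the LERW process this is Wilson's algorithm: the
#' union of within-node edges and bonds is a uniform spanning tree of the
#' lattice, and the nodes partition its sites.
#'
#' @param cfg a [growth_config()].
#' @return an object of class `physical_layout`: fields `substrate`,
#'   `N`, `trajectories` (list of site-index vectors), `volumes`,
#'   `bonds` (data.frame site_a, site_b, node_i, node_j), `V_t`
#'   (cumulative volume after each addition), `owner` (site -> node id),
#'   `events` (per-node log), `saturated`, `config`.
#' @export
grow_network <- function(cfg) {
  stopifnot(inherits(cfg, "growth_config"))
  if (!is.null(cfg$rng_seed)) set.seed(cfg$rng_seed)
  res <- cpp_grow_network(cfg$substrate$d, cfg$substrate$L,
                          process_code(cfg$process),
                          if (cfg$saturate) -1 else cfg$n_max,
                          cfg$v0, seed_budget(cfg), 200)
  if (res$seed_failed)
    warning("seed node failed to reach its v0 target within the proposal budget")
  N <- as.integer(res$N)
  offs <- c(res$offsets, length(res$sites))
  sites1 <- res$sites + 1L
  trajectories <- lapply(seq_len(N), function(i) {
    sites1[(offs[i] + 1):offs[i + 1]]
  })
  bonds <- data.frame(site_a = res$bond_a + 1L, site_b = res$bond_b + 1L,
                      node_i = res$bond_i, node_j = res$bond_j)
  events <- data.frame(t = seq_len(N), seed_site = as.integer(res$seed_site) + 1L,
                       volume = res$volumes, steps = res$steps,
                       erased = res$erased,
                       len_before_erasure = res$len_before_erasure,
                       partner = res$partner)
  structure(list(substrate = cfg$substrate, N = N,
                 trajectories = trajectories, volumes = res$volumes,
                 bonds = bonds, V_t = res$V_t, owner = res$owner,
                 events = events, saturated = res$saturated, config = cfg),
            class = "physical_layout")
}

#' @export
print.physical_layout <- function(x, ...) {
  cat(sprintf("<physical_layout> d=%d L=%d process=%s: %d nodes, %d bonds, V=%g%s\n",
              x$substrate$d, x$substrate$L, x$config$process, x$N,
              nrow(x$bonds), sum(x$volumes),
              if (x$saturated) " (saturated)" else ""))
  invisible(x)
}

#' Grow to saturation and return the site partition
#'
#' @param cfg a [growth_config()] with `n_max = "saturate"`.
#' @return list with the `layout` and `partition`, an integer vector
#'   mapping every site to the id of the node occupying it.
#' @export
saturate_and_partition <- function(cfg) {
  if (!cfg$saturate) stop("config must have n_max = \"saturate\"")
  layout <- grow_network(cfg)
  list(layout = layout, partition = layout$owner)
}

## --- derived structures ----------------------------------------------------

#' Extract the combinatorial network from a layout
#'
#' One vertex per physical node; one link per bond (for model-grown
#' networks all multiplicities are 1 and the result is a tree when every
#' node formed a bond).
#'
#' @param layout a `physical_layout`.
#' @return an object of class `combinatorial_network` with fields `N`,
#'   `edges` (data.frame i, j, mult), `degrees`, `volumes`.
#' @export
combinatorial_network <- function(layout) {
  b <- layout$bonds
  i <- pmin(b$node_i, b$node_j); j <- pmax(b$node_i, b$node_j)
  key <- paste(i, j)
  agg <- tapply(rep(1L, length(key)), key, sum)
  if (length(key)) {
    parts <- do.call(rbind, strsplit(names(agg), " "))
    edges <- data.frame(i = as.integer(parts[, 1]), j = as.integer(parts[, 2]),
                        mult = as.integer(agg))
  } else {
    edges <- data.frame(i = integer(0), j = integer(0), mult = integer(0))
  }
  deg <- numeric(layout$N)
  for (r in seq_len(nrow(edges))) {
    deg[edges$i[r]] <- deg[edges$i[r]] + edges$mult[r]
    deg[edges$j[r]] <- deg[edges$j[r]] + edges$mult[r]
  }
  structure(list(N = layout$N, edges = edges, degrees = deg,
                 volumes = layout$volumes),
            class = "combinatorial_network")
}

#' @export
print.combinatorial_network <- function(x, ...) {
  cat(sprintf("<combinatorial_network> %d nodes, %d links (total multiplicity %d)\n",
              x$N, nrow(x$edges), sum(x$edges$mult)))
  invisible(x)
}

#' Internal (within-node) lattice edges of a layout
#'
#' @param layout a `physical_layout`.
#' @return two-column integer matrix of site pairs (consecutive trajectory
#'   sites of every node).
#' @export
internal_edges <- function(layout) {
  pieces <- lapply(layout$trajectories, function(tr) {
    n <- length(tr)
    if (n < 2) return(NULL)
    cbind(tr[-n], tr[-1])
  })
  out <- do.call(rbind, pieces)
  if (is.null(out)) matrix(integer(0), ncol = 2) else out
}

#' Unwrapped trajectory coordinates
#'
#' Reconstructs absolute (periodically unwrapped) coordinates along a
#' trajectory by accumulating minimal-image steps, so bounding boxes are
#' not distorted by the wrap.
#'
#' @param traj integer vector of site indices (a lattice path).
#' @param s a [substrate()].
#' @return numeric matrix, one row per trajectory site.
#' @export
unwrap_trajectory <- function(traj, s) {
  cc <- site_to_coords(traj, s)
  if (length(traj) == 1) return(cc)
  d <- apply(cc, 2, diff)
  if (is.null(dim(d))) d <- matrix(d, ncol = s$d)
  d[d > s$L / 2] <- d[d > s$L / 2] - s$L
  d[d < -s$L / 2] <- d[d < -s$L / 2] + s$L
  cs <- apply(d, 2, cumsum)
  if (is.null(dim(cs))) cs <- matrix(cs, ncol = s$d)
  rbind(cc[1, , drop = FALSE], sweep(cs, 2, as.numeric(cc[1, ]), `+`))
}

#' Bounding-box extent of a trajectory
#'
#' Side length (in lattice units, max over axes of max - min + 1) of the
#' minimal axis-aligned box containing the unwrapped trajectory.
#'
#' @inheritParams unwrap_trajectory
#' @return numeric scalar extent l_i >= 1.
#' @export
bbox_extent <- function(traj, s) {
  u <- unwrap_trajectory(traj, s)
  max(apply(u, 2, function(x) diff(range(x)))) + 1
}
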