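#' Substrate lattice
#'
#' A d-dimensional cubic lattice with linear size L and periodic boundary
#' conditions. Sites are indexed 1..L^d in R array order (first coordinate
#' varies fastest): site = 1 + sum_k c_k * L^(k-1) with 0-based
#' coordinates c_k in [0, L).
#'
#' @param d integer dimension, >= 1.
#' @param L integer linear size, >= 2. Production growth runs require
#'   L >= 3 (for L = 2 the periodic wrap duplicates neighbors; neighbor
#'   lists are deduplicated and have fewer than 2d entries).
#' @return An object of class `substrate` with fields `d`, `L`, `n_sites`.
#' @examples
#' s <- substrate(2, 10)
#' coords_to_site(c(1, 0), s)  # 2: second cell in array order
#' @export
substrate <- function(d, L) {
  d <- as.integer(d); L <- as.integer(L)
  if (is.na(d) || d < 1L) stop("`d` must be an integer >= 1")
  if (is.na(L) || L < 2L) stop("`L` must be an integer >= 2")
  n <- as.numeric(L)^d
  if (n > 2^31 - 1) stop("lattice too large: L^d must fit in an integer")
  structure(list(d = d, L = L, n_sites = as.integer(n)), class = "substrate")
}

#' @export
print.substrate <- function(x, ...) {
  cat(sprintf("<substrate> d=%d, L=%d, %d sites, periodic\n",
              x$d, x$L, x$n_sites))
  invisible(x)
}

#' Convert lattice coordinates to a site index
#'
#' @param coords integer vector of length `d` with entries in [0, L), or a
#'   matrix with `d` columns (one row per site).
#' @param s a [substrate()].
#' @return integer site index (1-based), vectorized over rows.
#' @export
coords_to_site <- function(coords, s) {
  m <- if (is.matrix(coords)) coords else matrix(coords, nrow = 1)
  if (ncol(m) != s$d) stop("`coords` must have d = ", s$d, " entries")
  if (any(m < 0) || any(m >= s$L)) stop("coordinate out of range [0, L)")
  idx <- as.vector(m %*% s$L^(seq_len(s$d) - 1)) + 1
  as.integer(idx)
}

#' Convert site indices to lattice coordinates
#'
#' @param site integer vector of 1-based site indices.
#' @param s a [substrate()].
#' @return integer matrix with one row per site and `d` columns (0-based
#'   coordinates).
#' @export
site_to_coords <- function(site, s) {
  if (any(site < 1L) || any(site > s$n_sites)) stop("site index out of range")
  x <- site - 1L
  out <- matrix(0L, nrow = length(site), ncol = s$d)
  for (k in seq_len(s$d)) {
    out[, k] <- x %% s$L
    x <- x %/% s$L
  }
  out
}

#' Neighbors of a site under the periodic lattice
#'
#' Returns the face-adjacent (von Neumann) neighbors with periodic wrap.
#' For L >= 3 there are exactly 2d distinct neighbors; for L = 2 wrap
#' duplicates collapse and the list is deduplicated.
#'
#' @param site a single 1-based site index.
#' @param s a [substrate()].
#' @return integer vector of neighbor site indices.
#' @export
site_neighbors <- function(site, s) {
  cc <- site_to_coords(site, s)[1, ]
  out <- integer(0)
  for (k in seq_len(s$d)) {
    for (dir in c(1L, -1L)) {
      c2 <- cc
      c2[k] <- (c2[k] + dir) %% s$L
      out <- c(out, coords_to_site(c2, s))
    }
  }
  unique(out)
}

#' Occupancy bookkeeping
#'
#' Mutable record of which node (if any) owns each lattice site. Stored in
#' an environment so growth operations can update it in place.
#'
#' @param s a [substrate()].
#' @return an object of class `occupancy` with fields `owner` (integer
#'   vector, 0 = empty) and `n_occupied`.
#' @export
new_occupancy <- function(s) {
  e <- new.env(parent = emptyenv())
  e$owner <- integer(s$n_sites)
  e$n_occupied <- 0L
  e$substrate <- s
  class(e) <- "occupancy"
  e
}

#' @export
print.occupancy <- function(x, ...) {
  cat(sprintf("<occupancy> %d / %d sites occupied\n",
              x$n_occupied, x$substrate$n_sites))
  invisible(x)
}

#' Claim sites for a node
#'
#' @param occ an [new_occupancy()] object.
#' @param sites integer site indices, all currently empty.
#' @param node_id positive integer node id.
#' @return the occupancy, invisibly.
#' @export
occupy_sites <- function(occ, sites, node_id) {
  if (any(occ$owner[sites] != 0L)) stop("site already occupied")
  occ$owner[sites] <- as.integer(node_id)
  occ$n_occupied <- occ$n_occupied + length(sites)
  invisible(occ)
}

#' Sample a uniformly random unoccupied site
#'
#' Rejection sampling while less than half the lattice is occupied (O(1)
#' expected cost), then exact sampling from the list of empty sites.
#'
#' @param occ an [new_occupancy()] object.
#' @param s a [substrate()]; defaults to the occupancy's own substrate.
#' @return a site index, or `NA_integer_` when the substrate is saturated
#'   (the growth loop treats saturation as a normal exit, not an error).
#' @export
sample_unoccupied <- function(occ, s = occ$substrate) {
  n <- s$n_sites
  if (occ$n_occupied >= n) return(NA_integer_)
  if (occ$n_occupied < n / 2) {
    repeat {
      cand <- sample.int(n, 1L)
      if (occ$owner[cand] == 0L) return(cand)
    }
  }
  empty <- which(occ$owner == 0L)
  empty[sample.int(length(empty), 1L)]
}
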