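#' Layout (network-of-networks) Laplacian
#'
#' Weighted Laplacian of the physical layout: links within physical nodes
#' have weight 1, bonds between nodes have weight w. At w = 0 the matrix
#' is block-diagonal with one zero eigenvalue per physical node.
#'
#' @param layout a `physical_layout`.
#' @param w inter-node coupling weight (>= 0).
#' @return list of class `layout_laplacian`: `Q` (sparse symmetric
#'   V x V), `w`, `sites` (site index of each row), `node_of` (owning node
#'   per row).
#' @export
layout_laplacian <- function(layout, w) {
  if (w < 0) stop("`w` must be >= 0")
  occ_sites <- which(layout$owner != 0L)
  row_of <- integer(layout$substrate$n_sites)
  row_of[occ_sites] <- seq_along(occ_sites)
  ie <- internal_edges(layout)
  b <- layout$bonds
  ii <- c(ie[, 1], b$site_a)
  jj <- c(ie[, 2], b$site_b)
  ww <- c(rep(1, nrow(ie)), rep(w, nrow(b)))
  keep <- ww > 0
  ii <- row_of[ii[keep]]; jj <- row_of[jj[keep]]; ww <- ww[keep]
  V <- length(occ_sites)
  A <- Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii), x = c(ww, ww),
                            dims = c(V, V))
  Q <- Matrix::Diagonal(x = Matrix::rowSums(A)) - A
  structure(list(Q = Q, w = w, sites = occ_sites,
                 node_of = layout$owner[occ_sites]),
            class = "layout_laplacian")
}

#' Combinatorial (weighted) graph Laplacian
#'
#' @param G a `combinatorial_network` or `real_network`; link weight =
#'   multiplicity.
#' @param warn_disconnected warn when the graph is not connected.
#' @return sparse symmetric N x N Laplacian.
#' @export
combinatorial_laplacian <- function(G, warn_disconnected = TRUE) {
  N <- G$N
  e <- G$edges
  A <- Matrix::sparseMatrix(i = c(e$i, e$j), j = c(e$j, e$i),
                            x = c(e$mult, e$mult), dims = c(N, N))
  Q <- Matrix::Diagonal(x = Matrix::rowSums(A)) - A
  if (warn_disconnected) {
    g <- igraph::graph_from_edgelist(cbind(e$i, e$j), directed = FALSE)
    g <- igraph::add_vertices(g, max(0, N - igraph::vcount(g)))
    if (igraph::components(g)$no > 1)
      warning("combinatorial network is disconnected; spectrum still computable")
  }
  Q
}

#' Physical network Laplacian
#'
#' Volume-normalized Laplacian Q_phys = V^{-1/2} Q_G V^{-1/2}, the
#' generator of the slow diffusion modes of the layout at weak inter-node
#' coupling. The vector with entries sqrt(v_i) is its zero eigenvector.
#'
#' @param Q_G sparse combinatorial Laplacian.
#' @param volumes positive node volumes (length N).
#' @return list of class `physical_laplacian`: `Q_phys`, `Q_G`, `volumes`.
#' @export
physical_laplacian <- function(Q_G, volumes) {
  if (length(volumes) != nrow(Q_G)) stop("`volumes` must have length N")
  if (any(volumes <= 0)) stop("volumes must be positive")
  S <- Matrix::Diagonal(x = 1 / sqrt(volumes))
  structure(list(Q_phys = S %*% Q_G %*% S, Q_G = Q_G, volumes = volumes),
            class = "physical_laplacian")
}

#' Volume-shuffled physical Laplacian (null model)
#'
#' Destroys the degree-volume correlation by applying a uniformly random
#' permutation to the volumes before normalizing; the multiset of volumes
#' is unchanged.
#'
#' @inheritParams physical_laplacian
#' @return a `physical_laplacian` with an extra `permutation` field.
#' @export
shuffled_physical_laplacian <- function(Q_G, volumes) {
  perm <- sample.int(length(volumes))
  out <- physical_laplacian(Q_G, volumes[perm])
  out$permutation <- perm
  out
}

## --- eigensolvers ----------------------------------------------------------

dense_spectrum <- function(M) {
  eigen(as.matrix(M), symmetric = TRUE)
}

arpack_extremal <- function(M, which = "LA", nev = 1) {
  n <- nrow(M)
  f <- function(x, extra) as.numeric(M %*% x)
  res <- igraph::arpack(f, options = list(n = n, nev = nev,
                                          ncv = min(n, max(4 * nev + 3, 20)),
                                          which = which, maxiter = 5000),
                        sym = TRUE)
  res
}

#' Spectrum report of a symmetric matrix
#'
#' Dense full decomposition for dimension <= `dense_limit`; otherwise
#' extremal eigenpairs via ARPACK (largest directly; the algebraic
#' connectivity by deflating the supplied zero mode and spectrum
#' shifting).
#'
#' @param M symmetric (sparse or dense) matrix, e.g. a Laplacian.
#' @param mode `"full"`, `"auto"` or `"extremal"`.
#' @param zero_vector known zero eigenvector for deflation in extremal
#'   mode (default: the constant vector, correct for unnormalized
#'   Laplacians; pass sqrt(volumes) for a physical Laplacian).
#' @param dense_limit dimension at which to switch to the sparse path.
#' @return object of class `spectrum_report`: `values` (ascending; full
#'   spectrum in dense mode, extremal pair otherwise), `lambda_2`,
#'   `lambda_N`, `u_N` (unit-norm leading eigenvector), `i_star`
#'   (argmax |u_N|, ties broken by smallest index), `mode`.
#' @export
spectrum <- function(M, mode = c("auto", "full", "extremal"),
                     zero_vector = NULL, dense_limit = 2000) {
  mode <- match.arg(mode)
  n <- nrow(M)
  if (mode == "full" || (mode == "auto" && n <= dense_limit)) {
    e <- dense_spectrum(M)
    vals <- rev(e$values)           # ascending
    uN <- e$vectors[, 1]            # eigen returns descending order
    lam2 <- vals[2]
    lamN <- vals[n]
    used <- "full"
  } else {
    la <- arpack_extremal(M, "LA", 1)
    lamN <- la$values[1]
    uN <- as.numeric(la$vectors)
    # lambda_2: largest eigenvalue of sigma*I - (M + sigma z z^T)
    z <- if (is.null(zero_vector)) rep(1, n) else zero_vector
    z <- z / sqrt(sum(z^2))
    sigma <- max(Matrix::rowSums(abs(M))) + 1  # Gershgorin bound on lambda_N
    f <- function(x, extra) {
      as.numeric(sigma * x - M %*% x - sigma * z * sum(z * x))
    }
    r2 <- igraph::arpack(f, options = list(n = n, nev = 1,
                                           ncv = min(n, 25),
                                           which = "LA", maxiter = 5000),
                         sym = TRUE)
    lam2 <- sigma - r2$values[1]
    vals <- c(0, lam2, lamN)
    used <- "extremal"
  }
  uN <- uN / sqrt(sum(uN^2))
  i_star <- which.max(abs(uN))  # which.max takes the first (smallest id) on ties
  structure(list(values = vals, lambda_2 = lam2, lambda_N = lamN,
                 u_N = uN, i_star = i_star, mode = used, n = n),
            class = "spectrum_report")
}

#' @export
print.spectrum_report <- function(x, ...) {
  cat(sprintf("<spectrum_report> n=%d (%s): lambda_2=%.6g lambda_N=%.6g i*=%d\n",
              x$n, x$mode, x$lambda_2, x$lambda_N, x$i_star))
  invisible(x)
}

#' Perturbation-theory check for the physical Laplacian
#'
#' First-order perturbation theory in the inter-node coupling w predicts
#' that the N smallest eigenvalues of the layout Laplacian Q_P(w) equal
#' w times the eigenvalues of Q_phys = V^{-1/2} Q_G V^{-1/2}, while the
#' remaining eigenvalues stay O(1). This routine compares the two spectra
#' across a grid of w (dense path; layouts up to ~2000 sites).
#'
#' @param layout a `physical_layout`.
#' @param w_list positive coupling weights (checked in decreasing order).
#' @return data.frame with columns `w`, `max_rel_gap` (max over the N-1
#'   nonzero slow eigenvalues of |lambda_slow/w - lambda_phys| /
#'   lambda_phys), `min_fast` (smallest eigenvalue of the fast group) and
#'   `max_slow` (largest slow eigenvalue).
#' @export
perturbation_check <- function(layout, w_list) {
  if (any(w_list <= 0)) stop("`w_list` must be positive")
  w_list <- sort(w_list, decreasing = TRUE)
  V <- sum(layout$owner != 0L)
  if (V > 2000) stop("perturbation_check uses the dense path: <= 2000 sites")
  G <- combinatorial_network(layout)
  Qg <- combinatorial_laplacian(G, warn_disconnected = FALSE)
  Qp <- physical_laplacian(Qg, G$volumes)
  lam_phys <- sort(dense_spectrum(Qp$Q_phys)$values)
  N <- G$N
  rows <- lapply(w_list, function(w) {
    L <- layout_laplacian(layout, w)
    vals <- sort(dense_spectrum(L$Q)$values)
    slow <- vals[seq_len(N)]
    fast <- vals[(N + 1):length(vals)]
    nz <- 2:N  # skip the exact zero mode of both spectra
    gap <- max(abs(slow[nz] / w - lam_phys[nz]) / lam_phys[nz])
    data.frame(w = w, max_rel_gap = gap, min_fast = min(fast),
               max_slow = max(slow))
  })
  do.call(rbind, rows)
}

#' Eigenvector weight vs geodesic distance
#'
#' Mean absolute eigenvector component per BFS hop-distance shell from a
#' center node (multiplicities ignored for distances).
#'
#' @param G a `combinatorial_network` or `real_network`.
#' @param eigenvector numeric vector of length N.
#' @param center_node 1-based node index.
#' @return data.frame with `distance`, `mean_weight`, `n_nodes`.
#' @export
eigvec_distance_profile <- function(G, eigenvector, center_node) {
  g <- igraph::graph_from_edgelist(cbind(G$edges$i, G$edges$j),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0, G$N - igraph::vcount(g)))
  dist <- as.numeric(igraph::distances(g, v = center_node,
                                       mode = "all", weights = NA))
  keep <- is.finite(dist)
  df <- aggregate(list(mean_weight = abs(eigenvector[keep])),
                  by = list(distance = dist[keep]), mean)
  df$n_nodes <- as.vector(table(dist[keep]))
  df
}

#' Localization report for the leading eigenvectors
#'
#' Identifies the localization center of the leading eigenvector of the
#' combinatorial Laplacian (i_G, typically the largest hub) and of the
#' physical Laplacian (i_phys, the maximizer of the degree/volume ratio),
#' together with the degree rank and volume percentile of i_phys. Ties
#' are broken by smallest node id.
#'
#' @param spec_G a [spectrum()] report for Q_G.
#' @param spec_phys a [spectrum()] report for Q_phys.
#' @param degrees,volumes node degrees (weighted) and volumes.
#' @return list: `i_G`, `i_phys`, `degree_rank_i_phys` (1 = largest
#'   degree), `volume_percentile_i_phys` (fraction of nodes with volume <=
#'   v_{i_phys}), `argmax_kv` (argmax_i k_i/v_i) and
#'   `i_phys_matches_argmax_kv`.
#' @export
localization_report <- function(spec_G, spec_phys, degrees, volumes) {
  i_G <- spec_G$i_star
  i_phys <- spec_phys$i_star
  kv <- degrees / volumes
  argmax_kv <- which.max(kv)
  deg_rank <- rank(-degrees, ties.method = "min")[i_phys]
  vol_pct <- mean(volumes <= volumes[i_phys])
  list(i_G = i_G, i_phys = i_phys,
       degree_rank_i_phys = as.integer(deg_rank),
       volume_percentile_i_phys = vol_pct,
       argmax_kv = argmax_kv,
       i_phys_matches_argmax_kv = identical(as.integer(i_phys),
                                            as.integer(argmax_kv)))
}
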