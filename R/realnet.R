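#' Load a real physical network from TSV files
#'
#' The edge file has rows `node_i <TAB> node_j <TAB> multiplicity` (e.g.
#' synapse counts per neuron pair); the volume file has rows
#' `node_id <TAB> volume`. A header line is detected and skipped when the
#' third (resp. second) field of the first row is not numeric. Directed
#' duplicates are symmetrized by summing multiplicities in both
#' directions; self-links are dropped (count logged); every node present
#' in the edge list must have a volume, otherwise the missing ids are
#' named in the error. Volumes are also stored normalized to mean 1, the
#' unit convention under which Q_G and Q_phys spectra are comparable.
#'
#' @param edge_file,volume_file paths to TSV files.
#' @return object of class `real_network`: `ids` (original labels), `N`,
#'   `edges` (data.frame i, j, mult with 1-based internal indices),
#'   `volumes_raw`, `volumes` (normalized, mean 1), `degrees`
#'   (multiplicity-weighted), `n_self_links_dropped`.
#' @export
load_real_network <- function(edge_file, volume_file) {
  ed <- read_tsv_maybe_header(edge_file, 3, "edge")
  vo <- read_tsv_maybe_header(volume_file, 2, "volume")
  mult <- suppressWarnings(as.numeric(ed[[3]]))
  if (any(is.na(mult)) || any(mult < 1))
    stop("malformed edge rows: multiplicity must be numeric >= 1")
  vols <- suppressWarnings(as.numeric(vo[[2]]))
  if (any(is.na(vols)) || any(vols <= 0))
    stop("malformed volume rows: volume must be numeric > 0")
  vids <- as.character(vo[[1]])
  if (anyDuplicated(vids)) stop("duplicate node ids in volume file")

  a <- as.character(ed[[1]]); b <- as.character(ed[[2]])
  self <- a == b
  n_self <- sum(self)
  a <- a[!self]; b <- b[!self]; mult <- mult[!self]

  ids <- sort(unique(c(a, b, vids)))
  missing_vol <- setdiff(unique(c(a, b)), vids)
  if (length(missing_vol))
    stop("nodes missing volumes: ", paste(head(missing_vol, 10), collapse = ", "))
  i <- match(a, ids); j <- match(b, ids)
  lo <- pmin(i, j); hi <- pmax(i, j)
  key <- paste(lo, hi)
  m <- tapply(mult, key, sum)
  parts <- do.call(rbind, strsplit(names(m), " "))
  edges <- data.frame(i = as.integer(parts[, 1]), j = as.integer(parts[, 2]),
                      mult = as.numeric(m))
  N <- length(ids)
  volumes_raw <- setNames(rep(NA_real_, N), ids)
  volumes_raw[vids] <- vols
  volumes_raw <- unname(volumes_raw)
  deg <- numeric(N)
  for (r in seq_len(nrow(edges))) {
    deg[edges$i[r]] <- deg[edges$i[r]] + edges$mult[r]
    deg[edges$j[r]] <- deg[edges$j[r]] + edges$mult[r]
  }
  structure(list(ids = ids, N = N, edges = edges,
                 volumes_raw = volumes_raw,
                 volumes = normalize_volumes(volumes_raw),
                 degrees = deg, n_self_links_dropped = n_self),
            class = "real_network")
}

read_tsv_maybe_header <- function(path, ncol_expect, what) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < ncol_expect)
    stop("malformed ", what, " file: expected ", ncol_expect, " columns")
  numcol <- ncol_expect
  if (is.na(suppressWarnings(as.numeric(df[1, numcol])))) df <- df[-1, , drop = FALSE]
  if (nrow(df) == 0) stop("empty ", what, " file")
  df
}

#' Normalize volumes to unit mean
#'
#' Idempotent: normalizing twice equals normalizing once.
#'
#' @param v positive volumes.
#' @export
normalize_volumes <- function(v) {
  v / mean(v)
}

#' @export
print.real_network <- function(x, ...) {
  cat(sprintf("<real_network> %d nodes, %d links (total multiplicity %g), %d self-links dropped\n",
              x$N, nrow(x$edges), sum(x$edges$mult), x$n_self_links_dropped))
  invisible(x)
}

#' Multiplicity-weighted degree of a node
#'
#' @param network a `real_network`.
#' @param node node label (character) or 1-based index.
#' @return sum of link multiplicities incident to the node.
#' @export
weighted_degree <- function(network, node) {
  idx <- if (is.character(node)) match(node, network$ids) else as.integer(node)
  if (is.na(idx) || idx < 1 || idx > network$N) stop("unknown node: ", node)
  network$degrees[idx]
}

#' Fit a power law with exponential cutoff to a degree tail
#'
#' Maximum likelihood for P(k) proportional to k^{-gamma} e^{-k/kappa} on
#' k >= xmin (discrete normalization by truncated summation), with a
#' discrete lognormal fitted on the same range and the log-likelihood
#' ratio reported. As kappa -> Inf the model reduces to the pure power
#' law.
#'
#' @param degrees positive integer samples.
#' @param xmin lower cutoff of the tail (>= 1).
#' @param kappa `NULL` (default) to fit kappa by MLE, or `Inf` to pin the
#'   nested pure-power-law limit, in which case gamma equals the
#'   [fit_tail_exponent()] estimate exactly.
#' @return object of class `cutoff_fit`: `gamma`, `kappa`, `xmin`,
#'   `loglik`, `loglik_lognormal`, `loglik_ratio`, `n_tail`.
#' @export
fit_powerlaw_cutoff <- function(degrees, xmin, kappa = NULL) {
  x <- degrees[degrees >= xmin]
  n <- length(x)
  if (n < 50) stop("too few tail points: need >= 50 samples >= xmin")
  if (!is.null(kappa) && is.infinite(kappa)) {
    fit <- plfit_alpha(x, xmin)
    g <- fit$alpha
    ll <- sum(-g * log(x)) + n * (log(g - 1) + (g - 1) * log(xmin - 0.5))
    return(structure(list(gamma = g, kappa = Inf, xmin = xmin, loglik = ll,
                          loglik_lognormal = NA_real_, loglik_ratio = NA_real_,
                          n_tail = n),
                     class = "cutoff_fit"))
  }
  kmax <- max(x)
  support_max <- max(10 * kmax, 1e5)
  # log-likelihood on the discrete support {xmin, ..., support_max}
  nll <- function(par) {
    g <- par[1]; logk <- par[2]
    kap <- exp(logk)
    ks <- xmin:min(support_max, xmin + 2e6)
    logw <- -g * log(ks) - ks / kap
    mx <- max(logw)
    logZ <- mx + log(sum(exp(logw - mx)))
    -(sum(-g * log(x) - x / kap) - n * logZ)
  }
  init <- c(max(1.01, plfit_alpha(x, max(xmin, 2))$alpha), log(kmax * 2))
  op <- optim(init, nll, method = "Nelder-Mead",
              control = list(maxit = 2000, reltol = 1e-10))
  g <- op$par[1]; kap <- exp(op$par[2])
  ll <- -op$value

  # discrete lognormal on the same range
  nll_ln <- function(par) {
    mu <- par[1]; sdl <- exp(par[2])
    ks <- xmin:min(support_max, xmin + 2e6)
    logw <- -log(ks) - (log(ks) - mu)^2 / (2 * sdl^2)
    mx <- max(logw)
    logZ <- mx + log(sum(exp(logw - mx)))
    -(sum(-log(x) - (log(x) - mu)^2 / (2 * sdl^2)) - n * logZ)
  }
  op_ln <- optim(c(mean(log(x)), log(sd(log(x)) + 1e-6)), nll_ln,
                 method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-10))
  ll_ln <- -op_ln$value

  structure(list(gamma = g, kappa = kap, xmin = xmin, loglik = ll,
                 loglik_lognormal = ll_ln, loglik_ratio = ll - ll_ln,
                 n_tail = n),
            class = "cutoff_fit")
}

#' @export
print.cutoff_fit <- function(x, ...) {
  cat(sprintf("<cutoff_fit> gamma=%.3f kappa=%.3g xmin=%g n=%d logLR(pl+cut vs lognorm)=%.2f\n",
              x$gamma, x$kappa, x$xmin, x$n_tail, x$loglik_ratio))
  invisible(x)
}

#' Degree-volume report for a real network
#'
#' Volume-binned mean weighted degrees (logarithmic bins), least-squares
#' power-law slope on the binned means, and the Spearman rank correlation
#' between degree and volume.
#'
#' @param network a `real_network` (or anything with `degrees`, `volumes`).
#' @param bin_base logarithmic bin base.
#' @return list: `slope` ([scaling_fit()]), `table`, `spearman`.
#' @export
degree_volume_report <- function(network, bin_base = 1.5) {
  rel <- degree_volume_relation(network, bin_base = bin_base)
  rel$spearman <- cor(network$degrees, network$volumes, method = "spearman")
  rel
}

#' Spectral report comparing Q_G and Q_phys on a real network
#'
#' Restricts to the largest connected component (size logged), computes
#' the extremal eigenpairs of the combinatorial Laplacian, the physical
#' Laplacian (volumes normalized to mean 1 on the component) and the
#' volume-shuffled null, the localization report, and eigenvector-weight
#' vs geodesic-distance profiles for both leading eigenvectors.
#'
#' @param network a `real_network` or `combinatorial_network`.
#' @param dense_limit dimension at which to switch to sparse solvers.
#' @param full_spectra also return full eigenvalue vectors (dense path
#'   only) for CCDF tails.
#' @return list of class `physical_spectral_report`.
#' @export
physical_spectral_report <- function(network, dense_limit = 2000,
                                     full_spectra = TRUE) {
  g <- igraph::graph_from_edgelist(cbind(network$edges$i, network$edges$j),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0, network$N - igraph::vcount(g)))
  comp <- igraph::components(g)
  giant <- which.max(comp$csize)
  if (comp$csize[giant] < network$N / 2 && comp$no > 1)
    stop("no dominant connected component: largest has ",
         comp$csize[giant], " of ", network$N, " nodes")
  keep <- which(comp$membership == giant)
  remap <- integer(network$N); remap[keep] <- seq_along(keep)
  e <- network$edges
  in_cc <- comp$membership[e$i] == giant
  sub <- list(N = length(keep),
              edges = data.frame(i = remap[e$i[in_cc]], j = remap[e$j[in_cc]],
                                 mult = e$mult[in_cc]),
              degrees = network$degrees[keep],
              volumes = normalize_volumes(network$volumes[keep]))

  Qg <- combinatorial_laplacian(sub, warn_disconnected = FALSE)
  phys <- physical_laplacian(Qg, sub$volumes)
  shuf <- shuffled_physical_laplacian(Qg, sub$volumes)

  mode <- if (sub$N <= dense_limit) "full" else "extremal"
  sG <- spectrum(Qg, mode, zero_vector = rep(1, sub$N), dense_limit = dense_limit)
  sP <- spectrum(phys$Q_phys, mode, zero_vector = sqrt(sub$volumes),
                 dense_limit = dense_limit)
  sR <- spectrum(shuf$Q_phys, mode, zero_vector = sqrt(shuf$volumes),
                 dense_limit = dense_limit)

  loc <- localization_report(sG, sP, sub$degrees, sub$volumes)
  prof_G <- eigvec_distance_profile(sub, sG$u_N, sG$i_star)
  prof_P <- eigvec_distance_profile(sub, sP$u_N, sP$i_star)

  out <- list(n_component = sub$N, n_total = network$N,
              lambda_N_G = sG$lambda_N, lambda_N_phys = sP$lambda_N,
              lambda_N_shuffled = sR$lambda_N,
              lambda_N_ratio = sG$lambda_N / sP$lambda_N,
              lambda_2_G = sG$lambda_2, lambda_2_phys = sP$lambda_2,
              lambda_2_shuffled = sR$lambda_2,
              localization = loc,
              profile_G = prof_G, profile_phys = prof_P,
              spectrum_G = sG, spectrum_phys = sP, spectrum_shuffled = sR,
              component = sub)
  if (full_spectra && mode == "full") {
    out$eigenvalues <- list(G = sG$values, phys = sP$values, shuffled = sR$values)
  }
  class(out) <- "physical_spectral_report"
  out
}

#' @export
print.physical_spectral_report <- function(x, ...) {
  cat(sprintf(paste0("<physical_spectral_report> component %d/%d nodes\n",
                     "  lambda_N: G=%.4g phys=%.4g shuffled=%.4g (ratio G/phys = %.3g)\n",
                     "  lambda_2: G=%.4g phys=%.4g shuffled=%.4g\n",
                     "  i_G=%d i_phys=%d (degree rank %d, volume pct %.2f, argmax k/v %s)\n"),
              x$n_component, x$n_total,
              x$lambda_N_G, x$lambda_N_phys, x$lambda_N_shuffled, x$lambda_N_ratio,
              x$lambda_2_G, x$lambda_2_phys, x$lambda_2_shuffled,
              x$localization$i_G, x$localization$i_phys,
              x$localization$degree_rank_i_phys,
              x$localization$volume_percentile_i_phys,
              if (x$localization$i_phys_matches_argmax_kv) "yes" else "no"))
  invisible(x)
}

#' Generate a heavy-tailed physical-network fixture
#'
#' Offline stand-in for connectome-style data: a random tree with a
#' power-law-ish degree sequence (built from a Prüfer sequence so the
#' degrees are hit exactly), with node volumes tied to degree by the
#' chosen mode and normalized to mean 1.
#'
#' @param N number of nodes (>= 10).
#' @param gamma_target target degree exponent.
#' @param correlation_mode `"linear"` (v proportional to k), `"shuffled"`
#'   (volumes permuted; rank correlation ~0) or `"planted"` (volumes
#'   chosen so the degree-volume power law is k ~ v^slope, with
#'   multiplicative lognormal noise on the volumes).
#' @param slope planted exponent of the k-vs-v relation.
#' @param noise_sd lognormal sigma of the planted noise.
#' @return a `real_network`.
#' @export
generate_fixture <- function(N, gamma_target = 2.5,
                             correlation_mode = c("linear", "shuffled", "planted"),
                             slope = 0.8, noise_sd = 0.2) {
  correlation_mode <- match.arg(correlation_mode)
  if (N < 10) stop("N must be >= 10")
  deg <- as.numeric(rpowerlaw(N, gamma_target, 1))
  # adjust to a valid tree degree sequence: sum = 2(N-1), all >= 1
  target <- 2 * (N - 1)
  repeat {
    s <- sum(deg)
    if (s == target) break
    if (s > target) {
      i <- sample(which(deg > 1), 1)
      deg[i] <- deg[i] - 1
    } else {
      i <- sample.int(N, 1)
      deg[i] <- deg[i] + 1
    }
  }
  # Prüfer sequence with node i appearing deg_i - 1 times
  pruefer <- sample(rep.int(seq_len(N), deg - 1))
  edges_m <- pruefer_to_edges(pruefer, N)
  edges <- data.frame(i = pmin(edges_m[, 1], edges_m[, 2]),
                      j = pmax(edges_m[, 1], edges_m[, 2]), mult = 1)
  k <- tabulate(c(edges$i, edges$j), nbins = N)
  v <- switch(correlation_mode,
              linear = as.numeric(k),
              shuffled = as.numeric(k)[sample.int(N)],
              planted = k^(1 / slope) * exp(rnorm(N, 0, noise_sd)))
  structure(list(ids = as.character(seq_len(N)), N = N, edges = edges,
                 volumes_raw = v, volumes = normalize_volumes(v),
                 degrees = as.numeric(k), n_self_links_dropped = 0L,
                 correlation_mode = correlation_mode),
            class = "real_network")
}

# Standard linear-time Prüfer decoding: each node's degree is its count in
# the sequence plus one, and the tree realizes that degree sequence exactly.
pruefer_to_edges <- function(pruefer, N) {
  deg <- tabulate(pruefer, nbins = N) + 1L
  edges <- matrix(0L, nrow = N - 1L, ncol = 2)
  ptr <- 1L
  while (deg[ptr] != 1L) ptr <- ptr + 1L
  leaf <- ptr
  for (t in seq_along(pruefer)) {
    a <- pruefer[t]
    edges[t, ] <- c(leaf, a)
    deg[leaf] <- deg[leaf] - 1L
    deg[a] <- deg[a] - 1L
    if (deg[a] == 1L && a < ptr) {
      leaf <- a
    } else {
      while (deg[ptr] != 1L) ptr <- ptr + 1L
      leaf <- ptr
    }
  }
  edges[N - 1L, ] <- which(deg == 1L)
  edges
}
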