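# Hand-built layouts for spectral toys: path-shaped nodes laid head-to-tail
# on a 1-D ring, with one bond between consecutive nodes.
make_path_layout <- function(lengths, L = sum(lengths) + 2) {
  s <- substrate(1, L)
  N <- length(lengths)
  stops <- cumsum(lengths)
  starts <- c(1, head(stops, -1) + 1)
  trajectories <- lapply(seq_len(N), function(i) seq(starts[i], stops[i]))
  bonds <- if (N > 1) {
    data.frame(site_a = stops[-N], site_b = starts[-1],
               node_i = seq_len(N - 1), node_j = 2:N)
  } else {
    data.frame(site_a = integer(0), site_b = integer(0),
               node_i = integer(0), node_j = integer(0))
  }
  owner <- integer(L)
  for (i in seq_len(N)) owner[trajectories[[i]]] <- i
  structure(list(substrate = s, N = N, trajectories = trajectories,
                 volumes = as.numeric(lengths), bonds = bonds,
                 V_t = cumsum(lengths), owner = owner,
                 events = NULL, saturated = FALSE,
                 config = list(process = "manual", saturate = FALSE)),
            class = "physical_layout")
}

# Small real_network built directly from an edge table and volumes.
make_real_network <- function(edges, volumes) {
  N <- length(volumes)
  deg <- numeric(N)
  for (r in seq_len(nrow(edges))) {
    deg[edges$i[r]] <- deg[edges$i[r]] + edges$mult[r]
    deg[edges$j[r]] <- deg[edges$j[r]] + edges$mult[r]
  }
  structure(list(ids = as.character(seq_len(N)), N = N, edges = edges,
                 volumes_raw = volumes,
                 volumes = normalize_volumes(volumes), degrees = deg,
                 n_self_links_dropped = 0L),
            class = "real_network")
}

# Spanning-tree edge set of a saturated layout as a canonical string.
tree_signature <- function(layout) {
  ie <- internal_edges(layout)
  b <- layout$bonds
  e <- rbind(ie, cbind(b$site_a, b$site_b))
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  paste(e[order(e[, 1], e[, 2]), , drop = FALSE], collapse = ",")
}
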