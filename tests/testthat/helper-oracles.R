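# Independent oracles used to cross-check the implementation.

# Grid shortest path via igraph Dijkstra over the accessible voxels of a 3D
# logical array, 26-connectivity with Euclidean step weights. Independent of
# the package's C++ search.
oracle_grid_path <- function(blocked, src, dst, spacing = 1) {
  dims <- dim(blocked)
  idx <- function(v) v[1L] + dims[1L] * ((v[2L] - 1L) + dims[2L] * (v[3L] - 1L))
  free <- which(!blocked)
  coord <- arrayInd(free, dims)
  id_of <- integer(prod(dims))
  id_of[free] <- seq_along(free)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  # half-space offsets only; igraph edges are undirected
  offs <- offs[offs[, 1] > 0 | (offs[, 1] == 0 & offs[, 2] > 0) |
                 (offs[, 1] == 0 & offs[, 2] == 0 & offs[, 3] > 0), ,
               drop = FALSE]
  edges <- NULL
  weights <- NULL
  for (k in seq_len(nrow(offs))) {
    nb <- coord + matrix(offs[k, ], nrow(coord), 3L, byrow = TRUE)
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
      nb[, 2] >= 1 & nb[, 2] <= dims[2] &
      nb[, 3] >= 1 & nb[, 3] <= dims[3]
    lin <- nb[ok, 1L] + dims[1L] * ((nb[ok, 2L] - 1L) + dims[2L] * (nb[ok, 3L] - 1L))
    acc <- !blocked[lin]
    from <- seq_along(free)[ok][acc]
    to <- id_of[lin[acc]]
    edges <- c(edges, rbind(from, to))
    weights <- c(weights, rep(spacing * sqrt(sum(offs[k, ]^2)), length(from)))
  }
  g <- igraph::make_empty_graph(n = length(free), directed = FALSE)
  g <- igraph::add_edges(g, edges)
  s <- id_of[idx(src)]
  t <- id_of[idx(dst)]
  if (s == 0L || t == 0L) return(Inf)
  as.numeric(igraph::distances(g, v = s, to = t, weights = weights,
                               algorithm = "dijkstra"))
}

# O(n^2) brute-force contact count between two chains at a threshold
oracle_contact_count <- function(model, chain_a, chain_b, threshold) {
  a <- model$atoms[model$atoms$chain == chain_a & model$atoms$elety == "CA", ]
  b <- model$atoms[model$atoms$chain == chain_b & model$atoms$elety == "CA", ]
  n <- 0L
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      d <- sqrt((a$x[i] - b$x[j])^2 + (a$y[i] - b$y[j])^2 +
                  (a$z[i] - b$z[j])^2)
      if (d <= threshold) n <- n + 1L
    }
  }
  n
}

# Brute-force satisfied-crosslink recount straight off a truth table and a
# model's coordinates (plain arithmetic, no package distance code)
oracle_satisfied_count <- function(model, truth, cutoff) {
  n <- 0L
  for (i in seq_len(nrow(truth))) {
    a <- model$atoms[model$atoms$chain == truth$chain_a[i] &
                       model$atoms$resno == truth$resno_a[i] &
                       model$atoms$elety == "CA", ]
    b <- model$atoms[model$atoms$chain == truth$chain_b[i] &
                       model$atoms$resno == truth$resno_b[i] &
                       model$atoms$elety == "CA", ]
    d <- sqrt((a$x - b$x)^2 + (a$y - b$y)^2 + (a$z - b$z)^2)
    if (d <= cutoff) n <- n + 1L
  }
  n
}

# Score every decoy of a ladder and rank (shared by scoring/acceptance tests)
score_ladder <- function(spec) {
  model <- make_structure(spec)
  planted <- plant_crosslinks(model, spec)
  uniques <- dedupe_crosslinks(planted$csms)
  decoys <- make_decoys(model, spec)
  scores <- lapply(decoys, function(d) {
    mapped <- map_crosslinks(uniques, planted$chain_map, d)
    xl_score(measure_crosslinks(d, mapped))
  })
  mags <- stats::setNames(spec$decoy_ladder,
                          vapply(decoys, `[[`, "", "model_id"))
  list(model = model, planted = planted, decoys = decoys,
       scores = scores, ranking = rank_models(scores), magnitudes = mags)
}
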