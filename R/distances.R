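# Euclidean and solvent-accessible surface distances; crosslink satisfaction.

#' Distance measurement configuration
#'
#' Parameters governing crosslink distance measurement and satisfaction.
#' The default 37 Angstrom cutoff is the conventional maximum C-alpha to
#' C-alpha span of a DSSO crosslink between lysine residues.
#'
#' @param cutoff satisfaction cutoff in Angstrom (Euclidean criterion).
#' @param grid_spacing SASD voxel grid spacing, Angstrom.
#' @param probe_radius solvent probe radius added to every atom radius,
#'   Angstrom (water: 1.4).
#' @param atom_radii named numeric vector of van der Waals radii per element.
#' @param max_search_radius how far (Angstrom) a buried SASD endpoint may be
#'   snapped to the nearest solvent-accessible voxel before the crosslink is
#'   declared unreachable.
#' @param criterion which distance gates satisfaction: `"ed"` (Euclidean,
#'   default) or `"sasd"`.
#' @param sasd_cutoff cutoff applied when `criterion = "sasd"`; defaults to
#'   `cutoff`.
#' @param path_budget_factor SASD searches abandon paths longer than
#'   `path_budget_factor * cutoff` (such a crosslink is violated regardless).
#' @return list of class `xl_distance_config`.
#' @export
distance_config <- function(cutoff = 37,
                            grid_spacing = 1.0,
                            probe_radius = 1.4,
                            atom_radii = c(C = 1.7, N = 1.55, O = 1.52,
                                           S = 1.8),
                            max_search_radius = 5.0,
                            criterion = c("ed", "sasd"),
                            sasd_cutoff = cutoff,
                            path_budget_factor = 3) {
  stopifnot(cutoff > 0, grid_spacing > 0, probe_radius >= 0,
            max_search_radius >= 0, path_budget_factor > 0)
  criterion <- match.arg(criterion)
  structure(list(cutoff = cutoff, grid_spacing = grid_spacing,
                 probe_radius = probe_radius, atom_radii = atom_radii,
                 max_search_radius = max_search_radius,
                 criterion = criterion, sasd_cutoff = sasd_cutoff,
                 path_budget_factor = path_budget_factor),
            class = "xl_distance_config")
}

#' Euclidean C-alpha to C-alpha distance
#'
#' @param model an [xl_structure()].
#' @param a,b residue selectors: length-2 vectors `c(chain, resno)` (or lists
#'   `list(chain=, resno=)`).
#' @return distance in Angstrom.
#' @export
ca_distance <- function(model, a, b) {
  pa <- resolve_ca(model, a)
  pb <- resolve_ca(model, b)
  sqrt(sum((pa - pb)^2))
}

resolve_ca <- function(model, sel) {
  if (is.list(sel)) sel <- c(sel$chain, sel$resno)
  p <- ca_coord(model, as.character(sel[[1L]]), as.integer(sel[[2L]]))
  if (is.null(p)) {
    stop("no alpha-carbon for residue ", sel[[2L]], " in chain ", sel[[1L]])
  }
  p
}

#' Solvent-accessible surface distance between two alpha-carbons
#'
#' Shortest path between the voxels nearest the two alpha-carbons that stays
#' in solvent-accessible space, computed on a regular grid over the model's
#' bounding box padded by `cfg$cutoff`. A voxel is blocked when its center
#' lies within (atom radius + probe radius) of any atom; the two endpoint
#' alpha-carbons themselves do not block. Moves connect 26-neighbouring
#' accessible voxels with Euclidean step costs, which bounds the
#' overestimation relative to the continuous shortest path at about 8%.
#' Endpoints buried inside the blocked region are rescued by snapping to the
#' nearest accessible voxel within `cfg$max_search_radius`. Paths longer than
#' `cfg$path_budget_factor * cfg$cutoff` are abandoned.
#'
#' @inheritParams ca_distance
#' @param cfg a [distance_config()].
#' @return path length in Angstrom, or `Inf` when the endpoints are
#'   unreachable (buried beyond rescue, or no path within the budget).
#' @seealso [grid_shortest_path()] for the raw grid primitive.
#' @export
sasd <- function(model, a, b, cfg = distance_config()) {
  pa <- resolve_ca(model, a)
  pb <- resolve_ca(model, b)
  atoms <- model$atoms
  # the endpoint alpha-carbons must not wall themselves in
  sel_a <- normalize_selector(a)
  sel_b <- normalize_selector(b)
  own <- (atoms$elety == "CA") &
    ((atoms$chain == sel_a[1L] & atoms$resno == as.integer(sel_a[2L])) |
     (atoms$chain == sel_b[1L] & atoms$resno == as.integer(sel_b[2L])))
  blockers <- atoms[!own, , drop = FALSE]

  h <- cfg$grid_spacing
  pad <- cfg$cutoff
  all_xyz <- as.matrix(atoms[, c("x", "y", "z")])
  origin <- apply(all_xyz, 2L, min) - pad
  upper <- apply(all_xyz, 2L, max) + pad
  dims <- as.integer(floor((upper - origin) / h)) + 1L

  radii <- atom_radius(blockers$element, cfg$atom_radii)
  blocked <- build_block_mask_cpp(as.matrix(blockers[, c("x", "y", "z")]),
                                  radii, origin, dims, h, cfg$probe_radius)
  vox <- function(p) pmin(pmax(as.integer(round((p - origin) / h)), 0L),
                          dims - 1L)
  src <- rescue_voxel(blocked, dims, vox(pa), h, cfg$max_search_radius)
  dst <- rescue_voxel(blocked, dims, vox(pb), h, cfg$max_search_radius)
  if (is.null(src) || is.null(dst)) return(Inf)
  grid_dijkstra_cpp(blocked, dims, src, dst, h,
                    cfg$path_budget_factor * cfg$cutoff)
}

normalize_selector <- function(sel) {
  if (is.list(sel)) sel <- c(sel$chain, sel$resno)
  c(as.character(sel[[1L]]), as.character(sel[[2L]]))
}

atom_radius <- function(element, table, default = 1.7) {
  r <- unname(table[element])
  r[is.na(r)] <- default
  r
}

# Snap a voxel to the nearest accessible voxel within max_radius (Angstrom).
# Returns a 0-based triplet, or NULL if everything within reach is blocked.
rescue_voxel <- function(blocked, dims, v, spacing, max_radius) {
  at <- function(ix, iy, iz) {
    blocked[1L + ix + dims[1L] * (iy + dims[2L] * iz)]
  }
  if (!at(v[1L], v[2L], v[3L])) return(v)
  r_vox <- ceiling(max_radius / spacing)
  if (r_vox < 1L) return(NULL)
  off <- expand.grid(dx = -r_vox:r_vox, dy = -r_vox:r_vox, dz = -r_vox:r_vox)
  d2 <- off$dx^2 + off$dy^2 + off$dz^2
  keep <- d2 > 0 & sqrt(d2) * spacing <= max_radius
  off <- off[keep, , drop = FALSE][order(d2[keep]), , drop = FALSE]
  for (i in seq_len(nrow(off))) {
    w <- v + c(off$dx[i], off$dy[i], off$dz[i])
    if (any(w < 0L) || any(w >= dims)) next
    if (!at(w[1L], w[2L], w[3L])) return(as.integer(w))
  }
  NULL
}

#' Shortest accessible path on a voxel grid
#'
#' Low-level SASD primitive: Dijkstra shortest path between two voxels of a
#' 3D logical occupancy array, moving between 26-connected accessible voxels
#' with Euclidean step costs. Exposed so the grid search can be exercised on
#' hand-built fixtures.
#'
#' @param blocked 3D logical array; `TRUE` marks a blocked voxel.
#' @param src,dst 1-based voxel index triplets `c(ix, iy, iz)`.
#' @param spacing grid spacing (Angstrom per voxel).
#' @param budget abandon paths longer than this (default unbounded).
#' @return path length, or `Inf` if unreachable.
#' @export
grid_shortest_path <- function(blocked, src, dst, spacing = 1, budget = Inf) {
  stopifnot(is.logical(blocked), length(dim(blocked)) == 3L)
  dims <- as.integer(dim(blocked))
  src <- as.integer(src) - 1L
  dst <- as.integer(dst) - 1L
  if (any(src < 0L) || any(src >= dims) || any(dst < 0L) || any(dst >= dims)) {
    stop("voxel index out of bounds")
  }
  grid_dijkstra_cpp(as.logical(blocked), dims, src, dst, spacing, budget)
}

#' Measure crosslink distances on a model
#'
#' Computes one measurement per mapped unique crosslink. When a crosslink
#' maps to several candidate chain pairs (homo-oligomer ambiguity), the
#' candidate with minimal Euclidean distance is recorded. Satisfaction uses
#' the Euclidean C-alpha distance against `cfg$cutoff` by default; with
#' `cfg$criterion = "sasd"` the solvent-accessible surface distance gates
#' satisfaction instead. SASD is the expensive path and is only computed on
#' request.
#'
#' @param model an [xl_structure()].
#' @param mapped output of [map_crosslinks()].
#' @param cfg a [distance_config()].
#' @param compute_sasd also compute SASD for the selected candidate of every
#'   mapped crosslink (forced on when `cfg$criterion == "sasd"`).
#' @return data.frame of class `xl_measurements`: columns `model_id`,
#'   `xl_id`, `protein_a`, `position_a`, `protein_b`, `position_b`,
#'   `chain_a`, `resno_a`, `chain_b`, `resno_b`, `ed`, `sasd`, `satisfied`.
#'   Attributes `cutoff`, `criterion` and `n_unmapped` record the
#'   measurement conditions.
#' @export
measure_crosslinks <- function(model, mapped, cfg = distance_config(),
                               compute_sasd = FALSE) {
  stopifnot(inherits(model, "xl_structure"), inherits(cfg, "xl_distance_config"))
  mapped <- as.data.frame(mapped)
  if (cfg$criterion == "sasd") compute_sasd <- TRUE
  ok <- mapped[mapped$mapped %in% TRUE, , drop = FALSE]
  n_unmapped <- length(unique(mapped$xl_id[!(mapped$xl_id %in% ok$xl_id)]))
  rows <- lapply(split(ok, ok$xl_id), function(cand) {
    eds <- vapply(seq_len(nrow(cand)), function(i) {
      ca_distance(model, c(cand$chain_a[i], cand$resno_a[i]),
                  c(cand$chain_b[i], cand$resno_b[i]))
    }, numeric(1))
    best <- which.min(eds)
    r <- cand[best, , drop = FALSE]
    r$ed <- eds[best]
    r$sasd <- if (compute_sasd) {
      sasd(model, c(r$chain_a, r$resno_a), c(r$chain_b, r$resno_b), cfg)
    } else NA_real_
    r
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(xl_id = integer(), protein_a = character(),
                      position_a = integer(), protein_b = character(),
                      position_b = integer(), chain_a = character(),
                      resno_a = integer(), chain_b = character(),
                      resno_b = integer(), mapped = logical(),
                      reason = character(), lysine_a = logical(),
                      lysine_b = logical(), ed = numeric(), sasd = numeric(),
                      stringsAsFactors = FALSE)
  }
  out$satisfied <- if (cfg$criterion == "ed") {
    out$ed <= cfg$cutoff
  } else {
    is.finite(out$sasd) & out$sasd <= cfg$sasd_cutoff
  }
  out$mapped <- NULL; out$reason <- NULL
  out <- cbind(model_id = rep(model$model_id, nrow(out)), out)
  out <- out[order(out$xl_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "cutoff") <- cfg$cutoff
  attr(out, "criterion") <- cfg$criterion
  attr(out, "n_unmapped") <- n_unmapped
  class(out) <- c("xl_measurements", "data.frame")
  out
}

#' Write a crosslink measurement table
#'
#' @param measurements an `xl_measurements` table.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(measurements, path) {
  df <- as.data.frame(measurements)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
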