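# Synthetic study data: ideal-geometry multi-chain models, decoy ladders
# with known rigid perturbations, and crosslink tables with planted truth.
#
# All generator output is deterministic under the spec seed; every table is
# written through (and read back by) the package's own I/O so synthetic data
# exercises the same code paths as engine exports.

#' Specification of a synthetic structural study
#'
#' Defines the conditions under which synthetic models, decoys and crosslink
#' tables are generated: chain architecture, inter-chain placement, how many
#' satisfied/violated crosslinks to plant around the DSSO cutoff, the decoy
#' perturbation ladder, and the seed fixing all randomness.
#'
#' The defaults emulate a three-subunit complex in the size range of a
#' corepressor assembly: three parallel, partly helical chains of 90, 60 and
#' 40 residues whose axes sit 25-27 Angstrom apart, so that lysine pairs
#' exist on both sides of the 37 Angstrom criterion; 12 satisfied and 6
#' violated crosslinks planted with a 5 Angstrom guard band; a decoy ladder
#' of 0/15/30/60/120 Angstrom rigid displacements with 0.5 Angstrom
#' coordinate noise.
#'
#' @param chains data.frame with columns `chain_id`, `length`,
#'   `fraction_helix` (lengths >= 5).
#' @param inter_chain_offsets named list of length-3 numeric offsets
#'   (Angstrom), one per chain.
#' @param n_planted_satisfied,n_planted_violated how many lysine pairs to
#'   plant below / above the cutoff.
#' @param plant_margin guard band (Angstrom): satisfied pairs are planted at
#'   ED <= cutoff - margin, violated at ED >= cutoff + margin, so labels
#'   survive coordinate noise.
#' @param decoy_ladder perturbation magnitudes (Angstrom), one decoy each.
#' @param noise_sd per-coordinate Gaussian noise applied to decoys
#'   (Angstrom).
#' @param cutoff crosslink satisfaction cutoff (Angstrom).
#' @param lysine_period every `lysine_period`-th residue is a lysine, so
#'   crosslinkable sites exist at deterministic positions.
#' @param seed integer fixing all generator randomness.
#' @return list of class `xl_synthetic_spec`.
#' @export
synthetic_spec <- function(chains = data.frame(
                             chain_id = c("A", "B", "C"),
                             length = c(90L, 60L, 40L),
                             fraction_helix = c(0.7, 0.7, 0.7)),
                           inter_chain_offsets = list(
                             A = c(0, 0, 0),
                             B = c(26, 0, 0),
                             C = c(13, 22, 0)),
                           n_planted_satisfied = 12L,
                           n_planted_violated = 6L,
                           plant_margin = 5,
                           decoy_ladder = c(0, 15, 30, 60, 120),
                           noise_sd = 0.5,
                           cutoff = 37,
                           lysine_period = 7L,
                           seed = 1L) {
  stopifnot(all(chains$length >= 5L), all(decoy_ladder >= 0),
            plant_margin >= 0, cutoff > 0, lysine_period >= 2L)
  if (!all(chains$chain_id %in% names(inter_chain_offsets))) {
    stop("every chain needs an inter_chain_offset")
  }
  structure(list(chains = chains,
                 inter_chain_offsets = inter_chain_offsets,
                 n_planted_satisfied = as.integer(n_planted_satisfied),
                 n_planted_violated = as.integer(n_planted_violated),
                 plant_margin = plant_margin,
                 decoy_ladder = decoy_ladder, noise_sd = noise_sd,
                 cutoff = cutoff, lysine_period = as.integer(lysine_period),
                 seed = as.integer(seed)),
            class = "xl_synthetic_spec")
}

#' Generate a multi-chain model with ideal backbone geometry
#'
#' Builds a C-alpha trace per chain: an N-terminal helical segment with the
#' ideal alpha-helix parameters (1.5 Angstrom rise and 100 degrees twist per
#' residue, 3.6 residues per turn, giving ~3.8 Angstrom consecutive C-alpha
#' spacing), followed by a coil segment generated as a self-avoiding random
#' walk with 3.8 Angstrom steps. Lysines are placed every
#' `spec$lysine_period` residues (alanine elsewhere) and chains are
#' translated by their `inter_chain_offsets`. Deterministic under
#' `spec$seed`.
#'
#' @param spec an [synthetic_spec()].
#' @param model_id identifier for the generated model.
#' @return an [xl_structure()].
#' @export
make_structure <- function(spec = synthetic_spec(), model_id = "synthetic") {
  stopifnot(inherits(spec, "xl_synthetic_spec"))
  set.seed(spec$seed)
  rise <- 1.5
  twist <- 100 * pi / 180
  step <- 3.8
  radius <- sqrt(step^2 - rise^2) / (2 * sin(twist / 2))
  chains <- spec$chains
  atom_rows <- vector("list", nrow(chains))
  for (ci in seq_len(nrow(chains))) {
    len <- chains$length[ci]
    n_helix <- round(len * chains$fraction_helix[ci])
    coords <- matrix(NA_real_, len, 3L)
    if (n_helix > 0L) {
      i <- seq_len(n_helix)
      coords[i, ] <- cbind(radius * cos(i * twist),
                           radius * sin(i * twist),
                           rise * i)
    }
    if (n_helix < len) {
      prev <- if (n_helix > 0L) coords[n_helix, ] else c(0, 0, 0)
      for (i in (n_helix + 1L):len) {
        for (try in 1:200) {
          dir <- stats::rnorm(3)
          cand <- prev + step * dir / sqrt(sum(dir^2))
          clash <- FALSE
          if (i > 1L) {
            prior <- coords[seq_len(i - 1L), , drop = FALSE]
            d2 <- rowSums(sweep(prior, 2L, cand)^2)
            # consecutive residues sit at the step length; only non-bonded
            # residues count as clashes
            if (i > 2L &&
                any(d2[seq_len(i - 2L)] < 3.5^2)) clash <- TRUE
          }
          if (!clash) break
        }
        coords[i, ] <- cand
        prev <- cand
      }
    }
    off <- spec$inter_chain_offsets[[chains$chain_id[ci]]]
    coords <- sweep(coords, 2L, -as.numeric(off))
    resid <- ifelse((seq_len(len) - 1L) %% spec$lysine_period == 0L,
                    "LYS", "ALA")
    atom_rows[[ci]] <- data.frame(chain = chains$chain_id[ci],
                                  resno = seq_len(len), resid = resid,
                                  elety = "CA",
                                  x = coords[, 1L], y = coords[, 2L],
                                  z = coords[, 3L], element = "C",
                                  stringsAsFactors = FALSE)
  }
  xl_structure(do.call(rbind, atom_rows), model_id = model_id)
}

#' Plant crosslinks with known satisfaction labels
#'
#' Selects lysine pairs of the model with Euclidean C-alpha distance at most
#' `cutoff - plant_margin` (planted satisfied) and at least
#' `cutoff + plant_margin` (planted violated), and emits a CSM-style
#' crosslink table (with duplicated spectrum matches across replicates, in
#' shuffled row order and with randomly swapped endpoint orientation, to
#' exercise deduplication) plus a ground-truth table. Each chain acts as its
#' own protein (accession `SYN<chain>`, numbering offset 0), so same-chain
#' pairs are intra-molecular crosslinks.
#'
#' @param model an [xl_structure()] (normally from [make_structure()]).
#' @param spec the [synthetic_spec()] used to build the model.
#' @return list with `csms` (an `xl_csms` table), `truth` (data.frame of
#'   unique planted crosslinks, canonical endpoint order, with `ed` and
#'   `planted_satisfied`), and `chain_map` (an [chain_map()]).
#' @export
plant_crosslinks <- function(model, spec) {
  stopifnot(inherits(model, "xl_structure"),
            inherits(spec, "xl_synthetic_spec"))
  set.seed(spec$seed + 1L)
  lys <- ca_table(model)
  lys <- lys[lys$resid == "LYS", , drop = FALSE]
  n <- nrow(lys)
  if (n < 2L) stop("model has fewer than 2 lysines")
  d <- cross_dist(as.matrix(lys[, c("x", "y", "z")]),
                  as.matrix(lys[, c("x", "y", "z")]))
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  ed <- d[pairs]
  sat_pool <- which(ed <= spec$cutoff - spec$plant_margin)
  vio_pool <- which(ed >= spec$cutoff + spec$plant_margin)
  if (length(sat_pool) < spec$n_planted_satisfied ||
      length(vio_pool) < spec$n_planted_violated) {
    stop("insufficient eligible lysine pairs (",
         length(sat_pool), " satisfied-eligible, ",
         length(vio_pool), " violated-eligible)")
  }
  draw <- function(pool, n) pool[sample.int(length(pool), n)]
  pick <- c(draw(sat_pool, spec$n_planted_satisfied),
            draw(vio_pool, spec$n_planted_violated))
  label <- rep(c(TRUE, FALSE),
               c(spec$n_planted_satisfied, spec$n_planted_violated))
  sel <- data.frame(chain_a = lys$chain[pairs[pick, 1L]],
                    resno_a = lys$resno[pairs[pick, 1L]],
                    chain_b = lys$chain[pairs[pick, 2L]],
                    resno_b = lys$resno[pairs[pick, 2L]],
                    ed = ed[pick], planted_satisfied = label,
                    stringsAsFactors = FALSE)
  acc <- function(ch) paste0("SYN", ch)
  sel$protein_a <- acc(sel$chain_a)
  sel$position_a <- sel$resno_a
  sel$protein_b <- acc(sel$chain_b)
  sel$position_b <- sel$resno_b
  # canonical endpoint order for the truth table
  swap <- sel$protein_a > sel$protein_b |
    (sel$protein_a == sel$protein_b & sel$position_a > sel$position_b)
  for (cols in list(c("protein_a", "protein_b"), c("position_a", "position_b"),
                    c("chain_a", "chain_b"), c("resno_a", "resno_b"))) {
    tmp <- sel[[cols[1L]]][swap]
    sel[[cols[1L]]][swap] <- sel[[cols[2L]]][swap]
    sel[[cols[2L]]][swap] <- tmp
  }
  truth <- sel[order(sel$protein_a, sel$position_a,
                     sel$protein_b, sel$position_b),
               c("protein_a", "position_a", "protein_b", "position_b",
                 "chain_a", "resno_a", "chain_b", "resno_b",
                 "ed", "planted_satisfied")]
  rownames(truth) <- NULL

  support <- sample(1:3, nrow(truth), replace = TRUE)
  rows <- truth[rep(seq_len(nrow(truth)), support), , drop = FALSE]
  flip <- sample(c(TRUE, FALSE), nrow(rows), replace = TRUE)
  csms <- data.frame(
    csm_id = NA_character_,
    replicate = sample(paste0("rep", 1:3), nrow(rows), replace = TRUE),
    protein_a = ifelse(flip, rows$protein_b, rows$protein_a),
    position_a = ifelse(flip, rows$position_b, rows$position_a),
    protein_b = ifelse(flip, rows$protein_a, rows$protein_b),
    position_b = ifelse(flip, rows$position_a, rows$position_b),
    score = round(stats::runif(nrow(rows), 20, 200), 2),
    passes_fdr = TRUE,
    stringsAsFactors = FALSE)
  csms <- csms[sample(nrow(csms)), , drop = FALSE]
  csms$csm_id <- sprintf("csm%06d", seq_len(nrow(csms)))
  rownames(csms) <- NULL
  class(csms) <- c("xl_csms", "data.frame")

  cm <- chain_map(accession = acc(chain_ids(model)),
                  chain = chain_ids(model), offset = 0L)
  list(csms = csms, truth = truth, chain_map = cm)
}

#' Generate a decoy ladder of rigidly perturbed models
#'
#' Builds one decoy per perturbation magnitude: a single chain (chosen once
#' per ladder, seeded) is rigidly translated along a fixed random unit
#' vector scaled by the magnitude, and every atom receives Gaussian
#' coordinate noise of sd `spec$noise_sd`. Holding the chain and direction
#' fixed across the ladder makes it a controlled dose-response series in
#' perturbation size.
#'
#' @param model source [xl_structure()].
#' @param spec the [synthetic_spec()] (fields `decoy_ladder`, `noise_sd`,
#'   `seed`).
#' @return list of `xl_structure` decoys, one per rung, with model ids
#'   `<source>_decoy<k>_m<magnitude>`.
#' @export
make_decoys <- function(model, spec) {
  stopifnot(inherits(model, "xl_structure"),
            inherits(spec, "xl_synthetic_spec"),
            length(spec$decoy_ladder) >= 1L)
  set.seed(spec$seed + 2L)
  chain <- sample(chain_ids(model), 1L)
  dir <- stats::rnorm(3)
  dir <- dir / sqrt(sum(dir^2))
  lapply(seq_along(spec$decoy_ladder), function(k) {
    m <- spec$decoy_ladder[k]
    decoy <- model
    idx <- decoy$atoms$chain == chain
    shift <- matrix(dir * m, sum(idx), 3L, byrow = TRUE)
    decoy$atoms[idx, c("x", "y", "z")] <-
      decoy$atoms[idx, c("x", "y", "z")] + shift
    if (spec$noise_sd > 0) {
      noise <- matrix(stats::rnorm(3L * nrow(decoy$atoms),
                                   sd = spec$noise_sd),
                      ncol = 3L)
      decoy$atoms[, c("x", "y", "z")] <-
        decoy$atoms[, c("x", "y", "z")] + noise
    }
    decoy$model_id <- sprintf("%s_decoy%02d_m%g", model$model_id, k, m)
    decoy
  })
}

#' Check a ranking for consistency with a decoy ladder
#'
#' A ranking is consistent with the known perturbation magnitudes when no
#' decoy with a larger perturbation scores strictly more satisfied
#' crosslinks than a decoy with a smaller one (ties are allowed).
#'
#' @param ranking an `xl_ranking` from [rank_models()].
#' @param magnitudes named numeric vector: perturbation magnitude per
#'   `model_id`.
#' @return `TRUE`/`FALSE`.
#' @export
ladder_consistent <- function(ranking, magnitudes) {
  df <- as.data.frame(ranking)
  m <- magnitudes[df$model_id]
  s <- df$n_satisfied
  for (i in seq_along(m)) {
    for (j in seq_along(m)) {
      if (m[j] > m[i] && s[j] > s[i]) return(FALSE)
    }
  }
  TRUE
}

#' Simulate an SD3-style CSM dataset with fixed summary marginals
#'
#' Generates a synthetic crosslink spectrum match table in the style of a
#' search-engine export from an affinity-purification XL-MS experiment, with
#' planted dataset-level marginals: the total number of CSM rows, the
#' numbers of unique intra- and inter-molecular crosslinks they collapse to,
#' and the number of distinct proteins they touch. The defaults are the
#' summary statistics of the HDAC2:MIER1:MHAP1 affinity-purification
#' dataset this package's workflow was built around (525 CSMs, 165 intra /
#' 52 inter unique crosslinks, 148 proteins). The bait protein is a
#' synthetic stand-in sequence (`MHAP1_SYNTHETIC`) of 180 residues carrying
#' exactly `bait_n_lysines` lysines, of which exactly `bait_n_crosslinked`
#' appear in crosslinks — the lysine-coverage structure reported for the
#' real bait. All endpoints are lysines of the emitted sequences; CSM rows
#' carry random replicate labels, endpoint orientation and row order, so the
#' planted marginals are only recovered by actual deduplication.
#'
#' @param n_csms total CSM rows.
#' @param n_intra,n_inter unique intra-/inter-molecular crosslink counts
#'   (`n_intra` must be at least `n_proteins - 1` so every non-bait protein
#'   can be covered; `n_inter` at least `bait_inter + 1`).
#' @param n_proteins number of distinct protein accessions.
#' @param bait_n_lysines lysines in the bait sequence.
#' @param bait_n_crosslinked bait lysines that appear crosslinked.
#' @param seed integer seed fixing all randomness.
#' @return list with `csms` (an `xl_csms` table), `sequences` (named
#'   character vector, one-letter), `bait` (the bait accession), and
#'   `truth` (list of the planted marginals).
#' @export
simulate_csm_dataset <- function(n_csms = 525L, n_intra = 165L,
                                 n_inter = 52L, n_proteins = 148L,
                                 bait_n_lysines = 20L,
                                 bait_n_crosslinked = 4L, seed = 1L) {
  n_csms <- as.integer(n_csms); n_intra <- as.integer(n_intra)
  n_inter <- as.integer(n_inter); n_proteins <- as.integer(n_proteins)
  n_unique <- n_intra + n_inter
  if (n_csms < n_unique) stop("n_csms must be >= n_intra + n_inter")
  stopifnot(n_proteins >= 2L, bait_n_crosslinked >= 3L,
            bait_n_crosslinked <= bait_n_lysines)
  set.seed(as.integer(seed))
  aa_pool <- strsplit("ADEFGHILMNPQRSTVWY", "")[[1L]]  # everything but C, K

  bait <- "MHAP1_SYNTHETIC"
  accs <- c(bait, sprintf("SYNP%03d", seq_len(n_proteins - 1L) + 1L))

  # bait: 180 aa, exactly bait_n_lysines lysines at spread positions
  bait_len <- 180L
  bait_k <- sort(sample(5:(bait_len - 5L), bait_n_lysines))
  bait_seq <- sample(aa_pool, bait_len, replace = TRUE)
  bait_seq[bait_k] <- "K"
  # non-bait proteins: 120 aa with 8 lysines at fixed slots
  k_slots <- c(9L, 23L, 37L, 51L, 65L, 79L, 93L, 107L)
  other_seq <- function() {
    s <- sample(aa_pool, 120L, replace = TRUE)
    s[k_slots] <- "K"
    paste(s, collapse = "")
  }
  sequences <- c(stats::setNames(paste(bait_seq, collapse = ""), bait),
                 stats::setNames(vapply(seq_len(n_proteins - 1L),
                                        function(i) other_seq(),
                                        character(1)),
                                 accs[-1L]))

  # the bait's crosslinked lysines: pairs drawn only from these positions
  bait_xl_pos <- sort(sample(bait_k, bait_n_crosslinked))
  bait_pairs <- t(utils::combn(bait_xl_pos, 2L))
  n_bait_intra <- min(nrow(bait_pairs), max(3L, bait_n_crosslinked))
  bait_intra <- bait_pairs[seq_len(n_bait_intra), , drop = FALSE]

  # remaining intra crosslinks cover every non-bait protein at least once
  n_rest_intra <- n_intra - n_bait_intra
  if (n_rest_intra < n_proteins - 1L) {
    stop("n_intra too small to cover every protein")
  }
  rest_prot <- rep(accs[-1L], length.out = n_rest_intra)
  per_prot_count <- table(rest_prot)
  if (max(per_prot_count) * 2L > length(k_slots)) {
    stop("not enough lysine slots for the requested intra crosslink load")
  }
  idx_within <- stats::ave(seq_len(n_rest_intra), rest_prot,
                           FUN = seq_along)
  intra <- rbind(
    data.frame(protein_a = bait, position_a = bait_intra[, 1L],
               protein_b = bait, position_b = bait_intra[, 2L],
               stringsAsFactors = FALSE),
    data.frame(protein_a = rest_prot,
               position_a = k_slots[2L * idx_within - 1L],
               protein_b = rest_prot,
               position_b = k_slots[2L * idx_within],
               stringsAsFactors = FALSE))

  # inter crosslinks: a few bait-prey links (bait side restricted to the
  # crosslinked lysines), the rest between consecutive prey proteins
  n_bait_inter <- min(8L, n_inter - 1L)
  bait_partners <- accs[1L + seq_len(n_bait_inter)]
  inter_bait <- data.frame(
    protein_a = bait,
    position_a = sample(bait_xl_pos, n_bait_inter, replace = TRUE),
    protein_b = bait_partners,
    position_b = sample(k_slots, n_bait_inter, replace = TRUE),
    stringsAsFactors = FALSE)
  n_rest_inter <- n_inter - n_bait_inter
  if (n_rest_inter > n_proteins - 2L) {
    stop("n_inter too large for distinct consecutive prey pairs")
  }
  i1 <- 1L + seq_len(n_rest_inter)
  inter_rest <- data.frame(
    protein_a = accs[i1], position_a = k_slots[1L],
    protein_b = accs[i1 + 1L], position_b = k_slots[2L],
    stringsAsFactors = FALSE)
  uniques <- rbind(intra, inter_bait, inter_rest)
  stopifnot(nrow(uniques) == n_unique)

  # expand to CSM rows: every unique gets one CSM, the surplus is spread
  support <- rep(1L, n_unique)
  extra <- table(factor(sample(n_unique, n_csms - n_unique, replace = TRUE),
                        levels = seq_len(n_unique)))
  support <- support + as.integer(extra)
  rows <- uniques[rep(seq_len(n_unique), support), , drop = FALSE]
  flip <- sample(c(TRUE, FALSE), n_csms, replace = TRUE)
  csms <- data.frame(
    csm_id = NA_character_,
    replicate = sample(paste0("rep", 1:3), n_csms, replace = TRUE),
    protein_a = ifelse(flip, rows$protein_b, rows$protein_a),
    position_a = ifelse(flip, rows$position_b, rows$position_a),
    protein_b = ifelse(flip, rows$protein_a, rows$protein_b),
    position_b = ifelse(flip, rows$position_a, rows$position_b),
    score = round(stats::runif(n_csms, 20, 300), 2),
    passes_fdr = TRUE,
    stringsAsFactors = FALSE)
  csms <- csms[sample(n_csms), , drop = FALSE]
  csms$csm_id <- sprintf("csm%06d", seq_len(n_csms))
  rownames(csms) <- NULL
  class(csms) <- c("xl_csms", "data.frame")

  list(csms = csms, sequences = sequences, bait = bait,
       truth = list(n_csms = n_csms, n_intra = n_intra, n_inter = n_inter,
                    n_proteins = n_proteins,
                    bait_lysines = bait_n_lysines,
                    bait_crosslinked = bait_n_crosslinked,
                    bait_xl_positions = bait_xl_pos))
}

#' Write a CSM table in the canonical dialect
#' @param csms an `xl_csms` table.
#' @param path output path (`.csv` for comma-separated, otherwise tab).
#' @return `path`, invisibly.
#' @export
write_crosslink_table <- function(csms, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(as.data.frame(csms), path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Rotate part of a chain about a hinge point
#'
#' Builds hinge-motion fixtures: every residue of `chain` with residue
#' number >= `from_res` is rotated by `angle_deg` about an axis through the
#' hinge residue's C-alpha.
#'
#' @param model an [xl_structure()].
#' @param chain chain to bend.
#' @param from_res first residue of the moving segment (hinge pivot).
#' @param angle_deg rotation angle, degrees.
#' @param axis rotation axis (length-3, need not be normalized).
#' @return the bent `xl_structure`.
#' @export
hinge_rotate <- function(model, chain, from_res, angle_deg,
                         axis = c(0, 0, 1)) {
  stopifnot(inherits(model, "xl_structure"))
  pivot <- ca_coord(model, chain, from_res)
  if (is.null(pivot)) stop("hinge residue not found")
  rot <- rotation_about_axis(axis, angle_deg * pi / 180)
  idx <- model$atoms$chain == chain & model$atoms$resno >= from_res
  xyz <- as.matrix(model$atoms[idx, c("x", "y", "z")])
  xyz <- sweep(sweep(xyz, 2L, pivot) %*% t(rot), 2L, -pivot)
  model$atoms[idx, c("x", "y", "z")] <- xyz
  model
}

# Rodrigues rotation matrix about a (normalized) axis
rotation_about_axis <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  k <- matrix(c(0, -u[3], u[2],
                u[3], 0, -u[1],
                -u[2], u[1], 0), 3L, 3L, byrow = TRUE)
  diag(3L) + sin(angle) * k + (1 - cos(angle)) * (k %*% k)
}
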