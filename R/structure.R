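# Structural model container: multi-chain C-alpha-aware coordinate sets.

#' Construct a structural model
#'
#' `xl_structure()` builds the package's model container from an atom table.
#' Every chain must contain at least one residue with an alpha-carbon (`CA`)
#' atom; per-chain one-letter sequences are derived from the `CA` records in
#' residue-number order.
#'
#' @param atoms data.frame with columns `chain`, `resno` (author residue
#'   numbering, integer), `resid` (3-letter residue code), `elety` (atom
#'   name, e.g. `"CA"`), `x`, `y`, `z` (Angstrom) and optionally `element`.
#' @param model_id character scalar identifying the model.
#' @return An object of class `xl_structure`: a list with elements `model_id`,
#'   `atoms` (the validated atom table) and `chain_sequences` (named character
#'   vector of one-letter sequences, one per chain).
#' @examples
#' atoms <- data.frame(chain = "A", resno = 1:2, resid = "ALA", elety = "CA",
#'                     x = c(0, 3.8), y = 0, z = 0)
#' xl_structure(atoms, model_id = "toy")
#' @export
xl_structure <- function(atoms, model_id = "model") {
  stopifnot(is.data.frame(atoms))
  required <- c("chain", "resno", "resid", "elety", "x", "y", "z")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0L) {
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  atoms$chain <- as.character(atoms$chain)
  atoms$resno <- as.integer(atoms$resno)
  atoms$resid <- as.character(atoms$resid)
  atoms$elety <- as.character(atoms$elety)
  if (is.null(atoms$element)) {
    # infer element from the first letter of the atom name (C-alpha -> C)
    atoms$element <- substr(gsub("[^A-Za-z].*$", "", atoms$elety), 1L, 1L)
  }
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("non-finite atom coordinates")
  }
  key <- paste(atoms$chain, atoms$resno, atoms$elety)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    stop("duplicate (chain, residue, atom) record: ", dup)
  }
  atoms <- atoms[order(atoms$chain, atoms$resno), , drop = FALSE]
  rownames(atoms) <- NULL

  ca <- atoms[atoms$elety == "CA", , drop = FALSE]
  chains <- unique(atoms$chain)
  no_ca <- setdiff(chains, unique(ca$chain))
  if (length(no_ca) > 0L) {
    stop("chain(s) without any alpha-carbon atom: ",
         paste(no_ca, collapse = ", "))
  }
  chain_sequences <- vapply(chains, function(ch) {
    res <- ca[ca$chain == ch, , drop = FALSE]
    paste(aa_three_to_one(res$resid), collapse = "")
  }, character(1))
  names(chain_sequences) <- chains

  structure(list(model_id = as.character(model_id),
                 atoms = atoms,
                 chain_sequences = chain_sequences),
            class = "xl_structure")
}

# 3-letter -> 1-letter residue codes; unknown residues become "X"
aa_three_to_one <- function(resid) {
  out <- suppressWarnings(bio3d::aa321(resid))
  out[is.na(out) | !out %in% strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]] <- "X"
  out
}

#' @export
print.xl_structure <- function(x, ...) {
  cat("xl_structure:", x$model_id, "\n")
  cat(" chains:", length(x$chain_sequences),
      " atoms:", nrow(x$atoms), "\n")
  for (ch in names(x$chain_sequences)) {
    cat(sprintf("  %s  %d residues\n", ch, nchar(x$chain_sequences[[ch]])))
  }
  invisible(x)
}

#' Chain identifiers of a model
#' @param model an `xl_structure`.
#' @return character vector of chain identifiers.
#' @export
chain_ids <- function(model) names(model$chain_sequences)

# Internal: alpha-carbon table for one chain (or all chains)
ca_table <- function(model, chain = NULL) {
  ca <- model$atoms[model$atoms$elety == "CA", , drop = FALSE]
  if (!is.null(chain)) ca <- ca[ca$chain %in% chain, , drop = FALSE]
  ca
}

# Internal: coordinates of one alpha-carbon; NULL if absent
ca_coord <- function(model, chain, resno) {
  a <- model$atoms
  i <- which(a$chain == chain & a$resno == resno & a$elety == "CA")
  if (length(i) == 0L) return(NULL)
  as.numeric(a[i[1L], c("x", "y", "z")])
}

#' Read a structural model from a PDB file
#'
#' Parses `ATOM` records into an [xl_structure()]. Alternate locations are
#' resolved by keeping the first altloc encountered for each
#' (chain, residue, atom) triple; `HETATM` records are ignored (their count is
#' reported via a message). Residues carrying insertion codes are collapsed
#' onto the author residue number; if two records still claim the same
#' (chain, residue, atom) after altloc resolution, parsing fails.
#'
#' @param path path to a PDB file.
#' @param model_id model identifier; defaults to the file name without
#'   extension.
#' @return an `xl_structure`.
#' @seealso [write_pdb()]
#' @export
read_pdb <- function(path, model_id = NULL) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  if (is.null(model_id)) model_id <- sub("\\.[^.]*$", "", basename(path))
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  n_het <- sum(at$type == "HETATM")
  if (n_het > 0L) message("read_pdb: ignoring ", n_het, " HETATM records")
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records in ", path)
  # first altloc wins, in file order; records that collide without a
  # distinguishing altloc are true duplicates
  key <- paste(at$chain, at$resno, at$elety, at$insert)
  keep <- !duplicated(key)
  if (any(!keep)) {
    alt <- as.character(at$alt)
    alt[is.na(alt)] <- ""
    kept_alt <- alt[keep][match(key[!keep], key[keep])]
    if (any(alt[!keep] == kept_alt)) {
      stop("duplicate (chain, residue, atom) record in ", path)
    }
  }
  at <- at[keep, , drop = FALSE]
  key2 <- paste(at$chain, at$resno, at$elety)
  if (anyDuplicated(key2)) {
    stop("duplicate (chain, residue, atom) after altloc resolution in ", path)
  }
  element <- at$elesy
  if (is.null(element) || all(is.na(element)) || all(element == "")) {
    element <- substr(gsub("[^A-Za-z].*$", "", at$elety), 1L, 1L)
  }
  atoms <- data.frame(chain = as.character(at$chain),
                      resno = as.integer(at$resno),
                      resid = as.character(at$resid),
                      elety = as.character(at$elety),
                      x = at$x, y = at$y, z = at$z,
                      element = as.character(element),
                      stringsAsFactors = FALSE)
  xl_structure(atoms, model_id = model_id)
}

#' Write a structural model to a PDB file
#'
#' Emits standard `ATOM` records (coordinates at the PDB 3-decimal
#' convention) so that [read_pdb()] round-trips chain identifiers, residue
#' numbers and alpha-carbon coordinates.
#'
#' @param model an `xl_structure`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(model, path) {
  stopifnot(inherits(model, "xl_structure"))
  a <- model$atoms
  xyz <- as.numeric(t(as.matrix(a[, c("x", "y", "z")])))
  bio3d::write.pdb(pdb = NULL, file = path, xyz = xyz,
                   type = rep("ATOM", nrow(a)),
                   resno = a$resno, resid = a$resid,
                   eleno = seq_len(nrow(a)), elety = a$elety,
                   chain = a$chain, elesy = a$element)
  invisible(path)
}

#' Apply a rigid-body transform to a model
#'
#' @param model an `xl_structure`.
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 numeric translation (Angstrom).
#' @return the transformed `xl_structure`.
#' @export
apply_transform <- function(model, rotation, translation = c(0, 0, 0)) {
  stopifnot(inherits(model, "xl_structure"),
            is.matrix(rotation), all(dim(rotation) == c(3L, 3L)),
            length(translation) == 3L)
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  new_xyz <- xyz %*% t(rotation) +
    matrix(translation, nrow(xyz), 3L, byrow = TRUE)
  model$atoms$x <- new_xyz[, 1L]
  model$atoms$y <- new_xyz[, 2L]
  model$atoms$z <- new_xyz[, 3L]
  model
}
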