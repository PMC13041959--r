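# Rigid-body superposition (Kabsch) and per-residue displacement profiles.

#' Optimal rigid superposition of two paired point sets (Kabsch)
#'
#' Least-squares optimal rotation and translation mapping `coords_b` onto
#' `coords_a`. Reflections are excluded: the rotation determinant is forced
#' to +1 by sign correction of the smallest singular vector, as physical
#' structures must never be mirrored.
#'
#' @param coords_a,coords_b N x 3 matrices of paired coordinates (Angstrom),
#'   N >= 3, not collinear.
#' @return list of class `xl_superposition` with `rotation` (3x3,
#'   determinant +1), `translation` (length 3), and `rmsd` over the paired
#'   points after transformation. Transformed coordinates are
#'   `coords_b %*% t(rotation) + translation`.
#' @export
kabsch <- function(coords_a, coords_b) {
  coords_a <- as.matrix(coords_a)
  coords_b <- as.matrix(coords_b)
  if (!all(dim(coords_a) == dim(coords_b))) stop("coordinate length mismatch")
  n <- nrow(coords_a)
  if (n < 3L) stop("need at least 3 paired points")
  cen_a <- colMeans(coords_a)
  cen_b <- colMeans(coords_b)
  a0 <- sweep(coords_a, 2L, cen_a)
  b0 <- sweep(coords_b, 2L, cen_b)
  # degenerate (collinear) sets leave the rotation underdetermined
  sv_b <- svd(b0)$d
  if (sv_b[2L] < 1e-8 * max(sv_b[1L], 1)) stop("degenerate (collinear) point set")
  h <- crossprod(b0, a0)          # 3x3 covariance
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  trans <- as.numeric(cen_a - rot %*% cen_b)
  fitted <- b0 %*% t(rot)
  rmsd <- sqrt(mean(rowSums((a0 - fitted)^2)))
  structure(list(rotation = rot, translation = trans, rmsd = rmsd,
                 anchor = NULL, per_residue_displacement = NULL),
            class = "xl_superposition")
}

#' @export
print.xl_superposition <- function(x, ...) {
  cat(sprintf("superposition: rmsd %.4f A over %s\n", x$rmsd,
              if (is.null(x$anchor)) "paired points"
              else paste(nrow(x$anchor), "anchor residues")))
  invisible(x)
}

#' Superpose one model onto another on an anchor selection
#'
#' Fits `model_b` onto `model_a` using only the alpha-carbons of an anchor
#' selection (e.g. a rigid, well-resolved domain), then applies the
#' transform to the whole of `model_b` and reports the displacement of every
#' shared residue. Anchor residues are paired by identical (chain, residue
#' number); the given order is irrelevant.
#'
#' @param model_a,model_b [xl_structure()] models sharing chain ids and
#'   residue numbering over the anchor.
#' @param anchor data.frame with columns `chain` and `resno`, or a named
#'   list `list(A = 1:100)` of residue-number vectors per chain. `NULL`
#'   anchors on all shared residues.
#' @return list with `superposition` (an `xl_superposition` whose
#'   `per_residue_displacement` data.frame has columns `chain`, `resno`,
#'   `displacement`) and `model_b_transformed`.
#' @export
superpose_on_anchor <- function(model_a, model_b, anchor = NULL) {
  stopifnot(inherits(model_a, "xl_structure"), inherits(model_b, "xl_structure"))
  ca_a <- ca_table(model_a)
  ca_b <- ca_table(model_b)
  shared <- merge(ca_a[, c("chain", "resno")], ca_b[, c("chain", "resno")])
  if (is.null(anchor)) {
    sel <- shared
  } else {
    if (is.list(anchor) && !is.data.frame(anchor)) {
      anchor <- do.call(rbind, lapply(names(anchor), function(ch) {
        data.frame(chain = ch, resno = as.integer(anchor[[ch]]))
      }))
    }
    sel <- merge(shared, anchor[, c("chain", "resno")])
  }
  if (nrow(sel) == 0L) stop("empty anchor intersection between the models")
  sel <- sel[order(sel$chain, sel$resno), , drop = FALSE]
  key_a <- paste(ca_a$chain, ca_a$resno)
  key_b <- paste(ca_b$chain, ca_b$resno)
  key_s <- paste(sel$chain, sel$resno)
  pa <- as.matrix(ca_a[match(key_s, key_a), c("x", "y", "z")])
  pb <- as.matrix(ca_b[match(key_s, key_b), c("x", "y", "z")])
  fit <- kabsch(pa, pb)
  fit$anchor <- sel

  model_bt <- apply_transform(model_b, fit$rotation, fit$translation)
  ca_bt <- ca_table(model_bt)
  key_bt <- paste(ca_bt$chain, ca_bt$resno)
  key_sh <- paste(shared$chain, shared$resno)
  qa <- as.matrix(ca_a[match(key_sh, key_a), c("x", "y", "z")])
  qb <- as.matrix(ca_bt[match(key_sh, key_bt), c("x", "y", "z")])
  disp <- sqrt(rowSums((qa - qb)^2))
  fit$per_residue_displacement <- data.frame(chain = shared$chain,
                                             resno = shared$resno,
                                             displacement = disp)
  list(superposition = fit, model_b_transformed = model_bt)
}

#' Write a per-residue displacement profile
#' @param superposition an `xl_superposition` from [superpose_on_anchor()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_displacement <- function(superposition, path) {
  stopifnot(inherits(superposition, "xl_superposition"),
            !is.null(superposition$per_residue_displacement))
  utils::write.table(superposition$per_residue_displacement, path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
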