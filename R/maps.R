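# Residue contact maps, lysine-lysine distance heatmaps, difference maps.

#' Inter-chain residue contact map
#'
#' Full C-alpha distance matrix between two chains, thresholded at 30
#' Angstrom by default to show spatial proximity between subunits of a
#' complex. With `atoms = "all"` the per-residue-pair minimum over all atoms
#' is used instead of C-alpha (for models that carry side chains).
#'
#' @param model an [xl_structure()].
#' @param chain_a,chain_b chain identifiers (may be equal: the map is then
#'   symmetric with a zero diagonal).
#' @param threshold contact threshold, Angstrom.
#' @param atoms `"calpha"` (default) or `"all"` (minimum heavy-atom
#'   distance).
#' @return object of class `xl_contact_map`: list with `chain_a`, `chain_b`,
#'   `resno_a`, `resno_b` (axis residue numbers), `distances` (matrix,
#'   Angstrom), `threshold`, and `contacts` (`distances <= threshold`).
#' @export
contact_map <- function(model, chain_a, chain_b, threshold = 30,
                        atoms = c("calpha", "all")) {
  stopifnot(inherits(model, "xl_structure"), threshold > 0)
  atoms <- match.arg(atoms)
  for (ch in c(chain_a, chain_b)) {
    if (!ch %in% chain_ids(model)) stop("unknown chain: ", ch)
  }
  ca_a <- ca_table(model, chain_a)
  ca_b <- ca_table(model, chain_b)
  if (atoms == "calpha") {
    d <- cross_dist(as.matrix(ca_a[, c("x", "y", "z")]),
                    as.matrix(ca_b[, c("x", "y", "z")]))
  } else {
    at_a <- model$atoms[model$atoms$chain == chain_a, , drop = FALSE]
    at_b <- model$atoms[model$atoms$chain == chain_b, , drop = FALSE]
    dd <- cross_dist(as.matrix(at_a[, c("x", "y", "z")]),
                     as.matrix(at_b[, c("x", "y", "z")]))
    ia <- match(at_a$resno, ca_a$resno)
    ib <- match(at_b$resno, ca_b$resno)
    d <- matrix(Inf, nrow(ca_a), nrow(ca_b))
    for (r in seq_len(nrow(dd))) {
      row_min <- tapply(dd[r, ], ib, min)
      d[ia[r], as.integer(names(row_min))] <-
        pmin(d[ia[r], as.integer(names(row_min))], row_min)
    }
  }
  if (identical(chain_a, chain_b)) {
    # exact symmetry and zero self-distances despite float round-off
    d <- (d + t(d)) / 2
    diag(d) <- 0
  }
  dimnames(d) <- list(ca_a$resno, ca_b$resno)
  structure(list(chain_a = chain_a, chain_b = chain_b,
                 resno_a = ca_a$resno, resno_b = ca_b$resno,
                 distances = d, threshold = threshold,
                 contacts = d <= threshold),
            class = "xl_contact_map")
}

cross_dist <- function(a, b) {
  # pairwise Euclidean distances between row sets
  aa <- rowSums(a^2)
  bb <- rowSums(b^2)
  d2 <- outer(aa, bb, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

#' @export
print.xl_contact_map <- function(x, ...) {
  cat(sprintf("contact map %s x %s: %d x %d residues, %d contacts <= %g A\n",
              x$chain_a, x$chain_b, length(x$resno_a), length(x$resno_b),
              sum(x$contacts), x$threshold))
  invisible(x)
}

#' @export
as.matrix.xl_contact_map <- function(x, ...) x$distances

#' @export
plot.xl_contact_map <- function(x, main = NULL, ...) {
  if (is.null(main)) {
    main <- sprintf("Contacts %s:%s (<= %g A)", x$chain_a, x$chain_b,
                    x$threshold)
  }
  graphics::image(x$resno_a, x$resno_b, x$contacts * 1,
                  col = c("white", "firebrick"),
                  xlab = paste("chain", x$chain_a, "residue"),
                  ylab = paste("chain", x$chain_b, "residue"),
                  main = main, useRaster = TRUE, ...)
  invisible(x)
}

#' Lysine-lysine Euclidean distance heatmap
#'
#' Distance matrix restricted to the lysine residues of two chains, with the
#' same C-alpha distance definition as [contact_map()]: the heatmap is the
#' lysine submatrix of the full contact map.
#'
#' @inheritParams contact_map
#' @return object of class `xl_lysine_heatmap`: list with `chain_a`,
#'   `chain_b`, `lysines_a`, `lysines_b` (residue numbers) and `distances`.
#'   Axes may be empty when a chain has no lysines.
#' @export
lysine_heatmap <- function(model, chain_a, chain_b) {
  stopifnot(inherits(model, "xl_structure"))
  for (ch in c(chain_a, chain_b)) {
    if (!ch %in% chain_ids(model)) stop("unknown chain: ", ch)
  }
  ca_a <- ca_table(model, chain_a)
  ca_b <- ca_table(model, chain_b)
  lys_a <- ca_a[ca_a$resid == "LYS", , drop = FALSE]
  lys_b <- ca_b[ca_b$resid == "LYS", , drop = FALSE]
  d <- cross_dist(as.matrix(lys_a[, c("x", "y", "z")]),
                  as.matrix(lys_b[, c("x", "y", "z")]))
  dimnames(d) <- list(lys_a$resno, lys_b$resno)
  structure(list(chain_a = chain_a, chain_b = chain_b,
                 lysines_a = lys_a$resno, lysines_b = lys_b$resno,
                 distances = d),
            class = "xl_lysine_heatmap")
}

#' @export
print.xl_lysine_heatmap <- function(x, ...) {
  cat(sprintf("lysine heatmap %s x %s: %d x %d lysines\n",
              x$chain_a, x$chain_b, length(x$lysines_a), length(x$lysines_b)))
  invisible(x)
}

#' @export
plot.xl_lysine_heatmap <- function(x, ...) {
  if (length(x$lysines_a) == 0L || length(x$lysines_b) == 0L) {
    stop("empty lysine heatmap")
  }
  graphics::image(seq_along(x$lysines_a), seq_along(x$lysines_b),
                  x$distances, col = grDevices::hcl.colors(64, "YlOrRd",
                                                           rev = TRUE),
                  axes = FALSE, xlab = paste("chain", x$chain_a, "lysine"),
                  ylab = paste("chain", x$chain_b, "lysine"),
                  main = "Lysine-lysine C-alpha distances (A)", ...)
  graphics::axis(1, at = seq_along(x$lysines_a), labels = x$lysines_a,
                 las = 2, cex.axis = 0.6)
  graphics::axis(2, at = seq_along(x$lysines_b), labels = x$lysines_b,
                 las = 2, cex.axis = 0.6)
  graphics::box()
  invisible(x)
}

#' Difference between two contact maps
#'
#' Compares binary interactions between two assemblies of the same chain
#' pair (e.g. a heterodimer versus the trimer), labelling every contact cell
#' as present only in the first map, only in the second, or shared.
#'
#' @param map_1,map_2 [contact_map()] objects over the same chain pair with
#'   identical axis lengths.
#' @return list of class `xl_map_diff` with data.frames `only_1`, `only_2`,
#'   `shared` (columns `resno_a`, `resno_b`) and a `counts` vector.
#' @export
map_difference <- function(map_1, map_2) {
  stopifnot(inherits(map_1, "xl_contact_map"), inherits(map_2, "xl_contact_map"))
  if (!all(dim(map_1$contacts) == dim(map_2$contacts))) {
    stop("contact map axis mismatch: ",
         paste(dim(map_1$contacts), collapse = "x"), " vs ",
         paste(dim(map_2$contacts), collapse = "x"))
  }
  cells <- function(mask) {
    idx <- which(mask, arr.ind = TRUE)
    data.frame(resno_a = map_1$resno_a[idx[, 1L]],
               resno_b = map_1$resno_b[idx[, 2L]])
  }
  only_1 <- cells(map_1$contacts & !map_2$contacts)
  only_2 <- cells(!map_1$contacts & map_2$contacts)
  shared <- cells(map_1$contacts & map_2$contacts)
  structure(list(only_1 = only_1, only_2 = only_2, shared = shared,
                 counts = c(only_1 = nrow(only_1), only_2 = nrow(only_2),
                            shared = nrow(shared))),
            class = "xl_map_diff")
}

#' @export
print.xl_map_diff <- function(x, ...) {
  cat("contact map difference:\n")
  cat(sprintf("  only in map 1: %d\n  only in map 2: %d\n  shared: %d\n",
              x$counts["only_1"], x$counts["only_2"], x$counts["shared"]))
  invisible(x)
}

#' Contact hotspots (connected components)
#'
#' Interface hotspots are operationalized as 4-connected components of the
#' boolean contact matrix; each contact cell is labelled with a component id
#' and component sizes are reported (largest first).
#'
#' @param map an [contact_map()].
#' @return list with `cells` (data.frame `resno_a`, `resno_b`, `component`)
#'   and `sizes` (named integer vector, descending).
#' @export
contact_hotspots <- function(map) {
  stopifnot(inherits(map, "xl_contact_map"))
  m <- map$contacts
  lab <- matrix(0L, nrow(m), ncol(m))
  comp <- 0L
  for (start in which(m)) {
    if (lab[start] != 0L) next
    comp <- comp + 1L
    queue <- start
    lab[start] <- comp
    nr <- nrow(m)
    while (length(queue) > 0L) {
      v <- queue[[1L]]; queue <- queue[-1L]
      i <- (v - 1L) %% nr + 1L
      j <- (v - 1L) %/% nr + 1L
      for (nb in list(c(i - 1L, j), c(i + 1L, j), c(i, j - 1L), c(i, j + 1L))) {
        if (nb[1L] < 1L || nb[1L] > nr || nb[2L] < 1L || nb[2L] > ncol(m)) next
        w <- nb[1L] + (nb[2L] - 1L) * nr
        if (m[w] && lab[w] == 0L) {
          lab[w] <- comp
          queue <- c(queue, w)
        }
      }
    }
  }
  idx <- which(lab > 0L, arr.ind = TRUE)
  cells <- data.frame(resno_a = map$resno_a[idx[, 1L]],
                      resno_b = map$resno_b[idx[, 2L]],
                      component = lab[lab > 0L])
  sizes <- sort(table(cells$component), decreasing = TRUE)
  list(cells = cells, sizes = stats::setNames(as.integer(sizes),
                                              names(sizes)))
}

#' Write a distance matrix as delimited text
#' @param map an `xl_contact_map` or `xl_lysine_heatmap`.
#' @param path output TSV path (row/column names are residue numbers).
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  d <- map$distances
  utils::write.table(format(d, digits = 6), path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}
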