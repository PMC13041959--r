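# Distance-restraint container and writers for downstream refinement and
# docking engines.

#' Distance restraint set
#'
#' A set of atom-pair distance restraints with a permitted band
#' `[target - lower_margin, target + upper_margin]` (Angstrom). Two output
#' dialects exist: `"docking-tbl"` emits one `assign` statement per restraint
#' in the CNS-style table a docking engine consumes; `"refinement-list"`
#' emits plain whitespace-separated rows
#' (`residue_a chain_a residue_b chain_b target`) for fragment-assembly
#' refinement.
#'
#' @param chain_a,res_a,chain_b,res_b selector vectors (chain id, author
#'   residue number) of the two endpoints.
#' @param atom atom name used for both selectors (default `"CA"`,
#'   unambiguous C-alpha restraints).
#' @param target,lower_margin,upper_margin band definition in Angstrom;
#'   `target - lower_margin` must be non-negative.
#' @param dialect `"docking-tbl"` or `"refinement-list"`.
#' @return data.frame of class `xl_restraints` with attribute `dialect`.
#' @export
restraint_set <- function(chain_a, res_a, chain_b, res_b, atom = "CA",
                          target, lower_margin, upper_margin,
                          dialect = c("docking-tbl", "refinement-list")) {
  dialect <- match.arg(dialect)
  n <- length(chain_a)
  out <- data.frame(chain_a = as.character(chain_a),
                    res_a = as.integer(res_a),
                    atom_a = rep_len(atom, n),
                    chain_b = as.character(chain_b),
                    res_b = as.integer(res_b),
                    atom_b = rep_len(atom, n),
                    target = rep_len(as.numeric(target), n),
                    lower_margin = rep_len(as.numeric(lower_margin), n),
                    upper_margin = rep_len(as.numeric(upper_margin), n),
                    stringsAsFactors = FALSE)
  if (nrow(out) > 0L && any(out$target - out$lower_margin < -1e-9)) {
    stop("restraint lower bound below zero")
  }
  attr(out, "dialect") <- dialect
  class(out) <- c("xl_restraints", "data.frame")
  out
}

#' Write a restraint set
#'
#' Output is byte-identical for identical restraint content regardless of
#' input row order: rows are sorted ascending by
#' (chain_a, res_a, chain_b, res_b) before writing, and numbers are printed
#' fixed-point with one decimal.
#'
#' @param restraints an [restraint_set()].
#' @param path output file path.
#' @param model optional [xl_structure()]; when given, every selector must
#'   resolve to an atom in the model.
#' @return `path`, invisibly.
#' @export
write_restraints <- function(restraints, path, model = NULL) {
  stopifnot(inherits(restraints, "xl_restraints"))
  df <- as.data.frame(restraints)
  if (nrow(df) == 0L) stop("refusing to write an empty restraint set")
  if (!is.null(model)) {
    a <- model$atoms
    key <- paste(a$chain, a$resno, a$elety)
    sel <- c(paste(df$chain_a, df$res_a, df$atom_a),
             paste(df$chain_b, df$res_b, df$atom_b))
    bad <- setdiff(sel, key)
    if (length(bad) > 0L) {
      stop("restraint selector(s) do not resolve in model: ",
           paste(bad, collapse = "; "))
    }
  }
  df <- df[order(df$chain_a, df$res_a, df$chain_b, df$res_b), , drop = FALSE]
  dialect <- attr(restraints, "dialect")
  lines <- if (dialect == "docking-tbl") {
    sprintf(paste0("assign (segid %s and resid %d and name %s) ",
                   "(segid %s and resid %d and name %s) %.1f %.1f %.1f"),
            df$chain_a, df$res_a, df$atom_a,
            df$chain_b, df$res_b, df$atom_b,
            df$target, df$lower_margin, df$upper_margin)
  } else {
    sprintf("%d %s %d %s %.1f",
            df$res_a, df$chain_a, df$res_b, df$chain_b, df$target)
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Check a model against a restraint set
#'
#' Re-measures every restraint's C-alpha distance on a model and reports
#' whether it falls inside the permitted band.
#'
#' @param model an [xl_structure()].
#' @param restraints an [restraint_set()].
#' @return data.frame with the restraint columns plus `distance` and
#'   `within_band`.
#' @export
check_restraints <- function(model, restraints) {
  df <- as.data.frame(restraints)
  df$distance <- vapply(seq_len(nrow(df)), function(i) {
    ca_distance(model, c(df$chain_a[i], df$res_a[i]),
                c(df$chain_b[i], df$res_b[i]))
  }, numeric(1))
  df$within_band <- df$distance >= df$target - df$lower_margin - 1e-9 &
    df$distance <= df$target + df$upper_margin + 1e-9
  df
}
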