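# Crosslink-satisfaction scoring, model ranking, restraint selection, and
# the post-docking cluster window rule.

#' XL Score of a model
#'
#' The XL Score counts the crosslinks whose measured distance on a candidate
#' model falls within the cutoff; models with more satisfied crosslinks are
#' better supported by the XL-MS data.
#'
#' @param measurements an `xl_measurements` table from [measure_crosslinks()]
#'   (all rows must share one `model_id`).
#' @return list of class `xl_score` with fields `model_id`, `n_satisfied`,
#'   `n_mapped`, `n_unmapped`, `mean_satisfied_ed` (`NA` when nothing is
#'   satisfied).
#' @export
xl_score <- function(measurements) {
  df <- as.data.frame(measurements)
  ids <- unique(df$model_id)
  if (length(ids) > 1L) {
    stop("measurements mix model_ids: ", paste(ids, collapse = ", "))
  }
  n_unmapped <- attr(measurements, "n_unmapped")
  if (is.null(n_unmapped)) n_unmapped <- 0L
  sat <- df$satisfied %in% TRUE
  structure(list(
    model_id = if (length(ids) == 1L) ids else NA_character_,
    n_satisfied = sum(sat),
    n_mapped = nrow(df),
    n_unmapped = as.integer(n_unmapped),
    mean_satisfied_ed = if (any(sat)) mean(df$ed[sat]) else NA_real_),
    class = "xl_score")
}

#' @export
print.xl_score <- function(x, ...) {
  cat(sprintf("XL score [%s]: %d / %d satisfied (%d unmapped)",
              x$model_id, x$n_satisfied, x$n_mapped, x$n_unmapped))
  if (!is.na(x$mean_satisfied_ed)) {
    cat(sprintf("; mean satisfied ED %.2f A", x$mean_satisfied_ed))
  }
  cat("\n")
  invisible(x)
}

#' Rank candidate models by XL Score
#'
#' Orders models descending by number of satisfied crosslinks; ties are
#' broken by ascending mean satisfied Euclidean distance (a tighter model
#' wins), remaining ties lexicographically by `model_id`, making the ranking
#' a deterministic total order.
#'
#' @param scores a list of [xl_score()] results (or a data.frame with the
#'   same columns).
#' @return data.frame of class `xl_ranking` with one row per model and a
#'   `rank` column (1 = best).
#' @export
rank_models <- function(scores) {
  if (inherits(scores, "xl_score")) scores <- list(scores)
  df <- if (is.data.frame(scores)) {
    as.data.frame(scores)
  } else {
    stopifnot(length(scores) >= 1L)
    do.call(rbind, lapply(scores, function(s) {
      as.data.frame(unclass(s), stringsAsFactors = FALSE)
    }))
  }
  if (nrow(df) == 0L) stop("no scores to rank")
  tie_ed <- df$mean_satisfied_ed
  tie_ed[is.na(tie_ed)] <- Inf  # nothing satisfied ranks after any tie
  ord <- order(-df$n_satisfied, tie_ed, df$model_id)
  out <- df[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("xl_ranking", "data.frame")
  out
}

#' Write a model ranking report
#' @param ranking an `xl_ranking`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  df <- as.data.frame(ranking)
  df <- df[, c("model_id", "n_satisfied", "n_mapped", "n_unmapped",
               "mean_satisfied_ed", "rank")]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Select satisfied crosslinks as distance restraints
#'
#' Converts the satisfied crosslinks of a measurement table into C-alpha to
#' C-alpha distance restraints for refinement or docking engines. Each
#' restraint encodes the permitted band `[0, cutoff]` as
#' target = cutoff / 2 with both margins = cutoff / 2.
#'
#' @param measurements an `xl_measurements` table.
#' @param cutoff satisfaction cutoff in Angstrom; defaults to the cutoff the
#'   measurements were made at.
#' @param dialect output dialect, see [restraint_set()].
#' @return a [restraint_set()]; empty (with a warning) when nothing is
#'   satisfied.
#' @export
select_constraints <- function(measurements, cutoff = NULL,
                               dialect = c("docking-tbl", "refinement-list")) {
  dialect <- match.arg(dialect)
  if (is.null(cutoff)) cutoff <- attr(measurements, "cutoff")
  if (is.null(cutoff)) cutoff <- 37
  df <- as.data.frame(measurements)
  sat <- df[df$satisfied %in% TRUE, , drop = FALSE]
  if (nrow(sat) == 0L) {
    warning("no satisfied crosslinks; emitting an empty restraint set")
  }
  restraint_set(chain_a = sat$chain_a, res_a = sat$resno_a,
                chain_b = sat$chain_b, res_b = sat$resno_b,
                atom = "CA", target = cutoff / 2,
                lower_margin = cutoff / 2, upper_margin = cutoff / 2,
                dialect = dialect)
}

#' Shortlist docking clusters within one standard deviation of the best
#'
#' Applies the post-docking selection window: with engine scores where lower
#' is better, every cluster whose score lies within one standard deviation
#' (the best cluster's reported SD) of the best score is shortlisted. Final
#' selection among the shortlist is by XL Score of the cluster
#' representatives via [rank_models()].
#'
#' @param clusters data.frame with columns `cluster_id`, `engine_score`,
#'   `engine_score_sd` and optionally `representative_model`.
#' @return the shortlisted rows, best first.
#' @examples
#' cl <- data.frame(cluster_id = c("c1", "c2", "c3"),
#'                  engine_score = c(-120, -115, -95),
#'                  engine_score_sd = c(10, 8, 12))
#' cluster_window(cl)  # c1 and c2
#' @export
cluster_window <- function(clusters) {
  stopifnot(is.data.frame(clusters), nrow(clusters) >= 1L,
            all(c("cluster_id", "engine_score", "engine_score_sd") %in%
                  names(clusters)))
  if (any(!is.finite(clusters$engine_score))) stop("non-finite engine score")
  best <- which.min(clusters$engine_score)
  window_top <- clusters$engine_score[best] + clusters$engine_score_sd[best]
  short <- clusters[clusters$engine_score <= window_top, , drop = FALSE]
  short[order(short$engine_score), , drop = FALSE]
}
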