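# CSM deduplication, dataset summary statistics, and AP-FRET efficiency.

#' Deduplicate CSMs into unique crosslinks
#'
#' Collapses crosslink spectrum matches to unique residue-pair crosslinks.
#' The uniqueness key is the unordered pair of (accession, 1-based sequence
#' position) endpoints; peptide sequence and charge are ignored. Endpoints
#' are stored in canonical order (sorted by accession, then position) so the
#' result is independent of CSM row order and endpoint orientation. A
#' crosslink is `intra` iff both accessions are equal (accession level, not
#' chain level).
#'
#' @param csms an `xl_csms` table (see [read_crosslink_table()]).
#' @param fdr_only if `TRUE` (default) only CSMs with `passes_fdr = TRUE`
#'   contribute, matching a 1% FDR-filtered search export.
#' @return data.frame of class `xl_unique` with columns `protein_a`,
#'   `position_a`, `protein_b`, `position_b` (canonical order), `xl_class`
#'   (`"intra"`/`"inter"`) and `csm_support` (number of contributing CSMs).
#'   Rows are sorted by the canonical key.
#' @export
dedupe_crosslinks <- function(csms, fdr_only = TRUE) {
  csms <- as.data.frame(csms)
  if (isTRUE(fdr_only) && nrow(csms) > 0L) {
    csms <- csms[csms$passes_fdr, , drop = FALSE]
  }
  if (nrow(csms) == 0L) {
    out <- data.frame(protein_a = character(), position_a = integer(),
                      protein_b = character(), position_b = integer(),
                      xl_class = character(), csm_support = integer(),
                      stringsAsFactors = FALSE)
    class(out) <- c("xl_unique", "data.frame")
    return(out)
  }
  swap <- csms$protein_a > csms$protein_b |
    (csms$protein_a == csms$protein_b & csms$position_a > csms$position_b)
  pa <- ifelse(swap, csms$protein_b, csms$protein_a)
  xa <- ifelse(swap, csms$position_b, csms$position_a)
  pb <- ifelse(swap, csms$protein_a, csms$protein_b)
  xb <- ifelse(swap, csms$position_a, csms$position_b)
  key <- paste(pa, xa, pb, xb, sep = "\r")
  agg <- as.data.frame(table(key), stringsAsFactors = FALSE)
  parts <- do.call(rbind, strsplit(agg$key, "\r", fixed = TRUE))
  out <- data.frame(protein_a = parts[, 1L],
                    position_a = as.integer(parts[, 2L]),
                    protein_b = parts[, 3L],
                    position_b = as.integer(parts[, 4L]),
                    stringsAsFactors = FALSE)
  out$xl_class <- ifelse(out$protein_a == out$protein_b, "intra", "inter")
  out$csm_support <- as.integer(agg$Freq)
  out <- out[order(out$protein_a, out$position_a,
                   out$protein_b, out$position_b), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("xl_unique", "data.frame")
  out
}

#' Summarise a crosslink dataset
#'
#' Computes the dataset-level statistics reported for an XL-MS experiment:
#' total CSM count, unique intra-/inter-molecular crosslink counts, number of
#' distinct proteins, and per-protein lysine coverage (how many lysines the
#' sequence contains and how many are observed crosslinked).
#'
#' @param csms an `xl_csms` table.
#' @param uniques unique crosslinks from [dedupe_crosslinks()]; computed from
#'   `csms` if omitted.
#' @param sequences named character vector of one-letter protein sequences
#'   (e.g. from [read_fasta_sequences()]); lysine coverage is computed for
#'   every accession given in `coverage_accessions`.
#' @param coverage_accessions accessions for which lysine coverage is
#'   requested; defaults to `names(sequences)`. An accession requested
#'   without a sequence is an error.
#' @param fdr_only passed to [dedupe_crosslinks()] and applied to the CSM
#'   count.
#' @return list of class `xl_summary` with elements `n_csms`,
#'   `n_unique_intra`, `n_unique_inter`, `n_proteins`, and
#'   `per_protein_lysines` (data.frame `accession`, `n_lysines`,
#'   `n_crosslinked`).
#' @export
summarize_dataset <- function(csms, uniques = NULL, sequences = NULL,
                              coverage_accessions = names(sequences),
                              fdr_only = TRUE) {
  csms <- as.data.frame(csms)
  used <- if (isTRUE(fdr_only) && nrow(csms) > 0L) {
    csms[csms$passes_fdr, , drop = FALSE]
  } else csms
  if (is.null(uniques)) uniques <- dedupe_crosslinks(csms, fdr_only = fdr_only)
  accs <- unique(c(used$protein_a, used$protein_b))
  cov <- NULL
  if (length(coverage_accessions) > 0L) {
    missing_seq <- setdiff(coverage_accessions, names(sequences))
    if (length(missing_seq) > 0L) {
      stop("lysine coverage requested but sequence missing for: ",
           paste(missing_seq, collapse = ", "))
    }
    cov <- do.call(rbind, lapply(coverage_accessions, function(acc) {
      seq_chars <- strsplit(sequences[[acc]], "")[[1L]]
      k_pos <- which(seq_chars == "K")
      xl_pos <- unique(c(used$position_a[used$protein_a == acc],
                         used$position_b[used$protein_b == acc]))
      data.frame(accession = acc,
                 n_lysines = length(k_pos),
                 n_crosslinked = sum(xl_pos %in% k_pos),
                 stringsAsFactors = FALSE)
    }))
  }
  out <- list(n_csms = nrow(used),
              n_unique_intra = sum(uniques$xl_class == "intra"),
              n_unique_inter = sum(uniques$xl_class == "inter"),
              n_proteins = length(accs),
              per_protein_lysines = cov)
  class(out) <- "xl_summary"
  out
}

#' @export
print.xl_summary <- function(x, ...) {
  cat("XL-MS dataset summary\n")
  cat(sprintf("  CSMs:                %d\n", x$n_csms))
  cat(sprintf("  unique intra XLs:    %d\n", x$n_unique_intra))
  cat(sprintf("  unique inter XLs:    %d\n", x$n_unique_inter))
  cat(sprintf("  proteins:            %d\n", x$n_proteins))
  if (!is.null(x$per_protein_lysines)) {
    cat("  lysine coverage:\n")
    for (i in seq_len(nrow(x$per_protein_lysines))) {
      r <- x$per_protein_lysines[i, ]
      cat(sprintf("    %s  %d of %d lysines crosslinked\n",
                  r$accession, r$n_crosslinked, r$n_lysines))
    }
  }
  invisible(x)
}

#' Write a dataset summary to disk
#'
#' Emits a human-readable delimited report (one row per statistic, one row
#' per protein for lysine coverage) and a machine-readable JSON file.
#'
#' @param summary an `xl_summary`.
#' @param report_path TSV report path.
#' @param json_path JSON path (optional; default replaces the extension).
#' @return `report_path`, invisibly.
#' @export
write_summary <- function(summary, report_path,
                          json_path = sub("\\.[^.]*$", ".json", report_path)) {
  stopifnot(inherits(summary, "xl_summary"))
  stats <- data.frame(statistic = c("n_csms", "n_unique_intra",
                                    "n_unique_inter", "n_proteins"),
                      value = c(summary$n_csms, summary$n_unique_intra,
                                summary$n_unique_inter, summary$n_proteins))
  lines <- c("statistic\tvalue",
             sprintf("%s\t%d", stats$statistic, stats$value))
  if (!is.null(summary$per_protein_lysines)) {
    cov <- summary$per_protein_lysines
    lines <- c(lines, sprintf("lysines:%s\t%d of %d",
                              cov$accession, cov$n_crosslinked, cov$n_lysines))
  }
  writeLines(lines, report_path)
  jsonlite::write_json(unclass(summary), json_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(report_path)
}

#' Acceptor-photobleaching FRET efficiency
#'
#' Donor dequenching efficiency after acceptor photobleaching, in percent:
#' `E = (1 - I_pre / I_post) * 100`. Positive when the donor brightens after
#' the acceptor is bleached (energy transfer was occurring); negative or zero
#' otherwise.
#'
#' @param i_pre,i_post mean donor intensities before/after acceptor
#'   bleaching (arbitrary units, > 0). Vectorized.
#' @return FRET efficiency in percent.
#' @examples
#' fret_efficiency(80, 100)  # 20% transfer
#' @export
fret_efficiency <- function(i_pre, i_post) {
  if (any(!is.finite(i_pre)) || any(!is.finite(i_post)) ||
      any(i_pre <= 0) || any(i_post <= 0)) {
    stop("intensities must be positive and finite")
  }
  (1 - i_pre / i_post) * 100
}
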