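# Crosslink table parsing, chain maps, and residue mapping onto models.

#' Crosslink table column dialect
#'
#' XL-MS search engines export crosslink spectrum match (CSM) tables with
#' vendor-specific column layouts. A dialect names the columns that hold the
#' two protein accessions and the two 1-based crosslinked sequence positions,
#' plus optional metadata columns. The default is the package's canonical
#' layout (the one [simulate_csm_dataset()] writes); engine exports are
#' declared by supplying their column names, either directly or from a YAML
#' file via [read_dialect()].
#'
#' @param protein_a,position_a,protein_b,position_b column names of the two
#'   accessions and 1-based residue positions (required columns).
#' @param csm_id,replicate,score,passes_fdr optional metadata column names;
#'   `NA` means the column is absent and a default is filled in
#'   (`csm_id` = row number, `replicate` = `"1"`, `score` = `NA`,
#'   `passes_fdr` = `TRUE`).
#' @param sep field separator; `NA` picks `","` for `.csv` files and tab
#'   otherwise.
#' @return a list of class `xl_dialect`.
#' @export
xl_dialect <- function(protein_a = "protein_a", position_a = "position_a",
                       protein_b = "protein_b", position_b = "position_b",
                       csm_id = "csm_id", replicate = "replicate",
                       score = "score", passes_fdr = "passes_fdr",
                       sep = NA_character_) {
  structure(list(protein_a = protein_a, position_a = position_a,
                 protein_b = protein_b, position_b = position_b,
                 csm_id = csm_id, replicate = replicate,
                 score = score, passes_fdr = passes_fdr, sep = sep),
            class = "xl_dialect")
}

#' Read a crosslink-table dialect from a YAML file
#'
#' The file holds a flat mapping from dialect field names (see [xl_dialect()])
#' to column names in the export.
#'
#' @param path YAML file path.
#' @return an `xl_dialect`.
#' @export
read_dialect <- function(path) {
  if (!file.exists(path)) stop("dialect file not found: ", path)
  d <- yaml::read_yaml(path)
  do.call(xl_dialect, d)
}

#' Read a crosslink spectrum match (CSM) table
#'
#' Reads a delimited CSM export into the package's canonical CSM layout.
#' Rows failing the FDR flag are retained but flagged (`passes_fdr = FALSE`);
#' downstream deduplication excludes them by default.
#'
#' @param path delimited text file with a header row.
#' @param dialect an [xl_dialect()] naming the columns of this export.
#' @return data.frame of class `xl_csms` with columns `csm_id`, `replicate`,
#'   `protein_a`, `position_a`, `protein_b`, `position_b`, `score`,
#'   `passes_fdr`; one row per CSM.
#' @export
read_crosslink_table <- function(path, dialect = xl_dialect()) {
  if (!file.exists(path)) stop("crosslink table not found: ", path)
  stopifnot(inherits(dialect, "xl_dialect"))
  sep <- dialect$sep
  if (is.na(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "")
  required <- c("protein_a", "position_a", "protein_b", "position_b")
  cols <- unlist(dialect[required])
  absent <- cols[!cols %in% names(raw)]
  if (length(absent) > 0L) {
    stop("dialect columns not found in ", path, ": ",
         paste(absent, collapse = ", "))
  }
  n <- nrow(raw)
  grab <- function(field, default) {
    col <- dialect[[field]]
    if (!is.na(col) && col %in% names(raw)) raw[[col]] else rep(default, n)
  }
  pos_a <- parse_positions(grab("position_a", NA), "position_a")
  pos_b <- parse_positions(grab("position_b", NA), "position_b")
  acc_a <- as.character(grab("protein_a", NA))
  acc_b <- as.character(grab("protein_b", NA))
  if (any(acc_a == "" | acc_b == "" | is.na(acc_a) | is.na(acc_b))) {
    bad <- which(acc_a == "" | acc_b == "" | is.na(acc_a) | is.na(acc_b))[1L]
    stop("empty protein accession at data row ", bad)
  }
  out <- data.frame(
    csm_id = as.character(grab("csm_id", NA)),
    replicate = as.character(grab("replicate", "1")),
    protein_a = acc_a, position_a = pos_a,
    protein_b = acc_b, position_b = pos_b,
    score = suppressWarnings(as.numeric(grab("score", NA_real_))),
    passes_fdr = as.logical(grab("passes_fdr", TRUE)),
    stringsAsFactors = FALSE)
  if (anyNA(out$csm_id)) out$csm_id <- sprintf("csm%06d", seq_len(n))
  out$passes_fdr[is.na(out$passes_fdr)] <- TRUE
  class(out) <- c("xl_csms", "data.frame")
  out
}

parse_positions <- function(x, what) {
  num <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(num) | num != floor(num) | num < 1)
  if (length(bad) > 0L) {
    stop("non-integer ", what, " ('", x[bad[1L]], "') at data row ", bad[1L])
  }
  as.integer(num)
}

#' Chain map: protein accessions to model chains
#'
#' Bridges 1-based positions in the full-length protein sequence to author
#' residue numbering in a model: `residue_index = position + offset`. One
#' accession may map to several chains (homo-oligomers); downstream distance
#' measurement resolves the ambiguity by minimum distance.
#'
#' @param accession character vector of protein accessions.
#' @param chain character vector of chain identifiers.
#' @param offset integer numbering offsets (default 0: models numbered from 1,
#'   as AlphaFold emits them).
#' @return data.frame of class `xl_chain_map` with columns `accession`,
#'   `chain`, `offset`.
#' @export
chain_map <- function(accession, chain, offset = 0L) {
  out <- data.frame(accession = as.character(accession),
                    chain = as.character(chain),
                    offset = as.integer(offset),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out[, c("accession", "chain")])) {
    stop("duplicate (accession, chain) entry in chain map")
  }
  class(out) <- c("xl_chain_map", "data.frame")
  out
}

#' Read a chain map from YAML
#'
#' Layout: a top-level `chains` mapping from accession to either
#' `{chain: A, offset: 0}` or a list of such entries (homo-oligomer).
#'
#' @param path YAML file path.
#' @return an [chain_map()] data.frame.
#' @export
read_chain_map <- function(path) {
  if (!file.exists(path)) stop("chain map file not found: ", path)
  y <- yaml::read_yaml(path)
  entries <- if (!is.null(y$chains)) y$chains else y
  if (length(entries) == 0L) stop("chain map is empty: ", path)
  rows <- do.call(rbind, lapply(names(entries), function(acc) {
    e <- entries[[acc]]
    if (!is.null(e$chain)) e <- list(e)
    do.call(rbind, lapply(e, function(one) {
      data.frame(accession = acc, chain = as.character(one$chain),
                 offset = as.integer(if (is.null(one$offset)) 0L else one$offset),
                 stringsAsFactors = FALSE)
    }))
  }))
  chain_map(rows$accession, rows$chain, rows$offset)
}

#' Write a chain map to YAML
#' @param map an `xl_chain_map`.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_chain_map <- function(map, path) {
  stopifnot(inherits(map, "xl_chain_map"))
  entries <- lapply(split(map, map$accession), function(d) {
    lst <- lapply(seq_len(nrow(d)), function(i) {
      list(chain = d$chain[i], offset = d$offset[i])
    })
    if (length(lst) == 1L) lst[[1L]] else lst
  })
  yaml::write_yaml(list(chains = entries), path)
  invisible(path)
}

#' Map unique crosslinks onto a model
#'
#' Resolves each unique crosslink's (accession, sequence position) endpoints
#' to (chain, residue number) pairs in the model through a chain map. An
#' endpoint whose accession is absent from the map yields reason `"no-chain"`;
#' a mapped residue number absent from the model yields `"no-residue"`.
#' Unmappable crosslinks are values, not errors: they come back with
#' `mapped = FALSE` and a reason code. When an accession maps to several
#' chains, all candidate chain pairs are returned for downstream
#' minimum-distance resolution. Mapped residues that are not lysine are kept
#' (site-localization in CSMs can be off by one) but trigger a warning and
#' are flagged.
#'
#' @param uniques unique crosslinks from [dedupe_crosslinks()].
#' @param map an [chain_map()].
#' @param model an [xl_structure()].
#' @return data.frame of class `xl_mapped`: one row per candidate chain pair
#'   (or one row per unmapped crosslink) with columns `xl_id`, `protein_a`,
#'   `position_a`, `protein_b`, `position_b`, `chain_a`, `resno_a`,
#'   `chain_b`, `resno_b`, `mapped`, `reason`, `lysine_a`, `lysine_b`.
#' @export
map_crosslinks <- function(uniques, map, model) {
  stopifnot(inherits(map, "xl_chain_map"), inherits(model, "xl_structure"))
  uniques <- as.data.frame(uniques)
  ca <- ca_table(model)
  ca_key <- paste(ca$chain, ca$resno)
  is_lys <- function(chain, resno) {
    i <- match(paste(chain, resno), ca_key)
    !is.na(i) & ca$resid[i] == "LYS"
  }
  resolve <- function(acc, pos) {
    hits <- map[map$accession == acc, , drop = FALSE]
    if (nrow(hits) == 0L) return(list(reason = "no-chain"))
    cand <- data.frame(chain = hits$chain, resno = pos + hits$offset,
                       stringsAsFactors = FALSE)
    present <- paste(cand$chain, cand$resno) %in% ca_key
    if (!any(present)) return(list(reason = "no-residue"))
    list(reason = NA_character_, cand = cand[present, , drop = FALSE])
  }
  rows <- vector("list", nrow(uniques))
  for (i in seq_len(nrow(uniques))) {
    u <- uniques[i, ]
    ra <- resolve(u$protein_a, u$position_a)
    rb <- resolve(u$protein_b, u$position_b)
    base <- data.frame(xl_id = i,
                       protein_a = u$protein_a, position_a = u$position_a,
                       protein_b = u$protein_b, position_b = u$position_b,
                       stringsAsFactors = FALSE)
    if (!is.na(ra$reason) || !is.na(rb$reason)) {
      reason <- if (!is.na(ra$reason)) ra$reason else rb$reason
      rows[[i]] <- cbind(base, chain_a = NA_character_, resno_a = NA_integer_,
                         chain_b = NA_character_, resno_b = NA_integer_,
                         mapped = FALSE, reason = reason,
                         lysine_a = NA, lysine_b = NA)
      next
    }
    grid <- expand.grid(ia = seq_len(nrow(ra$cand)), ib = seq_len(nrow(rb$cand)))
    rows[[i]] <- cbind(base[rep(1L, nrow(grid)), , drop = FALSE],
                       chain_a = ra$cand$chain[grid$ia],
                       resno_a = ra$cand$resno[grid$ia],
                       chain_b = rb$cand$chain[grid$ib],
                       resno_b = rb$cand$resno[grid$ib],
                       mapped = TRUE, reason = NA_character_,
                       lysine_a = is_lys(ra$cand$chain[grid$ia],
                                         ra$cand$resno[grid$ia]),
                       lysine_b = is_lys(rb$cand$chain[grid$ib],
                                         rb$cand$resno[grid$ib]))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  n_nonlys <- sum(out$mapped & !(out$lysine_a & out$lysine_b), na.rm = TRUE)
  if (n_nonlys > 0L) {
    warning(n_nonlys, " mapped endpoint pair(s) involve non-lysine residues; ",
            "kept and flagged")
  }
  class(out) <- c("xl_mapped", "data.frame")
  out
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file.
#' @return named character vector of one-letter sequences; names are the
#'   first whitespace-delimited token of each header.
#' @export
read_fasta_sequences <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  ss <- Biostrings::readAAStringSet(path)
  out <- as.character(ss)
  names(out) <- vapply(strsplit(names(ss), "\\s+"), `[[`, character(1), 1L)
  out
}

#' Write protein sequences to FASTA
#' @param sequences named character vector of one-letter sequences.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_fasta_sequences <- function(sequences, path) {
  ss <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
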