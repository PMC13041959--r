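# Pipeline orchestration: subcommands, config, run manifests.

#' Pipeline configuration
#'
#' Shared settings for the pipeline subcommands. Thresholds default to the
#' DSSO crosslink criterion (37 Angstrom) and the residue contact threshold
#' (30 Angstrom).
#'
#' @param cutoff crosslink satisfaction cutoff, Angstrom.
#' @param contact_threshold contact map threshold, Angstrom.
#' @param distance_criterion `"ed"` or `"sasd"` (see [distance_config()]).
#' @param output_dir directory receiving artifacts (created if needed).
#' @param seed integer seed for any randomness (synthetic generation).
#' @param compute_sasd also measure SASD when scoring.
#' @param log_level `"quiet"`, `"info"` or `"debug"` (messages to stderr).
#' @return list of class `xl_pipeline_config`.
#' @export
pipeline_config <- function(cutoff = 37, contact_threshold = 30,
                            distance_criterion = c("ed", "sasd"),
                            output_dir = ".", seed = 1L,
                            compute_sasd = FALSE,
                            log_level = c("info", "quiet", "debug")) {
  if (cutoff <= 0 || contact_threshold <= 0) {
    stop(config_error("thresholds must be positive"))
  }
  structure(list(cutoff = cutoff, contact_threshold = contact_threshold,
                 distance_criterion = match.arg(distance_criterion),
                 output_dir = output_dir, seed = as.integer(seed),
                 compute_sasd = isTRUE(compute_sasd),
                 log_level = match.arg(log_level)),
            class = "xl_pipeline_config")
}

config_error <- function(msg) {
  errorCondition(paste("config error:", msg),
                 class = c("xl_config_error", "error", "condition"))
}
input_error <- function(msg) {
  errorCondition(paste("input error:", msg),
                 class = c("xl_input_error", "error", "condition"))
}

pipe_log <- function(config, level, ...) {
  ranks <- c(quiet = 0L, info = 1L, debug = 2L)
  if (ranks[[config$log_level]] >= ranks[[level]]) {
    message(format(Sys.time(), "[%H:%M:%S] "), ...)
  }
}

#' Run a pipeline subcommand
#'
#' Orchestrates one stage of the crosslink-guided modelling workflow and
#' writes its artifacts plus a run manifest (`manifest.json`: config echo,
#' input checksums, package version, artifact checksums) into the output
#' directory. Refinement and docking engines are boundary files, never
#' subprocess calls: `constraints` writes what they consume, `score` reads
#' what they produce.
#'
#' Subcommands and their inputs:
#' \describe{
#'   \item{`simulate`}{none; generates the default synthetic study
#'     (model PDB, decoy PDBs, crosslink table, chain map, truth table)
#'     under `config$seed`.}
#'   \item{`summarize`}{`table` (+ optional `fasta`, `dialect`); writes the
#'     dataset summary report and unique-crosslink table.}
#'   \item{`score`}{`models` (one or more PDB paths), `table`, `chain_map`;
#'     writes per-model measurement tables and the ranking report.}
#'   \item{`constraints`}{`model`, `table`, `chain_map`; writes satisfied
#'     crosslinks as restraint files in both dialects.}
#'   \item{`maps`}{`model`, `chains` (length-2); writes the contact map and
#'     lysine heatmap matrices (and PNG renderings when the R build can).}
#'   \item{`superpose`}{`model_a`, `model_b` (+ optional `anchor`
#'     data.frame/list); writes the transformed model and displacement
#'     profile.}
#' }
#'
#' @param name subcommand name.
#' @param config an [pipeline_config()].
#' @param inputs named list of input paths/objects (see above).
#' @return list of class `xl_pipeline_result` with `artifacts` (named file
#'   paths) and `manifest` (path to manifest.json), invisibly.
#' @export
run_subcommand <- function(name = c("simulate", "summarize", "score",
                                    "constraints", "maps", "superpose"),
                           config = pipeline_config(), inputs = list()) {
  name <- match.arg(name)
  stopifnot(inherits(config, "xl_pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(file) file.path(config$output_dir, file)
  need <- function(key, kind = "file") {
    val <- inputs[[key]]
    if (is.null(val)) stop(config_error(paste0("subcommand '", name,
                                               "' requires input '", key, "'")))
    if (kind == "file") {
      for (p in val) if (!file.exists(p)) {
        stop(input_error(paste("not found:", p)))
      }
    }
    val
  }
  dialect <- if (!is.null(inputs$dialect)) {
    if (is.character(inputs$dialect)) read_dialect(inputs$dialect)
    else inputs$dialect
  } else xl_dialect()
  input_files <- as.character(unlist(Filter(is.character, inputs),
                                     use.names = FALSE))
  input_files <- input_files[file.exists(input_files)]
  artifacts <- character()

  if (name == "simulate") {
    spec <- synthetic_spec(seed = config$seed, cutoff = config$cutoff)
    model <- make_structure(spec)
    planted <- plant_crosslinks(model, spec)
    decoys <- make_decoys(model, spec)
    write_pdb(model, out("model.pdb"))
    for (d in decoys) write_pdb(d, out(paste0(d$model_id, ".pdb")))
    write_crosslink_table(planted$csms, out("crosslinks.tsv"))
    write_chain_map(planted$chain_map, out("chain_map.yaml"))
    utils::write.table(planted$truth, out("truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    artifacts <- c(model = out("model.pdb"),
                   crosslinks = out("crosslinks.tsv"),
                   chain_map = out("chain_map.yaml"),
                   truth = out("truth.tsv"),
                   stats::setNames(out(paste0(vapply(decoys, `[[`, "",
                                                     "model_id"), ".pdb")),
                                   paste0("decoy_", seq_along(decoys))))
    pipe_log(config, "info", "simulated ", length(decoys), " decoys and ",
             nrow(planted$csms), " CSMs")
  } else if (name == "summarize") {
    csms <- read_crosslink_table(need("table"), dialect)
    sequences <- if (!is.null(inputs$fasta)) {
      read_fasta_sequences(need("fasta"))
    } else NULL
    uniques <- dedupe_crosslinks(csms)
    summ <- summarize_dataset(csms, uniques, sequences)
    write_summary(summ, out("summary.tsv"), out("summary.json"))
    utils::write.table(as.data.frame(uniques), out("unique_crosslinks.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    artifacts <- c(summary = out("summary.tsv"),
                   summary_json = out("summary.json"),
                   uniques = out("unique_crosslinks.tsv"))
    pipe_log(config, "info", summ$n_csms, " CSMs -> ",
             summ$n_unique_intra + summ$n_unique_inter, " unique XLs")
  } else if (name == "score") {
    model_paths <- need("models")
    table_path <- need("table")
    cmap_path <- need("chain_map")
    csms <- read_crosslink_table(table_path, dialect)
    cmap <- read_chain_map(cmap_path)
    uniques <- dedupe_crosslinks(csms)
    cfg <- distance_config(cutoff = config$cutoff,
                           criterion = config$distance_criterion)
    scores <- vector("list", length(model_paths))
    for (i in seq_along(model_paths)) {
      model <- read_pdb(model_paths[i])
      mapped <- map_crosslinks(uniques, cmap, model)
      meas <- measure_crosslinks(model, mapped, cfg,
                                 compute_sasd = config$compute_sasd)
      mfile <- out(paste0("measurements_", model$model_id, ".tsv"))
      write_measurements(meas, mfile)
      artifacts[paste0("measurements_", model$model_id)] <- mfile
      scores[[i]] <- xl_score(meas)
    }
    ranking <- rank_models(scores)
    write_ranking(ranking, out("ranking.tsv"))
    artifacts["ranking"] <- out("ranking.tsv")
    pipe_log(config, "info", "ranked ", length(scores), " models; best: ",
             ranking$model_id[1L])
  } else if (name == "constraints") {
    model_path <- need("model")
    table_path <- need("table")
    cmap_path <- need("chain_map")
    model <- read_pdb(model_path)
    csms <- read_crosslink_table(table_path, dialect)
    cmap <- read_chain_map(cmap_path)
    uniques <- dedupe_crosslinks(csms)
    mapped <- map_crosslinks(uniques, cmap, model)
    cfg <- distance_config(cutoff = config$cutoff,
                           criterion = config$distance_criterion)
    meas <- measure_crosslinks(model, mapped, cfg,
                               compute_sasd = config$compute_sasd)
    if (!any(meas$satisfied)) {
      stop(input_error("no satisfied crosslinks: nothing to write"))
    }
    tbl <- select_constraints(meas, dialect = "docking-tbl")
    lst <- select_constraints(meas, dialect = "refinement-list")
    write_restraints(tbl, out("restraints.tbl"), model = model)
    write_restraints(lst, out("restraints.list"), model = model)
    artifacts <- c(tbl = out("restraints.tbl"), list = out("restraints.list"))
    pipe_log(config, "info", nrow(tbl), " restraints written")
  } else if (name == "maps") {
    model <- read_pdb(need("model"))
    chains <- need("chains", kind = "value")
    if (length(chains) != 2L) {
      stop(config_error("'chains' must name exactly two chains"))
    }
    cmap <- contact_map(model, chains[1L], chains[2L],
                        threshold = config$contact_threshold)
    heat <- lysine_heatmap(model, chains[1L], chains[2L])
    write_map(cmap, out("contact_map.tsv"))
    artifacts <- c(contact_map = out("contact_map.tsv"))
    if (length(heat$lysines_a) > 0L && length(heat$lysines_b) > 0L) {
      write_map(heat, out("lysine_heatmap.tsv"))
      artifacts["lysine_heatmap"] <- out("lysine_heatmap.tsv")
    }
    if (capabilities("png")) {
      grDevices::png(out("contact_map.png"), width = 800, height = 800)
      plot(cmap)
      grDevices::dev.off()
      artifacts["contact_map_png"] <- out("contact_map.png")
    }
    pipe_log(config, "info", sum(cmap$contacts), " contacts at ",
             config$contact_threshold, " A")
  } else if (name == "superpose") {
    model_a <- read_pdb(need("model_a"))
    model_b <- read_pdb(need("model_b"))
    res <- superpose_on_anchor(model_a, model_b, anchor = inputs$anchor)
    write_pdb(res$model_b_transformed, out("superposed.pdb"))
    write_displacement(res$superposition, out("displacement.tsv"))
    artifacts <- c(superposed = out("superposed.pdb"),
                   displacement = out("displacement.tsv"))
    pipe_log(config, "info", sprintf("anchor rmsd %.3f A",
                                     res$superposition$rmsd))
  }

  manifest <- list(
    subcommand = name,
    config = unclass(config),
    package_version = as.character(utils::packageVersion("xlmstools")),
    input_checksums = as.list(stats::setNames(tools::md5sum(input_files),
                                              basename(input_files))),
    artifact_checksums = as.list(stats::setNames(
      tools::md5sum(unname(artifacts)), basename(unname(artifacts)))))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(structure(list(artifacts = artifacts,
                           manifest = out("manifest.json")),
                      class = "xl_pipeline_result"))
}
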