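# End-to-end comparative workflow over multiple constructs: ingest or
# generate each ensemble, optionally zymogenize, run the requested
# analyses, write per-construct TSV exports and a cross-construct summary.

.default_params <- function() {
  list(window = 50, n_boot = 1000, stride = 1, seed = 1,
       cutoff_his = 6.5, cutoff_ser = 6.0, n_frames = 500,
       selection_rmsd = "calpha", selection_pca = "heavy",
       cluster_k = 2, max_cluster_frames = 2000)
}

.write_tsv <- function(df, path, params = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(params)) {
    writeLines(paste0("# ", names(params), " = ",
                      vapply(params, function(p) paste(format(p),
                                                       collapse = ","),
                             character(1))), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Load or validate a pipeline run configuration
#'
#' A configuration holds a list of construct entries (`label` plus either a
#' generator `preset` or an input `path`, and an optional `zymogenize`
#' flag), the analysis toggles, and shared parameters. Unknown parameters
#' (e.g. engine/protocol metadata such as a force-field name) are retained
#' and echoed into the provenance log but never interpreted.
#'
#' @param config A list, or the path to a YAML file with top-level keys
#'   `constructs`, `analyses`, `params`.
#' @return Validated config list (class `run_config`).
#' @export
run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  constructs <- config$constructs
  if (is.null(constructs) || length(constructs) == 0) {
    stop("config must list at least one construct")
  }
  labels <- vapply(constructs, function(cc) {
    if (is.null(cc$label)) stop("every construct needs a `label`")
    cc$label
  }, character(1))
  if (anyDuplicated(labels)) stop("construct labels must be unique")
  for (cc in constructs) {
    if (is.null(cc$preset) && is.null(cc$path)) {
      stop("construct '", cc$label, "' needs a `preset` or a `path`")
    }
    if (!is.null(cc$path) && !file.exists(cc$path)) {
      stop("construct '", cc$label, "': input '", cc$path, "' not found")
    }
  }
  analyses <- config$analyses
  known <- c("rmsd", "rmsf", "classify", "pca", "cluster", "dcc")
  if (is.null(analyses)) analyses <- known
  bad <- setdiff(analyses, known)
  if (length(bad) > 0) {
    stop("unknown analysis toggle(s): ", paste(bad, collapse = ", "))
  }
  params <- utils::modifyList(.default_params(),
                              if (is.null(config$params)) list()
                              else config$params)
  out <- list(constructs = constructs, analyses = analyses, params = params,
              metadata = config$metadata)
  class(out) <- "run_config"
  out
}

.load_construct <- function(cc, params) {
  if (!is.null(cc$preset)) {
    gen <- generate_ensemble(
      preset_spec(cc$preset, n_frames = params$n_frames,
                  seed = params$seed),
      label = cc$label)
    ens <- gen$ensemble
  } else {
    ens <- read_structure(cc$path, model_policy = "all", label = cc$label)
    if (!inherits(ens, "zymo_ensemble")) {
      stop("construct '", cc$label, "': input has a single model; an ",
           "ensemble is required")
    }
  }
  if (isTRUE(cc$zymogenize)) ens <- zymogenize_ensemble(ens)$ensemble
  ens
}

.analyse_construct <- function(ens, cfg, out_dir) {
  p <- cfg$params
  res <- list(label = ens$label)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  toggles <- cfg$analyses

  if (any(c("rmsd", "rmsf", "pca", "dcc") %in% toggles)) {
    avg <- average_structure(ens, p$selection_rmsd)
    res$average <- avg
  }
  if ("rmsd" %in% toggles) {
    ser <- rmsd_series(ens, res$average, selection = p$selection_rmsd)
    ser$rmsd_ref1_smooth <- if (nrow(ser) >= p$window) {
      running_average(ser$rmsd_ref1, p$window)
    } else ser$rmsd_ref1
    .write_tsv(ser, file.path(out_dir, "rmsd.tsv"),
               list(selection = p$selection_rmsd, window = p$window))
    res$rmsd <- ser
  }
  if ("rmsf" %in% toggles) {
    prof <- rmsf_profile(ens, p$selection_rmsd)
    .write_tsv(as.data.frame(prof), file.path(out_dir, "rmsf.tsv"),
               list(selection = p$selection_rmsd))
    res$rmsf <- prof
    loop_res <- unique(unlist(lapply(
      c("AL1", "AL2", "AL3"),
      function(r) {
        rng <- region_map()[[r]]
        idx <- tryCatch(
          select_atoms(ens, paste0("region ", r)), error = function(e) integer())
        paste(ens$reference$atoms$residue_number[idx],
              ens$reference$atoms$insertion_code[idx], sep = "|")
      })))
    key <- paste(prof$residue_number, prof$insertion_code, sep = "|")
    res$mean_loop_rmsf <- mean(prof$rmsf[key %in% loop_res])
  }
  if ("classify" %in% toggles) {
    crit <- state_criterion(p$cutoff_his, p$cutoff_ser)
    ser <- classify_frames(ens, crit)
    pop <- population(ser, n_boot = p$n_boot, seed = p$seed)
    scatter_export(ser, file.path(out_dir, "states.tsv"))
    res$states <- ser
    res$population <- pop
  }
  if ("pca" %in% toggles) {
    k <- min(10, n_frames(ens) - 1)
    model <- pca_ensemble(ens, p$selection_pca, n_components = k)
    scores <- data.frame(frame = seq_len(nrow(model$projections)),
                         time = ens$frame_times)
    scores <- cbind(scores, as.data.frame(model$projections))
    .write_tsv(scores, file.path(out_dir, "pca_scores.tsv"),
               list(selection = p$selection_pca))
    .write_tsv(data.frame(component = seq_along(model$all_eigenvalues),
                          eigenvalue = model$all_eigenvalues),
               file.path(out_dir, "pca_eigenvalues.tsv"))
    res$pca <- model
    res$compactness <- subspace_compactness(model)
  }
  if ("cluster" %in% toggles) {
    dend <- upgma_cluster(ens, p$selection_rmsd, stride = p$stride,
                          max_frames = p$max_cluster_frames)
    exp <- dendrogram_export(dend)
    .write_tsv(exp$linkage, file.path(out_dir, "linkage.tsv"),
               list(stride = p$stride, selection = p$selection_rmsd))
    writeLines(exp$newick, file.path(out_dir, "dendrogram.nwk"))
    res$dendrogram <- dend
    res$clusters <- cut_dendrogram(dend, k = min(p$cluster_k,
                                                 dend$n_leaves))
  }
  if ("dcc" %in% toggles) {
    cc <- dynamic_cross_correlation(ens, p$selection_rmsd)
    utils::write.table(round(cc, 6), file.path(out_dir, "dcc.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
    res$dcc <- cc
  }
  res
}

#' Run the full comparative pipeline
#'
#' For each construct: load or generate the ensemble, optionally
#' zymogenize it, and run the toggled analyses, writing TSV exports per
#' construct plus a cross-construct `summary.tsv` (accessible-state
#' population with bootstrap SE, PC1-PC2 compactness, mean activation-loop
#' RMSF, cluster count) and a provenance log. Failure of one construct is
#' logged and does not abort the others.
#'
#' @param config A config list or YAML path (see [run_config()]).
#' @param out_dir Output directory.
#' @return Invisibly, a list with `results` (per construct), `summary`
#'   (data frame) and `failed` (named error messages).
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  failed <- character()
  log_lines <- c(sprintf("# pipeline run, seed = %d", cfg$params$seed),
                 sprintf("# analyses: %s",
                         paste(cfg$analyses, collapse = ", ")))
  for (cc in cfg$constructs) {
    t0 <- proc.time()["elapsed"]
    out <- tryCatch({
      ens <- .load_construct(cc, cfg$params)
      .analyse_construct(ens, cfg, file.path(out_dir, cc$label))
    }, error = function(e) e)
    if (inherits(out, "error")) {
      failed[cc$label] <- conditionMessage(out)
      log_lines <- c(log_lines, sprintf("FAIL\t%s\t%s", cc$label,
                                        conditionMessage(out)))
    } else {
      results[[cc$label]] <- out
      log_lines <- c(log_lines,
                     sprintf("OK\t%s\t%.1fs", cc$label,
                             proc.time()["elapsed"] - t0))
    }
  }
  summary_df <- do.call(rbind, lapply(results, function(r) {
    data.frame(
      label = r$label,
      p_accessible = if (!is.null(r$population)) r$population$p_accessible
                     else NA_real_,
      bootstrap_se = if (!is.null(r$population)) r$population$bootstrap_se
                     else NA_real_,
      n_transitions = if (!is.null(r$population)) r$population$n_transitions
                      else NA_integer_,
      pc12_variance = if (!is.null(r$compactness)) r$compactness$pc_variance
                      else NA_real_,
      mean_loop_rmsf = if (!is.null(r$mean_loop_rmsf)) r$mean_loop_rmsf
                       else NA_real_,
      n_clusters = if (!is.null(r$clusters)) length(unique(r$clusters))
                   else NA_integer_,
      stringsAsFactors = FALSE
    )
  }))
  if (!is.null(summary_df)) {
    rownames(summary_df) <- NULL
    .write_tsv(summary_df, file.path(out_dir, "summary.tsv"), cfg$params)
  }
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  jsonlite::write_json(
    list(analyses = cfg$analyses, params = cfg$params,
         metadata = cfg$metadata,
         constructs = lapply(cfg$constructs, function(cc) cc["label"])),
    file.path(out_dir, "provenance.json"), auto_unbox = TRUE, null = "null")
  invisible(list(results = results, summary = summary_df, failed = failed))
}
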