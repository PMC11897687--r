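#' Read / write the per-video metadata table
#'
#' Flat CSV with columns `video_id, mouse_id, sex, weight, group, beam,
#' trial` and optionally `cohort` and `fps`.
#'
#' @param path CSV file path.
#' @return data.frame.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  meta <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("video_id", "mouse_id", "sex", "weight", "group", "beam",
                "trial")
  missing <- setdiff(required, names(meta))
  if (length(missing))
    stop("metadata is missing column(s): ", paste(missing, collapse = ", "))
  if (any(meta$weight <= 0)) stop("weights must be positive")
  key <- paste(meta$mouse_id, meta$beam, meta$trial)
  if (anyDuplicated(key))
    stop("duplicate (mouse_id, beam, trial) in metadata")
  meta
}

#' @rdname read_metadata
#' @param metadata data.frame to write.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.csv(metadata, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read human foot-slip annotations
#'
#' CSV with columns `video_id, frame`: one row per human-scored slip.
#'
#' @param path CSV file path.
#' @return Named list of sorted frame vectors, one per video.
#' @export
read_annotations <- function(path) {
  ann <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("video_id", "frame") %in% names(ann)))
    stop("annotations need columns video_id, frame")
  lapply(split(ann$frame, ann$video_id), sort)
}

#' Run the full beam-walk analysis pipeline
#'
#' Executes, in order: simulate or ingest the tracking data; compute the
#' classical endpoints per trial; engineer the feature table and manifest;
#' run the nested leave-one-mouse-out classification per beam (when the
#' metadata has exactly two groups); project the features with LDA; build
#' per-group skeleton summaries and render them. Every intermediate artifact
#' is persisted under `out_dir`, and a machine-readable report closes the
#' run. With a fixed seed the run is idempotent.
#'
#' @param config List with elements:
#'   \describe{
#'     \item{sim}{optional list of [generate_experiment] arguments (mutually
#'       exclusive with `tracking_dir`)}
#'     \item{tracking_dir}{directory of DLC-dialect CSVs named
#'       `<video_id>.csv`}
#'     \item{metadata}{metadata CSV path (ingest mode)}
#'     \item{detection}{optional [detection_params]}
#'     \item{cv}{optional [cv_config]}
#'     \item{classify}{logical, run the classifier stage (default TRUE)}
#'     \item{out_dir}{output directory}
#'     \item{seed}{master seed}
#'   }
#' @return The run report (list), invisibly; written to
#'   `out_dir/report.json`.
#' @export
run_pipeline <- function(config) {
  out_dir <- config$out_dir %||% stop("config$out_dir is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  params <- config$detection %||% detection_params()
  report <- list(package_version = as.character(utils::packageVersion("beamwalkr")),
                 seed = seed,
                 detection = unclass(params), stages = list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  # -- ingest -----------------------------------------------------------
  if (!is.null(config$sim)) {
    exp <- stage("simulate",
                 do.call(generate_experiment,
                         utils::modifyList(config$sim, list(seed = seed))))
    tracks <- exp$tracks; metadata <- exp$metadata
  } else {
    metadata <- stage("ingest", read_metadata(config$metadata))
    tracks <- stage("ingest", {
      out <- lapply(seq_len(nrow(metadata)), function(i) {
        f <- file.path(config$tracking_dir,
                       paste0(metadata$video_id[i], ".csv"))
        if (!file.exists(f)) stop("tracking file not found: ", f)
        read_tracking(f, fps = metadata$fps[i] %||% 120,
                      video_id = metadata$video_id[i],
                      mouse_id = metadata$mouse_id[i],
                      alias = config$alias)
      })
      stats::setNames(out, metadata$video_id)
    })
  }
  report$stages$ingest <- list(n_videos = length(tracks))

  # -- endpoints --------------------------------------------------------
  endpoints <- stage("endpoints", {
    rows <- lapply(seq_len(nrow(metadata)), function(i) {
      m <- metadata[i, ]
      track <- tracks[[as.character(m$video_id)]]
      geom <- locate_region(track, beam_type = as.character(m$beam))
      ep <- trial_endpoints(track, geom, params)
      data.frame(video_id = m$video_id, mouse_id = m$mouse_id,
                 group = m$group, beam = m$beam, trial = m$trial,
                 time_to_cross = ep$time_to_cross, n_slips = ep$n_slips,
                 direction = ep$direction, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  utils::write.csv(endpoints, file.path(out_dir, "endpoints.csv"),
                   row.names = FALSE)
  report$stages$endpoints <- list(n_trials = nrow(endpoints),
                                  total_slips = sum(endpoints$n_slips))

  # -- features ---------------------------------------------------------
  registry <- feature_registry()
  features <- stage("features",
                    build_feature_table(tracks, metadata, registry, params))
  utils::write.csv(features, file.path(out_dir, "features.csv"),
                   row.names = FALSE)
  jsonlite::write_json(registry, file.path(out_dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE)
  report$stages$features <- list(n_trials = nrow(features),
                                 n_features = nrow(registry))

  # -- classify ---------------------------------------------------------
  groups <- unique(metadata$group)
  if (isTRUE(config$classify %||% TRUE) && length(groups) == 2) {
    cv <- config$cv %||% cv_config(seed = seed)
    cv_out <- list()
    for (b in unique(metadata$beam)) {
      ds <- dataset_from_feature_table(features, beam = b)
      res <- stage(paste0("classify[", b, "]"), run_nested_lomo(ds, cv))
      cv_out[[b]] <- list(
        beam = b, per_animal = res$per_animal,
        mean_accuracy = res$mean_accuracy,
        consensus_features = res$consensus_features,
        final_hyperparams = res$final_hyperparams,
        wilcoxon = res$wilcoxon)
    }
    jsonlite::write_json(cv_out, file.path(out_dir, "cvresult.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
    report$stages$classify <- lapply(cv_out, function(r)
      list(mean_accuracy = r$mean_accuracy,
           wilcoxon_p = if (!is.null(r$wilcoxon)) r$wilcoxon$p))
  }

  # -- lda --------------------------------------------------------------
  lda_out <- stage("lda", {
    feat_cols <- setdiff(names(features), id_columns())
    proj <- lda_project(as.matrix(features[, feat_cols]), features$group)
    cbind(features[, id_columns()], as.data.frame(proj))
  })
  utils::write.csv(lda_out, file.path(out_dir, "lda.csv"), row.names = FALSE)
  report$stages$lda <- list(dims = ncol(lda_out) - length(id_columns()))

  # -- skeletons --------------------------------------------------------
  skel <- stage("skeleton", {
    by_group <- split(metadata$video_id, metadata$group)
    lapply(by_group, function(vids) {
      by_mouse <- split(vids, metadata$mouse_id[match(vids,
                                                      metadata$video_id)])
      per_animal <- lapply(by_mouse, function(v) {
        trs <- tracks[as.character(v)]
        geoms <- lapply(trs, locate_region)
        skeleton_per_animal(trs, geoms)
      })
      skeleton_group_mean(per_animal)
    })
  })
  skel_tab <- do.call(rbind, lapply(names(skel), function(g)
    cbind(group = g, as.data.frame(skel[[g]]))))
  utils::write.csv(skel_tab, file.path(out_dir, "skeleton.csv"),
                   row.names = FALSE)
  stage("skeleton", render_skeletons(skel, file.path(out_dir,
                                                     "skeleton.svg")))
  report$stages$skeleton <- list(n_groups = length(skel))

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(report)
}
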