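FORMAT_VERSION <- "1.0"
ORIENTATION_NOTE <- "row = source, column = target"

#' Write / read a region-by-time session as TSV + sidecar JSON
#'
#' The TSV holds rows = time points and columns = regions with a header of
#' region names; the sidecar `<path>.json` records tr, subject, condition,
#' region count and the format version, and is checked on read.
#'
#' @param session A [mou_session()].
#' @param path Output TSV path.
#' @return `write_timeseries` returns `path` invisibly; `read_timeseries`
#'   returns a [mou_session()].
#' @export
write_timeseries <- function(session, path) {
  stopifnot(inherits(session, "mou_session"))
  df <- as.data.frame(t(session$data))
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- list(format_version = FORMAT_VERSION, n_rois = nrow(session$data),
               tr = session$tr, subject_id = session$subject_id,
               condition = session$condition)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_timeseries
#' @export
read_timeseries <- function(path) {
  if (!file.exists(path)) stop("time-series file not found: ", path)
  df <- read.delim(path, check.names = FALSE)
  bad <- !vapply(df, is.numeric, TRUE)
  if (any(bad))
    stop("non-numeric cells in column(s): ", paste(names(df)[bad], collapse = ", "))
  X <- as.matrix(df)
  nas <- which(is.na(X), arr.ind = TRUE)
  if (nrow(nas) > 0)
    stop(sprintf("NaN cell at row %d, column '%s'",
                 nas[1, 1], colnames(X)[nas[1, 2]]))
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) stop("sidecar JSON not found: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$n_rois) || meta$n_rois != ncol(X))
    stop(sprintf("orientation error: sidecar declares %s regions, header has %d columns",
                 ifelse(is.null(meta$n_rois), "?", meta$n_rois), ncol(X)))
  mou_session(t(X), tr = meta$tr,
              subject_id = ifelse(is.null(meta$subject_id), "", meta$subject_id),
              condition = ifelse(is.null(meta$condition), "", meta$condition))
}

#' Write / read a labeled square matrix as CSV
#'
#' Dense CSV with a first header row and column of region labels, preceded
#' by a comment line stating the format version and the EC orientation
#' convention (row = source, column = target). Readers warn when the
#' convention comment is absent and fail on non-square data or mismatched
#' row/column labels.
#'
#' @param m Square numeric matrix (labels taken from dimnames).
#' @param path CSV path.
#' @return `write_matrix` returns `path` invisibly; `read_matrix` returns
#'   the labeled matrix.
#' @export
write_matrix <- function(m, path) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("'m' must be square")
  if (is.null(rownames(m))) rownames(m) <- paste0("ROI", seq_len(nrow(m)))
  colnames(m) <- rownames(m)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# mouflow matrix format %s; orientation: %s",
                     FORMAT_VERSION, ORIENTATION_NOTE), con)
  write.csv(as.data.frame(m), con, row.names = TRUE, quote = FALSE)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  first <- readLines(path, n = 1)
  if (!grepl("^# mouflow matrix", first))
    warning("matrix file lacks the orientation convention comment; ",
            "cannot verify row = source, column = target")
  df <- read.csv(path, comment.char = "#", row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  if (nrow(m) != ncol(m)) stop("matrix file is not square")
  if (!identical(rownames(m), colnames(m)))
    stop("row and column labels disagree in ", path)
  m
}

#' Write / read a cohort manifest as JSON
#'
#' The manifest maps session files to subject IDs and condition labels.
#' On read, entries must have unique (subject, condition, session) triples
#' and all referenced files must exist.
#'
#' @param manifest Data frame with columns `file`, `subject`, `condition`
#'   (and optionally `session_id`, `tr`, `seed`).
#' @param path JSON path.
#' @param check_files Verify referenced files exist on read.
#' @return `read_manifest` returns the manifest data frame.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(is.data.frame(manifest),
            all(c("file", "subject", "condition") %in% names(manifest)))
  jsonlite::write_json(list(format_version = FORMAT_VERSION,
                            entries = manifest),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path, check_files = TRUE) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  man <- obj$entries
  if (is.null(man) || !all(c("file", "subject", "condition") %in% names(man)))
    stop("malformed manifest: needs 'entries' with file/subject/condition")
  key <- paste(man$subject, man$condition,
               if (!is.null(man$session_id)) man$session_id else seq_len(nrow(man)))
  if (anyDuplicated(key)) stop("manifest has duplicate session entries")
  if (check_files) {
    missing <- man$file[!file.exists(file.path(dirname(path), man$file)) &
                          !file.exists(man$file)]
    if (length(missing) > 0)
      stop("manifest references missing file(s): ",
           paste(missing, collapse = ", "))
  }
  man
}

#' Export a cohort to disk (sessions, mask, manifest, ground truth)
#'
#' @param cohort A `"mou_cohort"`.
#' @param outdir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, outdir) {
  stopifnot(inherits(cohort, "mou_cohort"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (id in names(cohort$sessions)) {
    f <- paste0(id, ".tsv")
    write_timeseries(cohort$sessions[[id]], file.path(outdir, f))
    files <- c(files, f)
  }
  man <- cohort$manifest
  man$file <- files
  man$tr <- cohort$spec$tr
  write_matrix(cohort$mask, file.path(outdir, "mask.csv"))
  write_matrix(cohort$ground_truth$ec, file.path(outdir, "ground_truth_ec.csv"))
  mpath <- file.path(outdir, "manifest.json")
  write_manifest(man, mpath)
  invisible(mpath)
}

# --- pipeline orchestration -------------------------------------------------

#' Run the full analysis pipeline from a configuration
#'
#' Executes the stages simulate -> fit -> flow -> communities -> classify
#' -> testlinks in order on a synthetic cohort, writing each stage's
#' artifacts, a log, and a summary JSON with content hashes so that a
#' rerun with the same configuration reproduces identical outputs. The
#' configuration is validated before any computation; a stage failure
#' halts with the stage name while preserving partial outputs.
#'
#' @param config A list (or path to a JSON file) with elements `seed`,
#'   `outdir`, `cohort` (arguments to [cohort_spec()]), and optional
#'   stage settings `fit` (list: control arguments), `flow`
#'   (list: t_max_tr, dt_tr), `communities` (list: t_tr, n_runs),
#'   `classify` (list: classifier, scheme, n_splits), `testlinks`
#'   (list: alpha).
#' @return List of stage outputs (invisibly also written to
#'   `outdir/summary.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  for (req in c("seed", "outdir", "cohort"))
    if (is.null(config[[req]]))
      stop("pipeline config validation: missing required entry '", req, "'")
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log <- character(0)
  note <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    message("[pipeline] ", msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  results <- list()

  note("stage simulate: generating cohort (seed %d)", config$seed)
  spec <- stage("simulate", do.call(cohort_spec,
                                    c(config$cohort, list(seed = config$seed))))
  cohort <- stage("simulate", make_cohort(spec))
  stage("simulate", write_cohort(cohort, file.path(outdir, "cohort")))
  results$simulate <- file.path(outdir, "cohort", "manifest.json")

  note("stage fit: estimating EC for %d sessions", length(cohort$sessions))
  ctrl <- do.call(mou_control, if (is.null(config$fit)) list() else config$fit)
  feats <- stage("fit", cohort_features_of(cohort, type = "ec", control = ctrl))
  fit_first <- stage("fit", mou_fit(cohort$sessions[[1]], mask = cohort$mask,
                                    tau = spec$tau, control = ctrl))
  stage("fit", write_matrix(coef(fit_first), file.path(outdir, "ec_session1.csv")))
  results$fit <- file.path(outdir, "ec_session1.csv")

  note("stage flow: dynamic flow of the first session fit")
  fl_cfg <- modifyList(list(t_max_tr = 20, dt_tr = 0.5),
                       if (is.null(config$flow)) list() else config$flow)
  tg <- seq(0, fl_cfg$t_max_tr * spec$tr, by = fl_cfg$dt_tr * spec$tr)
  ft <- stage("flow", dynamic_flow(fit_first$model, t_grid = tg))
  tf <- total_flow(ft)
  write.csv(data.frame(t = tg, total_flow = as.numeric(tf),
                       diversity = as.numeric(flow_diversity(ft))),
            file.path(outdir, "flow_summary.csv"), row.names = FALSE)
  results$flow <- file.path(outdir, "flow_summary.csv")

  note("stage communities: Louvain on the flow matrix")
  cm_cfg <- modifyList(list(t_tr = 4, n_runs = 20),
                       if (is.null(config$communities)) list() else config$communities)
  part <- stage("communities",
                detect_communities(ft, t = cm_cfg$t_tr * spec$tr,
                                   n_runs = cm_cfg$n_runs, seed = config$seed))
  jsonlite::write_json(as.list(part), file.path(outdir, "communities.json"),
                       auto_unbox = TRUE)
  results$communities <- file.path(outdir, "communities.json")

  note("stage classify: condition prediction from fitted EC")
  cl_cfg <- modifyList(list(classifier = "mlr", scheme = "shuffle", n_splits = 20),
                       if (is.null(config$classify)) list() else config$classify)
  cls <- stage("classify",
               classify_cv(feats, label_field = "condition",
                           classifier = cl_cfg$classifier,
                           scheme = cl_cfg$scheme,
                           n_splits = cl_cfg$n_splits, seed = config$seed))
  jsonlite::write_json(list(mean_accuracy = cls$mean_accuracy,
                            chance_level = cls$chance_level,
                            accuracies = cls$accuracies),
                       file.path(outdir, "classification.json"),
                       auto_unbox = TRUE, digits = NA)
  results$classify <- file.path(outdir, "classification.json")

  note("stage testlinks: link-wise condition tests")
  tl_cfg <- modifyList(list(alpha = 0.05),
                       if (is.null(config$testlinks)) list() else config$testlinks)
  keep <- apply(feats$features, 2, function(v) max(v) - min(v) > 0)
  if (any(!keep))
    note("testlinks: excluding %d constant link(s) from testing", sum(!keep))
  tfeats <- cohort_features(feats$features[, keep, drop = FALSE],
                            feats$subject, feats$condition,
                            index = feats$index[keep, , drop = FALSE],
                            session = feats$session)
  lt <- stage("testlinks", linkwise_tests(tfeats, alpha = tl_cfg$alpha))
  write.csv(data.frame(source = tfeats$index[, 1], target = tfeats$index[, 2],
                       p_value = lt$p_values, bh_rejected = lt$bh_rejections),
            file.path(outdir, "link_tests.csv"), row.names = FALSE)
  results$testlinks <- file.path(outdir, "link_tests.csv")

  hashes <- vapply(unlist(results), function(f) unname(tools::md5sum(f)), "")
  summary <- list(format_version = FORMAT_VERSION,
                  package_version = as.character(packageVersion("mouflow")),
                  seed = config$seed, stages = results, hashes = as.list(hashes),
                  log = log)
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(log, file.path(outdir, "pipeline.log"))
  invisible(summary)
}
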