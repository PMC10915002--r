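# On-disk container: one directory per session holding traces.csv (rows =
# ROIs, columns = frames) and meta.json (subject, state, frame times,
# movement mask, ground-truth sidecar). Cohorts are a directory of session
# directories plus a cohort.json manifest. CSVs are written with
# data.table (round-trippable doubles); JSON with full precision.

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
}

#' Write a session to a directory
#'
#' @param session A [calcium_session()].
#' @param path Target directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "calcium_session"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  tr <- data.table::as.data.table(session$fluorescence)
  data.table::setnames(tr, sprintf("frame_%05d", seq_len(ncol(tr))))
  tr <- cbind(data.table::data.table(roi = rownames(session$fluorescence) %||%
                                       sprintf("roi_%03d", seq_len(nrow(session$fluorescence)))),
              tr)
  data.table::fwrite(tr, file.path(path, "traces.csv"))
  meta <- list(session_id = session$session_id,
               subject_id = session$subject_id,
               state_label = session$state_label,
               frame_times = session$frame_times,
               movement_mask = session$movement_mask,
               ground_truth = session$ground_truth)
  write_json_file(meta, file.path(path, "meta.json"))
  invisible(path)
}

read_meta <- function(path) {
  f <- file.path(path, "meta.json")
  if (!file.exists(f)) stop("missing meta.json in ", path)
  meta <- jsonlite::read_json(f, simplifyVector = TRUE)
  for (field in c("session_id", "subject_id", "state_label", "frame_times",
                  "movement_mask")) {
    if (is.null(meta[[field]]))
      stop("session container schema mismatch: missing field '", field, "'")
  }
  meta
}

#' Read a session from a directory
#'
#' @param path Directory written by [write_session()].
#' @return A [calcium_session()].
#' @export
read_session <- function(path) {
  meta <- read_meta(path)
  f <- file.path(path, "traces.csv")
  if (!file.exists(f)) stop("missing traces.csv in ", path)
  tr <- data.table::fread(f)
  if (!"roi" %in% names(tr))
    stop("session container schema mismatch: missing field 'roi'")
  fl <- as.matrix(tr[, -1L])
  rownames(fl) <- tr$roi
  colnames(fl) <- NULL
  gt <- meta$ground_truth
  if (!is.null(gt)) {
    if (!is.null(gt$bouts)) gt$bouts <- as.data.frame(gt$bouts)
    for (f in c("up_rois", "down_rois"))  # JSON [] reads back as list()
      if (!is.null(gt[[f]]))
        gt[[f]] <- lapply(gt[[f]], function(v) as.integer(unlist(v)))
    if (!is.null(gt$seed)) gt$seed <- as.integer(gt$seed)
  }
  calcium_session(fluorescence = fl,
                  frame_times = meta$frame_times,
                  movement_mask = meta$movement_mask,
                  subject_id = meta$subject_id,
                  state_label = meta$state_label,
                  session_id = meta$session_id,
                  ground_truth = gt)
}

# sim_config <-> plain list with JSON-friendly matrices
serialize_config <- function(config) {
  x <- unclass(config)
  for (f in c("up_fraction", "down_fraction")) {
    m <- x[[f]]
    x[[f]] <- list(states = rownames(m), conditions = colnames(m),
                   values = unname(split(m, row(m))))
  }
  x$shared_drive_weight <- as.list(config$shared_drive_weight)
  x
}

deserialize_config <- function(x) {
  for (f in c("up_fraction", "down_fraction")) {
    s <- x[[f]]
    m <- if (is.matrix(s$values)) s$values else do.call(rbind, s$values)
    dimnames(m) <- list(s$states, s$conditions)
    x[[f]] <- m
  }
  w <- unlist(x$shared_drive_weight)
  do.call(simulation_config,
          c(x[setdiff(names(x), "shared_drive_weight")],
            list(shared_drive_weight = w)))
}

#' Write / read a cohort directory
#'
#' Sessions go under `sessions/<id>/`, reference recordings under
#' `references/<subject>/`, and `cohort.json` records the manifest and the
#' generating configuration. Writing is deterministic: writing the same
#' cohort twice produces byte-identical files.
#'
#' @param cohort A `calcium_cohort`.
#' @param path Target directory.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "calcium_cohort"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (s in cohort$sessions)
    write_session(s, file.path(path, "sessions", s$session_id))
  for (subj in names(cohort$references))
    write_session(cohort$references[[subj]], file.path(path, "references", subj))
  manifest <- list(session_ids = unname(vapply(cohort$sessions, `[[`,
                                               character(1), "session_id")),
                   reference_subjects = names(cohort$references),
                   config = serialize_config(cohort$config))
  write_json_file(manifest, file.path(path, "cohort.json"))
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  f <- file.path(path, "cohort.json")
  if (!file.exists(f)) stop("missing cohort.json in ", path)
  manifest <- jsonlite::read_json(f, simplifyVector = TRUE)
  sessions <- lapply(manifest$session_ids, function(id)
    read_session(file.path(path, "sessions", id)))
  names(sessions) <- manifest$session_ids
  references <- lapply(manifest$reference_subjects, function(subj)
    read_session(file.path(path, "references", subj)))
  names(references) <- manifest$reference_subjects
  structure(list(sessions = sessions, references = references,
                 config = deserialize_config(manifest$config)),
            class = "calcium_cohort")
}
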