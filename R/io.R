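# Persistent study container: a directory with JSON metadata, one array file
# per subject x condition, a behavior table, and a derived/ tree for
# downstream results.

CONTAINER_SCHEMA_VERSION <- "1"

config_to_list <- function(config) {
  out <- unclass(config)
  out$trial_counts <- as.list(out$trial_counts)
  out$topography <- as.list(out$topography)
  out
}

list_to_config <- function(lst) {
  do.call(simulation_config, list(
    n_subjects = lst$n_subjects, fs = lst$fs,
    epoch_window = unlist(lst$epoch_window),
    channel_labels = unlist(lst$channel_labels),
    topography = unlist(lst$topography),
    trial_counts = as.data.frame(lapply(lst$trial_counts, unlist),
                                 stringsAsFactors = FALSE),
    burst = lapply(lst$burst, unlist), noise = lapply(lst$noise, unlist),
    behavior = lapply(lst$behavior, unlist),
    behavior_coupling = lst$behavior_coupling, seed = lst$seed
  ))
}

#' Initialize a study container on disk
#'
#' @param path directory to create.
#' @param config the `fmtheta_config` that defines (or described) the study.
#' @return the path, invisibly.
#' @export
init_container <- function(path, config) {
  dir.create(file.path(path, "subjects"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(path, "derived"), showWarnings = FALSE)
  meta <- list(schema_version = CONTAINER_SCHEMA_VERSION,
               package_version = as.character(utils::packageVersion("fmtheta")),
               created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
               config = config_to_list(config))
  jsonlite::write_json(meta, file.path(path, "meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

read_meta <- function(path) {
  mf <- file.path(path, "meta.json")
  if (!file.exists(mf)) stop("not a study container (no meta.json): ", path)
  meta <- jsonlite::read_json(mf)
  if (!identical(as.character(meta$schema_version), CONTAINER_SCHEMA_VERSION))
    stop("container schema version ", meta$schema_version,
         " not supported by this package (expects ",
         CONTAINER_SCHEMA_VERSION, ")")
  meta
}

validate_epoch_set <- function(es) {
  need <- c("subject_id", "strategy", "trial_type", "data", "times", "fs",
            "channel_labels")
  miss <- setdiff(need, names(es))
  if (length(miss))
    stop("epoch set missing required field(s): ", paste(miss, collapse = ", "))
  if (length(es$times) != dim(es$data)[2])
    stop("epoch set times length does not match sample dimension")
  if (anyDuplicated(es$channel_labels)) stop("duplicate channel labels")
  invisible(es)
}

#' Write one subject's epoch sets into a container
#' @param path container directory.
#' @param subject_index subject identifier.
#' @param epochs named list of `epoch_set`s.
#' @export
write_subject_epochs <- function(path, subject_index, epochs) {
  sd <- file.path(path, "subjects", sprintf("sub-%03d", subject_index))
  dir.create(sd, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(epochs)) {
    validate_epoch_set(epochs[[nm]])
    saveRDS(epochs[[nm]], file.path(sd, paste0("epochs_", nm, ".rds")))
  }
  invisible(path)
}

#' Read one subject's epoch sets from a container
#' @param path container directory.
#' @param subject_index subject identifier.
#' @return named list of `epoch_set`s.
#' @export
read_subject_epochs <- function(path, subject_index) {
  read_meta(path)
  sd <- file.path(path, "subjects", sprintf("sub-%03d", subject_index))
  files <- list.files(sd, pattern = "^epochs_.*\\.rds$", full.names = TRUE)
  if (!length(files)) stop("no epochs stored for subject ", subject_index)
  out <- lapply(files, function(f) validate_epoch_set(readRDS(f)))
  names(out) <- sub("^epochs_(.*)\\.rds$", "\\1", basename(files))
  out
}

#' Write a whole in-memory study to a container
#' @param study an `fmtheta_study`.
#' @param path directory.
#' @export
write_study <- function(study, path) {
  stopifnot(inherits(study, "fmtheta_study"))
  init_container(path, study$config)
  utils::write.csv(study$behavior, file.path(path, "behavior.csv"),
                   row.names = FALSE)
  if (!is.null(study$subjects)) {
    for (i in seq_along(study$subjects)) {
      write_subject_epochs(path, i, study$subjects[[i]])
    }
  }
  invisible(path)
}

#' Read a study back from a container
#' @param path directory.
#' @return an `fmtheta_study`.
#' @export
read_study <- function(path) {
  meta <- read_meta(path)
  config <- list_to_config(meta$config)
  behavior <- utils::read.csv(file.path(path, "behavior.csv"),
                              stringsAsFactors = FALSE)
  subs <- list.files(file.path(path, "subjects"), pattern = "^sub-")
  subjects <- NULL
  if (length(subs)) {
    idx <- sort(as.integer(sub("^sub-", "", subs)))
    subjects <- lapply(idx, function(i) read_subject_epochs(path, i))
  }
  structure(list(config = config, subjects = subjects, behavior = behavior),
            class = "fmtheta_study")
}
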