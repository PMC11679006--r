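#' Read and write trial files
#'
#' A trial on disk is a wide CSV plus a JSON annotation sidecar (same path with
#' extension `.json`). Signal-form CSV columns:
#' `time,l_force,l_cop_x,l_cop_y,l_valid,r_force,r_cop_x,r_cop_y,r_valid`.
#' Grid-form CSV columns: `time,l_p_1..l_p_K,r_p_1..r_p_K`, with sensel mm
#' coordinates carried in the sidecar. The sidecar holds
#' `{participant_id, trial_id, fs, events: [{kind, start, end}, ...]}`.
#'
#' @param path path to the trial CSV; the sidecar is `<path without .csv>.json`.
#' @return [read_trial()] returns a `fog_trial`; [write_trial()] returns
#'   `path` invisibly.
#' @name trial_io
NULL

sidecar_path <- function(path) sub("\\.csv$", ".json", path)

#' @rdname trial_io
#' @export
read_trial <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  meta <- jsonlite::fromJSON(sidecar_path(path), simplifyDataFrame = TRUE)
  if (!"time" %in% names(df)) stop("trial CSV is missing column: time")
  events <- if (length(meta$events)) {
    fog_events(meta$events$kind, meta$events$start, meta$events$end)
  } else {
    fog_events()
  }
  grid_form <- any(grepl("^l_p_", names(df)))
  if (grid_form) {
    left <- read_grid_side(df, "l", meta$sensels$left)
    right <- read_grid_side(df, "r", meta$sensels$right)
  } else {
    left <- read_signal_side(df, "l")
    right <- read_signal_side(df, "r")
  }
  fog_trial(meta$participant_id, meta$trial_id, df$time, left, right,
            events = events, fs = meta$fs)
}

read_signal_side <- function(df, prefix) {
  cols <- paste0(prefix, c("_force", "_cop_x", "_cop_y", "_valid"))
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols)) {
    stop("trial CSV is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  list(force = df[[cols[1]]], cop_x = df[[cols[2]]], cop_y = df[[cols[3]]],
       valid = as.logical(df[[cols[4]]]))
}

read_grid_side <- function(df, prefix, sensels) {
  cols <- grep(paste0("^", prefix, "_p_"), names(df), value = TRUE)
  k <- as.integer(sub(paste0(prefix, "_p_"), "", cols))
  cols <- cols[order(k)]
  if (is.null(sensels)) stop("grid trial sidecar is missing field: sensels")
  list(pressure = as.matrix(df[cols]),
       sensel_x = as.numeric(sensels$x), sensel_y = as.numeric(sensels$y))
}

#' @rdname trial_io
#' @param trial a `fog_trial`.
#' @param digits numeric precision written to the CSV.
#' @export
write_trial <- function(trial, path, digits = 6) {
  grid_form <- !is.null(trial$left$pressure)
  if (grid_form) {
    lcols <- as.data.frame(trial$left$pressure)
    names(lcols) <- paste0("l_p_", seq_len(ncol(lcols)))
    rcols <- as.data.frame(trial$right$pressure)
    names(rcols) <- paste0("r_p_", seq_len(ncol(rcols)))
    df <- cbind(data.frame(time = trial$times), lcols, rcols)
  } else {
    df <- data.frame(
      time = trial$times,
      l_force = trial$left$force, l_cop_x = trial$left$cop_x,
      l_cop_y = trial$left$cop_y,
      l_valid = as.integer(side_valid(trial$left)),
      r_force = trial$right$force, r_cop_x = trial$right$cop_x,
      r_cop_y = trial$right$cop_y,
      r_valid = as.integer(side_valid(trial$right))
    )
  }
  is_num <- vapply(df, is.double, logical(1))
  df[is_num] <- lapply(df[is_num], function(x) round(x, digits))
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(participant_id = trial$participant_id, trial_id = trial$trial_id,
               fs = trial$fs,
               events = if (nrow(trial$events)) {
                 trial$events[c("kind", "start", "end")]
               } else {
                 list()
               })
  if (grid_form) {
    meta$sensels <- list(
      left = list(x = trial$left$sensel_x, y = trial$left$sensel_y),
      right = list(x = trial$right$sensel_x, y = trial$right$sensel_y))
  }
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

## valid flags: stored if present, otherwise from the 5% force rule later
side_valid <- function(side) {
  if (!is.null(side$valid)) side$valid else rep(TRUE, length(side$force))
}

#' Write / read a cohort of trials with a manifest
#'
#' The manifest (`manifest.json`) lists each participant's demographics and
#' trial CSV paths (relative to the manifest directory).
#'
#' @param ds a `fog_dataset`.
#' @param dir directory to write into (created if needed).
#' @return [write_cohort()] returns the manifest path invisibly;
#'   [read_cohort()] returns a `fog_dataset`.
#' @export
write_cohort <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- lapply(ds$participants, function(p) {
    paths <- vapply(p$trials, function(tr) {
      fn <- sprintf("%s_%s.csv", p$id, tr$trial_id)
      write_trial(tr, file.path(dir, fn))
      fn
    }, character(1))
    list(id = p$id, age = p$age,
         years_since_diagnosis = p$years_since_diagnosis,
         nfogq = p$nfogq, updrs3 = p$updrs3, trials = as.list(paths))
  })
  out <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(name = ds$name, participants = manifest), out,
                       auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(out)
}

#' @rdname write_cohort
#' @param manifest path to a cohort `manifest.json`.
#' @export
read_cohort <- function(manifest) {
  m <- jsonlite::fromJSON(manifest, simplifyDataFrame = FALSE)
  dir <- dirname(manifest)
  participants <- lapply(m$participants, function(p) {
    trials <- lapply(p$trials, function(fn) read_trial(file.path(dir, fn)))
    fog_participant(p$id, trials, age = p$age %||% NA_real_,
                    years_since_diagnosis = p$years_since_diagnosis %||% NA_real_,
                    nfogq = p$nfogq %||% NA_real_, updrs3 = p$updrs3 %||% NA_real_)
  })
  fog_dataset(m$name, participants)
}
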