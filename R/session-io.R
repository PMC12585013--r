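# On-disk session format: one directory per session holding plain-text tables.
#   meta.json                 animal_id, treatment, phase, schema version
#   units.csv                 unit_id, t_start, t_end
#   spikes.csv                unit_id, time_s
#   behavior.csv              time_s, pupil, speed, eye_x, eye_y   (optional)
#   stimuli.json              one record per stimulus: kind, file, ny, nx
#   stimulus_<k>.csv          frame_time_s + value column(s)
# Arrays are written with full double precision so that load(save(x)) is an
# identity up to float text representation, and writes are byte-stable.

SESSION_SCHEMA_VERSION <- 1L

#' Save a session to a plain-text directory
#'
#' @param session An [ln_session].
#' @param path Directory to create (overwritten if it already exists).
#' @return `path`, invisibly.
#' @seealso [load_session()]
#' @export
save_session <- function(session, path) {
  stopifnot(inherits(session, "ln_session"))
  if (!dir.exists(path)) {
    ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create session directory: ", path, call. = FALSE)
  }
  meta <- list(schema_version = SESSION_SCHEMA_VERSION,
               animal_id = session$animal_id,
               treatment = session$treatment,
               phase = session$phase)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  units_df <- data.table::data.table(
    unit_id = vapply(session$units, `[[`, "", "unit_id"),
    t_start = vapply(session$units, `[[`, 0, "t_start"),
    t_end = vapply(session$units, `[[`, 0, "t_end"))
  data.table::fwrite(units_df, file.path(path, "units.csv"))
  spikes_df <- data.table::rbindlist(lapply(session$units, function(u) {
    data.table::data.table(unit_id = rep(u$unit_id, length(u$spike_times)),
                           time_s = u$spike_times)
  }))
  if (!nrow(spikes_df)) {
    spikes_df <- data.table::data.table(unit_id = character(), time_s = numeric())
  }
  data.table::fwrite(spikes_df, file.path(path, "spikes.csv"))

  if (!is.null(session$behavior)) {
    b <- session$behavior
    data.table::fwrite(
      data.table::data.table(time_s = b$time, pupil = b$pupil_size,
                             speed = b$speed, eye_x = b$eye_x, eye_y = b$eye_y),
      file.path(path, "behavior.csv"))
  }

  stim_meta <- lapply(seq_along(session$stimuli), function(k) {
    s <- session$stimuli[[k]]
    file <- sprintf("stimulus_%d.csv", k)
    df <- data.table::data.table(frame_time_s = s$frame_times)
    if (s$kind == "checkerboard") {
      vals <- data.table::as.data.table(s$values)
      data.table::setnames(vals, sprintf("px_%d", seq_len(ncol(s$values))))
      df <- cbind(df, vals)
    } else {
      df$value <- s$values
    }
    data.table::fwrite(df, file.path(path, file))
    list(kind = s$kind, file = file,
         ny = if (is.null(s$ny)) NA else s$ny,
         nx = if (is.null(s$nx)) NA else s$nx)
  })
  jsonlite::write_json(stim_meta, file.path(path, "stimuli.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load a session from disk
#'
#' Reads the directory layout written by [save_session()] and re-validates all
#' container invariants (sorted spikes, increasing frame times, constant
#' checkerboard luminance).
#'
#' @param path Session directory.
#' @return An [ln_session].
#' @export
load_session <- function(path) {
  if (!dir.exists(path)) stop("session directory not found: ", path, call. = FALSE)
  need <- c("meta.json", "units.csv", "spikes.csv", "stimuli.json")
  for (f in need) {
    if (!file.exists(file.path(path, f))) {
      stop("session format error: missing dataset '", f, "'", call. = FALSE)
    }
  }
  meta <- jsonlite::read_json(file.path(path, "meta.json"))
  units_df <- data.table::fread(file.path(path, "units.csv"),
                                colClasses = list(character = "unit_id"))
  spikes_df <- data.table::fread(file.path(path, "spikes.csv"),
                                 colClasses = list(character = "unit_id"))
  units <- lapply(seq_len(nrow(units_df)), function(i) {
    uid <- units_df$unit_id[i]
    spike_train(uid, spikes_df$time_s[spikes_df$unit_id == uid],
                units_df$t_start[i], units_df$t_end[i])
  })

  behavior <- NULL
  if (file.exists(file.path(path, "behavior.csv"))) {
    b <- data.table::fread(file.path(path, "behavior.csv"))
    behavior <- behavior_trace(b$time_s, b$pupil, b$speed, b$eye_x, b$eye_y)
  }

  stim_meta <- jsonlite::read_json(file.path(path, "stimuli.json"))
  stimuli <- lapply(stim_meta, function(m) {
    f <- file.path(path, m$file)
    if (!file.exists(f)) {
      stop("session format error: missing dataset '", m$file, "'", call. = FALSE)
    }
    df <- data.table::fread(f)
    if (m$kind == "checkerboard") {
      vals <- as.matrix(df[, -1L])
      storage.mode(vals) <- "double"
      dimnames(vals) <- NULL
      stimulus_trace(m$kind, df$frame_time_s, vals, ny = m$ny, nx = m$nx)
    } else {
      stimulus_trace(m$kind, df$frame_time_s, df$value)
    }
  })

  ln_session(units, stimuli, behavior,
             animal_id = meta$animal_id, treatment = meta$treatment,
             phase = meta$phase)
}

#' Bin spike times on a frame clock
#'
#' Bins are half-open `[frame_i, frame_{i+1})`; a spike exactly on a frame
#' boundary is counted in the later bin. The last bin closes at the last frame
#' time plus the median frame interval, so that the count total equals the
#' number of spikes inside the covered span.
#'
#' @param train A [spike_train].
#' @param frame_times Strictly increasing frame onset times, seconds.
#' @return Integer vector of per-frame spike counts, `length(frame_times)`.
#' @export
bin_spikes <- function(train, frame_times) {
  stopifnot(inherits(train, "spike_train"))
  frame_times <- as.numeric(frame_times)
  if (!length(frame_times)) stop("frame_times must be non-empty", call. = FALSE)
  if (any(diff(frame_times) <= 0)) {
    stop("frame_times must be strictly increasing", call. = FALSE)
  }
  dt_med <- if (length(frame_times) > 1L) median(diff(frame_times)) else FRAME_DT
  edges <- c(frame_times, frame_times[length(frame_times)] + dt_med)
  counts <- findInterval(train$spike_times, edges, left.open = FALSE,
                         rightmost.closed = FALSE)
  # findInterval with default flags puts t == edge into the later interval's
  # index (edge i <= t < edge i+1), which is exactly the half-open convention.
  counts <- counts[counts >= 1L & counts <= length(frame_times)]
  tabulate(counts, nbins = length(frame_times))
}
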