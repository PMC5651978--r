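track_header <- c("trial_id", "frame", "time_s", "agent_id", "x_m", "y_m",
                  "orientation_rad", "vx_mps", "vy_mps", "status")
event_header <- c("trial_id", "agent_id", "exit_time_s")

#' Write / read trajectory tables
#'
#' The trajectory CSV dialect has the fixed header
#' `trial_id,frame,time_s,agent_id,x_m,y_m,orientation_rad,vx_mps,vy_mps,status`.
#' The reader validates the header, rejects duplicated
#' (trial, frame, agent) rows and non-monotone per-agent times, and names
#' the offending line in its error. Missing optional columns (orientation,
#' velocities, status) in externally produced exports are filled with NA
#' via `column_map`.
#'
#' @param tracks trajectory data frame (at least trial_id, frame, time_s,
#'   agent_id, x_m, y_m).
#' @param path file path.
#' @return `write_tracks` returns `path` invisibly; `read_tracks` the
#'   validated data frame.
#' @export
write_tracks <- function(tracks, path) {
  miss <- setdiff(track_header, names(tracks))
  for (m in miss) tracks[[m]] <- NA
  write.csv(tracks[, track_header], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @param column_map optional named character vector mapping this
#'   package's column names to the names used in an external tracking
#'   export, e.g. `c(x_m = "posX", y_m = "posY")`.
#' @export
read_tracks <- function(path, column_map = NULL) {
  first <- readLines(path, n = 1)
  if (length(first) == 0) stop("parse error: no header in ", path)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(column_map))
    for (std in names(column_map)) {
      if (!column_map[[std]] %in% names(tab))
        stop("parse error: mapped column '", column_map[[std]],
             "' not found in ", path)
      names(tab)[names(tab) == column_map[[std]]] <- std
    }
  required <- c("trial_id", "frame", "time_s", "agent_id", "x_m", "y_m")
  miss <- setdiff(required, names(tab))
  if (length(miss) > 0)
    stop("parse error: malformed header, missing column(s) ",
         paste(miss, collapse = ", "))
  for (m in setdiff(track_header, names(tab))) tab[[m]] <- NA
  tab <- tab[, track_header]
  key <- paste(tab$trial_id, tab$frame, tab$agent_id)
  if (anyDuplicated(key)) {
    line <- which(duplicated(key))[1] + 1  # + header line
    stop("parse error at line ", line,
         ": duplicate (trial, frame, agent) row")
  }
  for (g in split(seq_len(nrow(tab)),
                  interaction(tab$trial_id, tab$agent_id, drop = TRUE))) {
    tt <- tab$time_s[g]
    bad <- which(diff(tt[order(tab$frame[g])]) <= 0)
    if (length(bad) > 0)
      stop("parse error at line ", g[bad[1] + 1] + 1,
           ": times not strictly increasing for agent ",
           tab$agent_id[g[1]], " in trial ", tab$trial_id[g[1]])
  }
  tab
}

#' Write / read exit-event tables
#'
#' CSV dialect with header `trial_id,agent_id,exit_time_s`.
#'
#' @param events exit-event data frame.
#' @param path file path.
#' @return `write_events` returns `path` invisibly; `read_events` the
#'   data frame.
#' @export
write_events <- function(events, path) {
  write.csv(events[, event_header], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  first <- readLines(path, n = 1)
  if (length(first) == 0) stop("parse error: no header in ", path)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(event_header, names(tab))
  if (length(miss) > 0)
    stop("parse error: malformed header, missing column(s) ",
         paste(miss, collapse = ", "))
  tab[, event_header]
}
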