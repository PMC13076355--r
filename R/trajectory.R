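## Telemetry preprocessing: from raw repeated GPS readings to clean
## per-animal-year trajectories and derived step sequences.
##
## Field protocol emulated here: each relocation of a tracked animal gets
## an initial GPS reading; apparent movements of 1 m or less are not
## unique locations and inherit the previous coordinates; movements over
## 1 m require a second reading on another day, and the first pair of
## readings within 3 m of each other is averaged.  Readings that never
## produce a qualifying pair are unresolved and excluded with a warning.

.dist2d <- function(a, b) sqrt(sum((as.numeric(a) - as.numeric(b))^2))

#' Resolve one relocation from repeated GPS readings
#'
#' @param readings matrix/data.frame with columns x, y, one row per GPS
#'   reading of the same relocation, in reading order.
#' @param previous length-2 numeric of the previous relocation, or NULL.
#' @param move_threshold movements of at most this (m) are collapsed onto
#'   the previous location (default 1).
#' @param pair_tolerance max distance (m) between two readings for them to
#'   be averaged (default 3).
#' @param confirm if TRUE (the raw-protocol default) a single reading more
#'   than `move_threshold` from `previous` is rejected as unconfirmed; set
#'   FALSE for tables that were already field-averaged.
#' @return length-2 numeric coordinate of the resolved relocation.
#' @export
average_relocation <- function(readings, previous = NULL,
                               move_threshold = 1, pair_tolerance = 3,
                               confirm = TRUE) {
  if (is.data.frame(readings)) readings <- as.matrix(readings[, c("x", "y")])
  if (is.null(dim(readings))) readings <- matrix(readings, ncol = 2, byrow = TRUE)
  readings <- .check_coords(readings, "readings")
  n <- nrow(readings)
  if (n < 1L) stop("average_relocation: need at least one reading", call. = FALSE)
  if (!is.null(previous)) {
    d <- sqrt((readings[, 1] - previous[1])^2 + (readings[, 2] - previous[2])^2)
    if (all(d <= move_threshold)) return(as.numeric(previous))
  }
  if (n == 1L) {
    if (is.null(previous) || !confirm) return(readings[1, ])
    stop(structure(class = c("lc_unresolved_fix", "error", "condition"),
                   list(message = "unresolved fix: single reading > 1 m from previous with no confirming pair",
                        call = NULL)))
  }
  ## pairs in the order they become available in the field: as each new
  ## reading j arrives it is compared with every earlier reading i
  for (j in 2:n) for (i in 1:(j - 1L)) {
    if (.dist2d(readings[i, ], readings[j, ]) <= pair_tolerance)
      return((readings[i, ] + readings[j, ]) / 2)
  }
  stop(structure(class = c("lc_unresolved_fix", "error", "condition"),
                 list(message = sprintf(
                   "unresolved fix: no two of %d readings within %g m", n, pair_tolerance),
                   call = NULL)))
}

.parse_time <- function(ts) {
  if (inherits(ts, "POSIXct")) return(ts)
  out <- as.POSIXct(ts, tz = "UTC", tryFormats = c(
    "%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S", "%Y-%m-%d"))
  if (anyNA(out)) stop("unparseable timestamps (expect ISO-8601)", call. = FALSE)
  out
}

#' Build per-animal-year trajectories from raw fixes
#'
#' Groups readings by (animal, timestamp) into relocation events, resolves
#' each with [average_relocation()], assigns the calendar year, flags
#' movement (`moved` is TRUE when the relocation lies more than
#' `move_threshold` from the previous one), and drops animal-years with
#' fewer than two unique locations.
#'
#' @param fixes data.frame with columns animal_id, sex, timestamp, x, y
#'   and optionally reading_index (ordering repeated readings).
#' @param move_threshold,pair_tolerance see [average_relocation()].
#' @return a data.frame of class `lc_relocations` with columns animal_id,
#'   sex, year, timestamp, x, y, moved.
#' @export
build_trajectories <- function(fixes, move_threshold = 1, pair_tolerance = 3) {
  need <- c("animal_id", "sex", "timestamp", "x", "y")
  if (!all(need %in% names(fixes)))
    stop("fixes must have columns ", paste(need, collapse = ", "), call. = FALSE)
  fixes$timestamp <- .parse_time(fixes$timestamp)
  if (is.null(fixes$reading_index)) fixes$reading_index <- 1L
  fixes <- fixes[order(fixes$animal_id, fixes$timestamp, fixes$reading_index), ]
  ## a table in which no relocation event carries repeated readings is
  ## already field-averaged: single readings are then authoritative and
  ## only the <= 1 m collapse rule applies
  pre_averaged <- max(table(paste(fixes$animal_id, fixes$timestamp))) == 1L
  out <- list()
  for (aid in unique(fixes$animal_id)) {
    fa <- fixes[fixes$animal_id == aid, ]
    if (length(unique(fa$sex)) != 1L)
      stop("animal ", aid, " has inconsistent sex codes", call. = FALSE)
    events <- split(fa, format(fa$timestamp, "%Y-%m-%d %H:%M:%S"))
    events <- events[order(vapply(events, function(e) min(as.numeric(e$timestamp)), 0))]
    prev <- NULL
    rows <- vector("list", length(events))
    for (k in seq_along(events)) {
      ev <- events[[k]]
      pt <- tryCatch(
        average_relocation(ev[, c("x", "y")], prev,
                           move_threshold = move_threshold,
                           pair_tolerance = pair_tolerance,
                           confirm = !pre_averaged),
        lc_unresolved_fix = function(e) {
          warning(sprintf("animal %s @ %s: %s (excluded)", aid,
                          format(ev$timestamp[1]), conditionMessage(e)), call. = FALSE)
          NULL
        })
      if (is.null(pt)) next
      moved <- !is.null(prev) && .dist2d(pt, prev) > move_threshold
      rows[[k]] <- data.frame(
        animal_id = aid, sex = as.character(ev$sex[1]),
        year = as.integer(format(ev$timestamp[1], "%Y")),
        timestamp = ev$timestamp[1], x = pt[1], y = pt[2], moved = moved,
        stringsAsFactors = FALSE)
      prev <- pt
    }
    out[[length(out) + 1L]] <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  }
  relocs <- do.call(rbind, out)
  ## first relocation of each animal-year is not a move
  keep <- list()
  for (key in unique(paste(relocs$animal_id, relocs$year))) {
    tr <- relocs[paste(relocs$animal_id, relocs$year) == key, ]
    tr$moved[1] <- FALSE
    if (nrow(unique(tr[, c("x", "y")])) < 2L) {
      warning("dropping animal-year ", key, ": fewer than 2 unique locations",
              call. = FALSE)
      next
    }
    keep[[length(keep) + 1L]] <- tr
  }
  if (length(keep) == 0L) {
    warning("no usable trajectories", call. = FALSE)
    return(NULL)
  }
  res <- do.call(rbind, keep)
  rownames(res) <- NULL
  class(res) <- c("lc_relocations", "data.frame")
  res
}

#' Split relocations into per-animal-year trajectories
#' @param relocs an `lc_relocations` data.frame.
#' @return named list of data.frames, one per animal-year ("animal.year").
#' @export
split_trajectories <- function(relocs) {
  stopifnot(is.data.frame(relocs))
  sp <- split(as.data.frame(relocs), paste(relocs$animal_id, relocs$year, sep = "."))
  sp[order(names(sp))]
}

#' Collapse a trajectory to its unique locations
#' @param traj one animal-year data.frame (relocation rows in time order).
#' @return matrix of unique-location coordinates (the movement polyline).
#' @export
unique_locations <- function(traj) {
  xy <- as.matrix(traj[, c("x", "y")])
  if (nrow(xy) == 0L) return(xy)
  keep <- c(TRUE, (abs(diff(xy[, 1])) > .lc_eps) | (abs(diff(xy[, 2])) > .lc_eps))
  xy[keep, , drop = FALSE]
}

.wrap_angle <- function(a) {
  a <- (a + pi) %% (2 * pi) - pi
  ifelse(a == -pi, pi, a)  # (-pi, pi]
}

#' Derive the step sequence of a trajectory
#'
#' @param traj one animal-year data.frame.
#' @param movement_only if TRUE (default) steps connect consecutive unique
#'   locations (all lengths > 0); if FALSE steps connect consecutive
#'   relocations and stationary steps have length 0 and no heading.
#' @return data.frame with columns x0, y0, x1, y1, length, heading,
#'   turn_angle (NA where undefined: the first movement step, and
#'   stationary steps).  Turn angles are relative to the last non-zero
#'   heading and lie in (-pi, pi].
#' @export
derive_steps <- function(traj, movement_only = TRUE) {
  xy <- if (movement_only) unique_locations(traj) else as.matrix(traj[, c("x", "y")])
  n <- nrow(xy)
  if (n < 2L)
    return(data.frame(x0 = numeric(0), y0 = numeric(0), x1 = numeric(0),
                      y1 = numeric(0), length = numeric(0),
                      heading = numeric(0), turn_angle = numeric(0)))
  dx <- diff(xy[, 1]); dy <- diff(xy[, 2])
  len <- sqrt(dx^2 + dy^2)
  heading <- ifelse(len > 0, atan2(dy, dx), NA_real_)
  turn <- rep(NA_real_, n - 1L)
  last_heading <- NA_real_
  for (i in seq_len(n - 1L)) {
    if (is.na(heading[i])) next
    if (!is.na(last_heading)) turn[i] <- .wrap_angle(heading[i] - last_heading)
    last_heading <- heading[i]
  }
  data.frame(x0 = xy[-n, 1], y0 = xy[-n, 2], x1 = xy[-1, 1], y1 = xy[-1, 2],
             length = len, heading = heading, turn_angle = turn)
}

#' Read a relocation table from delimited text
#' @param path CSV file with header animal_id,sex,timestamp,x,y[,reading_index].
#' @export
read_relocations <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a relocation table to delimited text
#' @param relocs relocation data.frame.
#' @param path output CSV path.
#' @export
write_relocations <- function(relocs, path) {
  df <- as.data.frame(relocs)
  if (inherits(df$timestamp, "POSIXct"))
    df$timestamp <- format(df$timestamp, "%Y-%m-%dT%H:%M:%S")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
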