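#' Social interaction test arena geometry
#'
#' A square (or rectangular) open-field arena with a stimulus enclosure at
#' one wall. The interaction zone is the band covering exactly 1/3 of the
#' arena area nearest the stimulus wall; the avoidance zone is the band
#' covering exactly 1/4 of the arena area farthest from it. The bands span
#' the full arena width, the simplest geometry satisfying the stated area
#' fractions. Coordinates have the origin at the bottom-left corner, x
#' rightwards, y upwards.
#'
#' @param width,height arena dimensions in cm (default 40 x 40).
#' @param target_side wall holding the stimulus enclosure: `"left"`,
#'   `"right"`, `"bottom"` or `"top"` (default `"top"`).
#' @return An object of class `arena_geometry`.
#' @export
arena_geometry <- function(width = 40, height = 40,
                           target_side = c("top", "bottom", "left", "right")) {
  target_side <- match.arg(target_side)
  if (width <= 0 || height <= 0) stop("arena dimensions must be positive")
  structure(list(width = width, height = height, target_side = target_side),
            class = "arena_geometry")
}

#' @export
print.arena_geometry <- function(x, ...) {
  cat(sprintf(
    "<arena_geometry> %g x %g cm, stimulus at %s wall (interaction 1/3, avoidance 1/4)\n",
    x$width, x$height, x$target_side))
  invisible(x)
}

# Distance of points from the stimulus wall, and the arena extent along
# that axis.
stimulus_distance <- function(arena, x, y) {
  switch(arena$target_side,
         left   = list(d = x, L = arena$width),
         right  = list(d = arena$width - x, L = arena$width),
         bottom = list(d = y, L = arena$height),
         top    = list(d = arena$height - y, L = arena$height))
}

#' Zone membership of arena positions
#'
#' Interaction zone: distance from the stimulus wall `<= L/3`; avoidance
#' zone: distance `> 3L/4`. A point exactly on the avoidance boundary is
#' assigned to the neutral strip (the side nearer the stimulus), and a
#' point on the interaction boundary to the interaction zone — boundary
#' lines always resolve towards the stimulus.
#'
#' @param arena an [arena_geometry()].
#' @param x,y position vectors in arena coordinates.
#' @return Character vector: `"interaction"`, `"avoidance"` or `"none"`.
#' @export
zone_membership <- function(arena, x, y) {
  if (any(x < 0 | x > arena$width | y < 0 | y > arena$height))
    stop("positions must lie within the arena bounds")
  sd_ <- stimulus_distance(arena, x, y)
  ifelse(sd_$d <= sd_$L / 3, "interaction",
         ifelse(sd_$d > 3 * sd_$L / 4, "avoidance", "none"))
}

#' Trajectory of one social interaction test
#'
#' @param t strictly increasing sample times in seconds.
#' @param x,y positions at each sample, within the arena bounds.
#' @param duration total session length in seconds (SIT: 150 s); must be
#'   at least the last sample time.
#' @return An object of class `sit_trajectory`.
#' @export
sit_trajectory <- function(t, x, y, duration = 150) {
  if (length(t) == 0L) stop("empty trajectory")
  if (length(x) != length(t) || length(y) != length(t))
    stop("t, x, y must have equal length")
  if (any(diff(t) <= 0)) stop("sample times must be strictly increasing")
  if (t[1] < 0 || duration < t[length(t)])
    stop("samples must lie within [0, duration]")
  structure(list(t = as.numeric(t), x = as.numeric(x), y = as.numeric(y),
                 duration = as.numeric(duration)),
            class = "sit_trajectory")
}

#' @export
print.sit_trajectory <- function(x, ...) {
  cat(sprintf("<sit_trajectory> %d samples over %g s\n",
              length(x$t), x$duration))
  invisible(x)
}

#' Read a trajectory from CSV
#'
#' Format: columns `t_seconds, x, y`.
#'
#' @param path CSV path.
#' @param duration total session length in seconds (default 150).
#' @return A [sit_trajectory()].
#' @export
read_trajectory_csv <- function(path, duration = 150) {
  df <- read.csv(path, comment.char = "#")
  need <- c("t_seconds", "x", "y")
  if (!all(need %in% names(df)))
    stop("trajectory CSV must contain columns: ", paste(need, collapse = ", "))
  sit_trajectory(df$t_seconds, df$x, df$y, duration)
}

#' Zone occupancy of a trajectory
#'
#' Integrates zone membership over time with sample-and-hold between
#' timestamps (the position at sample i is held until sample i + 1; the
#' last sample is held to the end of the session), matching frame-based
#' tracking exports. Percentages are relative to the total duration.
#'
#' @param traj a [sit_trajectory()].
#' @param arena an [arena_geometry()].
#' @return Named numeric vector `c(time_interaction_pct, time_avoidance_pct)`.
#' @export
zone_occupancy <- function(traj, arena) {
  stopifnot(inherits(traj, "sit_trajectory"), inherits(arena, "arena_geometry"))
  zones <- zone_membership(arena, traj$x, traj$y)
  dwell <- diff(c(traj$t, traj$duration))
  tot <- traj$duration  # time before the first sample counts to no zone
  c(time_interaction_pct = 100 * sum(dwell[zones == "interaction"]) / tot,
    time_avoidance_pct = 100 * sum(dwell[zones == "avoidance"]) / tot)
}

#' Avoidant classification
#'
#' A mouse is avoidant iff it spent strictly more than 50% of the session
#' in the avoidance zone.
#'
#' @param time_avoidance_pct percentage of time in the avoidance zone,
#'   in \[0, 100\].
#' @return Logical.
#' @export
classify_avoidant <- function(time_avoidance_pct) {
  if (any(time_avoidance_pct < 0 | time_avoidance_pct > 100))
    stop("`time_avoidance_pct` must be in [0, 100]")
  time_avoidance_pct > 50
}

#' Subpopulation label from the two test timepoints
#'
#' Maps the avoidant flags at the test immediately after stress (0W) and
#' two weeks later (2W) onto the four subpopulations: both avoidant ->
#' `Av_both`; only at 0W -> `Av_0W`; only at 2W -> `Av_2W`; neither ->
#' `Non-Av`.
#'
#' @param avoidant_0w,avoidant_2w logical flags (vectorized).
#' @return Character vector of subpopulation labels.
#' @export
subpopulation <- function(avoidant_0w, avoidant_2w) {
  stopifnot(is.logical(avoidant_0w), is.logical(avoidant_2w),
            length(avoidant_0w) == length(avoidant_2w))
  ifelse(avoidant_0w & avoidant_2w, "Av_both",
         ifelse(avoidant_0w, "Av_0W",
                ifelse(avoidant_2w, "Av_2W", "Non-Av")))
}

#' Body-weight-change index
#'
#' `(weight on day 8 - weight on day 1) / weight on day 1 x 100`, in
#' signed percent.
#'
#' @param day1_g,day8_g body weights in grams (vectorized).
#' @return Signed percent change.
#' @export
body_weight_change <- function(day1_g, day8_g) {
  if (any(day1_g <= 0)) stop("baseline weight must be positive")
  (day8_g - day1_g) / day1_g * 100
}
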