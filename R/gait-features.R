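#' Detect the stance phase from a vertical ground reaction force signal
#'
#' Stance is the longest contiguous run of samples whose vertical ground
#' reaction force exceeds the contact threshold (20 N by default).
#' Returns the first and last sample indices of that run (1-based, closed
#' interval).
#'
#' @param vertical_grf Numeric vector of vertical ground reaction force
#'   in N, uniformly sampled.
#' @param threshold Contact threshold in N (default 20).
#' @return Named integer vector with elements `contact` and `toeoff`.
#' @examples
#' grf <- c(0, 0, 400, 800, 600, 0)
#' detect_stance(grf)
#' @export
detect_stance <- function(vertical_grf, threshold = 20) {
  if (!is.numeric(vertical_grf) || length(vertical_grf) == 0)
    stop("'vertical_grf' must be a non-empty numeric vector")
  above <- vertical_grf > threshold
  if (!any(above))
    stop("no stance detected: signal never exceeds ", threshold, " N")
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sup <- which(r$values)
  k <- sup[which.max(r$lengths[sup])]
  c(contact = starts[k], toeoff = ends[k])
}

#' Zero-lag low-pass Butterworth filter
#'
#' 4th-order low-pass Butterworth applied forward and backward
#' (`signal::filtfilt`), giving zero phase shift and doubling the
#' effective order.  The standard smoothing used on gait signals: 50 Hz
#' on ground reaction forces, 6 Hz on marker-derived kinematics.
#'
#' @param x Numeric vector or matrix (channels in columns).
#' @param cutoff Cut-off frequency in Hz; must be below the Nyquist
#'   frequency `fs / 2`.
#' @param fs Sampling rate in Hz.
#' @param order Filter order for a single pass (default 4).
#' @return Filtered signal, same shape as `x`.
#' @export
lowpass_filter <- function(x, cutoff, fs, order = 4) {
  if (cutoff >= fs / 2)
    stop("'cutoff' (", cutoff, " Hz) must be below the Nyquist frequency ",
         fs / 2, " Hz")
  if (cutoff <= 0) stop("'cutoff' must be positive")
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  nk <- max(length(bf$b), length(bf$a))
  pass <- function(v) {
    # start in steady state at the first sample's level (unity DC gain)
    s <- rep(v[1], nk - 1)
    as.numeric(signal::filter(bf$b, bf$a, v, init.x = s, init.y = s))
  }
  filt1 <- function(v) {
    n <- length(v)
    pl <- min(n - 1, 3 * nk)
    # odd reflection padding about the endpoints limits edge transients
    vp <- c(2 * v[1] - v[seq(pl + 1, 2)], v, 2 * v[n] - v[seq(n - 1, n - pl)])
    y <- pass(vp)
    y <- rev(pass(rev(y)))
    y[seq(pl + 1, pl + n)]
  }
  if (is.matrix(x)) apply(x, 2, filt1) else filt1(x)
}

#' Foot progression angle from the centre-of-pressure path
#'
#' Signed angle between the chord connecting the CoP at initial contact
#' and at toe-off and the anterior (forward) axis.  Positive values
#' represent toe-out, negative toe-in (right-foot convention with the
#' mediolateral axis positive toward lateral).
#'
#' @param cop Data frame or matrix with columns `x_ml` (mm, positive
#'   lateral) and `y_ap` (mm, positive anterior).
#' @param contact_index,toeoff_index Sample indices bounding stance
#'   (e.g. from [detect_stance()] applied to the synchronous force
#'   signal); default to the first and last row.
#' @return Angle in degrees.
#' @examples
#' cop <- generate_cop_trajectory(11.95)
#' foot_progression_angle(cop)
#' @export
foot_progression_angle <- function(cop,
                                   contact_index = 1L,
                                   toeoff_index = nrow(cop)) {
  cop <- as.data.frame(cop)
  if (!all(c("x_ml", "y_ap") %in% names(cop)))
    stop("'cop' must have columns 'x_ml' and 'y_ap'")
  n <- nrow(cop)
  if (contact_index < 1 || toeoff_index > n || contact_index >= toeoff_index)
    stop("invalid stance indices")
  dml <- cop$x_ml[toeoff_index] - cop$x_ml[contact_index]
  dap <- cop$y_ap[toeoff_index] - cop$y_ap[contact_index]
  if (dml == 0 && dap == 0)
    stop("zero-length CoP chord: cannot define a progression angle")
  atan2(dml, dap) * 180 / pi
}

#' Daily loading cycles from stride length and daily walking distance
#'
#' Number of loading cycles the knee experiences per day.  With the
#' default `count = "steps"` each of the two steps in a stride loads the
#' joint once, so cycles = 2 x distance / stride length; `"strides"`
#' counts ipsilateral contacts only (distance / stride length).  A
#' 6.0 km daily distance and a 1.71 m stride give about 7000 steps per
#' day, the conventional benchmark for health-relevant activity.
#'
#' @param stride_length Stride length in m (two consecutive ipsilateral
#'   foot contacts); must be positive.
#' @param daily_distance Daily walking distance in m (default 6000).
#' @param count `"steps"` (default) or `"strides"`.
#' @return Loading cycles per day.
#' @examples
#' daily_loading_cycles(1.7143)        # ~7000 steps/day
#' @export
daily_loading_cycles <- function(stride_length, daily_distance = 6000,
                                 count = c("steps", "strides")) {
  count <- match.arg(count)
  if (any(stride_length <= 0)) stop("'stride_length' must be positive")
  if (any(daily_distance < 0)) stop("'daily_distance' must be non-negative")
  k <- if (count == "steps") 2 else 1
  k * daily_distance / stride_length
}

#' Cumulative medial compartment load
#'
#' Mean stance-phase medial contact force divided by stride length, in
#' BW/m: the per-distance loading exposure of the compartment.
#'
#' @param mean_stance_force Mean stance-phase medial contact force in BW.
#' @param stride_length Stride length in m; must be positive.
#' @return Cumulative load in BW/m.
#' @examples
#' cumulative_load(1.4535, 1.71)   # 0.85 BW/m
#' @export
cumulative_load <- function(mean_stance_force, stride_length) {
  if (any(stride_length <= 0)) stop("'stride_length' must be positive")
  if (any(mean_stance_force < 0)) stop("'mean_stance_force' must be non-negative")
  mean_stance_force / stride_length
}

#' Mediolateral CoP offset from the foot centre of mass at peak force
#'
#' Difference between the mediolateral CoP position and the foot
#' centre-of-mass position at the instant of peak medial contact force;
#' positive values mean the CoP lies lateral to the foot centre of mass.
#'
#' @param cop_ml Numeric vector, mediolateral CoP position in mm
#'   (positive lateral).
#' @param foot_com_ml Numeric vector of the same length, mediolateral
#'   foot centre-of-mass position in mm.
#' @param peak_index Sample index of peak medial contact force.
#' @return Offset in mm.
#' @export
cop_offset_at_peak <- function(cop_ml, foot_com_ml, peak_index) {
  if (length(cop_ml) != length(foot_com_ml))
    stop("'cop_ml' and 'foot_com_ml' must be aligned (equal length)")
  if (peak_index < 1 || peak_index > length(cop_ml))
    stop("'peak_index' out of range")
  cop_ml[peak_index] - foot_com_ml[peak_index]
}

#' Convert a force in multiples of body weight to newtons
#'
#' @param force_bw Force in BW.
#' @param body_mass_kg Body mass in kg.
#' @param gravity Gravitational acceleration in m/s^2 (default 9.81).
#' @return Force in N.
#' @export
bw_to_newtons <- function(force_bw, body_mass_kg, gravity = 9.81) {
  force_bw * body_mass_kg * gravity
}
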