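#' Center of pressure of a pressure-grid frame
#'
#' The COP is the pressure-weighted centroid of the sensel coordinates,
#' `cop = sum(p_i * (x_i, y_i)) / sum(p_i)`. A frame with no positive pressure
#' has no COP and is returned as `NA` (flag the sample invalid downstream).
#'
#' @param pressure non-negative sensel pressures for one frame, or a
#'   frames-by-sensels matrix.
#' @param sensel_x,sensel_y sensel coordinates in mm (foot frame: x
#'   mediolateral, y anteroposterior).
#' @return For a vector frame, `c(cop_x, cop_y)`; for a matrix, a two-column
#'   matrix with one row per frame.
#' @examples
#' compute_cop(c(1, 1), sensel_x = c(0, 10), sensel_y = c(0, 0))  # 5, 0
#' @export
compute_cop <- function(pressure, sensel_x, sensel_y) {
  if (is.matrix(pressure)) {
    tot <- rowSums(pressure)
    cx <- as.vector(pressure %*% sensel_x) / tot
    cy <- as.vector(pressure %*% sensel_y) / tot
    cx[tot <= 0] <- NA_real_
    cy[tot <= 0] <- NA_real_
    return(cbind(cop_x = cx, cop_y = cy))
  }
  tot <- sum(pressure)
  if (tot <= 0) return(c(cop_x = NA_real_, cop_y = NA_real_))
  c(cop_x = sum(pressure * sensel_x) / tot,
    cop_y = sum(pressure * sensel_y) / tot)
}

#' Per-foot COP validity from the 5% ground-reaction-force rule
#'
#' A foot's COP at a sample is valid only when that foot carries more than
#' `threshold` (default 5%) of the two-foot total ground reaction force;
#' residual pressure during swing otherwise produces erroneous COP positions.
#' When both feet read zero force, both are invalid. The rule is
#' scale-invariant in the forces.
#'
#' @param left_force,right_force non-negative per-sample forces.
#' @param threshold fraction of total force a foot must exceed (strict `>`).
#' @return list with logical vectors `left` and `right`.
#' @export
validity_mask <- function(left_force, right_force, threshold = 0.05) {
  tot <- left_force + right_force
  list(left = left_force > threshold * tot & tot > 0,
       right = right_force > threshold * tot & tot > 0)
}

#' Bridge invalid spans of a series
#'
#' Interior invalid runs are linearly interpolated between the flanking valid
#' samples; leading/trailing invalid runs are held at the nearest valid value.
#' The validity mask itself is unchanged and should be carried alongside the
#' filled series.
#'
#' @param x numeric series.
#' @param valid logical mask, same length.
#' @return numeric series with every sample defined.
#' @export
fill_invalid <- function(x, valid) {
  if (!any(valid)) stop("cannot fill a fully invalid series")
  if (all(valid)) return(x)
  idx <- which(valid)
  stats::approx(idx, x[idx], xout = seq_along(x), method = "linear",
                rule = 2)$y
}

#' First derivative of a COP series
#'
#' Central differences in the interior (`(x[i+1] - x[i-1]) * fs / 2`),
#' one-sided differences at the two ends. Exact for linear series; identically
#' zero for constants.
#'
#' @param x numeric series (mm), gaps already filled.
#' @param fs sampling rate (Hz).
#' @return velocity series (mm/s), same length.
#' @export
cop_velocity <- function(x, fs = 100) {
  n <- length(x)
  if (n < 3L) stop("cop_velocity needs at least 3 samples")
  v <- numeric(n)
  v[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * fs / 2
  v[1] <- (x[2] - x[1]) * fs
  v[n] <- (x[n] - x[n - 1]) * fs
  v
}

#' COP kinematics for one trial
#'
#' Applies the force-validity rule, derives per-foot COP from pressure grids
#' where needed, fills invalid spans, and differentiates position to velocity.
#' This is the per-trial preprocessing step ahead of window feature extraction.
#'
#' @param trial a `fog_trial` (signal or grid form).
#' @param threshold validity-rule force fraction.
#' @return list with elements `left` and `right`, each a list
#'   `(cop_x, cop_y, vel_x, vel_y, valid)`.
#' @export
prepare_cop <- function(trial, threshold = 0.05) {
  sides <- lapply(list(left = trial$left, right = trial$right), function(side) {
    if (!is.null(side$pressure)) {
      cop <- compute_cop(side$pressure, side$sensel_x, side$sensel_y)
      list(force = rowSums(side$pressure), cop_x = cop[, 1], cop_y = cop[, 2])
    } else {
      side
    }
  })
  mask <- validity_mask(sides$left$force, sides$right$force, threshold)
  out <- lapply(c(left = "left", right = "right"), function(nm) {
    s <- sides[[nm]]
    ok <- mask[[nm]] & !is.na(s$cop_x) & !is.na(s$cop_y)
    if (!any(ok)) {
      ## foot never validly loaded: zero series, all-invalid mask carried on
      z <- numeric(length(ok))
      return(list(cop_x = z, cop_y = z, vel_x = z, vel_y = z, valid = ok))
    }
    x <- fill_invalid(s$cop_x, ok)
    y <- fill_invalid(s$cop_y, ok)
    list(cop_x = x, cop_y = y,
         vel_x = cop_velocity(x, trial$fs), vel_y = cop_velocity(y, trial$fs),
         valid = ok)
  })
  out
}
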