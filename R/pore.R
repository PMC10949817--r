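# run fn() with a private RNG stream; the caller's RNG state is untouched
.with_seed <- function(seed, fn) {
  if (is.null(seed)) return(fn())
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

# clearance of a probe centre c = (x, y) in the plane z = zs:
# min over atoms of (3D distance to atom centre - vdW radius)
.clearance <- function(cxy, zs, axyz, rvdw) {
  d <- sqrt((axyz[, 1] - cxy[1])^2 + (axyz[, 2] - cxy[2])^2 +
              (axyz[, 3] - zs)^2)
  min(d - rvdw)
}

# rotation taking unit vector v onto +z
.axis_rotation <- function(v) {
  v <- v / sqrt(sum(v^2))
  z <- c(0, 0, 1)
  if (sum((v - z)^2) < 1e-12) return(diag(3))
  if (sum((v + z)^2) < 1e-12) return(diag(c(1, -1, -1)))
  a <- c(v[2] * z[3] - v[3] * z[2], v[3] * z[1] - v[1] * z[3],
         v[1] * z[2] - v[2] * z[1])
  s <- sqrt(sum(a^2)); c0 <- sum(v * z)
  ax <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) + ax + ax %*% ax * ((1 - c0) / s^2)
}

#' Water-accessible pore profile of one frame
#'
#' For each position z along the channel axis, finds the largest sphere
#' centred in the plane z that touches no heavy-atom van der Waals
#' surface: the radius is the maximum over in-plane centres of the
#' minimum atom clearance. The maximization uses Nelder-Mead local
#' search from the previous slice's optimum plus jittered restarts,
#' which tracks the pore centre line through a channel the way a
#' sphere-chain pore profiler does. Radii are clamped at \code{r_max};
#' a slice whose optimum reaches \code{r_max} (or that has no atoms in
#' reach) is flagged unbounded and excluded from the minimum-diameter
#' summary. Hydrogens are ignored throughout (hard-sphere heavy-atom
#' model).
#'
#' @param frame a \code{\link{gj_structure}}.
#' @param axis channel axis direction (default +z; other axes are
#'   handled by rotating the frame).
#' @param z_range length-2 axial interval to sample; default the atom
#'   extent along the axis.
#' @param step slice spacing in Angstrom (default 0.5).
#' @param r_max radius clamp in Angstrom (default 15).
#' @param n_starts number of jittered restarts per slice (default 8, on
#'   top of the previous-slice start).
#' @param seed integer seed fixing the restart jitter; the same seed
#'   reproduces the profile bit for bit.
#' @param window optional length-2 axial interval (for example the
#'   extracellular region) over which a second, region-restricted
#'   minimum diameter is reported.
#' @param params \code{\link{analysis_parameters}} (radius table).
#' @return An object of class \code{"gj_pore_profile"}: list with
#'   \code{samples} (data.frame z, radius, cx, cy, unbounded),
#'   \code{min_diameter} (Angstrom, over bounded samples),
#'   \code{z_at_min}, and \code{min_diameter_window} when a window was
#'   given.
#' @export
pore_profile <- function(frame, axis = c(0, 0, 1), z_range = NULL,
                         step = 0.5, r_max = 15, n_starts = 8L, seed = NULL,
                         window = NULL, params = analysis_parameters()) {
  if (step <= 0) stop("step must be > 0", call. = FALSE)
  a <- frame$atoms[!frame$atoms$is_hydrogen, , drop = FALSE]
  if (!nrow(a)) stop("frame has no heavy atoms", call. = FALSE)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  R <- .axis_rotation(as.numeric(axis))
  if (!identical(R, diag(3))) xyz <- xyz %*% t(R)
  rvdw <- vdw_radius(a$element, params$vdw_radii)
  if (is.null(z_range)) z_range <- range(xyz[, 3])
  zs <- seq(z_range[1], z_range[2], by = step)
  reach <- r_max + max(rvdw)

  res <- .with_seed(seed, function() {
    prev <- NULL
    out <- matrix(NA_real_, length(zs), 4L)
    for (si in seq_along(zs)) {
      z0 <- zs[si]
      near <- abs(xyz[, 3] - z0) <= reach
      if (!any(near)) {
        out[si, ] <- c(z0, r_max, NA, NA)  # unbounded: nothing in reach
        next
      }
      sub <- xyz[near, , drop = FALSE]; rs <- rvdw[near]
      slab <- abs(sub[, 3] - z0) <= 6
      c0 <- if (any(slab)) colMeans(sub[slab, 1:2, drop = FALSE]) else
        colMeans(sub[, 1:2, drop = FALSE])
      starts <- rbind(if (!is.null(prev)) prev, c0)
      starts <- rbind(starts,
                      sweep(matrix(stats::runif(2L * n_starts, -2, 2),
                                   ncol = 2L), 2, c0, "+"))
      best <- -Inf; bxy <- c(NA, NA)
      for (k in seq_len(nrow(starts))) {
        o <- stats::optim(starts[k, ], function(p)
          -.clearance(p, z0, sub, rs), method = "Nelder-Mead",
          control = list(reltol = 1e-10, maxit = 400))
        val <- -o$value
        if (val > best) { best <- val; bxy <- o$par }
      }
      out[si, ] <- c(z0, max(best, 0), bxy)
      prev <- bxy
    }
    out
  })

  samples <- data.frame(z = res[, 1],
                        radius = pmin(res[, 2], r_max),
                        cx = res[, 3], cy = res[, 4])
  samples$unbounded <- res[, 2] >= r_max
  bounded <- samples[!samples$unbounded, , drop = FALSE]
  min_d <- if (nrow(bounded)) 2 * min(bounded$radius) else NA_real_
  z_min <- if (nrow(bounded)) bounded$z[which.min(bounded$radius)] else NA_real_
  prof <- list(samples = samples, axis = as.numeric(axis), step = step,
               r_max = r_max, min_diameter = min_d, z_at_min = z_min)
  if (!is.null(window)) {
    inw <- bounded[bounded$z >= window[1] & bounded$z <= window[2], ,
                   drop = FALSE]
    prof$window <- as.numeric(window)
    prof$min_diameter_window <- if (nrow(inw)) 2 * min(inw$radius) else NA_real_
  }
  class(prof) <- "gj_pore_profile"
  prof
}

#' @export
print.gj_pore_profile <- function(x, ...) {
  cat("<gj_pore_profile> ", nrow(x$samples), " slices, min diameter ",
      format(x$min_diameter, digits = 4), " A at z = ",
      format(x$z_at_min, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Axial window spanned by the extracellular loops
#'
#' @param frame a \code{\link{gj_structure}}.
#' @param annotation \code{\link{connexin_annotation}}.
#' @return Length-2 z interval covered by EL1/EL2 residues.
#' @export
extracellular_window <- function(frame, annotation = connexin_annotation()) {
  sel <- select_atoms(frame, resno = extracellular_residues(annotation),
                      heavy = TRUE)
  if (n_atoms(sel) == 0L)
    stop("frame has no extracellular-loop residues", call. = FALSE)
  range(sel$atoms$z)
}

#' Minimum channel diameter per frame
#'
#' Profiles every frame and reports the minimal pore diameter overall
#' and within a region window (by default the axial span of the
#' extracellular loops, recomputed per frame).
#'
#' @inheritParams pore_profile
#' @param trajectory a \code{\link{gj_trajectory}}.
#' @param window length-2 axial interval, or \code{"extracellular"} to
#'   use the EL1/EL2 span of each frame.
#' @param annotation used for the extracellular window.
#' @param stride analyse every \code{stride}-th frame.
#' @return data.frame: frame, time_ps, min_diameter, min_diameter_window,
#'   z_at_min.
#' @export
min_diameter_series <- function(trajectory, axis = c(0, 0, 1),
                                z_range = NULL, step = 0.5, r_max = 15,
                                window = "extracellular", seed = NULL,
                                annotation = connexin_annotation(),
                                params = analysis_parameters(), stride = 1L) {
  frames <- seq(1L, n_frames(trajectory), by = stride)
  out <- data.frame(frame = frames,
                    time_ps = frames * trajectory$frame_interval_ps,
                    min_diameter = NA_real_, min_diameter_window = NA_real_,
                    z_at_min = NA_real_)
  for (fi in seq_along(frames)) {
    s <- frame_structure(trajectory, frames[fi])
    w <- if (identical(window, "extracellular"))
      extracellular_window(s, annotation) else window
    pr <- pore_profile(s, axis = axis, z_range = z_range, step = step,
                       r_max = r_max,
                       seed = if (is.null(seed)) NULL else seed + frames[fi],
                       window = w, params = params)
    out$min_diameter[fi] <- pr$min_diameter
    out$min_diameter_window[fi] <- pr$min_diameter_window
    out$z_at_min[fi] <- pr$z_at_min
  }
  out
}
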