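# Quantitative autoradiography densitometry: film calibration against
# radioactive standards, Kety one-compartment CBF from tracer uptake,
# projective alignment/down-sampling to the MR grid, immunohistochemistry
# positive-pixel area fraction, and ROI statistics.

#' Calibration standards for autoradiography film
#'
#' @param activity known standard activities, µCi/g, strictly increasing
#'   (typically spanning 0-35 µCi/g).
#' @param reading corresponding film/scanner readings, monotone in activity.
#' @export
calibration_standards <- function(activity, reading) {
  if (length(activity) < 3) stop("need at least 3 standards")
  if (is.unsorted(activity, strictly = TRUE))
    stop("activities must be strictly increasing")
  dr <- diff(reading)
  if (!(all(dr > 0) || all(dr < 0)))
    stop("readings must be monotone in activity")
  structure(list(activity = activity, reading = reading,
                 increasing = all(dr > 0)),
            class = "calibration_standards")
}

#' Fit a monotone reading-to-activity calibration
#'
#' Shape-preserving monotone interpolation (Fritsch-Carlson, as in
#' `splinefun(method = "monoH.FC")`) of activity against reading; exact at
#' the standards. Readings outside the calibrated range are mapped to the
#' nearest end and flagged.
#'
#' @param standards a [calibration_standards()].
#' @return a function `f(reading)` returning activities with an
#'   `extrapolated` logical attribute.
#' @export
fit_calibration <- function(standards) {
  stopifnot(inherits(standards, "calibration_standards"))
  r <- standards$reading; a <- standards$activity
  if (!standards$increasing) { r <- rev(r); a <- rev(a) }
  sf <- stats::splinefun(r, a, method = "monoH.FC")
  lo <- min(r); hi <- max(r)
  function(reading) {
    extrap <- !is.na(reading) & (reading < lo | reading > hi)
    x <- pmin(pmax(reading, lo), hi)
    out <- sf(x)
    attr(out, "extrapolated") <- extrap
    out
  }
}

#' Convert a film scan to an activity map
#'
#' @param film image array of scanner readings.
#' @param calibration mapping from [fit_calibration()].
#' @param background scalar background reading to subtract (>= 0).
#' @return activity map, µCi/g, clamped at 0; attribute `flagged` marks
#'   pixels negative after background subtraction.
#' @export
quantify_activity <- function(film, calibration, background = 0) {
  if (background < 0) stop("background must be non-negative")
  x <- film - background
  flagged <- x < 0
  x[flagged] <- 0
  act <- calibration(x)
  act <- pmax(act, 0)
  out <- array(as.numeric(act), dim(film))
  attr(out, "flagged") <- flagged
  attr(out, "extrapolated") <- array(attr(act, "extrapolated"), dim(film))
  out
}

# integral of Ca(t) * exp(-K (T - t)) dt over [0, T] for a linear ramp
# Ca(t) = (caT / T) * t  (closed form)
.kety_uptake <- function(K, caT, T) {
  c0 <- caT / T
  if (K < 1e-12) return(K * c0 * T^2 / 2)  # -> 0 as K -> 0
  K * c0 * (T / K - (1 - exp(-K * T)) / K^2)
}

#' Kety one-compartment CBF from tissue tracer uptake
#'
#' Solves the operational equation
#' \deqn{C_i(T) = K \int_0^T C_a(t) e^{-K(T-t)} dt}
#' for the clearance constant `K` (monotone scalar root-find), with the
#' arterial input reconstructed as a linear ramp from 0 to the terminal
#' sample `ca_T` over the exposure time, or from supplied samples. CBF is
#' `f = K * lam * 6000` in mL/100 g/min.
#'
#' @param ci_T tissue activity at end of exposure, µCi/g (vectorised).
#' @param ca_T terminal arterial concentration, µCi/mL.
#' @param exposure_T tracer circulation time, seconds (default 120).
#' @param lam tissue-blood partition coefficient of iodoantipyrine, mL/g
#'   (default 0.8).
#' @param input arterial input shape; only `"linear_ramp"` is built in, or
#'   pass a function `Ca(t)` for a custom shape (integrated numerically).
#' @return CBF, mL/100 g/min.
#' @export
kety_cbf <- function(ci_T, ca_T, exposure_T = 120, lam = 0.8,
                     input = "linear_ramp") {
  if (ca_T < 0 || exposure_T <= 0) stop("invalid arterial input")
  if (any(ci_T < 0, na.rm = TRUE)) stop("tissue activity must be >= 0")
  uptake <- if (is.function(input)) {
    function(K) {
      if (K < 1e-12) return(0)
      K * stats::integrate(function(t) input(t) * exp(-K * (exposure_T - t)),
                           0, exposure_T, rel.tol = 1e-10)$value
    }
  } else {
    match.arg(input, "linear_ramp")
    function(K) .kety_uptake(K, ca_T, exposure_T)
  }
  k_max <- 50 / exposure_T * 120   # generous upper bound on clearance
  ci_max <- uptake(k_max)
  one <- function(ci) {
    if (is.na(ci)) return(NA_real_)
    if (ci == 0) return(0)
    if (ci >= ci_max)
      stop("tissue activity exceeds the model maximum: unphysical input")
    K <- stats::uniroot(function(K) uptake(K) - ci, c(0, k_max),
                        tol = 1e-12)$root
    K * lam * 6000
  }
  vapply(ci_T, one, numeric(1))
}

#' Forward Kety uptake for a given CBF
#'
#' Convenience inverse of [kety_cbf()] for simulation and round-trip checks.
#'
#' @param f CBF, mL/100 g/min.
#' @inheritParams kety_cbf
#' @return tissue activity at the end of exposure, µCi/g.
#' @export
kety_forward <- function(f, ca_T, exposure_T = 120, lam = 0.8) {
  K <- f / (lam * 6000)
  vapply(K, .kety_uptake, numeric(1), caT = ca_T, T = exposure_T)
}

# homography from >= 4 control point pairs (DLT, normalised)
.fit_homography <- function(src, dst) {
  stopifnot(nrow(src) >= 4, all(dim(src) == dim(dst)))
  n <- nrow(src)
  A <- matrix(0, 2 * n, 9)
  for (i in seq_len(n)) {
    x <- src[i, 1]; y <- src[i, 2]; u <- dst[i, 1]; v <- dst[i, 2]
    A[2 * i - 1, ] <- c(-x, -y, -1, 0, 0, 0, u * x, u * y, u)
    A[2 * i, ] <- c(0, 0, 0, -x, -y, -1, v * x, v * y, v)
  }
  sv <- svd(A, nv = 9)
  # a (near) two-dimensional null space means the points do not determine a
  # unique homography (collinear / repeated control points)
  if (sv$d[8] < 1e-8 * sv$d[1]) stop("degenerate control points")
  h <- sv$v[, 9]
  H <- matrix(h, 3, 3, byrow = TRUE)
  if (abs(H[3, 3]) < 1e-12) stop("degenerate control points")
  H / H[3, 3]
}

.apply_homography <- function(H, pts) {
  p <- cbind(pts, 1) %*% t(H)
  w <- p[, 3]
  if (any(abs(w) < 1e-12)) stop("degenerate projective mapping")
  cbind(p[, 1] / w, p[, 2] / w)
}

# bilinear sampling with NA outside
.bilinear <- function(img, x, y) {
  nx <- nrow(img); ny <- ncol(img)
  eps <- 1e-6   # snap warp coordinates that graze the image border
  x[x > nx & x < nx + eps] <- nx; x[x < 1 & x > 1 - eps] <- 1
  y[y > ny & y < ny + eps] <- ny; y[y < 1 & y > 1 - eps] <- 1
  x0 <- pmin(floor(x), nx - 1); y0 <- pmin(floor(y), ny - 1)
  fx <- x - x0; fy <- y - y0
  ok <- x >= 1 & y >= 1 & x <= nx & y <= ny
  out <- rep(NA_real_, length(x))
  i <- which(ok)
  g <- function(dx, dy) img[cbind(x0[i] + dx, y0[i] + dy)]
  out[i] <- g(0, 0) * (1 - fx[i]) * (1 - fy[i]) +
    g(1, 0) * fx[i] * (1 - fy[i]) +
    g(0, 1) * (1 - fx[i]) * fy[i] + g(1, 1) * fx[i] * fy[i]
  out
}

#' Projective alignment and block-mean down-sampling to the MR grid
#'
#' Fits a homography from control-point pairs (film pixel coordinates to
#' MR-frame coordinates on the film-resolution grid), inverse-warps the film
#' with bilinear interpolation, then block-averages down to the target grid
#' (64 x 64 by default).
#'
#' @param film image array (film-resolution readings or activities).
#' @param control_src,control_dst n x 2 matrices of >= 4 matching points
#'   (source on the film, destination in the MR-aligned frame, film-pixel
#'   units).
#' @param target target grid size, length 2 (default `c(64, 64)`).
#' @return list with `aligned` (target-grid map) and `H` (3 x 3 homography).
#' @export
align_downsample <- function(film, control_src, control_dst,
                             target = c(64, 64)) {
  H <- .fit_homography(as.matrix(control_dst), as.matrix(control_src))
  d <- dim(film)
  grid <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]))
  src <- .apply_homography(H, as.matrix(grid))
  warped <- array(.bilinear(film, src[, 1], src[, 2]), d)
  # block mean to the target grid (NA pixels carry no weight)
  bx <- d[1] / target[1]; by <- d[2] / target[2]
  gx <- pmin(floor((seq_len(d[1]) - 1) / bx) + 1, target[1])
  gy <- pmin(floor((seq_len(d[2]) - 1) / by) + 1, target[2])
  cell <- rep(gx, times = d[2]) + (rep(gy, each = d[1]) - 1) * target[1]
  vals <- as.numeric(warped)
  ok <- !is.na(vals)
  sums <- rowsum(vals[ok], cell[ok])
  cnts <- rowsum(rep(1, sum(ok)), cell[ok])
  out <- matrix(NA_real_, target[1], target[2])
  out[as.integer(rownames(sums))] <- sums / cnts
  list(aligned = out, H = H)
}

#' Positive-pixel area fraction of a stained section
#'
#' Fraction of analysed pixels whose intensity lies in the moderate range or
#' below the strong threshold, as a percentage (the two classes are disjoint
#' by construction of the thresholds).
#'
#' @param ihc grayscale image array (e.g. 0-255).
#' @param moderate_range length-2 intensity bounds, inclusive (default
#'   `c(185, 202)`).
#' @param strong_max strong-staining upper bound, exclusive (default 10).
#' @param region optional logical mask of the analysed area.
#' @return percentage in `[0, 100]` with attributes `moderate` and `strong`
#'   (component percentages).
#' @export
positive_pixel_fraction <- function(ihc, moderate_range = c(185, 202),
                                    strong_max = 10, region = NULL) {
  if (is.null(region)) region <- array(TRUE, dim(ihc))
  region <- as_mask(region, dim(ihc))
  if (!any(region)) stop("empty analysis region")
  v <- ihc[region]
  lo <- min(moderate_range); hi <- max(moderate_range)
  mod <- v >= lo & v <= hi
  strong <- v < strong_max
  if (strong_max > lo)
    mod <- mod & !strong  # guard against overlapping thresholds
  pct <- 100 * mean(mod | strong)
  structure(pct, moderate = 100 * mean(mod), strong = 100 * mean(strong))
}

#' Paired ROI statistics between two maps
#'
#' Per ROI: mean and SD of each map, a two-tailed (paired or unpaired)
#' t-test, a variance-ratio F-test, and Bonferroni adjustment of the t-test
#' p-values across ROIs.
#'
#' @param map_a,map_b numeric arrays on the same grid.
#' @param rois named list of logical masks.
#' @param paired logical; voxelwise pairing (default TRUE).
#' @return data.frame, one row per ROI.
#' @export
roi_stats <- function(map_a, map_b, rois, paired = TRUE) {
  stopifnot(identical(dim(map_a), dim(map_b)))
  if (!is.list(rois)) rois <- list(roi = rois)
  rows <- lapply(seq_along(rois), function(i) {
    m <- as_mask(rois[[i]], dim(map_a))
    a <- map_a[m]; b <- map_b[m]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2 || length(b) < 2)
      stop("need >= 2 observations per group")
    do_pair <- paired && length(a) == length(b)
    degen <- if (do_pair) stats::sd(a - b) == 0
             else stats::var(a) == 0 && stats::var(b) == 0
    tt <- if (degen && isTRUE(all.equal(mean(a), mean(b))))
      list(statistic = 0, p.value = 1)
    else if (degen)
      list(statistic = Inf * sign(mean(a) - mean(b)), p.value = 0)
    else stats::t.test(a, b, paired = do_pair)
    if (stats::var(b) == 0) stop("zero variance in F-test denominator")
    ft <- stats::var.test(a, b)
    data.frame(roi = names(rois)[i] %||% paste0("roi", i), n = length(a),
               mean_a = mean(a), sd_a = stats::sd(a), mean_b = mean(b),
               sd_b = stats::sd(b), t = unname(tt$statistic),
               p = tt$p.value, f = unname(ft$statistic),
               f_p = ft$p.value)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(out$p * nrow(out), 1)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
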