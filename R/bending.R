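#' Support span from total bone length
#'
#' Three-point-bending support-to-support distance: half the total tibial
#' length.
#'
#' @param L_total total tibial length, mm.
#' @return span, mm.
#' @export
span_from_length <- function(L_total) {
  if (!(L_total > 0)) stop("span_from_length: L_total must be positive")
  0.5 * L_total
}

#' Linear stiffness of a bending curve
#'
#' Least-squares slope of force on displacement over the ascending segment
#' between \code{lower} and \code{upper} fractions of the ultimate force.
#' When the specimen yields below \code{upper} x F_ult, a plain
#' force-fraction window would straddle the knee and dilute the slope, so
#' the window is truncated at the first sustained tangent-slope loss (a
#' 5-sample local slope falling below \code{trunc} of the running maximum);
#' on a curve that is linear throughout this leaves the window untouched.
#'
#' @param curve a \code{\link{force_displacement_curve}}.
#' @param lower,upper window bounds as fractions of F_ult.
#' @param trunc slope fraction that ends the elastic window.
#' @return k in N/mm; the fit window indices are attached as an attribute.
#' @export
stiffness <- function(curve, lower = 0.2, upper = 0.8, trunc = 0.9) {
  f <- curve$force_N; d <- curve$displacement_mm
  ipeak <- which.max(f)
  fult <- f[ipeak]
  win <- which(seq_along(f) <= ipeak & f >= lower * fult & f <= upper * fult)
  if (length(win) < 3)
    stop("stiffness: fewer than 3 samples in the ", lower, "-", upper,
         " F_ult window")
  dw <- d[win]; fw <- f[win]; m <- length(win)
  fit <- function(idx) {
    cf <- coef(lm(fw[idx] ~ dw[idx]))
    list(slope = as.numeric(cf[2]),
         sse = sum((fw[idx] - cf[1] - cf[2] * dw[idx])^2))
  }
  full <- fit(seq_len(m))
  k <- full$slope; kwin <- win
  if (m >= 6) {
    # two-segment changepoint search: if the window straddles the yield
    # knee, the first segment's slope is the elastic stiffness
    best <- NULL
    for (j in 3:(m - 3)) {
      a <- fit(1:j); b <- fit((j + 1):m)
      if (is.null(best) || a$sse + b$sse < best$sse)
        best <- list(sse = a$sse + b$sse, j = j, s1 = a$slope, s2 = b$slope)
    }
    if (!is.null(best) && is.finite(best$s2) &&
        best$s2 < trunc * best$s1 && best$sse < 0.5 * full$sse) {
      k <- best$s1
      kwin <- win[1:best$j]
    }
  }
  attr(k, "window") <- range(kwin)
  k
}

#' Yield point by tangent-stiffness loss
#'
#' The yield point is the first sample, after the start of the stiffness fit
#' window, where the smoothed local tangent slope (centred least-squares
#' over \code{smooth} samples) drops below \code{threshold} times the linear
#' stiffness; the returned point interpolates between the bracketing
#' samples. A curve that stays linear to fracture yields at the ultimate
#' point. (An offset criterion would need strain, which a force-displacement
#' record lacks; the 10 percent tangent-loss threshold is configurable.)
#'
#' @param curve a \code{\link{force_displacement_curve}}.
#' @param k linear stiffness from \code{\link{stiffness}}.
#' @param threshold tangent-slope fraction of k defining yield.
#' @param smooth odd window length for the local slope.
#' @return list(F_y, d_y).
#' @export
yield_point <- function(curve, k, threshold = 0.9, smooth = 5) {
  f <- curve$force_N; d <- curve$displacement_mm
  ipeak <- which.max(f)
  start <- attr(k, "window")[1]
  if (is.null(start)) start <- 2L
  h <- smooth %/% 2
  n <- length(f)
  slope_at <- function(i) {
    w <- max(1, i - h):min(n, i + h)
    if (diff(range(d[w])) == 0) return(Inf)
    as.numeric(coef(lm(f[w] ~ d[w]))[2])
  }
  for (i in seq(max(start, h + 1), ipeak)) {
    s <- slope_at(i)
    if (s < threshold * as.numeric(k)) {
      # refine: intersect the elastic line (through the fit window) with a
      # local post-knee line; for a bilinear curve this recovers the knee
      # exactly, since the smoothed-slope criterion fires half a window
      # early by construction
      el_win <- max(1, i - 4 * h):max(1, i - 2 * h)
      el <- coef(lm(f[el_win] ~ d[el_win]))
      py_win <- min(ipeak, i + h):min(ipeak, i + 3 * h)
      if (length(unique(d[py_win])) >= 2) {
        py <- coef(lm(f[py_win] ~ d[py_win]))
        if (abs(el[2] - py[2]) > 1e-9) {
          d_y <- as.numeric((py[1] - el[1]) / (el[2] - py[2]))
          d_y <- min(max(d_y, d[max(1, i - 2 * h)]), d[min(ipeak, i + h)])
          return(list(F_y = as.numeric(el[1] + el[2] * d_y), d_y = d_y))
        }
      }
      d_y <- d[i]
      return(list(F_y = approx(d, f, xout = d_y, ties = "ordered")$y, d_y = d_y))
    }
  }
  list(F_y = f[ipeak], d_y = d[ipeak])  # no knee: linear to fracture
}

#' Ultimate force and failure displacement
#'
#' F_ult is the curve maximum; failure is the first post-peak sample whose
#' force falls to half the peak or below, else the last sample.
#'
#' @param curve a \code{\link{force_displacement_curve}}.
#' @return list(F_ult, d_ult, d_fail).
#' @export
ultimate_and_failure <- function(curve) {
  f <- curve$force_N; d <- curve$displacement_mm
  ipeak <- which.max(f)
  fult <- f[ipeak]
  after <- which(seq_along(f) > ipeak & f <= 0.5 * fult)
  ifail <- if (length(after)) after[1] else length(f)
  list(F_ult = fult, d_ult = d[ipeak], d_fail = d[ifail])
}

#' Work and post-yield quantities
#'
#' Trapezoidal integrals of force over displacement up to yield and failure
#' (N.mm = mJ); post-yield displacement and energy follow by difference.
#'
#' @param curve a \code{\link{force_displacement_curve}}.
#' @param yield list(F_y, d_y) from \code{\link{yield_point}}.
#' @param failure list from \code{\link{ultimate_and_failure}}.
#' @return list(W_y, W_fail, PYD, PYE), mJ and mm.
#' @export
works_and_postyield <- function(curve, yield, failure) {
  f <- curve$force_N; d <- curve$displacement_mm
  integrate_to <- function(dmax) {
    keep <- d < dmax
    dd <- c(d[keep], dmax)
    ff <- c(f[keep], approx(d, f, xout = dmax, ties = "ordered")$y)
    sum(diff(dd) * (head(ff, -1) + tail(ff, -1)) / 2)
  }
  W_y <- integrate_to(yield$d_y)
  W_fail <- integrate_to(failure$d_fail)
  list(W_y = W_y, W_fail = W_fail,
       PYD = failure$d_fail - yield$d_y, PYE = W_fail - W_y)
}

#' Young's modulus from bending stiffness
#'
#' Euler-Bernoulli three-point bending: E = k L^3 / (48 I), converted to
#' GPa (k in N/mm, L in mm, I in mm^4).
#'
#' @param k stiffness, N/mm.
#' @param L_span support span, mm.
#' @param I cross-sectional second moment of area about the bending axis,
#'   mm^4.
#' @return E in GPa.
#' @export
youngs_modulus <- function(k, L_span, I) {
  if (!(I > 0)) stop("youngs_modulus: I must be positive")
  as.numeric(k) * L_span^3 / (48 * I) / 1000  # N/mm^2 = MPa -> GPa
}

#' Outer-fibre bending stress
#'
#' sigma = F L c / (4 I) for a centre load: F in N, span L and
#' centroid-to-outermost-point distance c in mm, I in mm^4, giving MPa.
#'
#' @param F force, N.
#' @param c_max centroid to outermost periosteal point, mm.
#' @param L_span span, mm.
#' @param I second moment of area, mm^4.
#' @return stress, MPa.
#' @export
bending_stress <- function(F, c_max, L_span, I) {
  if (!(I > 0)) stop("bending_stress: I must be positive")
  F * L_span * c_max / (4 * I)
}

#' Elastic energy density to yield
#'
#' Resilience = sigma_y^2 / (2 E), with sigma_y in MPa and E in GPa
#' (normalised to MPa internally), giving MPa.
#'
#' @param sigma_y yield stress, MPa.
#' @param E Young's modulus, GPa.
#' @return resilience, MPa.
#' @export
resilience <- function(sigma_y, E) {
  if (!(E > 0)) stop("resilience: E must be positive")
  sigma_y^2 / (2 * E * 1000)
}

#' Energy density to fracture from bending work
#'
#' Toughness = 0.75 W b^2 / (L I): with W the work to failure (mJ = N.mm),
#' b the anteroposterior section width (mm), L the span (mm) and I the
#' second moment of area (mm^4) this is dimensionally a stress (MPa) and
#' equals the beam-theory identity 3 U c^2 / (L I) with c = b/2.
#'
#' @param W_fail work to failure, mJ.
#' @param b_ap anteroposterior width of the mid-diaphysis section, mm.
#' @param L_span span, mm.
#' @param I second moment of area, mm^4.
#' @return toughness, MPa.
#' @export
toughness <- function(W_fail, b_ap, L_span, I) {
  if (!(I > 0)) stop("toughness: I must be positive")
  0.75 * W_fail * b_ap^2 / (L_span * I)
}

#' Outer-fibre strain from mid-span deflection
#'
#' Geometric beam strain epsilon = 12 c d / L^2, reported in microstrain;
#' at yield the elastic estimate sigma_y / E agrees with it on an ideal
#' beam and is returned alongside when stress and modulus are supplied.
#'
#' @param d mid-span displacement, mm.
#' @param c_max outer-fibre distance, mm.
#' @param L_span span, mm.
#' @param sigma optional stress at d, MPa.
#' @param E optional modulus, GPa.
#' @return list(geometric, elastic) in microstrain (elastic NA if sigma/E
#'   missing).
#' @export
bending_strains <- function(d, c_max, L_span, sigma = NULL, E = NULL) {
  geometric <- 12 * c_max * d / L_span^2 * 1e6
  elastic <- if (!is.null(sigma) && !is.null(E)) sigma / (E * 1000) * 1e6
             else NA_real_
  list(geometric = geometric, elastic = elastic)
}

#' Full property set of a three-point-bending test
#'
#' Runs the whole chain - stiffness, yield, ultimate/failure, works,
#' modulus, stresses, resilience, toughness, strains - from a curve plus
#' mid-diaphysis section geometry.
#'
#' @param curve a \code{\link{force_displacement_curve}}.
#' @param L_span support span, mm (see \code{\link{span_from_length}}).
#' @param I second moment of area about the bending axis, mm^4.
#' @param c_max centroid-to-outermost-point distance, mm.
#' @param b_ap anteroposterior section width, mm.
#' @param yield_threshold,stiffness_window tuning of the yield criterion and
#'   stiffness fit window.
#' @return \code{bending_result}: named list of all Table-style properties.
#' @export
analyze_bending_curve <- function(curve, L_span, I, c_max, b_ap,
                                  yield_threshold = 0.9,
                                  stiffness_window = c(0.2, 0.8)) {
  k <- stiffness(curve, stiffness_window[1], stiffness_window[2])
  yld <- yield_point(curve, k, threshold = yield_threshold)
  fail <- ultimate_and_failure(curve)
  works <- works_and_postyield(curve, yld, fail)
  E <- youngs_modulus(k, L_span, I)
  sig_y <- bending_stress(yld$F_y, c_max, L_span, I)
  sig_u <- bending_stress(fail$F_ult, c_max, L_span, I)
  structure(list(
    F_y = yld$F_y, F_ult = fail$F_ult, k = as.numeric(k),
    W_y = works$W_y, W_fail = works$W_fail,
    PYD = works$PYD, PYE = works$PYE, L_span = L_span,
    E = E, sigma_y = sig_y, sigma_ult = sig_u,
    resilience = resilience(sig_y, E),
    toughness = toughness(works$W_fail, b_ap, L_span, I),
    strain_to_yield = bending_strains(yld$d_y, c_max, L_span, sig_y, E)$geometric,
    strain_to_failure = bending_strains(fail$d_fail, c_max, L_span)$geometric),
    class = "bending_result")
}
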