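#' Radiograph landmark set
#'
#' Manually placed 2D landmarks (mm) on an anteroposterior (AP) or lateral
#' knee radiograph. Point ordering carries the anatomical convention:
#' `shaft_axis` is (proximal, distal); `plateau_line` is (medial, lateral)
#' on the AP view and (anterior, posterior) on the lateral view.
#'
#' @param view `"AP"` or `"lateral"`.
#' @param shaft_axis 2 x 2 matrix, rows = (proximal, distal) points.
#' @param plateau_line 2 x 2 matrix, rows ordered per view (see above).
#' @param incongruity_pairs optional k x 4 matrix (x1, y1, x2, y2), one row
#'   per point pair spanning the articular defect.
#' @return An object of class `radiograph_landmarks`.
#' @export
radiograph_landmarks <- function(view = c("AP", "lateral"), shaft_axis,
                                 plateau_line, incongruity_pairs = NULL) {
  view <- match.arg(view)
  sa <- matrix(as.numeric(shaft_axis), 2, 2)
  pl <- matrix(as.numeric(plateau_line), 2, 2)
  if (!all(is.finite(sa)) || !all(is.finite(pl)))
    stop("landmark coordinates must be finite")
  if (sum((sa[1, ] - sa[2, ])^2) < 1e-12)
    stop("shaft axis points are coincident")
  if (sum((pl[1, ] - pl[2, ])^2) < 1e-12)
    stop("plateau line points are coincident")
  if (!is.null(incongruity_pairs))
    incongruity_pairs <- matrix(as.numeric(incongruity_pairs), ncol = 4)
  structure(list(view = view, shaft_axis = sa, plateau_line = pl,
                 incongruity_pairs = incongruity_pairs),
            class = "radiograph_landmarks")
}

#' Medial proximal tibial angle (MPTA)
#'
#' Coronal alignment: the angle on the medial side between the tibial
#' plateau line and the shaft axis on the AP radiograph. Computed between
#' the medial plateau direction (medial minus lateral point) and the distal
#' shaft direction, so left/right mirroring leaves the value unchanged.
#' Normal is about 87 degrees.
#'
#' @param ap_landmarks AP-view [radiograph_landmarks()].
#' @return Angle in degrees, in (0, 180).
#' @export
#' @examples
#' lm <- radiograph_landmarks("AP", shaft_axis = rbind(c(0, 0), c(0, -100)),
#'                            plateau_line = rbind(c(-30, 0), c(30, 0)))
#' mpta(lm)  # 90
mpta <- function(ap_landmarks) {
  stopifnot(inherits(ap_landmarks, "radiograph_landmarks"))
  if (ap_landmarks$view != "AP") stop("MPTA requires AP-view landmarks")
  m <- ap_landmarks$plateau_line[1, ] - ap_landmarks$plateau_line[2, ]
  s <- ap_landmarks$shaft_axis[2, ] - ap_landmarks$shaft_axis[1, ]
  ang <- acos(min(1, max(-1, sum(m * s) / sqrt(sum(m^2) * sum(s^2))))) * 180 / pi
  ang
}

#' Posterior proximal tibial angle (PPTA, posterior slope)
#'
#' Sagittal alignment: the slope of the plateau line relative to the
#' perpendicular of the shaft axis on the lateral radiograph. Positive when
#' the posterior end of the plateau lies distal (posterior-inferior slope);
#' the anatomical target is about 9 degrees.
#'
#' @param lateral_landmarks lateral-view [radiograph_landmarks()].
#' @return Signed slope angle in degrees.
#' @export
ppta <- function(lateral_landmarks) {
  stopifnot(inherits(lateral_landmarks, "radiograph_landmarks"))
  if (lateral_landmarks$view != "lateral")
    stop("PPTA requires lateral-view landmarks")
  p <- lateral_landmarks$plateau_line[2, ] - lateral_landmarks$plateau_line[1, ]
  s <- lateral_landmarks$shaft_axis[2, ] - lateral_landmarks$shaft_axis[1, ]
  s <- s / sqrt(sum(s^2))
  along <- sum(p * s)                  # distal component of posterior direction
  perp <- sqrt(max(0, sum(p * p) - along^2))
  atan2(along, perp) * 180 / pi
}

#' Maximum articular incongruity (gap and step-off)
#'
#' For each landmark pair spanning the defect, the separation is decomposed
#' relative to the local plateau line: the component parallel to the
#' plateau line is the gap, the perpendicular component the step-off.
#' Returns the maxima over pairs.
#'
#' @param landmarks [radiograph_landmarks()] with `incongruity_pairs`.
#' @return Named numeric vector `c(gap_mm, step_mm)`.
#' @export
articular_incongruity <- function(landmarks) {
  stopifnot(inherits(landmarks, "radiograph_landmarks"))
  pr <- landmarks$incongruity_pairs
  if (is.null(pr) || nrow(pr) == 0)
    stop("at least one incongruity pair is required")
  u <- landmarks$plateau_line[2, ] - landmarks$plateau_line[1, ]
  u <- u / sqrt(sum(u^2))
  dx <- pr[, 3] - pr[, 1]
  dy <- pr[, 4] - pr[, 2]
  along <- abs(dx * u[1] + dy * u[2])
  perp <- abs(-dx * u[2] + dy * u[1])
  c(gap_mm = max(along), step_mm = max(perp))
}

#' Reduction assessment
#'
#' @param gap_mm,step_mm maximum articular gap and step-off (mm), >= 0.
#' @param mpta_deg,ppta_deg coronal and sagittal alignment angles (degrees).
#' @return An object of class `reduction_assessment`.
#' @export
reduction_assessment <- function(gap_mm, step_mm, mpta_deg, ppta_deg) {
  vals <- c(gap_mm = gap_mm, step_mm = step_mm, mpta_deg = mpta_deg,
            ppta_deg = ppta_deg)
  if (any(vapply(list(gap_mm, step_mm, mpta_deg, ppta_deg), length,
                 integer(1)) != 1) || any(is.na(vals)))
    stop("all four reduction measures must be present")
  if (gap_mm < 0 || step_mm < 0) stop("gap and step-off must be non-negative")
  if (mpta_deg <= 0 || mpta_deg >= 180) stop("MPTA out of range (0, 180)")
  structure(as.list(vals), class = "reduction_assessment")
}

#' Classify fracture reduction as anatomical or inadequate
#'
#' Anatomical reduction requires gap <= 2 mm, step-off <= 2 mm,
#' MPTA within 87 +/- 5 degrees and PPTA within 9 +/- 5 degrees (closed
#' intervals: boundary values count as anatomical).
#'
#' @param assessment A [reduction_assessment()].
#' @return `"anatomical"` or `"inadequate"`.
#' @export
#' @examples
#' classify_reduction(reduction_assessment(1, 1, 87, 9))   # anatomical
#' classify_reduction(reduction_assessment(2.5, 1, 87, 9)) # inadequate
classify_reduction <- function(assessment) {
  stopifnot(inherits(assessment, "reduction_assessment"))
  ok <- assessment$gap_mm <= 2 && assessment$step_mm <= 2 &&
    assessment$mpta_deg >= 82 && assessment$mpta_deg <= 92 &&
    assessment$ppta_deg >= 4 && assessment$ppta_deg <= 14
  if (ok) "anatomical" else "inadequate"
}

#' Read landmark CSV into per-case landmark sets
#'
#' CSV columns: `case_id`, `view` (AP/lateral), `point_role`, `x_mm`,
#' `y_mm`. Roles: `shaft_proximal`, `shaft_distal`; `plateau_medial`,
#' `plateau_lateral` (AP) or `plateau_anterior`, `plateau_posterior`
#' (lateral); incongruity pairs as `pair<k>_a` / `pair<k>_b`.
#'
#' @param path CSV path.
#' @return Named list (by case_id) of lists with `AP` and/or `lateral`
#'   [radiograph_landmarks()].
#' @export
read_landmarks <- function(path) {
  d <- read.csv(path)
  need <- c("case_id", "view", "point_role", "x_mm", "y_mm")
  if (!all(need %in% names(d)))
    stop("landmark CSV must have columns: ", paste(need, collapse = ", "))
  out <- list()
  for (cid in unique(d$case_id)) {
    out[[as.character(cid)]] <- list()
    for (vw in unique(d$view[d$case_id == cid])) {
      s <- d[d$case_id == cid & d$view == vw, ]
      get <- function(role) {
        r <- s[s$point_role == role, c("x_mm", "y_mm")]
        if (nrow(r) != 1) stop("missing or duplicated landmark '", role,
                               "' for case ", cid, " view ", vw)
        as.numeric(r)
      }
      pl_roles <- if (vw == "AP") c("plateau_medial", "plateau_lateral")
      else c("plateau_anterior", "plateau_posterior")
      pair_roles <- sort(unique(sub("_(a|b)$", "",
                                    grep("^pair", s$point_role, value = TRUE))))
      pairs <- if (length(pair_roles))
        do.call(rbind, lapply(pair_roles, function(pr)
          c(get(paste0(pr, "_a")), get(paste0(pr, "_b")))))
      out[[as.character(cid)]][[vw]] <- radiograph_landmarks(
        view = vw,
        shaft_axis = rbind(get("shaft_proximal"), get("shaft_distal")),
        plateau_line = rbind(get(pl_roles[1]), get(pl_roles[2])),
        incongruity_pairs = pairs)
    }
  }
  out
}
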