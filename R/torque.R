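#' Maximum isometric muscle force from PCSA
#'
#' `F_max = PCSA x specific tension`, with the widely used mammalian
#' specific tension of 0.3 N/mm^2 as default.
#'
#' @param pcsa Physiological cross-sectional area (mm^2), positive.
#' @param specific_tension N/mm^2 (default 0.3).
#' @return Maximum isometric force in N.
#' @examples
#' max_isometric_force(100)  # 30 N
#' @export
max_isometric_force <- function(pcsa, specific_tension = 0.3) {
  if (any(pcsa <= 0)) stop("PCSA must be positive", call. = FALSE)
  stopifnot(specific_tension > 0)
  pcsa * specific_tension
}

#' Muscle architecture record
#'
#' @param pcsa PCSA (mm^2).
#' @param optimal_fibre_length Resting fibre length (mm).
#' @param tendon_slack_length Tendon slack length (mm).
#' @param pennation Pennation angle of inserting fibres (degrees).
#' @param specific_tension N/mm^2 (default 0.3); `f_max` is derived.
#' @return An object of class `muscle_architecture`.
#' @export
muscle_architecture <- function(pcsa, optimal_fibre_length,
                                tendon_slack_length = 0, pennation = 0,
                                specific_tension = 0.3) {
  stopifnot(pcsa > 0, optimal_fibre_length > 0, tendon_slack_length >= 0,
            pennation >= 0, pennation < 90)
  structure(list(pcsa = pcsa,
                 optimal_fibre_length = optimal_fibre_length,
                 tendon_slack_length = tendon_slack_length,
                 pennation = pennation,
                 f_max = max_isometric_force(pcsa, specific_tension)),
            class = "muscle_architecture")
}

#' @export
print.muscle_architecture <- function(x, ...) {
  cat(sprintf(paste0("Muscle architecture: PCSA %.1f mm^2 (F_max %.2f N), ",
                     "L_opt %.1f mm, L_slack %.1f mm, pennation %.1f deg\n"),
              x$pcsa, x$f_max, x$optimal_fibre_length,
              x$tendon_slack_length, x$pennation))
  invisible(x)
}

#' Generalised musculotendon curves
#'
#' The four normalised Hill-type curves, as parametric defaults (none of
#' them species-specific): a Gaussian active force-length curve peaking at
#' normalised length 1 with width 0.45, an exponential passive curve
#' engaging above normalised length 1, a linear-region tendon curve, and a
#' force-velocity curve which is stored for completeness but unused by the
#' isometric torque calculation. Any curve can be replaced, e.g. by an
#' interpolator over a tabulated curve (see [tabulated_curve()]).
#'
#' @param active,passive,tendon,force_velocity Optional replacement
#'   functions mapping normalised length (or velocity) to normalised force.
#' @param active_width Width of the default Gaussian active curve (0.45
#'   normalised lengths).
#' @return An object of class `mt_curves` (a list of four functions).
#' @export
mt_curves <- function(active = NULL, passive = NULL, tendon = NULL,
                      force_velocity = NULL, active_width = 0.45) {
  if (is.null(active)) {
    active <- function(l) exp(-((l - 1) / active_width)^2)
  }
  if (is.null(passive)) {
    passive <- function(l) ifelse(l <= 1, 0, (exp(5 * (l - 1)) - 1) / (exp(5 * 0.4) - 1))
  }
  if (is.null(tendon)) {  # linear above slack, stiffness ~30 F_max per strain
    tendon <- function(l) pmax(0, 30 * (l - 1))
  }
  if (is.null(force_velocity)) {
    force_velocity <- function(v) ifelse(v >= 1, 0, (1 - v) / (1 + 4 * v))
  }
  structure(list(active = active, passive = passive, tendon = tendon,
                 force_velocity = force_velocity), class = "mt_curves")
}

#' Interpolating curve from a normalised table
#'
#' @param x,y Normalised abscissa (length or velocity) and force columns.
#' @return A function interpolating linearly, clamped at the table ends.
#' @export
tabulated_curve <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  stats::approxfun(x, y, rule = 2)
}

#' Normalised fibre length under the rigid-tendon assumption
#'
#' Fibre length is taken as the musculotendon length minus the tendon
#' slack length, divided by the cosine of the pennation angle, and
#' normalised by the optimal fibre length.
#'
#' @param mt_length Musculotendon (origin-to-insertion) length, mm.
#' @param arch A [muscle_architecture()].
#' @return Normalised fibre length (dimensionless, floored at 0).
#' @export
normalised_fibre_length <- function(mt_length, arch) {
  stopifnot(inherits(arch, "muscle_architecture"))
  lf <- (mt_length - arch$tendon_slack_length) /
    cos(arch$pennation * pi / 180)
  pmax(0, lf / arch$optimal_fibre_length)
}

#' Isometric muscle torque about one joint axis
#'
#' `tau = r * F_max * (a * activeFL(l) + passiveFL(l)) * cos(pennation)`:
#' the signed moment arm times the fibre force resolved along the tendon.
#' Isometric only; the force-velocity curve plays no part.
#'
#' @param r_theta Signed moment arm about the axis (mm).
#' @param arch A [muscle_architecture()].
#' @param curves An [mt_curves()] object (defaults used when omitted).
#' @param normalised_fibre_length Normalised fibre length (1 = optimal).
#' @param activation Activation in \[0, 1\] (default 1, maximal).
#' @return Torque in N mm (vectorised over `r_theta` and length).
#' @export
isometric_torque <- function(r_theta, arch, curves = mt_curves(),
                             normalised_fibre_length = 1, activation = 1) {
  stopifnot(inherits(arch, "muscle_architecture"),
            inherits(curves, "mt_curves"))
  if (any(activation < 0 | activation > 1)) {
    stop("activation must lie in [0, 1]", call. = FALSE)
  }
  l <- normalised_fibre_length
  fl <- activation * curves$active(l) + curves$passive(l)
  r_theta * arch$f_max * fl * cos(arch$pennation * pi / 180)
}

#' Sum per-muscle series with multi-head averaging
#'
#' Muscles modelled with several heads (several lines of action) are
#' averaged within their group first, so a multi-head muscle is not
#' over-represented; the group means are then summed. Applies identically
#' to moment-arm and torque series.
#'
#' @param series Named list of numeric vectors on a common abscissa.
#' @param head_groups Named list mapping group (muscle) names to the
#'   series belonging to them; series not mentioned form their own groups.
#' @return Numeric vector: the summed series.
#' @export
summed_series <- function(series, head_groups = NULL) {
  stopifnot(is.list(series), length(series) >= 1L)
  len <- unique(vapply(series, length, integer(1)))
  if (length(len) != 1L) {
    stop("series have different lengths; align abscissae first",
         call. = FALSE)
  }
  if (is.null(head_groups)) head_groups <- list()
  grouped <- unlist(head_groups, use.names = FALSE)
  missing_s <- setdiff(grouped, names(series))
  if (length(missing_s)) {
    stop("head group names not in series: ",
         paste(missing_s, collapse = ", "), call. = FALSE)
  }
  singles <- setdiff(names(series), grouped)
  groups <- c(head_groups, stats::setNames(as.list(singles), singles))
  total <- numeric(len)
  for (g in groups) {
    members <- series[unlist(g)]
    total <- total + Reduce(`+`, members) / length(members)
  }
  total
}

#' Rank motion directions by peak summed value
#'
#' Orders motion directions by the peak absolute value of their summed
#' series (moment arm or torque); ties break alphabetically.
#'
#' @param summed Named list of numeric vectors, one per motion direction.
#' @return Data frame with `motion`, `peak` (absolute), and `rank`,
#'   ordered largest first.
#' @export
peak_rank_order <- function(summed) {
  stopifnot(length(summed) >= 1L, !is.null(names(summed)))
  peaks <- vapply(summed, function(v) max(abs(v)), numeric(1))
  ord <- order(-peaks, names(peaks))
  data.frame(motion = names(peaks)[ord], peak = unname(peaks[ord]),
             rank = seq_along(peaks))
}

#' Compare two rank orders and report swapped pairs
#'
#' Reports which motions change position between two rankings, e.g. a
#' moment-arm ranking versus a torque ranking where a large-PCSA muscle
#' promotes one motion.
#'
#' @param rank_a,rank_b Data frames from [peak_rank_order()].
#' @return List with `identical` (logical) and `moved`, a data frame of
#'   motions whose rank differs (with both ranks).
#' @export
compare_rank_orders <- function(rank_a, rank_b) {
  a <- stats::setNames(rank_a$rank, rank_a$motion)
  b <- stats::setNames(rank_b$rank, rank_b$motion)
  stopifnot(setequal(names(a), names(b)))
  moved <- names(a)[a[names(a)] != b[names(a)]]
  list(identical = length(moved) == 0L,
       moved = data.frame(motion = moved,
                          rank_a = unname(a[moved]),
                          rank_b = unname(b[moved])))
}
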