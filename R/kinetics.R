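#' Signed contraction/expansion speeds of an evolution scenario
#'
#' For every time step and every face, the norm of the face-center velocity
#' signed by its direction relative to the outward surface normal at the
#' start of the step: positive = outward (expansion), negative = inward
#' (contraction). Speeds are reported in cm per 3 hours.
#'
#' @param scn an `evolution_scenario` (fitted or generator truth).
#' @return A `speed_field`: matrix `speeds` of shape (T, M) in cm/3h,
#'   `times_hours` (step end times), plus the scenario's step duration.
#' @export
signed_speed <- function(scn) {
  n_steps <- length(scn$surfaces_t) - 1L
  m <- nrow(scn$baseline$faces)
  sp <- matrix(NA_real_, n_steps, m)
  c_prev <- face_centers(scn$surfaces_t[[1]])
  n_prev <- face_normals(scn$surfaces_t[[1]])
  a_prev <- sqrt(rowSums(n_prev^2))
  if (any(a_prev <= 1e-12)) stop("signed_speed: degenerate face")
  dt <- scn$momenta$dt_hours
  for (t in seq_len(n_steps)) {
    c_next <- face_centers(scn$surfaces_t[[t + 1L]])
    d <- c_next - c_prev                      # mm per step
    mag <- sqrt(rowSums(d^2))
    sgn <- sign(rowSums(d * n_prev))          # outward unit normal direction
    sgn[sgn == 0 & mag > 0] <- 1              # tangential drift counted outward
    sp[t, ] <- mag * sgn * 3 / dt / 10        # mm/step -> cm per 3 h
    c_prev <- c_next
    n_prev <- face_normals(scn$surfaces_t[[t + 1L]])
    a_prev <- sqrt(rowSums(n_prev^2))
    if (any(a_prev <= 1e-12)) stop("signed_speed: degenerate face")
  }
  structure(list(speeds = sp, times_hours = scn$times_hours[-1],
                 dt_hours = dt),
            class = "speed_field")
}

#' @export
print.speed_field <- function(x, ...) {
  cat(sprintf("<speed_field> %d steps x %d faces, range [%.3g, %.3g] cm/3h\n",
              nrow(x$speeds), ncol(x$speeds), min(x$speeds), max(x$speeds)))
  invisible(x)
}

#' Extract highly contracting and highly expanding surface areas
#'
#' At the given step, the mean and standard deviation of the signed speed
#' are computed separately over the contracting (speed < 0) and expanding
#' (speed > 0) face subsets. Faces strictly below `mean - SD` of the
#' contraction subset are flagged `high_contraction`; faces strictly above
#' `mean + SD` of the expansion subset are flagged `high_expansion`.
#' An empty subset simply yields an empty flag set.
#'
#' @param sp a `speed_field`.
#' @param at_step step index used for extraction (default 1, the first
#'   inter-observation step at the baseline).
#' @return A `region_labels` object: logical vectors `high_contraction` and
#'   `high_expansion` (disjoint), the extraction step and thresholds.
#' @export
extract_regions <- function(sp, at_step = 1L) {
  at_step <- as.integer(at_step)
  if (at_step < 1L || at_step > nrow(sp$speeds))
    stop("extract_regions: step out of range")
  v <- sp$speeds[at_step, ]
  contr <- v[v < 0]
  expa <- v[v > 0]
  thr_c <- if (length(contr) >= 2L) mean(contr) - sd(contr) else
    if (length(contr) == 1L) contr else NA_real_
  thr_e <- if (length(expa) >= 2L) mean(expa) + sd(expa) else
    if (length(expa) == 1L) expa else NA_real_
  high_c <- if (is.na(thr_c)) rep(FALSE, length(v)) else v < thr_c
  high_e <- if (is.na(thr_e)) rep(FALSE, length(v)) else v > thr_e
  structure(list(high_contraction = high_c, high_expansion = high_e,
                 at_step = at_step,
                 threshold_contraction = thr_c, threshold_expansion = thr_e),
            class = "region_labels")
}

#' @export
print.region_labels <- function(x, ...) {
  cat(sprintf("<region_labels> step %d: %d high-contraction, %d high-expansion faces\n",
              x$at_step, sum(x$high_contraction), sum(x$high_expansion)))
  invisible(x)
}

#' Map region labels back to the baseline surface
#'
#' The flow preserves mesh connectivity, so face identity is the transport:
#' flags extracted at a later step index the same faces on the baseline
#' mesh (the discrete counterpart of pulling the areas back through the
#' inverse evolution function). The source step is recorded so successive
#' extractions can be layered into a first-flagged sequence.
#'
#' @param scn the `evolution_scenario` the labels came from.
#' @param labels a `region_labels` extracted from a step of `scn`.
#' @return The same flags as labels on the baseline mesh, with
#'   `source_step` recorded.
#' @export
map_regions_to_baseline <- function(scn, labels) {
  m <- nrow(scn$baseline$faces)
  if (length(labels$high_contraction) != m)
    stop("map_regions_to_baseline: label/scenario face-count mismatch")
  if (labels$at_step > length(scn$surfaces_t) - 1L)
    stop("map_regions_to_baseline: label step outside scenario")
  out <- labels
  out$source_step <- labels$at_step
  out$at_step <- 0L
  out
}

#' Transfer region labels from the DWI baseline to the MTT baseline
#'
#' When the MTT evolution scenario is seeded with the correspondence-
#' deformed DWI baseline `phi(S_DWI(t1))`, the two baselines share face
#' identity, so flags transfer directly through `phi`.
#'
#' @param phi the `correspondence_map` fitted from DWI(t1) to MTT(t1).
#' @param labels `region_labels` on the DWI baseline.
#' @return `region_labels` indexed on the phi-deformed (MTT-frame) baseline.
#' @export
transfer_dwi_to_mtt <- function(phi, labels) {
  m <- nrow(phi$source$faces)
  if (length(labels$high_contraction) != m)
    stop("transfer_dwi_to_mtt: labels do not match phi's source mesh")
  labels
}

#' Mean speed of flagged regions over the whole evolution
#'
#' Per time step, the mean signed speed over each flagged face set — the
#' spatiotemporal mean-speed trajectory of the highly contracting and
#' highly expanding areas.
#'
#' @param scn an `evolution_scenario`.
#' @param labels `region_labels` on the scenario's baseline.
#' @param sp optional precomputed [signed_speed()] field for `scn`.
#' @return Data frame with columns `time_hours`, `mean_speed_contracting`,
#'   `mean_speed_expanding` (cm/3h; NaN columns, with a warning, when a
#'   flag set is empty).
#' @export
mean_speed_curves <- function(scn, labels, sp = signed_speed(scn)) {
  m <- ncol(sp$speeds)
  if (length(labels$high_contraction) != m)
    stop("mean_speed_curves: label/scenario face-count mismatch")
  if (!any(labels$high_contraction) || !any(labels$high_expansion))
    warning("mean_speed_curves: empty flag set; corresponding column is NaN")
  mean_over <- function(flags) {
    if (!any(flags)) return(rep(NaN, nrow(sp$speeds)))
    rowMeans(sp$speeds[, flags, drop = FALSE])
  }
  data.frame(time_hours = sp$times_hours,
             mean_speed_contracting = mean_over(labels$high_contraction),
             mean_speed_expanding = mean_over(labels$high_expansion))
}
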