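#' Workflow time constants
#'
#' Fixed in-hospital and handoff intervals (all minutes) used by the three
#' transport-paradigm timelines. Defaults follow published quality
#' measures for stroke systems of care: onset to first medical response
#' 30, ambulance on-scene 30, door-to-needle 30 at both PSC and CSC,
#' needle-to-door 20 at the PSC, door-to-groin 60 at the CSC/CSC+ (30 when
#' the transferred patient arrives within 90 min of first imaging at the
#' PSC and needs no reimaging), needle-to-interventionalist-leave 10 and
#' interventionalist-arrival-to-groin 20 for drip-and-drive.
#'
#' @param onset_to_fmr Onset to first medical response.
#' @param on_scene Ambulance on-scene time.
#' @param dtn_psc Door-to-needle at the PSC.
#' @param ntd_psc Needle-to-door at the PSC (start of the transfer).
#' @param dtn_csc Door-to-needle at the CSC/CSC+.
#' @param dtg_csc Door-to-groin at the CSC/CSC+.
#' @param dtg_csc_fast Door-to-groin when no reimaging is needed.
#' @param reimage_window Maximum minutes from first imaging at the PSC to
#'   CSC arrival for the no-reimaging fast track (inclusive).
#' @param ntl_dd Needle to neurointerventionalist leaving the CSC+.
#' @param arr_to_groin_dd Interventionalist arrival at the PSC to groin.
#' @param imaging_offset_psc Minutes from PSC door to first imaging.
#' @return Object of class `workflow_times`.
#' @export
workflow_times <- function(onset_to_fmr = 30, on_scene = 30,
                           dtn_psc = 30, ntd_psc = 20,
                           dtn_csc = 30, dtg_csc = 60, dtg_csc_fast = 30,
                           reimage_window = 90,
                           ntl_dd = 10, arr_to_groin_dd = 20,
                           imaging_offset_psc = 0) {
  w <- list(onset_to_fmr = onset_to_fmr, on_scene = on_scene,
            dtn_psc = dtn_psc, ntd_psc = ntd_psc,
            dtn_csc = dtn_csc, dtg_csc = dtg_csc,
            dtg_csc_fast = dtg_csc_fast, reimage_window = reimage_window,
            ntl_dd = ntl_dd, arr_to_groin_dd = arr_to_groin_dd,
            imaging_offset_psc = imaging_offset_psc)
  for (nm in names(w)) .chk_num(w[[nm]], nm, lo = 0)
  if (w$dtg_csc_fast > w$dtg_csc) {
    stop("`dtg_csc_fast` must be <= `dtg_csc`", call. = FALSE)
  }
  structure(w, class = "workflow_times")
}

# door-to-X interval with a (possibly negative) traffic delta applied;
# never below zero
.delayed <- function(interval, delta, what) {
  out <- interval + delta
  if (out < 0) {
    warning(sprintf("negative delta pushed %s below 0; clamped", what),
            call. = FALSE)
    out <- 0
  }
  out
}

.timeline <- function(paradigm, t_needle, t_groin, trace) {
  stopifnot(all(diff(trace) >= -1e-9))
  structure(list(paradigm = paradigm, t_needle = t_needle,
                 t_groin = t_groin, trace = trace),
            class = "paradigm_timeline")
}

#' @export
print.paradigm_timeline <- function(x, ...) {
  cat(sprintf("<%s timeline: needle %g min, groin %g min>\n",
              x$paradigm, x$t_needle, x$t_groin))
  print(round(x$trace, 1))
  invisible(x)
}

#' Mothership timeline
#'
#' The patient is transported directly to the CSC/CSC+. The traffic delta
#' (delay or acceleration relative to the 3 a.m. baseline) is added to
#' both the door-to-needle and the door-to-groin time at the CSC.
#'
#' @param t_travel_to_csc Scene-to-CSC travel time, minutes.
#' @param delta Traffic delta in minutes (may be negative); door-to-X
#'   intervals are clamped at zero with a warning.
#' @param w A [workflow_times()].
#' @return A `paradigm_timeline` with onset-based `t_needle`, `t_groin`
#'   and an event trace.
#' @export
mothership_timeline <- function(t_travel_to_csc, delta = 0,
                                w = workflow_times()) {
  .chk_num(t_travel_to_csc, "t_travel_to_csc", lo = 0)
  .chk_num(delta, "delta")
  stopifnot(inherits(w, "workflow_times"))
  fmr <- w$onset_to_fmr
  depart <- fmr + w$on_scene
  door <- depart + t_travel_to_csc
  t_needle <- door + .delayed(w$dtn_csc, delta, "door-to-needle (CSC)")
  t_groin <- door + .delayed(w$dtg_csc, delta, "door-to-groin (CSC)")
  .timeline("mothership", t_needle, t_groin,
            c(onset = 0, first_response = fmr, scene_depart = depart,
              csc_door = door, needle = t_needle, groin = t_groin))
}

#' Drip-and-ship timeline
#'
#' IVT at the nearest PSC, then transfer of the patient to the CSC/CSC+
#' for EVT. If the patient arrives at the CSC within `reimage_window`
#' minutes of first imaging at the PSC (inclusive), no reimaging is needed
#' and the fast door-to-groin time applies; the traffic delta is added to
#' the door-to-groin time at the CSC.
#'
#' @param t_travel_to_psc Scene-to-PSC travel time, minutes.
#' @param t_transfer_psc_to_csc PSC-to-CSC transfer travel time, minutes.
#' @inheritParams mothership_timeline
#' @return A `paradigm_timeline`.
#' @export
drip_and_ship_timeline <- function(t_travel_to_psc, t_transfer_psc_to_csc,
                                   delta = 0, w = workflow_times()) {
  .chk_num(t_travel_to_psc, "t_travel_to_psc", lo = 0)
  .chk_num(t_transfer_psc_to_csc, "t_transfer_psc_to_csc", lo = 0)
  .chk_num(delta, "delta")
  stopifnot(inherits(w, "workflow_times"))
  fmr <- w$onset_to_fmr
  depart_scene <- fmr + w$on_scene
  psc_door <- depart_scene + t_travel_to_psc
  t_needle <- psc_door + w$dtn_psc
  depart_psc <- t_needle + w$ntd_psc
  csc_door <- depart_psc + t_transfer_psc_to_csc
  imaging <- psc_door + w$imaging_offset_psc
  dtg <- if (csc_door - imaging <= w$reimage_window) w$dtg_csc_fast else w$dtg_csc
  t_groin <- csc_door + .delayed(dtg, delta, "door-to-groin (CSC)")
  .timeline("drip_and_ship", t_needle, t_groin,
            c(onset = 0, first_response = fmr, scene_depart = depart_scene,
              psc_door = psc_door, needle = t_needle,
              psc_depart = depart_psc, csc_door = csc_door,
              groin = t_groin))
}

#' Drip-and-drive timeline
#'
#' IVT at the nearest PSC while the neurointerventionalist drives from the
#' CSC+ to the PSC to perform EVT there. The traffic delta is added to the
#' interventionalist-arrival-to-groin time. The groin time is the
#' interventionalist chain guarded by `max()` against patient readiness
#' (with the default constants the interventionalist chain always
#' dominates).
#'
#' @param t_travel_to_psc Scene-to-PSC travel time, minutes.
#' @param t_interventionalist_travel CSC+-to-PSC travel time for the
#'   neurointerventionalist, minutes.
#' @inheritParams mothership_timeline
#' @return A `paradigm_timeline`.
#' @export
drip_and_drive_timeline <- function(t_travel_to_psc,
                                    t_interventionalist_travel,
                                    delta = 0, w = workflow_times()) {
  .chk_num(t_travel_to_psc, "t_travel_to_psc", lo = 0)
  .chk_num(t_interventionalist_travel, "t_interventionalist_travel", lo = 0)
  .chk_num(delta, "delta")
  stopifnot(inherits(w, "workflow_times"))
  fmr <- w$onset_to_fmr
  depart_scene <- fmr + w$on_scene
  psc_door <- depart_scene + t_travel_to_psc
  t_needle <- psc_door + w$dtn_psc
  iv_leave <- t_needle + w$ntl_dd
  iv_arrive <- iv_leave + t_interventionalist_travel
  t_groin <- max(t_needle,
                 iv_arrive + .delayed(w$arr_to_groin_dd, delta,
                                      "arrival-to-groin (DD)"))
  .timeline("drip_and_drive", t_needle, t_groin,
            c(onset = 0, first_response = fmr, scene_depart = depart_scene,
              psc_door = psc_door, needle = t_needle,
              interventionalist_leave = iv_leave,
              interventionalist_arrive = iv_arrive, groin = t_groin))
}
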