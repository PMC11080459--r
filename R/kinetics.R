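#' LED switching protocol
#'
#' Builds the illumination schedule used in the time-series experiments:
#' after a lead-in in the dark, the switching LED is turned on for 4 min 30 s
#' and then off for 15 min, and this pair of steps is repeated (three times
#' by default). The LED alternates between UV (365 nm, drives trans -> cis)
#' and visible (465 nm, drives cis -> trans) so that each cycle switches the
#' membrane to the opposite state. Frames are acquired continuously, one
#' hyperspectral cube per `frame_period_s` (64 s).
#'
#' @param lead_in_s Dark time before the first LED event (s).
#' @param n_cycles Number of on/off cycles.
#' @param on_s LED-on duration per cycle (s; default 270 = 4 min 30 s).
#' @param off_s LED-off duration per cycle (s; default 900 = 15 min).
#' @param first_led `"UV"` or `"VIS"`; subsequent cycles alternate.
#' @param frame_period_s Cube acquisition period (s).
#' @param events Optionally, an explicit data.frame with columns
#'   `led` (`"UV"`/`"VIS"`), `start_s`, `duration_s`; overrides the cycle
#'   arguments. Events must be time-ordered and non-overlapping.
#' @return A `switch_protocol` object: list with `events` data.frame and
#'   `frame_period_s`.
#' @export
switch_protocol <- function(lead_in_s = 960, n_cycles = 3, on_s = 270,
                            off_s = 900, first_led = c("UV", "VIS"),
                            frame_period_s = 64, events = NULL) {
  if (frame_period_s <= 0) stop("switch_protocol: frame_period_s must be positive")
  if (is.null(events)) {
    first_led <- match.arg(first_led)
    leds <- rep(c("UV", "VIS"), length.out = n_cycles)
    if (first_led == "VIS") leds <- rep(c("VIS", "UV"), length.out = n_cycles)
    events <- data.frame(
      led = leds,
      start_s = lead_in_s + (seq_len(n_cycles) - 1) * (on_s + off_s),
      duration_s = on_s
    )
  } else {
    if (!all(c("led", "start_s", "duration_s") %in% names(events))) {
      stop("switch_protocol: events needs columns led, start_s, duration_s")
    }
    if (!all(events$led %in% c("UV", "VIS"))) {
      stop("switch_protocol: led must be 'UV' or 'VIS'")
    }
  }
  if (nrow(events) > 1) {
    ends <- events$start_s + events$duration_s
    if (any(diff(events$start_s) <= 0) ||
        any(events$start_s[-1] < ends[-nrow(events)])) {
      stop("switch_protocol: events must be time-ordered and non-overlapping")
    }
  }
  structure(list(events = events, frame_period_s = frame_period_s),
            class = "switch_protocol")
}

#' Photoisomerization kinetics parameters
#'
#' First-order relaxation toward the photostationary state (PSS) of the
#' active LED: under UV, `dc/dt = k_uv (pss_uv - c)`; under visible light,
#' `dc/dt = k_vis (pss_vis - c)`; in the dark the cis fraction is constant
#' (thermal relaxation of AzoPC is slow on the experiment timescale). The
#' default rates (0.02 s^-1, i.e. a 50 s time constant) complete the switch
#' well within the 4.5 min LED-on window, matching the full, repeatable
#' switching observed per cycle.
#'
#' @param k_uv,k_vis Relaxation rates (s^-1), non-negative.
#' @param pss_uv,pss_vis Photostationary cis fractions in `[0, 1]`;
#'   `pss_uv > pss_vis` is required.
#' @return A `kinetics_params` object.
#' @export
kinetics_params <- function(k_uv = 0.02, k_vis = 0.02,
                            pss_uv = 0.9, pss_vis = 0.1) {
  if (k_uv < 0 || k_vis < 0) stop("kinetics_params: rates must be >= 0")
  if (any(c(pss_uv, pss_vis) < 0) || any(c(pss_uv, pss_vis) > 1)) {
    stop("kinetics_params: pss values must lie in [0, 1]")
  }
  if (pss_uv <= pss_vis) stop("kinetics_params: pss_uv must exceed pss_vis")
  structure(list(k_uv = k_uv, k_vis = k_vis,
                 pss_uv = pss_uv, pss_vis = pss_vis),
            class = "kinetics_params")
}

## exact cis fraction at a single time t under the protocol (piecewise
## exponential; constant between events)
cis_fraction_at <- function(t, protocol, kinetics, c0) {
  ev <- protocol$events
  c_cur <- c0
  t_cur <- 0
  for (i in seq_len(nrow(ev))) {
    if (t <= ev$start_s[i]) break
    k <- if (ev$led[i] == "UV") kinetics$k_uv else kinetics$k_vis
    pss <- if (ev$led[i] == "UV") kinetics$pss_uv else kinetics$pss_vis
    dt_on <- min(t, ev$start_s[i] + ev$duration_s[i]) - ev$start_s[i]
    if (k > 0 && dt_on > 0) c_cur <- pss + (c_cur - pss) * exp(-k * dt_on)
    t_cur <- ev$start_s[i] + dt_on
  }
  min(max(c_cur, 0), 1)
}

#' Simulate a switching trajectory
#'
#' Integrates the piecewise first-order kinetics exactly (closed-form
#' exponential per LED event, constant in the dark) and samples the membrane
#' state at the cube acquisition times `0, frame_period_s, 2*frame_period_s,
#' ...` up to `t_end_s`.
#'
#' @param protocol A [switch_protocol()].
#' @param kinetics A [kinetics_params()].
#' @param initial Initial [membrane_state()].
#' @param t_end_s End time (s); defaults to the last event end plus one
#'   off-period of padding.
#' @return A data.frame with columns `frame`, `time_s`, `cis_fraction`,
#'   `led` (`"UV"`, `"VIS"` or `"off"`).
#' @export
switching_trajectory <- function(protocol, kinetics,
                                 initial = membrane_state(0.1),
                                 t_end_s = NULL) {
  stopifnot(inherits(protocol, "switch_protocol"),
            inherits(kinetics, "kinetics_params"),
            inherits(initial, "membrane_state"))
  ev <- protocol$events
  last_end <- if (nrow(ev)) max(ev$start_s + ev$duration_s) else 0
  if (is.null(t_end_s)) t_end_s <- last_end + 900
  if (t_end_s < last_end) {
    stop("switching_trajectory: t_end_s must cover the last event")
  }
  times <- seq(0, t_end_s, by = protocol$frame_period_s)
  cf <- vapply(times, cis_fraction_at, numeric(1),
               protocol = protocol, kinetics = kinetics,
               c0 = initial$cis_fraction)
  led <- rep("off", length(times))
  for (i in seq_len(nrow(ev))) {
    on <- times >= ev$start_s[i] & times < ev$start_s[i] + ev$duration_s[i]
    led[on] <- ev$led[i]
  }
  data.frame(frame = seq_along(times), time_s = times,
             cis_fraction = cf, led = led)
}
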