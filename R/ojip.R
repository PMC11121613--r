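#' Extract JIP-test landmarks from an OJIP transient
#'
#' Reads the four landmarks of a fast fluorescence induction curve:
#' O (minimum fluorescence over the trace), K (fluorescence at 300 us),
#' J (fluorescence at 2 ms) and P (maximum). K and J are obtained by
#' interpolation linear in log10(time), the natural scale of log-sampled
#' induction data.
#'
#' @param trace Data frame with columns `time_s` and `fluorescence`
#'   covering at least 300 us to 2 ms, with at least 10 points.
#' @return A list of class `ojip_landmarks`: `F_O`, `F_K`, `F_J`, `F_P`,
#'   `valid` (FALSE when the transient is degenerate, F_P = F_O) and
#'   `sample_id` when present in `trace`.
#' @examples
#' tr <- simulate_ojip(ojip_params(noise_sd = 0), study_design())
#' extract_landmarks(tr[tr$sample_id == "M1", ])
#' @export
extract_landmarks <- function(trace) {
  if (!all(c("time_s", "fluorescence") %in% names(trace))) {
    stop("trace needs columns time_s and fluorescence", call. = FALSE)
  }
  if (nrow(trace) < 10L) stop("trace too short (< 10 points)", call. = FALSE)
  if (any(!is.finite(trace$fluorescence)) || any(!is.finite(trace$time_s))) {
    stop("non-finite values in trace", call. = FALSE)
  }
  if (min(trace$time_s) > 3e-4 || max(trace$time_s) < 2e-3) {
    stop("trace must cover 300 us to 2 ms", call. = FALSE)
  }
  o <- order(trace$time_s)
  tt <- trace$time_s[o]; ff <- trace$fluorescence[o]
  f_o <- min(ff)
  f_p <- max(ff)
  f_k <- interp_log_time(tt, ff, 3e-4)
  f_j <- interp_log_time(tt, ff, 2e-3)
  structure(
    list(F_O = f_o, F_K = f_k, F_J = f_j, F_P = f_p,
         valid = f_p > f_o,
         sample_id = if ("sample_id" %in% names(trace))
           trace$sample_id[1] else NA_character_),
    class = "ojip_landmarks"
  )
}

#' Relative variable fluorescence Vt
#'
#' Double normalization between the O and P landmarks:
#' Vt = (Ft - F_O)/(F_P - F_O), so Vt(O) = 0 and Vt(P) = 1. Also reports
#' VJ, the value at 2 ms (the J step). Vt is invariant under affine
#' rescaling of the raw fluorescence.
#'
#' @param trace Transient data frame (`time_s`, `fluorescence`).
#' @param landmarks Optional precomputed [extract_landmarks()] result.
#' @return A list of class `ojip_curve` with `time_s`, `value`, `kind`
#'   (`"Vt"`) and `vj`.
#' @export
normalize_vt <- function(trace, landmarks = NULL) {
  if (is.null(landmarks)) landmarks <- extract_landmarks(trace)
  if (landmarks$F_P <= landmarks$F_O) {
    stop("degenerate transient: F_P must exceed F_O", call. = FALSE)
  }
  o <- order(trace$time_s)
  v <- (trace$fluorescence[o] - landmarks$F_O) /
    (landmarks$F_P - landmarks$F_O)
  structure(
    list(time_s = trace$time_s[o], value = v, kind = "Vt",
         vj = (landmarks$F_J - landmarks$F_O) /
           (landmarks$F_P - landmarks$F_O),
         sample_id = landmarks$sample_id),
    class = "ojip_curve"
  )
}

#' O-J normalized fluorescence Wt
#'
#' Double normalization between the O and J landmarks:
#' Wt = (Ft - F_O)/(F_J - F_O), so Wt(O) = 0 and Wt(2 ms) = 1. The
#' treatment-minus-control difference of Wt read at 300 us is the K-band
#' statistic (donor-side/OEC impairment indicator).
#'
#' @inheritParams normalize_vt
#' @return A list of class `ojip_curve` with `kind = "Wt"`.
#' @export
normalize_wt <- function(trace, landmarks = NULL) {
  if (is.null(landmarks)) landmarks <- extract_landmarks(trace)
  if (landmarks$F_J <= landmarks$F_O) {
    stop("degenerate transient: F_J must exceed F_O", call. = FALSE)
  }
  o <- order(trace$time_s)
  w <- (trace$fluorescence[o] - landmarks$F_O) /
    (landmarks$F_J - landmarks$F_O)
  structure(
    list(time_s = trace$time_s[o], value = w, kind = "Wt",
         sample_id = landmarks$sample_id),
    class = "ojip_curve"
  )
}

# mean normalized curve of one group on a common grid
group_mean_curve <- function(traces, group, kind, grid) {
  ids <- unique(traces$sample_id[traces$group == group])
  if (length(ids) == 0L) stop("empty group: ", group, call. = FALSE)
  curves <- vapply(ids, function(id) {
    tr <- traces[traces$sample_id == id, ]
    cv <- if (kind == "Vt") normalize_vt(tr) else normalize_wt(tr)
    if (isTRUE(all.equal(cv$time_s, grid))) cv$value
    else interp_log_time(cv$time_s, cv$value, grid)
  }, numeric(length(grid)))
  rowMeans(curves)
}

#' Treatment-minus-control difference curves (delta-Vt / delta-Wt)
#'
#' Normalizes every replicate transient (Vt or Wt), averages within group
#' (replicate-first: curves are normalized per replicate, then averaged),
#' and subtracts the control mean curve from the treatment mean curve.
#' `delta_j` is the difference read at 2 ms (positive values indicate QA-
#' accumulation on the PSII acceptor side) and `delta_k` the difference at
#' 300 us (positive values indicate donor-side/OEC damage).
#'
#' @param traces Long trace table (`time_s`, `fluorescence`, `sample_id`,
#'   `group`), as from [simulate_ojip()].
#' @param control,treatment Group labels.
#' @param kind `"Vt"` or `"Wt"`.
#' @return A list of class `delta_curve`: `time_s`, `value`, `kind`,
#'   `delta_j`, `delta_k`, `control`, `treatment`.
#' @examples
#' pars <- list(M = ojip_params(noise_sd = 0),
#'              N = ojip_params(noise_sd = 0, j_step_shift = 1.4))
#' tr <- simulate_ojip(pars, study_design())
#' delta_curves(tr, control = "M", treatment = "N", kind = "Vt")$delta_j
#' @export
delta_curves <- function(traces, control, treatment, kind = c("Vt", "Wt")) {
  kind <- match.arg(kind)
  for (g in c(control, treatment)) {
    if (!g %in% traces$group) stop("group not in traces: ", g, call. = FALSE)
  }
  first_id <- traces$sample_id[traces$group == control][1]
  grid <- sort(traces$time_s[traces$sample_id == first_id])
  ctrl <- group_mean_curve(traces, control, kind, grid)
  trt <- group_mean_curve(traces, treatment, kind, grid)
  d <- trt - ctrl
  structure(
    list(time_s = grid, value = d, kind = paste0("delta_", kind),
         delta_j = interp_log_time(grid, d, 2e-3),
         delta_k = interp_log_time(grid, d, 3e-4),
         control = control, treatment = treatment),
    class = "delta_curve"
  )
}

#' @export
print.delta_curve <- function(x, ...) {
  cat(sprintf("%s curve (%s - %s): delta_J = %.4f, delta_K = %.4f\n",
              x$kind, x$treatment, x$control, x$delta_j, x$delta_k))
  invisible(x)
}
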