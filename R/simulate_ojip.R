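#' Parameters of the OJIP transient generator
#'
#' The generator models a fast fluorescence induction transient as a sum of
#' three saturating-exponential rises standing in for the O-J, J-I and I-P
#' phases, plus an optional Gaussian-in-log-time "K-band" bump centred at
#' 300 microseconds. This is the minimal shape that carries every landmark
#' the JIP-test reads (O at the minimum, K at 300 us, J at 2 ms, P at the
#' maximum) while staying agnostic about photosystem biophysics.
#'
#' @param f_o Basal fluorescence (arbitrary units), the O level.
#' @param f_m Maximal fluorescence (a.u.), the P level; must exceed `f_o`.
#' @param phase_weights Three nonnegative fractions for the O-J, J-I and I-P
#'   rises; must sum to 1 (within 1e-9).
#' @param phase_timescales Three strictly increasing time constants in
#'   seconds. Defaults place the half-rises near the J (2 ms) and I (30 ms)
#'   regions of a Handy-PEA-style trace.
#' @param k_band_amp Additive amplitude of the K-band bump at 300 us (a.u.);
#'   0 disables it.
#' @param j_step_shift Dimensionless multiplier applied to the O-J phase
#'   weight (weights are renormalized afterwards, so the P level is
#'   preserved). Values > 1 raise the J step, emulating acceptor-side
#'   electron-transport blockage.
#' @param noise_sd Standard deviation of multiplicative lognormal noise on
#'   the fluorescence signal; 0 gives the noise-free ideal curve.
#'
#' @return An object of class `ojip_params` (a validated list).
#' @export
ojip_params <- function(f_o = 2000, f_m = 12000,
                        phase_weights = c(0.5, 0.3, 0.2),
                        phase_timescales = c(5e-4, 8e-3, 8e-2),
                        k_band_amp = 0, j_step_shift = 1,
                        noise_sd = 0.02) {
  if (!(f_m > f_o && f_o > 0)) {
    stop("require f_m > f_o > 0", call. = FALSE)
  }
  if (length(phase_weights) != 3L || any(phase_weights < 0) ||
      abs(sum(phase_weights) - 1) > 1e-9) {
    stop("phase_weights must be three nonnegative fractions summing to 1",
         call. = FALSE)
  }
  if (length(phase_timescales) != 3L || any(diff(phase_timescales) <= 0) ||
      any(phase_timescales <= 0)) {
    stop("phase_timescales must be three strictly increasing positive values",
         call. = FALSE)
  }
  if (k_band_amp < 0) stop("k_band_amp must be nonnegative", call. = FALSE)
  if (j_step_shift <= 0) stop("j_step_shift must be positive", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be nonnegative", call. = FALSE)
  structure(
    list(f_o = f_o, f_m = f_m,
         phase_weights = phase_weights,
         phase_timescales = phase_timescales,
         k_band_amp = k_band_amp,
         j_step_shift = j_step_shift,
         noise_sd = noise_sd),
    class = "ojip_params"
  )
}

#' Noise-free OJIP transient at given times
#'
#' Evaluates the generator's closed-form ideal curve: the J-step-shifted,
#' renormalized three-phase saturating rise between `f_o` and `f_m`, plus
#' the K-band bump (Gaussian in log10 time, sigma 0.15 decades, centred at
#' 300 us).
#'
#' @param t Times in seconds (positive).
#' @param params An [ojip_params()] object.
#' @return Fluorescence values (a.u.) at `t`.
#' @export
ojip_ideal <- function(t, params) {
  stopifnot(inherits(params, "ojip_params"))
  w <- params$phase_weights
  w[1] <- w[1] * params$j_step_shift
  w <- w / sum(w)
  tau <- params$phase_timescales
  rise <- w[1] * (1 - exp(-t / tau[1])) +
    w[2] * (1 - exp(-t / tau[2])) +
    w[3] * (1 - exp(-t / tau[3]))
  bump <- params$k_band_amp *
    exp(-(log10(t) - log10(3e-4))^2 / (2 * 0.15^2))
  params$f_o + (params$f_m - params$f_o) * rise + bump
}

#' Simulate OJIP transients for a study design
#'
#' Generates one fluorescence transient per sample on a logarithmic time
#' grid (default 120 points, 10 us to 1 s, the span of a 1-second
#' saturating-pulse measurement). Noise is multiplicative lognormal so
#' fluorescence stays positive. Per-group parameters allow planting J-step
#' and K-band treatment effects with known sign.
#'
#' @param params A single [ojip_params()] object applied to every group, or
#'   a named list of `ojip_params` keyed by group label.
#' @param design A [study_design()].
#' @param n_points Number of log-spaced time points.
#' @param t_min,t_max Time range in seconds.
#'
#' @return A long data frame with columns `time_s`, `fluorescence`,
#'   `sample_id`, `group` (class `fluor_traces`).
#' @examples
#' tr <- simulate_ojip(ojip_params(noise_sd = 0), study_design())
#' head(tr)
#' @export
simulate_ojip <- function(params, design, n_points = 120L,
                          t_min = 1e-5, t_max = 1) {
  stopifnot(inherits(design, "study_design"))
  if (inherits(params, "ojip_params")) {
    params <- stats::setNames(
      rep(list(params), length(design$groups)), design$groups)
  }
  if (!all(design$groups %in% names(params))) {
    stop("params must cover every design group", call. = FALSE)
  }
  tgrid <- 10^seq(log10(t_min), log10(t_max), length.out = n_points)
  # snap the nearest grid points onto the K (300 us) and J (2 ms) marks so
  # landmark reads need no interpolation error on generator output
  for (t0 in c(3e-4, 2e-3)) {
    if (t0 > t_min && t0 < t_max) {
      tgrid[which.min(abs(log10(tgrid) - log10(t0)))] <- t0
    }
  }
  set.seed(child_seed(design$seed, "ojip"))
  out <- lapply(seq_len(nrow(design$samples)), function(i) {
    s <- design$samples[i, ]
    p <- params[[s$group]]
    f <- ojip_ideal(tgrid, p)
    if (p$noise_sd > 0) {
      f <- f * exp(stats::rnorm(n_points, 0, p$noise_sd))
    }
    data.frame(time_s = tgrid, fluorescence = f,
               sample_id = s$sample_id, group = s$group,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  class(out) <- c("fluor_traces", class(out))
  out
}

#' Simulate PAM fluorescence records
#'
#' Draws per-sample dark-adapted (`Fo`, `Fm`) and light-adapted
#' (`Fm_prime`, `F`) fluorescence levels so that the group means of the
#' derived parameters Fv/Fm, Y(II) and Fo match the supplied targets. The
#' defaults reproduce a typical UV-B experiment: a strong Fv/Fm drop under
#' UV-B that is partly restored by exogenous ABA, a milder Y(II) response,
#' and essentially unchanged Fo.
#'
#' @param design A [study_design()].
#' @param fvfm,yii,fo Named numeric vectors of per-group target means for
#'   Fv/Fm, Y(II) and Fo (names must cover the design groups).
#' @param fvfm_sd,yii_sd,fo_sd Per-group replicate standard deviations.
#' @param fm_prime_mean Mean light-adapted maximal fluorescence (a.u.).
#'
#' @return A data frame of PAM records: `sample_id`, `group`, `Fo`, `Fm`,
#'   `Fm_prime`, `F`.
#' @export
simulate_pam <- function(design,
                         fvfm = c(M = 0.80, N = 0.57, Q = 0.68),
                         yii = c(M = 0.18, N = 0.13, Q = 0.17),
                         fo = c(M = 0.1065, N = 0.1072, Q = 0.1056),
                         fvfm_sd = c(M = 0.002, N = 0.017, Q = 0.029),
                         yii_sd = c(M = 0.008, N = 0.012, Q = 0.031),
                         fo_sd = c(M = 0.0016, N = 0.0036, Q = 0.0050),
                         fm_prime_mean = 0.5) {
  stopifnot(inherits(design, "study_design"))
  for (v in list(fvfm, yii, fo, fvfm_sd, yii_sd, fo_sd)) {
    if (!all(design$groups %in% names(v))) {
      stop("per-group parameter vectors must name every design group",
           call. = FALSE)
    }
  }
  set.seed(child_seed(design$seed, "pam"))
  g <- design$samples$group
  n <- nrow(design$samples)
  draw <- function(mu, sd, lo, hi) {
    pmin(hi, pmax(lo, stats::rnorm(n, mu[g], sd[g])))
  }
  fvfm_i <- draw(fvfm, fvfm_sd, 0.01, 0.99)
  yii_i <- draw(yii, yii_sd, 0.001, 0.99)
  fo_i <- draw(fo, fo_sd, 1e-4, Inf)
  fm_i <- fo_i / (1 - fvfm_i)
  fmp_i <- pmax(stats::rnorm(n, fm_prime_mean, 0.02 * fm_prime_mean), 1e-3)
  f_i <- fmp_i * (1 - yii_i)
  data.frame(sample_id = design$samples$sample_id, group = g,
             Fo = fo_i, Fm = fm_i, Fm_prime = fmp_i, F = f_i,
             stringsAsFactors = FALSE)
}
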