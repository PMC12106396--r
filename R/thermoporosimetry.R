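#' Gibbs-Thomson constants for water-in-pore melting
#'
#' Parameters of the melting-point-depression relation
#' `D = 4 T0 gamma cos(theta) / ((Tm - T0) rho Hf)` for water confined
#' in cylindrical pores: bulk melting temperature `T0`, ice-water
#' interfacial energy `gamma`, contact angle `theta` (180 degrees for a
#' non-wetting ice-wall contact, so `cos(theta) = -1` and D comes out
#' positive for depressed `Tm < T0`), density `rho` of the melting
#' phase and specific heat of fusion `Hf`.
#'
#' @param T0_K bulk melting temperature (K); default 273.15.
#' @param gamma_mJ_m2 interfacial energy (mJ/m^2); default 12.1.
#' @param theta_contact_deg contact angle (degrees); default 180.
#' @param rho_kg_m3 density (kg/m^3); default 1000.
#' @param Hf_J_g specific heat of fusion (J/g); default 334.
#' @return An object of class `gibbs_thomson_params`.
#' @export
gibbs_thomson_params <- function(T0_K = 273.15, gamma_mJ_m2 = 12.1,
                                 theta_contact_deg = 180,
                                 rho_kg_m3 = 1000, Hf_J_g = 334) {
  stopifnot(T0_K > 0, gamma_mJ_m2 > 0, rho_kg_m3 > 0, Hf_J_g > 0)
  structure(list(T0_K = T0_K, gamma_mJ_m2 = gamma_mJ_m2,
                 theta_contact_deg = theta_contact_deg,
                 rho_kg_m3 = rho_kg_m3, Hf_J_g = Hf_J_g),
            class = "gibbs_thomson_params")
}

#' @export
print.gibbs_thomson_params <- function(x, ...) {
  cat(sprintf(
    "Gibbs-Thomson constants: T0 = %.2f K, gamma = %.1f mJ/m^2, theta = %g deg, rho = %g kg/m^3, Hf = %g J/g\n",
    x$T0_K, x$gamma_mJ_m2, x$theta_contact_deg, x$rho_kg_m3, x$Hf_J_g))
  invisible(x)
}

# 4 T0 gamma |cos theta| / (rho Hf) in nm * K: the constant value of
# D * |Tm - T0|.
gt_constant_nm_K <- function(params) {
  4 * params$T0_K * (params$gamma_mJ_m2 * 1e-3) *
    abs(cos(params$theta_contact_deg * pi / 180)) /
    (params$rho_kg_m3 * params$Hf_J_g * 1000) * 1e9
}

#' Pore diameter from a depressed melting temperature (Gibbs-Thomson)
#'
#' `D = 4 T0 gamma cos(theta) / ((Tm - T0) rho Hf)`, with units
#' reconciled internally (gamma in J/m^2, Hf in J/kg) and the result
#' returned in nm. D is strictly increasing in `Tm` on `(-Inf, T0)` and
#' `D * |Tm - T0|` is constant at `4 T0 gamma |cos theta| / (rho Hf)`.
#'
#' @param Tm_K depressed melting temperature(s) in K, `< T0`.
#' @param params a [gibbs_thomson_params].
#' @return pore diameter(s) in nm.
#' @export
gibbs_thomson_diameter <- function(Tm_K, params = gibbs_thomson_params()) {
  stopifnot(inherits(params, "gibbs_thomson_params"))
  if (any(Tm_K >= params$T0_K)) {
    stop("Tm must be below T0 (no melting-point depression)", call. = FALSE)
  }
  gt_constant_nm_K(params) / (params$T0_K - Tm_K) *
    sign(-cos(params$theta_contact_deg * pi / 180))
}

#' Melting temperature of water in a pore of given diameter
#'
#' Exact algebraic inverse of [gibbs_thomson_diameter()]:
#' `Tm = T0 - 4 T0 gamma |cos theta| / (D rho Hf)`.
#'
#' @param D_nm pore diameter(s) in nm, > 0.
#' @param params a [gibbs_thomson_params].
#' @return melting temperature(s) in K.
#' @export
gibbs_thomson_temperature <- function(D_nm, params = gibbs_thomson_params()) {
  stopifnot(inherits(params, "gibbs_thomson_params"))
  if (any(D_nm <= 0)) stop("pore diameter must be positive", call. = FALSE)
  params$T0_K - gt_constant_nm_K(params) / D_nm *
    sign(-cos(params$theta_contact_deg * pi / 180))
}

#' DSC heat-flow trace container
#'
#' @param time_s time in seconds, strictly increasing.
#' @param temp_C sample temperature in Celsius.
#' @param heatflow_mW heat flow in mW, endotherm-positive.
#' @param mass_wet_mg fully saturated sample mass (mg), > dry mass.
#' @param mass_dry_mg oven-dry sample mass (mg), > 0.
#' @return A list of class `dsc_trace` with a `data` data frame and the
#'   two masses. Total water is `mass_wet_mg - mass_dry_mg`.
#' @export
dsc_trace <- function(time_s, temp_C, heatflow_mW, mass_wet_mg, mass_dry_mg) {
  stopifnot(length(time_s) == length(temp_C),
            length(time_s) == length(heatflow_mW))
  if (any(diff(time_s) <= 0)) {
    stop("time must be strictly increasing", call. = FALSE)
  }
  if (!(mass_dry_mg > 0) || !(mass_wet_mg > mass_dry_mg)) {
    stop("need mass_wet_mg > mass_dry_mg > 0", call. = FALSE)
  }
  structure(list(
    data = data.frame(time_s = time_s, temp_C = temp_C,
                      heatflow_mW = heatflow_mW),
    mass_wet_mg = mass_wet_mg, mass_dry_mg = mass_dry_mg),
    class = "dsc_trace")
}

#' @export
print.dsc_trace <- function(x, ...) {
  cat(sprintf(
    "DSC trace: %d points over %.0f s, T in [%.1f, %.1f] C, wet %.2f mg / dry %.2f mg\n",
    nrow(x$data), diff(range(x$data$time_s)), min(x$data$temp_C),
    max(x$data$temp_C), x$mass_wet_mg, x$mass_dry_mg))
  invisible(x)
}

#' Read a DSC trace from CSV plus a sample sheet
#'
#' The trace CSV has columns `time_s`, `temp_C`, `heatflow_mW`; the
#' sample sheet is a JSON file (or list) with `mass_wet_mg` and
#' `mass_dry_mg`.
#'
#' @param path trace CSV path.
#' @param sample sample-sheet JSON path or named list.
#' @return A [dsc_trace].
#' @export
read_dsc_trace <- function(path, sample) {
  df <- utils::read.csv(path)
  need <- c("time_s", "temp_C", "heatflow_mW")
  if (!all(need %in% names(df))) {
    stop("trace CSV must have columns time_s, temp_C, heatflow_mW: ", path,
         call. = FALSE)
  }
  if (is.character(sample)) sample <- jsonlite::read_json(sample, simplifyVector = TRUE)
  if (is.null(sample$mass_wet_mg) || is.null(sample$mass_dry_mg)) {
    stop("sample sheet must provide mass_wet_mg and mass_dry_mg", call. = FALSE)
  }
  dsc_trace(df$time_s, df$temp_C, df$heatflow_mW,
            sample$mass_wet_mg, sample$mass_dry_mg)
}

#' @rdname read_dsc_trace
#' @param trace a [dsc_trace] to write.
#' @export
write_dsc_trace <- function(trace, path) {
  stopifnot(inherits(trace, "dsc_trace"))
  utils::write.csv(trace$data, path, row.names = FALSE)
  invisible(path)
}

#' Default isothermal-step protocol
#'
#' Isotherms placed at the Gibbs-Thomson melting temperatures of the
#' reported pore-size bin edges (7 nm and 17 nm; about -5.66 and
#' -2.33 C with the default constants) plus a final melt above 0 C that
#' collects bulk/free water. Fully overridable: any ascending vector of
#' step temperatures is accepted downstream.
#'
#' @param params a [gibbs_thomson_params].
#' @param bin_edges_nm pore-diameter bin edges (nm).
#' @param final_C final step temperature (C) above the bulk melt.
#' @return ascending numeric vector of step temperatures in Celsius.
#' @export
default_thermo_protocol <- function(params = gibbs_thomson_params(),
                                    bin_edges_nm = c(7, 17),
                                    final_C = 5) {
  c(gibbs_thomson_temperature(sort(bin_edges_nm), params) - 273.15, final_C)
}

#' Integrate melting enthalpy at each isothermal step
#'
#' For each protocol temperature the contiguous hold (all samples
#' within `temp_tol` of the set temperature) is located; the
#' endothermic transient inside the hold is integrated over time
#' (trapezoidal, mW * s -> J) above a linear baseline drawn between the
#' quiescent heat-flow levels at the start and end of the hold, and
#' normalised per gram of wet sample. Slightly negative integrals
#' (baseline noise) are clipped to zero with a warning.
#'
#' @param trace a [dsc_trace].
#' @param protocol_C ascending vector of isotherm temperatures (C).
#' @param temp_tol hold-detection temperature tolerance (C).
#' @param quiescent_frac fraction of hold points (each end) averaged to
#'   anchor the baseline.
#' @return A data frame of class `isotherm_steps`: `T_set_C`, `T_set_K`,
#'   `enthalpy_J_g` (J per g wet sample).
#' @export
segment_isotherms <- function(trace, protocol_C, temp_tol = 0.05,
                              quiescent_frac = 0.1) {
  stopifnot(inherits(trace, "dsc_trace"))
  if (any(diff(protocol_C) <= 0)) {
    stop("protocol temperatures must be ascending", call. = FALSE)
  }
  d <- trace$data
  res <- lapply(protocol_C, function(Tset) {
    at <- abs(d$temp_C - Tset) <= temp_tol
    if (!any(at)) {
      stop(sprintf("protocol temperature %.2f C is never reached", Tset),
           call. = FALSE)
    }
    runs <- rle(at)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    ok <- which(runs$values)
    pick <- ok[which.max(runs$lengths[ok])]   # longest hold at this T
    i <- starts[pick]:ends[pick]
    if (length(i) < 5L) {
      stop(sprintf("hold at %.2f C too short to integrate", Tset),
           call. = FALSE)
    }
    nq <- max(2L, floor(quiescent_frac * length(i)))
    head_i <- i[seq_len(nq)]
    tail_i <- i[seq.int(length(i) - nq + 1L, length(i))]
    t0 <- mean(d$time_s[head_i]); y0 <- mean(d$heatflow_mW[head_i])
    t1 <- mean(d$time_s[tail_i]); y1 <- mean(d$heatflow_mW[tail_i])
    base <- y0 + (y1 - y0) * (d$time_s[i] - t0) / (t1 - t0)
    excess <- d$heatflow_mW[i] - base
    e_mJ <- sum(diff(d$time_s[i]) * (excess[-1L] + excess[-length(excess)]) / 2)
    e_J <- e_mJ / 1000
    if (e_J < 0) {
      if (e_J < -1e-9) {
        warning(sprintf("negative enthalpy (%.3g J) at %.2f C clipped to 0",
                        e_J, Tset), call. = FALSE)
      }
      e_J <- 0
    }
    c(Tset, e_J / (trace$mass_wet_mg / 1000))
  })
  m <- do.call(rbind, res)
  structure(data.frame(T_set_C = m[, 1L], T_set_K = m[, 1L] + 273.15,
                       enthalpy_J_g = m[, 2L]),
            class = c("isotherm_steps", "data.frame"))
}

#' Calibration offset from a measured pure-water melting point
#'
#' The instrument temperature scale is calibrated by melting milli-Q
#' water alone at 1 C/min; the offset (measured melting point minus
#' T0) is applied additively to every isotherm temperature before the
#' Gibbs-Thomson conversion.
#'
#' @param measured_melt_K observed pure-water melting temperature (K).
#' @param params a [gibbs_thomson_params].
#' @return offset in K.
#' @export
calibration_offset <- function(measured_melt_K,
                               params = gibbs_thomson_params()) {
  measured_melt_K - params$T0_K
}

#' Freezing-water pore-size distribution from isothermal-step enthalpies
#'
#' Applies the calibration offset to the step temperatures, converts
#' them to pore diameters by the Gibbs-Thomson relation, and partitions
#' the melted water mass: step `i` melts the water held in pores with
#' diameter in `(D(T_{i-1}), D(T_i)]` (the first step is the open bin
#' below `D(T_1)`). Mass melted at a step is
#' `enthalpy * m_wet / Hf`; ratios are percentages of the total water
#' `m_wet - m_dry`. Steps at or above the offset-corrected bulk melting
#' point are pooled as bulk/free water, and the remainder
#' (`100 - sum(bins) - bulk`) is reported as non-freezing water, so the
#' three categories always total exactly 100%.
#'
#' @param steps an `isotherm_steps` data frame (ascending `T_set_K`).
#' @param trace the [dsc_trace] the steps came from (for the masses).
#' @param params a [gibbs_thomson_params].
#' @param calibration_offset_K additive temperature correction (K),
#'   see [calibration_offset()].
#' @param mass_tol relative tolerance on the water mass balance: a
#'   melted-mass total overshooting the gravimetric total water by at
#'   most this fraction (integration noise at full saturation) is
#'   rescaled to 100% with a warning; a larger overshoot is an error
#'   (inconsistent inputs).
#' @return A list of class `pore_distribution`: `bins` (data frame
#'   `d_lo_nm`, `d_hi_nm`, `T_set_C`, `freezing_water_ratio` in %),
#'   `bulk_pct`, `nonfreezing_pct`, `total_water_mg`.
#' @export
pore_distribution <- function(steps, trace,
                              params = gibbs_thomson_params(),
                              calibration_offset_K = 0,
                              mass_tol = 1e-3) {
  stopifnot(inherits(steps, "isotherm_steps"), inherits(trace, "dsc_trace"))
  if (any(diff(steps$T_set_K) <= 0)) {
    stop("isotherm steps must be ordered by ascending temperature",
         call. = FALSE)
  }
  m_w <- trace$mass_wet_mg - trace$mass_dry_mg
  T_corr <- steps$T_set_K + calibration_offset_K
  mass_mg <- steps$enthalpy_J_g * (trace$mass_wet_mg / 1000) /
    params$Hf_J_g * 1000
  if (sum(mass_mg) > m_w * (1 + mass_tol)) {
    stop(sprintf(
      "melted mass (%.3f mg) exceeds total water (%.3f mg): inconsistent inputs",
      sum(mass_mg), m_w), call. = FALSE)
  }
  if (sum(mass_mg) > m_w) {
    warning(sprintf(
      "melted mass overshoots total water by %.3g%% (integration noise at full saturation); rescaled",
      100 * (sum(mass_mg) / m_w - 1)), call. = FALSE)
    mass_mg <- mass_mg * (m_w / sum(mass_mg))
  }
  confined <- T_corr < params$T0_K
  D <- rep(NA_real_, length(T_corr))
  D[confined] <- gibbs_thomson_diameter(T_corr[confined], params)
  d_lo <- c(0, D[confined][-sum(confined)])
  bins <- data.frame(
    d_lo_nm = if (any(confined)) d_lo else numeric(0),
    d_hi_nm = D[confined],
    T_set_C = steps$T_set_C[confined],
    freezing_water_ratio = 100 * mass_mg[confined] / m_w)
  bulk_pct <- 100 * sum(mass_mg[!confined]) / m_w
  nonfreezing_pct <- 100 - sum(bins$freezing_water_ratio) - bulk_pct
  structure(list(bins = bins, bulk_pct = bulk_pct,
                 nonfreezing_pct = nonfreezing_pct, total_water_mg = m_w,
                 calibration_offset_K = calibration_offset_K),
            class = "pore_distribution")
}

#' @export
print.pore_distribution <- function(x, ...) {
  cat(sprintf("Pore-size distribution (total water %.2f mg):\n",
              x$total_water_mg))
  if (nrow(x$bins)) {
    for (i in seq_len(nrow(x$bins))) {
      cat(sprintf("  %6.2f - %6.2f nm : %5.1f %% of water\n",
                  x$bins$d_lo_nm[i], x$bins$d_hi_nm[i],
                  x$bins$freezing_water_ratio[i]))
    }
  }
  cat(sprintf("  bulk/free water    : %5.1f %%\n", x$bulk_pct))
  cat(sprintf("  non-freezing water : %5.1f %%\n", x$nonfreezing_pct))
  invisible(x)
}
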