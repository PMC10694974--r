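# EN-norm material-property calculators: compression (EN 826), three-point
# bending strength and modulus (EN 310), transverse tension (EN 319), raw
# density (EN 323), soak swelling/absorption (EN 317), water vapour
# diffusion (EN 12086), thermal conductivity (two-plate apparatus), and the
# small-flame flammability rule set (EN 13501-1 classes).

#' Stress-strain record of a compression test
#'
#' @param displacement_mm crosshead displacement samples (mm, increasing).
#' @param force_N force samples (N).
#' @param A0_mm2 initial cross-section (mm^2).
#' @param d0_mm initial specimen thickness (mm).
#' @param preload_N preload; when > 0 the displacement and force origin is
#'   re-zeroed at the first crossing of this force.
#' @param crosshead_speed_mm_min metadata.
#' @param density_kg_m3 metadata.
#' @return object of class `stress_strain_curve`.
#' @export
stress_strain_curve <- function(displacement_mm, force_N, A0_mm2, d0_mm,
                                preload_N = 20, crosshead_speed_mm_min = NA,
                                density_kg_m3 = NA) {
  if (length(displacement_mm) != length(force_N))
    mycomat_error("config", "displacement and force must have equal length")
  if (is.unsorted(displacement_mm))
    mycomat_error("config", "displacement samples must be ordered")
  if (A0_mm2 <= 0 || d0_mm <= 0)
    mycomat_error("config", "A0 and d0 must be > 0")
  structure(list(displacement_mm = as.numeric(displacement_mm),
                 force_N = as.numeric(force_N), A0_mm2 = A0_mm2, d0_mm = d0_mm,
                 preload_N = preload_N,
                 crosshead_speed_mm_min = crosshead_speed_mm_min,
                 density_kg_m3 = density_kg_m3),
            class = "stress_strain_curve")
}

#' Compressive stress at 10% strain (EN 826)
#'
#' Stress is `10^3 F / A0` in kPa and strain `X / d0 * 100` in percent.
#' With a positive preload the origin is re-zeroed at the preload crossing
#' (displacement by interpolation, force by subtracting the preload), which
#' discounts the deformation of the soft aerial-mycelium skin. The stress
#' at exactly 10% strain is obtained by linear interpolation between the
#' bracketing samples.
#'
#' @param curve a [stress_strain_curve()].
#' @return list of class `compression_result`: `sigma10_kPa`,
#'   `sigma_max_kPa`, `strain_at_max_pct` (all `qty`-tagged where
#'   dimensional).
#' @export
compute_compression <- function(curve) {
  X <- curve$displacement_mm
  F <- curve$force_N
  if (curve$preload_N > 0) {
    i <- which(F >= curve$preload_N)[1]
    if (is.na(i))
      mycomat_error("insufficient_range", "curve never reaches the preload")
    X0 <- if (i == 1L) X[1] else {
      X[i - 1] + (curve$preload_N - F[i - 1]) / (F[i] - F[i - 1]) * (X[i] - X[i - 1])
    }
    keep <- X >= X0
    X <- c(X0, X[keep]) - X0
    F <- pmax(c(curve$preload_N, F[keep]) - curve$preload_N, 0)
  }
  strain_pct <- X / curve$d0_mm * 100
  stress_kPa <- 1e3 * F / curve$A0_mm2
  if (max(strain_pct) < 10)
    mycomat_error("insufficient_range", sprintf(
      "curve ends at %.2f%% strain; 10%% required", max(strain_pct)))
  sigma10 <- stats::approx(strain_pct, stress_kPa, xout = 10, ties = "ordered")$y
  imax <- which.max(stress_kPa)
  structure(list(sigma10_kPa = qty(sigma10, "kPa"),
                 sigma_max_kPa = qty(stress_kPa[imax], "kPa"),
                 strain_at_max_pct = strain_pct[imax]),
            class = "compression_result")
}

#' Board specimen geometry (EN 310/312)
#'
#' Specimen length `a = 20 t_N + 50` mm and bearing span `l1 = 20 t_N` mm
#' follow from the nominal board thickness.
#'
#' @param t_N nominal board thickness (mm, >= 0).
#' @param b specimen width (mm, default 50).
#' @param t measured thickness (mm, defaults to `t_N`).
#' @return list of class `board_geometry` with `t_N`, `a`, `b`, `t`, `l1`,
#'   `l2`.
#' @examples
#' board_geometry(5)$a   # 150 mm
#' board_geometry(10)$l1 # 200 mm
#' @export
board_geometry <- function(t_N, b = 50, t = t_N) {
  if (t_N < 0) mycomat_error("config", "t_N must be >= 0")
  a <- 20 * t_N + 50
  structure(list(t_N = t_N, a = a, b = b, t = t, l1 = 20 * t_N, l2 = a),
            class = "board_geometry")
}

#' Bending test record
#'
#' @param deflection_mm centre deflection samples (mm).
#' @param force_N force samples (N).
#' @param geometry a [board_geometry()].
#' @return object of class `bending_record`.
#' @export
bending_record <- function(deflection_mm, force_N, geometry) {
  if (length(deflection_mm) != length(force_N))
    mycomat_error("config", "deflection and force must have equal length")
  if (!inherits(geometry, "board_geometry"))
    mycomat_error("config", "geometry must be a board_geometry")
  structure(list(deflection_mm = as.numeric(deflection_mm),
                 force_N = as.numeric(force_N), geometry = geometry),
            class = "bending_record")
}

#' Flexural strength (EN 310)
#'
#' `f_m = 3 F_max l1 / (2 b t^2)` with `F_max` the breaking force (global
#' force maximum).
#'
#' @param rec a [bending_record()].
#' @return `qty` in N mm^-2.
#' @export
flexural_strength <- function(rec) {
  g <- rec$geometry
  if (g$b <= 0 || g$t <= 0) mycomat_error("config", "zero width or thickness")
  F_max <- max(rec$force_N)
  qty(3 * F_max * g$l1 / (2 * g$b * g$t^2), "N mm-2")
}

#' Modulus of elasticity from three-point bending (EN 310)
#'
#' `E_M = l1^3 (F2 - F1) / (4 b t^3 (a2 - a1))`, with `F1`/`F2` at exactly
#' 10% and 40% of the breaking force and the matching deflections obtained
#' by linear interpolation on the rising branch.
#'
#' @param rec a [bending_record()].
#' @return `qty` in N mm^-2.
#' @export
modulus_of_elasticity <- function(rec) {
  g <- rec$geometry
  F <- rec$force_N
  a <- rec$deflection_mm
  imax <- which.max(F)
  F_up <- F[1:imax]
  a_up <- a[1:imax]
  F1 <- 0.1 * F[imax]
  F2 <- 0.4 * F[imax]
  if (F2 == F1) return(qty(0, "N mm-2"))
  a1 <- stats::approx(F_up, a_up, xout = F1, ties = "ordered")$y
  a2 <- stats::approx(F_up, a_up, xout = F2, ties = "ordered")$y
  if (!is.finite(a1) || !is.finite(a2) || a2 == a1)
    mycomat_error("degenerate_deflection", "zero deflection increment between F1 and F2")
  qty(g$l1^3 * (F2 - F1) / (4 * g$b * g$t^3 * (a2 - a1)), "N mm-2")
}

#' Transverse tensile strength (EN 319)
#'
#' `f_t = F_max / (a b)`.
#'
#' @param F_max_N breaking force (N).
#' @param a_mm,b_mm specimen length and width (mm).
#' @return `qty` in N mm^-2.
#' @examples
#' transverse_tensile_strength(775, 50, 50) # 0.31, the P1 threshold for 3-6 mm
#' @export
transverse_tensile_strength <- function(F_max_N, a_mm, b_mm) {
  if (a_mm <= 0 || b_mm <= 0) mycomat_error("config", "zero specimen area")
  qty(F_max_N / (a_mm * b_mm), "N mm-2")
}

#' Raw density (EN 323)
#'
#' `rho = m / (a b t) * 10^6` with the mass in g and dimensions in mm,
#' giving kg m^-3.
#'
#' @param m_g specimen mass (g).
#' @param a_mm,b_mm,t_mm length, width, thickness (mm).
#' @return `qty` in kg m^-3.
#' @examples
#' raw_density(16.65, 50, 50, 10) # 666 kg m-3
#' @export
raw_density <- function(m_g, a_mm, b_mm, t_mm) {
  if (a_mm <= 0 || b_mm <= 0 || t_mm <= 0)
    mycomat_error("config", "zero specimen volume")
  qty(m_g / (a_mm * b_mm * t_mm) * 1e6, "kg m-3")
}

#' Soak swelling and water absorption (EN 317)
#'
#' `G_t = (t2 - t1) / t1 * 100` and `W_t = (m2 - m1) / m1 * 100`, both in
#' percent.
#'
#' @param t1_mm,t2_mm thickness before/after immersion (mm).
#' @param m1_g,m2_g mass before/after immersion (g).
#' @return list with `G_t_pct` and `W_t_pct` (`qty` in %).
#' @export
soak_metrics <- function(t1_mm, t2_mm, m1_g, m2_g) {
  if (t1_mm <= 0 || m1_g <= 0)
    mycomat_error("config", "initial thickness and mass must be > 0")
  list(G_t_pct = qty((t2_mm - t1_mm) / t1_mm * 100, "%"),
       W_t_pct = qty((m2_g - m1_g) / m1_g * 100, "%"))
}

#' Thermal conductivity from a two-plate record
#'
#' `lambda = phi d / (A (T1 - T2))`.
#'
#' @param phi_W heat flux power to the heating plate (W).
#' @param d_m specimen thickness (m).
#' @param A_m2 measuring area (m^2).
#' @param T1_K,T2_K warm/cold surface temperature (K), `T1 > T2`.
#' @return `qty` in W (m K)^-1.
#' @examples
#' thermal_conductivity(9, 0.05, 0.25, 293.15, 283.15) # 0.18
#' @export
thermal_conductivity <- function(phi_W, d_m, A_m2, T1_K, T2_K) {
  if (A_m2 <= 0 || d_m <= 0) mycomat_error("config", "area and thickness must be > 0")
  if (T1_K == T2_K) mycomat_error("zero_gradient", "T1 must differ from T2")
  qty(phi_W * d_m / (A_m2 * (T1_K - T2_K)), "W (m K)-1")
}

# standard vapour-pressure differences of the EN 12086 climates
VAPOUR_CONDITIONS <- c(A = 1400, B = 2390, C = 1210)

#' Vapour mass-gain series
#'
#' @param time_h timestamps (h, strictly increasing).
#' @param mass_g cup+specimen masses (g).
#' @param A_m2 exposed specimen area (m^2).
#' @param delta_p_Pa vapour partial-pressure difference (Pa); alternatively
#'   give `condition` as `"A"`, `"B"` or `"C"` (1400/2390/1210 Pa).
#' @param d_m specimen thickness (m).
#' @param condition optional standard climate label.
#' @return object of class `vapour_series`.
#' @export
vapour_series <- function(time_h, mass_g, A_m2, delta_p_Pa = NULL, d_m,
                          condition = NULL) {
  if (length(time_h) != length(mass_g))
    mycomat_error("config", "time and mass must have equal length")
  if (any(diff(time_h) <= 0))
    mycomat_error("config", "timestamps must be strictly increasing")
  if (!is.null(condition)) {
    if (!condition %in% names(VAPOUR_CONDITIONS))
      mycomat_error("config", "condition must be 'A', 'B' or 'C'")
    dp <- VAPOUR_CONDITIONS[[condition]]
    if (!is.null(delta_p_Pa) && delta_p_Pa != dp)
      mycomat_error("config", sprintf(
        "condition %s implies delta_p = %g Pa, got %g", condition, dp, delta_p_Pa))
    delta_p_Pa <- dp
  }
  if (is.null(delta_p_Pa) || delta_p_Pa <= 0 || A_m2 <= 0 || d_m <= 0)
    mycomat_error("config", "A_m2, delta_p_Pa and d_m must be > 0")
  structure(list(time_h = as.numeric(time_h), mass_g = as.numeric(mass_g),
                 A_m2 = A_m2, delta_p_Pa = delta_p_Pa, d_m = d_m,
                 condition = condition),
            class = "vapour_series")
}

#' Water vapour diffusion coefficients (EN 12086)
#'
#' Fits the steady-state periodic mass change `G` as the slope of the
#' longest trailing window of the mass-time series whose linear fit has
#' `R^2 >= r2_min` (and at least 3 points), then evaluates the chain
#' `g = G / A`, `W = G / (A dp)`, `delta = W d`, `mu = delta_air / delta`.
#'
#' @param series a [vapour_series()].
#' @param delta_air air vapour diffusion conductivity in mg (m h Pa)^-1;
#'   the standard still-air value 0.72 by default (0.707 reproduces a
#'   diffusion resistance of 1.72 for delta = 0.411).
#' @param r2_min minimum R^2 of the steady-state fit.
#' @return list of class `vapour_coefficients` with `qty` fields
#'   `G_g_per_h`, `g_g_per_m2h`, `W_mg_per_m2hPa`, `delta_mg_per_mhPa`,
#'   `mu` (dimensionless), `delta_air_mg_per_mhPa`, plus
#'   `steady_state_points`.
#' @examples
#' s <- synth_vapour_series(W_true = 8.22, A_m2 = 0.025, delta_p_Pa = 2390,
#'                          d_m = 0.05, n_points = 10, noise_sd_g = 0, seed = 1)
#' vapour_coefficients(s)$g_g_per_m2h # 19.65
#' @export
vapour_coefficients <- function(series, delta_air = 0.72, r2_min = 0.999) {
  t <- series$time_h
  m <- series$mass_g
  n <- length(t)
  G <- NA_real_
  used <- 0L
  for (start in seq_len(n - 2L)) {
    tt <- t[start:n]; mm <- m[start:n]
    fit <- stats::lm(mm ~ tt)
    ss_tot <- sum((mm - mean(mm))^2)
    r2 <- if (ss_tot == 0) 1 else 1 - sum(stats::residuals(fit)^2) / ss_tot
    if (r2 >= r2_min) { G <- coef(fit)[["tt"]]; used <- n - start + 1L; break }
  }
  if (!is.finite(G))
    mycomat_error("no_steady_state", sprintf(
      "no trailing window of >= 3 points reaches R^2 >= %g", r2_min))
  g <- G / series$A_m2                      # g m-2 h-1
  W <- g / series$delta_p_Pa * 1000         # mg m-2 h-1 Pa-1
  delta <- W * series$d_m                   # mg m-1 h-1 Pa-1
  if (delta == 0) mycomat_error("zero_conductivity", "delta = 0: mu undefined")
  structure(list(G_g_per_h = qty(G, "g h-1"),
                 g_g_per_m2h = qty(g, "g (m2 h)-1"),
                 W_mg_per_m2hPa = qty(W, "mg (m2 h Pa)-1"),
                 delta_mg_per_mhPa = qty(delta, "mg (m h Pa)-1"),
                 mu = delta_air / delta,
                 delta_air_mg_per_mhPa = qty(delta_air, "mg (m h Pa)-1"),
                 steady_state_points = used),
            class = "vapour_coefficients")
}

#' Flammability observation
#'
#' @param flame_spread_mm vertical flame spread above the ignition point at
#'   60 s (mm).
#' @param horizontal_spread logical: fire expansion parallel to the surface
#'   (typical of melting, highly flammable foams).
#' @param burning_droplets logical: burning parts falling off.
#' @param smoke_class `"s1"`, `"s2"` or `"s3"` (measured externally per
#'   EN 13823).
#' @param flaming_time_s applied flaming time the specimen sustained
#'   (30 s for classes B/C/D, 15 s for class E).
#' @return object of class `flammability_observation`.
#' @export
flammability_observation <- function(flame_spread_mm, horizontal_spread,
                                     burning_droplets, smoke_class = "s2",
                                     flaming_time_s = 30) {
  if (!smoke_class %in% c("s1", "s2", "s3"))
    mycomat_error("config", "smoke_class must be s1, s2 or s3")
  if (is.na(flame_spread_mm) || is.na(horizontal_spread) || is.na(burning_droplets))
    mycomat_error("config", "flame spread, horizontal spread and droplets are mandatory")
  structure(list(flame_spread_mm = flame_spread_mm,
                 horizontal_spread = isTRUE(horizontal_spread),
                 burning_droplets = isTRUE(burning_droplets),
                 smoke_class = smoke_class, flaming_time_s = flaming_time_s),
            class = "flammability_observation")
}

#' Small-flame flammability classification (EN 13501-1 rule set)
#'
#' Horizontal fire spread, or failure to sustain more than the 15 s
#' exposure, classifies the material as highly flammable (`"E"`). A
#' specimen surviving the 30 s exposure with a vertical flame spread of at
#' most 150 mm at 60 s, no horizontal spread and no burning droplets is
#' low-flammability `"B1"`, reported with its smoke class and droplet
#' suffix (`d0`). Anything else is `"unclassified"`, with the violated
#' rules attached as attribute `reasons`.
#'
#' @param obs a [flammability_observation()].
#' @return class label string.
#' @examples
#' classify_flammability(flammability_observation(120, FALSE, FALSE, "s2")) # "B1-s2-d0"
#' @export
classify_flammability <- function(obs) {
  if (!inherits(obs, "flammability_observation"))
    mycomat_error("config", "obs must be a flammability_observation")
  if (obs$horizontal_spread || obs$flaming_time_s <= 15) return("E")
  reasons <- character(0)
  if (obs$flaming_time_s < 30)
    reasons <- c(reasons, sprintf("flaming time %g s below the 30 s class-B exposure",
                                  obs$flaming_time_s))
  if (obs$flame_spread_mm > 150)
    reasons <- c(reasons, sprintf("flame spread %g mm exceeds 150 mm at 60 s",
                                  obs$flame_spread_mm))
  if (obs$burning_droplets)
    reasons <- c(reasons, "burning droplets observed")
  if (!length(reasons))
    return(paste0("B1-", obs$smoke_class, "-d0"))
  structure("unclassified", reasons = reasons)
}
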