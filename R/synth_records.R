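# Synthetic mechanical/physical test records with closed-form ground
# truth, emulating the structure of the laboratory measurements: foam-like
# compression curves, cup-method vapour mass gains, and linear-elastic
# bending ramps with a brittle break.

#' Piecewise foam compression model
#'
#' Stress (kPa) as a function of strain (fraction) for a foam-like
#' composite: a quadratic toe blending into a linear elastic branch of
#' modulus `E = stiffness_per_density * density`, then a shallow plateau.
#' The curve is continuous, differentiable at the toe and monotone
#' non-decreasing.
#'
#' @param strain strain as a fraction (0.1 = 10%).
#' @param density_kg_m3 specimen density; scales the elastic modulus.
#' @param model list with `toe_strain`, `plateau_strain`,
#'   `stiffness_per_density` (kPa per kg m^-3) and `plateau_ratio`
#'   (plateau slope / elastic slope).
#' @return stress in kPa.
#' @export
compression_model_stress <- function(strain, density_kg_m3,
                                     model = compression_model()) {
  E <- model$stiffness_per_density * density_kg_m3
  te <- model$toe_strain
  tp <- model$plateau_strain
  s_lin <- function(e) E * (e - te / 2)
  ifelse(strain <= 0, 0,
         ifelse(strain < te, E * strain^2 / (2 * te),
                ifelse(strain <= tp, s_lin(strain),
                       s_lin(tp) + model$plateau_ratio * E * (strain - tp))))
}

#' @rdname compression_model_stress
#' @param toe_strain extent of the initial soft toe (aerial-mycelium skin).
#' @param plateau_strain onset of the densification plateau.
#' @param stiffness_per_density elastic modulus per unit density.
#' @param plateau_ratio plateau slope relative to the elastic slope.
#' @export
compression_model <- function(toe_strain = 0.02, plateau_strain = 0.15,
                              stiffness_per_density = 4.5,
                              plateau_ratio = 0.15) {
  list(toe_strain = toe_strain, plateau_strain = plateau_strain,
       stiffness_per_density = stiffness_per_density,
       plateau_ratio = plateau_ratio)
}

#' Synthetic compression test record
#'
#' Emits a force-displacement record: a linear pre-travel up to the
#' preload, then `F = preload + A0 * sigma(strain) / 1000` with the
#' piecewise foam model, optionally with multiplicative noise. Stress is
#' monotone non-decreasing in strain and the elastic slope scales with
#' density.
#'
#' @param density_kg_m3 specimen density (> 0).
#' @param model a [compression_model()].
#' @param seed RNG seed.
#' @param A0_mm2,d0_mm specimen cross-section and height.
#' @param preload_N preload force.
#' @param max_strain last strain sampled (fraction).
#' @param n_points number of samples past the preload.
#' @param noise_sd relative (multiplicative) noise sd on the force.
#' @return a [stress_strain_curve()].
#' @export
synth_compression_curve <- function(density_kg_m3, model = compression_model(),
                                    seed = 1L, A0_mm2 = 1e4, d0_mm = 100,
                                    preload_N = 20, max_strain = 0.2,
                                    n_points = 201L, noise_sd = 0) {
  if (density_kg_m3 <= 0) mycomat_error("config", "density must be > 0")
  if (A0_mm2 <= 0 || d0_mm <= 0) mycomat_error("config", "geometry must be positive")
  set.seed(seed)
  pre_travel <- 0.5 # mm of seating travel before the preload is reached
  strain <- seq(0, max_strain, length.out = n_points)
  X <- c(seq(0, pre_travel, length.out = 5L)[-5L], pre_travel + strain * d0_mm)
  F_pre <- seq(0, preload_N, length.out = 5L)[-5L]
  F_main <- preload_N + A0_mm2 * compression_model_stress(strain, density_kg_m3, model) / 1e3
  F <- c(F_pre, F_main)
  if (noise_sd > 0) {
    F <- F * (1 + rnorm(length(F), 0, noise_sd))
    F <- cummax(F) # keep the record physically monotone
  }
  stress_strain_curve(X, F, A0_mm2 = A0_mm2, d0_mm = d0_mm,
                      preload_N = preload_N, density_kg_m3 = density_kg_m3)
}

#' Synthetic cup-method vapour series
#'
#' `mass(t) = m0 + W_true * A * dp * t + noise` with strictly increasing
#' hourly timestamps; the metadata (area, pressure difference, thickness)
#' is attached to the returned series.
#'
#' @param W_true true vapour diffusion transmittance in mg (m^2 h Pa)^-1.
#' @param A_m2 exposed area (m^2).
#' @param delta_p_Pa vapour pressure difference (Pa).
#' @param d_m specimen thickness (m).
#' @param n_points number of weighings (>= 3).
#' @param noise_sd_g balance/climate noise sd (g).
#' @param seed RNG seed.
#' @param m0_g starting mass of the installation.
#' @param dt_h weighing interval (h).
#' @return a [vapour_series()].
#' @export
synth_vapour_series <- function(W_true, A_m2, delta_p_Pa, d_m,
                                n_points = 10L, noise_sd_g = 0, seed = 1L,
                                m0_g = 500, dt_h = 1) {
  if (W_true <= 0 || A_m2 <= 0 || delta_p_Pa <= 0 || d_m <= 0 || dt_h <= 0)
    mycomat_error("config", "all physical quantities must be > 0")
  if (n_points < 3L) mycomat_error("config", "need at least 3 weighings")
  set.seed(seed)
  t <- (seq_len(n_points) - 1L) * dt_h
  rate_g_h <- W_true / 1000 * A_m2 * delta_p_Pa
  m <- m0_g + rate_g_h * t
  if (noise_sd_g > 0) m <- m + rnorm(n_points, 0, noise_sd_g)
  vapour_series(t, m, A_m2 = A_m2, delta_p_Pa = delta_p_Pa, d_m = d_m)
}

#' Synthetic three-point bending record
#'
#' Linear force-deflection ramp of the given stiffness up to the breaking
#' force `F_max = f_m_true * 2 b t^2 / (3 l1)`, after which the force
#' drops to zero (brittle break).
#'
#' @param f_m_true flexural strength to encode (N mm^-2).
#' @param geometry a [board_geometry()].
#' @param stiffness_N_mm ramp slope (N per mm of deflection, > 0).
#' @param seed RNG seed.
#' @param n_points samples on the rising ramp.
#' @param noise_sd relative noise on the ramp forces.
#' @return a [bending_record()].
#' @export
synth_bending_record <- function(f_m_true, geometry, stiffness_N_mm = 50,
                                 seed = 1L, n_points = 100L, noise_sd = 0) {
  if (stiffness_N_mm <= 0) mycomat_error("config", "stiffness must be > 0")
  if (f_m_true < 0) mycomat_error("config", "f_m_true must be >= 0")
  set.seed(seed)
  g <- geometry
  F_max <- f_m_true * 2 * g$b * g$t^2 / (3 * g$l1)
  a_max <- F_max / stiffness_N_mm
  a <- seq(0, a_max, length.out = n_points)
  F <- stiffness_N_mm * a
  if (noise_sd > 0) {
    F <- F * (1 + rnorm(n_points, 0, noise_sd))
    F <- cummax(pmin(F, F_max))
    F[n_points] <- F_max
  }
  # brittle break: force drops to zero
  a <- c(a, a_max + c(0.01, 0.02) * max(a_max, 1))
  F <- c(F, 0, 0)
  bending_record(a, F, geometry)
}
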