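# Report figures: stress-strain families, property-vs-density scatters,
# the branching-frequency-vs-distance profile, and a log-log Ashby-style
# modulus-density chart. Each figure is written as vector (PDF) and,
# when the device is available, raster (PNG).

with_figure <- function(stem, draw, width = 7, height = 5) {
  out <- character(0)
  pdf_path <- paste0(stem, ".pdf")
  grDevices::pdf(pdf_path, width = width, height = height)
  tryCatch(draw(), finally = grDevices::dev.off())
  out <- c(out, pdf_path)
  if (isTRUE(capabilities("png"))) {
    png_path <- paste0(stem, ".png")
    ok <- tryCatch({
      grDevices::png(png_path, width = width * 100, height = height * 100)
      tryCatch(draw(), finally = grDevices::dev.off())
      TRUE
    }, error = function(e) FALSE)
    if (ok) out <- c(out, png_path)
  }
  out
}

plot_stress_strain_family <- function(curves) {
  prep <- lapply(curves, function(cv) {
    X <- cv$displacement_mm; F <- cv$force_N
    strain <- X / cv$d0_mm * 100
    stress <- 1e3 * F / cv$A0_mm2
    list(strain = strain, stress = stress)
  })
  xmax <- max(vapply(prep, function(p) max(p$strain), 0))
  ymax <- max(vapply(prep, function(p) max(p$stress), 0))
  plot(NA, xlim = c(0, xmax), ylim = c(0, ymax),
       xlab = "strain [%]", ylab = "stress [kPa]",
       main = "Compression stress-strain curves")
  for (i in seq_along(prep))
    lines(prep[[i]]$strain, prep[[i]]$stress, col = i)
}

plot_shell_profile_fig <- function(profile) {
  x <- (profile$r_inner_um + profile$r_outer_um) / 2
  plot(x, profile$frequency_per_um, type = "b", pch = 16,
       xlab = "distance to shive surface [um]",
       ylab = "branching frequency [um-1]",
       main = "Hyphal branching frequency vs distance")
}

plot_property_density <- function(df, property, unit) {
  plot(df$density_kg_m3, df[[property]], pch = 16,
       xlab = "density [kg m-3]", ylab = paste0(property, " [", unit, "]"),
       main = paste(property, "as a function of density"))
}

plot_ashby_fig <- function(df, ref_regions = NULL) {
  plot(df$density_kg_m3, df$modulus_N_mm2, log = "xy", pch = 16,
       xlab = "density [kg m-3]", ylab = "modulus of elasticity [N mm-2]",
       main = "Ashby chart: modulus vs density")
  if (!is.null(ref_regions)) {
    for (i in seq_len(nrow(ref_regions))) {
      rect(ref_regions$d0[i], ref_regions$m0[i], ref_regions$d1[i],
           ref_regions$m1[i], border = "grey50", lty = 2)
      text(sqrt(ref_regions$d0[i] * ref_regions$d1[i]),
           sqrt(ref_regions$m0[i] * ref_regions$m1[i]),
           ref_regions$label[i], col = "grey40", cex = 0.8)
    }
  }
}

#' Generate report figures
#'
#' Writes the figures for which results are present: a stress-strain
#' family plot (`curves`), property-vs-density scatters (`properties`, a
#' data.frame with a `density_kg_m3` column plus one column per property),
#' the branching-frequency shell profile (`shell_profile`), and a log-log
#' Ashby-style modulus-density scatter (`ashby`, columns `density_kg_m3`
#' and `modulus_N_mm2`, optionally with `ashby_regions`). Requested plots
#' without data are skipped with a warning. Figures are written as PDF
#' plus PNG when a raster device is available.
#'
#' @param results named list with any of `curves`, `properties`,
#'   `shell_profile`, `ashby`, `ashby_regions`.
#' @param out_dir output directory.
#' @return character vector of written files, invisibly.
#' @export
run_report <- function(results, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  if (!is.null(results$curves) && length(results$curves)) {
    written <- c(written, with_figure(file.path(out_dir, "stress_strain"),
                                      function() plot_stress_strain_family(results$curves)))
  }
  if (!is.null(results$shell_profile) && nrow(results$shell_profile)) {
    written <- c(written, with_figure(file.path(out_dir, "branching_profile"),
                                      function() plot_shell_profile_fig(results$shell_profile)))
  }
  if (!is.null(results$properties) && nrow(results$properties)) {
    props <- setdiff(names(results$properties), "density_kg_m3")
    for (p in props) {
      written <- c(written,
                   with_figure(file.path(out_dir, paste0(p, "_vs_density")),
                               local({ pp <- p; function() plot_property_density(results$properties, pp, "") })))
    }
  }
  if (!is.null(results$ashby) && nrow(results$ashby)) {
    written <- c(written, with_figure(file.path(out_dir, "ashby"),
                                      function() plot_ashby_fig(results$ashby, results$ashby_regions)))
  }
  if (!length(written)) warning("no results to plot; no figures written")
  invisible(written)
}
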