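# Seeded synthetic-data generators emulating the study conditions:
# pressure-probe cohorts with the published group means/SDs, zone-graded
# suberin monomer tables, and toy count matrices for TPM.

#' Reference transport-parameter summary for barley seminal roots
#'
#' Reads the published group summary (mean, SD, n = 8 per group) of
#' hydrostatic and osmotic Lpr, Psr and sigma for roots grown under
#' control conditions and under osmotic stress (-0.8 MPa), shipped with
#' the package.  These values parameterize the default synthetic cohorts.
#'
#' @return data frame with columns `parameter`, `group`, `mean`, `sd`,
#'   `n`, `units`.
#' @export
transport_reference <- function() {
  utils::read.csv(system.file("extdata", "barley_transport_reference.csv",
                              package = "rootprobe"))
}

#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generators with defaults
#' matching the study conditions: cohorts of 8 roots per group drawn from
#' the reference transport means/SDs; sensor noise sd 0.002 MPa; suberin
#' tables with 3 replicates, lognormal noise cv 0.15, the basipetal
#' zone gradient (diacids and omega-OH acids about ten-fold from zone A
#' to zone C, alcohols and fatty acids about two-fold) and a two-fold
#' aliphatic increase in zone B under osmotic stress of -0.8 MPa or
#' stronger.
#'
#' @param seed integer RNG seed.
#' @param n_roots roots per treatment group (default 8).
#' @param noise_sd pressure sensor noise sd, MPa (default 0.002).
#' @param dt_hydro,dt_osmotic sampling intervals, s.
#' @param duration_hydro,duration_osmotic trace lengths, s.
#' @param delta_pi osmotic step, MPa (default: 60 mOsmol/kg NaCl at
#'   23 C).
#' @param n_reps suberin replicates per group (default 3).
#' @param cv lognormal coefficient of variation of suberin replicate
#'   noise (default 0.15).
#' @param suberin_zone_c_aliphatic control total aliphatic suberin in
#'   zone C, micrograms per cm^2 (default 3.5, rising to about 7 under
#'   stress).
#' @param stress_multiplier fold-increase of zone-B aliphatic suberin
#'   under stress of -0.8 MPa or stronger (default 2).
#' @param n_genes,n_count_samples toy count-matrix dimensions.
#' @return a list of class `"simulation_config"`.
#' @export
simulation_config <- function(seed = 1L, n_roots = 8L, noise_sd = 0.002,
                              dt_hydro = 0.05, duration_hydro = 60,
                              dt_osmotic = 0.5, duration_osmotic = 2400,
                              delta_pi = vant_hoff_osmotic_pressure(60, 23),
                              n_reps = 3L, cv = 0.15,
                              suberin_zone_c_aliphatic = 3.5,
                              stress_multiplier = 2,
                              n_genes = 200L, n_count_samples = 4L) {
  stopifnot(noise_sd >= 0, cv >= 0, n_roots >= 1, n_reps >= 2)
  structure(as.list(environment()), class = "simulation_config")
}

# draw truncated normal by resampling (no boundary atoms)
.rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n, mean, sd)
    out <- c(out, x[x > lower & x < upper])
  }
  out[seq_len(n)]
}

#' Generate a synthetic pressure-probe cohort
#'
#' For each root in each treatment group, draws true transport parameters
#' from the reference group means and SDs (normal, truncated to physical
#' bounds by resampling), simulates one hydrostatic relaxation and one
#' biphasic osmotic response with Gaussian sensor noise, and returns the
#' traces together with a ground-truth manifest.  The osmotic trace's
#' water phase uses the root's osmotic Lpr; the hydrostatic trace uses
#' its hydrostatic Lpr (the two pathways differ in planta).
#'
#' @param config a [simulation_config()].
#' @param probe a [probe_system()]; default beta = 1.09e10 MPa m^-3,
#'   Ar = 1.57e-4 m^2, giving half-times of about 5 s (water) and 10 min
#'   (solute) at the control reference values.
#' @param geometry a [root_geometry()].
#' @param dir optional directory; when given, traces are written as CSVs
#'   and the manifest as `manifest.csv`.
#' @return list with `traces` (nested list per group/root: `hydrostatic`,
#'   `osmotic`) and `manifest` (data frame of true parameters per root).
#' @export
generate_probe_traces <- function(config = simulation_config(),
                                  probe = probe_system(1.09e10, 1.57e-4),
                                  geometry = root_geometry(), dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  ref <- transport_reference()
  groups <- unique(ref$group)
  get <- function(par, grp, what) ref[ref$parameter == par & ref$group == grp,
                                      what]
  manifest <- NULL
  traces <- list()
  for (grp in groups) {
    gtr <- list()
    for (r in seq_len(config$n_roots)) {
      Lpr_h <- .rtruncnorm(1, get("Lpr_hydrostatic", grp, "mean"),
                           get("Lpr_hydrostatic", grp, "sd"), lower = 1e-10)
      Lpr_o <- .rtruncnorm(1, get("Lpr_osmotic", grp, "mean"),
                           get("Lpr_osmotic", grp, "sd"), lower = 1e-10)
      Psr <- .rtruncnorm(1, get("Psr", grp, "mean"), get("Psr", grp, "sd"),
                         lower = 1e-12)
      sigma <- .rtruncnorm(1, get("sigma", grp, "mean"),
                           get("sigma", grp, "sd"), lower = 0, upper = 1)
      hy <- simulate_hydrostatic_relaxation(
        transport_params(Lpr_h, Psr, sigma), probe,
        duration = config$duration_hydro, dt = config$dt_hydro,
        noise_sd = config$noise_sd)
      os <- simulate_osmotic_response(
        transport_params(Lpr_o, Psr, sigma), probe, geometry,
        delta_pi = config$delta_pi, duration = config$duration_osmotic,
        dt = config$dt_osmotic, noise_sd = config$noise_sd)
      gtr[[r]] <- list(hydrostatic = hy, osmotic = os)
      manifest <- rbind(manifest, data.frame(
        group = grp, root = r, Lpr_hydrostatic = Lpr_h, Lpr_osmotic = Lpr_o,
        Psr = Psr, sigma = sigma))
    }
    traces[[grp]] <- gtr
  }
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (grp in groups) for (r in seq_len(config$n_roots)) {
      write_pressure_trace(traces[[grp]][[r]]$hydrostatic,
                           file.path(dir, sprintf("%s_root%02d_hydro.csv", grp, r)))
      write_pressure_trace(traces[[grp]][[r]]$osmotic,
                           file.path(dir, sprintf("%s_root%02d_osmotic.csv", grp, r)))
    }
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
  }
  list(traces = traces, manifest = manifest)
}

# class-level zone profile: control means in micrograms/cm^2 per zone.
# Zone A shares 33/9/9/49 % (fa/alc/diacid/omega-OH); the A->C gradient is
# two-fold for alcohols and fatty acids, ten-fold for diacids and omega-OH
# acids; zone B sits midway (geometric mean of the zone factors).
.suberin_class_means <- function(zone_c_total) {
  shareA <- c(fatty_acid = 0.33, alcohol = 0.09, diacid = 0.09,
              omega_oh_acid = 0.49)
  grad <- c(fatty_acid = 2, alcohol = 2, diacid = 10, omega_oh_acid = 10)
  zoneC_rel <- shareA * grad
  totalA <- zone_c_total / sum(zoneC_rel)
  zoneA <- shareA * totalA
  list(A = zoneA, B = zoneA * sqrt(grad), C = zoneA * grad)
}

# representative monomer homologues per class with within-class weights
.monomer_registry <- list(
  fatty_acid = c("C16 fatty acid" = 0.4, "C18 fatty acid" = 0.3,
                 "C22 fatty acid" = 0.2, "C24 fatty acid" = 0.1),
  alcohol = c("C18 alcohol" = 0.5, "C20 alcohol" = 0.3, "C22 alcohol" = 0.2),
  diacid = c("C16 diacid" = 0.2, "C18:1 diacid" = 0.6, "C18 diacid" = 0.2),
  omega_oh_acid = c("C16 omega-OH acid" = 0.15, "C18:1 omega-OH acid" = 0.35,
                    "C22 omega-OH acid" = 0.15, "C24 omega-OH acid" = 0.35))

.treatments <- c("control", "-0.4", "-0.8", "-1.2")

#' Generate a synthetic suberin monomer table
#'
#' Builds a GC-style monomer table (amounts in micrograms per sample)
#' whose expectations carry the structure of zone-resolved suberin
#' chemistry: aliphatic class means follow the basipetal gradient, a
#' stress multiplier (default two-fold) acts on zone-B aliphatics for
#' treatments at or below -0.8 MPa and on zone C for every stress level,
#' aromatics (coumaric + ferulic) are twice the control aliphatic total
#' per zone and unaffected by treatment.  Replicate noise is lognormal
#' with the configured cv.  Amounts are pre-multiplied by the zone's
#' endodermal area so that aggregation with the same areas recovers the
#' configured micrograms-per-cm^2 means.
#'
#' @param config a [simulation_config()].
#' @param areas named endodermal areas (cm^2) per zone; default from a
#'   200 micrometer endodermis radius and zone lengths of a 20 cm root.
#' @return list with `records` (data frame: `compound_label`,
#'   `amount_ug`, `zone`, `treatment`, `replicate`), `areas`, and
#'   `truth` (configured class means per zone x treatment,
#'   micrograms/cm^2).
#' @export
generate_monomer_table <- function(config = simulation_config(),
                                   areas = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + 1L)
  if (is.null(areas)) {
    root_len <- 20  # cm
    zs <- zone_scheme("chemistry")
    lens <- (zs$end_fraction - zs$start_fraction) * root_len
    areas <- stats::setNames(endodermal_surface_area(0.02, lens), zs$label)
  }
  cm <- .suberin_class_means(config$suberin_zone_c_aliphatic)
  sdlog <- sqrt(log(1 + config$cv^2))
  rec <- NULL
  truth <- NULL
  for (zone in names(cm)) for (trt in .treatments) {
    stress_level <- if (trt == "control") 0 else -as.numeric(trt)
    mult <- 1
    if (zone == "B" && stress_level >= 0.8) mult <- config$stress_multiplier
    if (zone == "C" && stress_level >= 0.4) mult <- config$stress_multiplier
    class_mean <- cm[[zone]] * mult
    aromatic_total <- 2 * sum(cm[[zone]])  # treatment-independent
    class_mean <- c(class_mean,
                    coumaric_acid = aromatic_total / 2,
                    ferulic_acid = aromatic_total / 2)
    truth <- rbind(truth, data.frame(zone = zone, treatment = trt,
                                     substance_class = names(class_mean),
                                     mean_ug_cm2 = unname(class_mean)))
    for (rep_i in seq_len(config$n_reps)) {
      for (cls in names(class_mean)) {
        labs <- if (cls %in% names(.monomer_registry)) .monomer_registry[[cls]]
                else stats::setNames(1, gsub("_", " ", cls))
        for (li in seq_along(labs)) {
          m <- class_mean[[cls]] * labs[[li]] * areas[[zone]]
          amt <- if (config$cv > 0 && m > 0)
            stats::rlnorm(1, log(m) - sdlog^2 / 2, sdlog) else m
          rec <- rbind(rec, data.frame(
            compound_label = names(labs)[li], amount_ug = amt,
            zone = zone, treatment = trt, replicate = rep_i))
        }
      }
    }
  }
  rownames(rec) <- NULL
  list(records = rec, areas = areas, truth = truth)
}

#' Generate a toy count matrix with transcript lengths
#'
#' Negative-binomial counts for a configurable gene set, with known
#' lengths, as a fixture for TPM summaries.  Gene 1 can be boosted by
#' `fold` to create a known expression ranking.
#'
#' @param config a [simulation_config()].
#' @param fold expression boost of gene 1 (default 1 = none).
#' @param dispersion NB dispersion (size parameter; default 10).
#' @return list with `counts` (genes x samples integer matrix),
#'   `lengths` (bp per gene), `base_expression` (true relative
#'   expression per gene).
#' @export
generate_counts <- function(config = simulation_config(), fold = 1,
                            dispersion = 10) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + 2L)
  g <- config$n_genes
  lengths <- round(stats::runif(g, 500, 5000))
  base <- stats::rlnorm(g, meanlog = 3, sdlog = 1)
  base[1] <- base[1] * fold
  mu <- outer(base * lengths / mean(lengths), rep(1, config$n_count_samples))
  counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = dispersion),
                   nrow = g,
                   dimnames = list(sprintf("gene%03d", seq_len(g)),
                                   sprintf("sample%d", seq_len(config$n_count_samples))))
  list(counts = counts, lengths = lengths, base_expression = base)
}
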