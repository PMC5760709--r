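## Named parameter presets for the synthetic-data generator.
##
## The "control" and "gaucher" presets encode the published condition values
## of the glycosphingolipid-accumulation (Gaucher-model) macrophage study:
## high-GP area fractions 13% vs 48%, tether force medians 30 vs 27 pN,
## tether counts 4.8 +/- 2.4 vs 11.1 +/- 4.3 per curve, Young's modulus
## median/mean 614/1031 vs 459/795 Pa, transferrin endocytosed fraction
## ~0.60 vs ~0.30 at 45 min (cholera toxin B ~0.40 in both), and a 3-fold
## larger immobile fraction for the non-raft lipid analog in Gaucher-type
## cells. Quantities the study reports only graphically use fixed design
## values documented in the methods vignette.

.frapCommon <- list(a = 0.6, noise_sd = 0.02, acq_bleach_rate = 0.003)

.afmCommon <- list(
  tether_force_sdlog = 0.3,
  force_noise_sd = 2,           # pN
  spring_constant = 0.03,       # N/m
  contact_point_range = c(1500, 2500),  # nm
  approach_start = 6000,        # nm
  tether_rupture_range = c(200, 5600),  # nm
  max_load = 1000,              # pN (1 nN load cap)
  nu = 0.5,
  half_angle = 35,              # degrees
  velocity = 2                  # um/s
)

.gpCommon <- list(
  gp_high = -0.60, gp_low = -0.90,
  domain_length_scale = 8,      # px
  photon_noise = 0.05,
  total_intensity = 200,
  background = 10
)

.endoCommon <- list(
  n_cells = 100, nucleus_radius = 8, cell_radius = 20,
  membrane_thickness = 5        # px
)

.presetTable <- list(
  control = list(
    frap = c(list(b = 0.15, tau = 10), .frapCommon),
    afm = c(list(E_median = 614, E_mean = 1031,
                 tether_count_mean = 4.8, tether_count_sd = 2.4,
                 tether_force_median = 30), .afmCommon),
    gp = c(list(high_area_fraction = 0.13), .gpCommon),
    endo = c(list(f_endo = c(transferrin = 0.60, ctxb = 0.40)),
             .endoCommon)
  ),
  gaucher = list(
    frap = c(list(b = 0.45, tau = 25), .frapCommon),
    afm = c(list(E_median = 459, E_mean = 795,
                 tether_count_mean = 11.1, tether_count_sd = 4.3,
                 tether_force_median = 27), .afmCommon),
    gp = c(list(high_area_fraction = 0.48), .gpCommon),
    endo = c(list(f_endo = c(transferrin = 0.30, ctxb = 0.40)),
             .endoCommon)
  )
)

#' Build a named simulation preset
#'
#' Returns the fully populated parameter set for one experimental condition
#' of the synthetic-data generator. The two built-in presets, "control" and
#' "gaucher", differ only in the condition-anchored fields (immobile
#' fraction and recovery time constant; Young's modulus median/mean; tether
#' force median; tether count mean/SD; high-GP area fraction; endocytosed
#' fraction); acquisition and geometry parameters are shared.
#'
#' The Young's modulus distribution is lognormal with its log-scale spread
#' fixed by the median/mean pair, sigma^2 = 2 log(mean / median), so that
#' both printed moments are reproduced.
#'
#' @param name preset name: \code{"control"} or \code{"gaucher"}.
#' @param ligand which endocytosis ligand the \code{endo} block describes:
#'   \code{"transferrin"} (45-min uptake) or \code{"ctxb"} (cholera toxin
#'   subunit B, 40-min uptake).
#' @return a \linkS4class{MemPreset} object.
#' @examples
#' ctrl <- makePreset("control")
#' ctrl@afm$tether_force_median   # 30 pN
#' makePreset("gaucher")@gp$high_area_fraction  # 0.48
#' @export
makePreset <- function(name, ligand = c("transferrin", "ctxb")) {
  ligand <- match.arg(ligand)
  if (!is.character(name) || length(name) != 1 ||
      !name %in% names(.presetTable))
    stop("unknown preset '", paste(name, collapse = ","),
         "'; available presets: ",
         paste(names(.presetTable), collapse = ", "))
  p <- .presetTable[[name]]
  afm <- p$afm
  afm$E_sdlog <- sqrt(2 * log(afm$E_mean / afm$E_median))
  endo <- p$endo
  endo$f_endo <- unname(endo$f_endo[ligand])
  endo$ligand <- ligand
  new("MemPreset", name = name, frap = p$frap, afm = afm, gp = p$gp,
      endo = endo)
}

#' @describeIn makePreset names of the built-in presets.
#' @export
availablePresets <- function() names(.presetTable)

setMethod("show", "MemPreset", function(object) {
  cat("MemPreset '", object@name, "' (ligand: ", object@endo$ligand, ")\n",
      sep = "")
  cat(sprintf("  frap: a=%.2f b=%.2f tau=%.1fs noise=%.3f\n",
              object@frap$a, object@frap$b, object@frap$tau,
              object@frap$noise_sd))
  cat(sprintf("  afm:  E median/mean %.0f/%.0f Pa, tethers %.1f+/-%.1f, force median %.0f pN\n",
              object@afm$E_median, object@afm$E_mean,
              object@afm$tether_count_mean, object@afm$tether_count_sd,
              object@afm$tether_force_median))
  cat(sprintf("  gp:   high-GP fraction %.2f (levels %.2f / %.2f)\n",
              object@gp$high_area_fraction, object@gp$gp_high,
              object@gp$gp_low))
  cat(sprintf("  endo: f_endo %.2f, %d cells\n", object@endo$f_endo,
              object@endo$n_cells))
})
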