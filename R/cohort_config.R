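#' Configuration for the synthetic two-group cohort generator
#'
#' Bundles every tunable of the simulated ASD/TD cohort: dimensions of the
#' anatomical and functional data, planted multiplicative group effects on
#' regional volumes and cortical thickness, per-group structural-covariance
#' coupling, per-group seed-network and homotopic functional coupling, and a
#' linear model tying phenotype scores to latent imaging features.
#'
#' The defaults reproduce the dimensions of the real cohort the pipeline was
#' designed around: 148 cortical regions for thickness and cortical gray
#' matter, 112 bilateral ROIs with 180 time points at TR = 2 s for the
#' resting-state series, 45 subcortical and 70 white-matter volume regions.
#' Default planted effects are a few percent (volume increments in gray
#' matter, decrements in white matter, enlarged caudate) with stronger
#' thickness-covariance modularity in the ASD group, so the generated data
#' carry the qualitative group structure the downstream analysis looks for.
#'
#' @param n_per_group Subjects per group (two groups are generated).
#' @param n_cortical Number of cortical regions (thickness and GM volume).
#' @param n_roi Number of resting-state ROIs (must be even; half per
#'   hemisphere).
#' @param n_timepoints Number of fMRI volumes per subject.
#' @param tr_seconds Repetition time of the simulated fMRI series, seconds.
#' @param n_subcortical,n_wm Number of subcortical / white-matter volume
#'   regions.
#' @param volume_effects Named numeric vector of fractional group effects on
#'   regional volumes (ASD mean = TD mean times `1 + effect`). Names must
#'   match volume region names; see [region_layout()].
#' @param thickness_effects Same, for cortical thickness regions.
#' @param covariance_strength List with elements `TD` and `ASD`, each
#'   `c(spatial = ..., global = ...)`: the fraction of thickness variance
#'   carried by a spatially banded field (inter-regional correlation
#'   decaying as `spatial_decay^distance` along the region index within a
#'   hemisphere) and by a single global factor. `spatial + global` must be
#'   < 1. A larger spatial share produces a more lattice-like
#'   structural-covariance network, hence lower relative global
#'   efficiency; a larger global share pushes the thresholded network
#'   toward a random topology.
#' @param spatial_decay Decay rate of the banded component's correlation
#'   per unit region-index distance (default 0.97).
#' @param seed_connectivity List with elements `TD` and `ASD`, each a named
#'   numeric vector of within-network coupling strengths `c` in \[0, 1) for
#'   the four seed networks (`caudate`, `ifg_oper`, `ifg_tri`, `dmn`).
#' @param homotopic_strength Named numeric `c(TD = ..., ASD = ...)`: shared
#'   variance fraction between homotopic ROI pairs.
#' @param volume_noise_sd,thickness_noise_sd Residual coefficient of
#'   variation of regional volumes / thickness around the group mean.
#' @param band Frequency band (Hz) of the generated BOLD-like signals;
#'   everything is band-limited white noise in this range.
#' @param phenotype_model List of per-score linear models; see
#'   [default_phenotype_model()].
#' @param seed Integer seed; the whole cohort is a pure function of the
#'   configuration including this seed.
#'
#' @return An object of class `cohort_config` (a validated list).
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(n_per_group = 30,
                          n_cortical = 148,
                          n_roi = 112,
                          n_timepoints = 180,
                          tr_seconds = 2.0,
                          n_subcortical = 45,
                          n_wm = 70,
                          volume_effects = default_volume_effects(),
                          thickness_effects = default_thickness_effects(),
                          covariance_strength = list(
                            TD = c(spatial = 0.30, global = 0.15),
                            ASD = c(spatial = 0.65, global = 0.05)
                          ),
                          spatial_decay = 0.97,
                          seed_connectivity = list(
                            TD = c(caudate = 0.45, ifg_oper = 0.40,
                                   ifg_tri = 0.40, dmn = 0.45),
                            ASD = c(caudate = 0.30, ifg_oper = 0.25,
                                    ifg_tri = 0.25, dmn = 0.35)
                          ),
                          homotopic_strength = c(TD = 0.25, ASD = 0.15),
                          volume_noise_sd = 0.10,
                          thickness_noise_sd = 0.05,
                          band = c(0.005, 0.1),
                          phenotype_model = default_phenotype_model(),
                          seed = 1L) {
  counts <- c(n_per_group = n_per_group, n_cortical = n_cortical,
              n_roi = n_roi, n_timepoints = n_timepoints,
              n_subcortical = n_subcortical, n_wm = n_wm)
  if (any(counts < 1) || any(counts != floor(counts)))
    stop("all counts must be positive integers")
  if (tr_seconds <= 0) stop("tr_seconds must be > 0")
  if (n_roi %% 2 != 0) stop("n_roi must be even (half per hemisphere)")
  if (n_cortical %% 2 != 0) stop("n_cortical must be even")
  if (volume_noise_sd <= 0 || thickness_noise_sd <= 0)
    stop("noise SDs must be > 0")
  if (length(band) != 2 || band[1] < 0 || band[2] <= band[1])
    stop("band must be c(low, high) with 0 <= low < high")
  for (g in c("TD", "ASD")) {
    cs <- covariance_strength[[g]]
    if (is.null(cs) || any(cs < 0) || sum(cs) >= 1 ||
        !all(c("spatial", "global") %in% names(cs)))
      stop("covariance_strength[[", g,
           "]] needs spatial/global shares >= 0 with spatial+global < 1")
    sc <- seed_connectivity[[g]]
    if (is.null(sc) || any(sc < 0) || any(sc >= 1))
      stop("seed_connectivity[[", g, "]] must lie in [0, 1)")
    hs <- homotopic_strength[[g]]
    if (is.na(hs) || hs < 0 || hs >= 1)
      stop("homotopic_strength[", g, "] must lie in [0, 1)")
    if (any(sc + hs >= 1))
      stop("seed_connectivity + homotopic_strength must stay below 1")
  }
  if (spatial_decay < 0 || spatial_decay >= 1)
    stop("spatial_decay must lie in [0, 1)")
  if (any(volume_effects <= -1) || any(thickness_effects <= -1))
    stop("multiplicative effects must be > -1 (values would turn negative)")
  cfg <- list(n_per_group = as.integer(n_per_group),
              n_cortical = as.integer(n_cortical),
              n_roi = as.integer(n_roi),
              n_timepoints = as.integer(n_timepoints),
              tr_seconds = tr_seconds,
              n_subcortical = as.integer(n_subcortical),
              n_wm = as.integer(n_wm),
              volume_effects = volume_effects,
              thickness_effects = thickness_effects,
              covariance_strength = covariance_strength,
              spatial_decay = spatial_decay,
              seed_connectivity = seed_connectivity,
              homotopic_strength = homotopic_strength,
              volume_noise_sd = volume_noise_sd,
              thickness_noise_sd = thickness_noise_sd,
              band = band,
              phenotype_model = phenotype_model,
              seed = as.integer(seed))
  structure(cfg, class = "cohort_config")
}

#' Default planted volume effects
#'
#' Fractional ASD-vs-TD group effects on regional volumes: enlarged caudate
#' and hippocampus, gray-matter volume increments of 5-10% in a spread of
#' cortical regions, white-matter decrements of 3.5-5% -- the magnitude and
#' sign pattern reported for school-age ASD cohorts.
#'
#' @return Named numeric vector of fractional effects.
#' @export
default_volume_effects <- function() {
  eff <- c(sc_caudate_L = 0.08, sc_caudate_R = 0.10,
           sc_hippocampus_L = 0.05, sc_hippocampus_R = 0.05)
  gm <- paste0("gm_ctx_", sprintf("%s_%03d", rep(c("L", "R"), each = 6),
                                  c(1, 10, 20, 30, 40, 50)))
  eff <- c(eff, stats::setNames(rep(0.07, length(gm)), gm))
  wm <- paste0("wm_", sprintf("%s_%03d", rep(c("L", "R"), each = 3),
                              c(2, 12, 22)))
  c(eff, stats::setNames(rep(-0.045, length(wm)), wm))
}

#' Default planted thickness effects
#'
#' Cortical thickness increments of about 4% in 18 regions (9 homotopic
#' pairs), matching the 2.5-5% increment range typical of ASD thickness
#' findings.
#'
#' @return Named numeric vector of fractional effects.
#' @export
default_thickness_effects <- function() {
  idx <- c(3, 8, 15, 22, 29, 36, 43, 50, 57)
  regions <- c(sprintf("ctx_L_%03d", idx), sprintf("ctx_R_%03d", idx))
  stats::setNames(rep(0.04, length(regions)), regions)
}

#' Default phenotype coupling model
#'
#' Linear models tying each clinical score to standardized imaging
#' features: `score = intercept + scale * (sum(beta * z) + N(0, sd))`,
#' truncated and rounded to a plausible integer range. The planted signs
#' mirror the reported feature-phenotype correlation structure: ADOS scores
#' couple negatively to caudate and inferior-frontal connectivity
#' summaries, full-scale IQ negatively to caudate connectivity, VABS
#' socialization positively to caudate connectivity strength. Scores
#' specific to the clinical group (ADOS, ADI-R) are generated for ASD
#' subjects only and set to missing for controls.
#'
#' @return Named list of per-score models, each a list with elements
#'   `intercept`, `scale`, `sd`, `beta` (named numeric over canonical
#'   feature names), `range`, `integer`, `asd_only`.
#' @export
default_phenotype_model <- function() {
  score <- function(intercept, scale, sd, beta, range, asd_only = FALSE)
    list(intercept = intercept, scale = scale, sd = sd, beta = beta,
         range = range, integer = TRUE, asd_only = asd_only)
  list(
    ados_total = score(12, 4, 0.8,
                       c(fc_caudate_N = -0.45, fc_ifg_tri_N = -0.35),
                       c(0, 22), asd_only = TRUE),
    ados_module = score(10, 4, 0.8,
                        c(fc_ifg_oper_N = -0.55, fc_ifg_oper_Z = -0.30),
                        c(0, 22), asd_only = TRUE),
    ados_social_affect = score(10, 3.5, 0.8, c(fc_caudate_N = -0.45),
                               c(0, 20), asd_only = TRUE),
    ados_communication = score(4, 1.8, 0.9, c(fc_ifg_tri_N = -0.45),
                               c(0, 8), asd_only = TRUE),
    ados_research = score(11, 4, 0.85, c(fc_caudate_N = -0.43),
                          c(0, 22), asd_only = TRUE),
    adir_total = score(35, 9, 0.8, c(fc_caudate_N = -0.40,
                                     fc_ifg_oper_N = -0.30),
                       c(0, 60), asd_only = TRUE),
    iq_full = score(108, 16, 0.85, c(fc_caudate_N = -0.35,
                                     fc_caudate_Z = -0.35),
                    c(40, 160)),
    iq_verbal = score(106, 16, 0.9, c(fc_caudate_Z = -0.35), c(40, 160)),
    iq_performance = score(107, 16, 0.95, c(fc_caudate_N = -0.30),
                           c(40, 160)),
    srs_total = score(80, 30, 0.85, c(fc_ifg_oper_Z = -0.35),
                      c(0, 200), asd_only = TRUE),
    vabs_socialization = score(85, 13, 0.85, c(fc_caudate_Z = 0.35),
                               c(20, 160), asd_only = TRUE),
    vabs_interpersonal = score(84, 13, 0.85, c(fc_caudate_Z = -0.40),
                               c(20, 160), asd_only = TRUE),
    vabs_daily_living = score(86, 13, 0.9, c(fc_caudate_Z = 0.26),
                              c(20, 160), asd_only = TRUE)
  )
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(sprintf("  %d subjects/group; %d cortical regions, %d ROIs x %d vols (TR %gs)\n",
              x$n_per_group, x$n_cortical, x$n_roi, x$n_timepoints,
              x$tr_seconds))
  cat(sprintf("  %d subcortical + %d WM volume regions; seed %d\n",
              x$n_subcortical, x$n_wm, x$seed))
  invisible(x)
}
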