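#' Region and network layout implied by a cohort configuration
#'
#' Deterministically derives the naming and index structure of the
#' simulated data: cortical region names with their homotopic pairing,
#' volume region names (subcortical, white matter, cortical gray matter),
#' resting-state ROI names with homotopic pairs, the four seed sets
#' (bilateral caudate, IFG pars opercularis, IFG pars triangularis, DMN
#' core) and the larger coupled networks around each seed.
#'
#' ROIs are laid out left hemisphere first (indices `1..n_roi/2`), then
#' right; the homotopic partner of ROI `i` is `i + n_roi/2`. Cortical
#' regions follow the same convention.
#'
#' @param config A [cohort_config()].
#' @return A list with elements `cortical_names`, `cortical_pairs`,
#'   `volume_names`, `volume_baseline`, `roi_names`, `roi_pairs`,
#'   `seed_sets`, `networks`, `feature_volumes`.
#' @export
region_layout <- function(config) {
  h <- config$n_roi / 2L
  if (h < 13) stop("n_roi must be at least 26 to host the four seed networks")
  ch <- config$n_cortical / 2L

  cortical_names <- c(sprintf("ctx_L_%03d", seq_len(ch)),
                      sprintf("ctx_R_%03d", seq_len(ch)))
  cortical_pairs <- cbind(left = seq_len(ch), right = seq_len(ch) + ch)

  if (config$n_subcortical < 9)
    stop("n_subcortical must be >= 9 to host the named feature regions")
  feature_volumes <- c("sc_caudate_L", "sc_caudate_R", "sc_thalamus_L",
                       "sc_thalamus_R", "sc_pallidum_L", "sc_pallidum_R",
                       "sc_hippocampus_L", "sc_hippocampus_R",
                       "sc_cerebellum")
  n_other <- config$n_subcortical - 9L
  sc_names <- c(feature_volumes,
                if (n_other > 0) sprintf("sc_other_%02d", seq_len(n_other)))
  wm_half <- config$n_wm %/% 2L
  wm_names <- c(sprintf("wm_L_%03d", seq_len(wm_half)),
                sprintf("wm_R_%03d", seq_len(config$n_wm - wm_half)))
  gm_names <- paste0("gm_", cortical_names)
  volume_names <- c(sc_names, wm_names, gm_names)

  # fixed plausible baselines (arbitrary volume units, supratentorial ~1150)
  base <- c(sc_caudate_L = 3.8, sc_caudate_R = 3.9, sc_thalamus_L = 7.5,
            sc_thalamus_R = 7.4, sc_pallidum_L = 1.8, sc_pallidum_R = 1.8,
            sc_hippocampus_L = 4.2, sc_hippocampus_R = 4.3,
            sc_cerebellum = 140)
  if (n_other > 0)
    base <- c(base, stats::setNames(2 + 6 * (seq_len(n_other) %% 7) / 7,
                                    sc_names[-(1:9)]))
  base <- c(base, stats::setNames(3 + 5 * (seq_along(wm_names) %% 11) / 11,
                                  wm_names))
  base <- c(base, stats::setNames(1 + 18 * (seq_along(gm_names) %% 13) / 13,
                                  gm_names))

  roi_names <- c(sprintf("roi_L_%03d", seq_len(h)),
                 sprintf("roi_R_%03d", seq_len(h)))
  roi_pairs <- cbind(left = seq_len(h), right = seq_len(h) + h)

  bilat <- function(i) c(i, i + h)
  seed_sets <- list(caudate = bilat(1L), ifg_oper = bilat(2L),
                    ifg_tri = bilat(3L), dmn = c(bilat(4L), bilat(5L)))
  # coupled target ROIs, scaled with hemisphere size, appended after the seeds
  t_cau <- max(2L, round(h * 0.09))
  t_ifg <- max(2L, round(h * 0.07))
  t_dmn <- max(2L, round(h * 0.07))
  nxt <- 6L
  take <- function(k) {
    idx <- seq.int(nxt, length.out = k)
    nxt <<- nxt + k
    c(idx, idx + h)
  }
  networks <- list(caudate = c(seed_sets$caudate, take(t_cau)),
                   ifg_oper = c(seed_sets$ifg_oper, take(t_ifg)),
                   ifg_tri = c(seed_sets$ifg_tri, take(t_ifg)),
                   dmn = c(seed_sets$dmn, take(t_dmn)))
  if (nxt - 1L > h) stop("n_roi too small for the configured networks")

  list(cortical_names = cortical_names, cortical_pairs = cortical_pairs,
       volume_names = volume_names,
       volume_baseline = base, roi_names = roi_names, roi_pairs = roi_pairs,
       seed_sets = seed_sets, networks = networks,
       feature_volumes = feature_volumes)
}

#' Band-limited unit-variance noise
#'
#' White Gaussian noise restricted in the frequency domain to the
#' configured band and rescaled to unit variance. This is the elementary
#' signal from which all simulated BOLD-like series are mixed, so pairwise
#' correlations and spectral content of the generated data are analytically
#' predictable.
#'
#' @param n_timepoints Series length.
#' @param tr_seconds Sampling interval (s).
#' @param low,high Band edges in Hz; bins with `low <= f <= high` are kept.
#' @return Numeric vector of length `n_timepoints`, mean 0, sd 1.
#' @keywords internal
band_limited_noise <- function(n_timepoints, tr_seconds, low, high) {
  z <- stats::rnorm(n_timepoints)
  zf <- stats::fft(z)
  f <- seq(0, n_timepoints - 1) / (n_timepoints * tr_seconds)
  f <- pmin(f, 1 / tr_seconds - f)  # fold to [0, Nyquist]
  keep <- f >= low & f <= high
  if (!any(keep)) stop("band contains no frequency bins at this length/TR")
  zf[!keep] <- 0
  x <- Re(stats::fft(zf, inverse = TRUE)) / n_timepoints
  x <- x - mean(x)
  s <- stats::sd(x)
  if (s == 0) stop("degenerate band-limited draw")
  x / s
}

#' Generate one subject's ROI time-series matrix
#'
#' Each ROI in seed network \eqn{m} follows the single-factor form
#' \eqn{x_i(t) = \sqrt{c_m}\, g_m(t) + \sqrt{c_h}\, h_p(t) +
#' \sqrt{1 - c_m - c_h}\, e_i(t)} where \eqn{g_m} is a network-shared
#' signal, \eqn{h_p} a signal shared by the ROI's homotopic pair and
#' \eqn{e_i} ROI-private noise, all band-limited to the configured band.
#' Expected within-network correlation is therefore approximately
#' \eqn{c_m} and homotopic correlation approximately \eqn{c_h} (plus
#' network coupling where a pair lies inside one network). Background ROIs
#' have \eqn{c_m = 0}.
#'
#' @param config A [cohort_config()].
#' @param group `"TD"` or `"ASD"`; selects the coupling strengths.
#' @param seed Optional integer; if given, `set.seed()` is called first so
#'   the matrix is reproducible in isolation. Inside [generate_cohort()]
#'   the cohort-level seed governs instead.
#' @return Matrix `n_roi x n_timepoints` with ROI row names.
#' @export
generate_timeseries <- function(config, group = c("TD", "ASD"),
                                seed = NULL) {
  group <- match.arg(group)
  if (!is.null(seed)) set.seed(seed)
  lay <- region_layout(config)
  n_roi <- config$n_roi
  tp <- config$n_timepoints
  cnet <- config$seed_connectivity[[group]]
  chom <- config$homotopic_strength[[group]]
  bl <- function() band_limited_noise(tp, config$tr_seconds,
                                      config$band[1], config$band[2])

  c_roi <- numeric(n_roi)  # network coupling per ROI
  g_roi <- integer(n_roi)  # network id per ROI (0 = background)
  for (m in seq_along(lay$networks)) {
    idx <- lay$networks[[m]]
    c_roi[idx] <- cnet[[names(lay$networks)[m]]]
    g_roi[idx] <- m
  }
  if (any(c_roi + chom >= 1)) stop("coupling strengths must sum below 1")

  g_sig <- replicate(length(lay$networks), bl())
  h_sig <- replicate(nrow(lay$roi_pairs), bl())
  pair_of <- integer(n_roi)
  pair_of[lay$roi_pairs[, 1]] <- seq_len(nrow(lay$roi_pairs))
  pair_of[lay$roi_pairs[, 2]] <- seq_len(nrow(lay$roi_pairs))

  ts <- matrix(0, n_roi, tp, dimnames = list(lay$roi_names, NULL))
  for (i in seq_len(n_roi)) {
    ci <- c_roi[i]
    x <- sqrt(1 - ci - chom) * bl()
    if (ci > 0) x <- x + sqrt(ci) * g_sig[, g_roi[i]]
    if (chom > 0) x <- x + sqrt(chom) * h_sig[, pair_of[i]]
    ts[i, ] <- x
  }
  ts
}

#' Generate a synthetic two-group cohort
#'
#' Produces `2 * n_per_group` subjects (TD first, then ASD) with regional
#' cortical thickness, regional volumes, a supratentorial volume, ROI time
#' series, demographics and phenotype scores, carrying the planted group
#' structure of the configuration:
#' \itemize{
#'   \item volumes and thickness: ASD means are the TD means multiplied by
#'     `1 + effect` for each configured region;
#'   \item thickness covariance: a spatially banded field (correlation
#'     decaying with region-index distance within each hemisphere) plus a
#'     global factor, with group-specific variance shares, so the
#'     structural-covariance network topology (lattice-like vs random-like)
#'     differs between groups;
#'   \item time series: seed-network and homotopic couplings per group;
#'   \item phenotypes: linear couplings to standardized downstream imaging
#'     features (see [generate_phenotypes()]).
#' }
#' The cohort is a pure function of the configuration: identical configs
#' (including `seed`) give bit-identical cohorts.
#'
#' @param config A [cohort_config()].
#' @param components Which data blocks to generate. Dropping
#'   `"timeseries"` (and with it `"phenotypes"`, which needs the imaging
#'   features) makes generation far cheaper for studies that only use the
#'   anatomical data, e.g. structural-covariance calibration replicates.
#'   Note a partial cohort is not a byte-prefix of a full one (the RNG
#'   stream differs).
#' @return An object of class `cohort`: a list with `subjects` (data frame:
#'   id, group, age, sex, supratentorial), `thickness` and `volumes`
#'   (subject x region matrices), `timeseries` (named list of ROI x time
#'   matrices), `phenotypes` (data frame), `region_names`,
#'   `homotopic_pairs` (ROI index pairs), `cortical_pairs`, `seed_sets`,
#'   `networks` and the `config` echo.
#' @export
generate_cohort <- function(config,
                            components = c("thickness", "volumes",
                                           "timeseries", "phenotypes")) {
  stopifnot(inherits(config, "cohort_config"))
  components <- match.arg(components, several.ok = TRUE)
  if ("phenotypes" %in% components &&
      !all(c("timeseries", "volumes") %in% components))
    stop("phenotypes require the timeseries and volumes components")
  set.seed(config$seed)
  lay <- region_layout(config)
  n <- 2L * config$n_per_group
  group <- rep(c("TD", "ASD"), each = config$n_per_group)
  ids <- sprintf("sub%04d", seq_len(n))

  subjects <- data.frame(
    id = ids, group = group,
    age = round(stats::runif(n, 8, 20), 1),
    sex = ifelse(stats::rbinom(n, 1, 0.24) == 1, "F", "M"),
    stringsAsFactors = FALSE)

  ## --- cortical thickness: banded spatial field + global factor --------
  ## latent = sqrt(spatial) * AR(1) field along the region index (per
  ## hemisphere, corr decaying as spatial_decay^distance) +
  ## sqrt(global) * global factor + independent noise.
  ch <- config$n_cortical / 2L
  mu_pair <- 2.1 + 1.0 * (seq_len(ch) - 1) / max(1, ch - 1)
  mu_ctx <- c(mu_pair, mu_pair)  # homotopic partners share a baseline
  names(mu_ctx) <- lay$cortical_names
  eff_ctx <- numeric(config$n_cortical)
  names(eff_ctx) <- lay$cortical_names
  te <- config$thickness_effects
  if (length(te)) {
    bad <- setdiff(names(te), lay$cortical_names)
    if (length(bad)) stop("unknown thickness regions: ",
                          paste(bad, collapse = ", "))
    eff_ctx[names(te)] <- te
  }
  phi <- config$spatial_decay
  ar1 <- function(k) {
    u <- numeric(k)
    u[1] <- stats::rnorm(1)
    innov <- stats::rnorm(k - 1, sd = sqrt(1 - phi^2))
    for (r in 2:k) u[r] <- phi * u[r - 1] + innov[r - 1]
    u
  }
  thickness <- NULL
  if ("thickness" %in% components) {
    thickness <- matrix(0, n, config$n_cortical,
                        dimnames = list(ids, lay$cortical_names))
    for (s in seq_len(n)) {
      cs <- config$covariance_strength[[group[s]]]
      rs <- cs[["spatial"]]; rg <- cs[["global"]]
      u <- c(ar1(ch), ar1(ch))  # independent field per hemisphere
      fg <- stats::rnorm(1)
      eps <- stats::rnorm(config$n_cortical)
      lat <- sqrt(rs) * u + sqrt(rg) * fg + sqrt(1 - rs - rg) * eps
      mu_s <- mu_ctx * (1 + if (group[s] == "ASD") eff_ctx else 0)
      thickness[s, ] <- mu_s + config$thickness_noise_sd * mu_ctx * lat
    }
    if (any(thickness <= 0))
      stop("generated non-positive thickness; lower thickness_noise_sd")
  }

  ## --- regional volumes and supratentorial volume ----------------------
  ve <- config$volume_effects
  eff_vol <- numeric(length(lay$volume_names))
  names(eff_vol) <- lay$volume_names
  if (length(ve)) {
    bad <- setdiff(names(ve), lay$volume_names)
    if (length(bad)) stop("unknown volume regions: ",
                          paste(bad, collapse = ", "))
    eff_vol[names(ve)] <- ve
  }
  volumes <- NULL
  subjects$supratentorial <- NA_real_
  if ("volumes" %in% components) {
    volumes <- matrix(0, n, length(lay$volume_names),
                      dimnames = list(ids, lay$volume_names))
    supra <- numeric(n)
    for (s in seq_len(n)) {
      head_f <- max(0.7, stats::rnorm(1, 1, 0.08))
      mult <- 1 + (if (group[s] == "ASD") eff_vol else 0)
      volumes[s, ] <- lay$volume_baseline * head_f * mult *
        (1 + config$volume_noise_sd * stats::rnorm(length(eff_vol)))
      supra[s] <- 1150 * head_f * (1 + 0.02 * stats::rnorm(1))
    }
    if (any(volumes <= 0))
      stop("generated non-positive volume; lower volume_noise_sd")
    subjects$supratentorial <- supra
  }

  ## --- ROI time series --------------------------------------------------
  timeseries <- NULL
  if ("timeseries" %in% components) {
    timeseries <- vector("list", n)
    names(timeseries) <- ids
    for (s in seq_len(n))
      timeseries[[s]] <- generate_timeseries(config, group[s])
  }

  cohort <- structure(list(
    subjects = subjects, thickness = thickness, volumes = volumes,
    timeseries = timeseries, phenotypes = NULL,
    region_names = list(cortical = lay$cortical_names,
                        volume = lay$volume_names, roi = lay$roi_names),
    homotopic_pairs = lay$roi_pairs, cortical_pairs = lay$cortical_pairs,
    seed_sets = lay$seed_sets, networks = lay$networks,
    feature_volumes = lay$feature_volumes,
    config = config), class = "cohort")

  if ("phenotypes" %in% components)
    cohort <- generate_phenotypes(cohort, config)
  cohort
}

#' Attach phenotype scores coupled to imaging features
#'
#' Computes the cohort's canonical 22-feature table (see
#' [compute_feature_table()]), standardizes it, and draws each clinical
#' score as `intercept + scale * (sum(beta * z) + N(0, sd))`, truncated and
#' rounded to the score's plausible integer range. With all `beta = 0` the
#' scores are pure noise; a single standardized coupling `beta` with
#' residual sd `sigma` yields a theoretical feature-score correlation of
#' `beta / sqrt(beta^2 + sigma^2)` (before truncation, which attenuates it
#' only marginally at the default ranges).
#'
#' Called automatically at the end of [generate_cohort()]; exported so the
#' coupling model can be re-drawn on an existing cohort. Draws from the
#' current RNG stream.
#'
#' @param cohort A `cohort`.
#' @param config A [cohort_config()] supplying `phenotype_model`.
#' @return The cohort with a populated `phenotypes` data frame (one row per
#'   subject; ASD-only instruments are `NA` for controls).
#' @export
generate_phenotypes <- function(cohort, config = cohort$config) {
  feats <- compute_feature_table(cohort)
  z <- scale(as.matrix(feats[, feature_column_names()]))
  n <- nrow(z)
  pm <- config$phenotype_model
  out <- data.frame(id = cohort$subjects$id, stringsAsFactors = FALSE)
  for (nm in names(pm)) {
    m <- pm[[nm]]
    bad <- setdiff(names(m$beta), colnames(z))
    if (length(bad))
      stop("phenotype model for ", nm, " references unknown features: ",
           paste(bad, collapse = ", "))
    lin <- if (length(m$beta)) drop(z[, names(m$beta), drop = FALSE] %*% m$beta)
           else numeric(n)
    val <- m$intercept + m$scale * (lin + stats::rnorm(n, 0, m$sd))
    val <- pmin(m$range[2], pmax(m$range[1], val))
    if (isTRUE(m$integer)) val <- round(val)
    if (isTRUE(m$asd_only)) val[cohort$subjects$group != "ASD"] <- NA
    out[[nm]] <- val
  }
  cohort$phenotypes <- out
  cohort
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d subjects (%d TD / %d ASD)\n",
              nrow(x$subjects), sum(x$subjects$group == "TD"),
              sum(x$subjects$group == "ASD")))
  has <- function(m) if (is.null(m)) "-" else as.character(ncol(m))
  cat(sprintf("  thickness: %s regions; volumes: %s regions; ROIs: %s\n",
              has(x$thickness), has(x$volumes),
              if (is.null(x$timeseries)) "-" else
                paste(dim(x$timeseries[[1]]), collapse = " x ")))
  invisible(x)
}
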