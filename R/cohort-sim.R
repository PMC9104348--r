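# Planted temporal templates ------------------------------------------------

#' Planted temporal effect templates
#'
#' A template is a set of %lifetime anchor knots mapped to planted log2
#' fold changes (TKO over control), evaluated by piecewise-linear
#' interpolation. All templates anchor at 0 at 20 %lifetime — no
#' premalignant effect unless configured otherwise. The named shapes mirror
#' the temporal patterns the longitudinal analysis is designed to recover:
#' monotone drift up/down, the dip-recover-drop arc of lyso-phospholipids
#' (`inverted_U`, an inverted-U arc below baseline), the
#' down-up-down wave of amino acids / TCA-cycle metabolites, and the early
#' spike with late reversal of 20a-hydroxyprogesterone
#' (`late_spike_then_drop`, +0.99 during onset/early stages, -0.43 in the
#' advanced stage).
#'
#' @param shape template name.
#' @param anchors optional custom anchors: named numeric vector, names =
#'   %lifetime knots, values = planted log2 fold change.
#' @return Object of class `planted_template`.
#' @export
planted_template <- function(shape = c("flat", "monotone_up", "monotone_down",
                                       "inverted_U", "wave_down_up_down",
                                       "late_spike_then_drop"),
                             anchors = NULL) {
  shape <- match.arg(shape)
  if (is.null(anchors)) {
    anchors <- switch(shape,
      flat = c("20" = 0, "100" = 0),
      monotone_up = c("20" = 0, "100" = 1),
      monotone_down = c("20" = 0, "100" = -1),
      inverted_U = c("20" = 0, "50" = -0.7, "75" = -0.15, "100" = -0.9),
      wave_down_up_down = c("20" = 0, "45" = -0.4, "70" = 0.3, "100" = -0.5),
      late_spike_then_drop = c("20" = 0, "36" = 0, "37" = 0.99, "80" = 0.99,
                               "85" = -0.43, "100" = -0.43)
    )
  }
  if (length(anchors) == 0) stop("template anchors must be non-empty")
  knots <- as.numeric(names(anchors))
  if (any(is.na(knots))) stop("anchor names must be %lifetime knots")
  o <- order(knots)
  structure(list(shape = shape, knots = knots[o], values = unname(anchors)[o]),
            class = "planted_template")
}

#' Evaluate a planted template
#'
#' Piecewise-linear interpolation between anchor knots; outside the anchor
#' range the nearest anchor value is used.
#'
#' @param template a [planted_template()].
#' @param pct_lifetime evaluation points in \[0, 100]; vectorised.
#' @return Planted log2 fold change at each point.
#' @export
template_value <- function(template, pct_lifetime) {
  stopifnot(inherits(template, "planted_template"))
  if (length(template$knots) == 1) {
    return(rep(template$values, length(pct_lifetime)))
  }
  stats::approx(template$knots, template$values, xout = pct_lifetime,
                rule = 2)$y
}

#' Mean planted template value over a %lifetime bin
#'
#' Averages [template_value()] over a fine grid spanning the bin — the
#' reference quantity a per-bin empirical log2 fold change should recover.
#'
#' @param template a [planted_template()].
#' @param bin stage label (see [stage_bins()]) or numeric `c(lower, upper)`.
#' @return Mean planted log2 fold change over the bin.
#' @export
template_bin_mean <- function(template, bin) {
  if (is.character(bin)) bin <- stage_bins()[[bin]]
  grid <- seq(bin[1], bin[2], length.out = 201)
  mean(template_value(template, grid))
}

# Default lipid-class layout: template shape and amplitude per class.
# Amplitudes are |log2 FC| at template peak, scaled by effect_scale.
default_class_effects <- function() {
  data.frame(
    lipid_class = c("Cer", "SM", "HexCer", "PC", "PE", "PS", "PI",
                    "LPC", "LPE", "PC O-", "PE O-", "PS O-", "TG", "DG",
                    "FA", "VLCFA", "SiE", "polar", "OHP"),
    shape = c("monotone_up", "monotone_down", "monotone_up", "monotone_up",
              "monotone_up", "monotone_up", "monotone_up", "inverted_U",
              "inverted_U", "monotone_down", "monotone_down", "monotone_down",
              "monotone_up", "monotone_up", "monotone_down", "monotone_up",
              "monotone_down", "wave_down_up_down", "late_spike_then_drop"),
    amplitude = c(0.8, 0.8, 0.5, 0.5, 0.5, 0.6, 0.5, 0.8, 0.8, 0.6, 0.8,
                  0.6, 0.5, 0.6, 0.6, 0.7, 0.6, 1.0, 1.0),
    stringsAsFactors = FALSE
  )
}

# Simulation configuration ---------------------------------------------------

#' Configuration of the synthetic longitudinal cohort
#'
#' Defaults emulate the study conditions of the TKO serum cohort: 15 TKO and
#' 15 control mice bled every two weeks from 8 weeks of age, TKO lifespans
#' uniform on 24-40 weeks, controls followed to 40 weeks; roughly 1000
#' features spread over 17 lipid classes plus polar metabolites and
#' unstructured noise features; pooled-QC injections every 10 study
#' injections with 15% target RSD; blanks at 2% of baseline signal; 5% of
#' study/QC entries missing at random.
#'
#' @param n_tko,n_ctrl mice per group.
#' @param sampling_interval_weeks blood-draw spacing (weeks).
#' @param start_age_weeks age at first draw (weeks).
#' @param tko_lifespan_range_weeks `c(low, high)` of the uniform TKO
#'   lifespan distribution.
#' @param ctrl_followup_weeks control age at last collection.
#' @param n_features_per_class named counts per lipid class (see
#'   `default_class_effects()` for recognised classes).
#' @param n_noise_features unstructured (flat-template) features.
#' @param effect_scale multiplies every template amplitude; 0 gives a null
#'   cohort.
#' @param qc_every_n_injections pooled-QC spacing in the injection sequence.
#' @param qc_rsd_target QC dispersion (log-scale sd, approximately the RSD).
#' @param blank_level blank signal as a fraction of feature baseline.
#' @param dropout_fraction fraction of study/QC entries set missing.
#' @param meas_sdlog multiplicative log-normal measurement noise (sd of the
#'   natural-log scale).
#' @param drift_fold end-of-run over start-of-run sensitivity ratio (1 = no
#'   injection-order drift).
#' @param n_blanks blank injections (half at start, half at end of run).
#' @param seed RNG seed; identical configs give byte-identical cohorts.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_tko = 15, n_ctrl = 15, sampling_interval_weeks = 2,
                       start_age_weeks = 8,
                       tko_lifespan_range_weeks = c(24, 40),
                       ctrl_followup_weeks = 40,
                       n_features_per_class = NULL,
                       n_noise_features = 260,
                       effect_scale = 1,
                       qc_every_n_injections = 10,
                       qc_rsd_target = 0.15,
                       blank_level = 0.02,
                       dropout_fraction = 0.05,
                       meas_sdlog = 0.4,
                       drift_fold = 1,
                       n_blanks = 6,
                       seed = 1) {
  if (is.null(n_features_per_class)) {
    cls <- default_class_effects()
    n_features_per_class <- stats::setNames(
      ifelse(cls$lipid_class == "OHP", 1L,
             ifelse(cls$lipid_class == "polar", 60L, 40L)),
      cls$lipid_class
    )
  }
  stopifnot(n_tko >= 0, n_ctrl >= 0, sampling_interval_weeks > 0,
            start_age_weeks > 0,
            tko_lifespan_range_weeks[1] < tko_lifespan_range_weeks[2],
            ctrl_followup_weeks > 0, all(n_features_per_class >= 0),
            n_noise_features >= 0, effect_scale >= 0,
            qc_every_n_injections >= 1,
            qc_rsd_target > 0, qc_rsd_target < 1,
            blank_level >= 0, dropout_fraction >= 0, dropout_fraction <= 1)
  structure(as.list(environment()), class = "sim_config")
}

# Cohort generator -----------------------------------------------------------

#' Generate a synthetic longitudinal serum cohort
#'
#' Simulates the feature table, sample metadata and ground truth of a
#' two-arm longitudinal cohort. Per mouse, sampling ages run from
#' `start_age_weeks` to its lifespan at the configured interval. Feature
#' baselines are log-normal (log-mean uniform over a wide abundance range);
#' TKO abundances are multiplied by `2^(amplitude x template(%lifetime))`,
#' all study samples carry multiplicative log-normal measurement noise, and
#' an optional linear injection-order drift. Pooled-QC injections (at the
#' per-feature baseline with `qc_rsd_target` dispersion) are interleaved
#' every `qc_every_n_injections` study injections; blank injections sit at
#' the start and end of the run at `blank_level` of baseline. A
#' `dropout_fraction` of study/QC entries is set missing completely at
#' random.
#'
#' @param config a [sim_config()].
#' @return list with `table` (a [feature_table()]), `records` (sample
#'   metadata), and `truth` (feature annotations with planted class,
#'   template and amplitude; mouse lifespans; the templates; the config).
#' @export
generate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  n_mice <- config$n_tko + config$n_ctrl
  n_feat <- sum(config$n_features_per_class) + config$n_noise_features
  if (n_mice == 0) stop("no mice configured")
  if (n_feat == 0) stop("no features configured")

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(config$seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))

  cls_fx <- default_class_effects()
  # feature annotation + planted truth
  classes <- names(config$n_features_per_class)
  unknown <- setdiff(classes, cls_fx$lipid_class)
  if (length(unknown)) stop("unknown lipid class(es): ",
                            paste(unknown, collapse = ", "))
  feat_class <- c(rep(classes, config$n_features_per_class[classes]),
                  rep("noise", config$n_noise_features))
  n_feat <- length(feat_class)
  feat_id <- sprintf("F%04d", seq_len(n_feat))
  shape <- ifelse(feat_class == "noise", "flat",
                  cls_fx$shape[match(feat_class, cls_fx$lipid_class)])
  amplitude <- ifelse(feat_class == "noise", 0,
                      cls_fx$amplitude[match(feat_class, cls_fx$lipid_class)]) *
    config$effect_scale
  templates <- lapply(unique(shape), planted_template)
  names(templates) <- unique(shape)

  # mice and their sampling schedules
  mouse_id <- c(sprintf("TKO%02d", seq_len(config$n_tko)),
                sprintf("CTRL%02d", seq_len(config$n_ctrl)))
  group <- c(rep("TKO", config$n_tko), rep("CTRL", config$n_ctrl))
  lifespan <- c(stats::runif(config$n_tko, config$tko_lifespan_range_weeks[1],
                             config$tko_lifespan_range_weeks[2]),
                rep(config$ctrl_followup_weeks, config$n_ctrl))
  samples <- do.call(rbind, lapply(seq_len(n_mice), function(i) {
    if (lifespan[i] < config$start_age_weeks) return(NULL)
    ages <- seq(config$start_age_weeks, lifespan[i],
                by = config$sampling_interval_weeks)
    data.frame(mouse_id = mouse_id[i], group = group[i], age_weeks = ages,
               lifespan_weeks = lifespan[i])
  }))
  if (is.null(samples) || nrow(samples) == 0) {
    stop("no samples generated: lifespans shorter than start age")
  }
  ns <- nrow(samples)
  samples$sample_id <- sprintf("S%04d", seq_len(ns))
  pct <- 100 * samples$age_weeks / samples$lifespan_weeks

  # abundances
  baseline <- exp(stats::runif(n_feat, 9, 14))
  eff <- matrix(0, n_feat, ns)
  for (sh in unique(shape)) {
    rows <- which(shape == sh & amplitude != 0)
    if (length(rows) == 0) next
    tv <- template_value(templates[[sh]], pct)  # length ns
    eff[rows, ] <- outer(amplitude[rows], tv)
  }
  is_tko <- samples$group == "TKO"
  eff[, !is_tko] <- 0
  noise <- matrix(stats::rnorm(n_feat * ns, sd = config$meas_sdlog),
                  n_feat, ns)
  m_study <- baseline * 2^eff * exp(noise)

  # injection sequence: randomised study order, QC interleaved, blanks at ends
  study_order <- sample(ns)
  n_qc <- max(2L, floor(ns / config$qc_every_n_injections) + 1L)
  qc_id <- sprintf("QC%03d", seq_len(n_qc))
  n_bl <- config$n_blanks
  blank_id <- if (n_bl > 0) sprintf("BLANK%02d", seq_len(n_bl)) else character(0)

  seq_ids <- character(0)
  qi <- 0L
  for (b in seq_len(ceiling(n_bl / 2))) seq_ids <- c(seq_ids, blank_id[b])
  for (i in seq_len(ns)) {
    if ((i - 1) %% config$qc_every_n_injections == 0 && qi < n_qc) {
      qi <- qi + 1L
      seq_ids <- c(seq_ids, qc_id[qi])
    }
    seq_ids <- c(seq_ids, samples$sample_id[study_order[i]])
  }
  while (qi < n_qc) { qi <- qi + 1L; seq_ids <- c(seq_ids, qc_id[qi]) }
  if (n_bl > 0) seq_ids <- c(seq_ids, blank_id[(ceiling(n_bl / 2) + 1):n_bl])

  m_qc <- baseline * exp(matrix(stats::rnorm(n_feat * n_qc,
                                             sd = config$qc_rsd_target),
                                n_feat, n_qc))
  m_blank <- if (n_bl > 0) {
    config$blank_level * baseline *
      exp(matrix(stats::rnorm(n_feat * n_bl, sd = 0.3), n_feat, n_bl))
  } else matrix(numeric(0), n_feat, 0)

  m <- cbind(m_study, m_qc, m_blank)
  colnames(m) <- c(samples$sample_id, qc_id, blank_id)
  rownames(m) <- feat_id
  m <- m[, seq_ids, drop = FALSE]

  # injection-order drift (multiplicative, linear start -> end)
  inj <- seq_along(seq_ids)
  if (config$drift_fold != 1) {
    dr <- seq(1, config$drift_fold, length.out = length(inj))
    m <- sweep(m, 2, dr, "*")
  }

  # missingness (study + QC entries only)
  if (config$dropout_fraction > 0) {
    droppable <- which(!grepl("^BLANK", colnames(m))[col(m)])
    k <- floor(config$dropout_fraction * length(droppable))
    if (k > 0) m[droppable[sample(length(droppable), k)]] <- NA_real_
  }

  records <- sample_records(data.frame(
    sample_id = seq_ids,
    mouse_id = ifelse(grepl("^S", seq_ids),
                      samples$mouse_id[match(seq_ids, samples$sample_id)], NA),
    group = ifelse(grepl("^QC", seq_ids), "QC",
                   ifelse(grepl("^BLANK", seq_ids), "BLANK",
                          samples$group[match(seq_ids, samples$sample_id)])),
    age_weeks = samples$age_weeks[match(seq_ids, samples$sample_id)],
    lifespan_weeks = samples$lifespan_weeks[match(seq_ids, samples$sample_id)],
    injection_order = inj
  ))

  truth <- list(
    features = data.frame(feature_id = feat_id, lipid_class = feat_class,
                          shape = shape, amplitude = amplitude,
                          stringsAsFactors = FALSE),
    templates = templates,
    lifespans = stats::setNames(lifespan, mouse_id),
    config = config
  )
  list(table = feature_table(m, provenance = "generate_cohort"),
       records = records, truth = truth)
}

#' Simulate a single diagnostic marker with a planted population AUC
#'
#' Location-shift construction on the log2 scale: class-conditional values
#' are log-normal with a shift chosen so the population ROC AUC of the raw
#' values equals `auc` (binormal equal-variance model,
#' `delta = sqrt(2) * qnorm(auc)`).
#'
#' @param n samples (split evenly between classes).
#' @param auc target population AUC (0.5-1).
#' @param seed RNG seed.
#' @return list with `value` (raw positive marker values), `labels`
#'   ("TKO"/"CTRL"), `delta` (the planted log2-scale shift).
#' @export
simulate_auc_pair <- function(n, auc = 0.83, seed = 1) {
  stopifnot(auc >= 0.5, auc < 1, n >= 4)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  n1 <- floor(n / 2)
  n0 <- n - n1
  delta <- sqrt(2) * stats::qnorm(auc)
  z <- c(stats::rnorm(n1, mean = delta), stats::rnorm(n0))
  list(value = 2^(z + 10), labels = c(rep("TKO", n1), rep("CTRL", n0)),
       delta = delta)
}

# MSI phantom ----------------------------------------------------------------

#' Generate a 3-region MSI phantom
#'
#' Builds a rectangular pixel grid partitioned into contiguous anatomical
#' regions — by default a healthy ovary disk, a necrotic lobe with higher
#' intra-region variability, and an HGSC tumor field covering the rest.
#' Each feature gets a log-normal base intensity and region-specific
#' multipliers; per-pixel intensities are Poisson counts around the region
#' mean, scaled by a log-normal per-pixel total-signal factor. Spectra are
#' centroided with one exact peak per feature.
#'
#' @param width,height grid size in pixels (>= 2 each).
#' @param n_features number of m/z features.
#' @param region_effects optional named list `region -> multiplier vector`
#'   (length `n_features` or scalar) on the natural scale; default draws
#'   independent log2 effects ~ N(0, 1.5) for HGSC and necrotic vs healthy.
#' @param seed RNG seed.
#' @param mean_counts expected counts of the most intense features
#'   (controls the Poisson noise level).
#' @return list with `dataset` (an [msi_dataset()]), `truth` (pixel region
#'   labels, feature m/z, planted multipliers).
#' @export
generate_msi_phantom <- function(width = 30, height = 30, n_features = 50,
                                 region_effects = NULL, seed = 1,
                                 mean_counts = 200) {
  if (width < 2 || height < 2) stop("grid must be at least 2 x 2")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))

  coords <- expand.grid(x = seq_len(width), y = seq_len(height))
  # region geometry: healthy ovary disk, necrotic lobe, HGSC elsewhere
  r_heal <- min(width, height) / 5
  c_heal <- c(0.35 * width, 0.5 * height)
  r_necr <- min(width, height) / 4.5
  c_necr <- c(0.8 * width, 0.3 * height)
  d_heal <- sqrt((coords$x - c_heal[1])^2 + (coords$y - c_heal[2])^2)
  d_necr <- sqrt((coords$x - c_necr[1])^2 + (coords$y - c_necr[2])^2)
  region <- ifelse(d_heal <= r_heal, "healthy",
                   ifelse(d_necr <= r_necr, "necrotic", "HGSC"))

  mzs <- sort(stats::runif(n_features, 150, 1200))
  while (any(diff(mzs) < 0.01)) {
    mzs <- sort(stats::runif(n_features, 150, 1200))
  }
  mzs <- round(mzs, 4)
  base <- exp(stats::runif(n_features, log(mean_counts / 20),
                           log(mean_counts)))
  if (is.null(region_effects)) {
    region_effects <- list(
      healthy = rep(1, n_features),
      HGSC = 2^stats::rnorm(n_features, 0, 1.5),
      necrotic = 2^stats::rnorm(n_features, 0, 1.5)
    )
  }
  regions_present <- unique(region)
  if (!all(regions_present %in% names(region_effects))) {
    stop("region_effects must cover regions: ",
         paste(regions_present, collapse = ", "))
  }
  mult <- lapply(region_effects, function(v) {
    if (length(v) == 1) rep(v, n_features) else v
  })

  n_px <- nrow(coords)
  tic_factor <- exp(stats::rnorm(n_px, 0, 0.2))
  intensity <- vector("list", n_px)
  for (i in seq_len(n_px)) {
    mu <- base * mult[[region[i]]] * tic_factor[i]
    intensity[[i]] <- as.numeric(stats::rpois(n_features, mu))
  }
  ds <- msi_dataset(coords, mz = rep(list(mzs), n_px), intensity = intensity,
                    mz_range = c(150, 1200), polarity = "-")
  list(dataset = ds,
       truth = list(region = region, mz = mzs,
                    multipliers = mult, base = base))
}

#' Write a region-label raster as plain text
#'
#' One row per pixel row; labels tab-separated. Companion to the imzML
#' phantom output so planted truth survives on disk.
#'
#' @param coords data.frame `x`, `y`.
#' @param labels label per pixel.
#' @param path output path.
#' @export
write_region_raster <- function(coords, labels, path) {
  w <- max(coords$x)
  h <- max(coords$y)
  grid <- matrix("", h, w)
  grid[cbind(coords$y, coords$x)] <- as.character(labels)
  writeLines(apply(grid, 1, paste, collapse = "\t"), path)
  invisible(path)
}
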