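#' Default multi-study design table
#'
#' The study designs the generator emulates: seven training studies plus
#' four validation studies with heterogeneous sample sizes, trial counts,
#' thermal stimulus ranges (41.1 to 50 degrees C), and factor schemas
#' (expectation cues in some studies, social cues, perceived control),
#' mirroring a published multi-study evoked thermal pain corpus. Studies
#' whose stimulus intensity did not vary omit `temperature` from their
#' schema; psychological factors are listed only where manipulated.
#'
#' @return data.frame with one row per study: `study_id`, `n_participants`,
#'   `n_trials`, `temp_levels` (list column, degrees C), `factors` (list
#'   column of factor names), `validation` flag.
#' @export
default_study_table <- function() {
  tab <- data.frame(
    study_id = c("S1", "S2", "S3", "S4", "S5", "S6", "S7",
                 "V1", "V2", "V3", "V4"),
    n_participants = c(28L, 17L, 16L, 29L, 26L, 30L, 25L,
                       33L, 45L, 40L, 87L),
    n_trials = c(81L, 64L, 70L, 64L, 48L, 16L, 96L,
                 97L, 48L, 60L, 36L),
    validation = c(rep(FALSE, 7), rep(TRUE, 4)),
    stringsAsFactors = FALSE)
  tab$temp_levels <- list(
    c(46, 47, 48), c(41.1, 44.2, 47.1), c(48, 49), c(45, 47),
    seq(40.8, 47.0, length.out = 8), 47, c(48, 49, 50),
    c(44.3, 45.3, 46.3, 47.3, 48.3, 49.3), c(46, 47, 48), 46.4, c(47, 48, 49))
  tab$factors <- list(
    c("temperature", "expectation"), c("temperature", "expectation"),
    c("temperature", "expectation"),
    c("temperature", "expectation", "control"),
    "temperature", "social", c("temperature", "social"),
    "temperature", c("temperature", "expectation"), "expectation",
    "temperature")
  tab
}

#' Generator configuration
#'
#' Parameters of the synthetic multi-study corpus. Rating-model
#' coefficients are on the z-scored rating scale; the `scenario` sets the
#' ground-truth spatial scope of all brain signal patterns.
#'
#' @param studies design table as from [default_study_table()]; rows may be
#'   subset or replaced for smaller problems.
#' @param n_voxels in-mask voxel count V.
#' @param n_regions,n_frsn,n_crsn parcel counts at the three scales
#'   (defaults 486 / 32 / 7).
#' @param meta_frac fraction of voxels the meta-analytic mask covers
#'   (default 0.30).
#' @param pathway_frac fraction of voxels the a priori pathways set covers
#'   (default 0.30).
#' @param scenario one of "LOCAL", "MULTISYSTEM", "GLOBAL": all signal in
#'   one region; spread over >= 3 regions in >= 2 distinct cRSNs; or over
#'   >= 50 percent of regions.
#' @param b_temp,b_exp,b_social,b_control,b_habit standardized rating
#'   coefficients for the manipulated factors (habituation is linear in
#'   trial index).
#' @param b_latent coefficient of the latent trial-level pain signal that
#'   the brain expresses beyond the manipulated factors (gives decoders
#'   rating variance unique of the factors).
#' @param sd_intercept SD of participant mean-rating offsets.
#' @param sd_noise SD of trial-level rating noise.
#' @param amp_pattern total L2 norm of each factor's spatial signal
#'   pattern per unit of the (standardized) factor (split across the
#'   scenario's signal regions).
#' @param amp_pain total L2 norm of the latent pain pattern.
#' @param expr_noise_sd SD of the region-specific expression noise: each
#'   signal region expresses its own corrupted copy `x_f + expr_noise_sd *
#'   e` of every signal component, so single-region decoders face a
#'   correlation ceiling that integrating across regions lifts.
#' @param noise_rho within-parcel noise correlation (shared parcel factor).
#' @param sd_voxel_noise voxel noise SD.
#' @param sd_study_offset SD of the per-study additive offset map.
#' @param sd_study_amp SD of per-study log amplitude multipliers.
#' @param n_multisystem_regions regions carrying signal in the MULTISYSTEM
#'   scenario.
#' @param rating_scale,rating_center raw rating scale factor / center used
#'   before per-study jitter (ratings are later z-scored by the pipeline).
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(studies = default_study_table(),
                             n_voxels = 20000L, n_regions = 486L,
                             n_frsn = 32L, n_crsn = 7L,
                             meta_frac = 0.30, pathway_frac = 0.30,
                             scenario = c("MULTISYSTEM", "LOCAL", "GLOBAL"),
                             b_temp = 0.5, b_exp = 0.25, b_social = 0.2,
                             b_control = -0.15, b_habit = -0.2,
                             b_latent = 0.4,
                             sd_intercept = 0.6, sd_noise = 0.6,
                             amp_pattern = 2.4, amp_pain = 3.6,
                             expr_noise_sd = 2.5,
                             noise_rho = 0.1, sd_voxel_noise = 1,
                             sd_study_offset = 0.5, sd_study_amp = 0.2,
                             n_multisystem_regions = 5L,
                             rating_scale = 15, rating_center = 50) {
  scenario <- match.arg(scenario)
  cfg <- list(studies = studies, n_voxels = as.integer(n_voxels),
              n_regions = as.integer(n_regions), n_frsn = as.integer(n_frsn),
              n_crsn = as.integer(n_crsn), meta_frac = meta_frac,
              pathway_frac = pathway_frac, scenario = scenario,
              b = c(temperature = b_temp, expectation = b_exp, social = b_social,
                    control = b_control, habituation = b_habit),
              b_latent = b_latent, sd_intercept = sd_intercept,
              sd_noise = sd_noise, amp_pattern = amp_pattern,
              amp_pain = amp_pain, expr_noise_sd = expr_noise_sd,
              noise_rho = noise_rho,
              sd_voxel_noise = sd_voxel_noise,
              sd_study_offset = sd_study_offset, sd_study_amp = sd_study_amp,
              n_multisystem_regions = as.integer(n_multisystem_regions),
              rating_scale = rating_scale, rating_center = rating_center)
  if (!(cfg$n_regions >= cfg$n_frsn && cfg$n_frsn >= cfg$n_crsn && cfg$n_crsn >= 1L))
    stop("need n_regions >= n_frsn >= n_crsn >= 1")
  if (meta_frac <= 0 || meta_frac >= 1) stop("meta_frac must lie in (0,1)")
  if (cfg$n_voxels < cfg$n_regions) stop("fewer voxels than regions")
  class(cfg) <- "generator_config"
  cfg
}

#' Build a synthetic nested parcellation
#'
#' Partitions a compact 3-D voxel grid into `n_regions` spatially
#' contiguous regions (Voronoi cells of seeded points), groups regions into
#' fine networks and fine networks into coarse networks (again by seeded
#' Voronoi over centroids, so nesting is exact), flags a pathway region
#' subset covering about `pathway_frac` of voxels, and defines a meta mask
#' covering about `meta_frac` of voxels (built outward from the pathway
#' regions, so the two multisystem spaces overlap as real masks do).
#'
#' @param cfg a [generator_config()].
#' @param seed integer seed.
#' @return A [parcellation()].
#' @export
make_nested_parcellation <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "generator_config"))
  V <- cfg$n_voxels; R <- cfg$n_regions
  set.seed(derive_seed(seed, "parcellation"))
  side <- ceiling(V^(1 / 3))
  dims <- c(side, side, ceiling(V / side^2))
  idx <- seq_len(V)  # first V linear indices: a contiguous slab of the box
  coords <- arrayInd(idx, dims)
  assign_voronoi <- function(xy, n_seeds) {
    seeds <- xy[sample.int(nrow(xy), n_seeds), , drop = FALSE]
    d2 <- outer(rowSums(xy^2), rep(1, n_seeds)) - 2 * xy %*% t(seeds) +
      outer(rep(1, nrow(xy)), rowSums(seeds^2))
    max.col(-d2, ties.method = "first")
  }
  region <- assign_voronoi(coords, R)
  # guarantee all R labels occur (resample empty cells onto largest region)
  while (length(unique(region)) < R) {
    missing <- setdiff(seq_len(R), unique(region))
    big <- as.integer(names(which.max(table(region))))
    take <- which(region == big)[1]
    region[take] <- missing[1]
  }
  centroid <- function(lab_of, xy) {
    labs <- sort(unique(lab_of))
    t(vapply(labs, function(l) colMeans(xy[lab_of == l, , drop = FALSE]),
             numeric(ncol(xy))))
  }
  rc <- centroid(region, coords)
  frsn_of_region <- if (cfg$n_frsn == R) seq_len(R) else
    assign_voronoi(rc, cfg$n_frsn)
  fc <- centroid(frsn_of_region, rc)
  crsn_of_frsn <- if (cfg$n_crsn == length(unique(frsn_of_region))) {
    seq_along(unique(frsn_of_region))
  } else assign_voronoi(fc, cfg$n_crsn)
  # relabel network ids densely
  frsn_of_region <- as.integer(factor(frsn_of_region))
  crsn_of_frsn <- as.integer(factor(crsn_of_frsn))
  region_sizes <- tabulate(region, R)
  # pathway set: accumulate regions around a random anchor until ~pathway_frac
  anchor <- rc[sample.int(R, 1), ]
  ord <- order(rowSums(sweep(rc, 2, anchor)^2))
  cum <- cumsum(region_sizes[ord])
  pathway <- ord[seq_len(max(1L, sum(cum < cfg$pathway_frac * V) + 1L))]
  # meta mask: pathway regions first, then shuffled others, until ~meta_frac
  others <- sample(setdiff(seq_len(R), pathway))
  meta_order <- c(sample(pathway), others)
  cum2 <- cumsum(region_sizes[meta_order])
  n_meta <- max(1L, which(cum2 >= cfg$meta_frac * V)[1])
  if (is.na(n_meta)) n_meta <- R
  meta_regions <- meta_order[seq_len(n_meta)]
  labels <- data.frame(
    label = seq_len(R),
    region = sprintf("R%03d", seq_len(R)),
    frsn = sprintf("F%02d", frsn_of_region),
    crsn = sprintf("C%02d", crsn_of_frsn[frsn_of_region]),
    pathway = seq_len(R) %in% pathway,
    stringsAsFactors = FALSE)
  meta <- region %in% meta_regions
  parcellation(mask_geometry(dims, idx), region, labels, meta)
}

scenario_regions <- function(cfg, parc, seed) {
  set.seed(derive_seed(seed, "scenario"))
  R <- length(unique(parc$region))
  path_regions <- parc$labels$label[parc$labels$pathway]
  crsn_of <- setNames(parc$labels$crsn, parc$labels$label)
  switch(cfg$scenario,
    LOCAL = sample(path_regions, 1L),
    MULTISYSTEM = {
      m <- min(cfg$n_multisystem_regions, length(path_regions))
      for (try in 1:100) {
        cand <- sample(path_regions, m)
        if (m >= 3L && length(unique(crsn_of[as.character(cand)])) >= 2L) break
        if (m < 3L) {  # small pathway set: widen to any regions
          cand <- sample(seq_len(R), min(max(3L, m), R))
          if (length(unique(crsn_of[as.character(cand)])) >= 2L) break
        }
      }
      cand
    },
    GLOBAL = sample(seq_len(R), ceiling(R * 0.5)))
}

unit_pattern <- function(V, support_vox, norm) {
  p <- numeric(V)
  v <- rnorm(length(support_vox))
  p[support_vox] <- v / sqrt(sum(v^2)) * norm
  p
}

#' Simulate a multi-study trial-level corpus with ground truth
#'
#' Generates, for each study in the design table, per-trial factor values
#' (standardized temperature from the study's own levels, expectation and
#' social cues independent of intensity, perceived control, and a linear
#' habituation trend over trial index), participant rating intercepts, and
#' ratings `rating = sum_f b_f x_f + b_latent g + u_participant + noise`
#' where `g` is a latent per-trial pain signal expressed in the brain but
#' not caused by the manipulated factors. Trial images place each factor's
#' spatial pattern (scaled by the trial's factor value) plus `g` times the
#' pain pattern inside the scenario-defined regions, then add parcel-
#' correlated voxel noise, a per-study offset map, and a per-study
#' amplitude multiplier.
#'
#' @param cfg a [generator_config()].
#' @param parc parcellation from [make_nested_parcellation()].
#' @param seed integer seed.
#' @param include_validation also generate the validation-flagged studies.
#' @return list with `datasets` (list of [study_dataset()]) and
#'   `ground_truth` (patterns, signal regions, per-study coefficients).
#' @export
simulate_multistudy <- function(cfg, parc, seed = 1L, include_validation = FALSE) {
  stopifnot(inherits(cfg, "generator_config"), inherits(parc, "parcellation"))
  V <- n_voxels(parc$mask)
  if (V != cfg$n_voxels) stop("parcellation voxel count differs from config")
  studies <- cfg$studies
  if (!include_validation) studies <- studies[!studies$validation, , drop = FALSE]
  sig_regions <- scenario_regions(cfg, parc, seed)
  support <- which(parc$region %in% sig_regions)
  set.seed(derive_seed(seed, "patterns"))
  factor_names <- names(cfg$b)
  n_comp <- length(factor_names) + 1L  # factors + latent pain component
  m_sig <- length(sig_regions)
  region_vox <- lapply(sig_regions, function(rg) which(parc$region == rg))
  norms <- c(rep(cfg$amp_pattern, length(factor_names)), cfg$amp_pain) / sqrt(m_sig)
  # per signal region: an independent spatial subpattern per component, so
  # total pattern energy is constant across scenarios
  subpat <- lapply(region_vox, function(vox) {
    P <- matrix(rnorm(length(vox) * n_comp), length(vox), n_comp)
    sweep(P, 2, sqrt(colSums(P^2)) / norms, "/")
  })
  patterns <- matrix(0, V, length(factor_names),
                     dimnames = list(NULL, factor_names))
  pattern_pain <- numeric(V)
  for (j in seq_len(m_sig)) {
    patterns[region_vox[[j]], ] <- subpat[[j]][, seq_along(factor_names)]
    pattern_pain[region_vox[[j]]] <- subpat[[j]][, n_comp]
  }
  R <- length(unique(parc$region))
  truth <- list(scenario = cfg$scenario, signal_regions = sort(sig_regions),
                patterns = patterns, pattern_pain = pattern_pain,
                support = support, expr_noise_sd = cfg$expr_noise_sd,
                coefficients = list())
  datasets <- vector("list", nrow(studies))
  for (s in seq_len(nrow(studies))) {
    row <- studies[s, ]
    set.seed(derive_seed(seed, paste0("study_", row$study_id)))
    np <- row$n_participants; nt <- row$n_trials; n <- np * nt
    pid <- rep(sprintf("%s_p%02d", row$study_id, seq_len(np)), each = nt)
    tix <- rep(seq_len(nt), times = np)
    schema <- row$factors[[1]]
    temps <- row$temp_levels[[1]]
    x <- matrix(0, n, length(cfg$b), dimnames = list(NULL, names(cfg$b)))
    temp_raw <- sample(temps, n, replace = TRUE)
    if ("temperature" %in% schema && length(unique(temps)) > 1L)
      x[, "temperature"] <- as.vector(scale(temp_raw))
    if ("expectation" %in% schema)
      x[, "expectation"] <- as.vector(scale(sample(c(-1, 0, 1), n, replace = TRUE)))
    if ("social" %in% schema)
      x[, "social"] <- as.vector(scale(sample(c(-1, 1), n, replace = TRUE)))
    if ("control" %in% schema)
      x[, "control"] <- as.vector(scale(sample(c(0, 1), n, replace = TRUE)))
    if (nt > 1L) x[, "habituation"] <- as.vector(scale(tix))
    active <- colnames(x)[apply(x, 2, function(v) sd(v) > 0)]
    g <- rnorm(n)
    u <- rep(rnorm(np, 0, cfg$sd_intercept), each = nt)
    rating_z <- as.vector(x %*% cfg$b) + cfg$b_latent * g + u +
      rnorm(n, 0, cfg$sd_noise)
    scale_s <- cfg$rating_scale * exp(rnorm(1, 0, 0.2))
    center_s <- cfg$rating_center + rnorm(1, 0, 5)
    rating <- center_s + scale_s * rating_z
    amp_s <- exp(rnorm(1, 0, cfg$sd_study_amp))
    offset_s <- rnorm(V, 0, cfg$sd_study_offset)
    comp <- cbind(x, latent = g)
    signal <- matrix(0, n, V)
    for (j in seq_len(m_sig)) {
      expressed <- comp +
        cfg$expr_noise_sd * matrix(rnorm(n * n_comp), n, n_comp)
      signal[, region_vox[[j]]] <- expressed %*% t(subpat[[j]])
    }
    parcel_z <- matrix(rnorm(n * R), n, R)
    noise <- sqrt(cfg$noise_rho) * parcel_z[, parc$region, drop = FALSE] +
      sqrt(1 - cfg$noise_rho) * matrix(rnorm(n * V), n, V)
    feats <- amp_s * signal +
      cfg$sd_voxel_noise * noise +
      matrix(offset_s, n, V, byrow = TRUE)
    meta <- data.frame(participant_id = pid, trial_index = tix,
                       rating = rating, temperature = temp_raw,
                       stringsAsFactors = FALSE)
    for (f in setdiff(active, "temperature")) meta[[f]] <- x[, f]
    schema_cols <- intersect(c("temperature", setdiff(active, "temperature")),
                             names(meta))
    if (!("temperature" %in% active)) schema_cols <- setdiff(schema_cols, "temperature")
    datasets[[s]] <- study_dataset(row$study_id, feats, meta, parc$mask,
                                   factor_schema = schema_cols)
    truth$coefficients[[row$study_id]] <-
      c(cfg$b[active], latent = cfg$b_latent)
  }
  names(datasets) <- studies$study_id
  list(datasets = datasets, ground_truth = truth)
}

#' Simulate labeled task-contrast maps for specificity testing
#'
#' Generates per-participant mean contrast maps for a balanced set of
#' tasks: pain tasks in three modalities (heat, mechanical, visceral; two
#' studies each) containing the ground-truth pain pattern at a
#' modality-specific amplitude, and non-pain cognitive-demand and aversive
#' tasks that share only a salience component and task-specific patterns
#' with the pain tasks.
#'
#' @param cfg a [generator_config()] (noise settings reused).
#' @param parc the parcellation.
#' @param ground_truth `ground_truth` from [simulate_multistudy()] (supplies
#'   the pain pattern the decoders were trained against).
#' @param seed integer seed.
#' @param n_per_task participants (maps) per task, default 15.
#' @param pain_amp named amplitudes per pain modality.
#' @param salience_amp amplitude of the shared salience component.
#' @param task_amp amplitude of each task's idiosyncratic pattern.
#' @return list with `maps` (matrix maps x voxels) and `info` (data.frame
#'   of task, category, modality, participant_id, study_id per map).
#' @export
simulate_specificity_maps <- function(cfg, parc, ground_truth, seed = 1L,
                                      n_per_task = 15L,
                                      pain_amp = c(heat = 1.2, mechanical = 0.72,
                                                   visceral = 0.6),
                                      salience_amp = 0.5, task_amp = 0.5) {
  set.seed(derive_seed(seed, "specificity"))
  V <- n_voxels(parc$mask)
  tasks <- data.frame(
    task = c("Heat1", "Heat2", "Mech1", "Mech2", "Visc1", "Visc2",
             "WM1", "WM2", "Inhib1", "Inhib2", "RespSel1", "RespSel2",
             "AversiveImg1", "AversiveImg2", "Rejection", "VicariousPain",
             "AversiveSnd1", "AversiveSnd2"),
    category = c(rep("pain", 6), rep("cognitive", 6), rep("aversive", 6)),
    modality = c("heat", "heat", "mechanical", "mechanical", "visceral",
                 "visceral", rep(NA_character_, 12)),
    stringsAsFactors = FALSE)
  salience <- unit_pattern(V, seq_len(V), salience_amp * cfg$amp_pain)
  n_maps <- nrow(tasks) * n_per_task
  maps <- matrix(0, n_maps, V)
  info <- data.frame(task = character(n_maps), category = character(n_maps),
                     modality = character(n_maps),
                     participant_id = character(n_maps),
                     study_id = character(n_maps), stringsAsFactors = FALSE)
  at <- 1L
  for (t in seq_len(nrow(tasks))) {
    task_pattern <- unit_pattern(V, seq_len(V), task_amp * cfg$amp_pain)
    amp <- if (tasks$category[t] == "pain") pain_amp[[tasks$modality[t]]] else 0
    for (p in seq_len(n_per_task)) {
      noise <- cfg$sd_voxel_noise *
        (sqrt(cfg$noise_rho) * rnorm(length(unique(parc$region)))[parc$region] +
           sqrt(1 - cfg$noise_rho) * rnorm(V))
      maps[at, ] <- amp * ground_truth$pattern_pain + salience + task_pattern + noise
      info$task[at] <- tasks$task[t]
      info$category[at] <- tasks$category[t]
      info$modality[at] <- tasks$modality[t]
      info$participant_id[at] <- sprintf("%s_p%02d", tasks$task[t], p)
      info$study_id[at] <- tasks$task[t]
      at <- at + 1L
    }
  }
  list(maps = maps, info = info)
}

#' Simulate a participant x space performance table
#'
#' Direct generator of Fisher-z performance tables with study, study-by-
#' space, and participant variance components, used to check the calibration
#' of the mixed-effects comparison machinery without running decoders.
#'
#' @param n_studies,participants_per_study table shape.
#' @param space_means named numeric vector of true mean z per space.
#' @param sd_study SD of study intercepts.
#' @param sd_study_space SD of study-by-space (slope-like) effects.
#' @param sd_participant SD of participant offsets (shared across spaces).
#' @param sd_noise residual SD.
#' @param seed integer seed.
#' @return A `performance_table` data.frame (participant, study, space, z).
#' @export
simulate_performance_table <- function(n_studies = 7L, participants_per_study = 16L,
                                       space_means = setNames(rep(0.5, 6),
                                         c("REGION", "FRSN", "CRSN", "PATHWAYS",
                                           "META", "FULL")),
                                       sd_study = 0.15, sd_study_space = 0.10,
                                       sd_participant = 0.30, sd_noise = 0.30,
                                       seed = 1L) {
  set.seed(derive_seed(seed, "perftable"))
  spaces <- names(space_means)
  out <- list(); at <- 1L
  for (s in seq_len(n_studies)) {
    u_study <- rnorm(1, 0, sd_study)
    u_ss <- rnorm(length(spaces), 0, sd_study_space)
    for (p in seq_len(participants_per_study)) {
      u_p <- rnorm(1, 0, sd_participant)
      z <- space_means + u_study + u_ss + u_p + rnorm(length(spaces), 0, sd_noise)
      out[[at]] <- data.frame(
        participant = sprintf("s%02d_p%02d", s, p),
        study = sprintf("s%02d", s), space = spaces, z = as.numeric(z),
        n_points = 4L, stringsAsFactors = FALSE)
      at <- at + 1L
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("performance_table", "data.frame")
  res
}
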