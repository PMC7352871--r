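#' Configuration for the synthetic urinary-proteome cohort generator
#'
#' Defaults emulate the discovery study design: 35 good-prognosis (GPG) and
#' 19 poor-prognosis (PPG) type-2-diabetes patients, ~1200 urinary proteins,
#' six near-constant endogenous normalization proteins, a small set of
#' planted discriminative markers, and abundance-dependent (missing
#' not-at-random) dropout typical of label-free quantitation.
#'
#' The abundance model is per-protein log2-normal with protein mean
#' ~ U\[18, 30\] and SD ~ U\[0.4, 1.2\] (the typical LFQ dynamic range). Each
#' sample additionally carries three multiplicative factors: a urine dilution
#' factor tracked by urinary creatinine, a loading factor tracked by total
#' protein, and a residual technical factor that only the endogenous-protein
#' normalization removes.
#'
#' @param n_good,n_poor group sizes (GPG / PPG).
#' @param n_proteins total number of proteins.
#' @param n_markers number of planted discriminative proteins; half shift up
#'   in PPG and half down.
#' @param marker_effect group shift of each marker, in units of its own
#'   log2 SD.
#' @param n_norm_proteins number of planted stable normalization proteins
#'   (coefficient of variation <= 5%, no group shift, never missing).
#' @param missing_rate target average fraction of missing entries among
#'   non-normalization proteins.
#' @param mnar_strength slope of the logistic link between log2 abundance
#'   and missingness probability (0 = missing completely at random).
#' @param creatinine_mean,creatinine_sd urinary creatinine scale (mg/dL).
#' @param total_protein_mean,total_protein_sd urinary total protein (mg/dL).
#' @param dilution_sd SD (log2) of the per-sample urine dilution factor.
#' @param loading_sd SD (log2) of the per-sample protein loading factor.
#' @param sample_effect_sd SD (log2) of the residual per-sample technical
#'   factor that creatinine/total-protein correction cannot remove.
#' @param norm_protein_cv intrinsic CV of the normalization proteins.
#' @param seed integer seed; fixed seed gives identical cohorts.
#' @return a validated `cohort_config` list.
#' @export
cohort_config <- function(n_good = 35, n_poor = 19, n_proteins = 1200,
                          n_markers = 5, marker_effect = 1.5,
                          n_norm_proteins = 6, missing_rate = 0.15,
                          mnar_strength = 1.5,
                          creatinine_mean = 120, creatinine_sd = 45,
                          total_protein_mean = 15, total_protein_sd = 6,
                          dilution_sd = 1, loading_sd = 0.5,
                          sample_effect_sd = 0.4, norm_protein_cv = 0.04,
                          seed = NULL) {
  cfg <- list(n_good = n_good, n_poor = n_poor, n_proteins = n_proteins,
              n_markers = n_markers, marker_effect = marker_effect,
              n_norm_proteins = n_norm_proteins, missing_rate = missing_rate,
              mnar_strength = mnar_strength,
              creatinine_mean = creatinine_mean, creatinine_sd = creatinine_sd,
              total_protein_mean = total_protein_mean,
              total_protein_sd = total_protein_sd,
              dilution_sd = dilution_sd, loading_sd = loading_sd,
              sample_effect_sd = sample_effect_sd,
              norm_protein_cv = norm_protein_cv, seed = seed)
  counts <- c("n_good", "n_poor", "n_proteins")
  for (nm in counts) {
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1 || cfg[[nm]] < 1 ||
        cfg[[nm]] != round(cfg[[nm]])) {
      stop("configuration error: '", nm, "' must be a positive count")
    }
  }
  for (nm in c("n_markers", "n_norm_proteins")) {
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] < 0 || cfg[[nm]] != round(cfg[[nm]])) {
      stop("configuration error: '", nm, "' must be a nonnegative count")
    }
  }
  if (cfg$n_markers + cfg$n_norm_proteins > cfg$n_proteins) {
    stop("configuration error: n_markers + n_norm_proteins exceeds n_proteins")
  }
  if (cfg$missing_rate < 0 || cfg$missing_rate > 1) {
    stop("configuration error: missing_rate must be in [0, 1]")
  }
  if (cfg$mnar_strength < 0) stop("configuration error: mnar_strength must be >= 0")
  for (nm in c("creatinine_mean", "total_protein_mean")) {
    if (cfg[[nm]] <= 0) stop("configuration error: '", nm, "' must be positive")
  }
  if (cfg$norm_protein_cv < 0 || cfg$norm_protein_cv > 0.05) {
    stop("configuration error: norm_protein_cv must be in [0, 0.05]")
  }
  class(cfg) <- "cohort_config"
  cfg
}

#' Mask entries of a positive abundance matrix missing-not-at-random
#'
#' Missingness probability is `plogis(strength * (threshold - log2(x)))`,
#' with the threshold calibrated so that the expected missing fraction over
#' eligible entries equals `missing_rate`. With `strength = 0` this reduces
#' to missing completely at random.
#'
#' @param values positive numeric matrix.
#' @param missing_rate target average missing fraction.
#' @param strength logistic slope linking low abundance to dropout.
#' @param exempt_rows rownames never masked.
#' @param seed optional integer seed.
#' @return list with `values` (masked matrix) and `masked` (logical matrix).
#' @export
mask_mnar <- function(values, missing_rate, strength = 1.5,
                      exempt_rows = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  masked <- matrix(FALSE, nrow(values), ncol(values), dimnames = dimnames(values))
  if (missing_rate <= 0) return(list(values = values, masked = masked))
  eligible <- !(rownames(values) %in% exempt_rows)
  x <- log2(values[eligible, , drop = FALSE])
  if (strength <= 0) {
    pm <- matrix(missing_rate, nrow(x), ncol(x))
  } else {
    f <- function(thr) mean(stats::plogis(strength * (thr - x))) - missing_rate
    thr <- stats::uniroot(f, range(x) + c(-50, 50), tol = 1e-9)$root
    pm <- stats::plogis(strength * (thr - x))
  }
  hit <- matrix(stats::runif(length(x)) < pm, nrow(x), ncol(x))
  masked[eligible, ] <- hit
  values[masked] <- NA
  list(values = values, masked = masked)
}

#' Generate a synthetic urinary-proteome cohort
#'
#' Draws a raw LFQ matrix, per-sample clinical metadata (prognosis group,
#' urinary creatinine, total protein, ACR and the usual baseline covariates),
#' and the generating ground truth. Marker proteins are shifted between
#' groups on the log2 scale by `marker_effect` SD units; normalization
#' proteins have intrinsic CV <= 5%, no group shift, and are never masked
#' (they emulate always-quantified high-abundance endogenous references).
#' Missingness is generated missing-not-at-random with probability
#' decreasing in abundance (see [mask_mnar()]).
#'
#' @param config a [cohort_config()].
#' @return list with `abundance` (raw-stage [abundance_matrix()]), `meta`
#'   (data frame) and `truth` (list: `marker_ids`, `marker_direction`,
#'   `norm_protein_ids`, `true_group`, `complete` raw matrix before masking,
#'   `masked` logical matrix, `log2_base` group-and-noise component without
#'   sample factors).
#' @export
generate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config")) {
    config <- do.call(cohort_config, as.list(config))
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  p <- config$n_proteins
  n <- config$n_good + config$n_poor
  group <- factor(rep(c("GPG", "PPG"), c(config$n_good, config$n_poor)),
                  levels = c("GPG", "PPG"))
  pid <- sprintf("P%05d", seq_len(p))
  sid <- sprintf("S%02d", seq_len(n))

  special <- sample(p, config$n_markers + config$n_norm_proteins)
  marker_idx <- special[seq_len(config$n_markers)]
  norm_idx <- special[config$n_markers + seq_len(config$n_norm_proteins)]

  mu <- stats::runif(p, 18, 30)
  sdl <- stats::runif(p, 0.4, 1.2)
  # normalization proteins: high-abundance, tiny intrinsic variance
  mu[norm_idx] <- stats::runif(length(norm_idx), 26, 30)
  sdl[norm_idx] <- config$norm_protein_cv / log(2)

  beta <- numeric(p)
  if (config$n_markers > 0) {
    n_up <- ceiling(config$n_markers / 2)
    sign_m <- rep(c(1, -1), c(n_up, config$n_markers - n_up))
    beta[marker_idx] <- sign_m * config$marker_effect * sdl[marker_idx]
  }

  eps <- matrix(stats::rnorm(p * n, sd = sdl), p, n)   # sdl recycles by row
  log2_base <- mu + outer(beta, as.numeric(group == "PPG")) + eps

  dil <- stats::rnorm(n, 0, config$dilution_sd)        # log2 dilution
  load <- stats::rnorm(n, 0, config$loading_sd)        # log2 loading
  tech <- stats::rnorm(n, 0, config$sample_effect_sd)  # residual technical
  log2_raw <- sweep(log2_base, 2, dil + load + tech, "+")
  raw <- 2^log2_raw
  dimnames(raw) <- list(pid, sid)

  cv_c <- config$creatinine_sd / config$creatinine_mean
  cv_t <- config$total_protein_sd / config$total_protein_mean
  creatinine <- config$creatinine_mean * 2^dil * exp(stats::rnorm(n, 0, cv_c / 2))
  total_protein <- config$total_protein_mean * 2^load * exp(stats::rnorm(n, 0, cv_t / 2))

  mk <- mask_mnar(raw, config$missing_rate, config$mnar_strength,
                  exempt_rows = pid[norm_idx])

  meta <- data.frame(
    sample_id = sid,
    group = group,
    creatinine = creatinine,
    total_protein = total_protein,
    sex = sample(c("M", "F"), n, replace = TRUE, prob = c(0.35, 0.65)),
    age = round(stats::rnorm(n, 57, 10), 1),
    bmi = round(stats::rnorm(n, 23.4, 3.2), 1),
    followup_years = round(pmax(1, stats::rnorm(n, 4.75, 1.9)), 2),
    sbp = round(stats::rnorm(n, 126, 13)),
    ldl = round(stats::rnorm(n, 101, 35)),
    hdl = round(stats::rnorm(n, 51, 10)),
    triglycerides = round(stats::rlnorm(n, log(130), 0.6)),
    egfr_baseline = round(stats::rnorm(n, 89, 16), 1),
    hba1c = round(pmax(4.5, stats::rnorm(n, 7.6, 1.7)), 1),
    acr = round(stats::rlnorm(n, log(60), 1.3), 1),
    napcr = round(stats::rlnorm(n, log(120), 1.0), 1),
    pcr = round(stats::rlnorm(n, log(200), 1.1), 1),
    retinopathy = stats::rbinom(n, 1, 0.37),
    ras_inhibitor = stats::rbinom(n, 1, 0.39),
    antihypertensive = stats::rbinom(n, 1, 0.31),
    lipid_lowering = stats::rbinom(n, 1, 0.56),
    stringsAsFactors = FALSE
  )

  truth <- list(
    marker_ids = pid[marker_idx],
    marker_direction = stats::setNames(sign(beta[marker_idx]), pid[marker_idx]),
    norm_protein_ids = pid[norm_idx],
    true_group = stats::setNames(as.character(group), sid),
    complete = raw,
    masked = mk$masked,
    log2_base = `dimnames<-`(log2_base, list(pid, sid))
  )
  list(abundance = abundance_matrix(mk$values, stage = "raw"),
       meta = meta, truth = truth)
}

#' Generate a synthetic external gene-expression dataset
#'
#' Emulates a processed microarray/RNA series: a complete genes x samples
#' matrix (log2-like scale) containing at least the panel genes, with
#' optional per-gene mean shifts for chosen disease labels.
#'
#' @param n_per_group named integer vector: samples per disease label.
#' @param panel_genes character vector of panel gene symbols (nonempty).
#' @param effects numeric matrix of mean shifts, genes x labels (rownames in
#'   `panel_genes` or extra genes, colnames in `names(n_per_group)`); absent
#'   entries are 0.
#' @param n_extra_genes additional background genes.
#' @param noise_sd residual SD.
#' @param baseline_mean expression grand mean.
#' @param seed optional integer seed.
#' @return list with `matrix` (genes x samples) and `labels` (factor, named
#'   by sample).
#' @export
generate_expression_dataset <- function(n_per_group, panel_genes,
                                        effects = NULL, n_extra_genes = 50,
                                        noise_sd = 1, baseline_mean = 8,
                                        seed = NULL) {
  if (length(panel_genes) == 0) stop("panel_genes must be nonempty")
  if (is.null(names(n_per_group)) || any(names(n_per_group) == "")) {
    stop("n_per_group must be a named vector of group sizes")
  }
  if (!is.null(seed)) set.seed(seed)
  genes <- c(panel_genes,
             if (n_extra_genes > 0) sprintf("BG%04d", seq_len(n_extra_genes)))
  labels <- factor(rep(names(n_per_group), n_per_group),
                   levels = names(n_per_group))
  n <- length(labels)
  sid <- sprintf("GSM%04d", seq_len(n))
  gmu <- stats::rnorm(length(genes), baseline_mean, 1.5)
  mat <- gmu + matrix(stats::rnorm(length(genes) * n, 0, noise_sd),
                      length(genes), n)
  dimnames(mat) <- list(genes, sid)
  if (!is.null(effects)) {
    for (g in intersect(rownames(effects), genes)) {
      for (lb in intersect(colnames(effects), levels(labels))) {
        mat[g, labels == lb] <- mat[g, labels == lb] + effects[g, lb]
      }
    }
  }
  list(matrix = mat, labels = stats::setNames(labels, sid))
}

#' Generate synthetic eGFR follow-up trajectories
#'
#' Each series starts near `baseline_mean` and drifts linearly by its
#' annual `slope` plus measurement noise, over regular visits spanning
#' `follow_years`.
#'
#' @param n number of patients.
#' @param baseline_mean,baseline_sd baseline eGFR (mL/min/1.73 m2).
#' @param slope annual eGFR change (mL/min/1.73 m2 per year); scalar or
#'   length-`n` vector.
#' @param follow_years follow-up span in years (> 0).
#' @param n_visits measurements per patient (>= 2), evenly spaced from 0.
#' @param noise_sd measurement noise SD.
#' @param seed optional integer seed.
#' @return long data frame: `sample_id`, `time_years`, `egfr` (floored at 1).
#' @export
generate_egfr_trajectories <- function(n, baseline_mean = 90, baseline_sd = 10,
                                       slope = -1, follow_years = 5,
                                       n_visits = 6, noise_sd = 2.5,
                                       seed = NULL) {
  if (follow_years <= 0) stop("configuration error: follow_years must be > 0")
  if (n_visits < 2) stop("configuration error: n_visits must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  slope <- rep_len(slope, n)
  times <- seq(0, follow_years, length.out = n_visits)
  base <- stats::rnorm(n, baseline_mean, baseline_sd)
  out <- do.call(rbind, lapply(seq_len(n), function(i) {
    e <- base[i] + slope[i] * times + stats::rnorm(n_visits, 0, noise_sd)
    data.frame(sample_id = sprintf("S%02d", i), time_years = times,
               egfr = pmax(e, 1), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
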