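#' CKD-EPI (2009) estimated glomerular filtration rate
#'
#' eGFR = 141 x min(Scr/kappa, 1)^alpha x max(Scr/kappa, 1)^-1.209
#' x 0.993^age x 1.018 (if female) x 1.159 (if black), with kappa = 0.7 and
#' alpha = -0.329 for females, kappa = 0.9 and alpha = -0.411 for males.
#' Serum creatinine in mg/dL; result in mL/min/1.73 m2. All arguments are
#' vectorized.
#'
#' @param serum_creatinine serum creatinine, mg/dL (> 0).
#' @param age age in years (> 0; `age = 0` is accepted as a boundary case).
#' @param female logical, sex female.
#' @param black logical, race coefficient applied.
#' @return eGFR in mL/min/1.73 m2.
#' @examples
#' egfr_ckdepi(0.7, age = 50, female = TRUE)  # ~101
#' egfr_ckdepi(1.8, age = 60, female = FALSE) # ~40
#' @export
egfr_ckdepi <- function(serum_creatinine, age, female, black = FALSE) {
  if (any(serum_creatinine <= 0)) stop("domain error: serum creatinine must be > 0")
  if (any(age < 0)) stop("domain error: age must be nonnegative")
  n <- max(length(serum_creatinine), length(age), length(female), length(black))
  scr <- rep_len(serum_creatinine, n)
  age <- rep_len(age, n)
  female <- rep_len(as.logical(female), n)
  black <- rep_len(as.logical(black), n)
  kappa <- ifelse(female, 0.7, 0.9)
  alpha <- ifelse(female, -0.329, -0.411)
  r <- scr / kappa
  141 * pmin(r, 1)^alpha * pmax(r, 1)^(-1.209) * 0.993^age *
    ifelse(female, 1.018, 1) * ifelse(black, 1.159, 1)
}

#' Chronic kidney disease stage from eGFR
#'
#' Stages 1, 2, 3a, 3b, 4 and 5 correspond to eGFR >= 90, 60-89, 45-59,
#' 30-44, 15-29 and < 15 mL/min/1.73 m2 (half-open bins; 90 is stage 1,
#' 60 is stage 2, 45 is 3a, 30 is 3b, 15 is 4).
#'
#' @param egfr eGFR, mL/min/1.73 m2 (>= 0). Vectorized.
#' @return factor with ordered levels `1 < 2 < 3a < 3b < 4 < 5` (worse
#'   kidney function = higher stage).
#' @export
ckd_stage <- function(egfr) {
  if (any(egfr < 0)) stop("domain error: eGFR must be nonnegative")
  st <- cut(egfr, breaks = c(-Inf, 15, 30, 45, 60, 90, Inf),
            labels = c("5", "4", "3b", "3a", "2", "1"), right = FALSE)
  factor(as.character(st), levels = c("1", "2", "3a", "3b", "4", "5"),
         ordered = TRUE)
}

#' Rule set for renal-outcome labelling
#'
#' An outcome event is an eGFR below `egfr_floor`, an annual eGFR reduction
#' greater than `annual_decline`, or CKD progression (a worse CKD stage with
#' a >= `progression_drop_fraction` deterioration from baseline).
#'
#' @param egfr_floor mL/min/1.73 m2 (default 60).
#' @param annual_decline mL/min/1.73 m2 per year (default 3).
#' @param progression_drop_fraction fractional eGFR drop (default 0.25).
#' @param decline_method `"slope"` (least-squares eGFR-on-time slope, robust
#'   with > 2 visits) or `"endpoint"` ((first - last) / span).
#' @export
outcome_rule <- function(egfr_floor = 60, annual_decline = 3,
                         progression_drop_fraction = 0.25,
                         decline_method = c("slope", "endpoint")) {
  if (egfr_floor <= 0 || annual_decline <= 0 || progression_drop_fraction <= 0) {
    stop("all outcome thresholds must be positive")
  }
  list(egfr_floor = egfr_floor, annual_decline = annual_decline,
       progression_drop_fraction = progression_drop_fraction,
       decline_method = match.arg(decline_method))
}

#' Classify a renal outcome from an eGFR time series
#'
#' @param time_years visit times in years (>= 2 points spanning >= 1 year).
#' @param egfr eGFR at each visit.
#' @param rule an [outcome_rule()].
#' @return list with `outcome` (logical) and `reasons`, a subset of
#'   `c("floor", "decline", "progression")`:
#'   * `floor`: minimum observed eGFR below the floor;
#'   * `decline`: annual eGFR reduction above the threshold (least-squares
#'     slope by default);
#'   * `progression`: final CKD stage worse than baseline and a relative
#'     eGFR drop of at least `progression_drop_fraction` from baseline.
#' @export
classify_renal_outcome <- function(time_years, egfr, rule = outcome_rule()) {
  if (length(time_years) != length(egfr)) stop("time and eGFR lengths differ")
  ord <- order(time_years)
  t <- time_years[ord]; e <- egfr[ord]
  if (length(t) < 2 || diff(range(t)) < 1) {
    stop("insufficient data: need >= 2 eGFR measurements spanning >= 1 year")
  }
  reasons <- character(0)
  if (min(e) < rule$egfr_floor) reasons <- c(reasons, "floor")
  slope <- if (rule$decline_method == "slope") {
    unname(stats::coef(stats::lm(e ~ t))[2])
  } else {
    (e[length(e)] - e[1]) / (t[length(t)] - t[1])
  }
  if (-slope > rule$annual_decline) reasons <- c(reasons, "decline")
  st0 <- ckd_stage(e[1]); st1 <- ckd_stage(e[length(e)])
  drop_frac <- (e[1] - e[length(e)]) / e[1]
  if (st1 > st0 && drop_frac >= rule$progression_drop_fraction) {
    reasons <- c(reasons, "progression")
  }
  list(outcome = length(reasons) > 0, reasons = reasons,
       annual_slope = slope, baseline_stage = as.character(st0),
       final_stage = as.character(st1))
}

#' Albuminuria class from albumin-to-creatinine ratio
#'
#' Normal < 30 mg/g, microalbuminuria 30-300 mg/g (inclusive),
#' macroalbuminuria > 300 mg/g.
#'
#' @param acr urinary albumin-to-creatinine ratio, mg/g (>= 0). Vectorized.
#' @return factor with levels normal / microalbuminuria / macroalbuminuria.
#' @export
albuminuria_class <- function(acr) {
  if (any(acr < 0)) stop("domain error: ACR must be nonnegative")
  cls <- ifelse(acr < 30, "normal",
                ifelse(acr <= 300, "microalbuminuria", "macroalbuminuria"))
  factor(cls, levels = c("normal", "microalbuminuria", "macroalbuminuria"))
}

#' Baseline characteristics comparison between prognosis groups
#'
#' Compares each clinical variable between the two groups: continuous
#' variables by Mann-Whitney U test, categorical (character/factor/logical
#' or 0/1) by Fisher's exact test, with a Bonferroni family threshold
#' `family_alpha / number of variables` (0.05/17 = 0.0029 for the default
#' 17-variable baseline table).
#'
#' @param meta data frame with a two-level `group` column.
#' @param variables columns to test; default all except `sample_id`,
#'   `group`, `creatinine`, `total_protein`.
#' @param family_alpha family-wise alpha (default 0.05).
#' @return list with `table` (variable, type, statistic, p, flagged) and
#'   `threshold`.
#' @export
baseline_comparison <- function(meta, variables = NULL, family_alpha = 0.05) {
  meta <- validate_sample_meta(meta)
  if (is.null(meta$group) || nlevels(factor(meta$group)) != 2) {
    stop("baseline comparison needs exactly two groups")
  }
  g <- factor(meta$group)
  if (is.null(variables)) {
    variables <- setdiff(names(meta),
                         c("sample_id", "group", "creatinine", "total_protein"))
  }
  threshold <- family_alpha / length(variables)
  rows <- lapply(variables, function(v) {
    x <- meta[[v]]
    categorical <- is.character(x) || is.factor(x) || is.logical(x) ||
      (is.numeric(x) && all(x %in% c(0, 1)))
    if (categorical) {
      p <- stats::fisher.test(table(factor(x), g))$p.value
      data.frame(variable = v, type = "categorical", statistic = NA_real_,
                 p = p, stringsAsFactors = FALSE)
    } else {
      ht <- suppressWarnings(stats::wilcox.test(x ~ g))
      data.frame(variable = v, type = "continuous",
                 statistic = unname(ht$statistic), p = ht$p.value,
                 stringsAsFactors = FALSE)
    }
  })
  tab <- do.call(rbind, rows)
  tab$flagged <- tab$p < threshold
  list(table = tab, threshold = threshold)
}
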