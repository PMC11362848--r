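# Semiquantitative neuropathology scoring: tumor-infiltration grades,
# CERAD neuritic-plaque scores, ADNC categories, Braak-group/CERAD
# combined severity, APP and axonal-injury scores, cohort prevalence
# summaries, and Cohen's kappa for inter-rater agreement.

BRAAK_GROUPS <- c("0", "I-II", "III-IV", "V-VI")
CERAD_LEVELS <- c("0", "A", "B", "C")
ADNC_CATEGORIES <- c("AT", "T", "A", "vascular_only", "none")

#' Grade cortical tumor cell infiltration
#'
#' `high` above 70% nonneuronal cells; `medium` for an approximately
#' balanced neuron:nonneuron ratio, operationalized as a nonneuronal
#' fraction in \[0.45, 0.70\]; `low` otherwise.
#'
#' @param neuron_count,nonneuron_count non-negative counts, not both zero.
#' @return "low", "medium" or "high".
#' @export
grade_infiltration <- function(neuron_count, nonneuron_count) {
  stopifnot(neuron_count >= 0, nonneuron_count >= 0)
  if (neuron_count + nonneuron_count == 0) {
    stop("cannot grade infiltration: both counts are zero")
  }
  f <- nonneuron_count / (neuron_count + nonneuron_count)
  if (f > 0.70) "high" else if (f >= 0.45) "medium" else "low"
}

#' CERAD neuritic plaque score
#'
#' 0 = no neuritic plaques (diffuse plaques only, or none); A = 1-3 per
#' high-power field; B = 5-10; C = frequent (> 20). Counts falling in the
#' scale's gaps (4, 11-20) take the nearest boundary class (4 -> A,
#' 11-20 -> B).
#'
#' @param neuritic_per_hpf neuritic plaques per high-power field, >= 0.
#' @param diffuse_present whether diffuse plaques are present (recorded,
#'   does not change the score).
#' @return "0", "A", "B" or "C".
#' @export
cerad_score <- function(neuritic_per_hpf, diffuse_present = FALSE) {
  if (neuritic_per_hpf < 0) stop("neuritic plaque count must be >= 0")
  if (neuritic_per_hpf == 0) "0"
  else if (neuritic_per_hpf <= 4) "A"
  else if (neuritic_per_hpf <= 20) "B"
  else "C"
}

#' Classify the ADNC category of a sample
#'
#' AT = parenchymal amyloid plus tau; T = tau only; A = parenchymal
#' amyloid only; vascular_only = amyloid restricted to vessel walls;
#' none otherwise.
#'
#' @param abeta_parenchymal,ptau,abeta_vascular logical flags.
#' @return one of "AT", "T", "A", "vascular_only", "none".
#' @export
classify_adnc <- function(abeta_parenchymal, ptau, abeta_vascular = FALSE) {
  if (abeta_parenchymal && ptau) "AT"
  else if (ptau) "T"
  else if (abeta_parenchymal) "A"
  else if (abeta_vascular) "vascular_only"
  else "none"
}

#' Combined ADNC severity score
#'
#' Rank sum of the Braak group (0, I-II, III-IV, V-VI -> 0-3) and the
#' CERAD score (0, A, B, C -> 0-3); range 0-6, zero iff both components
#' are zero, monotone in each.
#'
#' @param braak_group one of "0", "I-II", "III-IV", "V-VI" (NA allowed).
#' @param cerad one of "0", "A", "B", "C" (NA allowed).
#' @return integer 0-6, or NA (with a warning) when either input is NA.
#' @export
combined_severity <- function(braak_group, cerad) {
  if (is.na(braak_group) || is.na(cerad)) {
    warning("combined_severity: NA component, returning NA")
    return(NA_integer_)
  }
  b <- match(braak_group, BRAAK_GROUPS)
  c_ <- match(cerad, CERAD_LEVELS)
  if (is.na(b)) stop("unknown Braak group: ", braak_group)
  if (is.na(c_)) stop("unknown CERAD score: ", cerad)
  as.integer((b - 1L) + (c_ - 1L))
}

#' Score cellular APP expression
#'
#' absent < 1% of cells; sparse 1-5%; moderate 10-30%; abundant > 50%.
#' Percentages in the scale's gaps take the nearest boundary class
#' (5-10 -> sparse/moderate split at 7.5; 30-50 -> moderate/abundant split
#' at 40).
#'
#' @param fraction_positive percentage of positive cells (0-100).
#' @return "absent", "sparse", "moderate" or "abundant".
#' @export
score_app <- function(fraction_positive) {
  stopifnot(fraction_positive >= 0, fraction_positive <= 100)
  if (fraction_positive < 1) "absent"
  else if (fraction_positive <= 7.5) "sparse"
  else if (fraction_positive <= 40) "moderate"
  else "abundant"
}

#' Score diffuse axonal injury from APP-positive spheroids
#'
#' absent = none; sparse = 1-10 per high-power field in hot spots;
#' moderate = 10-30; frequent > 30.
#'
#' @param spheroids_per_hpf_hotspot spheroid count per high-power field in
#'   hot spots, >= 0.
#' @return "absent", "sparse", "moderate" or "frequent".
#' @export
score_dai <- function(spheroids_per_hpf_hotspot) {
  stopifnot(spheroids_per_hpf_hotspot >= 0)
  x <- spheroids_per_hpf_hotspot
  if (x == 0) "absent"
  else if (x <= 10) "sparse"
  else if (x <= 30) "moderate"
  else "frequent"
}

#' Cohort prevalence summary
#'
#' Per-category counts and percentages of the total, with an "ADNC (any)"
#' rollup over the positive categories. Display percentages are rounded
#' half-up to integers (the convention of printed cohort tables); the raw
#' fractions are retained.
#'
#' @param records data.frame with an `adnc_category` column, >= 1 row.
#' @param include_vascular whether `vascular_only` counts as ADNC in the
#'   rollup (default TRUE).
#' @return data.frame with `category`, `count`, `fraction`, `percent`
#'   (half-up integer).
#' @export
cohort_prevalence <- function(records, include_vascular = TRUE) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop("empty cohort table")
  }
  cat <- factor(records$adnc_category, levels = ADNC_CATEGORIES)
  if (anyNA(cat)) stop("unknown adnc_category value(s) in records")
  n <- nrow(records)
  counts <- table(cat)
  adnc_cats <- c("AT", "T", "A", if (include_vascular) "vascular_only")
  out <- data.frame(
    category = c(ADNC_CATEGORIES, "ADNC_any"),
    count = c(as.integer(counts), sum(counts[adnc_cats])),
    stringsAsFactors = FALSE
  )
  out$fraction <- out$count / n
  out$percent <- round_half_up(100 * out$fraction)
  out
}

#' Prevalence percentage from printed counts
#'
#' Half-up integer percentage for a count out of a total — the rounding
#' used in printed cohort tables (e.g. 22/205 -> 11).
#'
#' @param count,total non-negative counts, total >= 1.
#' @return integer percentage.
#' @export
prevalence_percent <- function(count, total) {
  stopifnot(total >= 1, all(count >= 0))
  round_half_up(100 * count / total)
}

#' Cohen's kappa for inter-rater agreement
#'
#' kappa = (p_o - p_e) / (1 - p_e), with expected agreement p_e from the
#' product of the raters' marginal distributions. Perfect observed
#' agreement returns 1. The degenerate case p_e = 1 (both raters constant)
#' returns 1 when they agree — with a warning — and NA (flagged) when two
#' constant raters disagree, where chance agreement is undefined.
#'
#' @param rater1,rater2 equal-length categorical vectors (length >= 2)
#'   over a shared category space.
#' @return list with `kappa`, `p_observed`, `p_expected`, `n`,
#'   `table` (the contingency table).
#' @export
cohens_kappa <- function(rater1, rater2) {
  stopifnot(length(rater1) == length(rater2), length(rater1) >= 2)
  lev <- sort(unique(c(as.character(rater1), as.character(rater2))))
  r1 <- factor(as.character(rater1), levels = lev)
  r2 <- factor(as.character(rater2), levels = lev)
  tab <- table(r1, r2)
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  const1 <- length(unique(as.character(rater1))) == 1
  const2 <- length(unique(as.character(rater2))) == 1
  if (po == 1) {
    if (const1 && const2) {
      warning("both raters constant and identical; kappa defined as 1")
    }
    k <- 1
  } else if (const1 && const2) {
    warning("degenerate: constant but disagreeing raters; kappa undefined")
    k <- NA_real_
  } else {
    k <- (po - pe) / (1 - pe)
  }
  list(kappa = k, p_observed = po, p_expected = pe, n = n, table = tab)
}
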