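#' Percentage volume error of MTV against the CT reference
#'
#' `%VE = (MTV - CTV) / CTV * 100`, with the CT anatomical volume as the
#' reference standard. Positive values are overestimation by PET.
#' Scale-invariant in its two arguments; vectorised.
#'
#' @param mtv_mm3 PET metabolic tumor volume(s), cubic mm.
#' @param ctv_mm3 CT reference volume(s), cubic mm, strictly positive.
#' @return numeric percentage error(s).
#' @export
percent_volume_error <- function(mtv_mm3, ctv_mm3) {
  if (any(!is.finite(ctv_mm3)) || any(ctv_mm3 <= 0))
    stop("'ctv_mm3' must be positive")
  (mtv_mm3 - ctv_mm3) / ctv_mm3 * 100
}

#' Classify a percentage volume error into accuracy classes
#'
#' Errors within plus/minus 50% (inclusive) are acceptable (`"within"`);
#' more than +50% is `"over"` (overestimated), below -50% `"under"`.
#'
#' @param pct_ve finite numeric vector of percentage volume errors.
#' @return character vector of `"within"`, `"over"`, `"under"`.
#' @export
classify_accuracy <- function(pct_ve) {
  if (any(!is.finite(pct_ve))) stop("'pct_ve' must be finite")
  ifelse(abs(pct_ve) <= 50, "within", ifelse(pct_ve > 50, "over", "under"))
}

#' Assign size and uptake strata
#'
#' Size: long diameter at or below 20 mm (the T1a/T1b cut) is `"small"`,
#' above is `"large"`. Uptake: SUVmax at or below 2 is `"low"`, above is
#' `"high"` (early lung adenocarcinoma shows lower uptake than the usual
#' 2.5 malignancy cut). Both boundaries are inclusive to the lower group;
#' vectorised.
#'
#' @param long_diameter_mm positive lesion long diameter(s), mm.
#' @param suv_max lesion SUVmax value(s).
#' @return data frame with `size_group` and `uptake_group`.
#' @export
stratify <- function(long_diameter_mm, suv_max) {
  if (any(long_diameter_mm <= 0)) stop("'long_diameter_mm' must be positive")
  data.frame(size_group = ifelse(long_diameter_mm <= 20, "small", "large"),
             uptake_group = ifelse(suv_max <= 2, "low", "high"),
             stringsAsFactors = FALSE)
}

#' Band a Pearson correlation coefficient
#'
#' Consistency bands: 0.21-0.40 poor, 0.41-0.60 moderate, 0.61-0.80 good,
#' 0.81-1.00 excellent; values at or below 0.20 (including negative) fall
#' outside the scale and are banded `"none"`, as is `NA`.
#'
#' @param r Pearson correlation(s) in `[-1, 1]` (or `NA`).
#' @return character band(s).
#' @export
pearson_band <- function(r) {
  vapply(r, function(x) {
    if (is.na(x)) return("none")
    if (x > 0.80) "excellent"
    else if (x > 0.60) "good"
    else if (x > 0.40) "moderate"
    else if (x > 0.20) "poor"
    else "none"
  }, character(1))
}

#' Build per-lesion evaluation records
#'
#' Joins per-method MTVs with the per-case CT reference, computes the
#' percentage volume error, the accuracy class and the stratum labels.
#'
#' @param delineations data frame with columns `case_id`, `method`,
#'   `mtv_mm3`, `suv_max`.
#' @param references data frame with columns `case_id`, `ctv_mm3`,
#'   `long_diameter_mm`, `nodule_type`.
#' @return data frame of evaluation records (one row per case x method).
#' @export
evaluate_records <- function(delineations, references) {
  need_d <- c("case_id", "method", "mtv_mm3", "suv_max")
  need_r <- c("case_id", "ctv_mm3", "long_diameter_mm", "nodule_type")
  if (!all(need_d %in% names(delineations)))
    stop("'delineations' needs columns: ", paste(need_d, collapse = ", "))
  if (!all(need_r %in% names(references)))
    stop("'references' needs columns: ", paste(need_r, collapse = ", "))
  df <- merge(delineations, references[need_r], by = "case_id")
  df$pct_ve <- percent_volume_error(df$mtv_mm3, df$ctv_mm3)
  df$accuracy_class <- classify_accuracy(df$pct_ve)
  st <- stratify(df$long_diameter_mm, df$suv_max)
  df$size_group <- st$size_group
  df$uptake_group <- st$uptake_group
  df[order(df$case_id, df$method), ]
}

#' Summarise one stratum of evaluation records
#'
#' Accuracy is the percentage of records whose error lies within plus/minus
#' 50%; the MTV-CTV association is summarised by the Pearson correlation
#' and its consistency band (`NA`/`"none"` when fewer than 3 records or
#' degenerate variance).
#'
#' @param records data frame with columns `mtv_mm3`, `ctv_mm3`,
#'   `pct_ve`, `accuracy_class` (as from [evaluate_records()]).
#' @param label stratum label to carry along.
#' @return one-row data frame: `stratum`, `n`, `accuracy_pct`, `mean_ve`,
#'   `sd_ve`, `pearson_r`, `consistency_band`.
#' @export
summarize_stratum <- function(records, label = "all") {
  n <- nrow(records)
  if (is.null(n) || n < 1) stop("no records in stratum")
  r <- NA_real_
  if (n >= 3 && stats::sd(records$mtv_mm3) > 0 && stats::sd(records$ctv_mm3) > 0)
    r <- stats::cor(records$mtv_mm3, records$ctv_mm3)
  data.frame(stratum = label, n = n,
             accuracy_pct = 100 * mean(records$accuracy_class == "within"),
             mean_ve = mean(records$pct_ve),
             sd_ve = if (n > 1) stats::sd(records$pct_ve) else NA_real_,
             pearson_r = r,
             consistency_band = pearson_band(r),
             stringsAsFactors = FALSE)
}

#' Stratified per-method summary table
#'
#' Applies [summarize_stratum()] to every method overall and within each
#' nodule type, size group and uptake group.
#'
#' @param records data frame from [evaluate_records()].
#' @return data frame with one row per method x stratum.
#' @export
summarize_by_strata <- function(records) {
  out <- list()
  for (m in sort(unique(records$method))) {
    rm_ <- records[records$method == m, ]
    add <- function(rows, label) {
      if (nrow(rows) > 0) {
        s <- summarize_stratum(rows, label)
        s$method <- m
        out[[length(out) + 1]] <<- s
      }
    }
    add(rm_, "all")
    for (v in sort(unique(rm_$nodule_type)))
      add(rm_[rm_$nodule_type == v, ], paste0("type:", v))
    for (v in sort(unique(rm_$size_group)))
      add(rm_[rm_$size_group == v, ], paste0("size:", v))
    for (v in sort(unique(rm_$uptake_group)))
      add(rm_[rm_$uptake_group == v, ], paste0("uptake:", v))
  }
  df <- do.call(rbind, out)
  df[, c("method", setdiff(names(df), "method"))]
}

#' Intraclass correlation coefficient ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-rater ICC, computed
#' from the two-way ANOVA mean squares:
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`
#' for `n` cases rated by `k` observers. Absolute agreement is the relevant
#' form for inter-observer reproducibility of a measured volume. Reliability
#' bands: below 0.40 poor, above 0.75 good, otherwise intermediate.
#'
#' @param measurements numeric matrix, cases in rows, observers in columns
#'   (at least 2 x 2), with some variation across cases.
#' @return list with `icc` and `band`.
#' @export
icc_reliability <- function(measurements) {
  m <- as.matrix(measurements)
  if (nrow(m) < 2 || ncol(m) < 2) stop("need >= 2 cases and >= 2 observers")
  if (any(!is.finite(m))) stop("measurements must be finite")
  n <- nrow(m); k <- ncol(m)
  mu <- mean(m)
  rowm <- rowMeans(m); colm <- colMeans(m)
  msr <- k * sum((rowm - mu)^2) / (n - 1)
  msc <- n * sum((colm - mu)^2) / (k - 1)
  resid <- m - outer(rowm, rep(1, k)) - outer(rep(1, n), colm) + mu
  mse <- sum(resid^2) / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (denom <= 0) stop("zero total variance; ICC undefined for a constant matrix")
  icc <- (msr - mse) / denom
  band <- if (icc < 0.40) "poor" else if (icc > 0.75) "good" else "intermediate"
  list(icc = icc, band = band)
}

#' Recommend a delineation method for a lesion
#'
#' Decision rule distilled from the stratified comparison: nodule type is
#' considered first. Nonsolid and part-solid nodules (low-contrast,
#' partial-volume-dominated) go to the background-adaptive AT40%; solid
#' nodules go to the adaptive iterative method, except that small or
#' low-uptake solid nodules are tie-broken toward AT40%, the
#' background-aware choice. Vectorised.
#'
#' @param nodule_type `"nonsolid"`, `"part_solid"` or `"solid"`.
#' @param size_group `"small"` or `"large"`.
#' @param uptake_group `"low"` or `"high"`.
#' @return `"AT40"` or `"AIA"` per lesion.
#' @export
recommend_method <- function(nodule_type, size_group, uptake_group) {
  if (!all(nodule_type %in% c("nonsolid", "part_solid", "solid")))
    stop("invalid nodule_type")
  if (!all(size_group %in% c("small", "large"))) stop("invalid size_group")
  if (!all(uptake_group %in% c("low", "high"))) stop("invalid uptake_group")
  ifelse(nodule_type != "solid", "AT40",
         ifelse(size_group == "small" | uptake_group == "low", "AT40", "AIA"))
}
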