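# Slide-level diagnostic agreement statistics.
#
# Each diagnosed virtual slide is classified three ways against the optical
# ground truth: "lsen" (low sensitivity) when any critical region of
# interest was missed; otherwise "accurate" when the patterns of all regions
# were read correctly, else "lspe" (low specificity). Per-category counts
# are tabulated per rater and modality, with a sample-count-weighted average
# row, and cross-rater rates are averaged on the displayed (2-decimal)
# ratios — the rounding convention that reproduces the published aggregate
# rates from the per-rater tables.

#' Classify one slide assessment
#'
#' @param rois_truth number of critical regions of interest present.
#' @param rois_found number the rater identified (`0 <= found <= truth`).
#' @param patterns_all_correct logical: were the patterns of all regions
#'   read correctly? Only consulted (and then required) when every region
#'   was found.
#' @return `"lsen"`, `"accurate"` or `"lspe"`.
#' @export
classify <- function(rois_truth, rois_found, patterns_all_correct = NA) {
  if (rois_found < 0 || rois_found > rois_truth)
    stopf("rois_found must be between 0 and rois_truth")
  if (rois_found < rois_truth) return("lsen")
  if (is.na(patterns_all_correct))
    stopf("patterns_all_correct is required when all regions were found")
  if (isTRUE(patterns_all_correct)) "accurate" else "lspe"
}

#' Tabulate per-category agreement for one rater and modality
#'
#' @param records data.frame from [load_diagnosis_records()].
#' @param rater rater id to filter on.
#' @param modality modality to filter on (`optical`, `swsi_vs`,
#'   `scanner_vs`).
#' @return data.frame of class `agreement_table`: one row per category
#'   present plus an `average` row (column sums over the total n), with
#'   exact counts (`n`, `accurate_n`, `lsen_n`, `lspe_n`) and display
#'   ratios (`accurate`, `lsen`, `lspe`) rounded half-up to 2 decimals.
#' @export
tabulate_agreement <- function(records, rater, modality) {
  r <- records[records$rater_id == rater & records$modality == modality, ]
  if (!nrow(r)) stopf("no records for rater '%s', modality '%s'",
                      rater, modality)
  cats <- DIAG_CATEGORIES[DIAG_CATEGORIES %in% r$category]
  rows <- lapply(c(cats, "average"), function(cc) {
    sub <- if (cc == "average") r else r[r$category == cc, ]
    n <- nrow(sub)
    cnt <- vapply(DIAG_CLASSES, function(k) sum(sub$classification == k),
                  integer(1))
    data.frame(category = cc, n = n,
               accurate_n = cnt[["accurate"]], lsen_n = cnt[["lsen"]],
               lspe_n = cnt[["lspe"]],
               accurate = round_half_up(cnt[["accurate"]] / n),
               lsen = round_half_up(cnt[["lsen"]] / n),
               lspe = round_half_up(cnt[["lspe"]] / n))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- out$category
  class(out) <- c("agreement_table", class(out))
  attr(out, "rater") <- rater
  attr(out, "modality") <- modality
  out
}

#' Average one rate across two raters
#'
#' Averages the two displayed (2-decimal-rounded) ratios and rounds the
#' result half-up to 2 decimals. This round-then-average-then-round
#' convention is the one consistent with the published averaged rates;
#' averaging exact fractions is not (e.g. lung accuracy 13/31 and 17/31
#' averages to 0.48 exactly but 0.50 under this convention).
#'
#' @param table_a,table_b `agreement_table`s for the two raters.
#' @param category category row name (or `"average"`).
#' @param metric `"accurate"`, `"lsen"` or `"lspe"`.
#' @return the averaged displayed rate.
#' @export
cross_rater_average <- function(table_a, table_b, category, metric) {
  metric <- match.arg(metric, DIAG_CLASSES)
  for (tb in list(table_a, table_b))
    if (!category %in% tb$category)
      stopf("category '%s' missing from a table", category)
  round_half_up((table_a[category, metric] + table_b[category, metric]) / 2)
}

#' Normalize a scan time to the reference sample area
#'
#' Scan effort is compared across slides of different sizes by scaling the
#' measured time to the reference 15 x 15 mm (= 225 mm^2) sample area.
#'
#' @param minutes measured scan time.
#' @param area_mm2 scanned area in mm^2 (> 0).
#' @return minutes per 15 x 15 mm.
#' @export
normalize_scan_time <- function(minutes, area_mm2) {
  if (any(area_mm2 <= 0)) stopf("area must be positive")
  minutes * 225 / area_mm2
}

#' Expand per-category classification counts into per-sample records
#'
#' Utility for building record fixtures from published count tables: for
#' each category the first `accurate_n` samples are labelled accurate, the
#' next `lsen_n` low-sensitivity, the rest low-specificity. Sample ids are
#' `<category>_<nn>` so the same ids recur across raters.
#'
#' @param counts data.frame with columns `category, accurate_n, lsen_n,
#'   lspe_n`.
#' @param rater,modality values for all generated rows.
#' @return data.frame in the [load_diagnosis_records()] layout.
#' @export
expand_counts_to_records <- function(counts, rater, modality) {
  do.call(rbind, lapply(seq_len(nrow(counts)), function(i) {
    cl <- rep(DIAG_CLASSES,
              c(counts$accurate_n[i], counts$lsen_n[i], counts$lspe_n[i]))
    data.frame(sample_id = sprintf("%s_%02d", counts$category[i],
                                   seq_along(cl)),
               category = counts$category[i], modality = modality,
               rater_id = rater, classification = cl)
  }))
}
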