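#' False-detection artefact taxonomy
#'
#' Closed vocabularies for categorizing detector events that coincide with no
#' annotated seizure. Every false detection is assigned one artefact
#' category; events with no identifiable artefact additionally carry a
#' description of the EEG background at the time of the false detection.
#'
#' @return Character vector of allowed labels.
#' @examples
#' fd_categories()
#' fd_background_subcategories()
#' @export
fd_categories <- function() {
  c("respiration", "ecg_pulse", "chewing_sucking", "bad_electrode",
    "movement_handling", "electronic_equipment", "sweat",
    "unclassified_artefact", "no_artefact")
}

#' @rdname fd_categories
#' @export
fd_background_subcategories <- function() {
  c("normal_background", "highly_rhythmic", "sharp_waves", "low_amplitude")
}

#' Labelled false-detection records
#'
#' Builds a validated table of categorized false detections. The background
#' subcategory must be present exactly when the category is `no_artefact`;
#' unknown labels are rejected rather than coerced.
#'
#' @param events data.frame of the false-detection events (needs at least
#'   `record_id` and `threshold`; typically the `false_detections` component
#'   of [match_events()] plus a `patient_id` column).
#' @param category character vector of artefact categories, one per event;
#'   see [fd_categories()].
#' @param subcategory character vector of background subcategories; must be
#'   `NA` except where `category == "no_artefact"`.
#' @param patient_id optional character vector of patient identifiers; if
#'   absent, `events$patient_id` or `events$record_id` is used.
#' @return The events table with `category`, `subcategory` and `patient_id`
#'   columns appended.
#' @export
fd_records <- function(events, category, subcategory = NA_character_,
                       patient_id = NULL) {
  stopifnot(is.data.frame(events))
  n <- nrow(events)
  category <- as.character(category)
  if (length(category) != n) stop("one category per event required")
  bad <- setdiff(unique(category), fd_categories())
  if (length(bad))
    stop("unknown false-detection category: ", paste(bad, collapse = ", "))
  subcategory <- rep_len(as.character(subcategory), max(n, 1L))[seq_len(n)]
  bad <- setdiff(stats::na.omit(unique(subcategory)),
                 fd_background_subcategories())
  if (length(bad))
    stop("unknown background subcategory: ", paste(bad, collapse = ", "))
  noart <- category == "no_artefact"
  if (any(noart & is.na(subcategory)))
    stop("no_artefact events require a background subcategory")
  if (any(!noart & !is.na(subcategory)))
    stop("background subcategory only allowed for no_artefact events")
  out <- events
  out$category <- category
  out$subcategory <- subcategory
  if (!is.null(patient_id)) out$patient_id <- as.character(patient_id)
  else if (!"patient_id" %in% names(out)) out$patient_id <- out$record_id
  out
}

#' Aggregate false detections into a category table
#'
#' Tabulates categorized false detections at one sensitivity threshold:
#' count and percentage of all false detections per artefact category, plus
#' the breakdown of the `no_artefact` events by EEG background, expressed as
#' percentages of the `no_artefact` count (not of the total).
#'
#' @param records labelled false detections from [fd_records()], all at one
#'   threshold (a `threshold` column, if present, must be constant).
#' @param threshold optional threshold to stamp on the output (taken from
#'   the records if absent).
#' @return An object of class `"sda_fd_table"`: list with `categories`
#'   (data.frame `threshold`, `category`, `n`, `pct` over all categories in
#'   taxonomy order), `no_artefact` (data.frame `subcategory`, `n`, `pct`
#'   of the no-artefact total), `n_total`, and `threshold`.
#' @examples
#' ev <- data.frame(record_id = "r", threshold = 0.6)[rep(1, 3), ]
#' fd <- fd_records(ev, c("respiration", "sweat", "no_artefact"),
#'                  c(NA, NA, "highly_rhythmic"))
#' aggregate_fd(fd)$categories
#' @export
aggregate_fd <- function(records, threshold = NULL) {
  stopifnot(is.data.frame(records), "category" %in% names(records))
  bad <- setdiff(unique(records$category), fd_categories())
  if (length(bad))
    stop("unknown false-detection category: ", paste(bad, collapse = ", "))
  if ("threshold" %in% names(records) && nrow(records)) {
    thr <- unique(records$threshold)
    if (length(thr) > 1)
      stop("records mix thresholds: ", paste(thr, collapse = ", "))
    if (is.null(threshold)) threshold <- thr
  }
  if (is.null(threshold)) threshold <- NA_real_
  n_total <- nrow(records)
  counts <- table(factor(records$category, levels = fd_categories()))
  cat_tab <- data.frame(threshold = threshold,
                        category = fd_categories(),
                        n = as.integer(counts),
                        pct = if (n_total > 0) 100 * as.integer(counts) / n_total
                              else NA_real_,
                        stringsAsFactors = FALSE)
  na_rec <- records[records$category == "no_artefact", , drop = FALSE]
  n_na <- nrow(na_rec)
  sub_counts <- table(factor(na_rec$subcategory,
                             levels = fd_background_subcategories()))
  sub_tab <- data.frame(subcategory = fd_background_subcategories(),
                        n = as.integer(sub_counts),
                        pct = if (n_na > 0) 100 * as.integer(sub_counts) / n_na
                              else NA_real_,
                        stringsAsFactors = FALSE)
  structure(list(categories = cat_tab, no_artefact = sub_tab,
                 n_total = n_total, threshold = threshold),
            class = "sda_fd_table")
}

#' @export
print.sda_fd_table <- function(x, ...) {
  cat(sprintf("<sda_fd_table> threshold %s: %d false detections\n",
              format(x$threshold), x$n_total))
  tab <- x$categories
  tab$pct <- round(tab$pct, 1)
  print(tab, row.names = FALSE)
  if (any(x$no_artefact$n > 0)) {
    cat("no-artefact background breakdown:\n")
    tab <- x$no_artefact
    tab$pct <- round(tab$pct, 1)
    print(tab, row.names = FALSE)
  }
  invisible(x)
}

#' Per-patient concentration of a false-detection category
#'
#' False detections of a given artefact type are often dominated by a single
#' patient recording. This reports the patient contributing the most events
#' in the category and that patient's share of the category total.
#'
#' @param records labelled false detections from [fd_records()].
#' @param category one category from [fd_categories()].
#' @return List with `patient_id`, `n_patient`, `n_category`, and
#'   `share_pct` (in `(0, 100]`). Errors if the category is unrepresented.
#' @export
patient_concentration <- function(records, category) {
  stopifnot(is.data.frame(records))
  if (!category %in% fd_categories())
    stop("unknown false-detection category: ", category)
  sub <- records[records$category == category, , drop = FALSE]
  if (!nrow(sub))
    stop("no false detections in category '", category,
         "': concentration undefined")
  counts <- sort(table(sub$patient_id), decreasing = TRUE)
  list(patient_id = names(counts)[1],
       n_patient = as.integer(counts[1]),
       n_category = nrow(sub),
       share_pct = 100 * as.integer(counts[1]) / nrow(sub))
}

#' Threshold drop-off of false-detection categories
#'
#' How quickly each artefact category's false detections disappear as the
#' sensitivity threshold is raised: for each category, the count at every
#' threshold as a fraction of the count at the most sensitive (lowest)
#' threshold. Artefacts that closely mimic seizure morphology (e.g.
#' sustained rhythmic respiration artefact) produce high detector
#' probabilities and retain false detections at high thresholds, while
#' semi-rhythmic intermittent artefacts (e.g. sweat) drop off sharply.
#'
#' @param counts_by_threshold numeric matrix or data.frame of per-category
#'   counts, rows named by category, columns ordered by increasing
#'   threshold (most sensitive first).
#' @return Matrix of retention ratios (same shape); rows with a zero
#'   baseline count are `NA` with a warning.
#' @examples
#' m <- rbind(respiration = c(278, 249, 221), sweat = c(160, 97, 14))
#' threshold_dropoff(m)
#' @export
threshold_dropoff <- function(counts_by_threshold) {
  m <- as.matrix(counts_by_threshold)
  if (ncol(m) < 2) stop("need counts at >= 2 thresholds")
  if (any(m < 0)) stop("counts must be non-negative")
  base <- m[, 1]
  zero <- base == 0
  if (any(zero))
    warning("zero count at most sensitive threshold for: ",
            paste(rownames(m)[zero], collapse = ", "),
            "; retention undefined")
  out <- sweep(m, 1, base, "/")
  out[zero, ] <- NA_real_
  out
}

#' Compare false-detection rates between patient groups
#'
#' Mann--Whitney comparison of per-patient false-detection rates (FD/hr)
#' between the seizure and the non-seizure group, as done per threshold when
#' auditing whether seizure EEG attracts more false alarms than seizure-free
#' EEG.
#'
#' @param rates_seizure_group,rates_nonseizure_group numeric vectors of
#'   per-patient FD/hr.
#' @return See [mann_whitney()].
#' @export
compare_groups_fd <- function(rates_seizure_group, rates_nonseizure_group) {
  mann_whitney(rates_seizure_group, rates_nonseizure_group)
}
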