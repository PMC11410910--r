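#' Read or construct a phecode map
#'
#' The map links raw diagnosis codes (ICD-9/ICD-10 or synthetic) to phecodes,
#' carries a phenotype label, and an exclusion range: the interval of
#' phecodes whose carriers may not serve as controls for that phenotype
#' (written `"min-max"`, e.g. `"250-250.99"`, following the PheCODE
#' convention; the range always covers the phecode itself).
#'
#' @param path CSV file with columns `raw_code, phecode, label,
#'   exclusion_range`.
#' @return data.frame of class `ua_phecode_map`.
#' @export
read_phecode_map <- function(path) {
  map <- utils::read.csv(path, colClasses = "character")
  need <- c("raw_code", "phecode", "label", "exclusion_range")
  miss <- setdiff(need, names(map))
  if (length(miss)) stop("phecode map lacks columns: ", paste(miss, collapse = ", "))
  validate_phecode_map(map)
}

#' @rdname read_phecode_map
#' @param phecodes character vector of codes that are already phecodes; the
#'   identity map (each code maps to itself, exclusion range = itself) lets
#'   the synthetic generator's direct-phecode events flow through the same
#'   machinery as ICD-coded events.
#' @param labels optional labels, recycled against `phecodes`.
#' @export
phecode_identity_map <- function(phecodes, labels = phecodes) {
  validate_phecode_map(data.frame(
    raw_code = phecodes, phecode = phecodes, label = labels,
    exclusion_range = "", stringsAsFactors = FALSE))
}

validate_phecode_map <- function(map) {
  if (nrow(map) == 0L) stop("empty phecode map")
  if (anyDuplicated(map$raw_code)) {
    stop("raw codes mapping to more than one phecode: ",
         paste(unique(map$raw_code[duplicated(map$raw_code)]), collapse = ", "))
  }
  class(map) <- c("ua_phecode_map", "data.frame")
  map
}

# Phecodes are numeric-dotted strings; "death" sorts as non-numeric and only
# ever matches itself.
phecode_in_range <- function(phecode, range_str, self) {
  if (phecode == self) return(TRUE)
  if (is.na(range_str) || range_str == "") return(FALSE)
  lohi <- strsplit(range_str, "-", fixed = TRUE)[[1]]
  v <- suppressWarnings(as.numeric(phecode))
  lo <- suppressWarnings(as.numeric(lohi[1]))
  hi <- suppressWarnings(as.numeric(lohi[length(lohi)]))
  if (is.na(v) || is.na(lo) || is.na(hi)) return(FALSE)
  v >= lo & v <= hi
}

#' Map raw diagnosis events to per-person first phecode onsets
#'
#' Collapses a dated event table (possibly multiple sources and multiple raw
#' codes per phecode) to one record per (person, phecode) carrying the
#' earliest date seen anywhere. Codes absent from the map are dropped and
#' counted in the `n_unmapped` attribute.
#'
#' @param events data.frame with `person_id`, a code column (`phecode` or
#'   `code`), `date`.
#' @param map a `ua_phecode_map`.
#' @return data.frame `person_id`, `phecode`, `first_date`, one row per
#'   (person, phecode); attribute `n_unmapped`.
#' @export
map_events <- function(events, map) {
  if (!inherits(map, "ua_phecode_map")) map <- validate_phecode_map(map)
  code_col <- if ("code" %in% names(events)) "code" else "phecode"
  idx <- match(events[[code_col]], map$raw_code)
  n_unmapped <- sum(is.na(idx))
  ev <- events[!is.na(idx), , drop = FALSE]
  ev$phecode <- map$phecode[idx[!is.na(idx)]]
  dates <- as.Date(ev$date)
  key <- paste(ev$person_id, ev$phecode, sep = "\r")
  first <- tapply(as.integer(dates), key, min)
  parts <- strsplit(names(first), "\r", fixed = TRUE)
  out <- data.frame(
    person_id = vapply(parts, `[[`, character(1), 1L),
    phecode = vapply(parts, `[[`, character(1), 2L),
    first_date = as.Date(as.integer(first), origin = "1970-01-01"),
    stringsAsFactors = FALSE)
  out <- out[order(out$person_id, out$phecode), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_unmapped") <- n_unmapped
  out
}

#' Incident-case washout filter
#'
#' Restricts a mapped event table to incident disease relative to the
#' exposure measurement: first onsets dated on or before
#' `assessment_date + washout_days` are removed. Persons with a
#' pre-assessment record of a phecode (prevalent disease) are flagged for
#' removal from that phenotype's cases and controls alike; persons whose
#' first onset falls inside the post-assessment washout window are likewise
#' flagged (they have the disease, so they cannot be controls, but they are
#' not incident cases either). Persons lacking an assessment date are
#' excluded entirely, with a warning.
#'
#' The default of 183 days fixes "six months"; the boundary day itself is
#' excluded (an onset exactly 183 days after assessment is removed; 184 is
#' retained).
#'
#' @param phecode_events output of [map_events()].
#' @param cohort data.frame with `person_id`, `assessment_date`.
#' @param washout_days length of the washout window.
#' @return filtered events; attribute `removed` is a data.frame
#'   (`person_id`, `phecode`, `reason` in prevalent/washout) for
#'   [define_case_control()] to honour.
#' @export
incident_filter <- function(phecode_events, cohort, washout_days = 183) {
  idx <- match(phecode_events$person_id, cohort$person_id)
  ad <- cohort$assessment_date[idx]
  if (anyNA(ad)) {
    warning(sum(is.na(ad)), " events from persons without assessment date excluded")
  }
  delta <- as.integer(phecode_events$first_date) - as.integer(ad)
  prevalent <- !is.na(delta) & delta <= 0
  washed <- !is.na(delta) & delta > 0 & delta <= washout_days
  keep <- !is.na(delta) & delta > washout_days
  removed <- data.frame(
    person_id = phecode_events$person_id[prevalent | washed],
    phecode = phecode_events$phecode[prevalent | washed],
    reason = ifelse(prevalent[prevalent | washed], "prevalent", "washout"),
    stringsAsFactors = FALSE)
  out <- phecode_events[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- removed
  attr(out, "washout_days") <- washout_days
  out
}

#' Define case/control/excluded groups per phenotype
#'
#' For each phecode present in the events: cases are its carriers; excluded
#' persons are non-carriers who carry any phecode inside its exclusion range
#' (clinically neighbouring disease, e.g. type 1 diabetes when the phenotype
#' is type 2 diabetes); controls are everyone else in the cohort. Persons
#' listed in `removed` (washout/prevalent, from [incident_filter()]) are
#' barred from both cases and controls of that phenotype. Phenotypes with
#' fewer than `min_cases` cases are dropped to protect power.
#'
#' @param phecode_events mapped (and usually washout-filtered) events.
#' @param map a `ua_phecode_map` supplying labels and exclusion ranges.
#' @param cohort cohort table (`person_id` defines the analysis universe).
#' @param min_cases minimum case count for a phenotype to be retained.
#' @param removed optional removal data.frame from [incident_filter()].
#' @return object of class `ua_phenome`: named list of phenotype
#'   definitions, each a list with `phecode`, `label`, `case_ids`,
#'   `control_ids`, `excluded_ids`, `removed_ids`, `n_cases`; attribute
#'   `n_dropped` counts phenotypes under the case floor.
#' @export
define_case_control <- function(phecode_events, map, cohort,
                                min_cases = 200, removed = NULL) {
  if (!inherits(map, "ua_phecode_map")) map <- validate_phecode_map(map)
  if (is.null(removed)) removed <- attr(phecode_events, "removed")
  all_ids <- cohort$person_id
  carriers <- split(phecode_events$person_id, phecode_events$phecode)
  phecodes <- names(carriers)
  map_row <- match(phecodes, map$phecode)

  out <- list()
  n_dropped <- 0L
  for (i in seq_along(phecodes)) {
    pc <- phecodes[i]
    cases <- unique(carriers[[pc]])
    rng <- if (!is.na(map_row[i])) map$exclusion_range[map_row[i]] else ""
    in_range <- vapply(phecodes, phecode_in_range, logical(1),
                       range_str = rng, self = pc)
    range_carriers <- unique(unlist(carriers[in_range], use.names = FALSE))
    rem <- if (!is.null(removed)) {
      unique(removed$person_id[removed$phecode == pc])
    } else character(0)
    cases <- setdiff(cases, rem)  # safety; the filter already removed them
    excl <- setdiff(range_carriers, c(cases, rem))
    controls <- setdiff(all_ids, c(cases, excl, rem))
    if (length(cases) < min_cases) {
      n_dropped <- n_dropped + 1L
      next
    }
    out[[pc]] <- list(
      phecode = pc,
      label = if (!is.na(map_row[i])) map$label[map_row[i]] else pc,
      case_ids = cases,
      control_ids = controls,
      excluded_ids = excl,
      removed_ids = rem,
      n_cases = length(cases))
  }
  structure(out, class = "ua_phenome", n_dropped = n_dropped)
}

#' @export
print.ua_phenome <- function(x, ...) {
  cat(sprintf("phenome: %d phenotypes retained (%d below the case floor)\n",
              length(x), attr(x, "n_dropped")))
  if (length(x)) {
    tab <- data.frame(phecode = names(x),
                      n_cases = vapply(x, `[[`, integer(1), "n_cases"),
                      n_controls = vapply(x, function(d) length(d$control_ids),
                                          integer(1)),
                      row.names = NULL)
    print(utils::head(tab, 20))
  }
  invisible(x)
}
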