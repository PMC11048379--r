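# Per-voltage peak tables -> normalized dissociation courses.
#
# A "scan" is the combined centroided spectrum recorded at one collision cell
# voltage difference (dcv). Intensities are peak heights (not areas).

#' Scan peak table
#'
#' The centroided peak list recorded at one collision cell voltage difference.
#'
#' @param series_id Replicate series label.
#' @param dcv Collision cell voltage difference in V (>= 0).
#' @param mz,intensity Numeric vectors of equal length; intensities are peak
#'   heights in arbitrary units (>= 0). Peaks are stored sorted by m/z.
#' @return An object of class `scan_peak_table`.
#' @export
scan_peak_table <- function(series_id, dcv, mz, intensity) {
  stopifnot(length(dcv) == 1L, dcv >= 0, length(mz) == length(intensity))
  if (any(intensity < 0)) stop("peak intensities must be >= 0")
  o <- order(mz)
  structure(list(series_id = as.character(series_id), dcv = as.numeric(dcv),
                 peaks = data.frame(mz = as.numeric(mz)[o],
                                    intensity = as.numeric(intensity)[o])),
            class = "scan_peak_table")
}

#' Read peak tables from a long-format table
#'
#' Expects columns `series_id`, `dcv`, `mz`, `intensity` (CSV/TSV path or a
#' data frame) and returns one [scan_peak_table()] per (series_id, dcv).
#'
#' @param x Path to a CSV/TSV file, or a data frame.
#' @return List of [scan_peak_table()] objects.
#' @export
read_peak_tables <- function(x) {
  if (is.character(x)) {
    sep <- if (grepl("\\.tsv$", x, ignore.case = TRUE)) "\t" else ","
    x <- utils::read.table(x, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  }
  need <- c("series_id", "dcv", "mz", "intensity")
  if (!all(need %in% names(x))) {
    stop("peak table needs columns: ", paste(need, collapse = ", "))
  }
  key <- interaction(x$series_id, x$dcv, drop = TRUE)
  lapply(split(x, key), function(d) {
    scan_peak_table(d$series_id[1], d$dcv[1], d$mz, d$intensity)
  })
}

#' Species assignment
#'
#' Maps an expected ion to an m/z matching window. Either a fixed half-width
#' in m/z units or a ppm half-width may be given; the window centre defaults
#' to the calculated m/z and can be overridden with a measured value.
#'
#' @param ion An [oligomer_ion()].
#' @param window_mz Half-width of the matching window in m/z units.
#' @param window_ppm Optional half-width in ppm (overrides `window_mz`).
#' @param mz_measured Optional measured m/z used as the window centre.
#' @param satellite_of Optional symbol of a parent species; intensities of a
#'   satellite assignment (oxidation, sodiation) are summed into the parent.
#' @return An object of class `species_assignment`.
#' @export
species_assignment <- function(ion, window_mz = 0.5, window_ppm = NULL,
                               mz_measured = NULL, satellite_of = NULL) {
  stopifnot(inherits(ion, "oligomer_ion"))
  centre <- if (is.null(mz_measured)) ion$mz_calc else mz_measured
  half <- if (!is.null(window_ppm)) centre * window_ppm * 1e-6 else window_mz
  if (half <= 0) stop("matching window must be > 0")
  structure(list(ion = ion, symbol = ion$species$symbol, centre = centre,
                 half_width = half, satellite_of = satellite_of),
            class = "species_assignment")
}

#' Extract the intensity of one assignment from a scan
#'
#' Returns the maximum peak height within the assignment's m/z window (peak
#' height, not area), or 0 when no peak falls in the window.
#'
#' @param scan A [scan_peak_table()].
#' @param assignment A [species_assignment()].
#' @return Intensity (arbitrary units).
#' @export
extract_intensity <- function(scan, assignment) {
  stopifnot(inherits(scan, "scan_peak_table"),
            inherits(assignment, "species_assignment"))
  p <- scan$peaks
  sel <- abs(p$mz - assignment$centre) <= assignment$half_width
  if (!any(sel)) return(0)
  max(p$intensity[sel])
}

# Extract all assignments from one scan, resolving window overlaps: a peak
# claimed by several windows is counted only for the nearest window centre.
.extract_scan <- function(scan, assignments) {
  centres <- vapply(assignments, `[[`, numeric(1), "centre")
  halves <- vapply(assignments, `[[`, numeric(1), "half_width")
  p <- scan$peaks
  out <- stats::setNames(numeric(length(assignments)),
                         vapply(assignments, `[[`, character(1), "symbol"))
  if (nrow(p) == 0L) return(out)
  dist <- abs(outer(p$mz, centres, "-"))
  inwin <- sweep(dist, 2, halves, "<=")
  multi <- rowSums(inwin) > 1L
  if (any(multi)) {
    warning(sprintf(
      "scan (series %s, dcv %g): %d peak(s) fall in overlapping m/z windows; assigned to nearest centre",
      scan$series_id, scan$dcv, sum(multi)))
    for (i in which(multi)) {
      keep <- which.min(ifelse(inwin[i, ], dist[i, ], Inf))
      inwin[i, ] <- FALSE
      inwin[i, keep] <- TRUE
    }
  }
  for (j in seq_along(assignments)) {
    if (any(inwin[, j])) out[j] <- max(p$intensity[inwin[, j]])
  }
  out
}

#' Normalize a scan's intensities to percent of total
#'
#' The intensities assigned at one voltage setting are summed and the sum set
#' to 100 percent.
#'
#' @param intensities Named numeric vector (species -> intensity), at least
#'   one value > 0.
#' @param dcv Optional voltage, used only in the error message.
#' @return Named numeric vector summing to 100.
#' @export
normalize_scan <- function(intensities, dcv = NULL) {
  tot <- sum(intensities)
  if (tot <= 0) {
    stop("all-zero scan",
         if (!is.null(dcv)) sprintf(" at dcv = %g V", dcv) else "")
  }
  intensities * 100 / tot
}

#' Build a dissociation course from scans
#'
#' Extracts every assignment from every scan, normalizes per scan (within a
#' replicate series), then averages across series per voltage. Voltages
#' present in only one series are kept with `sd = NA`.
#'
#' @param scans List of [scan_peak_table()]s.
#' @param assignments List of [species_assignment()]s; satellites are summed
#'   into their parent species before normalization.
#' @param educt Symbol of the educt species (must be among the assignments).
#' @return A `dissociation_course` object: list with
#'   \describe{
#'     \item{data}{long data frame `species, dcv, series_id, normalized`}
#'     \item{summary}{data frame `species, dcv, mean, sd, n`}
#'     \item{educt, products}{species symbols}
#'     \item{dcv_grid}{sorted unique voltages}
#'   }
#' @export
build_course <- function(scans, assignments, educt) {
  stopifnot(length(scans) >= 1L, length(assignments) >= 1L)
  symbols <- vapply(assignments, `[[`, character(1), "symbol")
  parents <- vapply(assignments, function(a)
    if (is.null(a$satellite_of)) a$symbol else a$satellite_of, character(1))
  if (!educt %in% parents) stop("educt '", educt, "' is not among the assignments")
  key <- vapply(scans, function(s) paste(s$series_id, s$dcv, sep = "\r"),
                character(1))
  if (anyDuplicated(key)) {
    stop("duplicate (series, dcv) scans: ",
         paste(unique(sub("\r", " @ ", key[duplicated(key)])), collapse = ", "))
  }
  ndcv <- length(unique(vapply(scans, `[[`, numeric(1), "dcv")))
  if (ndcv < 4L) stop("need scans at >= 4 distinct dcv settings, got ", ndcv)

  rows <- lapply(scans, function(s) {
    raw <- .extract_scan(s, assignments)
    agg <- tapply(raw, parents, sum)           # fold satellites into parents
    pct <- normalize_scan(agg, dcv = s$dcv)
    data.frame(species = names(pct), dcv = s$dcv, series_id = s$series_id,
               normalized = as.numeric(pct), row.names = NULL)
  })
  data <- do.call(rbind, rows)
  data <- data[order(data$species, data$dcv, data$series_id), , drop = FALSE]
  rownames(data) <- NULL
  new_dissociation_course(data, educt = educt,
                          products = setdiff(unique(parents), educt))
}

# Construct the course container from long per-replicate normalized data.
new_dissociation_course <- function(data, educt, products) {
  agg <- stats::aggregate(normalized ~ species + dcv, data = data,
                          FUN = function(v) c(mean = mean(v),
                                              sd = if (length(v) >= 2) stats::sd(v) else NA_real_,
                                              n = length(v)))
  summary <- data.frame(species = agg$species, dcv = agg$dcv,
                        mean = agg$normalized[, "mean"],
                        sd = agg$normalized[, "sd"],
                        n = as.integer(agg$normalized[, "n"]))
  summary <- summary[order(summary$species, summary$dcv), , drop = FALSE]
  rownames(summary) <- NULL
  structure(list(data = data, summary = summary, educt = educt,
                 products = products,
                 dcv_grid = sort(unique(data$dcv))),
            class = "dissociation_course")
}

#' @export
print.dissociation_course <- function(x, ...) {
  cat("<dissociation_course>\n")
  cat("  educt:   ", x$educt, "\n")
  cat("  products:", paste(x$products, collapse = ", "), "\n")
  cat(sprintf("  %d dcv settings (%g-%g V), %d series\n",
              length(x$dcv_grid), min(x$dcv_grid), max(x$dcv_grid),
              length(unique(x$data$series_id))))
  invisible(x)
}

#' Mean normalized course of one species
#'
#' @param course A `dissociation_course`.
#' @param species Species symbol (defaults to the educt).
#' @return Data frame `dcv, mean, sd, n`.
#' @export
course_means <- function(course, species = course$educt) {
  stopifnot(inherits(course, "dissociation_course"))
  s <- course$summary[course$summary$species == species, , drop = FALSE]
  if (nrow(s) == 0L) stop("species '", species, "' not in course")
  s[order(s$dcv), c("dcv", "mean", "sd", "n")]
}

#' Write a tidy course table
#'
#' @param course A `dissociation_course`.
#' @param path Output CSV path.
#' @return The written data frame, invisibly.
#' @export
write_course <- function(course, path) {
  m <- merge(course$data, course$summary, by = c("species", "dcv"))
  m <- m[order(m$species, m$dcv, m$series_id),
         c("species", "dcv", "series_id", "normalized", "mean", "sd")]
  utils::write.csv(m, path, row.names = FALSE)
  invisible(m)
}
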