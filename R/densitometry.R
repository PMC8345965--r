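## Gel densitometry: detached-protein quantification.
##
## During urea incubation a fraction of the apolipoproteins detaches from the
## HDL particle and migrates as a free-protein band on native PAGE. The total
## area under all protein-stained peaks of a lane's densitogram is taken as
## 100% of HDL protein; the detached fraction is the area share of the peaks
## not associated with lipoprotein cholesterol.

#' Construct a densitogram
#'
#' Absorbance-vs-migration trace extracted from one stained gel lane.
#'
#' @param sample_id Sample label.
#' @param time_h Incubation time in hours.
#' @param positions Strictly increasing migration coordinate (arbitrary units).
#' @param absorbance Finite absorbance values >= 0, one per position.
#' @param stain `"protein"` (Coomassie) or `"cholesterol"` (enzymatic).
#' @return An object of class `densitogram`.
#' @export
densitogram <- function(sample_id, time_h, positions, absorbance,
                        stain = c("protein", "cholesterol")) {
  stain <- match.arg(stain)
  positions <- as.numeric(positions)
  absorbance <- as.numeric(absorbance)
  if (length(positions) != length(absorbance))
    stop_format("positions and absorbance differ in length")
  if (!is_strictly_increasing(positions))
    stop_format("positions must be strictly increasing")
  if (any(!is.finite(absorbance)) || any(absorbance < 0))
    stop_format("absorbance must be finite and >= 0")
  structure(
    list(sample_id = as.character(sample_id), time_h = as.numeric(time_h),
         positions = positions, absorbance = absorbance, stain = stain),
    class = "densitogram")
}

#' @export
print.densitogram <- function(x, ...) {
  cat(sprintf("<densitogram> %s  t = %g h  %s stain  %d points (%g-%g)\n",
              x$sample_id, x$time_h, x$stain, length(x$positions),
              min(x$positions), max(x$positions)))
  invisible(x)
}

#' Define a labeled peak region
#'
#' @param label `"hdl_associated"` or `"free_protein"`.
#' @param start,end Region bounds on the migration coordinate, `start < end`.
#' @return An object of class `peak_region`.
#' @export
peak_region <- function(label = c("hdl_associated", "free_protein"),
                        start, end) {
  label <- match.arg(label)
  if (!is.finite(start) || !is.finite(end) || start >= end)
    stop_format("peak region needs finite start < end (got [%g, %g])", start, end)
  structure(list(label = label, start = start, end = end),
            class = "peak_region")
}

check_regions <- function(regions) {
  if (!length(regions)) stop_format("no peak regions supplied")
  ok <- vapply(regions, inherits, logical(1), "peak_region")
  if (!all(ok)) stop_format("all regions must be peak_region objects")
  b <- t(vapply(regions, function(r) c(r$start, r$end), numeric(2)))
  o <- order(b[, 1])
  b <- b[o, , drop = FALSE]
  if (nrow(b) > 1L && any(b[-1, 1] < b[-nrow(b), 2] - 1e-9))
    stop_format("peak regions overlap")
  invisible(regions)
}

#' Integrate absorbance over a peak region
#'
#' Trapezoidal integration of the raw trace over `[start, end]`, with the
#' boundary values obtained by linear interpolation when they fall between
#' grid points. No baseline is subtracted.
#'
#' @param d A [densitogram()].
#' @param region A [peak_region()] inside the position span.
#' @return Area in absorbance x position units.
#' @export
integrate_region <- function(d, region) {
  stopifnot(inherits(d, "densitogram"), inherits(region, "peak_region"))
  p <- d$positions; a <- d$absorbance
  if (region$start < min(p) - 1e-9 || region$end > max(p) + 1e-9)
    stop_format("region [%g, %g] outside the trace span [%g, %g]",
                region$start, region$end, min(p), max(p))
  inside <- p > region$start & p < region$end
  xs <- c(region$start, p[inside], region$end)
  ys <- c(stats::approx(p, a, xout = region$start, ties = "ordered")$y,
          a[inside],
          stats::approx(p, a, xout = region$end, ties = "ordered")$y)
  sum(diff(xs) * (ys[-length(ys)] + ys[-1]) / 2)
}

#' Fraction of protein detached from HDL
#'
#' `100 * area(free_protein regions) / area(all regions)`. The regions must
#' cover the lane's peaks without overlapping; the densitogram must be the
#' protein stain (the cholesterol stain identifies which peaks are
#' lipoprotein-associated, but the fraction is computed on protein).
#'
#' @param d A protein-stain [densitogram()].
#' @param regions List of labeled [peak_region()]s.
#' @return Percent of total protein area in free-protein regions.
#' @export
free_protein_fraction <- function(d, regions) {
  stopifnot(inherits(d, "densitogram"))
  if (d$stain != "protein")
    stop_format("free-protein fraction is defined on the protein stain, got '%s'",
                d$stain)
  check_regions(regions)
  areas <- vapply(regions, function(r) integrate_region(d, r), numeric(1))
  total <- sum(areas)
  if (total <= 0) stop_format("total peak area is zero")
  labels <- vapply(regions, `[[`, character(1), "label")
  100 * sum(areas[labels == "free_protein"]) / total
}

#' Suggest peak regions from local extrema
#'
#' Scans the trace for local maxima whose prominence (height above the higher
#' of the two flanking valleys) exceeds `min_prominence`, and returns
#' valley-to-valley regions around each. Labels are left for the user to
#' assign: peak identity (HDL-associated vs free protein) is a judgement tied
#' to migration position and the cholesterol stain, not to shape.
#'
#' @param d A [densitogram()].
#' @param min_prominence Minimum peak prominence in absorbance units.
#' @return List of unlabeled region descriptors (`start`, `end`, `peak_position`,
#'   `prominence`); empty if no peak qualifies.
#' @export
suggest_regions <- function(d, min_prominence) {
  stopifnot(inherits(d, "densitogram"))
  a <- d$absorbance; p <- d$positions
  if (diff(range(a)) == 0)
    return(list())
  n <- length(a)
  # interior local maxima (plateau-tolerant: first point of a plateau)
  is_max <- which(vapply(2:(n - 1), function(i) {
    a[i] > a[i - 1] && a[i] >= a[i + 1]
  }, logical(1))) + 1L
  out <- list()
  for (i in is_max) {
    # walk to flanking valleys
    l <- i; while (l > 1L && a[l - 1L] <= a[l]) l <- l - 1L
    r <- i; while (r < n && a[r + 1L] <= a[r]) r <- r + 1L
    prom <- a[i] - max(a[l], a[r])
    if (prom >= min_prominence) {
      out[[length(out) + 1L]] <- list(start = p[l], end = p[r],
                                      peak_position = p[i], prominence = prom)
    }
  }
  out
}

#' Read densitograms from long CSV
#'
#' Columns: `sample_id`, `time_h`, `stain`, `position`, `absorbance`.
#'
#' @param path CSV path.
#' @return List of [densitogram()]s, one per (sample_id, time_h, stain).
#' @export
read_densitogram_table <- function(path) {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("sample_id", "time_h", "stain", "position", "absorbance")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop_format("missing required column(s): %s", paste(missing, collapse = ", "))
  key <- interaction(df$sample_id, df$time_h, df$stain, drop = TRUE)
  lapply(split(df, key), function(g) {
    o <- order(g$position)
    densitogram(g$sample_id[1], g$time_h[1], g$position[o], g$absorbance[o],
                stain = g$stain[1])
  })
}

#' Read labeled peak regions from CSV
#'
#' Columns: `label` (`hdl_associated`/`free_protein`), `start`, `end`.
#'
#' @param path CSV path.
#' @return List of [peak_region()]s.
#' @export
read_region_table <- function(path) {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("label", "start", "end"), names(df))
  if (length(missing))
    stop_format("missing required column(s): %s", paste(missing, collapse = ", "))
  lapply(seq_len(nrow(df)), function(i)
    peak_region(df$label[i], df$start[i], df$end[i]))
}
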