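#' Detect peaks in a spectrum
#'
#' Local maxima whose topographic prominence exceeds `min_prominence` times
#' the spectrum maximum, thinned so surviving peaks are separated by at least
#' `min_separation` (keeping the taller of two close peaks). Frequencies may
#' be rounded to the nearest 5 cm^-1 for reporting, the convention of
#' experimental peak tables.
#'
#' @param spec a `vib_spectrum`
#' @param min_prominence prominence threshold as a fraction of the spectrum
#'   maximum (default 0.05)
#' @param min_separation minimum peak separation, cm^-1 (default 10)
#' @param round5 round reported frequencies to the nearest 5 cm^-1?
#' @return data.frame of class `peak_table`: frequency, height, prominence,
#'   width (half-prominence width, cm^-1); zero rows allowed
#' @export
detect_peaks <- function(spec, min_prominence = 0.05, min_separation = 10,
                         round5 = FALSE) {
  y <- spec$intensity
  x <- spec$wavenumbers
  n <- length(y)
  empty <- data.frame(frequency = numeric(0), height = numeric(0),
                      prominence = numeric(0), width = numeric(0))
  class(empty) <- c("peak_table", "data.frame")
  if (n < 3) return(empty)
  cand <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  if (length(cand) == 0) return(empty)
  prom <- vapply(cand, function(i) {
    h <- y[i]
    left <- if (any(y[1:i] > h)) {
      j <- max(which(y[1:i] > h)); min(y[j:i])
    } else min(y[1:i])
    right <- if (any(y[i:n] > h)) {
      j <- i - 1L + min(which(y[i:n] > h)); min(y[i:j])
    } else min(y[i:n])
    h - max(left, right)
  }, numeric(1))
  keep <- prom >= min_prominence * max(y)
  cand <- cand[keep]; prom <- prom[keep]
  if (length(cand) == 0) return(empty)
  ord <- order(y[cand], decreasing = TRUE)
  sel <- integer(0)
  for (i in ord) {
    if (all(abs(x[cand[i]] - x[cand[sel]]) >= min_separation))
      sel <- c(sel, i)
  }
  sel <- sel[order(x[cand[sel]])]
  idxs <- cand[sel]
  width <- vapply(seq_along(idxs), function(kk) {
    i <- idxs[kk]
    half <- y[i] - prom[sel[kk]] / 2
    l <- i; while (l > 1 && y[l] > half) l <- l - 1L
    r <- i; while (r < n && y[r] > half) r <- r + 1L
    x[r] - x[l]
  }, numeric(1))
  freq <- x[idxs]
  if (round5) freq <- 5 * round(freq / 5)
  out <- data.frame(frequency = freq, height = y[idxs],
                    prominence = prom[sel], width = width)
  class(out) <- c("peak_table", "data.frame")
  out
}

#' Assign local-mode character to detected peaks
#'
#' For each peak, every local mode's contribution is the spectral mass of its
#' unit-area spectrum within +/- `window_halfwidth` of the peak frequency.
#' Modes below `floor_frac` of the top contributor are omitted; survivors are
#' listed in descending order of contribution (ties broken alphabetically by
#' mode label). Peaks with no mode above the floor are reported unassigned.
#'
#' @param peaks a `peak_table` (or data.frame with a `frequency` column)
#' @param local_spectra named list of unit-area `vib_spectrum` objects on a
#'   common grid ([local_mode_spectra()])
#' @param window_halfwidth assignment window half-width, cm^-1 (default 25)
#' @param floor_frac contribution floor as a fraction of the top contributor
#' @return an `assignment_table`: data.frame with frequency, assignment
#'   (comma-separated labels, descending contribution) and a `contributions`
#'   list-column of named numeric vectors
#' @export
assign_peaks <- function(peaks, local_spectra, window_halfwidth = 25,
                         floor_frac = 0.10) {
  stopifnot(is.data.frame(peaks))
  if (any(vapply(local_spectra, function(s) s$normalization, "")
          != "unit_area"))
    stop("local spectra must be unit_area normalized")
  rows <- lapply(peaks$frequency, function(f) {
    contrib <- vapply(local_spectra, function(s)
      spectrum_integral(s, c(f - window_halfwidth, f + window_halfwidth)),
      numeric(1))
    top <- max(contrib)
    if (top <= 0) return(list(assignment = "", contributions = numeric(0)))
    kept <- contrib[contrib >= floor_frac * top]
    kept <- kept[order(-kept, names(kept))]
    list(assignment = paste(names(kept), collapse = ", "),
         contributions = kept)
  })
  out <- data.frame(frequency = peaks$frequency,
                    assignment = vapply(rows, `[[`, "", "assignment"),
                    stringsAsFactors = FALSE)
  out$contributions <- lapply(rows, `[[`, "contributions")
  class(out) <- c("assignment_table", "data.frame")
  out
}

.primary_label <- function(assignment)
  trimws(vapply(strsplit(assignment, ","), `[[`, "", 1L))

#' Coverage-to-coverage peak shifts by assignment label
#'
#' For each assignment label present in both tables, shift = high-coverage
#' frequency minus low-coverage frequency (positive = blue shift). Labels
#' present in only one table are reported unmatched with NA shift. Matching
#' is by label, never by nearest frequency.
#'
#' @param table_low data.frame with `frequency` and `label` columns (the
#'   low-coverage peak list)
#' @param table_high same for the high-coverage peak list
#' @return data.frame: label, freq_low, freq_high, shift (cm^-1; NA when
#'   unmatched)
#' @export
peak_shifts <- function(table_low, table_high) {
  labels <- union(table_low$label, table_high$label)
  lo <- table_low$frequency[match(labels, table_low$label)]
  hi <- table_high$frequency[match(labels, table_high$label)]
  data.frame(label = labels, freq_low = lo, freq_high = hi,
             shift = hi - lo, stringsAsFactors = FALSE)
}

#' RMS discrepancy between calculated and reference peak frequencies
#'
#' rms_abs = sqrt(mean((calc - ref)^2)) in cm^-1 and
#' rms_rel = sqrt(mean(((calc - ref)/ref)^2)) * 100 in percent, over the
#' label-matched pairs after removing any excluded labels. Statistics are
#' reported rounded to 1 cm^-1 and 0.1%, the precision of published
#' comparisons.
#'
#' @param pairs data.frame with columns `reference`, `calculated` and
#'   optionally `label`
#' @param exclude character vector of labels to drop (requires a `label`
#'   column); matching is by exact label
#' @return a `discrepancy_stats` list: `pairs`, `rms_abs`, `rms_rel`,
#'   `excluded_labels` (rounded), plus unrounded `rms_abs_full`,
#'   `rms_rel_full`
#' @export
rms_discrepancy <- function(pairs, exclude = character(0)) {
  if (length(exclude) > 0) {
    if (is.null(pairs$label)) stop("exclusion requires a label column")
    pairs <- pairs[!(pairs$label %in% exclude), , drop = FALSE]
  }
  if (nrow(pairs) == 0) stop("no pairs remain after exclusion")
  d <- pairs$calculated - pairs$reference
  rms_abs <- sqrt(mean(d^2))
  rms_rel <- 100 * sqrt(mean((d / pairs$reference)^2))
  structure(list(pairs = pairs, rms_abs = round(rms_abs),
                 rms_rel = round(rms_rel, 1), rms_abs_full = rms_abs,
                 rms_rel_full = rms_rel, excluded_labels = exclude),
            class = "discrepancy_stats")
}

#' @export
print.discrepancy_stats <- function(x, ...) {
  cat(sprintf("rms discrepancy over %d pairs: %g cm^-1 (%g%% relative)%s\n",
              nrow(x$pairs), x$rms_abs, x$rms_rel,
              if (length(x$excluded_labels))
                paste0("; excluded: ",
                       paste(x$excluded_labels, collapse = ", ")) else ""))
  invisible(x)
}
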