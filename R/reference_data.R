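#' Reference RAIRS/MD peak pairs for glycinate on Cu{110}
#'
#' The bundled reconciliation list for the 1/3 ML phase: published RAIRS peak
#' frequencies (Barlow et al.'s experiment) paired by assignment label with
#' vibrational-DOS peak positions from first-principles MD. Pairing is by
#' assignment, not nearest frequency, and includes the deliberate
#' reassignment of the 969 cm^-1 experimental peak to the CN stretch; the
#' ambiguous 1417 cm^-1 experimental peak appears against two calculated
#' candidates.
#'
#' @return data.frame with columns `reference`, `calculated`, `label`, `note`
#' @export
glycinate_reference_peaks <- function() {
  utils::read.csv(system.file("extdata", "glycinate_cu110_rairs_md.csv",
                              package = "vibmd", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' Coverage-resolved DOS peak table for glycinate on Cu{110}
#'
#' The bundled peak list at 1/6 ML and 1/3 ML coverage with local-mode
#' assignments (full assignment strings in descending order of
#' contribution). `label` is a unique matching key (the dominant mode, with
#' a suffix where the same dominant mode appears in more than one peak).
#'
#' @param coverage "both" (default), or "low" / "high" for a two-column
#'   frequency/label table suitable for [peak_shifts()]
#' @return data.frame
#' @export
glycinate_coverage_peaks <- function(coverage = c("both", "low", "high")) {
  coverage <- match.arg(coverage)
  tab <- utils::read.csv(system.file("extdata",
                                     "glycinate_cu110_dos_peaks.csv",
                                     package = "vibmd", mustWork = TRUE),
                         stringsAsFactors = FALSE)
  if (coverage == "both") return(tab)
  col <- if (coverage == "low") "freq_low" else "freq_high"
  out <- data.frame(frequency = tab[[col]], label = tab$label,
                    assignment = tab$assignment, stringsAsFactors = FALSE)
  out[!is.na(out$frequency), , drop = FALSE]
}

#' Standard wavenumber bands of the adsorbed-glycinate spectrum
#'
#' Band edges (cm^-1) mirroring the conventional reading of the spectrum:
#' substrate phonons below 250, frustrated rotations/translations up to the
#' fingerprint region (500-1550, overlapping intramolecular modes), CH2
#' stretches 2850-3200 and NH2 stretches 3200-3650.
#'
#' @return named list of c(lo, hi) band edges
#' @export
default_bands <- function() {
  list(phonon = c(0, 250), fingerprint = c(500, 1550),
       ch2_stretch = c(2850, 3200), nh2_stretch = c(3200, 3650))
}
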