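.vibmd_env <- new.env(parent = emptyenv())

#' Standard atomic weights
#'
#' Returns the bundled table of standard atomic weights (IUPAC 2021
#' conventional values) used to assign per-atom masses from element symbols.
#'
#' @return data.frame with columns `symbol` and `mass_amu`
#' @export
atomic_weights <- function() {
  if (is.null(.vibmd_env$weights)) {
    path <- system.file("extdata", "atomic_weights.csv", package = "vibmd",
                        mustWork = TRUE)
    .vibmd_env$weights <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  .vibmd_env$weights
}

#' Look up atomic masses by element symbol
#'
#' @param symbols character vector of element symbols (case sensitive, e.g.
#'   "Cu" not "CU")
#' @return numeric vector of masses in amu
#' @export
element_masses <- function(symbols) {
  tab <- atomic_weights()
  idx <- match(symbols, tab$symbol)
  if (anyNA(idx)) {
    bad <- unique(symbols[is.na(idx)])
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  }
  tab$mass_amu[idx]
}
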