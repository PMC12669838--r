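#' @keywords internal
"_PACKAGE"

# package-local cache so the constants file is parsed once per session
.diveO2_env <- new.env(parent = emptyenv())

#' Printed model constants
#'
#' All constants taken from the source study's printed tables and methods
#' (Hill-plot coefficients for the giant fulmar, emperor penguin P50 anchors,
#' blood O2 content constants, compartment fractions, myoglobin desaturation
#' rates, filtering thresholds, ...) live in a single versioned parameter file
#' shipped with the package (`inst/extdata/printed_constants.dcf`). Operations
#' read their defaults from here and never hard-code them.
#'
#' @return A named list of numeric scalars and vectors.
#' @export
#' @examples
#' o2_params()$emperor_anchor_p50
o2_params <- function() {
  if (!is.null(.diveO2_env$params)) {
    return(.diveO2_env$params)
  }
  path <- system.file("extdata", "printed_constants.dcf", package = "diveO2",
                      mustWork = TRUE)
  raw <- read.dcf(path)
  vals <- lapply(seq_len(ncol(raw)), function(i) {
    scan(text = raw[1L, i], what = numeric(), quiet = TRUE)
  })
  names(vals) <- colnames(raw)
  .diveO2_env$params <- vals
  vals
}

#' Per-compartment O2 store inputs by dive-duration class
#'
#' Initial store sizes (ml O2 kg-1) and net depletion rates
#' (ml O2 kg-1 min-1) for the five body compartments (arterial, venous,
#' respiratory, chest muscle, leg muscle), for short (5-6 min) and long
#' (10-12 min) dive-duration classes, as printed in the study's total-body
#' budget table. Note the long-class chest-muscle rate in the budget table
#' (2.0) differs from the methods-text value (2.3); see
#' [chest_muscle_rate()] for the reconciliation.
#'
#' @param class Optional `"short"` or `"long"` to subset.
#' @return A data.frame with columns `compartment`, `class`,
#'   `initial_ml_o2_kg`, `dmr_ml_o2_kg_min`.
#' @export
o2_store_params <- function(class = NULL) {
  path <- system.file("extdata", "o2_store_params.csv", package = "diveO2",
                      mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(class)) {
    class <- match.arg(class, c("short", "long"))
    df <- df[df$class == class, , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}
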