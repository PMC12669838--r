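# CSV dialects and key-value (DCF) curve configuration files.

#' Read a blood-sample panel from CSV
#'
#' Expected columns: `penguin_id`, `year` (optional), `mass_kg`, `site`,
#' `condition`, `ph`, `pco2_mmHg`, `po2_mmHg`, `lactate_mmol_l`; one header
#' row; empty fields are missing values.
#'
#' @param path CSV file path.
#' @return A [blood_samples()] data.frame.
#' @export
read_blood_samples <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"))
  need <- c("penguin_id", "mass_kg", "site", "condition", "ph",
            "pco2_mmHg", "po2_mmHg", "lactate_mmol_l")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop("missing columns in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  blood_samples(data.frame(penguin_id = raw$penguin_id, ph = raw$ph,
                           pco2 = raw$pco2_mmHg, po2 = raw$po2_mmHg,
                           lactate = raw$lactate_mmol_l,
                           body_mass = raw$mass_kg, site = raw$site,
                           condition = raw$condition))
}

#' Write a blood-sample panel to CSV (inverse of [read_blood_samples()])
#'
#' @param samples A [blood_samples()] data.frame.
#' @param path Output path.
#' @param year Optional year column value(s).
#' @return `path`, invisibly.
#' @export
write_blood_samples <- function(samples, path, year = NA) {
  samples <- blood_samples(as.data.frame(samples))
  out <- data.frame(penguin_id = samples$penguin_id, year = year,
                    mass_kg = samples$body_mass, site = samples$site,
                    condition = samples$condition, ph = samples$ph,
                    pco2_mmHg = samples$pco2, po2_mmHg = samples$po2,
                    lactate_mmol_l = samples$lactate)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read dive PO2/depth profiles from CSV
#'
#' Expected columns: `dive_id`, `site`, `t_s`, `depth_m`, `po2_mmHg`.
#'
#' @param path CSV file path.
#' @return A named list of [dive_record()] objects, one per `dive_id`.
#' @export
read_dive_profiles <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("dive_id", "site", "t_s", "depth_m", "po2_mmHg")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop("missing columns in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  lapply(split(raw, raw$dive_id), function(g) {
    g <- g[order(g$t_s), ]
    dive_record(data.frame(t = g$t_s, depth = g$depth_m, po2 = g$po2_mmHg),
                dive_id = g$dive_id[1L], site = g$site[1L])
  })
}

#' Write a dive record (or several) to the profile CSV dialect
#'
#' @param records A [dive_record()] or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dive_profiles <- function(records, path) {
  if (inherits(records, "dive_record")) records <- list(records)
  out <- do.call(rbind, lapply(records, function(r) {
    data.frame(dive_id = attr(r, "dive_id"), site = attr(r, "site"),
               t_s = r$t, depth_m = r$depth, po2_mmHg = r$po2)
  }))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write saturation profiles to CSV
#'
#' The output adds `ph`, `saturation` and `phase` to the profile dialect.
#'
#' @param profiles A `saturation_profile` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_saturation_profiles <- function(profiles, path) {
  if (inherits(profiles, "saturation_profile")) profiles <- list(profiles)
  out <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(dive_id = attr(p, "dive_id"), site = attr(p, "site"),
               ph = attr(p, "ph"), curve = attr(p, "curve_label"),
               t_s = p$t, depth_m = p$depth, po2_mmHg = p$po2,
               saturation = p$saturation, phase = p$phase)
  }))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read dive endpoints (start/end blood state per dive) from CSV
#'
#' Expected columns: `dive_id`, `site`, `duration_min`, `po2_start_mmHg`,
#' `po2_end_mmHg`.
#'
#' @param path CSV file path.
#' @return A data.frame with internal column names.
#' @export
read_dive_endpoints <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("dive_id", "site", "duration_min", "po2_start_mmHg",
            "po2_end_mmHg")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop("missing columns in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  raw
}

#' Load a dissociation-curve / Bohr-model definition from a key-value file
#'
#' The file is in Debian-control (DCF) key-value format. A Bohr model needs
#' fields `anchors_ph` and `anchors_p50` (space-separated numbers) and
#' optionally `hill_n` and `label`; a single curve needs `p50` plus
#' optionally `hill_n` and `label`.
#'
#' @param path DCF file path.
#' @return A [bohr_model()] (when anchors are present) or a
#'   [dissociation_curve()].
#' @export
read_curve_config <- function(path) {
  raw <- read.dcf(path)
  fields <- colnames(raw)
  num <- function(key) scan(text = raw[1L, key], what = numeric(), quiet = TRUE)
  if (all(c("anchors_ph", "anchors_p50") %in% fields)) {
    return(bohr_model(num("anchors_ph"), num("anchors_p50")))
  }
  if ("p50" %in% fields) {
    hill_n <- if ("hill_n" %in% fields) num("hill_n") else o2_params()$emperor_hill_n
    label <- if ("label" %in% fields) raw[1L, "label"] else ""
    return(dissociation_curve(num("p50"), hill_n, label))
  }
  stop("curve config needs either anchors_ph/anchors_p50 or p50", call. = FALSE)
}
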