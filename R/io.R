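# Configuration documents (schema-versioned JSON with unit annotations),
# result serialisation, and run manifests.

.CONFIG_SCHEMA_VERSION <- "1.0"

# Declarative schema: every leaf key carries its unit; unknown keys are
# rejected on load; numeric constraints are checked by the constructors.
.config_schema <- function() {
  rate_units <- function(nm, u) stats::setNames(rep(u, length(nm)), nm)
  list(
    sglt1 = c(rate_units(c("k12", "k65"), "mM^-2.s^-1"),
              rate_units(c("k23", "k54"), "mM^-1.s^-1"),
              rate_units(c("k21", "k32", "k34", "k43", "k45", "k56", "k61"),
                         "s^-1"),
              rate_units(c("q12", "q34", "q61"), "dimensionless"),
              n_copies = "count"),
    glut2_apical = c(rate_units(c("k_on_out", "k_on_in"), "mM^-1.s^-1"),
                     rate_units(c("k_off_out", "k_off_in", "k_tl_oi",
                                  "k_tl_io", "k_mt_io"), "s^-1"),
                     n_copies = "count"),
    glut2_basolateral = NULL,   # same as glut2_apical
    pump = c(k_max = "s^-1", km_na = "mM", km_k = "mM",
             h_na = "dimensionless", h_k = "dimensionless",
             n_copies = "count"),
    channels = "p_area m^3.s^-1 by membrane_ion",
    water = "lp m^3.s^-1.mOsm^-1 by pathway",
    osmolytes = c(amount = "mol", valence = "dimensionless"),
    blood = c(volume = "m^3", flow = "m^3.s^-1"),
    compositions = "mM and pH"
  )
}

#' Serialise a model configuration to a structured-text (JSON) document
#'
#' The document is schema-versioned, annotates every quantity block with its
#' units, and round-trips losslessly through [load_config()].
#'
#' @param config a [model_config()].
#' @param path file to write; if `NULL` the JSON string is returned.
#' @return `path` invisibly (or the JSON string).
#' @export
save_config <- function(config, path = NULL) {
  ch <- lapply(config$channels, function(x)
    list(p_area = x$p_area, valence = x$valence, membrane = x$membrane))
  wt <- lapply(config$water, function(x)
    list(lp = x$lp, membrane = x$membrane, sigma = as.list(x$sigma)))
  doc <- list(
    schema = "enterosim-config",
    schema_version = .CONFIG_SCHEMA_VERSION,
    units = list(concentration = "mM", volume = "m^3", flow = "m^3/s",
                 rate_first_order = "1/s", rate_binding = "1/(mM s)",
                 rate_na_binding = "1/(mM^2 s)",
                 water_permeability = "m^3/(s mOsm)",
                 channel_permeability = "m^3/s", potential = "mV"),
    sglt1 = c(as.list(config$sglt1$rates[setdiff(names(config$sglt1$rates),
                                                 "k16")]),
              as.list(config$sglt1$charges),
              list(n_copies = config$sglt1$n_copies)),
    glut2_apical = c(as.list(config$glut2_apical$rates[
      setdiff(names(config$glut2_apical$rates), "k_mt_oi")]),
      list(n_copies = config$glut2_apical$n_copies)),
    glut2_basolateral = c(as.list(config$glut2_basolateral$rates[
      setdiff(names(config$glut2_basolateral$rates), "k_mt_oi")]),
      list(n_copies = config$glut2_basolateral$n_copies)),
    pump = list(k_max = config$pump$k_max, km_na = config$pump$km_na,
                km_k = config$pump$km_k, h_na = config$pump$h_na,
                h_k = config$pump$h_k, n_copies = config$pump$n_copies),
    channels = ch,
    water = wt,
    osmolytes = config$osmolytes,
    blood = list(volume = config$blood_volume, flow = config$blood_flow,
                 inflow = config$blood_inflow),
    lumen = config$lumen,
    cells_per_cm = config$cells_per_cm,
    lumen_finite = config$lumen_finite,
    lumen_volume = config$lumen_volume
  )
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

.known_top_keys <- c("schema", "schema_version", "units", "sglt1",
                     "glut2_apical", "glut2_basolateral", "pump", "channels",
                     "water", "osmolytes", "blood", "lumen", "cells_per_cm",
                     "lumen_finite", "lumen_volume", "protocol")

#' Load and validate a model configuration document
#'
#' Reads a structured-text (JSON) configuration, validates it against the
#' schema (unknown keys are rejected; constraint violations name the
#' offending field) and fills every omitted block with the published baseline
#' defaults (transporter copy numbers 3e7 SGLT1 / 1e8 apical GLUT2 / 2e8
#' basolateral GLUT2; blood volume 1e-16 m^3; inlet flow 1e-17 m^3/s).
#' An empty document therefore yields the full baseline configuration.
#'
#' @param path path to the JSON document (or a JSON string).
#' @return A list with `config` (a [model_config()]) and `protocol` (a
#'   [protocol()] or `NULL` if the document schedules none).
#' @export
load_config <- function(path) {
  txt <- if (file.exists(path)) readLines(path, warn = FALSE) else path
  txt <- paste(txt, collapse = "\n")
  if (!nzchar(trimws(txt))) txt <- "{}"
  doc <- tryCatch(jsonlite::fromJSON(txt, simplifyVector = TRUE),
                  error = function(e)
                    stop("load_config: parse error: ", conditionMessage(e),
                         call. = FALSE))
  unknown <- setdiff(names(doc), .known_top_keys)
  if (length(unknown))
    stop("load_config: unknown key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!is.null(doc$schema_version) &&
      doc$schema_version != .CONFIG_SCHEMA_VERSION)
    stop("load_config: unsupported schema_version '", doc$schema_version, "'",
         call. = FALSE)

  num_field <- function(block, nm, default, positive = FALSE, nonneg = FALSE) {
    v <- if (is.null(block[[nm]])) default else block[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v))
      stop("load_config: field '", nm, "' must be a finite number", call. = FALSE)
    if (positive && v <= 0)
      stop("load_config: field '", nm, "' must be > 0", call. = FALSE)
    if (nonneg && v < 0)
      stop("load_config: field '", nm, "' must be >= 0", call. = FALSE)
    as.numeric(v)          # JSON integers parse as integer; keep doubles
  }

  sg <- doc$sglt1
  sglt1 <- sglt1_params(
    k12 = num_field(sg, "k12", .SGLT1_DEFAULT$k12, positive = TRUE),
    k21 = num_field(sg, "k21", .SGLT1_DEFAULT$k21, positive = TRUE),
    k23 = num_field(sg, "k23", .SGLT1_DEFAULT$k23, positive = TRUE),
    k32 = num_field(sg, "k32", .SGLT1_DEFAULT$k32, positive = TRUE),
    k34 = num_field(sg, "k34", .SGLT1_DEFAULT$k34, positive = TRUE),
    k43 = num_field(sg, "k43", .SGLT1_DEFAULT$k43, positive = TRUE),
    k45 = num_field(sg, "k45", .SGLT1_DEFAULT$k45, positive = TRUE),
    k54 = num_field(sg, "k54", .SGLT1_DEFAULT$k54, positive = TRUE),
    k56 = num_field(sg, "k56", .SGLT1_DEFAULT$k56, positive = TRUE),
    k65 = num_field(sg, "k65", .SGLT1_DEFAULT$k65, positive = TRUE),
    k61 = num_field(sg, "k61", .SGLT1_DEFAULT$k61, positive = TRUE),
    q12 = num_field(sg, "q12", 0.6), q34 = num_field(sg, "q34", 0),
    q61 = num_field(sg, "q61", 1.4),
    n_copies = num_field(sg, "n_copies", 3e7, nonneg = TRUE))

  carrier_from <- function(block, n_default) {
    carrier_params(
      k_on_out = num_field(block, "k_on_out", .GLUT2_DEFAULT$k_on_out, TRUE),
      k_off_out = num_field(block, "k_off_out", .GLUT2_DEFAULT$k_off_out, TRUE),
      k_on_in = num_field(block, "k_on_in", .GLUT2_DEFAULT$k_on_in, TRUE),
      k_off_in = num_field(block, "k_off_in", .GLUT2_DEFAULT$k_off_in, TRUE),
      k_tl_oi = num_field(block, "k_tl_oi", .GLUT2_DEFAULT$k_tl_oi, TRUE),
      k_tl_io = num_field(block, "k_tl_io", .GLUT2_DEFAULT$k_tl_io, TRUE),
      k_mt_io = num_field(block, "k_mt_io", .GLUT2_DEFAULT$k_mt_io, TRUE),
      n_copies = num_field(block, "n_copies", n_default, nonneg = TRUE))
  }
  glut2_ap <- carrier_from(doc$glut2_apical, 1e8)
  bl_def <- .GLUT2_BL_DEFAULT
  blb <- doc$glut2_basolateral
  glut2_bl <- carrier_params(
    k_on_out = num_field(blb, "k_on_out", bl_def$k_on_out, TRUE),
    k_off_out = num_field(blb, "k_off_out", bl_def$k_off_out, TRUE),
    k_on_in = num_field(blb, "k_on_in", bl_def$k_on_in, TRUE),
    k_off_in = num_field(blb, "k_off_in", bl_def$k_off_in, TRUE),
    k_tl_oi = num_field(blb, "k_tl_oi", bl_def$k_tl_oi, TRUE),
    k_tl_io = num_field(blb, "k_tl_io", bl_def$k_tl_io, TRUE),
    k_mt_io = num_field(blb, "k_mt_io", bl_def$k_mt_io, TRUE),
    n_copies = num_field(blb, "n_copies", 2e8, nonneg = TRUE))

  pm <- doc$pump
  pump <- pump_params(
    k_max = num_field(pm, "k_max", .PUMP_DEFAULT$k_max, positive = TRUE),
    km_na = num_field(pm, "km_na", .PUMP_DEFAULT$km_na, positive = TRUE),
    km_k = num_field(pm, "km_k", .PUMP_DEFAULT$km_k, positive = TRUE),
    h_na = num_field(pm, "h_na", 3, positive = TRUE),
    h_k = num_field(pm, "h_k", 2, positive = TRUE),
    n_copies = num_field(pm, "n_copies", .PUMP_DEFAULT$n_copies, nonneg = TRUE))

  channels <- default_channels()
  if (!is.null(doc$channels)) {
    for (nm in names(doc$channels)) {
      if (!nm %in% names(channels))
        stop("load_config: unknown channel '", nm, "'", call. = FALSE)
      b <- doc$channels[[nm]]
      channels[[nm]] <- channel_params(
        num_field(b, "p_area", channels[[nm]]$p_area, nonneg = TRUE),
        if (is.null(b$valence)) channels[[nm]]$valence else b$valence,
        if (is.null(b$membrane)) channels[[nm]]$membrane else b$membrane)
    }
  }
  water <- default_water_pathways()
  if (!is.null(doc$water)) {
    for (nm in names(doc$water)) {
      if (!nm %in% names(water))
        stop("load_config: unknown water pathway '", nm, "'", call. = FALSE)
      b <- doc$water[[nm]]
      sg_ <- if (is.null(b$sigma)) water[[nm]]$sigma else unlist(b$sigma)
      water[[nm]] <- water_params(
        num_field(b, "lp", water[[nm]]$lp, nonneg = TRUE),
        water[[nm]]$membrane, sigma = sg_)
    }
  }

  osl <- doc$osmolytes
  osmolytes <- list(
    amount = num_field(osl, "amount", .CELL_DEFAULT$osmolyte_amount,
                       nonneg = TRUE),
    valence = num_field(osl, "valence", .CELL_DEFAULT$osmolyte_valence))

  bl <- doc$blood
  comp_from <- function(block, defaults) {
    out <- defaults
    if (!is.null(block)) {
      bad <- setdiff(names(block), names(defaults))
      if (length(bad))
        stop("load_config: unknown composition key(s): ",
             paste(bad, collapse = ", "), call. = FALSE)
      for (nm in names(block))
        out[[nm]] <- num_field(block, nm, defaults[[nm]],
                               nonneg = (nm != "ph"))
    }
    out
  }
  inflow <- comp_from(bl$inflow, list(na = 150, k = 5, cl = 150, hco3 = 0,
                                      glucose = 4, ph = 7.4))
  lumen <- comp_from(doc$lumen, list(na = 150, k = 5, cl = 150, hco3 = 0,
                                     glucose = 0, ph = 7.4))

  cfg <- model_config(
    sglt1 = sglt1, glut2_apical = glut2_ap, glut2_basolateral = glut2_bl,
    pump = pump, channels = channels, water = water, osmolytes = osmolytes,
    blood_volume = num_field(bl, "volume", 1e-16, positive = TRUE),
    blood_flow = num_field(bl, "flow", 1e-17, nonneg = TRUE),
    blood_inflow = inflow, lumen = lumen,
    cells_per_cm = num_field(doc, "cells_per_cm", 1.3e9 / 75, positive = TRUE),
    lumen_finite = isTRUE(doc$lumen_finite),
    lumen_volume = num_field(doc, "lumen_volume", 1e-14, positive = TRUE))

  prot <- NULL
  if (!is.null(doc$protocol)) {
    p <- doc$protocol
    evs <- lapply(seq_len(nrow(p$events)), function(i) {
      ev <- list(time = as.numeric(p$events$time[i]))
      if (!is.null(p$events$lumen)) {
        lu <- lapply(as.list(p$events$lumen[i, , drop = FALSE]), as.numeric)
        ev$lumen <- lu[!vapply(lu, function(x) is.null(x) || is.na(x),
                               logical(1))]
      }
      ev
    })
    prot <- protocol(t_end = as.numeric(p$t_end), events = evs,
                     record_dt = if (is.null(p$record_dt)) 20
                                 else as.numeric(p$record_dt))
  }
  list(config = cfg, protocol = prot)
}

#' Write a trajectory or sweep table as delimited text with units in the header
#'
#' @param x a `trajectory` data frame or any data frame whose column names
#'   carry unit suffixes.
#' @param path output file (CSV).
#' @return `path`, invisibly.
#' @export
write_result_table <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Run manifest
#'
#' Records everything needed to reproduce a run bit-for-bit: the full
#' configuration snapshot, package version, solver tolerances and the output
#' file inventory.
#'
#' @param config the [model_config()] used.
#' @param outputs character vector of output files written.
#' @param tolerances named list of solver tolerances.
#' @param path file to write (JSON).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config, outputs, tolerances = list(rtol = 1e-7,
                                                              rate_tol = 1e-9),
                           path) {
  man <- list(
    tool = "enterosim",
    version = tryCatch(as.character(utils::packageVersion("enterosim")),
                       error = function(e) "dev"),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    tolerances = tolerances,
    outputs = outputs,
    config = jsonlite::fromJSON(save_config(config))
  )
  writeLines(jsonlite::toJSON(man, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), path)
  invisible(path)
}
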