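# Configuration files, event-log persistence, JSON reports.
# Times are stored in integer simulation steps everywhere; conversion to
# physical units happens only in reporting via physical_units().

.config_keys <- c("side_sites", "compartment_sites", "spacing", "timestep",
                  "crossing_prob", "reaction_prob", "mean_dimer_lifetime",
                  "n_particles", "n_steps", "seed", "tracer_id",
                  "inter_reaction_convention", "tau_crit")

#' Read a simulation configuration from a YAML or JSON file
#'
#' The file is a flat key-value document over the documented keys
#' (`side_sites`, `compartment_sites`, `spacing`, `timestep`,
#' `crossing_prob`, `reaction_prob`, `mean_dimer_lifetime`, `n_particles`,
#' `n_steps`, `seed`, `tracer_id`, `inter_reaction_convention`,
#' `tau_crit`).  Missing optional keys take the [sim_params()] defaults;
#' unknown keys are rejected; every value passes the full validation of
#' [sim_config()].
#'
#' @param path File path; dialect chosen by extension (`.json` is JSON,
#'   anything else YAML).
#' @return A validated [sim_config()].
#' @export
load_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) jsonlite::fromJSON(path)
         else yaml::read_yaml(path)
  unknown <- setdiff(names(raw), .config_keys)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  need <- c("side_sites", "compartment_sites", "crossing_prob")
  missing <- setdiff(need, names(raw))
  if (length(missing))
    stop("missing required key(s): ", paste(missing, collapse = ", "), call. = FALSE)
  spec <- lattice_spec(raw$side_sites, raw$compartment_sites,
                       spacing = raw$spacing %||% 1, timestep = raw$timestep %||% 1)
  params <- sim_params(
    crossing_prob = raw$crossing_prob,
    reaction_prob = raw$reaction_prob %||% 1,
    mean_dimer_lifetime = raw$mean_dimer_lifetime %||% 100,
    n_particles = raw$n_particles %||% 10,
    n_steps = raw$n_steps %||% 1e6,
    seed = raw$seed %||% 1L,
    tracer_id = raw$tracer_id %||% 0L,
    inter_reaction_convention = raw$inter_reaction_convention %||% "dissociation_to_reaction")
  sim_config(spec, params, tau_crit = raw$tau_crit)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname load_config
#' @param config A [sim_config()] to write.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  x <- c(config$spec[c("side_sites", "compartment_sites", "spacing", "timestep")],
         config$params[c("crossing_prob", "reaction_prob", "mean_dimer_lifetime",
                         "n_particles", "n_steps", "seed", "tracer_id",
                         "inter_reaction_convention")])
  if (!is.null(config$tau_crit)) x$tau_crit <- config$tau_crit
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' Write and read tracer event logs
#'
#' The log is written as a CSV with header `step`, `event_type`,
#' `partner_id`, `x`, `y`, `comp_x`, `comp_y`, alongside a JSON sidecar
#' (`<path>.json`) holding the configuration snapshot, the total step
#' count, and the tracer monomer fraction.  The reader validates the
#' strict reaction/dissociation alternation and round-trips the object
#' losslessly.
#'
#' @param log An `event_log`.
#' @param path CSV path (sidecar written next to it).
#' @export
write_event_log <- function(log, path) {
  stopifnot(inherits(log, "event_log"))
  utils::write.csv(log$events, path, row.names = FALSE, quote = FALSE)
  # the sidecar doubles as the run manifest: configuration snapshot (with
  # seed), code version, timestamp and a checksum of the CSV are enough to
  # re-create the log bit-exactly
  side <- list(schema_version = "1.0",
               package_version = as.character(utils::packageVersion("reactburst")),
               created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
               events_file = basename(path),
               events_md5 = unname(tools::md5sum(path)),
               n_steps = log$n_steps,
               tracer_monomer_fraction = log$tracer_monomer_fraction,
               config = jsonlite::fromJSON(config_json(log$config)))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

config_json <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  save_config(config, tmp)
  paste(readLines(tmp), collapse = "")
}

#' @rdname write_event_log
#' @return `read_event_log()` returns the reconstructed `event_log`.
#' @export
read_event_log <- function(path) {
  sidecar_path <- paste0(path, ".json")
  if (file.exists(sidecar_path)) {
    md5 <- jsonlite::fromJSON(sidecar_path)$events_md5
    if (!is.null(md5) && !identical(unname(tools::md5sum(path)), md5))
      stop("event log integrity error: checksum mismatch (truncated or edited file)",
           call. = FALSE)
  }
  ev <- utils::read.csv(path, stringsAsFactors = FALSE)
  want <- c("step", "event_type", "partner_id", "x", "y", "comp_x", "comp_y")
  if (!identical(names(ev), want))
    stop("event log integrity error: malformed header or truncated file", call. = FALSE)
  if (anyNA(ev) || (nrow(ev) && !all(ev$event_type %in% c("reaction", "dissociation"))))
    stop("event log integrity error: malformed rows", call. = FALSE)
  if (nrow(ev)) {
    if (is.unsorted(ev$step, strictly = FALSE))
      stop("event log integrity error: steps out of order", call. = FALSE)
    expect_type <- rep(c("reaction", "dissociation"), length.out = nrow(ev))
    if (!all(ev$event_type == expect_type))
      stop("event log integrity error: reaction/dissociation alternation violated",
           call. = FALSE)
  }
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop("event log integrity error: missing sidecar ", sidecar, call. = FALSE)
  side <- jsonlite::fromJSON(sidecar)
  ctmp <- tempfile(fileext = ".json")
  on.exit(unlink(ctmp))
  jsonlite::write_json(side$config, ctmp, auto_unbox = TRUE, digits = NA)
  cfg <- load_config(ctmp)
  ev <- tibble::as_tibble(ev)
  ev$partner_id <- as.integer(ev$partner_id)
  ev$x <- as.integer(ev$x); ev$y <- as.integer(ev$y)
  ev$comp_x <- as.integer(ev$comp_x); ev$comp_y <- as.integer(ev$comp_y)
  structure(list(events = ev, config = cfg, n_steps = side$n_steps,
                 tracer_monomer_fraction = side$tracer_monomer_fraction),
            class = "event_log")
}

#' Assemble a stable-key JSON report
#'
#' Wraps analysis or theory outputs in a versioned JSON document with the
#' time unit annotated, suitable for regression testing.
#'
#' @param results Named list (or one-row data frame) of quantities.
#' @param path Optional file to write; when `NULL` the JSON string is
#'   returned.
#' @param units Time unit of the reported quantities.
#' @return The JSON string, invisibly when written to file.
#' @export
report <- function(results, path = NULL, units = "steps") {
  if (is.data.frame(results)) results <- as.list(results)
  doc <- list(schema_version = "1.0", units = units, results = results)
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
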