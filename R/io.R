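# Configuration schema, trace CSV input/output, run manifests and the
# command-line interface. One JSON file fully determines a run; identical
# config + seed reproduce byte-identical outputs.

#' Default simulation configuration
#'
#' The complete configuration tree with every tunable named by the other
#' modules, as a plain nested list (JSON-serialisable). [load_config()]
#' merges a user file over these defaults and validates the result.
#'
#' @return nested list of defaults.
#' @export
default_config <- function() {
  list(
    titin = list(n_proximal_ig = 50L, n_distal_ig = 26L,
                 n_pevk_residues = 800L,
                 folded_pl = 10, unfolded_pl = 0.65, pevk_pl = 1.0,
                 pevk_modulus = 150, folded_contour = 4.5,
                 unfolding_gain = 26, residue_contour = 0.36,
                 distal_end_filament_length = 117,
                 half_a_band_length = 800, a_band_stiffness = 1e4,
                 temperature = DEFAULT_TEMPERATURE,
                 calcium_force_factor = 1.25),
    unfolding = list(k0 = 1e-4, width_max = 0.25, width_min = 0.15,
                     calcium_width_multiplier = 0.87),
    crossbridge = list(x_min = -22, x_max = 26, n_x = 193L, kappa = 2,
                       delta = 8, reference_isometric_stress = 150),
    overlap = list(lengths = c(1.27, 2.0, 2.4, 4.0),
                   fractions = c(0, 1, 1, 0)),
    ensemble = list(n_strands = 500L, seed = 1L, dt = 1e-4,
                    strands_per_um2 = 500, record_every = 50L),
    scenario = list(calcium_ordering = "instantaneous-calcium",
                    deactivation_unbinding = "keep-bound"),
    protocol = "rfe",
    variant = "full",
    rupture_force = 600
  )
}

merge_config <- function(defaults, user, path = "") {
  if (!is.list(user)) stop("config section ", sQuote(path),
                           " must be an object")
  extra <- setdiff(names(user), names(defaults))
  if (length(extra))
    stop("unknown config key", if (length(extra) > 1) "s", ": ",
         paste0(sub("^\\.", "", paste0(path, ".", extra)), collapse = ", "))
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]],
                                    paste0(path, ".", k))
    } else {
      v <- user[[k]]
      if (is.list(v)) v <- unlist(v)
      mode_ok <- (is.numeric(defaults[[k]]) && is.numeric(v)) ||
        (is.character(defaults[[k]]) && is.character(v))
      if (!mode_ok)
        stop("config key ", sQuote(sub("^\\.", "", paste0(path, ".", k))),
             " must be of type ", mode(defaults[[k]]))
      defaults[[k]] <- if (is.integer(defaults[[k]]) &&
                           all(v == round(v))) as.integer(v) else v
    }
  }
  defaults
}

#' Load and validate a simulation configuration
#'
#' Reads a JSON configuration file, merges it over [default_config()]
#' (unknown keys are rejected with the offending key named), and builds
#' the validated model objects. An empty file yields the full-defaults
#' configuration.
#'
#' @param path path to a JSON config file.
#' @return object of class `simulation_config`: the raw merged list plus
#'   constructed `iso`, `unfold`, `xb` (lazy), `ensemble`, `scenario`
#'   components.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  user <- if (!nzchar(trimws(txt))) list()
          else jsonlite::fromJSON(txt, simplifyVector = TRUE)
  build_config(merge_config(default_config(), user))
}

#' Build a validated configuration from a (merged) config list
#'
#' @param raw a complete config list shaped like [default_config()].
#' @return a `simulation_config`.
#' @export
build_config <- function(raw) {
  ti <- raw$titin
  iso <- titin_isoform(
    n_proximal_ig = ti$n_proximal_ig, n_distal_ig = ti$n_distal_ig,
    n_pevk_residues = ti$n_pevk_residues, folded_pl = ti$folded_pl,
    unfolded_pl = ti$unfolded_pl, pevk_pl = ti$pevk_pl,
    pevk_modulus = ti$pevk_modulus, folded_contour = ti$folded_contour,
    unfolding_gain = ti$unfolding_gain,
    residue_contour = ti$residue_contour,
    distal_end_filament_length = ti$distal_end_filament_length,
    half_a_band_length = ti$half_a_band_length,
    a_band_stiffness = ti$a_band_stiffness, temperature = ti$temperature,
    calcium_force_factor = ti$calcium_force_factor)
  un <- raw$unfolding
  unfold <- unfolding_params(k0 = un$k0, width_max = un$width_max,
                             width_min = un$width_min,
                             n_domains = ti$n_proximal_ig,
                             calcium_width_multiplier =
                               un$calcium_width_multiplier,
                             temperature = ti$temperature)
  en <- raw$ensemble
  ens <- ensemble_config(n_strands = en$n_strands, seed = en$seed,
                         dt = en$dt, strands_per_um2 = en$strands_per_um2,
                         record_every = en$record_every)
  scen <- scenario_flags(raw$scenario$calcium_ordering,
                         raw$scenario$deactivation_unbinding)
  ov <- overlap_fn(raw$overlap$lengths, raw$overlap$fractions)
  structure(list(raw = raw, iso = iso, unfold = unfold, ensemble = ens,
                 scenario = scen, overlap = ov,
                 protocol = raw$protocol, variant = raw$variant,
                 rupture_force = raw$rupture_force),
            class = "simulation_config")
}

# cross-bridge construction is comparatively expensive (steady-state
# calibration), so it is built on demand
config_crossbridge <- function(cfg) {
  cb <- cfg$raw$crossbridge
  crossbridge_params(x_min = cb$x_min, x_max = cb$x_max, n_x = cb$n_x,
                     kappa = cb$kappa, delta = cb$delta,
                     reference_isometric_stress =
                       cb$reference_isometric_stress,
                     fn = cfg$overlap)
}

#' Save a configuration list as JSON
#'
#' @param raw a config list (e.g. `cfg$raw` or [default_config()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(raw, path) {
  jsonlite::write_json(raw, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

TRACE_COLUMNS <- c("time_s", "sarcomere_um", "active_nN_um2",
                   "titin_nN_um2", "total_nN_um2", "mean_unfolded",
                   "titin_sd_nN_um2")

#' Write / read a force trace as CSV
#'
#' Fixed column contract (`time_s`, `sarcomere_um`, `active_nN_um2`,
#' `titin_nN_um2`, `total_nN_um2`, `mean_unfolded`, `titin_sd_nN_um2`);
#' full double precision, locale-independent decimal points.
#' `read_trace(write_trace(x))` reproduces the numbers to float round-trip
#' accuracy (run attributes such as the event log are not persisted).
#'
#' @param trace a `force_trace`.
#' @param path CSV path.
#' @return `write_trace`: `path` invisibly; `read_trace`: a `force_trace`.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "data.frame"),
            all(TRACE_COLUMNS %in% names(trace)))
  df <- as.data.frame(trace)[, TRACE_COLUMNS]
  old <- Sys.getlocale("LC_NUMERIC")
  on.exit(suppressWarnings(Sys.setlocale("LC_NUMERIC", old)), add = TRUE)
  suppressWarnings(Sys.setlocale("LC_NUMERIC", "C"))
  utils::write.csv(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(TRACE_COLUMNS, names(df))
  if (length(missing))
    stop("malformed trace CSV ", path, ": missing column",
         if (length(missing) > 1) "s", " ",
         paste(missing, collapse = ", "))
  for (cn in TRACE_COLUMNS) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    bad <- which(is.na(v) & !is.na(df[[cn]]))
    if (length(bad))
      stop("malformed trace CSV ", path, ": non-numeric value in column ",
           cn, " at data line ", bad[1])
    df[[cn]] <- v
  }
  structure(df[, TRACE_COLUMNS], class = c("force_trace", "data.frame"))
}

#' Run manifest for reproducibility
#'
#' Records everything needed to reproduce a run bit-identically: the
#' configuration (and its MD5 hash), seed, package version, timestamp and
#' the per-phase event log of the run.
#'
#' @param cfg a `simulation_config`.
#' @param seed the seed actually used.
#' @param trace the resulting `force_trace` (for the event log).
#' @param outputs character vector of output paths.
#' @return manifest list.
#' @export
run_manifest <- function(cfg, seed, trace, outputs = character()) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp), add = TRUE)
  save_config(cfg$raw, tmp)
  ev <- attr(trace, "events")
  list(config_hash = unname(tools::md5sum(tmp)),
       seed = as.integer(seed),
       tool = "sarcomech",
       version = as.character(utils::packageVersion("sarcomech")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       ruptured = isTRUE(attr(trace, "ruptured")),
       outputs = outputs,
       events = if (is.null(ev)) list()
                else lapply(seq_len(nrow(ev)), function(i)
                  list(time_s = ev$time_s[i], event = ev$event[i])))
}

write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

cli_usage <- function() {
  paste(
    "usage: sarcomech <subcommand> [options]",
    "",
    "subcommands:",
    "  simulate   --protocol <name> [--config f.json] [--seed N]",
    "             [--strands N] [--scenario ord,unbind] [--variant v]",
    "             --out trace.csv",
    "  calibrate  --data loop.csv --out report  [--config f.json]",
    "  protocols  (list canonical protocol names)",
    "  synth-data --out loop.csv [--seed N] [--n-samples N] [--noise SD]",
    sep = "\n")
}

parse_flags <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--"))
      stop("unexpected argument: ", a)
    if (i == length(args) || startsWith(args[[i + 1L]], "--"))
      stop("flag ", a, " needs a value")
    flags[[substring(a, 3L)]] <- args[[i + 1L]]
    i <- i + 2L
  }
  flags
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (run a canonical protocol and write the trace
#' CSV plus a JSON run manifest), `calibrate` (fit a passive hysteresis
#' CSV and write a calibration report plus a loadable config fragment),
#' `protocols` (list the canonical registry) and `synth-data` (write a
#' synthetic hysteresis dataset). An executable wrapper is installed under
#' `system.file("cli", "sarcomech", package = "sarcomech")`.
#'
#' @param argv character vector of command-line arguments (excluding the
#'   program name).
#' @return integer exit code: 0 on success, 2 on usage errors, 1 on
#'   runtime failure.
#' @export
cli_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (!length(argv)) { message(cli_usage()); return(2L) }
  sub <- argv[[1]]
  if (!sub %in% c("simulate", "calibrate", "protocols", "synth-data")) {
    message("unknown subcommand: ", sub, "\n", cli_usage())
    return(2L)
  }
  flags <- tryCatch(parse_flags(argv[-1]),
                    error = function(e) e)
  if (inherits(flags, "error")) {
    message(conditionMessage(flags), "\n", cli_usage())
    return(2L)
  }
  res <- tryCatch({
    switch(sub,
      protocols = {
        reg <- canonical_protocols()
        for (nm in names(reg)) {
          cat(nm, ":", length(reg[[nm]]$phases), "phases\n")
        }
        0L
      },
      simulate = cli_simulate(flags),
      calibrate = cli_calibrate(flags),
      `synth-data` = cli_synth(flags))
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  res
}

cli_simulate <- function(flags) {
  if (is.null(flags$out)) stop("simulate needs --out")
  cfg <- if (!is.null(flags$config)) load_config(flags$config)
         else build_config(default_config())
  raw <- cfg$raw
  if (!is.null(flags$protocol)) raw$protocol <- flags$protocol
  if (!is.null(flags$seed)) raw$ensemble$seed <- as.integer(flags$seed)
  if (!is.null(flags$strands))
    raw$ensemble$n_strands <- as.integer(flags$strands)
  if (!is.null(flags$variant)) raw$variant <- flags$variant
  if (!is.null(flags$scenario)) {
    parts <- strsplit(flags$scenario, ",", fixed = TRUE)[[1]]
    if (length(parts) != 2)
      stop("--scenario must be <calcium_ordering>,<deactivation_unbinding>")
    raw$scenario$calcium_ordering <- parts[1]
    raw$scenario$deactivation_unbinding <- parts[2]
  }
  cfg <- build_config(raw)
  proto <- canonical_protocols(cfg$protocol)
  xb <- config_crossbridge(cfg)
  trace <- run_protocol(proto, cfg$scenario, cfg$iso, cfg$unfold, xb,
                        cfg$ensemble, seed = cfg$ensemble$seed,
                        variant = cfg$variant,
                        rupture_force = cfg$rupture_force)
  write_trace(trace, flags$out)
  mpath <- paste0(flags$out, ".manifest.json")
  write_manifest(run_manifest(cfg, cfg$ensemble$seed, trace, flags$out),
                 mpath)
  message("wrote ", flags$out, " and ", mpath)
  0L
}

cli_calibrate <- function(flags) {
  if (is.null(flags$data) || is.null(flags$out))
    stop("calibrate needs --data and --out")
  cfg <- if (!is.null(flags$config)) load_config(flags$config)
         else build_config(default_config())
  df <- utils::read.csv(flags$data, stringsAsFactors = FALSE)
  need <- c("sarcomere_um", "stress_nN_um2")
  if (!all(need %in% names(df)))
    stop("calibration CSV needs columns ", paste(need, collapse = ", "))
  if (!"phase" %in% names(df)) {
    turn <- which.max(df$sarcomere_um)
    df$phase <- rep(c("stretch", "shorten"),
                    c(turn, nrow(df) - turn))
  }
  ds <- classify_regions(df)
  r1 <- fit_region1(ds, cfg$iso,
                    strands_per_um2 = cfg$ensemble$strands_per_um2)
  r4 <- fit_region4(ds, r1,
                    strands_per_um2 = cfg$ensemble$strands_per_um2)
  report <- paste0(flags$out, ".txt")
  con <- file(report, "w"); on.exit(close(con), add = TRUE)
  sink(con); print(r4); sink()
  frag <- cfg$raw$titin
  frag$folded_pl <- r4$folded_pl
  frag$pevk_pl <- r4$pevk_pl
  frag$pevk_modulus <- r4$pevk_modulus
  frag$unfolded_pl <- r4$unfolded_pl
  save_config(list(titin = frag), paste0(flags$out, "_config.json"))
  message("wrote ", report, " and ", paste0(flags$out, "_config.json"))
  0L
}

cli_synth <- function(flags) {
  if (is.null(flags$out)) stop("synth-data needs --out")
  seed <- if (is.null(flags$seed)) 1L else as.integer(flags$seed)
  n <- if (is.null(flags[["n-samples"]])) 100L
       else as.integer(flags[["n-samples"]])
  noise <- if (is.null(flags$noise)) 0.02 else as.numeric(flags$noise)
  ds <- synthesize_hysteresis(n_samples = n, noise_sd = noise, seed = seed)
  utils::write.csv(as.data.frame(ds), flags$out, row.names = FALSE,
                   quote = FALSE)
  message("wrote ", flags$out)
  0L
}
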