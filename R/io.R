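#' Read a configuration from JSON
#'
#' Dispatches on the file's `"type"` field: `"scenario"` builds a
#' [scenario_config()], `"continuum"` a [continuum_params()], `"averaged"`
#' an [averaged_params()]. Unknown keys are rejected with a message naming
#' them; omitted keys take the documented defaults, which the returned
#' object echoes.
#'
#' @param path Path to a JSON file.
#' @return A validated configuration object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  type <- raw$type %||% "scenario"
  raw$type <- NULL
  ctor <- switch(type,
                 scenario = scenario_config,
                 continuum = continuum_params,
                 averaged = averaged_params,
                 stop("unknown config type: ", type, call. = FALSE))
  known <- names(formals(ctor))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown key(s) in ", basename(path), ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (!is.null(raw$food_sources) && type %in% c("scenario", "continuum")) {
    fs <- raw$food_sources
    raw$food_sources <- if (is.matrix(fs))
      lapply(seq_len(nrow(fs)), function(k) fs[k, ]) else as.list(fs)
  }
  do.call(ctor, raw)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a configuration to JSON
#'
#' Writes all user-settable fields (derived/cached fields are dropped), so
#' a round trip through [read_config()] reproduces the object.
#'
#' @param config A `scenario_config`, `continuum_params` or
#'   `averaged_params`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  type <- switch(class(config)[1],
                 scenario_config = "scenario",
                 continuum_params = "continuum",
                 averaged_params = "averaged",
                 stop("not a configuration object", call. = FALSE))
  ctor <- switch(type, scenario = scenario_config,
                 continuum = continuum_params, averaged = averaged_params)
  fields <- unclass(config)[intersect(names(formals(ctor)),
                                      names(unclass(config)))]
  if (!is.null(fields$food_sources)) {
    fm <- fields$food_sources
    fields$food_sources <- lapply(seq_len(nrow(fm)), function(k)
      unname(fm[k, ]))
  }
  jsonlite::write_json(c(list(type = type), fields), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write / read a lattice snapshot as CSV
#'
#' One snapshot becomes two plain CSV files in `dir`: `ants_<time>.csv`
#' (columns `id`, `x`, `y`, `mode`) and `field_<time>.csv` (long form `x`,
#' `y`, `c`). Floating point is written with full precision so the round
#' trip is lossless.
#'
#' @param snapshot One element of a `lattice_run`'s `snapshots` list.
#' @param dir Output directory (created if needed).
#' @return (write) The two file paths, invisibly; (read) the snapshot list.
#' @export
write_snapshot <- function(snapshot, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  t <- snapshot$time
  fa <- file.path(dir, sprintf("ants_%d.csv", t))
  ff <- file.path(dir, sprintf("field_%d.csv", t))
  ok <- FALSE
  on.exit(if (!ok) unlink(c(fa, ff)))
  utils::write.csv(snapshot$ants, fa, row.names = FALSE)
  M <- nrow(snapshot$field); N <- ncol(snapshot$field)
  grid <- tidyr::expand_grid(x = seq_len(M), y = seq_len(N))
  fld <- data.frame(x = grid$x, y = grid$y,
                    c = format(snapshot$field[cbind(grid$x, grid$y)],
                               digits = 17, trim = TRUE, scientific = TRUE))
  utils::write.csv(fld, ff, row.names = FALSE, quote = FALSE)
  ok <- TRUE
  invisible(c(fa, ff))
}

#' @rdname write_snapshot
#' @param time Snapshot time to read back.
#' @export
read_snapshot <- function(dir, time) {
  fa <- file.path(dir, sprintf("ants_%d.csv", time))
  ff <- file.path(dir, sprintf("field_%d.csv", time))
  if (!file.exists(fa) || !file.exists(ff))
    stop("no snapshot at time ", time, " in ", dir, call. = FALSE)
  ants <- tibble::as_tibble(utils::read.csv(fa, stringsAsFactors = FALSE))
  fld <- utils::read.csv(ff)
  M <- max(fld$x); N <- max(fld$y)
  field <- matrix(0, M, N)
  field[cbind(fld$x, fld$y)] <- as.numeric(fld$c)
  list(time = time, ants = ants, field = field)
}

#' Write a whole lattice run with a manifest
#'
#' Saves the configuration (JSON), every snapshot (CSV pairs) and a run
#' manifest (`manifest.json`: seed, config hash, timestamps, discovery
#' time, inventory of every file written). The manifest is written even if
#' a snapshot write fails part-way.
#'
#' @param run A `lattice_run`.
#' @param dir Output directory.
#' @return The manifest path, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  started <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  cfg_path <- file.path(dir, "config.json")
  files <- character(0)
  status <- "ok"
  tryCatch({
    write_config(run$config, cfg_path)
    files <- "config.json"
    for (s in run$snapshots) {
      paths <- write_snapshot(s, dir)
      files <- c(files, basename(paths))
    }
  }, error = function(e) status <<- conditionMessage(e))
  manifest <- list(
    seed = run$config$seed,
    config_hash = unname(tools::md5sum(cfg_path)),
    code_version = as.character(utils::packageVersion("anttrails")),
    started = started,
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    status = status,
    discovery_time = if (is.finite(run$discovery_time))
      run$discovery_time else "never",
    files = files)
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (status != "ok") stop("run output incomplete: ", status, call. = FALSE)
  invisible(mpath)
}
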