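# Known config keys per section; unknown keys are rejected by name.
.config_schema <- list(
  top = c("workflow", "input", "output_dir", "csa", "dda", "dia",
          "search", "aggregate", "fixtures", "threads", "seed",
          "log_level"),
  input = c("scans", "peaklists", "aligned", "library", "query",
            "targets"),
  aggregate = c("rt_window", "entsim_min", "fragment_mz_tol",
                "tanimoto_min", "quorum"),
  fixtures = c("preset", "n_compounds", "rt_range", "scan_interval",
               "n_noise_peaks")
)

.check_keys <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown)) {
    stop("unknown configuration key(s) in ", where, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
}

#' Load and validate a run configuration
#'
#' The configuration is a plain-text JSON file with a `workflow` name, an
#' `input` section of paths, and optional per-workflow parameter sections
#' (`csa`, `dda`, `dia`, `search`, `aggregate`).  Unknown keys are
#' rejected by name; parameter values are range-checked through the same
#' constructors the API uses, so an out-of-range value fails validation
#' with the offending parameter named.
#'
#' @param path JSON config path.
#' @return a validated `run_config` list with all defaults filled.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  .check_keys(raw, .config_schema$top, "top level")
  wf <- raw$workflow
  if (is.null(wf) || !wf %in% c("csa", "dda", "dia", "aggregate",
                                "build-db", "search", "summarize",
                                "fixtures")) {
    stop("config must name a workflow: csa, dda, dia, aggregate, ",
         "build-db, search, summarize or fixtures", call. = FALSE)
  }
  if (!is.null(raw$input)) .check_keys(raw$input, .config_schema$input,
                                       "input")
  if (!is.null(raw$aggregate)) .check_keys(raw$aggregate,
                                           .config_schema$aggregate,
                                           "aggregate")
  make <- function(section, ctor) {
    args <- raw[[section]]
    if (is.null(args)) args <- list()
    .check_keys(args, names(formals(ctor)), section)
    tryCatch(do.call(ctor, args), error = function(e) {
      stop("invalid ", section, " parameters: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  cfg <- list(
    workflow = wf,
    input = as.list(raw$input),
    output_dir = if (is.null(raw$output_dir)) "." else raw$output_dir,
    csa = make("csa", csa_params),
    dda = make("dda", dda_params),
    dia = make("dia", dia_params),
    search = make("search", search_params),
    aggregate = utils::modifyList(
      list(rt_window = 0.1, entsim_min = 0.75, fragment_mz_tol = 0.01,
           tanimoto_min = 0.5, quorum = 0.5),
      as.list(raw$aggregate)),
    fixtures = as.list(raw$fixtures),
    threads = if (is.null(raw$threads)) 1L else as.integer(raw$threads),
    seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed),
    log_level = if (is.null(raw$log_level)) "info" else raw$log_level
  )
  stopifnot(cfg$threads >= 1L)
  class(cfg) <- "run_config"
  cfg
}

.manifest <- function(cfg, files, statuses, counts) {
  list(
    package = jsonlite::unbox("mscsa"),
    version = jsonlite::unbox(
      as.character(utils::packageVersion("mscsa"))),
    workflow = jsonlite::unbox(cfg$workflow),
    seed = jsonlite::unbox(cfg$seed),
    threads = jsonlite::unbox(cfg$threads),
    config = rapply(unclass(cfg)[c("csa", "dda", "dia", "search",
                                   "aggregate")],
                    function(v) v, how = "unlist"),
    files = as.character(files),
    status = as.character(statuses),
    counts = as.integer(counts)
  )
}

# run one file of the csa/dda/dia workflows; returns an output path
.run_one_file <- function(cfg, i) {
  scans <- read_scans(cfg$input$scans[i])
  stem <- tools::file_path_sans_ext(basename(cfg$input$scans[i]))
  out <- file.path(cfg$output_dir, paste0(stem, "_", cfg$workflow, ".msp"))
  spectra <- switch(cfg$workflow,
    csa = {
      peaks <- read_peaklist(cfg$input$peaklists[i])
      aligned <- if (!is.null(cfg$input$aligned))
        read_aligned(cfg$input$aligned) else NULL
      clusters_to_spectra(
        deconvolute_file(scans, peaks, aligned, cfg$csa, file_id = stem))
    },
    dda = extract_dda(scans, read_peaklist(cfg$input$peaklists[i]),
                      cfg$dda),
    dia = extract_dia(scans, read_peaklist(cfg$input$peaklists[i]),
                      cfg$dia)
  )
  if (!length(spectra)) {
    return(list(path = NA_character_, n = 0L))
  }
  write_msp(spectra, out)
  list(path = out, n = length(spectra))
}

#' Run a configured workflow
#'
#' Dispatches to the named workflow over all input files.  Per-file
#' failures are logged and skipped; the run fails (nonzero status) only
#' when every file fails.  With `threads > 1` files are processed in
#' parallel with per-file isolation, so results are independent of the
#' worker count.  A JSON manifest (configuration snapshot, package
#' version, file list, per-file status and output counts) is written to
#' the output directory.
#'
#' @param cfg a [load_config()] result.
#' @return invisibly, a list with `status` (0 = success), `outputs`,
#'   `manifest_path`.
#' @export
run_workflow <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  if (!cfg$workflow %in% c("csa", "dda", "dia")) {
    stop("run_workflow drives the per-file workflows (csa, dda, dia); ",
         "call the ", cfg$workflow, " functions directly", call. = FALSE)
  }
  files <- cfg$input$scans
  if (is.null(files) || !length(files)) {
    stop("config names no input scan files", call. = FALSE)
  }
  worker <- function(i) {
    tryCatch(c(.run_one_file(cfg, i), list(ok = TRUE, err = NA_character_)),
             error = function(e) list(path = NA_character_, n = 0L,
                                      ok = FALSE,
                                      err = conditionMessage(e)))
  }
  results <- if (cfg$threads > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(seq_along(files), worker,
                       mc.cores = cfg$threads)
  } else {
    lapply(seq_along(files), worker)
  }
  ok <- vapply(results, `[[`, logical(1), "ok")
  for (i in which(!ok)) {
    message("file failed: ", files[i], " (", results[[i]]$err, ")")
  }
  manifest <- .manifest(cfg, files,
                        ifelse(ok, "ok", "failed"),
                        vapply(results, `[[`, integer(1), "n"))
  mpath <- file.path(cfg$output_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, digits = NA, pretty = TRUE)
  invisible(list(status = if (any(ok)) 0L else 1L,
                 outputs = vapply(results, `[[`, character(1), "path"),
                 manifest_path = mpath))
}
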