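trial_required_cols <- c("subject_id", "group", "session", "block", "trial",
                         "role", "endpoint_cm", "score", "mistrial")

#' Read a trial table from CSV
#'
#' Reads the package's CSV dialect (UTF-8, `.` decimal separator, header
#' `subject_id, group, session, block, trial, role, endpoint_cm, score,
#' mistrial`). Columns are matched by name, so column order does not matter,
#' and unknown columns are preserved untouched.
#'
#' @param path Path to a CSV file.
#' @return A tibble of trial records.
#' @export
read_trial_table <- function(path) {
  # doubles are re-parsed with base R's correctly-rounded parser so that
  # read(write(x)) reproduces every value bit for bit
  tab <- readr::read_csv(
    path, show_col_types = FALSE,
    col_types = readr::cols(.default = readr::col_character()))
  missing_cols <- setdiff(trial_required_cols, names(tab))
  if (length(missing_cols) > 0) {
    stop("trial table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  parse_num <- function(x, what) {
    out <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(out) & !is.na(x))
    if (length(bad) > 0) {
      stop(sprintf("non-numeric %s at data row(s): %s", what,
                   paste(utils::head(bad, 5), collapse = ", ")),
           call. = FALSE)
    }
    out
  }
  tab |>
    dplyr::mutate(block = as.integer(.data$block),
                  trial = as.integer(.data$trial),
                  endpoint_cm = parse_num(.data$endpoint_cm, "endpoint_cm"),
                  score = parse_num(.data$score, "score"),
                  mistrial = as.logical(.data$mistrial)) |>
    dplyr::relocate(dplyr::all_of(trial_required_cols))
}

#' Write a trial table to CSV
#'
#' Writes the package CSV dialect. Endpoints are carried at 4-decimal (0.1
#' micrometre) precision throughout the package, so `read(write(x))`
#' round-trips exactly.
#'
#' @param trials A trial table.
#' @param path Output path.
#' @return `trials`, invisibly.
#' @export
write_trial_table <- function(trials, path) {
  missing_cols <- setdiff(trial_required_cols, names(trials))
  if (length(missing_cols) > 0) {
    stop("trial table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- dplyr::mutate(trials,
                       endpoint_cm = sprintf("%.4f", .data$endpoint_cm))
  readr::write_csv(out, path)
  invisible(trials)
}

#' Assemble a run configuration
#'
#' A run configuration captures everything needed to reproduce a simulated
#' session: the protocol (preset name or session list and alpha schedule),
#' the gain function, the subject model, the analysis options and the seed.
#' It serialises to YAML and carries a content hash for provenance.
#'
#' @param preset Protocol preset name (see [protocol()]).
#' @param n_subjects Cohort size.
#' @param seed Integer root seed.
#' @param model A [subject_model()].
#' @param gf A [gain_function()].
#' @param analysis Named list of analysis options (baseline window, split
#'   point, bootstrap repetitions, tie rules, ...).
#' @return A list of class `run_config`.
#' @export
run_config <- function(preset = "exp1b", n_subjects = 8, seed = 1L,
                       model = subject_model(), gf = gain_function(),
                       analysis = list(baseline = "baseline_session",
                                       split_at = 0, n_boot = 50000,
                                       tie = "geq", win_tie = "half")) {
  cfg <- list(
    protocol = preset, n_subjects = as.integer(n_subjects),
    seed = as.integer(seed),
    gain_function = list(boundary_cm = gf$boundary, max_score = gf$max_score,
                         dead_zone_cm = gf$dead_zone, shape = gf$shape,
                         knots = if (gf$shape == "tabulated")
                           as.data.frame(gf$knots[-1, ]) else NULL),
    subject_model = unclass(model),
    analysis = analysis)
  cfg$hash <- rlang::hash(cfg)
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param cfg A `run_config`.
#' @param path File path for the YAML serialisation.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(cfg)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  stored <- cfg$hash
  cfg$hash <- NULL
  cfg$hash <- rlang::hash(cfg)
  if (!is.null(stored) && !identical(stored, cfg$hash)) {
    warning("config hash mismatch: file was edited after it was written.",
            call. = FALSE)
  }
  class(cfg) <- "run_config"
  cfg
}

#' Materialise the objects described by a run configuration
#'
#' @param cfg A `run_config` (or path to one).
#' @return A list with `protocol`, `model`, `gf`, `seed`, `n_subjects`,
#'   `analysis`, `hash`.
#' @export
instantiate_config <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  g <- cfg$gain_function
  gf <- if (identical(g$shape, "tabulated")) {
    gain_function(g$boundary_cm, g$max_score, g$dead_zone_cm, "tabulated",
                  knots = as.data.frame(g$knots))
  } else {
    gain_function(g$boundary_cm %||% 30, g$max_score %||% 100,
                  g$dead_zone_cm %||% 7)
  }
  sm <- cfg$subject_model
  model <- do.call(subject_model, sm[names(sm) %in% names(formals(subject_model))])
  list(protocol = protocol(cfg$protocol), model = model, gf = gf,
       seed = cfg$seed, n_subjects = cfg$n_subjects,
       analysis = cfg$analysis, hash = cfg$hash)
}
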