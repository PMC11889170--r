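# CSV time-series format, YAML run configuration, JSON results, fixtures.
#
# Time-series CSV: header `experiment,time,<species...>`, one row per time
# point, empty cells = unobserved.  Metadata (units, y0, mask,
# normalization) travels in leading `#` comment lines so a write/read round
# trip is lossless.

#' Write a dataset to CSV
#'
#' @param ds a `rom_dataset`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_timeseries_csv <- function(ds, path) {
  stopifnot(inherits(ds, "rom_dataset"))
  con <- file(path, "w")
  on.exit(close(con))
  meta <- c(
    "# concentration_unit: uM",
    "# time_unit: arbitrary",
    paste0("# y0: ", paste(
      format(vapply(ds$experiments, `[[`, numeric(1), "y0"), digits = 17,
             trim = TRUE), collapse = ",")),
    paste0("# mask: ", ds$mask),
    paste0("# normalization: ", ds$normalization$mode),
    if (!is.null(ds$normalization$scales))
      paste0("# scales: ", paste(
        format(ds$normalization$scales, digits = 17, trim = TRUE),
        collapse = ",")),
    if (!is.null(ds$model_id)) paste0("# model_id: ", ds$model_id),
    paste0("# t_end: ", format(ds$t_end, digits = 17)),
    paste0("# noise_sd: ", format(ds$noise_sd, digits = 17)))
  writeLines(meta, con)
  df <- as.data.frame(ds)
  utils::write.table(
    cbind(df[1:2], lapply(df[-(1:2)], format, digits = 17, trim = TRUE)),
    con, sep = ",", row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a dataset from CSV
#'
#' Parses the time-series format written by
#' \code{\link{write_timeseries_csv}} (metadata comment lines are optional
#' for externally produced files).  Missing cells are treated as
#' unobserved.
#'
#' @param path CSV file with header `experiment,time,<species...>`.
#' @return a `rom_dataset`.
#' @export
read_timeseries_csv <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines)
  meta <- list()
  for (l in lines[meta_lines]) {
    kv <- sub("^#\\s*", "", l)
    key <- sub(":.*$", "", kv)
    val <- trimws(sub("^[^:]*:", "", kv))
    meta[[key]] <- val
  }
  body_start <- if (length(meta_lines)) max(meta_lines) + 1L else 1L
  df <- utils::read.csv(text = paste(lines[body_start:length(lines)],
                                     collapse = "\n"),
                        stringsAsFactors = FALSE)
  need <- c("experiment", "time")
  if (!all(need %in% names(df)))
    stop("parse error: header must start with 'experiment,time'",
         call. = FALSE)
  species <- setdiff(names(df), need)
  bad <- setdiff(species, .valid_bins)
  if (length(bad))
    stop("parse error: unknown species token(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (!length(species)) stop("parse error: no species columns", call. = FALSE)
  exp_ids <- unique(df$experiment)
  y0 <- if (!is.null(meta$y0)) as.numeric(strsplit(meta$y0, ",")[[1]])
        else rep(NA_real_, length(exp_ids))
  experiments <- lapply(seq_along(exp_ids), function(i) {
    sub <- df[df$experiment == exp_ids[i], , drop = FALSE]
    dt <- diff(sub$time)
    if (any(dt <= 0)) {
      row_in_sub <- which(dt <= 0)[1] + 1L
      line_no <- body_start + which(df$experiment == exp_ids[i])[row_in_sub]
      stop("parse error at line ", line_no, ": ",
           if (any(dt == 0)) "duplicate" else "non-monotone",
           " time within experiment ", exp_ids[i], call. = FALSE)
    }
    obs <- as.matrix(sub[, species, drop = FALSE])
    list(id = as.character(exp_ids[i]), y0 = y0[i], times = sub$time,
         observed = obs)
  })
  scales <- if (!is.null(meta$scales)) {
    v <- strsplit(meta$scales, ",")[[1]]
    v[v == "NA"] <- NA_character_
    as.numeric(v)
  } else NULL
  structure(list(
    experiments = experiments, species = species,
    model_id = if (!is.null(meta$model_id)) as.integer(meta$model_id)
               else NULL,
    mask = if (!is.null(meta$mask)) meta$mask else "all",
    n_obs = sum(vapply(experiments,
                       function(e) sum(!is.na(e$observed)), numeric(1))),
    normalization = list(
      mode = if (!is.null(meta$normalization)) meta$normalization
             else "none",
      scales = scales),
    t_end = if (!is.null(meta$t_end)) as.numeric(meta$t_end)
            else max(experiments[[1]]$times),
    noise_sd = if (!is.null(meta$noise_sd)) as.numeric(meta$noise_sd)
               else NA_real_,
    seed = NULL
  ), class = "rom_dataset")
}

.default_run_config <- function() list(
  model = "auto",
  orders = list(n = 2, m = 2, s = 2, c = 2, p = 2),
  pinn = list(hidden_layers = 3, width = 6, activation = "tanh",
              epochs = 35000, learning_rate = 0.001, optimizer = "adam",
              seed = 1, physics_mode = "collocation",
              loss_weights = c(1, 1)),
  generator = list(y0 = c(1, 1.4, 2, 3, 5), n_points = 200, t_end = 100,
                   noise_sd = 0, seed = 1, mask = "all"),
  reduction = list(improvement_threshold = 0.005,
                   identifiability = "advisory", engine = "pinn"),
  output_dir = ".")

#' Read a YAML run configuration
#'
#' Loads a run configuration and fills every unset field with its default,
#' so the returned object is fully explicit.
#'
#' @param path YAML file (or `NULL` for pure defaults).
#' @return nested list with all defaults resolved.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- .default_run_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, user)
  }
  cfg
}

#' Write a run configuration to YAML
#'
#' @param cfg configuration list.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Serialize a fit result to JSON
#'
#' Writes the learned rates (both namings), fit error, configuration, seed
#' and (thinned) training histories.
#'
#' @param fit a `rom_fit`.
#' @param path output JSON file.
#' @param thin keep every `thin`-th epoch of the histories (default: the
#'   fit config's `thin`).
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path, thin = NULL) {
  stopifnot(inherits(fit, "rom_fit"))
  if (is.null(thin)) thin <- fit$config$thin
  hist <- fit$history
  if (!is.null(hist) && thin > 1)
    hist <- hist[seq(1, nrow(hist), by = thin), , drop = FALSE]
  out <- list(model_id = fit$model$model_id, engine = fit$engine,
              params = as.list(fit$params),
              alpha_beta = as.list(fit$alpha_beta),
              final_mae = fit$final_mae,
              config = unclass(fit$config),
              seed = fit$config$seed,
              history = hist)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Canned datasets used by the test suite
#'
#' Small deterministic datasets: `model1_clean` (noiseless Model 1,
#' all bins observed), `model7_noisy` (Model 7, sd 0.02),
#' `fibril_only` (Model 3, terminal bin only), and `tiny_3pt`
#' (three time points, hand-checkable).
#'
#' @param name fixture name.
#' @return a `rom_dataset`.
#' @export
make_fixture <- function(name = c("model1_clean", "model7_noisy",
                                  "fibril_only", "tiny_3pt")) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% c("model1_clean", "model7_noisy", "fibril_only", "tiny_3pt"))
    stop("unknown fixture name: ", paste(name, collapse = ","),
         call. = FALSE)
  switch(name,
    model1_clean = generate_dataset(
      rom_model(1), c(a1 = 0.1, a2 = 0.05), y0 = c(1, 1.4, 2, 3, 5),
      n_points = 60, t_end = 100, noise_sd = 0, seed = 101),
    model7_noisy = generate_dataset(
      rom_model(7), c(a1 = 0.05, a2 = 0.1, a3 = 0.05, a4 = 0.1,
                      a5 = 0.05, a6 = 0.1),
      y0 = c(1, 1.4, 2, 3, 5), n_points = 100, t_end = 100,
      noise_sd = 0.02, seed = 707),
    fibril_only = generate_dataset(
      rom_model(3), c(a1 = 0.05, a2 = 0.1, a3 = 0.05, a4 = 0.1),
      y0 = c(1, 1.4, 2, 3, 5), n_points = 100, t_end = 100,
      noise_sd = 0.01, seed = 303, mask = "fibril_only"),
    tiny_3pt = generate_dataset(
      rom_model(1), c(a1 = 0.1, a2 = 0.05), y0 = 2,
      n_points = 3, t_end = 10, noise_sd = 0, seed = 3))
}
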