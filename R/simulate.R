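# Forward integration and synthetic multi-experiment datasets.

#' Integrate a reduced-order model
#'
#' Deterministic forward solution of a model's ODE system with
#' \code{\link[deSolve]{ode}} (lsoda).
#'
#' @param model a `rom_model`.
#' @param params named rate vector for the model.
#' @param y0 initial state (one concentration per bin, micromolar).
#' @param times numeric vector of output times, strictly increasing.
#' @param rtol,atol solver tolerances.
#' @param method deSolve integration method (default `"lsoda"`).
#' @param maxsteps solver step budget per output interval; integration that
#'   exhausts it (e.g. blow-up under unphysical rates) raises an error
#'   carrying the failure time.
#' @return a `rom_trajectory`: list with `times`, `states` (matrix, one row
#'   per time point) and the model id.
#' @export
rom_integrate <- function(model, params, y0, times,
                          rtol = 1e-8, atol = 1e-10, method = "lsoda",
                          maxsteps = 5000) {
  stopifnot(inherits(model, "rom_model"))
  params <- .check_params(model, params)
  if (length(y0) != model$n_species)
    stop("y0 has length ", length(y0), "; model has ", model$n_species,
         " species", call. = FALSE)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing",
                                  call. = FALSE)
  if (!all(is.finite(y0)) || !all(is.finite(params)))
    stop("non-finite inputs to rom_integrate", call. = FALSE)
  st <- model$steps
  nstep <- nrow(st)
  parms <- numeric(13)  # layout documented in src/ode_chain.c
  parms[1] <- nstep
  parms[1 + seq_len(nstep)] <- st$order
  parms[1 + nstep + seq_len(nstep)] <- unname(params[st$fwd_param])
  parms[1 + 2 * nstep + seq_len(nstep)] <- unname(params[st$bwd_param])
  sol <- deSolve::ode(y = unname(y0), times = times, func = "rom_derivs",
                      parms = parms, dllname = "romkin",
                      initfunc = "rom_initmod",
                      method = method, rtol = rtol, atol = atol,
                      maxsteps = maxsteps)
  n_ok <- nrow(sol)
  if (n_ok < length(times) || any(!is.finite(sol[, -1])))
    stop("integration failed at t = ",
         if (n_ok >= 1) signif(sol[n_ok, 1], 6) else times[1],
         " (model ", model$model_id, ")", call. = FALSE)
  states <- unname(sol[, -1, drop = FALSE])
  colnames(states) <- model$species$name
  structure(list(times = times, states = states, model_id = model$model_id,
                 species = model$species$name),
            class = "rom_trajectory")
}

#' @export
print.rom_trajectory <- function(x, ...) {
  cat("rom_trajectory: model ", x$model_id, ", ", length(x$times),
      " time points in [", signif(min(x$times), 4), ", ",
      signif(max(x$times), 4), "], bins ",
      paste(x$species, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Generate a synthetic multi-experiment dataset
#'
#' Emulates the study design behind the fitting experiments: several
#' aggregation time courses started from different initial monomer
#' concentrations, observed on a uniform time grid with additive Gaussian
#' noise.  All initial mass is placed in the smallest bin; other bins start
#' at zero.
#'
#' @param model a `rom_model` (the generating kinetics).
#' @param params named rate vector.
#' @param y0 initial monomer concentrations, one per experiment (micromolar);
#'   default `c(1, 1.4, 2, 3, 5)`.
#' @param n_points number of uniformly spaced observation times (default 200).
#' @param t_end end of the observation window (time units; default 100).
#' @param noise_sd standard deviation of additive Gaussian observation noise.
#' @param seed integer seed making the noise reproducible.
#' @param mask observability: `"all"` (every bin observed) or
#'   `"fibril_only"` (only the terminal fibril bin, as in fluorescence data).
#' @param nonneg_obs truncate noisy observations at zero.
#' @return an object of class `rom_dataset`.
#' @export
generate_dataset <- function(model, params, y0 = c(1, 1.4, 2, 3, 5),
                             n_points = 200, t_end = 100, noise_sd = 0,
                             seed = NULL, mask = c("all", "fibril_only"),
                             nonneg_obs = FALSE) {
  stopifnot(inherits(model, "rom_model"))
  mask <- match.arg(mask)
  if (n_points < 2) stop("n_points must be >= 2", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  times <- seq(0, t_end, length.out = n_points)
  nsp <- model$n_species
  observed_cols <- if (mask == "all") seq_len(nsp) else nsp
  experiments <- lapply(seq_along(y0), function(i) {
    init <- c(y0[i], rep(0, nsp - 1L))
    traj <- rom_integrate(model, params, init, times)
    obs <- traj$states
    if (noise_sd > 0)
      obs <- obs + matrix(stats::rnorm(length(obs), 0, noise_sd), nrow(obs))
    if (nonneg_obs) obs <- pmax(obs, 0)
    obs[, setdiff(seq_len(nsp), observed_cols)] <- NA_real_
    list(id = paste0("exp", i), y0 = y0[i], times = times, observed = obs)
  })
  structure(list(
    experiments = experiments,
    species = model$species$name,
    model_id = model$model_id,
    mask = mask,
    n_obs = sum(vapply(experiments,
                       function(e) sum(!is.na(e$observed)), numeric(1))),
    normalization = list(mode = "none", scales = NULL),
    t_end = t_end, noise_sd = noise_sd, seed = seed
  ), class = "rom_dataset")
}

#' @export
print.rom_dataset <- function(x, ...) {
  cat("rom_dataset: ", length(x$experiments), " experiments, bins ",
      paste(x$species, collapse = ", "), "\n", sep = "")
  cat("  y0 (uM): ",
      paste(vapply(x$experiments, `[[`, numeric(1), "y0"), collapse = ", "),
      "; ", length(x$experiments[[1]]$times), " time points; n_obs = ",
      x$n_obs, "\n", sep = "")
  cat("  mask: ", x$mask, "; normalization: ", x$normalization$mode,
      "; noise sd: ", x$noise_sd, "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.rom_dataset <- function(x, ...) {
  do.call(rbind, lapply(x$experiments, function(e) {
    df <- data.frame(experiment = e$id, time = e$times)
    obs <- as.data.frame(e$observed)
    names(obs) <- x$species
    cbind(df, obs)
  }))
}

#' Normalize a dataset
#'
#' Scales observations so the maximum of each normalization unit is exactly
#' one.  `per_species_max` scales every species column by its own maximum
#' over all experiments; `global_max` divides everything by the single
#' largest observation (preserving relative amplitudes across species and
#' experiments).  Scale factors are stored for exact inversion by
#' \code{\link{denormalize_dataset}}.
#'
#' @param ds a `rom_dataset` with `normalization$mode == "none"`.
#' @param mode `"per_species_max"` or `"global_max"`.
#' @return the normalized dataset.
#' @export
normalize_dataset <- function(ds, mode = c("per_species_max", "global_max")) {
  stopifnot(inherits(ds, "rom_dataset"))
  mode <- match.arg(mode)
  if (ds$normalization$mode != "none")
    stop("dataset is already normalized (", ds$normalization$mode, ")",
         call. = FALSE)
  all_obs <- do.call(rbind, lapply(ds$experiments, `[[`, "observed"))
  if (mode == "per_species_max") {
    scales <- apply(all_obs, 2, function(col) {
      if (all(is.na(col))) return(NA_real_)
      max(col, na.rm = TRUE)
    })
    bad <- which(!is.na(scales) & scales == 0)
    if (length(bad))
      stop("cannot normalize all-zero series: ",
           paste(ds$species[bad], collapse = ", "), call. = FALSE)
    div <- ifelse(is.na(scales), 1, scales)
  } else {
    g <- max(all_obs, na.rm = TRUE)
    if (!is.finite(g) || g == 0)
      stop("cannot normalize: no nonzero observation", call. = FALSE)
    scales <- g
    div <- rep(g, ncol(all_obs))
  }
  ds$experiments <- lapply(ds$experiments, function(e) {
    e$observed <- sweep(e$observed, 2, div, "/")
    e
  })
  ds$normalization <- list(mode = mode, scales = scales)
  ds
}

#' Undo dataset normalization
#'
#' @param ds a normalized `rom_dataset`.
#' @return the dataset on its original concentration scale.
#' @export
denormalize_dataset <- function(ds) {
  stopifnot(inherits(ds, "rom_dataset"))
  if (ds$normalization$mode == "none") return(ds)
  scales <- ds$normalization$scales
  div <- if (length(scales) == 1L) rep(scales, length(ds$species))
         else ifelse(is.na(scales), 1, scales)
  ds$experiments <- lapply(ds$experiments, function(e) {
    e$observed <- sweep(e$observed, 2, div, "*")
    e
  })
  ds$normalization <- list(mode = "none", scales = NULL)
  ds
}

#' Pool an observed dataset onto a coarser model's bins
#'
#' Applies the monomer-equivalent pooling of \code{\link{collapse_trajectory}}
#' to every experiment's observations, so data recorded on a finer binning
#' can be fitted (and normalized) under a coarser candidate model.  All
#' constituent bins of a coarse bin must be observed; otherwise the pooled
#' column is marked unobserved.
#'
#' @param ds a `rom_dataset` whose species match `fine`.
#' @param fine,coarse `rom_model` objects with a lattice path coarse -> fine.
#' @return a `rom_dataset` on the coarse model's bins.
#' @export
rebin_dataset <- function(ds, fine, coarse) {
  stopifnot(inherits(ds, "rom_dataset"))
  if (!identical(ds$species, fine$species$name))
    stop("dataset species do not match the fine model", call. = FALSE)
  ds$experiments <- lapply(ds$experiments, function(e) {
    obs <- e$observed
    nas <- is.na(obs)
    obs[nas] <- 0
    pooled <- collapse_trajectory(obs, fine, coarse)
    # a coarse bin is observed only if all its members were
    fine_spans <- .bin_spans(fine)
    coarse_spans <- .bin_spans(coarse)
    for (j in seq_len(coarse$n_species)) {
      members <- which(vapply(fine_spans, function(sp)
        all(sp %in% coarse_spans[[j]]), logical(1)))
      miss <- rowSums(nas[, members, drop = FALSE]) > 0
      pooled[miss, j] <- NA_real_
    }
    e$observed <- pooled
    e
  })
  ds$species <- coarse$species$name
  ds$model_id <- coarse$model_id
  ds$n_obs <- sum(vapply(ds$experiments,
                         function(e) sum(!is.na(e$observed)), numeric(1)))
  ds
}
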