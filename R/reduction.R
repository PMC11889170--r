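# Automatic reaction-order reduction: greedy search over the model lattice.

#' Configuration for the reduction workflow
#'
#' @param improvement_threshold minimum absolute MAE improvement (in the
#'   dataset's units; default 0.005, intended for normalized data) a finer
#'   model must deliver to displace the current one.
#' @param identifiability `"advisory"` (profiles of the newly introduced
#'   rates are computed and logged but do not veto; default), `"strict"`
#'   (non-identifiable successors are inadmissible), or `"off"`.
#' @param engine fitting engine passed to \code{\link{fit_rom}}.
#' @param pinn a \code{\link{pinn_config}} for the per-model fits.
#' @param polish refine each candidate's rates by a short Levenberg-
#'   Marquardt pass warm-started from the neural estimate, and take the
#'   decision metric from the integrated-ODE residual at those rates
#'   (default TRUE).  The surrogate's own residual cannot arbitrate between
#'   mechanisms -- given enough training any candidate's network tracks the
#'   data -- so model selection is scored against trajectories the
#'   candidate ODEs can actually produce.
#' @param greedy_first take the first improving successor instead of
#'   fitting all successors and taking the best (default FALSE).
#' @param profile_n_grid grid size for the identifiability profiles.
#' @param penalty `"none"` (default) or `"aic"`: with `"aic"` the
#'   improvement criterion compares \eqn{2k + n \log(SSE/n)} instead of raw
#'   MAE.
#' @return list of class `reduction_config`.
#' @export
reduction_config <- function(improvement_threshold = 0.005,
                             identifiability = c("advisory", "strict", "off"),
                             engine = c("pinn", "lm"),
                             pinn = pinn_config(),
                             polish = TRUE,
                             greedy_first = FALSE,
                             profile_n_grid = 7,
                             penalty = c("none", "aic")) {
  structure(list(improvement_threshold = improvement_threshold,
                 identifiability = match.arg(identifiability),
                 engine = match.arg(engine), pinn = pinn,
                 polish = polish,
                 greedy_first = greedy_first,
                 profile_n_grid = profile_n_grid,
                 penalty = match.arg(penalty)),
            class = "reduction_config")
}

#' Is a finer fit an improvement?
#'
#' @param coarse_mae,fine_mae nonnegative mean absolute errors.
#' @param threshold absolute improvement threshold.
#' @return `TRUE` iff `coarse_mae - fine_mae > threshold`.
#' @export
improvement <- function(coarse_mae, fine_mae, threshold) {
  stopifnot(coarse_mae >= 0, fine_mae >= 0)
  (coarse_mae - fine_mae) > threshold
}

# the two rates of the step created by refining `from` into `to`
.new_step_params <- function(from_id, to_id) {
  added <- setdiff(.rom_defs[[to_id]]$boundaries,
                   .rom_defs[[from_id]]$boundaries)
  pos <- match(added, sort(.rom_defs[[to_id]]$boundaries))
  c(paste0("a", 2L * pos - 1L), paste0("a", 2L * pos))
}

#' Automatic reaction-order reduction
#'
#' Implements the three-stage workflow: (1) fit the maximally reduced
#' Model 1 and record its residuals; (2) unpack primary-nucleation bins --
#' fit the primary successors of the current model, advance to the best one
#' only if its MAE improves on the current fit by more than the threshold
#' (and, in strict mode, its newly introduced rates are identifiable),
#' otherwise backtrack; (3) repeat with secondary-nucleation unpacking.
#' The workflow never leaves the lattice and never revisits a model; it
#' terminates at a model with no admissible improving successor.
#'
#' @param dataset a `rom_dataset`.
#' @param config a \code{\link{reduction_config}}.
#' @return an object of class `rom_reduction`: `steps` (audit trail),
#'   `selected_model_id`, `fits` (all fitted models, by id), `profiles`
#'   (identifiability summaries) and the echoed criteria.
#' @export
run_reduction <- function(dataset, config = reduction_config()) {
  stopifnot(inherits(dataset, "rom_dataset"))
  fit_one <- function(id) {
    f <- fit_rom(dataset, rom_model(id), config = config$pinn,
                 engine = config$engine)
    if (config$engine == "pinn" && config$polish) {
      # multi-start refinement: the neural estimate plus a fresh default
      # start, so an under-trained warm start cannot sink a candidate
      starts <- list(
        tryCatch(suppressWarnings(
          fit_least_squares(f$model, dataset, init = coef(f),
                            max_iter = 50)),
          error = function(e) NULL),
        tryCatch(suppressWarnings(
          fit_least_squares(f$model, dataset,
                            seed = config$pinn$seed, max_iter = 100)),
          error = function(e) NULL))
      starts <- Filter(Negate(is.null), starts)
      if (length(starts)) {
        lsq <- starts[[which.min(vapply(starts, `[[`, numeric(1), "sse"))]]
        f$params <- lsq$params
        f$alpha_beta <- alpha_beta(lsq$params)
        f$mech_mae <- lsq$mae
      } else {
        f$mech_mae <- Inf
      }
    } else if (config$engine == "lm") {
      f$mech_mae <- f$final_mae
    } else {
      f$mech_mae <- mean(abs(.ode_residuals(f$model, coef(f), dataset)))
    }
    f
  }
  score <- function(fit) {
    if (config$penalty == "aic") {
      r <- .ode_residuals(fit$model, fit$params, dataset)
      n <- length(r)
      2 * fit$model$n_params + n * log(sum(r^2) / n)
    } else fit$mech_mae
  }
  fits <- list(); profiles <- list()
  steps <- data.frame(step = integer(), model_id = integer(),
                      phase = character(), mae = numeric(),
                      surrogate_mae = numeric(),
                      n_params = integer(), identifiable = logical(),
                      decision = character(), stringsAsFactors = FALSE)
  add_step <- function(id, phase, fit, identifiable, decision) {
    steps[nrow(steps) + 1L, ] <<- list(nrow(steps) + 1L, id, phase,
                                       fit$mech_mae, fit$final_mae,
                                       fit$model$n_params,
                                       identifiable, decision)
  }
  current <- 1L
  fits[["1"]] <- fit_one(1L)
  add_step(1L, "initial", fits[["1"]], NA, "advance")
  visited <- 1L
  for (phase in c("primary", "secondary")) {
    repeat {
      succ <- setdiff(lattice_successors(current, label = phase), visited)
      if (!length(succ)) break
      cand_fits <- list()
      advanced <- FALSE
      # fit successors (all of them, or stop at the first improving one)
      for (id in succ) {
        f <- tryCatch(fit_one(id), error = function(e) NULL)
        visited <- c(visited, id)
        if (is.null(f)) next
        cand_fits[[as.character(id)]] <- f
        if (config$greedy_first &&
            improvement(score(fits[[as.character(current)]]), score(f),
                        config$improvement_threshold)) break
      }
      if (!length(cand_fits)) break
      ord <- order(vapply(cand_fits, score, numeric(1)))
      cur_score <- score(fits[[as.character(current)]])
      for (k in ord) {
        f <- cand_fits[[k]]
        id <- f$model$model_id
        improving <- improvement(cur_score, score(f),
                                 config$improvement_threshold)
        ident <- NA
        if (improving && config$identifiability != "off") {
          new_p <- .new_step_params(current, id)
          prof <- lapply(new_p, function(p) tryCatch(
            profile_likelihood(f$model, dataset, f$params, p,
                               n_grid = config$profile_n_grid,
                               refine = FALSE),
            error = function(e) NULL))
          names(prof) <- new_p
          profiles[[as.character(id)]] <- prof
          ident <- all(vapply(prof, function(pr)
            !is.null(pr) && isTRUE(pr$identifiable), logical(1)))
        }
        admissible <- improving &&
          (config$identifiability != "strict" || isTRUE(ident))
        if (admissible) {
          fits[[as.character(id)]] <- f
          add_step(id, phase, f, ident, "advance")
          current <- id
          advanced <- TRUE
          break
        } else {
          fits[[as.character(id)]] <- f
          add_step(id, phase, f, ident, "backtrack")
        }
      }
      if (!advanced) break
    }
  }
  steps$decision[steps$model_id == current &
                   steps$decision == "advance"] <- "stop"
  structure(list(steps = steps, selected_model_id = current,
                 fits = fits, profiles = profiles,
                 criteria = list(
                   improvement_threshold = config$improvement_threshold,
                   identifiability_required =
                     config$identifiability == "strict"),
                 config = config),
            class = "rom_reduction")
}

#' @export
print.rom_reduction <- function(x, ...) {
  cat("Automatic reaction-order reduction\n")
  print(x$steps, row.names = FALSE)
  cat("selected model: ", x$selected_model_id, "\n", sep = "")
  invisible(x)
}

#' Rank fitted models by residual error
#'
#' Orders fits by MAE ascending; fits tied within `tol` are broken in favor
#' of fewer parameters.  All fits must be on the same dataset.
#'
#' @param fits list of `rom_fit` objects.
#' @param tol MAE tie tolerance.
#' @return data.frame (method, model, n_params, mae, rank), best first.
#' @export
compare_models <- function(fits, tol = 1e-6) {
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, logical(1),
                                          "rom_fit")))
  n_obs <- vapply(fits, function(f) f$dataset$n_obs, numeric(1))
  if (length(unique(n_obs)) != 1L)
    stop("fits are on incomparable datasets (different n_obs)",
         call. = FALSE)
  df <- data.frame(
    method = vapply(fits, function(f)
      if (f$engine == "lm") "Levenberg-Marquardt" else "PINN", character(1)),
    model = vapply(fits, function(f) f$model$model_id, integer(1)),
    n_params = vapply(fits, function(f) f$model$n_params, integer(1)),
    mae = vapply(fits, function(f) f$final_mae, numeric(1)))
  # round MAE to the tie tolerance, then break ties by parameter count
  ord <- order(round(df$mae / tol) * tol, df$n_params)
  df <- df[ord, , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}

#' Fit quality across sampling densities
#'
#' Re-generates synthetic data at several time-grid densities and refits,
#' reporting the mean squared error of fit for each model at each point
#' count -- the scaling analogue of a timescale-robustness table.  By
#' default each model is fitted to data generated from its own kinetics
#' (matched seeds across point counts); pass `generator_spec$model` to fit
#' every model against one fixed reference dataset instead.
#'
#' @param model_ids models to sweep (default 1:8).
#' @param generator_spec list of generator settings: `params` (named rates,
#'   or `NULL` for forward 0.1 / backward 0.05 on every step), `y0`,
#'   `t_end`, `noise_sd`, `seed`, `mask`, and optionally `model` (a
#'   `rom_model` used as the fixed data source).
#' @param point_counts time-grid sizes (at least two; e.g. `c(50, 200)`).
#' @param engine,config fitting engine and `pinn_config`.
#' @return object of class `rom_sweep`: `mse` (rows = point counts,
#'   columns = models), `normalized` (each column scaled by its own
#'   maximum) and the sweep design.
#' @export
timescale_sweep <- function(model_ids = 1:8,
                            generator_spec = list(),
                            point_counts = c(50, 200),
                            engine = c("lm", "pinn"),
                            config = pinn_config()) {
  engine <- match.arg(engine)
  if (length(point_counts) < 2) stop("need at least two point counts",
                                     call. = FALSE)
  gs <- utils::modifyList(list(params = NULL, y0 = c(1, 1.4, 2, 3, 5),
                               t_end = 100, noise_sd = 0.02, seed = 1,
                               mask = "fibril_only", model = NULL),
                          generator_spec)
  default_rates <- function(m)
    stats::setNames(rep(c(0.05, 0.1), m$n_params / 2), m$param_names)
  mse <- matrix(NA_real_, length(point_counts), length(model_ids),
                dimnames = list(paste0("n", point_counts),
                                paste0("model", model_ids)))
  for (i in seq_along(point_counts)) {
    np <- point_counts[i]
    for (j in seq_along(model_ids)) {
      m <- rom_model(model_ids[j])
      src <- if (is.null(gs$model)) m else gs$model
      pars <- if (is.null(gs$params)) default_rates(src) else gs$params
      ds <- generate_dataset(src, pars, y0 = gs$y0, n_points = np,
                             t_end = gs$t_end, noise_sd = gs$noise_sd,
                             seed = gs$seed, mask = gs$mask)
      fit <- fit_rom(ds, m, config = config, engine = engine)
      r <- unlist(lapply(seq_along(ds$experiments), function(k) {
        e <- ds$experiments[[k]]
        keep <- !is.na(e$observed)
        (fit$predictions[[k]] - e$observed)[keep]
      }))
      mse[i, j] <- mean(r^2)
    }
  }
  normalized <- sweep(mse, 2, apply(mse, 2, max), "/")
  structure(list(mse = mse, normalized = normalized,
                 point_counts = point_counts, model_ids = model_ids,
                 engine = engine, generator_spec = gs),
            class = "rom_sweep")
}

#' @export
print.rom_sweep <- function(x, ...) {
  cat("Fit MSE across sampling densities (normalized per model):\n")
  print(round(x$normalized, 5))
  invisible(x)
}
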