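# Physics-informed fitting of rate parameters.

#' Training configuration for the physics-informed fit
#'
#' Defaults follow the reference training setup: three hidden layers of
#' width six with tanh activation, Adam with learning rate 0.001 for
#' 35,000 epochs, and equal weighting of the data and physics losses.
#'
#' @param hidden_layers number of hidden layers.
#' @param width units per hidden layer.
#' @param activation hidden activation (only `"tanh"` is supported).
#' @param epochs training epochs.
#' @param learning_rate Adam learning rate for the network weights.
#' @param param_learning_rate Adam learning rate for the kinetic rate
#'   parameters (default `10 * learning_rate`: the rates see far smaller
#'   gradients than the weights, and a shared step size leaves them
#'   crawling long after the trajectories are fitted).
#' @param lr_decay geometric learning-rate decay factor reached at the last
#'   epoch (1 = constant rate, the default).
#' @param warmup_epochs ramp the physics-loss weight linearly from 0 over
#'   this many initial epochs (0 = off, the default).
#' @param time_warp feed the network log-warped scaled time so fast early
#'   transients occupy a usable share of the input range (default TRUE);
#'   the collocation derivative is chain-ruled through the warp exactly.
#' @param optimizer only `"adam"` is supported.
#' @param seed integer seed for weight and rate initialization.
#' @param physics_mode `"collocation"` (ODE residual with the surrogate's
#'   exact time derivative; default) or `"literal"` (pointwise
#'   \eqn{|F(Y)-F(\hat Y)|}).
#' @param loss_weights length-2 numeric `(w_data, w_physics)`.
#' @param ic_constraint pin the surrogate to the known initial state
#'   (all mass in the smallest bin) so hidden species are anchored at t = 0.
#' @param nonneg constrain rates to be nonnegative via a softplus
#'   reparameterization (off by default: negative estimates are allowed).
#' @param param_init range of the uniform initialization of the rates.
#' @param thin keep every `thin`-th epoch when serializing histories
#'   (in-memory histories are always full length).
#' @return a list of class `pinn_config`.
#' @export
pinn_config <- function(hidden_layers = 3, width = 6, activation = "tanh",
                        epochs = 35000, learning_rate = 0.001,
                        param_learning_rate = 10 * learning_rate,
                        lr_decay = 1, warmup_epochs = 0,
                        time_warp = TRUE,
                        optimizer = "adam", seed = 1,
                        physics_mode = c("collocation", "literal"),
                        loss_weights = c(data = 1, physics = 1),
                        ic_constraint = TRUE, nonneg = FALSE,
                        param_init = c(0.01, 0.5), thin = 1) {
  physics_mode <- match.arg(physics_mode)
  stopifnot(epochs >= 1, learning_rate > 0, param_learning_rate > 0,
            width >= 1, hidden_layers >= 1,
            identical(activation, "tanh"), identical(optimizer, "adam"),
            length(loss_weights) == 2, all(loss_weights >= 0))
  structure(list(hidden_layers = hidden_layers, width = width,
                 activation = activation, epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 param_learning_rate = param_learning_rate,
                 lr_decay = lr_decay,
                 warmup_epochs = as.integer(warmup_epochs),
                 time_warp = time_warp,
                 optimizer = optimizer,
                 seed = as.integer(seed), physics_mode = physics_mode,
                 loss_weights = loss_weights, ic_constraint = ic_constraint,
                 nonneg = nonneg, param_init = param_init,
                 thin = as.integer(thin)),
            class = "pinn_config")
}

# Glorot-uniform initial weights for one experiment's network
.init_net <- function(width, hidden_layers, nsp) {
  sizes_in <- c(1, rep(width, hidden_layers - 1L), width)
  sizes_out <- c(rep(width, hidden_layers), nsp)
  W <- vector("list", hidden_layers + 1L)
  b <- vector("list", hidden_layers + 1L)
  for (l in seq_along(W)) {
    lim <- sqrt(6 / (sizes_in[l] + sizes_out[l]))
    W[[l]] <- matrix(stats::runif(sizes_in[l] * sizes_out[l], -lim, lim),
                     sizes_out[l], sizes_in[l])
    b[[l]] <- rep(0, sizes_out[l])
  }
  list(W = W, b = b)
}

# Map the dataset's observed columns onto the candidate model's bins.
# Same schema -> identity.  Fibril-only data map onto the candidate's
# terminal bin regardless of binning (fluorescence reports aggregated mass
# in arbitrary units, so no weight conversion is applied).
.align_dataset <- function(ds, model) {
  nsp <- model$n_species
  same <- identical(ds$species, model$species$name)
  obs_cols <- which(vapply(seq_along(ds$species), function(j)
    any(vapply(ds$experiments,
               function(e) any(!is.na(e$observed[, j])), logical(1))),
    logical(1)))
  if (!same) {
    if (!(length(obs_cols) == 1L && obs_cols == length(ds$species)))
      stop("dataset bins (", paste(ds$species, collapse = ","),
           ") do not match model ", model$model_id,
           "; pool them first with rebin_dataset()", call. = FALSE)
  }
  lapply(ds$experiments, function(e) {
    n_t <- length(e$times)
    Y <- matrix(0, n_t, nsp)
    M <- matrix(0, n_t, nsp)
    if (same) {
      keep <- !is.na(e$observed)
      Y[keep] <- e$observed[keep]
      M[keep] <- 1
    } else {
      v <- e$observed[, length(ds$species)]
      keep <- !is.na(v)
      Y[keep, nsp] <- v[keep]
      M[keep, nsp] <- 1
    }
    list(times = e$times, Y = Y, M = M, y0 = e$y0)
  })
}

# Transient timescale of the observed series, in scaled time: median time
# (over experiments and observed species) at which a series first covers
# 63% of its total change.  Sets the range of the initial-condition
# constraint factor g(tau) = 1 - exp(-tau/tau0).
.transient_scale <- function(exps, t_scale) {
  t63 <- unlist(lapply(exps, function(e) {
    obs_cols <- which(colSums(e$M) > 0)
    vapply(obs_cols, function(j) {
      y <- e$Y[e$M[, j] == 1, j]
      tt <- e$times[e$M[, j] == 1]
      dy <- abs(y - y[1])
      if (max(dy) <= 0) return(NA_real_)
      tt[which(dy >= 0.63 * max(dy))[1]] / t_scale
    }, numeric(1))
  }))
  t63 <- t63[!is.na(t63)]
  if (!length(t63)) return(0.3)
  min(max(stats::median(t63), 0.02), 1)
}

# scaled initial state for one experiment (all mass in the smallest bin)
.initial_state <- function(model, y0, normalization) {
  init <- c(y0, rep(0, model$n_species - 1L))
  sc <- normalization$scales
  if (normalization$mode == "global_max") init <- init / sc
  if (normalization$mode == "per_species_max") {
    s1 <- sc[1]
    if (is.finite(s1) && !is.na(s1) && s1 > 0) init[1] <- init[1] / s1
  }
  init
}

#' Fit a reduced-order model to a dataset
#'
#' The main model-fitting entry point.  With `engine = "pinn"` (default), a
#' small multilayer perceptron per experiment is trained jointly with the
#' shared rate constants on the combined loss
#' \eqn{L = w_d L_{MSE} + w_p L_{PI}}; this is a global fit, with one
#' kinetic parameter set constrained by all initial concentrations at once.
#' With `engine = "lm"` the rates are estimated by Levenberg-Marquardt
#' least squares on integrated trajectories (see
#' \code{\link{fit_least_squares}}).
#'
#' @param dataset a `rom_dataset`.
#' @param model a `rom_model` (or integer id, taken with default orders).
#' @param config a \code{\link{pinn_config}}.
#' @param engine `"pinn"` or `"lm"`.
#' @param init optional named vector of initial rate values (defaults to a
#'   uniform draw in `config$param_init` under `config$seed`).
#' @return an object of class `rom_fit` with components `params` (named
#'   rates), `alpha_beta`, `history` (per-epoch total/MSE/physics losses and
#'   parameter values), `final_mae`, `predictions` (per experiment, on the
#'   data grid), and the echoed `config`.
#' @seealso \code{\link{profile_likelihood}}, \code{\link{run_reduction}}
#' @export
fit_rom <- function(dataset, model, config = pinn_config(),
                    engine = c("pinn", "lm"), init = NULL) {
  engine <- match.arg(engine)
  stopifnot(inherits(dataset, "rom_dataset"))
  if (!inherits(model, "rom_model")) model <- rom_model(model)
  if (engine == "lm") {
    lsq <- fit_least_squares(model, dataset, init = init,
                             seed = config$seed,
                             param_init = config$param_init)
    fit <- structure(list(
      model = model, engine = "lm", params = lsq$params,
      alpha_beta = alpha_beta(lsq$params), history = NULL,
      final_mae = lsq$mae, sse = lsq$sse, converged = lsq$converged,
      predictions = lsq$predictions, nets = NULL,
      config = config, dataset = dataset), class = "rom_fit")
    return(fit)
  }
  set.seed(config$seed)
  exps <- .align_dataset(dataset, model)
  nsp <- model$n_species
  nE <- length(exps)
  t_scale <- max(vapply(exps, function(e) max(e$times), numeric(1)))
  if (t_scale <= 0) t_scale <- 1
  nets <- replicate(nE, .init_net(config$width, config$hidden_layers, nsp),
                    simplify = FALSE)
  if (is.null(init))
    init <- stats::runif(model$n_params, config$param_init[1],
                         config$param_init[2])
  a0 <- unname(.check_params(model, init))
  y0s <- lapply(exps, function(e)
    .initial_state(model, e$y0, dataset$normalization))
  # per-species output scale conditions the network on the data's magnitude
  s <- vapply(seq_len(nsp), function(j) {
    obs <- unlist(lapply(seq_len(nE), function(i) {
      y <- exps[[i]]$Y[, j][exps[[i]]$M[, j] == 1]
      y
    }))
    if (length(obs) && max(abs(obs)) > 0) return(max(abs(obs)))
    y0m <- max(vapply(y0s, `[`, numeric(1), 1))
    max(y0m / model$species$mass_weight[j], 1e-6)
  }, numeric(1))
  tau0 <- .transient_scale(exps, t_scale)
  if (config$ic_constraint) {
    gs <- lapply(exps, function(e) 1 - exp(-(e$times / t_scale) / tau0))
    gds <- lapply(exps, function(e)
      exp(-(e$times / t_scale) / tau0) / (tau0 * t_scale))
  } else {
    y0s <- lapply(y0s, function(v) v * 0)
    gs <- lapply(exps, function(e) rep(1, length(e$times)))
    gds <- lapply(exps, function(e) rep(0, length(e$times)))
  }
  # network input: scaled time, log-warped so a fast transient occupies a
  # usable share of the input range (exact derivative kept for collocation)
  tau_w <- if (config$time_warp) tau0 else NA_real_
  xw <- .time_warp(lapply(exps, function(e) e$times), t_scale, tau_w)
  res <- pinn_train_cpp(
    xw$x, xw$xd,
    lapply(exps, function(e) t(e$Y)),
    lapply(exps, function(e) t(e$M)),
    y0s, s, gs, gds, nets, a0, .reaction_struct(model),
    config$epochs, config$learning_rate, config$param_learning_rate,
    config$lr_decay, config$warmup_epochs,
    config$loss_weights[[1]], config$loss_weights[[2]],
    as.integer(config$physics_mode == "literal"),
    as.integer(config$nonneg))
  params <- stats::setNames(as.numeric(res$params), model$param_names)
  history <- data.frame(epoch = seq_len(config$epochs),
                        total = res$loss_hist[, 1],
                        mse = res$loss_hist[, 2],
                        physics = res$loss_hist[, 3])
  ph <- res$param_hist
  colnames(ph) <- model$param_names
  history <- cbind(history, as.data.frame(ph))
  predictions <- lapply(res$Yhat, function(m) {
    colnames(m) <- model$species$name
    m
  })
  fit <- structure(list(
    model = model, engine = "pinn", params = params,
    alpha_beta = alpha_beta(params), history = history,
    final_mae = NA_real_, converged = TRUE,
    predictions = predictions, nets = res$nets,
    s = s, t_scale = t_scale, y0s = y0s,
    tau0 = if (config$ic_constraint) tau0 else NA_real_, tau_w = tau_w,
    config = config, dataset = dataset), class = "rom_fit")
  fit$final_mae <- rom_mae(fit)
  fit
}

# network input warp: x = log1p(tau/tau_w) / log1p(1/tau_w) (identity when
# tau_w is NA); xd = dx/dt
.time_warp <- function(times_list, t_scale, tau_w) {
  if (is.na(tau_w)) {
    return(list(x = lapply(times_list, function(tt) tt / t_scale),
                xd = lapply(times_list,
                            function(tt) rep(1 / t_scale, length(tt)))))
  }
  denom <- log1p(1 / tau_w)
  list(x = lapply(times_list,
                  function(tt) log1p((tt / t_scale) / tau_w) / denom),
       xd = lapply(times_list, function(tt)
         1 / ((tt / t_scale + tau_w) * denom * t_scale)))
}

# R-side forward pass mirroring the trainer (used by predict)
.net_forward <- function(net, tau, y0, s, tau0, tau_w) {
  x <- if (is.na(tau_w)) tau else log1p(tau / tau_w) / log1p(1 / tau_w)
  H <- matrix(x, nrow = 1)
  L <- length(net$W) - 1L
  for (l in seq_len(L))
    H <- tanh(net$W[[l]] %*% H + as.numeric(net$b[[l]]))
  N <- net$W[[L + 1L]] %*% H + as.numeric(net$b[[L + 1L]])
  Y <- if (!is.na(tau0)) {
    g <- 1 - exp(-tau / tau0)
    sweep(sweep(N, 2, g, "*"), 1, s, "*") + matrix(y0, length(y0), length(tau))
  } else {
    sweep(N, 1, s, "*")
  }
  t(Y)
}

#' Predict from a fitted model
#'
#' Evaluates the trained surrogate on an arbitrary time grid.  Times beyond
#' the training span are extrapolations; they are still returned (finite)
#' but flagged via the `"extrapolated"` attribute and a warning.
#'
#' @param object a `rom_fit` with `engine = "pinn"` (for `engine = "lm"`
#'   prediction integrates the ODE at the fitted rates).
#' @param times time grid (default: the training grid).
#' @param experiment experiment index (default 1).
#' @param ... unused.
#' @return matrix of predicted concentrations, one row per time, with a
#'   logical attribute `"extrapolated"` marking out-of-span rows.
#' @export
predict.rom_fit <- function(object, times = NULL, experiment = 1, ...) {
  e <- object$dataset$experiments[[experiment]]
  if (is.null(times)) times <- e$times
  span <- max(e$times)
  extra <- times > span | times < min(e$times)
  if (object$engine == "lm") {
    y0 <- .initial_state(object$model, e$y0, object$dataset$normalization)
    tt <- sort(unique(c(0, times)))
    traj <- rom_integrate(object$model, object$params, y0, tt)
    out <- traj$states[match(times, tt), , drop = FALSE]
  } else {
    net <- object$nets[[experiment]]
    out <- .net_forward(net, times / object$t_scale,
                        object$y0s[[experiment]], object$s, object$tau0,
                        object$tau_w)
    colnames(out) <- object$model$species$name
  }
  if (any(extra))
    warning("prediction at ", sum(extra), " time(s) outside the training span")
  attr(out, "extrapolated") <- extra
  out
}

#' @export
coef.rom_fit <- function(object, ...) object$params

#' @export
residuals.rom_fit <- function(object, ...) {
  ds <- object$dataset
  lapply(seq_along(ds$experiments), function(i) {
    al <- .align_dataset_one(ds, object$model, ds$experiments[[i]])
    r <- object$predictions[[i]] - al$Y
    r[al$M == 0] <- NA_real_
    colnames(r) <- object$model$species$name
    r
  })
}

#' @export
print.rom_fit <- function(x, ...) {
  cat("rom_fit: model ", x$model$model_id, " (", x$model$n_params,
      " rates), engine ", x$engine, "\n", sep = "")
  cat("  rates:\n")
  print(signif(x$params, 4))
  cat("  alpha/beta view:\n")
  print(signif(x$alpha_beta, 4))
  cat("  MAE on training data: ", signif(x$final_mae, 5), "\n", sep = "")
  invisible(x)
}

#' @export
summary.rom_fit <- function(object, ...) {
  out <- list(model_id = object$model$model_id, engine = object$engine,
              params = object$params, alpha_beta = object$alpha_beta,
              final_mae = object$final_mae,
              n_obs = object$dataset$n_obs,
              final_loss = if (!is.null(object$history))
                utils::tail(object$history$total, 1) else NA_real_)
  class(out) <- "summary.rom_fit"
  out
}

#' @export
print.summary.rom_fit <- function(x, ...) {
  cat("Reduced-order kinetic fit (model ", x$model_id, ", engine ",
      x$engine, ")\n", sep = "")
  cat("  n_obs = ", x$n_obs, ";  MAE = ", signif(x$final_mae, 5), sep = "")
  if (is.finite(x$final_loss))
    cat(";  final training loss = ", signif(x$final_loss, 5), sep = "")
  cat("\n  estimated rates (alpha_i forward, beta_i backward):\n")
  print(signif(x$alpha_beta, 4))
  invisible(x)
}

#' @export
plot.rom_fit <- function(x, which = c("fit", "loss", "params"), ...) {
  which <- match.arg(which)
  ds <- x$dataset
  if (which == "fit") {
    obs_col <- which(colSums(!is.na(do.call(
      rbind, lapply(ds$experiments, `[[`, "observed")))) > 0)[1]
    plot(NA, xlim = range(ds$experiments[[1]]$times),
         ylim = range(unlist(lapply(seq_along(ds$experiments), function(i)
           c(ds$experiments[[i]]$observed[, obs_col],
             x$predictions[[i]][, obs_col]))), na.rm = TRUE),
         xlab = "time", ylab = ds$species[obs_col],
         main = paste0("model ", x$model$model_id, " fit"))
    for (i in seq_along(ds$experiments)) {
      graphics::points(ds$experiments[[i]]$times,
                       ds$experiments[[i]]$observed[, obs_col],
                       col = i, pch = 16, cex = 0.4)
      graphics::lines(ds$experiments[[i]]$times,
                      x$predictions[[i]][, obs_col], col = i, lwd = 2)
    }
  } else if (which == "loss") {
    if (is.null(x$history)) stop("no training history (engine lm)")
    plot(x$history$epoch, x$history$total, type = "l", log = "y",
         xlab = "epoch", ylab = "loss", main = "training loss")
    graphics::lines(x$history$epoch, x$history$mse, col = 2)
    graphics::lines(x$history$epoch, x$history$physics, col = 4)
    graphics::legend("topright", c("total", "data", "physics"),
                     col = c(1, 2, 4), lty = 1, bty = "n")
  } else {
    if (is.null(x$history)) stop("no training history (engine lm)")
    pn <- x$model$param_names
    ph <- as.matrix(x$history[, pn, drop = FALSE])
    graphics::matplot(x$history$epoch, ph, type = "l", lty = 1,
                      xlab = "epoch", ylab = "rate value",
                      main = "learned rate parameters")
    graphics::legend("topright", pn, col = seq_along(pn), lty = 1, bty = "n")
  }
  invisible(x)
}

#' Simulate new datasets from a fitted model
#'
#' Draws synthetic datasets from the fitted kinetics under the training
#' design (same initial concentrations, grid and noise level).
#'
#' @param object a `rom_fit`.
#' @param nsim number of datasets.
#' @param seed integer seed.
#' @param ... unused.
#' @return a list of `rom_dataset` objects.
#' @export
simulate.rom_fit <- function(object, nsim = 1, seed = NULL, ...) {
  ds <- object$dataset
  y0 <- vapply(ds$experiments, `[[`, numeric(1), "y0")
  n_points <- length(ds$experiments[[1]]$times)
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, nsim)
  lapply(seeds, function(sd)
    generate_dataset(object$model, object$params, y0 = y0,
                     n_points = n_points, t_end = ds$t_end,
                     noise_sd = ds$noise_sd, seed = sd, mask = ds$mask))
}
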