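# Training losses: data misfit and physics (ODE-residual) terms.

#' Mean squared data loss
#'
#' \eqn{L_{MSE} = (1/n) \sum_t (Y_t - \hat Y_t)^2}, summed over all retained
#' (non-missing) observations across experiments and species.
#'
#' @param Y observations (vector or matrix; `NA` marks unobserved entries).
#' @param Yhat predictions of the same shape.
#' @return nonnegative scalar.
#' @export
data_loss <- function(Y, Yhat) {
  if (!identical(dim(Y), dim(Yhat)) || length(Y) != length(Yhat))
    stop("Y and Yhat must have identical shapes", call. = FALSE)
  keep <- !is.na(Y)
  n <- sum(keep)
  if (n < 1) stop("no retained observations", call. = FALSE)
  sum((Y[keep] - Yhat[keep])^2) / n
}

#' Physics-informed loss
#'
#' Measures how far predictions are from satisfying the model's kinetics.
#' Two readings are provided.  `"literal"` applies the model right-hand side
#' \eqn{F} pointwise to both series and averages
#' \eqn{|F(Y_t) - F(\hat Y_t)|}; it vanishes whenever the prediction matches
#' the data, independent of the rate parameters.  `"collocation"` (the form
#' used in training) averages the ODE residual
#' \eqn{|d\hat Y/dt - F(\hat Y_t)|}; the surrogate derivative is
#' differentiated exactly inside the trainer, while this standalone function
#' accepts it via `dYhat_dt` or falls back to central differences on `Yhat`.
#'
#' @param model a `rom_model`.
#' @param params named rate vector.
#' @param Y observed states, matrix `n_t x n_species` (literal mode only).
#' @param Yhat predicted states, same shape.
#' @param times time grid for the rows.
#' @param mode `"collocation"` (default) or `"literal"`.
#' @param dYhat_dt optional matrix of surrogate time derivatives; if `NULL`
#'   in collocation mode, finite differences of `Yhat` are used.
#' @return nonnegative scalar: mean absolute residual over species and times.
#' @export
physics_loss <- function(model, params, Y, Yhat, times,
                         mode = c("collocation", "literal"),
                         dYhat_dt = NULL) {
  mode <- tryCatch(match.arg(mode),
                   error = function(e) stop("unknown physics mode: ",
                                            mode[1], call. = FALSE))
  stopifnot(inherits(model, "rom_model"))
  Yhat <- as.matrix(Yhat)
  F_of <- function(M) t(apply(M, 1, function(x) rom_rhs(model, x, params)))
  if (mode == "literal") {
    Y <- as.matrix(Y)
    if (!identical(dim(Y), dim(Yhat)))
      stop("Y and Yhat must have identical shapes", call. = FALSE)
    R <- F_of(Y) - F_of(Yhat)
  } else {
    if (is.null(dYhat_dt)) dYhat_dt <- .fd_derivative(Yhat, times)
    R <- as.matrix(dYhat_dt) - F_of(Yhat)
  }
  mean(abs(R))
}

# central differences (one-sided at the ends)
.fd_derivative <- function(M, times) {
  M <- as.matrix(M)
  n <- nrow(M)
  if (n < 2) stop("need at least two time points", call. = FALSE)
  D <- M
  D[1, ] <- (M[2, ] - M[1, ]) / (times[2] - times[1])
  D[n, ] <- (M[n, ] - M[n - 1, ]) / (times[n] - times[n - 1])
  if (n > 2) {
    idx <- 2:(n - 1)
    D[idx, ] <- (M[idx + 1, , drop = FALSE] - M[idx - 1, , drop = FALSE]) /
      (times[idx + 1] - times[idx - 1])
  }
  D
}

#' Mean absolute error of a fit
#'
#' Mean of |prediction - observation| over all retained observations of the
#' dataset the fit was trained on (in the dataset's units).
#'
#' @param fit a `rom_fit`.
#' @param dataset optionally, a dataset to score instead of the training one.
#' @return nonnegative scalar.
#' @export
rom_mae <- function(fit, dataset = NULL) {
  stopifnot(inherits(fit, "rom_fit"))
  ds <- if (is.null(dataset)) fit$dataset else dataset
  tot <- 0; n <- 0
  for (i in seq_along(ds$experiments)) {
    e <- ds$experiments[[i]]
    al <- .align_dataset_one(ds, fit$model, e)
    pred <- fit$predictions[[i]]
    keep <- al$M == 1
    tot <- tot + sum(abs(pred[keep] - al$Y[keep]))
    n <- n + sum(keep)
  }
  tot / n
}
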