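# Reduced-order aggregation models 1-8.
#
# Every model is a linear chain of reversible condensation steps between
# species bins (pooled oligomer size ranges).  Step i joins bin i (smaller
# aggregates) to bin i+1 (larger) with reaction order k_i:
#
#   d(bin_i)/dt   += k_i * ( b_i * bin_{i+1} - f_i * bin_i^{k_i} )
#   d(bin_{i+1})/dt +=       f_i * bin_i^{k_i} - b_i * bin_{i+1}
#
# where f_i = a_{2i} is the forward (aggregation) rate and b_i = a_{2i-1}
# the backward (dissolution) rate; in the alpha/beta view alpha_i = a_{2i},
# beta_i = a_{2i-1}.

# Chain composition on the fully granular five-bin scale
# B1 | B1_4 | B2 | B3 | B5.  Each model keeps a subset of the four
# boundaries; its bins pool the elementary bins between kept boundaries.
.rom_defs <- list(
  list(species = c("B1_35", "B4"),                    syms = "c",
       boundaries = 3L),
  list(species = c("B1", "B1_7", "B4"),               syms = c("n", "m"),
       boundaries = c(1L, 3L)),
  list(species = c("B1_35", "B3", "B5"),              syms = c("n", "m"),
       boundaries = c(3L, 4L)),
  list(species = c("B1", "B1_7", "B3", "B5"),         syms = c("n", "m", "s"),
       boundaries = c(1L, 3L, 4L)),
  list(species = c("B1_2", "B2", "B4"),               syms = c("n", "m"),
       boundaries = c(2L, 3L)),
  list(species = c("B1", "B1_4", "B2", "B4"),         syms = c("n", "m", "s"),
       boundaries = c(1L, 2L, 3L)),
  list(species = c("B1_2", "B2", "B3", "B5"),         syms = c("n", "m", "s"),
       boundaries = c(2L, 3L, 4L)),
  list(species = c("B1", "B1_4", "B2", "B3", "B5"),   syms = c("n", "m", "s", "p"),
       boundaries = c(1L, 2L, 3L, 4L))
)

.valid_bins <- c("B1", "B1_2", "B1_4", "B1_7", "B1_35", "B2", "B3", "B4", "B5")

#' Construct a reduced-order aggregation model
#'
#' Builds one of the eight reduced-order mass-action models of amyloid
#' aggregation.  Each model pools oligomer size ranges into 2--5 species
#' bins joined by reversible condensation steps; the forward rate of step
#' \eqn{i} is \eqn{a_{2i}} (alias \eqn{\alpha_i}) and the backward rate
#' \eqn{a_{2i-1}} (alias \eqn{\beta_i}).
#'
#' @param model_id integer in 1..8. Model 1 is the maximally reduced
#'   two-bin model; Model 8 the fully granular five-bin chain.
#' @param orders named list or vector giving the reaction orders the model
#'   uses (`c` for Model 1; `n`,`m` for Models 2, 3, 5; `n`,`m`,`s` for
#'   Models 4, 6, 7; `n`,`m`,`s`,`p` for Model 8).  All default to 2.
#' @return an object of class `rom_model` with the species table, per-step
#'   orders and parameter names.
#' @examples
#' m1 <- rom_model(1, orders = c(c = 2))
#' m8 <- rom_model(8)
#' rom_rhs(m1, c(B1_35 = 2, B4 = 0), c(a1 = 0, a2 = 1))
#' @export
rom_model <- function(model_id, orders = NULL) {
  if (length(model_id) != 1L || !is.numeric(model_id) ||
      is.na(model_id) || model_id != as.integer(model_id) ||
      model_id < 1 || model_id > 8)
    stop("unknown model_id: ", deparse(substitute(model_id)),
         " = ", paste(model_id, collapse = ","),
         " (must be an integer in 1..8)", call. = FALSE)
  model_id <- as.integer(model_id)
  def <- .rom_defs[[model_id]]
  ord <- vapply(def$syms, function(sym) {
    v <- if (is.null(orders)) NULL else orders[[sym]]
    if (is.null(v) || is.na(v)) v <- 2
    if (!is.numeric(v) || length(v) != 1L || v < 1)
      stop("invalid reaction order '", sym, "': must be a number >= 1",
           call. = FALSE)
    as.numeric(v)
  }, numeric(1))
  extra <- setdiff(names(orders), c(def$syms, NA))
  nsp <- length(def$species)
  weights <- cumprod(c(1, ord))
  roles <- c("monomer_bin", rep("intermediate", max(nsp - 2L, 0L)), "fibril")
  species <- data.frame(name = def$species, role = roles[seq_len(nsp)],
                        mass_weight = weights, stringsAsFactors = FALSE)
  nstep <- nsp - 1L
  steps <- data.frame(
    step = seq_len(nstep),
    from = def$species[seq_len(nstep)],
    to = def$species[seq_len(nstep) + 1L],
    order_symbol = def$syms,
    order = unname(ord),
    fwd_param = paste0("a", 2L * seq_len(nstep)),       # alpha_i
    bwd_param = paste0("a", 2L * seq_len(nstep) - 1L),  # beta_i
    stringsAsFactors = FALSE)
  structure(list(
    model_id = model_id,
    species = species,
    steps = steps,
    orders = stats::setNames(unname(ord), def$syms),
    n_species = nsp,
    n_params = 2L * nstep,
    param_names = paste0("a", seq_len(2L * nstep)),
    boundaries = def$boundaries
  ), class = "rom_model")
}

#' @export
print.rom_model <- function(x, ...) {
  cat("Reduced-order aggregation model ", x$model_id, "\n", sep = "")
  cat("  bins: ", paste(x$species$name, collapse = " <-> "), "\n", sep = "")
  cat("  orders: ",
      paste(x$steps$order_symbol, "=", x$steps$order, collapse = ", "),
      "\n  parameters: ", paste(x$param_names, collapse = ", "),
      "  (alpha_i = a_{2i} forward, beta_i = a_{2i-1} backward)\n", sep = "")
  invisible(x)
}

.check_params <- function(model, params) {
  params <- unlist(params)
  if (is.null(names(params)) || !all(names(params) != "")) {
    if (length(params) != model$n_params)
      stop("parameter vector has length ", length(params), "; model ",
           model$model_id, " needs ", model$n_params, call. = FALSE)
    names(params) <- model$param_names
  }
  miss <- setdiff(model$param_names, names(params))
  if (length(miss))
    stop("missing rate parameters: ", paste(miss, collapse = ", "),
         call. = FALSE)
  params[model$param_names]
}

#' Right-hand side of a reduced-order model
#'
#' Evaluates the time derivatives of all species bins under mass-action
#' kinetics for a given state and rate-parameter set.
#'
#' @param model a `rom_model`.
#' @param state numeric vector of bin concentrations (micromolar), length
#'   equal to the model's species count.
#' @param params named numeric vector of rates `a1`, `a2`, ... (or unnamed
#'   in that order).
#' @return numeric vector `d(state)/dt`, named by species bin.
#' @export
rom_rhs <- function(model, state, params) {
  stopifnot(inherits(model, "rom_model"))
  if (length(state) != model$n_species)
    stop("state has length ", length(state), "; model ", model$model_id,
         " has ", model$n_species, " species", call. = FALSE)
  params <- .check_params(model, params)
  d <- numeric(model$n_species)
  st <- model$steps
  for (i in seq_len(nrow(st))) {
    k <- st$order[i]
    x <- state[i]
    if (x < 0 && k != round(k))
      stop("fractional power of a negative concentration in bin ",
           st$from[i], call. = FALSE)
    fwd <- params[[st$fwd_param[i]]] * x^k
    bwd <- params[[st$bwd_param[i]]] * state[i + 1L]
    d[i] <- d[i] + k * (bwd - fwd)
    d[i + 1L] <- d[i + 1L] + fwd - bwd
  }
  stats::setNames(d, model$species$name)
}

#' Mass-conservation weights of a model
#'
#' Returns the monomer-equivalent weight of each species bin: the first bin
#' has weight 1 and each subsequent bin's weight is the previous one's
#' multiplied by the step's reaction order.  For every state and parameter
#' set, `sum(mass_weights(m) * rom_rhs(m, state, params))` is zero.
#'
#' @param model a `rom_model`.
#' @return numeric vector of positive weights, named by bin.
#' @export
mass_weights <- function(model) {
  stopifnot(inherits(model, "rom_model"))
  stats::setNames(model$species$mass_weight, model$species$name)
}

#' Alpha/beta view of a rate-parameter set
#'
#' Rate constants are stored as `a1`, `a2`, ...; reversible step \eqn{i} has
#' forward (aggregation) rate \eqn{\alpha_i = a_{2i}} and backward
#' (dissolution) rate \eqn{\beta_i = a_{2i-1}}.
#'
#' @param params named numeric vector of `a` rates.
#' @return named numeric vector `alpha1, beta1, alpha2, beta2, ...`.
#' @export
alpha_beta <- function(params) {
  nstep <- length(params) %/% 2L
  out <- numeric(0)
  for (i in seq_len(nstep)) {
    out[[paste0("alpha", i)]] <- unname(params[[paste0("a", 2L * i)]])
    out[[paste0("beta", i)]] <- unname(params[[paste0("a", 2L * i - 1L)]])
  }
  out
}

# internal: reaction table in the flat form the trainer and integrator use
.reaction_struct <- function(model) {
  st <- model$steps
  nstep <- nrow(st)
  nsp <- model$n_species
  nR <- 2L * nstep
  species <- integer(nR); exponent <- numeric(nR); param <- integer(nR)
  S <- matrix(0, nR, nsp)
  for (i in seq_len(nstep)) {
    rf <- 2L * i - 1L  # forward reaction row
    species[rf] <- i - 1L; exponent[rf] <- st$order[i]
    param[rf] <- 2L * i - 1L           # a_{2i}, 0-based
    S[rf, i] <- -st$order[i]; S[rf, i + 1L] <- 1
    rb <- 2L * i       # backward
    species[rb] <- i; exponent[rb] <- 1
    param[rb] <- 2L * i - 2L           # a_{2i-1}, 0-based
    S[rb, i] <- st$order[i]; S[rb, i + 1L] <- -1
  }
  list(species = species, exponent = exponent, param = param, stoich = S)
}

#' The model-reduction lattice
#'
#' The eight models form a lattice ordered by granularity: each directed
#' edge refines one bin split, increasing the species count by exactly one.
#' Edges that split a pre-nucleation bin are labelled `primary`; edges that
#' split a post-nucleation bin are labelled `secondary`.  Model 1 is the
#' unique source and Model 8 the unique sink.
#'
#' @return an object of class `rom_lattice`: list with `nodes` (1:8) and
#'   `edges` (data.frame from, to, label).
#' @export
rom_lattice <- function() {
  edges <- data.frame(
    from = c(1L, 1L, 1L, 2L, 3L, 3L, 5L, 5L, 4L, 6L, 7L),
    to   = c(2L, 3L, 5L, 4L, 4L, 7L, 6L, 7L, 8L, 8L, 8L))
  # the boundary added by each edge decides its label: boundaries 1 and 2
  # subdivide pre-nucleation bins (primary), boundary 4 post-nucleation
  # (secondary); boundary 3 (the nucleation split) is present in every model
  edges$label <- vapply(seq_len(nrow(edges)), function(i) {
    added <- setdiff(.rom_defs[[edges$to[i]]]$boundaries,
                     .rom_defs[[edges$from[i]]]$boundaries)
    if (added < 3L) "primary" else "secondary"
  }, character(1))
  structure(list(nodes = 1:8, edges = edges), class = "rom_lattice")
}

#' @export
print.rom_lattice <- function(x, ...) {
  cat("Model-reduction lattice (coarse -> fine):\n")
  print(x$edges, row.names = FALSE)
  invisible(x)
}

#' Successors of a model in the reduction lattice
#'
#' @param model_id integer model id.
#' @param label optional filter: `"primary"` or `"secondary"` unpacking.
#' @return integer vector of finer model ids one refinement away.
#' @export
lattice_successors <- function(model_id, label = NULL) {
  lat <- rom_lattice()
  e <- lat$edges[lat$edges$from == model_id, ]
  if (!is.null(label)) e <- e[e$label == label, ]
  e$to
}

# reachability coarse -> fine along lattice edges
.lattice_path_exists <- function(coarse_id, fine_id) {
  if (coarse_id == fine_id) return(TRUE)
  frontier <- coarse_id
  seen <- coarse_id
  while (length(frontier)) {
    nxt <- unique(unlist(lapply(frontier, lattice_successors)))
    nxt <- setdiff(nxt, seen)
    if (fine_id %in% nxt) return(TRUE)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  FALSE
}

# spans of elementary bins (1..5) covered by each bin of a model
.bin_spans <- function(model) {
  cuts <- c(0L, model$boundaries, 5L)
  lapply(seq_len(model$n_species),
         function(j) seq.int(cuts[j] + 1L, cuts[j + 1L]))
}

#' Collapse a fine-model trajectory onto a coarser model's bins
#'
#' Pools the bins of a finer model into the bins of a coarser model in
#' monomer equivalents: each coarse bin is the mass-weight-weighted sum of
#' its constituent fine bins divided by the coarse bin's own mass weight.
#' Total monomer-equivalent mass is preserved at every time point.
#'
#' @param traj a `rom_trajectory` (or a matrix of states, one row per time
#'   point, columns in the fine model's species order).
#' @param fine,coarse `rom_model` objects; a lattice path coarse -> fine
#'   must exist.
#' @return a trajectory of the same shape on the coarse model's bins.
#' @export
collapse_trajectory <- function(traj, fine, coarse) {
  stopifnot(inherits(fine, "rom_model"), inherits(coarse, "rom_model"))
  if (!.lattice_path_exists(coarse$model_id, fine$model_id))
    stop("models ", coarse$model_id, " and ", fine$model_id,
         " are not lattice-comparable (no path coarse -> fine)",
         call. = FALSE)
  states <- if (inherits(traj, "rom_trajectory")) traj$states else as.matrix(traj)
  if (ncol(states) != fine$n_species)
    stop("trajectory has ", ncol(states), " columns; fine model has ",
         fine$n_species, " species", call. = FALSE)
  if (coarse$model_id == fine$model_id) return(traj)
  wf <- mass_weights(fine)
  wc <- mass_weights(coarse)
  fine_spans <- .bin_spans(fine)
  coarse_spans <- .bin_spans(coarse)
  out <- matrix(0, nrow(states), coarse$n_species)
  colnames(out) <- coarse$species$name
  for (j in seq_len(coarse$n_species)) {
    members <- which(vapply(fine_spans, function(sp)
      all(sp %in% coarse_spans[[j]]), logical(1)))
    pooled <- states[, members, drop = FALSE] %*% wf[members]
    out[, j] <- pooled / wc[j]
  }
  if (inherits(traj, "rom_trajectory")) {
    traj$states <- out
    traj$model_id <- coarse$model_id
    traj$species <- coarse$species$name
    traj
  } else out
}
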