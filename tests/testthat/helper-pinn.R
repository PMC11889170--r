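# Assemble trainer inputs for a tiny problem, mirroring fit_rom's plumbing,
# so the loss/gradient kernel can be checked against finite differences.

pinn_toy_inputs <- function(model, n_t = 4, n_exp = 2, width = 3,
                            hidden = 2, seed = 99, tau_w = NA_real_,
                            ic = TRUE) {
  set.seed(seed)
  t_scale <- 10
  times <- lapply(seq_len(n_exp), function(i) seq(0, t_scale,
                                                  length.out = n_t))
  nsp <- model$n_species
  Y <- lapply(seq_len(n_exp), function(i)
    matrix(stats::runif(n_t * nsp, 0, 2), n_t, nsp))
  M <- lapply(seq_len(n_exp), function(i) matrix(1, n_t, nsp))
  y0s <- lapply(seq_len(n_exp), function(i) c(2, rep(0, nsp - 1)))
  if (!ic) y0s <- lapply(y0s, function(v) v * 0)
  nets <- replicate(n_exp, romkin:::.init_net(width, hidden, nsp),
                    simplify = FALSE)
  # move biases off zero: with zero biases the net output vanishes exactly
  # at t = 0, parking some physics residuals on the |.| kink where the
  # one-sided finite difference and the subgradient legitimately disagree
  nets <- lapply(nets, function(n) {
    n$b <- lapply(n$b, function(b) stats::runif(length(b), -0.2, 0.2))
    n
  })
  s <- rep(1.5, nsp)
  tau0 <- 0.2
  if (ic) {
    gs <- lapply(times, function(tt) 1 - exp(-(tt / t_scale) / tau0))
    gds <- lapply(times, function(tt)
      exp(-(tt / t_scale) / tau0) / (tau0 * t_scale))
  } else {
    gs <- lapply(times, function(tt) rep(1, length(tt)))
    gds <- lapply(times, function(tt) rep(0, length(tt)))
  }
  xw <- romkin:::.time_warp(times, t_scale, tau_w)
  list(x = xw$x, xd = xw$xd,
       Yt = lapply(Y, t), Mt = lapply(M, t), y0s = y0s, s = s,
       gs = gs, gds = gds, nets = nets,
       reactions = romkin:::.reaction_struct(model))
}

pinn_toy_eval <- function(inp, a, w_data = 1, w_phys = 1, literal = 0) {
  romkin:::pinn_loss_grad_cpp(inp$x, inp$xd, inp$Yt, inp$Mt, inp$y0s, inp$s,
                              inp$gs, inp$gds, inp$nets, a, inp$reactions,
                              w_data, w_phys, literal)
}
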