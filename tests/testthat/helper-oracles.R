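# Independent hand-coded right-hand sides for all eight models, written
# directly from the printed equation lists, sharing no code with the
# package implementation.  States and parameters are named explicitly.

oracle_rhs <- list(
  # Model 1: B1_35 <-> B4, order c
  function(st, p, o) {
    c(p["a1"] * o["c"] * st["B4"] - p["a2"] * o["c"] * st["B1_35"]^o["c"],
      p["a2"] * st["B1_35"]^o["c"] - p["a1"] * st["B4"])
  },
  # Model 2: B1 <-> B1_7 <-> B4, orders n, m
  function(st, p, o) {
    c(p["a1"] * o["n"] * st["B1_7"] - p["a2"] * o["n"] * st["B1"]^o["n"],
      p["a2"] * st["B1"]^o["n"] - p["a1"] * st["B1_7"] +
        p["a3"] * o["m"] * st["B4"] - p["a4"] * o["m"] * st["B1_7"]^o["m"],
      p["a4"] * st["B1_7"]^o["m"] - p["a3"] * st["B4"])
  },
  # Model 3: B1_35 <-> B3 <-> B5
  function(st, p, o) {
    c(p["a1"] * o["n"] * st["B3"] - p["a2"] * o["n"] * st["B1_35"]^o["n"],
      p["a2"] * st["B1_35"]^o["n"] - p["a1"] * st["B3"] +
        p["a3"] * o["m"] * st["B5"] - p["a4"] * o["m"] * st["B3"]^o["m"],
      p["a4"] * st["B3"]^o["m"] - p["a3"] * st["B5"])
  },
  # Model 4: B1 <-> B1_7 <-> B3 <-> B5
  function(st, p, o) {
    c(p["a1"] * o["n"] * st["B1_7"] - p["a2"] * o["n"] * st["B1"]^o["n"],
      p["a2"] * st["B1"]^o["n"] - p["a1"] * st["B1_7"] +
        p["a3"] * o["m"] * st["B3"] - p["a4"] * o["m"] * st["B1_7"]^o["m"],
      p["a4"] * st["B1_7"]^o["m"] - p["a3"] * st["B3"] +
        p["a5"] * o["s"] * st["B5"] - p["a6"] * o["s"] * st["B3"]^o["s"],
      p["a6"] * st["B3"]^o["s"] - p["a5"] * st["B5"])
  },
  # Model 5: B1_2 <-> B2 <-> B4
  function(st, p, o) {
    c(p["a1"] * o["n"] * st["B2"] - p["a2"] * o["n"] * st["B1_2"]^o["n"],
      p["a2"] * st["B1_2"]^o["n"] - p["a1"] * st["B2"] +
        p["a3"] * o["m"] * st["B4"] - p["a4"] * o["m"] * st["B2"]^o["m"],
      p["a4"] * st["B2"]^o["m"] - p["a3"] * st["B4"])
  },
  # Model 6: B1 <-> B1_4 <-> B2 <-> B4
  function(st, p, o) {
    c(p["a1"] * o["n"] * st["B1_4"] - p["a2"] * o["n"] * st["B1"]^o["n"],
      p["a2"] * st["B1"]^o["n"] - p["a1"] * st["B1_4"] +
        p["a3"] * o["m"] * st["B2"] - p["a4"] * o["m"] * st["B1_4"]^o["m"],
      p["a4"] * st["B1_4"]^o["m"] - p["a3"] * st["B2"] +
        p["a5"] * o["s"] * st["B4"] - p["a6"] * o["s"] * st["B2"]^o["s"],
      p["a6"] * st["B2"]^o["s"] - p["a5"] * st["B4"])
  },
  # Model 7: B1_2 <-> B2 <-> B3 <-> B5
  function(st, p, o) {
    c(p["a1"] * o["n"] * st["B2"] - p["a2"] * o["n"] * st["B1_2"]^o["n"],
      p["a2"] * st["B1_2"]^o["n"] - p["a1"] * st["B2"] +
        p["a3"] * o["m"] * st["B3"] - p["a4"] * o["m"] * st["B2"]^o["m"],
      p["a4"] * st["B2"]^o["m"] - p["a3"] * st["B3"] +
        p["a5"] * o["s"] * st["B5"] - p["a6"] * o["s"] * st["B3"]^o["s"],
      p["a6"] * st["B3"]^o["s"] - p["a5"] * st["B5"])
  },
  # Model 8: B1 <-> B1_4 <-> B2 <-> B3 <-> B5
  function(st, p, o) {
    c(p["a1"] * o["n"] * st["B1_4"] - p["a2"] * o["n"] * st["B1"]^o["n"],
      p["a2"] * st["B1"]^o["n"] - p["a1"] * st["B1_4"] +
        p["a3"] * o["m"] * st["B2"] - p["a4"] * o["m"] * st["B1_4"]^o["m"],
      p["a4"] * st["B1_4"]^o["m"] - p["a3"] * st["B2"] +
        p["a5"] * o["s"] * st["B3"] - p["a6"] * o["s"] * st["B2"]^o["s"],
      p["a6"] * st["B2"]^o["s"] - p["a5"] * st["B3"] +
        p["a7"] * o["p"] * st["B5"] - p["a8"] * o["p"] * st["B3"]^o["p"],
      p["a8"] * st["B3"]^o["p"] - p["a7"] * st["B5"])
  }
)

# species names per model, for building named oracle states
oracle_species <- list(
  c("B1_35", "B4"),
  c("B1", "B1_7", "B4"),
  c("B1_35", "B3", "B5"),
  c("B1", "B1_7", "B3", "B5"),
  c("B1_2", "B2", "B4"),
  c("B1", "B1_4", "B2", "B4"),
  c("B1_2", "B2", "B3", "B5"),
  c("B1", "B1_4", "B2", "B3", "B5")
)

oracle_orders <- list(
  c(c = 2), c(n = 2, m = 2), c(n = 2, m = 2), c(n = 2, m = 2, s = 2),
  c(n = 2, m = 2), c(n = 2, m = 2, s = 2), c(n = 2, m = 2, s = 2),
  c(n = 2, m = 2, s = 2, p = 2)
)

random_params <- function(model, sd = NULL) {
  stats::setNames(stats::runif(model$n_params, 0, 1), model$param_names)
}
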