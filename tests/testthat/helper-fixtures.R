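# Shared, lazily computed fixtures for the test suite. Wave solves take a
# second or two, so each is computed once per test run and cached.

fw_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = fw_cache))
    assign(name, force(expr), envir = fw_cache)
  get(name, envir = fw_cache)
}

sym_fixture <- function() cached("sym_fx", fixture_generator("symmetric_standing"))
asym_fixture <- function() cached("asym_fx", fixture_generator("asymmetric_traveling"))

sym_wave <- function() cached("sym_wave", {
  fx <- sym_fixture()
  solve_wave(fx$F, fx$w, n_grid = 513L)
})

asym_wave <- function() cached("asym_wave", {
  fx <- asym_fixture()
  solve_wave(fx$F, fx$w, n_grid = 1025L)
})

# standard small lattice used by the Markov-chain experiments
lln_geometry <- function() cached("lln_geom", {
  fx <- sym_fixture()
  discretize_weights(fx$w, 4, 2)   # P = 16
})

# interior front-shaped initial activities on that lattice
lln_x0 <- function() cached("lln_x0", {
  fx <- sym_fixture()
  g <- lln_geometry()
  gain_eval(fx$F, fx$F$a1 + (fx$F$a2 - fx$F$a1) *
              stats::plogis(2 * g$positions))
})
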