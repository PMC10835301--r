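# Shared fixtures: grids and specs kept deliberately small so the whole
# suite stays fast; the methods under test are resolution-independent.

# short noiseless/analysis grid: 10 days at 0.01 h, store every 0.1 h
short_grid <- function(days = 10, dt = 0.01, stride = 10L, transient = 0) {
  sim_grid(dt = dt, t_end = days * 24, transient = transient,
           record_stride = stride)
}

# reduced Goodwin grid: 50 days, 10-day transient (>> the ~23.6 h cycle)
goodwin_test_grid <- function() {
  sim_grid(dt = 0.05, t_end = 1200, transient = 240, record_stride = 1L)
}

# drift of a single Poincare oscillator as a plain function, for use with
# the generic integrators
poincare_drift <- function(p) {
  function(t, s) ensemble_drift(s, list(p))
}
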