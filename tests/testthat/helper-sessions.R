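# shared small session configurations used across test files

# two-region session with a planted synchronous ensemble
ensemble_config <- function(seed, duration_s = 240, sp_rate_hz = 0.06,
                            n_cbl = 10L, n_ctx = 10L, frac = 0.3, ...) {
  synth_config(
    n_cells = c(CBL = n_cbl, CTX = n_ctx),
    sp_ensemble_fraction = c(CBL = frac, CTX = frac),
    duration_s = duration_s, sp_rate_hz = sp_rate_hz,
    p_move_given_sp = 0, seed = seed, ...
  )
}

default_onset_params <- function(...) {
  onset_params(t_half_s = c(CBL = 0.217, CTX = 0.488), ...)
}
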