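## memoised expensive simulations shared across test files
.bw_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .bw_cache))
    assign(key, force(expr), envir = .bw_cache)
  get(key, envir = .bw_cache)
}

## endogenous bursting attractor at the reference point of the bursting
## region (theta_K2 = -0.0075, theta_h = 0.038)
colD_trace <- function() cached("colD", {
  run_to_attractor(neuron_params(), t_transient = 100, t_record = 200)
})

colD_stats <- function() cached("colD_stats", trace_stats(colD_trace()))

## 5-cell chain at the fastest coregulation-path instantiation
row1_experiment <- function() cached("row1", {
  p <- neuron_params(theta_K2 = 0.0059, theta_h = 0.040736)
  run_metachronal_experiment(build_chain(params = p), n_cycles = 12)
})

row1_cell_stats <- function() cached("row1_cell", {
  p <- neuron_params(theta_K2 = 0.0059, theta_h = 0.040736)
  trace_stats(run_to_attractor(p, t_transient = 150, t_record = 300))
})
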