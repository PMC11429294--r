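# shared fixtures: the reference E. coli design point
ecoli_params <- function(initial_total = 1e4) {
  selection_parameters(mu1 = 0.25, mu2 = -0.7, f = 1e-4, s = 0.02,
                       initial_total = initial_total)
}

ecoli_schedule <- function() {
  build_schedule(required_time(ecoli_params()),
                 generation_time = log(2) / 0.25)
}

# independent oracle for the required selection time: direct evaluation of
# the closed form, bypassing the package's requirement object
oracle_required_time <- function(mu1, mu2, f, s) {
  log(s * f / (1 - f)) / (mu2 - mu1)
}
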