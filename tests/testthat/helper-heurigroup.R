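# small builders shared across test files

# option set with binary cues given directly (continuous slot mirrors them,
# shifted so that dichotomize() at 0 reproduces the binaries)
binary_option_set <- function(criterion, cues_bin) {
  cues_bin <- as.matrix(cues_bin)
  option_set(criterion, cues_cont = cues_bin - 0.5, cues_bin = cues_bin)
}

# signal-free environment: criterion is pure noise, cues carry nothing
noise_only_env <- function() {
  task_environment("noise-only", betas = rep(0, 5), beta_e = 1)
}

ld_env <- function() task_environment("LD")
sd_env <- function() task_environment("SD")
nd_env <- function() task_environment("ND")
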