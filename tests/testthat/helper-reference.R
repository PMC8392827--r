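# shared fixtures and a per-session cache so the expensive PSO runs are
# computed once and reused across test files

ref_init <- function() reference_initial_state()[1:3]

.fermco2_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fermco2_cache)) {
    assign(key, force(expr), envir = .fermco2_cache)
  }
  get(key, envir = .fermco2_cache)
}

ref_const_ds <- function() cached("dsc", reference_constant_dataset())
ref_step_ds <- function() cached("dss", reference_step_dataset(3))

stage1_run <- function(seed) {
  cached(paste0("s1_", seed),
         identify_stage1(ref_const_ds(), ref_init(), seed = seed))
}

stage2_run <- function(seed) {
  cached(paste0("s2_", seed),
         identify_stage2(ref_step_ds(), reference_parameters(), ref_init(),
                         seed = seed))
}

rel_err <- function(x, truth) abs(x - truth) / abs(truth)
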