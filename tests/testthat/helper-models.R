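# Shared fixtures: small compiled models built once per test run.

fast_params <- function(...) ffl_params(...)

# an input-plus-single-unregulated-node model: the two linear subsystems
# with exact closed-form moments
input_node_crn <- function(fano = 1.83, mean = 6, total = 60) {
  e <- fflnoise:::.entry(
    "input-node", "isolated", c("S", "X"),
    data.frame(from = character(0), to = character(0),
               sign = integer(0), stringsAsFactors = FALSE),
    character(0), logical(0), character(0), "n/a")
  fflnoise:::.assemble_crn(e, "one-step", ffl_params(total = total),
                           calibrate_input(fano, mean), NA_real_)
}

c1_or <- local({
  crn <- NULL
  function() {
    if (is.null(crn)) crn <<- build_model(catalog_entry("c1-OR"))
    crn
  }
})
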