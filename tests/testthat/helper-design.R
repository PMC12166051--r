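# The default design is deterministic; build it once per test run.
ynat_test_design <- local({
  cached <- NULL
  function() {
    if (is.null(cached)) cached <<- build_default_design()
    cached
  }
})

# flat vector of all 320 goal offsets of a design, in session order
design_offsets <- function(design) {
  unlist(lapply(design$blocks, `[[`, "offsets"), use.names = FALSE)
}
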