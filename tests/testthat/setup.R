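# report every expectation: the acceptance checks at the end of the suite
# must not curtail the run
options(testthat.progress.max_fails = Inf)
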