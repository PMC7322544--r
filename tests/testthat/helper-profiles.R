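# Shared small-scale simulation profiles. The control protocol is reused
# across files so each variant's steady state is computed once per session
# (ord_steady_state caches on variant + protocol).
ctrl_protocol <- pacing_protocol(n_beats = 100)
drug_protocol <- pacing_protocol(n_beats = 40)

test_population <- local({
  pop <- NULL
  function() {
    if (is.null(pop)) pop <<- sample_population(5, seed = 11)
    pop
  }
})

pure_ikr_block <- list(IKr = list(ic50 = 1, hill = 1))
balanced_block <- list(IKr = list(ic50 = 3, hill = 1),
                       ICaL = list(ic50 = 1.5, hill = 1))
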