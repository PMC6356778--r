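# Shared full-scale ladder runs (1 Mb, 30 individuals) for the acceptance
# checks.  Computed lazily and memoised so several tests reuse one run.

.ladderCache <- new.env(parent = emptyenv())

ladderRun <- function(seed) {
  key <- paste0("seed", seed)
  if (is.null(.ladderCache[[key]]))
    .ladderCache[[key]] <- runComparison(simConfig(seed = seed),
                                         mantelIterations = 199L)
  .ladderCache[[key]]
}
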