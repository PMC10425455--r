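# Shared synthetic fixtures, built once per test run.

.fixtureEnv <- new.env()

# 200-fruit quality table + SNV spectra under the default generator
synthFixture <- function() {
  if (is.null(.fixtureEnv$fx)) {
    params <- synthSpectraParams()
    tab <- simulateQualityTable(200, seed = 100)
    spec <- simulateSpectra(tab, params, seed = 101)
    .fixtureEnv$fx <- list(params = params, table = tab, raw = spec,
                           snv = snv(spec))
  }
  .fixtureEnv$fx
}

# small deterministic scene for cube tests
sceneFixture <- function() {
  if (is.null(.fixtureEnv$scene)) {
    tab <- simulateQualityTable(5, seed = 2)
    .fixtureEnv$scene <- c(simulateScene(tab[3, ], 48, 48, seed = 4),
                           list(record = tab[3, ]))
  }
  .fixtureEnv$scene
}
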