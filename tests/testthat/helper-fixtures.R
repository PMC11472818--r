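# shared fixtures: scaffold, the four analog candidates, tiny spectra
fx_scaffold <- buildDelftibactinScaffold()

fx_tails <- list(`C14:1` = lipidTail(14, 1), `C14:0` = lipidTail(14, 0),
                 `C12:1` = lipidTail(12, 1), `C12:0` = lipidTail(12, 0))

fx_candidates <- lapply(fx_tails, analogFormula, sc = fx_scaffold)

fx_parent <- analogFormula(fx_scaffold, NULL)

# minimal two-peak spectrum helper
fx_spectrum <- function(id, prec, mz, intensity = rep(1, length(mz)),
                        sampleId = "s") {
  spectrum(id, prec, cbind(mz, intensity), sampleId = sampleId)
}
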