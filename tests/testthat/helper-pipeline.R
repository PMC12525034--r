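# Render a scene and push it through the full chain with the shared fixtures.
runSynthetic <- function(scn, model = noiselessModel(), seed = 1,
                         lut = testLUT(), table = testExtinction(),
                         phantom = testPhantom(table)) {
  raw <- renderRaw(scn, model, lut, table, phantom, seed = seed)
  runPipeline(raw, lut, table, phantom)
}

# ROI trend rows for one quantity over a list of pipeline results
trendRows <- function(results, quantity, wavelength, roi) {
  do.call(rbind, lapply(seq_along(results), function(t) {
    pm <- results[[t]]$props[[as.character(wavelength)]]
    vals <- if (quantity == "mu_s_prime") pm@mu_s_prime else pm@mu_a
    st <- roiStats(vals, pm@valid_mask, roi)
    data.frame(timepoint = t, quantity = quantity, wavelength = wavelength,
               mean = st$mean, sd = st$sd)
  }))
}
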