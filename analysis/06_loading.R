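#!/usr/bin/env Rscript
# Render and verify the bioreactor chewing-simulation waveform: 10
# pre-cycles at 0.25 Hz between -5 and -45 N, then 1,400 cycles at 1 Hz
# between -5 and -100 N, sampled at 100 Hz.

library(periomap)

dir.create("results", showWarnings = FALSE)

regime <- default_regime()
print(as.data.frame(regime))

wave <- render_waveform(regime, sample_rate = 100)
cat(sprintf("total duration: %g s; force span: [%g, %g] N\n",
            nrow(wave) / 100, min(wave$force_N), max(wave$force_N)))
cat(sprintf("counted cycles: pre = %d, main = %d\n",
            count_cycles(wave, "pre_cycle"), count_cycles(wave, "main")))

write_waveform_csv(wave, "results/chewing_waveform.csv")
cat("written: results/chewing_waveform.csv\n")
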