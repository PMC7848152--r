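#!/usr/bin/env Rscript
# Calibrate the phantom slice to a per-pixel porosity map with the
# two-endpoint linear scale (air -> 100% porosity, cortical -> 0%), and
# check that quantile-based endpoint estimation lands near the configured
# levels despite greyscale noise.

library(periomap)

dir.create("results", showWarnings = FALSE)

params <- phantom_params()
phantom <- make_phantom(params)

est <- estimate_endpoints(phantom$slice)     # 1%/99% quantile estimate
cat(sprintf("estimated endpoints: air = %.1f, cortical = %.1f (true: %g, %g)\n",
            est["air_endpoint"], est["cortical_endpoint"],
            params$levels["air"], params$levels["cortical"]))

porosity <- calibrate_porosity(phantom$slice,
                               air_endpoint = params$levels[["air"]],
                               cortical_endpoint = params$levels[["cortical"]])
print(porosity)

write_porosity(porosity, "results/porosity.tif", "results/porosity.png")
cat("written: results/porosity.tif, results/porosity.png\n")
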