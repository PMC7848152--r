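#!/usr/bin/env Rscript
# Generate the labelled molar-in-mandible phantom slice that stands in for
# the coronal microCT slice: cortical shell, graded trabecular bone,
# two-rooted tooth with an enclosed furcation, PDL gap, gingival cap,
# inferior alveolar canal, and the three medium inlets (two at the
# junctional epithelium, one at the canal).

library(periomap)

dir.create("results", showWarnings = FALSE)

phantom <- make_phantom(phantom_params())
print(phantom)

paths <- write_phantom(phantom, "results", "phantom")
cat("written:\n"); print(unname(paths))

counts <- table(attr(phantom$labels, "classes")[as.character(phantom$labels)])
write.csv(data.frame(class = names(counts), pixels = as.integer(counts)),
          "results/phantom_class_counts.csv", row.names = FALSE)
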