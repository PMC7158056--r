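#!/usr/bin/env Rscript
# Quantify the simulated GC/MS olefin peak table against its triacontane
# internal standard (40 ug: 4 mL hexane x 10 ug/mL), normalize per mL of
# culture and to OD600 = 1, and summarize the chain-length x isomer-class
# profile.

suppressMessages(library(olekit))
dir.create("results/lipids", showWarnings = FALSE, recursive = TRUE)

peaks <- read_peak_table("results/inputs/peaks_host.csv")
pr <- quantify_peaks(peaks,
                     is_spec = list(compound = "triacontane", amount_ug = 40),
                     ctx = list(culture_volume_mL = 10, od600 = 1.4))
print(pr)
m <- marginal_distributions(pr)
message("Chain-length marginal:")
print(round(m$chain, 3))
message("Isomer-class marginal:")
print(round(m$isomer, 3))
message(sprintf("Modal chain length: C%s",
                names(m$chain)[which.max(m$chain)]))
write.csv(pr$amounts, "results/lipids/profile.csv", row.names = FALSE)
jsonlite::write_json(list(chain = as.list(m$chain),
                          isomer = as.list(m$isomer)),
                     "results/lipids/marginals.json", auto_unbox = TRUE,
                     digits = NA)
message("Wrote results/lipids/ (profile.csv, marginals.json)")
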