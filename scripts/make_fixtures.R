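#!/usr/bin/env Rscript
# Regenerates the JSON model resources under inst/extdata/ from the
# published-parameter constructors, plus a small synthetic demonstration
# spectra file. Deterministic; run from the repository root.

suppressPackageStartupMessages(library(mimicolor))

fixdir <- file.path("inst", "extdata", "fixtures")
dir.create(fixdir, recursive = TRUE, showWarnings = FALSE)

fx <- bee_fixtures()
write_discrimination_json(fx$successive_blue,
                          file.path(fixdir, "successive_blue.json"))
write_discrimination_json(fx$successive_yellow,
                          file.path(fixdir, "successive_yellow.json"))
write_discrimination_json(fx$absolute, file.path(fixdir, "absolute.json"))
for (nm in names(fx$pdfs))
  write_pdf_json(fx$pdfs[[nm]], file.path(fixdir, paste0(nm, ".json")))

# synthetic UV-blue flower spectra for the worked example (not measured data)
set.seed(1234)
specs <- lapply(1:6, function(i)
  make_spectrum(baseline = 0.04,
                components = data.frame(center = c(350, 438 + rnorm(1, 0, 5)),
                                        width = c(40, 52),
                                        amplitude = c(0.22, 0.35)),
                noise_sd = 0.004))
names(specs) <- sprintf("synthetic_flower_%02d", 1:6)
write_spectra_csv(specs, file.path("inst", "extdata",
                                   "synthetic_flower_spectra.csv"))
cat("fixtures written under inst/extdata/\n")
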