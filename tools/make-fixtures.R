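# Regenerates the packaged text fixtures under inst/extdata/ from the
# in-code definitions: one community directory (CSV parameter frames +
# manifest) per builtin community, and the synthetic bioreactor
# observation set. Run from the package root after changing the builtin
# definitions: Rscript tools/make-fixtures.R

library(coreferm)

for (which in c("bioreactor", "cm_only", "others_only")) {
  comm <- builtin_community(which)
  write_community(comm, file.path("inst", "extdata", "communities", which))
}

# Synthetic observation series emulating the bioreactor time courses the
# model is scored against. Genus values are pseudo-log10 bacteria/L,
# SCFAs are mM; lactate is undetected at every sampled time. All values
# are constructed (hence "synthetic" in the file name), shaped to the
# reported averages and end points of the fermentation: persisting genera
# fluctuate around a constant level, washed-out genera decline linearly.
times <- default_sampling_times()
nt <- length(times)

persister <- function(base, wiggle) {
  base + wiggle[seq_len(nt)]
}
w1 <- c(-0.16, 0.04, 0.14, 0.24, 0.14, 0.04, 0.04, -0.06, -0.06, -0.06,
        -0.16, -0.06, -0.06)
w2 <- c(-0.13, -0.03, 0.07, 0.17, 0.07, 0.07, -0.03, -0.03, -0.03, -0.03,
        -0.03, -0.03, -0.03)
w3 <- c(-0.16, 0.14, 0.44, 0.24, 0.04, -0.26, 0.04, -0.06, 0.14, -0.16,
        0.04, -0.06, -0.06)

decline <- function(start, end) start + (end - start) * times / max(times)

genus_series <- list(
  Prevotella            = persister(12.46, w1),
  Megasphaera           = persister(11.13, w2),
  others                = persister(12.50, w2 / 2),
  Succinivibrio         = persister(9.86, w3),
  Blautia               = persister(9.91, w2),
  Ruminococcus          = persister(10.72, w1),
  RC9                   = decline(11.28, 6.2),
  Streptococcus         = decline(11.41, 5.9),
  Lactobacillus         = decline(10.99, 5.6),
  Alloprevotella        = decline(11.07, 6.0),
  Clostridium           = decline(11.24, 5.8),
  Treponema             = decline(10.49, 5.5),
  Faecalibacterium      = decline(10.49, 6.1),
  Phascolarctobacterium = decline(10.16, 0),
  Parabacteroides       = decline(9.30, 5.2),
  Escherichia           = decline(8.70, 4.9),
  Turicibacter          = decline(9.55, 5.3)
)

scfa_series <- list(
  acetate    = c(25.88, 80.62, 70.5, 62.3, 55.4, 58.9, 50.77, 49.2, 48.5,
                 48.1, 47.9, 47.8, 47.69),
  propionate = c(10.68, 49.04, 45.2, 38.72, 41.0, 40.1, 39.3, 35.68, 34.9,
                 34.2, 33.6, 33.0, 32.68),
  butyrate   = c(6.00, 20.5, 21.2, 21.0, 21.3, 27.9, 26.5, 26.0, 26.4,
                 26.6, 26.8, 26.9, 26.90),
  lactate    = rep(0, nt)
)

obs <- dplyr::bind_rows(
  purrr::imap_dfr(genus_series, function(v, nm) {
    tibble::tibble(time_h = times, variable = nm, kind = "genus",
                   value = round(pmax(v, 0), 2))
  }),
  purrr::imap_dfr(scfa_series, function(v, nm) {
    tibble::tibble(time_h = times, variable = nm, kind = "scfa",
                   value = v)
  })
)
dir.create(file.path("inst", "extdata", "observations"),
           showWarnings = FALSE, recursive = TRUE)
write_observations(obs, file.path("inst", "extdata", "observations",
                                  "bioreactor_observations_synthetic.tsv"))
cat("fixtures written\n")
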