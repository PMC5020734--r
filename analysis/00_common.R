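# shared setup for the numbered analysis scripts: seed, paths, and the
# study conditions (survey effort by year, life-cycle structure, scheme)
suppressMessages(library(coralmpm))

seed <- {
  a <- commandArgs(trailingOnly = TRUE)
  i <- match("--seed", a)
  if (is.na(i) || i == length(a)) 1L else as.integer(a[i + 1])
}

res_dir <- "results"
dir.create(res_dir, showWarnings = FALSE)

scheme <- size_class_scheme()
struct <- porites_structure()

# survey effort mirroring the monitoring record: 20 transects in 2007,
# 3 in 2010, 6 in 2013 and 2014; 2008-09 and 2011-12 unsurveyed
effort <- stats::setNames(c(20L, 3L, 6L, 6L), c(2007, 2010, 2013, 2014))
start_year <- 2007L
ref_transects <- 6L
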