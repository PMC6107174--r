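#!/usr/bin/env Rscript
# Step 1: generate the synthetic study cohort.
#
# The cohort mirrors the repeated-measures sway design: 21 subjects, each
# measured once under wind stimulation (condition 1) and once without
# (condition 0), one 6012-sample displacement series per measurement at
# 50 samples/s. Wind series carry the "narrowing" nonlinearity (amplitude-
# stabilised frequency modulation, so their multifractal spectra should
# come out narrower than their linear surrogates); no-wind series carry
# the "widening" mechanism (cascade amplitude coupling). Writes one
# delimited file per series plus the manifest and the generating spec.

library(mfsway)

out_dir <- "results/cohort"
spec <- cohort_spec(seed = 101)
coh <- synth_cohort(spec)
man_path <- write_cohort(coh, out_dir)

cat(sprintf("wrote %d series (%d subjects x 2 conditions, %d samples each)\n",
            length(coh$series), spec$n_subjects, spec$series_length))
cat("manifest:", man_path, "\n")
print(head(coh$truth))
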