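#!/usr/bin/env Rscript
# Resistance values and cross-reactivity profile of the specificity panel
# simulated in 01_simulate_panels.R. The main target defines 100%;
# entries below 10% are annotated not significant.

suppressMessages(library(exoprofiler))

plate <- read_timecourses("results/profile_timecourses.csv")
rt <- resistance_table(plate)
profile <- build_profile(rt, reference_ligand = "mephedrone")

write_results(list(profile_resistance = rt,
                   cross_reactivity = profile), "results")
message("ligands profiled: ", nrow(profile))
message("reference (mephedrone) CR: ",
        profile$cr_percent[profile$annotation == "reference"], "%")
analog <- profile[profile$ligand_id == "methedrone", ]
message("10-fold-weaker analog (methedrone) CR: ",
        round(analog$cr_percent, 1), "% [", analog$annotation, "]")
message("not-significant ligands: ",
        paste(profile$ligand_id[profile$annotation == "not significant"],
              collapse = ", "))

jsonlite::write_json(
  list(script = "02_profile_cross_reactivity.R",
       reference_ligand = "mephedrone", significance_bound = 10,
       inputs = "profile_timecourses.csv",
       outputs = c("profile_resistance.csv", "cross_reactivity.csv")),
  "results/02_provenance.json", auto_unbox = TRUE)
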