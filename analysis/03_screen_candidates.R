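#!/usr/bin/env Rscript
# Call binders among the 29 screened candidates from their resistance
# values at the shared 200 uM screening concentration (threshold 0.1).

suppressMessages(library(exoprofiler))

plate <- read_timecourses("results/screen_timecourses.csv")
rt <- resistance_table(plate)
calls <- call_binders(rt, threshold = 0.1)

write_results(list(screen_resistance = rt, screen_calls = calls), "results")
binders <- calls[calls$call == "binder", ]
message(nrow(calls), " candidates screened; ", nrow(binders),
        " binders called: ", paste(binders$aptamer_id, collapse = ", "))
message("binder resistance range: ",
        round(min(binders$resistance_mean), 2), " - ",
        round(max(binders$resistance_mean), 2))
message("non-binder |R| maximum: ",
        round(max(abs(calls$resistance_mean[calls$call == "non-binder"])), 3))

jsonlite::write_json(
  list(script = "03_screen_candidates.R", threshold = 0.1,
       inputs = "screen_timecourses.csv",
       outputs = c("screen_resistance.csv", "screen_calls.csv")),
  "results/03_provenance.json", auto_unbox = TRUE)
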