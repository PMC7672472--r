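#!/usr/bin/env Rscript
# Simulate the synthetic plate experiments every later stage consumes:
#  - a 29-candidate mephedrone screen (control + 200 uM target, 2 replicates)
#  - a 6-ligand specificity panel for one high-affinity aptamer
#  - a 7-point calibration concentration series (0-800 uM, 3 replicates)
# Writes long-format time-course CSVs plus a provenance JSON under results/.

suppressMessages(library(exoprofiler))

seed <- 20260926L
out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)

# screen: candidates read from the bundled synthetic panel files
fa <- system.file("extdata", "synthetic_mephedrone_panel.fasta",
                  package = "exoprofiler")
bt <- read_binding_table(system.file("extdata",
                                     "synthetic_binding_table.csv",
                                     package = "exoprofiler"))
aptamers <- read_aptamer_panel(fa)
screen_plate <- simulate_panel(aptamers,
                               list(ligand_condition("mephedrone", 200)),
                               bt, n_replicates = 2,
                               params = digestion_params(noise_cv = 0.05),
                               seed = seed)
write_timecourses(screen_plate, file.path(out_dir, "screen_timecourses.csv"))
message("screen: ", length(aptamers), " candidates, ",
        nrow(screen_plate), " reads -> results/screen_timecourses.csv")

# specificity profile: one aptamer against a 6-ligand panel at 200 uM
prof <- profile_ligand_panel()
profile_plate <- simulate_panel(list(prof$aptamer), prof$conditions,
                                prof$binding_table, n_replicates = 3,
                                seed = seed + 1L)
write_timecourses(profile_plate, file.path(out_dir, "profile_timecourses.csv"))
message("profile: ", length(prof$conditions), " ligands -> ",
        "results/profile_timecourses.csv")

# calibration series for dose-response fitting (true apparent Kd 100 uM)
cal_apt <- aptamer_spec("CAL", 73, 42)
cal_bind <- binding_params("CAL", "mdpv", 100)
conds <- lapply(setdiff(calibration_concentrations(), 0), function(cc) {
  ligand_condition("mdpv", cc)
})
cal_plate <- simulate_panel(list(cal_apt), conds,
                            data.frame(aptamer_id = "CAL", ligand_id = "mdpv",
                                       kd_app = 100),
                            n_replicates = 3, seed = seed + 2L)
write_timecourses(cal_plate, file.path(out_dir, "calibration_timecourses.csv"))
message("calibration: ", length(conds) + 1, " concentrations -> ",
        "results/calibration_timecourses.csv")

jsonlite::write_json(
  list(script = "01_simulate_panels.R", seed = seed,
       package_version = as.character(utils::packageVersion("exoprofiler")),
       outputs = c("screen_timecourses.csv", "profile_timecourses.csv",
                   "calibration_timecourses.csv")),
  file.path(out_dir, "01_provenance.json"), auto_unbox = TRUE)
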