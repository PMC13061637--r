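#!/usr/bin/env Rscript
# Stage 4: diffusive O2 uptake (SCOC) from the simulated porewater
# microprofile via Fick's first law.

library(darkoxygen)

dir.create("results/scoc", recursive = TRUE, showWarnings = FALSE)
cfg <- profile_sim_config(seed = derive_seed(20210521L, 50L))
sim <- simulate_microprofile(cfg)
prof <- average_replicates(sim$readings)
idx <- detect_surface(prof)
ds <- effective_diffusivity(D0_O2_DEEPSEA, cfg$porosity)
res <- scoc_fick(prof, cfg$porosity, ds, surface_index = idx)
print(res)
cat(sprintf("detected interface at %.2f mm (true %.2f mm)\n",
            prof$depth_mm[idx], sim$truth$surface_depth_mm))
cat(sprintf("generating flux %.2f mmol m-2 d-1; porewater is a net O2 sink\n",
            cfg$true_flux))
write_result_table(
  data.frame(flux_mmol_m2_d = res$flux, gradient_umol_l_mm = res$gradient,
             surface_mm = prof$depth_mm[idx], porosity = cfg$porosity,
             ds_cm2_s = ds, true_flux = cfg$true_flux),
  "results/scoc/microprofile_scoc.csv")
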