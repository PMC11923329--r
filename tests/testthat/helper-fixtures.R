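# Shared scaled-down pipeline fixture: an 8-patient phantom cohort at
# 64-pixel network input with one-epoch stages. Structure-complete but fast.
tiny_pipeline <- function(seed = 1L, n_runs = 1L, regimes = c(0, 1.0)) {
  pipeline_config(
    phantom = phantom_config(image_height = 96L, image_width = 80L,
                             n_patients = 8L,
                             lesion_radius_range = c(18L, 20L),
                             lesion_count_range = c(1L, 1L), seed = seed),
    scan = scan_params(scan_patch_size = 32L, scan_stride = 16L),
    target_size = 64L,
    backbone = backbone_config("tiny"),
    curriculum = curriculum_config(stage_patch_sizes = c(8L, 16L),
                                   stage_epochs = 1L, final_epochs = 1L,
                                   learning_rate = 1e-3, n_runs = n_runs),
    regimes = regimes, dev_fraction = 0.75, seed = seed
  )
}
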