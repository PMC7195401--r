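# Frozen experiment worlds shared by the acceptance tests (and a few unit
# tests).  Settings were fixed before the acceptance results were read off;
# see the methods vignette for the rationale of every number.
#
# Slides are rendered in memory and quantised to 8 bits per channel --
# bit-identical to a PPM write/read round trip -- so tiling here produces
# exactly the patches a disk-based cohort would.

.world_cache <- new.env(parent = emptyenv())

world_memo <- function(key, fn) {
  if (!exists(key, envir = .world_cache)) assign(key, fn(), envir = .world_cache)
  get(key, envir = .world_cache)
}

quantize_levels <- function(pyr) {
  pyr$levels <- lapply(pyr$levels, function(l) round(l * 255) / 255)
  pyr
}

# render + tile one planned cohort row (1024^2 base, 2 levels, level 0)
tile_row <- function(row, shift = stain_shift()) {
  pyr <- quantize_levels(slideuq:::render_cohort_row(
    row, base_size = c(1024L, 1024L), n_levels = 2L, ring_contrast = 0.6,
    shift = shift))
  ps <- extract_patches(pyr, 0, max_patches = 6L, seed = 1L)
  if (row$class_label != "OOD") ps <- label_patches(ps, row$class_label)
  ps
}

world_diagnose <- function(model, sets, ids, sd, manifest) {
  out <- diagnosis_table(lapply(ids, function(id) {
    diagnose_slide(model, sets[[id]], T = 50L, seed = mix_seed(sd, "p", id))
  }))
  out$truth <- manifest$class_label[match(out$slide_id, manifest$slide_id)]
  out$correct <- out$label == out$truth
  out
}

# Moderate-difficulty world (errors present): 24 slides/class, per-slide
# ring-fraction spread 0.35.  Used by the Fig. 4 / Fig. 5a analog criteria.
world_moderate <- function(sd) {
  world_memo(paste0("M", sd), function() {
    specs <- cohort_specs(24L, seed = sd * 1000 + 7, ring_fraction_sd = 0.35)
    sets <- list()
    for (i in seq_len(nrow(specs)))
      sets[[specs$slide_id[i]]] <- tile_row(specs[i, ])
    cfg <- model_config(seed = sd * 77 + 5, max_iterations = 500L,
                        eval_every = 25L)
    model <- train_model(build_model(cfg),
                         sets[specs$slide_id[specs$split == "train"]],
                         sets[specs$slide_id[specs$split == "val"]], cfg)
    dte <- world_diagnose(model, sets, specs$slide_id[specs$split == "test"],
                          sd, specs)
    list(dte = dte, curve = model$learning_curve)
  })
}

# Clean high-separability world (confident internal cohort) with
# stain-shifted external and OOD test slides: 20 slides/class internal.
# Used by the Fig. 2 and Fig. 6/7 analog criteria.
world_clean <- function(sd) {
  world_memo(paste0("H", sd), function() {
    specs <- cohort_specs(20L, seed = sd * 1000 + 7, ring_fraction_sd = 0,
                          external_test_per_class = 4L, n_ood = 6L)
    sets <- list()
    for (i in seq_len(nrow(specs)))
      sets[[specs$slide_id[i]]] <- tile_row(specs[i, ])
    int <- specs$centre == "internal" & specs$class_label != "OOD"
    cfg <- model_config(seed = sd * 77 + 5, max_iterations = 500L,
                        eval_every = 25L)
    model <- train_model(build_model(cfg),
                         sets[specs$slide_id[specs$split == "train" & int]],
                         sets[specs$slide_id[specs$split == "val" & int]], cfg)
    res <- list(
      dte = world_diagnose(model, sets,
                           specs$slide_id[specs$split == "test" & int],
                           sd, specs),
      dva = world_diagnose(model, sets,
                           specs$slide_id[specs$split == "val" & int],
                           sd, specs),
      dex = world_diagnose(model, sets,
                           specs$slide_id[specs$centre == "external"],
                           sd, specs),
      doo = diagnosis_table(lapply(specs$slide_id[specs$class_label == "OOD"],
        function(id) diagnose_slide(model, sets[[id]], T = 50L,
                                    seed = mix_seed(sd, "p", id)))),
      curve = model$learning_curve,
      model = model)
    res
  })
}
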