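#' Plan a synthetic cohort without rendering it
#'
#' Derives, purely from the arguments, every slide specification of a
#' cohort: internal class-A/B slides with a seeded train/val/test split,
#' optional stain-shifted "external-centre" test slides, and optional
#' out-of-distribution test slides. [generate_cohort()] renders exactly
#' this plan; exposing it separately lets callers tile slides in memory
#' without touching disk.
#'
#' @inheritParams generate_cohort
#' @return a data frame with one row per slide: `slide_id`, `class_label`,
#'   `centre`, `split`, `ring_fraction`, `shifted` (logical), `spec_seed`.
#' @export
cohort_specs <- function(n_per_class, fractions = c(0.5, 0.25, 0.25),
                         seed = 1L, ring_fraction_sd = 0,
                         external_test_per_class = 0L, n_ood = 0L) {
  if (abs(sum(fractions) - 1) > 1e-9 || length(fractions) != 3)
    stop("fractions must be three proportions summing to 1")
  if (n_per_class < 0) stop("n_per_class must be >= 0")

  # per-class split counts by largest-remainder rounding
  split_counts <- function(n) {
    k <- floor(n * fractions)
    rem <- n * fractions - k
    short <- n - sum(k)
    if (short > 0) {
      bump <- order(rem, decreasing = TRUE)[seq_len(short)]
      k[bump] <- k[bump] + 1
    }
    k
  }
  fraction_of <- function(tag, cl, i) {
    centre <- if (cl == "A") 0.1 else 0.9
    if (ring_fraction_sd <= 0) return(centre)
    local_seed(mix_seed(seed, "fraction", tag, cl, i),
               min(max(rnorm(1, centre, ring_fraction_sd), 0), 1))
  }
  rows <- list()
  add <- function(...) rows[[length(rows) + 1]] <<- data.frame(
    ..., stringsAsFactors = FALSE)
  for (cl in c("A", "B")) {
    if (n_per_class == 0) next
    splits <- rep(c("train", "val", "test"), times = split_counts(n_per_class))
    perm <- local_seed(mix_seed(seed, "split", cl), sample.int(n_per_class))
    for (i in seq_len(n_per_class)) {
      add(slide_id = sprintf("%s_int_%03d", cl, i), class_label = cl,
          centre = "internal", split = splits[perm[i]],
          ring_fraction = fraction_of("int", cl, i), shifted = FALSE,
          spec_seed = mix_seed(seed, "slide", cl, i))
    }
  }
  for (cl in c("A", "B")) {
    for (i in seq_len(external_test_per_class)) {
      add(slide_id = sprintf("%s_ext_%03d", cl, i), class_label = cl,
          centre = "external", split = "test",
          ring_fraction = fraction_of("ext", cl, i), shifted = TRUE,
          spec_seed = mix_seed(seed, "slide-ext", cl, i))
    }
  }
  for (i in seq_len(n_ood)) {
    add(slide_id = sprintf("OOD_%03d", i), class_label = "OOD",
        centre = "internal", split = "test", ring_fraction = 0,
        shifted = FALSE, spec_seed = mix_seed(seed, "slide-ood", i))
  }
  if (length(rows) == 0) {
    return(data.frame(slide_id = character(0), class_label = character(0),
                      centre = character(0), split = character(0),
                      ring_fraction = numeric(0), shifted = logical(0),
                      spec_seed = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

# Render one planned cohort row into a pyramid (optionally stain-shifted).
render_cohort_row <- function(row, base_size, n_levels, ring_contrast, shift) {
  spec <- slide_spec(row$slide_id, row$class_label,
                     centre = row$centre, base_size = base_size,
                     ring_fraction = if (row$class_label == "OOD") NULL else row$ring_fraction,
                     ring_contrast = ring_contrast, seed = row$spec_seed)
  pyr <- generate_slide(spec, n_levels = n_levels)
  if (row$shifted) pyr <- apply_stain_shift(pyr, shift)
  pyr
}

#' Generate a seeded synthetic slide cohort
#'
#' Renders the plan from [cohort_specs()] and writes one pyramid directory
#' per slide plus a `manifest.csv` with the header
#' `slide_id,class_label,centre,split,path` (paths relative to `out_dir`).
#' Per-class split counts match `fractions` up to integer rounding and the
#' split assignment is a seeded permutation. External-centre slides are
#' stain-shifted with `shift` and out-of-distribution slides use the
#' laminar band texture; both are appended to the test split.
#'
#' @param n_per_class internal slides per class (>= 0).
#' @param fractions train/val/test proportions summing to 1 (default the
#'   usual 50/25/25 split).
#' @param seed master seed; every slide and the split assignment derive
#'   from it.
#' @param out_dir output directory (created if needed).
#' @param base_size level-0 size in pixels, passed to [slide_spec()].
#' @param n_levels pyramid levels per slide.
#' @param ring_contrast ring rendering contrast passed to [slide_spec()].
#' @param ring_fraction_sd case-to-case difficulty spread: each slide's
#'   ring fraction is drawn (seeded) from a normal centred on its class
#'   default (0.1 for A, 0.9 for B) with this standard deviation, clipped
#'   to `[0, 1]`. Zero gives a clean, confidently separable cohort;
#'   values around 0.3 produce genuinely ambiguous slides whose evidence
#'   is mixed, the analog of borderline cases.
#' @param external_test_per_class number of additional external-centre
#'   slides per class (default 0).
#' @param n_ood number of additional OOD slides in the test split
#'   (default 0).
#' @param shift [stain_shift()] applied to external slides.
#' @return the `cohort_manifest`, invisibly; also written to
#'   `file.path(out_dir, "manifest.csv")`.
#' @export
generate_cohort <- function(n_per_class, fractions = c(0.5, 0.25, 0.25),
                            seed = 1L, out_dir,
                            base_size = c(4096L, 4096L), n_levels = 3L,
                            ring_contrast = 0.6, ring_fraction_sd = 0,
                            external_test_per_class = 0L, n_ood = 0L,
                            shift = stain_shift()) {
  specs <- cohort_specs(n_per_class, fractions, seed, ring_fraction_sd,
                        external_test_per_class, n_ood)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("out_dir is not writable: ", out_dir)
  for (i in seq_len(nrow(specs))) {
    pyr <- render_cohort_row(specs[i, ], base_size, n_levels, ring_contrast,
                             shift)
    write_pyramid(pyr, file.path(out_dir, specs$slide_id[i]))
  }
  manifest <- specs[, c("slide_id", "class_label", "centre", "split")]
  manifest$path <- specs$slide_id
  class(manifest) <- c("cohort_manifest", "data.frame")
  write.csv(manifest, file.path(out_dir, "manifest.csv"),
            row.names = FALSE, quote = FALSE)
  invisible(manifest)
}
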