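#' @title Monte-Carlo-dropout inference
#' @description Keeping dropout active at test time approximates Bayesian
#'   inference over the network weights: several stochastic forward passes
#'   are drawn per input, their mean \eqn{\mu} is the decision and the
#'   variance \eqn{\sigma} of the class-A probability over draws is the
#'   uncertainty. Slide-level diagnosis averages patch predictions over the
#'   whole slide within each draw, so the slide uncertainty couples all
#'   patches of one dropout realisation.
#' @name bayes-inference
NULL

#' Monte-Carlo-dropout prediction for one patch
#'
#' Performs `T` stochastic forward passes with dropout enabled. Draw `t`
#' uses the seed `mix_seed(seed, "mc", t)` — or, when grid coordinates are
#' supplied, `mix_seed(seed, "mc", row_index, col_index, t)`, the same
#' bookkeeping [diagnose_slide()] uses — so results are reproducible and
#' independent of call order.
#'
#' @param model a trained `slide_model` with at least one dropout site.
#' @param patch an `H x W x 3` array in `[0, 1]`.
#' @param T number of draws (>= 2; the default 50 follows the usual
#'   MC-dropout practice of a few dozen samples).
#' @param seed integer seed.
#' @param row_index,col_index optional grid coordinates tying the draw
#'   seeds to patch identity.
#' @return a `patch_prediction`: list with `draws` (`T x 2` matrix, each
#'   row summing to 1), `mu` (column means), `sigma` (population variance
#'   of the class-A probability, in `[0, 0.25]`), and `label` (argmax of
#'   `mu`, ties toward `"A"`).
#' @export
mc_predict_patch <- function(model, patch, T = 50L, seed = 1L,
                             row_index = NULL, col_index = NULL) {
  stopifnot(inherits(model, "slide_model"))
  if (T < 2) stop("T must be >= 2 (variance undefined for a single draw)")
  if (dropout_sites(model) < 1) stop("model has no dropout sites")
  x <- prep_patch(patch)
  draw_seed <- function(t) {
    if (is.null(row_index)) mix_seed(seed, "mc", t)
    else mix_seed(seed, "mc", row_index, col_index, t)
  }
  draws <- matrix(0, T, 2, dimnames = list(NULL, c("A", "B")))
  for (t in seq_len(T)) {
    draws[t, ] <- local_seed(draw_seed(t),
                             .cpp_forward_mc(model$params, x,
                                             model$config$dropout_rate, 1L,
                                             model$config$stem_pool))
  }
  mu <- colMeans(draws)
  structure(list(slide_id = NA_character_, level = model$level,
                 row_index = if (is.null(row_index)) NA_integer_ else row_index,
                 col_index = if (is.null(col_index)) NA_integer_ else col_index,
                 draws = draws, mu = mu,
                 sigma = mean((draws[, 1] - mu[1])^2),
                 label = classify(mu[1])),
            class = "patch_prediction")
}

#' Slide-level classification rule
#'
#' @param mu_slide mean class-A probability in `[0, 1]`.
#' @return `"A"` if `mu_slide >= 0.5` else `"B"`. The tie at exactly 0.5 is
#'   broken toward class A (the lymphoma analog): the screening aim is not
#'   to miss a malignant case.
#' @export
classify <- function(mu_slide) {
  if (any(mu_slide < 0 | mu_slide > 1)) stop("mu_slide must be in [0, 1]")
  ifelse(mu_slide >= 0.5, "A", "B")
}

#' Monte-Carlo-dropout diagnosis of one slide
#'
#' For each draw `t`, every patch gets its own dropout mask seeded by
#' `mix_seed(seed, "mc", row, col, t)` (tied to grid coordinates, not
#' iteration order, so the diagnosis is invariant to patch ordering). The
#' slide score of draw `t` is the mean class-A probability across patches;
#' `mu_slide`/`sigma_slide` are the mean and population variance of the `T`
#' slide scores. `sigma_patch_mean`, the mean over patches of the
#' per-patch draw variance, is also reported as an alternative slide
#' uncertainty.
#'
#' @param model a trained `slide_model`.
#' @param patch_set a non-empty `patch_set`.
#' @param T number of draws (>= 2).
#' @param seed integer seed.
#' @return a `slide_diagnosis`: list with `slide_id`, `level`, `n_patches`,
#'   `slide_scores` (length `T`), `mu_slide`, `sigma_slide`,
#'   `sigma_patch_mean`, `label`, and `patch_mu`/`patch_sigma` vectors.
#' @export
diagnose_slide <- function(model, patch_set, T = 50L, seed = 1L) {
  stopifnot(inherits(model, "slide_model"), inherits(patch_set, "patch_set"))
  if (T < 2) stop("T must be >= 2")
  if (length(patch_set$patches) == 0)
    stop("no-tissue slide: patch set '", patch_set$slide_id,
         "' is empty, no diagnosis emitted")
  n <- length(patch_set$patches)
  P <- matrix(0, T, n) # class-A probability per draw x patch
  for (i in seq_len(n)) {
    x <- prep_patch(patch_set$patches[[i]])
    r <- patch_set$coords$row_index[i]
    cc <- patch_set$coords$col_index[i]
    for (t in seq_len(T)) {
      P[t, i] <- local_seed(mix_seed(seed, "mc", r, cc, t),
                            .cpp_forward_mc(model$params, x,
                                            model$config$dropout_rate, 1L,
                                            model$config$stem_pool))[1]
    }
  }
  stats <- slide_summary(P)
  structure(c(list(slide_id = patch_set$slide_id, level = patch_set$level,
                   n_patches = n), stats,
              list(label = classify(stats$mu_slide))),
            class = "slide_diagnosis")
}

# Reduce a T x n_patches matrix of per-draw class-A probabilities to the
# slide-level summary: per-draw slide scores (mean over patches within a
# draw), their mean and population variance, plus per-patch summaries and
# the mean per-patch variance (the alternative slide uncertainty).
slide_summary <- function(P) {
  s <- rowMeans(P)
  mu_slide <- mean(s)
  patch_mu <- colMeans(P)
  patch_sigma <- colMeans(sweep(P, 2, patch_mu)^2)
  list(slide_scores = s, mu_slide = mu_slide,
       sigma_slide = mean((s - mu_slide)^2),
       sigma_patch_mean = mean(patch_sigma),
       patch_mu = patch_mu, patch_sigma = patch_sigma)
}

#' @export
print.slide_diagnosis <- function(x, ...) {
  cat(sprintf("slide_diagnosis '%s' (level %d, %d patches): label %s, mu = %.4f, sigma = %.3g\n",
              x$slide_id, x$level, x$n_patches, x$label, x$mu_slide,
              x$sigma_slide))
  invisible(x)
}

#' Collect slide diagnoses into a data frame
#'
#' @param diagnoses list of `slide_diagnosis` objects.
#' @return `data.frame(slide_id, level, n_patches, mu_slide, sigma_slide,
#'   sigma_patch_mean, label)`.
#' @export
diagnosis_table <- function(diagnoses) {
  stopifnot(all(vapply(diagnoses, inherits, TRUE, "slide_diagnosis")))
  do.call(rbind, lapply(diagnoses, function(d) {
    data.frame(slide_id = d$slide_id, level = d$level,
               n_patches = d$n_patches, mu_slide = d$mu_slide,
               sigma_slide = d$sigma_slide,
               sigma_patch_mean = d$sigma_patch_mean, label = d$label,
               stringsAsFactors = FALSE)
  }))
}
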