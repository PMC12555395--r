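#' Plant template for the desk-scale segmentation experiment
#'
#' A two-class (stem/leaf, no soil) plant whose organ geometry is
#' resolvable at the 512-point working resolution of the reduced model:
#' thin, line-like stems (radius well below the mean point spacing) against
#' two large planar leaf blades held off the stem by a petiole stand-off.
#' Point allocation is balanced 30/70 so the minority stem class retains
#' enough training signal under unweighted cross-entropy.
#'
#' @param n_points Parent cloud size (default 2048; working subsamples are
#'   drawn from it at train time).
#' @return A [plant_spec()].
#' @export
scaled_plant_template <- function(n_points = 2048L) {
  plant_spec(
    n_points = n_points,
    stem = list(height = 1.3, radius = 0.004, curvature = 0.08,
                n_branches = 1L, branch_angle = c(30, 55)),
    leaves = list(count = 2L, length = 0.7, width = 0.5, bend = 0.18,
                  jitter = 0.02, stand_off = 0.2),
    soil = list(present = FALSE),
    class_balance = c(0.3, 0.7, 0),
    density_gradient = 0.3,
    junction_blend = 0.01,
    surface_noise = 0.001,
    seed = 1L)
}

#' Run the desk-scale training experiment
#'
#' The package's scaled-down learning benchmark: a reduced network (one
#' GCASM layer of width 32, k = 10) trained for 30 epochs with the
#' reference optimizer settings (batch 8, lr 0.1 halved every 20 epochs,
#' momentum 0.9, weight decay 1e-4) on 24 synthetic two-class plants,
#' evaluated on 8 held-out plants at 512 points per cloud.
#'
#' @param train_seed Seed for weight init, shuffling, dropout and the
#'   per-epoch point resampling.
#' @param data_seed Seed of the synthetic plant population.
#' @param epochs Training epochs (default 30).
#' @param n_plants Total plants generated (default 32, split 24/8).
#' @param n_points Working points per cloud (default 512).
#' @param verbose Print per-epoch progress.
#' @return List: `fit` (see [fit()]), `metrics` (test-set `seg_metrics`
#'   of the best-epoch model), `config`, `test_set` (the sampled test
#'   clouds).
#' @export
run_scaled_experiment <- function(train_seed = 1L, data_seed = 5L,
                                  epochs = 30L, n_plants = 32L,
                                  n_points = 512L, verbose = FALSE) {
  plants <- generate_dataset(scaled_plant_template(), n_plants,
                             seed = data_seed, variation = 0.2)
  plants <- lapply(plants, normalize_cloud)
  sp <- split_dataset(plants, 0.75, seed = data_seed)
  cfg <- reduced_model_config(n_classes = 2L, dropout_rate = 0.25)
  tc <- train_config(epochs = epochs, seed = train_seed)
  r <- fit(cfg, sp$train, sp$test, tc, resample_n = n_points,
           verbose = verbose)
  test_set <- lapply(seq_along(sp$test), function(i)
    random_sample(sp$test[[i]], n_points, seed = train_seed + 5000L + i))
  list(fit = r, metrics = evaluate(r$params, cfg, test_set),
       config = cfg, test_set = test_set)
}
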