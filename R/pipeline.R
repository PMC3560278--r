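#' Run the canonical phantom-to-SVM classification benchmark
#'
#' The end-to-end experiment the package is built around: generate a balanced
#' labelled set of colony phantoms, simulate their forward-scatter patterns,
#' extract pseudo-Zernike magnitude features, rank them by Fisher's criterion
#' on the training split only, select the top `k`, train an SVM and report
#' held-out per-class distinguish rates. Everything is deterministic given
#' `seed`.
#'
#' @param n_good,n_bad phantoms per class.
#' @param seed master seed for phantoms, detector noise and the stratified
#'   split.
#' @param split training fraction (stratified; default 0.7).
#' @param n_max maximum pseudo-Zernike order (default 17, 171 magnitudes).
#' @param k number of Fisher-selected features (default 161).
#' @param kernel,cost SVM hyperparameters (see [train_classifier()]).
#' @param good_params,bad_params phantom generator settings.
#' @param config optical configuration.
#' @param noise apply detector shot noise?
#' @return A list: `report` (held-out [confusion_report()]), `recall`
#'   (held-out per-class fractions), `model`, `ranking`, `features`
#'   (full feature table), `train_idx`, `majority_accuracy` (baseline on the
#'   held-out set), `n_test`.
#' @export
run_scatter_benchmark <- function(n_good = 100, n_bad = 100, seed = 42,
                                  split = 0.7, n_max = 17L, k = 161L,
                                  kernel = "linear", cost = 1,
                                  good_params = phantom_params("good"),
                                  bad_params = phantom_params("bad"),
                                  config = optical_config(),
                                  noise = TRUE) {
  if (split <= 0 || split >= 1) stop("`split` must lie in (0, 1)",
                                     call. = FALSE)
  with_seed_if(seed, {
    phantoms <- generate_dataset(n_good, n_bad, good_params, bad_params)
    patterns <- lapply(phantoms, simulate_pattern, config = config,
                       noise = noise)
    features <- extract_feature_table(patterns, n_max = n_max)
    labels <- features$label
    train_idx <- unlist(lapply(unique(labels), function(cl) {
      i <- which(labels == cl)
      sort(sample(i, floor(split * length(i))))
    }))
    train_idx <- sort(train_idx)

    fm <- feature_matrix(features)
    Xtr <- fm$x[train_idx, , drop = FALSE]
    ytr <- labels[train_idx]
    ranking <- fisher_scores(Xtr[ytr == "good", , drop = FALSE],
                             Xtr[ytr == "bad", , drop = FALSE], k = k)
    Xtr_sel <- select_features(ranking, Xtr)
    model <- train_classifier(Xtr_sel, ytr, kernel = kernel, cost = cost)

    Xte <- fm$x[-train_idx, , drop = FALSE]
    yte <- labels[-train_idx]
    report <- confusion_report(yte, predict(model,
                                            select_features(ranking, Xte)))
    list(report = report,
         recall = report$recall,
         model = model, ranking = ranking, features = features,
         train_idx = train_idx,
         majority_accuracy = max(table(yte)) / length(yte),
         n_test = length(yte))
  })
}

#' Recover class height statistics from synthetic z-stacks
#'
#' Generates `n_per_class` phantoms per class, converts each to a z-stack and
#' estimates its height with [estimate_height()]; returns the per-class
#' samples and the Student t comparison.
#'
#' @param n_per_class colonies per class.
#' @param z_step slice spacing in micrometres.
#' @param noise_sd z-stack noise level (0 = noiseless).
#' @param seed master seed.
#' @param good_params,bad_params phantom generator settings.
#' @param variant t-test variant for the summary.
#' @return A list: `heights_good`, `heights_bad` (um), `mean` (named
#'   per-class means), `se` (standard errors of those means), `summary`
#'   (a `height_summary`).
#' @export
run_height_study <- function(n_per_class = 100, z_step = 2, noise_sd = 0,
                             seed = 42,
                             good_params = phantom_params("good"),
                             bad_params = phantom_params("bad"),
                             variant = "student") {
  with_seed_if(seed, {
    est <- function(p) {
      vapply(seq_len(n_per_class), function(i) {
        estimate_height(phantom_to_zstack(generate_phantom_impl(p),
                                          z_step = z_step,
                                          noise_sd = noise_sd))
      }, numeric(1))
    }
    hg <- est(good_params)
    hb <- est(bad_params)
    list(heights_good = hg, heights_bad = hb,
         mean = c(good = mean(hg), bad = mean(hb)),
         se = c(good = sd(hg) / sqrt(n_per_class),
                bad = sd(hb) / sqrt(n_per_class)),
         summary = compare_heights(hg, hb, variant = variant))
  })
}

#' Oct-4/DAPI expression-ratio study on synthetic colonies
#'
#' Generates `n_per_class` fluorescence pairs per class — good colonies at a
#' high pluripotent fraction, bad colonies at a lower one — measures each
#' colony's background-subtracted Oct-4/DAPI integrated-intensity ratio, and
#' compares the classes with a two-sample t-test.
#'
#' @param n_per_class colonies per class (default 18, the standard assay
#'   size).
#' @param good_fraction,bad_fraction Oct-4-positive fractions used to
#'   generate each class.
#' @param noise_sd per-channel Gaussian noise sd.
#' @param seed master seed.
#' @param good_params,bad_params phantom generator settings.
#' @param variant t-test variant.
#' @return A list: `ratios_good`, `ratios_bad`, `mean`, `summary`
#'   (a `ratio_summary`).
#' @export
run_ratio_study <- function(n_per_class = 18, good_fraction = 0.9,
                            bad_fraction = 0.5, noise_sd = 0.01, seed = 42,
                            good_params = phantom_params("good"),
                            bad_params = phantom_params("bad"),
                            variant = "student") {
  with_seed_if(seed, {
    one <- function(p, frac) {
      vapply(seq_len(n_per_class), function(i) {
        ph <- generate_phantom_impl(p)
        oct4_dapi_ratio(generate_fluorescence_pair(ph, frac,
                                                   noise_sd = noise_sd))
      }, numeric(1))
    }
    rg <- one(good_params, good_fraction)
    rb <- one(bad_params, bad_fraction)
    list(ratios_good = rg, ratios_bad = rb,
         mean = c(good = mean(rg), bad = mean(rb)),
         summary = compare_ratios(rg, rb, variant = variant))
  })
}
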