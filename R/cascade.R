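#' Pseudo-label a batch of images with a trained model
#'
#' Predicts a mask per image; when `cleanup` is TRUE the morphological
#' finishing used by the auto-labeller (noise removal, stem discarding,
#' hole filling — no colour thresholding) is applied to every predicted
#' mask. Pseudo-labels for the final field stage are deliberately left
#' unfinished (`cleanup = FALSE`).
#'
#' @param model a trained `pomseg_model`.
#' @param images non-empty list of H x W x 3 RGB arrays.
#' @param cleanup apply morphological finishing to each predicted mask?
#' @param config an [autolabel_config()] supplying the cleanup parameters.
#' @param ids optional character vector of sample ids (default
#'   `pseudo-001` ...).
#' @return List of [labeled_sample]s with provenance `"pseudo"`.
#' @export
pseudo_label <- function(model, images, cleanup = TRUE,
                         config = autolabel_config(), ids = NULL) {
  if (!is.list(images) || length(images) == 0L)
    stopf("images must be a non-empty list")
  if (is.null(ids)) ids <- sprintf("pseudo-%03d", seq_along(images))
  lapply(seq_along(images), function(i) {
    mask <- predict_mask(model, images[[i]])
    if (isTRUE(cleanup)) {
      mask <- remove_small_components(mask, config$min_area,
                                      config$connectivity)
      mask <- discard_stems(mask, config)
      mask <- fill_holes(mask, config$connectivity)
    }
    labeled_sample(images[[i]], mask, "pseudo", ids[i])
  })
}

#' True-negative samples: all-zero masks for fruitless images
#'
#' @param images list of H x W x 3 RGB arrays (may be empty).
#' @param ids optional character vector of sample ids.
#' @return List of [labeled_sample]s with all-zero masks and provenance
#'   `"negative"`.
#' @export
make_negative_samples <- function(images, ids = NULL) {
  if (length(images) == 0L) return(list())
  if (is.null(ids)) ids <- sprintf("negative-%03d", seq_along(images))
  lapply(seq_along(images), function(i) {
    img <- images[[i]]
    check_rgb_image(img)
    labeled_sample(img, matrix(0, dim(img)[1], dim(img)[2]),
                   "negative", ids[i])
  })
}

#' Configuration of one cascade training stage
#'
#' The three-stage pseudo-labeling curriculum:
#' \describe{
#'   \item{stage1_first_ce}{train on auto-labelled uniform-light (set1)
#'     images only.}
#'   \item{stage2_ce}{add harsh-light (set2) images pseudo-labelled by the
#'     first-stage net, with morphological cleanup.}
#'   \item{stage3_tna}{add fruitless true-negative images with all-zero
#'     masks to the stage-2 training set.}
#'   \item{stage3_fia}{add field frames pseudo-labelled by the stage-2 net,
#'     without cleanup, to the stage-2 training set.}
#'   \item{manual}{train on externally supplied masks for field frames
#'     (the comparison arm).}
#' }
#'
#' @param stage one of `"stage1_first_ce"`, `"stage2_ce"`, `"stage3_tna"`,
#'   `"stage3_fia"`, `"manual"`.
#' @param set1_images list of RGB arrays (stage 1, and auto-label reuse).
#' @param set1_samples auto-labelled set1 samples (stages >= 2; built by
#'   [run_stage()] for stage 1).
#' @param set2_images list of RGB arrays to pseudo-label (stage 2).
#' @param ce_samples the assembled stage-2 training samples (stage 3).
#' @param negative_images fruitless RGB arrays (stage3_tna).
#' @param field_images field-frame RGB arrays (stage3_fia).
#' @param manual_samples externally labelled samples (manual arm).
#' @param pseudo_label_model trained model that produces pseudo-labels;
#'   required exactly for `stage2_ce` and `stage3_fia`.
#' @param base_model model whose weights warm-start training (stage 3
#'   restarts from the stage-2 net by default); NULL builds a fresh model.
#' @param cleanup_pseudo_labels morphological finishing of pseudo-labels;
#'   forced TRUE for `stage2_ce` and FALSE for `stage3_fia`.
#' @param negatives_as_zero_masks keep TRUE: negative images enter training
#'   with all-zero masks.
#' @param augmentation_seed seed of the 20-fold augmentation.
#' @param autolabel_cfg an [autolabel_config()].
#' @return A `stage_config` object.
#' @export
stage_config <- function(stage, set1_images = NULL, set1_samples = NULL,
                         set2_images = NULL, ce_samples = NULL,
                         negative_images = NULL, field_images = NULL,
                         manual_samples = NULL, pseudo_label_model = NULL,
                         base_model = NULL, cleanup_pseudo_labels = NULL,
                         negatives_as_zero_masks = TRUE,
                         augmentation_seed = 0L,
                         autolabel_cfg = autolabel_config()) {
  stage <- match.arg(stage, c("stage1_first_ce", "stage2_ce", "stage3_tna",
                              "stage3_fia", "manual"))
  needs_model <- stage %in% c("stage2_ce", "stage3_fia")
  if (needs_model && is.null(pseudo_label_model))
    stopf("%s requires a pseudo_label_model (train the previous stage first)",
          stage)
  if (!needs_model && !is.null(pseudo_label_model))
    stopf("%s does not pseudo-label: pseudo_label_model must be NULL", stage)
  if (is.null(cleanup_pseudo_labels))
    cleanup_pseudo_labels <- (stage == "stage2_ce")
  if (stage == "stage2_ce" && !isTRUE(cleanup_pseudo_labels))
    stopf("stage2_ce pseudo-labels are always cleaned up")
  if (stage == "stage3_fia" && isTRUE(cleanup_pseudo_labels))
    stopf("stage3_fia pseudo-labels are never cleaned up")
  structure(list(stage = stage, set1_images = set1_images,
                 set1_samples = set1_samples, set2_images = set2_images,
                 ce_samples = ce_samples, negative_images = negative_images,
                 field_images = field_images, manual_samples = manual_samples,
                 pseudo_label_model = pseudo_label_model,
                 base_model = base_model,
                 cleanup_pseudo_labels = cleanup_pseudo_labels,
                 negatives_as_zero_masks = negatives_as_zero_masks,
                 augmentation_seed = as.integer(augmentation_seed),
                 autolabel_cfg = autolabel_cfg),
            class = "stage_config")
}

assemble_stage_samples <- function(cfg) {
  switch(cfg$stage,
    stage1_first_ce = {
      if (is.null(cfg$set1_samples)) {
        if (is.null(cfg$set1_images) || length(cfg$set1_images) == 0L)
          stopf("stage1_first_ce needs set1_images (or set1_samples)")
        lapply(seq_along(cfg$set1_images), function(i)
          labeled_sample(cfg$set1_images[[i]],
                         autolabel(cfg$set1_images[[i]], cfg$autolabel_cfg),
                         "set1", sprintf("set1-auto-%03d", i)))
      } else cfg$set1_samples
    },
    stage2_ce = {
      if (is.null(cfg$set1_samples) || length(cfg$set1_samples) == 0L)
        stopf("stage2_ce needs the stage-1 set1_samples")
      if (is.null(cfg$set2_images) || length(cfg$set2_images) == 0L)
        stopf("stage2_ce needs set2_images to pseudo-label")
      c(cfg$set1_samples,
        pseudo_label(cfg$pseudo_label_model, cfg$set2_images,
                     cleanup = TRUE, config = cfg$autolabel_cfg,
                     ids = sprintf("set2-pseudo-%03d",
                                   seq_along(cfg$set2_images))))
    },
    stage3_tna = {
      if (is.null(cfg$ce_samples) || length(cfg$ce_samples) == 0L)
        stopf("stage3_tna needs the stage-2 training samples (ce_samples)")
      if (is.null(cfg$negative_images) || length(cfg$negative_images) == 0L)
        stopf("stage3_tna needs negative_images")
      if (!isTRUE(cfg$negatives_as_zero_masks))
        stopf("negatives always enter training with all-zero masks")
      c(cfg$ce_samples, make_negative_samples(cfg$negative_images))
    },
    stage3_fia = {
      if (is.null(cfg$ce_samples) || length(cfg$ce_samples) == 0L)
        stopf("stage3_fia needs the stage-2 training samples (ce_samples)")
      if (is.null(cfg$field_images) || length(cfg$field_images) == 0L)
        stopf("stage3_fia needs field_images to pseudo-label")
      c(cfg$ce_samples,
        pseudo_label(cfg$pseudo_label_model, cfg$field_images,
                     cleanup = FALSE,
                     ids = sprintf("field-pseudo-%03d",
                                   seq_along(cfg$field_images))))
    },
    manual = {
      if (is.null(cfg$manual_samples) || length(cfg$manual_samples) == 0L)
        stopf("manual arm needs manual_samples")
      cfg$manual_samples
    })
}

stage_tag_of <- function(stage) {
  switch(stage, stage1_first_ce = "first_ce", stage2_ce = "ce",
         stage3_tna = "tna", stage3_fia = "fia", manual = "manual")
}

#' Run one cascade training stage
#'
#' Assembles the stage's training set (auto-labels, pseudo-labels,
#' zero-mask negatives, per the stage), applies the 20-fold augmentation,
#' trains (warm-starting from `cfg$base_model` when given) and returns the
#' tagged model. The pre- and post-augmentation sample counts are recorded
#' in the model's `stage_log` attribute.
#'
#' @param cfg a [stage_config()].
#' @param hp a [train_hyperparams()].
#' @param net_config a [network_config()] used when no base model is given.
#' @return A trained `pomseg_model` with attribute `stage_log`.
#' @export
run_stage <- function(cfg, hp = train_hyperparams(),
                      net_config = network_config()) {
  if (!inherits(cfg, "stage_config")) stopf("cfg must be a stage_config")
  samples <- assemble_stage_samples(cfg)
  n_orig <- length(samples)
  augmented <- augment_dataset(samples, cfg$augmentation_seed)
  model <- if (!is.null(cfg$base_model)) cfg$base_model
           else build_model(net_config, seed = hp$seed)
  model <- train_model(model, augmented, hp,
                       stage_tag = stage_tag_of(cfg$stage))
  attr(model, "stage_log") <- list(
    stage = cfg$stage,
    n_samples = n_orig,
    n_augmented = length(augmented),
    provenance_counts = table(vapply(samples, function(s) s$provenance,
                                     character(1))))
  model
}

#' Desk-scale cascade configuration
#'
#' Counts, sizes and seeds for an end-to-end synthetic run of the cascade.
#' Defaults are sized so the whole cascade (data generation, four training
#' stages, evaluation) runs in well under two minutes on one CPU while
#' leaving each stage enough signal to learn from.
#'
#' @param n_set1,n_set2 controlled-environment originals per set.
#' @param n_negative fruitless true-negative scenes.
#' @param n_field_train field frames pseudo-labelled for the final stage.
#' @param n_field_test held-out field test frames (disjoint seeds).
#' @param image_size (height, width) of every scene.
#' @param seed master seed; scene seeds, augmentation seeds and training
#'   seeds all derive from it.
#' @param hp a [train_hyperparams()].
#' @param net_config a [network_config()].
#' @param autolabel_cfg an [autolabel_config()]; by default `min_area` is
#'   rescaled to `image_size`.
#' @param run_manual_arm also train the manual-label comparison arm, using
#'   generator ground truth in place of hand labels?
#' @return A `cascade_config` list.
#' @export
cascade_config <- function(n_set1 = 16L, n_set2 = 12L, n_negative = 12L,
                           n_field_train = 12L, n_field_test = 40L,
                           image_size = c(96L, 96L), seed = 1L,
                           hp = train_hyperparams(),
                           net_config = network_config(input_size = image_size),
                           autolabel_cfg = autolabel_config(
                             min_area = scaled_min_area(image_size)),
                           run_manual_arm = FALSE) {
  structure(list(n_set1 = n_set1, n_set2 = n_set2, n_negative = n_negative,
                 n_field_train = n_field_train, n_field_test = n_field_test,
                 image_size = as.integer(image_size), seed = as.integer(seed),
                 hp = hp, net_config = net_config,
                 autolabel_cfg = autolabel_cfg,
                 run_manual_arm = run_manual_arm),
            class = "cascade_config")
}

#' Run the full three-stage pseudo-labeling cascade on synthetic data
#'
#' Generates the four synthetic data sets, trains the four nets of the
#' curriculum (first-stage controlled-environment net, final CE net, the
#' true-negative-augmented TNA net and the field-image-augmented FIA net,
#' plus optionally a manually-labelled comparison arm), and evaluates every
#' trained net on a shared held-out field-style test set whose scene seeds
#' are disjoint from all training scenes.
#'
#' @param config a [cascade_config()].
#' @return List with `models` (named list of trained `pomseg_model`s),
#'   `reports` (a `metrics_report` per model on the shared test set),
#'   `test_set`, and `logs` (per-stage sample counts).
#' @export
run_cascade <- function(config = cascade_config()) {
  if (!inherits(config, "cascade_config")) stopf("config must be a cascade_config")
  sz <- config$image_size
  base <- config$seed * 100000L

  set1 <- generate_batch("set1", config$n_set1, seed = base + 1000L,
                         image_size = sz)
  set2 <- generate_batch("set2", config$n_set2, seed = base + 2000L,
                         image_size = sz)
  negatives <- generate_batch("negative", config$n_negative,
                              seed = base + 3000L, image_size = sz)
  field_train <- generate_batch("field", config$n_field_train,
                                seed = base + 4000L, image_size = sz)
  test_set <- generate_batch("field", config$n_field_test,
                             seed = base + 5000L, image_size = sz)

  # data hygiene: no test scene may enter any training set
  train_ids <- c(vapply(c(set1, set2, negatives, field_train),
                        function(s) s$sample_id, character(1)))
  test_ids <- vapply(test_set, function(s) s$sample_id, character(1))
  if (length(intersect(train_ids, test_ids)) > 0L)
    stopf("test set overlaps a training set")

  images_of <- function(samples) lapply(samples, function(s) s$image)
  hp <- config$hp
  acfg <- config$autolabel_cfg

  cfg1 <- stage_config("stage1_first_ce", set1_images = images_of(set1),
                       augmentation_seed = config$seed + 11L,
                       autolabel_cfg = acfg)
  set1_samples <- assemble_stage_samples(cfg1)
  cfg1$set1_samples <- set1_samples
  first_ce <- run_stage(cfg1, hp, config$net_config)

  cfg2 <- stage_config("stage2_ce", set1_samples = set1_samples,
                       set2_images = images_of(set2),
                       pseudo_label_model = first_ce, base_model = first_ce,
                       augmentation_seed = config$seed + 12L,
                       autolabel_cfg = acfg)
  ce_samples <- assemble_stage_samples(cfg2)
  ce <- run_stage(cfg2, hp, config$net_config)

  cfg3a <- stage_config("stage3_tna", ce_samples = ce_samples,
                        negative_images = images_of(negatives),
                        base_model = ce,
                        augmentation_seed = config$seed + 13L,
                        autolabel_cfg = acfg)
  tna <- run_stage(cfg3a, hp, config$net_config)

  cfg3b <- stage_config("stage3_fia", ce_samples = ce_samples,
                        field_images = images_of(field_train),
                        pseudo_label_model = ce, base_model = ce,
                        augmentation_seed = config$seed + 14L,
                        autolabel_cfg = acfg)
  fia <- run_stage(cfg3b, hp, config$net_config)

  models <- list(first_ce = first_ce, ce = ce, tna = tna, fia = fia)

  if (isTRUE(config$run_manual_arm)) {
    manual_samples <- lapply(field_train, function(s)
      labeled_sample(s$image, s$mask, "synthetic-gt",
                     paste0(s$sample_id, "-manual")))
    cfgm <- stage_config("manual",
                         manual_samples = c(ce_samples, manual_samples),
                         base_model = ce,
                         augmentation_seed = config$seed + 15L,
                         autolabel_cfg = acfg)
    models$manual <- run_stage(cfgm, hp, config$net_config)
  }

  reports <- lapply(models, evaluate_test_set, test = test_set)
  logs <- lapply(models, attr, "stage_log")
  list(models = models, reports = reports, test_set = test_set, logs = logs)
}

#' Summarise per-net test metrics of a cascade run
#'
#' @param result the list returned by [run_cascade()].
#' @return Data frame with one row per net: per-image-averaged precision,
#'   recall and F1 (fractions in \[0, 1\]).
#' @export
cascade_summary <- function(result) {
  do.call(rbind, lapply(names(result$reports), function(nm) {
    s <- result$reports[[nm]]$summary
    data.frame(net = nm, precision = s[["precision"]],
               recall = s[["recall"]], f1 = s[["f1"]],
               row.names = NULL)
  }))
}
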