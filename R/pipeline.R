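#' Pipeline configuration
#'
#' Collects every tunable parameter of the analysis pipeline with its
#' default. Unknown arguments are rejected, so typos cannot silently fall
#' back to defaults.
#'
#' @param denoise_method,denoise_window Preprocessing filter
#'   (`"median"`/`"none"`) and odd window size.
#' @param delta,connectivity,mean_mode Region-growing intensity tolerance
#'   (8-bit scale), pixel connectivity (4 or 8) and mean update mode.
#' @param seed_mode `"auto"` (centroid of the brightest 1 percent) or
#'   `"manual"` (seeds passed to [run_single()]).
#' @param se_shape,se_size,min_component_px Morphological cleanup:
#'   structuring element and minimum surviving component size.
#' @param wavelet,levels,bands,boundary Wavelet decomposition settings.
#' @param glcm_levels,glcm_distance,angles,aggregate,glcm_symmetric GLCM
#'   settings (`G`, `S`, angle set, angle aggregation, symmetry).
#' @param sigma,classes PNN kernel width and class order (the first class
#'   wins exact ties).
#' @param psnr_formula `"as_printed"` or `"standard"`, see [psnr()].
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(denoise_method = "median",
                            denoise_window = 3L,
                            delta = 10,
                            connectivity = 4L,
                            mean_mode = "running",
                            seed_mode = "auto",
                            se_shape = "square",
                            se_size = 3L,
                            min_component_px = 25L,
                            wavelet = "haar",
                            levels = 4L,
                            bands = c("LL", "HL"),
                            boundary = "symmetric",
                            glcm_levels = 8L,
                            glcm_distance = 1L,
                            angles = c(0, 45, 90, 135),
                            aggregate = "mean",
                            glcm_symmetric = TRUE,
                            sigma = 0.5,
                            classes = c("normal", "abnormal"),
                            psnr_formula = "as_printed") {
  cfg <- list(denoise_method = denoise_method,
              denoise_window = denoise_window,
              delta = delta, connectivity = connectivity,
              mean_mode = mean_mode, seed_mode = seed_mode,
              se_shape = se_shape, se_size = se_size,
              min_component_px = min_component_px,
              wavelet = wavelet, levels = levels, bands = bands,
              boundary = boundary,
              glcm_levels = glcm_levels, glcm_distance = glcm_distance,
              angles = angles, aggregate = aggregate,
              glcm_symmetric = glcm_symmetric,
              sigma = sigma, classes = classes,
              psnr_formula = psnr_formula)
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (k in names(x))
    cat(sprintf("  %-18s %s\n", k, paste(x[[k]], collapse = ", ")))
  invisible(x)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    abort("[stage ", stage, "] ", conditionMessage(e)))
}

config_se <- function(cfg) structuring_element(cfg$se_shape, cfg$se_size)

#' Extract the texture feature vector of one image
#'
#' Denoise, decompose with the configured wavelet, select the configured
#' subbands and compute GLCM features. This is the feature pathway shared
#' by [run_single()] and [run_experiment()].
#'
#' @param img A [gray_image] or image file path.
#' @param cfg A [pipeline_config()].
#' @return Named numeric feature vector (see [feature_vector()]).
#' @export
extract_features <- function(img, cfg = pipeline_config()) {
  if (is.character(img)) img <- load_image(img)
  assert_gray_image(img)
  den <- with_stage("denoise",
                    denoise(img, cfg$denoise_method, cfg$denoise_window))
  dec <- with_stage("wavelet",
                    dwt2(den, cfg$wavelet, cfg$levels, cfg$boundary))
  sb <- with_stage("subbands",
                   select_subbands(dec, seq_len(cfg$levels), cfg$bands))
  with_stage("glcm", feature_vector(
    sb, G = cfg$glcm_levels, S = cfg$glcm_distance, angles = cfg$angles,
    aggregate = cfg$aggregate, symmetric = cfg$glcm_symmetric))
}

#' Run the full pipeline on one image
#'
#' Stages, in order: load, denoise, seeded region growing, morphological
#' cleanup, quality/area report (fidelity of the denoised image against
#' the original, plus tumor region area), wavelet decomposition, subband
#' selection, GLCM feature vector.
#'
#' @param img A [gray_image] or image file path.
#' @param cfg A [pipeline_config()].
#' @param seeds Seed coordinates for `seed_mode = "manual"`; ignored (and
#'   replaced by [auto_seed()]) under `seed_mode = "auto"`.
#' @param verbose Emit one message per stage.
#' @return List with `quality` ([quality_report()]), `mask`
#'   ([binary_mask]), `features` (named numeric vector) and `seeds`
#'   (the seed coordinates used).
#' @export
run_single <- function(img, cfg = pipeline_config(), seeds = NULL,
                       verbose = FALSE) {
  say <- function(...) if (verbose) message("glioscan: ", ...)
  if (is.character(img)) {
    say("load ", img)
    img <- with_stage("load", load_image(img))
  }
  assert_gray_image(img)
  say("denoise method=", cfg$denoise_method, " window=", cfg$denoise_window)
  den <- with_stage("denoise",
                    denoise(img, cfg$denoise_method, cfg$denoise_window))
  if (identical(cfg$seed_mode, "auto")) {
    seeds <- with_stage("seed", auto_seed(den))
  } else if (is.null(seeds)) {
    abort_validation("seed_mode='manual' requires seeds")
  }
  say("grow_region delta=", cfg$delta, " connectivity=", cfg$connectivity,
      " mean_mode=", cfg$mean_mode)
  grown <- with_stage("grow_region",
                      grow_region(den, seeds, cfg$delta, cfg$connectivity,
                                  cfg$mean_mode))
  say("clean_mask se=", cfg$se_shape, cfg$se_size,
      " min_component_px=", cfg$min_component_px)
  mask <- with_stage("clean_mask",
                     clean_mask(grown, config_se(cfg),
                                cfg$min_component_px))
  quality <- with_stage("quality",
                        quality_report(img, den, mask, cfg$psnr_formula))
  say("features wavelet=", cfg$wavelet, " levels=", cfg$levels,
      " bands=", paste(cfg$bands, collapse = "+"))
  feats <- extract_features(den, modifyList(
    cfg, list(denoise_method = "none")))
  list(quality = quality, mask = mask, features = feats,
       seeds = as_seed_matrix(seeds))
}

read_labeled_dir <- function(dir) {
  lab_path <- file.path(dir, "labels.csv")
  if (!file.exists(lab_path))
    abort_validation("missing labels file: ", lab_path)
  lab <- utils::read.csv(lab_path, stringsAsFactors = FALSE)
  if (!all(c("filename", "label") %in% names(lab)))
    abort_validation("labels.csv must have columns filename,label")
  lapply(seq_len(nrow(lab)), function(i) list(
    image = load_image(file.path(dir, lab$filename[i])),
    label = lab$label[i], name = lab$filename[i]))
}

as_labeled_set <- function(x, what) {
  if (is.character(x) && length(x) == 1L) return(read_labeled_dir(x))
  if (is.list(x) && length(x) > 0L &&
      all(vapply(x, function(e) is_gray_image(e$image) &&
                   is.character(e$label), logical(1)))) {
    for (i in seq_along(x))
      if (is.null(x[[i]]$name)) x[[i]]$name <- sprintf("item_%04d", i)
    return(x)
  }
  abort_validation(what, " must be a directory path or a list of ",
                   "records with $image (gray_image) and $label")
}

#' Train and evaluate the classifier end to end
#'
#' Extracts the texture feature vector of every image in the training and
#' test sets, fits the PNN on the training features, and reports the
#' classification accuracy on both sets. The training-set
#' (resubstitution) accuracy is optimistic by construction and is
#' reported only because it is a standard companion figure to held-out
#' accuracy.
#'
#' @param train,test Either a directory containing images plus a
#'   `labels.csv` (`filename,label`), or an in-memory list of records
#'   with `$image` ([gray_image]) and `$label` (e.g. from
#'   [generate_dataset()]).
#' @param cfg A [pipeline_config()].
#' @return List with `model` (the fitted [pnn()]), `train_accuracy` and
#'   `test_accuracy` (percent), `predictions` (one row per test image:
#'   name, truth, predicted, per-class scores), the feature matrices, and
#'   a `provenance` record (parameter dump plus a config hash).
#' @export
run_experiment <- function(train, test, cfg = pipeline_config()) {
  train <- as_labeled_set(train, "train")
  test <- as_labeled_set(test, "test")
  tr_labels <- vapply(train, `[[`, character(1), "label")
  te_labels <- vapply(test, `[[`, character(1), "label")
  if (length(unique(tr_labels)) < 2L)
    abort_validation("training set must contain at least two classes")

  feat_of <- function(set) t(vapply(
    set, function(e) extract_features(e$image, cfg),
    extract_features(set[[1L]]$image, cfg)))
  X_tr <- feat_of(train)
  X_te <- feat_of(test)

  classes <- if (all(unique(c(tr_labels, te_labels)) %in% cfg$classes))
    cfg$classes else unique(tr_labels)
  model <- pnn(X_tr, tr_labels, sigma = cfg$sigma, classes = classes)

  train_acc <- pnn_accuracy(model, X_tr, tr_labels)
  test_acc <- pnn_accuracy(model, X_te, te_labels)
  scores <- predict(model, X_te, type = "scores")
  predictions <- data.frame(
    image = vapply(test, `[[`, character(1), "name"),
    truth = te_labels,
    predicted = predict(model, X_te),
    stringsAsFactors = FALSE)
  predictions <- cbind(predictions, as.data.frame(scores))

  list(model = model,
       train_accuracy = train_acc,
       test_accuracy = test_acc,
       predictions = predictions,
       train_features = X_tr, test_features = X_te,
       provenance = list(config = unclass(cfg),
                         config_hash = config_hash(cfg),
                         n_train = length(train), n_test = length(test)))
}

# polynomial hash over the JSON form of the config: a dependency-free
# fingerprint (exact in doubles: intermediate values stay below 2^53)
config_hash <- function(cfg) {
  bytes <- utf8ToInt(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE,
                                      digits = NA))
  h <- 0
  for (b in bytes) h <- (h * 257 + b) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Write pipeline CSV outputs
#'
#' `write_feature_csv()` writes one row per image and subband with the
#' five texture features (`image,level,band,CON,COR,ENE,HOM,ENT`);
#' `write_quality_csv()` writes one row per image
#' (`image,psnr,mse,area_image_px,area_tumor_px`).
#'
#' @param features Named list mapping image name to a feature vector from
#'   [feature_vector()] with `aggregate = "mean"`.
#' @param reports Named list mapping image name to a [quality_report()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(features, path) {
  rows <- list()
  for (img in names(features)) {
    v <- features[[img]]
    parts <- strsplit(names(v), ".", fixed = TRUE)
    key <- vapply(parts, function(p) paste(p[1:2], collapse = "."),
                  character(1))
    for (k in unique(key)) {
      sub <- v[key == k]
      feat <- vapply(parts[key == k], `[[`, character(1), 3L)
      lv <- as.integer(sub("^L", "", strsplit(k, ".", fixed = TRUE)[[1]][1]))
      band <- strsplit(k, ".", fixed = TRUE)[[1]][2]
      rows[[length(rows) + 1L]] <- data.frame(
        image = img, level = lv, band = band,
        CON = unname(sub[feat == "CON"]), COR = unname(sub[feat == "COR"]),
        ENE = unname(sub[feat == "ENE"]), HOM = unname(sub[feat == "HOM"]),
        ENT = unname(sub[feat == "ENT"]))
    }
  }
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
write_quality_csv <- function(reports, path) {
  out <- do.call(rbind, lapply(names(reports), function(img) {
    q <- reports[[img]]
    data.frame(image = img, psnr = q$psnr_db, mse = q$mse,
               area_image_px = q$area_image_px,
               area_tumor_px = q$area_region_px)
  }))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
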