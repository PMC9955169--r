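#' End-to-end pipeline configuration
#'
#' Bundles every stage's configuration plus the stage toggles and the master
#' seed.  The stage order is fixed: simulate (or load), split, denoise
#' (optional), skull strip, augment (training split only), edge-detect and
#' segment, texture features, feature selection, network training,
#' evaluation.  The split is stratified and performed before augmentation so
#' no augmented copy of a test image can leak into training.
#'
#' @param simulate list with \code{n_per_class} and optionally
#'   \code{spec_template} (a \code{\link{phantomSpec}}).
#' @param split training fraction of the stratified split.
#' @param denoise TRUE / FALSE / "auto" (apply when the estimated
#'   salt-and-pepper fraction exceeds 0.5 percent).
#' @param strip_skull logical.
#' @param augment an \code{\link{augmentationPlan}} or NULL to skip.
#' @param canny a \code{\link{cannyConfig}}.
#' @param mayfly a \code{\link{mayflyConfig}} or NULL (default: off — the
#'   swarm search per image is expensive and optional).
#' @param sgldm an \code{\link{sgldmConfig}}.
#' @param selection TRUE to run wrapper feature selection.
#' @param choa,wrapper selection configurations.
#' @param network a \code{\link{networkConfig}} (feature mode is the
#'   default dataflow).
#' @param train a \code{\link{trainConfig}}.
#' @param seed master seed; every stage seed derives from it.
#' @param out_dir optional directory for per-stage artifacts.
#' @return list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(simulate = list(n_per_class = 50L),
                           split = 0.8,
                           denoise = "auto",
                           strip_skull = TRUE,
                           augment = augmentationPlan(),
                           canny = cannyConfig(),
                           mayfly = NULL,
                           sgldm = sgldmConfig(),
                           selection = TRUE,
                           choa = choaConfig(mode = "standard"),
                           wrapper = wrapperConfig(),
                           network = networkConfig(mode = "feature"),
                           train = trainConfig(epochs = 40L),
                           seed = 1L,
                           out_dir = NULL) {
  structure(list(simulate = simulate, split = split, denoise = denoise,
                 strip_skull = strip_skull, augment = augment,
                 canny = canny, mayfly = mayfly, sgldm = sgldm,
                 selection = selection, choa = choa, wrapper = wrapper,
                 network = network, train = train,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "PipelineConfig")
}

# preprocess + segment + featurize one image; returns the feature vector
# and bookkeeping about the decisions taken
process_image <- function(image, cfg) {
  den <- maybeDenoise(image, cfg$denoise)
  img <- den$image
  brain_mask <- NULL
  if (isTRUE(cfg$strip_skull)) {
    ss <- tryCatch(stripSkull(img), error = function(e) NULL)
    if (!is.null(ss)) {
      img <- ss$image
      brain_mask <- ss$mask
    }
  }
  edges <- detectEdges(img, cfg$canny, mayfly = cfg$mayfly)
  e <- maskMatrix(edges)
  if (!is.null(brain_mask)) {
    # edges on the brain-mask boundary are artifacts of the masking step,
    # not image structure; drop them before looking for an enclosed ROI
    rim <- brain_mask & !morph_rcpp(brain_mask, disk_se(2L), TRUE)
    e <- e & !rim
  }
  roi <- suppressMessages(
    segmentRoi(img, new("EdgeMap", edges = e,
                        provenance = edges@provenance)))
  roi_fallback <- FALSE
  mask <- maskMatrix(roi)
  if (!any(mask)) {
    mask <- if (!is.null(brain_mask)) brain_mask
            else matrix(TRUE, nrow(pixels(img)), ncol(pixels(img)))
    roi_fallback <- TRUE
  }
  feats <- extractRoiFeatures(img, mask, cfg$sgldm)
  list(features = feats, denoised = den$applied,
       roi_fallback = roi_fallback)
}

#' Run the full classification pipeline
#'
#' Executes the staged dataflow on a seeded synthetic phantom dataset and
#' returns a \linkS4class{PipelineRun} whose report holds the confusion
#' matrix, per-class and macro metrics, and one-vs-rest ROC areas on the
#' held-out split.  Identical configuration and seed give identical
#' reports.  Stage failures abort with the stage name; artifacts written so
#' far are retained.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @return a \linkS4class{PipelineRun}.
#' @export
runPipeline <- function(config = pipelineConfig()) {
  stopifnot(inherits(config, "PipelineConfig"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  out_dir <- config$out_dir
  if (!is.null(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  # -- simulate
  spec <- config$simulate$spec_template
  if (is.null(spec)) spec <- phantomSpec()
  dataset <- stage("simulate",
    generateImageDataset(config$simulate$n_per_class, spec,
                         seed = derive_seed(config$seed, 1L)))
  n <- length(dataset@images)
  labels <- dataset@labels

  # -- stratified split, before augmentation
  test_idx <- with_seed(derive_seed(config$seed, 2L), {
    unlist(lapply(split(seq_len(n), labels), function(ix)
      sample(ix, max(1L, round((1 - config$split) * length(ix))))))
  })
  test_idx <- sort(test_idx)
  train_idx <- setdiff(seq_len(n), test_idx)

  # -- preprocess + augment (train only) + segment + features
  proc_train <- stage("features_train", {
    feats <- list(); ys <- integer(0); fallbacks <- 0L; denoised <- 0L
    for (i in train_idx) {
      imgs <- list(dataset@images[[i]])
      if (!is.null(config$augment))
        imgs <- c(imgs, augmentImage(dataset@images[[i]], config$augment))
      for (im in imgs) {
        r <- process_image(im, config)
        feats[[length(feats) + 1L]] <- r$features
        ys <- c(ys, labels[i])
        fallbacks <- fallbacks + r$roi_fallback
        denoised <- denoised + r$denoised
      }
    }
    list(x = do.call(rbind, feats), y = ys, fallbacks = fallbacks,
         denoised = denoised)
  })
  proc_test <- stage("features_test", {
    feats <- list(); fallbacks <- 0L
    for (i in test_idx) {
      r <- process_image(dataset@images[[i]], config)
      feats[[length(feats) + 1L]] <- r$features
      fallbacks <- fallbacks + r$roi_fallback
    }
    list(x = do.call(rbind, feats), y = labels[test_idx],
         fallbacks = fallbacks)
  })

  # -- feature selection (training split only)
  sel <- NULL
  if (isTRUE(config$selection)) {
    sel <- stage("selection", {
      cfg <- config$choa
      cfg$seed <- derive_seed(config$seed, 3L)
      selectFeatures(proc_train$x, proc_train$y, cfg, config$wrapper)
    })
    keep <- includedFeatures(sel)
  } else {
    keep <- rep(TRUE, ncol(proc_train$x))
  }
  xtr <- proc_train$x[, keep, drop = FALSE]
  xte <- proc_test$x[, keep, drop = FALSE]

  # -- standardize by training statistics
  mu <- colMeans(xtr)
  sdv <- apply(xtr, 2L, stats::sd); sdv[sdv == 0] <- 1
  xtr <- sweep(sweep(xtr, 2L, mu), 2L, sdv, "/")
  xte <- sweep(sweep(xte, 2L, mu), 2L, sdv, "/")

  # -- train
  fit <- stage("train", {
    ncfg <- config$network
    ncfg$seed <- derive_seed(config$seed, 4L)
    net <- buildNetwork(ncfg, input_dim = ncol(xtr))
    tcfg <- config$train
    tcfg$seed <- derive_seed(config$seed, 5L)
    trainNetwork(net, xtr, proc_train$y, tcfg)
  })

  # -- evaluate
  report <- stage("evaluate", {
    pred <- predictNetwork(fit$network, xte)
    cc <- confusionCounts(pred$class, proc_test$y,
                          class_labels = as.character(1:3))
    sm <- summaryMetrics(cc)
    aucs <- vapply(1:3, function(k)
      aucValue(rocCurve(pred$probabilities[, k], proc_test$y, k)),
      numeric(1))
    list(confusion = cc@table,
         per_class = sm$per_class,
         macro = as.list(sm$macro),
         micro_accuracy = sm$micro_accuracy,
         roc_auc = stats::setNames(aucs, paste0("class", 1:3)),
         n_train = length(proc_train$y), n_test = length(proc_test$y),
         selection = if (is.null(sel)) "off" else "on",
         n_features_selected = sum(keep),
         selected_features = names(which(keep)),
         roi_fallbacks = proc_train$fallbacks + proc_test$fallbacks,
         denoised_images = proc_train$denoised,
         final_train_loss = utils::tail(fit$trace, 1))
  })
  provenance <- list(config = serializable_config(config),
                     seed = config$seed,
                     stage_seeds = list(simulate = derive_seed(config$seed, 1L),
                                        split = derive_seed(config$seed, 2L),
                                        selection = derive_seed(config$seed, 3L),
                                        network = derive_seed(config$seed, 4L),
                                        train = derive_seed(config$seed, 5L)),
                     test_indices = test_idx)
  run <- new("PipelineRun", report = report, provenance = provenance)
  if (!is.null(out_dir)) {
    jsonlite::write_json(runReportJson(run, parsed = TRUE),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  run
}

serializable_config <- function(config) {
  strip <- function(x) {
    if (inherits(x, c("PhantomSpec", "AugmentationPlan", "CannyConfig",
                      "MayflyConfig", "SgldmConfig", "ChoaConfig",
                      "WrapperConfig", "NetworkConfig", "TrainConfig",
                      "MorphConfig", "PipelineConfig")))
      x <- unclass(x)
    if (is.list(x)) lapply(x, strip) else x
  }
  strip(config)
}

#' @rdname runReport
#' @export
setMethod("runReport", "PipelineRun", function(x) x@report)

#' @rdname runProvenance
#' @export
setMethod("runProvenance", "PipelineRun", function(x) x@provenance)

setMethod("show", "PipelineRun", function(object) {
  r <- object@report
  cat(sprintf(paste0("PipelineRun: %d train / %d test images, ",
                     "accuracy %.3f (micro)\n"),
              r$n_train, r$n_test, r$micro_accuracy))
  cat(sprintf("  ROC AUC: %s\n",
              paste(sprintf("%s=%.3f", names(r$roc_auc), r$roc_auc),
                    collapse = ", ")))
})

#' Serialize a pipeline run to JSON
#'
#' Deterministic rendering of the report and provenance: two runs with
#' identical configuration and seed produce byte-identical strings.
#'
#' @param run a \linkS4class{PipelineRun}.
#' @param parsed return the list (for re-serialization) instead of the
#'   JSON string.
#' @return character scalar (or list when \code{parsed}).
#' @export
runReportJson <- function(run, parsed = FALSE) {
  stopifnot(is(run, "PipelineRun"))
  rep <- run@report
  rep$confusion <- as.data.frame.matrix(rep$confusion)
  obj <- list(report = rep, provenance = run@provenance)
  if (parsed) return(obj)
  as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
}
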