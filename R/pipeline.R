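#' Extract the 120-entry feature vector of one image
#'
#' Runs preprocessing, then the 21-entry color block and the 99-entry
#' texture block, in registry order. The preprocessing QC counts (foreground
#' pixels per stage, crop window) are attached as the \code{"qc"} attribute.
#'
#' @param image H x W x 3 array in 0..255, or a path to a PNG file.
#' @param preprocess a [preprocessParams()] list.
#' @param color a [colorParams()] list.
#' @param texture a [textureParams()] list.
#' @return Named numeric vector of length 120.
#' @export
extractFeatures <- function(image,
                            preprocess = preprocessParams(),
                            color = colorParams(),
                            texture = textureParams()) {
  if (is.character(image)) image <- readSaffronImage(image)
  pp <- preprocessImage(image, preprocess)
  cb <- colorFeatureBlock(pp$image, pp$mask, color)
  tb <- textureFeatureBlock(toGray(pp$image), pp$mask, texture)
  out <- c(cb, tb)
  attr(out, "qc") <- c(pp$qc, unlist(pp$window))
  out
}

#' The full feature registry
#'
#' Names of all 120 features in fixed order: the 21 \code{color.*} features
#' followed by the 99 \code{tex.*} features.
#'
#' @param color,texture parameter lists.
#' @return Character vector of length 120.
#' @export
#' @examples
#' length(featureRegistry())
featureRegistry <- function(color = colorParams(), texture = textureParams()) {
  c(paste0("color.", c(COLOR_CHANNELS, "foreign_pct", "stigma_pct",
                       "foreign_to_stigma_pct")),
    textureFeatureNames(texture))
}

#' Build a feature table from a synthetic dataset or image files
#'
#' Extracts the 120-entry feature vector of every sample and assembles a
#' \code{SummarizedExperiment} with features in rows, samples in columns, and
#' the manifest (sample_id, class, style_fraction) as column metadata.
#' Samples whose foreground is empty after preprocessing are dropped with a
#' warning naming them.
#'
#' @param dataset a [generateDataset()] result, or a manifest data frame with
#'   columns \code{sample_id}, \code{path}, \code{class}.
#' @param preprocess,color,texture parameter lists.
#' @return A \code{SummarizedExperiment}.
#' @export
buildFeatureTable <- function(dataset,
                              preprocess = scaledPreprocessParams(),
                              color = colorParams(),
                              texture = textureParams()) {
  if (is.data.frame(dataset)) {
    manifest <- dataset
    getImage <- function(i) readSaffronImage(manifest$path[i])
  } else {
    manifest <- dataset$manifest
    getImage <- function(i) dataset$scenes[[manifest$sample_id[i]]]$image
  }
  n <- nrow(manifest)
  vecs <- vector("list", n)
  ok <- logical(n)
  for (i in seq_len(n)) {
    v <- tryCatch(extractFeatures(getImage(i), preprocess, color, texture),
                  error = function(e) e)
    if (inherits(v, "error")) {
      warning("sample ", manifest$sample_id[i], " excluded: ",
              conditionMessage(v))
    } else {
      vecs[[i]] <- v; ok[i] <- TRUE
    }
  }
  stopifnot(any(ok))
  mat <- do.call(cbind, vecs[ok])
  colnames(mat) <- manifest$sample_id[ok]
  cd <- S4Vectors::DataFrame(manifest[ok, setdiff(names(manifest), "path"),
                                      drop = FALSE])
  rownames(cd) <- manifest$sample_id[ok]
  SummarizedExperiment::SummarizedExperiment(
    assays = list(features = mat), colData = cd)
}

#' Write and read the feature table as CSV
#'
#' Column layout: \code{sample_id}, \code{class}, then the 120 feature
#' columns in registry order. Values are written with 17 significant digits,
#' so a write/read round trip preserves them to within 1e-12 and the column
#' order exactly.
#'
#' @param se a \code{SummarizedExperiment} from [buildFeatureTable()].
#' @param path CSV file path.
#' @return \code{writeFeatureCSV} returns \code{path} invisibly;
#'   \code{readFeatureCSV} returns a \code{SummarizedExperiment}.
#' @export
writeFeatureCSV <- function(se, path) {
  mat <- SummarizedExperiment::assay(se)
  df <- data.frame(sample_id = colnames(mat),
                   class = as.character(SummarizedExperiment::colData(se)$class),
                   stringsAsFactors = FALSE)
  fmt <- as.data.frame(t(mat))
  fmt[] <- lapply(fmt, function(x) sprintf("%.17g", x))
  write.csv(cbind(df, fmt), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeFeatureCSV
#' @export
readFeatureCSV <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- t(as.matrix(df[, setdiff(names(df), c("sample_id", "class")),
                        drop = FALSE]))
  colnames(mat) <- df$sample_id
  cd <- S4Vectors::DataFrame(sample_id = df$sample_id, class = df$class,
                             row.names = df$sample_id)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(features = mat), colData = cd)
}

#' Deterministic hash of a configuration
#'
#' MD5 of the canonical JSON serialization; changes iff any parameter
#' changes.
#'
#' @param config any JSON-serializable list.
#' @return Character MD5 string.
#' @export
configHash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Run the full synthetic grading experiment
#'
#' Generates a labeled synthetic dataset, extracts the 120-feature table,
#' benchmarks a classifier suite under repeated stratified k-fold
#' cross-validation, and compares classifiers by one-way ANOVA with Duncan's
#' multiple range test. Per-classifier rate tables and one-vs-rest AUCs are
#' computed from the pooled predictions of the first repetition.
#'
#' @param counts named per-class sample counts.
#' @param seed master seed for generation and cross-validation.
#' @param models list of [ModelSpec]s (default the full 22-model suite).
#' @param cv a [cvConfig()]; its seed is derived from \code{seed}.
#' @param alpha significance level of the classifier comparison.
#' @param paramsByClass optional scene parameter templates per class.
#' @param preprocess,color,texture parameter lists (desk-scale preprocessing
#'   defaults).
#' @param outDir optional directory; if given, writes \code{features.csv},
#'   \code{accuracy.csv}, \code{rates.csv}, \code{auc.csv},
#'   \code{stats.json} and \code{manifest.json}.
#' @return list with \code{features} (SummarizedExperiment), \code{cv} (list
#'   of [CvResult]), \code{accuracy} (ranked data.frame), \code{rates},
#'   \code{auc}, \code{anova}, \code{duncan}, \code{configHash}.
#' @export
runExperiment <- function(counts = c(Pushal = 30, Negin = 30, Sargol = 30),
                          seed = 1L,
                          models = modelSuite(),
                          cv = cvConfig(k = 5L, repetitions = 10L,
                                        seed = seed),
                          alpha = 0.05,
                          paramsByClass = NULL,
                          preprocess = scaledPreprocessParams(),
                          color = colorParams(),
                          texture = textureParams(),
                          outDir = NULL) {
  ds <- generateDataset(counts, seed = seed, paramsByClass = paramsByClass)
  se <- buildFeatureTable(ds, preprocess, color, texture)

  cvResults <- lapply(models, function(spec) runCV(se, spec = spec,
                                                   config = cv))
  accuracy <- data.frame(
    id = vapply(cvResults, function(r) r@modelId, character(1)),
    name = vapply(cvResults, function(r) r@modelName, character(1)),
    mean_accuracy = vapply(cvResults, meanAccuracy, numeric(1)),
    sd_accuracy = vapply(cvResults, sdAccuracy, numeric(1)),
    row.names = NULL)
  accuracy <- accuracy[order(-accuracy$mean_accuracy), ]

  evals <- lapply(cvResults, evaluateCvResult)
  rates <- do.call(rbind, lapply(names(evals), function(id)
    cbind(id = id, evals[[id]]$rates)))
  auc <- do.call(rbind, lapply(names(evals), function(id)
    as.data.frame(as.list(c(id = id, round(evals[[id]]$auc, 6))))))

  groups <- lapply(cvResults, accuracies)
  an <- anovaOneway(groups)
  mns <- vapply(groups, mean, numeric(1))
  dunc <- duncanGroups(mns, nPerGroup = cv$repetitions,
                       errorMeanSquare = an$errorMeanSquare,
                       dfWithin = an$dfWithin, alpha = alpha)

  cfg <- list(counts = as.list(counts), seed = seed, cv = cv, alpha = alpha,
              preprocess = preprocess, color = color, texture = texture)
  hash <- configHash(cfg)

  if (!is.null(outDir)) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    writeFeatureCSV(se, file.path(outDir, "features.csv"))
    write.csv(accuracy, file.path(outDir, "accuracy.csv"), row.names = FALSE)
    write.csv(rates, file.path(outDir, "rates.csv"), row.names = FALSE)
    write.csv(auc, file.path(outDir, "auc.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(anova = an[c("F", "dfBetween", "dfWithin", "errorMeanSquare", "p")],
           duncan = list(means = as.list(round(dunc@means, 4)),
                         letters = as.list(groupLetters(dunc)))),
      file.path(outDir, "stats.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(list(configHash = hash, seed = seed),
                         file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE)
  }

  list(features = se, cv = cvResults, accuracy = accuracy, rates = rates,
       auc = auc, anova = an, duncan = dunc, configHash = hash)
}
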