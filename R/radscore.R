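#' Sparse linear radiomics-score model
#'
#' A Rad-score is the linear combination of selected, standardised
#' radiomics features weighted by their LASSO coefficients plus an
#' intercept, used as a single imaging biomarker.
#'
#' @param feature_names character vector of feature names.
#' @param coefficients numeric coefficients, same length.
#' @param intercept scalar intercept.
#' @return an object of class `rad_score_model`.
#' @export
rad_score_model <- function(feature_names, coefficients, intercept) {
  stopifnot(length(feature_names) == length(coefficients),
            !anyDuplicated(feature_names),
            is.numeric(coefficients), length(intercept) == 1L)
  structure(list(feature_names = as.character(feature_names),
                 coefficients = as.numeric(coefficients),
                 intercept = as.numeric(intercept)),
            class = "rad_score_model")
}

#' @rdname rad_score_model
#' @param selection a [lasso_select()] result.
#' @export
rad_score_model_from_selection <- function(selection) {
  stopifnot(inherits(selection, "lasso_selection"))
  rad_score_model(selection$selected, unname(selection$coefficients),
                  selection$intercept)
}

#' The published 16-coefficient PET Rad-score
#'
#' The packaged instance of the reported PET radiomics signature for
#' LVSI: 16 texture/histogram features (co-occurrence correlation,
#' inverse difference moment, inertia, cluster prominence and energy;
#' run-length emphasis statistics; zone-size high-intensity-large-area
#' and low-intensity emphasis; the 2.5% SUV quantile) with their
#' printed coefficients and intercept -0.075.  It expects Z-score
#' standardised features.
#'
#' @return a [rad_score_model()].
#' @export
#' @examples
#' m <- published_radscore_model()
#' rad_score(m, setNames(rep(0, 16), m$feature_names))  # intercept -0.075
published_radscore_model <- function() {
  rad_score_model(
    feature_names = c(
      "Correlation_angle45_offset7",
      "InverseDifferenceMoment_angle45_offset4",
      "HighIntensityLargeAreaEmphasis",
      "LowIntensityEmphasis",
      "HaralickCorrelation_AllDirection_offset1_SD",
      "InverseDifferenceMoment_AllDirection_offset7_SD",
      "HighGreyLevelRunEmphasis_AllDirection_offset4_SD",
      "ShortRunEmphasis_AllDirection_offset7_SD",
      "LongRunHighGreyLevelEmphasis_AllDirection_offset1_SD",
      "Quantile0.025",
      "ClusterProminence_angle45_offset7",
      "LongRunEmphasis_angle0_offset1",
      "Inertia_angle45_offset4",
      "InverseDifferenceMoment_angle90_offset7",
      "ShortRunLowGreyLevelEmphasis_AllDirection_offset7_SD",
      "GLCMEnergy_AllDirection_offset7"),
    coefficients = c(-0.328, -0.361, 0.291, -0.273, -0.531, -0.47,
                     0.499, -0.335, -0.482, 0.415, -0.626, 0.065,
                     0.63, 0.316, 0.507, -0.004),
    intercept = -0.075)
}

#' Evaluate a Rad-score
#'
#' `intercept + sum(coefficient * feature)` for each case.  Every model
#' feature must be present in the input; missing names are rejected and
#' listed.
#'
#' @param model a [rad_score_model()].
#' @param features named numeric vector (one case) or matrix/data.frame
#'   with feature columns (cases in rows), on the standardised scale the
#'   model was built on.
#' @return numeric score(s).
#' @export
rad_score <- function(model, features) {
  stopifnot(inherits(model, "rad_score_model"))
  if (is.null(dim(features))) {
    features <- matrix(features, nrow = 1L,
                       dimnames = list(NULL, names(features)))
  }
  features <- as.matrix(features)
  missing <- setdiff(model$feature_names, colnames(features))
  if (length(missing))
    stop("features missing from input: ",
         paste(missing, collapse = ", "))
  as.numeric(model$intercept +
               features[, model$feature_names, drop = FALSE] %*%
               model$coefficients)
}

#' Serialize or restore a Rad-score model as JSON
#'
#' The JSON records the feature names, coefficients, intercept and
#' (optionally) the Z-score normalisation parameters needed to apply
#' the model to raw features.
#'
#' @param model a [rad_score_model()].
#' @param path JSON file path.
#' @param center,scale optional named normalisation parameters.
#' @return the path (writer) / a list with `model`, `center`, `scale`
#'   (reader).
#' @export
write_radscore_json <- function(model, path, center = NULL, scale = NULL) {
  stopifnot(inherits(model, "rad_score_model"))
  jsonlite::write_json(
    list(feature_names = model$feature_names,
         coefficients = model$coefficients,
         intercept = model$intercept,
         normalization = if (!is.null(center))
           list(center = as.list(center), scale = as.list(scale))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_radscore_json
#' @export
read_radscore_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- rad_score_model(j$feature_names, j$coefficients, j$intercept)
  list(model = model,
       center = if (!is.null(j$normalization))
         unlist(j$normalization$center),
       scale = if (!is.null(j$normalization))
         unlist(j$normalization$scale))
}
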