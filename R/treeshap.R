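#' Double-precision TreeSHAP contributions for an xgboost model
#'
#' Computes per-sample Shapley additive explanations with the
#' path-dependent TreeSHAP algorithm, re-implemented in C++ in double
#' precision over the parsed tree ensemble. The contributions satisfy the
#' additivity identity `rowSums(phi) == margin` (raw model output,
#' recomputed in double precision from the same trees) to numerical
#' precision, which float32 contribution outputs of the underlying library
#' do not.
#'
#' @param model A trained `xgb.Booster` (binary logistic objective).
#' @param x Numeric feature matrix with the training column order.
#' @return List with `phi` (n x (p+1) matrix, last column `BIAS`),
#'   `margin` (length-n raw model output) and `base_value` (expected raw
#'   output under the training cover distribution).
#' @export
treeshap_values <- function(model, x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  feats <- xgboost::getinfo(model, "feature_name")
  if (is.null(feats) || length(feats) == 0L) feats <- colnames(x)
  stopifnot(identical(colnames(x), feats))
  dt <- as.data.frame(xgboost::xgb.model.dt.tree(model = model))
  is_leaf <- dt$Feature == "Leaf"
  feature <- ifelse(is_leaf, -1L, match(dt$Feature, feats) - 1L)
  if (anyNA(feature)) stop("mismatched model/feature naming")
  child_idx <- function(ids) {
    out <- match(ids, dt$ID) - 1L
    out[is.na(out)] <- -1L
    as.integer(out)
  }
  cfg <- xgboost::xgb.config(model)
  base_score <- as.numeric(cfg$learner$learner_model_param$base_score)
  objective <- cfg$learner$objective$name %||%
    cfg$learner$learner_train_param$objective %||% "binary:logistic"
  intercept <- if (grepl("logistic", objective)) {
    stats::qlogis(base_score)
  } else {
    base_score
  }
  res <- .treeshap_cpp(
    x = x,
    roots = as.integer(which(dt$Node == 0) - 1L),
    feature = as.integer(feature),
    threshold = ifelse(is_leaf, 0, dt$Split),
    yes = child_idx(dt$Yes), no = child_idx(dt$No),
    missing = child_idx(dt$Missing),
    value = ifelse(is_leaf, dt$Gain, 0),
    cover = dt$Cover,
    intercept = intercept
  )
  colnames(res$phi) <- c(feats, "BIAS")
  res
}
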