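#' Fit the harmonized asset index
#'
#' The benchmark pipeline: wave-aware zero-imputation, pooling of all waves
#' onto one standardized scale, first principal component of the pooled
#' Pearson correlation matrix, orientation (electricity loads positive), and
#' household scoring. Returns the fitted model together with the pooled
#' design and scores so downstream diagnostics and sensitivity refits reuse
#' the same objects.
#'
#' @param panel An `asset_panel`.
#' @param codebook An `asset_codebook`.
#' @param items Items to pool (default: the 19-item benchmark set).
#' @param waves Waves to pool (default: all codebook waves).
#' @param method Extraction backend: `"pca"` (benchmark), `"efa"`, `"mca"`.
#' @param corr Correlation kind for pca/efa: `"pearson"` (benchmark) or
#'   `"polychoric"` (crowding binarized at 0.75).
#' @param ordinal_items Items pooled on their three-level ordinal coding
#'   (used by the S5 variant; requires `corr = "polychoric"`).
#' @param impute Apply the codebook's zero-imputation rules first?
#' @param reference Orientation reference item.
#' @return A `harmonized_index` list: `model`, `design`, `scores`, plus the
#'   call parameters.
#' @export
harmonized_index <- function(panel, codebook,
                             items = harmonized_item_set(codebook),
                             waves = NULL,
                             method = c("pca", "efa", "mca"),
                             corr = c("pearson", "polychoric"),
                             ordinal_items = character(),
                             impute = TRUE,
                             reference = "electricity") {
  method <- match.arg(method)
  corr <- match.arg(corr)
  if (impute) panel <- impute_not_asked_as_zero(panel, codebook)
  crowding_binary <- method == "mca" || corr == "polychoric"
  crowding_item <- codebook$item[codebook$kind == "crowding"]
  design <- pool(panel, items, waves = waves,
                 ordinal_items = ordinal_items,
                 crowding_binary = crowding_binary,
                 crowding_item = crowding_item)
  model <- if (method == "mca") {
    fit_mca(design, reference = reference)
  } else {
    cm <- if (corr == "pearson") pearson_matrix(design) else
      polychoric_matrix(design)
    if (method == "pca") {
      fit_pca(cm, means = design$means, sds = design$sds,
              reference = reference, crowding_binary = crowding_binary,
              ordinal_items = ordinal_items)
    } else {
      fit_efa_minres(cm, means = design$means, sds = design$sds,
                     score_corr = pearson_matrix(design),
                     reference = reference, crowding_binary = crowding_binary,
                     ordinal_items = ordinal_items)
    }
  }
  scores <- score(model, design)
  structure(list(model = model, design = design, scores = scores,
                 items = design$items, waves = design$waves,
                 method = method, corr = corr),
            class = "harmonized_index")
}

#' @export
print.harmonized_index <- function(x, ...) {
  cat("<harmonized_index> ", x$method, "/", x$corr, ", pooled n = ",
      x$design$n, ", ", length(x$items), " items, PC1 share = ",
      sprintf("%.3f", x$model$var_explained), "\n", sep = "")
  invisible(x)
}

#' @method tidy harmonized_index
#' @export
tidy.harmonized_index <- function(x, ...) tidy(x$model)

#' @method glance harmonized_index
#' @export
glance.harmonized_index <- function(x, ...) {
  dplyr::bind_cols(glance(x$model),
                   tibble::tibble(n = x$design$n,
                                  n_waves = length(x$waves)))
}
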