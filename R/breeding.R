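# Breeding-site suitability: presence/absence label construction from
# survey records, random-forest training and validation on static soil and
# terrain covariates, 0-100 suitability prediction, and the per-cell
# egg-laying triggers (stochastic site acceptance and recent moisture).

#' Presence/absence labels from survey records
#'
#' Presence points are all Hoppers and Bands records. Absence candidates
#' are Ecology-class records (ecological-condition surveys made regardless
#' of locust presence); a candidate becomes an absence point only when no
#' presence record lies within `exclusion_radius_km` (haversine). Ecology
#' records at identical coordinates deduplicate to one candidate.
#'
#' @param records Survey data frame with columns `class`, `lon`, `lat`
#'   (classes among Hoppers, Adults, Bands, Swarms, Ecology, Control).
#' @param exclusion_radius_km Exclusion radius, km (default 1).
#' @return Data frame with columns `lon`, `lat`, `label`
#'   ("presence"/"absence"), `source_class`.
#' @export
build_labels <- function(records, exclusion_radius_km = 1) {
  known <- c("Hoppers", "Adults", "Bands", "Swarms", "Ecology", "Control")
  bad <- setdiff(unique(records$class), known)
  if (length(bad)) stop("unknown survey class(es): ", paste(bad, collapse = ", "))
  pres <- records[records$class %in% c("Hoppers", "Bands"), , drop = FALSE]
  eco <- records[records$class == "Ecology", , drop = FALSE]
  eco <- eco[!duplicated(eco[, c("lon", "lat")]), , drop = FALSE]
  out_p <- if (nrow(pres)) data.frame(lon = pres$lon, lat = pres$lat,
                                      label = "presence",
                                      source_class = pres$class) else NULL
  out_a <- NULL
  if (nrow(eco)) {
    pm <- as.matrix(pres[, c("lon", "lat")])
    keep <- vapply(seq_len(nrow(eco)), function(i) {
      if (nrow(pres) == 0L) return(TRUE)
      all(haversine_km(c(eco$lon[i], eco$lat[i]), pm) > exclusion_radius_km)
    }, logical(1))
    if (any(keep))
      out_a <- data.frame(lon = eco$lon[keep], lat = eco$lat[keep],
                          label = "absence", source_class = "Ecology")
  }
  out <- rbind(out_p, out_a)
  rownames(out) <- NULL
  out
}

#' Train and validate the breeding-suitability classifier
#'
#' Fits a random forest (100 trees, 2 variables per split, minimum node
#' size 2) of presence/absence on the three static covariates (elevation,
#' sand content, clay content), using a stratified random 80/20
#' train/validation split. Predicted probability is the fraction of trees
#' voting presence. Validation metrics (percent correctly classified,
#' sensitivity, specificity at probability 0.5, and AUC) are computed on
#' the held-out split only.
#'
#' @param labels Output of [build_labels()].
#' @param covariates Named list of three `raster_layer`s: `elevation`,
#'   `sand`, `clay`, covering every labelled point.
#' @param split Training fraction (default 0.8).
#' @param seed Integer seed for the split and forest.
#' @return Object of class `suitability_model` with elements `forest`,
#'   `importances` (normalised to sum 1), and `validation` (list: pcc,
#'   sensitivity, specificity, auc, confusion).
#' @export
train_suitability <- function(labels, covariates, split = 0.8, seed = 0) {
  stopifnot(all(c("elevation", "sand", "clay") %in% names(covariates)))
  if (sum(labels$label == "presence") < 20 || sum(labels$label == "absence") < 20)
    stop("need at least 20 points per class")
  X <- data.frame(
    elevation = mapply(function(lo, la) raster_value_at(covariates$elevation, lo, la),
                       labels$lon, labels$lat),
    sand = mapply(function(lo, la) raster_value_at(covariates$sand, lo, la),
                  labels$lon, labels$lat),
    clay = mapply(function(lo, la) raster_value_at(covariates$clay, lo, la),
                  labels$lon, labels$lat))
  if (anyNA(X)) stop("coverage error: labelled point on nodata covariate cell")
  y <- factor(labels$label, levels = c("absence", "presence"))

  idx_train <- with_seed(derive_seed(seed, 101L), {
    unlist(lapply(levels(y), function(lv) {
      ids <- which(y == lv)
      sample(ids, size = round(split * length(ids)))
    }))
  })
  forest <- with_seed(derive_seed(seed, 202L), {
    randomForest::randomForest(X[idx_train, ], y[idx_train],
                               ntree = 100, mtry = 2, nodesize = 2)
  })
  imp <- randomForest::importance(forest)[, 1L]
  importances <- imp / sum(imp)

  test <- setdiff(seq_along(y), idx_train)
  prob <- stats::predict(forest, X[test, ], type = "prob")[, "presence"]
  truth <- y[test]
  pred <- factor(ifelse(prob >= 0.5, "presence", "absence"),
                 levels = levels(y))
  cm <- table(truth = truth, pred = pred)
  tp <- cm["presence", "presence"]; tn <- cm["absence", "absence"]
  fp <- cm["absence", "presence"]; fn <- cm["presence", "absence"]
  validation <- list(
    pcc = (tp + tn) / sum(cm),
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    auc = as.numeric(pROC::auc(pROC::roc(response = truth, predictor = prob,
                                         levels = c("absence", "presence"),
                                         direction = "<", quiet = TRUE))),
    confusion = cm)
  structure(list(forest = forest, importances = importances,
                 validation = validation),
            class = "suitability_model")
}

#' @export
print.suitability_model <- function(x, ...) {
  v <- x$validation
  cat("Breeding-suitability random forest (100 trees)\n")
  cat(sprintf("  importances: %s\n",
              paste(sprintf("%s %.2f", names(x$importances), x$importances),
                    collapse = ", ")))
  cat(sprintf("  validation: PCC %.2f, sens %.2f, spec %.2f, AUC %.2f\n",
              v$pcc, v$sensitivity, v$specificity, v$auc))
  invisible(x)
}

#' Predict a 0-100 suitability map
#'
#' Per-cell presence probability of the fitted forest, rescaled to 0-100.
#' Cells where any covariate is nodata are nodata.
#'
#' @param model A `suitability_model`.
#' @param covariates Named list of `elevation`, `sand`, `clay`
#'   `raster_layer`s on one common grid.
#' @return `raster_layer` of suitability in [0, 100].
#' @export
predict_suitability <- function(model, covariates) {
  g <- covariates$elevation$grid
  for (nm in c("sand", "clay"))
    if (!identical(covariates[[nm]]$grid, g))
      stop("alignment error: covariates on different grids")
  X <- data.frame(elevation = as.vector(covariates$elevation$values),
                  sand = as.vector(covariates$sand$values),
                  clay = as.vector(covariates$clay$values))
  ok <- stats::complete.cases(X)
  out <- rep(NA_real_, nrow(X))
  if (any(ok))
    out[ok] <- stats::predict(model$forest, X[ok, , drop = FALSE],
                              type = "prob")[, "presence"] * 100
  raster_layer(g, matrix(out, nrow = g$n_lat, ncol = g$n_lon),
               variable = "suitability")
}

#' Stochastic breeding-site acceptance
#'
#' A site is accepted for egg laying when a uniform draw is below the
#' cell's suitability/100 (current RNG stream).
#'
#' @param suitability Cell suitability in [0, 100].
#' @return Logical.
#' @export
breeding_site_accepted <- function(suitability) {
  stopifnot(is.finite(suitability), suitability >= 0, suitability <= 100)
  stats::runif(1) < suitability / 100
}

#' Recent-moisture condition for egg laying
#'
#' Egg laying additionally requires moist soil: a precipitation event
#' (precipitation > 0) or soil moisture above `sm_threshold_mm`, at any
#' 3-hourly record in the closed window 24-48 hours before the lay date
#' (taken as 00:00 UTC of the lay day).
#'
#' @param lay_date `Date` of egg laying.
#' @param precip_series,sm_series `cell_series` of 3-hourly precipitation
#'   (mm) and 0-10 cm soil moisture (mm) at the site.
#' @param sm_threshold_mm Soil-moisture threshold (default 12).
#' @return Logical.
#' @export
moisture_ok <- function(lay_date, precip_series, sm_series,
                        sm_threshold_mm = 12) {
  t0 <- as.POSIXct(paste(format(as.Date(lay_date)), "00:00:00"), tz = "UTC")
  lo <- t0 - 48 * 3600; hi <- t0 - 24 * 3600
  sel_p <- precip_series$times >= lo & precip_series$times <= hi
  sel_s <- sm_series$times >= lo & sm_series$times <= hi
  if (!any(sel_p) || !any(sel_s))
    stop("data gap: moisture window not covered by series")
  pv <- precip_series$values[sel_p]; sv <- sm_series$values[sel_s]
  if (anyNA(pv) || anyNA(sv)) stop("data gap: missing records in window")
  any(pv > 0) || any(sv > sm_threshold_mm)
}
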