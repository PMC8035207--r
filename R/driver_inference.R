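#' @title Climate reduction and multimodel driver inference
#' @name driver_inference
NULL

#' Bioclimatic variable blocks
#'
#' Names of the temperature (11) and precipitation (8) bioclim-style
#' variables expected in a plot climate table.
#' @return named list with elements `temperature` and `precipitation`.
#' @export
climate_blocks <- function() {
  list(
    temperature = c("MAT", "MDR", "Isoth", "TS", "MaxTWarmM", "MinTCM",
                    "TAR", "MeanTWarmQ", "MeanTDQ", "MeanTWetQ", "MeanTCQ"),
    precipitation = c("MAP", "PWetM", "PDM", "PS", "PWetQ", "PDQ",
                      "PWarmQ", "PCQ")
  )
}

#' Principal-component reduction of plot climate
#'
#' Runs one PCA on the temperature variable block and a separate PCA on the
#' precipitation block (each variable centred and scaled to unit variance)
#' and returns the first two axes of each. Axis signs are fixed so the
#' variable with the largest absolute loading loads positively, making
#' scores reproducible across platforms.
#'
#' @param climate data frame with a `plot_id` column plus all variables in
#'   [climate_blocks()].
#' @return object of class `climate_axes`: `scores` (data frame with
#'   `plot_id`, `PCA_temp_1`, `PCA_temp_2`, `PCA_prec_1`, `PCA_prec_2`),
#'   `loadings` and `variance_explained` per block.
#' @export
climate_pca <- function(climate) {
  blocks <- climate_blocks()
  missing_vars <- setdiff(unlist(blocks), names(climate))
  if (length(missing_vars) > 0L) {
    stop("climate table is missing variable(s): ",
         paste(missing_vars, collapse = ", "))
  }
  run_block <- function(vars) {
    x <- as.matrix(climate[vars])
    p <- stats::prcomp(x, center = TRUE, scale. = TRUE)
    ve <- p$sdev^2 / sum(p$sdev^2)
    sc <- p$x[, 1:2, drop = FALSE]
    ld <- p$rotation[, 1:2, drop = FALSE]
    for (j in 1:2) {
      top <- which.max(abs(ld[, j]))
      if (ld[top, j] < 0) {
        ld[, j] <- -ld[, j]
        sc[, j] <- -sc[, j]
      }
    }
    list(scores = sc, loadings = ld, variance_explained = ve[1:2])
  }
  tb <- run_block(blocks$temperature)
  pb <- run_block(blocks$precipitation)
  scores <- data.frame(plot_id = climate$plot_id,
                       PCA_temp_1 = tb$scores[, 1], PCA_temp_2 = tb$scores[, 2],
                       PCA_prec_1 = pb$scores[, 1], PCA_prec_2 = pb$scores[, 2],
                       stringsAsFactors = FALSE)
  structure(list(scores = scores,
                 loadings = list(temperature = tb$loadings,
                                 precipitation = pb$loadings),
                 variance_explained = list(temperature = tb$variance_explained,
                                           precipitation = pb$variance_explained)),
            class = "climate_axes")
}

#' @export
print.climate_axes <- function(x, ...) {
  cat("<climate_axes> ", nrow(x$scores), " plots\n", sep = "")
  cat("  temperature axes explain ",
      paste(round(100 * x$variance_explained$temperature, 1), collapse = " + "),
      " % of block variance\n", sep = "")
  cat("  precipitation axes explain ",
      paste(round(100 * x$variance_explained$precipitation, 1), collapse = " + "),
      " % of block variance\n", sep = "")
  invisible(x)
}

#' Partial-standard-deviation coefficient standardization
#'
#' For each predictor in a fitted linear model, computes the variance
#' inflation factor `VIF_i = 1 / (1 - R2_i)` (from regressing predictor i
#' on the remaining predictors), the partial standard deviation
#' `S*_i = S_i * sqrt(1/VIF_i) * sqrt((n - 1) / (n - p))`, and the
#' standardized coefficient `beta*_i = beta_i * S*_i`. With a single
#' predictor VIF = 1 by convention.
#'
#' @param fit an [stats::lm] fit with at least one predictor.
#' @return data frame: `predictor`, `beta`, `s_x`, `vif`, `s_star`,
#'   `beta_star`, `n`, `p`. Perfectly collinear predictors get infinite VIF
#'   and `NA` standardized values, with a warning.
#' @export
partial_sd_standardize <- function(fit) {
  stopifnot(inherits(fit, "lm"))
  X <- stats::model.matrix(fit)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  p <- ncol(X)
  n <- nrow(X)
  if (p < 1) stop("model has no predictors")
  if (n <= p) stop("need n > p observations")
  beta <- stats::coef(fit)[colnames(X)]
  vif <- vapply(seq_len(p), function(i) {
    if (p == 1) return(1)
    r2 <- summary(stats::lm(X[, i] ~ X[, -i, drop = FALSE]))$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  if (any(!is.finite(vif))) {
    warning("perfectly collinear predictor(s): ",
            paste(colnames(X)[!is.finite(vif)], collapse = ", "))
  }
  s_x <- apply(X, 2, stats::sd)
  s_star <- s_x * sqrt(1 / vif) * sqrt((n - 1) / (n - p))
  data.frame(predictor = colnames(X), beta = unname(beta), s_x = unname(s_x),
             vif = vif, s_star = unname(s_star),
             beta_star = unname(beta * s_star), n = n, p = p,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Information-theoretic multimodel inference with natural averaging
#'
#' Enumerates Gaussian linear models over all subsets of the candidate
#' predictors (including the intercept-only model), ranks them by AIC,
#' retains the set with `delta AIC <= delta_max`, and computes the natural
#' (conditional) model average of each coefficient: the Akaike-weighted mean
#' over the retained models in which the predictor appears, with weights
#' renormalized within those models. Coefficients are reported raw and
#' partial-SD standardized (see [partial_sd_standardize()]).
#'
#' @param data data frame holding the response and predictors.
#' @param response name of the response column.
#' @param predictors character vector of candidate predictor columns
#'   (at most 12).
#' @param delta_max AIC retention window (default 4).
#' @param standardize standardize predictors to mean 0, sd 1 before fitting
#'   (default `TRUE`).
#' @return object of class `it_model_set`: `models` (subset, k, AIC, delta,
#'   weight, retained), `coefficients` (predictor, n_models, weight_sum,
#'   estimate, estimate_std), `best` (the best model's predictor subset),
#'   `retained` (count).
#' @export
it_model_average <- function(data, response, predictors, delta_max = 4,
                             standardize = TRUE) {
  stopifnot(response %in% names(data), all(predictors %in% names(data)))
  k <- length(predictors)
  if (k < 1) stop("need at least one candidate predictor")
  if (k > 12) stop("all-subsets enumeration limited to 12 predictors")
  n <- nrow(data)
  if (n <= k + 2) stop("too few observations for the full model (n <= p + 2)")
  df <- data[c(response, predictors)]
  if (anyNA(df)) stop("missing values in response or predictors")
  if (standardize) {
    for (v in predictors) df[[v]] <- as.numeric(scale(df[[v]]))
  }

  subsets <- lapply(0:(2^k - 1), function(mask) predictors[
    bitwAnd(mask, 2^(seq_len(k) - 1)) > 0])
  fits <- vector("list", length(subsets))
  aic <- numeric(length(subsets))
  for (i in seq_along(subsets)) {
    rhs <- if (length(subsets[[i]]) == 0) "1" else
      paste(subsets[[i]], collapse = " + ")
    fits[[i]] <- stats::lm(stats::as.formula(paste(response, "~", rhs)),
                           data = df)
    aic[i] <- stats::AIC(fits[[i]])
  }
  delta <- aic - min(aic)
  retained <- delta <= delta_max
  w <- exp(-delta / 2)
  w <- w / sum(w[retained])
  w[!retained] <- 0

  coef_rows <- lapply(predictors, function(v) {
    in_model <- retained & vapply(subsets, function(s) v %in% s, logical(1))
    if (!any(in_model)) {
      return(data.frame(predictor = v, n_models = 0L, weight_sum = 0,
                        estimate = NA_real_, estimate_std = NA_real_,
                        stringsAsFactors = FALSE))
    }
    wv <- w[in_model] / sum(w[in_model])
    est <- vapply(fits[in_model], function(f) stats::coef(f)[[v]], numeric(1))
    est_std <- vapply(fits[in_model], function(f) {
      ps <- partial_sd_standardize(f)
      ps$beta_star[ps$predictor == v]
    }, numeric(1))
    data.frame(predictor = v, n_models = sum(in_model),
               weight_sum = sum(w[in_model]),
               estimate = sum(wv * est), estimate_std = sum(wv * est_std),
               stringsAsFactors = FALSE)
  })

  models <- data.frame(
    subset = vapply(subsets, function(s)
      if (length(s) == 0) "(intercept)" else paste(s, collapse = "+"),
      character(1)),
    k = vapply(subsets, length, integer(1)),
    aic = aic, delta = delta, weight = w, retained = retained,
    stringsAsFactors = FALSE)
  models <- models[order(models$delta), ]
  rownames(models) <- NULL

  structure(list(models = models,
                 coefficients = do.call(rbind, coef_rows),
                 best = models$subset[1L],
                 retained = sum(retained),
                 response = response, n = n, delta_max = delta_max),
            class = "it_model_set")
}

#' @export
print.it_model_set <- function(x, ...) {
  cat("<it_model_set> response: ", x$response, " (n = ", x$n, ")\n",
      "  best model: ", x$best, "\n",
      "  retained (delta AIC <= ", x$delta_max, "): ", x$retained,
      " of ", nrow(x$models), " models\n", sep = "")
  print(x$coefficients, digits = 3)
  invisible(x)
}
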