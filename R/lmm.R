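#' Fit a linear mixed model with optional Gaussian spatial correlation
#'
#' The estimation engine behind the realm, taxon and driver models: a linear
#' mixed-effects model fitted by REML with random intercepts for taxonomic
#' group and/or study (study nested in taxon group), and residual spatial
#' correlation between sites i and j of the Gaussian form
#' `(1 - nugget) * exp(-(d_ij / rho)^2)`, with the range rho (and optional
#' nugget) estimated jointly with the variance components. Distances are
#' Euclidean on a local equirectangular projection of lon/lat to kilometres
#' (`spatial_coords = "degrees"` uses raw degree coordinates instead). With
#' the spatial structure on, correlation applies among sites within the
#' innermost random-effect group.
#'
#' With `random = "none"` and `spatial = "none"` the model is ordinary least
#' squares (via `stats::lm`), exactly; with `random = "none"` and a spatial
#' structure it is a generalised least-squares fit (`nlme::gls`). Otherwise
#' `nlme::lme` is used. If the spatial fit fails to converge the model is
#' refitted without the spatial term, with a warning.
#'
#' @param data Data.frame with all model variables (and `longitude`,
#'   `latitude` when `spatial = "gauss"`).
#' @param fixed Fixed-effects formula, e.g. `rate ~ temp_change`.
#' @param random One of `"none"`, `"study"` (random intercept per
#'   `study_id`), `"taxon_study"` (`study_id` nested in `taxon_group`).
#' @param spatial `"none"` or `"gauss"`.
#' @param nugget Estimate a nugget at distance 0?
#' @param spatial_coords `"km"` (default) or `"degrees"`.
#' @return Object of class `"model_fit"`: `terms` (data.frame with
#'   `term`, `estimate`, `se`, `df`, `t`, `p`), `varcomp` (random-effect and
#'   residual standard deviations), `rho`, `nugget`, `logLik`, `n`,
#'   `excluded` (ids dropped by [refit_without_outliers()], empty here),
#'   the underlying `model`, and the fit specification.
#' @export
fit_lmm <- function(data, fixed, random = c("none", "study", "taxon_study"),
                    spatial = c("none", "gauss"), nugget = FALSE,
                    spatial_coords = c("km", "degrees")) {
  random <- match.arg(random)
  spatial <- match.arg(spatial)
  spatial_coords <- match.arg(spatial_coords)
  data <- as.data.frame(data)
  vars <- all.vars(fixed)
  miss <- setdiff(vars, names(data))
  if (length(miss))
    stop("data lacks model variable(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  data <- data[stats::complete.cases(data[vars]), , drop = FALSE]
  mm <- stats::model.matrix(fixed, data)
  qr_ <- qr(mm)
  if (qr_$rank < ncol(mm)) {
    aliased <- colnames(mm)[qr_$pivot[(qr_$rank + 1L):ncol(mm)]]
    stop("singular fixed-effect design; aliased term(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  if (random == "study" && !"study_id" %in% names(data))
    stop("random = 'study' needs a 'study_id' column", call. = FALSE)
  if (random == "taxon_study" &&
      !all(c("taxon_group", "study_id") %in% names(data)))
    stop("random = 'taxon_study' needs 'taxon_group' and 'study_id' columns",
         call. = FALSE)
  if (spatial == "gauss") {
    if (!all(c("longitude", "latitude") %in% names(data)))
      stop("spatial = 'gauss' needs 'longitude' and 'latitude' columns",
           call. = FALSE)
    if (spatial_coords == "km") {
      lat0 <- mean(data$latitude) * pi / 180
      data$.sx <- 111.320 * cos(lat0) * data$longitude
      data$.sy <- 110.574 * data$latitude
    } else {
      data$.sx <- data$longitude
      data$.sy <- data$latitude
    }
  }
  cor_struct <- if (spatial == "gauss")
    nlme::corGaus(form = ~ .sx + .sy, nugget = nugget) else NULL
  fit_once <- function(cs) {
    if (random == "none" && is.null(cs)) {
      stats::lm(fixed, data = data)
    } else if (random == "none") {
      nlme::gls(fixed, data = data, correlation = cs, method = "REML",
                control = nlme::glsControl(maxIter = 100, msMaxIter = 100,
                                           returnObject = TRUE))
    } else {
      re <- if (random == "study") stats::as.formula("~ 1 | study_id")
      else stats::as.formula("~ 1 | taxon_group/study_id")
      nlme::lme(fixed, random = re, data = data, correlation = cs,
                method = "REML",
                control = nlme::lmeControl(maxIter = 100, msMaxIter = 100,
                                           opt = "optim",
                                           returnObject = TRUE))
    }
  }
  model <- tryCatch(fit_once(cor_struct), error = function(e) e)
  used_spatial <- spatial
  if (inherits(model, "error") && spatial == "gauss") {
    warning("spatial correlation fit failed (",
            conditionMessage(model), "); refitting without the spatial term",
            call. = FALSE)
    used_spatial <- "none"
    model <- fit_once(NULL)
  }
  if (inherits(model, "error")) stop(model)
  out <- extract_model_fit(model, data)
  out$spec <- list(fixed = fixed, random = random, spatial = used_spatial,
                   nugget = nugget, spatial_coords = spatial_coords)
  out
}

# Pull a uniform summary out of an lm / gls / lme object.
extract_model_fit <- function(model, data) {
  if (inherits(model, "lme") || inherits(model, "gls")) {
    tt <- summary(model)$tTable
    terms <- data.frame(term = rownames(tt),
                        estimate = tt[, "Value"],
                        se = tt[, "Std.Error"],
                        df = if ("DF" %in% colnames(tt)) tt[, "DF"]
                        else nrow(data) - nrow(tt),
                        t = tt[, "t-value"], p = tt[, "p-value"],
                        stringsAsFactors = FALSE)
    varcomp <- if (inherits(model, "lme")) {
      vc <- nlme::VarCorr(model)
      sds <- suppressWarnings(as.numeric(vc[, "StdDev"]))
      lvl <- rownames(vc)
      keep <- is.finite(sds)
      stats::setNames(sds[keep], make.unique(lvl[keep]))
    } else c(Residual = model$sigma)
    cs <- model$modelStruct$corStruct
    rho <- nug <- NA_real_
    if (!is.null(cs)) {
      cp <- stats::coef(cs, unconstrained = FALSE)
      rho <- unname(cp["range"])
      if ("nugget" %in% names(cp)) nug <- unname(cp["nugget"])
    }
    ll <- as.numeric(stats::logLik(model))
  } else {  # lm
    cf <- suppressWarnings(summary(model))$coefficients
    terms <- data.frame(term = rownames(cf), estimate = cf[, 1L],
                        se = cf[, 2L],
                        df = stats::df.residual(model),
                        t = cf[, 3L], p = cf[, 4L],
                        stringsAsFactors = FALSE)
    varcomp <- c(Residual = suppressWarnings(summary(model))$sigma)
    rho <- nug <- NA_real_
    ll <- as.numeric(stats::logLik(model))
  }
  rownames(terms) <- NULL
  structure(list(terms = terms, varcomp = varcomp, rho = rho, nugget = nug,
                 logLik = ll, n = nrow(data), excluded = character(),
                 model = model, data = data),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("model_fit (n = %d%s):\n", x$n,
              if (length(x$excluded))
                sprintf(", %d outlier(s) excluded", length(x$excluded))
              else ""))
  print(cbind(x$terms[1L],
              round(x$terms[c("estimate", "se", "t", "p")], 4L)))
  if (length(x$varcomp)) {
    cat("variance components (sd):\n")
    print(round(x$varcomp, 5L))
  }
  if (is.finite(x$rho))
    cat(sprintf("spatial range rho = %.3f%s\n", x$rho,
                if (is.finite(x$nugget))
                  sprintf(", nugget = %.3f", x$nugget) else ""))
  invisible(x)
}

#' Coefficient accessor for a model_fit
#' @param fit A `model_fit`.
#' @param term Term name (as in `fit$terms$term`).
#' @return Named list `estimate`, `se`, `t`, `p` for the term.
#' @export
fit_term <- function(fit, term) {
  i <- match(term, fit$terms$term)
  if (is.na(i)) stop("no term '", term, "' in fit", call. = FALSE)
  as.list(fit$terms[i, c("estimate", "se", "t", "p")])
}

#' One-pass residual-outlier exclusion and refit
#'
#' Excludes observations whose model residual lies more than `k_sd` standard
#' deviations from the mean residual, then refits the same model once (no
#' iteration) on the remaining rows — the usual residual-normality safeguard
#' for the driver models.
#'
#' @param fit A `model_fit` from [fit_lmm()].
#' @param k_sd Cutoff in residual standard deviations (default 2).
#' @return A new `model_fit`; `excluded` records the dropped row ids
#'   (`site_id` when present, otherwise row numbers). With nothing beyond
#'   the cutoff the refit equals the input fit.
#' @export
refit_without_outliers <- function(fit, k_sd = 2) {
  res <- stats::residuals(fit$model)
  if (!is.finite(k_sd)) k_sd <- Inf
  s <- stats::sd(res)
  # guard against numerically-zero residual spread (e.g. a saturated fit)
  degenerate <- !is.finite(s) ||
    s <= .Machine$double.eps^0.5 * max(1, max(abs(res)))
  keep <- if (degenerate) rep(TRUE, length(res))
  else abs(res - mean(res)) <= k_sd * s
  if (all(keep)) {
    fit$excluded <- character()
    return(fit)
  }
  ids <- if ("site_id" %in% names(fit$data)) fit$data$site_id[!keep]
  else as.character(which(!keep))
  refit <- fit_lmm(fit$data[keep, , drop = FALSE], fit$spec$fixed,
                   random = fit$spec$random, spatial = fit$spec$spatial,
                   nugget = fit$spec$nugget,
                   spatial_coords = fit$spec$spatial_coords)
  refit$excluded <- ids
  refit
}

#' Realm comparison of thermophilisation rates
#'
#' Two models over the assembled site results: `rate ~ realm` (is the mean
#' rate different between freshwater and terrestrial communities?) and
#' `rate ~ temp_change * realm` (does the temperature-change effect differ
#' between realms?), both with study-in-taxon random intercepts and the
#' spatial structure of [fit_lmm()].
#'
#' @param sites Data.frame of site results (see [assemble_predictors()]).
#' @param spatial,nugget Passed to [fit_lmm()].
#' @return List of `model_fit`s: `realm` and `interaction`.
#' @export
realm_comparison <- function(sites, spatial = "gauss", nugget = FALSE) {
  if (length(unique(sites$realm)) < 2L)
    stop("realm comparison needs both realms present", call. = FALSE)
  sites$realm <- factor(sites$realm)
  list(
    realm = fit_lmm(sites, rate ~ realm, random = "taxon_study",
                    spatial = spatial, nugget = nugget),
    interaction = fit_lmm(sites, rate ~ temp_change * realm,
                          random = "taxon_study", spatial = spatial,
                          nugget = nugget))
}

#' Taxon-group comparison of thermophilisation rates, per realm
#'
#' Within each realm, fits `rate ~ taxon_group` with a study random
#' intercept and reports the joint (conditional F) test of the taxon factor.
#' A realm with a single taxon group is skipped with a warning.
#'
#' @param sites Data.frame of site results.
#' @param spatial,nugget Passed to [fit_lmm()].
#' @return Named list (by realm) of lists: `fit` (`model_fit`) and `joint`
#'   (`F`, `df_num`, `df_den`, `p`).
#' @export
taxon_comparison <- function(sites, spatial = "none", nugget = FALSE) {
  out <- list()
  for (rl in unique(sites$realm)) {
    sub <- sites[sites$realm == rl, , drop = FALSE]
    if (length(unique(sub$taxon_group)) < 2L) {
      warning("realm '", rl, "' has a single taxon group; factor dropped",
              call. = FALSE)
      next
    }
    sub$taxon_group <- factor(sub$taxon_group)
    fit <- fit_lmm(sub, rate ~ taxon_group, random = "study",
                   spatial = spatial, nugget = nugget)
    av <- stats::anova(fit$model)
    i <- match("taxon_group", rownames(av))
    joint <- list(F = av[i, "F-value"], df_num = av[i, "numDF"],
                  df_den = av[i, "denDF"], p = av[i, "p-value"])
    out[[rl]] <- list(fit = fit, joint = joint)
  }
  out
}

#' Driver model of thermophilisation rates
#'
#' Fits the full predictor model on z-scored drivers: main effects of
#' temperature change, community mean body size, mean thermal niche breadth,
#' baseline temperature, series length and species richness; interactions of
#' temperature change with body size, niche breadth, baseline temperature
#' and richness; the body size x niche breadth interaction; and the
#' three-way temperature change x body size x niche breadth interaction.
#' Scope `"realm"` (fit across taxon groups of one realm) uses
#' study-in-taxon random intercepts, scope `"taxon"` (one taxon group) a
#' study intercept only. The fit is followed by a single 2-SD
#' residual-outlier exclusion and refit (see [refit_without_outliers()]);
#' the pre-exclusion fit is kept in `$initial`.
#'
#' @param sites Data.frame of site results (raw scale; z-scoring happens
#'   here).
#' @param scope `"realm"` or `"taxon"`.
#' @param spatial,nugget Passed to [fit_lmm()].
#' @param config An [analysis_config()] (supplies `outlier_sd`).
#' @param refit_outliers Apply the outlier exclusion pass (default `TRUE`)?
#' @return A `model_fit` (post-exclusion when applied) with the
#'   pre-exclusion fit in `$initial`.
#' @export
driver_model <- function(sites, scope = c("realm", "taxon"),
                         spatial = "gauss", nugget = FALSE,
                         config = analysis_config(),
                         refit_outliers = TRUE) {
  scope <- match.arg(scope)
  pred <- c("temp_change", "mean_body_size", "mean_niche_breadth",
            "baseline_temp", "series_length", "richness")
  need <- c("rate", pred)
  d <- sites[stats::complete.cases(sites[need]), , drop = FALSE]
  for (nm in pred) d[[nm]] <- zscore(d[[nm]], nm)
  fixed <- rate ~ temp_change * mean_body_size * mean_niche_breadth +
    baseline_temp + series_length + richness +
    temp_change:baseline_temp + temp_change:richness
  random <- if (scope == "realm") "taxon_study" else "study"
  if (scope == "realm" && length(unique(d$taxon_group)) < 2L)
    random <- "study"  # nesting collapses with a single taxon level
  fit <- fit_lmm(d, fixed, random = random, spatial = spatial,
                 nugget = nugget)
  if (!refit_outliers) {
    fit$initial <- NULL
    return(fit)
  }
  final <- refit_without_outliers(fit, k_sd = config$outlier_sd)
  final$initial <- fit
  final
}
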