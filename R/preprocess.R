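## Preprocessing of UPLC peak areas: total-area normalisation to percent,
## natural-log transformation, parametric empirical-Bayes (ComBat) batch
## correction on the log scale, and back-transformation to a linear scale
## for derived-trait computation. The stage order is enforced through a
## scale flag carried by the matrix container.

#' Construct a scale-tagged glycan matrix
#'
#' Light container around a subjects x peaks numeric matrix that records
#' the current scale (`percent`, `log`, `log-adjusted`,
#' `percent-adjusted`), optional batch labels, and an append-only
#' provenance log of the preprocessing steps applied.
#'
#' @param values numeric matrix, subjects in rows, peaks in columns
#' @param scale one of `"percent"`, `"log"`, `"log-adjusted"`,
#'   `"percent-adjusted"`
#' @param batch optional per-subject batch labels
#' @param provenance character vector of applied steps
#' @return an object of class `glyco_matrix`
#' @export
glyco_matrix <- function(values, scale, batch = NULL,
                         provenance = character()) {
  values <- as.matrix(values)
  scale <- match.arg(scale,
    c("percent", "log", "log-adjusted", "percent-adjusted"))
  assert_that(is.numeric(values), "values must be numeric")
  if (!is.null(batch)) {
    assert_that(length(batch) == nrow(values),
                "batch labels must match the number of subjects")
  }
  structure(values, class = c("glyco_matrix", class(values)),
            scale = scale, batch = batch, provenance = provenance)
}

unclass_matrix <- function(x) {
  attrs <- c("scale", "batch", "provenance")
  for (a in attrs) attr(x, a) <- NULL
  class(x) <- setdiff(class(x), "glyco_matrix")
  x
}

log_step <- function(x, step) {
  attr(x, "provenance") <- c(attr(x, "provenance"), step)
  x
}

#' @export
print.glyco_matrix <- function(x, ...) {
  cat(sprintf("<glyco_matrix> %d subjects x %d peaks, scale = %s\n",
              nrow(x), ncol(x), attr(x, "scale")))
  if (length(attr(x, "provenance")))
    cat("  steps:", paste(attr(x, "provenance"), collapse = " -> "), "\n")
  invisible(x)
}

require_scale <- function(m, scale, op) {
  assert_that(inherits(m, "glyco_matrix"),
              "%s expects a glyco_matrix (see total_area_normalize)", op)
  assert_that(attr(m, "scale") %in% scale,
              "%s requires scale %s, got '%s' (pipeline order is normalize -> log -> adjust -> back-transform)",
              op, paste(sQuote(scale), collapse = " or "), attr(m, "scale"))
  invisible(m)
}

#' Normalise raw peak areas to percent of total chromatogram area
#'
#' Each subject's peak vector is divided by its total and scaled to 100,
#' removing run-to-run differences in injected amount and detector
#' response. The result is compositional: every row sums to 100.
#'
#' @param raw numeric matrix or data frame of raw integrated areas,
#'   subjects x peaks
#' @param batch optional per-subject batch labels carried forward for
#'   [combat_adjust()]
#' @return a [glyco_matrix] on the `percent` scale
#' @export
total_area_normalize <- function(raw, batch = NULL) {
  m <- as.matrix(as.data.frame(raw))
  tot <- rowSums(m)
  bad <- which(!is.finite(tot) | tot <= 0)
  assert_that(length(bad) == 0,
              "rows with non-positive total area: %s",
              paste(head(bad, 5), collapse = ", "))
  out <- 100 * sweep(m, 1, tot, "/")
  log_step(glyco_matrix(out, "percent", batch = batch),
           "total_area_normalize")
}

#' Natural-log transform a percent-scale matrix
#'
#' Values at or below `floor` (instrument-censored near-zero areas) are
#' floored before taking logs; every flooring event is recorded in the
#' `floored` attribute and the provenance log.
#'
#' @param m a percent-scale [glyco_matrix]
#' @param floor positive flooring threshold in percent (default `1e-4`)
#' @return a [glyco_matrix] on the `log` scale
#' @export
log_transform <- function(m, floor = 1e-4) {
  require_scale(m, "percent", "log_transform")
  assert_that(is.numeric(floor) && floor > 0, "floor must be positive")
  v <- unclass_matrix(m)
  floored <- which(v < floor, arr.ind = TRUE)
  v[v < floor] <- floor
  out <- glyco_matrix(log(v), "log", batch = attr(m, "batch"),
                      provenance = attr(m, "provenance"))
  attr(out, "floored") <- floored
  log_step(out, sprintf("log_transform(floor=%g, n_floored=%d)",
                        floor, nrow(floored)))
}

#' Empirical-Bayes batch correction of log-scale glycan data
#'
#' Removes additive and multiplicative batch effects with the parametric
#' ComBat model (normal prior on batch means, inverse-gamma on batch
#' variances, moment-matched), as implemented in the sva package. After
#' adjustment each peak is re-centred to its pre-adjustment grand mean:
#' the overall location is not identified by the batch model and keeping
#' it fixed makes the back-transformed rows remain near 100.
#'
#' With a single batch the input is returned unchanged with a warning.
#'
#' @param m a log-scale [glyco_matrix]
#' @param batch per-subject batch labels; defaults to those stored in `m`
#' @param covariates optional numeric design matrix (no intercept) of
#'   biological covariates to protect during adjustment
#' @param parametric use parametric empirical-Bayes priors (the default
#'   and only supported mode)
#' @return a [glyco_matrix] on the `log-adjusted` scale
#' @export
combat_adjust <- function(m, batch = NULL, covariates = NULL,
                          parametric = TRUE) {
  require_scale(m, "log", "combat_adjust")
  batch <- batch %||% attr(m, "batch")
  assert_that(!is.null(batch), "batch labels required")
  assert_that(length(batch) == nrow(m), "batch length must equal subjects")
  assert_that(isTRUE(parametric), "only parametric priors are supported")
  v <- unclass_matrix(m)
  sizes <- table(batch)
  if (length(sizes) < 2) {
    warning("single batch: returning input unchanged")
    out <- glyco_matrix(v, "log-adjusted", batch = batch,
                        provenance = attr(m, "provenance"))
    return(log_step(out, "combat_adjust(single batch, identity)"))
  }
  assert_that(all(sizes >= 2), "every batch needs at least 2 subjects")
  mod <- NULL
  if (!is.null(covariates)) {
    mod <- cbind(1, as.matrix(covariates))
    assert_that(qr(mod)$rank == ncol(mod),
                "covariate design is rank deficient")
  }
  pre_means <- colMeans(v)
  adj <- t(suppressMessages(
    sva::ComBat(dat = t(v), batch = as.factor(batch), mod = mod,
                par.prior = TRUE, prior.plots = FALSE)))
  adj <- sweep(adj, 2, colMeans(adj) - pre_means, "-")
  out <- glyco_matrix(adj, "log-adjusted", batch = batch,
                      provenance = attr(m, "provenance"))
  log_step(out, sprintf("combat_adjust(%d batches%s)", length(sizes),
                        if (is.null(covariates)) "" else ", covariates"))
}

#' Back-transform a batch-adjusted log matrix to the linear scale
#'
#' Exponentiates without re-closing rows to 100 (batch adjustment moves
#' row totals slightly; re-closure would re-introduce compositional
#' coupling). Row sums are recorded in the provenance log.
#'
#' @param m a `log-adjusted` [glyco_matrix]
#' @return a [glyco_matrix] on the `percent-adjusted` scale
#' @export
back_transform <- function(m) {
  require_scale(m, "log-adjusted", "back_transform")
  v <- exp(unclass_matrix(m))
  rs <- rowSums(v)
  out <- glyco_matrix(v, "percent-adjusted", batch = attr(m, "batch"),
                      provenance = attr(m, "provenance"))
  log_step(out, sprintf("back_transform(row sums %.2f-%.2f)",
                        min(rs), max(rs)))
}

#' Run the full preprocessing chain on raw areas
#'
#' Convenience wrapper: [total_area_normalize()] then [log_transform()],
#' [combat_adjust()] and [back_transform()].
#'
#' @inheritParams total_area_normalize
#' @inheritParams log_transform
#' @inheritParams combat_adjust
#' @return a `percent-adjusted` [glyco_matrix]
#' @export
preprocess_peaks <- function(raw, batch, floor = 1e-4, covariates = NULL) {
  m <- total_area_normalize(raw, batch = batch)
  m <- log_transform(m, floor = floor)
  m <- combat_adjust(m, covariates = covariates)
  back_transform(m)
}
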