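#' @include AllClasses.R
NULL

#' Factor specification for a screening design
#'
#' @param name factor name (must be a valid column name).
#' @param levels >= 2 distinct numeric levels; stored sorted.
#' @param role \code{"quantitative"} (typically 2-3 levels) or
#'   \code{"quantitative-multilevel"} (e.g. cycle counts 0..3).
#' @return A list of class \code{FactorSpec}.
#' @export
factorSpec <- function(name, levels,
                       role = c("quantitative", "quantitative-multilevel")) {
  role <- match.arg(role)
  levels <- sort(unique(as.numeric(levels)))
  if (length(levels) < 2L) stop("factor '", name, "' needs >= 2 distinct levels")
  structure(list(name = name, levels = levels, role = role),
            class = "FactorSpec")
}

#' Full-factorial design
#'
#' All combinations of the factor levels, ordered lexicographically by
#' factor (first factor varies slowest) then level; run count equals the
#' product of the level counts.
#'
#' @param factors list of \code{\link{factorSpec}} objects.
#' @return A data.frame with \code{run_id} and one column per factor;
#'   the factor specs are kept in \code{attr(, "factors")}.
#' @examples
#' d <- fullFactorial(list(
#'   factorSpec("pressure_bar", c(500, 1000, 1500)),
#'   factorSpec("biomass_gdcw_per_l", c(10, 55, 100)),
#'   factorSpec("cycles", 0:3, "quantitative-multilevel")))
#' nrow(d)  # 36
#' @export
fullFactorial <- function(factors) {
  if (!length(factors)) stop("empty factor list")
  if (!all(vapply(factors, inherits, logical(1), "FactorSpec")))
    stop("'factors' must be a list of factorSpec objects")
  lv <- lapply(factors, `[[`, "levels")
  names(lv) <- vapply(factors, `[[`, character(1), "name")
  grid <- rev(expand.grid(rev(lv), KEEP.OUT.ATTRS = FALSE))
  out <- cbind(run_id = seq_len(nrow(grid)), grid)
  rownames(out) <- NULL
  attr(out, "factors") <- factors
  out
}

#' Code design factors onto [-1, +1]
#'
#' Each factor is mapped affinely so its minimum level becomes -1 and its
#' maximum +1 (midpoint 0), the standard coding for screening-model
#' coefficients.
#'
#' @param design a design data.frame (e.g. from \code{\link{fullFactorial}});
#'   factor columns are inferred from \code{attr(design, "factors")} or
#'   taken from \code{factor_names}.
#' @param factor_names optional character vector naming the factor columns.
#' @return The design with factor columns replaced by coded values; the
#'   min/max coding map is kept in \code{attr(, "coding")}.
#' @export
codeFactors <- function(design, factor_names = NULL) {
  if (is.null(factor_names)) {
    fs <- attr(design, "factors")
    if (is.null(fs)) stop("supply 'factor_names' or a design with factor specs")
    factor_names <- vapply(fs, `[[`, character(1), "name")
  }
  coding <- data.frame(factor = factor_names, min = NA_real_, max = NA_real_)
  out <- design
  for (k in seq_along(factor_names)) {
    x <- design[[factor_names[k]]]
    lo <- min(x); hi <- max(x)
    if (hi == lo) stop("factor '", factor_names[k], "' is constant")
    out[[factor_names[k]]] <- (x - (lo + hi) / 2) / ((hi - lo) / 2)
    coding$min[k] <- lo; coding$max[k] <- hi
  }
  attr(out, "coding") <- coding
  out
}

doe_formula <- function(factor_names, interactions) {
  rhs <- if (interactions && length(factor_names) > 1L)
    paste0("(", paste(factor_names, collapse = " + "), ")^2")
  else paste(factor_names, collapse = " + ")
  stats::as.formula(paste(".response ~", rhs))
}

#' Fit the coded-factor screening model
#'
#' Ordinary least squares of the response on the coded factors (intercept,
#' main effects and, by default, all two-factor interactions).
#' Goodness of fit \eqn{R^2 = 1 - SSE/SS_{tot}}; goodness of prediction
#' \eqn{Q^2 = 1 - PRESS/SS_{tot}} with the leave-one-out prediction
#' residuals \eqn{e_i/(1-h_i)} obtained from the hat values; two-sided
#' coefficient p-values from the t distribution on the residual degrees of
#' freedom.
#'
#' @param design design data.frame in natural units with one row per run;
#'   coded internally via \code{\link{codeFactors}}.
#' @param response numeric response per run (e.g. biomass-normalized total
#'   AUC).
#' @param factor_names optional character vector naming the factor columns.
#' @param interactions include two-factor interactions? Default TRUE.
#' @return A \code{\link{DoEModel}}.
#' @export
fitScreeningModel <- function(design, response, factor_names = NULL,
                              interactions = TRUE) {
  coded <- codeFactors(design, factor_names)
  coding <- attr(coded, "coding")
  fn <- coding$factor
  if (length(response) != nrow(coded))
    stop("'response' length must equal the number of runs")
  if (anyNA(response) || any(!is.finite(response)))
    stop("'response' must be finite")
  dat <- coded[, fn, drop = FALSE]
  dat$.response <- response
  fit <- stats::lm(doe_formula(fn, interactions), data = dat)
  cf <- stats::coef(fit)
  if (anyNA(cf))
    stop("rank-deficient design; aliased terms: ",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  sm <- summary(fit)
  res <- stats::residuals(fit)
  sstot <- sum((response - mean(response))^2)
  if (sstot == 0) stop("constant response; model quality undefined")
  h <- stats::hatvalues(fit)
  if (any(h >= 1 - 1e-12))
    stop("saturated design (leverage 1); Q2 undefined")
  press <- sum((res / (1 - h))^2)
  r2 <- 1 - sum(res^2) / sstot
  q2 <- 1 - press / sstot
  pv <- sm$coefficients[, "Pr(>|t|)"]
  new("DoEModel", coefficients = cf, pValues = pv, r2 = r2, q2 = q2,
      press = press, coding = coding, fit = fit)
}

#' @rdname fitScreeningModel
#' @param model a \code{DoEModel}.
#' @export
modelCoefficients <- function(model) { stopifnot(is(model, "DoEModel")); model@coefficients }
#' @rdname fitScreeningModel
#' @export
modelPValues <- function(model) { stopifnot(is(model, "DoEModel")); model@pValues }
#' @rdname fitScreeningModel
#' @export
modelR2 <- function(model) { stopifnot(is(model, "DoEModel")); model@r2 }
#' @rdname fitScreeningModel
#' @export
modelQ2 <- function(model) { stopifnot(is(model, "DoEModel")); model@q2 }

# map natural-unit values of one factor onto the stored coding
code_values <- function(model, name, x) {
  cd <- model@coding
  k <- match(name, cd$factor)
  if (is.na(k)) stop("unknown factor: ", name)
  (x - (cd$min[k] + cd$max[k]) / 2) / ((cd$max[k] - cd$min[k]) / 2)
}

#' Predict a response surface over two factors
#'
#' Evaluates the fitted screening model on a grid of two factors (natural
#' units), the remaining factors held at fixed values. Grid points outside
#' the design space trigger an extrapolation warning.
#'
#' @param model a \code{\link{DoEModel}}.
#' @param axis1,axis2 named lists \code{list(name = , grid = )} giving the
#'   factor and its evaluation grid in natural units.
#' @param fixed named numeric vector of the remaining factors' values.
#' @return A \code{\link{ContourGrid}}.
#' @export
predictSurface <- function(model, axis1, axis2, fixed = numeric()) {
  stopifnot(is(model, "DoEModel"))
  cd <- model@coding
  nms <- c(axis1$name, axis2$name, names(fixed))
  if (!setequal(nms, cd$factor) || anyDuplicated(nms))
    stop("axes plus fixed values must name each design factor exactly once")
  for (nm in c(axis1$name, axis2$name)) {
    k <- match(nm, cd$factor)
    g <- if (nm == axis1$name) axis1$grid else axis2$grid
    if (min(g) < cd$min[k] - 1e-9 || max(g) > cd$max[k] + 1e-9)
      warning("grid for '", nm, "' extrapolates beyond the design space")
  }
  grid <- expand.grid(.a1 = axis1$grid, .a2 = axis2$grid,
                      KEEP.OUT.ATTRS = FALSE)
  newdata <- data.frame(row.names = seq_len(nrow(grid)))
  newdata[[axis1$name]] <- code_values(model, axis1$name, grid$.a1)
  newdata[[axis2$name]] <- code_values(model, axis2$name, grid$.a2)
  for (nm in names(fixed))
    newdata[[nm]] <- code_values(model, nm, rep(fixed[[nm]], nrow(grid)))
  pred <- stats::predict(model@fit, newdata = newdata)
  new("ContourGrid", axisNames = c(axis1$name, axis2$name),
      axis1 = as.numeric(axis1$grid), axis2 = as.numeric(axis2$grid),
      fixed = if (length(fixed)) unlist(fixed) else numeric(),
      predicted = matrix(pred, nrow = length(axis1$grid)))
}

#' Export a contour grid as a matrix file with axis headers
#'
#' @param grid a \code{ContourGrid}.
#' @param path output path (delimited text; first row/column are the axes).
#' @return \code{path}, invisibly.
#' @export
writeContourGrid <- function(grid, path) {
  stopifnot(is(grid, "ContourGrid"))
  m <- grid@predicted
  rownames(m) <- grid@axis1
  colnames(m) <- grid@axis2
  utils::write.table(
    cbind(data.frame(axis = rownames(m), check.names = FALSE), m),
    path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
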