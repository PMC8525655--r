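# Internal design-matrix construction shared by the propensity (exposure)
# model and the outcome model. Continuous variables are standardized before
# raw powers are taken (numerically safer, spans the same column space);
# categorical variables are one-hot encoded against the first level.

#' Covariate parameterisation for the exposure (propensity) model
#'
#' @param continuous names of continuous covariates.
#' @param categorical names of categorical covariates.
#' @param degree polynomial degree applied to every continuous covariate:
#'   2 (quadratic, the default specification) or 3 (cubic, the sensitivity
#'   specification); 1 gives a linear-only model.
#' @return an object of class `covariate_spec`.
#' @export
covariate_spec <- function(continuous = character(),
                           categorical = character(),
                           degree = 2L) {
  if (!degree %in% 1:3) stop("degree must be 1, 2 or 3")
  if (length(intersect(continuous, categorical))) {
    stop("continuous and categorical covariate names must be disjoint")
  }
  structure(list(continuous = continuous, categorical = categorical,
                 degree = as.integer(degree)),
            class = "covariate_spec")
}

# degrees: named integer vector over continuous variables
build_design <- function(table, continuous = character(),
                         categorical = character(),
                         degrees = NULL, check_rank = TRUE) {
  n <- nrow(table)
  if (is.null(degrees)) degrees <- stats::setNames(rep(1L, length(continuous)), continuous)
  cols <- list("(Intercept)" = rep(1, n))
  for (v in continuous) {
    x <- table[[v]]
    if (is.null(x)) stop("covariate column not found: ", v)
    z <- .zscore(x)
    d <- degrees[[v]]
    cols[[v]] <- z
    if (d >= 2L) cols[[paste0(v, "^2")]] <- z^2
    if (d >= 3L) cols[[paste0(v, "^3")]] <- z^3
  }
  for (v in categorical) {
    x <- table[[v]]
    if (is.null(x)) stop("covariate column not found: ", v)
    f <- if (is.factor(x)) droplevels(x) else factor(x)
    lev <- levels(f)
    if (length(lev) > 1L) {
      for (l in lev[-1]) cols[[paste0(v, lev_label(l))]] <- as.numeric(f == l)
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  if (check_rank) assert_full_rank(X)
  X
}

lev_label <- function(l) paste0("=", l)

assert_full_rank <- function(X) {
  q <- qr(X)
  if (q$rank < ncol(X)) {
    bad <- colnames(X)[q$pivot[(q$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}
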