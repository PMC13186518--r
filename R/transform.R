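#' Yeo-Johnson power transform
#'
#' Elementwise monotone power transform toward normality, defined for any
#' real `x`: for `x >= 0`, `((x+1)^lambda - 1)/lambda` (`log(x+1)` when
#' `lambda = 0`); for `x < 0`, `-(((-x+1)^(2-lambda) - 1)/(2-lambda))`
#' (`-log(-x+1)` when `lambda = 2`). `lambda = 1` is the identity.
#'
#' @param x Numeric vector.
#' @param lambda Transform exponent.
#' @return Transformed vector.
#' @export
yeo_johnson <- function(x, lambda) {
  out <- numeric(length(x))
  pos <- !is.na(x) & x >= 0
  neg <- !is.na(x) & x < 0
  out[pos] <- if (abs(lambda) < 1e-12) log1p(x[pos]) else
    (exp(lambda * log1p(x[pos])) - 1) / lambda
  out[neg] <- if (abs(lambda - 2) < 1e-12) -log1p(-x[neg]) else
    -(exp((2 - lambda) * log1p(-x[neg])) - 1) / (2 - lambda)
  out[is.na(x)] <- NA_real_
  out
}

# Gaussian profile log-likelihood of lambda for one column
yj_loglik <- function(x, lambda) {
  z <- yeo_johnson(x, lambda)
  s2 <- mean((z - mean(z))^2)
  if (s2 <= 0) return(-Inf)
  n <- length(x)
  -n / 2 * log(s2) + (lambda - 1) * sum(sign(x) * log1p(abs(x)))
}

#' Fit per-feature Yeo-Johnson transforms with standardization
#'
#' For each column, `lambda` is chosen by maximizing the Gaussian profile
#' log-likelihood over `lambda` in `[-5, 5]` (one-dimensional continuous
#' optimization); the transformed column's training mean and SD are stored
#' so [yeo_johnson_apply()] returns standardized values. A constant column
#' gets `lambda = 1` with a warning and scale 1. Fitting on a training split
#' only, then applying to held-out rows, keeps the transform leak-free.
#'
#' @param df Data frame of numeric feature columns.
#' @param features Columns to fit (default: all numeric columns).
#' @return A list of class `yj_spec` with per-feature `lambda`, `center`,
#'   `scale`.
#' @export
yeo_johnson_fit <- function(df, features = NULL) {
  features <- features %||% names(df)[vapply(df, is.numeric, logical(1))]
  spec <- lapply(features, function(f) {
    x <- df[[f]]
    x <- x[is.finite(x)]
    if (length(unique(x)) < 2) {
      warn(paste0("constant column '", f, "': lambda fixed at 1."))
      return(list(lambda = 1, center = yeo_johnson(x[1] %||% 0, 1), scale = 1))
    }
    opt <- optimize(function(l) yj_loglik(x, l), interval = c(-5, 5),
                    maximum = TRUE, tol = 1e-6)
    z <- yeo_johnson(x, opt$maximum)
    s <- sd(z)
    list(lambda = opt$maximum, center = mean(z),
         scale = if (is.finite(s) && s > 0) s else 1)
  })
  names(spec) <- features
  structure(spec, class = "yj_spec")
}

#' @rdname yeo_johnson_fit
#' @param spec A `yj_spec` from [yeo_johnson_fit()].
#' @param newdata Data frame containing the fitted columns.
#' @return `newdata` with fitted columns transformed and standardized.
#' @export
yeo_johnson_apply <- function(spec, newdata) {
  for (f in names(spec)) {
    s <- spec[[f]]
    newdata[[f]] <- (yeo_johnson(newdata[[f]], s$lambda) - s$center) / s$scale
  }
  newdata
}
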