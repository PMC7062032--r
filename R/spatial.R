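# Spatial-autocorrelation robustness: grid neighbourhood weights, ML
# estimation of the simultaneous autoregressive (SAR) error model, and
# Moran's I residual diagnostics.

#' Build a spatial weights object from grid coordinates
#'
#' @param coords data.frame with integer `grid_row` and `grid_col` columns
#'   (one row per unit; duplicates are an error), or a matrix with two
#'   columns.
#' @param scheme `"rook"` (shared edges, 4 neighbours) or `"queen"`
#'   (edges + corners, 8 neighbours).
#' @param style `"row_standardized"` (rows sum to 1; 0 for islands) or
#'   `"binary"`.
#' @return object of class `spatial_weights`: `n`, `neighbours` (list),
#'   `W` (weight matrix), `style`, `islands` (indices with no neighbour).
#' @export
build_weights <- function(coords, scheme = c("rook", "queen"),
                          style = c("row_standardized", "binary")) {
  scheme <- match.arg(scheme)
  style <- match.arg(style)
  if (is.data.frame(coords)) {
    stop_if(!all(c("grid_row", "grid_col") %in% names(coords)),
            "coords needs grid_row and grid_col columns")
    rc <- cbind(coords$grid_row, coords$grid_col)
  } else rc <- as.matrix(coords)
  stop_if(any(rc != round(rc)), "grid coordinates must be integers")
  key <- paste(rc[, 1], rc[, 2])
  stop_if(anyDuplicated(key) > 0, "duplicate grid coordinates")
  n <- nrow(rc)
  lookup <- setNames(seq_len(n), key)
  offsets <- if (scheme == "rook")
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  else
    cbind(rep(-1:1, 3), rep(-1:1, each = 3))[-5, , drop = FALSE]
  neighbours <- vector("list", n)
  B <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb_keys <- paste(rc[i, 1] + offsets[, 1], rc[i, 2] + offsets[, 2])
    nb <- unname(lookup[nb_keys])
    nb <- sort(nb[!is.na(nb)])
    neighbours[[i]] <- nb
    B[i, nb] <- 1
  }
  islands <- which(lengths(neighbours) == 0L)
  W <- if (style == "row_standardized") {
    rs <- rowSums(B)
    B / ifelse(rs > 0, rs, 1)
  } else B
  structure(list(n = n, neighbours = neighbours, W = W, style = style,
                 scheme = scheme, islands = islands),
            class = "spatial_weights")
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat("Spatial weights:", x$n, "units,", x$scheme, "adjacency,",
      x$style, "style\n")
  if (length(x$islands))
    cat("  islands (no neighbours):", length(x$islands), "\n")
  invisible(x)
}

#' Fit a simultaneous autoregressive (SAR) error model by ML
#'
#' Fits `y = X beta + u`, `u = lambda W u + eps`, `eps ~ N(0, sigma^2 I)`.
#' The spatial parameter is profiled over its eigenvalue-bounded feasible
#' interval with `beta` and `sigma^2` concentrated out; the log-Jacobian
#' `ln|I - lambda W|` uses the precomputed eigenvalues of `W`.  At
#' `lambda = 0` the fit equals OLS exactly.
#'
#' @param y numeric response.
#' @param X numeric predictor matrix (columns named); an intercept column
#'   is added unless `intercept = FALSE`.
#' @param weights a [build_weights()] object (or a bare weight matrix).
#' @param intercept add an intercept column.
#' @param fix_lambda optional value at which to fix the spatial parameter
#'   instead of estimating it (e.g. 0 for the OLS-equivalent fit).
#' @return object of class `sar_fit`: `coefficients`, `std_coefficients`
#'   (predictor sd / response sd scaling, intercept excluded), `lambda`,
#'   `sigma2`, `loglik`, `se`, `lambda_interval`, `boundary` flag.
#' @export
fit_sar_error <- function(y, X, weights, intercept = TRUE,
                          fix_lambda = NULL) {
  W <- if (inherits(weights, "spatial_weights")) weights$W else
    as.matrix(weights)
  n <- length(y)
  stop_if(nrow(W) != n || ncol(W) != n, "weight matrix does not match y")
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (intercept) X <- cbind(`(Intercept)` = 1, X)
  stop_if(qr(X)$rank < ncol(X), "X is not of full column rank")

  ev <- eigen(W, only.values = TRUE)$values
  stop_if(max(abs(Im(ev))) > 1e-8, "weight matrix has complex eigenvalues")
  ev <- Re(ev)
  lo <- if (min(ev) < 0) 1 / min(ev) else -Inf
  hi <- if (max(ev) > 0) 1 / max(ev) else Inf
  interval <- c(max(lo, -0.999999) , min(hi, 0.999999))
  if (all(W == 0)) interval <- c(0, 0)

  profile <- function(lambda) {
    A <- diag(n) - lambda * W
    Ay <- A %*% y
    AX <- A %*% X
    fit <- lm.fit(AX, Ay)
    e <- fit$residuals
    sigma2 <- sum(e^2) / n
    ldet <- sum(log(1 - lambda * ev))
    ll <- -n / 2 * (log(2 * pi) + log(sigma2) + 1) + ldet
    list(ll = ll, beta = fit$coefficients, sigma2 = sigma2, A = A, AX = AX)
  }
  if (!is.null(fix_lambda)) {
    lambda <- fix_lambda
    boundary <- FALSE
  } else if (diff(interval) <= 0) {
    lambda <- 0
    boundary <- FALSE
  } else {
    shrink <- interval + c(1, -1) * 1e-6 * diff(interval)
    opt <- optimize(function(l) profile(l)$ll, interval = shrink,
                    maximum = TRUE, tol = 1e-9)
    lambda <- opt$maximum
    boundary <- min(lambda - interval[1], interval[2] - lambda) <
      1e-4 * diff(interval)
  }
  pr <- profile(lambda)
  beta <- pr$beta
  # GLS standard errors at the profiled lambda
  XtX <- crossprod(pr$AX)
  se <- sqrt(diag(pr$sigma2 * solve(XtX)))
  sx <- apply(X, 2, sd)
  sy <- sd(y)
  keep <- colnames(X) != "(Intercept)"
  std <- beta[keep] * sx[keep] / sy
  structure(list(coefficients = beta, std_coefficients = std,
                 lambda = lambda, sigma2 = pr$sigma2, loglik = pr$ll,
                 se = se, lambda_interval = interval, boundary = boundary,
                 n = n, residuals = drop(y - X %*% beta)),
            class = "sar_fit")
}

#' @export
print.sar_fit <- function(x, digits = 4, ...) {
  cat("SAR error model (ML): n =", x$n, "\n")
  cat(sprintf("  lambda = %.4f%s, sigma2 = %.4g, logLik = %.4f\n",
              x$lambda, if (x$boundary) " [at interval boundary]" else "",
              x$sigma2, x$loglik))
  print(round(cbind(estimate = x$coefficients, se = x$se), digits))
  invisible(x)
}

#' Moran's I with analytic randomisation moments
#'
#' Computes Moran's I for a variable (typically model residuals) under the
#' randomisation assumption, with the classical analytic expectation
#' `-1/(n-1)` and variance, and a normal-approximation p-value.
#'
#' @param x numeric vector (constant input is an error).
#' @param weights a [build_weights()] object or weight matrix.
#' @param alternative `"greater"` (positive autocorrelation, default),
#'   `"less"`, or `"two_sided"`.
#' @return list: `statistic`, `expectation`, `variance`, `p_value`.
#' @export
moran_i <- function(x, weights,
                    alternative = c("greater", "less", "two_sided")) {
  alternative <- match.arg(alternative)
  W <- if (inherits(weights, "spatial_weights")) weights$W else
    as.matrix(weights)
  n <- length(x)
  stop_if(nrow(W) != n, "weight matrix does not match x")
  stop_if(sd(x) == 0, "input is constant; Moran's I undefined")
  z <- x - mean(x)
  S0 <- sum(W)
  stop_if(S0 <= 0, "all weights are zero")
  I <- (n / S0) * sum(W * tcrossprod(z)) / sum(z^2)
  EI <- -1 / (n - 1)
  S1 <- sum((W + t(W))^2) / 2
  S2 <- sum((rowSums(W) + colSums(W))^2)
  b2 <- n * sum(z^4) / sum(z^2)^2
  VI <- (n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * S0^2) -
           b2 * ((n^2 - n) * S1 - 2 * n * S2 + 6 * S0^2)) /
    ((n - 1) * (n - 2) * (n - 3) * S0^2) - EI^2
  zstat <- (I - EI) / sqrt(VI)
  p <- switch(alternative,
              greater = pnorm(zstat, lower.tail = FALSE),
              less = pnorm(zstat),
              two_sided = 2 * pnorm(-abs(zstat)))
  list(statistic = I, expectation = EI, variance = VI, z = zstat,
       p_value = p)
}
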