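# Recursive path analysis over observed variables: OLS/ML coefficient
# estimation, model-implied covariance by path tracing, chi-square fit and
# RMSEA. Observed-variable models only (no latents), independent error
# terms, correlated exogenous variables allowed.

#' Parse a path-model specification
#'
#' Plain-text edge list: one statement per line, `A -> B` for a directed
#' path and `A ~~ B` for a freed exogenous covariance, optionally followed
#' by a numeric value (a planted coefficient for simulation). `#` starts a
#' comment.
#'
#' @param x Character vector of lines, a single multi-line string, or a
#'   file path.
#' @return List of class `"pathSpec"`: `edges` (`data.frame` from, to,
#'   coefficient), `covariances` (`data.frame` a, b, value), `variables`
#'   (topologically ordered), `exogenous`.
#' @export
readPathSpec <- function(x) {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x))
    x <- readLines(x)
  x <- unlist(strsplit(x, "\n", fixed = TRUE))
  x <- sub("#.*$", "", x)
  x <- trimws(x)
  x <- x[nzchar(x)]
  pat <- "^([A-Za-z_][A-Za-z0-9_.]*)\\s*(->|~~)\\s*([A-Za-z_][A-Za-z0-9_.]*)\\s*([-+]?[0-9.]+([eE][-+]?[0-9]+)?)?$"
  m <- regmatches(x, regexec(pat, x))
  bad <- vapply(m, length, 0L) == 0L
  if (any(bad))
    stop("cannot parse path statement(s): ",
         paste(x[bad], collapse = " | "))
  from <- vapply(m, `[[`, "", 2L)
  op <- vapply(m, `[[`, "", 3L)
  to <- vapply(m, `[[`, "", 4L)
  val <- suppressWarnings(as.numeric(vapply(m, `[[`, "", 5L)))
  edges <- data.frame(from = from[op == "->"], to = to[op == "->"],
                      coefficient = val[op == "->"],
                      stringsAsFactors = FALSE)
  covs <- data.frame(a = from[op == "~~"], b = to[op == "~~"],
                     value = val[op == "~~"], stringsAsFactors = FALSE)
  vars <- unique(c(edges$from, edges$to, covs$a, covs$b))
  ord <- .topoOrder(vars, edges)
  exog <- setdiff(vars, edges$to)
  structure(list(edges = edges, covariances = covs, variables = ord,
                 exogenous = exog), class = "pathSpec")
}

# Kahn topological sort; errors on cycles.
.topoOrder <- function(vars, edges) {
  indeg <- stats::setNames(integer(length(vars)), vars)
  tab <- table(edges$to)
  indeg[names(tab)] <- as.integer(tab)
  out <- character(0)
  avail <- sort(names(indeg)[indeg == 0L])
  while (length(avail)) {
    v <- avail[1L]; avail <- avail[-1L]
    out <- c(out, v)
    ch <- edges$to[edges$from == v]
    for (c_ in ch) {
      indeg[c_] <- indeg[c_] - 1L
      if (indeg[c_] == 0L) avail <- sort(c(avail, c_))
    }
  }
  if (length(out) != length(vars))
    stop("path specification contains a cycle")
  out
}

#' Example seven-variable path specification
#'
#' A small recursive model of how latitude, climate and geochemistry drive
#' prokaryotic abundance and richness and, through them, viral richness:
#' distance from the equator shapes mean annual temperature, precipitation
#' and prokaryotic richness; temperature, precipitation and pH drive
#' prokaryotic abundance; prokaryotic richness (with a direct pH effect)
#' drives viral richness. Coefficients are standardized planted values used
#' by [simulatePathData()]; magnitudes are chosen so every endogenous
#' implied variance stays below 1.
#'
#' @return A `"pathSpec"` (see [readPathSpec()]).
#' @export
examplePathSpec <- function() {
  readPathSpec(c(
    "lat -> MAT -0.6",
    "lat -> MAP -0.32",
    "lat -> prok_richness -0.42",
    "MAT -> prok_abundance 0.5",
    "MAP -> prok_abundance -0.25",
    "pH -> prok_abundance -0.32",
    "prok_richness -> votu_richness 0.86",
    "pH -> votu_richness -0.2",
    "lat ~~ pH 0"))
}

# Implied covariance among already-generated variables, built in topological
# order from planted coefficients. Used by the simulator to keep every
# variable at unit variance (so planted coefficients are standardized).
.impliedSigma <- function(spec) {
  vars <- spec$variables
  p <- length(vars)
  S <- matrix(0, p, p, dimnames = list(vars, vars))
  for (v in vars) {
    pa <- spec$edges$from[spec$edges$to == v]
    if (!length(pa)) {
      S[v, v] <- 1
      for (w in setdiff(spec$exogenous, v)) {
        cv <- spec$covariances
        hit <- (cv$a == v & cv$b == w) | (cv$a == w & cv$b == v)
        if (any(hit) && !is.na(cv$value[hit][1L]))
          S[v, w] <- S[w, v] <- cv$value[hit][1L]
      }
    } else {
      b <- spec$edges$coefficient[spec$edges$to == v]
      if (anyNA(b)) stop("simulation requires planted coefficients")
      ev <- 1 - drop(t(b) %*% S[pa, pa, drop = FALSE] %*% b)
      if (ev <= 0.01)
        stop("planted coefficients imply variance >= 1 for ", v)
      S[v, v] <- 1
      prev <- vars[seq_len(match(v, vars) - 1L)]
      S[v, prev] <- S[prev, v] <- drop(S[prev, pa, drop = FALSE] %*% b)
    }
  }
  S
}

#' Simulate data from a planted recursive path model
#'
#' Linear structural equations with Gaussian errors, evaluated in
#' topological order; error variances are set so every variable has unit
#' variance, making the planted coefficients standardized and directly
#' recoverable.
#'
#' @param spec A `"pathSpec"` with planted coefficients.
#' @param n Sample size.
#' @param seed Integer seed.
#' @return `data.frame` of n observations of the model variables.
#' @export
simulatePathData <- function(spec, n, seed = 1L) {
  Sigma <- .impliedSigma(spec)   # also validates feasibility
  vars <- spec$variables
  withSeed(seed, {
    dat <- matrix(0, n, length(vars), dimnames = list(NULL, vars))
    for (v in vars) {
      pa <- spec$edges$from[spec$edges$to == v]
      if (!length(pa)) {
        dat[, v] <- stats::rnorm(n)
      } else {
        b <- spec$edges$coefficient[spec$edges$to == v]
        ev <- 1 - drop(t(b) %*% Sigma[pa, pa, drop = FALSE] %*% b)
        dat[, v] <- dat[, pa, drop = FALSE] %*% b +
          stats::rnorm(n, sd = sqrt(ev))
      }
    }
    # freed nonzero exogenous covariances
    cv <- spec$covariances
    nz <- which(!is.na(cv$value) & cv$value != 0)
    for (i in nz) {
      a <- cv$a[i]; b_ <- cv$b[i]; rho <- cv$value[i]
      dat[, b_] <- rho * dat[, a] + sqrt(1 - rho^2) * dat[, b_]
    }
    as.data.frame(dat)
  })
}

#' Fit a recursive path model
#'
#' Variables are standardized; each endogenous variable's coefficients are
#' estimated by OLS on its stated parents (maximum likelihood for a
#' recursive model with independent errors). The model-implied covariance
#' is assembled by path tracing and compared with the sample covariance via
#' the ML discrepancy
#' \deqn{F = \log|\Sigma| + \mathrm{tr}(S\Sigma^{-1}) - \log|S| - p,}
#' giving \eqn{\chi^2 = (n-1)F} with
#' df = #moments - #free parameters, a chi-square p-value, and RMSEA.
#'
#' @param data `data.frame` containing every model variable; n greater than
#'   the number of free parameters.
#' @param spec A `"pathSpec"` (planted coefficients, if any, are ignored).
#' @param freeAllExogenous Free every exogenous covariance (default TRUE;
#'   pairs listed with `~~` are always free).
#' @return List of class `"pathModelFit"`: `coefficients` (`data.frame`
#'   from, to, estimate, se, p), `r2` (named, endogenous), `chi2`, `df`,
#'   `p_value`, `rmsea`, `saturated`, `n`, `implied`, `sample` covariance
#'   matrices.
#' @export
fitPathModel <- function(data, spec, freeAllExogenous = TRUE) {
  vars <- spec$variables
  miss <- setdiff(vars, names(data))
  if (length(miss))
    stop("data lacks model variable(s): ", paste(miss, collapse = ", "))
  X <- scale(as.matrix(data[, vars, drop = FALSE]))
  n <- nrow(X)
  S <- stats::cor(X)
  p <- length(vars)
  endo <- intersect(vars, unique(spec$edges$to))
  exog <- spec$exogenous
  # freed exogenous pairs
  freePairs <- list()
  if (nrow(spec$covariances))
    freePairs <- Map(c, spec$covariances$a, spec$covariances$b)
  if (freeAllExogenous && length(exog) > 1L) {
    cmb <- utils::combn(sort(exog), 2L)
    freePairs <- unique(c(freePairs,
                          lapply(seq_len(ncol(cmb)), function(i) cmb[, i])))
  }
  freePairs <- unique(lapply(freePairs, sort))
  B <- matrix(0, p, p, dimnames = list(vars, vars))   # B[to, from]
  Omega <- matrix(0, p, p, dimnames = list(vars, vars))
  coefRows <- list()
  r2 <- stats::setNames(numeric(0), character(0))
  for (v in vars) {
    pa <- spec$edges$from[spec$edges$to == v]
    if (!length(pa)) {
      Omega[v, v] <- S[v, v]
      next
    }
    Spp <- S[pa, pa, drop = FALSE]
    b <- solve(Spp, S[pa, v])
    B[v, pa] <- b
    res <- S[v, v] - drop(t(b) %*% Spp %*% b)
    Omega[v, v] <- res
    r2[v] <- 1 - res / S[v, v]
    # analytic OLS standard errors on standardized data
    dfres <- n - length(pa) - 1L
    se <- sqrt(pmax(res * (n - 1) / dfres, 0) *
                 diag(solve(Spp)) / (n - 1))
    tval <- b / se
    coefRows[[v]] <- data.frame(
      from = pa, to = v, estimate = unname(b), se = unname(se),
      p = 2 * stats::pt(abs(tval), dfres, lower.tail = FALSE),
      stringsAsFactors = FALSE)
  }
  for (pr in freePairs) {
    if (all(pr %in% exog))
      Omega[pr[1L], pr[2L]] <- Omega[pr[2L], pr[1L]] <- S[pr[1L], pr[2L]]
  }
  Inv <- solve(diag(p) - B)
  Sigma <- Inv %*% Omega %*% t(Inv)
  detS <- det(S); detSig <- det(Sigma)
  if (detSig <= 0 || detS <= 0)
    stop("singular implied or sample covariance; model not identified ",
         "for these data")
  Fml <- log(detSig) + sum(diag(S %*% solve(Sigma))) - log(detS) - p
  chi2 <- max(0, (n - 1) * Fml)
  nFreeCov <- sum(vapply(freePairs, function(pr) all(pr %in% exog),
                         logical(1L)))
  free <- nrow(spec$edges) + nFreeCov + p
  df <- p * (p + 1) / 2 - free
  if (df < 0) stop("model has more free parameters than moments")
  fit <- evaluateFit(chi2, df, n)
  coefs <- do.call(rbind, coefRows)
  rownames(coefs) <- NULL
  structure(list(coefficients = coefs, r2 = r2, chi2 = chi2, df = df,
                 p_value = fit$p_value, rmsea = fit$rmsea,
                 saturated = fit$saturated, n = n,
                 implied = Sigma, sample = S),
            class = "pathModelFit")
}

#' Chi-square p-value and RMSEA for a fitted path model
#'
#' \deqn{\mathrm{RMSEA} = \sqrt{\max\!\left(0,
#'   \frac{\chi^2 - df}{df\,(n - 1)}\right)}}
#' A saturated model (df = 0) reports RMSEA 0 with a saturation flag.
#'
#' @param chi2 Non-negative chi-square statistic.
#' @param df Degrees of freedom (>= 0).
#' @param n Sample size (>= 2).
#' @return List: `p_value`, `rmsea`, `saturated`.
#' @export
#' @examples
#' evaluateFit(20, 10, 101)  # rmsea = sqrt(10/1000) = 0.1
evaluateFit <- function(chi2, df, n) {
  if (chi2 < 0) stop("chi2 must be non-negative")
  if (df < 0 || n < 2) stop("df >= 0 and n >= 2 required")
  if (df == 0)
    return(list(p_value = 1, rmsea = 0, saturated = TRUE))
  list(p_value = stats::pchisq(chi2, df, lower.tail = FALSE),
       rmsea = sqrt(max(0, (chi2 - df) / (df * (n - 1)))),
       saturated = FALSE)
}

#' @export
print.pathModelFit <- function(x, ...) {
  cat("Recursive path model: n =", x$n, "\n")
  cat(sprintf("chi2 = %.4f on %d df (p = %.4g), RMSEA = %.4f%s\n",
              x$chi2, x$df, x$p_value, x$rmsea,
              if (x$saturated) " [saturated]" else ""))
  print(x$coefficients, digits = 3)
  invisible(x)
}
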