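`%||%` <- function(x, y) if (is.null(x)) y else x

# Covariate columns of a study as a numeric matrix (0-column matrix if none).
covariate_matrix <- function(study, covariates) {
  if (length(covariates) == 0) {
    return(matrix(numeric(0), nrow = nrow(study), ncol = 0))
  }
  miss <- setdiff(covariates, names(study))
  if (length(miss) > 0) {
    stop("covariate columns not found: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  as.matrix(study[, covariates, drop = FALSE])
}

# Build a linear-predictor design matrix from a term list.
# Terms: "intercept", the exposure term (named `xname`, e.g. "C" or "X"),
# "t", "<xname>:t", and covariate names (columns of W).
build_terms_matrix <- function(terms, x, t, W, xname) {
  n <- length(t)
  cols <- lapply(terms, function(tm) {
    if (tm == "intercept") return(rep(1, n))
    if (tm == xname) return(x)
    if (tm == "t") return(t)
    if (tm %in% c(paste0(xname, ":t"), paste0("t:", xname))) return(x * t)
    if (tm %in% colnames(W)) return(W[, tm])
    stop("unknown term '", tm, "'; available covariates: ",
         paste(colnames(W), collapse = ", "), call. = FALSE)
  })
  m <- do.call(cbind, cols)
  colnames(m) <- terms
  m
}

term_covariates <- function(terms, xname) {
  setdiff(terms, c("intercept", xname, "t", paste0(xname, ":t"),
                   paste0("t:", xname)))
}

# Central-difference numeric Jacobian of a vector-valued function.
numeric_jacobian <- function(f, x, h = NULL) {
  f0 <- f(x)
  J <- matrix(0, nrow = length(f0), ncol = length(x))
  for (k in seq_along(x)) {
    hk <- if (is.null(h)) 1e-6 * (1 + abs(x[k])) else h
    xp <- x; xp[k] <- x[k] + hk
    xm <- x; xm[k] <- x[k] - hk
    J[, k] <- (f(xp) - f(xm)) / (2 * hk)
  }
  J
}
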