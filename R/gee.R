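#' Build an outcome-model design matrix
#'
#' Expands the outcome-model terms (intercept, exposure-history value X, time
#' t, the X-by-t product, covariates W) into per-occasion design rows aligned
#' with the study rows. Occasions whose history value is `NA` (an excluded
#' baseline) are dropped.
#'
#' @param study A [study_data()] tibble.
#' @param xvals Exposure-history values: the tibble returned by
#'   [exposure_history()] (aligned row-for-row) or a numeric vector.
#' @param terms Character vector of outcome-model terms, e.g.
#'   `c("intercept", "X", "t", "X:t")` plus covariate names.
#' @return A list with the design matrix `X` (colnames = terms), outcome `y`,
#'   subject `id`, outcome time `t`, occasion index `occasion` (position of
#'   `t` in the sorted set of distinct outcome times), and the logical vector
#'   `kept` of retained study rows.
#' @export
build_design <- function(study, xvals, terms) {
  xv <- if (is.data.frame(xvals)) xvals$value else as.numeric(xvals)
  if (length(xv) != nrow(study)) {
    stop("`xvals` must supply one value per study row (",
         length(xv), " vs ", nrow(study), ")", call. = FALSE)
  }
  kept <- !is.na(xv)
  W <- covariate_matrix(study, study_covariates(study))
  X <- build_terms_matrix(terms, xv[kept], study$.t_out[kept],
                          W[kept, , drop = FALSE], xname = "X")
  grid <- sort(unique(study$.t_out))
  list(X = X, y = study$.y[kept], id = study$.id[kept],
       t = study$.t_out[kept],
       occasion = match(study$.t_out[kept], grid),
       grid = grid, kept = kept)
}

#' Moment estimates of the working covariance
#'
#' Estimates the scale and working-correlation parameters from per-subject
#' residual vectors: `phi = sum(e^2) / (N_obs - p)`; for AR(1),
#' `rho = sum of lag-1 products / (phi * sum(m_i - 1))`, clamped to
#' (-0.99, 0.99); for exchangeable, the all-pairs analogue; for unstructured,
#' available-pairs moments on a common occasion grid.
#'
#' @param residuals List of per-subject residual vectors.
#' @param structure `"independence"`, `"ar1"`, `"exchangeable"` or
#'   `"unstructured"`.
#' @param p Number of mean-model parameters (used in the `phi` denominator).
#' @param occasions For `"unstructured"`: list of integer occasion positions
#'   (into the common grid) per subject, same shapes as `residuals`.
#' @param grid_size For `"unstructured"`: number of grid occasions.
#' @return A list with `structure`, `phi`, and `rho` (scalar, or the full
#'   correlation matrix for `"unstructured"`).
#' @examples
#' estimate_working(list(c(1, 0.5), c(-1, -0.5)), "ar1", p = 0)
#' @export
estimate_working <- function(residuals,
                             structure = c("independence", "ar1",
                                           "exchangeable", "unstructured"),
                             p, occasions = NULL, grid_size = NULL) {
  structure <- match.arg(structure)
  nobs <- sum(lengths(residuals))
  if (nobs <= p) stop("fewer observations than parameters", call. = FALSE)
  phi <- sum(vapply(residuals, function(e) sum(e^2), 0)) / (nobs - p)
  # guard against an exactly saturated fit (zero residual variance)
  phi <- max(phi, 1e-12)
  rho <- NULL
  if (structure == "ar1") {
    num <- sum(vapply(residuals, function(e) {
      m <- length(e); if (m < 2) 0 else sum(e[-m] * e[-1])
    }, 0))
    den <- phi * sum(pmax(lengths(residuals) - 1, 0))
    rho <- if (den > 0) min(max(num / den, -0.99), 0.99) else 0
  } else if (structure == "exchangeable") {
    num <- sum(vapply(residuals, function(e) {
      (sum(e)^2 - sum(e^2)) / 2
    }, 0))
    mi <- lengths(residuals)
    den <- phi * sum(mi * (mi - 1) / 2)
    rho <- if (den > 0) min(max(num / den, -0.99), 0.99) else 0
  } else if (structure == "unstructured") {
    if (is.null(occasions) || is.null(grid_size)) {
      stop("unstructured working correlation requires `occasions` on a ",
           "common grid", call. = FALSE)
    }
    S <- matrix(0, grid_size, grid_size)
    Np <- matrix(0, grid_size, grid_size)
    for (i in seq_along(residuals)) {
      pos <- occasions[[i]]
      e <- residuals[[i]]
      S[pos, pos] <- S[pos, pos] + tcrossprod(e)
      Np[pos, pos] <- Np[pos, pos] + 1
    }
    R <- ifelse(Np > 0, S / (pmax(Np, 1) * phi), 0)
    diag(R) <- 1
    R <- (R + t(R)) / 2
    rho <- R
  }
  list(structure = structure, phi = phi, rho = rho)
}

working_matrix <- function(working, m, pos = NULL) {
  phi <- working$phi
  switch(working$structure,
    independence = diag(phi, m),
    ar1 = phi * working$rho^abs(outer(seq_len(m), seq_len(m), "-")),
    exchangeable = phi * ((1 - working$rho) * diag(m) +
                            working$rho * matrix(1, m, m)),
    unstructured = phi * working$rho[pos, pos, drop = FALSE]
  )
}

# Group subjects by covariance pattern for vectorised accumulation.
# Assumes rows sorted by subject with within-subject occasion order.
make_groups <- function(id, occasion, structure) {
  runs <- rle(as.character(id))
  if (any(duplicated(runs$values))) {
    stop("rows must be grouped contiguously by subject", call. = FALSE)
  }
  mlens <- runs$lengths
  starts <- cumsum(c(1L, mlens[-length(mlens)]))
  key <- if (structure == "unstructured") {
    vapply(seq_along(starts), function(s) {
      paste(occasion[starts[s] + seq_len(mlens[s]) - 1L], collapse = ",")
    }, "")
  } else {
    as.character(mlens)
  }
  lapply(split(seq_along(starts), key), function(subj) {
    m <- mlens[subj[1]]
    IDX <- outer(seq_len(m) - 1L, starts[subj], "+")  # m x n_g row indices
    pos <- if (!is.null(occasion)) occasion[IDX[, 1]] else seq_len(m)
    list(subjects = runs$values[subj], m = m, n = length(subj),
         IDX = IDX, pos = pos)
  })
}

group_inverses <- function(groups, working) {
  lapply(groups, function(g) {
    V <- working_matrix(working, g$m, g$pos)
    Vi <- tryCatch(chol2inv(chol(V)), error = function(e) {
      stop("singular working covariance (m = ", g$m, ")", call. = FALSE)
    })
    Vi
  })
}

# Accumulate M = sum_i X_i' V_i^-1 X_i and v = sum_i X_i' V_i^-1 y_i.
accumulate_wls <- function(X, y, groups, Vis) {
  p <- ncol(X)
  M <- matrix(0, p, p)
  v <- numeric(p)
  for (gi in seq_along(groups)) {
    g <- groups[[gi]]
    Vi <- Vis[[gi]]
    Yg <- matrix(y[g$IDX], nrow = g$m)
    ViY <- Vi %*% Yg
    Xg <- lapply(seq_len(g$m), function(j) X[g$IDX[j, ], , drop = FALSE])
    for (j in seq_len(g$m)) {
      v <- v + crossprod(Xg[[j]], ViY[j, ])
      for (k in seq_len(g$m)) {
        if (Vi[j, k] != 0) {
          M <- M + Vi[j, k] * crossprod(Xg[[j]], Xg[[k]])
        }
      }
    }
  }
  list(M = M, v = v)
}

group_residual_list <- function(r, groups) {
  out <- vector("list", sum(vapply(groups, function(g) g$n, 0L)))
  pos_list <- vector("list", length(out))
  ids <- character(length(out))
  k <- 0L
  for (g in groups) {
    Rg <- matrix(r[g$IDX], nrow = g$m)
    for (i in seq_len(g$n)) {
      k <- k + 1L
      out[[k]] <- Rg[, i]
      pos_list[[k]] <- g$pos
      ids[k] <- g$subjects[i]
    }
  }
  list(residuals = out, occasions = pos_list, ids = ids)
}

#' Solve a linear generalized estimating equation
#'
#' Iterates weighted-least-squares updates of the mean parameters with moment
#' updates of the working covariance until the coefficient change is below
#' `tol` (default 1e-8) or `maxit` iterations (default 50). The estimating
#' function is `psi_beta = sum_i X_i' V_i^-1 (y_i - X_i beta)`; per-subject
#' contributions at the solution and the bread block `-sum_i X_i' V_i^-1 X_i`
#' are returned for sandwich assembly.
#'
#' @param X Design matrix (rows sorted by subject, occasions in order).
#' @param y Response vector.
#' @param id Subject identifier per row.
#' @param structure Working-correlation structure.
#' @param occasion Integer occasion positions on a common grid (required for
#'   `"unstructured"`).
#' @param grid_size Number of grid occasions (for `"unstructured"`; defaults
#'   to `max(occasion)`).
#' @param maxit,tol Iteration controls.
#' @return An object of class `memlong_gee`: coefficients, robust (sandwich)
#'   `vcov`, per-subject score matrix `psi`, `bread`, the fitted working
#'   covariance, and convergence information.
#' @export
gee_solve <- function(X, y, id,
                      structure = c("independence", "ar1", "exchangeable",
                                    "unstructured"),
                      occasion = NULL, grid_size = NULL,
                      maxit = 50, tol = 1e-8) {
  structure <- match.arg(structure)
  X <- as.matrix(X)
  p <- ncol(X)
  if (length(y) < p) stop("fewer rows than parameters", call. = FALSE)
  if (structure == "unstructured" && is.null(occasion)) {
    stop("unstructured working correlation requires `occasion` positions ",
         "on a common grid", call. = FALSE)
  }
  if (is.null(grid_size) && !is.null(occasion)) grid_size <- max(occasion)

  qrX <- qr(X)
  if (qrX$rank < p) stop("singular design matrix", call. = FALSE)
  beta <- qr.coef(qrX, y)

  groups <- make_groups(id, occasion, structure)
  converged <- FALSE
  n_iter <- 0L
  working <- NULL
  Vis <- NULL
  for (it in seq_len(maxit)) {
    n_iter <- it
    r <- y - drop(X %*% beta)
    gl <- group_residual_list(r, groups)
    working <- estimate_working(gl$residuals, structure, p,
                                occasions = gl$occasions,
                                grid_size = grid_size)
    Vis <- group_inverses(groups, working)
    acc <- accumulate_wls(X, y, groups, Vis)
    beta_new <- drop(solve(acc$M, acc$v))
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < tol) { converged <- TRUE; break }
  }
  r <- y - drop(X %*% beta)

  # per-subject scores psi_i = X_i' V_i^-1 r_i and bread -sum X_i' V_i^-1 X_i
  n_subj <- sum(vapply(groups, function(g) g$n, 0L))
  psi <- matrix(0, n_subj, p)
  ids <- character(n_subj)
  off <- 0L
  M <- matrix(0, p, p)
  for (gi in seq_along(groups)) {
    g <- groups[[gi]]
    Vi <- Vis[[gi]]
    Rg <- matrix(r[g$IDX], nrow = g$m)
    Sg <- Vi %*% Rg
    psig <- matrix(0, g$n, p)
    for (j in seq_len(g$m)) {
      Xgj <- X[g$IDX[j, ], , drop = FALSE]
      psig <- psig + Xgj * Sg[j, ]
      for (k in seq_len(g$m)) {
        if (Vi[j, k] != 0) {
          M <- M + Vi[j, k] * crossprod(Xgj, X[g$IDX[k, ], , drop = FALSE])
        }
      }
    }
    psi[off + seq_len(g$n), ] <- psig
    ids[off + seq_len(g$n)] <- g$subjects
    off <- off + g$n
  }
  rownames(psi) <- ids
  colnames(psi) <- colnames(X)
  names(beta) <- colnames(X)
  A <- crossprod(psi)
  Mi <- solve(M)
  vcov <- Mi %*% A %*% t(Mi)
  vcov <- (vcov + t(vcov)) / 2
  dimnames(vcov) <- list(colnames(X), colnames(X))
  dimnames(M) <- dimnames(vcov)

  structure(list(coefficients = beta, vcov = vcov, psi = psi, bread = -M,
                 working = working, n_iter = n_iter, converged = converged,
                 residuals = r, n_subjects = n_subj, n_obs = length(y),
                 groups = groups, Vis = Vis, X = X, y = y),
            class = "memlong_gee")
}

# sum_i A_i' V_i^-1 b_i over the fit's cluster structure, with V fixed at
# the fitted working covariance.
sum_wprod <- function(fit, A, b) {
  out <- numeric(ncol(A))
  for (gi in seq_along(fit$groups)) {
    g <- fit$groups[[gi]]
    Vi <- fit$Vis[[gi]]
    Bg <- matrix(b[g$IDX], nrow = g$m)
    Sg <- Vi %*% Bg
    for (j in seq_len(g$m)) {
      out <- out + crossprod(A[g$IDX[j, ], , drop = FALSE], Sg[j, ])
    }
  }
  drop(out)
}

# Sum of the estimating function for a (possibly new) design at fixed beta
# and fixed working covariance; used by the cross-Jacobian.
sum_psi_at <- function(fit, Xnew, beta) {
  p <- ncol(Xnew)
  r <- fit$y - drop(Xnew %*% beta)
  v <- numeric(p)
  for (gi in seq_along(fit$groups)) {
    g <- fit$groups[[gi]]
    Vi <- fit$Vis[[gi]]
    Rg <- matrix(r[g$IDX], nrow = g$m)
    Sg <- Vi %*% Rg
    for (j in seq_len(g$m)) {
      v <- v + crossprod(Xnew[g$IDX[j, ], , drop = FALSE], Sg[j, ])
    }
  }
  drop(v)
}
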