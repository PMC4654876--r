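#' Build the fixed-effect design for the trait-adjustment model
#'
#' Reference-level dummy coding (first level alphabetically as reference) of
#' breed type, gender and production system, plus linear covariates age at
#' slaughter, days slaughter-to-extraction and diet metabolic energy;
#' marbling score is added as a further linear covariate for muscle traits.
#'
#' @param traits trait table as produced by [simulate_phenotypes()] (columns
#'   breed, gender, system, age, days_ext, diet_me, marbling, cg).
#' @param marbling include the marbling covariate (muscle traits).
#' @return list(X = fixed design incl. intercept, Zcg = contemporary-group
#'   incidence matrix, keep = logical rows retained).  Animals with missing
#'   covariates are dropped with a warning.
#' @export
adjustment_design <- function(traits, marbling = FALSE) {
  covars <- c("age", "days_ext", "diet_me", if (marbling) "marbling")
  used <- c("breed", "gender", "system", "cg", covars)
  keep <- stats::complete.cases(traits[, used, drop = FALSE])
  if (!all(keep))
    warning(sum(!keep), " animals dropped for missing covariates")
  tr <- traits[keep, , drop = FALSE]
  fml <- stats::as.formula(paste("~ breed + gender + system +",
                                 paste(covars, collapse = " + ")))
  X <- stats::model.matrix(fml, data = droplevels(tr))
  cg <- droplevels(factor(tr$cg))
  Zcg <- stats::model.matrix(~ cg - 1)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) X <- X[, qr_x$pivot[seq_len(qr_x$rank)], drop = FALSE]
  list(X = X, Zcg = Zcg, keep = keep)
}

#' Average-information REML for the animal model
#'
#' Fits `y = X b + c + u + e` with `c ~ N(0, Zcg Zcg' sigma2_cg)`,
#' `u ~ N(0, G sigma2_a)` and `e ~ N(0, I sigma2_e)` by average-information
#' REML with EM fallback steps whenever the AI update leaves the parameter
#' space or decreases the restricted likelihood.  Variances are kept
#' non-negative by boundary projection against a small floor.
#'
#' @param y numeric response vector.
#' @param X fixed-effect design matrix (full column rank, with intercept).
#' @param G n x n genomic (or pedigree) relationship matrix aligned with `y`.
#' @param Zcg optional contemporary-group incidence matrix; omit (NULL) for
#'   a two-component additive + residual model.
#' @param ridge small value added to diag(G) for numerical stability (G from
#'   sample-centered markers is singular by construction).
#' @param max_iter,tol_loglik,tol_par iteration cap and convergence
#'   tolerances on the restricted log-likelihood change and relative
#'   parameter change.
#' @param h2_includes_cg if TRUE (default) heritability is
#'   `sigma2_a / (sigma2_a + sigma2_cg + sigma2_e)`; if FALSE the
#'   contemporary-group variance is excluded from the denominator.
#' @param verbose print per-iteration restricted log-likelihoods.
#' @return a `varcomp_fit`: sigma2_a, sigma2_cg (NA when Zcg is NULL),
#'   sigma2_e, h2, se_h2, beta (fixed-effect solutions), loglik_history,
#'   converged, plus internals used by [adjust_phenotypes()].
#' @export
fit_reml <- function(y, X, G, Zcg = NULL, ridge = 1e-6,
                     max_iter = 50L, tol_loglik = 1e-6, tol_par = 1e-8,
                     h2_includes_cg = TRUE, verbose = FALSE) {
  n <- length(y)
  stopifnot(nrow(X) == n, nrow(G) == n, ncol(G) == n)
  if (n < ncol(X) + 10L) stop("too few records for the fixed-effect design")
  Gr <- G + diag(ridge, n)
  have_cg <- !is.null(Zcg)
  comps <- c(list(a = Gr), if (have_cg) list(cg = tcrossprod(Zcg)), list(e = diag(n)))
  k <- length(comps)

  vy <- stats::var(y)
  theta <- rep(vy / k, k)
  floor_v <- 1e-8 * vy

  restricted_ll <- function(theta) {
    V <- matrix(0, n, n)
    for (i in seq_len(k)) V <- V + theta[i] * comps[[i]]
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    Vinv <- chol2inv(ch)
    XtVinv <- crossprod(X, Vinv)
    XtVinvX <- XtVinv %*% X
    chx <- tryCatch(chol(XtVinvX), error = function(e) NULL)
    if (is.null(chx)) return(NULL)
    P <- Vinv - t(XtVinv) %*% chol2inv(chx) %*% XtVinv
    Py <- P %*% y
    ll <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chx))) +
                  sum(y * Py))
    list(ll = ll, P = P, Py = Py, Vinv = Vinv, XtVinvX = XtVinvX,
         XtVinv = XtVinv)
  }

  st <- restricted_ll(theta)
  if (is.null(st)) stop("initial variance matrix not positive definite")
  history <- st$ll
  converged <- FALSE
  AI <- NULL
  for (iter in seq_len(max_iter)) {
    Py <- st$Py
    P <- st$P
    VIPy <- lapply(comps, function(Vi) Vi %*% Py)
    # score: -0.5 (tr(P Vi) - y'P Vi P y); tr(P Vi) = sum(P * Vi) (symmetric)
    trPVi <- vapply(comps, function(Vi) sum(P * Vi), numeric(1))
    yPViPy <- vapply(VIPy, function(v) sum(Py * v), numeric(1))
    score <- -0.5 * (trPVi - yPViPy)
    AI <- matrix(0, k, k)
    PVIPy <- lapply(VIPy, function(v) P %*% v)
    for (i in seq_len(k)) for (j in i:k) {
      AI[i, j] <- AI[j, i] <- 0.5 * sum(VIPy[[i]] * PVIPy[[j]])
    }
    step <- tryCatch(solve(AI, score), error = function(e) NULL)
    accepted <- FALSE
    if (!is.null(step)) {
      halve <- 0
      while (halve < 6) {
        cand <- pmax(theta + step, floor_v)
        st_new <- restricted_ll(cand)
        if (!is.null(st_new) && st_new$ll >= history[length(history)] - 1e-10) {
          accepted <- TRUE; break
        }
        step <- step / 2; halve <- halve + 1
      }
    }
    if (!accepted) {
      # EM step: theta_i' = theta_i + theta_i^2 (y'P Vi P y - tr(P Vi)) / n
      cand <- pmax(theta + theta^2 * (yPViPy - trPVi) / n, floor_v)
      st_new <- restricted_ll(cand)
      if (is.null(st_new)) break
    }
    d_ll <- st_new$ll - history[length(history)]
    d_par <- max(abs(cand - theta) / pmax(abs(theta), floor_v))
    theta <- cand
    st <- st_new
    history <- c(history, st$ll)
    if (verbose) message(sprintf("iter %d  logL %.6f", iter, st$ll))
    if (abs(d_ll) < tol_loglik || d_par < tol_par) { converged <- TRUE; break }
  }
  if (!converged)
    warning("REML did not converge in ", max_iter,
            " iterations; returning last estimates")
  if (!is.null(AI)) {
    cond_ai <- tryCatch(kappa(AI, exact = FALSE), error = function(e) Inf)
    if (!is.finite(cond_ai) || cond_ai > 1e10)
      warning("average-information matrix is near-singular: ",
              "variance components are weakly identifiable ",
              "(e.g. G close to identity); boundary solution reported")
  }

  names(theta) <- names(comps)
  sigma2_a <- theta[["a"]]
  sigma2_cg <- if (have_cg) theta[["cg"]] else NA_real_
  sigma2_e <- theta[["e"]]
  denom <- sigma2_a + sigma2_e + if (h2_includes_cg && have_cg) sigma2_cg else 0
  h2 <- sigma2_a / denom

  se_h2 <- NA_real_
  Cth <- tryCatch(solve(AI), error = function(e) NULL)
  if (!is.null(Cth)) {
    grad <- numeric(k)
    ia <- match("a", names(comps)); ie <- match("e", names(comps))
    icg <- match("cg", names(comps))
    grad[ia] <- (denom - sigma2_a) / denom^2
    grad[ie] <- -sigma2_a / denom^2
    if (have_cg) grad[icg] <- if (h2_includes_cg) -sigma2_a / denom^2 else 0
    v <- drop(crossprod(grad, Cth %*% grad))
    if (is.finite(v) && v >= 0) se_h2 <- sqrt(v)
  }

  beta <- drop(solve(st$XtVinvX, st$XtVinv %*% y))
  names(beta) <- colnames(X)
  structure(list(sigma2_a = sigma2_a, sigma2_cg = sigma2_cg,
                 sigma2_e = sigma2_e, h2 = unname(h2), se_h2 = se_h2,
                 beta = beta, loglik_history = history,
                 converged = converged, n = n,
                 h2_includes_cg = h2_includes_cg,
                 Py = drop(st$Py)),
            class = "varcomp_fit")
}

#' @export
print.varcomp_fit <- function(x, ...) {
  cat("REML variance components\n")
  cat(sprintf("  sigma2_a  = %.4f\n", x$sigma2_a))
  if (!is.na(x$sigma2_cg)) cat(sprintf("  sigma2_cg = %.4f\n", x$sigma2_cg))
  cat(sprintf("  sigma2_e  = %.4f\n", x$sigma2_e))
  cat(sprintf("  h2        = %.3f (SE %.3f)\n", x$h2, x$se_h2))
  invisible(x)
}

#' Adjust phenotypes for fixed and contemporary-group effects
#'
#' Computes `y* = y - X b_hat - Zcg c_hat` where `b_hat` are the GLS
#' fixed-effect solutions and `c_hat` the contemporary-group BLUPs from the
#' REML fit; additive genetic and residual parts remain in `y*`.
#'
#' @param y,X,Zcg data used in [fit_reml()] (same row order).
#' @param fit the `varcomp_fit`.
#' @return numeric vector of adjusted phenotypes (mean approximately 0 when
#'   `X` contains an intercept).
#' @export
adjust_phenotypes <- function(y, X, Zcg, fit) {
  y_star <- y - drop(X %*% fit$beta)
  if (!is.null(Zcg) && !is.na(fit$sigma2_cg)) {
    c_hat <- fit$sigma2_cg * drop(crossprod(Zcg, fit$Py))
    y_star <- y_star - drop(Zcg %*% c_hat)
  }
  y_star
}
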