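orth_basis <- function(X, tol = 1e-8) {
  # orthonormal basis of the column space of the centred predictor matrix
  X <- as.matrix(X)
  if (ncol(X) == 0) return(matrix(0, nrow(X), 0))
  Xc <- scale(X, center = TRUE, scale = FALSE)
  sv <- svd(Xc)
  keep <- sv$d > tol * max(sv$d, .Machine$double.eps)
  sv$u[, keep, drop = FALSE]
}

mat_rank <- function(X, tol = 1e-8) ncol(orth_basis(X, tol))

#' Redundancy-analysis R-squared
#'
#' The fraction of the total variance of the (column-centred) response matrix
#' explained by its least-squares projection onto the predictors plus an
#' intercept: `R2 = SS(fitted) / SS(Y)` with `SS` the sum of squared elements
#' of the centred matrices. The number of predictors `m` is the numerical
#' rank of the centred predictor matrix, not its column count, so redundant
#' codings do not inflate the adjustment.
#'
#' @param Y Response matrix (e.g., Hellinger-transformed community data);
#'   centred internally.
#' @param X Predictor matrix.
#' @param label Optional label for printing.
#' @return An object of class `rda_fit` with elements `R2`, `R2adj`, `n`, `m`.
#' @export
rda_r2 <- function(Y, X, label = deparse(substitute(X))) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  ss_tot <- sum(Yc^2)
  if (ss_tot <= 0) stop("zero total variance in the response")
  Q <- orth_basis(X)
  m <- ncol(Q)
  if (nrow(Q) != n) stop("row mismatch between response and predictors")
  if (n <= m + 1)
    stop("saturated model (n <= m + 1): adjusted R-squared undefined")
  R2 <- if (m == 0) 0 else sum(crossprod(Q, Yc)^2) / ss_tot
  structure(list(label = label, n = n, m = m, R2 = R2,
                 R2adj = adjusted_r2(R2, n, m)),
            class = "rda_fit")
}

#' @export
print.rda_fit <- function(x, ...) {
  cat("RDA fit [", x$label, "]: n = ", x$n, ", m = ", x$m,
      ", R2 = ", format(x$R2, digits = 4),
      ", adj R2 = ", format(x$R2adj, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Ezekiel-adjusted R-squared
#'
#' `R2adj = 1 - (1 - R2) (n - 1) / (n - m - 1)`; makes explained fractions
#' comparable across predictor sets of different sizes. Can be negative.
#'
#' @param R2 Unadjusted R-squared.
#' @param n Number of observations.
#' @param m Number of (linearly independent) predictors.
#' @return Adjusted R-squared.
#' @export
adjusted_r2 <- function(R2, n, m) {
  if (n - m - 1 < 1) stop("n - m - 1 must be at least 1")
  1 - (1 - R2) * (n - 1) / (n - m - 1)
}

#' Permutation test of a pure fraction (Freedman-Lane)
#'
#' Tests whether `X` explains the response over and above the conditioning
#' set `Z`. The reduced model (on `Z`) supplies fitted values and residuals;
#' each permutation rebuilds a pseudo-response from the fitted values plus
#' row-permuted residuals and recomputes the pseudo-F
#' `((SS_full - SS_reduced)/m_x) / (SS_res_full/(n - m_x - m_z - 1))`.
#' With `scheme = "raw"` the response rows themselves are permuted.
#'
#' @param Y Response matrix; centred internally.
#' @param X Predictor block under test.
#' @param Z Conditioning block (may have zero columns).
#' @param n_perm Number of permutations (default 999, so the smallest
#'   attainable p-value is 1/1000).
#' @param seed Optional integer seed for reproducible permutations.
#' @param scheme `"freedman_lane"` (default) or `"raw"`.
#' @return List with `pseudoF`, `p`, `m_x`, `m_z`, `n`, `n_perm`.
#' @export
pure_fraction_test <- function(Y, X, Z = NULL, n_perm = 999, seed = NULL,
                               scheme = c("freedman_lane", "raw")) {
  scheme <- match.arg(scheme)
  if (n_perm < 1) stop("n_perm must be at least 1")
  Y <- as.matrix(Y)
  n <- nrow(Y)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  if (is.null(Z)) Z <- matrix(0, n, 0)
  Qz <- orth_basis(Z)
  Qf <- orth_basis(cbind(as.matrix(Z), as.matrix(X)))
  m_z <- ncol(Qz)
  m_f <- ncol(Qf)
  m_x <- m_f - m_z
  df_res <- n - m_f - 1
  if (m_x < 1) stop("test block adds no rank beyond the conditioning block")
  if (df_res < 1) stop("saturated model: no residual degrees of freedom")

  pseudo_f <- function(Ym) {
    ss_z <- if (m_z == 0) 0 else sum(crossprod(Qz, Ym)^2)
    ss_f <- sum(crossprod(Qf, Ym)^2)
    ((ss_f - ss_z) / m_x) / ((sum(Ym^2) - ss_f) / df_res)
  }
  F_obs <- pseudo_f(Yc)

  Fz <- if (m_z == 0) matrix(0, n, ncol(Yc)) else Qz %*% crossprod(Qz, Yc)
  Rz <- Yc - Fz
  if (!is.null(seed)) set.seed(seed)
  F_perm <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    idx <- sample.int(n)
    Ystar <- if (scheme == "freedman_lane") Fz + Rz[idx, , drop = FALSE]
             else Yc[idx, , drop = FALSE]
    F_perm[b] <- pseudo_f(Ystar)
  }
  p <- (1 + sum(F_perm >= F_obs)) / (1 + n_perm)
  list(pseudoF = F_obs, p = p, m_x = m_x, m_z = m_z, n = n, n_perm = n_perm)
}

#' Three-matrix variation partitioning of community composition
#'
#' Partitions the variance of a (typically Hellinger-transformed) community
#' matrix into eight adjusted components with respect to environmental (E),
#' spatial (S) and temporal (T) predictor blocks: the pure fractions `E`,
#' `S`, `T`, the pairwise shared fractions `SE`, `TE`, `ST`, the three-way
#' shared fraction `STE`, and the unexplained remainder `U`. Fractions are
#' obtained by inclusion-exclusion over the Ezekiel-adjusted R-squared of the
#' seven nested RDA models, so shared fractions may be negative; the eight
#' components always sum to 1. The pure fractions are tested by Freedman-Lane
#' permutation ([pure_fraction_test()]) conditioning each block on the other
#' two.
#'
#' @param Y Response matrix (observations x taxa), e.g. from [hellinger()].
#' @param env,space,time Predictor blocks, row-aligned to `Y`
#'   (see [align_observations()]).
#' @param n_perm Permutations for the pure-fraction tests (default 999);
#'   `0` skips the tests (p-values `NA`).
#' @param seed Master seed; the three tests use `seed + 1:3`.
#' @param scheme Permutation scheme, see [pure_fraction_test()].
#' @return An object of class `varpart3`; see [print.varpart3()],
#'   [summary.varpart3()], [coef.varpart3()], [plot.varpart3()].
#' @examples
#' set.seed(1)
#' Y <- matrix(rpois(60, 4), 20, 3)
#' E <- matrix(rnorm(40), 20, 2)
#' S <- matrix(rnorm(40), 20, 2)
#' Tm <- cbind(rep(c(1, 0), each = 10))
#' vp <- varpart3(hellinger(Y), E, S, Tm, n_perm = 99, seed = 1)
#' coef(vp)
#' @export
varpart3 <- function(Y, env, space, time, n_perm = 999, seed = NULL,
                     scheme = c("freedman_lane", "raw")) {
  scheme <- match.arg(scheme)
  Y <- as.matrix(Y)
  blocks <- list(E = as.matrix(env), S = as.matrix(space), T = as.matrix(time))
  for (nm in names(blocks)) {
    if (nrow(blocks[[nm]]) != nrow(Y))
      stop("block ", nm, " is not row-aligned with the response")
    if (ncol(blocks[[nm]]) == 0 || mat_rank(blocks[[nm]]) == 0)
      stop("block ", nm, " has rank 0 after alignment")
  }
  fit <- function(...) rda_r2(Y, do.call(cbind, blocks[c(...)]),
                              label = paste(c(...), collapse = "+"))
  fits <- list(E = fit("E"), S = fit("S"), T = fit("T"),
               ES = fit("E", "S"), ET = fit("E", "T"), ST = fit("S", "T"),
               EST = fit("E", "S", "T"))
  a <- vapply(fits, `[[`, numeric(1), "R2adj")

  g <- a["E"] + a["S"] + a["T"] - a["ES"] - a["ET"] - a["ST"] + a["EST"]
  fractions <- c(
    E   = unname(a["EST"] - a["ST"]),
    S   = unname(a["EST"] - a["ET"]),
    T   = unname(a["EST"] - a["ES"]),
    SE  = unname((a["E"] + a["S"] - a["ES"]) - g),
    TE  = unname((a["E"] + a["T"] - a["ET"]) - g),
    ST  = unname((a["S"] + a["T"] - a["ST"]) - g),
    STE = unname(g),
    U   = unname(1 - a["EST"]))

  p <- c(E = NA_real_, S = NA_real_, T = NA_real_)
  tests <- NULL
  if (n_perm > 0) {
    cond <- list(E = c("S", "T"), S = c("E", "T"), T = c("E", "S"))
    tests <- lapply(seq_along(cond), function(k) {
      nm <- names(cond)[k]
      pure_fraction_test(Y, blocks[[nm]],
                         do.call(cbind, blocks[cond[[k]]]),
                         n_perm = n_perm,
                         seed = if (is.null(seed)) NULL else seed + k,
                         scheme = scheme)
    })
    names(tests) <- names(cond)
    p <- vapply(tests, `[[`, numeric(1), "p")
  }

  structure(list(fractions = fractions, p = p, fits = fits, tests = tests,
                 n = nrow(Y), n_perm = n_perm, seed = seed, scheme = scheme,
                 call = match.call()),
            class = "varpart3")
}

#' @export
coef.varpart3 <- function(object, ...) object$fractions

#' Printed view of a three-way variation partition
#'
#' Mirrors the usual figure convention: adjusted fractions as percentages,
#' values below 0.5% shown as "0" (stored values are never truncated), and
#' significant pure fractions starred.
#'
#' @param x A `varpart3` object.
#' @param alpha Significance threshold for the stars.
#' @param ... Unused.
#' @export
print.varpart3 <- function(x, alpha = 0.05, ...) {
  cat("Three-way variation partition (n = ", x$n, ", ",
      x$n_perm, " permutations)\n", sep = "")
  pct <- 100 * x$fractions
  disp <- ifelse(abs(pct) < 0.5, "0", sprintf("%.1f", pct))
  stars <- rep("", 8)
  stars[1:3] <- ifelse(!is.na(x$p) & x$p <= alpha, " *", "")
  for (k in seq_along(pct))
    cat(sprintf("  %-4s %6s%%%s\n", names(pct)[k], disp[k], stars[k]))
  if (any(!is.na(x$p)))
    cat("pure-fraction p-values: ",
        paste(names(x$p), format(x$p, digits = 3), sep = " = ", collapse = ", "),
        "\n", sep = "")
  invisible(x)
}

#' @export
summary.varpart3 <- function(object, ...) {
  comp <- data.frame(
    component = names(object$fractions),
    adj_fraction = unname(object$fractions),
    percent = unname(100 * object$fractions),
    p_value = c(unname(object$p), rep(NA_real_, 5)),
    stringsAsFactors = FALSE)
  fits <- data.frame(
    model = names(object$fits),
    m = vapply(object$fits, `[[`, numeric(1), "m"),
    R2 = vapply(object$fits, `[[`, numeric(1), "R2"),
    R2adj = vapply(object$fits, `[[`, numeric(1), "R2adj"),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(components = comp, fits = fits, n = object$n,
                 n_perm = object$n_perm, seed = object$seed),
            class = "summary.varpart3")
}

#' @export
print.summary.varpart3 <- function(x, ...) {
  cat("Variation partition, n =", x$n, "\n\nComponents:\n")
  print(x$components, digits = 4, row.names = FALSE)
  cat("\nModel fits:\n")
  print(x$fits, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Barplot of the eight partition components
#'
#' @param x A `varpart3` object.
#' @param ... Passed to [graphics::barplot()].
#' @importFrom graphics barplot abline
#' @export
plot.varpart3 <- function(x, ...) {
  barplot(100 * x$fractions, ylab = "adjusted fraction (%)",
          main = "Variation partition", ...)
  abline(h = 0)
  invisible(x)
}
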