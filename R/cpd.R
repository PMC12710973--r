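#' Coherent point drift registration
#'
#' EM registration of a source point cloud onto a target under a
#' Gaussian-mixture correspondence model with a uniform outlier component.
#' Both clouds are translated to a common origin (centroid subtraction)
#' before EM. Rigid mode estimates a similarity transform (rotation R,
#' isotropic scale s, translation t) in closed form each M-step; non-rigid
#' mode estimates a kernel-regularized displacement field
#' \eqn{v(y) = G(y, Y) W} with Gaussian kernel width `beta` and motion
#' coherence penalty \eqn{\frac{\lambda}{2} tr(W' G W)}.
#'
#' @param source moving cloud ([point_cloud()] or n x 3 matrix, mm).
#' @param target fixed cloud.
#' @param mode `"rigid"` or `"nonrigid"`.
#' @param w expected outlier fraction, in [0, 1).
#' @param beta non-rigid Gaussian kernel width, mm.
#' @param lambda non-rigid regularization weight.
#' @param max_iter maximum EM iterations.
#' @param tol relative change in the mixture variance at which to stop.
#' @param allow_scale estimate isotropic scale in rigid mode.
#' @return object of class `cpd_result` with the transform parameters,
#'   `registered` source points (target frame), per-iteration objective
#'   trace (`objective`, penalized negative log-likelihood), `final_sigma2`,
#'   `iterations_run` and `converged`.
#' @export
register_cpd <- function(source, target, mode = c("rigid", "nonrigid"),
                         w = 0.1, beta = 2, lambda = 3,
                         max_iter = 100L, tol = 1e-5, allow_scale = TRUE) {
  mode <- match.arg(mode)
  Y <- if (inherits(source, "point_cloud")) source$points else as.matrix(source)
  X <- if (inherits(target, "point_cloud")) target$points else as.matrix(target)
  stopifnot(ncol(Y) == 3, ncol(X) == 3, w >= 0, w < 1)
  M <- nrow(Y); N <- nrow(X); D <- 3
  if (mode == "rigid" && M < 4)
    stop("rigid registration needs at least 4 source points")
  if (mode == "nonrigid" && M < 10)
    stop("nonrigid registration needs at least 10 source points")
  mu_y <- colMeans(Y); mu_x <- colMeans(X)
  Yc <- sweep(Y, 2, mu_y); Xc <- sweep(X, 2, mu_x)
  if (mode == "rigid") {
    sv <- svd(crossprod(Yc))$d
    if (sv[2] / max(sv[1], 1e-300) < 1e-9)
      stop("degenerate source cloud (collinear points): rotation unidentifiable")
  }
  sigma2 <- sum(outer(rowSums(Xc^2), rowSums(Yc^2), "+") -
                  2 * Xc %*% t(Yc)) / (D * N * M)
  s <- 1; R <- diag(3); t_c <- c(0, 0, 0)
  G <- NULL; W <- NULL
  if (mode == "nonrigid") {
    d2 <- outer(rowSums(Yc^2), rowSums(Yc^2), "+") - 2 * Yc %*% t(Yc)
    G <- exp(-pmax(d2, 0) / (2 * beta^2))
    W <- matrix(0, M, D)
  }
  TY <- Yc
  obj <- numeric(0)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    # E-step: posterior correspondences
    d2 <- outer(rowSums(TY^2), rowSums(Xc^2), "+") - 2 * TY %*% t(Xc)  # M x N
    num <- exp(-pmax(d2, 0) / (2 * sigma2))
    c_out <- (2 * pi * sigma2)^(D / 2) * w / (1 - w) * M / N
    den <- colSums(num) + c_out
    den[den < 1e-300] <- 1e-300
    P <- sweep(num, 2, den, "/")
    # penalized negative log-likelihood (monitored objective)
    nll <- -sum(log(den / M * (1 - w) / (2 * pi * sigma2)^(D / 2) +
                      .Machine$double.xmin))
    if (mode == "nonrigid")
      nll <- nll + lambda / 2 * sum(W * (G %*% W))
    obj <- c(obj, nll)
    P1 <- rowSums(P)     # length M
    Pt1 <- colSums(P)    # length N
    Np <- sum(P1)
    PX <- P %*% Xc
    if (mode == "rigid") {
      mx <- colSums(PX) / Np
      my <- colSums(P1 * Yc) / Np
      # closed-form similarity solution from the correspondence moments
      A <- t(PX) %*% Yc - Np * outer(mx, my)
      sv <- svd(A)
      Cdiag <- c(1, 1, det(sv$u %*% t(sv$v)))
      R <- sv$u %*% diag(Cdiag) %*% t(sv$v)
      denom <- sum(P1 * rowSums(Yc^2)) - Np * sum(my^2)
      s <- if (allow_scale) sum(diag(diag(Cdiag) %*% diag(sv$d))) / denom else 1
      t_c <- mx - s * as.vector(R %*% my)
      TY <- s * Yc %*% t(R) + matrix(t_c, M, 3, byrow = TRUE)
      trXPX <- sum(Pt1 * rowSums(Xc^2)) - Np * sum(mx^2)
      sigma2_new <- (trXPX - s * sum(diag(diag(Cdiag) %*% diag(sv$d)))) /
        (Np * D)
    } else {
      dP1 <- P1
      LHS <- G * 0
      LHS <- sweep(G, 1, dP1, "*") + lambda * sigma2 * diag(M)
      RHS <- PX - dP1 * Yc
      W <- solve(LHS, RHS)
      TY <- Yc + G %*% W
      sigma2_new <- (sum(Pt1 * rowSums(Xc^2)) - 2 * sum(PX * TY) +
                       sum(P1 * rowSums(TY^2))) / (sum(P1) * D)
    }
    if (!is.finite(sigma2_new) || sigma2_new < 1e-12) {
      sigma2 <- max(sigma2_new, 1e-12)
      converged <- TRUE
      break
    }
    if (abs(sigma2 - sigma2_new) / sigma2 < tol) {
      sigma2 <- sigma2_new
      converged <- TRUE
      break
    }
    sigma2 <- sigma2_new
  }
  registered <- TY + matrix(mu_x, M, 3, byrow = TRUE)
  res <- list(mode = mode, s = s, R = R, t = NULL, mu_x = mu_x, mu_y = mu_y,
              t_centered = t_c, beta = beta, lambda = lambda, W = W,
              source_points = Y, G = G,
              registered = registered, objective = obj,
              final_sigma2 = sigma2, iterations_run = iter,
              converged = converged)
  if (mode == "rigid")
    res$t <- mu_x + t_c - s * as.vector(R %*% mu_y)
  structure(res, class = "cpd_result")
}

#' @export
print.cpd_result <- function(x, ...) {
  cat(sprintf("CPD %s registration: %d iteration(s), sigma2 = %.3g, %s\n",
              x$mode, x$iterations_run, x$final_sigma2,
              if (x$converged) "converged" else "NOT converged"))
  if (x$mode == "rigid")
    cat(sprintf("  scale %.4f, translation (%.3f, %.3f, %.3f) mm\n",
                x$s, x$t[1], x$t[2], x$t[3]))
  invisible(x)
}

#' Apply a fitted CPD transform to points
#'
#' Maps arbitrary points (for example, sensor coordinates labelled in the MR
#' frame) into the target frame: the rigid similarity is applied exactly;
#' the non-rigid displacement at off-source locations is evaluated through
#' the same Gaussian kernel against the source points.
#'
#' @param result a `cpd_result`.
#' @param points [point_cloud()] or n x 3 matrix (mm, source frame).
#' @return [point_cloud()] in the target frame.
#' @export
transform_points <- function(result, points) {
  stopifnot(inherits(result, "cpd_result"))
  p <- if (inherits(points, "point_cloud")) points$points else as.matrix(points)
  if (result$mode == "rigid") {
    out <- result$s * p %*% t(result$R) +
      matrix(result$t, nrow(p), 3, byrow = TRUE)
  } else {
    Y <- result$source_points
    d2 <- outer(rowSums(p^2), rowSums(Y^2), "+") - 2 * p %*% t(Y)
    K <- exp(-pmax(d2, 0) / (2 * result$beta^2))
    out <- p + K %*% result$W +
      matrix(result$mu_x - result$mu_y, nrow(p), 3, byrow = TRUE)
  }
  point_cloud(out, frame_label = "registered")
}
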