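# AI-REML engines for the animal model, univariate and bivariate.
#
# Both work in the eigenbasis of the relationship matrix K = U D U': after
# rotating y and X by U', the phenotypic covariance is diagonal (univariate)
# or block-diagonal in 2x2 per-individual blocks (bivariate), which makes
# every REML quantity an O(n p^2) expression. Updates are average-information
# steps with an EM fallback (univariate) or step-halving plus projection to
# the positive-semidefinite cone (bivariate) when an AI update leaves the
# parameter space.

# ---- univariate ------------------------------------------------------------

# Inner quantities at a parameter point th = c(sigma_g2, sigma_e2).
.uni_inner <- function(th, d, yt, Xt) {
  v <- th[1] * d + th[2]
  if (any(v <= 0)) return(NULL)
  w <- 1 / v
  XtWX <- crossprod(Xt, Xt * w)
  ch <- tryCatch(chol(XtWX), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  beta <- backsolve(ch, forwardsolve(t(ch), crossprod(Xt, w * yt)))
  r <- yt - Xt %*% beta
  Py <- w * r
  ll <- -0.5 * (sum(log(v)) + 2 * sum(log(diag(ch))) + sum(r * Py))
  list(ll = as.numeric(ll), w = w, XtWX = XtWX, chol = ch, beta = beta, Py = Py)
}

.P_apply_uni <- function(q, o, Xt) {
  o$w * q - o$w * (Xt %*% solve(o$XtWX, crossprod(Xt, o$w * q)))
}

# AI-REML for y = Xb + u + e, u ~ N(0, K sg2), e ~ N(0, I se2).
# Returns variance components, SEs (inverse AI), h2 with delta-method SE,
# log REML likelihood, and the rotation (U, d) for reuse.
.reml_uni <- function(y, X, K, tol = 1e-8, max_iter = 100L) {
  n <- length(y)
  if (qr(X)$rank < ncol(X)) stop("fixed-effect design matrix is singular")
  if (n < ncol(X) + 2) stop("too few records for REML")
  ee <- eigen(K, symmetric = TRUE)
  d <- pmax(ee$values, 0)
  U <- ee$vectors
  yt <- drop(crossprod(U, y))
  Xt <- crossprod(U, X)
  vP <- stats::var(y)
  fl <- 1e-8 * vP
  th <- c(vP / 2, vP / 2)
  o <- .uni_inner(th, d, yt, Xt)
  conv <- FALSE
  it <- 0L
  AI <- diag(2)
  a_list <- list(d, rep(1, n))
  repeat {
    it <- it + 1L
    trPA <- score <- numeric(2)
    q <- vector("list", 2)
    for (k in 1:2) {
      a <- a_list[[k]]
      trVA <- sum(o$w * a)
      Mk <- crossprod(Xt, Xt * (o$w^2 * a))
      trPA[k] <- trVA - sum(diag(solve(o$XtWX, Mk)))
      yAy <- sum(a * o$Py^2)
      score[k] <- -0.5 * (trPA[k] - yAy)
      q[[k]] <- a * o$Py
    }
    Pq <- lapply(q, .P_apply_uni, o = o, Xt = Xt)
    for (j in 1:2) for (k in 1:2) AI[j, k] <- 0.5 * sum(q[[j]] * Pq[[k]])
    step <- tryCatch(solve(AI, score), error = function(e) score / (diag(AI) + fl))
    # AI step, projected onto the parameter space (components floored)
    newth <- pmax(th + step, fl)
    o_new <- .uni_inner(newth, d, yt, Xt)
    h <- 0L
    while ((is.null(o_new) || o_new$ll < o$ll - 1e-10) && h < 20L) {
      step <- step / 2
      newth <- pmax(th + step, fl)
      o_new <- .uni_inner(newth, d, yt, Xt)
      h <- h + 1L
    }
    if (is.null(o_new) || o_new$ll < o$ll - 1e-10) {
      # EM-REML fallback: guaranteed uphill, always inside the space
      em <- vapply(1:2, function(k) sum(a_list[[k]] * o$Py^2) - trPA[k], 0)
      newth <- pmax(th + th^2 * em / n, fl)
      o_new <- .uni_inner(newth, d, yt, Xt)
    }
    if (is.null(o_new)) break
    rel <- max(abs(newth - th) / (abs(th) + 1e-6 * vP))
    dll <- o_new$ll - o$ll
    th <- newth
    o <- o_new
    if (rel < tol || abs(dll) < 1e-10) { conv <- TRUE; break }
    if (it >= max_iter) break
  }
  Cai <- tryCatch(solve(AI), error = function(e) matrix(NA_real_, 2, 2))
  at_bound <- th <= 2 * fl
  se <- sqrt(pmax(diag(Cai), 0))
  se[at_bound] <- NA_real_
  h2 <- th[1] / sum(th)
  gr <- c(th[2], -th[1]) / sum(th)^2
  h2_se <- if (any(at_bound)) NA_real_ else sqrt(max(drop(t(gr) %*% Cai %*% gr), 0))
  beta <- stats::setNames(drop(o$beta), colnames(Xt))
  bv <- solve(o$XtWX)
  dimnames(bv) <- list(colnames(Xt), colnames(Xt))
  list(sigma_g2 = th[1], sigma_e2 = th[2], se = se, h2 = h2, h2_se = h2_se,
       logLik = o$ll, iterations = it, converged = conv,
       beta = beta, beta_vcov = bv,
       U = U, d = d, ai_inv = Cai)
}

# ---- bivariate -------------------------------------------------------------

# th = c(g11, g12, g22, r11, r12, r22) for 2x2 genetic (G0) and residual
# (R0) covariance matrices; V_i = d_i G0 + R0 per rotated individual.
.biv_inner <- function(th, d, Yt, Xt) {
  v11 <- th[1] * d + th[4]; v12 <- th[2] * d + th[5]; v22 <- th[3] * d + th[6]
  det <- v11 * v22 - v12^2
  if (any(det <= 0) || any(v11 <= 0) || any(v22 <= 0)) return(NULL)
  i11 <- v22 / det; i12 <- -v12 / det; i22 <- v11 / det
  p <- ncol(Xt)
  B11 <- crossprod(Xt, Xt * i11); B12 <- crossprod(Xt, Xt * i12)
  B22 <- crossprod(Xt, Xt * i22)
  XtWX <- rbind(cbind(B11, B12), cbind(B12, B22))
  ch <- tryCatch(chol(XtWX), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  y1 <- Yt[, 1]; y2 <- Yt[, 2]
  XtWy <- c(crossprod(Xt, i11 * y1 + i12 * y2), crossprod(Xt, i12 * y1 + i22 * y2))
  beta <- backsolve(ch, forwardsolve(t(ch), XtWy))
  r1 <- y1 - drop(Xt %*% beta[1:p]); r2 <- y2 - drop(Xt %*% beta[p + (1:p)])
  P1 <- i11 * r1 + i12 * r2; P2 <- i12 * r1 + i22 * r2
  ll <- -0.5 * (sum(log(det)) + 2 * sum(log(diag(ch))) + sum(r1 * P1 + r2 * P2))
  list(ll = as.numeric(ll), i11 = i11, i12 = i12, i22 = i22,
       XtWX = XtWX, beta = beta, P1 = P1, P2 = P2)
}

# clip a symmetric 2x2 to eigenvalues >= fl
.psd2 <- function(M, fl) {
  ee <- eigen(M, symmetric = TRUE)
  val <- pmax(ee$values, fl)
  ee$vectors %*% diag(val) %*% t(ee$vectors)
}

.reml_biv <- function(Y, X, K, tol = 1e-8, max_iter = 200L) {
  n <- nrow(Y)
  if (qr(X)$rank < ncol(X)) stop("fixed-effect design matrix is singular")
  ee <- eigen(K, symmetric = TRUE)
  d <- pmax(ee$values, 0)
  U <- ee$vectors
  Yt <- crossprod(U, Y)
  Xt <- crossprod(U, X)
  p <- ncol(Xt)
  S <- stats::cov(Y)
  vP <- diag(S)
  fl <- 1e-8 * min(vP)
  pack <- function(G0, R0) c(G0[1, 1], G0[1, 2], G0[2, 2], R0[1, 1], R0[1, 2], R0[2, 2])
  unpack <- function(th) list(G0 = matrix(th[c(1, 2, 2, 3)], 2),
                              R0 = matrix(th[c(4, 5, 5, 6)], 2))
  project <- function(th) {
    m <- unpack(th)
    pack(.psd2(m$G0, fl), .psd2(m$R0, max(fl, 1e-6 * min(vP))))
  }
  th <- project(pack(S / 2, S / 2))
  o <- .biv_inner(th, d, Yt, Xt)
  if (is.null(o)) {      # e.g. collinear traits: fall back to diagonal start
    th <- pack(diag(diag(S) / 2), diag(diag(S) / 2))
    o <- .biv_inner(th, d, Yt, Xt)
  }
  if (is.null(o)) stop("could not evaluate the bivariate REML start values")
  zero <- rep(0, n)
  # weight triples (a11, a12, a22) of dV/dtheta_k per individual block
  bases <- list(list(d, zero, zero), list(zero, d, zero), list(zero, zero, d),
                list(zero + 1, zero, zero), list(zero, zero + 1, zero),
                list(zero, zero, zero + 1))
  AI <- diag(6)
  conv <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    score <- numeric(6)
    qlist <- vector("list", 6)
    for (k in 1:6) {
      a <- bases[[k]]
      a11 <- a[[1]]; a12 <- a[[2]]; a22 <- a[[3]]
      trVA <- sum(o$i11 * a11 + 2 * o$i12 * a12 + o$i22 * a22)
      # M = Vinv A Vinv, per 2x2 block
      b11 <- a11 * o$i11 + a12 * o$i12; b12 <- a11 * o$i12 + a12 * o$i22
      b21 <- a12 * o$i11 + a22 * o$i12; b22 <- a12 * o$i12 + a22 * o$i22
      m11 <- o$i11 * b11 + o$i12 * b21; m12 <- o$i11 * b12 + o$i12 * b22
      m22 <- o$i12 * b12 + o$i22 * b22
      XtMX <- rbind(cbind(crossprod(Xt, Xt * m11), crossprod(Xt, Xt * m12)),
                    cbind(crossprod(Xt, Xt * m12), crossprod(Xt, Xt * m22)))
      trPA <- trVA - sum(diag(solve(o$XtWX, XtMX)))
      yPAPy <- sum(a11 * o$P1^2 + 2 * a12 * o$P1 * o$P2 + a22 * o$P2^2)
      score[k] <- -0.5 * (trPA - yPAPy)
      qlist[[k]] <- cbind(a11 * o$P1 + a12 * o$P2, a12 * o$P1 + a22 * o$P2)
    }
    Pq <- lapply(qlist, function(q) {
      Vq1 <- o$i11 * q[, 1] + o$i12 * q[, 2]
      Vq2 <- o$i12 * q[, 1] + o$i22 * q[, 2]
      al <- solve(o$XtWX, c(crossprod(Xt, Vq1), crossprod(Xt, Vq2)))
      Xa1 <- drop(Xt %*% al[1:p]); Xa2 <- drop(Xt %*% al[p + (1:p)])
      cbind(Vq1 - (o$i11 * Xa1 + o$i12 * Xa2), Vq2 - (o$i12 * Xa1 + o$i22 * Xa2))
    })
    for (j in 1:6) for (k in 1:6)
      AI[j, k] <- 0.5 * sum(qlist[[j]] * Pq[[k]])
    step <- tryCatch(solve(AI, score), error = function(e) score / (abs(diag(AI)) + 1))
    newth <- project(th + step)
    o_new <- .biv_inner(newth, d, Yt, Xt)
    h <- 0L
    while ((is.null(o_new) || o_new$ll < o$ll - 1e-10) && h < 25L) {
      step <- step / 2
      newth <- project(th + step)
      o_new <- .biv_inner(newth, d, Yt, Xt)
      h <- h + 1L
    }
    if (is.null(o_new)) break
    rel <- max(abs(newth - th) / (abs(th) + 1e-6 * min(vP)))
    dll <- o_new$ll - o$ll
    th <- newth
    o <- o_new
    if (rel < tol || abs(dll) < 1e-10) { conv <- TRUE; break }
    if (it >= max_iter) break
  }
  m <- unpack(th)
  Cai <- tryCatch(solve(AI), error = function(e) matrix(NA_real_, 6, 6))
  g11 <- th[1]; g12 <- th[2]; g22 <- th[3]
  rg <- g12 / sqrt(g11 * g22)
  gr_rg <- c(-rg / (2 * g11), 1 / sqrt(g11 * g22), -rg / (2 * g22), 0, 0, 0)
  rg_se <- sqrt(max(drop(t(gr_rg) %*% Cai %*% gr_rg), 0))
  h2 <- c(g11 / (g11 + th[4]), g22 / (g22 + th[6]))
  h2_se <- vapply(1:2, function(t) {
    ig <- if (t == 1) 1L else 3L; ir <- if (t == 1) 4L else 6L
    g <- th[ig]; r <- th[ir]
    gr <- numeric(6); gr[ig] <- r / (g + r)^2; gr[ir] <- -g / (g + r)^2
    sqrt(max(drop(t(gr) %*% Cai %*% gr), 0))
  }, 0)
  list(G0 = m$G0, R0 = m$R0, rg = rg, rg_se = rg_se, h2 = h2, h2_se = h2_se,
       se = sqrt(pmax(diag(Cai), 0)),
       logLik = o$ll, iterations = it, converged = conv,
       beta = drop(o$beta), U = U, d = d, ai_inv = Cai)
}
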