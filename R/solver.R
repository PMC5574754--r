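# Constrained nonlinear least-squares engine for the joint model.
#
# The objective is Q(Pi, c) = sum_j || clr(yhat_j) - clr(y_j) ||^2 with
#   yhat_j = Pi[j, ] %*% Xt(c),   Xt(c)[i, ] = (c * X[i, ]) / sum(c * X[i, ]),
# subject to: each diet row on the simplex (Pi >= 0, rowSums = 1) and the
# calibration coefficients bounded below (c >= lb) with a fixed sum
# (sum(c) = cc_sum, the identifiability constraint).
#
# Strategy: Levenberg--Marquardt on the residual vector with the linear
# equality constraints eliminated through orthonormal null-space bases, and
# the inequality constraints handled by an active set (variables at a bound
# are frozen; Lagrange multipliers decide when to release them).  The
# Jacobian is block-structured -- each predator's residuals depend only on
# its own diet row and on the shared coefficients -- so the normal equations
# are solved through a Schur complement on the coefficient block, which
# keeps every factorization small.  Near a zero-residual solution the
# damping vanishes and the iteration is pure Gauss--Newton, giving the
# quadratic tail convergence needed to drive Q to the numerical floor.

# Orthonormal basis of {z in R^f : sum(z) = 0}.
sumzero_basis <- function(f) {
  if (f <= 1L) return(matrix(0, nrow = f, ncol = 0L))
  qr.Q(qr(matrix(1, f, 1L)), complete = TRUE)[, -1L, drop = FALSE]
}

# Model evaluation: transformed means, fitted signatures, clr residuals, Q.
qj_eval <- function(Pi, cc, X, clrY) {
  s <- as.vector(X %*% cc)
  U <- X / s
  Xt <- sweep(U, 2L, cc, "*")
  Yhat <- Pi %*% Xt
  if (any(Yhat <= 0) || anyNA(Yhat)) {
    return(list(s = s, U = U, Xt = Xt, Yhat = Yhat, R = NULL, Q = Inf))
  }
  R <- clr_rows(Yhat) - clrY
  list(s = s, U = U, Xt = Xt, Yhat = Yhat, R = R, Q = sum(R * R))
}

qj_solve <- function(Y, X, diet0 = NULL, cc0 = NULL, fix_cc = FALSE,
                     lb_cc = 0.02, cc_sum = ncol(Y),
                     tol_grad = 1e-12, maxit = 5000L, q_floor = NULL,
                     lambda0 = 1e-4) {
  J <- nrow(Y); K <- ncol(Y); I <- nrow(X)
  if (is.null(q_floor)) {
    ## Each residual carries rounding noise of order eps on the log scale,
    ## so Q cannot be driven reliably below ~ J*K*(100*eps)^2.
    q_floor <- J * K * (100 * .Machine$double.eps)^2
  }
  clrY <- clr_rows(Y)
  Pi <- if (is.null(diet0)) matrix(1 / I, J, I) else as.matrix(diet0)
  cc <- if (is.null(cc0)) rep(1, K) * (cc_sum / K) else as.numeric(cc0)
  activeP <- Pi <= 0
  Pi[activeP] <- 0
  activeC <- if (fix_cc) rep(TRUE, K) else cc <= lb_cc
  zb_cache <- new.env(parent = emptyenv())
  zb <- function(f) {
    key <- as.character(f)
    if (is.null(zb_cache[[key]])) zb_cache[[key]] <- sumzero_basis(f)
    zb_cache[[key]]
  }

  ev <- qj_eval(Pi, cc, X, clrY)
  lambda <- lambda0
  lambda_min <- 1e-14; lambda_max <- 1e12
  iter <- 0L
  converged <- FALSE
  msg <- "maximum iterations reached"
  pgnorm <- Inf

  repeat {
    if (iter >= maxit) break
    iter <- iter + 1L

    Fc <- which(!activeC)
    kc <- length(Fc)
    Zc <- zb(kc)
    ncc <- ncol(Zc)
    tXt <- t(ev$Xt)

    ## Per-predator Jacobian blocks (reduced coordinates) and gradients.
    gP <- matrix(0, J, I)
    gC <- numeric(K)
    D0 <- vector("list", J); B0 <- vector("list", J)
    a0 <- vector("list", J); At <- vector("list", J); Gt <- vector("list", J)
    Csum <- matrix(0, ncc, ncc)
    bsum <- numeric(ncc)
    Fj_list <- vector("list", J)
    for (j in seq_len(J)) {
      invY <- 1 / ev$Yhat[j, ]
      A0 <- tXt * invY
      A <- sweep(A0, 2L, colMeans(A0))
      rj <- ev$R[j, ]
      gP[j, ] <- 2 * crossprod(A, rj)
      Fj <- which(!activeP[j, ])
      Fj_list[[j]] <- Fj
      Zj <- zb(length(Fj))
      Atj <- A[, Fj, drop = FALSE] %*% Zj
      At[[j]] <- Atj
      a0[[j]] <- crossprod(Atj, rj)
      D0[[j]] <- crossprod(Atj)
      if (!fix_cc) {
        pw <- Pi[j, ] * ev$U
        w <- colSums(pw)
        H <- -tXt %*% pw
        diag(H) <- diag(H) + w
        G0 <- H * invY
        G <- sweep(G0, 2L, colMeans(G0))
        gC <- gC + 2 * as.vector(crossprod(G, rj))
        Gtj <- G[, Fc, drop = FALSE] %*% Zc
        Gt[[j]] <- Gtj
        B0[[j]] <- crossprod(Atj, Gtj)
        Csum <- Csum + crossprod(Gtj)
        bsum <- bsum + as.vector(crossprod(Gtj, rj))
      }
    }

    ## Projected (reduced) gradient, for convergence and multipliers.
    pgnorm <- 0
    for (j in seq_len(J)) {
      gf <- gP[j, Fj_list[[j]]]
      if (length(gf) > 1L) pgnorm <- max(pgnorm, abs(gf - mean(gf)))
    }
    if (!fix_cc && kc > 1L) {
      gf <- gC[Fc]
      pgnorm <- max(pgnorm, abs(gf - mean(gf)))
    }
    if (ev$Q <= q_floor || pgnorm <= tol_grad) {
      rel <- qj_release(gP, gC, Pi, cc, activeP, activeC, Fj_list, Fc,
                        fix_cc, tol_grad)
      if (length(rel$P) || length(rel$C)) {
        activeP[rel$P] <- FALSE
        activeC[rel$C] <- FALSE
        next
      }
      converged <- TRUE
      msg <- if (ev$Q <= q_floor) "objective at numerical floor"
             else "first-order optimality satisfied"
      break
    }

    ## Damped step with retry on rejection.
    accepted <- FALSE
    while (!accepted && lambda <= lambda_max) {
      uc <- numeric(ncc)
      if (!fix_cc && ncc > 0L) {
        S <- Csum + diag(lambda, ncc)
        rhs <- -bsum
        sol_a <- vector("list", J)
        sol_B <- vector("list", J)
        for (j in seq_len(J)) {
          nu <- ncol(At[[j]])
          if (nu == 0L) next
          M <- solve(D0[[j]] + diag(lambda, nu), cbind(a0[[j]], B0[[j]]))
          sol_a[[j]] <- M[, 1L]
          sol_B[[j]] <- M[, -1L, drop = FALSE]
          S <- S - crossprod(B0[[j]], sol_B[[j]])
          rhs <- rhs + as.vector(crossprod(B0[[j]], sol_a[[j]]))
        }
        uc <- tryCatch(solve(S, rhs), error = function(e) rep(NA_real_, ncc))
        if (anyNA(uc)) { lambda <- lambda * 10; next }
      }
      dPi <- matrix(0, J, I)
      for (j in seq_len(J)) {
        nu <- ncol(At[[j]])
        if (nu == 0L) next
        uj <- if (!fix_cc && ncc > 0L) {
          -(sol_a[[j]] + sol_B[[j]] %*% uc)
        } else {
          -solve(D0[[j]] + diag(lambda, nu), a0[[j]])
        }
        Fj <- Fj_list[[j]]
        dPi[j, Fj] <- zb(length(Fj)) %*% uj
      }
      dcc <- numeric(K)
      if (!fix_cc && ncc > 0L) dcc[Fc] <- Zc %*% uc

      ## Candidate (a): full projected step -- clamp every bound violation
      ## at once (identifies many active constraints per iteration).
      ## Candidate (b): ratio-test step to the first blocking bound.
      make_trial <- function(alpha) {
        Pi2 <- Pi + alpha * dPi
        Pi2[activeP | Pi2 < 0] <- 0
        rs <- rowSums(Pi2)
        dead <- rs <= 0
        if (any(dead)) {          # a fully clamped row: keep its current diet
          Pi2[dead, ] <- Pi[dead, , drop = FALSE]
          rs[dead] <- 1
        }
        Pi2 <- Pi2 / rs
        cc2 <- cc
        if (!fix_cc) {
          cc2 <- cc + alpha * dcc
          cc2[activeC | cc2 < lb_cc] <- lb_cc
          free2 <- cc2 > lb_cc
          if (any(free2)) {
            cc2[free2] <- cc2[free2] + (cc_sum - sum(cc2)) / sum(free2)
          }
        }
        list(Pi = Pi2, cc = cc2)
      }
      tinyd <- 1e-300
      ratio_P <- ifelse(dPi < -tinyd & !activeP, Pi / pmax(-dPi, tinyd), Inf)
      ratio_C <- if (fix_cc) Inf else
        ifelse(dcc < -tinyd & !activeC, (cc - lb_cc) / pmax(-dcc, tinyd), Inf)
      alpha_max <- min(1, ratio_P, ratio_C)
      alphas <- if (alpha_max < 1) c(1, alpha_max) else 1
      for (alpha in alphas) {
        tr <- make_trial(alpha)
        ev2 <- qj_eval(tr$Pi, tr$cc, X, clrY)
        if (is.finite(ev2$Q) && ev2$Q < ev$Q) {
          accepted <- TRUE
          Pi <- tr$Pi; cc <- tr$cc; ev <- ev2
          break
        }
      }
      if (accepted) {
        activeP <- activeP | Pi == 0
        if (!fix_cc) activeC <- activeC | cc <= lb_cc
        lambda <- max(lambda / 3, lambda_min)
      } else {
        lambda <- lambda * 10
      }
    }

    if (!accepted) {
      ## No descent possible on this face at any damping: either optimal on
      ## the face (release or stop) or genuinely stalled.
      rel <- qj_release(gP, gC, Pi, cc, activeP, activeC, Fj_list, Fc,
                        fix_cc, tol_grad)
      if (length(rel$P) || length(rel$C)) {
        activeP[rel$P] <- FALSE
        activeC[rel$C] <- FALSE
        lambda <- lambda0
        next
      }
      converged <- ev$Q <= q_floor || pgnorm <= tol_grad * 100
      msg <- if (converged) "no further progress at numerical floor"
             else "stalled: no descent step found"
      break
    }
  }

  list(diet = Pi, cc = cc, objective = ev$Q, residuals = ev$R,
       converged = converged, iterations = iter, message = msg,
       grad_norm = pgnorm, active_cc = which(activeC & !fix_cc))
}

# Lagrange-multiplier screen: for a variable held at a bound, the KKT
# multiplier is its gradient component minus the multiplier of the sum
# constraint (estimated from the free components).  A clearly negative
# multiplier means the bound is holding the objective up; release it.
qj_release <- function(gP, gC, Pi, cc, activeP, activeC, Fj_list, Fc,
                       fix_cc, tol_grad) {
  gmax <- max(abs(gP), if (fix_cc) 0 else abs(gC))
  tol_mult <- max(tol_grad, 1e-8 * gmax)
  relP <- integer(0)
  J <- nrow(Pi)
  for (j in seq_len(J)) {
    act <- which(activeP[j, ])
    if (!length(act)) next
    nu_j <- mean(gP[j, Fj_list[[j]]])
    mu <- gP[j, act] - nu_j
    bad <- act[mu < -tol_mult]
    if (length(bad)) relP <- c(relP, (bad - 1L) * J + j)
  }
  relC <- integer(0)
  if (!fix_cc) {
    act <- which(activeC)
    if (length(act) && length(Fc)) {
      nu_c <- mean(gC[Fc])
      mu <- gC[act] - nu_c
      relC <- act[mu < -tol_mult]
    }
  }
  list(P = relP, C = relC)
}
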