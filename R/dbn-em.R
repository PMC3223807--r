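# Latent-chain machinery: scaled forward-backward, Viterbi, Baum-Welch EM.
# The chain lives on the transition pairs; each maximal run of consecutive
# years is a segment and the chain restarts from `initial` at segment starts.

# parent-config index and observed state per hidden child
.childConfigs <- function(model, tdata) {
  lapply(setNames(model@hiddenChildren, model@hiddenChildren), function(v) {
    pa <- model@interParents[[v]]
    list(j = configIndex(tdata@prev[, pa, drop = FALSE],
                         unname(model@arities[pa])),
         y = tdata@cur[, v])
  })
}

# emission matrix E[i, h] = prod over hidden children of
# P(child_cur[i] | lagged parent config, H = h)
.emissionMatrix <- function(model, tdata, configs = .childConfigs(model, tdata)) {
  nH <- model@nHidden
  E <- matrix(1, nRecords(tdata), nH)
  for (v in model@hiddenChildren) {
    cf <- configs[[v]]
    tc <- model@hiddenCPTs[[v]]
    for (h in seq_len(nH)) E[, h] <- E[, h] * tc[cbind(cf$j, h, cf$y)]
  }
  E
}

# log-likelihood contribution of the H-free observables (constant during EM)
.obsLogLik <- function(model, tdata) {
  ll <- 0
  for (v in setdiff(model@obsNodes, model@hiddenChildren)) {
    pa <- model@interParents[[v]]
    j <- configIndex(tdata@prev[, pa, drop = FALSE], unname(model@arities[pa]))
    ll <- ll + sum(log(model@obsCPTs[[v]][cbind(j, tdata@cur[, v])]))
  }
  ll
}

# scaled forward-backward; returns filtered/predicted/smoothed posteriors,
# pairwise expected transitions and the chain log-likelihood
.forwardBackward <- function(initial, transition, E, newSegment) {
  P <- nrow(E)
  nH <- ncol(E)
  alpha <- matrix(0, P, nH)   # filtered P(H_i | obs 1..i)
  pred <- matrix(0, P, nH)    # predictive P(H_i | obs 1..i-1)
  scale <- numeric(P)
  for (i in seq_len(P)) {
    p <- if (newSegment[i]) initial else as.vector(crossprod(transition, alpha[i - 1L, ]))
    pred[i, ] <- p
    a <- p * E[i, ]
    scale[i] <- sum(a)
    if (scale[i] <= 0) {  # impossible observation under current tables
      return(list(ll = -Inf))
    }
    alpha[i, ] <- a / scale[i]
  }
  beta <- matrix(0, P, nH)
  for (i in rev(seq_len(P))) {
    if (i == P || newSegment[i + 1L]) {
      beta[i, ] <- 1
    } else {
      b <- transition %*% (E[i + 1L, ] * beta[i + 1L, ])
      beta[i, ] <- as.vector(b) / scale[i + 1L]
    }
  }
  gamma <- alpha * beta
  gamma <- gamma / rowSums(gamma)
  xi <- matrix(0, nH, nH)     # expected within-segment transition counts
  for (i in seq_len(P - 1L)) {
    if (newSegment[i + 1L]) next
    x <- (alpha[i, ] %o% (E[i + 1L, ] * beta[i + 1L, ])) * transition /
      scale[i + 1L]
    xi <- xi + x
  }
  list(filtered = alpha, predicted = pred, smoothed = gamma, xi = xi,
       ll = sum(log(scale)))
}

.viterbi <- function(initial, transition, E, newSegment) {
  P <- nrow(E)
  nH <- ncol(E)
  lA <- log(transition)
  delta <- matrix(-Inf, P, nH)
  back <- matrix(0L, P, nH)
  lE <- log(E)
  for (i in seq_len(P)) {
    if (newSegment[i]) {
      delta[i, ] <- log(initial) + lE[i, ]
    } else {
      for (h in seq_len(nH)) {
        v <- delta[i - 1L, ] + lA[, h]
        back[i, h] <- which.max(v)
        delta[i, h] <- v[back[i, h]] + lE[i, h]
      }
    }
  }
  path <- integer(P)
  for (i in rev(seq_len(P))) {
    if (i == P || newSegment[i + 1L]) {
      path[i] <- which.max(delta[i, ])
    } else {
      path[i] <- back[i + 1L, path[i + 1L]]
    }
  }
  path
}

# Laplace-smoothed M-step for the latent-chain parameters
.mStep <- function(model, tdata, fb,
                   configs = .childConfigs(model, tdata)) {
  nH <- model@nHidden
  starts <- which(tdata@newSegment)
  init <- colSums(fb$smoothed[starts, , drop = FALSE]) + 1
  transition <- fb$xi + 1
  for (v in model@hiddenChildren) {
    cf <- configs[[v]]
    r <- model@arities[[v]]
    q <- dim(model@hiddenCPTs[[v]])[1]
    cnt <- array(0, dim = c(q, nH, r))
    for (i in seq_len(nRecords(tdata))) {
      cnt[cf$j[i], , cf$y[i]] <- cnt[cf$j[i], , cf$y[i]] + fb$smoothed[i, ]
    }
    cnt <- cnt + 1
    norm <- apply(cnt, c(1, 2), sum)
    for (k in seq_len(r)) cnt[, , k] <- cnt[, , k] / norm
    model@hiddenCPTs[[v]] <- cnt
  }
  model@initial <- init / sum(init)
  model@transition <- transition / rowSums(transition)
  model
}

#' Fit a latent-regime DBN by EM
#'
#' Parameters of the hidden-state chain (initial distribution, transition
#' matrix and the target's emission table) are estimated by Baum-Welch EM:
#' forward-backward over the latent chain, then a Laplace-smoothed
#' (add-one expected count) M-step, so transferred parameters stay finite on
#' configurations unseen in the donor region.  The H-free observable tables
#' are closed-form Laplace counts fit once up front.  Multiple restarts are
#' run from random initialisations; the restart with the highest final
#' log-likelihood wins.
#'
#' @param skeleton a [DBNModel-class] (e.g. from [dbnSkeleton()]).
#' @param tdata a [TransitionDataset-class] covering the model's observables.
#' @param init `"random"` (independent Dirichlet-like draws with a sticky
#'   diagonal-dominant transition start, since the latent node models a
#'   persistent regime) or `"perturbed"` (empirical target conditionals
#'   plus noise).
#' @param tol relative log-likelihood convergence tolerance.
#' @param maxIter iteration cap per restart; exceeding it flags
#'   `converged = FALSE` but still returns the fit.
#' @param nRestarts number of EM restarts (default 10).
#' @param seed base seed; restart k uses `seed + k - 1`.
#' @param initStates optional integer vector (one entry per transition
#'   pair, values in `1..nHidden`) of initial hard latent-state guesses;
#'   the first restart then starts from the M-step of this labelling
#'   instead of a random draw.  Passing the pre/post-collapse labelling
#'   seeds EM in the step-change basin, which a random restart finds only
#'   unreliably; EM remains free to move away from it.
#' @return list with `model` (fitted [DBNModel-class]) and `report`:
#'   per-restart traces of the penalized log-likelihood (data
#'   log-likelihood plus the Dirichlet log prior implied by the add-one
#'   M-step -- the objective EM ascends, non-decreasing within each
#'   restart), `converged`, `bestRestart`, `logLik` (best final value of
#'   that objective) and `seed`.
#' @export
fitEM <- function(skeleton, tdata, init = c("random", "perturbed"),
                  tol = 1e-6, maxIter = 500L, nRestarts = 10L, seed = 1L,
                  initStates = NULL) {
  init <- match.arg(init)
  stopIfNot(nRestarts >= 1L, "nRestarts must be >= 1")
  stopIfNot(all(skeleton@obsNodes %in% variableNames(tdata)),
            "tdata must cover the model's observables")
  model <- skeleton
  # closed-form Laplace fit of the H-free observable tables
  for (v in setdiff(model@obsNodes, model@hiddenChildren)) {
    pa <- model@interParents[[v]]
    stacked <- cbind(tdata@prev, tdata@cur[, v, drop = FALSE])
    ar <- c(unname(model@arities[colnames(tdata@prev)]), model@arities[[v]])
    F <- .familyCountsC(stacked, ncol(stacked),
                        match(pa, colnames(tdata@prev)), as.integer(ar))
    model@obsCPTs[[v]] <- (F + 1) / (rowSums(F) + model@arities[[v]])
  }
  obsLL <- .obsLogLik(model, tdata)

  nH <- model@nHidden
  configs <- .childConfigs(model, tdata)

  # the add-one M-step is the Dirichlet(2) MAP update, so the quantity EM
  # ascends (and the trace records) is the penalized log-likelihood:
  # data log-likelihood plus the log parameter prior
  logPrior <- function(m) {
    sum(log(m@initial)) + sum(log(m@transition)) +
      sum(vapply(m@hiddenCPTs, function(tc) sum(log(tc)), 0))
  }

  randomInit <- function(m) {
    m@initial <- local({p <- runif(nH, 0.2, 1); p / sum(p)})
    # sticky start: the latent node models a *persistent* regime with an
    # autoregressive link, so restarts begin diagonal-dominant
    A <- matrix(runif(nH * nH, 0.05, 0.3), nH, nH)
    diag(A) <- diag(A) + runif(nH, 1.5, 3)
    m@transition <- A / rowSums(A)
    for (v in m@hiddenChildren) {
      r <- m@arities[[v]]
      q <- dim(m@hiddenCPTs[[v]])[1]
      tc <- array(runif(q * nH * r, 0.2, 1), dim = c(q, nH, r))
      if (init == "perturbed") {
        cf <- configs[[v]]
        emp <- matrix(1 / r, q, r)
        for (i in seq_along(cf$j)) {
          emp[cf$j[i], cf$y[i]] <- emp[cf$j[i], cf$y[i]] + 1
        }
        emp <- emp / rowSums(emp)
        for (h in seq_len(nH)) tc[, h, ] <- emp + 0.3 * tc[, h, ]
      }
      norm <- apply(tc, c(1, 2), sum)
      for (k in seq_len(r)) tc[, , k] <- tc[, , k] / norm
      m@hiddenCPTs[[v]] <- tc
    }
    m
  }

  hardInit <- function(m, states) {
    P <- nRecords(tdata)
    stopIfNot(length(states) == P, "one initial state per pair required")
    gamma <- matrix(0, P, nH)
    gamma[cbind(seq_len(P), states)] <- 1
    xi <- matrix(0, nH, nH)
    for (i in seq_len(P - 1L)) {
      if (!tdata@newSegment[i + 1L])
        xi[states[i], states[i + 1L]] <- xi[states[i], states[i + 1L]] + 1
    }
    .mStep(m, tdata, list(smoothed = gamma, xi = xi))
  }

  best <- NULL
  traces <- vector("list", nRestarts)
  convs <- logical(nRestarts)
  for (rs in seq_len(nRestarts)) {
    m <- if (rs == 1L && !is.null(initStates)) {
      hardInit(model, as.integer(initStates))
    } else {
      withSeed(seed + rs - 1L, randomInit(model))
    }
    tr <- numeric(0)
    ll <- -Inf
    conv <- FALSE
    for (it in seq_len(maxIter)) {
      fb <- .forwardBackward(m@initial, m@transition,
                             .emissionMatrix(m, tdata, configs),
                             tdata@newSegment)
      if (!is.finite(fb$ll)) break
      llNew <- fb$ll + obsLL + logPrior(m)
      tr <- c(tr, llNew)
      if (is.finite(ll) && (llNew - ll) <= tol * (abs(ll) + 1e-3)) {
        conv <- TRUE
        ll <- max(ll, llNew)
        break
      }
      ll <- llNew
      m <- .mStep(m, tdata, fb, configs)
    }
    traces[[rs]] <- tr
    convs[rs] <- conv
    if (is.null(best) || ll > best$ll) best <- list(model = m, ll = ll, rs = rs)
  }
  list(model = best$model,
       report = list(traces = traces, converged = convs[best$rs],
                     convergedAll = convs, bestRestart = best$rs,
                     logLik = best$ll, nRestarts = nRestarts, seed = seed))
}
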