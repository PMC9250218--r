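## Unsupervised parameter estimation by Monte Carlo EM with blocked Gibbs
## sampling over hidden stages, complication onset times, and noisy-or
## cause attributions.

#' Control settings for model fitting
#'
#' @param n_em_iterations maximum EM iterations (default 200).
#' @param n_gibbs_sweeps Gibbs sweeps per E-step, including burn-in
#'   (default 20).
#' @param burn_in sweeps discarded at the start of each E-step; latent
#'   states are kept warm across iterations, so a small value suffices
#'   (default 2).
#' @param seed integer seed driving all sampling.
#' @param convergence_tol relative change in the smoothed complete-data
#'   log-likelihood below which an iteration counts as converged
#'   (default 1e-4).
#' @param convergence_window consecutive converged iterations required to
#'   stop (default 5).
#' @param anchor_init initial activation probability of anchored links
#'   (default 0.8).
#' @param freeze_anchors keep anchored activation probabilities fixed at
#'   \code{anchor_init} instead of learning them.
#' @param beta_a,beta_b Beta pseudo-counts smoothing every probability
#'   parameter (default 1, 1).
#' @param gamma_shape,gamma_rate Gamma pseudo-counts smoothing the stage
#'   intensities (default 1, 1).
#' @param init_a,init_b Beta shape parameters for drawing initial
#'   unanchored activation, leak and onset parameters (default 1, 3 — a
#'   sparse-data-friendly mean of 0.25).
#' @param average_last average the parameter estimates of the last k EM
#'   iterations into the returned model (default 5).  Monte Carlo EM
#'   dithers around its fixed point rather than converging pointwise;
#'   iterate averaging reports the centre of that stationary region.
#' @param initial_stage_prior optional length-K prior over the stage at a
#'   patient's first encounter.  The default \code{NULL} is uniform — the
#'   right choice for real patients who enter observation at an unknown
#'   point of their progression.  For cohorts observed from disease onset
#'   (such as generated patients, who start in stage I at year 0) a
#'   degenerate prior like \code{c(1, 0, ..., 0)} matches the data-
#'   generating process.
#' @param verbose print per-iteration telemetry.
#' @return a list of class \code{fit_control}.
#' @export
fit_control <- function(n_em_iterations = 200, n_gibbs_sweeps = 20,
                        burn_in = 2, seed = 1,
                        convergence_tol = 1e-4, convergence_window = 5,
                        anchor_init = 0.8, freeze_anchors = FALSE,
                        beta_a = 1, beta_b = 1,
                        gamma_shape = 1, gamma_rate = 1,
                        init_a = 1, init_b = 3, average_last = 5,
                        initial_stage_prior = NULL, verbose = FALSE) {
  stopifnot(n_em_iterations >= 1, n_gibbs_sweeps >= 1,
            burn_in >= 0, burn_in < n_gibbs_sweeps,
            convergence_tol > 0, beta_a > 0, beta_b > 0,
            gamma_shape > 0, gamma_rate > 0,
            is.null(initial_stage_prior) ||
              (all(initial_stage_prior >= 0) && sum(initial_stage_prior) > 0))
  structure(as.list(environment()), class = "fit_control")
}

#' Initialize a progression model
#'
#' Builds a valid starting model: anchored activation entries at
#' \code{anchor_init}, unanchored activation / leak / onset parameters
#' drawn from the configured Beta initialization prior, and intensities of
#' 0.1 per year to the adjacent stage.
#'
#' @param K,W dimensions.
#' @param vocabulary a \code{finding_vocabulary} (or character vector).
#' @param anchors an \code{anchor_set} or \code{NULL}.
#' @param seed integer seed (same seed, same model).
#' @param control a [fit_control()] list.
#' @return a valid \code{progression_model}.
#' @export
init_model <- function(K, W, vocabulary, anchors = NULL, seed = 1,
                       control = fit_control()) {
  set.seed(seed)
  vocabulary <- new_vocabulary(as.character(vocabulary))
  N <- length(vocabulary)
  mask <- if (is.null(anchors)) matrix(TRUE, W, N)
          else make_connectivity_mask(anchors, vocabulary, W)
  a <- control$init_a; b <- control$init_b
  A <- matrix(stats::rbeta(W * N, a, b), W, N)
  A[!mask] <- 0
  bound <- attr(mask, "anchored")
  if (length(bound)) {
    for (code in names(bound)) {
      A[bound[[code]], code_index(vocabulary, code)] <- control$anchor_init
    }
  }
  leak <- stats::rbeta(N, a, b)
  ## onset parameters are sorted within each complication so hazards start
  ## increasing with stage severity — breaks the symmetry of the ordered
  ## latent stages and speeds early EM progress
  pi_onset <- apply(matrix(stats::rbeta(K * W, a, b), K, W), 2, sort)
  h_onset <- apply(matrix(stats::rbeta(K * W, a, b), K, W), 2, sort)
  dim(pi_onset) <- dim(h_onset) <- c(K, W)
  Q <- matrix(0, K, K)
  for (k in seq_len(K - 1)) Q[k, k + 1] <- 0.1
  diag(Q) <- -rowSums(Q)
  progression_model(K, W, vocabulary, Q, pi_onset, h_onset, A, leak,
                    mask = mask, anchors = anchors)
}

#' Anchor-guided warm-start model
#'
#' Builds a data-driven starting point for EM from deterministic
#' pseudo-latents: each patient's slices are split into K equal runs as a
#' provisional stage path, and a complication is marked active from the
#' first slice containing one of its anchor codes (anchors make onsets
#' quasi-observable, which is what makes this warm start work).  Moment
#' estimates of all parameters from these pseudo-latents, smoothed by the
#' Beta/Gamma pseudo-counts, give the initial model; complications without
#' anchors fall back to the [init_model()] draws.
#'
#' @param histories list of \code{patient_history}.
#' @param K,W dimensions.
#' @param vocabulary a \code{finding_vocabulary}.
#' @param anchors an \code{anchor_set}.
#' @param seed seed for the fallback draws.
#' @param control a [fit_control()] list.
#' @return a valid \code{progression_model}.
#' @export
warm_start_model <- function(histories, K, W, vocabulary, anchors, seed = 1,
                             control = fit_control()) {
  base <- init_model(K, W, vocabulary, anchors, seed = seed, control = control)
  mask <- base$mask
  N <- base$N
  bound <- attr(mask, "anchored")
  anch_idx <- lapply(seq_len(W), function(w)
    code_index(base$vocabulary, names(bound)[bound == w]))
  a <- control$beta_a; b <- control$beta_b
  pi_s <- matrix(0, K, W); pi_n <- matrix(0, K, W)
  h_s <- matrix(0, K, W); h_y <- matrix(0, K, W)
  A_s <- matrix(0, W, N); A_e <- matrix(0, W, N)
  leak_s <- numeric(N); leak_e <- 0
  jumps <- matrix(0, K, K); time_in <- numeric(K)
  for (hst in histories) {
    T_ <- length(hst$year)
    stg <- ceiling(K * seq_len(T_) / T_)          # provisional equal split
    act <- matrix(FALSE, T_, W)
    for (w in seq_len(W)) {
      if (!length(anch_idx[[w]])) next
      hit <- which(vapply(hst$findings, function(f)
        any(anch_idx[[w]] %in% f), TRUE))
      if (length(hit)) act[, w] <- seq_len(T_) >= hit[1]
    }
    pi_n[stg[1], ] <- pi_n[stg[1], ] + 1
    pi_s[stg[1], ] <- pi_s[stg[1], ] + act[1, ]
    if (T_ > 1) for (t in 2:T_) {
      dt <- hst$year[t] - hst$year[t - 1]
      k <- stg[t]
      time_in[stg[t - 1]] <- time_in[stg[t - 1]] + dt
      if (stg[t] > stg[t - 1]) jumps[stg[t - 1], stg[t]] <- jumps[stg[t - 1], stg[t]] + 1
      new <- act[t, ] & !act[t - 1, ]
      h_s[k, new] <- h_s[k, new] + 1
      h_y[k, !act[t, ]] <- h_y[k, !act[t, ]] + dt
    }
    for (t in seq_len(T_)) {
      leak_e <- leak_e + 1
      pos <- hst$findings[[t]]
      on <- act[t, ]
      if (any(on)) A_e[on, ] <- A_e[on, ] + mask[on, , drop = FALSE]
      if (length(pos)) {
        A_s[on, pos] <- A_s[on, pos] + mask[on, pos, drop = FALSE]
        nopar <- pos[colSums(mask[on, pos, drop = FALSE]) == 0]
        leak_s[nopar] <- leak_s[nopar] + 1
      }
    }
  }
  A <- (a + A_s) / (a + b + A_e)
  A[!mask] <- 0
  for (w in seq_len(W)) A[w, anch_idx[[w]]] <- control$anchor_init
  leak <- (a + leak_s) / (a + b + leak_e)
  anch_w <- lengths(anch_idx) > 0
  pi_onset <- (a + pi_s) / (a + b + pi_n)
  h_onset <- (a + h_s) / (a + b + h_s + h_y)
  pi_onset[, !anch_w] <- base$pi_onset[, !anch_w]
  h_onset[, !anch_w] <- base$h_onset[, !anch_w]
  Q <- matrix(0, K, K)
  for (i in seq_len(K - 1)) for (j in (i + 1):K) {
    Q[i, j] <- (control$gamma_shape + jumps[i, j]) /
               (control$gamma_rate + time_in[i])
  }
  diag(Q) <- -rowSums(Q)
  progression_model(K, W, base$vocabulary, Q, pi_onset, h_onset, A, leak,
                    mask = mask, anchors = anchors)
}

## ---- per-model precomputation shared across patients in one iteration ----

## pc caches, per distinct interval length (indexed by position in pc$ud):
## interval transition matrices and their logs, and the K x W interval
## onset / no-onset log-probabilities; plus first-encounter onset logs and
## per-complication noisy-or factor vectors.
precompute_params <- function(model, dts, initial_stage_prior = NULL) {
  ud <- sort(unique(dts))
  P <- lapply(ud, function(dt) stage_transition_matrix(model$Q, dt))
  lh1 <- log1p(-model$h_onset)          # K x W, log(1 - h)
  wfac <- lapply(seq_len(model$W), function(w) {
    f <- 1 - model$A[w, ]
    f[!model$mask[w, ]] <- 1
    f
  })
  linit <- if (is.null(initial_stage_prior)) rep(-log(model$K), model$K)
           else log(initial_stage_prior / sum(initial_stage_prior))
  list(ud = ud, P = P, logP = lapply(P, log), linit = linit,
       lon = lapply(ud, function(dt) log1p(-exp(dt * lh1))),
       loff = lapply(ud, function(dt) dt * lh1),
       lpi1 = log(model$pi_onset), lpi0 = log1p(-model$pi_onset),
       wfac = wfac, wnn = lapply(seq_len(model$W), function(w) which(model$mask[w, ])),
       one_minus_leak = 1 - model$leak)
}

dt_index <- function(pc, dts) match(dts, pc$ud)

## Emission log-weights over stages for every slice, given a monotone
## complication activity matrix (T x W).  Onset-chain terms only: the
## noisy-or terms do not depend on the stage and cancel in the stage
## conditional.
## Indexed row sums rather than a matrix product: degenerate parameters
## put -Inf into the log tables, and 0 * -Inf would poison a product.
stage_emissions <- function(active, dti, pc) {
  T_ <- nrow(active); K <- nrow(pc$lpi1)
  E <- matrix(0, T_, K)
  a1 <- which(active[1, ])
  E[1, ] <- rowSums(pc$lpi1[, a1, drop = FALSE]) +
            rowSums(pc$lpi0[, which(!active[1, ]), drop = FALSE])
  if (T_ > 1) for (t in 2:T_) {
    d <- dti[t - 1]
    on <- which(active[t, ] & !active[t - 1, ])
    off <- which(!active[t, ])
    E[t, ] <- rowSums(pc$lon[[d]][, on, drop = FALSE]) +
              rowSums(pc$loff[[d]][, off, drop = FALSE])
  }
  E
}

#' Draw a stage sequence from its conditional posterior
#'
#' Forward filtering / backward sampling over the K-stage chain with
#' interval transition matrices \code{expm(Q * dt)}, a uniform prior over
#' the initial stage, and per-slice emissions from the complication onset
#' chains.  The forward-only transition structure guarantees every draw is
#' nondecreasing.
#'
#' @param history a \code{patient_history}.
#' @param complications \code{T x W} logical matrix of complication
#'   activity per slice (monotone within each column).
#' @param model a \code{progression_model}.
#' @return integer stage sequence of length T.
#' @export
sample_stages <- function(history, complications, model) {
  dts <- diff(history$year)
  pc <- precompute_params(model, dts)
  sample_stages_(complications, dt_index(pc, dts), model$K, pc)
}

sample_stages_ <- function(active, dti, K, pc) {
  T_ <- nrow(active)
  E <- stage_emissions(active, dti, pc)
  E[1, ] <- E[1, ] + pc$linit
  alpha <- matrix(0, T_, K)
  a <- exp(E[1, ] - max(E[1, ]))
  if (all(a == 0) || anyNA(a)) stop("zero-probability evidence at slice 1")
  alpha[1, ] <- a / sum(a)
  if (T_ > 1) for (t in 2:T_) {
    pred <- alpha[t - 1, ] %*% pc$P[[dti[t - 1]]]
    a <- as.numeric(pred) * exp(E[t, ] - max(E[t, ]))
    if (sum(a) == 0 || anyNA(a)) stop("zero-probability evidence at slice ", t)
    alpha[t, ] <- a / sum(a)
  }
  s <- integer(T_)
  s[T_] <- sample.int(K, 1, prob = alpha[T_, ])
  if (T_ > 1) for (t in (T_ - 1):1) {
    w <- alpha[t, ] * pc$P[[dti[t]]][, s[t + 1]]
    s[t] <- sample.int(K, 1, prob = w)
  }
  s
}

#' Draw complication onset times from their conditional posterior
#'
#' For each complication in turn (a Gibbs scan), enumerates all monotone
#' onset slices (including "never"), combines the stage-conditioned onset
#' chain prior with the noisy-or observation likelihood, and samples one.
#' Every draw is monotone by construction.
#'
#' @param history a \code{patient_history}.
#' @param stages integer stage sequence (nondecreasing).
#' @param complications current \code{T x W} activity matrix (Gibbs state).
#' @param model a \code{progression_model}.
#' @return list with \code{active} (new \code{T x W} logical matrix) and
#'   \code{onset_slice} (length-W integer; \code{NA} = never active).
#' @export
sample_complications <- function(history, stages, complications, model) {
  dts <- diff(history$year)
  pc <- precompute_params(model, dts)
  pos_nn <- pos_in_mask(history$findings, model$mask)
  sample_complications_(pos_nn, stages, complications, dt_index(pc, dts),
                        model, pc)
}

## Per complication w, the positions (within the mask-allowed finding set
## of w) of each slice's positive findings.  Static per patient.
pos_in_mask <- function(findings, mask) {
  lapply(seq_len(nrow(mask)), function(w) {
    nn <- which(mask[w, ])
    lapply(findings, function(f) which(nn %in% f))
  })
}

sample_complications_ <- function(pos_nn, stages, active, dti, model, pc) {
  T_ <- length(stages); W <- model$W
  onset <- rep(NA_integer_, W)
  for (w in seq_len(W)) {
    nn <- pc$wnn[[w]]
    omA <- pc$wfac[[w]][nn]              # 1 - A[w, nn]
    pw <- pos_nn[[w]]
    ## observation log-lik at each slice with w active / inactive, grouping
    ## slices that share the other complications' activity pattern
    if (W > 1) {
      oth <- active[, -w, drop = FALSE]
      cfg_id <- as.integer(oth %*% 2^(seq_len(W - 1) - 1)) + 1L
    } else cfg_id <- rep(1L, T_)
    lw <- numeric(T_); lwo <- numeric(T_)
    for (cfg in unique(cfg_id)) {
      ts <- which(cfg_id == cfg)
      q <- pc$one_minus_leak[nn]
      if (W > 1) {
        for (w2 in seq_len(W)[-w][oth[ts[1], ]]) q <- q * pc$wfac[[w2]][nn]
      }
      lq <- log(q);       lp0 <- log1p(-q)
      lqa <- lq + log(omA); lp1 <- log1p(-q * omA)
      S0 <- sum(lq); S1 <- sum(lqa)
      for (t in ts) {
        ii <- pw[[t]]
        lwo[t] <- S0 + sum(lp0[ii] - lq[ii])
        lw[t]  <- S1 + sum(lp1[ii] - lqa[ii])
      }
    }
    ## prior over onset slice tau in {1..T, never}
    k1 <- stages[1]
    lp <- numeric(T_ + 1)
    lp[1] <- pc$lpi1[k1, w]
    surv <- pc$lpi0[k1, w]
    if (T_ > 1) for (t in 2:T_) {
      d <- dti[t - 1]
      lp[t] <- surv + pc$lon[[d]][stages[t], w]
      surv <- surv + pc$loff[[d]][stages[t], w]
    }
    lp[T_ + 1] <- surv
    ## likelihood: slices < tau use w-inactive terms, >= tau use w-active
    cum_lwo <- c(0, cumsum(lwo))          # sum of lwo over slices < tau
    cum_lw <- rev(c(0, cumsum(rev(lw))))  # sum of lw over slices >= tau
    lwt <- lp + cum_lwo + cum_lw
    m <- max(lwt)
    if (!is.finite(m)) stop("zero-probability evidence for complication ", w)
    tau <- sample.int(T_ + 1, 1, prob = exp(lwt - m))
    if (tau <= T_) {
      active[, w] <- seq_len(T_) >= tau
      onset[w] <- tau
    } else {
      active[, w] <- FALSE
    }
  }
  list(active = active, onset_slice = onset)
}

#' Draw noisy-or cause attributions for every positive observation
#'
#' For each observed positive finding, samples the latent firing vector of
#' its potential causes (active mask-allowed complications plus the leak),
#' conditioned on at least one cause firing — the exact noisy-or
#' augmentation.  A single "attributed" cause is also reported, drawn
#' uniformly among the firing causes.
#'
#' @param history a \code{patient_history}.
#' @param complications \code{T x W} logical activity matrix.
#' @param model a \code{progression_model}.
#' @return list (per slice) of lists (per positive finding) with elements
#'   \code{finding}, \code{fired} (integer causes, 0 = leak) and
#'   \code{attributed} (single cause, 0 = leak).
#' @export
sample_attributions <- function(history, complications, model) {
  out <- vector("list", length(history$findings))
  for (t in seq_along(history$findings)) {
    pos <- history$findings[[t]]
    slice <- vector("list", length(pos))
    for (i in seq_along(pos)) {
      n <- pos[i]
      parents <- which(complications[t, ] & model$mask[, n])
      y <- sample_or_vector(c(model$A[parents, n], model$leak[n]))
      if (is.null(y)) {
        stop("positive finding ", as.character(model$vocabulary)[n],
             " at slice ", t, " has zero total activation probability")
      }
      fired <- c(parents, 0L)[y]
      slice[[i]] <- list(finding = n, fired = fired,
                         attributed = if (length(fired) == 1) fired
                                      else fired[sample.int(length(fired), 1)])
    }
    out[[t]] <- slice
  }
  out
}

## Exact draw of independent Bernoulli(p_i) firing indicators conditioned
## on at least one success, by sequential conditioning.  Returns a logical
## vector, or NULL when no cause can fire.
sample_or_vector <- function(p) {
  m <- length(p)
  if (m == 1) {
    if (p <= 0) return(NULL)
    return(TRUE)                     # single cause must have fired
  }
  surv <- cumprod((1 - p)[m:1])[m:1] # surv[i] = prod_{j>=i}(1-p_j)
  if (surv[1] >= 1) return(NULL)     # all p zero: observation impossible
  u <- stats::runif(m)
  y <- logical(m)
  fired_yet <- FALSE
  for (i in seq_len(m)) {
    if (fired_yet) {
      y[i] <- u[i] < p[i]
    } else {
      y[i] <- u[i] < p[i] / (1 - surv[i])  # P(y_i=1 | no fire yet, OR = 1)
      fired_yet <- y[i]
    }
  }
  y
}

## ---- endpoint-conditioned stage-path sampling (uniformization) ----------

make_bridge_ctx <- function(Q) {
  K <- nrow(Q)
  lambda <- max(-diag(Q))
  ctx <- new.env(parent = emptyenv())
  ctx$lambda <- lambda
  ctx$K <- K
  ctx$wcache <- list()
  if (lambda > 0) {
    ctx$M <- diag(K) + Q / lambda
    ctx$Mpow <- list(diag(K))        # Mpow[[j+1]] = M^j
  }
  ctx
}

get_Mpow <- function(ctx, j) {
  while (length(ctx$Mpow) < j + 1) {
    ctx$Mpow[[length(ctx$Mpow) + 1]] <-
      ctx$Mpow[[length(ctx$Mpow)]] %*% ctx$M
  }
  ctx$Mpow[[j + 1]]
}

## Poisson-weighted endpoint probabilities for the jump count, cached per
## (a, b, dt).
bridge_weights <- function(ctx, a, b, dt) {
  key <- paste0(a, "_", b, "_", dt)
  w <- ctx$wcache[[key]]
  if (!is.null(w)) return(w)
  mu <- ctx$lambda * dt
  jmax <- max(stats::qpois(1 - 1e-12, mu), b - a, 4)
  repeat {
    get_Mpow(ctx, jmax)
    mab <- vapply(0:jmax, function(j) ctx$Mpow[[j + 1]][a, b], 0)
    wts <- stats::dpois(0:jmax, mu) * mab
    if (sum(wts) > 0) break
    jmax <- jmax * 2
    if (jmax > 10000) stop("endpoint-conditioned bridge: transition ", a,
                           " -> ", b, " has no support")
  }
  ctx$wcache[[key]] <- wts
  wts
}

## One exact draw of the continuous stage path on an interval of length dt
## conditioned on its endpoint stages; returns time spent in each stage and
## the matrix of realized jumps.
sample_bridge <- function(ctx, a, b, dt) {
  K <- ctx$K
  time_in <- numeric(K); jumps <- matrix(0, K, K)
  if (a == b || ctx$lambda == 0) {  # forward-only: equal endpoints = no move
    time_in[a] <- dt
    return(list(time_in = time_in, jumps = jumps))
  }
  wts <- bridge_weights(ctx, a, b, dt)
  J <- sample.int(length(wts), 1, prob = wts) - 1L
  states <- integer(J + 1)
  states[1] <- a; states[J + 1] <- b
  if (J > 1) for (i in 2:J) {
    pr <- ctx$M[states[i - 1], ] * ctx$Mpow[[J - i + 2]][, b]
    states[i] <- sample.int(K, 1, prob = pr)
  }
  times <- c(0, sort(stats::runif(J)) * dt, dt)
  for (i in seq_len(J + 1)) {
    time_in[states[i]] <- time_in[states[i]] + times[i + 1] - times[i]
  }
  if (J > 0) for (i in seq_len(J)) {
    if (states[i + 1] != states[i]) {
      jumps[states[i], states[i + 1]] <- jumps[states[i], states[i + 1]] + 1
    }
  }
  list(time_in = time_in, jumps = jumps)
}

## ---- sufficient statistics and the M-step --------------------------------

empty_stats <- function(K, W, N) {
  list(A_succ = matrix(0, W, N), A_expose = matrix(0, W, N),
       leak_succ = numeric(N), leak_expose = 0,
       pi_succ = matrix(0, K, W), pi_n = matrix(0, K, W),
       h_succ = matrix(0, K, W), h_years = matrix(0, K, W),
       Q_jumps = matrix(0, K, K), Q_time = numeric(K),
       n_sweeps = 0)
}

#' Posterior-mean parameter updates from sampled sufficient statistics
#'
#' Beta-smoothed updates for all probability parameters (activation, leak,
#' initial onset, per-year onset) and Gamma-smoothed updates of the
#' forward-only intensities from jump counts over exposure time.  Mask
#' zeros (and, if frozen, anchored values) are preserved.
#'
#' @param stats accumulated statistics as produced during Gibbs sweeps
#'   (see [fit_progression()]).
#' @param model the current \code{progression_model} (provides dimensions,
#'   mask and vocabulary).
#' @param control a [fit_control()] list (priors, freeze option).
#' @return an updated \code{progression_model}.
#' @export
m_step <- function(stats, model, control = fit_control()) {
  stopifnot(stats$n_sweeps >= 1)
  a <- control$beta_a; b <- control$beta_b
  K <- model$K; W <- model$W; N <- model$N
  A <- (a + stats$A_succ) / (a + b + stats$A_expose)
  A[!model$mask] <- 0
  if (control$freeze_anchors) {
    bound <- attr(model$mask, "anchored")
    for (code in names(bound)) {
      A[bound[[code]], code_index(model$vocabulary, code)] <- control$anchor_init
    }
  }
  leak <- (a + stats$leak_succ) / (a + b + stats$leak_expose)
  pi_onset <- (a + stats$pi_succ) / (a + b + stats$pi_n)
  h_onset <- (a + stats$h_succ) / (a + b + stats$h_succ + stats$h_years)
  Q <- matrix(0, K, K)
  for (i in seq_len(K - 1)) {
    for (j in (i + 1):K) {
      Q[i, j] <- (control$gamma_shape + stats$Q_jumps[i, j]) /
                 (control$gamma_rate + stats$Q_time[i])
    }
  }
  diag(Q) <- -rowSums(Q)
  progression_model(K, W, model$vocabulary, Q, pi_onset, h_onset, A, leak,
                    mask = model$mask, anchors = model$anchors)
}

## Complete-data log-likelihood of one patient's sampled latents.
complete_ll_patient <- function(findings, dti, stages, active, model, pc) {
  T_ <- length(stages)
  ll <- pc$linit[stages[1]]
  if (T_ > 1) for (t in 2:T_) {
    ll <- ll + pc$logP[[dti[t - 1]]][stages[t - 1], stages[t]]
  }
  E <- stage_emissions(active, dti, pc)
  ll <- ll + sum(E[cbind(seq_len(T_), stages)])
  cfg_id <- as.integer(active %*% 2^(seq_len(model$W) - 1)) + 1L
  for (cfg in unique(cfg_id)) {
    ts <- which(cfg_id == cfg)
    q <- pc$one_minus_leak
    for (w in which(active[ts[1], ])) q <- q * pc$wfac[[w]]
    lq <- log(q); lp <- log1p(-q)
    S <- sum(lq)
    for (t in ts) {
      f <- findings[[t]]
      ll <- ll + S + sum(lp[f] - lq[f])
    }
  }
  ll
}

#' Fit the progression model by Monte Carlo EM
#'
#' Blocked Gibbs sampling over hidden stages (forward filtering / backward
#' sampling), complication onset times, noisy-or cause attributions and
#' endpoint-conditioned continuous stage paths provides the E-step;
#' posterior-mean conjugate updates provide the M-step.  Iterates until the
#' smoothed complete-data log-likelihood stabilises or the iteration cap is
#' reached.  Fully reproducible for a given seed.
#'
#' @param histories list of \code{patient_history} objects over
#'   \code{vocabulary}.
#' @param K,W number of stages and complications.
#' @param vocabulary a \code{finding_vocabulary} (or character vector of
#'   codes) indexing the histories' findings.
#' @param anchors optional \code{anchor_set} pruning the activation layer.
#' @param control a [fit_control()] list.
#' @param init optional starting \code{progression_model} (default: from
#'   [init_model()]).
#' @return an object of class \code{progression_fit} with elements
#'   \code{model}, \code{diagnostics} (per-iteration log-likelihood
#'   estimate, Monte Carlo standard error, monotonicity check, wall time),
#'   \code{converged}, \code{control}.
#' @export
fit_progression <- function(histories, K, W, vocabulary, anchors = NULL,
                            control = fit_control(), init = NULL) {
  if (length(histories) == 0) stop("no patient histories supplied")
  vocabulary <- new_vocabulary(as.character(vocabulary))
  N <- length(vocabulary)
  ## deterministic patient order
  ids <- vapply(histories, function(h) h$patient_id, "")
  histories <- histories[order(ids, method = "radix")]
  for (h in histories) {
    f <- unlist(h$findings)
    if (length(f) && max(f) > N) stop("history findings outside vocabulary")
  }
  set.seed(control$seed)
  model <- if (!is.null(init)) {
    init
  } else if (!is.null(anchors) && n_anchored_codes(anchors) > 0) {
    warm_start_model(histories, K, W, vocabulary, anchors,
                     seed = sample.int(2^31 - 1, 1), control = control)
  } else {
    init_model(K, W, vocabulary, anchors, seed = sample.int(2^31 - 1, 1),
               control = control)
  }
  K <- model$K; W <- model$W

  mask_cols <- lapply(seq_len(N), function(n) which(model$mask[, n]))
  all_dts <- sort(unique(unlist(lapply(histories, function(h) diff(h$year)))))
  pdat <- lapply(histories, function(h) {
    dts <- diff(h$year)
    list(findings = h$findings, dts = dts,
         dti = match(dts, all_dts),
         pos_nn = pos_in_mask(h$findings, model$mask),
         T_ = length(h$year))
  })
  ## warm latent state
  lat <- lapply(pdat, function(p) {
    list(stages = rep(1L, p$T_), active = matrix(FALSE, p$T_, W))
  })

  diag_rows <- vector("list", control$n_em_iterations)
  navg <- max(1, min(control$average_last, control$n_em_iterations))
  recent <- vector("list", navg)
  ll_prev <- -Inf
  n_conv <- 0
  converged <- FALSE
  t0 <- proc.time()[["elapsed"]]

  for (iter in seq_len(control$n_em_iterations)) {
    pc <- precompute_params(model, all_dts, control$initial_stage_prior)
    bctx <- make_bridge_ctx(model$Q)
    sstats <- empty_stats(K, W, N)
    ll_sweeps <- numeric(0)
    mono_ok <- TRUE
    for (sweep in seq_len(control$n_gibbs_sweeps)) {
      collect <- sweep > control$burn_in
      ll_sweep <- 0
      for (i in seq_along(pdat)) {
        p <- pdat[[i]]
        st <- sample_stages_(lat[[i]]$active, p$dti, K, pc)
        cs <- sample_complications_(p$pos_nn, st, lat[[i]]$active,
                                    p$dti, model, pc)
        lat[[i]] <- list(stages = st, active = cs$active)
        if (is.unsorted(st)) mono_ok <- FALSE
        if (collect) {
          sstats <- accumulate_stats(sstats, p, st, cs, model, bctx, mask_cols)
          ll_sweep <- ll_sweep +
            complete_ll_patient(p$findings, p$dti, st, cs$active, model, pc)
        }
      }
      if (collect) {
        sstats$n_sweeps <- sstats$n_sweeps + 1
        ll_sweeps <- c(ll_sweeps, ll_sweep + log_prior(model, control))
      }
    }
    ll <- mean(ll_sweeps)
    ll_se <- if (length(ll_sweeps) > 1)
      stats::sd(ll_sweeps) / sqrt(length(ll_sweeps)) else NA_real_
    diag_rows[[iter]] <- data.frame(
      iteration = iter, loglik = ll, loglik_se = ll_se,
      monotone_ok = mono_ok,
      elapsed = proc.time()[["elapsed"]] - t0)
    if (control$verbose) {
      message(sprintf("EM iter %3d  logLik %.2f (se %.2f)  %.1fs",
                      iter, ll, ll_se, proc.time()[["elapsed"]] - t0))
    }
    model <- m_step(sstats, model, control)
    recent[[1 + (iter - 1) %% navg]] <- model
    rel <- abs(ll - ll_prev) / (abs(ll_prev) + 1e-8)
    n_conv <- if (is.finite(rel) && rel < control$convergence_tol) n_conv + 1 else 0
    ll_prev <- ll
    if (n_conv >= control$convergence_window) { converged <- TRUE; break }
  }
  recent <- recent[!vapply(recent, is.null, TRUE)]
  if (length(recent) > 1) model <- average_models(recent)

  structure(list(model = model,
                 diagnostics = do.call(rbind, diag_rows[!vapply(diag_rows, is.null, TRUE)]),
                 converged = converged,
                 n_patients = length(histories),
                 control = control),
            class = "progression_fit")
}

## Accumulate one patient-sweep's sufficient statistics; returns the
## updated statistics list.
accumulate_stats <- function(sstats, p, stages, cs, model, bctx, mask_cols) {
  W <- model$W
  active <- cs$active
  T_ <- p$T_
  ## attribution draws for A / leak
  for (t in seq_len(T_)) {
    act <- active[t, ]
    if (any(act)) {
      sstats$A_expose[act, ] <- sstats$A_expose[act, ] +
        model$mask[act, , drop = FALSE]
    }
    sstats$leak_expose <- sstats$leak_expose + 1
    for (n in p$findings[[t]]) {
      wm <- mask_cols[[n]]
      parents <- wm[act[wm]]
      y <- sample_or_vector(c(model$A[parents, n], model$leak[n]))
      if (is.null(y)) stop("positive finding with zero activation probability")
      np <- length(parents)
      if (np) {
        fired_p <- parents[y[seq_len(np)]]
        sstats$A_succ[fired_p, n] <- sstats$A_succ[fired_p, n] + 1
      }
      if (y[np + 1]) sstats$leak_succ[n] <- sstats$leak_succ[n] + 1
    }
  }
  ## onset-chain statistics
  k1 <- stages[1]
  sstats$pi_n[k1, ] <- sstats$pi_n[k1, ] + 1
  sstats$pi_succ[k1, ] <- sstats$pi_succ[k1, ] + active[1, ]
  if (T_ > 1) for (t in 2:T_) {
    dt <- p$dts[t - 1]; k <- stages[t]
    for (w in seq_len(W)) {
      if (active[t - 1, w]) next
      if (active[t, w]) {
        h <- model$h_onset[k, w]
        j <- if (dt == 1) 1L else {
          pr <- (1 - h)^(0:(dt - 1)) * h
          if (sum(pr) == 0) 1L else sample.int(dt, 1, prob = pr)
        }
        sstats$h_succ[k, w] <- sstats$h_succ[k, w] + 1
        sstats$h_years[k, w] <- sstats$h_years[k, w] + (j - 1)
      } else {
        sstats$h_years[k, w] <- sstats$h_years[k, w] + dt
      }
    }
  }
  ## endpoint-conditioned intensity statistics (equal endpoints of a
  ## forward-only chain mean the whole interval was spent in that stage)
  if (T_ > 1) for (t in 2:T_) {
    a <- stages[t - 1]; b <- stages[t]
    if (a == b) {
      sstats$Q_time[a] <- sstats$Q_time[a] + p$dts[t - 1]
    } else {
      br <- sample_bridge(bctx, a, b, p$dts[t - 1])
      sstats$Q_time <- sstats$Q_time + br$time_in
      sstats$Q_jumps <- sstats$Q_jumps + br$jumps
    }
  }
  sstats
}

## Element-wise mean of the parameter arrays of several models sharing one
## topology.
average_models <- function(models) {
  m <- models[[length(models)]]
  avg <- function(f) Reduce(`+`, lapply(models, `[[`, f)) / length(models)
  progression_model(m$K, m$W, m$vocabulary, avg("Q"), avg("pi_onset"),
                    avg("h_onset"), avg("A"), avg("leak"),
                    mask = m$mask, anchors = m$anchors)
}

## Log-prior of the current parameters (the smoothing term of the smoothed
## complete-data log-likelihood).  Constant under the default Beta(1,1)
## except for the Gamma terms on the intensities.
log_prior <- function(model, control) {
  a <- control$beta_a; b <- control$beta_b
  probs <- c(model$A[model$mask], model$leak, model$pi_onset, model$h_onset)
  probs <- pmin(pmax(probs, 1e-12), 1 - 1e-12)
  lp <- sum(stats::dbeta(probs, a, b, log = TRUE))
  rates <- model$Q[upper.tri(model$Q)]
  lp + sum(stats::dgamma(pmax(rates, 1e-12), control$gamma_shape,
                         control$gamma_rate, log = TRUE))
}

#' @export
print.progression_fit <- function(x, ...) {
  cat("Monte Carlo EM progression model fit\n")
  cat(sprintf("  %d patients, %d EM iterations (%s)\n", x$n_patients,
              nrow(x$diagnostics),
              if (x$converged) "converged" else "iteration cap reached"))
  ll <- x$diagnostics$loglik
  cat(sprintf("  final smoothed complete-data logLik: %.2f\n", ll[length(ll)]))
  print(x$model)
  invisible(x)
}

#' @export
summary.progression_fit <- function(object, ...) {
  m <- object$model
  cat("Stage intensity matrix Q (per year):\n")
  print(round(m$Q, 4))
  cat("\nMean holding time per non-absorbing stage (years):\n")
  print(round(-1 / diag(m$Q)[-m$K], 2))
  cat("\nOnset hazards h (stage x complication):\n")
  print(round(m$h_onset, 3))
  cat("\nAnchored activation probabilities:\n")
  bound <- attr(m$mask, "anchored")
  for (code in names(bound)) {
    cat(sprintf("  complication %d -> %s: %.3f\n", bound[[code]], code,
                m$A[bound[[code]], code_index(m$vocabulary, code)]))
  }
  invisible(object)
}

#' @export
coef.progression_fit <- function(object, ...) {
  m <- object$model
  list(Q = m$Q, pi_onset = m$pi_onset, h_onset = m$h_onset,
       A = m$A, leak = m$leak)
}

#' @export
logLik.progression_fit <- function(object, ...) {
  ll <- object$diagnostics$loglik
  structure(ll[length(ll)],
            df = count_parameters(object$model$K, object$model$W,
                                  object$model$N,
                                  anchored_count(object$model), free = TRUE),
            class = "logLik")
}

#' @export
plot.progression_fit <- function(x, ...) {
  d <- x$diagnostics
  graphics::plot(d$iteration, d$loglik, type = "b", pch = 16,
                 xlab = "EM iteration",
                 ylab = "smoothed complete-data log-likelihood", ...)
  invisible(x)
}

#' Simulate synthetic cohorts from a fitted model
#'
#' @param object a \code{progression_fit}.
#' @param nsim number of patients.
#' @param seed integer seed.
#' @param ... passed to [generate_cohort()] (\code{horizon_years},
#'   \code{residence_years}).
#' @return a \code{synthetic_cohort}.
#' @export
simulate.progression_fit <- function(object, nsim = 1, seed = 1, ...) {
  generate_cohort(object$model, n_patients = nsim, seed = seed, ...)
}
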