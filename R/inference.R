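## MAP trajectory inference for individual patients, forward prediction,
## and the exhaustive-enumeration oracle used to test it.

## Observation log-likelihood table B[t, S+1] for every slice t and every
## active-complication bitmask S (bit w-1 set = complication w active),
## built incrementally over bits so each subset costs one O(N) vector op.
obs_table <- function(findings, model) {
  W <- model$W; N <- model$N; T_ <- length(findings)
  nS <- 2^W
  q <- matrix(0, nS, N)        # q[S+1, ] = (1-leak) * prod_active (1-A)
  q[1, ] <- 1 - model$leak
  if (nS > 1) for (S in 1:(nS - 1)) {
    w <- which(bitwAnd(S, 2^(0:(W - 1))) > 0)[1]          # lowest set bit
    fac <- ifelse(model$mask[w, ], 1 - model$A[w, ], 1)
    q[S + 1, ] <- q[bitwAnd(S, bitwNot(2^(w - 1))) + 1, ] * fac
  }
  B <- matrix(0, T_, nS)
  for (t in seq_len(T_)) {
    pos <- rep(FALSE, N); pos[findings[[t]]] <- TRUE
    for (S in 0:(nS - 1)) {
      p <- 1 - q[S + 1, ]
      B[t, S + 1] <- sum(log(ifelse(pos, p, 1 - p)))
    }
  }
  B
}

bit_active <- function(S, W) as.logical(bitwAnd(S, 2^(0:(W - 1))))

#' Jointly most probable latent trajectory (MAP)
#'
#' Dynamic programming over the product lattice of (stage, active
#' complication set): stages are forward-only, complication activity is
#' monotone, and the per-interval onset factors decompose over
#' complications, which lets the maximisation over predecessor activity
#' sets be done with a weighted superset transform in \code{W * 2^W} steps
#' instead of \code{3^W}.  Deterministic; ties resolve toward earlier
#' stages and earlier onsets.
#'
#' @param history a \code{patient_history} over the model vocabulary.
#' @param model a \code{progression_model}.
#' @return object of class \code{latent_trajectory}: per-slice \code{stage}
#'   and \code{active} (\code{T x W}), plus \code{onset_slice} and the
#'   joint log-probability \code{logp}.
#' @export
map_trajectory <- function(history, model) {
  K <- model$K; W <- model$W
  T_ <- length(history$year)
  dts <- diff(history$year)
  pc <- precompute_params(model, dts)
  dti <- dt_index(pc, dts)
  B <- obs_table(history$findings, model)
  nS <- 2^W
  Smask <- t(vapply(0:(nS - 1), function(S) bit_active(S, W), logical(W)))
  if (W == 1) Smask <- matrix(Smask, ncol = 1)

  ## selective accumulation, not a matrix product: degenerate parameters
  ## yield -Inf log terms and 0 * -Inf would poison a product
  sum_over <- function(select, vals) {
    out <- numeric(nS)
    for (w in seq_len(W)) {
      rows <- if (select) Smask[, w] else !Smask[, w]
      out[rows] <- out[rows] + vals[w]
    }
    out
  }
  ## V[k, S+1]: best log-prob ending at (stage k, active set S)
  V <- matrix(-Inf, K, nS)
  for (k in seq_len(K)) {
    V[k, ] <- -log(K) + sum_over(TRUE, pc$lpi1[k, ]) +
              sum_over(FALSE, pc$lpi0[k, ]) + B[1, ]
  }
  back <- vector("list", T_)   # back[[t]]: K x nS matrix of packed (k,S) predecessors
  if (all(!is.finite(V))) stop("zero-probability evidence at slice 1")

  if (T_ > 1) for (t in 2:T_) {
    d <- dti[t - 1]
    lon <- pc$lon[[d]]; loff <- pc$loff[[d]]
    logP <- pc$logP[[d]]
    Vnew <- matrix(-Inf, K, nS)
    bk <- matrix(NA_integer_, K, nS)
    for (k2 in seq_len(K)) {
      ## for each predecessor stage k, max over predecessor subsets S of
      ## V[k, S] + sum_{w added} lon[k2, w]  (weighted superset transform)
      best_val <- rep(-Inf, nS); best_k <- rep(NA_integer_, nS)
      best_from <- rep(NA_integer_, nS)
      for (k in seq_len(k2)) {
        if (!is.finite(logP[k, k2])) next
        U <- V[k, ] + logP[k, k2]
        from <- 0:(nS - 1)
        for (w in seq_len(W)) {
          has <- which(Smask[, w]) # subsets (1-based) containing w
          cand <- U[has - 2^(w - 1)] + lon[k2, w]
          upd <- cand > U[has]
          U[has[upd]] <- cand[upd]
          from[has[upd]] <- from[has - 2^(w - 1)][upd]
        }
        upd <- U > best_val
        best_val[upd] <- U[upd]
        best_k[upd] <- k
        best_from[upd] <- from[upd]
      }
      Vnew[k2, ] <- best_val + sum_over(FALSE, loff[k2, ]) + B[t, ]
      bk[k2, ] <- best_k * nS + best_from   # pack predecessor (k, S)
    }
    V <- Vnew
    back[[t]] <- bk
    if (all(!is.finite(V))) stop("zero-probability evidence at slice ", t)
  }

  ## backtrace (row-major scan prefers earlier stages, then earlier onsets:
  ## subsets with more/earlier-indexed active bits come first via ordering)
  pick <- which(V == max(V), arr.ind = TRUE)
  pick <- pick[order(pick[, 1], -pick[, 2]), , drop = FALSE][1, ]
  k_cur <- pick[["row"]]; S_cur <- pick[["col"]] - 1L
  stages <- integer(T_); sets <- integer(T_)
  stages[T_] <- k_cur; sets[T_] <- S_cur
  if (T_ > 1) for (t in T_:2) {
    packed <- back[[t]][k_cur, S_cur + 1]
    k_cur <- packed %/% nS; S_cur <- packed %% nS
    stages[t - 1] <- k_cur; sets[t - 1] <- S_cur
  }
  active <- t(vapply(sets, function(S) bit_active(S, W), logical(W)))
  if (W == 1) active <- matrix(active, ncol = 1)
  new_trajectory(history, stages, active, logp = max(V))
}

new_trajectory <- function(history, stages, active, logp = NA_real_) {
  onset <- apply(active, 2, function(a) if (any(a)) which(a)[1] else NA_integer_)
  structure(list(patient_id = history$patient_id, year = history$year,
                 stage = as.integer(stages), active = active,
                 onset_slice = as.integer(onset), logp = logp),
            class = "latent_trajectory")
}

#' @export
print.latent_trajectory <- function(x, ...) {
  cat("MAP latent trajectory for patient", x$patient_id, "\n")
  for (t in seq_along(x$year)) {
    act <- which(x$active[t, ])
    cat(sprintf("  year %2d: stage %s (%d)  complications {%s}\n",
                x$year[t], utils::as.roman(x$stage[t]), x$stage[t],
                paste(act, collapse = ",")))
  }
  if (!is.null(x$forecast)) {
    f <- x$forecast
    ent <- which(!is.na(f$stage_entry))
    if (length(ent)) cat("  forecast stage entries:",
      paste(sprintf("stage %d in year %d", ent, f$stage_entry[ent]),
            collapse = "; "), "\n")
    on <- which(!is.na(f$onset_year))
    if (length(on)) cat("  forecast complication onsets:",
      paste(sprintf("w%d in year %d", on, f$onset_year[on]),
            collapse = "; "), "\n")
  }
  invisible(x)
}

#' Exhaustive-enumeration MAP oracle
#'
#' Enumerates every monotone (stage sequence, onset-time vector) assignment
#' and returns the maximiser of the same joint log-probability as
#' [map_trajectory()], breaking ties toward the lexicographically smallest
#' stage sequence, then the smallest onset-time vector.  Guarded to at most
#' one million configurations — a test oracle, not a production path.
#'
#' @param history a \code{patient_history}.
#' @param model a \code{progression_model}.
#' @return a \code{latent_trajectory}.
#' @export
brute_force_map <- function(history, model) {
  K <- model$K; W <- model$W
  T_ <- length(history$year)
  dts <- diff(history$year)
  n_stage_seqs <- choose(T_ + K - 1, K - 1)
  if (n_stage_seqs * (T_ + 1)^W > 1e6) {
    stop("brute_force_map: more than 1e6 configurations")
  }
  pc <- precompute_params(model, dts)
  dti <- dt_index(pc, dts)
  B <- obs_table(history$findings, model)

  stage_seqs <- monotone_sequences(K, T_)
  ## all onset-time vectors (column w = tau_w; T_+1 encodes "never"),
  ## ordered lexicographically by (tau_1, tau_2, ...)
  taus <- as.matrix(expand.grid(replicate(W, 1:(T_ + 1), simplify = FALSE)))
  dimnames(taus) <- NULL
  taus <- taus[do.call(order, as.data.frame(taus)), , drop = FALSE]

  best <- -Inf; best_s <- NULL; best_tau <- NULL
  for (si in seq_len(nrow(stage_seqs))) {
    s <- stage_seqs[si, ]
    for (ti in seq_len(nrow(taus))) {
      tau <- taus[ti, ]
      lp <- -log(K)
      if (T_ > 1) for (t in 2:T_) {
        lp <- lp + pc$logP[[dti[t - 1]]][s[t - 1], s[t]]
      }
      for (w in seq_len(W)) {
        if (tau[w] == 1) lp <- lp + pc$lpi1[s[1], w]
        else {
          lp <- lp + pc$lpi0[s[1], w]
          if (T_ > 1 && tau[w] > 2) for (t in 2:min(tau[w] - 1, T_)) {
            lp <- lp + pc$loff[[dti[t - 1]]][s[t], w]
          }
          if (tau[w] <= T_) {
            lp <- lp + pc$lon[[dti[tau[w] - 1]]][s[tau[w]], w]
          }
        }
      }
      for (t in seq_len(T_)) {
        S <- sum(2^(which(tau <= t) - 1))
        lp <- lp + B[t, S + 1]
      }
      if (lp > best) { best <- lp; best_s <- s; best_tau <- tau }
    }
  }
  if (!is.finite(best)) stop("zero-probability evidence under the model")
  active <- outer(seq_len(T_), best_tau, ">=")
  new_trajectory(history, best_s, active, logp = best)
}

monotone_sequences <- function(K, T_) {
  if (T_ == 1) return(matrix(seq_len(K), ncol = 1))
  prev <- monotone_sequences(K, T_ - 1)
  out <- list()
  for (i in seq_len(nrow(prev))) {
    for (k in prev[i, T_ - 1]:K) out[[length(out) + 1]] <- c(prev[i, ], k)
  }
  do.call(rbind, out)
}

#' Forward forecast from a MAP trajectory
#'
#' From the last inferred stage and active set, projects the stage forward
#' through the interval transition matrices and reports, per future year,
#' the smallest stage whose cumulative probability of having been reached
#' is at least \code{threshold} (a forward-only chain makes this path
#' nondecreasing), plus for each still-inactive complication the first year
#' its cumulative onset probability along that stage path exceeds
#' \code{threshold}.
#'
#' @param trajectory a \code{latent_trajectory} from [map_trajectory()].
#' @param model a \code{progression_model}.
#' @param horizon_years number of years to project (> 0).
#' @param threshold cumulative-probability threshold for calling a
#'   predicted stage entry or complication onset (default 0.5).
#' @return the trajectory with a \code{forecast} element: \code{years}
#'   (offsets 1..horizon), \code{stage} (projected stage per year),
#'   \code{stage_entry} (length-K first projected entry year, \code{NA} if
#'   not within the horizon) and \code{onset_year} (length-W, \code{NA}
#'   likewise; already-active complications are \code{NA}).
#' @export
forecast <- function(trajectory, model, horizon_years, threshold = 0.5) {
  if (horizon_years <= 0) stop("horizon_years must be positive")
  K <- model$K; W <- model$W
  T_ <- length(trajectory$year)
  k0 <- trajectory$stage[T_]
  act0 <- trajectory$active[T_, ]
  eps <- 1e-9
  years <- seq_len(horizon_years)
  stage_path <- integer(horizon_years)
  for (y in years) {
    P <- stage_transition_matrix(model$Q, y)[k0, ]
    tail_p <- rev(cumsum(rev(P)))          # P(stage >= s)
    stage_path[y] <- max(which(tail_p >= threshold - eps))
  }
  stage_path <- cummax(stage_path)
  stage_entry <- rep(NA_integer_, K)
  for (s in seq_len(K)) {
    hit <- which(stage_path >= s)
    if (s > k0 && length(hit)) stage_entry[s] <- hit[1]
  }
  onset_year <- rep(NA_integer_, W)
  for (w in seq_len(W)) {
    if (act0[w]) next
    surv <- cumprod(1 - model$h_onset[stage_path, w])
    hit <- which(1 - surv >= threshold - eps)
    if (length(hit)) onset_year[w] <- hit[1]
  }
  trajectory$forecast <- list(years = years, stage = stage_path,
                              stage_entry = stage_entry,
                              onset_year = onset_year,
                              threshold = threshold)
  trajectory
}

#' Posterior complication activation probabilities
#'
#' Monte Carlo posterior marginals of each complication's activity at each
#' slice, from Gibbs sweeps over stages and onset times at fixed model
#' parameters.
#'
#' @param history a \code{patient_history}.
#' @param model a \code{progression_model}.
#' @param n_samples number of retained sweeps (>= 1).
#' @param seed integer seed.
#' @param burn_in discarded initial sweeps (default 100).
#' @return \code{T x W} matrix of activation probabilities.
#' @export
posterior_complication_probs <- function(history, model, n_samples,
                                         seed = 1, burn_in = 100) {
  stopifnot(n_samples >= 1)
  set.seed(seed)
  T_ <- length(history$year)
  dts <- diff(history$year)
  pc <- precompute_params(model, dts)
  dti <- dt_index(pc, dts)
  pos_nn <- pos_in_mask(history$findings, model$mask)
  active <- matrix(FALSE, T_, model$W)
  acc <- matrix(0, T_, model$W)
  for (s in seq_len(burn_in + n_samples)) {
    st <- sample_stages_(active, dti, model$K, pc)
    cs <- sample_complications_(pos_nn, st, active, dti, model, pc)
    active <- cs$active
    if (s > burn_in) acc <- acc + active
  }
  acc / n_samples
}

#' Predict method for fitted progression models
#'
#' MAP trajectory inference (and optional forward forecast) for new
#' patient histories under the fitted model.
#'
#' @param object a \code{progression_fit}.
#' @param newdata a \code{patient_history} or list of them.
#' @param horizon_years if positive, attach a [forecast()] to each
#'   trajectory (default 0: no forecast).
#' @param ... unused.
#' @return a \code{latent_trajectory} (or list of them).
#' @export
predict.progression_fit <- function(object, newdata, horizon_years = 0, ...) {
  one <- function(h) {
    tr <- map_trajectory(h, object$model)
    if (horizon_years > 0) tr <- forecast(tr, object$model, horizon_years)
    tr
  }
  if (inherits(newdata, "patient_history")) one(newdata)
  else lapply(newdata, one)
}
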