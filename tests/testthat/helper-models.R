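## Shared fixtures: random valid models, random histories, and hand-built
## synthetic patients for the cohort analytics.

rand_model <- function(K = 3, W = 2, N = 4, anchors = NULL) {
  vocab <- paste0("F", seq_len(N))
  Q <- matrix(0, K, K)
  for (i in seq_len(K - 1)) for (j in (i + 1):K) Q[i, j] <- stats::runif(1, 0.05, 0.5)
  diag(Q) <- -rowSums(Q)
  mask <- if (is.null(anchors)) NULL
          else make_connectivity_mask(anchors, prognet:::new_vocabulary(vocab), W)
  A <- matrix(stats::runif(W * N, 0.1, 0.9), W, N)
  if (!is.null(mask)) A[!mask] <- 0
  progression_model(K, W, vocab,
                    Q = Q,
                    pi_onset = matrix(stats::runif(K * W, 0.05, 0.6), K, W),
                    h_onset = matrix(stats::runif(K * W, 0.05, 0.5), K, W),
                    A = A,
                    leak = stats::runif(N, 0.02, 0.4),
                    mask = mask, anchors = anchors)
}

rand_history <- function(T_ = 3, N = 4, p = 0.4, id = "p1") {
  patient_history(id, 0:(T_ - 1),
                  lapply(seq_len(T_), function(t) which(stats::runif(N) < p)))
}

## Minimal synthetic patient carrying only the latent trajectory, for the
## retrospective analytics (which do not look at encounters).
latent_patient <- function(entry_time, onset_year, end_time) {
  structure(list(entry_time = entry_time, onset_year = onset_year,
                 end_time = end_time,
                 year = integer(0), stage = integer(0), findings = list()),
            class = "synthetic_patient")
}

latent_cohort <- function(patients, K, W) {
  structure(patients, class = "synthetic_cohort", K = K, W = W)
}

## A small two-stage model whose quantities are all hand-computable.
toy2_model <- function() {
  progression_model(2, 1, c("F1", "F2"),
                    Q = matrix(c(-0.4, 0.4, 0, 0), 2, 2, byrow = TRUE),
                    pi_onset = matrix(c(0.1, 0.5), 2, 1),
                    h_onset = matrix(c(0.2, 0.4), 2, 1),
                    A = matrix(c(0.6, 0.3), 1, 2),
                    leak = c(0.1, 0.2))
}
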