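## The three-layer generative progression model: parameter container,
## validation, and single-step probability computations.

#' Construct a progression model
#'
#' Container for all learnable parameters of the three layers:
#' \describe{
#'   \item{Q}{\code{K x K} stage intensity matrix (per year) of the
#'     forward-only continuous-time jump process: off-diagonal entries are
#'     nonnegative only above the diagonal, rows sum to zero, and the last
#'     row is zero (stage \code{K} is absorbing).}
#'   \item{pi_onset}{\code{K x W} probability that complication \code{w} is
#'     already active at a patient's first encounter given stage \code{k}.}
#'   \item{h_onset}{\code{K x W} per-year onset probability of an inactive
#'     complication while the patient is in stage \code{k}.}
#'   \item{A}{\code{W x N} noisy-or activation probabilities, zero wherever
#'     the connectivity mask forbids the link.}
#'   \item{leak}{length-\code{N} leak probability of each finding firing
#'     with no active complication parent.}
#' }
#'
#' @param K,W number of stages and complications.
#' @param vocabulary \code{finding_vocabulary} of the N findings.
#' @param Q,pi_onset,h_onset,A,leak parameter arrays as described above.
#' @param mask \code{W x N} logical connectivity mask (default: from
#'   \code{anchors}, or fully connected).
#' @param anchors optional \code{anchor_set} used to build \code{mask} and
#'   kept for labelling.
#' @return object of class \code{progression_model}.
#' @export
progression_model <- function(K, W, vocabulary, Q, pi_onset, h_onset, A, leak,
                              mask = NULL, anchors = NULL) {
  N <- length(vocabulary)
  if (is.null(mask)) {
    mask <- if (is.null(anchors)) matrix(TRUE, W, N)
            else make_connectivity_mask(anchors, vocabulary, W)
  }
  m <- structure(list(K = as.integer(K), W = as.integer(W), N = as.integer(N),
                      vocabulary = new_vocabulary(as.character(vocabulary)),
                      Q = Q, pi_onset = pi_onset, h_onset = h_onset,
                      A = A, leak = leak, mask = mask, anchors = anchors),
                 class = "progression_model")
  v <- validate_model(m)
  if (length(v)) stop("invalid progression model:\n  ", paste(v, collapse = "\n  "))
  m
}

#' Validate a progression model
#'
#' Checks every structural invariant of the parameter container and returns
#' the violations found (an empty character vector for a valid model).
#'
#' @param model a \code{progression_model} (or a bare list with its fields).
#' @return character vector of violation messages, empty if valid.
#' @export
validate_model <- function(model) {
  v <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) v <<- c(v, msg)
  K <- model$K; W <- model$W; N <- model$N
  chk(K >= 2, "K must be >= 2")
  chk(W >= 1, "W must be >= 1")
  chk(N >= 1, "N must be >= 1")
  Q <- model$Q
  chk(is.matrix(Q) && all(dim(Q) == c(K, K)), "Q must be K x K")
  if (is.matrix(Q) && all(dim(Q) == c(K, K))) {
    lower <- Q[lower.tri(Q)]
    chk(all(lower == 0), "Q: lower-triangle entries must be 0 (forward-only)")
    chk(all(Q[upper.tri(Q)] >= 0), "Q: off-diagonal rates must be >= 0")
    chk(max(abs(rowSums(Q))) < 1e-8, "Q: rows must sum to 0")
    chk(all(Q[K, ] == 0), "Q: last row must be 0 (stage K absorbing)")
  }
  for (nm in c("pi_onset", "h_onset")) {
    P <- model[[nm]]
    chk(is.matrix(P) && all(dim(P) == c(K, W)), paste(nm, "must be K x W"))
    if (is.numeric(P)) chk(all(P >= 0 & P <= 1), paste(nm, "entries must lie in [0,1]"))
  }
  A <- model$A; mask <- model$mask
  chk(is.matrix(A) && all(dim(A) == c(W, N)), "A must be W x N")
  chk(is.matrix(mask) && all(dim(mask) == c(W, N)), "mask must be W x N")
  if (is.matrix(A)) chk(all(A >= 0 & A <= 1), "A entries must lie in [0,1]")
  if (is.matrix(A) && is.matrix(mask) && all(dim(A) == dim(mask))) {
    off <- which(!mask & A != 0, arr.ind = TRUE)
    for (i in seq_len(nrow(off))) {
      v <- c(v, sprintf("A[%d,%d] nonzero where mask forbids the link",
                        off[i, 1], off[i, 2]))
    }
    chk(all(colSums(mask) >= 1), "mask: no finding may have zero allowed parents")
  }
  chk(length(model$leak) == N, "leak must have length N")
  if (is.numeric(model$leak)) chk(all(model$leak >= 0 & model$leak <= 1),
                                  "leak entries must lie in [0,1]")
  v
}

#' @export
print.progression_model <- function(x, ...) {
  cat("Three-layer progression model\n")
  cat(sprintf("  stages K = %d, complications W = %d, findings N = %d\n",
              x$K, x$W, x$N))
  nc <- sum(!x$mask)
  cat(sprintf("  activation links: %d of %d (%d pruned by anchors)\n",
              sum(x$mask), x$W * x$N, nc))
  cat(sprintf("  parameters: %d (Eq-style count), %d with free forward-only rates\n",
              count_parameters(x$K, x$W, x$N, anchored_count(x)),
              count_parameters(x$K, x$W, x$N, anchored_count(x), free = TRUE)))
  invisible(x)
}

anchored_count <- function(model) {
  b <- attr(model$mask, "anchored")
  if (is.null(b)) sum(colSums(model$mask) == 1 & model$W > 1) else length(b)
}

#' Noisy-or activation probability of one finding
#'
#' Probability that finding \code{n} is observed given the set of active
#' complications: \code{1 - (1 - leak_n) * prod_w (1 - A[w,n])} over active,
#' mask-allowed parents \code{w}.
#'
#' @param active logical length-W vector of active complications.
#' @param finding_index finding position (1-based).
#' @param model a \code{progression_model}.
#' @return probability in \code{[0, 1]}.
#' @export
noisy_or_prob <- function(active, finding_index, model) {
  par <- which(active & model$mask[, finding_index])
  1 - (1 - model$leak[finding_index]) * prod(1 - model$A[par, finding_index])
}

## Vectorised over findings: probability vector p (length N) for an active set.
noisy_or_vec <- function(active, model) {
  q <- 1 - model$leak
  for (w in which(active)) {
    f <- 1 - model$A[w, ]
    f[!model$mask[w, ]] <- 1
    q <- q * f
  }
  unname(1 - q)
}

#' Log-likelihood of one encounter's observations
#'
#' Bernoulli log-likelihood of the full binary finding vector under the
#' noisy-or layer, given the active complication set.  Returns \code{-Inf}
#' when a deterministic activation probability (0 or 1) contradicts the
#' observation.
#'
#' @param findings integer vector of observed (positive) finding indices.
#' @param active logical length-W vector of active complications.
#' @param model a \code{progression_model}.
#' @return log-probability.
#' @export
observation_log_likelihood <- function(findings, active, model) {
  p <- noisy_or_vec(active, model)
  pos <- rep(FALSE, model$N)
  pos[findings] <- TRUE
  sum(log(ifelse(pos, p, 1 - p)))
}

#' Stage transition probabilities over an interval
#'
#' Matrix exponential \code{expm(Q * dt)} of the forward-only intensity
#' matrix, computed by uniformization with the series truncated at 1e-12
#' tail mass.  Rows sum to one and the lower triangle is exactly zero.
#'
#' @param Q \code{K x K} intensity matrix (upper-triangular rates, rows sum
#'   to zero).
#' @param dt interval length in years (> 0).
#' @return \code{K x K} row-stochastic matrix.
#' @export
stage_transition_matrix <- function(Q, dt) {
  if (dt <= 0) stop("dt must be positive")
  K <- nrow(Q)
  lambda <- max(-diag(Q))
  if (lambda == 0) return(diag(K))
  M <- diag(K) + Q / lambda
  mu <- lambda * dt
  ## Poisson(mu) weights until the tail mass drops below 1e-12
  jmax <- max(10, ceiling(mu + 10 * sqrt(mu) + 30))
  while (stats::ppois(jmax, mu, lower.tail = FALSE) > 1e-12) jmax <- jmax * 2
  wts <- stats::dpois(0:jmax, mu)
  P <- wts[1] * diag(K)
  Mj <- diag(K)
  for (j in seq_len(jmax)) {
    Mj <- Mj %*% M
    P <- P + wts[j + 1] * Mj
  }
  P[lower.tri(P)] <- 0
  P <- P / rowSums(P)
  P
}

#' Interval onset probability of a complication
#'
#' Probability that an inactive complication \code{w} activates over an
#' interval of \code{dt} years spent in stage \code{k}:
#' \code{1 - (1 - h_onset[k, w])^dt}.  At a patient's first encounter the
#' initial-onset probability \code{pi_onset[k, w]} applies instead
#' (\code{first = TRUE}).
#'
#' @param w complication index.
#' @param k stage index.
#' @param dt interval in years (ignored when \code{first = TRUE}).
#' @param model a \code{progression_model}.
#' @param first if \code{TRUE} return the first-encounter initial-onset
#'   probability.
#' @return probability in \code{[0, 1]}.
#' @export
onset_prob <- function(w, k, dt, model, first = FALSE) {
  if (first) return(model$pi_onset[k, w])
  if (dt <= 0) stop("dt must be positive")
  1 - (1 - model$h_onset[k, w])^dt
}

#' Save / load a progression model as JSON
#'
#' Full-precision round-trip of dimensions, vocabulary, anchor bindings and
#' all parameter arrays in a single JSON document.
#'
#' @param model a \code{progression_model}.
#' @param path file path.
#' @export
write_model <- function(model, path) {
  anchors <- model$anchors
  doc <- list(
    K = model$K, W = model$W, N = model$N,
    vocabulary = as.character(model$vocabulary),
    anchors = if (is.null(anchors)) NULL else unclass(anchors),
    Q = model$Q, pi_onset = model$pi_onset, h_onset = model$h_onset,
    A = model$A, leak = model$leak)
  ## I(17) significant digits: doubles survive the round trip bit-exactly
  jsonlite::write_json(doc, path, digits = I(17), auto_unbox = TRUE,
                       matrix = "rowmajor", null = "null")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  doc <- jsonlite::fromJSON(path)
  anchors <- if (is.null(doc$anchors)) NULL else anchor_set(doc$anchors)
  progression_model(
    K = doc$K, W = doc$W, vocabulary = doc$vocabulary,
    Q = matrix(doc$Q, doc$K, doc$K, byrow = FALSE),
    pi_onset = doc$pi_onset, h_onset = doc$h_onset,
    A = doc$A, leak = doc$leak, anchors = anchors)
}
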