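## Anchor prior knowledge and the pruned complication -> finding topology.

#' Construct an anchor set
#'
#' An anchor asserts that an ICD-10 code belongs to exactly one complication
#' category; in the observation network the anchored code keeps only the
#' link from its anchor complication and every other link to it is pruned.
#'
#' @param anchors a list of length \code{W}; element \code{w} is a character
#'   vector of ICD-10 codes anchored to complication \code{w} (may be
#'   empty).  Optionally named with complication labels.
#' @return object of class \code{anchor_set}.
#' @export
anchor_set <- function(anchors) {
  anchors <- lapply(anchors, as.character)
  all_codes <- unlist(anchors, use.names = FALSE)
  if (anyDuplicated(all_codes)) {
    stop("each code may be anchored to at most one complication: duplicated ",
         paste(unique(all_codes[duplicated(all_codes)]), collapse = ", "))
  }
  if (is.null(names(anchors))) {
    names(anchors) <- paste0("complication_", seq_along(anchors))
  }
  structure(anchors, class = "anchor_set")
}

#' @export
print.anchor_set <- function(x, ...) {
  cat("Anchor set:", length(x), "complications,",
      length(unlist(x)), "anchored codes\n")
  for (w in seq_along(x)) {
    cat(sprintf("  %2d %-24s %s\n", w, names(x)[w],
                paste(x[[w]], collapse = ", ")))
  }
  invisible(x)
}

#' Number of anchored codes in an anchor set
#' @param anchors an \code{anchor_set}.
#' @export
n_anchored_codes <- function(anchors) length(unlist(anchors, use.names = FALSE))

#' Read an anchor set from YAML or JSON
#'
#' The file maps complication labels to code lists, either as a top-level
#' mapping or as a list of \code{{name, codes}} records ordered by
#' complication index.
#'
#' @param path file path (\code{.yaml}/\code{.yml} or \code{.json}).
#' @return an \code{anchor_set}.
#' @export
read_anchors <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  }
  if (!is.null(raw$complications)) raw <- raw$complications
  if (all(vapply(raw, function(x) is.list(x) && !is.null(x$codes), TRUE))) {
    anchors <- lapply(raw, function(x) as.character(unlist(x$codes)))
    names(anchors) <- vapply(raw, function(x)
      as.character(x$name %||% ""), "")
  } else {
    anchors <- lapply(raw, function(x) as.character(unlist(x)))
  }
  anchor_set(anchors)
}

#' The bundled type 2 diabetes anchor settings
#'
#' Twelve complication categories with 28 expert-asserted ICD-10 anchor
#' codes (diabetes itself is category 1, anchored to E11.9, to represent
#' "no complications").
#'
#' @return an \code{anchor_set} of length 12.
#' @export
t2d_anchors <- function() {
  read_anchors(system.file("extdata", "anchors_t2d.yaml", package = "prognet",
                           mustWork = TRUE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build the pruned complication-to-finding connectivity mask
#'
#' Starting from a fully connected \code{W x N} bipartite layer, each
#' anchored code's column is pruned to the single link from its anchor
#' complication; columns of unanchored codes stay fully connected.  Anchor
#' codes absent from the vocabulary are ignored with a message (they carry
#' no observable finding).
#'
#' @param anchors an \code{anchor_set}; its length (or \code{W}) gives the
#'   number of complications.
#' @param vocabulary a \code{finding_vocabulary}.
#' @param W number of complications; defaults to \code{length(anchors)}.
#' @return \code{W x N} logical matrix of allowed links, with the bound
#'   anchor map stored in attribute \code{"anchored"} (named integer vector:
#'   code -> complication).
#' @export
make_connectivity_mask <- function(anchors, vocabulary, W = length(anchors)) {
  N <- length(vocabulary)
  if (length(anchors) > W) stop("anchor set has more complications than W")
  mask <- matrix(TRUE, nrow = W, ncol = N,
                 dimnames = list(NULL, as.character(vocabulary)))
  bound <- integer(0)
  for (w in seq_along(anchors)) {
    for (code in anchors[[w]]) {
      n <- code_index(vocabulary, code)
      if (is.na(n)) {
        message("anchor code ", code, " not in vocabulary; ignored")
        next
      }
      mask[, n] <- FALSE
      mask[w, n] <- TRUE
      bound[code] <- w
    }
  }
  structure(mask, anchored = bound)
}

#' Count model parameters
#'
#' Total parameter count of the three layers: \code{K*K} stage-transition
#' parameters, \code{2*K*W} onset parameters (an initial-onset probability
#' and a per-year onset hazard for each stage/complication pair) and
#' \code{N*W} activation parameters, minus \code{W - 1} pruned links for
#' each anchored code.
#'
#' @param K number of disease stages.
#' @param W number of complications.
#' @param N number of findings (distinct ICD-10 codes).
#' @param anchored_codes number of anchored codes (each prunes \code{W-1}
#'   activation links); default 0.
#' @param free if \code{TRUE}, count only the free stage-transition
#'   parameters of the forward-only intensity matrix (\code{K*(K-1)/2}
#'   upper-triangle rates) instead of the nominal \code{K*K}.
#' @return integer parameter count.
#' @export
count_parameters <- function(K, W, N, anchored_codes = 0, free = FALSE) {
  stopifnot(K >= 0, W >= 0, N >= 0,
            anchored_codes >= 0, anchored_codes <= N)
  stage_terms <- if (free) K * (K - 1) / 2 else K * K
  as.integer(stage_terms + 2 * (K * W) + N * W - anchored_codes * (W - 1))
}
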