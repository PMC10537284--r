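# Distribution-partition normalisation (MDN): feature planes are grouped by
# the similarity of their value histograms under KL divergence, and each
# group is divided by the Euclidean norm of all of its elements. The intent
# is to separate "visual subject" planes from "environment" planes so the
# background's contribution is rescaled relative to the dish itself.

#' Kullback-Leibler divergence between two histograms
#'
#' Computes \eqn{KL(P\|Q) = \sum_x P(x)\,\ln(P(x)/Q(x))} in nats. Terms with
#' `P(x) = 0` contribute zero. If `Q` is zero anywhere `P` is positive, `Q`
#' is additively smoothed by `eps` and renormalised before the sum, so the
#' divergence is always finite.
#'
#' @param P,Q Numeric probability vectors of equal length (nonnegative,
#'   summing to 1 within 1e-9).
#' @param eps Additive smoothing used only when supports are disjoint.
#' @return A nonnegative scalar (nats).
#' @examples
#' kl_divergence(c(1, 0), c(0.5, 0.5))  # log(2)
#' @export
kl_divergence <- function(P, Q, eps = 1e-8) {
  if (length(P) != length(Q))
    dimension_error(sprintf("distribution lengths differ: %d vs %d", length(P), length(Q)))
  .check_distribution(P, "P"); .check_distribution(Q, "Q")
  pos <- P > 0
  if (any(Q[pos] == 0)) {
    Q <- Q + eps
    Q <- Q / sum(Q)
  }
  sum(P[pos] * log(P[pos] / Q[pos]))
}

.check_distribution <- function(p, name) {
  if (any(p < 0))
    validation_error(sprintf("%s has negative entries", name))
  if (abs(sum(p) - 1) > 1e-9)
    validation_error(sprintf("%s must sum to 1 (got %.12f)", name, sum(p)))
  invisible(p)
}

#' Histogram of a feature plane
#'
#' Bins a plane's values into `B` equal-width bins spanning its min-max range
#' and normalises the counts to a probability vector. A constant plane puts
#' all mass in its single occupied bin.
#'
#' @param plane A nonempty numeric matrix or vector.
#' @param B Number of bins (at least 1).
#' @return A length-`B` probability vector.
#' @export
plane_histogram <- function(plane, B = 32L) {
  if (!is.numeric(B) || B < 1) config_error("bin count B must be at least 1")
  B <- as.integer(B)
  v <- as.numeric(plane)
  if (length(v) == 0L) validation_error("plane must be nonempty")
  .hist_on_range(v, B, min(v), max(v))
}

.hist_on_range <- function(v, B, lo, hi) {
  if (hi <= lo) {
    out <- numeric(B); out[1L] <- 1
    return(out)
  }
  bin <- pmin(floor((v - lo) / (hi - lo) * B) + 1L, B)
  tabulate(bin, nbins = B) / length(v)
}

# Smoothed histogram used for KL comparisons between planes. Bins span the
# whole tensor's value range (not the plane's own), so planes concentrated
# at different levels — e.g. a dim background plane and a bright subject
# plane — produce distinguishable distributions.
.smoothed_hist <- function(v, B, lo, hi, eps = 1e-8) {
  p <- .hist_on_range(v, B, lo, hi) + eps
  p / sum(p)
}

#' Partition feature planes by distributional similarity
#'
#' Builds `K` reference histograms and assigns every channel plane of the
#' tensor to the reference minimising the KL divergence from the plane's own
#' histogram. For `K = 2` the references are the histograms of the planes
#' with the highest and lowest mean absolute activation (a proxy for the
#' subject/background contrast); for larger `K`, medoids are seeded at evenly
#' spaced ranks of mean absolute activation and refined by a deterministic
#' k-medoids sweep under KL. Ties break toward the lower partition index.
#'
#' @param t An `H x W x C` feature tensor (array).
#' @param K Number of partitions (1 to `C`).
#' @param B Histogram bin count.
#' @return A list of class `partition_map` with integer `assignment`
#'   (length `C`, labels in `0:(K-1)`) and `K`.
#' @export
partition_planes <- function(t, K = 2L, B = 32L) {
  if (length(dim(t)) == 3L) M <- tensor_to_tokens(t)
  else if (is.matrix(t)) M <- t
  else validation_error("partition_planes() expects an H x W x C array")
  .partition_cols(M, K, B)
}

.partition_cols <- function(M, K, B) {
  C <- ncol(M)
  K <- as.integer(K)
  if (K < 1L) config_error("K must be at least 1")
  if (K > C) config_error(sprintf("K = %d exceeds the number of planes (%d)", K, C))
  if (K == 1L)
    return(structure(list(assignment = integer(C), K = 1L), class = "partition_map"))
  lo <- min(M); hi <- max(M)
  hists <- lapply(seq_len(C), function(j) .smoothed_hist(M[, j], B, lo, hi))
  act <- colMeans(abs(M))
  ord <- order(act)                      # ascending mean |activation|
  if (K == 2L) {
    med <- c(ord[C], ord[1L])            # highest first, lowest second
  } else {
    med <- ord[round(seq(1, C, length.out = K))]
    med <- unique(med)
    while (length(med) < K) med <- c(med, setdiff(ord, med)[1L])
  }
  assign_to <- function(med) {
    D <- vapply(med, function(m) {
      vapply(hists, function(h) kl_divergence(h, hists[[m]]), numeric(1))
    }, numeric(C))
    max.col(-D, ties.method = "first")
  }
  lab <- assign_to(med)
  if (K > 2L) {
    for (it in 1:20) {
      new_med <- vapply(seq_len(K), function(k) {
        members <- which(lab == k)
        if (length(members) == 0L) return(med[k])
        cost <- vapply(members, function(m)
          sum(vapply(members, function(j) kl_divergence(hists[[j]], hists[[m]]), numeric(1))),
          numeric(1))
        members[which.min(cost)]
      }, integer(1))
      if (all(new_med == med)) break
      med <- new_med
      lab <- assign_to(med)
    }
  }
  structure(list(assignment = lab - 1L, K = K), class = "partition_map")
}

#' Divide each partition by its Euclidean norm
#'
#' Every element of the tensor is divided by
#' \eqn{\mathrm{norm}(x) = \sqrt{x_1^2 + \dots + x_n^2}} taken over all
#' elements of the partition its plane belongs to, so each nonzero partition
#' leaves with unit Euclidean norm. Zero-norm partitions pass through
#' unchanged.
#'
#' @param t An `H x W x C` feature tensor (array) or an `(H*W) x C` matrix.
#' @param pm A `partition_map` from [partition_planes()] covering all planes.
#' @return The normalised tensor, same shape and type as the input.
#' @export
mdn_normalize <- function(t, pm) {
  is_arr <- length(dim(t)) == 3L
  M <- if (is_arr) tensor_to_tokens(t) else t
  if (length(pm$assignment) != ncol(M))
    dimension_error("partition map does not cover all planes of the tensor")
  out <- .mdn_forward(M, pm$assignment)$Y
  if (is_arr) array(out, dim(t)) else out
}

.mdn_forward <- function(M, assignment) {
  norms <- numeric(max(assignment) + 1L)
  Y <- M
  for (k in sort(unique(assignment))) {
    cols <- which(assignment == k)
    L <- sqrt(sum(M[, cols]^2))
    norms[k + 1L] <- L
    if (L > 0) Y[, cols] <- M[, cols] / L
  }
  list(Y = Y, norms = norms)
}

# Gradient of the norm division; the plane-to-partition routing is treated
# as a constant of the forward pass.
.mdn_backward <- function(dY, M, assignment, norms) {
  dX <- dY
  for (k in sort(unique(assignment))) {
    cols <- which(assignment == k)
    L <- norms[k + 1L]
    if (L > 0) {
      x <- M[, cols]; g <- dY[, cols]
      dX[, cols] <- g / L - x * (sum(g * x) / L^3)
    }
  }
  dX
}
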