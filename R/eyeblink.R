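#' PCA + ICA decomposition of one recording block
#'
#' Concatenates a block's (baseline-corrected) epochs into a continuous
#' `C x N` array, reduces it to `k` principal components, and unmixes those
#' with symmetric fixed-point ICA (tanh contrast). Reconstruction from all
#' components reproduces the rank-`k` PCA approximation of the input.
#' Deterministic given `seed`; component signs are fixed so each column of
#' the mixing matrix has a positive entry of largest magnitude, and
#' components are ordered by explained variance.
#'
#' @param recording an [epoched_recording].
#' @param block block index to decompose.
#' @param k number of components (default 10).
#' @param seed seed for the ICA initialisation.
#' @param max_iter,tol fixed-point iteration controls.
#' @return List of class `decomposition`: `mixing` (`C x k` channel
#'   weights), `activations` (`k x N` component time courses), `block`,
#'   `epochs` (epoch indices concatenated), `T` (samples per epoch),
#'   `channels`, `periocular`, `fs`, `center` (per-channel means removed).
#' @export
decompose_block <- function(recording, block = 1, k = 10, seed = 1,
                      max_iter = 200, tol = 1e-6) {
  eps <- which(recording$block_of == block)
  if (!length(eps)) stop("no epochs in block ", block)
  C <- n_channels(recording); T <- n_samples(recording)
  # time-contiguous concatenation: epoch 1 samples 1..T, epoch 2, ...
  X <- matrix(aperm(recording$data[, eps, , drop = FALSE], c(1, 3, 2)),
              C, length(eps) * T)
  if (ncol(X) <= C) stop("block too short: need more samples than channels")
  ctr <- rowMeans(X)
  X <- X - ctr
  cv <- tcrossprod(X) / ncol(X)
  eg <- eigen(cv, symmetric = TRUE)
  if (k > C || eg$values[k] <= eg$values[1] * 1e-12)
    stop("data rank below ", k, " components; choose a lower k")
  U <- eg$vectors[, seq_len(k), drop = FALSE]
  D <- eg$values[seq_len(k)]
  Y <- crossprod(U, X) / sqrt(D)       # whitened k x N scores
  # estimate W on a deterministic subsample of columns (plenty for a k x k
  # rotation), then apply to the full data
  sub <- if (ncol(Y) > 50000) Y[, seq(1, ncol(Y), length.out = 50000)] else Y
  W <- with_seed(seed, fastica_symmetric(sub, max_iter = max_iter, tol = tol))
  A <- W %*% Y                          # source activations, k x N
  mixing <- U %*% (sqrt(D) * t(W))      # channel-space patterns, C x k
  # canonical sign and variance ordering
  for (j in seq_len(k)) {
    s <- sign(mixing[which.max(abs(mixing[, j])), j])
    if (s < 0) { mixing[, j] <- -mixing[, j]; A[j, ] <- -A[j, ] }
  }
  ord <- order(colSums(mixing^2) * rowMeans(A^2), decreasing = TRUE)
  structure(list(mixing = mixing[, ord, drop = FALSE],
                 activations = A[ord, , drop = FALSE],
                 block = block, epochs = eps, T = T,
                 channels = recording$channels,
                 periocular = recording$periocular,
                 fs = recording$fs, center = ctr),
            class = "decomposition")
}

# Symmetric fixed-point ICA on whitened k x N data; returns orthonormal
# unmixing matrix W (sources = W %*% Y). tanh contrast.
fastica_symmetric <- function(Y, max_iter = 200, tol = 1e-8) {
  k <- nrow(Y); N <- ncol(Y)
  orth <- function(M) {
    s <- svd(M)
    s$u %*% t(s$v)
  }
  W <- orth(matrix(rnorm(k * k), k, k))
  for (it in seq_len(max_iter)) {
    G <- tanh(W %*% Y)
    W1 <- G %*% t(Y) / N - diag(rowMeans(1 - G^2)) %*% W
    W1 <- orth(W1)
    conv <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (conv < tol) break
  }
  W
}

#' @exportS3Method print decomposition
print.decomposition <- function(x, ...) {
  cat(sprintf("<decomposition> block %d: %d components over %d channels x %d samples\n",
              x$block, ncol(x$mixing), nrow(x$mixing), ncol(x$activations)))
  invisible(x)
}

# Fraction of activation power below f_hi Hz.
low_freq_fraction <- function(a, fs, f_hi = 5) {
  n <- length(a)
  pw <- Mod(fft(a - mean(a)))^2
  half <- pw[seq_len(floor(n / 2))]
  if (sum(half) == 0) return(0)
  freqs <- (seq_along(half) - 1) * fs / n
  sum(half[freqs < f_hi]) / sum(half)
}

#' Score components for blink likeness
#'
#' Blink components load heavily on the periocular sites: the score is the
#' mean absolute mixing weight over the flagged periocular channels divided
#' by the mean over all channels (1 = no frontal preference). The score is
#' scale-free, so on low channel counts a chance-frontal noise component
#' can land within sampling error of the true blink component: scores
#' within `tie_tol` (relative) of the maximum are treated as tied and
#' ordered by the low-frequency (< 5 Hz) power fraction of the activation,
#' where the slow blink lobe dominates.
#'
#' @param dec a [decompose_block()] result.
#' @param tie_tol relative score band treated as a tie at the top.
#' @return Data frame ranked by descending blink likeness: `component`,
#'   `score`, `lf_power`.
#' @export
score_blink_components <- function(dec, tie_tol = 0.1) {
  if (!length(dec$periocular)) stop("no periocular channels flagged in montage")
  peri <- match(dec$periocular, dec$channels)
  absw <- abs(dec$mixing)
  denom <- colMeans(absw)
  denom[denom == 0] <- 1
  score <- colMeans(absw[peri, , drop = FALSE]) / denom
  lf <- apply(dec$activations, 1, low_freq_fraction, fs = dec$fs)
  out <- data.frame(component = seq_len(ncol(dec$mixing)), score = score,
                    lf_power = lf)
  out <- out[order(-out$score, -out$lf_power), , drop = FALSE]
  tied <- out$score >= (1 - tie_tol) * out$score[1]
  out[tied, ] <- out[tied, , drop = FALSE][order(-out$lf_power[tied],
                                                 -out$score[tied]), ]
  out
}

#' Subtract blink components from a recording block
#'
#' Reconstructs the block with the contributions of up to `k_max`
#' top-scoring blink components removed; only components whose periocular
#' score exceeds `score_min` are touched, so blink-free data pass through
#' (nearly) unchanged. Non-blink components are untouched.
#'
#' @param recording the [epoched_recording] the decomposition came from.
#' @param dec a [decompose_block()] result for one of its blocks.
#' @param k_max maximum number of components to subtract (>= 0).
#' @param score_min periocular-score floor for a component to qualify.
#' @return The [epoched_recording] with the selected components removed
#'   from that block.
#' @export
remove_blinks <- function(recording, dec, k_max = 2, score_min = 1.5) {
  if (k_max < 0) stop("k_max must be >= 0")
  if (k_max == 0) return(recording)
  ranked <- score_blink_components(dec)
  pick <- ranked$component[ranked$score > score_min]
  pick <- head(pick, k_max)
  if (!length(pick)) return(recording)
  contrib <- dec$mixing[, pick, drop = FALSE] %*%
    dec$activations[pick, , drop = FALSE]
  C <- n_channels(recording)
  E_b <- length(dec$epochs)
  X <- matrix(aperm(recording$data[, dec$epochs, , drop = FALSE], c(1, 3, 2)),
              C, E_b * dec$T)
  recording$data[, dec$epochs, ] <- aperm(array(X - contrib,
                                                c(C, dec$T, E_b)), c(1, 3, 2))
  recording
}

#' Flag blink epochs and count blink frequency
#'
#' Zero-means the selected blink component's activation across the
#' subject's data, sets a subject-specific threshold of `sd_multiplier`
#' standard deviations, and flags an epoch as containing a blink when the
#' activation within it exceeds the threshold at any sample. The component
#' defaults to the top of the blink-likeness ranking; pass `component` to
#' reproduce a manual choice.
#'
#' @param recording the [epoched_recording] the decomposition came from.
#' @param dec a [decompose_block()] result.
#' @param sd_multiplier threshold in SD units.
#' @param component optional component index override.
#' @return List of class `blink_count`: `flagged` (logical per epoch of the
#'   block), `n_blinks`, `frequency` (flagged / total epochs), `component`,
#'   `threshold`.
#' @export
count_blinks <- function(recording, dec, sd_multiplier = 3,
                         component = NULL) {
  if (is.null(component))
    component <- score_blink_components(dec)$component[1]
  a <- dec$activations[component, ]
  a <- a - mean(a)
  s <- sd(a)
  if (!is.finite(s) || s == 0) {
    warning("blink component activation has zero variance; no blinks counted")
    flagged <- rep(FALSE, length(dec$epochs))
  } else {
    thr <- sd_multiplier * s
    am <- matrix(a, dec$T, length(dec$epochs))
    flagged <- apply(am, 2, function(col) max(col) > thr)
  }
  structure(list(flagged = flagged, n_blinks = sum(flagged),
                 frequency = mean(flagged), component = component,
                 threshold = if (exists("thr", inherits = FALSE)) thr else NA_real_,
                 epochs = dec$epochs),
            class = "blink_count")
}

#' @exportS3Method print blink_count
print.blink_count <- function(x, ...) {
  cat(sprintf("<blink_count> %d / %d epochs flagged (frequency %.3f), component %d\n",
              x$n_blinks, length(x$flagged), x$frequency, x$component))
  invisible(x)
}

#' Per-subject blink summary across blocks
#'
#' Decomposes each block, picks the top blink-scored component per block,
#' and pools the per-epoch flags into a subject-level blink frequency.
#'
#' @param recording an [epoched_recording] (baseline-corrected recommended).
#' @param seed seed forwarded to the per-block decompositions.
#' @param k number of components per block.
#' @param sd_multiplier threshold in SD units.
#' @return List: `n_blinks`, `frequency`, `flagged_epochs` (global epoch
#'   indices), `per_block` (list of [count_blinks()] results).
#' @export
blink_summary <- function(recording, seed = 1, k = 10, sd_multiplier = 3) {
  blocks <- sort(unique(recording$block_of))
  per_block <- vector("list", length(blocks))
  flagged <- integer(0)
  for (i in seq_along(blocks)) {
    dec <- decompose_block(recording, block = blocks[i], k = k,
                     seed = derive_seed(seed, i))
    bc <- count_blinks(recording, dec, sd_multiplier = sd_multiplier)
    per_block[[i]] <- bc
    flagged <- c(flagged, dec$epochs[bc$flagged])
  }
  list(n_blinks = length(flagged),
       frequency = length(flagged) / n_epochs(recording),
       flagged_epochs = flagged, per_block = per_block)
}
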