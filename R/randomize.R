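#' Randomize the gold signal in a subtomogram
#'
#' Subtomogram averaging aligns on the gold, not the macromolecule, because
#' gold dominates the intensity.  This operator hides the gold: every voxel
#' brighter than `mu + k_sd * sigma` (statistics of *this* subtomogram, never
#' pooled) is replaced by an independent draw within one standard deviation
#' of the mean; all other voxels are untouched.  With the original
#' statistics, no output voxel exceeds the original threshold (for
#' `k_sd >= 1`), so a second pass finds nothing left to hide beyond noise.
#'
#' The replacement draw is uniform on `[mu - sigma, mu + sigma]` by default —
#' the least-assuming reading of "within one standard deviation of the mean";
#' `method = "gaussian"` draws N(mu, sigma) truncated to the same interval.
#'
#' A constant subtomogram (sigma = 0, e.g. an all-padding box) is returned
#' unchanged with a warning rather than an error, so batch runs survive.
#'
#' @param sub a [volume_grid()] with `contrast == "density_bright"`.
#' @param k_sd threshold multiplier (default 3.3).
#' @param seed integer seed; identical (input, seed) gives bit-identical
#'   output.  The caller's RNG state is left untouched.
#' @param method `"uniform"` or `"gaussian"` replacement distribution.
#' @return a `volume_grid`; attribute `n_randomized` counts replaced voxels.
#' @export
randomize_gold_signal <- function(sub, k_sd = 3.3, seed = 1,
                                  method = c("uniform", "gaussian")) {
  require_bright(sub, "randomize_gold_signal")
  method <- match.arg(method)
  mu <- mean(sub$data)
  sg <- stats::sd(sub$data)
  if (sg == 0) {
    warning("constant subtomogram (sd = 0): returned unchanged")
    attr(sub, "n_randomized") <- 0L
    return(sub)
  }
  flag <- sub$data > mu + k_sd * sg
  n <- sum(flag)
  if (n > 0) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
    repl <- if (method == "uniform") {
      stats::runif(n, mu - sg, mu + sg)
    } else {
      x <- stats::rnorm(3 * n + 10, mu, sg)
      x <- x[abs(x - mu) <= sg]
      while (length(x) < n)
        x <- c(x, Filter(function(v) abs(v - mu) <= sg,
                         stats::rnorm(2 * n, mu, sg)))
      x[seq_len(n)]
    }
    sub$data[flag] <- repl
  }
  attr(sub, "n_randomized") <- as.integer(n)
  sub
}

#' Randomize a stack of subtomograms
#'
#' Applies [randomize_gold_signal()] per box, with per-box statistics
#' ("per-particle basis") and child seed `master_seed + i - 1` for box `i`,
#' so each output depends only on its own input and position — permuting the
#' stack permutes the outputs identically.
#'
#' @param subs non-empty list of [volume_grid()] boxes.
#' @param k_sd threshold multiplier.
#' @param master_seed integer; keep below 2^31 - length(subs).
#' @param method replacement distribution, see [randomize_gold_signal()].
#' @return list of randomized boxes, each with an `n_randomized` attribute.
#' @export
randomize_stack <- function(subs, k_sd = 3.3, master_seed = 1,
                            method = c("uniform", "gaussian")) {
  if (!length(subs)) stop("empty stack")
  method <- match.arg(method)
  lapply(seq_along(subs), function(i)
    randomize_gold_signal(subs[[i]], k_sd = k_sd,
                          seed = master_seed + i - 1L, method = method))
}
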