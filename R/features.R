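# Constrained maximum-entropy feature model: patch statistics, dictionary
# selection, and cue rendering.

#' Binarize a grayscale image
#'
#' Thresholds a grayscale image into a 0/1 matrix. The default method
#' thresholds at the image median; values equal to the threshold map to 1,
#' so a constant image becomes all ones.
#'
#' @param image Numeric matrix of finite grayscale values.
#' @param method Thresholding rule: `"median"` (default) or `"mean"`.
#' @return Integer matrix of the same shape with values in `{0, 1}`.
#' @examples
#' binarize_image(matrix(c(10, 200, 200, 10), 2))
#' @export
binarize_image <- function(image, method = c("median", "mean")) {
  method <- match.arg(method)
  if (!is.matrix(image) || length(image) == 0) {
    stop("`image` must be a non-empty numeric matrix")
  }
  if (!all(is.finite(image))) stop("`image` contains non-finite values")
  thr <- switch(method, median = stats::median(image), mean = mean(image))
  out <- matrix(as.integer(image >= thr), nrow(image), ncol(image))
  out
}

#' Empirical distribution of binary patches
#'
#' Counts every `patch_side` x `patch_side` window (stride 1, no wraparound)
#' in a set of binary images and returns the empirical probability of each of
#' the `2^(patch_side^2)` possible patches. Patch codes are row-major with the
#' most-significant bit at the top-left cell.
#'
#' @param images A binary matrix or list of binary matrices (values in 0/1).
#' @param patch_side Patch side length in cells (default 3).
#' @return A `patch_distribution`: list with `patch_side`, `probs` (length
#'   `2^(patch_side^2)`), `counts`, and `total_count`.
#' @export
estimate_patch_distribution <- function(images, patch_side = 3L) {
  if (is.matrix(images)) images <- list(images)
  stopifnot(length(images) >= 1, patch_side >= 1, patch_side <= 5)
  s <- as.integer(patch_side)
  nbits <- s * s
  ncodes <- 2L^nbits
  counts <- numeric(ncodes)
  for (i in seq_along(images)) {
    img <- images[[i]]
    if (!is.matrix(img) || nrow(img) < s || ncol(img) < s) {
      stop(sprintf("image %d is smaller than the %dx%d patch", i, s, s))
    }
    if (!all(img %in% c(0, 1))) {
      stop(sprintf("image %d is not binary; run binarize_image() first", i))
    }
    nr <- nrow(img) - s + 1L
    nc <- ncol(img) - s + 1L
    code <- matrix(0, nr, nc)
    bit <- nbits
    for (r in seq_len(s)) {
      for (cc in seq_len(s)) {
        bit <- bit - 1L
        code <- code + img[r:(r + nr - 1L), cc:(cc + nc - 1L), drop = FALSE] *
          2^bit
      }
    }
    counts <- counts + tabulate(as.integer(code) + 1L, nbins = ncodes)
  }
  total <- sum(counts)
  structure(
    list(patch_side = s, probs = counts / total, counts = counts,
         total_count = total),
    class = "patch_distribution"
  )
}

#' @export
print.patch_distribution <- function(x, ...) {
  cat(sprintf(
    "Patch distribution: side %d (%d codes), %d windows, %d codes observed\n",
    x$patch_side, length(x$probs), x$total_count, sum(x$counts > 0)))
  invisible(x)
}

new_feature_dictionary <- function(patches, probs, N, W, kind, empty = FALSE) {
  structure(
    list(patches = as.integer(patches), probs = as.numeric(probs),
         N = as.integer(N), W = W, achieved_entropy = entropy_bits(probs),
         kind = kind, empty = empty),
    class = "feature_dictionary"
  )
}

#' @export
print.feature_dictionary <- function(x, ...) {
  cat(sprintf(
    "%s feature dictionary: %d patches (N = %d%s), H = %.4f bits, mass %.4f\n",
    x$kind, length(x$patches), x$N,
    if (is.null(x$W)) "" else sprintf(", W = %g", x$W),
    x$achieved_entropy, sum(x$probs)))
  invisible(x)
}

# Exact solver: branch and bound over items ordered by entropy contribution.
# Maximises H(D) = -sum p log2 p subject to |D| <= N, sum p <= W.
select_exact <- function(p, N, W) {
  h <- ifelse(p > 0, -p * log2(p), 0)
  ord <- order(h, decreasing = TRUE)
  p <- p[ord]; h <- h[ord]
  m <- length(p)
  best <- list(H = -Inf, sel = integer(0))
  # prefix sums of h for the admissible bound
  rec <- function(i, sel, mass, H) {
    if (H > best$H) best <<- list(H = H, sel = sel)
    if (i > m || length(sel) >= N) return()
    # bound: take the largest remaining h terms ignoring the mass constraint
    slots <- N - length(sel)
    rem <- h[i:m]
    ub <- H + sum(rem[seq_len(min(slots, length(rem)))])
    if (ub <= best$H + 1e-15) return()
    if (mass + p[i] <= W + 1e-12) rec(i + 1L, c(sel, i), mass + p[i], H + h[i])
    rec(i + 1L, sel, mass, H)
  }
  rec(1L, integer(0), 0, 0)
  ord[best$sel]
}

# Heuristic for large alphabets: rank by |p - W/N| ascending, greedy add,
# then pairwise swap improvement; guaranteed >= the greedy-by-entropy baseline.
select_heuristic <- function(p, N, W) {
  h <- ifelse(p > 0, -p * log2(p), 0)
  greedy_fill <- function(ord) {
    sel <- integer(0); mass <- 0
    for (i in ord) {
      if (length(sel) >= N) break
      if (mass + p[i] <= W + 1e-12) {
        sel <- c(sel, i); mass <- mass + p[i]
      }
    }
    sel
  }
  cand <- greedy_fill(order(abs(p - W / N)))
  base <- greedy_fill(order(h, decreasing = TRUE))
  improve <- function(sel) {
    repeat {
      mass <- sum(p[sel])
      out <- setdiff(which(p > 0), sel)
      gained <- FALSE
      # try to add while feasible
      if (length(sel) < N) {
        add <- out[mass + p[out] <= W + 1e-12]
        if (length(add)) {
          sel <- c(sel, add[which.max(h[add])]); gained <- TRUE
          next
        }
      }
      # pairwise swaps
      for (s_i in sel) {
        repl <- out[mass - p[s_i] + p[out] <= W + 1e-12]
        repl <- repl[h[repl] > h[s_i] + 1e-15]
        if (length(repl)) {
          u <- repl[which.max(h[repl])]
          sel <- c(setdiff(sel, s_i), u)
          gained <- TRUE
          break
        }
      }
      if (!gained) return(sel)
    }
  }
  cand <- improve(cand)
  if (sum(h[cand]) >= sum(h[base])) cand else improve(base)
}

#' Select the entropy-optimal feature dictionary
#'
#' Selects the patch set maximising the transmitted entropy
#' `H(D) = -sum_{i in D} p_i log2 p_i` subject to a dictionary-size bound
#' `|D| <= N` (limited storage) and a bandwidth bound `sum_{i in D} p_i <= W`
#' (limited output rate). Solved exactly (branch and bound) when at most 20
#' patches have positive probability, otherwise by a documented heuristic
#' (rank by `|p - W/N|`, greedy fill, local swap improvement) whose result is
#' never below the greedy-by-entropy baseline.
#'
#' @param dist A [patch_distribution][estimate_patch_distribution].
#' @param N Maximum dictionary size (default 50).
#' @param W Bandwidth bound on total selected probability mass, in (0, 1].
#' @param exact Force the exact solver (`TRUE`/`FALSE`); default chooses by
#'   alphabet size.
#' @return A `feature_dictionary` with fields `patches` (codes), `probs`, `N`,
#'   `W`, `achieved_entropy` (bits), `kind = "optimal"`, and `empty` flag.
#' @export
select_optimal_features <- function(dist, N = 50L, W = 0.05, exact = NULL) {
  stopifnot(inherits(dist, "patch_distribution"), N >= 1, W > 0, W <= 1)
  p <- dist$probs
  pos <- which(p > 0)
  if (length(pos) == 0) stop("all patch probabilities are zero")
  if (W < min(p[pos]) - 1e-15) {
    warning("bandwidth W below the smallest positive probability; ",
            "returning an empty dictionary")
    return(new_feature_dictionary(integer(0), numeric(0), N, W, "optimal",
                                  empty = TRUE))
  }
  use_exact <- exact %||% (length(pos) <= 20)
  psub <- p[pos]
  sel <- if (use_exact) select_exact(psub, N, W) else select_heuristic(psub, N, W)
  codes <- pos[sel] - 1L
  o <- order(codes)
  new_feature_dictionary(codes[o], psub[sel][o], N, W, "optimal")
}

#' Select the non-optimal (lowest-probability) feature dictionary
#'
#' Returns the `N` patches with the smallest positive probability of
#' occurrence; ties are broken by ascending patch code.
#'
#' @inheritParams select_optimal_features
#' @return A `feature_dictionary` with `kind = "nonoptimal"`.
#' @export
select_nonoptimal_features <- function(dist, N = 50L) {
  stopifnot(inherits(dist, "patch_distribution"), N >= 1)
  p <- dist$probs
  pos <- which(p > 0)
  if (length(pos) < N) {
    stop(sprintf("only %d patches have positive probability (need N = %d)",
                 length(pos), N))
  }
  ord <- pos[order(p[pos], pos)]
  sel <- sort(ord[seq_len(N)])
  new_feature_dictionary(sel - 1L, p[sel], N, NULL, "nonoptimal")
}

patch_bits <- function(patch_code, patch_side) {
  nbits <- patch_side^2
  if (patch_code < 0 || patch_code >= 2^nbits) {
    stop(sprintf("patch code %d out of range [0, %d)", patch_code, 2^nbits))
  }
  bits <- as.integer(intToBits(as.integer(patch_code)))[seq_len(nbits)]
  # intToBits is little-endian; we want MSB first (top-left, row-major)
  matrix(rev(bits), patch_side, patch_side, byrow = TRUE)
}

#' Render a patch code as a luminance cue bitmap
#'
#' Expands each patch cell to a `cell_px` x `cell_px` pixel block. Defaults
#' (`patch_side = 3`, `cell_px = 3`) produce the 9 x 9 pixel cue used in the
#' experiments, with black pixels at 4 cd/m2 and white at 44 cd/m2. Bit order
#' of the code is row-major with the most-significant bit at the top-left.
#'
#' @param patch_code Integer in `[0, 2^(patch_side^2))`.
#' @param patch_side Patch side in cells (default 3).
#' @param cell_px Pixels per cell (default 3).
#' @param lum_black,lum_white Luminances (cd/m2) for 0/1 cells.
#' @return A `cue_bitmap`: list with `pixels` (matrix, cd/m2), `side_px`,
#'   `lum_black`, `lum_white`.
#' @export
render_cue <- function(patch_code, patch_side = 3L, cell_px = 3L,
                       lum_black = 4, lum_white = 44) {
  stopifnot(cell_px >= 1)
  bits <- patch_bits(patch_code, patch_side)
  px <- kronecker(bits, matrix(1, cell_px, cell_px))
  pixels <- ifelse(px == 1, lum_white, lum_black)
  structure(
    list(pixels = pixels, side_px = patch_side * cell_px,
         lum_black = lum_black, lum_white = lum_white,
         patch_code = as.integer(patch_code)),
    class = "cue_bitmap"
  )
}

#' Render a uniform control-condition cue
#'
#' The luminance-control condition replaces structured cues by uniform grey
#' patches: 20 cd/m2 (low) and 23 cd/m2 (high) on a 16 cd/m2 background, the
#' "equivalent contrast" matched to the optimal/non-optimal saliency
#' difference.
#'
#' @param level `"low"` (20 cd/m2) or `"high"` (23 cd/m2).
#' @inheritParams render_cue
#' @return A `cue_bitmap`; the reference background luminance is stored in
#'   field `background`.
#' @export
render_control_cue <- function(level = c("low", "high"), patch_side = 3L,
                               cell_px = 3L) {
  level <- match.arg(level)
  lum <- if (level == "low") 20 else 23
  side <- patch_side * cell_px
  structure(
    list(pixels = matrix(lum, side, side), side_px = side,
         lum_black = lum, lum_white = lum, level = level, background = 16),
    class = "cue_bitmap"
  )
}

#' Mean-luminance difference between two feature dictionaries
#'
#' Renders every patch of both dictionaries and returns the absolute
#' difference of the mean cue luminances, used to verify that optimal and
#' non-optimal cue sets are luminance-balanced.
#'
#' @param setA,setB `feature_dictionary` objects.
#' @param tolerance Flagging tolerance in cd/m2 (default 0.5).
#' @inheritParams render_cue
#' @return Absolute difference in cd/m2, with attribute `balanced` (logical).
#' @export
check_luminance_balance <- function(setA, setB, tolerance = 0.5,
                                    patch_side = 3L, cell_px = 3L,
                                    lum_black = 4, lum_white = 44) {
  mean_lum <- function(d) {
    if (length(d$patches) == 0) stop("empty feature dictionary")
    mean(vapply(d$patches, function(code) {
      mean(render_cue(code, patch_side, cell_px, lum_black, lum_white)$pixels)
    }, numeric(1)))
  }
  diff <- abs(mean_lum(setA) - mean_lum(setB))
  structure(diff, balanced = diff <= tolerance)
}

#' Synthetic stand-in for natural scenes
#'
#' Generates smoothed-noise grayscale images whose binarized patch statistics
#' are non-uniform (spatially correlated), standing in for the natural-image
#' ensemble from which patch probabilities are estimated.
#'
#' @param n Number of images.
#' @param size Image side in pixels.
#' @param smoothing Box-smoothing half width in pixels (default 2).
#' @param seed Optional integer seed.
#' @return List of `size` x `size` numeric matrices in `[0, 255]`.
#' @export
simulate_natural_images <- function(n, size = 128L, smoothing = 2L,
                                    seed = NULL) {
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      z <- matrix(stats::rnorm(size^2), size, size)
      if (smoothing > 0) {
        k <- rep(1, 2 * smoothing + 1)
        sm <- function(m) {
          m <- apply(m, 2, function(col)
            stats::filter(col, k / length(k), sides = 2, circular = TRUE))
          t(apply(t(m), 2, function(col)
            stats::filter(col, k / length(k), sides = 2, circular = TRUE)))
        }
        z <- sm(z)
      }
      z <- (z - min(z)) / (max(z) - min(z)) * 255
      matrix(as.numeric(z), size, size)
    })
  })
}
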