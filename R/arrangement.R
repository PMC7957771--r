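#' Channel-by-channel Pearson correlation matrix
#'
#' Pearson correlation coefficients between all channel pairs, computed on
#' the concatenated per-channel series of the supplied recordings or signal
#' matrices.  The orderings downstream use `|rho|`; the matrix stores the
#' signed coefficients.
#'
#' @param x An `eeg_recording`, a list of them, or a channels-x-samples
#'   numeric matrix with channel rownames.
#' @return Symmetric correlation matrix with unit diagonal and channel
#'   labels as dimnames.
#' @export
correlation_matrix <- function(x) {
  m <- if (inherits(x, "eeg_recording")) x$signals
  else if (is.list(x) && all(vapply(x, inherits, TRUE, "eeg_recording")))
    do.call(cbind, lapply(x, `[[`, "signals"))
  else as.matrix(x)
  if (ncol(m) < 2) stop("need at least two samples per channel")
  sds <- apply(m, 1, sd)
  if (any(sds == 0))
    stop("zero-variance channel(s): ", paste(rownames(m)[sds == 0], collapse = ", "))
  cor(t(m))
}

#' Adjacent absolute-correlation sum of a channel order
#'
#' The objective both greedy orderings act on: the sum of `|rho|` over
#' consecutive pairs of the order.
#'
#' @param corr Correlation matrix with channel dimnames.
#' @param order Character vector, a permutation of the channel labels.
#' @return Scalar score (0 for a single channel).
#' @export
adjacent_abs_rho_sum <- function(corr, order) {
  if (length(order) < 2) return(0)
  i <- match(order, rownames(corr))
  sum(abs(corr[cbind(i[-length(i)], i[-1])]))
}

# Greedy two-ended chain construction shared by MaxCBO/MinCBO.
# objective = which.max for MaxCBO, which.min for MinCBO.
# Tie rules: seed pair = best |rho| with lexicographically smallest labels,
# oriented lexicographically; extension ties broken by lexicographic
# candidate label, then by preferring the left end.
greedy_cbo <- function(corr, maximize) {
  labels <- rownames(corr)
  n <- length(labels)
  if (n == 1) return(labels)
  a <- abs(corr); diag(a) <- NA
  better <- if (maximize) function(x, y) x > y + 1e-12 else function(x, y) x < y - 1e-12
  # seed pair
  best <- NULL; best_val <- NULL
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    pair <- sort(c(labels[i], labels[j]))
    v <- a[labels[i], labels[j]]
    if (is.null(best) || better(v, best_val) ||
        (abs(v - best_val) <= 1e-12 &&
         paste(pair, collapse = "") < paste(best, collapse = ""))) {
      best <- pair; best_val <- v
    }
  }
  chain <- best
  while (length(chain) < n) {
    unused <- setdiff(labels, chain)
    ends <- c(chain[1], chain[length(chain)])
    cand <- expand.grid(channel = unused, end = c("left", "right"),
                        stringsAsFactors = FALSE)
    cand$val <- mapply(function(ch, e)
      a[ch, if (e == "left") ends[1] else ends[2]],
      cand$channel, cand$end)
    # order candidates so the first row wins ties: by objective value, then
    # lexicographic channel label, then left end first
    ord <- order(if (maximize) -cand$val else cand$val,
                 cand$channel, cand$end != "left")
    pick <- cand[ord[1], ]
    chain <- if (pick$end == "left") c(pick$channel, chain)
    else c(chain, pick$channel)
  }
  chain
}

new_channel_order <- function(order, method, seed = NA_integer_) {
  structure(list(order = order, method = method, seed = seed),
            class = "channel_order")
}

#' @export
print.channel_order <- function(x, ...) {
  cat(sprintf("<channel_order> %s: %s\n", x$method,
              paste(x$order, collapse = " ")))
  invisible(x)
}

#' Maximal correlation-based ordering (MaxCBO)
#'
#' Greedy chain that places strongly correlated channels adjacently: start
#' from the pair with maximal `|rho|`, then repeatedly append at either chain
#' end the unused channel with the largest `|rho|` to that end.
#'
#' @param corr Correlation matrix from [correlation_matrix()].
#' @return A `channel_order` (method `"maxcbo"`).
#' @export
order_maxcbo <- function(corr) {
  new_channel_order(greedy_cbo(corr, maximize = TRUE), "maxcbo")
}

#' Minimal correlation-based ordering (MinCBO)
#'
#' As [order_maxcbo()] but picking the least `|rho|` at every step, placing
#' dissimilar channels adjacently.
#'
#' @param corr Correlation matrix from [correlation_matrix()].
#' @return A `channel_order` (method `"mincbo"`).
#' @export
order_mincbo <- function(corr) {
  new_channel_order(greedy_cbo(corr, maximize = FALSE), "mincbo")
}

#' Seeded uniform random channel order
#'
#' The benchmark ordering; the sorting-experiment protocol averages over 20
#' seeded draws.
#'
#' @param labels Channel labels to permute.
#' @param seed Integer seed.
#' @return A `channel_order` (method `"random"`) with the seed recorded.
#' @export
order_random <- function(labels, seed) {
  set.seed(seed)
  new_channel_order(sample(labels), "random", seed = as.integer(seed))
}

#' Exhaustive-search ordering oracle
#'
#' Enumerates all permutations (feasible up to 8 channels) and returns one
#' minimizing or maximizing the adjacent `|rho|` sum.  Serves as the
#' independent optimum bound the greedy orderings are tested against.
#'
#' @param corr Correlation matrix.
#' @param objective `"max"` or `"min"`.
#' @return A `channel_order` (method `"brute_max"` / `"brute_min"`).
#' @export
brute_force_order <- function(corr, objective = c("max", "min")) {
  objective <- match.arg(objective)
  labels <- rownames(corr)
  n <- length(labels)
  if (n > 8) stop("exhaustive search supported for at most 8 channels")
  if (n == 1)
    return(new_channel_order(labels, paste0("brute_", objective)))
  perms <- all_permutations(n)
  scores <- apply(perms, 1, function(p) adjacent_abs_rho_sum(corr, labels[p]))
  pick <- if (objective == "max") which.max(scores) else which.min(scores)
  new_channel_order(labels[perms[pick, ]], paste0("brute_", objective))
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (i in seq_len(nrow(sub))) for (pos in seq_len(n)) {
    r <- r + 1L
    out[r, ] <- append(sub[i, ] + 1L, 1L, after = pos - 1L)
  }
  out
}

#' Scalp-top-view 5 x 3 grid layout of the montage
#'
#' Places the 12 channels on a width-5, height-3 grid imitating the
#' electrode positions seen from above (anterior row on top, Pz centred in
#' the posterior row since the Cz reference is absent).  The three unfilled
#' cells are zero-padded in the tensor construction.
#'
#' @return A `grid_layout`: list with `width`, `height`, and a `placement`
#'   data frame (`label`, `col`, `row`; 0-based, row 0 anterior).
#' @export
default_grid_layout <- function() {
  placement <- data.frame(
    label = c("Fp1", "Fp2",
              "F7", "F3", "Fz", "F4", "F8",
              "T3", "C3", "Pz", "C4", "T4"),
    col = c(1, 3, 0, 1, 2, 3, 4, 0, 1, 2, 3, 4),
    row = c(0, 0, 1, 1, 1, 1, 1, 2, 2, 2, 2, 2)
  )
  structure(list(width = 5L, height = 3L, placement = placement),
            class = "grid_layout")
}

#' Stack a window onto the scalp grid
#'
#' Builds the 3D-input tensor for one window: filled grid cells carry the
#' corresponding channel's time series, pad cells are all zeros.
#'
#' @param window_signals 12 x T numeric matrix with channel rownames.
#' @param layout A [default_grid_layout()].
#' @return Numeric array of dimension `c(5, 3, T)` (col, row, time).
#' @export
to_grid3d <- function(window_signals, layout = default_grid_layout()) {
  pl <- layout$placement
  missing <- setdiff(pl$label, rownames(window_signals))
  if (length(missing))
    stop("window is missing channel(s): ", paste(missing, collapse = ", "))
  T_ <- ncol(window_signals)
  g <- array(0, dim = c(layout$width, layout$height, T_))
  for (i in seq_len(nrow(pl)))
    g[pl$col[i] + 1L, pl$row[i] + 1L, ] <- window_signals[pl$label[i], ]
  g
}

#' Recover the channel matrix from a grid tensor
#'
#' Inverse of [to_grid3d()] on the filled cells; used to verify the grid
#' construction is lossless.
#'
#' @param grid Array from [to_grid3d()].
#' @param layout A [default_grid_layout()].
#' @return 12 x T matrix with channel rownames.
#' @export
grid_to_channels <- function(grid, layout = default_grid_layout()) {
  pl <- layout$placement
  out <- matrix(0, nrow(pl), dim(grid)[3], dimnames = list(pl$label, NULL))
  for (i in seq_len(nrow(pl)))
    out[i, ] <- grid[pl$col[i] + 1L, pl$row[i] + 1L, ]
  out[match(eeg_channels(), rownames(out)), , drop = FALSE]
}
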