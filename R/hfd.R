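#' Higuchi fractal dimension of a time series
#'
#' Estimates the fractal complexity of a series from the scaling of
#' normalized curve lengths. For each delay `k = 1..kmax` and offset
#' `m = 1..k` the curve length is
#' \deqn{L_m(k) = \left[\sum_{i=1}^{\lfloor (N-m)/k \rfloor}
#'   |x(m+ik) - x(m+(i-1)k)|\right]\cdot
#'   \frac{N-1}{\lfloor (N-m)/k \rfloor \, k} \cdot \frac{1}{k},}
#' `L(k)` is the mean over offsets, and the dimension is the ordinary
#' least-squares slope of `ln L(k)` against `ln(1/k)` over the full range
#' `k = 1..kmax` (no subset selection). Values lie near 1 for smooth
#' signals and near 2 for uncorrelated noise. The exact normalization
#' factor matters and is kept as in the original formulation.
#'
#' A constant series has zero curve length at every delay; by convention
#' it returns dimension 1.0 with `degenerate = TRUE`.
#'
#' @param x numeric series of length N > 2 * kmax.
#' @param kmax maximum delay, default 13.
#' @return A list with `hfd` (slope), `r2` (goodness of the log-log fit)
#'   and `degenerate` flag.
#' @examples
#' higuchi_fd(seq_len(4000))$hfd # ~1
#' @export
higuchi_fd <- function(x, kmax = 13) {
  n <- length(x)
  assert_scalar_num(kmax, "kmax", lower = 2)
  kmax <- as.integer(kmax)
  if (n <= 2 * kmax) {
    abort(sprintf("series length (%d) must exceed 2 * kmax (%d)", n, 2 * kmax))
  }
  lk <- numeric(kmax)
  for (k in seq_len(kmax)) {
    lm <- numeric(k)
    for (m in seq_len(k)) {
      ni <- (n - m) %/% k
      idx <- m + (0:ni) * k
      lm[m] <- sum(abs(diff(x[idx]))) * (n - 1) / (ni * k) / k
    }
    lk[k] <- mean(lm)
  }
  if (all(lk == 0)) {
    return(list(hfd = 1.0, r2 = NA_real_, degenerate = TRUE))
  }
  lx <- log(1 / seq_len(kmax))
  ly <- log(lk)
  fit <- stats::lm.fit(cbind(1, lx), ly)
  slope <- fit$coefficients[2]
  r2 <- 1 - sum(fit$residuals^2) / sum((ly - mean(ly))^2)
  list(hfd = unname(slope), r2 = r2, degenerate = FALSE)
}

#' Per-epoch and animal-average Higuchi fractal dimension
#'
#' Computes the fractal dimension of every retained 4-s epoch of one
#' channel and the arithmetic epoch mean.
#'
#' @param epochs an [epoch_set()] of retained epochs.
#' @param channel channel label.
#' @param kmax maximum delay, default 13.
#' @return A tibble with one row per epoch: `channel`, `epoch`, `hfd`,
#'   `r2`, `degenerate`, plus attributes-free summary columns
#'   `animal_mean` and `n_epochs` repeated per row (use
#'   `dplyr::distinct(channel, animal_mean, n_epochs)` for the summary).
#' @export
hfd_animal <- function(epochs, channel, kmax = 13) {
  stopifnot(inherits(epochs, "epoch_set"))
  ci <- match(channel, epochs$channel_labels)
  if (is.na(ci)) abort(sprintf("unknown channel `%s`", channel))
  ne <- dim(epochs$epochs)[1]
  if (ne < 1) abort("at least one retained epoch is required")
  rows <- purrr::map_dfr(seq_len(ne), function(i) {
    res <- higuchi_fd(epochs$epochs[i, ci, ], kmax)
    tibble::tibble(channel = channel, epoch = epochs$index[i],
                   hfd = res$hfd, r2 = res$r2, degenerate = res$degenerate)
  })
  rows$animal_mean <- mean(rows$hfd)
  rows$n_epochs <- ne
  rows
}
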