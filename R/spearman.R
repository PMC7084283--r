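#' Spearman rank correlation with tie handling and exact small-sample p-values
#'
#' Computes the Spearman coefficient as the product-moment correlation of
#' midranks (average ranks for ties). The two-sided p-value uses the
#' t-approximation `t = rho * sqrt((n-2) / (1 - rho^2))` on `n - 2` degrees
#' of freedom for `n >= exact_n`, and an exact, deterministic full
#' permutation enumeration of the second ranking for `n < exact_n` (the
#' permutation null is valid under ties as well).
#'
#' A constant input vector leaves the coefficient undefined; the result is
#' then flagged (`undefined = TRUE`) with `NA` estimates rather than an
#' error.
#'
#' @param x,y Numeric vectors of equal length (>= 3). Incomplete pairs are
#'   dropped.
#' @param exact_n Sample-size switch point between the exact permutation
#'   p-value and the t-approximation (default 10).
#' @return An object of class `spearman_cor`: list with `rho`, `p_value`,
#'   `n`, `method` ("exact permutation" or "t approximation"), and
#'   `undefined`. [tidy()] returns it as a one-row tibble.
#' @examples
#' spearman_cor(1:8, (1:8)^2)   # rho = 1, monotone transform
#' @export
spearman_cor <- function(x, y, exact_n = 10) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  keep <- stats::complete.cases(x, y)
  x <- as.numeric(x[keep])
  y <- as.numeric(y[keep])
  n <- length(x)
  if (n < 3) abort("Need at least 3 complete pairs.")

  res <- structure(
    list(rho = NA_real_, p_value = NA_real_, n = n,
         method = NA_character_, undefined = FALSE),
    class = "spearman_cor"
  )
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    res$undefined <- TRUE
    return(res)
  }

  rx <- rank(x)
  ry <- rank(y)
  rho <- rank_pearson(rx, ry)
  res$rho <- rho

  if (n >= exact_n) {
    res$method <- "t approximation"
    if (abs(rho) >= 1) {
      res$p_value <- 0
    } else {
      tval <- rho * sqrt((n - 2) / (1 - rho^2))
      res$p_value <- 2 * pt(-abs(tval), df = n - 2)
    }
  } else {
    res$method <- "exact permutation"
    perms <- all_permutations(n)
    # rho is affine in sum(rx * ry_perm) because permuting preserves the
    # mean and spread of the ranks; compute all n! sums by one multiply.
    ry_mat <- matrix(ry[perms], nrow = nrow(perms))
    s_all <- as.vector(ry_mat %*% rx)
    denom <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
    rho_all <- (s_all - n * mean(rx) * mean(ry)) / denom
    res$p_value <- mean(abs(rho_all) >= abs(rho) - 1e-12)
  }
  res
}

rank_pearson <- function(rx, ry) {
  dx <- rx - mean(rx)
  dy <- ry - mean(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# All permutations of 1..n as an n! x n integer matrix (n <= 9 in practice).
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  blocks <- lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(rep(k, nrow(sub)),
          matrix(rest[sub], nrow = nrow(sub)))
  })
  do.call(rbind, blocks)
}

#' @export
print.spearman_cor <- function(x, ...) {
  if (x$undefined) {
    cat("Spearman rank correlation: undefined (constant input), n =", x$n, "\n")
  } else {
    cat(sprintf("Spearman rank correlation: rho = %.4f, p = %.4g (%s), n = %d\n",
                x$rho, x$p_value, x$method, x$n))
  }
  invisible(x)
}

#' @rdname spearman_cor
#' @param x A `spearman_cor` object.
#' @param ... Unused.
#' @method tidy spearman_cor
#' @export
tidy.spearman_cor <- function(x, ...) {
  tibble(rho = x$rho, p_value = x$p_value, n = x$n,
         method = x$method, undefined = x$undefined)
}

#' @rdname spearman_cor
#' @method glance spearman_cor
#' @export
glance.spearman_cor <- function(x, ...) tidy.spearman_cor(x)
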