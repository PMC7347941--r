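#' Majority (plurality) vote over per-signal predictions
#'
#' The molecular identity of a sample is the class receiving the most
#' per-signal predictions. Ties are resolved per `tie_rule`: raise an error,
#' pick lexicographically, or pick uniformly at random (seeded).
#'
#' @param labels Character vector of predicted labels (length >= 1).
#' @param tie_rule One of `"error"`, `"lexicographic"`, `"random"`.
#' @param seed Seed for `tie_rule = "random"`.
#' @return A `vote_result`: per-class `counts` tibble, `winner`, `tie` flag,
#'   `n_signals`.
#' @export
majority_vote <- function(labels, tie_rule = c("error", "lexicographic",
                                               "random"), seed = 1L) {
  tie_rule <- match.arg(tie_rule)
  if (!length(labels)) {
    stop_nanosig("majority vote needs at least one label",
      "nanosig_domain_error")
  }
  counts <- sort(table(labels), decreasing = TRUE)
  top <- names(counts)[counts == max(counts)]
  tie <- length(top) > 1
  winner <- if (!tie) {
    top
  } else {
    switch(tie_rule,
      error = stop_nanosig(
        sprintf("plurality tie between %s", paste(top, collapse = ", ")),
        "nanosig_tie_error"
      ),
      lexicographic = sort(top)[1],
      random = with_seed(seed, sample(top, 1))
    )
  }
  structure(
    list(
      counts = tibble(class = names(counts), count = as.integer(counts)),
      winner = winner, tie = tie, n_signals = length(labels)
    ),
    class = "vote_result"
  )
}

#' @export
print.vote_result <- function(x, ...) {
  cat(sprintf("<vote_result> winner: %s%s (n = %d; %s)\n",
    x$winner, if (x$tie) " [tie]" else "", x$n_signals,
    paste(x$counts$class, x$counts$count, sep = "=", collapse = ", ")))
  invisible(x)
}

#' @rdname majority_vote
#' @param x A `vote_result`.
#' @param ... Unused.
#' @method tidy vote_result
#' @export
tidy.vote_result <- function(x, ...) x$counts

#' @rdname majority_vote
#' @method glance vote_result
#' @export
glance.vote_result <- function(x, ...) {
  tibble(winner = x$winner, tie = x$tie, n_signals = x$n_signals)
}

check_simplex <- function(p, tol = 1e-9) {
  if (any(p < -tol) || abs(sum(p) - 1) > 1e-6) {
    stop_nanosig("probabilities must be non-negative and sum to 1",
      "nanosig_domain_error")
  }
  invisible(TRUE)
}

#' Exact plurality-vote accuracy under trinomial sampling
#'
#' When each of `n` independent signals is predicted as the true class with
#' probability `p[1]` and as the two competitors with `p[2]` and `p[3]`, the
#' plurality vote identifies the molecule correctly with the probability
#' returned here, computed by exact enumeration of all `(n1, n2, n3)`
#' compositions of `n` with their multinomial probabilities. Success means
#' the true-class count is strictly maximal; with `tie_credit` a k-way tie
#' at the maximum that includes the true class contributes `1/k` of its
#' probability (a random tie-break).
#'
#' @param p Probability triple `(true, other, other)` on the simplex.
#' @param n Number of aggregated signals.
#' @param tie_credit Logical; default `TRUE` (fractional credit). `FALSE`
#'   counts strict plurality wins only.
#' @return Probability in `[0, 1]`.
#' @examples
#' plurality_accuracy_exact(c(0.5, 0.3, 0.2), 20)
#' @export
plurality_accuracy_exact <- function(p, n, tie_credit = TRUE) {
  stopifnot(length(p) == 3, n >= 1)
  check_simplex(p)
  grid <- tidyr::expand_grid(n1 = 0:n, n2 = 0:n)
  grid <- filter(grid, .data$n1 + .data$n2 <= n)
  n1 <- grid$n1
  n2 <- grid$n2
  n3 <- n - n1 - n2
  logp <- lgamma(n + 1) - lgamma(n1 + 1) - lgamma(n2 + 1) - lgamma(n3 + 1) +
    xlogp(n1, p[1]) + xlogp(n2, p[2]) + xlogp(n3, p[3])
  prob <- exp(logp)
  m <- pmax(n1, n2, n3)
  at_max <- n1 == m
  k_ties <- (n1 == m) + (n2 == m) + (n3 == m)
  if (tie_credit) {
    sum(prob[at_max] / k_ties[at_max])
  } else {
    sum(prob[at_max & k_ties == 1])
  }
}

# x * log(p) with the 0 * log(0) = 0 convention; x > 0 with p = 0 gives -Inf.
xlogp <- function(x, p) {
  out <- ifelse(x == 0, 0, x * log(p))
  out
}

#' Monte-Carlo plurality-vote accuracy
#'
#' Seeded simulation oracle for [plurality_accuracy_exact()]: draws `reps`
#' multinomial votes and scores plurality wins (with the same fractional
#' tie credit), returning the estimate and its binomial standard error.
#'
#' @inheritParams plurality_accuracy_exact
#' @param reps Number of replicates (>= 100).
#' @param seed Integer seed.
#' @return A list with `estimate` and `se`.
#' @export
plurality_accuracy_mc <- function(p, n, reps = 1e4, seed = 1L,
                                  tie_credit = TRUE) {
  stopifnot(length(p) == 3, n >= 1, reps >= 100)
  check_simplex(p)
  with_seed(seed, {
    draws <- rmultinom(reps, n, p)
    m <- apply(draws, 2, max)
    at_max <- draws[1, ] == m
    k <- colSums(draws == rep(m, each = 3))
    score <- if (tie_credit) {
      ifelse(at_max, 1 / k, 0)
    } else {
      as.numeric(at_max & k == 1)
    }
    est <- mean(score)
    list(estimate = est, se = sqrt(est * (1 - est) / reps))
  })
}

#' Signals needed to reach a target vote accuracy
#'
#' Smallest `n` with `plurality_accuracy_exact(p, n) >= target`, by linear
#' scan (the accuracy is not strictly monotone in `n` because of parity
#' effects, so no bisection). Requires the true-class probability `p[1]` to
#' be the unique maximum, otherwise the accuracy cannot approach 1.
#'
#' @inheritParams plurality_accuracy_exact
#' @param target_accuracy Target probability in `(0, 1)`.
#' @param n_max Search cap.
#' @return Integer count.
#' @export
signals_needed <- function(p, target_accuracy, tie_credit = TRUE,
                           n_max = 5000L) {
  stopifnot(length(p) == 3, target_accuracy > 0, target_accuracy < 1)
  check_simplex(p)
  if (max(p[-1]) >= p[1]) {
    stop_nanosig(
      "true-class probability must be the unique maximum for the accuracy to reach the target",
      "nanosig_domain_error"
    )
  }
  for (n in seq_len(n_max)) {
    if (plurality_accuracy_exact(p, n, tie_credit) >= target_accuracy) {
      return(n)
    }
  }
  stop_nanosig(sprintf("target accuracy not reached by n = %d", n_max),
    "nanosig_domain_error")
}

#' Mixture composition from predicted label counts
#'
#' Normalizes per-class predicted signal counts into composition ratios,
#' attaches Goodman simultaneous 95% multinomial confidence intervals, and
#' (for three classes) the ternary-plot coordinates of the ratio triple.
#' The raw count ratios are the canonical output — no confusion-matrix
#' unmixing is applied by default, since per-signal misclassification means
#' the ratios are qualitative, not quantitative, concentration estimates.
#'
#' @param labels Character vector of predicted labels, or a named integer
#'   vector of per-class counts.
#' @param classes Class order for ratios and ternary axes (default
#'   [nanosig_classes()] restricted to observed labels when `labels` is a
#'   label vector).
#' @param conf_level Simultaneous confidence level (default 0.95).
#' @return A `mixture_estimate`: tibble `composition` (class, count, ratio,
#'   conf_low, conf_high), `n_signals`, `ternary` coordinates (3 classes
#'   only), and the vote winner.
#' @export
estimate_mixture <- function(labels, classes = NULL, conf_level = 0.95) {
  if (is.numeric(labels) && !is.null(names(labels))) {
    counts <- labels
    classes <- classes %||% names(counts)
  } else {
    if (!length(labels)) {
      stop_nanosig("mixture estimation needs at least one label",
        "nanosig_domain_error")
    }
    classes <- classes %||%
      (if (all(labels %in% NANOSIG_CLASSES)) NANOSIG_CLASSES else
        sort(unique(labels)))
    counts <- table(factor(labels, levels = classes))
  }
  counts <- as.integer(counts[classes])
  counts[is.na(counts)] <- 0L
  n <- sum(counts)
  if (n < 1) {
    stop_nanosig("mixture estimation needs at least one counted signal",
      "nanosig_domain_error")
  }
  ratios <- counts / n
  ci <- goodman_ci(counts, conf_level)
  comp <- tibble(
    class = classes, count = counts, ratio = ratios,
    conf_low = ci$lower, conf_high = ci$upper
  )
  structure(
    list(
      composition = comp, n_signals = n,
      ternary = if (length(classes) == 3) ternary_coordinates(ratios) else NULL,
      winner = classes[which.max(counts)]
    ),
    class = "mixture_estimate"
  )
}

# Goodman (1965) simultaneous multinomial confidence intervals.
goodman_ci <- function(counts, conf_level = 0.95) {
  k <- length(counts)
  n <- sum(counts)
  a <- qchisq(1 - (1 - conf_level) / k, df = 1)
  half <- sqrt(a * (a + 4 * counts * (n - counts) / n))
  list(
    lower = pmax(0, (a + 2 * counts - half) / (2 * (n + a))),
    upper = pmin(1, (a + 2 * counts + half) / (2 * (n + a)))
  )
}

#' @export
print.mixture_estimate <- function(x, digits = 3, ...) {
  cat(sprintf("<mixture_estimate> n = %d, plurality: %s\n",
    x$n_signals, x$winner))
  print(mutate(x$composition, across(dplyr::where(is.double),
    ~ round(.x, digits))))
  invisible(x)
}

#' @rdname estimate_mixture
#' @param x A `mixture_estimate`.
#' @param ... Unused.
#' @method tidy mixture_estimate
#' @export
tidy.mixture_estimate <- function(x, ...) x$composition

#' @rdname estimate_mixture
#' @method glance mixture_estimate
#' @export
glance.mixture_estimate <- function(x, ...) {
  tibble(n_signals = x$n_signals, winner = x$winner,
    max_ratio = max(x$composition$ratio))
}

#' Barycentric-to-Cartesian ternary coordinates
#'
#' Maps a composition triple `(r1, r2, r3)` on the simplex onto an
#' equilateral triangle with unit side: vertex 1 at the origin, vertex 2 at
#' `(1, 0)`, vertex 3 at `(1/2, sqrt(3)/2)`. The mapping is affine, so
#' mixtures of compositions map to the same mixtures of points.
#'
#' @param ratios Simplex triple.
#' @return A tibble with columns `x`, `y`.
#' @export
ternary_coordinates <- function(ratios) {
  stopifnot(length(ratios) == 3)
  check_simplex(ratios)
  tibble(
    x = ratios[2] + ratios[3] / 2,
    y = ratios[3] * sqrt(3) / 2
  )
}
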