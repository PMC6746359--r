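#' Nearest-neighbour propensity-score matching
#'
#' Greedy nearest-neighbour matching on the estimated propensity score to
#' construct a comparable control group before outcome modelling. Treated
#' units are processed in descending propensity order (hardest-to-match
#' first); each is matched to the `ratio` available controls closest in
#' absolute propensity difference. Ties are broken by the lowest control
#' index. With `replacement = FALSE` a control is used at most once; if
#' controls run out, the remaining treated units are left unmatched with a
#' warning rather than an error.
#'
#' @param ps propensity scores for all units.
#' @param d 0/1 treatment indicator.
#' @param ratio controls matched per treated unit (default 1).
#' @param replacement may a control be reused?
#' @param caliper optional maximum admissible propensity distance; candidate
#'   matches beyond it are discarded.
#' @return An object of class `match_result`: `matched_pairs` (data frame with
#'   columns `treated`, `control`), `unmatched_treated`, `retained` (sorted
#'   union of matched indices) and `mean_abs_ps_gap`.
#' @export
nearest_neighbor_match <- function(ps, d, ratio = 1L, replacement = FALSE,
                                   caliper = NULL) {
  if (length(ps) != length(d)) .stopf("ps and d must have equal length")
  if (!all(d %in% c(0, 1))) .stopf("d must be a 0/1 vector")
  treated <- which(d == 1)
  controls <- which(d == 0)
  if (length(treated) == 0 || length(controls) == 0) {
    .stopf("both treatment arms must be non-empty")
  }
  if (ratio < 1) .stopf("ratio must be >= 1")
  treated <- treated[order(ps[treated], decreasing = TRUE)]
  available <- rep(TRUE, length(controls))
  cps <- ps[controls]
  pair_t <- integer(0); pair_c <- integer(0)
  unmatched <- integer(0)
  for (ti in treated) {
    got <- 0L
    for (r in seq_len(ratio)) {
      if (!replacement && !any(available)) break
      dist <- abs(cps - ps[ti])
      if (!replacement) dist[!available] <- Inf
      j <- which.min(dist)  # first minimum = lowest control index on ties
      if (!is.null(caliper) && dist[j] > caliper) break
      pair_t <- c(pair_t, ti)
      pair_c <- c(pair_c, controls[j])
      if (!replacement) available[j] <- FALSE
      got <- got + 1L
    }
    if (got == 0L) unmatched <- c(unmatched, ti)
  }
  if (length(unmatched) > 0) {
    warning(sprintf("%d treated unit(s) left unmatched", length(unmatched)),
            call. = FALSE)
  }
  pairs <- data.frame(treated = pair_t, control = pair_c)
  structure(list(matched_pairs = pairs,
                 unmatched_treated = unmatched,
                 retained = sort(unique(c(pair_t, pair_c))),
                 mean_abs_ps_gap = if (nrow(pairs) > 0)
                   mean(abs(ps[pair_t] - ps[pair_c])) else NA_real_),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("Nearest-neighbour match: %d pairs, %d unmatched treated, mean |PS gap| %.4f\n",
              nrow(x$matched_pairs), length(x$unmatched_treated), x$mean_abs_ps_gap))
  invisible(x)
}

#' Standardized mean difference of a variable between arms
#'
#' Balance diagnostic: difference in arm means divided by the pooled standard
#' deviation.
#'
#' @param x numeric variable (e.g. the propensity score).
#' @param d 0/1 treatment indicator.
#' @return Scalar standardized mean difference.
#' @export
standardized_mean_difference <- function(x, d) {
  m1 <- mean(x[d == 1]); m0 <- mean(x[d == 0])
  s <- sqrt((stats::var(x[d == 1]) + stats::var(x[d == 0])) / 2)
  (m1 - m0) / s
}
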